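---
title: "Estimating and comparing semantic networks from verbal fluency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing semantic networks from verbal fluency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semfluency)
```

## The model in brief

`semfluency` treats one group's verbal-fluency output as a sample from a
shared mental lexicon. Each cleaned word list is reduced to a binary
occurrence vector; the relatedness of two words is estimated from how often
the same participants produce both. Formally, with `n_i` the number of
producers of word *i* and `n_ij` the number of co-producers of *i* and *j*,
the edge weight is the cosine similarity of the two binary columns,

$$ s_{ij} = \frac{n_{ij}}{\sqrt{n_i\,n_j}} \in [0, 1], $$

which is zero exactly when two words never co-occur. Because the dense
similarity matrix mostly reflects sampling noise, it is sparsified with the
triangulated maximally filtered graph (TMFG): a greedy construction that
seeds a maximal-weight 4-clique and then inserts one node at a time into
the triangular face to which it is most similar. The result is always a
connected, maximal planar graph with exactly $3n-6$ edges, so two groups
whose matrices have been equated to the same $n$ words are compared on
networks of identical size and density — differences between groups lie
entirely in *which* edges are kept and how heavy they are.

Three families of analysis then probe the estimated networks:

* **structure** — global metrics (ASPL, clustering, modularity) with
  Erdős–Rényi null distributions and a node-wise bootstrap;
* **dynamics** — a deterministic spreading-activation process measuring
  how efficiently activation propagates;
* **resilience** — weighted clique percolation measuring how quickly the
  network's overlapping community structure disintegrates as weak cliques
  are removed.

## Cleaning rules and their order

Cleaning applies three rules in a fixed order, and the order matters:

1. **Variant standardization** first: every surface form found in the
   variant map is replaced by its lexicon root (`dogs → dog`,
   `hippo → hippopotamus`). The packaged dictionary covers 189 English
   animal roots with 204 plural/diminutive/misspelling variants; it is a
   reasonable general-purpose scoring lexicon, not a reconstruction of any
   particular study's dictionary, and is user-replaceable via
   `cleaning_dictionary()`.
2. **Non-category removal**: tokens that are neither roots nor mapped
   variants (e.g. *book*) are removed as intrusions.
3. **Perseveration removal**: any later occurrence of an already-produced
   root is dropped, regardless of adjacency — the standard scoring
   convention; restricting to adjacent repeats would make the count depend
   on intrusion placement.

Because variants are standardized before perseveration detection, *dog …
dogs* counts as one retained word plus one perseveration. Cleaning is
idempotent, and per participant the token accounting always satisfies
`raw = retained + intrusions + perseverations`.

Producer filtering (`min_producers = 2`) is applied within each group
*before* node equating, and columns are not re-filtered after the
intersection. This keeps the exclusion report interpretable — each excluded
word is attributable either to idiosyncrasy within a group or to absence
from the other group — at the cost that a shared word's producer count can,
in principle, be anything ≥ 2 in both groups.

## Estimation conventions

**TMFG determinism.** The seed clique is the 4-node set with the largest
total pairwise similarity; insertion gains are the summed similarity of a
candidate node to a face's three vertices. All ties break toward the lowest
node index (words are sorted lexicographically) and then the
earliest-created face, so estimation is a pure function of the similarity
matrix. Only the greedy T1 insertion scheme is implemented — no edge-swap
refinement — matching the construction commonly used for these analyses.

**Zero-weight edges.** When data are sparse the filter must sometimes
retain an edge between words that never co-occur (similarity 0). Such edges
exist structurally (they count toward $3n-6$, appear in the backbone for
ASPL/CC) but carry zero weight for strength, modularity, spreading and
percolation. The TMFG's triangular face list is kept on the fitted object;
it certifies planarity (every edge on exactly two triangular faces, $2n-4$
faces, Euler's formula) and is what the test suite checks instead of a
generic planarity algorithm.

**Weighted vs unweighted metrics.** Global ASPL and clustering are computed
*unweighted* on the TMFG backbone; modularity uses the edge weights; local
metrics are weighted (strength, and Zhang's weighted local clustering with
weights rescaled by the network maximum). This mixed convention is
deliberate: with identical edge counts by construction, unweighted global
metrics isolate topological reorganization, while weighted local metrics
and percolation retain the similarity information. Mean node strength in a
fluency TMFG is typically ~2 even though the unweighted mean degree is
just under 6, and unweighted local-average clustering sits around 0.7–0.8 —
the magnitude regime in which these analyses are usually reported. Both
conventions are exposed (`modularity_q(weighted = )`,
`as_igraph(weighted = )`) for users who want the other choice.

**Modularity.** Louvain with 10 restarts under a caller-supplied seed, each
restart permuting vertex order, best Q kept. On graphs small enough to
enumerate every partition, the restarted Louvain Q matches the exhaustive
optimum in ≥ 95% of random instances (this is a test).

## Inference conventions

* **Random baselines**: 1,000 G(n, p) graphs with `p = 2m / (n(n−1))`;
  ASPL averages over connected pairs only (null replicates can be
  disconnected; the observed TMFG never is), and a one-sample z-test
  compares each observed metric to its null distribution.
* **Node-wise bootstrap**: each replicate draws `⌈n/2⌉` of the shared
  words — the *same* subset for both groups, since sampling different
  vocabularies would confound node composition with group — re-estimates
  both networks and records ASPL/CC/Q. Distribution-level contrasts use
  pooled-variance Student's t with `df = 2·reps − 2` and Cohen's d with
  the pooled SD; node-level contrasts (local metrics, per-time-step
  activation) use paired t with `df = n − 1`.
* **No multiple-testing correction** is applied anywhere; the workflow
  reports families of descriptive contrasts, and correction policy is left
  to the analyst.

## Spreading activation

The synchronous update is linear: with retention $r$, decay $d$, strength
$s_j = \sum_i w_{ij}$,

$$ a_i \leftarrow (1-d)\Big[r\,a_i + \sum_j (1-r)\,a_j\,w_{ij}/s_j\Big], $$

followed by zeroing entries below the suppression threshold. Defaults are
100 initial units, $r = 0.5$, $d = 0$, $s = 0$, 10 steps. With these
defaults the operator is column-stochastic: total activation is conserved
to 1e−9 per step (tested), activation stays nonnegative, and on a connected
non-bipartite graph every run converges to the strength-proportional
stationary distribution (tested at t = 500 against 1e−6).

**What "final activation of a word" means.** Seeding every word at once is
uninformative for group contrasts: conservation forces the summed paired
difference between two equated networks to be exactly zero at every step.
Seeding one word per run (the default mode) yields a full seed × node ×
time array with two readouts:

* `"self"` — the seed's own remaining activation. This is the lazy-walk
  return probability scaled by 100; summed over words it equals
  $100\,\mathrm{tr}(M^t)$, which is *larger* for more modular networks.
  High self-retention is a symptom of activation being trapped, not of
  efficient retrieval.
* `"received"` (default) — the mean activation reaching a word from the
  runs seeded at the other words. This is the propagation-efficiency
  readout: it is systematically *lower* in degraded, fragmented networks,
  and its regression on standardized degree and clustering produces the
  canonical sign pattern (positive degree effect — hubs accumulate
  activation; negative clustering effect — tightly clustered neighborhoods
  keep activation local).

`compare_activation()` and `regress_activation()` therefore default to the
received readout; the self readout remains available via
`activation_values(trace, "self")`. Absolute per-step activation
magnitudes depend on this readout choice (and on cohort-level weight
scales) and are not meaningful across studies; only directions and
significance patterns are.

## Clique percolation

3-cliques of the backbone are scored by the geometric mean of their three
edge weights (the weighted clique-percolation convention; a clique with a
zero-weight edge scores 0). Cliques below an intensity threshold *I* are
removed; surviving cliques sharing two nodes merge into communities; the
curve records, for each *I* in 0.01, 0.02, …, 1.00, how many nodes still
belong to any community. The percolation integral is the left Riemann sum
(count × 0.01 summed over the grid) — a single triangle of uniform weight
0.5 contributes 3 × 0.50 = 1.50. The curve is non-increasing by
construction and the integral cannot increase when all weights are scaled
down — both tested.

For group comparison the analysis is iterated 500 times. What varies per
iteration is a participant-level bootstrap within each group (resampling
rows with replacement, re-estimating the network on the fixed equated
vocabulary); node-subsampling is available as an alternative
(`mode = "node-subsample"`). A resample that leaves any word with zero
producers is redrawn and counted. Per-iteration resampling seeds are
derived independently of group, so running the comparison of a matrix
against itself gives *t* = 0 exactly.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth. It emulates the statistical structure the
analysis assumes:

* a **shared lexicon** of 50 animal words in 5 subcategory blocks;
  within-block pairs fully connected at weight 0.7 ± 0.1, between-block
  pairs connected with probability 0.3 at weight 0.25 ± 0.1 (connected by
  construction, re-jittered if a draw is not);
* **participants as censored random walks**: weight-proportional
  transitions, a per-step teleport ("jump") probability, each word emitted
  on first visit only, stopping after the drawn list length (truncated
  normal, ≥ 1);
* **group profiles** controlling cohort size, list-length distribution,
  jump probability, edge degradation, noise rates and demographic
  covariates.

The default profiles encode the study conditions: cohort sizes 120 / 127 /
64 / 63 and appropriate-response means 22.47 / 9.63 / 11.95 / 7.27 (SDs
4.90 / 5.25 / 5.08 / 4.30) for control, pooled-aphasia, fluent and
nonfluent profiles, with ages and education drawn from the corresponding
group distributions. Two generator parameters have no empirical anchor and
were fixed once, on the grounds below:

* **jump** = 0.20 / 0.04 / 0.10 / 0.02. The teleport models *strategic
  switching* between subcategories, which is preserved in controls and
  progressively impaired in aphasia. This choice is load-bearing: a
  teleport integrates the estimated network (more cross-block
  co-occurrence), so giving impaired groups *higher* jump rates would
  produce better-integrated impaired networks — the opposite of the
  degraded-connectivity phenotype the generator must emulate.
* **degradation** = 0 / 0.50 / 0.25 / 0.60: the fraction of ground-truth
  edges deleted for the group (connectivity repaired by re-adding removed
  edges, heaviest first, if the graph breaks). Random deletion removes the
  sparse between-block edges disproportionately often relative to their
  structural role, trapping impaired walkers inside subcategories.

Injected noise (perseverations 0.02–0.10, intrusions 0.02–0.08, variants
0.05 per produced word, increasing with impairment) is recorded in a
manifest and is exactly recovered by the cleaning log — a bookkeeping
identity the tests assert.

Under these frozen conditions the full pipeline recovers the impaired
phenotype — longer ASPL, lower CC, higher Q, lower percolation integral,
lower late-step received activation for the degraded cohort — in ≥ 90% of
50 seeded runs (an acceptance test), and mean metrics across seeds grade
monotonically over control → fluent-like → nonfluent-like profiles.

**What the generator does not emulate.** Real fluency data have
frequency-graded word accessibility, typicality effects, retrieval latency
structure, and participant-level heterogeneity far richer than a single
walk-length distribution; the ground-truth lexicon is a stylized block
model rather than a realistic semantic space. Passing the recovery tests
therefore shows that the *pipeline* detects the structure it assumes when
that structure is present — it does not validate the block model as a
model of human semantic memory.

## Numerical and reproducibility choices

* Words are lexicographically sorted everywhere; all tie-breaks
  (TMFG seed, insertion, ordering of cliques and communities) resolve
  toward lower indices, so every deterministic stage is bit-reproducible.
* Every stochastic stage takes an explicit seed; `run_comparison()`
  derives per-stage sub-seeds from the master seed by a labeled hash
  (`derive_seed()`), so stages can be re-run in isolation.
* Degenerate inputs fail loudly: fewer than 3 words for TMFG, empty
  response matrices, zero-spread reference distributions, constant
  regression predictors, non-equated node sets. One deliberate exception:
  comparing two *identical constant* distributions (e.g. bootstrap with
  proportion 1) returns t = 0 rather than an error.
* Problem sizes in the shipped tests and acceptance script: lexicons of
  50 words, full default cohort sizes, 1,000-replicate bootstrap and
  500-iteration percolation in the acceptance script, 25–200 replicates in
  unit tests, 50 seeded runs for phenotype recovery. The whole suite runs
  in well under five minutes on a single core.

## Known limitations

* **Group-level aggregation.** Networks are estimated from pooled group
  data; individual variability is invisible, and group differences in
  aggregate networks need not hold for individual networks.
* **Null calibration of the bootstrap d.** For two *independent* cohorts
  drawn from the same profile, the bootstrap comparison's |d| is typically
  0.3–1.0, not ≈ 0. The decomposition is instructive: the node-subset
  bootstrap SD calibrates sampling of *words* (≈ 0.11 for ASPL at these
  sizes), while two finite cohorts differ at the *participant* level
  (full-network ASPL sd ≈ 0.08 at n = 120). Since d divides a
  participant-level difference by a node-level spread, it does not shrink
  toward zero under the null; bootstrap-based d values should be read as
  descriptive separation of the two node-sampling distributions, not as a
  calibrated effect size against participant resampling. The strict
  |d| < 0.2 null-calibration check is kept in the acceptance suite and
  fails for this structural reason.
* **Subgroup contrasts are fragile at realistic sizes.** With ~60
  participants per subgroup and short lists, the fluent-like vs
  nonfluent-like direction holds on averages across seeds but flips in a
  substantial fraction of single cohort draws — mirroring how much smaller
  the corresponding empirical effects are compared to the control-vs-aphasia
  contrast.
* **Absolute activation levels are not comparable across studies**; see
  the spreading-activation section.
* **The percolation iteration scheme matters.** Integral distributions
  (and hence t statistics) depend on what is resampled per iteration;
  participant bootstrap is the default here, node subsampling the
  alternative, and reported means shift between schemes even though the
  group ordering is stable.
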