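# semfluency

Semantic-network analysis of verbal fluency data in R.

## What this package is for

In a semantic (category) fluency task, participants name as many members of
a category — classically *animals* — as they can in one minute. Clinically
the task is usually scored by counting appropriate responses, but the count
discards the most interesting part of the data: which words co-occur across
people, and what that co-occurrence implies about the organization of the
mental lexicon. This matters particularly in post-stroke aphasia, where
lexical retrieval failures may reflect degraded semantic structure, impaired
access to intact structure, or both.

`semfluency` implements the group-level semantic-network workflow for such
data, end to end:

1. **Cleaning** — raw token lists are standardized against a category
   lexicon and variant map (`dogs → dog`), non-category intrusions and
   perseverations are removed, and everything is logged
   (`clean_fluency()`).
2. **Response matrix** — cleaned lists become a binary participants × words
   matrix; words produced by fewer than two participants are dropped and
   the two groups' matrices are restricted to their shared vocabulary
   (`response_matrix()`, `filter_min_producers()`, `equate_nodes()`).
3. **Network estimation** — edge weights are cosine similarities between
   word occurrence columns,
   `sim(i, j) = n_ij / sqrt(n_i * n_j)`
   (co-producer count over the geometric mean of producer counts), and the
   dense similarity matrix is sparsified with the **triangulated maximally
   filtered graph** (TMFG), a greedy planar filter that retains exactly
   `3n − 6` edges (`semantic_network()`).
4. **Graph metrics and inference** — average shortest path length, global
   clustering and Louvain modularity on the backbone; node strength and
   Zhang's weighted local clustering; z-tests against 1,000 Erdős–Rényi
   graphs of matched density; node-wise bootstrap (re-estimating networks
   from random half-subsets of the shared words) with pooled t-tests and
   Cohen's d (`global_metrics()`, `local_metrics()`, `er_baseline()`,
   `bootstrap_networks()`).
5. **Spreading activation** — a deterministic diffusion in which each word
   keeps a retention share `r` of its activation per step and passes the
   rest to neighbors in proportion to edge weight,
   `a_i ← r·a_i + Σ_j (1 − r)·a_j·w_ij / s_j`,
   with optional decay and suppression; group networks are compared by
   paired t-tests per time step, and final activation is regressed on
   standardized degree and clustering (`simulate_spreading()`,
   `compare_activation()`, `regress_activation()`).
6. **Clique percolation resilience** — weighted 3-clique percolation across
   an intensity grid (clique intensity = geometric mean of its edge
   weights, thresholds 0.01–1.00 in steps of 0.01); the **percolation
   integral** (area under the connected-node curve) summarizes how quickly
   the network fragments, and an iterated participant-bootstrap compares
   the two groups' integrals (`percolation_curve()`,
   `percolation_integral()`, `percolation_comparison()`).
7. **Synthetic cohorts** — a generator with full ground truth (censored
   weighted random walks over a block-structured lexicon, plus injected
   perseverations, intrusions and spelling variants) so that the entire
   pipeline can be exercised and validated without any external data
   (`simulate_cohort()`, `default_profiles()`).

`run_comparison()` chains all of this for one two-group contrast from a
single configuration object (or YAML file) and returns a comprehensive
report; `write_report()` serializes it as JSON/CSV/GraphML.

## Worked example

```r
library(semfluency)

cfg <- run_config(profiles = default_profiles()[c("control", "aphasia")],
                  seed = 42, er_reps = 200, bootstrap_reps = 200,
                  percolation_iterations = 100)
report <- run_comparison(cfg)
report
```

```
=== Semantic-network comparison: control vs aphasia ===
Appropriate-response count comparison (OLS)
  group means: control = 22.23, aphasia = 9.87
  groupaphasia: beta = -12.49, t(243) = -19.24, p = 9.68e-51
Shared nodes after equating: 50 (excluded: 0 from control, 0 from aphasia)
Full-network metrics  control: ASPL 2.651 CC 0.736 Q 0.539 | aphasia: ASPL 3.497 CC 0.695 Q 0.625
Node-wise bootstrap comparison (200 replicates, proportion 0.50)
  aspl  A: 2.117 (0.126)  B: 2.338 (0.136)  t(398) = -16.83, p = 2.09e-48, d = -1.68
  cc    A: 0.734 (0.012)  B: 0.714 (0.011)  t(398) = 17.41, p = 7.01e-51, d = 1.74
  q     A: 0.396 (0.037)  B: 0.463 (0.028)  t(398) = -20.27, p = 2.75e-63, d = -2.03
Local paired tests: strength t(49) = 2.34 (p = 0.0232); local CC t(49) = 2.51 (p = 0.0155)
Activation (received), late steps: mean t = 0.10, all p < 0.948
Percolation comparison (100 iterations, participant-bootstrap)
  integral A: 30.17 (0.47)  B: 25.29 (0.73)  t(198) = 56.28, p = 9e-124
```

Reading the output: the impaired synthetic cohort produces fewer
appropriate responses (9.9 vs 22.2; the OLS coefficient is adjusted for age
and education), and its estimated lexical network is less integrated —
longer average shortest paths (bootstrap means 2.34 vs 2.12), lower
clustering (0.714 vs 0.734), higher modularity (0.463 vs 0.396) — and less
resilient: its percolation integral (25.3 vs 30.2 node·threshold units) is
smaller, i.e. its clique structure disintegrates at lower intensity
thresholds.

## Learn more

The methods vignette (`vignettes/semantic-fluency-networks.Rmd`) documents
the model conventions (what is computed weighted vs unweighted, and why),
all tunable parameters with their defaults, the numerical tie-breaking
rules that make the pipeline deterministic, what the synthetic generator
does and does not emulate, and known limitations.
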