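test_that("delimited transcripts are parsed with order preserved and case folded", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,group,responses",
               "p1,HC,Dog cat dog",
               "p2,PWA,cat"), f)
  d <- read_fluency(f)
  expect_s3_class(d, "fluency_data")
  expect_equal(d$participant, c("p1", "p2"))
  expect_equal(d$responses[[1]], c("dog", "cat", "dog"))
  expect_equal(d$responses[[2]], "cat")

  # long format
  fl <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,group,token",
               "p1,HC,dog", "p1,HC,cat", "p2,HC,emu"), fl)
  dl <- read_fluency(fl, long = TRUE)
  expect_equal(dl$responses[[1]], c("dog", "cat"))

  # configuration errors
  writeLines(c("id,grp,resp", "p1,HC,dog"), f)
  expect_error(read_fluency(f), "missing columns")
  writeLines("participant,group,responses", f)
  expect_error(read_fluency(f), "empty dataset")
})

test_that("written cohorts round-trip through the reader", {
  pf <- list(g1 = group_profile("g1", n = 6, list_mean = 8, list_sd = 2),
             g2 = group_profile("g2", n = 5, list_mean = 6, list_sd = 2))
  co <- simulate_cohort(pf, seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fluency(co$data, f)
  back <- read_fluency(f, response_sep = ";")
  expect_equal(back$participant, co$data$participant)
  expect_equal(back$group, co$data$group)
  expect_equal(back$responses, co$data$responses)
})

test_that("cleaning standardizes variants, removes intrusions and perseverations", {
  d <- fluency_data("p1", "HC", list(c("dogs", "book", "dog")))
  cl <- clean_fluency(d)
  expect_equal(cl$data$responses[[1]], "dog")
  expect_equal(cl$log$counts$variants, 1)
  expect_equal(cl$log$counts$intrusions, 1)
  expect_equal(cl$log$counts$perseverations, 1)
  expect_setequal(cl$log$removed$p1$reason, c("non-category", "perseveration"))

  # empty list stays empty with an empty log
  d0 <- fluency_data("p1", "HC", list(character(0)))
  cl0 <- clean_fluency(d0)
  expect_equal(cl0$data$responses[[1]], character(0))
  expect_equal(sum(unlist(cl0$log$counts[, c("variants", "intrusions",
                                             "perseverations")])), 0)
})

test_that("cleaning is idempotent and conserves tokens", {
  pf <- list(g = group_profile("g", n = 15, list_mean = 10, list_sd = 3,
                               perseveration = 0.2, intrusion = 0.15,
                               variant = 0.2))
  co <- simulate_cohort(pf, seed = 11)
  c1 <- clean_fluency(co$data)
  c2 <- clean_fluency(c1$data)
  expect_equal(c2$data$responses, c1$data$responses)
  expect_equal(sum(c2$log$counts$intrusions), 0)
  expect_equal(sum(c2$log$counts$perseverations), 0)
  # raw = retained + removed, participant-wise
  with(c1$log$counts,
       expect_equal(raw, retained + intrusions + perseverations))
})

test_that("response matrices binarize production and validate input", {
  d <- fluency_data(c("p1", "p2"), c("g", "g"),
                    list(c("dog", "cat"), "cat"))
  m <- response_matrix(d)
  expect_equal(colnames(m), c("cat", "dog"))
  expect_equal(unname(m["p1", c("dog", "cat")]), c(1L, 1L))
  expect_equal(unname(m["p2", c("dog", "cat")]), c(0L, 1L))
  # repeated production does not change the cell
  d2 <- fluency_data("p1", "g", list(c("dog", "dog", "dog")))
  expect_equal(unname(response_matrix(d2)[1, 1]), 1L)
  expect_equal(dim(response_matrix(d2)), c(1L, 1L))
  expect_error(fluency_data(c("p1", "p1"), c("g", "g"),
                            list("a", "b")), "duplicate participant")
})

test_that("producer filtering matches a brute-force column scan", {
  set.seed(3)
  for (rep in 1:5) {
    m <- make_rm(setNames(lapply(1:12, function(i) {
      sample(letters[1:10], sample(2:6, 1))
    }), paste0("p", 1:12)))
    for (mp in 1:3) {
      keep <- colnames(m)[vapply(colnames(m), function(w) sum(m[, w]) >= mp, TRUE)]
      if (length(keep) == 0) {
        expect_error(filter_min_producers(m, mp), "empty matrix")
      } else {
        expect_equal(colnames(filter_min_producers(m, mp)), keep)
      }
    }
    expect_identical(colnames(filter_min_producers(m, 1)), colnames(m))
  }
})

test_that("node equating intersects vocabularies symmetrically", {
  a <- make_rm(list(p1 = c("dog", "cat", "emu"), p2 = c("dog", "cat", "emu")))
  b <- make_rm(list(q1 = c("dog", "cat", "yak"), q2 = c("dog", "cat", "yak")))
  eq <- equate_nodes(a, b)
  expect_equal(colnames(eq$a), c("cat", "dog"))
  expect_equal(colnames(eq$b), c("cat", "dog"))
  expect_equal(eq$exclusions$a, "emu")
  expect_equal(eq$exclusions$b, "yak")
  # symmetric reporting
  eq2 <- equate_nodes(b, a)
  expect_equal(eq2$exclusions$shared_nodes, eq$exclusions$shared_nodes)
  expect_equal(eq2$exclusions$a, eq$exclusions$b)
  # identical word lists -> no exclusions
  eq3 <- equate_nodes(a, a)
  expect_equal(eq3$exclusions$n_a + eq3$exclusions$n_b, 0)
  # disjoint vocabularies
  c1 <- make_rm(list(p1 = "owl", p2 = "owl"))
  expect_error(equate_nodes(a, c1), "empty shared lexicon")
})

test_that("appropriate-response counts follow the cleaned lists", {
  d <- fluency_data(c("p1", "p2"), c("g", "g"),
                    list(c("dog", "cat"), character(0)))
  cts <- response_counts(d)
  expect_equal(cts$count, c(2L, 0L))
})

test_that("count comparison reduces to a mean difference with constant covariates", {
  y <- c(10, 12, 14, 5, 6, 7)
  g <- rep(c("a", "b"), each = 3)
  cmp <- compare_counts(y, g, covariates = data.frame(cov = rep(1, 6)))
  expect_equal(cmp$estimate, mean(y[4:6]) - mean(y[1:3]))
  expect_equal(cmp$dropped_constant_covariates, "cov")
  # matches a plain t-test-style OLS fit
  fit <- lm(y ~ factor(g))
  expect_equal(unname(cmp$t), unname(summary(fit)$coefficients[2, "t value"]),
               tolerance = 1e-10)
})

test_that("count regression recovers a planted group effect", {
  set.seed(99)
  n <- 400
  g <- rep(c("ctrl", "pat"), each = n / 2)
  age <- rnorm(n, 60, 10)
  edu <- rnorm(n, 16, 2)
  beta <- -8
  y <- 25 + beta * (g == "pat") + 0.1 * age - 0.2 * edu + rnorm(n, 0, 3)
  cmp <- compare_counts(y, g, covariates = data.frame(age = age, edu = edu),
                        reference = "ctrl")
  expect_lt(abs(cmp$estimate - beta), 3 * cmp$se)
  expect_lt(cmp$p, 0.001)
  # missing covariates are dropped listwise and logged
  age[1:5] <- NA
  cmp2 <- compare_counts(y, g, covariates = data.frame(age = age, edu = edu))
  expect_equal(cmp2$n_dropped_listwise, 5)
})
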