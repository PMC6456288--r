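test_that("relevance profile scores features against the class", {
  # one feature identical to the class
  d <- tibble::tibble(f1 = c(0, 0, 1, 1), class = factor(c("a", "a", "b", "b")))
  p <- relevance_profile(d, binning = "none")
  expect_equal(p$feature, "f1")
  expect_identical(p$relevance, 1)
  expect_identical(attr(p, "r_max"), 1)
  expect_identical(attr(p, "r_bar"), 1)

  # tau drops the class-independent feature
  d2 <- tibble::tibble(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1),
                       class = factor(c("a", "a", "b", "b")))
  p2 <- relevance_profile(d2, tau = 0.5, binning = "none")
  expect_equal(p2$feature, "f1")
  expect_equal(attr(p2, "dropped")$feature, "f2")
  expect_error(relevance_profile(d2, tau = 2, binning = "none"),
               "empty after irrelevance filter")
})

test_that("r_bar equals the oracle mean over per-feature relevances", {
  d <- synth_table(n_instances = 100, n_informative = 4, n_irrelevant = 6,
                   shift = 1, seed = 31)
  p <- relevance_profile(d)
  # recompute every R_i,c with the naive oracle path on the same binning
  oracle_r <- vapply(setdiff(names(d), "class"), function(f) {
    codes <- as.integer(discretize(d[[f]], n_bins = 10))
    naive_su(d$class, codes)
  }, numeric(1))
  expect_equal(attr(p, "r_bar"), mean(oracle_r), tolerance = 1e-10)
  expect_equal(sort(p$relevance), sort(unname(oracle_r)), tolerance = 1e-10)
})

test_that("single-feature tables select that feature with no pair evaluations", {
  d <- tibble::tibble(f1 = rnorm(20), class = factor(rep(c("a", "b"), 10)))
  fit <- fsbrr(d)
  expect_equal(fit$selected$feature, "f1")
  expect_identical(fit$pair_evaluations, 0L)
})

test_that("an exact duplicate always falls to redundancy rule 1", {
  withr::with_seed(5, {
    f1 <- rnorm(100, mean = rep(c(0, 2), each = 50))
  })
  d <- tibble::tibble(f1 = f1, f2 = f1,
                      class = factor(rep(c("a", "b"), each = 50)))
  fit <- fsbrr(d)
  expect_equal(fit$selected$feature, "f1")
  log <- fit$removal_log
  expect_equal(log$removed, "f2")
  expect_equal(log$rule, "redundancy_rule_1")
  expect_identical(log$r_pivot_removed, 1)
})

test_that("selection matches the naive algorithm transcription", {
  withr::with_seed(1203, {
    for (rep in 1:8) {
      d <- random_synth_table(seed = sample.int(1e6, 1))
      fit <- suppressWarnings(fsbrr(d))
      ref <- naive_fsbrr(d)
      expect_equal(fit$selected$feature, ref$selected)
      red <- fit$removal_log[fit$removal_log$rule != "irrelevant", ]
      expect_equal(red$pivot, ref$removal_log$pivot)
      expect_equal(red$removed, ref$removal_log$removed)
      expect_equal(red$rule, ref$removal_log$rule)
    }
  })
})

test_that("selection is deterministic and ordered by descending relevance", {
  d <- random_synth_table(seed = 88)
  f1 <- suppressWarnings(fsbrr(d))
  f2 <- suppressWarnings(fsbrr(d))
  expect_identical(f1, f2)
  expect_true(all(diff(f1$selected$relevance) <= 0))
  # partition: selected and removed are disjoint and cover the input
  removed <- f1$removal_log$removed
  expect_length(intersect(f1$selected$feature, removed), 0)
  expect_setequal(c(f1$selected$feature, removed), setdiff(names(d), "class"))
})

test_that("pair evaluations realize the best and worst complexity cases", {
  for (n in c(10L, 50L)) {
    # best case: every feature duplicates the first -> n - 1 evaluations
    base <- synth_table(n_instances = 60, n_informative = 1,
                        n_exact_duplicates = n - 1L, seed = n)
    fit <- fsbrr(base)
    expect_identical(fit$pair_evaluations, n - 1L)
    expect_equal(nrow(fit$selected), 1L)

    # worst case: independent features, thresholds such that nothing is
    # removed -> n (n - 1) / 2 evaluations
    ind <- synth_table(n_instances = 60, n_informative = 1,
                       n_irrelevant = n - 1L, shift = 0, seed = n + 1L)
    fit2 <- suppressWarnings(fsbrr(ind, delta = 0, alpha = 1e-12))
    expect_identical(fit2$pair_evaluations, as.integer(n * (n - 1L) / 2L))
    expect_equal(nrow(fit2$selected), n)
  }
})

test_that("a feature weakly correlated with every pivot is never removed", {
  # Construct discrete features: two moderately informative pivots and one
  # feature independent of everything. Its pairwise relevance with each
  # pivot must fall below both rule bars, so it survives regardless of its
  # own (low) class relevance.
  withr::with_seed(2024, {
    n <- 600
    cls <- rep(c(0L, 1L), each = n / 2)
    flip <- function(v, p) ifelse(runif(n) < p, 1L - v, v)
    d <- tibble::tibble(
      p1 = as.numeric(flip(cls, 0.10)),
      p2 = as.numeric(flip(cls, 0.15)),
      lone = as.numeric(rbinom(n, 1L, 0.5)),
      class = factor(cls)
    )
  })
  fit <- fsbrr(d, binning = "none")
  # verify the construction: for every pivot, R_ij is below both bars
  codes <- lapply(d[c("p1", "p2", "lone")], function(v) as.integer(v))
  ccode <- as.integer(d$class) - 1L
  r_c <- vapply(codes, symmetric_uncertainty, numeric(1), y = ccode)
  for (piv in c("p1", "p2")) {
    r_ij <- symmetric_uncertainty(codes[[piv]], codes$lone)
    expect_lt(r_ij, r_c[[piv]])                        # below rule-1 bar
    expect_lt(r_ij, (fit$r_bar + r_c[["lone"]]) / 2)   # below rule-2 bar
  }
  expect_true("lone" %in% fit$selected$feature)
})

test_that("duplicate groups never keep more than one member", {
  withr::with_seed(5150, {
    for (rep in 1:10) {
      d <- synth_table(n_instances = sample(50:150, 1),
                       n_informative = sample(1:4, 1),
                       n_exact_duplicates = sample(1:5, 1),
                       n_irrelevant = sample(0:5, 1),
                       seed = sample.int(1e6, 1))
      fit <- suppressWarnings(fsbrr(d))
      truth <- feature_truth(d)
      groups <- split(truth$feature,
                      ifelse(is.na(truth$parent), truth$feature, truth$parent))
      for (g in groups) {
        if (length(g) > 1L) {
          expect_lte(sum(fit$selected$feature %in% g), 1L)
        }
      }
    }
  })
})

test_that("out-of-range parameters warn but proceed", {
  d <- synth_table(n_instances = 60, n_informative = 2, seed = 3)
  expect_warning(fsbrr(d, delta = 0.3), "outside recommended range")
  expect_warning(fsbrr(d, alpha = 0.9), "outside recommended range")
  expect_warning(
    expect_warning(fsbrr(d, delta = 0.7, alpha = 0.64), "rule 2 can never fire"),
    "outside recommended range"
  )
})

test_that("constant features are retained at tau = 0 with a warning", {
  d <- tibble::tibble(f1 = c(0, 0, 1, 1), f2 = c(1, 1, 1, 1),
                      class = factor(c("a", "a", "b", "b")))
  expect_warning(fit <- fsbrr(d, binning = "none"), "constant feature")
  expect_true("f2" %in% fit$selected$feature)
})

test_that("tidy and glance summarise a selection consistently", {
  d <- synth_table(n_instances = 100, n_informative = 3,
                   n_exact_duplicates = 2, n_irrelevant = 3, seed = 11)
  fit <- fsbrr(d)
  td <- tidy(fit)
  expect_setequal(td$feature, setdiff(names(d), "class"))
  expect_equal(sum(td$fate == "selected"), nrow(fit$selected))
  gl <- glance(fit)
  expect_equal(gl$n_features, 8L)
  expect_equal(gl$n_selected + gl$n_irrelevant + gl$n_redundant, 8L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("a sweep reproduces pointwise selections", {
  d <- synth_table(n_instances = 100, n_informative = 3,
                   n_exact_duplicates = 2, n_irrelevant = 3, seed = 19)
  grid <- suppressWarnings(fsbrr_sweep(d, delta = c(0, 0.1, 0.2)))
  expect_equal(nrow(grid), 3L)
  for (i in seq_len(nrow(grid))) {
    fit <- suppressWarnings(fsbrr(d, delta = grid$delta[i],
                                  alpha = grid$alpha[i]))
    expect_equal(grid$n_selected[i], nrow(fit$selected))
  }
  # all-duplicates table collapses to one feature for any delta >= 0
  dup <- synth_table(n_instances = 60, n_informative = 1,
                     n_exact_duplicates = 5, seed = 2)
  g2 <- suppressWarnings(fsbrr_sweep(dup, delta = c(0, 0.1, 0.2)))
  expect_true(all(g2$n_selected == 1L))
  expect_error(fsbrr_sweep(d, delta = c(0.05, 0.1), alpha = c(0.6, 0.66)),
               "one parameter at a time")
  expect_s3_class(autoplot(g2), "ggplot")
})
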