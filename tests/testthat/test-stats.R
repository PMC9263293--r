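test_that("permutation test matches the exhaustive enumeration oracle", {
  # {1,2,3} vs {101,102,103}: of the C(6,3) = 20 splits only the two extreme
  # ones reach |mean diff| = 100, so the smallest achievable two-sided p is
  # 2/20 = 0.1 (frozen from full enumeration)
  res <- permutation_test(c(1, 2, 3), c(101, 102, 103), exact = TRUE)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$observed, -100)
  expect_equal(res$n_permutations, 20)
  # sampled version is deterministic given seed and respects p >= 1/(B+1)
  r1 <- permutation_test(c(1, 2, 3), c(101, 102, 103), 999, seed = 5)
  r2 <- permutation_test(c(1, 2, 3), c(101, 102, 103), 999, seed = 5)
  expect_identical(r1$p_value, r2$p_value)
  expect_gte(r1$p_value, 1 / 1000)
  expect_lte(r1$p_value, 1)
  # degenerate pooled sample
  expect_warning(rz <- permutation_test(rep(2, 5), rep(2, 4)), "zero variance")
  expect_equal(rz$p_value, 1)
  expect_error(permutation_test(numeric(0), 1:3), "non-empty")
})

test_that("permutation p-values are valid under exchangeability", {
  set.seed(31)
  B <- 400
  pvals <- vapply(seq_len(B), function(i) {
    a <- rnorm(8); b <- rnorm(8)
    permutation_test(a, b, n_permutations = 199, seed = i)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= alpha), alpha + 1 / 200 + 2.6 * sqrt(alpha / B))
})

test_that("two_sample_t matches the textbook formula and stats::t.test", {
  for (seed in 1:100) {
    set.seed(seed)
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), mean = 0.3)
    res <- two_sample_t(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    # independent recomputation from the raw formula
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    expect_equal(res$t, tref, tolerance = 1e-12)
  }
  ident <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_sample_t(c(0, 0), c(1, 1)), "zero pooled variance")
})

test_that("chi_square_2x2 matches the O-E formula and chisq.test", {
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$chi2, 0)
  for (seed in 1:50) {
    set.seed(seed)
    tab <- matrix(rpois(4, 20) + 1, 2)
    res <- chi_square_2x2(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - e)^2 / e), tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(0, 2, 2)), "marginal")
  expect_error(chi_square_2x2(matrix(1, 3, 2)), "2 x 2")
})

test_that("pearson_correlation matches cor.test and handles exact fits", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x)) + 0.4 * x
    res <- pearson_correlation(x, y)
    ref <- cor.test(x, y)
    expect_equal(res$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "n >= 3")
})

test_that("statistics are invariant to subject order within groups", {
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10)
  r1 <- permutation_test(a, b, 499, seed = 2)
  r2 <- permutation_test(sample(a), sample(b), 499, seed = 2)
  expect_equal(r1$observed, r2$observed)
  # exact enumeration is fully order-invariant (sampled p is so only in
  # distribution, since permutation indices land on reordered elements)
  a5 <- rnorm(5); b5 <- rnorm(5)
  e1 <- permutation_test(a5, b5, exact = TRUE)
  e2 <- permutation_test(sample(a5), sample(b5), exact = TRUE)
  expect_equal(e1$p_value, e2$p_value)
  expect_equal(two_sample_t(a, b)$t, two_sample_t(rev(a), sample(b))$t)
})

make_metric_fixture <- function(n_per_group, seed, effect = 0) {
  # tiny synthetic metric table: 2 bands x 3 sparsities, optional alpha shift
  set.seed(seed)
  grid <- c(0.12, 0.2, 0.3)
  ids <- c(sprintf("TC%02d", 1:n_per_group), sprintf("CT%02d", 1:n_per_group))
  grp <- rep(c("TC", "control"), each = n_per_group)
  rows <- list()
  for (s in seq_along(ids)) {
    for (bn in c("alpha", "beta")) {
      base <- rnorm(1, 0.5, 0.05) + (bn == "alpha") * (grp[s] == "TC") * effect
      for (sp in grid) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = ids[s], band = bn, sparsity = sp,
          L = 2 - base + rnorm(1, 0, 0.01), C = base + rnorm(1, 0, 0.01),
          Eglobal = base / 2 + rnorm(1, 0, 0.01),
          Elocal = base + rnorm(1, 0, 0.01), stringsAsFactors = FALSE)
      }
    }
  }
  list(metrics = do.call(rbind, rows),
       cohort = data.frame(subject_id = ids, group = grp,
                           rt_ms = rnorm(length(ids), 400, 30),
                           stringsAsFactors = FALSE))
}

test_that("group_contrast_sweep output structure and copied-group zeros", {
  fx <- make_metric_fixture(6, seed = 3)
  res <- group_contrast_sweep(fx$metrics, fx$cohort, n_permutations = 199,
                              seed = 4)
  expect_equal(sort(unique(res$range_level$band)), c("alpha", "beta"))
  expect_equal(nrow(res$range_level), 8)           # 2 bands x 4 metrics
  expect_equal(nrow(res$threshold_level), 2 * 3 * 4)
  expect_true(all(res$threshold_level$p_bh >= res$threshold_level$p - 1e-12))
  # identical groups (control copied onto TC): all observed stats exactly 0
  fx2 <- fx
  n <- nrow(fx2$metrics)
  tc_rows <- grepl("^TC", fx2$metrics$subject_id)
  ct <- fx2$metrics[!tc_rows, ]
  ct2 <- ct
  ct2$subject_id <- sub("^CT", "TC", ct2$subject_id)
  fx2$metrics <- rbind(ct2, ct)
  res2 <- group_contrast_sweep(fx2$metrics, fx2$cohort, n_permutations = 199,
                               seed = 4)
  expect_true(all(res2$range_level$observed == 0))
  expect_true(all(res2$threshold_level$observed == 0))
  # planted alpha effect is detected, beta is not
  fx3 <- make_metric_fixture(10, seed = 5, effect = 0.4)
  res3 <- group_contrast_sweep(fx3$metrics, fx3$cohort, n_permutations = 999,
                               seed = 6)
  ra <- res3$range_level
  expect_lt(ra$p[ra$band == "alpha" & ra$metric == "C"], 0.01)
  expect_gt(ra$p[ra$band == "beta" & ra$metric == "C"], 0.05)
  expect_error(group_contrast_sweep(fx$metrics,
                                    data.frame(subject_id = "zz", group = "TC"),
                                    n_permutations = 9),
               "subject mismatch|two groups")
})

test_that("rt_metric_correlations computes within-group range-level r", {
  fx <- make_metric_fixture(8, seed = 12)
  # tie rt to the alpha range-level C within TC
  agg <- aggregate(C ~ subject_id,
                   data = fx$metrics[fx$metrics$band == "alpha", ], FUN = mean)
  fx$cohort$rt_ms <- 400 + 100 * agg$C[match(fx$cohort$subject_id,
                                             agg$subject_id)]
  res <- rt_metric_correlations(fx$metrics, fx$cohort)
  row <- res[res$group == "TC" & res$band == "alpha" & res$metric == "C", ]
  expect_equal(row$r, 1, tolerance = 1e-9)
  expect_equal(row$n, 8)
  expect_equal(nrow(res), 2 * 2 * 4)
})
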