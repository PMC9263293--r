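test_that("von Mises sampler matches the Bessel phasor mean", {
  # |E e^{i(ex - ey)}| for independent von Mises jitter = (I1(k)/I0(k))^2;
  # Monte-Carlo over 2e6 draws agreed with the closed form to < 1e-3
  set.seed(7)
  for (k in c(0.5, 1, 2, 5)) {
    d <- rvonmises(2e5, k) - rvonmises(2e5, k)
    expect_lt(abs(Mod(mean(exp(1i * d))) - plv_von_mises(k)), 0.004)
  }
  expect_equal(plv_von_mises(0), 0)
  expect_lt(abs(plv_von_mises(2) - 0.486889), 1e-6)
  expect_error(rvonmises(10, -1), "kappa")
  expect_error(plv_von_mises(-0.1), "kappa")
  # kappa = 0 is circular-uniform
  set.seed(8)
  u <- rvonmises(1e4, 0)
  expect_true(all(u >= -pi & u <= pi))
  expect_lt(abs(mean(u > 0) - 0.5), 0.02)
})

test_that("simulate_channel_pair: limits, validation and determinism", {
  p0 <- simulate_channel_pair(0, 1000, seed = 1)
  expect_equal(p0$true_plv, 0)
  pinf <- simulate_channel_pair(Inf, 1000, seed = 1)
  expect_equal(pinf$true_plv, 1)
  expect_identical(pinf$x, pinf$y)  # no jitter: identical waveforms
  p2a <- simulate_channel_pair(2, 1000, seed = 9)
  p2b <- simulate_channel_pair(2, 1000, seed = 9)
  expect_identical(p2a, p2b)
  expect_false(identical(p2a$x, simulate_channel_pair(2, 1000, seed = 10)$x))
  expect_true(all(is.finite(p2a$x)) && all(is.finite(p2a$y)))
  expect_error(simulate_channel_pair(-1, 100), "kappa")
  expect_error(simulate_channel_pair(1, 0), "n_samples")
})

test_that("estimated PLV converges to the closed form across kappa (20 seeds)", {
  # beta-band pairs so the half-period jitter blocks are short (6 samples):
  # per-seed estimates at 60000 samples, pooled aggregation
  for (k in c(0, 1, 2, 5)) {
    errs <- vapply(1:20, function(s) {
      p <- simulate_channel_pair(k, 60000, band_center_hz = 21.5,
                                 seed = 1000 * k + s)
      rec <- eeg_recording(rbind(p$x, p$y), 250, c("x", "y"))
      pm <- plv_matrix(segment_epochs(rec, 15, 16, contiguous = TRUE),
                       aggregate = "pooled")
      pm$values[1, 2] - p$true_plv
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.02)
  }
})

test_that("cohort simulation is deterministic and respects the group effect", {
  spec <- cohort_spec(n_per_group = 3, n_channels = 16, duration_s = 30,
                      bands = eeg_bands(c("alpha", "beta")), seed = 77)
  co1 <- simulate_cohort(spec)
  co2 <- simulate_cohort(spec)
  expect_identical(co1$table, co2$table)
  expect_identical(co1$recordings[[5]]$data, co2$recordings[[5]]$data)
  expect_equal(nrow(co1$table), 6)
  expect_setequal(unique(co1$table$group), c("TC", "control"))
  # TC ground truth carries the planted frontal alpha cluster, controls do not
  gt_tc <- co1$ground_truth[[1]]
  gt_ct <- co1$ground_truth[[4]]
  expect_equal(gt_tc$group, "TC")
  expect_equal(gt_ct$group, "control")
  i_fp1 <- match("FP1", spec$montage$channel)
  i_fp2 <- match("FP2", spec$montage$channel)
  expect_gt(gt_tc$true_plv$alpha[i_fp1, i_fp2], 0.1)
  expect_equal(gt_ct$true_plv$alpha[i_fp1, i_fp2], 0)
  # no beta coupling planted for anyone
  expect_equal(gt_tc$true_plv$beta, diag(1, 16))
  # true PLV matrices are valid
  for (gt in co1$ground_truth) {
    tp <- gt$true_plv$alpha
    expect_true(isSymmetric(tp))
    expect_equal(unname(diag(tp)), rep(1, 16))
    expect_true(all(tp >= 0 & tp <= 1))
  }
  # all signals finite
  expect_true(all(vapply(co1$recordings, function(r) all(is.finite(r$data)),
                         logical(1))))
})

test_that("null cohorts have group-identical ground truth distributions", {
  spec <- cohort_spec(n_per_group = 3, n_channels = 12, duration_s = 30,
                      bands = eeg_bands("alpha"),
                      group_effect = list(band = "alpha", nodes = c("FP1", "FP2"),
                                          kappa = 0),
                      seed = 5)
  co <- simulate_cohort(spec)
  offdiag <- function(m) m[upper.tri(m)]
  # every subject's true alpha matrix contains no coupling (posterior baseline
  # nodes are outside the reduced 12-channel montage)
  for (gt in co$ground_truth)
    expect_equal(offdiag(gt$true_plv$alpha), rep(0, 66))
})

test_that("rt model links reaction time to true weighted alpha efficiency", {
  spec <- cohort_spec(n_per_group = 40, n_channels = 30, duration_s = 30,
                      bands = eeg_bands("alpha"), seed = 11)
  co <- simulate_cohort(spec)
  ew <- vapply(co$ground_truth, function(g) g$true_alpha_efficiency, numeric(1))
  rtexp <- vapply(co$ground_truth, function(g) g$rt_expected, numeric(1))
  fit <- stats::lm(rtexp ~ ew)
  expect_equal(unname(stats::coef(fit)), c(520, -1500), tolerance = 1e-8)
  # TC group is faster on average (higher true connectivity)
  expect_lt(mean(co$table$rt_ms[co$table$group == "TC"]),
            mean(co$table$rt_ms[co$table$group == "control"]))
})

test_that("coupling_spec validation", {
  expect_error(coupling_spec(10, data.frame(i = 1, j = 1, kappa = 2)),
               "self-coupling")
  expect_error(coupling_spec(10, data.frame(i = c(1, 2), j = c(2, 1),
                                            kappa = c(1, 1))),
               "duplicate")
  expect_error(coupling_spec(10, data.frame(i = 1, j = 2, kappa = -2)),
               "kappa")
  # inconsistent kappa inside one connected component is rejected at synthesis
  cs <- coupling_spec(10, data.frame(i = c(1, 2), j = c(2, 3), kappa = c(1, 2)))
  expect_error(plvnet:::coupling_components(cs$pairs, 5), "share kappa")
  expect_error(plvnet:::coupling_components(data.frame(i = 1, j = 9, kappa = 1), 5),
               "exceeds channel count")
  expect_error(cohort_spec(n_per_group = 1), "n_per_group")
  expect_error(cohort_spec(n_channels = 31), "montage")
})

test_that("cohort export writes recordings plus a cohort table", {
  spec <- cohort_spec(n_per_group = 2, n_channels = 12, duration_s = 16,
                      bands = eeg_bands("alpha"), epoch_length_s = 4, seed = 2)
  co <- simulate_cohort(spec)
  dir <- file.path(tempdir(), "cohort_export")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.tsv")))
  expect_length(list.files(dir, pattern = "\\.tsv$"), 5)  # 4 subjects + table
  tab <- read.delim(file.path(dir, "cohort.tsv"))
  expect_equal(names(tab), c("subject_id", "group", "age", "sex", "rt_ms",
                             "psycap_total"))
  back <- read_recording(file.path(dir, paste0(co$table$subject_id[1], ".tsv")),
                         sampling_rate_hz = 250, expected_channels = 12)
  expect_equal(unname(back$data), unname(co$recordings[[1]]$data),
               tolerance = 1e-6)
})
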