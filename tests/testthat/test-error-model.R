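test_that("window error is the demeaned RMS difference", {
  set.seed(21)
  n <- 1250
  sig_m <- matrix(rnorm(8 * n), 8)
  sig_r <- matrix(rnorm(8 * n), 8)
  ref <- make_epoch(sig_r, is_reference = TRUE)
  mot <- make_epoch(sig_m)
  # identical epochs -> zero for every modality
  ref2 <- make_epoch(sig_m, is_reference = TRUE)
  for (m_ in c("accel_x", "accel_y", "accel_z", "eeg_avg")) {
    expect_equal(measure_window_error(mot, ref2, m_)$value, 0)
  }
  # brute-force oracle: sample-by-sample RMS of the averaged series
  got <- measure_window_error(mot, ref, "eeg_avg")$value
  brute_rms <- function(mat) {
    avg <- numeric(ncol(mat))
    for (t in seq_len(ncol(mat))) avg[t] <- mean(mat[, t])
    avg <- avg - sum(avg) / length(avg)
    sqrt(sum(avg^2) / length(avg))
  }
  expect_equal(got, brute_rms(sig_m) - brute_rms(sig_r), tolerance = 1e-12)
})

test_that("constructed RMS amplitudes subtract as expected", {
  n <- 1000
  t <- seq_len(n)
  # sin has RMS amp/sqrt(2); build motion RMS 3, reference RMS 1
  mot <- make_epoch(matrix(0, 8, n),
                    accel = rbind(3 * sqrt(2) * sin(2 * pi * t / 50),
                                  0 * t, 0 * t))
  ref <- make_epoch(matrix(0, 8, n),
                    accel = rbind(1 * sqrt(2) * sin(2 * pi * t / 50),
                                  0 * t, 0 * t),
                    is_reference = TRUE)
  expect_equal(measure_window_error(mot, ref, "accel_x")$value, 2,
               tolerance = 1e-9)
})

test_that("measurement preconditions are enforced", {
  a <- make_epoch(matrix(rnorm(8 * 100), 8))
  b <- make_epoch(matrix(rnorm(8 * 100), 8), is_reference = TRUE)
  expect_error(measure_window_error(a, a, "eeg_avg"), "reference")
  short <- make_epoch(matrix(rnorm(8 * 50), 8), is_reference = TRUE)
  expect_error(measure_window_error(a, short, "eeg_avg"), "length")
  expect_error(measure_window_error(a, b, "gyro_x"), "modality")
})

test_that("weight factors solve the one-condition model exactly", {
  expect_equal(fit_weight_factor(3.0, 1.5, 2.0), 1)     # E_n = ratio * E_1
  expect_equal(fit_weight_factor(1.0, 2.0, 2.0), 0.25)
  expect_error(fit_weight_factor(1.0, 0, 2.0), "zero reference")
  expect_error(fit_weight_factor(1.0, 1.0, -1), "ratio")
})

test_that("weight-factor averaging is the arithmetic mean", {
  expect_equal(average_weight_factors(c(1, 1, 1, 1)), 1)
  expect_equal(average_weight_factors(c(0.5, 1.5)), 1)
  set.seed(4)
  v <- runif(9, 0.5, 2)
  acc <- 0; for (x in v) acc <- acc + x
  expect_equal(average_weight_factors(v), acc / 9, tolerance = 1e-12)
  expect_error(average_weight_factors(numeric(0)), "empty")
})

test_that("correction factors are mean hold-out residuals", {
  expect_equal(fit_correction_factor(c(s4 = 2, s5 = 3), c(s4 = 1.5, s5 = 2.5)), 0.5)
  expect_equal(fit_correction_factor(c(s4 = 2, s5 = 3), c(s4 = 2, s5 = 3)), 0)
  expect_equal(fit_correction_factor(c(s4 = 2, s5 = 2), c(s4 = 2.5, s5 = 1.5)), 0)
  expect_error(fit_correction_factor(c(s4 = 2), c(s5 = 2)), "keys")
})

test_that("factor-error prediction follows ratio * wf * ref + cf", {
  expect_equal(predict_factor_error(1.7, 1, 1, 0), 1.7)   # reference fixed point
  expect_equal(predict_factor_error(2, 2, 1, 0), 4)
  expect_equal(predict_factor_error(1.5, 0.8, 1.1, 0.2), 1.52)
  # strictly increasing in every argument with cf fixed
  base <- predict_factor_error(1.5, 0.8, 1.1, 0.2)
  expect_gt(predict_factor_error(1.6, 0.8, 1.1, 0.2), base)
  expect_gt(predict_factor_error(1.5, 0.9, 1.1, 0.2), base)
  expect_gt(predict_factor_error(1.5, 0.8, 1.2, 0.2), base)
})

test_that("axis combination is Euclidean, sign/permutation invariant", {
  expect_equal(combine_axes(3, 4, 0), 5)
  expect_equal(combine_axes(0, 0, 0), 0)
  expect_equal(combine_axes(1, 1, 1), sqrt(3))
  set.seed(2)
  v <- rnorm(3)
  expect_equal(combine_axes(-v[1], v[3], -v[2]), combine_axes(v[1], v[2], v[3]))
  expect_gte(combine_axes(v[1], v[2], v[3]), max(abs(v)))
})

test_that("accelerometer and total errors are plain averages", {
  expect_equal(accel_error(1, 2, 3), 2)
  expect_equal(accel_error(0.7, 0.7, 0.7), 0.7)
  expect_equal(accel_error(0, 0, 6), 2)
  expect_equal(total_error(2, 2, 2, 2), 2)
  expect_equal(total_error(0, 0, 0, 4), 1)
  expect_equal(total_error(1, 2, 3, 4), 2.5)
})

test_that("a self-consistent zero-noise grid calibrates to Wf=1, Cf=0", {
  cfg <- calib_config()
  grid <- generate_condition_grid(cfg, seed = 8)
  p <- calibrate(grid$reference, grid$recordings)
  expect_equal(unname(as.vector(p$weight_factors)), rep(1, 12), tolerance = 1e-6)
  expect_equal(unname(as.vector(p$correction_factors)), rep(0, 12), tolerance = 1e-6)
  expect_true(all(p$reference_errors > 0))
})

test_that("non-unit weight factors are recovered from the grid ground truth", {
  wf <- c(surface = 0.8, subject = 1.25, wheelchair = 1.0)
  # zero noise: exact
  grid0 <- generate_condition_grid(calib_config(wf), seed = 9)
  p0 <- calibrate(grid0$reference, grid0$recordings)
  for (f in names(wf)) {
    expect_equal(unname(p0$weight_factors[, f]), rep(wf[[f]], 4), tolerance = 1e-6)
  }
  # low background noise: within 5%
  gridn <- generate_condition_grid(calib_config(wf, noise_rms = 1,
                                                n_trials_per_class = 2), seed = 10)
  pn <- calibrate(gridn$reference, gridn$recordings)
  for (f in names(wf)) {
    expect_equal(unname(pn$weight_factors["eeg_avg", f]), wf[[f]], tolerance = 0.05)
  }
})

test_that("calibration demands the hold-out conditions", {
  cfg <- calib_config()
  grid <- generate_condition_grid(cfg, seed = 12)
  keep <- vapply(grid$recordings, function(r)
    !r$meta$surface_id %in% c("s4", "s5"), logical(1))
  expect_error(calibrate(grid$reference, grid$recordings[keep]),
               "hold-out|non-reference")
  expect_error(calibrate(NULL, grid$recordings), "reference")
})

test_that("hold-out residuals have zero mean after fitting Cf", {
  cfg <- calib_config(noise_rms = 2, n_trials_per_class = 2)
  grid <- generate_condition_grid(cfg, seed = 14)
  p <- calibrate(grid$reference, grid$recordings)
  # recompute measured hold-out errors for the eeg surface factor
  ref_eps <- segment_by_cues(grid$reference)
  meas <- vapply(c("s4", "s5"), function(s) {
    recs <- Filter(function(r) r$meta$surface_id == s &&
                     r$meta$subject_id == "w1" && r$meta$wheelchair_id == "u1",
                   grid$recordings)
    vals <- unlist(lapply(recs, function(r) {
      eps <- segment_by_cues(r)
      vapply(seq_along(eps), function(i)
        measure_window_error(eps[[i]], ref_eps[[i]], "eeg_avg")$value, numeric(1))
    }))
    mean(vals)
  }, numeric(1))
  pred <- vapply(c("s4", "s5"), function(s)
    predict_factor_error(p$reference_errors["eeg_avg", "surface"],
                         p$friction_table[["s1"]] / p$friction_table[[s]],
                         p$weight_factors["eeg_avg", "surface"],
                         p$correction_factors["eeg_avg", "surface"]),
    numeric(1))
  expect_equal(mean(meas - pred), 0, tolerance = 1e-12)
})

test_that("the RMS correction shrinks, passes through, or floors", {
  set.seed(33)
  x <- rnorm(1000)
  expect_identical(apply_correction(x, 0), x)
  expect_identical(apply_correction(x, -1), x)
  x2 <- x / rms(x) * 2                       # RMS exactly 2
  expect_equal(rms(apply_correction(x2, 1)), 1, tolerance = 1e-12)
  expect_equal(apply_correction(x2, 5), x2 * 0)
})

test_that("corrected epochs carry less artifact than uncorrected ones", {
  cfg <- synth_config(n_trials_per_class = 2, n_grid_trials = 1)
  grid <- generate_condition_grid(cfg, seed = 15)
  p <- calibrate(grid$reference, grid$recordings)
  sel <- Filter(function(r) r$meta$subject_id == "w1" &&
                  r$meta$wheelchair_id == "u1", grid$recordings)
  eps <- unlist(lapply(sel, segment_by_cues), recursive = FALSE)
  expect_gte(length(eps), 30)
  shrunk <- 0L
  for (e in eps) {
    ce <- wheelbci:::correct_epoch(e, p)
    raw_art <- rms(e$ground_truth$eeg_artifact)
    scale_ <- rms(ce$corrected_avg) / rms(reshape1(e$eeg)$avg)
    expect_lte(scale_, 1 + 1e-12)
    if (scale_ * raw_art < raw_art) shrunk <- shrunk + 1L
  }
  expect_equal(shrunk, length(eps))   # paired: every epoch strictly reduced
})
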