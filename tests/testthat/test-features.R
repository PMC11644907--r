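test_that("Hjorth mobility matches closed forms for noise and sinusoids", {
  set.seed(0)
  # iid noise: var(diff) = 2 var -> mobility ~ sqrt(2)
  x <- rnorm(1e5)
  expect_equal(hjorth_params(x)$mobility, sqrt(2), tolerance = 0.02)
  # sampled sinusoid: mobility = 2 sin(pi f / fs)
  fs <- 250; f <- 10
  s <- sin(2 * pi * f * seq_len(5000) / fs)
  expect_equal(hjorth_params(s)$mobility, 2 * sin(pi * f / fs), tolerance = 0.01)
  # brute-force differencing oracle on the same series
  d <- s[-1] - s[-length(s)]
  expect_equal(hjorth_params(s)$mobility,
               sqrt(stats::var(d) / stats::var(s)), tolerance = 1e-12)
  expect_error(hjorth_params(rep(3, 100)), "degenerate")
  expect_error(hjorth_params(c(1, 2)), "length")
})

test_that("moment features match brute-force moments", {
  # constant series keeps first-order stats, flags higher moments
  m <- moment_features(rep(1, 4))
  expect_equal(m$mean, 1); expect_equal(m$max, 1)
  expect_equal(m$variance, 0); expect_equal(m$coeff_variation, 0)
  expect_true(m$var_degenerate)

  # symmetric series -> zero skewness, flagged CV at zero mean
  sym <- rep(c(-2, 2), 50)
  ms <- moment_features(sym)
  expect_equal(ms$skewness, 0)
  expect_true(ms$cv_degenerate)

  set.seed(0)
  z <- rnorm(1e6)
  mz <- moment_features(z)
  expect_equal(mz$kurtosis, 0, tolerance = 0.02)
  # brute-force oracle
  mu <- sum(z) / length(z)
  m2 <- sum((z - mu)^2) / length(z)
  m3 <- sum((z - mu)^3) / length(z)
  expect_equal(mz$skewness, m3 / m2^1.5, tolerance = 1e-10)
  expect_equal(mz$coeff_variation, sd(z) / abs(mu), tolerance = 1e-10)
})

test_that("wavelet transform conserves energy (Parseval)", {
  set.seed(3)
  x <- rnorm(1024)
  d <- dwt_db4(x, 4)
  tot <- sum(d$approx^2) + sum(vapply(d$details, function(v) sum(v^2), numeric(1)))
  expect_equal(tot, sum(x^2), tolerance = 1e-8)
  wf <- wavelet_features(x)
  expect_equal(wf$detail_energy + sum(d$approx^2), sum(x^2), tolerance = 1e-8)
})

test_that("wavelet detail features handle degenerate energy distributions", {
  expect_equal(wavelet_features(numeric(64)),
               list(detail_energy = 0, detail_entropy = 0))
  # synthesize a series whose detail energy sits in level 1 only, via the
  # adjoint of the analysis step (single nonzero level-1 detail coefficient)
  filt <- wheelbci:::db4_filters()
  n <- 64
  x <- numeric(n)
  k <- 5  # coefficient index
  for (m in seq_along(filt$hi)) {
    x[(2 * k + m - 3) %% n + 1] <- x[(2 * k + m - 3) %% n + 1] + filt$hi[m]
  }
  wf <- wavelet_features(x)
  expect_equal(wf$detail_entropy, 0, tolerance = 1e-10)
  expect_equal(wf$detail_energy, 1, tolerance = 1e-10)
  expect_error(dwt_db4(rnorm(8), 4), "too short")
})

test_that("band max powers localize tones and match a direct DFT oracle", {
  fs <- 250; n <- 1250
  t <- seq_len(n) / fs
  pure <- sin(2 * pi * 10 * t)
  bp <- band_max_powers(pure, fs)
  expect_gt(bp$fft_alpha_max_power, bp$fft_delta_max_power)
  expect_gt(bp$fft_alpha_max_power, bp$fft_theta_max_power)
  expect_gt(bp$fft_alpha_max_power, bp$fft_beta_max_power)

  z <- band_max_powers(numeric(n), fs)
  expect_true(all(unlist(z) == 0))

  # 2 Hz amp 1 + 20 Hz amp 2: beta max = 4x delta max (power ratio amp^2)
  mix <- sin(2 * pi * 2 * t) + 2 * sin(2 * pi * 20 * t)
  bm <- band_max_powers(mix, fs)
  expect_equal(bm$fft_beta_max_power / bm$fft_delta_max_power, 4,
               tolerance = 1e-6)
  # direct DFT oracle at the two line frequencies (bins 10 and 100)
  dft_pow <- function(x, k) {
    n <- length(x)
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    (re^2 + im^2) / n
  }
  expect_equal(bm$fft_delta_max_power, dft_pow(mix - mean(mix), 10),
               tolerance = 1e-6)
  expect_equal(bm$fft_beta_max_power, dft_pow(mix - mean(mix), 100),
               tolerance = 1e-6)
  expect_error(band_max_powers(rnorm(100), fs = 50), "beta")
})

test_that("band max powers are shift-invariant for periodic inputs", {
  fs <- 250; n <- 1000
  x <- sin(2 * pi * 10 * seq_len(n) / fs)   # period 25 divides n
  x_shift <- c(x[26:n], x[1:25])
  expect_equal(unlist(band_max_powers(x, fs)),
               unlist(band_max_powers(x_shift, fs)), tolerance = 1e-9)
})

test_that("features scale as expected under x -> c x", {
  set.seed(9)
  fs <- 250
  x <- rnorm(1250) + sin(2 * pi * 10 * seq_len(1250) / fs)
  c_ <- 3.7
  f1 <- wheelbci:::feature_vector_from_series(x, fs)
  f2 <- wheelbci:::feature_vector_from_series(c_ * x, fs)
  inv <- c("mobility", "complexity", "kurtosis", "coeff_variation", "skewness",
           "wavelet_detail_entropy")
  lin <- c("mean", "max")
  quad <- c("variance", "wavelet_detail_energy", "fft_delta_max_power",
            "fft_theta_max_power", "fft_alpha_max_power", "fft_beta_max_power")
  expect_equal(f2[inv], f1[inv], tolerance = 1e-9)
  expect_equal(f2[lin], c_ * f1[lin], tolerance = 1e-9)
  expect_equal(f2[quad], c_^2 * f1[quad], tolerance = 1e-9)
})

test_that("the feature vector has the documented names, order and determinism", {
  expect_length(feature_names(), 14L)
  expect_length(feature_names(c("min", "peak_to_peak")), 16L)
  expect_error(feature_names("median"), "unknown extra")
  set.seed(12)
  ep <- make_epoch(matrix(rnorm(8 * 1250), 8))
  v1 <- extract_feature_vector(ep, "raw_avg")
  v2 <- extract_feature_vector(ep, "raw_avg")
  expect_identical(v1, v2)
  expect_identical(names(v1), feature_names())
  expect_identical(attr(v1, "label"), "RELAX")
  # degenerate epoch errors out naming the feature, rather than yielding NaN
  expect_error(extract_feature_vector(make_epoch(matrix(0, 8, 1250)), "raw_avg"),
               "mobility|variance|degenerate")
  # corrected source requires the correction to have run
  expect_error(extract_feature_vector(ep, "corrected_avg"), "corrected")
})

test_that("feature matrices have the configured geometry", {
  set.seed(13)
  ep <- make_epoch(matrix(rnorm(8 * 1250), 8))
  g <- build_feature_matrix(ep, source = "raw_avg")
  expect_equal(dim(g), c(8L, 14L))
  expect_false(anyNA(g))
  expect_identical(attr(g, "label"), "RELAX")

  # periodic input whose period divides the sub-window step -> identical rows
  x <- 2 + sin(2 * pi * seq_len(1250) / 139) + 0.5 * sin(4 * pi * seq_len(1250) / 139)
  epp <- make_epoch(matrix(rep(x, each = 8), 8))
  gp <- build_feature_matrix(epp, source = "raw_avg")
  for (i in 2:8) expect_equal(gp[i, ], gp[1, ], tolerance = 1e-9)
})

test_that("standardization round-trips with training statistics", {
  set.seed(14)
  mats <- lapply(1:12, function(i) {
    ep <- make_epoch(matrix(rnorm(8 * 1250, sd = i), 8))
    build_feature_matrix(ep, source = "raw_avg")
  })
  st <- compute_feature_stats(mats[1:8])
  std <- standardize_features(mats, st)
  back <- standardize_features(std, st, invert = TRUE)
  for (i in seq_along(mats)) {
    expect_equal(unclass(back[[i]]), unclass(mats[[i]]), tolerance = 1e-9)
  }
  pooled <- do.call(rbind, lapply(std[1:8], unclass))
  expect_equal(unname(colMeans(pooled)), rep(0, 14), tolerance = 1e-9)
})
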