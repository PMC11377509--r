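test_that("charge matches rectangle and Gaussian integrals", {
  # constant current c over total duration T -> c * T
  E <- seq(-0.05, -0.45, length.out = 101)
  vg <- voltammogram(E, rep(2.5, 101), scan_rate = 0.05)
  T_total <- 0.4 / 0.05
  expect_equal(charge(vg), 2.5 * T_total, tolerance = 1e-12)
  expect_equal(charge(voltammogram(E, rep(0, 101))), 0)

  # noiseless Gaussian on a zero baseline, wide window:
  # Q = A * sigma * sqrt(2*pi) / scan_rate
  A <- 2; s <- 0.03
  vg <- gaussian_trace(amplitude = A, sd = s, n = 2048)
  expect_equal(charge(vg), A * s * sqrt(2 * pi) / 0.05, tolerance = 0.005)

  # independent oracle: dense-grid trapezoid at 10x resolution
  E10 <- seq(-0.05, -0.45, length.out = 20480)
  I10 <- A * exp(-(E10 + 0.25)^2 / (2 * s^2))
  t10 <- cumsum(c(0, abs(diff(E10)))) / 0.05
  dense <- sum(diff(t10) * (utils::head(I10, -1) + utils::tail(I10, -1)) / 2)
  expect_equal(charge(vg), dense, tolerance = 0.005)
})

test_that("peak geometry recovers Gaussian closed forms", {
  A <- 1.5; E0 <- -0.25; s <- 0.035
  vg <- gaussian_trace(amplitude = A, center = E0, sd = s, n = 4096)
  h <- grid_step(vg)
  pk <- peak_descriptors(vg)
  expect_false(pk$degenerate)
  expect_equal(pk$positive_peak_current, A, tolerance = 1e-4)
  expect_lt(abs(pk$positive_peak_potential - E0), h)
  # FWHM = 2*sqrt(2*ln 2)*sigma within two grid steps
  expect_lt(abs(pk$peak_width_half_height - 2 * sqrt(2 * log(2)) * s), 2 * h)
  # half-peak potential on the flank toward the sweep start: the sweep
  # descends from -0.05, so the preceding flank sits above the centre
  expect_lt(abs(pk$half_peak_potential - (E0 + sqrt(2 * log(2)) * s)), 2 * h)
})

test_that("negating a trace swaps the positive and negative peaks", {
  vg <- gaussian_trace(amplitude = 2, baseline_intercept = 0.3, n = 256)
  neg <- voltammogram(vg$potential, -vg$current, vg$scan_rate)
  a <- peak_descriptors(vg); b <- peak_descriptors(neg)
  expect_equal(b$positive_peak_current, -a$negative_peak_current)
  expect_equal(b$negative_peak_current, -a$positive_peak_current)
  expect_equal(b$positive_peak_potential, a$negative_peak_potential)
  expect_equal(b$negative_peak_potential, a$positive_peak_potential)
})

test_that("flat traces are flagged degenerate with zero half-height geometry", {
  E <- seq(-0.05, -0.45, length.out = 64)
  vg <- voltammogram(E, rep(1.2, 64))
  pk <- peak_descriptors(vg)
  expect_true(pk$degenerate)
  expect_equal(pk$peak_width_half_height, 0)
  expect_equal(pk$half_peak_potential, 0)
  mo <- distribution_moments(vg)
  expect_true(mo$degenerate)
  expect_equal(mo$mean_current, 1.2)
  expect_equal(mo$median_current, 1.2)
  expect_equal(mo$std_current, 0)
  expect_equal(mo$skewness, 0)
  expect_equal(mo$kurtosis, 0)
})

test_that("moments match independent textbook recomputation", {
  set.seed(42)
  E <- seq(-0.05, -0.45, length.out = 100)
  x <- rnorm(100, sd = 2) + 0.5 * seq_len(100) / 100
  vg <- voltammogram(E, x)
  mo <- distribution_moments(vg)
  or <- oracle_moments(x)
  expect_equal(mo$mean_current, or$mean, tolerance = 1e-10)
  expect_equal(mo$median_current, median(x), tolerance = 1e-10)
  expect_equal(mo$std_current, or$sd, tolerance = 1e-10)
  expect_equal(mo$skewness, or$skewness, tolerance = 1e-10)
  expect_equal(mo$kurtosis, or$kurtosis, tolerance = 1e-10)

  # symmetric trace about its mean -> zero skewness
  sym <- voltammogram(E, c(seq(0, 1, length.out = 50),
                           seq(1, 0, length.out = 50)))
  expect_lt(abs(distribution_moments(sym)$skewness), 1e-12)
})

test_that("derivative extrema are exact on ramps and Gaussian flanks", {
  E <- seq(-0.05, -0.45, length.out = 128)
  dv <- derivative_extrema(voltammogram(E, 3 + 2 * E))
  expect_equal(dv$peak_derivative, 2, tolerance = 1e-9)
  expect_equal(dv$peak_second_derivative, 0, tolerance = 1e-9)

  dv0 <- derivative_extrema(voltammogram(E, rep(1, 128)))
  expect_equal(dv0$peak_derivative, 0)
  expect_equal(dv0$peak_second_derivative, 0)

  A <- 2; s <- 0.04
  vg <- gaussian_trace(amplitude = A, sd = s, n = 4096)
  dv <- derivative_extrema(vg)
  expect_equal(abs(dv$peak_derivative), A * exp(-0.5) / s, tolerance = 0.01)
})

test_that("the assembled feature vector composes the per-operation oracles", {
  A <- 2; E0 <- -0.25; s <- 0.04
  vg <- gaussian_trace(amplitude = A, center = E0, sd = s, n = 4096)
  f <- extract_features(vg)
  expect_identical(names(f), cv_feature_names())
  expect_length(f, 14)
  expect_true(all(is.finite(f)))
  h <- grid_step(vg)
  expect_equal(f[["charge_Q"]], A * s * sqrt(2 * pi) / 0.05,
               tolerance = 0.005)
  expect_lt(abs(f[["peak_width_half_height"]] - 2 * sqrt(2 * log(2)) * s),
            2 * h)
  expect_equal(abs(f[["peak_derivative"]]), A * exp(-0.5) / s,
               tolerance = 0.01)
  expect_equal(f[["positive_peak_current"]], A, tolerance = 1e-4)
  expect_gte(f[["positive_peak_current"]], f[["negative_peak_current"]])
  expect_gte(f[["peak_width_half_height"]], 0)

  # sign flip: peak fields swap, mean negates, spread is invariant
  g <- extract_features(voltammogram(vg$potential, -vg$current,
                                     vg$scan_rate))
  expect_equal(g[["positive_peak_current"]], -f[["negative_peak_current"]])
  expect_equal(g[["negative_peak_current"]], -f[["positive_peak_current"]])
  expect_equal(g[["mean_current"]], -f[["mean_current"]])
  expect_equal(g[["std_current"]], f[["std_current"]])

  # pure function: repeated calls are bit-identical
  expect_identical(f, extract_features(vg))
})

test_that("errors halve under grid refinement (within a factor 3)", {
  A <- 1; s <- 0.03
  err <- function(n) {
    vg <- gaussian_trace(amplitude = A, sd = s, n = n)
    f <- extract_features(vg)
    c(q = abs(f[["charge_Q"]] - A * s * sqrt(2 * pi) / 0.05),
      w = abs(f[["peak_width_half_height"]] - 2 * sqrt(2 * log(2)) * s),
      d = abs(abs(f[["peak_derivative"]]) - A * exp(-0.5) / s))
  }
  e1 <- err(256); e2 <- err(512)
  expect_true(all(e2 <= e1 / 2 * 3 + 1e-12))
})

test_that("shifting the potential axis shifts potentials and nothing else", {
  vg <- gaussian_trace(amplitude = 1.3, baseline_intercept = 0.2, n = 512)
  delta <- 0.17
  shifted <- voltammogram(vg$potential + delta, vg$current, vg$scan_rate)
  f <- extract_features(vg); g <- extract_features(shifted)
  pot_fields <- c("half_peak_potential", "positive_peak_potential",
                  "negative_peak_potential")
  for (p in pot_fields) expect_equal(g[[p]], f[[p]] + delta, tolerance = 1e-9)
  same <- setdiff(cv_feature_names(), pot_fields)
  expect_equal(g[same], f[same], tolerance = 1e-9)
})

test_that("feature matrices stack traces with canonical columns", {
  vgs <- list(gaussian_trace(1, n = 64), gaussian_trace(2, n = 64))
  fm <- extract_feature_matrix(vgs, labels = c("a", "b"))
  expect_equal(dim(fm), c(2, 15))
  expect_identical(names(fm)[1:14], cv_feature_names())
  expect_identical(fm$label, c("a", "b"))
})
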