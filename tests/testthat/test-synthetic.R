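test_that("dose-response is linear inside the window and saturates outside", {
  p0 <- response_params(intercept = 0, slope = 0.004, linear_min = 0,
                        linear_max = 100)
  expect_equal(concentration_to_peak(0, p0), 0)

  p <- response_params(intercept = 0.1, slope = 0.004)
  expect_equal(concentration_to_peak(50, p), 0.3, tolerance = 1e-12)
  expect_gt(concentration_to_peak(100, p), concentration_to_peak(5, p))
  # saturation at the window boundaries
  expect_equal(concentration_to_peak(1, p), concentration_to_peak(5, p))
  expect_equal(concentration_to_peak(500, p), concentration_to_peak(100, p))
  # monotone non-decreasing over an arbitrary grid
  grid <- seq(0, 150, by = 2.5)
  amps <- concentration_to_peak(grid, p)
  expect_true(all(diff(amps) >= 0))

  expect_error(concentration_to_peak(-1, p), ">= 0")
  expect_error(response_params(linear_min = 10, linear_max = 5), "linear_min")
})

test_that("simulated traces follow the signal model deterministically", {
  flat <- peak_model(baseline_intercept = 0.7, baseline_slope = 0,
                     peak_amplitude = 0, noise_sd = 0)
  vg <- simulate_voltammogram(flat, 1)
  expect_true(all(vg$current == 0.7))
  expect_equal(length(vg$potential), 256)
  expect_equal(range(vg$potential), c(-0.45, -0.05))
  # uniform grid
  expect_lt(diff(range(diff(vg$potential))), 1e-12)

  # noiseless peak: maximum at the grid point nearest the centre
  m <- peak_model(baseline_intercept = 0, baseline_slope = 0,
                  peak_amplitude = 1, peak_center = -0.213, noise_sd = 0)
  vg <- simulate_voltammogram(m, 1)
  nearest <- which.min(abs(vg$potential - (-0.213)))
  expect_equal(which.max(vg$current), nearest)

  # seeded determinism
  noisy <- peak_model(noise_sd = 0.05)
  expect_identical(simulate_voltammogram(noisy, 42)$current,
                   simulate_voltammogram(noisy, 42)$current)
  expect_false(identical(simulate_voltammogram(noisy, 42)$current,
                         simulate_voltammogram(noisy, 43)$current))

  expect_error(peak_model(peak_sd = 0), "peak_sd")
  expect_error(peak_model(n_points = 8), "n_points")
  expect_error(peak_model(e_start = -0.1, e_end = -0.1), "e_start")
})

test_that("labelled datasets keep class bookkeeping and ordering", {
  specs <- list(class_spec("a", 10, concentration_cv = 0),
                class_spec("b", 80, concentration_cv = 0))
  ds <- simulate_labeled_dataset(specs, 3, seed = 1)
  expect_length(ds$voltammograms, 6)
  expect_equal(as.vector(table(ds$labels)), c(3, 3))

  # disjoint concentration supports + no noise: every class-b peak
  # current exceeds every class-a one (brute force over all pairs)
  specs <- list(class_spec("a", 10, concentration_cv = 0,
                           nuisance_jitter = 0),
                class_spec("b", 80, concentration_cv = 0,
                           nuisance_jitter = 0))
  ds <- simulate_labeled_dataset(specs, 4, base_model = peak_model(noise_sd = 0),
                                 seed = 2)
  peaks <- vapply(ds$voltammograms,
                  function(v) peak_descriptors(v)$positive_peak_current,
                  numeric(1))
  expect_true(all(outer(peaks[ds$labels == "b"], peaks[ds$labels == "a"],
                        `>`)))

  # the study design: 17 tumor + 1 control
  study <- list(class_spec("tumor", 50), class_spec("control", 2))
  ds <- simulate_labeled_dataset(study, 1, seed = 3)
  expect_length(ds$voltammograms, 2)
  ds17 <- c(simulate_labeled_dataset(study, 17, seed = 3)$voltammograms)
  expect_length(ds17, 34)

  expect_error(simulate_labeled_dataset(list(class_spec("a", 1)), 3),
               "at least 2 classes")
  # determinism
  d1 <- simulate_labeled_dataset(specs, 2, seed = 9)
  d2 <- simulate_labeled_dataset(specs, 2, seed = 9)
  expect_identical(lapply(d1$voltammograms, `[[`, "current"),
                   lapply(d2$voltammograms, `[[`, "current"))
})

test_that("feature extraction recovers the generating peak parameters", {
  m <- peak_model(baseline_intercept = 0, baseline_slope = 0,
                  peak_center = -0.27, peak_sd = 0.05, peak_amplitude = 1.4,
                  noise_sd = 0, n_points = 512)
  vg <- simulate_voltammogram(m, 1)
  h <- grid_step(vg)
  f <- extract_features(vg)
  expect_lt(abs(f[["positive_peak_potential"]] - (-0.27)), h)
  expect_lt(abs(f[["peak_width_half_height"]] -
                  2 * sqrt(2 * log(2)) * 0.05), 2 * h)
})

test_that("synthetic cohorts honour couplings and marginals", {
  co <- simulate_cohort(17, seed = 1)
  expect_equal(nrow(co), 17)
  expect_true(all(co$lobe %in% 3:5))
  expect_true(all(co$t_stage %in% 1:2))
  expect_true(all(co$n_stage %in% 0:1))
  expect_true(all(co$m_stage %in% 0:1))
  expect_true(all(co$grade %in% 1:3))
  expect_true(all(co$muc1_score %in% 0:3))
  expect_identical(co, simulate_cohort(17, seed = 1))
  expect_error(simulate_cohort(2), ">= 3")

  # zero coupling: mean rho(size, grade) across many replicates ~ 0
  rhos <- vapply(1:200, function(s) {
    c2 <- simulate_cohort(20, seed = s)
    if (sd(c2$t_stage) == 0 || sd(c2$grade) == 0) return(NA_real_)
    spearman_test(c2$t_stage, c2$grade)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos, na.rm = TRUE)), 0.1)

  # strong positive size -> grade coupling on a large cohort
  big <- simulate_cohort(500, assoc = list(size = 0.9), seed = 5)
  r <- spearman_test(big$t_stage, big$grade)
  expect_gt(r$rho, 0.5)
  # independent rank-then-moment arithmetic agrees
  expect_equal(r$rho, oracle_spearman(big$t_stage, big$grade),
               tolerance = 1e-12)
})
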