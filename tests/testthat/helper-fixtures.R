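# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately avoid the package's own code
# paths.

# noiseless single-Gaussian trace over the instrument window
gaussian_trace <- function(amplitude = 1, center = -0.25, sd = 0.04,
                           baseline_intercept = 0, baseline_slope = 0,
                           n = 1024, e_start = -0.05, e_end = -0.45,
                           scan_rate = 0.05) {
  E <- seq(e_start, e_end, length.out = n)
  I <- baseline_intercept + baseline_slope * E +
    amplitude * exp(-(E - center)^2 / (2 * sd^2))
  voltammogram(E, I, scan_rate = scan_rate)
}

grid_step <- function(vg) abs(diff(vg$potential[1:2]))

# brute-force Spearman: explicit tie-averaged ranks + explicit Pearson
# formula, no calls into the package or into cor()
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# textbook moment formulas, written out rather than reusing any library
oracle_moments <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu,
       sd = sqrt(sum((x - mu)^2) / (n - 1)),
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# closed-form OLS through explicit sums
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# nearest-centroid LOOCV accuracy on z-scored features: independent
# check that a dataset is actually separable / carries a learnable
# signal (scaling stops huge-magnitude descriptors, e.g. the signed
# derivative extrema, from drowning the informative ones)
nearest_centroid_loocv <- function(X, y) {
  X <- scale(as.matrix(X))
  y <- as.character(y)
  correct <- 0L
  for (i in seq_len(nrow(X))) {
    cls <- unique(y[-i])
    cent <- vapply(cls, function(k)
      colMeans(X[-i, , drop = FALSE][y[-i] == k, , drop = FALSE]),
      numeric(ncol(X)))
    d <- colSums((cent - X[i, ])^2)
    if (cls[which.min(d)] == y[i]) correct <- correct + 1L
  }
  correct / nrow(X)
}

# reduced-capacity configurations of the four families, for Monte-Carlo
# loops where the default capacities would dominate runtime
light_model_specs <- function(seed = 1) {
  list(rf  = model_spec("rf",  list(ntree = 100), seed = seed),
       xgb = model_spec("xgb", list(nrounds = 50), seed = seed),
       gbm = model_spec("gbm", list(nrounds = 50), seed = seed),
       ann = model_spec("ann", list(size = 4, maxit = 150), seed = seed))
}

# well-separated two-class feature set built from voltammograms
separable_two_class <- function(n_per_class = 20, seed = 7) {
  specs <- list(class_spec("low", 8, concentration_cv = 0.05,
                           nuisance_jitter = 0.01),
                class_spec("high", 95, concentration_cv = 0.05,
                           nuisance_jitter = 0.01))
  base <- peak_model(noise_sd = 0.005)
  ds <- simulate_labeled_dataset(specs, n_per_class, base_model = base,
                                 seed = seed)
  list(X = extract_feature_matrix(ds$voltammograms)[cv_feature_names()],
       y = ds$labels)
}

# three-grade dataset with monotone concentration signal and moderate
# noise: the benchmark task for grade prediction
three_grade_dataset <- function(n_per_class = 20, seed = 11) {
  ds <- simulate_labeled_dataset(grade_class_specs(include_control = FALSE),
                                 n_per_class, seed = seed)
  list(X = extract_feature_matrix(ds$voltammograms)[cv_feature_names()],
       y = ds$labels)
}
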