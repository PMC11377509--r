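#' Canonical CV feature names
#'
#' The 14 engineered descriptors computed from each voltammogram, in
#' their fixed canonical order: total charge, half-peak potential, peak
#' width at half height, distributional moments of the current samples,
#' derivative extrema, and the positive/negative peak currents and
#' potentials.
#'
#' @return Character vector of length 14.
#' @export
cv_feature_names <- function() {
  c("charge_Q", "half_peak_potential", "peak_width_half_height",
    "mean_current", "median_current", "std_current",
    "kurtosis", "skewness",
    "peak_derivative", "peak_second_derivative",
    "positive_peak_current", "negative_peak_current",
    "positive_peak_potential", "negative_peak_potential")
}

## time axis reconstructed from the sweep: CV instruments export (E, I)
## only, so t is |dE| accumulated at the scan rate.
sweep_time <- function(vg) {
  cumsum(c(0, abs(diff(vg$potential)))) / vg$scan_rate
}

#' Total charge of a voltammogram
#'
#' Signed charge Q (uC) passed during the sweep: the trapezoidal
#' integral of current over time, with time reconstructed from the
#' potential increments at the scan rate. Currents of opposite sign
#' cancel.
#'
#' @param vg A `voltammogram`.
#' @return Charge in microcoulombs.
#' @export
charge <- function(vg) {
  validate_voltammogram(vg)
  pracma::trapz(sweep_time(vg), vg$current)
}

## straight-line baseline through the means of the first and last 10%
## of samples; half-height geometry is undefined without one.
trace_baseline <- function(vg) {
  n <- length(vg$potential)
  k <- max(2L, floor(0.1 * n))
  head_idx <- seq_len(k)
  tail_idx <- seq.int(n - k + 1L, n)
  x1 <- mean(vg$potential[head_idx]); y1 <- mean(vg$current[head_idx])
  x2 <- mean(vg$potential[tail_idx]); y2 <- mean(vg$current[tail_idx])
  slope <- if (x2 == x1) 0 else (y2 - y1) / (x2 - x1)
  y1 + slope * (vg$potential - x1)
}

## first crossing of `level` on one side of index `peak`, linearly
## interpolated in potential; NA when the flank never crosses.
half_crossing <- function(E, y, peak, level, direction) {
  idx <- if (direction < 0) seq.int(peak, 1L) else seq.int(peak, length(E))
  for (j in seq_along(idx)[-1]) {
    a <- idx[j - 1L]; b <- idx[j]
    if ((y[a] - level) * (y[b] - level) <= 0 && y[a] != y[b]) {
      frac <- (level - y[a]) / (y[b] - y[a])
      return(E[a] + frac * (E[b] - E[a]))
    }
  }
  NA_real_
}

#' Peak geometry of a voltammogram
#'
#' Locates the positive (maximum) and negative (minimum) current peaks
#' and measures the half-height geometry of the dominant peak after
#' subtracting a straight-line baseline fitted through the means of the
#' first and last 10% of samples. The dominant peak is whichever
#' baseline-corrected excursion has the larger magnitude. The half-peak
#' potential is the linearly interpolated potential on the flank
#' preceding the peak (in sweep order) where the corrected current first
#' reaches half its peak value; the width at half height is the distance
#' between the two interpolated half-maximum crossings (an uncrossed
#' flank is clamped to the sweep endpoint).
#'
#' @param vg A `voltammogram`.
#' @return Named list: `positive_peak_current`, `positive_peak_potential`,
#'   `negative_peak_current`, `negative_peak_potential`,
#'   `half_peak_potential`, `peak_width_half_height`, and a logical
#'   `degenerate` flag (TRUE for a flat trace, in which case the
#'   half-height quantities are 0).
#' @export
peak_descriptors <- function(vg) {
  validate_voltammogram(vg)
  E <- vg$potential; I <- vg$current
  i_max <- which.max(I); i_min <- which.min(I)
  corrected <- I - trace_baseline(vg)
  i_dom <- which.max(abs(corrected))
  peak_val <- corrected[i_dom]
  degenerate <- abs(peak_val) < .Machine$double.eps^0.5 * max(1, max(abs(I)))
  if (degenerate) {
    half_E <- 0
    width <- 0
  } else {
    level <- peak_val / 2
    left <- half_crossing(E, corrected, i_dom, level, -1)
    right <- half_crossing(E, corrected, i_dom, level, +1)
    if (is.na(left)) left <- E[1L]
    if (is.na(right)) right <- E[length(E)]
    width <- abs(right - left)
    # flank preceding the peak in sweep order = toward the sweep start
    half_E <- if (is.na(half_crossing(E, corrected, i_dom, level, -1))) E[1L]
              else half_crossing(E, corrected, i_dom, level, -1)
  }
  list(positive_peak_current = I[i_max],
       positive_peak_potential = E[i_max],
       negative_peak_current = I[i_min],
       negative_peak_potential = E[i_min],
       half_peak_potential = half_E,
       peak_width_half_height = width,
       degenerate = degenerate)
}

#' Distributional moments of the current samples
#'
#' Mean, median, standard deviation (n-1 denominator), skewness (third
#' standardised moment) and excess kurtosis (normal -> 0) of the current
#' readings. A zero-variance trace returns skewness and kurtosis 0 with
#' the degenerate flag set rather than NaN, so batch pipelines do not
#' abort on a flat electrode read.
#'
#' @param vg A `voltammogram`.
#' @return Named list: `mean_current`, `median_current`, `std_current`,
#'   `skewness`, `kurtosis`, `degenerate`.
#' @export
distribution_moments <- function(vg) {
  validate_voltammogram(vg)
  I <- vg$current
  s <- stats::sd(I)
  degenerate <- s == 0
  list(mean_current = mean(I),
       median_current = stats::median(I),
       std_current = s,
       skewness = if (degenerate) 0 else e1071::skewness(I, type = 1),
       kurtosis = if (degenerate) 0 else e1071::kurtosis(I, type = 1),
       degenerate = degenerate)
}

## central differences, one-sided at the endpoints
num_deriv <- function(x, y) {
  n <- length(x)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  d
}

#' Derivative extrema of a voltammogram
#'
#' First and second derivatives of current with respect to potential,
#' estimated by central differences (one-sided at the sweep endpoints).
#' Each reported value is the extremum of the absolute derivative,
#' carrying the sign it attains at the maximising point.
#'
#' @param vg A `voltammogram`.
#' @return Named list: `peak_derivative` (uA/V),
#'   `peak_second_derivative` (uA/V^2).
#' @export
derivative_extrema <- function(vg) {
  validate_voltammogram(vg)
  d1 <- num_deriv(vg$potential, vg$current)
  d2 <- num_deriv(vg$potential, d1)
  list(peak_derivative = d1[which.max(abs(d1))],
       peak_second_derivative = d2[which.max(abs(d2))])
}

#' Extract the 14 canonical features from one voltammogram
#'
#' Assembles the full engineered descriptor vector: charge, half-peak
#' potential, peak width at half height, mean/median/sd of current,
#' excess kurtosis, skewness, derivative extrema, and the positive and
#' negative peak currents and potentials. Deterministic and pure: the
#' same trace always yields the identical vector.
#'
#' @param vg A `voltammogram`.
#' @return Named numeric vector of length 14 in the order of
#'   [cv_feature_names()], with attribute `degenerate` (logical) set if
#'   the trace was flat.
#' @examples
#' E <- seq(-0.05, -0.45, length.out = 256)
#' vg <- voltammogram(E, exp(-(E + 0.25)^2 / (2 * 0.04^2)))
#' extract_features(vg)
#' @export
extract_features <- function(vg) {
  validate_voltammogram(vg)
  pk <- peak_descriptors(vg)
  mo <- distribution_moments(vg)
  dv <- derivative_extrema(vg)
  out <- c(charge_Q = charge(vg),
           half_peak_potential = pk$half_peak_potential,
           peak_width_half_height = pk$peak_width_half_height,
           mean_current = mo$mean_current,
           median_current = mo$median_current,
           std_current = mo$std_current,
           kurtosis = mo$kurtosis,
           skewness = mo$skewness,
           peak_derivative = dv$peak_derivative,
           peak_second_derivative = dv$peak_second_derivative,
           positive_peak_current = pk$positive_peak_current,
           negative_peak_current = pk$negative_peak_current,
           positive_peak_potential = pk$positive_peak_potential,
           negative_peak_potential = pk$negative_peak_potential)
  stopifnot(identical(names(out), cv_feature_names()))
  attr(out, "degenerate") <- pk$degenerate || mo$degenerate
  out
}

#' Build a feature matrix from a set of voltammograms
#'
#' Applies [extract_features()] to each trace and stacks the results
#' into a data frame with the 14 canonical columns, plus a `label`
#' column when labels are supplied.
#'
#' @param voltammograms List of `voltammogram` objects.
#' @param labels Optional vector of class labels, one per trace.
#' @return Data frame with one row per trace.
#' @export
extract_feature_matrix <- function(voltammograms, labels = NULL) {
  stopifnot(length(voltammograms) >= 1)
  rows <- lapply(voltammograms, extract_features)
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- cv_feature_names()
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(voltammograms))
    df$label <- labels
  }
  df
}
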