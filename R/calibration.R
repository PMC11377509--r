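#' Fit a linear calibration curve
#'
#' Ordinary least-squares fit of sensor response (peak current, uA)
#' against analyte concentration (U/mL), with the coefficient of
#' determination, the area-normalised sensitivity (slope divided by
#' electrode area), and — when a blank standard deviation is supplied —
#' the limit of detection.
#'
#' @param concentrations Concentrations (U/mL); >= 3 distinct values.
#' @param responses Responses (uA), same length.
#' @param electrode_area Working-electrode area (cm^2); default 2, the
#'   gold electrodes used with this sensor class.
#' @param sigma_blank Optional blank standard deviation (uA) for the
#'   LOD.
#' @param lod_multiplier Multiplier for [limit_of_detection()]
#'   (default 3.3).
#' @return List of class `calibration_fit`: `slope`, `intercept`,
#'   `r_squared`, `sensitivity_per_area`, `sigma_blank`, `lod`,
#'   `linear_range`, `degenerate` (TRUE when the responses carry no
#'   variance).
#' @examples
#' conc <- c(5, 10, 25, 50, 75, 100)
#' fit_calibration(conc, 0.1 + 0.004 * conc)
#' @export
fit_calibration <- function(concentrations, responses, electrode_area = 2,
                            sigma_blank = NULL, lod_multiplier = 3.3) {
  if (length(concentrations) != length(responses))
    stop("concentrations and responses must have equal length", call. = FALSE)
  if (length(unique(concentrations)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (stats::var(concentrations) == 0)
    stop("zero concentration variance", call. = FALSE)
  if (electrode_area <= 0) stop("electrode_area must be > 0", call. = FALSE)
  degenerate <- stats::var(responses) == 0
  if (degenerate) {
    slope <- 0; intercept <- responses[1]; r2 <- 0
  } else {
    fit <- stats::lm(responses ~ concentrations)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    # summary.lm warns on numerically perfect fits; those are a
    # legitimate input here (noiseless reference lines)
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  lod <- if (!is.null(sigma_blank) && slope > 0)
    limit_of_detection(sigma_blank, slope, multiplier = lod_multiplier)
  else NA_real_
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 sensitivity_per_area = slope / electrode_area,
                 sigma_blank = if (is.null(sigma_blank)) NA_real_
                               else sigma_blank,
                 lod = lod,
                 linear_range = range(concentrations),
                 degenerate = degenerate),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: response = %.4g + %.4g * conc (R^2 = %.4f)\n",
              x$intercept, x$slope, x$r_squared))
  cat(sprintf("  range %g-%g U/mL; sensitivity %.4g uA/(cm^2 * conc unit)\n",
              x$linear_range[1], x$linear_range[2], x$sensitivity_per_area))
  if (!is.na(x$lod)) cat(sprintf("  LOD %.4g U/mL\n", x$lod))
  invisible(x)
}

#' Limit of detection
#'
#' The smallest concentration reliably distinguishable from blank,
#' `multiplier * sigma_blank / slope`. The default multiplier 3.3 is
#' the ICH convention; 3.0 is a common alternative.
#'
#' @param sigma_blank Standard deviation of the blank response (uA),
#'   >= 0.
#' @param slope Calibration slope (uA per U/mL), > 0.
#' @param multiplier LOD multiplier, > 0 (default 3.3).
#' @return LOD in U/mL.
#' @export
limit_of_detection <- function(sigma_blank, slope, multiplier = 3.3) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be > 0", call. = FALSE)
  if (sigma_blank < 0) stop("sigma_blank must be >= 0", call. = FALSE)
  if (multiplier <= 0) stop("multiplier must be > 0", call. = FALSE)
  multiplier * sigma_blank / slope
}

#' Selectivity ratio against an interferent panel
#'
#' Ratio of the target analyte's response magnitude to the mean
#' response magnitude over the interfering species; values well above
#' 1 indicate a sensor that responds preferentially to its target.
#'
#' @param target_delta Response change for the target analyte (uA).
#' @param interferent_deltas Response changes for the interferents
#'   (uA), >= 1 value, not all zero.
#' @return Dimensionless selectivity ratio.
#' @export
selectivity <- function(target_delta, interferent_deltas) {
  if (length(interferent_deltas) < 1)
    stop("need at least one interferent", call. = FALSE)
  denom <- mean(abs(interferent_deltas))
  if (denom == 0)
    stop("selectivity undefined: all interferent responses are zero",
         call. = FALSE)
  abs(target_delta) / denom
}
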