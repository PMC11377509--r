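#' Construct a voltammogram
#'
#' A voltammogram is one cyclic-voltammetry trace: a potential sweep (V)
#' with the recorded current (microamperes) and the scan rate that links
#' the potential axis to time.
#'
#' @param potential Numeric vector of electrode potentials (V), strictly
#'   monotone in either direction, length >= 16.
#' @param current Numeric vector of currents (uA), same length as
#'   `potential`.
#' @param scan_rate Scan rate (V/s), > 0. Default 0.05 (50 mV/s).
#' @param meta Named list of sample metadata (e.g. `sample_id`,
#'   `biomarker`, `concentration`, `label`). Optional.
#' @return An object of class `voltammogram`: a list with elements
#'   `potential`, `current`, `scan_rate`, `meta`.
#' @examples
#' E <- seq(-0.05, -0.45, length.out = 64)
#' vg <- voltammogram(E, 0.2 + exp(-(E + 0.25)^2 / (2 * 0.05^2)))
#' vg
#' @export
voltammogram <- function(potential, current, scan_rate = 0.05, meta = list()) {
  vg <- structure(
    list(potential = as.numeric(potential), current = as.numeric(current),
         scan_rate = scan_rate, meta = meta),
    class = "voltammogram"
  )
  validate_voltammogram(vg)
  vg
}

#' Validate a voltammogram
#'
#' Checks the structural invariants of a CV trace: equal-length finite
#' series of at least 16 samples, strictly monotone potential and a
#' positive scan rate. Called by every feature-extraction entry point.
#'
#' @param vg A `voltammogram`.
#' @return `vg`, invisibly, if valid; otherwise an error naming every
#'   violated invariant.
#' @export
validate_voltammogram <- function(vg) {
  problems <- character(0)
  E <- vg$potential
  I <- vg$current
  if (length(E) != length(I))
    problems <- c(problems, sprintf(
      "potential and current lengths differ (%d vs %d)", length(E), length(I)))
  if (length(E) < 16)
    problems <- c(problems, sprintf("fewer than 16 samples (%d)", length(E)))
  if (!all(is.finite(E)) || !all(is.finite(I))) {
    bad <- which(!is.finite(E) | !is.finite(I))
    problems <- c(problems, sprintf("non-finite values at rows %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(E) >= 2 && all(is.finite(E))) {
    d <- diff(E)
    if (!(all(d > 0) || all(d < 0)))
      problems <- c(problems, "potential is not strictly monotone")
  }
  if (!is.numeric(vg$scan_rate) || length(vg$scan_rate) != 1 ||
      !is.finite(vg$scan_rate) || vg$scan_rate <= 0)
    problems <- c(problems, "scan_rate must be a single positive number")
  if (length(problems))
    stop("invalid voltammogram: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(vg)
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("<voltammogram> %d points, E in [%.4g, %.4g] V, scan rate %g V/s\n",
              length(x$potential), min(x$potential), max(x$potential),
              x$scan_rate))
  if (length(x$meta)) {
    kv <- vapply(names(x$meta), function(k)
      sprintf("%s=%s", k, format(x$meta[[k]])), character(1))
    cat("  meta:", paste(kv, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a voltammogram from CSV
#'
#' The on-disk dialect is a plain CSV with numeric columns `potential_V`
#' and `current_uA`, optionally preceded by metadata header lines of the
#' form `#key=value` (`scan_rate` is recognised and parsed as a number;
#' all other keys land in `meta`).
#'
#' @param path Path to the CSV file.
#' @return A `voltammogram`.
#' @seealso [write_voltammogram()]
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      key <- substr(kv, 1, eq - 1)
      val <- substr(kv, eq + 1, nchar(kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!is_meta]
  if (length(body) < 2) stop("parse error: no data rows in ", path, call. = FALSE)
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  for (col in c("potential_V", "current_uA"))
    if (!col %in% names(df))
      stop("parse error: missing column '", col, "' in ", path, call. = FALSE)
  for (col in c("potential_V", "current_uA")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop(sprintf("parse error: non-numeric cell in column '%s', row %d",
                   col, bad[1]), call. = FALSE)
    }
  }
  if (nrow(df) < 16)
    stop(sprintf("parse error: fewer than 16 samples (%d rows)", nrow(df)),
         call. = FALSE)
  scan_rate <- if (!is.null(meta$scan_rate)) meta$scan_rate else 0.05
  meta$scan_rate <- NULL
  voltammogram(df$potential_V, df$current_uA, scan_rate = scan_rate, meta = meta)
}

#' Write a voltammogram to CSV
#'
#' Inverse of [read_voltammogram()]: emits `#key=value` metadata lines
#' (including `scan_rate`) followed by the `potential_V,current_uA`
#' table at full double precision, so a write-read round trip is exact.
#'
#' @param vg A `voltammogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(vg, path) {
  validate_voltammogram(vg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#scan_rate=%s", format(vg$scan_rate, digits = 17)), con)
  for (k in names(vg$meta))
    writeLines(sprintf("#%s=%s", k, format(vg$meta[[k]], digits = 17)), con)
  writeLines("potential_V,current_uA", con)
  writeLines(paste(format(vg$potential, digits = 17, trim = TRUE),
                   format(vg$current, digits = 17, trim = TRUE), sep = ","), con)
  invisible(path)
}
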