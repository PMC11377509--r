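## md5 of the packaged cohort transcription; guards against silent
## edits of the fixture.
.cohort_md5 <- "f3a71c15a322e56e7658cca2cb43c5c0"

#' Load the packaged clinical cohort
#'
#' Returns the 17 malignant-mammary-tumor cases plus one healthy
#' control, transcribed from the study's clinical and histopathology
#' tables: age, breed, weight, tumor location (side and mammary lobe
#' 3/4/5), TNM staging parsed from strings such as `"R5/T1N0M0"`,
#' histological grade I-III, superficial inguinal lymph node (SILN)
#' metastasis and MUC-1 immunohistochemistry score 0-3. The fixture's
#' md5 checksum is verified on load.
#'
#' @param path Optional override of the fixture path (used in tests;
#'   skips the checksum when pointing elsewhere).
#' @return Data frame of class `clinical_cohort`, 18 rows (17 cases +
#'   1 control, flagged by `is_control`).
#' @export
load_packaged_cohort <- function(path = NULL) {
  checked <- is.null(path)
  if (is.null(path))
    path <- system.file("extdata", "clinical_cohort.csv",
                        package = "voltsense", mustWork = TRUE)
  if (checked) {
    sum <- unname(tools::md5sum(path))
    if (!identical(sum, .cohort_md5))
      stop("cohort fixture integrity error: checksum mismatch (", sum, ")",
           call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tum <- df[!df$is_control, ]
  stopifnot(
    all(tum$lobe %in% 3:5), all(tum$t_stage %in% 1:2),
    all(tum$n_stage %in% 0:1), all(tum$m_stage %in% 0:1),
    all(tum$grade %in% 1:3), all(tum$muc1_score %in% 0:3),
    all(tum$n_stage == tum$siln_metastasis)
  )
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' Encode the cohort as a numeric analysis matrix
#'
#' Default coding for the rank-correlation analysis: location = mammary
#' lobe number (3/4/5, increasingly caudal), size = T stage (1/2),
#' lymph node = N (0/1), lung = M (0/1), MUC-1 = immunohistochemistry
#' score (0-3), grade = 1-3. The control animal carries no staging and
#' is excluded by default.
#'
#' @param records A `clinical_cohort` data frame.
#' @param coding Coding scheme; only `"default"` is defined.
#' @param include_control Keep the control row (default FALSE).
#' @return Numeric matrix with columns `location`, `size`,
#'   `lymph_node`, `lung`, `muc1`, `grade`.
#' @export
encode_cohort <- function(records, coding = "default",
                          include_control = FALSE) {
  if (!identical(coding, "default"))
    stop("unknown coding '", coding, "'; available: default", call. = FALSE)
  if (!include_control) records <- records[!records$is_control, ]
  cbind(location = records$lobe, size = records$t_stage,
        lymph_node = records$n_stage, lung = records$m_stage,
        muc1 = records$muc1_score, grade = records$grade)
}

#' Spearman rank correlation with tie handling
#'
#' Assigns average ranks to ties, computes rho as the Pearson
#' correlation of the rank vectors, and obtains a two-sided p-value
#' from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom (the large-sample t approximation). An exact permutation
#' p-value is available for small samples. The significance label
#' follows the convention NS (p > 0.05), `+` (p <= 0.05), `++`
#' (p <= 0.01).
#'
#' @param x,y Numeric vectors of equal length n >= 3; neither constant.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param seed Seed for the permutation draw.
#' @return List of class `spearman_cor`: `rho`, `p_value`, `n`,
#'   `label`.
#' @examples
#' spearman_test(c(1, 2, 2, 3, 5), c(2, 1, 4, 4, 5))
#' @export
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 10000, seed = 1) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    p <- with_seed(seed, {
      obs <- abs(rho)
      hits <- sum(replicate(n_perm,
        abs(stats::cor(rank(x), rank(sample(y)))) >= obs - 1e-12))
      (hits + 1) / (n_perm + 1)
    })
  }
  structure(list(rho = rho, p_value = p, n = n,
                 label = significance_label(p)),
            class = "spearman_cor")
}

significance_label <- function(p) {
  if (p <= 0.01) "++" else if (p <= 0.05) "+" else "NS"
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.3f (n = %d) %s\n",
              x$rho, x$p_value, x$n, x$label))
  invisible(x)
}

#' Clinical variables versus tumor grade
#'
#' Runs [spearman_test()] of each encoded clinical variable (location,
#' size, lymph-node metastasis, lung metastasis, MUC-1 expression)
#' against histological grade, reporting rho and the two-sided p-value
#' rounded to 3 decimals with significance labels. The control animal
#' is excluded.
#'
#' @param records A `clinical_cohort` data frame (defaults to the
#'   packaged cohort).
#' @param coding Coding scheme passed to [encode_cohort()].
#' @return Data frame with columns `variable`, `rho`, `p_value`, `n`,
#'   `label`, one row per clinical variable.
#' @examples
#' \donttest{correlation_table(load_packaged_cohort())}
#' @export
correlation_table <- function(records = load_packaged_cohort(),
                              coding = "default") {
  m <- encode_cohort(records, coding = coding)
  vars <- setdiff(colnames(m), "grade")
  rows <- lapply(vars, function(v) {
    r <- spearman_test(m[, v], m[, "grade"])
    data.frame(variable = v, rho = round(r$rho, 3),
               p_value = round(r$p_value, 3), n = r$n, label = r$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Descriptive summary of the cohort
#'
#' Arithmetic mean and n-1 standard deviation of age and weight,
#' medians, counts per mammary lobe, grade distribution, SILN-positive
#' count and number of MUC-1-stained tumors (score > 0). The control
#' animal is excluded throughout.
#'
#' @param records A `clinical_cohort` data frame.
#' @return List of class `cohort_summary`.
#' @export
cohort_summary <- function(records = load_packaged_cohort()) {
  tum <- records[!records$is_control, ]
  if (nrow(tum) < 1) stop("empty cohort", call. = FALSE)
  lobe_counts <- table(factor(tum$lobe, levels = c(5, 4, 3)))
  structure(list(
    n = nrow(tum),
    age_mean = mean(tum$age_years), age_sd = stats::sd(tum$age_years),
    age_median = stats::median(tum$age_years),
    weight_mean = mean(tum$weight_kg), weight_sd = stats::sd(tum$weight_kg),
    lobe_counts = c(inguinal = unname(lobe_counts["5"]),
                    caudoabdominal = unname(lobe_counts["4"]),
                    cranioabdominal = unname(lobe_counts["3"])),
    grade_counts = table(factor(tum$grade, levels = 1:3)),
    siln_positive = sum(tum$siln_metastasis),
    muc1_stained = sum(tum$muc1_score > 0)
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d tumor cases\n", x$n))
  cat(sprintf("  age:    %.2f +/- %.2f years (median %g)\n",
              x$age_mean, x$age_sd, x$age_median))
  cat(sprintf("  weight: %.2f +/- %.2f kg\n", x$weight_mean, x$weight_sd))
  cat(sprintf("  lobes:  inguinal %d, caudoabdominal %d, cranioabdominal %d\n",
              x$lobe_counts["inguinal"], x$lobe_counts["caudoabdominal"],
              x$lobe_counts["cranioabdominal"]))
  cat(sprintf("  grades I/II/III: %s\n", paste(x$grade_counts, collapse = "/")))
  cat(sprintf("  SILN-positive: %d; MUC-1-stained tumors: %d\n",
              x$siln_positive, x$muc1_stained))
  invisible(x)
}
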