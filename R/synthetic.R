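## Seeded evaluation that leaves the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Parametric model of one synthetic CV trace
#'
#' Describes a single-sweep voltammogram as a linear baseline plus one
#' redox peak plus i.i.d. Gaussian noise. Defaults mirror a typical
#' immunosensor run: a sweep from -0.05 V to -0.45 V at 50 mV/s sampled
#' at 256 points, with the redox peak near the middle of the window.
#'
#' @param baseline_intercept Baseline current at E = 0 (uA).
#' @param baseline_slope Baseline slope (uA/V).
#' @param peak_center Peak potential (V).
#' @param peak_sd Peak width parameter sigma (V), > 0.
#' @param peak_amplitude Peak height above baseline (uA).
#' @param noise_sd Standard deviation of additive Gaussian noise (uA),
#'   >= 0.
#' @param n_points Number of samples along the sweep, >= 16.
#' @param e_start,e_end Sweep limits (V); must differ.
#' @param scan_rate Scan rate (V/s), > 0.
#' @param peak_shape `"gaussian"` (default) for a symmetric peak or
#'   `"emg"` for an exponentially modified Gaussian, whose skew lets
#'   shape descriptors (skewness, kurtosis) carry class signal.
#' @param emg_tau Exponential tail constant (V) for the `"emg"` shape.
#' @return Object of class `peak_model`.
#' @export
peak_model <- function(baseline_intercept = 0.2, baseline_slope = -0.5,
                       peak_center = -0.25, peak_sd = 0.045,
                       peak_amplitude = 1, noise_sd = 0.02,
                       n_points = 256, e_start = -0.05, e_end = -0.45,
                       scan_rate = 0.05,
                       peak_shape = c("gaussian", "emg"), emg_tau = 0.03) {
  peak_shape <- match.arg(peak_shape)
  m <- structure(
    list(baseline_intercept = baseline_intercept,
         baseline_slope = baseline_slope,
         peak_center = peak_center, peak_sd = peak_sd,
         peak_amplitude = peak_amplitude, noise_sd = noise_sd,
         n_points = as.integer(n_points), e_start = e_start, e_end = e_end,
         scan_rate = scan_rate, peak_shape = peak_shape, emg_tau = emg_tau),
    class = "peak_model"
  )
  validate_peak_model(m)
  m
}

validate_peak_model <- function(m) {
  problems <- character(0)
  if (!is.finite(m$peak_sd) || m$peak_sd <= 0)
    problems <- c(problems, "peak_sd must be > 0")
  if (m$n_points < 16)
    problems <- c(problems, "n_points must be >= 16")
  if (m$e_start == m$e_end)
    problems <- c(problems, "e_start and e_end must differ")
  if (!is.finite(m$scan_rate) || m$scan_rate <= 0)
    problems <- c(problems, "scan_rate must be > 0")
  if (!is.finite(m$noise_sd) || m$noise_sd < 0)
    problems <- c(problems, "noise_sd must be >= 0")
  if (length(problems))
    stop("invalid peak_model: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(m)
}

#' Linear dose-response parameters of the sensor
#'
#' Maps biomarker concentration to redox-peak amplitude: a straight
#' line over the linear window, saturating at its boundary values
#' outside it. Defaults put the linear range at 5-100 U/mL, the span
#' the sensor resolves.
#'
#' @param intercept Amplitude at zero concentration (uA).
#' @param slope Amplitude gain (uA per U/mL); must be finite.
#' @param linear_min,linear_max Bounds of the linear window (U/mL),
#'   `linear_min < linear_max`.
#' @return Object of class `response_params`.
#' @export
response_params <- function(intercept = 0.1, slope = 0.004,
                            linear_min = 5, linear_max = 100) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  if (!(linear_min < linear_max))
    stop("linear_min must be < linear_max", call. = FALSE)
  structure(list(intercept = intercept, slope = slope,
                 linear_min = linear_min, linear_max = linear_max),
            class = "response_params")
}

#' Peak amplitude at a given biomarker concentration
#'
#' Evaluates the linear dose-response inside the sensor's linear window
#' and clamps to the boundary amplitude outside it (the sensor
#' saturates below and above the window). Monotone non-decreasing in
#' concentration whenever the slope is positive. Vectorised over
#' `concentration`.
#'
#' @param concentration Concentration(s) in U/mL, >= 0.
#' @param params A [response_params()] object.
#' @return Peak amplitude(s) in uA.
#' @export
concentration_to_peak <- function(concentration, params) {
  stopifnot(inherits(params, "response_params"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  c_eff <- pmin(pmax(concentration, params$linear_min), params$linear_max)
  params$intercept + params$slope * c_eff
}

peak_profile <- function(E, m, amplitude) {
  z <- (E - m$peak_center)
  if (m$peak_shape == "gaussian") {
    amplitude * exp(-z^2 / (2 * m$peak_sd^2))
  } else {
    # exponentially modified Gaussian, tail toward increasing index of
    # the sweep; normalised so the mode height is ~amplitude
    tau <- m$emg_tau
    sgn <- sign(m$e_end - m$e_start)
    u <- sgn * z
    h <- (m$peak_sd / tau) * sqrt(pi / 2) *
      exp(0.5 * (m$peak_sd / tau)^2 - u / tau) *
      pracma::erfc((m$peak_sd / tau - u / m$peak_sd) / sqrt(2))
    amplitude * h / max(h)
  }
}

#' Simulate one voltammogram
#'
#' Generates a single linear sweep from `e_start` to `e_end`:
#' `current(E) = baseline_intercept + baseline_slope * E + peak + noise`,
#' where the peak is Gaussian (or exponentially modified Gaussian) with
#' the model's centre, width and amplitude, and the noise is i.i.d.
#' Gaussian. The same `(model, seed)` pair reproduces a bit-identical
#' trace; the caller's RNG stream is left untouched.
#'
#' @param model A [peak_model()].
#' @param seed Integer seed.
#' @return A `voltammogram` whose `meta` records the seed.
#' @export
simulate_voltammogram <- function(model, seed = 1) {
  validate_peak_model(model)
  E <- seq(model$e_start, model$e_end, length.out = model$n_points)
  signal <- model$baseline_intercept + model$baseline_slope * E +
    peak_profile(E, model, model$peak_amplitude)
  noise <- if (model$noise_sd > 0)
    with_seed(seed, stats::rnorm(model$n_points, sd = model$noise_sd))
  else rep(0, model$n_points)
  voltammogram(E, signal + noise, scan_rate = model$scan_rate,
               meta = list(seed = seed))
}

#' Class specification for labelled simulation
#'
#' Ties a class label (e.g. control or a histological grade) to a
#' concentration distribution: concentrations are drawn lognormally
#' with median `concentration_mean` and coefficient of variation
#' `concentration_cv`, then passed through the dose-response to set
#' each trace's peak amplitude. `nuisance_jitter` perturbs the peak
#' centre, peak width and baseline fractionally per trace, emulating
#' electrode-to-electrode variability that carries no class signal.
#'
#' @param label Class label (character).
#' @param concentration_mean Median concentration (U/mL), >= 0.
#' @param concentration_cv Coefficient of variation (>= 0; 0 means all
#'   members share the exact concentration).
#' @param nuisance_jitter Fractional perturbation applied to
#'   peak_center, peak_sd and baseline terms (>= 0).
#' @return Object of class `class_spec`.
#' @export
class_spec <- function(label, concentration_mean, concentration_cv = 0.25,
                       nuisance_jitter = 0.05) {
  if (concentration_mean < 0) stop("concentration_mean must be >= 0",
                                   call. = FALSE)
  if (concentration_cv < 0) stop("concentration_cv must be >= 0",
                                 call. = FALSE)
  structure(list(label = as.character(label),
                 concentration_mean = concentration_mean,
                 concentration_cv = concentration_cv,
                 nuisance_jitter = nuisance_jitter),
            class = "class_spec")
}

#' Study-like class specifications
#'
#' Default grade-to-concentration mapping used by the synthetic
#' benchmark: a control class below the sensor's linear window and
#' three tumor grades with increasing median biomarker concentration
#' (15, 45, 85 U/mL), moderate biological spread (CV 0.25) and mild
#' electrode jitter.
#'
#' @param include_control Include the control class (default TRUE).
#' @return List of [class_spec()] objects.
#' @export
grade_class_specs <- function(include_control = TRUE) {
  specs <- list(
    class_spec("grade_I", 15),
    class_spec("grade_II", 45),
    class_spec("grade_III", 85)
  )
  if (include_control)
    specs <- c(list(class_spec("control", 2)), specs)
  specs
}

#' Simulate a labelled voltammogram dataset
#'
#' Draws `n_per_class` traces per class: each trace's concentration
#' comes from its class distribution, is mapped to a peak amplitude by
#' [concentration_to_peak()], and the trace is generated from a
#' jittered copy of `base_model`. Reproducible per seed.
#'
#' @param class_specs List of [class_spec()] objects (>= 2 classes).
#' @param n_per_class Traces per class, >= 1.
#' @param params A [response_params()].
#' @param base_model A [peak_model()]; its `peak_amplitude` is
#'   overridden per trace.
#' @param seed Integer seed.
#' @return List with `voltammograms` (list), `labels` (factor),
#'   `concentrations` (numeric).
#' @export
simulate_labeled_dataset <- function(class_specs, n_per_class,
                                     params = response_params(),
                                     base_model = peak_model(),
                                     seed = 1) {
  if (length(class_specs) < 2)
    stop("at least 2 classes are required", call. = FALSE)
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  stopifnot(all(vapply(class_specs, inherits, logical(1), "class_spec")))
  with_seed(seed, {
    vgs <- list(); labels <- character(0); concs <- numeric(0)
    for (cs in class_specs) {
      for (i in seq_len(n_per_class)) {
        conc <- if (cs$concentration_cv == 0) cs$concentration_mean else {
          sdlog <- sqrt(log(1 + cs$concentration_cv^2))
          stats::rlnorm(1, meanlog = log(max(cs$concentration_mean,
                                             .Machine$double.eps)),
                        sdlog = sdlog)
        }
        amp <- concentration_to_peak(conc, params)
        j <- cs$nuisance_jitter
        jit <- function(x) x * (1 + stats::runif(1, -j, j))
        m <- base_model
        m$peak_center <- jit(m$peak_center)
        m$peak_sd <- jit(m$peak_sd)
        m$baseline_intercept <- jit(m$baseline_intercept)
        m$baseline_slope <- jit(m$baseline_slope)
        m$peak_amplitude <- amp
        trace_seed <- stats::runif(1, 1, 2^31 - 1)
        vgs[[length(vgs) + 1L]] <- simulate_voltammogram(m, seed = trace_seed)
        vgs[[length(vgs)]]$meta$label <- cs$label
        vgs[[length(vgs)]]$meta$concentration <- conc
        labels <- c(labels, cs$label)
        concs <- c(concs, conc)
      }
    }
    list(voltammograms = vgs,
         labels = factor(labels, levels = unique(labels)),
         concentrations = concs)
  })
}

#' Simulate a clinical cohort
#'
#' Generates records with the structure of the packaged cohort: grade
#' 1-3, mammary lobe 3-5, tumor size stage 1-2, nodal and lung
#' metastasis 0/1 and MUC-1 immunohistochemistry score 0-3. Each
#' variable can be coupled monotonically to grade through a Gaussian
#' copula: with coupling 0 the variable is independent of grade; with
#' coupling near 1 it is almost a monotone function of grade.
#'
#' @param n Number of records, >= 3.
#' @param assoc Named list of couplings in [0, 1) for any of
#'   `location`, `size`, `lymph_node`, `lung`, `muc1`. Missing entries
#'   default to 0.
#' @param seed Integer seed.
#' @return Data frame with columns `case_id`, `age_years`, `weight_kg`,
#'   `lobe`, `t_stage`, `n_stage`, `m_stage`, `grade`,
#'   `siln_metastasis`, `muc1_score`.
#' @export
simulate_cohort <- function(n, assoc = list(), seed = 1) {
  if (n < 3) stop("n must be >= 3", call. = FALSE)
  a <- function(key) {
    v <- if (is.null(assoc[[key]])) 0 else assoc[[key]]
    if (v < 0 || v >= 1) stop("association for '", key,
                              "' must be in [0, 1)", call. = FALSE)
    v
  }
  ## coupled ordinal draw: latent = a*z_grade + sqrt(1-a^2)*noise,
  ## categorised at the quantiles of the target marginal
  coupled <- function(z, coupling, levels, probs) {
    latent <- coupling * z + sqrt(1 - coupling^2) * stats::rnorm(length(z))
    qs <- stats::qnorm(cumsum(probs)[-length(probs)])
    levels[findInterval(latent, qs) + 1L]
  }
  with_seed(seed, {
    grade <- sample(1:3, n, replace = TRUE, prob = c(0.15, 0.45, 0.40))
    z <- (grade - mean(1:3)) / stats::sd(1:3) +
      stats::rnorm(n, sd = 0.25)  # jitter breaks ties in the latent scale
    lobe <- coupled(z, a("location"), c(3L, 4L, 5L), c(0.2, 0.3, 0.5))
    t_stage <- coupled(z, a("size"), c(1L, 2L), c(0.6, 0.4))
    n_stage <- coupled(z, a("lymph_node"), c(0L, 1L), c(0.65, 0.35))
    m_stage <- coupled(z, a("lung"), c(0L, 1L), c(0.85, 0.15))
    muc1 <- coupled(z, a("muc1"), 0:3, c(0.35, 0.4, 0.15, 0.1))
    data.frame(
      case_id = seq_len(n),
      age_years = pmax(4, round(stats::rnorm(n, 11.2, 1.6))),
      weight_kg = round(pmax(3, stats::rnorm(n, 17.5, 8.2)), 1),
      lobe = lobe, t_stage = t_stage, n_stage = n_stage,
      m_stage = m_stage, grade = grade,
      siln_metastasis = n_stage, muc1_score = muc1
    )
  })
}
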