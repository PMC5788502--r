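#' Regulation model parameters
#'
#' Parameters of the ligand-to-translation dose-effect model. The model is
#' a minimal saturating (Hill/Emax) form: ligand occupancy follows a Hill
#' curve with half-occupancy concentration `K` and coefficient `h`;
#' repression scales a maximal fractional effect `Emax_r`; activation
#' scales a maximal fold-change `Fmax`; and the effect of aptamer valency
#' (1-3 copies per device) saturates with half-saturation constant
#' `kappa`.
#'
#' @param K Ligand concentration at half occupancy (uM), > 0.
#' @param h Hill coefficient, > 0.
#' @param Emax_r Maximal fractional repression, in \[0, 1).
#' @param Fmax Maximal fold-activation, >= 1.
#' @param kappa Valency half-saturation constant (copies), > 0.
#' @return An object of class `regulation_params`.
#' @export
regulation_params <- function(K = 300, h = 1.3, Emax_r = 0.9, Fmax = 15,
                              kappa = 0.5) {
  stopifnot(K > 0, h > 0, Emax_r >= 0, Emax_r < 1, Fmax >= 1, kappa > 0)
  structure(list(K = K, h = h, Emax_r = Emax_r, Fmax = Fmax, kappa = kappa),
            class = "regulation_params")
}

#' @export
print.regulation_params <- function(x, ...) {
  cat(sprintf("regulation params: K = %.4g uM, h = %.3g, Emax_r = %.3g, Fmax = %.3g, kappa = %.3g\n",
              x$K, x$h, x$Emax_r, x$Fmax, x$kappa))
  invisible(x)
}

#' Hill occupancy of the sensor aptamer
#'
#' `theta = L^h / (K^h + L^h)`: 0 at zero ligand, 1/2 at `L = K`,
#' saturating to 1.
#'
#' @param L Ligand concentration (uM), vectorised, >= 0.
#' @param params A [regulation_params()].
#' @return Occupancy in \[0, 1\].
#' @export
occupancy <- function(L, params) {
  stopifnot(all(L >= 0))
  Lh <- L^params$h
  Lh / (params$K^params$h + Lh)
}

#' Valency scaling of the device effect
#'
#' Devices carry 1-3 aptamer copies. Effects rise steeply from one to two
#' copies but saturate between two and three (three-copy devices are only
#' a little stronger than two-copy ones; one-copy devices are much
#' weaker). The raw saturation curve is `c / (c + kappa)`; the normalised
#' scale divides by the two-copy reference and caps at 1, so the standard
#' two-copy device has valency weight exactly 1 and the scaling never
#' pushes an effect beyond its calibrated maximum.
#'
#' @param copies Number of aptamer copies (1-3).
#' @param kappa Half-saturation constant in copy units.
#' @param normalize If `FALSE`, return the raw `c / (c + kappa)` curve.
#' @return Valency weight in (0, 1\].
#' @export
valency_scale <- function(copies, kappa = 0.5, normalize = TRUE) {
  if (!all(copies %in% 1:3)) {
    stop("copies must be 1, 2 or 3", call. = FALSE)
  }
  raw <- copies / (copies + kappa)
  if (!normalize) return(raw)
  pmin(1, raw / (2 / (2 + kappa)))
}

#' Relative expression under roadblock repression
#'
#' `E = 1 - Emax_r * v(copies) * efficacy * theta(L)`: the ligand-aptamer
#' complex obstructs scanning/elongating ribosomes in proportion to sensor
#' occupancy, device efficacy (composite design score) and valency.
#' Expression is 1 (unchanged) without ligand and is floored at
#' `1 - Emax_r`.
#'
#' @param efficacy Device efficacy in (0, 1\] (composite design score).
#' @param copies Aptamer copies (1-3).
#' @param L Ligand concentration (uM), vectorised.
#' @param params A [regulation_params()].
#' @return Relative expression in (0, 1\].
#' @export
repression_output <- function(efficacy, copies, L, params) {
  stopifnot(efficacy >= 0, efficacy <= 1)
  v <- valency_scale(copies, params$kappa)
  1 - params$Emax_r * v * efficacy * occupancy(L, params)
}

#' Fold-activation under eIF4G recruitment
#'
#' `F = 1 + (Fmax - 1) * v(copies) * efficacy * theta_sensor`: tethered
#' initiation-factor aptamers raise translation initiation in proportion
#' to effector valency, device efficacy and the occupancy of the sensing
#' arm (1 for constitutive activator designs).
#'
#' @param efficacy Device efficacy in (0, 1\].
#' @param copies Effector aptamer copies (1-3).
#' @param theta_sensor Sensor occupancy in \[0, 1\] (1 for constitutive
#'   designs), vectorised.
#' @param params A [regulation_params()].
#' @return Fold-change >= 1, bounded by `Fmax`.
#' @export
activation_output <- function(efficacy, copies, theta_sensor, params) {
  stopifnot(efficacy >= 0, efficacy <= 1,
            all(theta_sensor >= 0), all(theta_sensor <= 1))
  v <- valency_scale(copies, params$kappa)
  1 + (params$Fmax - 1) * v * efficacy * theta_sensor
}

#' Simulate a dose-response experiment
#'
#' Generates (dose, response) points from the regulation model, optionally
#' with multiplicative log-normal noise. Used for calibration tests and as
#' the synthetic counterpart of reporter-assay dose series.
#'
#' @param params A [regulation_params()].
#' @param doses Numeric vector of ligand concentrations (uM).
#' @param mode `"repression"` (relative expression) or `"activation"`
#'   (fold-change).
#' @param efficacy,copies Device efficacy and valency.
#' @param noise_sd Standard deviation of multiplicative noise
#'   (`response * exp(rnorm(., 0, noise_sd))`); 0 = noise-free.
#' @return Data frame with columns `dose`, `response`.
#' @export
simulate_dose_response <- function(params, doses,
                                   mode = c("repression", "activation"),
                                   efficacy = 1, copies = 2L, noise_sd = 0) {
  mode <- match.arg(mode)
  resp <- switch(mode,
    repression = repression_output(efficacy, copies, doses, params),
    activation = activation_output(efficacy, copies, occupancy(doses, params),
                                   params))
  if (noise_sd > 0) resp <- resp * exp(stats::rnorm(length(resp), 0, noise_sd))
  data.frame(dose = doses, response = resp)
}

#' Calibrate regulation parameters from dose-response data
#'
#' Least-squares fit of the free Hill/Emax parameters (`K`, `h`, and
#' `Emax_r` or `Fmax` depending on mode) to (dose, response) points. To
#' avoid local minima the fit is deterministic multi-start: a 3 x 3 x 3
#' grid of log-spaced starting values is refined by Levenberg-Marquardt
#' least squares and the best converged fit wins (ties broken by grid
#' order). Residuals are taken on the log scale by default, the
#' appropriate objective for the multiplicative noise of reporter
#' assays.
#'
#' @param points Data frame with columns `dose` (>= 0) and `response`
#'   (> 0); at least 4 points spanning low and high dose.
#' @param mode `"repression"` or `"activation"`.
#' @param fixed Optional named list of parameters to hold fixed (any of
#'   `K`, `h`, `Emax_r`, `Fmax`, `kappa`).
#' @param efficacy,copies Device efficacy and valency assumed during the
#'   fit (defaults: 1 and the 2-copy reference).
#' @param objective Residual scale: `"log"` (default; matched to the
#'   multiplicative noise of reporter assays) or `"linear"`.
#' @return List with `params` ([regulation_params()]), `rmse`,
#'   `residuals`, `converged`, `mode`, `n`.
#' @export
calibrate <- function(points, mode = c("repression", "activation"),
                      fixed = list(), efficacy = 1, copies = 2L,
                      objective = c("log", "linear")) {
  mode <- match.arg(mode)
  objective <- match.arg(objective)
  stopifnot(is.data.frame(points), all(c("dose", "response") %in% names(points)))
  points <- points[order(points$dose), , drop = FALSE]
  if (nrow(points) < 4L) {
    stop("calibration needs at least 4 dose-response points", call. = FALSE)
  }
  if (any(points$dose < 0) || any(points$response <= 0)) {
    stop("doses must be >= 0 and responses > 0", call. = FALSE)
  }
  if (stats::sd(points$response) == 0) {
    stop("all responses are equal: parameters are unidentifiable", call. = FALSE)
  }

  amp_name <- if (mode == "repression") "Emax_r" else "Fmax"
  free <- setdiff(c("K", "h", amp_name), names(fixed))
  kappa <- if (!is.null(fixed$kappa)) fixed$kappa else 0.5
  v <- valency_scale(copies, kappa)

  model_fun <- function(dose, K, h, amp) {
    th <- dose^h / (K^h + dose^h)
    if (mode == "repression") 1 - amp * v * efficacy * th
    else 1 + (amp - 1) * v * efficacy * th
  }

  pos <- points$dose[points$dose > 0]
  K_grid <- exp(seq(log(max(min(pos), 1e-6)), log(max(pos)), length.out = 3))
  h_grid <- c(0.5, 1, 2)
  amp_grid <- if (mode == "repression") c(0.3, 0.6, 0.9) else c(2, 8, 20)
  starts <- expand.grid(K = K_grid, h = h_grid, amp = amp_grid,
                        KEEP.OUT.ATTRS = FALSE)

  lower <- c(K = 1e-9, h = 0.05, amp = if (mode == "repression") 0.001 else 1)
  upper <- c(K = 1e9, h = 10, amp = if (mode == "repression") 0.999 else 1e6)

  # residuals on the log scale by default: reporter noise is multiplicative
  resid_fun <- function(par) {
    full <- list(K = if ("K" %in% free) par$K else fixed$K,
                 h = if ("h" %in% free) par$h else fixed$h,
                 amp = if (amp_name %in% free) par$amp else fixed[[amp_name]])
    pred <- model_fun(points$dose, full$K, full$h, full$amp)
    if (objective == "log") {
      log(points$response) - log(pmax(pred, 1e-12))
    } else {
      points$response - pred
    }
  }

  par_names <- c(free[free %in% c("K", "h")],
                 if (amp_name %in% free) "amp")
  best <- NULL
  for (r in seq_len(nrow(starts))) {
    start <- as.list(starts[r, par_names, drop = FALSE])
    if (length(start) == 0L) break
    fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower[par_names], upper = upper[par_names],
      fn = function(p) resid_fun(p),
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("calibration failed to converge from any starting point", call. = FALSE)
  }

  cf <- best$fit$par
  K <- if ("K" %in% names(cf)) cf$K else fixed$K
  h <- if ("h" %in% names(cf)) cf$h else fixed$h
  amp <- if ("amp" %in% names(cf)) cf$amp else fixed[[amp_name]]
  params <- if (mode == "repression") {
    regulation_params(K = K, h = h, Emax_r = amp, Fmax = 1.0001, kappa = kappa)
  } else {
    regulation_params(K = K, h = h, Emax_r = 0, Fmax = amp, kappa = kappa)
  }
  res <- as.numeric(best$fit$fvec)
  list(params = params, rmse = sqrt(mean(res^2)), residuals = res,
       converged = best$fit$info %in% 1:4, mode = mode, n = nrow(points))
}

#' Load packaged device parameter sets
#'
#' The package ships calibrated parameter sets for its standard devices
#' (theophylline and tetracycline repressors, the two-copy eIF4G
#' activator, and protein-sensing connectors used in network scenarios) in
#' `extdata/device_params.json`.
#'
#' @param name Parameter-set name; call with `name = NULL` to list the
#'   available sets.
#' @return A [regulation_params()] (or a character vector of names).
#' @export
load_device_params <- function(name = NULL) {
  path <- system.file("extdata", "device_params.json", package = "sigcon")
  sets <- jsonlite::read_json(path)
  if (is.null(name)) return(names(sets))
  if (!name %in% names(sets)) {
    stop("unknown parameter set '", name, "'; available: ",
         paste(names(sets), collapse = ", "), call. = FALSE)
  }
  p <- sets[[name]]
  regulation_params(K = p$K, h = p$h, Emax_r = p$Emax_r, Fmax = p$Fmax,
                    kappa = p$kappa)
}

#' Identifiability-oriented dose design for calibration
#'
#' A 20-point dose panel for parameter recovery: anchors at zero ligand
#' and deep saturation plus duplicated log-spaced doses across the
#' transition region (`K/4` to `4K`), where the Hill coefficient is
#' identified.
#'
#' @param K Expected half-occupancy concentration (uM).
#' @param n Total number of doses (default 20).
#' @return Numeric vector of doses.
#' @export
dose_design <- function(K = 300, n = 20L) {
  n <- as.integer(n)
  stopifnot(n >= 6L)
  n_trans <- n - 2L
  reps <- exp(seq(log(K / 4), log(4 * K), length.out = ceiling(n_trans / 2)))
  doses <- c(0, K * 40 / 3, rep(reps, 2L)[seq_len(n_trans)])
  sort(doses)
}
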