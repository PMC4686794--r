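#' @include AllClasses.R
NULL

# Gas constant in kcal/(mol K); 25 C binding buffer -> 298.15 K default.
R_KCAL <- 1.987e-3

#' Observed pseudo-first-order rate
#'
#' Under probe excess the approach to equilibrium is single-exponential with
#' rate `k_obs = ka * L + kd`, linear in the probe concentration `L`.
#'
#' @param ka association rate constant, 1/(M s), > 0.
#' @param kd dissociation rate constant, 1/s, >= 0.
#' @param concentration probe concentration, mol/L, >= 0.
#' @return k_obs in 1/s.
#' @export
kObs <- function(ka, kd, concentration) {
  if (any(ka <= 0)) stop("ka must be > 0")
  if (any(kd < 0)) stop("kd must be >= 0")
  if (any(concentration < 0)) stop("concentration must be >= 0")
  ka * concentration + kd
}

#' Noiseless association time course
#'
#' Pseudo-first-order association of a trace receptor with probe in excess:
#' `signal(t) = amplitude * L/(L + kd/ka) * (1 - exp(-(ka L + kd) t))`.
#' Starts at 0, rises monotonically to the equilibrium plateau
#' `amplitude * L/(L + KD)`.
#'
#' @inheritParams kObs
#' @param amplitude signal per unit bound fraction.
#' @param times nonnegative times, seconds.
#' @param receptor optional receptor concentration (mol/L); when given and
#'   the probe is in less than 10-fold excess, a warning flags that the
#'   pseudo-first-order regime is strained.
#' @return Numeric signals, same length as `times`.
#' @export
associationCurve <- function(ka, kd, concentration, amplitude, times,
                             receptor = NULL) {
  if (any(times < 0)) stop("negative time")
  if (kd < 0 || ka <= 0 || concentration < 0) stop("negative rate or concentration")
  if (!is.null(receptor) && concentration < 10 * receptor)
    warning("probe less than 10-fold over receptor: pseudo-first-order assumption strained")
  plateau <- amplitude * concentration / (concentration + kd / ka)
  plateau * (1 - exp(-kObs(ka, kd, concentration) * times))
}

#' Simulate one noisy association time course
#'
#' [associationCurve()] values plus independent Gaussian noise; reproducible
#' for a fixed seed. The caller's RNG state is left untouched.
#'
#' @inheritParams associationCurve
#' @param noise_sd Gaussian noise standard deviation (signal units), >= 0.
#' @param seed integer seed.
#' @param label curve label.
#' @return data.frame with columns label, conc, time, signal (conc in mol/L,
#'   time in s) and attribute `noise_sd`.
#' @export
simulateTimeCourse <- function(ka, kd, concentration, amplitude, times,
                               noise_sd, seed, label = "sim") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- associationCurve(ka, kd, concentration, amplitude, times)
  noise <- withPreservedSeed(seed, stats::rnorm(length(times), 0, noise_sd))
  out <- data.frame(label = label, conc = concentration, time = times,
                    signal = mu + noise, stringsAsFactors = FALSE)
  attr(out, "noise_sd") <- noise_sd
  out
}

withPreservedSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a multi-concentration association experiment
#'
#' One noisy curve per probe concentration with a shared amplitude, the
#' layout of the gel-shift association assays (default: 10/20/40/60 nM
#' probe, 12 time points to 3 h). Noise per curve uses `seed`, `seed + 1`,
#' ... so curves are independent yet reproducible.
#'
#' @inheritParams simulateTimeCourse
#' @param concentrations probe concentrations, mol/L.
#' @param times sampling times, seconds.
#' @param noise_frac noise sd as a fraction of the largest plateau.
#' @return data.frame of all curves (label, conc, time, signal), attribute
#'   `noise_sd` carrying the common absolute noise sd.
#' @export
simulateExperiment <- function(ka, kd,
                               concentrations = c(10, 20, 40, 60) * 1e-9,
                               amplitude = 1,
                               times = seq(0, 10800, length.out = 12),
                               noise_frac = 0.02, seed = 1) {
  plateau_max <- amplitude * max(concentrations) /
    (max(concentrations) + kd / ka)
  noise_sd <- noise_frac * plateau_max
  curves <- lapply(seq_along(concentrations), function(i)
    simulateTimeCourse(ka, kd, concentrations[i], amplitude, times, noise_sd,
                       seed = seed + i - 1L,
                       label = sprintf("conc_%g_nM", concentrations[i] * 1e9)))
  out <- do.call(rbind, curves)
  attr(out, "noise_sd") <- noise_sd
  out
}

#' Derive equilibrium constants from rate constants
#'
#' The apparent dissociation constant `K*D = kd/ka`, the complex half-life
#' `t1/2 = ln 2 / kd`, and the binding free energy magnitude
#' `-dG = -R T ln K*D` (R = 1.987e-3 kcal/(mol K), KD in mol/L, standard
#' state 1 M).
#'
#' @inheritParams kObs
#' @param temperature kelvin; default 298.15 (the 25 C binding buffer).
#' @return Named numeric: `kStarD` (mol/L), `tHalf` (s), `minusDeltaG`
#'   (kcal/mol).
#' @examples
#' deriveConstants(2.3e3, 1.8e-4)  # ~78 nM, ~64 min, ~9.7 kcal/mol
#' @export
deriveConstants <- function(ka, kd, temperature = 298.15) {
  if (ka <= 0 || kd <= 0 || temperature <= 0)
    stop("ka, kd and temperature must be positive")
  kStarD <- kd / ka
  c(kStarD = kStarD,
    tHalf = log(2) / kd,
    minusDeltaG = -R_KCAL * temperature * log(kStarD))
}

#' Globally fit association kinetics across concentrations
#'
#' Nonlinear least squares over all curves jointly with shared `ka`, `kd`
#' and (by default) a shared signal amplitude. Bounded Levenberg-Marquardt
#' with a deterministic initialization: `kd0 = 1e-4` 1/s and `ka0` from the
#' slope of a crude per-curve single-exponential `k_obs` vs concentration
#' prefit. Standard errors come from the fit covariance.
#'
#' @param timecourses data.frame with columns label, conc (mol/L), time (s),
#'   signal; one label per curve, at least two distinct concentrations and
#'   five points per curve.
#' @param temperature kelvin, for the derived free energy.
#' @param sharedAmplitude fit one amplitude across curves (default) or one
#'   per curve.
#' @return A [KineticsFit-class].
#' @export
fitKinetics <- function(timecourses, temperature = 298.15,
                        sharedAmplitude = TRUE) {
  tc <- as.data.frame(timecourses)
  need <- c("label", "conc", "time", "signal")
  if (!all(need %in% names(tc)))
    stop("timecourses needs columns: ", paste(need, collapse = ", "))
  tc$label <- as.character(tc$label)
  curves <- split(tc, tc$label)
  if (length(unique(tc$conc)) < 2L)
    stop("at least two distinct concentrations are needed to separate ka from kd")
  if (any(vapply(curves, nrow, 0L) < 5L))
    stop("each curve needs at least 5 time points")
  if (all(abs(tc$signal) < .Machine$double.eps))
    stop("all signals are zero: no binding to fit")

  # crude prefit: per-curve single-exponential k_obs, then slope over conc
  kobs0 <- vapply(curves, function(cv) crudeKobs(cv$time, cv$signal), 0)
  conc0 <- vapply(curves, function(cv) cv$conc[1], 0)
  ka0 <- tryCatch({
    sl <- stats::coef(stats::lm(kobs0 ~ conc0))[[2]]
    min(max(sl, 1), 1e9)
  }, error = function(e) 1e6)
  kd0 <- 1e-4
  amp0 <- max(tc$signal) * (max(conc0) + kd0 / ka0) / max(conc0)

  lower <- c(log(1), log(1e-7), rep(-Inf, if (sharedAmplitude) 1L else length(curves)))
  upper <- c(log(1e9), log(1), rep(Inf, if (sharedAmplitude) 1L else length(curves)))
  start <- c(lka = log(ka0), lkd = log(kd0),
             stats::setNames(rep(log(max(amp0, 1e-12)),
                                 if (sharedAmplitude) 1L else length(curves)),
                             if (sharedAmplitude) "lamp"
                             else paste0("lamp", seq_along(curves))))

  idx <- match(tc$label, names(curves))
  predict_all <- function(p) {
    ka <- exp(p[["lka"]]); kd <- exp(p[["lkd"]])
    amps <- exp(p[-(1:2)])
    a <- if (sharedAmplitude) rep(amps[1], nrow(tc)) else amps[idx]
    a * tc$conc / (tc$conc + kd / ka) *
      (1 - exp(-(ka * tc$conc + kd) * tc$time))
  }
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) tc$signal - predict_all(p),
    lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500))
  if (fit$info == 0 || fit$info == 9)
    stop("kinetics fit did not converge (info ", fit$info, ", ",
         fit$niter, " iterations): ", fit$message)
  p <- fit$par
  ka <- exp(p[["lka"]]); kd <- exp(p[["lkd"]])
  amps <- exp(unlist(p[-(1:2)]))
  nobs <- nrow(tc); npar <- length(start)
  sigma2 <- fit$deviance / max(1L, nobs - npar)
  covm <- tryCatch(sigma2 * chol2inv(chol(fit$hessian / 2)),
                   error = function(e) matrix(NA_real_, npar, npar))
  se_log <- sqrt(pmax(diag(covm), 0))
  # delta method back from the log scale
  se <- c(ka = ka * se_log[1], kd = kd * se_log[2],
          amplitude = unname(amps[1] * se_log[3]))
  new("KineticsFit", ka = ka, kd = kd, amplitude = unname(amps[1]),
      se = se, temperature = temperature,
      derived = deriveConstants(ka, kd, temperature),
      diagnostics = list(residual_sd = sqrt(sigma2), iterations = fit$niter,
                         n_points = nobs, n_curves = length(curves),
                         shared_amplitude = sharedAmplitude,
                         per_curve_amplitudes = unname(amps),
                         info = fit$info, message = fit$message))
}

# single-exponential rate guess for one curve: time to reach 1 - 1/e of the
# top signal, robust to noise via the first crossing of a smoothed curve
crudeKobs <- function(time, signal) {
  top <- max(signal)
  if (top <= 0) return(1e-4)
  target <- top * (1 - exp(-1))
  above <- which(signal >= target & time > 0)
  if (!length(above)) return(1 / max(time[time > 0]))
  1 / time[above[1]]
}

#' Two-species association kinetics by numerical integration
#'
#' Exact mass-action model `d[C]/dt = ka (L0 - C)(R0 - C) - kd C` without
#' the probe-excess approximation, integrated with `deSolve::lsoda`.
#' Exposed for checking when the pseudo-first-order regime (trace receptor,
#' probe excess) is adequate.
#'
#' @inheritParams kObs
#' @param receptor total receptor concentration R0, mol/L.
#' @param times seconds.
#' @return data.frame with columns time and bound (complex concentration,
#'   mol/L).
#' @export
twoSpeciesCurve <- function(ka, kd, concentration, receptor, times) {
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("the exact two-species mode needs the deSolve package")
  deriv <- function(t, y, parms)
    list(ka * (concentration - y[1]) * (receptor - y[1]) - kd * y[1])
  out <- deSolve::lsoda(c(C = 0), times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-14)
  data.frame(time = out[, "time"], bound = out[, "C"])
}

#' Read / write time-course tables
#'
#' CSV dialect `label,conc_nM,time_s,signal`; concentrations convert to
#' mol/L on read and back to nM on write.
#'
#' @param path CSV file.
#' @return data.frame with columns label, conc, time, signal.
#' @export
readTimeCourses <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "conc_nM", "time_s", "signal")
  if (!all(need %in% names(df)))
    stop("time-course CSV must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(label = as.character(df$label),
                    conc = df$conc_nM * 1e-9,
                    time = df$time_s, signal = df$signal,
                    stringsAsFactors = FALSE)
  for (cv in split(out, out$label))
    if (is.unsorted(cv$time, strictly = TRUE))
      stop("times must be strictly increasing within curve '", cv$label[1], "'")
  if (any(out$conc <= 0)) stop("concentrations must be positive")
  out
}

#' @rdname readTimeCourses
#' @param timecourses data.frame with columns label, conc, time, signal.
#' @export
writeTimeCourses <- function(timecourses, path) {
  utils::write.csv(data.frame(label = timecourses$label,
                              conc_nM = timecourses$conc * 1e9,
                              time_s = timecourses$time,
                              signal = timecourses$signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a kinetics fit to JSON
#'
#' @param fit a [KineticsFit-class].
#' @param path output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
kineticsFitJson <- function(fit, path = NULL) {
  d <- derivedConstants(fit)
  obj <- list(
    ka = fit@ka, kd = fit@kd, amplitude = fit@amplitude,
    se = as.list(standardErrors(fit)),
    temperature_K = fit@temperature,
    derived = list(kStarD_M = unname(d[["kStarD"]]),
                   kStarD_nM = unname(d[["kStarD"]]) * 1e9,
                   tHalf_s = unname(d[["tHalf"]]),
                   tHalf_min = unname(d[["tHalf"]]) / 60,
                   minusDeltaG_kcal_mol = unname(d[["minusDeltaG"]])),
    diagnostics = fit@diagnostics[c("residual_sd", "iterations", "n_points",
                                    "n_curves")])
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
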