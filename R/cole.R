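#' Cole relaxation parameters
#'
#' Parameters of the single-dispersion Cole model
#' \deqn{Z(\omega) = R_\infty + \frac{R_0 - R_\infty}{1 + (i\omega\tau)^\alpha}}
#' whose complex-plane locus is a circular arc depressed below the real axis
#' by the angle \eqn{(1-\alpha)\pi/2}. `R0` is the zero-frequency (membrane
#' intact, extracellular-path) resistance, `Rinf` the infinite-frequency
#' resistance where membranes are short-circuited, `tau` the characteristic
#' relaxation time of the beta dispersion and `alpha` its broadening.
#'
#' @param R0 Zero-frequency resistance, ohm; `R0 > Rinf`.
#' @param Rinf Infinite-frequency resistance, ohm; positive.
#' @param tau Characteristic time, s; positive.
#' @param alpha Dispersion broadening, in (0, 1].
#' @return Object of class `cole_parameters`.
#' @export
#' @examples
#' p <- cole_parameters(100, 50, 1e-5, 0.8)
#' py_parameter(p)  # 50
cole_parameters <- function(R0, Rinf, tau, alpha) {
  if (!is.finite(R0) || !is.finite(Rinf) || !is.finite(tau) || !is.finite(alpha)) {
    stop("Cole parameters must be finite", call. = FALSE)
  }
  if (!(R0 > Rinf && Rinf > 0)) {
    stop("Cole parameters require R0 > Rinf > 0", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  structure(list(R0 = R0, Rinf = Rinf, tau = tau, alpha = alpha),
            class = "cole_parameters")
}

#' @export
print.cole_parameters <- function(x, ...) {
  cat(sprintf("<cole_parameters> R0 = %.4g, Rinf = %.4g ohm, tau = %.4g s, alpha = %.4g (Py = %.3g)\n",
              x$R0, x$Rinf, x$tau, x$alpha, py_parameter(x)))
  invisible(x)
}

#' Evaluate the Cole model on a frequency grid
#'
#' @param params A `cole_parameters` object (or list with the same fields).
#' @param frequency_Hz Frequencies in Hz.
#' @return Complex impedance vector, one element per frequency; the real part
#'   is resistance, the imaginary part signed reactance (capacitive negative).
#' @export
cole_impedance <- function(params, frequency_Hz) {
  if (!inherits(params, "cole_parameters")) {
    params <- cole_parameters(params$R0, params$Rinf, params$tau, params$alpha)
  }
  validate_frequency_grid(frequency_Hz)
  iwt <- (1i * 2 * pi * frequency_Hz * params$tau)^params$alpha
  params$Rinf + (params$R0 - params$Rinf) / (1 + iwt)
}

#' Algebraic circle-fit initialization for the Cole fit
#'
#' Least-squares (Kasa) circle through the impedance locus points
#' (R, -X). The two real-axis intercepts estimate `Rinf` and `R0`
#' (smaller/larger), the depression of the circle center below the real axis
#' gives `alpha` through the depression-angle identity
#' alpha = 1 - (2/pi) * atan(depth / half-chord), and `tau` comes from the
#' frequency of maximal -X via omega * tau = 1. Degenerate loci (collinear or
#' dispersion-free points) fall back to range-based defaults and are flagged.
#'
#' @param sample An `impedance_sample` with at least 5 distinct frequencies.
#' @return A `cole_parameters` object; attribute `fallback` is `TRUE` when
#'   the circle fit was degenerate and defaults were used.
#' @export
init_cole_fit <- function(sample) {
  f <- sample$frequency_Hz
  if (length(unique(f)) < 5L) {
    stop("need at least 5 distinct frequencies to initialize a Cole fit",
         call. = FALSE)
  }
  x <- sample$resistance_ohm
  y <- -sample$reactance_ohm      # capacitive arc plotted above the axis
  fallback <- function() {
    tau0 <- 1 / (2 * pi * stats::median(f))
    r0 <- max(x) * (1 + 1e-6) + 1e-9   # keep R0 > Rinf strictly
    structure(cole_parameters(r0, max(min(x), 1e-12), tau0, 0.8),
              fallback = TRUE)
  }
  if (stats::sd(x) < 1e-12 * max(abs(x)) && max(abs(y)) < 1e-12 * max(abs(x))) {
    return(fallback())
  }
  # Kasa fit: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- tryCatch(unname(qr.solve(A, b)), error = function(e) NULL)
  if (is.null(coef) || any(!is.finite(coef))) return(fallback())
  cx <- -coef[1L] / 2
  cy <- -coef[2L] / 2
  rad2 <- cx^2 + cy^2 - coef[3L]
  if (!is.finite(rad2) || rad2 <= 0) return(fallback())
  disc <- rad2 - cy^2               # (half-chord)^2 at y = 0
  if (disc <= 0) return(fallback())
  half_chord <- sqrt(disc)
  r_lo <- cx - half_chord
  r_hi <- cx + half_chord
  if (!(r_hi > 0) || r_hi - max(r_lo, 0) < 1e-9 * r_hi) return(fallback())
  R0 <- r_hi
  Rinf <- max(r_lo, 1e-9 * r_hi)
  depth <- max(-cy, 0)              # center below the real axis when alpha < 1
  alpha <- 1 - (2 / pi) * atan2(depth, half_chord)
  alpha <- min(max(alpha, 0.3), 1.0)
  k_peak <- which.max(y)
  tau <- 1 / (2 * pi * f[k_peak])
  structure(cole_parameters(R0, Rinf, tau, alpha), fallback = FALSE)
}

#' Fit the Cole model to a measured spectrum
#'
#' Complex nonlinear least squares: minimizes the magnitude-weighted residual
#' \deqn{\sum_k |Z_k - Z(\omega_k)|^2 / |Z_k|^2} over (R0, Rinf, tau, alpha)
#' with a Levenberg-Marquardt search in the box-constrained parameterization
#' (Rinf, R0 - Rinf, log tau, alpha), which encodes R0 > Rinf > 0, tau > 0
#' and alpha in (0, 1] as simple bounds. Relative weighting keeps the fit
#' balanced across spectra that span orders of magnitude between 10 Hz and
#' 510 kHz.
#'
#' @param sample An `impedance_sample` with at least 5 distinct frequencies.
#' @param init Optional `cole_parameters` starting point; default is the
#'   circle-fit initialization [init_cole_fit()].
#' @param max_iter Iteration cap (default 500).
#' @param tol Relative parameter-step convergence tolerance (default 1e-8).
#' @return List of class `cole_fit` with elements `params`
#'   (`cole_parameters`), `residual_rms` (unweighted RMS of |Z_meas - Z_fit|,
#'   ohm), `objective` (weighted sum of squares), `converged`, `n_iter`,
#'   `flagged` (bound projection or degenerate initialization).
#' @export
fit_cole <- function(sample, init = NULL, max_iter = 500L, tol = 1e-8) {
  f <- sample$frequency_Hz
  if (length(unique(f)) < 5L) {
    stop("need at least 5 distinct frequencies to fit the Cole model",
         call. = FALSE)
  }
  z_meas <- complex(real = sample$resistance_ohm,
                    imaginary = sample$reactance_ohm)
  w <- 1 / Mod(z_meas)
  flagged <- FALSE
  if (is.null(init)) {
    init <- init_cole_fit(sample)
    flagged <- isTRUE(attr(init, "fallback"))
  } else if (!inherits(init, "cole_parameters")) {
    init <- cole_parameters(init$R0, init$Rinf, init$tau, init$alpha)
  }
  resid_fun <- function(p) {
    params <- list(Rinf = p[1L], R0 = p[1L] + p[2L], tau = exp(p[3L]),
                   alpha = p[4L])
    iwt <- (1i * 2 * pi * f * params$tau)^params$alpha
    z_mod <- params$Rinf + (params$R0 - params$Rinf) / (1 + iwt)
    d <- (z_meas - z_mod) * w
    c(Re(d), Im(d))
  }
  scale0 <- max(init$R0, 1)
  # tau is only identifiable within about a decade of the measured band:
  # outside it the dispersion degenerates into a flat offset and the
  # R0/Rinf split becomes arbitrary
  tau_lo <- 1 / (2 * pi * max(f) * 10)
  tau_hi <- 10 / (2 * pi * min(f))
  p0 <- c(init$Rinf, init$R0 - init$Rinf,
          log(min(max(init$tau, tau_lo), tau_hi)), init$alpha)
  lower <- c(1e-9 * scale0, 1e-9 * scale0, log(tau_lo), 1e-3)
  upper <- c(Inf, Inf, log(tau_hi), 1)
  p0 <- pmin(pmax(p0, lower), upper)
  fit <- minpack.lm::nls.lm(
    par = p0, lower = lower, upper = upper, fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = tol * 1e-4, gtol = 0,
      maxfev = 100L * max_iter))
  p <- unname(fit$par)
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)
  # projection back into the open constraint set, flagged when it bites
  if (p[2L] <= 0 || p[1L] <= 0) flagged <- TRUE
  params <- cole_parameters(
    R0 = max(p[1L], 1e-12) + max(p[2L], 1e-12),
    Rinf = max(p[1L], 1e-12),
    tau = exp(p[3L]),
    alpha = min(max(p[4L], 1e-3), 1))
  z_fit <- cole_impedance(params, f)
  structure(list(params = params,
                 residual_rms = sqrt(mean(Mod(z_meas - z_fit)^2)),
                 objective = fit$deviance,
                 converged = converged,
                 n_iter = fit$niter,
                 flagged = flagged),
            class = "cole_fit")
}

#' @export
print.cole_fit <- function(x, ...) {
  cat(sprintf("<cole_fit> converged = %s (%d iter), residual RMS = %.4g ohm\n",
              x$converged, x$n_iter, x$residual_rms))
  print(x$params)
  invisible(x)
}

#' Py membrane-integrity parameter
#'
#' The percent-scale magnitude of the beta dispersion derived from
#' Cole-fitted resistances: `Py = (R0 - Rinf) * 100 / R0`. It is a direct
#' measure of the abundance of intact, current-impeding cell membranes; full
#' membrane destruction collapses the dispersion and drives Py to 0.
#'
#' @param params A `cole_parameters` object, or any list with `R0` and
#'   `Rinf` fields satisfying `R0 >= Rinf > 0` (boundary `R0 == Rinf`
#'   allowed: no dispersion, `Py = 0`).
#' @return Py in percent, in \[0, 100).
#' @export
py_parameter <- function(params) {
  R0 <- params$R0
  Rinf <- params$Rinf
  if (!is.finite(R0) || R0 <= 0) stop("R0 must be positive", call. = FALSE)
  if (!is.finite(Rinf) || Rinf <= 0 || Rinf > R0) {
    stop("Py requires R0 >= Rinf > 0", call. = FALSE)
  }
  (R0 - Rinf) * 100 / R0
}

#' Fit every measurement in a cohort and tabulate Cole parameters and Py
#'
#' @param cohort An `ft_cohort`.
#' @return Data frame with one row per measurement: sample_id, treatment,
#'   time_s, temperature_C, next_day, R0, Rinf, tau, alpha, Py,
#'   residual_rms, converged, flagged.
#' @export
fit_cole_cohort <- function(cohort) {
  trajs <- cohort_trajectories(cohort)
  rows <- lapply(unlist(trajs, recursive = FALSE), function(s) {
    fit <- fit_cole(s)
    data.frame(sample_id = s$sample_id, treatment = s$treatment,
               time_s = s$time_s, temperature_C = s$temperature_C,
               next_day = is_next_day(s),
               R0 = fit$params$R0, Rinf = fit$params$Rinf,
               tau = fit$params$tau, alpha = fit$params$alpha,
               Py = py_parameter(fit$params),
               residual_rms = fit$residual_rms,
               converged = fit$converged, flagged = fit$flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
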