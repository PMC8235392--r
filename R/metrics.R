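#' Impedance magnitude and phase angle
#'
#' |Z| = sqrt(R^2 + X^2), phi = arctan(X/R) in degrees, the sign following
#' the reactance (capacitive spectra give negative phase).
#'
#' @param resistance_ohm Resistance R, ohm (vectorized).
#' @param reactance_ohm Signed reactance X, ohm.
#' @return List with numeric vectors `magnitude_ohm` and `phase_deg`.
#' @export
#' @examples
#' magnitude_phase(3, 4)  # |Z| = 5, phi = 53.13 deg
magnitude_phase <- function(resistance_ohm, reactance_ohm) {
  if (length(resistance_ohm) != length(reactance_ohm)) {
    stop("resistance and reactance must have equal length", call. = FALSE)
  }
  if (any(resistance_ohm == 0 & reactance_ohm == 0)) {
    stop("magnitude and phase are undefined at R = X = 0", call. = FALSE)
  }
  list(magnitude_ohm = sqrt(resistance_ohm^2 + reactance_ohm^2),
       phase_deg = atan2(reactance_ohm, resistance_ohm) * 180 / pi)
}

#' Relative change in impedance between a reference and a later measurement
#'
#' The storage-change index relating a day-0 impedance magnitude `z_ref`
#' (|Z0|) to a later one `z_obs` (|Zi|). The `"corrected"` mode (default)
#' returns `100 * (z_ref - z_obs) / z_ref`, so a decline in impedance is a
#' positive percentage and no change is 0. The `"as_printed"` mode retains
#' the additive form `100 * (z_ref + z_obs) / z_ref` found in some reports,
#' which cannot express a decrease below 100%; it is kept only for
#' comparability.
#'
#' @param z_ref Reference magnitude |Z0|, ohm; positive.
#' @param z_obs Observed magnitude |Zi|, ohm; non-negative.
#' @param mode `"corrected"` or `"as_printed"`.
#' @return Percentage (vectorized over `z_obs`).
#' @export
relative_change <- function(z_ref, z_obs, mode = c("corrected", "as_printed")) {
  mode <- match.arg(mode)
  if (any(!is.finite(z_ref)) || any(z_ref <= 0)) {
    stop("reference impedance must be positive", call. = FALSE)
  }
  if (any(z_obs < 0)) stop("observed impedance must be non-negative",
                           call. = FALSE)
  if (mode == "corrected") 100 * (z_ref - z_obs) / z_ref
  else 100 * (z_ref + z_obs) / z_ref
}

#' Fresh-vs-thawed resistance and reactance indices
#'
#' Geometry-free damage indices comparing the unfrozen (fresh) measurement of
#' a sample to its post-freeze-thaw measurement at the same frequency:
#' `R_index = (R_un - R_ft) / R_un`, `X_index = (X_un - X_ft) / X_un`.
#' Because both are ratios within one sample, they cancel the
#' electrode-geometry scale that makes absolute impedance incomparable
#' across samples.
#'
#' @param r_un,x_un Fresh resistance/reactance, ohm (`r_un > 0`).
#' @param r_ft,x_ft Post-thaw resistance/reactance, ohm (`r_ft > 0`).
#' @return List with `R_index`, `X_index` (NA where `x_un == 0`) and logical
#'   `x_defined`.
#' @export
freshness_index <- function(r_un, x_un, r_ft, x_ft) {
  if (any(r_un <= 0) || any(r_ft <= 0)) {
    stop("resistances must be strictly positive", call. = FALSE)
  }
  x_defined <- x_un != 0
  x_index <- ifelse(x_defined, (x_un - x_ft) / x_un, NA_real_)
  list(R_index = (r_un - r_ft) / r_un, X_index = x_index,
       x_defined = x_defined)
}

#' Impedance change rate along a thawing trajectory
#'
#' Normalized backward difference of the impedance magnitude at one grid
#' frequency: `ICR_k = (|Z|_{k-1} - |Z|_k) / (|Z|_{k-1} * delta_k)` where
#' `delta_k` is the increment of the chosen axis (time in s or core
#' temperature in degrees C). The ICR drops sharply where latent heat is
#' absorbed, making it a marker of the phase-change zone. Pairs with zero
#' axis increment are skipped and flagged.
#'
#' @param trajectory List of `impedance_sample` objects ordered along the
#'   thaw (e.g. one element of [cohort_trajectories()]); timeless next-day
#'   measurements are dropped.
#' @param frequency_Hz Grid frequency at which to evaluate |Z| (must be on
#'   the grid to within 1e-9 relative).
#' @param axis `"time"` (per second) or `"temperature"` (per degree C).
#' @return Data frame with columns `axis_from`, `axis_to`, `icr`; attribute
#'   `skipped` counts zero-increment pairs.
#' @export
impedance_change_rate <- function(trajectory, frequency_Hz,
                                  axis = c("time", "temperature")) {
  axis <- match.arg(axis)
  trajectory <- Filter(Negate(is_next_day), trajectory)
  if (length(trajectory) < 2L) {
    stop("need at least 2 measurements for a change rate", call. = FALSE)
  }
  zmag <- vapply(trajectory, function(s) {
    k <- which(abs(s$frequency_Hz - frequency_Hz) <=
                 1e-9 * frequency_Hz)
    if (length(k) == 0L) {
      stop("frequency ", frequency_Hz, " Hz is not on the measurement grid",
           call. = FALSE)
    }
    sqrt(s$resistance_ohm[k[1L]]^2 + s$reactance_ohm[k[1L]]^2)
  }, numeric(1L))
  ax <- vapply(trajectory, function(s) {
    if (axis == "time") s$time_s else s$temperature_C
  }, numeric(1L))
  if (any(is.na(ax))) stop("axis values missing on the trajectory",
                           call. = FALSE)
  if (any(diff(ax) < 0)) {
    stop("axis values must be non-decreasing along the trajectory",
         call. = FALSE)
  }
  d_ax <- diff(ax)
  keep <- d_ax > 0
  icr <- (zmag[-length(zmag)] - zmag[-1L]) / (zmag[-length(zmag)] * d_ax)
  out <- data.frame(axis_from = ax[-length(ax)][keep],
                    axis_to = ax[-1L][keep], icr = icr[keep])
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Batch impedance descriptors for a cohort
#'
#' Per (measurement, frequency): magnitude and phase; per trajectory, the
#' temperature-axis ICR at `icr_frequency_Hz` joined on the interval's upper
#' temperature; fresh-vs-thawed indices when the trajectory includes a fresh
#' measurement.
#'
#' @param cohort An `ft_cohort`.
#' @param icr_frequency_Hz Frequency for the ICR column (default: lowest grid
#'   frequency, where membrane damage expresses most strongly).
#' @return Data frame `(sample_id, treatment, time_s, temperature_C,
#'   frequency_Hz, magnitude_ohm, phase_deg, R_index, X_index, icr)`; index
#'   columns are NA without a fresh reference.
#' @export
cohort_metrics <- function(cohort, icr_frequency_Hz = NULL) {
  df <- cohort$data
  mp <- magnitude_phase(df$resistance_ohm, df$reactance_ohm)
  df$magnitude_ohm <- mp$magnitude_ohm
  df$phase_deg <- mp$phase_deg
  df$R_index <- NA_real_
  df$X_index <- NA_real_
  df$icr <- NA_real_
  trajs <- cohort_trajectories(cohort)
  if (is.null(icr_frequency_Hz) && nrow(df) > 0L) {
    icr_frequency_Hz <- min(df$frequency_Hz)
  }
  for (traj in trajs) {
    sid <- traj[[1L]]$sample_id
    fresh <- Filter(function(s) s$treatment == "fresh", traj)
    if (length(fresh) > 0L) {
      fr <- fresh[[1L]]
      for (s in Filter(function(s) s$treatment != "fresh", traj)) {
        idx <- freshness_index(fr$resistance_ohm, fr$reactance_ohm,
                               s$resistance_ohm, s$reactance_ohm)
        sel <- df$sample_id == sid & !is.na(df$temperature_C) &
          df$temperature_C == s$temperature_C &
          (is.na(df$time_s) == is.na(s$time_s)) &
          (is.na(df$time_s) | df$time_s %in% s$time_s)
        df$R_index[sel] <- idx$R_index
        df$X_index[sel] <- idx$X_index
      }
    }
    thaw <- Filter(function(s) !is_next_day(s) && s$treatment != "fresh" &&
                     !is.na(s$time_s), traj)
    if (length(thaw) >= 2L) {
      icr <- impedance_change_rate(thaw, icr_frequency_Hz, axis = "temperature")
      for (j in seq_len(nrow(icr))) {
        sel <- df$sample_id == sid & df$temperature_C == icr$axis_to[j]
        df$icr[sel] <- icr$icr[j]
      }
    }
  }
  df
}
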