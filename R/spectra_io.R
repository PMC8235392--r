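#' Default 36-point measurement frequency grid
#'
#' Logarithmically spaced stimulus frequencies spanning 10 Hz to 510 kHz,
#' the grid used throughout the thawing measurements. The instrument's
#' spacing is not documented, so log spacing -- the convention in impedance
#' spectroscopy -- is assumed.
#'
#' @param n Number of frequency points (default 36).
#' @param f_min,f_max Grid endpoints in Hz.
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @export
#' @examples
#' f <- default_frequency_grid()
#' range(f)  # 10 510000
default_frequency_grid <- function(n = 36L, f_min = 10, f_max = 510e3) {
  validate_frequency_grid(exp(seq(log(f_min), log(f_max), length.out = n)))
}

#' Validate a frequency grid
#'
#' @param frequencies Numeric vector of stimulus frequencies in Hz.
#' @return The grid, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_frequency_grid <- function(frequencies) {
  if (!is.numeric(frequencies) || length(frequencies) < 1L) {
    stop("frequency grid must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  }
  if (any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  frequencies
}

#' Construct a single impedance spectrum
#'
#' One multi-frequency measurement of a tissue sample: resistance and signed
#' reactance at every grid frequency (capacitive reactance stored negative),
#' tagged with sample identity, treatment group, elapsed thawing time and
#' core temperature.
#'
#' @param sample_id Identifier of the physical sample.
#' @param treatment One of `"fresh"`, `"fast_thaw"`, `"slow_thaw"`.
#' @param time_s Seconds since thawing start; `NA` for fresh or next-day
#'   measurements taken outside the thawing run.
#' @param temperature_C Core temperature in degrees Celsius.
#' @param frequency_Hz Frequency grid, Hz.
#' @param resistance_ohm Resistance per frequency, ohm (strictly positive).
#' @param reactance_ohm Signed reactance per frequency, ohm.
#' @return An object of class `impedance_sample`.
#' @export
impedance_sample <- function(sample_id, treatment, time_s, temperature_C,
                             frequency_Hz, resistance_ohm, reactance_ohm) {
  treatment <- match.arg(treatment, c("fresh", "fast_thaw", "slow_thaw"))
  validate_frequency_grid(frequency_Hz)
  n <- length(frequency_Hz)
  if (length(resistance_ohm) != n || length(reactance_ohm) != n) {
    stop("resistance and reactance must match the grid length", call. = FALSE)
  }
  if (any(!is.finite(resistance_ohm)) || any(resistance_ohm <= 0)) {
    stop("resistance must be finite and strictly positive at every frequency",
         call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id), treatment = treatment,
         time_s = as.numeric(time_s), temperature_C = as.numeric(temperature_C),
         frequency_Hz = as.numeric(frequency_Hz),
         resistance_ohm = as.numeric(resistance_ohm),
         reactance_ohm = as.numeric(reactance_ohm)),
    class = "impedance_sample")
}

#' Is a measurement a next-day (post-storage) measurement?
#'
#' Next-day measurements were taken after >16 h chilled storage at 2--4
#' degrees C; they carry no thawing clock, so they are encoded with absent
#' `time_s` and a core temperature inside the chilling band.
#'
#' @param sample An `impedance_sample`.
#' @return Logical.
#' @export
is_next_day <- function(sample) {
  is.na(sample$time_s) && sample$treatment != "fresh" &&
    sample$temperature_C >= 2 && sample$temperature_C <= 4
}

spectra_columns <- c("sample_id", "treatment", "time_s", "temperature_C",
                     "frequency_Hz", "resistance_ohm", "reactance_ohm")

#' Assemble a cohort from a long spectra table
#'
#' @param data Data frame with one row per (measurement, frequency) using the
#'   canonical column names (see [read_spectra_csv()]).
#' @param metadata Free-form provenance list (seed, generator config,
#'   ground truth, ...).
#' @param grid_policy `"strict"` requires all measurements to share one
#'   frequency grid; `"infer"` allows per-measurement grids.
#' @return An object of class `ft_cohort`: list with elements `data`
#'   (the long table, ordered), `metadata`.
#' @export
ft_cohort <- function(data, metadata = list(), grid_policy = c("strict", "infer")) {
  grid_policy <- match.arg(grid_policy)
  missing_cols <- setdiff(spectra_columns, names(data))
  if (length(missing_cols) > 0L) {
    stop("spectra table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, spectra_columns]
  data$sample_id <- as.character(data$sample_id)
  data$treatment <- as.character(data$treatment)
  bad_treat <- !data$treatment %in% c("fresh", "fast_thaw", "slow_thaw")
  if (any(bad_treat)) {
    stop("unknown treatment label(s): ",
         paste(unique(data$treatment[bad_treat]), collapse = ", "),
         call. = FALSE)
  }
  bad_r <- which(!is.finite(data$resistance_ohm) | data$resistance_ohm <= 0)
  if (length(bad_r) > 0L) {
    stop("non-positive or non-finite resistance at data row ", bad_r[1L],
         call. = FALSE)
  }
  # one measurement = one (sample_id, time_s, temperature_C) cell
  key <- measurement_key(data)
  ord <- order(data$sample_id, data$temperature_C,
               ifelse(is.na(data$time_s), Inf, data$time_s), data$frequency_Hz)
  data <- data[ord, , drop = FALSE]
  rownames(data) <- NULL
  key <- measurement_key(data)
  grids <- lapply(split(data$frequency_Hz, key), function(f) {
    validate_frequency_grid(f)
  })
  if (grid_policy == "strict" && length(grids) > 1L) {
    ref <- grids[[1L]]
    same <- vapply(grids, function(g) {
      length(g) == length(ref) && all(abs(g - ref) <= 1e-9 * ref)
    }, logical(1L))
    if (!all(same)) {
      stop("mixed frequency grids under grid_policy = \"strict\"",
           call. = FALSE)
    }
  }
  structure(list(data = data, metadata = metadata), class = "ft_cohort")
}

measurement_key <- function(data) {
  paste(data$sample_id,
        ifelse(is.na(data$time_s), "NA", format(data$time_s, digits = 12)),
        format(data$temperature_C, digits = 12), sep = "\r")
}

#' @export
print.ft_cohort <- function(x, ...) {
  tr <- cohort_trajectories(x)
  cat("<ft_cohort> ", length(tr), " trajectories, ",
      sum(vapply(tr, length, integer(1L))), " measurements, ",
      nrow(x$data), " rows\n", sep = "")
  invisible(x)
}

#' Number of thawing trajectories in a cohort
#' @param cohort An `ft_cohort`.
#' @return Integer count of distinct sample ids.
#' @export
n_trajectories <- function(cohort) length(unique(cohort$data$sample_id))

#' Split a cohort into per-sample trajectories
#'
#' @param cohort An `ft_cohort`.
#' @return Named list (by sample id) of lists of `impedance_sample` objects,
#'   ordered by time within each trajectory (timeless next-day measurements
#'   last).
#' @export
cohort_trajectories <- function(cohort) {
  stopifnot(inherits(cohort, "ft_cohort"))
  per_sample <- split(cohort$data, cohort$data$sample_id)
  lapply(per_sample, function(df) {
    cells <- split(df, measurement_key(df))
    samples <- lapply(cells, function(cell) {
      impedance_sample(cell$sample_id[1L], cell$treatment[1L],
                       cell$time_s[1L], cell$temperature_C[1L],
                       cell$frequency_Hz, cell$resistance_ohm,
                       cell$reactance_ohm)
    })
    ord <- order(vapply(samples, function(s) {
      if (is.na(s$time_s)) Inf else s$time_s
    }, numeric(1L)), vapply(samples, `[[`, numeric(1L), "temperature_C"))
    unname(samples[ord])
  })
}

#' Read an impedance spectra CSV into a cohort
#'
#' Expects the canonical long layout, one row per (measurement, frequency):
#' `sample_id,treatment,time_s,temperature_C,frequency_Hz,resistance_ohm,reactance_ohm`
#' (units encoded in the column names; capacitive reactance negative). A JSON
#' sidecar `<path>.meta.json`, if present, is loaded as cohort metadata.
#'
#' @param path CSV file path.
#' @param grid_policy `"strict"` (default) or `"infer"`; see [ft_cohort()].
#' @return An `ft_cohort`.
#' @export
read_spectra_csv <- function(path, grid_policy = c("strict", "infer")) {
  grid_policy <- match.arg(grid_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(spectra_columns, names(df))
  if (length(missing_cols) > 0L) {
    stop("spectra CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  metadata <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    metadata <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (nrow(df) == 0L) {
    return(structure(list(data = df[, spectra_columns], metadata = metadata),
                     class = "ft_cohort"))
  }
  ft_cohort(df, metadata = metadata, grid_policy = grid_policy)
}

#' Write a cohort to the canonical spectra CSV
#'
#' Inverse of [read_spectra_csv()] up to floating-point round-trip; writes one
#' row per (measurement, frequency) and, when the cohort carries metadata, a
#' JSON sidecar `<path>.meta.json`.
#'
#' @param cohort An `ft_cohort`.
#' @param path Output CSV path.
#' @return Number of data rows written, invisibly.
#' @export
write_spectra_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "ft_cohort"))
  df <- cohort$data
  num <- vapply(df, is.numeric, logical(1L))
  out <- df
  # 17 significant digits: lossless double round-trip
  out[num] <- lapply(df[num], function(x) {
    s <- sprintf("%.17g", x)
    s[is.na(x)] <- NA_character_
    s
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  if (length(cohort$metadata) > 0L) {
    jsonlite::write_json(cohort$metadata, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(nrow(df))
}

#' Select, per trajectory, the measurement nearest a target temperature
#'
#' Used to slice a cohort at one analysis temperature (0, 0.5, ..., 4 degrees
#' C in the thawing protocol). Trajectories with no measurement within `tol`
#' of the target are omitted. Next-day measurements (no thawing clock) are
#' excluded unless `next_day = TRUE`, in which case only they are searched.
#'
#' @param cohort An `ft_cohort`.
#' @param temperature_C Target core temperature, degrees C.
#' @param tol Matching tolerance, degrees C (default 0.25, half the 0.5
#'   degree measurement step).
#' @param next_day Select among next-day measurements instead.
#' @return List of `impedance_sample` objects, at most one per trajectory.
#' @export
select_at_temperature <- function(cohort, temperature_C, tol = 0.25,
                                  next_day = FALSE) {
  stopifnot(tol >= 0)
  out <- lapply(cohort_trajectories(cohort), function(traj) {
    pool <- Filter(function(s) is_next_day(s) == next_day, traj)
    if (length(pool) == 0L) return(NULL)
    dev <- vapply(pool, function(s) abs(s$temperature_C - temperature_C),
                  numeric(1L))
    if (min(dev) > tol) return(NULL)
    pool[[which.min(dev)]]
  })
  unname(Filter(Negate(is.null), out))
}

#' Collect all next-day measurements, one per trajectory
#' @param cohort An `ft_cohort`.
#' @return List of `impedance_sample` objects.
#' @export
select_next_day <- function(cohort) {
  out <- lapply(cohort_trajectories(cohort), function(traj) {
    pool <- Filter(is_next_day, traj)
    if (length(pool) == 0L) NULL else pool[[1L]]
  })
  unname(Filter(Negate(is.null), out))
}
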