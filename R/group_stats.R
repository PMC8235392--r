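#' Mann-Whitney U test (exact enumeration or tie-corrected normal)
#'
#' Two-sided two-sample rank test. U statistics are computed from midranks,
#' so ties are handled identically on both paths. The exact method
#' enumerates all `choose(n_a + n_b, n_a)` group assignments of the pooled
#' values and reads the two-sided p-value off the permutation distribution
#' of U_a as `min(1, 2 * min(P(U_a <= u), P(U_a >= u)))`. The normal method
#' applies the tie-corrected Gaussian approximation with a 0.5 continuity
#' correction. `"auto"` picks exact when `n_a + n_b <= 12`, otherwise
#' normal -- the balance used throughout the per-temperature comparisons
#' (combined n = 20 takes the normal path, matching common practice).
#'
#' @param a,b Numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`. Exact enumeration is
#'   supported up to a combined n of 22.
#' @return List with `U` (min of the two U statistics), `p_value`
#'   (two-sided) and `method` used.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) stop("values must be finite", call. = FALSE)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  if (method == "auto") method <- if (n <= 12L) "exact" else "normal"
  r <- rank(c(a, b))                      # midranks
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_b <- n_a * n_b - u_a
  if (method == "exact") {
    if (n > 22L) stop("exact enumeration limited to combined n <= 22",
                      call. = FALSE)
    idx <- utils::combn(n, n_a)
    u_all <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_a + eps), mean(u_all >= u_a - eps)))
  } else {
    mu <- n_a * n_b / 2
    ties <- table(r)
    sigma2 <- (n_a * n_b / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all pooled values tied: no evidence either way
    } else {
      z <- u_a - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
      p <- min(1, 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    }
  }
  list(U = min(u_a, u_b), p_value = p, method = method)
}

#' Two-sample t-test on drip loss (Welch by default)
#'
#' Thin wrapper over the standard two-sample t machinery with the degenerate
#' convention the comparison tables need: when both groups have zero
#' variance and equal means the test is uninformative and returns t = 0,
#' p = 1, flagged.
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @param equal_var Pooled-variance test instead of Welch.
#' @return List with `t`, `p_value`, `df`, `flagged`.
#' @export
two_sample_t <- function(a, b, equal_var = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p_value = 1, df = NA_real_, flagged = TRUE))
    }
    stop("zero variance in both groups with unequal means: t undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = equal_var)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), flagged = FALSE)
}

#' Drip loss as a percentage of initial weight
#'
#' `100 * (initial - final) / initial`, optionally rescaled linearly to a
#' common storage duration so records stored 16--26 h become comparable.
#'
#' @param initial_weight_g,final_weight_g Weights in g,
#'   `0 < final <= initial`.
#' @param storage_hours Storage duration, h (required for normalization).
#' @param normalize_hours Target duration, h, or `NULL` for no rescaling.
#' @return Drip loss percentage.
#' @export
#' @examples
#' drip_loss_percent(200, 190, 25, normalize_hours = 20)  # 4
drip_loss_percent <- function(initial_weight_g, final_weight_g,
                              storage_hours = NA_real_,
                              normalize_hours = NULL) {
  if (any(final_weight_g <= 0) || any(final_weight_g > initial_weight_g)) {
    stop("weights must satisfy 0 < final <= initial", call. = FALSE)
  }
  loss <- 100 * (initial_weight_g - final_weight_g) / initial_weight_g
  if (!is.null(normalize_hours)) {
    if (any(is.na(storage_hours)) || any(storage_hours <= 0)) {
      stop("storage_hours must be positive when normalizing", call. = FALSE)
    }
    loss <- loss * (normalize_hours / storage_hours)
  }
  loss
}

group_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  list(count = length(x), median = stats::median(x), mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0, iqr = q[2L] - q[1L])
}

#' Per-temperature comparison table of Py between thawing groups
#'
#' One row per scheduled temperature (default 0, 0.5, ..., 4 degrees C) plus
#' a final next-day row. Each row carries per-group summaries (count,
#' median, mean, SD, IQR with linearly interpolated quantiles) and a
#' two-sided Mann-Whitney p-value. No multiple-testing correction is applied
#' to `p_value`, matching the per-temperature presentation; a Holm-adjusted
#' column `p_holm` is emitted alongside as a clearly separate extension.
#' Rows with an empty cell get NA summaries for that group, no p-value, and
#' `flagged = TRUE`.
#'
#' @param py Data frame with columns `temperature_label` (character:
#'   `"0"`, `"0.5"`, ..., `"next_day"`), `group` (two levels) and `py`.
#' @param temperatures Numeric schedule (default `seq(0, 4, 0.5)`).
#' @param groups Character vector of the two group labels, first = fast.
#' @param mwu_method Passed to [mann_whitney_u()].
#' @return Data frame, one row per (temperature, group) pair in table
#'   layout: `temperature_label, group, count, median, mean, sd, iqr,
#'   p_value, p_holm, flagged` (test columns repeated on both group rows).
#' @export
comparison_table <- function(py, temperatures = seq(0, 4, by = 0.5),
                             groups = c("fast_thaw", "slow_thaw"),
                             mwu_method = "auto") {
  stopifnot(all(c("temperature_label", "group", "py") %in% names(py)))
  labels <- c(as.character(temperatures), "next_day")
  rows <- list()
  p_per_label <- rep(NA_real_, length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    cells <- lapply(groups, function(g) {
      py$py[py$temperature_label == lab & py$group == g]
    })
    have_both <- all(vapply(cells, length, integer(1L)) > 0L)
    p <- if (have_both) {
      mann_whitney_u(cells[[1L]], cells[[2L]], method = mwu_method)$p_value
    } else NA_real_
    p_per_label[i] <- p
    for (j in seq_along(groups)) {
      s <- if (length(cells[[j]]) > 0L) group_summary(cells[[j]]) else
        list(count = 0L, median = NA_real_, mean = NA_real_,
             sd = NA_real_, iqr = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_label = lab, group = groups[j], count = s$count,
        median = s$median, mean = s$mean, sd = s$sd, iqr = s$iqr,
        p_value = p, flagged = !have_both, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  holm <- rep(NA_real_, length(labels))
  ok <- !is.na(p_per_label)
  holm[ok] <- stats::p.adjust(p_per_label[ok], method = "holm")
  out$p_holm <- rep(holm, each = length(groups))
  rownames(out) <- NULL
  out
}

#' Label fitted Py values with the nearest scheduled temperature
#'
#' Maps each Cole-fit row (see [fit_cole_cohort()]) to the analysis schedule:
#' next-day rows get the `"next_day"` label, thawing rows the nearest
#' scheduled temperature within `tol`; unmatched rows are dropped.
#'
#' @param fits Data frame from [fit_cole_cohort()].
#' @param temperatures Numeric schedule (default `seq(0, 4, 0.5)`).
#' @param tol Matching tolerance, degrees C.
#' @return Data frame `(temperature_label, group, py)` ready for
#'   [comparison_table()].
#' @export
py_by_temperature <- function(fits, temperatures = seq(0, 4, by = 0.5),
                              tol = 0.25) {
  out <- lapply(seq_len(nrow(fits)), function(i) {
    row <- fits[i, ]
    if (isTRUE(row$next_day)) {
      lab <- "next_day"
    } else {
      dev <- abs(temperatures - row$temperature_C)
      if (min(dev) > tol) return(NULL)
      lab <- as.character(temperatures[which.min(dev)])
    }
    data.frame(temperature_label = lab, group = row$treatment, py = row$Py,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(temperature_label = character(), group = character(),
                      py = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
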