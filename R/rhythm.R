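# Circadian statistics on fitted lambda series: repeat averaging, per-day
# normalization, hour-of-day aggregation with standard errors, Cleveland
# LOWESS smoothing and operator-pair Pearson correlations.

#' Average repeated measurements per photograph
#'
#' Each photograph is measured repeatedly to reduce operator-induced error;
#' the series entering the rhythm analysis carries the arithmetic mean of the
#' repeats per (photograph, operator).
#'
#' @param records A tibble with at least `operator`, `filename`,
#'   `capture_time` and `lambda` (e.g. from [read_records()]).
#' @return A tibble with one row per (operator, photograph): the mean `lambda`
#'   and the repeat count `n_repeats`.
#' @export
average_repeats <- function(records) {
  records %>%
    group_by(.data$operator, .data$filename, .data$capture_time) %>%
    summarise(lambda = mean(.data$lambda), n_repeats = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$operator, .data$capture_time)
}

#' Normalize lambda per calendar day
#'
#' Sets each day's mean to 100%: every value becomes
#' `100 * value / mean(values of its day)`, separately per operator. Days are
#' calendar dates of the capture time as recorded by the camera (no timezone
#' shifting). The operation is idempotent.
#'
#' @param series A tibble with `operator`, `capture_time` (POSIXct) and
#'   `lambda`.
#' @return The input with columns `day` (Date) and `lambda_pct` (percent of
#'   the daily mean) added.
#' @export
normalize_per_day <- function(series) {
  series %>%
    mutate(day = as.Date(format(.data$capture_time, "%Y-%m-%d"))) %>%
    group_by(.data$operator, .data$day) %>%
    mutate(lambda_pct = 100 * .data$lambda / mean(.data$lambda)) %>%
    ungroup()
}

#' Hour-of-day profile with standard errors
#'
#' Groups the per-day normalized series by hour of day and reports, per
#' operator and hour, the mean normalized lambda, the standard error across
#' the contributing days (sample SD / sqrt(n)), and the day count. Hours
#' observed on a single day get an `NA` standard error.
#'
#' @param normalized Output of [normalize_per_day()].
#' @return A tibble with `operator`, `hour`, `mean_pct`, `se_pct`, `n_days`.
#' @export
hourly_profile <- function(normalized) {
  normalized %>%
    mutate(hour = as.integer(format(.data$capture_time, "%H"))) %>%
    group_by(.data$operator, .data$hour) %>%
    summarise(mean_pct = mean(.data$lambda_pct),
              se_pct = ifelse(dplyr::n() > 1,
                              sd(.data$lambda_pct) / sqrt(dplyr::n()), NA_real_),
              n_days = dplyr::n(), .groups = "drop") %>%
    arrange(.data$operator, .data$hour)
}

#' LOWESS smoothing
#'
#' Cleveland's locally weighted scatterplot smoother (tricube weights,
#' locally linear, no robustness iterations), with the smoothing strength
#' given as the percentage `p` of neighboring points entering each local fit.
#' `p = 10` suits a raw multi-day series; `p = 30` a 24-point daily profile.
#'
#' @param x,y Numeric vectors of equal length (at least 3 points).
#' @param p Percentage of neighbors in each local fit, in (0, 100].
#' @return The smoothed values, aligned with the input order of `x`.
#' @export
lowess_smooth <- function(x, y, p = 30) {
  stopifnot(length(x) == length(y), length(x) >= 3, p > 0, p <= 100)
  ord <- order(x)
  sm <- lowess(x[ord], y[ord], f = p / 100, iter = 0)
  out <- numeric(length(x))
  out[ord] <- sm$y
  out
}

#' Pearson product-moment correlation
#'
#' Product-moment `r` with the two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length (at least 3); pairs with a
#'   missing value in either vector are dropped.
#' @return A tibble with `r`, `p` and `n`.
#' @export
pearson_cor <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  stopifnot(length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0) {
    pc_abort("Correlation undefined: zero variance in one input.",
             "pathcurve_zero_variance")
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Two-sided p-value for a given Pearson r and sample size
#'
#' @param r Correlation coefficient.
#' @param n Number of data points.
#' @return The two-sided p-value.
#' @export
pearson_r_pvalue <- function(r, n) {
  stopifnot(abs(r) < 1, n > 2)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Pairwise operator correlations (hourly means and smoothed profiles)
#'
#' For every pair of operators, the Pearson correlation of their hourly mean
#' profiles and of the LOWESS-smoothed profiles, computed on the hours both
#' operators observed (pairwise deletion of missing hours).
#'
#' @param profile Output of [hourly_profile()] covering several operators.
#' @param p Smoothing percentage for the smoothed-profile correlation.
#' @return A tibble with one row per operator pair: `op_a`, `op_b`,
#'   `r_hourly`, `p_hourly`, `r_smoothed`, `p_smoothed`, `n`.
#' @export
operator_correlations <- function(profile, p = 30) {
  ops <- sort(unique(profile$operator))
  if (length(ops) < 2) {
    pc_abort("Need at least two operators for correlations.",
             "pathcurve_bad_input")
  }
  wide <- profile %>%
    select("operator", "hour", "mean_pct") %>%
    tidyr::pivot_wider(names_from = "operator", values_from = "mean_pct") %>%
    arrange(.data$hour)
  smoothed <- lapply(ops, function(op) {
    v <- wide[[op]]
    ok <- is.finite(v)
    out <- rep(NA_real_, length(v))
    out[ok] <- lowess_smooth(wide$hour[ok], v[ok], p = p)
    out
  })
  names(smoothed) <- ops
  pairs <- utils::combn(ops, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    hm <- pearson_cor(wide[[pr[1]]], wide[[pr[2]]])
    sm <- pearson_cor(smoothed[[pr[1]]], smoothed[[pr[2]]])
    tibble(op_a = pr[1], op_b = pr[2],
           r_hourly = hm$r, p_hourly = hm$p,
           r_smoothed = sm$r, p_smoothed = sm$p, n = hm$n)
  }))
}

#' Peak hour of a daily profile
#'
#' The hour at which the LOWESS-smoothed daily profile is maximal; used to
#' compare a recovered circadian phase against a known acrophase. Because the
#' hour axis is circular, the profile is extended periodically by a quarter
#' day on each side before smoothing (with the neighbor fraction rescaled so
#' each local fit spans the same number of hours), which removes the end
#' artifacts a plain linear smoother shows at midnight.
#'
#' @param profile One operator's rows from [hourly_profile()].
#' @param p Smoothing percentage (of the 24-hour profile).
#' @return The peak hour (integer 0-23).
#' @export
profile_peak_hour <- function(profile, p = 30) {
  stopifnot(length(unique(profile$operator)) <= 1)
  profile <- profile[order(profile$hour), ]
  h <- profile$hour
  v <- profile$mean_pct
  n <- length(h)
  k <- max(3L, ceiling(n / 4))
  hp <- c(h[(n - k + 1):n] - 24, h, h[1:k] + 24)
  vp <- c(v[(n - k + 1):n], v, v[1:k])
  sm <- lowess(hp, vp, f = (p / 100) * n / (n + 2 * k), iter = 0)$y
  h[which.max(sm[(k + 1):(k + n)])]
}

#' Full rhythm analysis of a measurement CSV
#'
#' Chains the whole statistical procedure: repeat averaging per photograph,
#' per-day normalization, hour-of-day profiles with standard errors, LOWESS
#' smoothing of the raw series (`p_raw`) and of the daily profiles
#' (`p_profile`), and -- when several operators are present -- pairwise
#' Pearson correlations.
#'
#' @param records Measurement records tibble (see [read_records()]) or the
#'   path of a results CSV.
#' @param p_raw LOWESS percentage for the raw series.
#' @param p_profile LOWESS percentage for the daily profiles.
#' @return An object of class `rhythm_analysis`: a list with `series`
#'   (per-photo means plus `lambda_smooth`), `normalized`, `profile` (with
#'   `mean_smooth`), and `correlations` (or `NULL` for a single operator).
#' @export
analyze_records <- function(records, p_raw = 10, p_profile = 30) {
  if (is.character(records)) records <- read_records(records)
  series <- average_repeats(records) %>%
    group_by(.data$operator) %>%
    mutate(lambda_smooth = lowess_smooth(as.numeric(.data$capture_time),
                                         .data$lambda, p = p_raw)) %>%
    ungroup()
  normalized <- normalize_per_day(series)
  profile <- hourly_profile(normalized) %>%
    group_by(.data$operator) %>%
    mutate(mean_smooth = lowess_smooth(.data$hour, .data$mean_pct,
                                       p = p_profile)) %>%
    ungroup()
  correlations <- if (length(unique(records$operator)) >= 2) {
    operator_correlations(profile, p = p_profile)
  }
  structure(list(series = series, normalized = normalized, profile = profile,
                 correlations = correlations,
                 p_raw = p_raw, p_profile = p_profile),
            class = "rhythm_analysis")
}

#' @export
print.rhythm_analysis <- function(x, ...) {
  ops <- unique(x$series$operator)
  cat(sprintf("<rhythm_analysis> %d measurements, %d operator(s)\n",
              nrow(x$series), length(ops)))
  for (op in ops) {
    pr <- x$profile[x$profile$operator == op, ]
    cat(sprintf("  %s: peak hour %02d:00, profile range %.2f-%.2f%%\n",
                op, profile_peak_hour(pr, x$p_profile),
                min(pr$mean_pct), max(pr$mean_pct)))
  }
  if (!is.null(x$correlations)) print(x$correlations)
  invisible(x)
}

#' @rdname analyze_records
#' @param x A `rhythm_analysis` object.
#' @param ... Unused.
#' @export
tidy.rhythm_analysis <- function(x, ...) x$profile

#' @rdname analyze_records
#' @export
glance.rhythm_analysis <- function(x, ...) {
  ops <- unique(x$series$operator)
  tibble(n_measurements = nrow(x$series), n_operators = length(ops),
         n_days = length(unique(x$normalized$day)),
         min_r_hourly = if (is.null(x$correlations)) NA_real_
                        else min(x$correlations$r_hourly))
}
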