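#' Tidy a path-curve fit
#'
#' @param x A `pathcurve_fit` from [staged_fit()] or [fit_outline()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`),
#'   including the drawn width `w_eff`.
#' @export
tidy.pathcurve_fit <- function(x, ...) {
  p <- x$params
  tibble(term = c("lambda", "h", "w", "w_eff", "alpha", "x0", "y0"),
         estimate = c(p$lambda, p$h, p$w, w_eff(p), p$alpha, p$x0, p$y0))
}

#' @rdname tidy.pathcurve_fit
#' @export
glance.pathcurve_fit <- function(x, ...) {
  tibble(lambda = x$params$lambda, energy = x$energy, n_pixels = x$n_pixels,
         evaluations = x$evaluations, n_stages = nrow(x$stage_log),
         rotation_locked = isTRUE(x$params$rotation_locked))
}

#' Plot a sampled path curve
#'
#' @param object A [sample_curve()] result.
#' @param ... Unused.
#' @return A ggplot of the curve in model coordinates.
#' @export
autoplot.sampled_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$side)) +
    ggplot2::geom_path(color = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = sprintf("Path curve, lambda = %.3f",
                                  object$params$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted curve over its contour, or its deviation profile
#'
#' With `type = "overlay"` (default, requires the fit to carry its contour,
#' as fits from [fit_outline()] do) the measured outline and the fitted curve
#' are drawn together in image coordinates. With `type = "deviation"` the
#' straightened per-point distance profile is shown, left base to apex to
#' right base.
#'
#' @param object A `pathcurve_fit`.
#' @param type `"overlay"` or `"deviation"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathcurve_fit <- function(object, type = c("overlay", "deviation"),
                                   ...) {
  type <- match.arg(type)
  if (type == "deviation") {
    if (is.null(object$dmap)) {
      pc_abort("Fit carries no distance map; refit with fit_outline().",
               "pathcurve_bad_input")
    }
    dev <- deviation_profile(object$params, object$dmap, object$sampling)
    return(
      ggplot2::ggplot(dev, ggplot2::aes(x = .data$position,
                                        y = .data$distance)) +
        ggplot2::geom_line(color = "firebrick") +
        ggplot2::labs(x = "curve position (left base to apex to right base)",
                      y = "distance to contour (px)") +
        ggplot2::theme_minimal())
  }
  if (is.null(object$contour)) {
    pc_abort("Fit carries no contour; refit with fit_outline().",
             "pathcurve_bad_input")
  }
  shape <- attr(object$contour, "shape")
  curve <- as_tibble(sample_curve(object$params, object$sampling)) %>%
    mutate(row = shape[1] + 1 - .data$y, col = .data$x)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = as.data.frame(object$contour),
                        ggplot2::aes(x = .data$col, y = .data$row),
                        size = 0.3, color = "goldenrod3") +
    ggplot2::geom_path(data = curve,
                       ggplot2::aes(x = .data$col, y = .data$row,
                                    group = .data$side),
                       color = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (px)", y = "row (px)") +
    ggplot2::theme_minimal()
}

#' Plot a rhythm analysis
#'
#' `type = "profile"` shows the daily profiles (mean +/- SE per hour with the
#' LOWESS curve); `type = "series"` the raw per-photo mean series with its
#' smoother.
#'
#' @param object A [analyze_records()] result.
#' @param type `"profile"` or `"series"`.
#' @param ... Unused.
#' @return A ggplot, faceted by operator when several are present.
#' @export
autoplot.rhythm_analysis <- function(object, type = c("profile", "series"),
                                     ...) {
  type <- match.arg(type)
  if (type == "series") {
    return(
      ggplot2::ggplot(object$series,
                      ggplot2::aes(x = .data$capture_time, y = .data$lambda,
                                   color = .data$operator)) +
        ggplot2::geom_point(size = 0.8, alpha = 0.7) +
        ggplot2::geom_line(ggplot2::aes(y = .data$lambda_smooth)) +
        ggplot2::labs(x = "capture time", y = "lambda (mean of repeats)") +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$hour, y = .data$mean_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        color = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$se_pct,
                                        ymax = .data$mean_pct + .data$se_pct),
                           width = 0.3, color = "steelblue") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_smooth), color = "purple") +
    ggplot2::facet_wrap(~operator) +
    ggplot2::labs(x = "hour of day", y = "lambda (% of daily mean)") +
    ggplot2::theme_minimal()
}
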