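#' Path-curve parameters
#'
#' Bundles the six parameters that define a two-dimensional path curve in an
#' image: the shape parameter `lambda` (`lambda = 1` is a symmetric egg,
#' `lambda > 1` sharpens the apex, `0 < lambda < 1` sharpens the base), the
#' height `h` and width factor `w` in pixels, a rotation `alpha` in radians
#' about the curve's center, and a translation `(x0, y0)` in model
#' coordinates. The drawn half-width scale is always the product
#' `w_eff = w * lambda`, which is the value the optimizer actually moves when
#' it alters the width; both `w` and `w_eff` are reported in measurement
#' records.
#'
#' Model space is y-up with the curve base at the origin and the apex at
#' `(0, h)` before rotation and translation. Conversion to image space (row 1
#' at the top) happens only at rasterization time via a single flip,
#' `row = nrow + 1 - y`, `col = x`.
#'
#' @param lambda Shape parameter, must be positive. Vortex forms
#'   (`lambda < 0`) are not supported.
#' @param h Curve height in pixels, positive.
#' @param w Width factor in pixels, positive. The drawn half-width scale is
#'   `w * lambda`.
#' @param alpha Rotation in radians about the curve center `(0, h/2)`;
#'   normalized to `(-pi, pi]`. Positive values rotate the apex toward
#'   positive x (clockwise in model space).
#' @param x0,y0 Translation in model coordinates (pixels).
#' @param rotation_locked Logical; when `TRUE` the optimizer never alters
#'   `alpha` (set by [apply_mirror_axis()]).
#'
#' @return An object of class `path_curve_params`.
#' @seealso [sample_curve()], [staged_fit()]
#' @export
#' @examples
#' path_curve_params(lambda = 1.2, h = 200, w = 100)
path_curve_params <- function(lambda, h, w, alpha = 0, x0 = 0, y0 = 0,
                              rotation_locked = FALSE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, is.finite(lambda),
            is.numeric(h), length(h) == 1, is.finite(h),
            is.numeric(w), length(w) == 1, is.finite(w),
            is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            is.numeric(x0), length(x0) == 1, is.finite(x0),
            is.numeric(y0), length(y0) == 1, is.finite(y0))
  if (lambda <= 0) {
    pc_abort("`lambda` must be > 0 (vortex forms are not supported).",
             "pathcurve_bad_lambda")
  }
  if (h <= 0 || w <= 0) {
    pc_abort("`h` and `w` must be positive.", "pathcurve_bad_params")
  }
  structure(
    list(lambda = lambda, h = h, w = w,
         alpha = normalize_angle(alpha), x0 = x0, y0 = y0,
         rotation_locked = isTRUE(rotation_locked)),
    class = "path_curve_params"
  )
}

# Wrap an angle into (-pi, pi].
normalize_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  if (a == -pi) a <- pi
  a
}

#' @export
print.path_curve_params <- function(x, ...) {
  cat(sprintf(
    "<path_curve_params> lambda=%.4f h=%.1f w=%.2f (w_eff=%.2f) alpha=%.4f x0=%.1f y0=%.1f%s\n",
    x$lambda, x$h, x$w, w_eff(x), x$alpha, x$x0, x$y0,
    if (x$rotation_locked) " [rotation locked]" else ""))
  invisible(x)
}

#' Effective (drawn) width scale
#'
#' The drawing always uses the product `w * lambda` as its half-width scale,
#' so that the stored width factor `w` and the shape parameter act on the
#' drawn curve through a single quantity.
#'
#' @param params A [path_curve_params()] object.
#' @return The drawn half-width scale in pixels.
#' @export
w_eff <- function(params) params$w * params$lambda

#' Sampling grid for the curve parameter
#'
#' The curve is evaluated on an equidistant grid of the parameter `tau`.
#' Values beyond about +/-20 are indistinguishable from the limit points at
#' raster resolution, so the default grid spans `[-20, 20]` with step 0.05,
#' which yields 801 points per curve side.
#'
#' @param tau_min,tau_max Grid bounds, `tau_min < tau_max`.
#' @param step Grid spacing, positive.
#' @return An object of class `curve_sampling`.
#' @export
curve_sampling <- function(tau_min = -20, tau_max = 20, step = 0.05) {
  stopifnot(is.numeric(tau_min), is.numeric(tau_max), is.numeric(step),
            tau_min < tau_max, step > 0)
  structure(list(tau_min = tau_min, tau_max = tau_max, step = step),
            class = "curve_sampling")
}

#' Number of sample points per curve side
#' @param sampling A [curve_sampling()] object.
#' @return Integer point count, `round((tau_max - tau_min)/step) + 1`.
#' @export
n_sample_points <- function(sampling) {
  as.integer(round((sampling$tau_max - sampling$tau_min) / sampling$step)) + 1L
}

tau_grid <- function(sampling) {
  sampling$tau_min + sampling$step * (seq_len(n_sample_points(sampling)) - 1L)
}

#' Normalized height along the curve
#'
#' Maps the curve parameter to the normalized height `u` in `(0, 1)` via a
#' logistic, `u(tau) = 1 / (1 + exp(-rate * tau))`. The curve itself uses
#' `rate = 1 + lambda`, the rate at which the projective parameterisation
#' approaches base (`u = 0`) and apex (`u = 1`); for equidistant `tau` the
#' resulting points lie denser toward both ends of the curve.
#'
#' @param tau Numeric vector of curve parameter values.
#' @param rate Positive logistic rate (the curve uses `1 + lambda`).
#' @return Values in `(0, 1)`, strictly increasing in `tau`; `u(0) = 0.5`.
#' @export
#' @examples
#' normalized_height(0)            # 0.5
#' normalized_height(-20) < 1e-8   # TRUE
normalized_height <- function(tau, rate = 1) {
  stopifnot(is.numeric(tau), all(is.finite(tau)), rate > 0)
  1 / (1 + exp(-rate * tau))
}

#' Path-curve profile radius
#'
#' The half-width of the egg profile at normalized height `u`,
#' `r(u) = w_eff * u^(1/(1+lambda)) * (1-u)^(lambda/(1+lambda))`, with `u = 0`
#' at the base and `u = 1` at the apex. For `lambda > 1` the apex is sharper
#' and the base flatter; for `0 < lambda < 1` the opposite; `lambda = 1` is
#' symmetric.
#'
#' @param u Normalized height(s) in `[0, 1]`.
#' @param lambda Positive shape parameter.
#' @param w_eff Drawn half-width scale in pixels, positive.
#' @return Radius in pixels; zero exactly at `u = 0` and `u = 1`.
#' @export
#' @examples
#' profile_radius(0.5, lambda = 1, w_eff = 100) # 50
profile_radius <- function(u, lambda, w_eff) {
  stopifnot(is.numeric(u), all(u >= 0 & u <= 1))
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    pc_abort("`lambda` must be a single positive number.",
             "pathcurve_bad_lambda")
  }
  stopifnot(w_eff > 0)
  a <- 1 / (1 + lambda)
  # powers grouped first so the lambda = 1 profile is symmetric bit-exactly
  w_eff * (u^a * (1 - u)^(1 - a))
}

#' Sample a path curve
#'
#' Evaluates both sides of the path curve on the `tau` grid, in model
#' coordinates. Each grid value gives the normalized height
#' `u = 1/(1 + exp(-(1+lambda) tau))` and the two points
#' `(-r(u), h u)` and `(+r(u), h u)` with `r` from [profile_radius()] at the
#' drawn width `w_eff = w * lambda`; the points are then rotated by `alpha`
#' about the curve center `(0, h/2)` and translated by `(x0, y0)`.
#'
#' @param params A [path_curve_params()] object.
#' @param sampling A [curve_sampling()] object.
#' @return An object of class `sampled_curve`: a list with `left` and `right`
#'   (n x 2 matrices of model x, y ordered base to apex), `u` (normalized
#'   heights), `params` and `sampling`.
#' @export
sample_curve <- function(params, sampling = curve_sampling()) {
  stopifnot(inherits(params, "path_curve_params"),
            inherits(sampling, "curve_sampling"))
  tau <- tau_grid(sampling)
  u <- normalized_height(tau, rate = 1 + params$lambda)
  r <- profile_radius(u, params$lambda, w_eff(params))
  y <- params$h * u
  structure(
    list(left = transform_points(-r, y, params),
         right = transform_points(r, y, params),
         u = u, params = params, sampling = sampling),
    class = "sampled_curve"
  )
}

# Rotation by alpha about (0, h/2) followed by translation (x0, y0).
transform_points <- function(x, y, params) {
  ca <- cos(params$alpha); sa <- sin(params$alpha)
  yc <- y - params$h / 2
  cbind(x = x * ca + yc * sa + params$x0,
        y = -x * sa + yc * ca + params$h / 2 + params$y0)
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("<sampled_curve> %d points per side, lambda=%.4f\n",
              nrow(x$left), x$params$lambda))
  invisible(x)
}

#' @rdname sample_curve
#' @param x A `sampled_curve`.
#' @param ... Unused.
#' @export
as_tibble.sampled_curve <- function(x, ...) {
  bind_rows(
    tibble(side = "left", tau = tau_grid(x$sampling), u = x$u,
           x = x$left[, 1], y = x$left[, 2]),
    tibble(side = "right", tau = tau_grid(x$sampling), u = x$u,
           x = x$right[, 1], y = x$right[, 2])
  )
}

# Digital differential analyzer: pixel chain covering a polyline given in
# continuous image coordinates. Consecutive emitted pixels are 8-connected
# (step count per segment is max(|dx|, |dy|) rounded up). Returns an n x 2
# matrix of (row, col) integer pixels, consecutive duplicates removed.
dda_polyline <- function(row, col) {
  n <- length(row)
  if (n == 1L) return(cbind(round(row), round(col)))
  dr <- diff(row); dc <- diff(col)
  ns <- pmax(1L, ceiling(pmax(abs(dr), abs(dc))))
  idx <- rep.int(seq_len(n - 1L), ns)
  frac <- sequence(ns) / ns[idx]
  r <- round(c(row[1], row[idx] + dr[idx] * frac))
  c <- round(c(col[1], col[idx] + dc[idx] * frac))
  keep <- c(TRUE, diff(r) != 0 | diff(c) != 0)
  cbind(r[keep], c[keep])
}

# Model -> continuous image coordinates (row 1 at top).
model_to_image <- function(pts, shape) {
  cbind(row = shape[1] + 1 - pts[, 2], col = pts[, 1])
}

#' Rasterize a sampled curve
#'
#' Connects consecutive sample points of each curve side with straight line
#' segments and returns the set of integer pixels they cover in an image of
#' the given shape. Pixels falling outside the image are retained and flagged
#' so the fitting energy can penalize them instead of silently clamping.
#'
#' @param curve A [sample_curve()] result.
#' @param shape Integer vector `c(rows, cols)` of the target image.
#' @return A tibble with columns `row`, `col` (integer pixels, unique) and
#'   `oob` (logical, `TRUE` when the pixel lies outside the image).
#' @export
rasterize_curve <- function(curve, shape) {
  stopifnot(inherits(curve, "sampled_curve"), length(shape) == 2)
  l <- model_to_image(curve$left, shape)
  r <- model_to_image(curve$right, shape)
  px <- rbind(dda_polyline(l[, 1], l[, 2]), dda_polyline(r[, 1], r[, 2]))
  keep <- !duplicated(complex(real = px[, 1], imaginary = px[, 2]))
  px <- px[keep, , drop = FALSE]
  tibble(row = as.integer(px[, 1]), col = as.integer(px[, 2]),
         oob = px[, 1] < 1 | px[, 1] > shape[1] |
               px[, 2] < 1 | px[, 2] > shape[2])
}
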