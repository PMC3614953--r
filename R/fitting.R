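#' Energy configuration: apex/base cut-off bands
#'
#' Mistletoe berries carry a small cap at the apex and sit on a stipe at the
#' base; both deviate from the ideal path-curve shape. Fractions of the curve
#' near apex and base can therefore be excluded from the congruence measure.
#'
#' @param cut_top Fraction of the curve height excluded at the apex.
#' @param cut_bottom Fraction excluded at the base.
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(cut_top = 0.05, cut_bottom = 0.10) {
  stopifnot(cut_top >= 0, cut_bottom >= 0, cut_top + cut_bottom < 0.5)
  structure(list(cut_top = cut_top, cut_bottom = cut_bottom),
            class = "energy_config")
}

#' Hill-climbing configuration
#'
#' The greedy search alters the curve parameters by a proportion `delta`,
#' keeping any alteration that lowers the energy; when no alteration improves,
#' `delta` is divided by `decay`, and the search stops once `delta` reaches
#' `delta_min`. With the defaults the `delta` schedule is exactly
#' `0.5 / 1.6^k`, k = 0..9.
#'
#' @param delta0 Initial alteration proportion.
#' @param decay Divisor applied to `delta` when no alteration improves.
#' @param delta_min Stopping threshold for `delta`.
#' @param mode Which parameters may be altered: `"full"` (all six),
#'   `"width_only"` (the drawn width), or `"lambda_only"`.
#' @param rotation_locked When `TRUE`, `alpha` is never altered (used after
#'   the operator fixes the mirror axis).
#' @return An object of class `hill_climb_config`.
#' @export
hill_climb_config <- function(delta0 = 0.5, decay = 1.6, delta_min = 0.005,
                              mode = c("full", "width_only", "lambda_only"),
                              rotation_locked = FALSE) {
  mode <- match.arg(mode)
  stopifnot(delta0 > delta_min, delta_min > 0, decay > 1)
  structure(list(delta0 = delta0, decay = decay, delta_min = delta_min,
                 mode = mode, rotation_locked = isTRUE(rotation_locked)),
            class = "hill_climb_config")
}

#' Curve-to-contour congruence energy
#'
#' Rasterizes the curve (after removing the apex/base cut bands), looks up the
#' Euclidean distance of every curve pixel to the measured contour in the
#' distance map, and returns the mean of the squared distances together with
#' the pixel count `n`. A perfectly fitted curve has energy 0: every pixel
#' lies on the measured contour. Curve pixels outside the image are assigned
#' the image diagonal as penalty distance, which pushes the optimizer back
#' into frame.
#'
#' @param params A [path_curve_params()] object.
#' @param dmap Distance map from [distance_map()].
#' @param ecfg An [energy_config()].
#' @param sampling A [curve_sampling()].
#' @return A list with `value` (mean squared distance, px^2) and `n` (number
#'   of scored pixels).
#' @section Errors: Raises `pathcurve_degenerate_curve` when fewer than 32
#'   pixels survive the cut bands.
#' @export
curve_energy <- function(params, dmap, ecfg = energy_config(),
                         sampling = curve_sampling()) {
  shape <- dim(dmap)
  px <- scored_pixels(params, shape, ecfg, sampling)
  n <- nrow(px)
  if (n < 32) {
    pc_abort("Degenerate curve: fewer than 32 pixels survive the cut bands.",
             "pathcurve_degenerate_curve")
  }
  penalty <- sqrt(shape[1]^2 + shape[2]^2)
  inb <- px[, 1] >= 1 & px[, 1] <= shape[1] & px[, 2] >= 1 & px[, 2] <= shape[2]
  d <- rep(penalty, n)
  d[inb] <- dmap[px[inb, , drop = FALSE]]
  list(value = sum(d^2) / n, n = n)
}

# Unique raster pixels of the curve with cut bands applied (matrix row, col;
# may include out-of-frame pixels).
scored_pixels <- function(params, shape, ecfg, sampling) {
  tau <- tau_grid(sampling)
  u <- normalized_height(tau, rate = 1 + params$lambda)
  keep <- u >= ecfg$cut_bottom & u <= 1 - ecfg$cut_top
  u <- u[keep]
  r <- profile_radius(u, params$lambda, w_eff(params))
  y <- params$h * u
  l <- model_to_image(transform_points(-r, y, params), shape)
  rt <- model_to_image(transform_points(r, y, params), shape)
  px <- rbind(dda_polyline(l[, 1], l[, 2]), dda_polyline(rt[, 1], rt[, 2]))
  px[!duplicated(complex(real = px[, 1], imaginary = px[, 2])), , drop = FALSE]
}

#' Candidate parameter alterations
#'
#' Deterministic candidate set for one hill-climbing sweep. For each active
#' parameter two candidates are generated, the decrease before the increase,
#' in the fixed order lambda, h, w, alpha, x0, y0. Scale-like parameters move
#' multiplicatively by `(1 +/- delta)`; position-like ones additively by
#' `delta * 0.2` rad (`alpha`) or `delta * 0.2 * h` px (`x0`, `y0`).
#'
#' A lambda alteration holds the drawn width `w_eff = w * lambda` fixed (the
#' stored `w` is co-adjusted), so that altering lambda changes the bow of the
#' curve rather than its width; a width alteration scales `w_eff` via `w`.
#'
#' @param params Current [path_curve_params()].
#' @param delta Alteration proportion, positive.
#' @param mode `"full"`, `"width_only"` or `"lambda_only"`.
#' @param rotation_locked When `TRUE`, `alpha` candidates are omitted.
#' @return A list of `path_curve_params` candidates (12 for unlocked full
#'   mode, 10 locked, 2 for the single-parameter modes).
#' @export
propose_alterations <- function(params, delta,
                                mode = c("full", "width_only", "lambda_only"),
                                rotation_locked = FALSE) {
  mode <- match.arg(mode)
  stopifnot(delta > 0)
  active <- switch(mode,
    width_only = "w",
    lambda_only = "lambda",
    full = c("lambda", "h", "w", "alpha", "x0", "y0"))
  if (rotation_locked) active <- setdiff(active, "alpha")
  out <- vector("list", 2L * length(active))
  i <- 0L
  for (nm in active) {
    for (s in c(-1, 1)) {
      q <- params
      if (nm == "lambda") {
        f <- 1 + s * delta
        q$lambda <- params$lambda * f
        q$w <- params$w / f          # keep w_eff = w * lambda unchanged
      } else if (nm %in% c("h", "w")) {
        q[[nm]] <- params[[nm]] * (1 + s * delta)
      } else if (nm == "alpha") {
        q$alpha <- normalize_angle(params$alpha + s * delta * 0.2)
      } else {
        q[[nm]] <- params[[nm]] + s * delta * 0.2 * params$h
      }
      i <- i + 1L
      out[[i]] <- q
    }
  }
  out[seq_len(i)]
}

#' Hill-climbing parameter search
#'
#' Greedy local search over the curve parameters: at each alteration
#' proportion `delta`, all candidate alterations are evaluated and the best
#' strictly improving one is accepted, repeating until none improves; then
#' `delta` is divided by `decay` until it reaches `delta_min`. The accepted
#' energies form a non-increasing sequence and the result is fully
#' deterministic.
#'
#' @param start Starting [path_curve_params()].
#' @param dmap Distance map of the measured contour.
#' @param ecfg An [energy_config()].
#' @param hcfg A [hill_climb_config()].
#' @param sampling A [curve_sampling()].
#' @return An object of class `pathcurve_fit`; see [staged_fit()] for the
#'   fields.
#' @export
hill_climb <- function(start, dmap, ecfg = energy_config(),
                       hcfg = hill_climb_config(), sampling = curve_sampling()) {
  rot_locked <- hcfg$rotation_locked || isTRUE(start$rotation_locked)
  e <- curve_energy(start, dmap, ecfg, sampling)
  params <- start
  energy <- e$value
  start_energy <- energy
  nev <- 0L
  trace <- energy
  delta <- hcfg$delta0
  levels <- numeric(0)
  while (delta > hcfg$delta_min) {
    levels <- c(levels, delta)
    repeat {
      cands <- propose_alterations(params, delta, hcfg$mode, rot_locked)
      es <- vapply(cands, function(q) {
        tryCatch(curve_energy(q, dmap, ecfg, sampling)$value,
                 pathcurve_degenerate_curve = function(e) Inf)
      }, numeric(1))
      nev <- nev + length(es)
      if (min(es) < energy) {
        k <- which.min(es)
        params <- cands[[k]]
        energy <- es[k]
        trace <- c(trace, energy)
      } else break
    }
    delta <- delta / hcfg$decay
  }
  n_final <- curve_energy(params, dmap, ecfg, sampling)$n
  new_pathcurve_fit(
    params = params, energy = energy, n_pixels = n_final, evaluations = nev,
    stage_log = tibble(stage = hcfg$mode, start_energy = start_energy,
                       end_energy = energy, evaluations = nev),
    trace = trace, delta_levels = levels, ecfg = ecfg, sampling = sampling)
}

new_pathcurve_fit <- function(params, energy, n_pixels, evaluations, stage_log,
                              trace, delta_levels, ecfg, sampling) {
  structure(list(params = params, energy = energy, n_pixels = n_pixels,
                 evaluations = evaluations, stage_log = stage_log,
                 trace = trace, delta_levels = delta_levels, ecfg = ecfg,
                 sampling = sampling),
            class = "pathcurve_fit")
}

#' @export
print.pathcurve_fit <- function(x, ...) {
  cat(sprintf(
    "<pathcurve_fit> lambda=%.4f energy=%.4f px^2 (n=%d pixels, %d evaluations)\n",
    x$params$lambda, x$energy, x$n_pixels, x$evaluations))
  print(x$stage_log)
  invisible(x)
}

#' Staged curve fit: width, then lambda, then all parameters
#'
#' The hill climbing works particularly well run in three chained cycles:
#' first only the width is optimized, then only lambda (at fixed drawn
#' width), and finally all parameters together. Each stage restarts the
#' `delta` schedule.
#'
#' @inheritParams hill_climb
#' @return An object of class `pathcurve_fit` with fields `params` (the
#'   optimized [path_curve_params()]), `energy` (mean squared distance,
#'   px^2), `n_pixels`, `evaluations` (total energy-function calls on
#'   candidates), `stage_log` (one row per stage with start/end energy) and
#'   `trace` (all accepted energies, non-increasing).
#' @export
staged_fit <- function(start, dmap, ecfg = energy_config(),
                       hcfg = hill_climb_config(), sampling = curve_sampling()) {
  stages <- c("width_only", "lambda_only", "full")
  fit <- NULL
  params <- start
  logs <- list()
  trace <- numeric(0)
  nev <- 0L
  for (st in stages) {
    cfg <- hill_climb_config(hcfg$delta0, hcfg$decay, hcfg$delta_min,
                             mode = st, rotation_locked = hcfg$rotation_locked)
    fit <- hill_climb(params, dmap, ecfg, cfg, sampling)
    params <- fit$params
    logs[[st]] <- fit$stage_log
    trace <- c(trace, fit$trace)
    nev <- nev + fit$evaluations
  }
  new_pathcurve_fit(
    params = params, energy = fit$energy, n_pixels = fit$n_pixels,
    evaluations = nev, stage_log = bind_rows(logs), trace = trace,
    delta_levels = fit$delta_levels, ecfg = ecfg, sampling = sampling)
}

#' Mirror-axis constraint
#'
#' Almost-round berries make the rotation nearly unidentifiable for the hill
#' climber, so the operator marks the intended apex (`top`) and base
#' (`bottom`) of the curve. This fixes the height to the axis length, the
#' rotation to the axis direction, and the translation so the curve base maps
#' onto `bottom`; the returned partial parameters carry
#' `rotation_locked = TRUE` so subsequent fitting leaves the orientation
#' untouched.
#'
#' @param top,bottom Numeric `c(x, y)` positions in image coordinates
#'   (x = column, y = row, y growing downward).
#' @param shape Image shape `c(rows, cols)`.
#' @return A list with `h`, `alpha`, `x0`, `y0` and `rotation_locked = TRUE`,
#'   suitable for [axis_start_params()].
#' @export
apply_mirror_axis <- function(top, bottom, shape) {
  stopifnot(length(top) == 2, length(bottom) == 2, length(shape) == 2)
  if (all(top == bottom)) {
    pc_abort("Mirror axis has zero length.", "pathcurve_zero_length_axis")
  }
  # image (x, y-down) -> model (x, y-up)
  tm <- c(top[1], shape[1] + 1 - top[2])
  bm <- c(bottom[1], shape[1] + 1 - bottom[2])
  d <- tm - bm
  h <- sqrt(sum(d^2))
  alpha <- atan2(d[1], d[2])
  # base of the untransformed curve is (0, 0); after rotation about (0, h/2)
  # it lands at (-h/2 sin a, h/2 (1 - cos a)); translate so it maps to bm.
  list(h = h, alpha = alpha,
       x0 = bm[1] + h / 2 * sin(alpha),
       y0 = bm[2] - h / 2 * (1 - cos(alpha)),
       rotation_locked = TRUE)
}

#' Build start parameters from a mirror axis
#'
#' @param lambda_start Start value for lambda (an integer larger than 10 is
#'   read as milli-lambda, i.e. `lambda * 1000`, matching the convention of
#'   entering e.g. 1000 for lambda = 1).
#' @param axis Result of [apply_mirror_axis()] (or [auto_axis()] +
#'   [apply_mirror_axis()]).
#' @param half_width Estimated maximum half-width of the object in pixels;
#'   used to seed the drawn width.
#' @return A [path_curve_params()] with `rotation_locked = TRUE`.
#' @export
axis_start_params <- function(lambda_start, axis, half_width) {
  lambda0 <- interpret_lambda_start(lambda_start)
  a <- 1 / (1 + lambda0)
  weff0 <- half_width / (a^a * (1 - a)^(1 - a))
  path_curve_params(lambda = lambda0, h = axis$h, w = weff0 / lambda0,
                    alpha = axis$alpha, x0 = axis$x0, y0 = axis$y0,
                    rotation_locked = TRUE)
}

# "Lambda*1000" convention: an integer-valued start above 10 is milli-lambda.
interpret_lambda_start <- function(lambda_start) {
  if (lambda_start > 10) lambda_start / 1000 else lambda_start
}

#' Automatic mirror axis from the silhouette
#'
#' Headless substitute for the operator's apex/base clicks: the axis
#' direction is the principal (largest-variance) axis of the foreground's
#' second moments, oriented so that the wider half of the silhouette is the
#' base. The endpoints come from the silhouette's width profile along the
#' axis: appendages much thinner than the organ (the stipe below the base,
#' the small cap at the apex) are excluded by keeping only the contiguous
#' region wider than 30% of the maximum width, and each end of that region's
#' width trend is extrapolated to zero width to place the base and apex.
#' Reliable when the organ really is wider toward its base; for nearly
#' symmetric silhouettes the orientation is arbitrary and an explicit axis
#' should be preferred.
#'
#' @param bw Logical foreground matrix from [binarize()].
#' @param width_floor Fraction of the maximum width below which the profile
#'   is treated as an appendage rather than the organ.
#' @return A list with `top` and `bottom`, each `c(x, y)` in image
#'   coordinates, ready for [apply_mirror_axis()].
#' @export
auto_axis <- function(bw, width_floor = 0.3) {
  idx <- which(bw, arr.ind = TRUE)
  if (nrow(idx) < 16) {
    pc_abort("No object found for axis estimation.", "pathcurve_no_object")
  }
  x <- idx[, 2]
  y <- nrow(bw) + 1 - idx[, 1]        # model orientation, y up
  cx <- mean(x); cy <- mean(y)
  cv <- stats::cov(cbind(x - cx, y - cy))
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  tproj <- (x - cx) * v[1] + (y - cy) * v[2]
  pproj <- -(x - cx) * v[2] + (y - cy) * v[1]
  ends <- axis_endpoints(tproj, pproj, width_floor)
  if (ends$flip) {
    v <- -v
    ends[c("base", "apex")] <- list(-ends$apex, -ends$base)
  }
  top_m <- c(cx, cy) + ends$apex * v
  bot_m <- c(cx, cy) + ends$base * v
  list(top = c(top_m[1], nrow(bw) + 1 - top_m[2]),
       bottom = c(bot_m[1], nrow(bw) + 1 - bot_m[2]))
}

# Base/apex positions along the axis, plus the orientation decision. The
# organ is the contiguous region wider than width_floor * max width in the
# binned width profile; thin appendages beyond it (stipe, cap) are excluded.
# The gate boundaries are interpolated width-floor crossings, and the
# endpoints come from the first two moments of the axial pixel distribution
# inside the gate: for an egg profile near lambda = 1 the axial density is a
# (truncated) Beta(3/2, 3/2), whose known mean and SD map the measured
# moments onto base and apex sub-pixel-stably. The base is the end with the
# longer appendage (the stipe extends further than the cap); with no
# appendages, the wider half is taken as the base.
axis_endpoints <- function(tproj, pproj, width_floor) {
  nb <- 64
  breaks <- seq(min(tproj) - 1e-6, max(tproj) + 1e-6, length.out = nb + 1)
  bin <- cut(tproj, breaks, labels = FALSE)
  width <- rep(0, nb)
  agg <- vapply(split(abs(pproj), bin), max, numeric(1))
  width[as.integer(names(agg))] <- agg
  centers <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  floor_w <- width_floor * max(width)
  wide <- width >= floor_w
  k <- which.max(width)
  lo <- k; while (lo > 1 && wide[lo - 1]) lo <- lo - 1
  hi <- k; while (hi < nb && wide[hi + 1]) hi <- hi + 1
  cross <- function(i_out, i_in) {
    # interpolated crossing of floor_w between an outside and an inside bin
    if (i_out < 1 || i_out > nb || width[i_out] >= floor_w) return(centers[i_in])
    centers[i_out] + (centers[i_in] - centers[i_out]) *
      (floor_w - width[i_out]) / (width[i_in] - width[i_out])
  }
  gate_lo <- cross(lo - 1, lo)
  gate_hi <- cross(hi + 1, hi)
  inside <- tproj >= gate_lo & tproj <= gate_hi
  m <- mean(tproj[inside])
  s <- sd(tproj[inside])
  bu <- beta_gate_moments(width_floor)
  h_est <- s / bu$sd
  base <- m - bu$mean * h_est
  apex <- base + h_est
  below <- if (lo > 1 && any(width[1:(lo - 1)] > 0)) {
    centers[lo] - centers[min(which(width[1:(lo - 1)] > 0))]
  } else 0
  above <- if (hi < nb && any(width[(hi + 1):nb] > 0)) {
    centers[hi + max(which(width[(hi + 1):nb] > 0))] - centers[hi]
  } else 0
  flip <- if (below > 0 || above > 0) {
    above > below                       # longer appendage marks the base
  } else {
    half <- tproj > (gate_lo + gate_hi) / 2
    mean(abs(pproj[half])) > mean(abs(pproj[!half]))  # wider half is the base
  }
  list(base = base, apex = apex, flip = flip)
}

# Mean and SD of the normalized height u under the symmetric egg's axial
# density w(u) ~ sqrt(u(1-u)), truncated to the gate where the width exceeds
# width_floor of the maximum.
beta_gate_moments <- function(width_floor) {
  ub <- (1 - sqrt(1 - width_floor^2)) / 2
  u <- seq(ub, 1 - ub, length.out = 2001)
  w <- sqrt(u * (1 - u))
  w <- w / sum(w)
  mu <- sum(u * w)
  list(mean = mu, sd = sqrt(sum((u - mu)^2 * w)))
}

#' Deviation profile of a fitted curve
#'
#' For every curve sample point, the (bilinearly interpolated, hence possibly
#' fractional) distance-map value at that point: the two curve sides
#' straightened into one sequence running from the left base up to the apex
#' at the center and down the right side to the right base. A perfect fit is
#' identically zero; localized misfit shows as isolated bumps.
#'
#' @param params Fitted [path_curve_params()].
#' @param dmap Distance map of the measured contour.
#' @param sampling A [curve_sampling()].
#' @return A tibble with columns `position` (1..2n), `side`, `u` and
#'   `distance` (px).
#' @export
deviation_profile <- function(params, dmap, sampling = curve_sampling()) {
  shape <- dim(dmap)
  sc <- sample_curve(params, sampling)
  l <- model_to_image(sc$left, shape)
  r <- model_to_image(sc$right, shape)
  n <- length(sc$u)
  # left base -> apex, then right apex -> base
  rows <- c(l[, 1], rev(r[, 1]))
  cols <- c(l[, 2], rev(r[, 2]))
  tibble(position = seq_len(2L * n),
         side = rep(c("left", "right"), each = n),
         u = c(sc$u, rev(sc$u)),
         distance = bilinear_lookup(dmap, rows, cols))
}

# Bilinear interpolation with the image diagonal as out-of-frame value.
bilinear_lookup <- function(dmap, row, col) {
  nr <- nrow(dmap); nc <- ncol(dmap)
  out <- rep(sqrt(nr^2 + nc^2), length(row))
  inb <- row >= 1 & row <= nr & col >= 1 & col <= nc
  r <- row[inb]; c <- col[inb]
  r0 <- pmin(pmax(floor(r), 1), nr - 1); c0 <- pmin(pmax(floor(c), 1), nc - 1)
  fr <- r - r0; fc <- c - c0
  out[inb] <-
    dmap[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    dmap[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    dmap[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    dmap[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

#' Fit a path curve to a photograph
#'
#' End-to-end single-image pipeline: grayscale conversion, thresholding,
#' outline extraction, exact distance transform, mirror-axis constraint
#' (explicit or automatic), and the staged hill-climbing fit.
#'
#' @param img Grayscale matrix (0-255) or path to a JPEG/PNG file.
#' @param threshold Binarization threshold, 0-255.
#' @param lambda_start Start value of lambda (milli-lambda accepted; see
#'   [axis_start_params()]).
#' @param axis Either `NULL` (use [auto_axis()]) or a list with `top` and
#'   `bottom` points `c(x, y)` in image coordinates.
#' @param polarity Foreground polarity for [binarize()].
#' @param ecfg,hcfg,sampling Configuration objects.
#' @param min_area Minimum object area for [extract_contour()].
#' @return A `pathcurve_fit` whose `params` describe the best-fitting curve;
#'   the binarization threshold and cut fractions used are attached.
#' @export
fit_outline <- function(img, threshold, lambda_start = 1, axis = NULL,
                        polarity = "dark", ecfg = energy_config(),
                        hcfg = hill_climb_config(), sampling = curve_sampling(),
                        min_area = 16) {
  if (is.character(img)) img <- read_image(img)
  gray <- to_gray(img)
  bw <- binarize(gray, threshold, polarity)
  contour <- extract_contour(bw, min_area)
  dmap <- distance_map(contour, dim(bw))
  if (is.null(axis)) axis <- auto_axis(bw)
  partial <- apply_mirror_axis(axis$top, axis$bottom, dim(bw))
  half_width <- axis_half_width(contour, partial, dim(bw))
  start <- axis_start_params(lambda_start, partial, half_width)
  fit <- staged_fit(start, dmap, ecfg, hcfg, sampling)
  fit$threshold <- threshold
  fit$dmap <- dmap
  fit$contour <- contour
  fit
}

# Maximum perpendicular distance of contour pixels from the mirror axis.
axis_half_width <- function(contour, partial, shape) {
  x <- contour$col
  y <- shape[1] + 1 - contour$row
  # axis passes through the base point in model coordinates
  bx <- partial$x0 - partial$h / 2 * sin(partial$alpha)
  by <- partial$y0 + partial$h / 2 * (1 - cos(partial$alpha))
  dirx <- sin(partial$alpha); diry <- cos(partial$alpha)
  perp <- -(x - bx) * diry + (y - by) * dirx
  max(abs(perp))
}
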