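# Ground-truthed synthetic berry photographs and time series. The generator
# emulates the validation study's design: a single berry silhouetted dark
# against a bright background, photographed hourly for six days by a fixed
# camera, its shape carrying a small (~0.5%) circadian lambda modulation; a
# cap at the apex and a stipe at the base deviate from the ideal path curve,
# which is what the energy's cut-off bands are for.

#' Describe a synthetic berry scene
#'
#' @param params True [path_curve_params()] of the berry outline. The default
#'   places a berry of height 300 px in the middle of a 480 x 390 frame -- a
#'   close-up in which the berry fills about two thirds of the height, as a
#'   fixed camera photographing a single berry would deliver.
#' @param shape Image shape `c(rows, cols)`.
#' @param cap Semi-axes `c(rx, ry)` in px of the elliptical cap pasted at the
#'   apex, or `NULL` for none.
#' @param stipe `c(width, length)` in px of the rectangular stipe below the
#'   base, or `NULL` for none.
#' @param bg,fg Background and object intensities (0-255); they must be
#'   separated by at least four noise standard deviations so thresholding
#'   stays trivially solvable.
#' @param vignette Amplitude in intensity units of a horizontal illumination
#'   ramp across the frame.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise.
#' @param seed RNG seed making the rendering deterministic.
#' @return An object of class `berry_scene`.
#' @export
berry_scene <- function(params = path_curve_params(lambda = 1, h = 300,
                                                   w = 180, x0 = 195, y0 = 90),
                        shape = c(480, 390), cap = c(18, 12), stipe = c(15, 27),
                        bg = 200, fg = 30, vignette = 10, noise_sd = 4,
                        seed = 1) {
  stopifnot(inherits(params, "path_curve_params"), length(shape) == 2)
  if (abs(bg - fg) < 4 * noise_sd) {
    pc_abort("Object and background intensities must differ by >= 4 noise SD.",
             "pathcurve_bad_scene")
  }
  structure(list(params = params, shape = as.integer(shape), cap = cap,
                 stipe = stipe, bg = bg, fg = fg, vignette = vignette,
                 noise_sd = noise_sd, seed = seed),
            class = "berry_scene")
}

#' Render a synthetic berry photograph
#'
#' Fills the closed path-curve region at the object intensity, pastes the cap
#' and stipe, applies the illumination ramp and Gaussian intensity noise, and
#' quantizes to 8 bits. Region filling is anti-aliased (2x2 subsampling), so
#' contours carry the realistic ~1 px uncertainty of a real photograph's
#' edge. Rendering is deterministic given the scene seed.
#'
#' @param scene A [berry_scene()].
#' @return A list with `image` (rows x cols matrix, 0-255) and `truth` (a
#'   one-row tibble of the exact parameters).
#' @export
render_berry <- function(scene) {
  withr::with_seed(scene$seed, render_berry_impl(scene))
}

render_berry_impl <- function(scene) {
  p <- scene$params
  nr <- scene$shape[1]; nc <- scene$shape[2]
  # curve must fit in the frame
  sc <- sample_curve(p)
  pts <- model_to_image(rbind(sc$left, sc$right), scene$shape)
  if (min(pts) < 2 || max(pts[, 1]) > nr - 1 || max(pts[, 2]) > nc - 1) {
    pc_abort("Berry outline exceeds the image frame.", "pathcurve_bad_scene")
  }
  coverage <- matrix(0, nr, nc)
  for (dr in c(-0.25, 0.25)) for (dc in c(-0.25, 0.25)) {
    coverage <- coverage + inside_scene(scene, dr, dc)
  }
  coverage <- coverage / 4
  ramp <- matrix(scene$vignette * (2 * (seq_len(nc) - (nc + 1) / 2) / (nc - 1)),
                 nr, nc, byrow = TRUE)
  img <- scene$bg + (scene$fg - scene$bg) * coverage + ramp
  img <- img + rnorm(nr * nc, sd = scene$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))
  truth <- tibble(lambda = p$lambda, h = p$h, w = p$w, w_eff = w_eff(p),
                  alpha = p$alpha, x0 = p$x0, y0 = p$y0)
  list(image = img, truth = truth)
}

# 0/1 inside-test for the berry + cap + stipe at subpixel offset (dr, dc).
inside_scene <- function(scene, dr, dc) {
  p <- scene$params
  nr <- scene$shape[1]; nc <- scene$shape[2]
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE) + dc
  row <- matrix(seq_len(nr), nr, nc) + dr
  # image -> model: undo flip, translation, rotation about (0, h/2)
  xa <- col - p$x0
  ya <- (nr + 1 - row) - p$y0 - p$h / 2
  ca <- cos(p$alpha); sa <- sin(p$alpha)
  x <- xa * ca - ya * sa
  y <- xa * sa + ya * ca + p$h / 2
  u <- pmin(pmax(y / p$h, 0), 1)
  inside <- y > 0 & y < p$h & abs(x) <= profile_radius(u, p$lambda, w_eff(p))
  if (!is.null(scene$cap)) {
    inside <- inside |
      (x / scene$cap[1])^2 + ((y - p$h) / scene$cap[2])^2 <= 1
  }
  if (!is.null(scene$stipe)) {
    inside <- inside |
      (abs(x) <= scene$stipe[1] / 2 & y >= -scene$stipe[2] & y <= 1)
  }
  inside * 1
}

#' Describe a synthetic photo time series
#'
#' Defaults mirror the validation study's design: one photograph every hour
#' for six days (144 images) of a berry whose lambda carries a circadian
#' modulation of 0.5% relative amplitude,
#' `lambda(t) = baseline * (1 + amplitude * cos(2 pi (hour - acrophase) / 24))`,
#' plus small per-shot lambda jitter and sub-pixel camera jitter.
#'
#' @param start Start timestamp (parsed as UTC).
#' @param cadence_hours Hours between shots; must divide 24.
#' @param n_days Number of days.
#' @param lambda_baseline Baseline lambda.
#' @param amplitude Relative circadian amplitude of lambda.
#' @param acrophase Hour of day (0-24) at which lambda peaks.
#' @param lambda_jitter_sd Relative SD of per-shot lambda jitter.
#' @param shift_sd SD in px of per-shot camera translation jitter.
#' @param rot_sd SD in radians of per-shot camera rotation jitter.
#' @param seed RNG seed for the whole series.
#' @return An object of class `series_spec`.
#' @export
series_spec <- function(start = "2011-10-01 00:00:00", cadence_hours = 1,
                        n_days = 6, lambda_baseline = 1, amplitude = 0.005,
                        acrophase = 6, lambda_jitter_sd = 0.002,
                        shift_sd = 0.5, rot_sd = 0.005, seed = 1) {
  stopifnot(cadence_hours > 0, (24 %% cadence_hours) == 0, n_days >= 1,
            amplitude >= 0, lambda_jitter_sd >= 0)
  structure(list(start = as.POSIXct(start, tz = "UTC"),
                 cadence_hours = cadence_hours, n_days = n_days,
                 lambda_baseline = lambda_baseline, amplitude = amplitude,
                 acrophase = acrophase, lambda_jitter_sd = lambda_jitter_sd,
                 shift_sd = shift_sd, rot_sd = rot_sd, seed = seed),
            class = "series_spec")
}

#' Render a synthetic photo time series
#'
#' Writes one EXIF-timestamped JPEG per time point into `directory` plus a
#' `truth.csv` table of the exact parameters behind every image.
#'
#' @param spec A [series_spec()].
#' @param scene Template [berry_scene()]; its `params` provide the berry
#'   geometry that the series modulates.
#' @param directory Output directory (created if needed).
#' @return The truth tibble, invisibly: `filename`, `timestamp`, `hour`,
#'   `lambda_true` and the per-shot geometry.
#' @export
render_series <- function(spec, scene = berry_scene(), directory) {
  stopifnot(inherits(spec, "series_spec"), inherits(scene, "berry_scene"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- as.integer(spec$n_days * 24 / spec$cadence_hours)
  times <- spec$start + 3600 * spec$cadence_hours * (seq_len(n) - 1)
  p0 <- scene$params
  truth <- withr::with_seed(spec$seed, {
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      hr <- as.numeric(format(times[i], "%H")) +
        as.numeric(format(times[i], "%M")) / 60
      lam <- spec$lambda_baseline *
        (1 + spec$amplitude * cos(2 * pi * (hr - spec$acrophase) / 24)) *
        (1 + rnorm(1, sd = spec$lambda_jitter_sd))
      pi_ <- path_curve_params(
        lambda = lam, h = p0$h, w = w_eff(p0) / lam,
        alpha = p0$alpha + rnorm(1, sd = spec$rot_sd),
        x0 = p0$x0 + rnorm(1, sd = spec$shift_sd),
        y0 = p0$y0 + rnorm(1, sd = spec$shift_sd))
      sc_i <- scene
      sc_i$params <- pi_
      rb <- render_berry_impl(sc_i)
      fname <- sprintf("img_%03d.jpg", i)
      write_jpeg_with_time(rb$image, file.path(directory, fname), times[i])
      rows[[i]] <- mutate(rb$truth,
                          filename = fname,
                          timestamp = format(times[i], "%Y-%m-%dT%H:%M:%S"),
                          hour = hr, .before = 1)
    }
    bind_rows(rows)
  })
  readr::write_csv(truth, file.path(directory, "truth.csv"))
  invisible(truth)
}

#' Measure a coded image directory
#'
#' Batch driver for the blinded workflow: codes the directory, then for every
#' code takes `repeats` measurements with [fit_outline()] and appends each to
#' the results CSV. Operator variability can be emulated by jittering the
#' threshold and the mirror-axis endpoints between repeats -- the two places
#' where a human operator's choices enter the measurement.
#'
#' @param directory Directory of images (coded via [code_images()]).
#' @param threshold Binarization threshold.
#' @param operator Operator id written into the records.
#' @param repeats Measurements per image.
#' @param lambda_start Start lambda (milli-lambda accepted).
#' @param threshold_jitter SD of per-repeat threshold jitter (intensity
#'   levels).
#' @param axis_jitter_sd SD in px of per-repeat jitter on the auto-axis
#'   endpoints.
#' @param ecfg,hcfg,sampling Fit configuration.
#' @param seed RNG seed for the operator's jitter stream.
#' @param csv_path Results CSV (default `measurements.csv` in the directory).
#' @return The records tibble for this run, invisibly.
#' @export
measure_directory <- function(directory, threshold, operator = "P1",
                              repeats = 1, lambda_start = 1,
                              threshold_jitter = 0, axis_jitter_sd = 0,
                              ecfg = energy_config(),
                              hcfg = hill_climb_config(),
                              sampling = curve_sampling(), seed = 1,
                              csv_path = file.path(directory, RESULTS_FILE)) {
  set <- code_images(directory)
  rows <- withr::with_seed(seed, {
    out <- vector("list", nrow(set$entries) * repeats)
    k <- 0L
    for (code in set$entries$code) {
      path <- code_path(set, code)
      img <- read_image(path)
      capture <- suppressWarnings(read_capture_time(path))
      for (rep in seq_len(repeats)) {
        th <- round(threshold + rnorm(1, sd = threshold_jitter))
        th <- min(max(th, 1), 255)
        bw <- binarize(img, th)
        axis <- auto_axis(bw)
        if (axis_jitter_sd > 0) {
          axis$top <- axis$top + rnorm(2, sd = axis_jitter_sd)
          axis$bottom <- axis$bottom + rnorm(2, sd = axis_jitter_sd)
        }
        fit <- fit_outline(img, th, lambda_start, axis = axis,
                           ecfg = ecfg, hcfg = hcfg, sampling = sampling)
        rec <- measurement_record(code, basename(path), capture, fit,
                                  operator, threshold = th)
        append_record(rec, csv_path)
        k <- k + 1L
        out[[k]] <- rec
      }
    }
    bind_rows(out)
  })
  invisible(rows)
}
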