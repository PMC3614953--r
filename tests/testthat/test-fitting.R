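test_that("a curve scored against its own raster has energy exactly zero", {
  p <- path_curve_params(1.15, 140, 80, alpha = 0.2, x0 = 100, y0 = 30)
  shape <- c(220, 200)
  dmap <- raster_dmap(p, shape)
  e <- curve_energy(p, dmap, energy_config(0, 0))
  expect_identical(e$value, 0)
  expect_gt(e$n, 32)
  # with cut bands the scored pixels are a subset: still zero
  expect_identical(curve_energy(p, dmap, energy_config())$value, 0)
})

test_that("energy of a curve k px away from a straight contour is about k^2", {
  shape <- c(300, 120)
  # vertical line contour at col 60, long enough to dominate the curve extent
  ct <- tibble::tibble(row = 1:300, col = 60L)
  dmap <- distance_map(ct, shape)
  # a very slim curve hugging the line, then shifted k px sideways
  p0 <- path_curve_params(1, 250, w = 2, x0 = 60, y0 = 25)
  for (k in c(3, 7)) {
    pk <- path_curve_params(1, 250, w = 2, x0 = 60 + k, y0 = 25)
    e <- curve_energy(pk, dmap, energy_config(0, 0))$value
    expect_lt(abs(e - k^2), k + 1)   # slim curve bulges ~1 px around the line
  }
})

test_that("distance-map energy equals exhaustive nearest-contour search", {
  set.seed(11)
  shape <- c(60, 60)
  n <- 25
  pts <- unique(cbind(sample(60, n, TRUE), sample(60, n, TRUE)))
  ct <- tibble::tibble(row = pts[, 1], col = pts[, 2])
  dmap <- distance_map(ct, shape)
  p <- path_curve_params(0.9, 40, 20, x0 = 30, y0 = 10)
  e <- curve_energy(p, dmap, energy_config(0, 0))
  px <- pathcurve:::scored_pixels(p, shape, energy_config(0, 0),
                                  curve_sampling())
  d2 <- vapply(seq_len(nrow(px)), function(i) {
    min((pts[, 1] - px[i, 1])^2 + (pts[, 2] - px[i, 2])^2)
  }, numeric(1))
  expect_equal(e$value, mean(d2))
  expect_identical(e$n, nrow(px))
})

test_that("degenerate curves are rejected from the energy", {
  p <- path_curve_params(1, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  tiny <- path_curve_params(1, h = 1.5, w = 1, x0 = 100, y0 = 30)
  expect_error(curve_energy(tiny, dmap), class = "pathcurve_degenerate_curve")
})

test_that("alteration candidates are deterministic, ordered and counted", {
  p <- path_curve_params(1.2, 100, 50, alpha = 0.1, x0 = 10, y0 = 20)
  full <- propose_alterations(p, 0.5, "full")
  expect_length(full, 12)
  locked <- propose_alterations(p, 0.5, "full", rotation_locked = TRUE)
  expect_length(locked, 10)
  expect_true(all(vapply(locked, function(q) q$alpha == p$alpha, logical(1))))
  expect_length(propose_alterations(p, 0.5, "width_only"), 2)
  expect_length(propose_alterations(p, 0.5, "lambda_only"), 2)
  # order: lambda first, decrease before increase
  expect_equal(full[[1]]$lambda, 1.2 * 0.5)
  expect_equal(full[[2]]$lambda, 1.2 * 1.5)
  # lambda alterations keep the drawn width fixed
  expect_equal(w_eff(full[[1]]), w_eff(p))
  expect_equal(w_eff(full[[2]]), w_eff(p))
  # width alterations scale the drawn width
  widths <- vapply(propose_alterations(p, 0.1, "width_only"), w_eff, numeric(1))
  expect_equal(widths, w_eff(p) * c(0.9, 1.1))
})

test_that("hill climbing follows the printed schedule at a local minimum", {
  p <- path_curve_params(1.1, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  # start at the exact optimum: every sweep fails, one sweep per delta level
  fit <- hill_climb(p, dmap, energy_config(0, 0),
                    hill_climb_config(mode = "full"))
  expect_identical(fit$energy, 0)
  expect_identical(fit$evaluations, 10L * 12L)
  expect_equal(fit$delta_levels, 0.5 / 1.6^(0:9))
  expect_gt(min(fit$delta_levels), 0.005)
  expect_lt(min(fit$delta_levels) / 1.6, 0.005)
})

test_that("accepted energies are non-increasing and width-only mode recovers w", {
  p <- path_curve_params(1.05, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  start <- p; start$w <- p$w * 1.10
  fit <- hill_climb(start, dmap, energy_config(0, 0),
                    hill_climb_config(mode = "width_only"))
  expect_true(all(diff(fit$trace) <= 0))
  expect_lt(abs(fit$params$w - p$w) / p$w, 0.01)
  expect_identical(fit$params$lambda, p$lambda)   # untouched in this mode
})

test_that("fits are deterministic", {
  p <- path_curve_params(0.95, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  start <- p; start$w <- p$w * 0.9; start$lambda <- 1.1; start$h <- p$h * 1.03
  f1 <- staged_fit(start, dmap)
  f2 <- staged_fit(start, dmap)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$energy, f2$energy)
  expect_identical(f1$evaluations, f2$evaluations)
})

test_that("mirror axis fixes height, rotation and base position", {
  shape <- c(480, 640)
  ax <- apply_mirror_axis(top = c(100, 100), bottom = c(100, 200), shape)
  expect_equal(ax$h, 100)
  expect_equal(ax$alpha, 0)
  expect_true(ax$rotation_locked)
  ax2 <- apply_mirror_axis(top = c(200, 100), bottom = c(100, 200), shape)
  expect_equal(ax2$h, 100 * sqrt(2))
  expect_equal(ax2$alpha, pi / 4)
  # the curve base lands on the clicked bottom point
  p <- axis_start_params(1, ax2, half_width = 40)
  base <- pathcurve:::transform_points(0, 0, p)
  expect_equal(base[1], 100, tolerance = 1e-9)
  expect_equal(shape[1] + 1 - base[2], 200, tolerance = 1e-9)
  expect_error(apply_mirror_axis(c(5, 5), c(5, 5), shape),
               class = "pathcurve_zero_length_axis")
})

test_that("milli-lambda start values are understood", {
  expect_equal(pathcurve:::interpret_lambda_start(1000), 1)
  expect_equal(pathcurve:::interpret_lambda_start(850), 0.85)
  expect_equal(pathcurve:::interpret_lambda_start(1.3), 1.3)
})

test_that("axis locking speeds up convergence on a synthetic berry", {
  p <- path_curve_params(1.0, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  start <- p; start$w <- 70; start$lambda <- 1.15
  locked <- start; locked$rotation_locked <- TRUE
  f_locked <- staged_fit(locked, dmap)
  free <- start; free$rotation_locked <- FALSE
  f_free <- staged_fit(free, dmap)
  expect_lt(f_locked$evaluations, f_free$evaluations)
})

test_that("staged fit recovers lambda on noise-free rasters and chains stages", {
  for (lam in c(0.8, 1.0, 1.3)) {
    p <- path_curve_params(lam, 200, 120 / lam, x0 = 130, y0 = 55)
    dmap <- raster_dmap(p, c(320, 260))
    start <- p; start$lambda <- 1.0; start$w <- 120; start$h <- p$h * 1.02
    start$rotation_locked <- TRUE
    fit <- staged_fit(start, dmap, energy_config(0, 0))
    expect_lt(abs(fit$params$lambda - lam), 0.02)
    expect_identical(fit$stage_log$stage,
                     c("width_only", "lambda_only", "full"))
    expect_true(all(fit$energy <= fit$stage_log$end_energy + 1e-12))
  }
})

test_that("staged fit is invariant under integer image translation", {
  lam <- 1.2
  p <- path_curve_params(lam, 200, 120 / lam, x0 = 120, y0 = 40)
  dmap <- raster_dmap(p, c(320, 260))
  start <- p; start$lambda <- 1.0; start$w <- 120; start$rotation_locked <- TRUE
  f0 <- staged_fit(start, dmap, energy_config(0, 0))
  shift <- c(9, -7)  # (x, y) in model coordinates
  p2 <- p; p2$x0 <- p$x0 + shift[1]; p2$y0 <- p$y0 + shift[2]
  dmap2 <- raster_dmap(p2, c(320, 260))
  start2 <- start; start2$x0 <- start$x0 + shift[1]; start2$y0 <- start$y0 + shift[2]
  f2 <- staged_fit(start2, dmap2, energy_config(0, 0))
  expect_lt(abs(f2$params$lambda - f0$params$lambda), 0.005)
})

test_that("deviation profile is zero for a perfect fit and apex-centered", {
  p <- path_curve_params(1.05, 140, 80, x0 = 100, y0 = 30)
  dmap <- raster_dmap(p, c(220, 200))
  dev <- deviation_profile(p, dmap)
  expect_tibble(dev, c("position", "side", "u", "distance"))
  expect_identical(nrow(dev), 2L * 801L)
  expect_lt(max(dev$distance), 1)            # on-raster points, sub-pixel
  # apex (u ~ 1) sits at the center of the sequence
  expect_gt(min(dev$u[c(801, 802)]), 0.999)
  expect_lt(max(dev$u[c(1, 1602)]), 0.001)
  # max >= mean consistency against the energy
  off <- p; off$x0 <- p$x0 + 2
  dev2 <- deviation_profile(off, dmap)
  e2 <- curve_energy(off, dmap, energy_config(0, 0))
  expect_gte(max(dev2$distance)^2, e2$value)
})

test_that("auto axis approximates the true axis on a clean berry", {
  scene <- berry_scene(seed = 5)
  bw <- binarize(render_berry(scene)$image, 115)
  ax <- auto_axis(bw)
  tr <- true_axis(scene$params, scene$shape)
  expect_lt(sqrt(sum((ax$top - tr$top)^2)), 8)
  expect_lt(sqrt(sum((ax$bottom - tr$bottom)^2)), 8)
  # orientation: base below apex for an upright berry
  expect_gt(ax$bottom[2], ax$top[2])
})

test_that("cut bands shield the fit from cap and stipe", {
  lam <- 1.1
  p <- path_curve_params(lam, 300, 180 / lam, x0 = 195, y0 = 90)
  plain <- berry_scene(p, cap = NULL, stipe = NULL, seed = 9)
  dressed <- berry_scene(p, seed = 9)
  ax <- true_axis(p, plain$shape)
  f_plain <- fit_outline(render_berry(plain)$image, 115, axis = ax)
  f_dressed <- fit_outline(render_berry(dressed)$image, 115, axis = ax)
  err_plain <- abs(f_plain$params$lambda - lam)
  err_dressed <- abs(f_dressed$params$lambda - lam)
  expect_lt(err_dressed, 2 * err_plain + 0.005)
})
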