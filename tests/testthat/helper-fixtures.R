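# Shared fixtures: all built in code at test time.

# Brute-force exact Euclidean distance map (the independent oracle).
brute_force_dmap <- function(pts, shape) {
  out <- matrix(0, shape[1], shape[2])
  for (i in seq_len(shape[1])) {
    for (j in seq_len(shape[2])) {
      out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
    }
  }
  out
}

# Distance map of the raster of a curve (noise-free "measured contour").
raster_dmap <- function(params, shape, sampling = curve_sampling()) {
  px <- rasterize_curve(sample_curve(params, sampling), shape)
  px <- px[!px$oob, ]
  distance_map(px, shape)
}

# The operator's mirror-axis clicks for a known berry, in image coordinates.
true_axis <- function(params, shape) {
  apex <- pathcurve:::transform_points(0, params$h, params)
  base <- pathcurve:::transform_points(0, 0, params)
  list(top = c(apex[1], shape[1] + 1 - apex[2]),
       bottom = c(base[1], shape[1] + 1 - base[2]))
}

# A small, fast berry scene for pipeline behavior tests (precision-critical
# tests use the full-size default scene instead).
tiny_scene <- function(lambda = 1, seed = 1, ...) {
  berry_scene(path_curve_params(lambda, h = 100, w = 60 / lambda,
                                x0 = 65, y0 = 30),
              shape = c(160, 130), cap = c(8, 5), stipe = c(6, 10),
              seed = seed, ...)
}

expect_tibble <- function(x, cols) {
  testthat::expect_s3_class(x, "tbl_df")
  testthat::expect_true(all(cols %in% names(x)))
}
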