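# pathcurve

Shape analysis of plant-organ outlines with projective-geometry path curves.

Certain plant organs -- mistletoe (*Viscum album*) berries, tree buds -- have
two-dimensional silhouettes that closely follow the egg-shaped profiles of
*path curves*, a curve family from projective geometry studied by Lawrence
Edwards. One parameter, **λ (lambda)**, captures the profile's character:
λ = 1 is a symmetric egg, λ > 1 sharpens the apex and flattens the base,
0 < λ < 1 the opposite. Because λ is scale-free, tracking it through a series
of photographs turns subtle shape change -- for example a circadian rhythm of
a fraction of a percent -- into a measurable signal.

`pathcurve` is an R toolkit for exactly that workflow:

* **Geometry.** The profile is `r(u) = w_eff · u^(1/(1+λ)) (1−u)^(λ/(1+λ))`
  at normalized height `u ∈ (0,1)`, sampled along
  `u(τ) = 1/(1+e^{−(1+λ)τ})` for τ in [−20, 20] (step 0.05, 801 points per
  side), then rotated, translated and rasterized into image pixels.
* **Image processing.** Operator-chosen thresholding, outer-contour tracing
  of the largest silhouette, and an exact Euclidean distance transform.
* **Fitting.** The congruence of curve and contour is the mean of squared
  distance-map values over the curve's pixels ("energy"; 0 for a perfect
  fit). A deterministic hill climb alters the six parameters
  (λ, h, w, α, x, y) by a proportion δ = 0.5, dividing by 1.6 whenever no
  alteration improves, until δ ≤ 0.005 -- run in three chained cycles
  (width-only, λ-only, all parameters). A mirror axis set by two clicked
  points (or estimated from the silhouette) fixes the orientation first.
* **Blinded batch workflow.** Image directories are shuffled into persisted
  coded orders, measurements are appended to a CSV with EXIF capture times,
  and the operator only ever sees codes and measurement counts.
* **Rhythm statistics.** Repeat averaging, per-day normalization (daily
  mean = 100%), hourly profiles with standard errors, Cleveland LOWESS
  smoothing, and operator-pair Pearson correlations.
* **Synthetic data.** A ground-truthed berry renderer and hourly time-series
  generator (cap, stipe, vignette, sensor noise, camera jitter, EXIF
  timestamps) so the entire pipeline is testable end to end.

## Worked example

Render a synthetic berry photograph, fit it, and inspect the result:

```r
library(pathcurve)

scene <- berry_scene(path_curve_params(lambda = 1.25, h = 300, w = 144,
                                       x0 = 195, y0 = 90), seed = 13)
shot  <- render_berry(scene)

# the operator marks apex and base (x, y image coordinates, top first):
fit <- fit_outline(shot$image, threshold = 115,
                   axis = list(top = c(195, 91), bottom = c(195, 391)))

glance(fit)
#> # A tibble: 1 × 6
#>   lambda energy n_pixels evaluations n_stages rotation_locked
#>    <dbl>  <dbl>    <int>       <int>    <int> <lgl>
#> 1   1.25  0.196      520         166        3 TRUE
```

The fitted λ of 1.2455 recovers the true 1.25 within 0.005; the energy of
0.196 px² says the 520 scored curve pixels sit on average ~0.4 px from the
measured contour (a perfect fit scores exactly 0). `tidy(fit)` lists all six
parameters plus the drawn width `w_eff = w·λ`; `autoplot(fit)` overlays the
fitted curve on the traced contour, and `autoplot(fit, "deviation")` shows
the per-point distance profile from the left base over the apex to the right
base.

A whole blinded series runs as:

```r
dir <- tempfile()
render_series(series_spec(n_days = 6, amplitude = 0.005, acrophase = 6),
              berry_scene(), dir)                 # 144 EXIF-stamped JPEGs
measure_directory(dir, threshold = 115, operator = "P1", repeats = 10,
                  threshold_jitter = 2, axis_jitter_sd = 1, seed = 201)
analysis <- analyze_records(file.path(dir, "measurements.csv"))
print(analysis)
#> <rhythm_analysis> 144 measurements, 1 operator(s)
#>   P1: peak hour 07:00, profile range 99.53-100.37%
autoplot(analysis)            # Daily profile, mean ± SE, with LOWESS
```

The profile peaks within an hour of the injected 06:00 acrophase with a
swing of roughly ±0.4% of the daily mean -- the size of rhythm the method is
designed to resolve.

A command-line wrapper with subcommands `code`, `fit`, `analyze` and
`simulate` is installed at
`system.file("cli", "pathcurve.R", package = "pathcurve")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","pathcurve.R",package="pathcurve"))')" \
    code /path/to/photos --seed 7
```

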