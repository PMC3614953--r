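---
title: "Path-curve shape analysis: model, fitting and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path-curve shape analysis: model, fitting and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcurve)
```

This vignette is the package's own account of its method: the curve model
and its assumptions, the energy and the hill-climbing schedule, the blinded
workflow and rhythm statistics, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was genuinely
open. No empirical claim is made here that the test suite or the acceptance
script does not itself compute.

## The curve model

Path curves are a projective-geometry curve family whose two-dimensional
egg-shaped members fit the silhouettes of many plant organs. The profile is
parameterized by the normalized height $u \in (0,1)$ ($u = 0$ at the base,
$u = 1$ at the apex):

$$ r(u) \;=\; w_{\mathrm{eff}} \; u^{\,1/(1+\lambda)} \, (1-u)^{\,\lambda/(1+\lambda)} $$

$\lambda > 0$ is the single shape parameter: $\lambda = 1$ gives a symmetric
egg, $\lambda > 1$ a sharper apex and flatter base, $0 < \lambda < 1$ the
opposite. The widest point sits at $u = 1/(1+\lambda)$. Negative $\lambda$
(vortex forms) is out of scope and rejected. The curve is traversed along

$$ u(\tau) \;=\; \frac{1}{1 + e^{-(1+\lambda)\tau}},
   \qquad \tau \in [-20, 20], \; \Delta\tau = 0.05 , $$

which is the projective parameterization: equidistant $\tau$ values fall
densest near base and apex, exactly where curvature is highest, and the
endpoints are reached to within $\max(e^{-20}, e^{-20\lambda}) \cdot
w_{\mathrm{eff}}$ — below $10^{-6} h$ for every biologically plausible
$\lambda \ge 0.7$ with $w_{\mathrm{eff}} \lesssim h$. The default grid
yields 801 points per side. The $(1+\lambda)$ rate in $u(\tau)$ (rather
than a fixed-rate logistic) is deliberate: with a fixed rate the
$x$-coordinate at $\tau = \pm 20$ would still be
$\mathcal{O}(10^{-5})\,w_{\mathrm{eff}}$, visibly short of the limit points
at raster precision.

Six parameters place the curve in an image: $\lambda$, the height $h$ (px),
the width factor $w$ (px), a rotation $\alpha$ about the curve center
$(0, h/2)$, and a translation $(x_0, y_0)$. The drawing always uses
$w_{\mathrm{eff}} = w\lambda$ as its width scale, and measurement records
report both. Model space is y-up with the base at the origin; the one flip
to image rows happens at rasterization.

## Energy and hill climbing

The measured contour is turned into an exact Euclidean distance map, so the
congruence of a candidate curve is a set of lookups: the energy is the mean
of squared distance values over the curve's raster pixels, $E =
\frac{1}{n}\sum_i d_i^2$ (px²), 0 exactly when every pixel lies on the
contour. The mean (rather than the sum) makes values comparable across
curves of different pixel counts; $n$ is always reported alongside. Curve
pixels outside the frame are charged the image diagonal, which pushes the
optimizer back into frame. Exactness of the distance transform matters for
the least-squares reading of $E$; the implementation is verified elementwise
against brute-force nearest-pixel search on random fixtures.

The optimizer is a deterministic greedy hill climb. At alteration proportion
$\delta$ each active parameter contributes two candidates (decrease before
increase, in the order $\lambda, h, w, \alpha, x_0, y_0$): multiplicative
$p(1\pm\delta)$ for the scale-like $\lambda, h, w$, additive
$\pm\,0.2\,\delta$ rad for $\alpha$ and $\pm\,0.2\,\delta h$ px for
$x_0, y_0$ (a multiplicative rule is meaningless near zero translation). The
best strictly improving candidate is accepted and the sweep repeats; when no
candidate improves, $\delta$ is divided by 1.6, stopping at
$\delta \le 0.005$ — ten $\delta$ levels from the 0.5 start. Fits are fully
deterministic and their accepted-energy trace is non-increasing.

Two couplings keep the search well-conditioned:

* **$\lambda$ moves at fixed drawn width.** In this parameterization the
  profile's maximum half-width is $w_{\mathrm{eff}} \, a^a b^b$ with
  $a + b = 1$, which varies by under 3% across $\lambda \in [0.5, 2]$ — the
  drawn width is essentially $w_{\mathrm{eff}}$. A $\lambda$ alteration
  therefore co-adjusts $w$ to hold $w_{\mathrm{eff}}$ fixed, so that
  $\lambda$ changes the bow of the curve rather than its width. Without
  this, the $\lambda$-only cycle cannot leave $\lambda \approx 1$: every
  $\lambda$ step would swing the width proportionally and be rejected
  (verified during development; recovery failed across the whole grid).
* **Staged cycles.** A full fit runs three chained hill climbs: width only,
  then $\lambda$ only, then all parameters. Each stage restarts the
  $\delta$ ladder.

Because mistletoe berries are nearly round, the rotation is poorly
identifiable; the workflow therefore fixes a **mirror axis** first. Two
points (apex, base) set $h$, $\alpha$ and the base position, and lock
$\alpha$ for the subsequent fit. Headless runs can use `auto_axis()`: the
direction comes from the silhouette's principal second-moment axis; the
endpoints from the first two moments of the axial pixel distribution inside
the region wider than 30% of the maximum width (for a near-symmetric egg
that distribution is a truncated Beta(3/2, 3/2), so its mean and SD map to
base and apex); and the orientation from the appendage cue — the end with
the longer thin appendage beyond the wide region is the base, because the
stipe extends further than the cap. With no appendage the wider half is
taken as the base, which is ambiguous for $\lambda < 1$ silhouettes; an
explicit axis should be preferred whenever absolute $\lambda$ accuracy
matters.

**Cut-off bands.** Real berries wear a small cap at the apex and sit on a
stipe at the base; neither belongs to the path-curve shape. Fractions of
the curve near apex (default 5%) and base (default 10%) can be excluded
from the energy. The defaults are deliberately conservative: with the
operator axis set, they fully shield the fit from the default cap and stipe
geometries. On clean synthetic berries without appendages the bands should
be set to 0 — they remove exactly the high-curvature regions that are most
informative about $\lambda$, and with the default bands active the
raster-limited recovery error near $\lambda = 1.4$ grows to about 0.03.

## Numerical behavior and precision

$\lambda$ precision is raster-limited. On noise-free synthetic berries of
height 300 px, the staged fit recovers $\lambda$ across the biological
range (0.7–1.4) to within ±0.02 (typically ±0.005); at berry heights near
100 px the quantization of the energy surface already traps the greedy
search ~0.03 away from the optimum near the range edges. A berry should
span at least ~150 px of image height for ±0.02 work.

The energy surface is piecewise constant in the raster, so fits are
sensitive to their starting axis: moving an axis endpoint by 1 px moves the
converged $\lambda$ by up to ~0.02 between neighboring local basins. This
is the reason the measurement workflow averages repeated fits per
photograph — repeats with independently jittered operator input decorrelate
the basins. The validation analysis below uses 10 repeats per photo, the
same design the original three-operator comparison settled on (its series
with only 6 repeats correlated visibly worse than the 10-repeat series).

Ties in the candidate sweep cannot occur in practice (energies are sums of
distinct squared distances), but the rule is deterministic anyway: the
first of the best candidates in the fixed order wins. Degenerate curves
(fewer than 32 scored pixels) raise an error rather than returning a
meaningless energy.

## Blinded workflow and rhythm statistics

Coded measurement prevents the operator from knowing a photograph's capture
time. `code_images()` shuffles a directory once with a seeded RNG and
persists the order in a small versioned text file; re-opening reproduces
the identical mapping, deleting the file is the only way to reshuffle, and
a corrupt order file is refused rather than silently regenerated. The
blinded listing shows codes and measurement counts only; `unblind()` is a
deliberate, separate step. Each completed fit appends one CSV row: code,
filename, EXIF capture time (with provenance; file mtime is the logged
fallback), wall time, operator, all six parameters plus $w_{\mathrm{eff}}$,
energy, pixel count, threshold and cut fractions — enough to reproduce any
measurement.

The rhythm statistics mirror the validation design: per-photo repeat means;
per-day normalization (each calendar day's mean set to 100%, using the
camera's local dates, no timezone arithmetic); hour-of-day means with
standard errors across the contributing days (SD/√n, undefined for a
single day); Cleveland LOWESS (tricube, locally linear, no robustness
iterations) with the neighbor percentage P = 10 for raw series and P = 30
for 24-point daily profiles; and Pearson correlations between operators on
the hours both observed, with the two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$. For peak-hour estimation the profile is
extended periodically by a quarter day before smoothing, since the hour
axis is circular and a linear smoother is unreliable at its ends.

## The synthetic-data generator

`berry_scene()` and `render_series()` emulate the validation study's
conditions: one berry, fixed camera, one photograph per hour for six days
(144 images). The defaults — decided once, on realism grounds — are:

| Quantity | Default | Why |
|---|---|---|
| berry height | 300 px in a 480×390 frame | close-up of a single berry from a fixed DSLR |
| cap / stipe | 18×12 px ellipse / 15×27 px bar | small apex cap, basal peduncle |
| intensities | object 30, background 200 | clearly silhouetted, as the method requires |
| illumination ramp | ±10 intensity | mild uneven lighting |
| sensor noise | SD 4 (and 8 in stress tests) | consumer-camera luminance noise |
| circadian modulation | 0.5% relative amplitude, peak 06:00 | the effect size the method claims to resolve; λ above its daily mean in the first half of the day |
| per-shot λ jitter | 0.2% | biological + exposure variation between shots |
| camera jitter | 0.5 px shift, 0.005 rad rotation | a "fixed" camera is never perfectly fixed |

Rendering inverts the curve transform analytically per pixel, with 2×2
subsampling and 8-bit quantization, so edges carry the realistic ~1 px
uncertainty; images are written as JPEG with an EXIF `DateTimeOriginal`
(via a minimal EXIF segment writer, since no installed package writes
EXIF). Operator variability in `measure_directory()` enters exactly where a
human's choices enter the real workflow: the threshold (jitter SD 2
levels) and the axis clicks (jitter SD 1 px), independently per repeat.

What the generator does **not** emulate: specular highlights, shadows,
defocus, occluding neighbors, background clutter, perspective
foreshortening, or genuinely non-path-curve shape deviations beyond the cap
and stipe. Passing tests therefore demonstrate the pipeline's correctness
and its noise economy under idealized silhouettes, not segmentation
robustness on difficult field photographs — on real data the
operator-supervised threshold and axis remain essential.

## Validation at a glance

The acceptance tests (in `tests/testthat/test-acceptance.R`) compute, among
others: exactly 801 samples per side on the default grid; energy exactly 0
for a curve scored against its own raster; endpoint limits within
$10^{-6}h$; elementwise agreement of the distance transform with brute
force; λ recovery within ±0.02 (noise-free) and ±0.05 (intensity noise
SD 8) across λ = 0.7…1.4; the exact δ schedule 0.5/1.6^k, k = 0…9; profile
symmetry at λ = 1 to machine precision; p = 0.0019 for r = 0.6005 at
n = 24; and full-pipeline recovery of a 0.5% circadian rhythm from 144
rendered photographs measured by two simulated operators (peak hour within
±2 h, hourly-mean correlation r > 0.6). Problem sizes — 480×390 px frames,
144-image series, 10 repeats — are the study-design values stated above.

## Known limitations

* The hill climb is local by design; it inherits the original method's
  reliance on a sensible start. Headless use trades the human supervisor
  for the moment-based auto-axis plus repeat averaging.
* `auto_axis()` orientation is heuristic for silhouettes without a stipe
  cue and near-symmetric width profiles.
* Absolute λ carries a raster-scale bias (size-dependent, up to ~0.01 at
  300 px); within-series *changes* of λ, which the rhythm analysis uses,
  are unaffected.
* LOWESS endpoints of a linear (non-circular) smooth are unreliable; only
  the peak-hour estimator compensates by periodic extension, the plotted
  smooths are the plain Cleveland fits.
* The EXIF support reads and writes timestamps only.
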