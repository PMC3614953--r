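fake_records <- function(lambda_fun, days = 2, operators = "P1", repeats = 1,
                         noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    times <- as.POSIXct("2011-10-01 00:00:00", tz = "UTC") +
      3600 * (seq_len(days * 24) - 1)
    grid <- expand.grid(i = seq_along(times), operator = operators,
                        rep = seq_len(repeats), stringsAsFactors = FALSE)
    tibble::tibble(
      operator = grid$operator,
      filename = sprintf("img_%03d.jpg", grid$i),
      capture_time = times[grid$i],
      lambda = lambda_fun(as.numeric(format(times[grid$i], "%H"))) +
        rnorm(nrow(grid), sd = noise_sd))
  })
}

test_that("repeat averaging is the arithmetic mean, order-invariant", {
  rec <- tibble::tibble(
    operator = "P1", filename = "a.jpg",
    capture_time = as.POSIXct("2011-10-01 05:00:00", tz = "UTC"),
    lambda = c(1.00, 1.02))
  m <- average_repeats(rec)
  expect_equal(m$lambda, 1.01)
  expect_identical(m$n_repeats, 2L)
  expect_equal(average_repeats(rec[2:1, ])$lambda, 1.01)
  single <- average_repeats(rec[1, ])
  expect_equal(single$lambda, 1.00)
  expect_identical(single$n_repeats, 1L)
})

test_that("per-day normalization sets each day's mean to 100 and is idempotent", {
  rec <- fake_records(function(h) 1.0, days = 2)
  n1 <- normalize_per_day(rec)
  expect_true(all(n1$lambda_pct == 100))
  rec2 <- tibble::tibble(
    operator = "P1", filename = c("a", "b"),
    capture_time = as.POSIXct(c("2011-10-01 01:00:00", "2011-10-01 13:00:00"),
                              tz = "UTC"),
    lambda = c(0.9, 1.1))
  expect_equal(normalize_per_day(rec2)$lambda_pct, c(90, 110))
  noisy <- fake_records(function(h) 1 + 0.01 * sin(h), days = 3,
                        noise_sd = 0.01)
  n2 <- normalize_per_day(noisy)
  daily <- dplyr::summarise(dplyr::group_by(n2, day),
                            m = mean(lambda_pct))
  expect_true(all(abs(daily$m - 100) < 1e-10))
  # idempotence: normalizing the normalized series changes nothing
  renorm <- normalize_per_day(dplyr::mutate(n2, lambda = lambda_pct))
  expect_equal(renorm$lambda_pct, n2$lambda_pct)
})

test_that("hourly profile reports means, SEs and day counts", {
  rec <- fake_records(function(h) 1.0, days = 6)
  pr <- hourly_profile(normalize_per_day(rec))
  expect_identical(nrow(pr), 24L)
  expect_true(all(pr$se_pct == 0))
  expect_true(all(pr$n_days == 6L))
  # a sinusoid of amplitude a% shows a peak-trough span of ~2a% at the right phase
  a <- 2
  rec2 <- fake_records(function(h) 1 + a / 100 * cos(2 * pi * (h - 6) / 24),
                       days = 6)
  pr2 <- hourly_profile(normalize_per_day(rec2))
  expect_equal(max(pr2$mean_pct) - min(pr2$mean_pct), 2 * a, tolerance = 0.05)
  expect_identical(profile_peak_hour(pr2), 6L)
  # an hour observed on a single day has no standard error
  rec3 <- rec[format(rec$capture_time, "%H") != "03" |
              as.Date(rec$capture_time) == as.Date("2011-10-01"), ]
  pr3 <- hourly_profile(normalize_per_day(rec3))
  expect_true(is.na(pr3$se_pct[pr3$hour == 3]))
  expect_identical(pr3$n_days[pr3$hour == 3], 1L)
})

test_that("LOWESS reproduces linear data exactly and smooths noise", {
  x <- 1:50
  y <- 2.5 * x - 7
  for (p in c(10, 30, 100)) {
    expect_equal(max(abs(lowess_smooth(x, y, p) - y)), 0, tolerance = 1e-8)
  }
  # P = 100 on linear-plus-noise is close to the least-squares line
  set.seed(3)
  yn <- y + rnorm(50, sd = 1)
  sm <- lowess_smooth(x, yn, 100)
  ols <- unname(stats::fitted(stats::lm(yn ~ x)))
  expect_lt(max(abs(sm - ols)), 0.5)
  # total variation does not increase
  set.seed(4)
  yr <- cumsum(rnorm(60))
  tv <- function(v) sum(abs(diff(v)))
  for (p in c(20, 50)) expect_lte(tv(lowess_smooth(1:60, yr, p)), tv(yr))
  # output is aligned with the input order
  ord <- sample(50)
  expect_equal(lowess_smooth(x[ord], yn[ord], 30),
               lowess_smooth(x, yn, 30)[ord])
})

test_that("pearson correlation matches the t-distribution p-value", {
  a <- c(1, 2, 3, 4, 5); b <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  pc <- pearson_cor(a, a)
  expect_equal(pc$r, 1)
  pc2 <- pearson_cor(a, b)
  expect_equal(pc2$p, pearson_r_pvalue(pc2$r, 5), tolerance = 1e-12)
  # affine invariance (positive scale)
  pc3 <- pearson_cor(3 * a + 2, 0.5 * b - 1)
  expect_equal(pc3$r, pc2$r, tolerance = 1e-12)
  expect_error(pearson_cor(rep(1, 5), b), class = "pathcurve_zero_variance")
})

test_that("the test keeps its nominal type-I rate", {
  set.seed(123)
  n <- 24; reps <- 10000
  a <- matrix(rnorm(n * reps), n)
  b <- matrix(rnorm(n * reps), n)
  r <- vapply(seq_len(reps), function(i) cor(a[, i], b[, i]), numeric(1))
  p <- vapply(r, pearson_r_pvalue, numeric(1), n = n)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.04)
  expect_lt(rate, 0.06)
})

test_that("operator correlations use common hours pairwise", {
  rec <- fake_records(function(h) 1 + 0.02 * cos(2 * pi * (h - 6) / 24),
                      days = 6, operators = c("P1", "P2"), noise_sd = 0.004,
                      seed = 9)
  pr <- hourly_profile(normalize_per_day(rec))
  ct <- operator_correlations(pr)
  expect_tibble(ct, c("op_a", "op_b", "r_hourly", "p_hourly",
                      "r_smoothed", "p_smoothed", "n"))
  expect_identical(ct$n, 24L)
  expect_gt(ct$r_hourly, 0.6)
  direct <- pearson_cor(pr$mean_pct[pr$operator == "P1"],
                        pr$mean_pct[pr$operator == "P2"])
  expect_equal(ct$r_hourly, direct$r)
  expect_equal(ct$p_hourly, direct$p)
})

test_that("profiles are equivariant under day relabeling", {
  rec <- fake_records(function(h) 1 + 0.01 * sin(2 * pi * h / 24), days = 4,
                      noise_sd = 0.002, seed = 5)
  pr1 <- hourly_profile(normalize_per_day(rec))
  shuffled <- rec[sample(nrow(rec)), ]
  shuffled$capture_time <- shuffled$capture_time  # order only; days intact
  pr2 <- hourly_profile(normalize_per_day(shuffled))
  expect_equal(pr1, pr2)
})

test_that("the full analysis chains the pieces and prints a summary", {
  rec <- fake_records(function(h) 1 + 0.01 * cos(2 * pi * (h - 6) / 24),
                      days = 6, operators = c("P1", "P2"), repeats = 2,
                      noise_sd = 0.003, seed = 2)
  an <- analyze_records(rec)
  expect_s3_class(an, "rhythm_analysis")
  expect_tibble(an$profile, c("operator", "hour", "mean_pct", "se_pct",
                              "n_days", "mean_smooth"))
  expect_identical(nrow(an$profile), 48L)
  expect_false(is.null(an$correlations))
  g <- glance(an)
  expect_identical(g$n_operators, 2L)
  expect_identical(g$n_days, 6L)
  expect_output(print(an), "peak hour")
  # constant single day: flat 100% profile
  flat <- analyze_records(fake_records(function(h) 1.0, days = 1))
  expect_true(all(abs(flat$profile$mean_pct - 100) < 1e-10))
  expect_null(flat$correlations)
})
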