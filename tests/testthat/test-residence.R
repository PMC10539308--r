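test_that("immobile runs become dwells with the n_frames * interval convention", {
  still <- track_set(list(make_track(0:9, rep(1, 10), rep(1, 10))),
                     dt = 0.5, regime = "slow")
  dw <- extract_dwells(still)
  expect_equal(dw$durations, 5.0)
  expect_true(dw$censored)  # run ends with the track

  # one 0.5 um jump after the 6th frame splits the track into two runs
  x <- c(rep(0, 6), rep(0.5, 6))
  split_tr <- track_set(list(make_track(0:11, x, rep(0, 12))),
                        dt = 0.5, regime = "slow")
  dw2 <- extract_dwells(split_tr, r_immobile = 0.2)
  expect_equal(dw2$durations, c(3.0, 3.0))
  expect_equal(dw2$censored, c(FALSE, TRUE))
})

test_that("rendered dwell tracks round-trip durations and censoring", {
  cfg <- slow_movie_config(movie_length = 300,
                           k_off_components = list(c(1, 0.03)),
                           k_bleach = 0.01)
  dw <- simulate_slow_movie_dwells(cfg, 800, seed = 51)
  dw2 <- extract_dwells(dwells_to_tracks(dw, seed = 52))
  expect_equal(sort(dw2$durations), sort(dw$durations))
  expect_equal(mean(dw2$censored), mean(dw$censored))
})

test_that("empirical survival matches the two-point example", {
  dw <- dwell_set(c(2.5, 5.0), frame_interval = 0.5)
  cv <- survival_curve(dw)
  expect_equal(survival_eval(cv, c(2.5, 3.0, 5.0, 5.5)),
               c(1, 0.5, 0.5, 0))
})

test_that("survival is invariant to duplicate ordering and ties", {
  d <- c(2.5, 2.5, 3.0, 4.5, 4.5, 6.0)
  c1 <- survival_curve(dwell_set(d, frame_interval = 0.5))
  c2 <- survival_curve(dwell_set(rev(d), frame_interval = 0.5))
  expect_identical(c1$times, c2$times)
  expect_identical(c1$survival, c2$survival)
})

test_that("truncated-exponential survival lies inside the DKW band", {
  k <- 0.05; n <- 1e5
  dur <- withr::with_seed(53, 2.5 + floor(stats::rexp(n, k) / 0.5) * 0.5)
  cv <- survival_curve(dwell_set(dur, frame_interval = 0.5))
  tg <- seq(2.5, 100, by = 0.5)
  eps <- sqrt(log(2 / 0.001) / (2 * n))
  expect_lt(max(abs(survival_eval(cv, tg) - exp(-k * (tg - 2.5)))), eps)
})

test_that("bleach rate is the slowest component of the H2B two-exponential fit", {
  dw <- simulate_slow_movie_dwells(h2b_dwell_fixture(), 5e4, seed = 54)
  est <- estimate_bleach_rate(dw)
  expect_equal(est$k_b, 0.0316, tolerance = 0.1)
  expect_equal(est$k_b, min(est$rates))
})

test_that("noise-free multi-exponential survival is refit exactly", {
  S <- function(t) 0.4 * exp(-0.15 * (t - 2.5)) + 0.6 * exp(-0.0316 * (t - 2.5))
  dw <- dwells_from_survival(S, n = 2e5, t_max = 200)
  est <- suppressWarnings(estimate_bleach_rate(dw))
  expect_equal(est$rates, c(0.0316, 0.15), tolerance = 0.02)
  expect_equal(est$weights, c(0.6, 0.4), tolerance = 0.02)
  expect_lt(est$sse, 1e-4)
})

test_that("single-exponential data collapse both components onto one rate", {
  S <- function(t) exp(-0.05 * (t - 2.5))
  dw <- dwells_from_survival(S, n = 1e5, t_max = 150)
  est <- suppressWarnings(estimate_bleach_rate(dw))
  expect_equal(est$k_b, 0.05, tolerance = 0.02)
  expect_equal(sum(est$weights * est$rates) / sum(est$weights), 0.05,
               tolerance = 0.05)
})

test_that("bleach correction obeys the exponential algebra", {
  tg <- seq(2.5, 200, by = 0.5)
  k_off <- 0.01; k_b <- 0.0316
  cv <- make_curve(tg, exp(-(k_off + k_b) * (tg - 2.5)), corrected = FALSE)
  out <- correct_bleaching(cv, k_b)
  expect_equal(out$survival, exp(-k_off * (tg - 2.5)), tolerance = 1e-12)
  expect_true(out$corrected)
  expect_equal(out$k_b_applied, k_b)
  # k_b = 0 is the identity; double correction is refused
  expect_equal(correct_bleaching(cv, 0)$survival, cv$survival)
  expect_error(correct_bleaching(out, k_b), "twice")
})

test_that("restricted mean survival matches closed forms", {
  tg <- seq(2.5, 100, by = 0.5)
  # S == 1 on the whole window
  top <- make_curve(tg, rep(1, length(tg)))
  s_top <- summarize_residence(top, dwell_set(rep(100, 20),
                                              frame_interval = 0.5),
                               n_resamples = 10, seed = 1)
  expect_equal(s_top$rmst, 97.5, tolerance = 1e-9)
  expect_equal(s_top$frac_gt_end, 1)

  # S = exp(-0.02 (t - 2.5)): closed form (1 - e^-1.95) / 0.02
  cv <- make_curve(tg, exp(-0.02 * (tg - 2.5)))
  expect_lt(abs(mitfkinetics:::.rmst_trapz(cv, 2.5, 100) -
                  (1 - exp(-0.02 * 97.5)) / 0.02), 0.1)
  expect_equal(survival_eval(cv, 100), exp(-0.02 * 97.5), tolerance = 1e-9)
})

test_that("pointwise survival dominance implies RMST ordering", {
  tg <- seq(2.5, 100, by = 0.5)
  a <- make_curve(tg, exp(-0.01 * (tg - 2.5)))
  b <- make_curve(tg, exp(-0.03 * (tg - 2.5)))
  expect_gte(mitfkinetics:::.rmst_trapz(a, 2.5, 100),
             mitfkinetics:::.rmst_trapz(b, 2.5, 100))
})

test_that("delete-half errors are zero for zero-variance dwells and", {
  dw <- dwell_set(rep(10, 40), frame_interval = 0.5)
  cv <- survival_curve(dw)
  s <- summarize_residence(cv, dw, n_resamples = 50, seed = 2,
                           allow_uncorrected = TRUE)
  expect_equal(s$err_rmst, 0)
  expect_equal(s$err_frac, 0)
  expect_true(s$rmst >= 0 && s$rmst <= 97.5)
})

test_that("summaries refuse uncorrected curves and out-of-support windows", {
  cfg <- slow_movie_config(movie_length = 60,
                           k_off_components = list(c(1, 0.05)),
                           k_bleach = 0.02)
  dw <- simulate_slow_movie_dwells(cfg, 2000, seed = 55)
  cv <- survival_curve(dw)
  expect_error(summarize_residence(cv, dw, n_resamples = 5),
               "not bleach-corrected")
  corr <- correct_bleaching(cv, 0.02)
  expect_error(summarize_residence(corr, dw, n_resamples = 5),
               "truncate")
})

test_that("end-to-end residence summary recovers a known k_off", {
  # movie long enough that movie-end truncation inside the 100 s window
  # is a few percent (uniform start times leave a (1 - t/L) deficit the
  # bleach correction does not remove)
  k_off <- 0.02; k_b <- 0.0316
  cfg <- slow_movie_config(movie_length = 2000,
                           k_off_components = list(c(1, k_off)),
                           k_bleach = k_b)
  dw <- simulate_slow_movie_dwells(cfg, 3e4, seed = 56)
  corr <- correct_bleaching(survival_curve(dw), k_b)
  s <- summarize_residence(corr, dw, n_resamples = 200, seed = 57)
  expect_equal(s$rmst, (1 - exp(-k_off * 97.5)) / k_off, tolerance = 0.05)
  expect_equal(s$frac_gt_end, exp(-k_off * 97.5), tolerance = 0.15)
  expect_gt(s$err_rmst, 0)
})
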