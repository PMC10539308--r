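wt <- wt_diffusion_fixture()

test_that("model bin probabilities normalize and peak at the Rayleigh mode", {
  mids <- seq(0.01, 1.49, by = 0.02)
  p <- displacement_bin_prob(wt, mids, 0.02)
  expect_gte(sum(p), 0.999)

  one <- diffusion_params(c(1, 0, 0), c(0.46, 1, 2), dt = 0.01)
  fine <- seq(0.001, 0.5, by = 0.001)
  mode <- fine[which.max(displacement_bin_prob(one, fine, 0.001))]
  expect_equal(mode, sqrt(2 * 0.46 * 0.01), tolerance = 0.01)
})

test_that("cumulative bin probability matches the closed-form CDF", {
  mids <- seq(0.01, 1.49, by = 0.02)
  p <- displacement_bin_prob(wt, mids, 0.02)
  # the bin-center rule carries a small convexity bias vs the exact mass
  expect_lt(abs(sum(p[mids < 0.1]) -
                  oracle_mixture_cdf(0.1, wt$fractions, wt$coeffs, wt$dt)),
            0.02)
})

test_that("a zero-coefficient state appears as a point mass in the first bin", {
  p0 <- diffusion_params(c(0.3, 0.3, 0.4), c(0, 0.4, 3), dt = 0.01)
  p <- displacement_bin_prob(p0, seq(0.01, 1.49, 0.02), 0.02)
  expect_gte(p[1], 0.3)
})

test_that("simulated histogram is consistent with the model (chi-square)", {
  r <- simulate_jumps(wt, 1e5, seed = 41)
  h <- jump_histogram(r, dt = wt$dt)
  expect_equal(sum(h$counts) + h$overflow, h$n_jumps)
  # exact per-bin masses from the closed-form CDF (the bin-center rule of
  # displacement_bin_prob is biased at this sample size)
  cdf <- oracle_mixture_cdf(h$breaks, wt$fractions, wt$coeffs, wt$dt)
  p <- diff(cdf)
  probs <- c(p, max(1 - sum(p), 1e-12))
  obs <- c(h$counts, h$overflow)
  keep <- probs * h$n_jumps >= 5
  stat <- sum((obs[keep] - h$n_jumps * probs[keep])^2 /
                (h$n_jumps * probs[keep]))
  pval <- stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.001)
})

test_that("histogram construction from tracks counts every consecutive jump", {
  ts <- track_set(list(make_track(0:4, rep(0, 5))), dt = 0.01)
  hl <- build_jump_histogram(ts)
  expect_equal(hl[[1]]$n_jumps, 4L)        # L points -> L-1 jumps
  expect_equal(hl[[1]]$counts[1], 4L)      # stationary -> all in [0, 0.02)
  expect_error(build_jump_histogram(
    track_set(list(make_track(0, 0)), dt = 0.01)), "no jumps")
})

test_that("single-component data collapse onto one fitted component", {
  p1 <- diffusion_params(c(1, 0, 0), c(0.03, 0.4, 3), dt = 0.01)
  r <- simulate_jumps(p1, 5e4, seed = 42)
  fit <- fit_three_component(jump_histogram(r, dt = 0.01))
  expect_gte(fit$params$fractions[1], 0.95)
  expect_equal(fit$params$coeffs[1], 0.03, tolerance = 0.1)
})

test_that("refitting the model's exact expected fractions returns the truth", {
  mids <- seq(0.01, 1.49, by = 0.02)
  p <- displacement_bin_prob(wt, mids, 0.02)
  N <- 1e6
  h <- structure(
    list(breaks = seq(0, 1.5, 0.02), mids = mids, counts = p * N,
         overflow = (1 - sum(p)) * N, n_jumps = N, bin_width = 0.02,
         dt = 0.01, cell_id = "exact"),
    class = "jump_histogram"
  )
  fit <- fit_three_component(h)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$params$fractions, wt$fractions, tolerance = 0.01)
  expect_equal(fit$params$coeffs, wt$coeffs, tolerance = 0.01)
})

test_that("wild-type fixture parameters are recovered within 10 percent", {
  r <- simulate_jumps(wt, 2e5, seed = 43)
  fit <- fit_three_component(jump_histogram(r, dt = wt$dt))
  expect_true(fit$converged)
  expect_equal(fit$params$fractions[1], 0.44, tolerance = 0.1)
  expect_equal(fit$params$fractions[2], 0.34, tolerance = 0.1)
  expect_equal(fit$params$coeffs, c(0.034, 0.46, 3.4), tolerance = 0.1)
})

test_that("fitted fractions stay on the simplex with sorted coefficients", {
  for (seed in 44:46) {
    r <- simulate_jumps(wt, 2e4, seed = seed)
    fit <- fit_three_component(jump_histogram(r, dt = wt$dt))
    expect_equal(sum(fit$params$fractions), 1, tolerance = 1e-9)
    expect_true(all(fit$params$fractions >= 0))
    expect_true(all(diff(fit$params$coeffs) > 0))
  }
})

test_that("supplying an initialization does not change the optimum found", {
  r <- simulate_jumps(wt, 5e4, seed = 47)
  h <- jump_histogram(r, dt = wt$dt)
  f_default <- fit_three_component(h)
  f_init <- fit_three_component(h, init = wt)
  expect_equal(f_init$params$fractions, f_default$params$fractions,
               tolerance = 0.02)
  expect_equal(f_init$params$coeffs, f_default$params$coeffs,
               tolerance = 0.02)
})

test_that("pinning D1 fixes the slowest coefficient exactly", {
  r <- simulate_jumps(wt, 5e4, seed = 48)
  fit <- fit_three_component(jump_histogram(r, dt = wt$dt), fix_d1 = 0.034)
  expect_equal(fit$params$coeffs[1], 0.034, tolerance = 1e-6)
})

test_that("a sparse histogram warns but still fits", {
  r <- simulate_jumps(wt, 500, seed = 49)
  expect_warning(fit <- fit_three_component(jump_histogram(r, dt = wt$dt)),
                 "500 jumps")
  expect_s3_class(fit, "diffusion_fit")
})

test_that("identical groups give H = 0, p = 1 in the group comparison", {
  df <- data.frame(condition = rep(c("a", "b"), each = 3),
                   F1 = rep(c(0.4, 0.45, 0.5), 2))
  cmp <- compare_groups(df, "F1")
  expect_equal(cmp$tests$H, 0)
  expect_equal(cmp$tests$p_value, 1)
  expect_equal(cmp$summaries$median, c(0.45, 0.45))
})

test_that("group comparison holds its type-I error rate under the null", {
  reject <- withr::with_seed(50, {
    vapply(1:1000, function(i) {
      df <- data.frame(condition = rep(c("a", "b", "c"), each = 10),
                       s = stats::rnorm(30))
      compare_groups(df, "s")$tests$p_value < 0.05
    }, logical(1))
  })
  # 3 sigma binomial band around 5%
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("per-cell median bound fraction recovers the generating value", {
  f1 <- vapply(1:20, function(i) {
    r <- simulate_jumps(wt, 1e4, seed = 600 + i)
    fit_three_component(jump_histogram(r, dt = wt$dt))$params$fractions[1]
  }, numeric(1))
  expect_lt(abs(stats::median(f1) - 0.44), 0.03)
})
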