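test_that("isotherm limits: free probe at x = 0, saturation at large x", {
  expect_equal(anisotropy_isotherm(0, kd = 50, b0 = 0.05, bmax = 0.2), 0.05)
  y_sat <- anisotropy_isotherm(1e5 * 50, kd = 50, b0 = 0.05, bmax = 0.2)
  expect_lt(abs(y_sat - 0.2), 1e-3 * 0.15)
})

test_that("isotherm value matches the independent quadratic evaluation", {
  y <- anisotropy_isotherm(50, kd = 50, b0 = 0.05, bmax = 0.2, c = 1.33)
  expect_equal(y, oracle_quadratic_isotherm(50, 50, 0.05, 0.2, 1.33))
  expect_equal(y, 0.1245, tolerance = 1e-3)
  # near the hyperbolic value b0 + (bmax-b0) x/(x+kd) = 0.125 at small c
  expect_equal(y, 0.125, tolerance = 0.005)
})

test_that("isotherm is monotone in x and converges to the hyperbola as c -> 0", {
  x <- seq(0, 1000, length.out = 200)
  for (kd in c(2, 50, 700)) {
    y <- anisotropy_isotherm(x, kd, 0.05, 0.2, c = 1.33)
    expect_true(all(diff(y) >= -1e-12))
  }
  hyp <- 0.05 + 0.15 * x / (x + 50)
  expect_lt(max(abs(anisotropy_isotherm(x, 50, 0.05, 0.2, c = 1e-6) - hyp)),
            1e-4)
})

test_that("noiseless triplicates return the generating KD exactly", {
  xg <- c(0, 2, 5, 10, 20, 35, 50, 75, 100, 200, 400, 800)
  s <- simulate_titration(50, 0.05, 0.2, x_grid = xg, noise_sd = 0, seed = 61)
  f <- fit_kd(s)
  expect_true(f$converged)
  expect_equal(f$kd, 50, tolerance = 1e-4)
  expect_equal(f$kd_sd, 0, tolerance = 1e-4)
  expect_equal(f$b0, 0.05, tolerance = 1e-4)
  expect_equal(f$bmax, 0.2, tolerance = 1e-3)
})

test_that("KD recovery is unbiased across the dynamic range (noiseless)", {
  for (kd in c(1, 10, 100, 1e3, 1e4)) {
    xg <- kd * c(0, 0.05, 0.1, 0.25, 0.5, 1, 2, 4, 8, 16)
    s <- simulate_titration(kd, 0.04, 0.18, x_grid = xg, noise_sd = 0,
                            seed = 62, n_replicates = 1)
    f <- fit_kd(s)
    expect_equal(f$kd, kd, tolerance = 0.005)
  }
})

test_that("noisy triplicates recover KD within 15 percent", {
  xg <- c(0, 2, 5, 10, 20, 35, 50, 75, 100, 200, 400, 800)
  s <- simulate_titration(50, 0.05, 0.2, x_grid = xg, noise_sd = 0.002,
                          seed = 63)
  f <- fit_kd(s)
  expect_equal(f$kd, 50, tolerance = 0.15)
  expect_gt(f$kd_sd, 0)
})

test_that("raw-plus-baseline input is subtracted before fitting", {
  xg <- c(0, 5, 15, 40, 100, 250, 600)
  s <- simulate_titration(30, 0, 0.12, x_grid = xg, noise_sd = 0, seed = 64)
  raw <- s
  raw$anisotropy <- raw$anisotropy + 0.07
  raw$baseline <- 0.07
  expect_equal(fit_kd(raw)$kd, fit_kd(s)$kd, tolerance = 1e-6)
})

test_that("identical conditions give ratio 1 and p near 1", {
  xg <- c(0, 2, 5, 10, 20, 50, 100, 300, 800)
  s <- simulate_titration(50, 0.05, 0.2, x_grid = xg, noise_sd = 0.002,
                          seed = 65)
  f <- fit_kd(s)
  tab <- compare_kd(list(a = f, b = f))
  expect_equal(tab$ratio, 1)
  expect_gt(tab$p_value, 0.99)
})

test_that("a ten-fold affinity difference is recovered as such", {
  xg <- c(0, 2, 5, 10, 20, 50, 100, 200, 400, 1000, 2000, 4000)
  f_hi <- fit_kd(simulate_titration(20, 0.05, 0.2, x_grid = xg,
                                    noise_sd = 0.002, seed = 66))
  f_lo <- fit_kd(simulate_titration(200, 0.05, 0.2, x_grid = xg,
                                    noise_sd = 0.002, seed = 67))
  tab <- compare_kd(list(weak = f_lo, tight = f_hi), reference = "tight")
  expect_gt(tab$ratio, 7)
  expect_lt(tab$ratio, 13)
})

test_that("point-level comparison flags separated titrations", {
  xg <- c(0, 5, 20, 50, 150, 500)
  a <- simulate_titration(10, 0.05, 0.2, x_grid = xg, noise_sd = 0.001,
                          seed = 68)
  b <- simulate_titration(300, 0.05, 0.2, x_grid = xg, noise_sd = 0.001,
                          seed = 69)
  pts <- compare_titration_points(a, b)
  expect_equal(nrow(pts), length(xg))
  # intermediate concentrations separate clearly; x = 0 does not
  expect_gt(pts$p_value[pts$protein_nM == 0], 0.01)
  expect_lt(min(pts$p_value[pts$protein_nM %in% c(20, 50)]), 1e-3)
})
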