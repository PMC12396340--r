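test_that("high-pass detrending preserves the mean and handles edge cases", {
  arr <- array(7, dim = c(10, 4, 4))
  ser <- image_series(arr, pixel_size_nm = 50, frame_interval_s = 1)
  expect_equal(highpass_detrend(ser, 4L)$data, arr)

  set.seed(1)
  arr2 <- array(rpois(20 * 16, 30), dim = c(20, 4, 4))
  ser2 <- image_series(arr2, pixel_size_nm = 50, frame_interval_s = 1)
  out <- highpass_detrend(ser2, 6L)
  expect_equal(mean(out$data), mean(arr2))
  # window = T degenerates to per-pixel temporal mean subtraction
  outT <- highpass_detrend(ser2, 20L)
  manual <- arr2
  pm <- apply(arr2, c(2, 3), mean)
  for (t in 1:20) manual[t, , ] <- arr2[t, , ] - pm
  manual <- manual + mean(arr2)
  expect_equal(outT$data, manual)
  expect_error(highpass_detrend(ser2, 21L), "window")
  expect_error(highpass_detrend(ser2, 1L), "window")
})

test_that("detrending removes a linear drift by >= 10x", {
  t <- 1:100
  arr <- array(0, dim = c(100, 2, 2))
  for (i in 1:2) for (j in 1:2) arr[, i, j] <- 100 + 0.8 * t
  ser <- image_series(arr, pixel_size_nm = 50, frame_interval_s = 1)
  out <- highpass_detrend(ser, 10L)
  interior <- 6:95   # full averaging windows
  amp_in <- stats::sd(arr[interior, 1, 1])
  amp_out <- stats::sd(out$data[interior, 1, 1])
  expect_lt(amp_out, amp_in / 10)
})

test_that("masked ACF equals the quadruple-loop brute force", {
  set.seed(42)
  arr <- array(rpois(5 * 8 * 8, 50), dim = c(5, 8, 8))
  ser <- image_series(arr, pixel_size_nm = 50, frame_interval_s = 1)
  for (seed in 1:3) {
    set.seed(seed)
    mask <- matrix(stats::runif(64) > 0.3, 8, 8)
    surf <- arbitrary_region_acf(ser, mask, max_lag_x = 7L, max_lag_y = 7L)
    oracle <- acf_bruteforce(arr, mask, 7L, 7L)
    expect_equal(surf$n_pairs, oracle$n_pairs)
    expect_lt(max(abs(surf$G - oracle$G), na.rm = TRUE), 1e-12)
  }
})

test_that("ACF symmetry, constant-image zero, and shot-noise closed form", {
  arr <- array(5, dim = c(3, 8, 8))
  ser <- image_series(arr, pixel_size_nm = 50, frame_interval_s = 1)
  surf0 <- arbitrary_region_acf(ser, matrix(TRUE, 8, 8), 4L, 4L)
  expect_true(all(abs(surf0$G) < 1e-15, na.rm = TRUE))

  set.seed(9)
  arr2 <- array(rpois(60 * 32 * 32, 50), c(60, 32, 32))
  ser2 <- image_series(arr2, pixel_size_nm = 50, frame_interval_s = 1)
  surf <- arbitrary_region_acf(ser2, matrix(TRUE, 32, 32), 5L, 5L)
  # exact lag-negation symmetry
  expect_equal(surf$G, surf$G[rev(seq_along(surf$lag_y)), rev(seq_along(surf$lag_x))])
  # G(0,0) ~ 1/mu for Poisson shot noise, off-lags ~ 0
  mu <- mean(arr2)
  expect_equal(surf$G[6, 6] * mu, 1, tolerance = 0.05)
  off <- surf$G; off[6, 6] <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 0.002)
  # full-frame mask pair counts match the analytic (ny-|psi|)(nx-|xi|)
  np_analytic <- outer(32 - abs(surf$lag_y), 32 - abs(surf$lag_x))
  expect_equal(surf$n_pairs, np_analytic)

  expect_error(arbitrary_region_acf(
    image_series(array(0, c(3, 8, 8)), pixel_size_nm = 50,
                 frame_interval_s = 1), matrix(TRUE, 8, 8)),
    "not positive")
})

test_that("rics_model reproduces its closed-form anchor points", {
  sc <- raster_scan_config(waist_nm = 250)
  for (D in c(0, 0.1, 1, 10))
    expect_equal(rics_model(0, 0, D, 1, sc), 2^(-3 / 2), tolerance = 1e-12)
  expect_equal(rics_model(0, 0, 1, 4, sc), 2^(-3 / 2) / 4, tolerance = 1e-12)
  # D = 0 Gaussian limit: delta_r 50 nm, waist 250 nm, xi = 5
  expect_equal(rics_model(5, 0, 0, 1, sc), 2^(-3 / 2) * exp(-1),
               tolerance = 1e-12)
  expect_error(rics_model(0, 0, 1, 0, sc), "N")
  expect_error(rics_model(0, 0, -1, 1, sc), "D")
})

test_that("rics_model decreases along the fast axis and is finite", {
  sc <- raster_scan_config(waist_nm = 250)
  for (D in c(0, 0.5, 5)) {
    g <- rics_model(0:30, 0, D, 1, sc)
    expect_true(all(diff(g) < 0))
    expect_true(all(is.finite(g)))
  }
})

test_that("fitting a noiseless model surface recovers D and N to 1e-6", {
  sc <- raster_scan_config(waist_nm = 250)
  lag_x <- -16:16; lag_y <- -4:4
  G <- outer(lag_y, lag_x, function(psi, xi)
    vapply(seq_along(xi), function(k) rics_model(xi[k], psi[k], 0.5, 10, sc),
           numeric(1)))
  surf <- structure(list(G = G, lag_x = lag_x, lag_y = lag_y,
                         n_pairs = matrix(1000, length(lag_y), length(lag_x)),
                         scan = sc),
                    class = "correlation_surface")
  fit <- fit_rics(surf)
  expect_true(fit$converged)
  expect_lt(abs(fit$D - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$N - 10) / 10, 1e-6)
  expect_lt(abs(fit$offset), 1e-8)
  # algebraic identity: model at zero lag = gamma / N (+ offset)
  expect_equal(rics_model(0, 0, fit$D, fit$N, sc) + fit$offset,
               sc$gamma / fit$N + fit$offset)
})

test_that("end-to-end simulation recovery and monotone ordering", {
  d1 <- recover_D(1.0, n_frames = 50L, seed = 2L)
  expect_lt(abs(d1 - 1.0) / 1.0, 0.2)
  d_slow <- recover_D(0.2, n_frames = 50L, seed = 13L)
  d_fast <- recover_D(2.0, n_frames = 50L, seed = 13L)
  expect_lt(d_slow, d_fast)
})

test_that("recovery error shrinks when the frame count doubles", {
  e_short <- vapply(1:7, function(s) abs(recover_D(1, 24L, s) - 1), numeric(1))
  e_long <- vapply(1:7, function(s) abs(recover_D(1, 48L, s + 100L) - 1),
                   numeric(1))
  expect_lt(stats::median(e_long), stats::median(e_short))
  expect_lt(stats::median(e_long), 0.2)
})

test_that("compare_regions fits regions of one acquisition consistently", {
  sim <- sim_series(1, n_frames = 50L, seed = 11L)
  m1 <- matrix(FALSE, 64, 64); m1[, 1:32] <- TRUE
  m2 <- matrix(FALSE, 64, 64); m2[, 33:64] <- TRUE
  tab <- compare_regions(sim, list(region_mask(m1, "left"),
                                   region_mask(m2, "right")))
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$converged))
  # same-D regions agree within the spread established by repeated
  # simulation (max observed 0.15 over 8 seeds at this scale)
  expect_lt(abs(diff(tab$D)), 0.25)
  # single mask equals a direct fit
  det <- highpass_detrend(sim, 10L)
  direct <- fit_rics(arbitrary_region_acf(det, m1), scan = sim$scan)
  single <- compare_regions(sim, list(region_mask(m1, "left")))
  expect_equal(single$D, direct$D)
  expect_error(compare_regions(sim, list()), "at least one mask")
})
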