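test_that("piv_config validates its fields", {
  expect_error(piv_config(window_sizes = c(16, 32)), "decreasing")
  expect_error(piv_config(window_sizes = c(16, 4)), ">= 8")
  expect_error(piv_config(overlap = 0.9), "overlap")
})

test_that("CLAHE equalizes local contrast and is nearly idempotent", {
  expect_error(clahe(matrix(1, 10, 10), tile = 20), "smaller than one tile")
  cst <- clahe(matrix(5, 40, 40), tile = 20)
  expect_equal(stats::sd(cst), 0)

  set.seed(3)
  fr <- matrix(0, 80, 80)
  fr[, 1:40] <- 100 + 5 * matrix(stats::rnorm(80 * 40), 80, 40)
  fr[, 41:80] <- 100 + 60 * matrix(stats::rnorm(80 * 40), 80, 40)
  eq <- clahe(fr, tile = 20)
  r_in <- stats::sd(fr[, 1:40]) / stats::sd(fr[, 41:80])
  r_out <- stats::sd(eq[, 1:40]) / stats::sd(eq[, 41:80])
  expect_gt(r_out, 1.5 * r_in)          # local contrast pulled toward parity
  expect_lte(max(eq), max(fr) + 1e-9)   # range preserved to [0, max]
  expect_gte(min(eq), 0)
  # approximate idempotence on an already-equalized frame
  eq2 <- clahe(eq, tile = 20)
  expect_lt(max(abs(eq2 - eq)) / diff(range(eq)), 0.25)
  expect_gt(stats::cor(as.vector(eq), as.vector(eq2)), 0.98)
})

test_that("piv_pass recovers constructed shifts", {
  pr_id <- make_shifted_pair(1L, displacement_spec(shift = c(0, 0)), size = 96L)
  f0 <- piv_pass(pr_id$a, pr_id$b, window = 32L)
  expect_true(all(abs(f0$u[f0$valid]) < 1e-9))
  expect_true(all(abs(f0$v[f0$valid]) < 1e-9))

  pr <- make_shifted_pair(1L, displacement_spec(shift = c(3, 2)), size = 128L)
  f2 <- two_pass(pr)
  expect_true(any(f2$valid))
  expect_true(all(abs(f2$u[f2$valid] - 3) <= 0.05))
  expect_true(all(abs(f2$v[f2$valid] - 2) <= 0.05))

  prs <- make_shifted_pair(2L, displacement_spec(shift = c(0.5, 0)), size = 128L)
  fs <- two_pass(prs)
  expect_lt(abs(mean(fs$u[fs$valid]) - 0.5), 0.1)
  expect_lt(abs(mean(fs$v[fs$valid])), 0.1)

  expect_error(piv_pass(pr$a, pr$b[1:64, 1:64], 32L), "same shape")
  expect_error(piv_pass(pr$a, pr$b, window = 4L), ">= 8")
})

test_that("flat windows are flagged invalid, not errors", {
  pr <- make_shifted_pair(4L, displacement_spec(shift = c(1, 0)), size = 96L)
  a <- pr$a; b <- pr$b
  a[1:40, 1:40] <- 50; b[1:40, 1:40] <- 50   # constant corner
  f <- piv_pass(a, b, window = 32L)
  corner <- f$x < 32 & f$y < 32
  expect_true(all(!f$valid[corner & f$sd_window == 0]))
  expect_true(any(f$valid[!corner]))
})

test_that("translation equivariance and sign antisymmetry hold", {
  pr <- make_shifted_pair(5L, displacement_spec(shift = c(2, 1)), size = 96L)
  f <- piv_pass(pr$a, pr$b, window = 32L)
  fr <- piv_pass(cytodyn:::roll2d(pr$a, 5, 7), cytodyn:::roll2d(pr$b, 5, 7),
                 window = 32L)
  # rolling both frames by the same vector leaves the field's distribution
  # unchanged; compare medians (vector-to-window assignment shifts)
  expect_lt(abs(stats::median(f$u[f$valid]) - stats::median(fr$u[fr$valid])), 0.05)
  expect_lt(abs(stats::median(f$v[f$valid]) - stats::median(fr$v[fr$valid])), 0.05)
  fswap <- piv_pass(pr$b, pr$a, window = 32L)
  ok <- f$valid & fswap$valid
  expect_lt(max(abs(f$u[ok] + fswap$u[ok])), 0.35)
  expect_lt(abs(stats::median(f$u[ok] + fswap$u[ok])), 0.1)
})

test_that("two passes beat a single fine pass on subpixel phantoms", {
  err1 <- err2 <- numeric(10)
  for (s in 1:10) {
    pr <- make_shifted_pair(s + 40L, displacement_spec(shift = c(0.4, -0.3)),
                            size = 96L)
    coarse <- piv_pass(pr$a, pr$b, window = 32L)
    single <- piv_pass(pr$a, pr$b, window = 16L)  # fine pass, no predictor
    double <- piv_pass(pr$a, pr$b, window = 16L, predictor = coarse)
    err1[s] <- mean(sqrt((single$u[single$valid] - 0.4)^2 +
                           (single$v[single$valid] + 0.3)^2))
    err2[s] <- mean(sqrt((double$u[double$valid] - 0.4)^2 +
                           (double$v[double$valid] + 0.3)^2))
  }
  expect_lte(stats::median(err2), stats::median(err1))
})

test_that("multipass handles series, blank movies, and short input", {
  pr <- make_shifted_pair(6L, displacement_spec(shift = c(3, 2)), size = 128L)
  f <- multipass_piv(pair_series(pr))[[1]]
  expect_lt(abs(mean(f$u[f$valid]) - 3), 0.1)
  expect_lt(abs(mean(f$v[f$valid]) - 2), 0.1)

  one <- image_series(array(1:64, c(1, 8, 8)), pixel_size_nm = 100,
                      frame_interval_s = 1)
  expect_error(multipass_piv(one), "two frames")

  blank <- image_series(array(3, c(2, 64, 64)), pixel_size_nm = 100,
                        frame_interval_s = 1)
  fb <- multipass_piv(blank)[[1]]
  expect_false(any(fb$valid))
  expect_error(mean_velocity(fb), "no valid vectors")
})

test_that("filter_vectors applies contrast and median tests", {
  # hand-built 5x5 uniform field
  grid <- expand.grid(x = seq(8, 72, 16), y = seq(8, 72, 16))
  grid <- grid[order(grid$y, grid$x), ]
  df <- data.frame(x = grid$x, y = grid$y, u = 1, v = 0, sd_window = 10,
                   valid = TRUE)
  df$magnitude <- sqrt(df$u^2 + df$v^2)
  fld <- structure(df, class = c("vector_field", "data.frame"),
                   window = 16L, pixel_size_nm = 100, frame_interval_s = 60,
                   grid_x = seq(8, 72, 16), grid_y = seq(8, 72, 16))
  cfg <- piv_config(contrast_threshold = 5)
  expect_equal(filter_vectors(fld, cfg)$valid, rep(TRUE, 25))
  # planted low-contrast corner: exactly those vectors invalidated
  f2 <- fld; f2$sd_window[f2$x < 20 & f2$y < 20] <- 1
  out <- filter_vectors(f2, cfg)
  expect_identical(out$valid, f2$sd_window >= 5)
  # planted single outlier: removed by the normalized median test
  f3 <- fld; f3$u[13] <- 8
  out3 <- filter_vectors(f3, cfg)
  expect_false(out3$valid[13])
  expect_true(all(out3$valid[-13]))
})

test_that("mean_velocity converts to nm/min over valid vectors only", {
  df <- data.frame(x = c(0, 16, 32, 48), y = 0, u = c(2, 2, 9, 9),
                   v = 0, sd_window = 10, valid = c(TRUE, TRUE, FALSE, FALSE))
  df$magnitude <- sqrt(df$u^2 + df$v^2)
  fld <- structure(df, class = c("vector_field", "data.frame"),
                   window = 16L, pixel_size_nm = 100, frame_interval_s = 180,
                   grid_x = c(0, 16, 32, 48), grid_y = 0)
  # 2 px per 3 min at 100 nm pixels -> 66.67 nm/min, invalid vectors ignored
  expect_equal(mean_velocity(fld), 2 * 100 / 3, tolerance = 1e-12)
  fz <- fld; fz$u <- 0; fz$magnitude <- 0
  expect_equal(mean_velocity(fz), 0)
  fh <- fld; fh$valid <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(mean_velocity(fh), mean(c(2, 2, 9)) * 100 / 3)
})
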