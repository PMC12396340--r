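test_that("preprocess_stack removes impulses and is identity on constants", {
  arr <- array(11, c(3, 40, 40))
  ser <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 6)
  out <- preprocess_stack(ser, ball_radius = 0, register = FALSE)
  expect_equal(out$data, arr)
  # single hot pixel removed by the radius-1 median filter
  arr2 <- arr; arr2[2, 20, 20] <- 5000
  ser2 <- image_series(arr2, pixel_size_nm = 100, frame_interval_s = 6)
  out2 <- preprocess_stack(ser2, ball_radius = 0, register = FALSE)
  expect_equal(out2$data[2, 20, 20], 11)
})

test_that("rolling-ball subtraction flattens a smooth background", {
  gy <- matrix(seq(0, 40, length.out = 64), 64, 64)
  spots <- matrix(0, 64, 64); spots[cbind(c(10, 30, 50), c(15, 40, 55))] <- 200
  img <- gy + spots
  bg <- cytodyn:::cpp_rolling_ball_background(img, 30)
  corrected <- img - bg
  # the large-scale gradient is mostly gone, the spots survive
  expect_lt(stats::sd(corrected[spots == 0]), 0.25 * stats::sd(gy))
  expect_gt(corrected[10, 15], 150)
})

test_that("rigid registration brings frames back within 0.5 px", {
  base <- speckle_frame(96L, seed = 2L)
  arr <- array(0, c(2, 96, 96))
  arr[1, , ] <- base
  arr[2, , ] <- cytodyn:::rigid_transform_image(base, 0.04, 2.3, -1.6)
  ser <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 6)
  pp <- preprocess_stack(ser, ball_radius = 0)
  expect_true(all(attr(pp, "registered")))
  a <- pp$data[1, , ]; b <- pp$data[2, , ]
  cc <- cytodyn:::xcorr2d(a - mean(a), b - mean(b), 6, 6)
  pk <- which(cc$cc == max(cc$cc), arr.ind = TRUE)[1, ]
  C <- cc$cc
  res_y <- cc$lag_y[pk[1]] +
    cytodyn:::subpixel_3pt(C[pk[1] - 1, pk[2]], C[pk[1], pk[2]], C[pk[1] + 1, pk[2]])
  res_x <- cc$lag_x[pk[2]] +
    cytodyn:::subpixel_3pt(C[pk[1], pk[2] - 1], C[pk[1], pk[2]], C[pk[1], pk[2] + 1])
  expect_lt(sqrt(res_x^2 + res_y^2), 0.5)
})

test_that("Huang binarization matches an independent direct implementation", {
  set.seed(1)
  v <- c(stats::rnorm(3000, 30, 3), stats::rnorm(1000, 200, 10))
  expect_equal(huang_threshold(v), huang_direct(v))
  set.seed(2)
  v2 <- c(stats::rexp(2000, 1 / 20), stats::rnorm(500, 150, 30))
  expect_equal(huang_threshold(v2), huang_direct(v2))
  expect_error(huang_threshold(rep(4, 100)), "constant")

  # two-level image: threshold strictly between levels, mask exact
  arr <- array(0, c(2, 32, 32)); arr[, , 1:16] <- 10; arr[, , 17:32] <- 200
  ser <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 6)
  bz <- binarize_lamella(ser)
  thr <- attr(bz, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_true(all(bz$data[, , 17:32] == 1))
  expect_true(all(bz$data[, , 1:16] == 0))
  # per-frame masks non-empty while the object persists
  expect_true(all(apply(bz$data, 1, sum) > 0))
})

test_that("coverage counts moving pixels exactly", {
  sq <- matrix(FALSE, 64, 64); sq[10:19, 10:19] <- TRUE
  ser <- make_translating_mask_series(sq, c(2L, 0L), 6L,
                                      frame_interval_s = 60)
  cv <- coverage(ser, span = 300)
  expect_equal(cv$per_interval, rep(40L, 5))
  expect_equal(cv$total_px, 200L)
  expect_equal(cv$total_um2, 200 * 0.1^2)  # 100-nm pixels
  # additions-only mode
  expect_equal(coverage(ser, span = 300, mode = "additions")$per_interval,
               rep(20L, 5))
  # static movie
  st <- make_translating_mask_series(sq, c(0L, 0L), 3L)
  expect_equal(coverage(st, span = NULL)$total_px, 0L)
  # an object vanishing between frames contributes its whole area to the
  # symmetric difference (all of its pixels changed state)
  arr <- array(0, c(2, 32, 32)); arr[1, 5:14, 5:14] <- 1
  van <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 60)
  expect_equal(coverage(van, span = NULL)$per_interval, 100L)
})

test_that("coverage is time-reversal symmetric and scales with perimeter", {
  sq <- matrix(FALSE, 64, 64); sq[10:19, 10:19] <- TRUE
  ser <- make_translating_mask_series(sq, c(2L, 1L), 5L)
  rev_ser <- ser
  rev_ser$data <- ser$data[5:1, , ]
  expect_equal(coverage(ser, span = NULL)$per_interval,
               rev(coverage(rev_ser, span = NULL)$per_interval))
  # per-interval count = 2 * side * step for a side x side square
  for (side in c(6L, 10L, 14L)) {
    s <- matrix(FALSE, 64, 64); s[20:(19 + side), 20:(19 + side)] <- TRUE
    cv <- coverage(make_translating_mask_series(s, c(2L, 0L), 3L), span = NULL)
    expect_equal(cv$per_interval, rep(2L * side * 2L, 2))
  }
})

test_that("ctcf follows its definition and invariances", {
  img <- matrix(10, 50, 50)
  cm <- matrix(FALSE, 50, 50); cm[1:10, 1:5] <- TRUE
  bm <- matrix(FALSE, 50, 50); bm[40:49, 40:49] <- TRUE
  img[cm] <- 100
  expect_equal(ctcf(img, cm, bm), 100 * 50 - 50 * 10)
  img0 <- img; img0[bm] <- 0
  expect_equal(ctcf(img0, cm, bm), sum(img0[cm]))     # zero background
  imgf <- matrix(42, 50, 50)
  expect_equal(ctcf(imgf, cm, bm), 0)                 # background = cell mean
  expect_equal(ctcf(img + 7, cm, bm), ctcf(img, cm, bm))  # +constant invariant
  expect_error(ctcf(img, matrix(FALSE, 50, 50), bm), "empty")
  expect_error(ctcf(img, cm, cm), "overlap")
})

test_that("cross-section profiles are normalized over the masked extent", {
  img <- matrix(50, 60, 60)
  mask <- matrix(FALSE, 60, 60); mask[25:35, 10:50] <- TRUE
  pr <- cross_section_profile(img, c(5, 30, 55, 30), mask, n_bins = 10L)
  expect_equal(pr$density, rep(1, 10), tolerance = 1e-9)
  expect_equal(cross_section_profile(img, c(5, 30, 55, 30), mask,
                                     n_bins = 1L)$density, 1)
  # doubled intensity in the outer 10% of the masked extent
  img2 <- img
  img2[, 10:13] <- 100; img2[, 47:50] <- 100
  pr2 <- cross_section_profile(img2, c(5, 30, 55, 30), mask, n_bins = 10L)
  expect_gt(pr2$density[1] / pr2$density[5], 1.8)
  expect_gt(pr2$density[10] / pr2$density[5], 1.8)
  expect_error(cross_section_profile(img, c(0, 5, 59, 5), mask), "misses")
})
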