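test_that("skeleton constructor validates structure", {
  nodes <- rbind(c(0, 0, 0), c(3, 4, 0))
  sk <- skeleton(nodes, rbind(c(1L, 2L)))
  expect_true(sk$is_tree)
  expect_equal(total_branch_length(sk), 5)
  expect_error(skeleton(nodes, rbind(c(1L, 3L))), "out of range")
  expect_error(skeleton(rbind(nodes, c(9, 9, 9)), rbind(c(1L, 2L))),
               "not connected")
  # random tree length matches a plain per-edge loop
  set.seed(4)
  n <- 20L
  nds <- matrix(stats::runif(n * 3, 0, 50), n, 3)
  egs <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  skr <- skeleton(nds, egs)
  manual <- 0
  for (r in seq_len(nrow(egs)))
    manual <- manual + sqrt(sum((nds[egs[r, 1], ] - nds[egs[r, 2], ])^2))
  expect_equal(total_branch_length(skr), manual)
})

test_that("sholl counts exact sphere crossings", {
  sk <- make_star_skeleton(6L, 20)
  sh <- sholl(sk, step = 5, max_radius = 25)
  expect_equal(sh$intersections, c(6L, 6L, 6L, 0L, 0L))
  expect_error(sholl(sk, step = 0), "step")
  # a chord edge dipping inside a shell counts twice
  nodes <- rbind(c(0, 0, 0), c(10, -6, 0), c(10, 6, 0))
  skc <- skeleton(nodes, rbind(c(1L, 2L), c(2L, 3L)), soma = 1L)
  # edge 2-3 runs from r=11.66 to r=11.66 passing r_min = 10 at its middle
  sh2 <- sholl(skc, step = 1, max_radius = 12)
  expect_equal(sh2$intersections[11], 3L)  # radial edge 1 + chord crossing 2
})

test_that("sholl and branch length are rigid-motion invariant", {
  # bifurcation radius off the integer grid: a node exactly on a Sholl
  # sphere is degenerate and not rotation-stable in floating point
  sk <- make_star_skeleton(5L, 12, bifurcate_at = 6.5)
  th <- 0.7; ph <- 0.3
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  nodes2 <- sk$nodes %*% t(Rz %*% Rx) +
    matrix(c(5, -3, 2), nrow(sk$nodes), 3, byrow = TRUE)
  sk2 <- skeleton(nodes2, sk$edges, soma = sk$soma)
  expect_equal(total_branch_length(sk2), total_branch_length(sk))
  expect_equal(sholl(sk2, 1, 14)$intersections, sholl(sk, 1, 14)$intersections)
})

test_that("crossings x step approximates total length on radial trees", {
  sk <- make_star_skeleton(6L, 20)
  step <- 20 / 100
  sh <- sholl(sk, step = step, max_radius = 20)
  expect_lt(abs(sum(sh$intersections) * step - 120) / 120, 0.05)
})

test_that("skeleton_from_mask reduces phantoms to their centrelines", {
  # straight 3 x 3 bar, 51 voxels long
  vol <- array(FALSE, c(30, 60, 5))
  vol[14:16, 5:55, 2:4] <- TRUE
  sk <- skeleton_from_mask(vol, soma_seed = c(5, 14, 2))
  deg <- tabulate(sk$edges, nbins = nrow(sk$nodes))
  expect_equal(sum(deg == 1), 2)             # a single path
  expect_true(all(deg <= 2))
  # thinning may recede each tip by about a voxel
  expect_lt(abs(total_branch_length(sk) - 50), 2.5)

  # solid sphere collapses to (almost) a point
  vol2 <- array(FALSE, c(21, 21, 21))
  ctr <- 11
  for (z in 1:21) for (x in 1:21) for (y in 1:21)
    if ((x - ctr)^2 + (y - ctr)^2 + (z - ctr)^2 <= 64) vol2[y, x, z] <- TRUE
  sk2 <- skeleton_from_mask(vol2, soma_seed = c(10, 10, 10))
  expect_lte(nrow(sk2$nodes), 3)

  # star phantom recovers k = 4 branches
  vol3 <- array(FALSE, c(61, 61, 3))
  for (b in 0:3) {
    th <- b * pi / 2
    for (t in seq(0, 25, by = 0.25)) {
      x <- round(31 + t * cos(th)); y <- round(31 + t * sin(th))
      vol3[(y - 1):(y + 1), (x - 1):(x + 1), 2] <- TRUE
    }
  }
  sk3 <- skeleton_from_mask(vol3, soma_seed = c(30, 30, 1), prune_len = 3)
  deg3 <- tabulate(sk3$edges, nbins = nrow(sk3$nodes))
  expect_equal(sum(deg3 == 1), 4)
  expect_lt(abs(total_branch_length(sk3) - 100) / 100, 0.1)

  expect_error(skeleton_from_mask(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               "empty")
  vol4 <- array(FALSE, c(10, 10, 3))
  vol4[2:3, 2:3, 2] <- TRUE; vol4[8:9, 8:9, 2] <- TRUE
  expect_error(skeleton_from_mask(vol4, soma_seed = c(2, 2, 1)),
               "disconnected|component")
})

test_that("motility index follows its definition exactly", {
  sq <- matrix(FALSE, 64, 64); sq[10:19, 10:19] <- TRUE
  ser <- make_translating_mask_series(sq, c(2L, 0L), 6L)
  mi <- motility_index(ser)
  expect_equal(mi$per_frame, rep(0.2, 5))
  expect_equal(mi$mean, 0.2)
  # static movie
  expect_equal(motility_index(make_translating_mask_series(sq, c(0L, 0L), 3L))$mean, 0)
  # pure growth: 10 new px on a cell growing 100 -> 110
  arr <- array(0, c(2, 32, 32))
  arr[1, 1:10, 1:10] <- 1
  arr[2, 1:10, 1:11] <- 1
  gr <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 60)
  expect_equal(motility_index(gr)$per_frame, 10 / 110)
  expect_equal(motility_index(gr, normalize = "t")$per_frame, 10 / 100)
  arr0 <- array(0, c(2, 8, 8)); arr0[1, 1, 1] <- 1
  expect_error(motility_index(image_series(arr0, pixel_size_nm = 1,
                                           frame_interval_s = 1)), "empty")
})

test_that("motility index stays in [0,1] and is 0 iff non-increasing", {
  set.seed(8)
  for (rep in 1:5) {
    arr <- array(stats::runif(4 * 16 * 16) > 0.4, c(4, 16, 16)) * 1
    arr[, 1, 1] <- 1  # keep frames non-empty
    ser <- image_series(arr, pixel_size_nm = 100, frame_interval_s = 1)
    mi <- motility_index(ser)
    expect_true(all(mi$per_frame >= 0 & mi$per_frame <= 1))
    nonincreasing <- all(vapply(1:3, function(t)
      !any(arr[t + 1, , ] > 0 & arr[t, , ] == 0), logical(1)))
    expect_equal(all(mi$per_frame == 0), nonincreasing)
  }
})

test_that("process speeds classify extension and retraction runs", {
  # outward 1 um/min for 3 min
  tr <- process_track(cbind(0:3, 0), c(0, 0), frame_interval_s = 60)
  ev <- process_speeds(tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event, "extension")
  expect_equal(ev$speed_um_min, 1)
  # stationary tip
  expect_equal(nrow(process_speeds(process_track(cbind(c(2, 2, 2), 0), c(0, 0),
                                                 60))), 0)
  # out 2 um in 2 min then in 1 um in 1 min
  tr2 <- process_track(cbind(c(0, 1, 2, 1), 0), c(0, 0), frame_interval_s = 60)
  ev2 <- process_speeds(tr2)
  expect_equal(ev2$event, c("extension", "retraction"))
  expect_equal(ev2$speed_um_min, c(1, 1))
  # single small step below the excursion threshold: no event
  tr3 <- process_track(cbind(c(1, 1.2), 0), c(0, 0), frame_interval_s = 60)
  expect_equal(nrow(process_speeds(tr3)), 0)
})
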