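#' Preprocess a lamellipodial time-lapse stack
#'
#' Per frame: 3x3 median filter (radius 1) to remove impulse noise, then
#' rolling-ball background subtraction (ball radius 30 px), then rigid-body
#' (rotation + translation) registration of every frame onto the first to
#' remove drift. Frames whose registration fails are flagged via the
#' `registered` attribute and should be excluded downstream.
#'
#' @param series an [image_series()] with >= 2 frames
#' @param median_radius median filter radius in px
#' @param ball_radius rolling-ball radius in px (0 disables)
#' @param register register frames to the first (rigid body)?
#' @param max_rotation search half-range for the rotation angle, radians
#' @return preprocessed [image_series()]; attribute `registered` is a
#'   logical per-frame flag, `transforms` the per-frame (theta, dy, dx)
#' @export
preprocess_stack <- function(series, median_radius = 1L, ball_radius = 30,
                             register = TRUE, max_rotation = 0.2) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (nt < 2) stop("preprocess_stack: need at least two frames")
  d <- dim(series$data)
  out <- array(0, dim = d)
  for (t in seq_len(nt)) {
    fr <- cpp_median_filter2d(frame_of(series, t), median_radius)
    if (ball_radius > 0)
      fr <- fr - cpp_rolling_ball_background(fr, ball_radius)
    out[t, , ] <- fr
  }
  registered <- rep(TRUE, nt)
  transforms <- matrix(0, nt, 3, dimnames = list(NULL, c("theta", "dy", "dx")))
  if (register) {
    ref <- out[1, , ]
    for (t in 2:nt) {
      est <- tryCatch(estimate_rigid(ref, out[t, , ], max_rotation),
                      error = function(e) NULL)
      if (is.null(est) || !est$ok) { registered[t] <- FALSE; next }
      transforms[t, ] <- c(est$theta, est$dy, est$dx)
      out[t, , ] <- rigid_transform_image(out[t, , ], -est$theta,
                                          -est$dy, -est$dx)
    }
  }
  res <- series
  res$data <- out
  attr(res, "registered") <- registered
  attr(res, "transforms") <- transforms
  res
}

# estimate the rigid transform carrying `ref` onto `mov`:
# mov = rotate(ref, theta) then translate by (dy, dx).
# Rotation by bounded golden-section search over the phase-correlation peak.
estimate_rigid <- function(ref, mov, max_rotation = 0.2) {
  score_shift <- function(theta) {
    un <- rigid_transform_image(mov, -theta)
    cc <- xcorr2d(ref - mean(ref), un - mean(un),
                  min(nrow(ref) %/% 4, 40), min(ncol(ref) %/% 4, 40))
    C <- cc$cc
    pk <- which(C == max(C), arr.ind = TRUE)[1, , drop = FALSE]
    i <- pk[1, 1]; j <- pk[1, 2]
    dy <- cc$lag_y[i]; dx <- cc$lag_x[j]
    if (i > 1 && i < nrow(C))
      dy <- dy + subpixel_3pt(C[i - 1, j], C[i, j], C[i + 1, j])
    if (j > 1 && j < ncol(C))
      dx <- dx + subpixel_3pt(C[i, j - 1], C[i, j], C[i, j + 1])
    list(score = max(C), dy = dy, dx = dx)
  }
  theta <- if (max_rotation > 0)
    stats::optimize(function(th) -score_shift(th)$score,
                    interval = c(-max_rotation, max_rotation), tol = 1e-4)$minimum
  else 0
  best <- score_shift(theta)
  denom <- stats::sd(ref) * stats::sd(mov) * length(ref)
  ok <- is.finite(best$score) && denom > 0 && best$score / denom > 0.05
  list(theta = theta, dy = best$dy, dx = best$dx, ok = ok)
}

#' Huang's fuzzy threshold
#'
#' Minimizes the Shannon entropy of the fuzzy membership function over all
#' candidate thresholds of a 256-bin histogram (Huang & Wang 1995). Used to
#' binarize lamellipodial movies with one global threshold.
#'
#' @param x numeric vector or matrix of intensities
#' @param n_bins histogram resolution
#' @return threshold on the intensity scale; pixels strictly above are
#'   foreground
#' @export
huang_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("huang_threshold: constant image, threshold undefined")
  bin <- pmin(as.integer((v - rng[1]) / (rng[2] - rng[1]) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * (rng[2] - rng[1]) / n_bins
  W <- cumsum(h); WX <- cumsum(h * mids)
  total <- W[n_bins]; totalX <- WX[n_bins]
  first <- which(h > 0)[1]; last <- max(which(h > 0))
  C <- mids[n_bins] - mids[1]
  best <- Inf; best_t <- first
  for (t in first:(last - 1L)) {
    mu0 <- WX[t] / W[t]
    n1 <- total - W[t]
    if (n1 == 0) next
    mu1 <- (totalX - WX[t]) / n1
    # membership of bin i: 1 / (1 + |x_i - mu_class| / C), in [0.5, 1]
    mu_of <- c(rep(mu0, t), rep(mu1, n_bins - t))
    u <- 1 / (1 + abs(mids - mu_of) / C)
    s <- -u * log(u) - (1 - u) * log(1 - u)
    s[!is.finite(s)] <- 0
    ent <- sum(h * s)
    if (ent < best) { best <- ent; best_t <- t }
  }
  rng[1] + best_t * (rng[2] - rng[1]) / n_bins
}

#' Binarize a lamellipodial movie with one global threshold
#'
#' A single threshold -- Huang's method computed on the temporal-mean frame,
#' or a user-fixed value -- is applied identically to every frame, so the
#' lamellipodium stays present across the movie rather than flickering with
#' per-frame re-thresholding.
#'
#' @param series a preprocessed [image_series()]
#' @param threshold `"huang"` or a fixed numeric value
#' @return binary [image_series()]; the threshold used is attached as an
#'   attribute
#' @export
binarize_lamella <- function(series, threshold = "huang") {
  stopifnot(inherits(series, "image_series"))
  thr <- if (identical(threshold, "huang")) {
    huang_threshold(apply(series$data, c(2, 3), mean))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  res <- series
  res$data <- (series$data > thr) * 1
  attr(res, "threshold") <- thr
  res
}

#' Covered area of a moving lamellipodium
#'
#' Consecutive binarized frames are pairwise subtracted; the "moving" pixels
#' of an interval are the symmetric set difference (pixels gained plus
#' pixels lost; `mode = "additions"` counts only gains). The covered area is
#' the sum of these counts over the analysis span (default 300 s = 5 min).
#'
#' @param masks binary [image_series()]
#' @param span analysis span in seconds; frames beyond it are ignored
#'   (requires a finite frame interval). `NULL` uses the whole movie.
#' @param mode `"symmetric"` (default) or `"additions"`
#' @return a `coverage_result`: list with `per_interval` (pixel counts),
#'   `total_px`, `total_um2`, `span_s`, `mode`
#' @export
coverage <- function(masks, span = 300, mode = c("symmetric", "additions")) {
  stopifnot(inherits(masks, "image_series"))
  mode <- match.arg(mode)
  nt <- n_frames(masks)
  if (nt < 2) stop("coverage: need at least two frames")
  n_use <- nt
  if (!is.null(span) && is.finite(masks$frame_interval_s))
    n_use <- max(2L, min(nt, 1L + as.integer(floor(span / masks$frame_interval_s))))
  per <- integer(n_use - 1L)
  for (t in seq_len(n_use - 1L)) {
    a <- masks$data[t, , ] > 0
    b <- masks$data[t + 1L, , ] > 0
    per[t] <- if (mode == "symmetric") sum(xor(a, b)) else sum(b & !a)
  }
  px_um <- masks$pixel_size_nm / 1000
  structure(list(per_interval = per, total_px = sum(per),
                 total_um2 = sum(per) * px_um^2,
                 span_s = if (is.null(span)) NA_real_ else span, mode = mode),
            class = "coverage_result")
}

#' Corrected total cell fluorescence
#'
#' `CTCF = integrated intensity over the cell mask - cell area * mean
#' background intensity`. Invariant under adding a constant to the image.
#'
#' @param image 2D matrix
#' @param cell_mask,background_mask disjoint non-empty logical matrices
#' @return CTCF value (intensity units x pixels)
#' @export
ctcf <- function(image, cell_mask, background_mask) {
  cell_mask <- cell_mask > 0; background_mask <- background_mask > 0
  if (!any(cell_mask)) stop("ctcf: empty cell mask")
  if (!any(background_mask)) stop("ctcf: empty background mask")
  if (any(cell_mask & background_mask))
    stop("ctcf: cell and background masks overlap")
  sum(image[cell_mask]) - sum(cell_mask) * mean(image[background_mask])
}

#' F-actin density profile across a binarized cross section
#'
#' Samples intensity along a straight section line at sub-pixel resolution,
#' keeps only samples inside the binarized mask, rescales their positions to
#' the [0, 1] masked extent, averages into equidistant bins, and normalizes
#' the profile to its own mean (so a uniform cell gives a flat profile of 1).
#'
#' @param image 2D matrix
#' @param section_line numeric c(x1, y1, x2, y2), 0-based pixel coordinates
#' @param mask logical matrix (the binarized cell/lamellipodium)
#' @param n_bins number of profile bins
#' @return a `section_profile`: list with `position` (bin centres in 0..1),
#'   `density` (mean-normalized), `n_bins`
#' @export
cross_section_profile <- function(image, section_line, mask, n_bins = 20L) {
  stopifnot(length(section_line) == 4L)
  mask <- mask > 0
  x1 <- section_line[1]; y1 <- section_line[2]
  x2 <- section_line[3]; y2 <- section_line[4]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  n_s <- max(2L * n_bins, as.integer(ceiling(len * 4)))
  tt <- seq(0, 1, length.out = n_s)
  sx <- x1 + tt * (x2 - x1); sy <- y1 + tt * (y2 - y1)
  ix <- pmin(pmax(round(sx), 0), ncol(mask) - 1)
  iy <- pmin(pmax(round(sy), 0), nrow(mask) - 1)
  inside <- mask[cbind(iy + 1, ix + 1)]
  if (!any(inside)) stop("cross_section_profile: section line misses the mask")
  vals <- bilinear_sample(image, sy[inside], sx[inside])
  span <- range(tt[inside])
  pos <- if (diff(span) > 0) (tt[inside] - span[1]) / diff(span) else rep(0.5, sum(inside))
  bin <- pmin(as.integer(pos * n_bins) + 1L, n_bins)
  dens <- vapply(seq_len(n_bins), function(b)
    if (any(bin == b)) mean(vals[bin == b]) else NA_real_, numeric(1))
  m <- mean(dens, na.rm = TRUE)
  if (is.finite(m) && m != 0) dens <- dens / m
  structure(list(position = (seq_len(n_bins) - 0.5) / n_bins,
                 density = dens, n_bins = as.integer(n_bins)),
            class = "section_profile")
}
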