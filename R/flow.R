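#' PIV configuration
#'
#' @param window_sizes interrogation window sizes in px, coarse to fine
#' @param overlap window overlap fraction in [0, 0.75]
#' @param clahe_tile CLAHE tile size in px
#' @param denoise_radius median-filter radius in px
#' @param contrast_threshold minimum source-window intensity standard
#'   deviation for a vector to stay valid; `NULL` = the 5th percentile of
#'   the observed window deviations (computed per field)
#' @return a `piv_config` object
#' @export
piv_config <- function(window_sizes = c(32L, 16L), overlap = 0.5,
                       clahe_tile = 20L, denoise_radius = 3L,
                       contrast_threshold = NULL) {
  window_sizes <- as.integer(window_sizes)
  if (any(diff(window_sizes) >= 0))
    stop("piv_config: window_sizes must be strictly decreasing")
  if (any(window_sizes < 8L)) stop("piv_config: windows must be >= 8 px")
  if (overlap < 0 || overlap > 0.75) stop("piv_config: overlap must be in [0, 0.75]")
  structure(list(window_sizes = window_sizes, overlap = overlap,
                 clahe_tile = as.integer(clahe_tile),
                 denoise_radius = as.integer(denoise_radius),
                 contrast_threshold = contrast_threshold),
            class = "piv_config")
}

#' Contrast-limited adaptive histogram equalization
#'
#' Classic CLAHE: per-tile clipped histograms (excess redistributed
#' uniformly), cumulative mappings, and bilinear blending of the four
#' surrounding tile mappings at every pixel. The output is rescaled to the
#' input's [0, max] range.
#'
#' @param frame 2D numeric matrix
#' @param tile tile size in px
#' @param n_bins histogram bins
#' @param clip_limit normalized clip limit (fraction of tile pixels per bin)
#' @return equalized matrix
#' @export
clahe <- function(frame, tile = 20L, n_bins = 256L, clip_limit = 0.01) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (ny < tile || nx < tile) stop("clahe: frame smaller than one tile")
  rng <- range(frame)
  if (rng[1] == rng[2]) return(frame)
  z <- (frame - rng[1]) / (rng[2] - rng[1])
  bin <- matrix(pmin(as.integer(z * n_bins) + 1L, n_bins), ny, nx)
  nty <- max(1L, floor(ny / tile)); ntx <- max(1L, floor(nx / tile))
  ty_of <- pmin(((seq_len(ny) - 1L) %/% ceiling(ny / nty)) + 1L, nty)
  tx_of <- pmin(((seq_len(nx) - 1L) %/% ceiling(nx / ntx)) + 1L, ntx)
  # per-tile clipped CDF mappings
  maps <- array(0, dim = c(n_bins, nty, ntx))
  for (a in seq_len(nty)) for (b in seq_len(ntx)) {
    sel <- bin[ty_of == a, tx_of == b]
    h <- tabulate(sel, nbins = n_bins)
    clip <- max(1, clip_limit * length(sel))
    excess <- sum(pmax(h - clip, 0))
    h <- pmin(h, clip) + excess / n_bins
    maps[, a, b] <- cumsum(h) / sum(h)
  }
  # tile centres (pixel index of centre of each tile band)
  cy <- (vapply(seq_len(nty), function(a) mean(which(ty_of == a)), numeric(1)))
  cx <- (vapply(seq_len(ntx), function(b) mean(which(tx_of == b)), numeric(1)))
  iy <- rep(seq_len(ny), times = nx)
  ix <- rep(seq_len(nx), each = ny)
  a0 <- pmin(pmax(findInterval(iy, cy), 1L), max(nty - 1L, 1L))
  b0 <- pmin(pmax(findInterval(ix, cx), 1L), max(ntx - 1L, 1L))
  a1 <- pmin(a0 + 1L, nty); b1 <- pmin(b0 + 1L, ntx)
  fy <- if (nty > 1) pmin(pmax((iy - cy[a0]) / (cy[a1] - cy[a0] + (a1 == a0)), 0), 1) else rep(0, length(iy))
  fx <- if (ntx > 1) pmin(pmax((ix - cx[b0]) / (cx[b1] - cx[b0] + (b1 == b0)), 0), 1) else rep(0, length(ix))
  bv <- as.vector(bin)
  look <- function(aa, bb) maps[cbind(bv, aa, bb)]
  out <- look(a0, b0) * (1 - fy) * (1 - fx) + look(a0, b1) * (1 - fy) * fx +
    look(a1, b0) * fy * (1 - fx) + look(a1, b1) * fy * fx
  matrix(out, ny, nx) * rng[2]
}

#' PIV preprocessing: CLAHE then median denoising
#'
#' @param frame 2D matrix
#' @param config a [piv_config()]
#' @return preprocessed matrix
#' @export
piv_preprocess <- function(frame, config = piv_config()) {
  eq <- clahe(frame, tile = config$clahe_tile)
  cpp_median_filter2d(eq, config$denoise_radius)
}

# 3-point Gaussian (log-parabolic) subpixel refinement along one axis
subpixel_3pt <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && (2 * log(c0) - log(cm) - log(cp)) > 0) {
    (log(cm) - log(cp)) / (2 * (log(cm) + log(cp) - 2 * log(c0)))
  } else {
    den <- 2 * (cm + cp - 2 * c0)
    if (den == 0) 0 else (cm - cp) / den
  }
}

#' Single-pass FFT cross-correlation PIV
#'
#' Displacement per interrogation window is the argmax of the zero-padded
#' FFT cross-correlation, refined per axis by a 3-point Gaussian fit. When a
#' predictor field is supplied, each frame-B window is read at the location
#' shifted by the rounded interpolated predictor, and the result is the
#' predictor plus the measured residual (first-order window deformation).
#' Windows with zero intensity variance are flagged invalid.
#'
#' @param frame_a,frame_b 2D matrices of equal shape
#' @param window interrogation window size in px (>= 8)
#' @param overlap overlap fraction
#' @param predictor optional `vector_field` from a coarser pass
#' @param pixel_size_nm,frame_interval_s calibration carried on the result
#' @return a `vector_field`: data.frame (x, y, u, v, magnitude, sd_window,
#'   valid) with grid attributes; coordinates are 0-based window centres
#' @export
piv_pass <- function(frame_a, frame_b, window = 32L, overlap = 0.5,
                     predictor = NULL, pixel_size_nm = 100,
                     frame_interval_s = 180) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("piv_pass: frames must have the same shape")
  if (window < 8L) stop("piv_pass: window must be >= 8 px")
  ny <- nrow(frame_a); nx <- ncol(frame_a)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  ys <- seq(1L, ny - window + 1L, by = step)
  xs <- seq(1L, nx - window + 1L, by = step)
  max_lag <- window %/% 2L - 1L
  pred_uv <- function(cx, cy) {
    if (is.null(predictor)) return(c(0, 0))
    interp_field(predictor, cx, cy)
  }
  rows <- vector("list", length(ys) * length(xs))
  k <- 0L
  for (y0 in ys) for (x0 in xs) {
    k <- k + 1L
    cy <- y0 - 1 + (window - 1) / 2
    cx <- x0 - 1 + (window - 1) / 2
    p0 <- round(pred_uv(cx, cy))
    ax <- x0:(x0 + window - 1L); ay <- y0:(y0 + window - 1L)
    # clamp the predictor shift so the deformed window stays in the frame;
    # a binding clamp means the tracked material leaves the field of view,
    # so the vector is flagged invalid below
    p <- c(min(max(p0[1], 1L - x0), nx - (x0 + window - 1L)),
           min(max(p0[2], 1L - y0), ny - (y0 + window - 1L)))
    clamped <- any(p != p0)
    bx <- ax + p[1]; by <- ay + p[2]
    wa <- frame_a[ay, ax]; wb <- frame_b[by, bx]
    sd_a <- stats::sd(wa)
    if (!is.finite(sd_a) || sd_a == 0 || stats::sd(wb) == 0) {
      rows[[k]] <- data.frame(x = cx, y = cy, u = NA_real_, v = NA_real_,
                              sd_window = sd_a, valid = FALSE)
      next
    }
    cc <- xcorr2d(wa - mean(wa), wb - mean(wb), max_lag, max_lag)
    # unbiased estimator: remove the triangular overlap bias of the
    # zero-padded correlation so broad peaks are not pulled toward zero lag
    C <- cc$cc / outer(window - abs(cc$lag_y), window - abs(cc$lag_x))
    pk <- which(C == max(C), arr.ind = TRUE)
    if (nrow(pk) > 1) {   # tie: prefer the smaller displacement
      d2 <- cc$lag_y[pk[, 1]]^2 + cc$lag_x[pk[, 2]]^2
      pk <- pk[which.min(d2), , drop = FALSE]
    }
    i <- pk[1, 1]; j <- pk[1, 2]
    du <- cc$lag_x[j]; dv <- cc$lag_y[i]
    if (i > 1 && i < nrow(C)) dv <- dv + subpixel_3pt(C[i - 1, j], C[i, j], C[i + 1, j])
    if (j > 1 && j < ncol(C)) du <- du + subpixel_3pt(C[i, j - 1], C[i, j], C[i, j + 1])
    rows[[k]] <- data.frame(x = cx, y = cy, u = du + p[1], v = dv + p[2],
                            sd_window = sd_a, valid = !clamped)
  }
  df <- do.call(rbind, rows)
  df$magnitude <- sqrt(df$u^2 + df$v^2)
  structure(df, class = c("vector_field", "data.frame"),
            window = as.integer(window), pixel_size_nm = pixel_size_nm,
            frame_interval_s = frame_interval_s,
            grid_x = sort(unique(df$x)), grid_y = sort(unique(df$y)))
}

# bilinear interpolation of a vector field's (u, v) at one point;
# invalid vectors are replaced by the field's valid median first
interp_field <- function(field, cx, cy) {
  gx <- attr(field, "grid_x"); gy <- attr(field, "grid_y")
  # piv_pass emits rows with x varying fastest, hence byrow = TRUE
  U <- matrix(field$u, length(gy), length(gx), byrow = TRUE)
  V <- matrix(field$v, length(gy), length(gx), byrow = TRUE)
  ok <- matrix(field$valid, length(gy), length(gx), byrow = TRUE)
  if (!any(ok)) return(c(0, 0))
  U[!ok] <- stats::median(U[ok]); V[!ok] <- stats::median(V[ok])
  fx <- stats::approx(gx, seq_along(gx), xout = cx, rule = 2)$y
  fy <- stats::approx(gy, seq_along(gy), xout = cy, rule = 2)$y
  x0 <- floor(fx); y0 <- floor(fy)
  x1 <- min(x0 + 1, length(gx)); y1 <- min(y0 + 1, length(gy))
  ax <- fx - x0; ay <- fy - y0
  u <- U[y0, x0] * (1 - ay) * (1 - ax) + U[y0, x1] * (1 - ay) * ax +
    U[y1, x0] * ay * (1 - ax) + U[y1, x1] * ay * ax
  v <- V[y0, x0] * (1 - ay) * (1 - ax) + V[y0, x1] * (1 - ay) * ax +
    V[y1, x0] * ay * (1 - ax) + V[y1, x1] * ay * ax
  c(u, v)
}

#' Multipass PIV over an image series
#'
#' For every consecutive frame pair: preprocessing (CLAHE + median
#' denoising), a coarse pass, finer passes using the previous pass as
#' predictor, then contrast / outlier filtering.
#'
#' @param series an [image_series()] with >= 2 frames
#' @param config a [piv_config()]
#' @return list of `vector_field`s, one per frame pair
#' @export
multipass_piv <- function(series, config = piv_config()) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (nt < 2) stop("multipass_piv: need at least two frames")
  out <- vector("list", nt - 1L)
  prev <- piv_preprocess(frame_of(series, 1), config)
  for (t in seq_len(nt - 1L)) {
    nxt <- piv_preprocess(frame_of(series, t + 1L), config)
    fld <- NULL
    for (w in config$window_sizes)
      fld <- piv_pass(prev, nxt, window = w, overlap = config$overlap,
                      predictor = fld,
                      pixel_size_nm = series$pixel_size_nm,
                      frame_interval_s = series$frame_interval_s)
    out[[t]] <- filter_vectors(fld, config)
    prev <- nxt
  }
  out
}

#' Filter PIV vectors
#'
#' Invalidates (a) vectors whose source-window intensity standard deviation
#' falls below the contrast threshold (default: the field's 5th percentile)
#' and (b) isolated outliers failing a 3x3 normalized-median test
#' (normalized residual > 2, per Westerweel's universal outlier detection).
#'
#' @param field a `vector_field`
#' @param config a [piv_config()]
#' @return the field with updated `valid` flags
#' @export
filter_vectors <- function(field, config = piv_config()) {
  thr <- config$contrast_threshold
  if (is.null(thr))
    thr <- stats::quantile(field$sd_window, 0.05, na.rm = TRUE, names = FALSE)
  field$valid <- field$valid & is.finite(field$sd_window) & field$sd_window >= thr
  gx <- attr(field, "grid_x"); gy <- attr(field, "grid_y")
  nyg <- length(gy); nxg <- length(gx)
  U <- matrix(field$u, nyg, nxg, byrow = TRUE)
  V <- matrix(field$v, nyg, nxg, byrow = TRUE)
  OK <- matrix(field$valid, nyg, nxg, byrow = TRUE)
  eps0 <- 0.1
  bad <- matrix(FALSE, nyg, nxg)
  for (i in seq_len(nyg)) for (j in seq_len(nxg)) {
    if (!OK[i, j]) next
    ii <- max(1, i - 1):min(nyg, i + 1)
    jj <- max(1, j - 1):min(nxg, j + 1)
    sel <- OK[ii, jj]; sel[which(ii == i), which(jj == j)] <- FALSE
    nu <- U[ii, jj][sel]; nv <- V[ii, jj][sel]
    if (length(nu) < 3) next
    ru <- abs(U[i, j] - stats::median(nu)) /
      (stats::median(abs(nu - stats::median(nu))) + eps0)
    rv <- abs(V[i, j] - stats::median(nv)) /
      (stats::median(abs(nv - stats::median(nv))) + eps0)
    if (max(ru, rv) > 2) bad[i, j] <- TRUE
  }
  field$valid <- field$valid & !as.vector(t(bad))
  field
}

#' Mean vector velocity of a field
#'
#' Mean of valid vector magnitudes converted to physical units:
#' `px/frame * pixel_size_nm / (frame_interval_s / 60)`, i.e. nm/min.
#'
#' @param field a `vector_field`
#' @return scalar velocity in nm/min
#' @export
mean_velocity <- function(field) {
  v <- field$magnitude[field$valid]
  if (!length(v)) stop("mean_velocity: no valid vectors")
  mean(v) * attr(field, "pixel_size_nm") / (attr(field, "frame_interval_s") / 60)
}
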