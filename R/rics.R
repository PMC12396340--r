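#' High-pass detrending of an image series
#'
#' Removes slow fluctuations (cell and organelle movement, photobleaching)
#' before autocorrelation: each pixel's time trace has its centred moving
#' average subtracted, and the global mean is added back so the overall
#' intensity scale is preserved. At the series edges the averaging window
#' shrinks; `window >= T` degenerates to subtracting the per-pixel temporal
#' mean (immobile-fraction removal).
#'
#' @param series an [image_series()]
#' @param window moving-average window in frames (2..T)
#' @return a detrended [image_series()]
#' @export
highpass_detrend <- function(series, window = 10L) {
  stopifnot(inherits(series, "image_series"))
  nt <- n_frames(series)
  if (!is_count(window) || window < 2) stop("highpass_detrend: window must be >= 2")
  if (window > nt) stop("highpass_detrend: window exceeds the frame count")
  d <- dim(series$data)
  m <- matrix(series$data, nrow = nt)          # T x (Y*X)
  if (window >= nt) {
    ma <- matrix(colMeans(m), nt, ncol(m), byrow = TRUE)
  } else {
    half_lo <- floor((window - 1) / 2)
    half_hi <- window - 1 - half_lo
    cs <- rbind(0, apply(m, 2, cumsum))
    lo <- pmax(1, seq_len(nt) - half_lo)
    hi <- pmin(nt, seq_len(nt) + half_hi)
    ma <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  out <- m - ma
  out <- out - mean(out) + mean(m)             # exact mean preservation
  res <- series
  res$data <- array(out, dim = d)
  res
}

#' Arbitrary-region spatial autocorrelation
#'
#' Computes the RICS correlation surface
#' \deqn{G(\xi,\psi) = \langle \delta I(x,y)\,\delta I(x+\xi,y+\psi)\rangle
#'       / \langle I \rangle^2}
#' where the averages run over all pixel pairs with both endpoints inside
#' the mask, \eqn{\delta I = I - \langle I\rangle_{mask}} per frame, and the
#' normalisation uses the frame-averaged masked mean. Implemented as an FFT
#' of the zero-filled masked images normalised by the mask's own
#' autocorrelation (the per-lag pair count), which is algebraically
#' identical to the direct pair sum; a quadruple-loop oracle is kept in the
#' test-suite to prove it.
#'
#' @param series a detrended [image_series()]
#' @param mask a [region_mask()] (or logical matrix)
#' @param max_lag_x,max_lag_y largest lags retained, in pixels (fast / slow
#'   axis); defaults cover the default fit window
#' @return a `correlation_surface`: list with `G` (lag_y x lag_x matrix),
#'   `lag_x`, `lag_y`, `n_pairs`, `scan`
#' @export
arbitrary_region_acf <- function(series, mask, max_lag_x = 16L, max_lag_y = 8L) {
  stopifnot(inherits(series, "image_series"))
  if (inherits(mask, "region_mask")) mask <- mask$mask
  mask <- if (is.logical(mask)) mask else mask > 0
  d <- dim(series$data)
  if (!all(dim(mask) == d[2:3]))
    stop("arbitrary_region_acf: mask shape does not match the frames")
  max_lag_x <- min(max_lag_x, d[3] - 1L)
  max_lag_y <- min(max_lag_y, d[2] - 1L)
  M <- mask * 1
  pc <- xcorr2d(M, M, max_lag_y, max_lag_x)
  n_pairs <- round(pc$cc)
  num <- matrix(0, nrow(n_pairs), ncol(n_pairs))
  mu_frames <- numeric(d[1])
  for (t in seq_len(d[1])) {
    fr <- series$data[t, , ]
    mu <- mean(fr[mask])
    mu_frames[t] <- mu
    dI <- (fr - mu) * M
    num <- num + xcorr2d(dI, dI, max_lag_y, max_lag_x)$cc
  }
  mu_bar <- mean(mu_frames)
  if (!is.finite(mu_bar) || mu_bar <= 0)
    stop("arbitrary_region_acf: masked mean intensity is not positive")
  G <- num / (d[1] * pmax(n_pairs, 1) * mu_bar^2)
  G[n_pairs < 1] <- NA_real_
  structure(list(G = G, lag_x = pc$lag_x, lag_y = pc$lag_y,
                 n_pairs = n_pairs, scan = series$scan),
            class = "correlation_surface")
}

#' RICS diffusion model
#'
#' Closed-form spatial autocorrelation of freely diffusing fluorophores
#' under a raster scan with a 2D-Gaussian focus:
#' \deqn{G(\xi,\psi) = \frac{\gamma}{N}
#'   \left(1 + \frac{4D|\xi\tau_p + \psi\tau_l|}{\omega_r^2}\right)^{-1}
#'   \exp\!\left[-\frac{\delta_r^2(\xi^2+\psi^2)}
#'        {\omega_r^2 + 4D|\xi\tau_p + \psi\tau_l|}\right]}
#' with \eqn{\gamma = 2^{-3/2}}. The time lag between two pixels separated
#' by \eqn{(\xi,\psi)} is \eqn{|\xi\tau_p + \psi\tau_l|}, which is what
#' makes the raster timing sensitive to diffusion.
#'
#' @param xi,psi spatial lags in pixels (fast / slow scan axis); vectorized
#' @param D diffusion coefficient in um^2/s
#' @param N mean number of particles in the focal area
#' @param scan a [raster_scan_config()]
#' @return model G values
#' @export
rics_model <- function(xi, psi, D, N, scan = raster_scan_config()) {
  stopifnot(inherits(scan, "raster_scan_config"))
  if (!is.finite(N) || N <= 0) stop("rics_model: N must be > 0")
  if (!is.finite(D) || D < 0) stop("rics_model: D must be >= 0")
  D_m <- D * 1e-12                              # um^2/s -> m^2/s
  tau <- abs(xi * scan$tau_p + psi * scan$tau_l)
  w2 <- scan$omega_r^2
  denom <- 1 + 4 * D_m * tau / w2
  scan$gamma / N / denom *
    exp(-scan$delta_r^2 * (xi^2 + psi^2) / (w2 + 4 * D_m * tau))
}

#' Fit the RICS diffusion model to a correlation surface
#'
#' Weighted nonlinear least squares of [rics_model()] plus a constant
#' offset over a lag window (default +/-12 px along the fast axis, +/-6 px
#' along the slow axis), with the zero-lag point excluded because
#' uncorrelated shot noise inflates G(0,0). Weights are the per-lag pair
#' counts. Initial N is \eqn{\gamma / G} at the smallest nonzero lag;
#' initial D comes from a coarse grid search. Optimisation runs on
#' log-transformed (D, N); failures are reported via `converged = FALSE`,
#' never as an exception.
#'
#' @param surface a `correlation_surface` from [arbitrary_region_acf()]
#' @param scan a [raster_scan_config()]; defaults to the surface's own
#' @param init optional c(D0, N0) starting values
#' @param fit_lag_x,fit_lag_y half-widths of the fit window in pixels
#' @return a `rics_fit`: list with `D` (um^2/s), `N`, `offset`, `converged`,
#'   `residual_norm`, `covariance` (of D and N), `n_points`
#' @export
fit_rics <- function(surface, scan = NULL, init = NULL,
                     fit_lag_x = 12L, fit_lag_y = 6L) {
  stopifnot(inherits(surface, "correlation_surface"))
  if (is.null(scan)) scan <- surface$scan
  if (is.null(scan)) stop("fit_rics: no scan configuration available")
  if (max(surface$lag_x) < 8)
    stop("fit_rics: surface must cover at least +/-8 px along the fast axis")
  sel_x <- abs(surface$lag_x) <= fit_lag_x
  sel_y <- abs(surface$lag_y) <= fit_lag_y
  xi <- rep(surface$lag_x[sel_x], each = sum(sel_y))
  psi <- rep(surface$lag_y[sel_y], times = sum(sel_x))
  g <- as.vector(surface$G[sel_y, sel_x])
  w <- as.vector(surface$n_pairs[sel_y, sel_x])
  keep <- !(xi == 0 & psi == 0) & is.finite(g) & w > 0
  xi <- xi[keep]; psi <- psi[keep]; g <- g[keep]; w <- w[keep]
  if (!length(g) || all(g == 0)) stop("fit_rics: surface is empty or all zero")

  g_small <- g[which.min(xi^2 + psi^2)]
  N0 <- if (is.null(init)) max(scan$gamma / max(g_small, 1e-9), 1e-3) else init[2]
  ss <- function(th) {
    m <- rics_model(xi, psi, exp(th[1]), exp(th[2]), scan) + th[3]
    sum(w * (g - m)^2)
  }
  if (is.null(init)) {
    grid <- 10^seq(-3, 2, by = 0.25)
    sses <- vapply(grid, function(Dg) ss(c(log(Dg), log(N0), 0)), numeric(1))
    D0 <- grid[which.min(sses)]
  } else D0 <- max(init[1], 1e-6)

  th0 <- c(log(D0), log(N0), 0)
  opt <- tryCatch(
    stats::optim(th0, ss, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(opt)) opt <- list(par = th0, value = ss(th0), convergence = 99L)
  # polish with Nelder-Mead from the BFGS solution
  opt2 <- tryCatch(
    stats::optim(opt$par, ss, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-15)),
    error = function(e) opt)
  if (opt2$value < opt$value) opt <- opt2

  th <- opt$par
  D_hat <- exp(th[1]); N_hat <- exp(th[2]); offset <- th[3]
  conv <- isTRUE(opt$convergence == 0)
  # covariance of (D, N) via the Gauss-Newton approximation and delta method
  covDN <- matrix(NA_real_, 2, 2)
  res <- g - (rics_model(xi, psi, D_hat, N_hat, scan) + offset)
  dof <- length(g) - 3
  if (dof > 0) {
    eps <- 1e-5
    J <- cbind(
      (rics_model(xi, psi, D_hat * (1 + eps), N_hat, scan) -
         rics_model(xi, psi, D_hat, N_hat, scan)) / (D_hat * eps),
      (rics_model(xi, psi, D_hat, N_hat * (1 + eps), scan) -
         rics_model(xi, psi, D_hat, N_hat, scan)) / (N_hat * eps),
      rep(1, length(g)))
    JtWJ <- crossprod(J * sqrt(w))
    s2 <- sum(w * res^2) / dof
    cv <- tryCatch(solve(JtWJ) * s2, error = function(e) NULL)
    if (!is.null(cv)) covDN <- cv[1:2, 1:2]
  }
  structure(list(D = D_hat, N = N_hat, offset = offset, converged = conv,
                 residual_norm = sqrt(opt$value), covariance = covDN,
                 n_points = length(g)),
            class = "rics_fit")
}

#' @export
print.rics_fit <- function(x, ...) {
  cat(sprintf("rics_fit: D = %.4g um^2/s, N = %.4g, offset = %.3g (%s, %d lags)\n",
              x$D, x$N, x$offset,
              if (x$converged) "converged" else "NOT converged", x$n_points))
  invisible(x)
}

#' Fit several masked regions of the same acquisition
#'
#' Shared detrending, one fit per region; the typical use is contrasting
#' diffusion in actin-rich versus cytoskeleton-free cytosol.
#'
#' @param series a raw [image_series()] (detrended internally)
#' @param masks list of [region_mask()] objects
#' @param window detrending window ([highpass_detrend()])
#' @param ... forwarded to [fit_rics()]
#' @return data.frame with one row per region (label, D, N, offset,
#'   converged, residual_norm, se_D)
#' @export
compare_regions <- function(series, masks, window = 10L, ...) {
  if (!length(masks)) stop("compare_regions: need at least one mask")
  if (inherits(masks, "region_mask")) masks <- list(masks)
  det <- highpass_detrend(series, window = window)
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    fit <- fit_rics(arbitrary_region_acf(det, m), scan = series$scan, ...)
    data.frame(label = if (inherits(m, "region_mask")) m$label else paste0("region", i),
               D = fit$D, N = fit$N, offset = fit$offset,
               converged = fit$converged, residual_norm = fit$residual_norm,
               se_D = sqrt(fit$covariance[1, 1]))
  })
  do.call(rbind, rows)
}
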