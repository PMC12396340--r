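# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# reduced-scale scan: 64 x 64 px keeps simulations fast while preserving the
# standard pixel/line timing (frame time = ny * line time, back-to-back lines)
small_scan <- function(n = 64L, waist_nm = 250) {
  raster_scan_config(image_size = c(n, n), frame_s = n * 4.92e-3,
                     waist_nm = waist_nm)
}

sim_series <- function(D, n_frames = 50L, seed = 1L, n = 64L) {
  simulate_diffusion_raster(diffusion_sim_spec(
    D_true = D, particle_density = 1, brightness = 5,
    scan = small_scan(n), n_frames = n_frames, seed = seed))
}

# end-to-end D recovery at reduced scale; the detrend window spans the whole
# movie because the simulation has no slow cell movement to remove (the
# filter then only subtracts the per-pixel temporal mean)
recover_D <- function(D, n_frames = 50L, seed = 1L, n = 64L) {
  sim <- sim_series(D, n_frames, seed, n)
  det <- highpass_detrend(sim, n_frames)
  fit_rics(arbitrary_region_acf(det, matrix(TRUE, n, n)))$D
}

# quadruple-loop brute-force oracle for the masked autocorrelation;
# implements the definition directly, independent of any FFT
acf_bruteforce <- function(data, mask, lx, ly) {
  nt <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  lags_x <- -lx:lx; lags_y <- -ly:ly
  num <- matrix(0, length(lags_y), length(lags_x))
  np <- matrix(0, length(lags_y), length(lags_x))
  mus <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- data[t, , ]
    mu <- mean(fr[mask]); mus[t] <- mu
    dI <- fr - mu
    for (a in seq_along(lags_y)) for (b in seq_along(lags_x)) {
      s <- 0; n <- 0
      for (y in seq_len(ny)) for (x in seq_len(nx)) {
        y2 <- y + lags_y[a]; x2 <- x + lags_x[b]
        if (y2 >= 1 && y2 <= ny && x2 >= 1 && x2 <= nx &&
            mask[y, x] && mask[y2, x2]) {
          s <- s + dI[y, x] * dI[y2, x2]
          n <- n + 1
        }
      }
      num[a, b] <- num[a, b] + s
      if (t == 1) np[a, b] <- n
    }
  }
  G <- num / (nt * pmax(np, 1) * mean(mus)^2)
  G[np < 1] <- NA_real_
  list(G = G, n_pairs = np)
}

# wrap a frame pair into a 2-frame image series
pair_series <- function(pr, pixel_size_nm = 100, frame_interval_s = 180) {
  n <- nrow(pr$a)
  image_series(aperm(array(c(pr$a, pr$b), dim = c(n, n, 2)), c(3, 1, 2)),
               pixel_size_nm = pixel_size_nm,
               frame_interval_s = frame_interval_s)
}

# two-pass PIV on a raw (unpreprocessed) phantom pair
two_pass <- function(pr, filter = TRUE) {
  f1 <- piv_pass(pr$a, pr$b, window = 32L)
  f2 <- piv_pass(pr$a, pr$b, window = 16L, predictor = f1)
  if (filter) filter_vectors(f2, piv_config()) else f2
}

# independent Huang threshold: plain double-loop over thresholds and bins
huang_direct <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  bin <- pmin(as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * diff(rng) / n_bins
  C <- mids[n_bins] - mids[1]
  ents <- rep(Inf, n_bins)
  lo <- which(h > 0)[1]; hi <- max(which(h > 0))
  for (t in lo:(hi - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / w0
    mu1 <- sum(h[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    ent <- 0
    for (i in seq_len(n_bins)) {
      mu <- if (i <= t) mu0 else mu1
      u <- 1 / (1 + abs(mids[i] - mu) / C)
      s <- -u * log(u) - (1 - u) * log(1 - u)
      if (is.finite(s)) ent <- ent + h[i] * s
    }
    ents[t] <- ent
  }
  rng[1] + which.min(ents) * diff(rng) / n_bins
}

# brute-force maximum bipartite matching count under a distance threshold
# (exhaustive over assignments; only for tiny instances)
match_bruteforce <- function(ca, cb, max_distance) {
  na <- nrow(ca); nb <- nrow(cb)
  if (na == 0 || nb == 0) return(0L)
  d <- as.matrix(stats::dist(rbind(ca, cb)))[seq_len(na), na + seq_len(nb),
                                             drop = FALSE]
  best <- 0L
  rec <- function(i, used_b, count) {
    if (count + (na - i + 1L) <= best) return()
    if (i > na) { best <<- max(best, count); return() }
    rec(i + 1L, used_b, count)  # leave punctum i unmatched
    for (j in seq_len(nb)) {
      if (!used_b[j] && d[i, j] < max_distance) {
        used_b[j] <- TRUE
        rec(i + 1L, used_b, count + 1L)
        used_b[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nb), 0L)
  best
}

# speckle frame for registration tests
speckle_frame <- function(n = 96L, n_spots = 30L, seed = 2L) {
  set.seed(seed)
  base <- matrix(0, n, n)
  for (k in seq_len(n_spots)) {
    i <- sample(20:(n - 20), 1); j <- sample(20:(n - 20), 1)
    base[i + (-1:1), j + (-1:1)] <- base[i + (-1:1), j + (-1:1)] + 50
  }
  base + matrix(stats::rnorm(n * n, 10, 1), n, n)
}
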