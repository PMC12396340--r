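#' Simulation settings for a raster-scanned diffusion experiment
#'
#' Ground-truth description of a photon-counting raster scan over a field of
#' freely diffusing fluorophores. `D_true` is the 2D diffusion coefficient
#' the downstream RICS fit should recover.
#'
#' @param D_true diffusion coefficient in um^2/s (>= 0; 0 freezes particles)
#' @param particle_density particles per um^2
#' @param brightness expected photons per particle per pixel dwell when the
#'   particle sits at the PSF centre
#' @param scan a [raster_scan_config()]
#' @param n_frames number of frames (>= 2)
#' @param seed integer RNG seed
#' @return a `diffusion_sim_spec` object
#' @export
diffusion_sim_spec <- function(D_true = 1.0, particle_density = 1.0,
                               brightness = 5.0,
                               scan = raster_scan_config(),
                               n_frames = 100L, seed = 1L) {
  fields <- list(D_true = D_true, particle_density = particle_density,
                 brightness = brightness, n_frames = n_frames, seed = seed)
  for (nm in names(fields)) {
    v <- fields[[nm]]
    if (length(v) != 1L || !is.finite(v))
      stop("diffusion_sim_spec: non-finite field: ", nm)
  }
  if (D_true < 0) stop("diffusion_sim_spec: D_true must be >= 0")
  if (particle_density <= 0) stop("diffusion_sim_spec: particle_density must be > 0")
  if (brightness <= 0) stop("diffusion_sim_spec: brightness must be > 0")
  if (n_frames < 2) stop("diffusion_sim_spec: n_frames must be >= 2")
  stopifnot(inherits(scan, "raster_scan_config"))
  structure(list(D_true = D_true, particle_density = particle_density,
                 brightness = brightness, scan = scan,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "diffusion_sim_spec")
}

#' Simulate a raster scan over Brownian fluorophores
#'
#' Each pixel (x, y) of frame f is sampled at its true acquisition time
#' t = f * tau_frame + y * tau_l + x * tau_p, and particle positions are
#' advanced between consecutive pixel samples (per-axis Gaussian increments
#' with variance 2 D dt), so intra-line and intra-frame motion is present
#' exactly as the RICS model assumes. Particles live in a periodic box that
#' extends a guard margin of 3 waists beyond the imaged field, keeping the
#' density stationary. The detected signal is Poisson photon noise on the
#' Gaussian-PSF expectation `brightness * exp(-2 r^2 / omega_r^2)` summed
#' over particles (photon-counting detection; no read noise).
#'
#' @param spec a [diffusion_sim_spec()]
#' @return an [image_series()] of photon counts, with the ground truth
#'   attached as attributes `D_true` and `n_particles`
#' @export
simulate_diffusion_raster <- function(spec) {
  stopifnot(inherits(spec, "diffusion_sim_spec"))
  scan <- spec$scan
  ny <- scan$image_size[1]; nx <- scan$image_size[2]
  nt <- spec$n_frames
  px_m <- scan$delta_r                       # pixel size, m
  omega <- scan$omega_r                      # waist, m
  margin <- 3 * omega
  Ly <- ny * px_m + 2 * margin               # periodic box, m
  Lx <- nx * px_m + 2 * margin
  dens_m2 <- spec$particle_density * 1e12    # per m^2
  n_part <- max(1L, as.integer(round(dens_m2 * Lx * Ly)))
  D <- spec$D_true * 1e-12                   # m^2/s

  n_s <- nt * ny * nx
  # acquisition time of each sample, scan order: x fastest, then y, then frame
  t_frame <- rep(seq_len(nt) - 1, each = ny * nx) * scan$tau_frame
  t_line <- rep(rep(seq_len(ny) - 1, each = nx), times = nt) * scan$tau_l
  t_px <- rep(seq_len(nx) - 1, times = nt * ny) * scan$tau_p
  tt <- t_frame + t_line + t_px
  dt <- diff(tt)
  sd_step <- sqrt(2 * D * dt)
  # pixel centre coordinates inside the box (guard margin offset)
  pcx <- margin + (rep(seq_len(nx) - 1, times = nt * ny) + 0.5) * px_m
  pcy <- margin + (rep(rep(seq_len(ny) - 1, each = nx), times = nt) + 0.5) * px_m

  lambda <- with_seed(spec$seed, {
    lam <- numeric(n_s)
    for (p in seq_len(n_part)) {
      x0 <- stats::runif(1, 0, Lx)
      y0 <- stats::runif(1, 0, Ly)
      if (D > 0) {
        posx <- (x0 + cumsum(c(0, stats::rnorm(n_s - 1, 0, sd_step)))) %% Lx
        posy <- (y0 + cumsum(c(0, stats::rnorm(n_s - 1, 0, sd_step)))) %% Ly
      } else {
        posx <- rep(x0, n_s); posy <- rep(y0, n_s)
      }
      dx <- posx - pcx; dx <- dx - round(dx / Lx) * Lx  # minimum image
      dy <- posy - pcy; dy <- dy - round(dy / Ly) * Ly
      lam <- lam + exp(-2 * (dx * dx + dy * dy) / (omega * omega))
    }
    lam <- spec$brightness * lam
    stats::rpois(n_s, lam)
  })

  # scan order was x-fastest: fill a nx x ny x nt array then permute to T,Y,X
  arr <- aperm(array(lambda, dim = c(nx, ny, nt)), c(3, 2, 1))
  out <- image_series(arr, scan = scan, channel = "sim-diffusion")
  attr(out, "D_true") <- spec$D_true
  attr(out, "n_particles") <- n_part
  attr(out, "seed") <- spec$seed
  out
}

#' Displacement specification for synthetic PIV frame pairs
#'
#' @param shift numeric (dx, dy) displacement in pixels (fractional allowed)
#' @param noise_sd standard deviation of additive Gaussian noise on frame 2
#' @param seed RNG seed for the noise
#' @return a `displacement_spec` object
#' @export
displacement_spec <- function(shift = c(0, 0), noise_sd = 0, seed = 1L) {
  if (length(shift) != 2L || any(!is.finite(shift)))
    stop("displacement_spec: shift must be two finite numbers")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("displacement_spec: noise_sd must be >= 0")
  structure(list(shift = as.numeric(shift), noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "displacement_spec")
}

#' Make a frame pair with a known displacement
#'
#' Frame A is smoothed broadband noise (a speckle texture); frame B is A
#' translated by the requested displacement. Integer displacements are an
#' exact array roll; fractional displacements are applied in the Fourier
#' domain (band-limited interpolation). Independent Gaussian noise is added
#' to frame B if requested.
#'
#' @param base_texture_seed seed for the texture
#' @param spec a [displacement_spec()]
#' @param size frame size in pixels (square)
#' @param smooth_sigma Gaussian blur sigma (px) applied to the white noise
#' @return list with `a`, `b` (matrices) and `shift` (the ground truth)
#' @export
make_shifted_pair <- function(base_texture_seed, spec, size = 128L,
                              smooth_sigma = 2) {
  stopifnot(inherits(spec, "displacement_spec"))
  if (any(abs(spec$shift) > size / 2))
    stop("make_shifted_pair: displacement exceeds half the frame")
  a <- with_seed(base_texture_seed, {
    w <- matrix(stats::rnorm(size * size), size, size)
    f <- c(0:floor((size - 1) / 2), -(ceiling((size - 1) / 2):1)) / size
    g <- exp(-2 * pi^2 * smooth_sigma^2 * (outer(f^2, rep(1, size)) +
                                           outer(rep(1, size), f^2)))
    sm <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / (size * size)
    100 + 50 * sm / stats::sd(sm)
  })
  dx <- spec$shift[1]; dy <- spec$shift[2]
  b <- fourier_shift(a, dy, dx)
  if (spec$noise_sd > 0)
    b <- b + with_seed(spec$seed,
                       matrix(stats::rnorm(size * size, 0, spec$noise_sd),
                              size, size))
  list(a = a, b = b, shift = spec$shift)
}

#' Make a movie of a rigidly translating binary mask
#'
#' Frame k holds the shape translated by (k - 1) * step; ground truth for
#' covered-area and motility-index analyses.
#'
#' @param shape logical matrix, the object in frame 1
#' @param step_px integer (dx, dy) translation per frame
#' @param n_frames number of frames
#' @param pixel_size_nm calibration forwarded to the series
#' @param frame_interval_s calibration forwarded to the series
#' @return a binary [image_series()]
#' @export
make_translating_mask_series <- function(shape, step_px, n_frames,
                                         pixel_size_nm = 100,
                                         frame_interval_s = 60) {
  if (!is.matrix(shape)) stop("make_translating_mask_series: shape must be a matrix")
  shape <- if (is.logical(shape)) shape else shape > 0
  step_px <- as.integer(step_px)
  if (length(step_px) != 2L)
    stop("make_translating_mask_series: step_px must be (dx, dy)")
  if (!is_count(n_frames) || n_frames < 1)
    stop("make_translating_mask_series: n_frames must be a positive count")
  ny <- nrow(shape); nx <- ncol(shape)
  idx <- which(shape, arr.ind = TRUE)
  arr <- array(0, dim = c(n_frames, ny, nx))
  for (k in seq_len(n_frames)) {
    ii <- idx[, 1] + (k - 1L) * step_px[2]
    jj <- idx[, 2] + (k - 1L) * step_px[1]
    if (any(ii < 1 | ii > ny | jj < 1 | jj > nx))
      stop("make_translating_mask_series: shape leaves the field at frame ", k)
    fr <- matrix(0, ny, nx)
    fr[cbind(ii, jj)] <- 1
    arr[k, , ] <- fr
  }
  image_series(arr, pixel_size_nm = pixel_size_nm,
               frame_interval_s = frame_interval_s, channel = "sim-mask")
}

#' Make a star-shaped 3D skeleton phantom
#'
#' `k` straight radial branches of the given length at equal angles in the
#' xy plane, rooted at the soma. With `bifurcate_at`, each branch splits
#' into two children at that radius (children diverge by +/- 15 degrees from
#' the parent direction and extend so each branch's total path length equals
#' `length`). Analytic ground truth: total branch length is `k * length`
#' (or `k * bifurcate_at + 2k * (length - bifurcate_at)` with bifurcations)
#' and the Sholl count below the first branch point is `k`.
#'
#' @param k number of primary branches (>= 1)
#' @param length branch path length in um
#' @param soma numeric (x, y, z) soma position in um
#' @param bifurcate_at optional split radius in um (must be < length)
#' @return a [skeleton()] object
#' @export
make_star_skeleton <- function(k, length, soma = c(0, 0, 0),
                               bifurcate_at = NULL) {
  if (!is_count(k) || k < 1) stop("make_star_skeleton: k must be >= 1")
  if (!is.finite(length) || length <= 0)
    stop("make_star_skeleton: length must be > 0")
  if (!is.null(bifurcate_at) && bifurcate_at >= length)
    stop("make_star_skeleton: bifurcate_at must be < length")
  ang <- 2 * pi * (seq_len(k) - 1) / k
  nodes <- matrix(soma, 1, 3, byrow = TRUE)
  edges <- matrix(integer(0), 0, 2)
  for (b in seq_len(k)) {
    dir <- c(cos(ang[b]), sin(ang[b]), 0)
    if (is.null(bifurcate_at)) {
      nodes <- rbind(nodes, soma + length * dir)
      edges <- rbind(edges, c(1L, nrow(nodes)))
    } else {
      split <- soma + bifurcate_at * dir
      nodes <- rbind(nodes, split)
      i_split <- nrow(nodes)
      edges <- rbind(edges, c(1L, i_split))
      for (s in c(-1, 1)) {
        th <- ang[b] + s * pi / 12
        child_dir <- c(cos(th), sin(th), 0)
        nodes <- rbind(nodes, split + (length - bifurcate_at) * child_dir)
        edges <- rbind(edges, c(i_split, nrow(nodes)))
      }
    }
  }
  skeleton(nodes, edges, soma = 1L)
}

#' Planted-puncta specification for colocalization ground truth
#'
#' Describes a two-channel field with `n_pairs` cross-channel puncta pairs
#' separated by exactly `pair_distance`, plus unpaired singles in each
#' channel. All puncta (other than within a pair) are kept at least
#' `4 * pair_distance` apart (and never closer than 1 um) so the matching is
#' unambiguous.
#'
#' @param n_pairs number of cross-channel pairs
#' @param pair_distance centre-to-centre pair separation in nm
#' @param n_singles_a,n_singles_b unpaired puncta per channel
#' @param field_size field side length in um
#' @param pixel_size rendered pixel size in nm
#' @param seed RNG seed
#' @return a `planted_puncta_spec` object
#' @export
planted_puncta_spec <- function(n_pairs = 7L, pair_distance = 30,
                                n_singles_a = 5L, n_singles_b = 5L,
                                field_size = 10, pixel_size = 20,
                                seed = 1L) {
  if (!is_count(n_pairs) || !is_count(n_singles_a) || !is_count(n_singles_b))
    stop("planted_puncta_spec: counts must be non-negative integers")
  if (!is.finite(pair_distance) || pair_distance < 0)
    stop("planted_puncta_spec: pair_distance must be >= 0")
  if (field_size <= 0 || pixel_size <= 0)
    stop("planted_puncta_spec: field_size and pixel_size must be > 0")
  structure(list(n_pairs = as.integer(n_pairs), pair_distance = pair_distance,
                 n_singles_a = as.integer(n_singles_a),
                 n_singles_b = as.integer(n_singles_b),
                 field_size = field_size, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "planted_puncta_spec")
}

# rejection-sample points in [lo, hi]^2 (nm) keeping >= min_sep from `others`
place_points <- function(n, lo, hi, min_sep, others, label) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n) {
    if ((tries <- tries + 1L) > 20000L)
      stop("infeasible packing while placing ", label,
           ": field too small for the requested counts and spacing")
    cand <- stats::runif(2, lo, hi)
    all_pts <- rbind(others, pts)
    if (nrow(all_pts) == 0 ||
        min(sqrt(rowSums((all_pts - matrix(cand, nrow(all_pts), 2,
                                           byrow = TRUE))^2))) >= min_sep)
      pts <- rbind(pts, cand)
  }
  pts
}

render_spots <- function(centers_nm, ny, nx, pixel_size, sigma_nm,
                         amplitude = 1000) {
  img <- matrix(0, ny, nx)
  if (nrow(centers_nm) == 0) return(img)
  gx <- (matrix(0:(nx - 1), ny, nx, byrow = TRUE) + 0.5) * pixel_size
  gy <- (matrix(0:(ny - 1), ny, nx) + 0.5) * pixel_size
  for (i in seq_len(nrow(centers_nm))) {
    r2 <- (gx - centers_nm[i, 1])^2 + (gy - centers_nm[i, 2])^2
    img <- img + amplitude * exp(-r2 / (2 * sigma_nm^2))
  }
  img
}

#' Plant two-channel puncta with known colocalization ground truth
#'
#' Places pair anchors and singles by seeded rejection sampling under the
#' spacing guard, then renders each punctum as a Gaussian spot (sigma = 3
#' pixels) in its channel. Returns the ground-truth centroids alongside the
#' images so downstream tests never re-derive them.
#'
#' @param spec a [planted_puncta_spec()]
#' @return list with `truth_a`, `truth_b` (nm centroid matrices, pairs
#'   first), `image_a`, `image_b`, `pixel_size`, `n_pairs`
#' @export
plant_puncta <- function(spec) {
  stopifnot(inherits(spec, "planted_puncta_spec"))
  side_nm <- spec$field_size * 1000
  npx <- as.integer(round(side_nm / spec$pixel_size))
  min_sep <- max(4 * spec$pair_distance, 1000)  # nm
  border <- max(min_sep / 2, 500)
  with_seed(spec$seed, {
    anchors <- place_points(spec$n_pairs, border, side_nm - border, min_sep,
                            matrix(numeric(0), 0, 2), "pairs")
    a_pts <- anchors
    b_pts <- matrix(numeric(0), 0, 2)
    if (spec$n_pairs > 0) {
      th <- stats::runif(spec$n_pairs, 0, 2 * pi)
      b_pts <- anchors + spec$pair_distance * cbind(cos(th), sin(th))
    }
    singles_a <- place_points(spec$n_singles_a, border, side_nm - border,
                              min_sep, rbind(a_pts, b_pts), "channel-A singles")
    singles_b <- place_points(spec$n_singles_b, border, side_nm - border,
                              min_sep, rbind(a_pts, b_pts, singles_a),
                              "channel-B singles")
    truth_a <- unname(rbind(a_pts, singles_a))
    truth_b <- unname(rbind(b_pts, singles_b))
    sigma_nm <- 3 * spec$pixel_size
    list(truth_a = truth_a, truth_b = truth_b,
         image_a = render_spots(truth_a, npx, npx, spec$pixel_size, sigma_nm),
         image_b = render_spots(truth_b, npx, npx, spec$pixel_size, sigma_nm),
         pixel_size = spec$pixel_size, n_pairs = spec$n_pairs)
  })
}

#' Plant puncta inside / straddling / outside a cell mask
#'
#' Ground truth for engulfment scoring: `n_inside` puncta whose disk
#' footprint lies entirely within the mask, `n_partial` straddling the
#' boundary, `n_outside` fully outside. Returns the rendered image and a
#' [puncta_set()] carrying the planted footprints.
#'
#' @param cell_mask logical matrix (the cell body)
#' @param n_inside,n_partial,n_outside planted counts per class
#' @param seed RNG seed
#' @param radius_px punctum footprint radius in pixels
#' @param pixel_size_nm calibration for the returned puncta set
#' @return list with `image`, `puncta` ([puncta_set()]) and `truth`
#'   (class label per punctum)
#' @export
plant_engulfment <- function(cell_mask, n_inside, n_partial, n_outside,
                             seed = 1L, radius_px = 2, pixel_size_nm = 50) {
  if (!is.matrix(cell_mask)) stop("plant_engulfment: cell_mask must be a matrix")
  cell_mask <- if (is.logical(cell_mask)) cell_mask else cell_mask > 0
  if (!any(cell_mask)) stop("plant_engulfment: empty cell mask")
  ny <- nrow(cell_mask); nx <- ncol(cell_mask)
  offs <- expand.grid(di = -radius_px:radius_px, dj = -radius_px:radius_px)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius_px^2, ]
  footprint_at <- function(i, j) cbind(i + offs$di, j + offs$dj)
  class_of <- function(fp) {
    if (any(fp[, 1] < 1 | fp[, 1] > ny | fp[, 2] < 1 | fp[, 2] > nx))
      return(NA_character_)
    inside <- cell_mask[fp]
    if (all(inside)) "inside" else if (any(inside)) "partial" else "outside"
  }
  with_seed(seed, {
    want <- c(inside = n_inside, partial = n_partial, outside = n_outside)
    centers <- matrix(numeric(0), 0, 2)
    labels <- character(0)
    for (cls in names(want)) {
      placed <- 0L; tries <- 0L
      while (placed < want[[cls]]) {
        if ((tries <- tries + 1L) > 50000L)
          stop("plant_engulfment: infeasible placement for class ", cls)
        i <- sample.int(ny, 1); j <- sample.int(nx, 1)
        fp <- footprint_at(i, j)
        if (identical(class_of(fp), cls) &&
            (nrow(centers) == 0 ||
             min((centers[, 1] - i)^2 + (centers[, 2] - j)^2) >
               (4 * radius_px + 2)^2)) {
          centers <- rbind(centers, c(i, j))
          labels <- c(labels, cls)
          placed <- placed + 1L
        }
      }
    }
    footprints <- lapply(seq_len(nrow(centers)), function(q) {
      fp <- footprint_at(centers[q, 1], centers[q, 2])
      (fp[, 2] - 1) * ny + fp[, 1]   # column-major linear indices
    })
    centers_nm <- cbind((centers[, 2] - 0.5) * pixel_size_nm,
                        (centers[, 1] - 0.5) * pixel_size_nm)
    img <- render_spots(centers_nm, ny, nx, pixel_size_nm,
                        sigma_nm = radius_px * pixel_size_nm / 2)
    ps <- puncta_set(centroids = centers_nm, footprints = footprints,
                     intensities = rep(1, nrow(centers)),
                     channel = "planted", pixel_size_nm = pixel_size_nm,
                     image_dim = c(ny, nx))
    list(image = img, puncta = ps, truth = labels)
  })
}
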