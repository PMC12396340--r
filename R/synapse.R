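#' Set of detected puncta
#'
#' @param centroids numeric n x 2 (or n x 3) matrix, intensity-weighted
#'   centroids in nm ((x, y[, z]))
#' @param footprints list of integer vectors: column-major linear pixel
#'   indices of each punctum's footprint
#' @param intensities integrated intensity per punctum
#' @param channel channel label
#' @param pixel_size_nm lateral pixel size
#' @param image_dim dim of the source image
#' @return a `puncta_set` object
#' @export
puncta_set <- function(centroids, footprints, intensities, channel = "",
                       pixel_size_nm = NA_real_, image_dim = NULL) {
  centroids <- matrix(as.numeric(centroids), ncol = ncol(as.matrix(centroids)))
  if (length(footprints) != nrow(centroids))
    stop("puncta_set: one footprint per centroid required")
  all_px <- unlist(footprints)
  if (anyDuplicated(all_px)) stop("puncta_set: footprints overlap")
  structure(list(centroids = centroids, footprints = footprints,
                 intensities = as.numeric(intensities), channel = channel,
                 pixel_size_nm = pixel_size_nm, image_dim = image_dim),
            class = "puncta_set")
}

#' @export
length.puncta_set <- function(x) nrow(x$centroids)

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta%s, pixel %.1f nm\n", length(x),
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else "",
              x$pixel_size_nm))
  invisible(x)
}

#' Detect puncta by top-percentile thresholding
#'
#' The brightest `threshold_percent` of pixels are selected (the threshold
#' is the k-th largest intensity with k = ceil(n * p / 100), so an image
#' whose brightest p% sit at one value yields exactly those pixels).
#' 8-connected components of at least `min_size` pixels become puncta;
#' centroids are intensity-weighted and reported in nm. The alternative
#' `threshold_mode = "max_fraction"` thresholds at p% of the maximum
#' intensity instead.
#'
#' @param image 2D numeric matrix
#' @param threshold_percent percentage of pixels (or of max intensity) kept
#' @param min_size minimum component size in px
#' @param pixel_size_nm lateral pixel size
#' @param threshold_mode `"percentile"` (area fraction, default) or
#'   `"max_fraction"`
#' @param channel channel label
#' @return a [puncta_set()]
#' @export
detect_puncta <- function(image, threshold_percent = 1.10, min_size = 4L,
                          pixel_size_nm = 50,
                          threshold_mode = c("percentile", "max_fraction"),
                          channel = "") {
  threshold_mode <- match.arg(threshold_mode)
  if (!is.matrix(image)) stop("detect_puncta: image must be a matrix")
  rng <- range(image)
  if (rng[1] == rng[2])
    stop("detect_puncta: constant image, threshold degenerate")
  thr <- if (threshold_mode == "percentile") {
    k <- max(1L, as.integer(ceiling(length(image) * threshold_percent / 100)))
    sort(image, decreasing = TRUE)[k]
  } else {
    rng[2] * threshold_percent / 100
  }
  mask <- image >= thr
  lab <- cpp_label_components(as.logical(mask), dim(image), 2L)
  nlab <- attr(lab, "max")
  lab <- matrix(lab, nrow(image), ncol(image))
  centroids <- matrix(numeric(0), 0, 2)
  footprints <- list()
  intensities <- numeric(0)
  ny <- nrow(image)
  for (l in seq_len(nlab)) {
    px <- which(lab == l)
    if (length(px) < min_size) next
    ii <- (px - 1) %% ny + 1
    jj <- (px - 1) %/% ny + 1
    w <- image[px]
    cx <- sum((jj - 0.5) * w) / sum(w) * pixel_size_nm
    cy <- sum((ii - 0.5) * w) / sum(w) * pixel_size_nm
    centroids <- rbind(centroids, c(cx, cy))
    footprints[[length(footprints) + 1L]] <- px
    intensities <- c(intensities, sum(w))
  }
  puncta_set(centroids, footprints, intensities, channel = channel,
             pixel_size_nm = pixel_size_nm, image_dim = dim(image))
}

#' Colocalize two puncta channels
#'
#' Greedy one-to-one matching in increasing centroid-distance order; a pair
#' is admitted only while its distance is strictly below `max_distance`
#' (default 50 nm, so a pair at exactly 50 nm does not count). Ties are
#' broken toward the lower punctum index. Distances are 3D when z is
#' present.
#'
#' @param a,b [puncta_set()]s in the same coordinate frame
#' @param max_distance matching threshold in nm (strict inequality)
#' @return a `coloc_result`: list with `pairs` (data.frame index_a,
#'   index_b, distance_nm), `count`, `density_per_um2` (when the image area
#'   is known)
#' @export
colocalize <- function(a, b, max_distance = 50) {
  stopifnot(inherits(a, "puncta_set"), inherits(b, "puncta_set"))
  na <- length(a); nb <- length(b)
  pairs <- data.frame(index_a = integer(0), index_b = integer(0),
                      distance_nm = numeric(0))
  if (na > 0 && nb > 0) {
    ca <- a$centroids; cb <- b$centroids
    k <- min(ncol(ca), ncol(cb))
    dmat <- matrix(0, na, nb)
    for (d in seq_len(k))
      dmat <- dmat + outer(ca[, d], cb[, d], "-")^2
    dmat <- sqrt(dmat)
    ord <- order(dmat, row(dmat), col(dmat))
    used_a <- logical(na); used_b <- logical(nb)
    for (o in ord) {
      if (dmat[o] >= max_distance) break
      i <- (o - 1) %% na + 1
      j <- (o - 1) %/% na + 1
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      pairs <- rbind(pairs, data.frame(index_a = i, index_b = j,
                                       distance_nm = dmat[o]))
    }
  }
  dens <- NA_real_
  if (!is.null(a$image_dim) && is.finite(a$pixel_size_nm)) {
    area_um2 <- prod(a$image_dim) * (a$pixel_size_nm / 1000)^2
    dens <- nrow(pairs) / area_um2
  }
  structure(list(pairs = pairs, count = nrow(pairs),
                 density_per_um2 = dens),
            class = "coloc_result")
}

#' Engulfment scoring: puncta entirely inside a cell body
#'
#' A punctum counts for a cell iff every pixel of its footprint lies inside
#' that cell's mask -- strict containment, so boundary-straddling puncta
#' are excluded.
#'
#' @param puncta a [puncta_set()] with footprints
#' @param cell_mask integer matrix labelling cells (0 = background); a
#'   logical matrix is treated as a single cell
#' @return data.frame with `cell` label and `engulfed` count
#' @export
engulfment <- function(puncta, cell_mask) {
  stopifnot(inherits(puncta, "puncta_set"))
  if (is.logical(cell_mask)) cell_mask <- cell_mask * 1L
  cells <- sort(setdiff(unique(as.vector(cell_mask)), 0))
  counts <- stats::setNames(integer(length(cells)), as.character(cells))
  for (q in seq_len(length(puncta))) {
    fp <- puncta$footprints[[q]]
    if (any(fp < 1 | fp > length(cell_mask))) next
    labs <- unique(cell_mask[fp])
    if (length(labs) == 1L && labs != 0)
      counts[as.character(labs)] <- counts[as.character(labs)] + 1L
  }
  data.frame(cell = cells, engulfed = as.integer(counts))
}
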