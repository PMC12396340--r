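#' 3D skeleton of a ramified cell
#'
#' Node/edge graph in physical coordinates with a designated soma node.
#' Connectivity is checked; non-tree (cyclic) skeletons are accepted but
#' flagged.
#'
#' @param nodes numeric n x 3 matrix of (x, y, z) positions in um
#' @param edges integer m x 2 matrix of node index pairs (1-based)
#' @param soma index of the soma node
#' @return a `skeleton` object (fields: nodes, edges, soma, is_tree, units)
#' @export
skeleton <- function(nodes, edges, soma = 1L) {
  nodes <- as.matrix(nodes)
  if (ncol(nodes) == 2L) nodes <- cbind(nodes, 0)
  if (ncol(nodes) != 3L) stop("skeleton: nodes must be n x 3")
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(nodes)
  if (nrow(edges) > 0 && (min(edges) < 1L || max(edges) > n))
    stop("skeleton: edge index out of range")
  if (!is_count(soma) || soma < 1 || soma > n)
    stop("skeleton: soma must be a node index")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  if (n > 1 && igraph::components(g)$no != 1L)
    stop("skeleton: graph is not connected")
  is_tree <- nrow(edges) == n - 1L
  structure(list(nodes = nodes, edges = edges, soma = as.integer(soma),
                 is_tree = is_tree, units = "um"),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("skeleton: %d nodes, %d edges%s, total length %.2f um\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$is_tree) " (tree)" else " (cyclic)",
              total_branch_length(x)))
  invisible(x)
}

edge_lengths <- function(skel) {
  if (nrow(skel$edges) == 0) return(numeric(0))
  a <- skel$nodes[skel$edges[, 1], , drop = FALSE]
  b <- skel$nodes[skel$edges[, 2], , drop = FALSE]
  sqrt(rowSums((a - b)^2))
}

#' Total branch length of a skeleton
#'
#' Sum of Euclidean edge lengths, in um.
#'
#' @param skel a [skeleton()]
#' @return length in um
#' @export
total_branch_length <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  sum(edge_lengths(skel))
}

#' Sholl analysis by exact segment-sphere intersection
#'
#' For each radius, counts how many times skeleton segments cross the
#' sphere of that radius centred on the soma. Crossings are found by
#' solving the segment-sphere quadratic, so an edge that enters and leaves
#' a shell contributes two crossings and the result is independent of how
#' finely edges are subdivided.
#'
#' @param skel a [skeleton()]
#' @param step radius step in um (first shell at `step`, not 0)
#' @param max_radius largest radius; default reaches past the farthest node
#' @return a `sholl_profile`: list with `radii`, `intersections`
#' @export
sholl <- function(skel, step = 1, max_radius = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  if (!is.finite(step) || step <= 0) stop("sholl: step must be > 0")
  center <- skel$nodes[skel$soma, ]
  if (is.null(max_radius)) {
    dmax <- sqrt(max(rowSums((skel$nodes -
      matrix(center, nrow(skel$nodes), 3, byrow = TRUE))^2)))
    max_radius <- ceiling(dmax / step) * step + step
  }
  radii <- seq(step, max_radius, by = step)
  counts <- integer(length(radii))
  if (nrow(skel$edges) == 0)
    return(structure(list(radii = radii, intersections = counts),
                     class = "sholl_profile"))
  A <- skel$nodes[skel$edges[, 1], , drop = FALSE] -
    matrix(center, nrow(skel$edges), 3, byrow = TRUE)
  B <- skel$nodes[skel$edges[, 2], , drop = FALSE] -
    matrix(center, nrow(skel$edges), 3, byrow = TRUE)
  V <- B - A
  vv <- rowSums(V * V)
  av <- rowSums(A * V)
  aa <- rowSums(A * A)
  for (r in seq_along(radii)) {
    r2 <- radii[r]^2
    disc <- av^2 - vv * (aa - r2)
    ok <- vv > 0 & disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-av - sq) / vv
    t2 <- (-av + sq) / vv
    counts[r] <- sum(ok & t1 > 0 & t1 < 1) + sum(ok & t2 > 0 & t2 < 1)
  }
  structure(list(radii = radii, intersections = counts),
            class = "sholl_profile")
}

#' Extract a skeleton from a binary 3D mask
#'
#' Topology-preserving 3D thinning reduces the mask to a one-voxel-wide
#' centreline; 26-adjacent centreline voxels become graph edges, a spanning
#' tree is taken, and leaf spurs shorter than `prune_len` voxels are
#' removed. This is a basic substitute for dedicated tracing algorithms and
#' is intended for phantoms and simple cell shapes.
#'
#' @param mask logical 3D array (a 2D matrix is promoted to one slice)
#' @param soma_seed numeric (x, y, z), 0-based voxel coordinates of the soma
#' @param voxel_size_um physical voxel size (isotropic scalar or length-3)
#' @param prune_len spur length threshold in voxels
#' @return a [skeleton()] with coordinates in um
#' @export
skeleton_from_mask <- function(mask, soma_seed, voxel_size_um = 1,
                               prune_len = 2) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  if (length(dim(mask)) != 3L) stop("skeleton_from_mask: mask must be 3D")
  mask <- mask > 0
  if (!any(mask)) stop("skeleton_from_mask: empty mask")
  lab <- cpp_label_components(as.logical(mask), dim(mask), 2L)
  seed_idx <- c(soma_seed[2], soma_seed[1], soma_seed[3]) + 1  # (y, x, z)
  seed_lab <- lab[seed_idx[1] + (seed_idx[2] - 1) * dim(mask)[1] +
                    (seed_idx[3] - 1) * dim(mask)[1] * dim(mask)[2]]
  if (seed_lab == 0) stop("skeleton_from_mask: soma seed not inside the mask")
  if (attr(lab, "max") > 1L)
    stop("skeleton_from_mask: mask is disconnected (",
         attr(lab, "max"), " components)")

  thin <- cpp_thin3d(as.logical(mask), dim(mask))
  vox <- which(array(thin, dim(mask)), arr.ind = TRUE)   # (y, x, z), 1-based
  nv <- nrow(vox)
  if (nv == 0) stop("skeleton_from_mask: thinning removed all voxels")
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  nodes <- cbind((vox[, 2] - 1) * voxel_size_um[1],
                 (vox[, 1] - 1) * voxel_size_um[2],
                 (vox[, 3] - 1) * voxel_size_um[3])
  # adjacency between 26-neighbouring skeleton voxels
  key <- (vox[, 3] - 1) * (dim(mask)[1] * dim(mask)[2]) +
    (vox[, 2] - 1) * dim(mask)[1] + (vox[, 1] - 1)
  idx_of <- new.env(hash = TRUE, size = nv)
  for (q in seq_len(nv)) assign(as.character(key[q]), q, envir = idx_of)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  e1 <- integer(0); e2 <- integer(0)
  for (q in seq_len(nv)) {
    for (o in seq_len(nrow(offs))) {
      yy <- vox[q, 1] + offs[o, 1]; xx <- vox[q, 2] + offs[o, 2]
      zz <- vox[q, 3] + offs[o, 3]
      if (yy < 1 || yy > dim(mask)[1] || xx < 1 || xx > dim(mask)[2] ||
          zz < 1 || zz > dim(mask)[3]) next
      kk <- (zz - 1) * (dim(mask)[1] * dim(mask)[2]) +
        (xx - 1) * dim(mask)[1] + (yy - 1)
      p <- idx_of[[as.character(kk)]]
      if (!is.null(p) && p > q) { e1 <- c(e1, q); e2 <- c(e2, p) }
    }
  }
  w <- sqrt(rowSums((nodes[e1, , drop = FALSE] - nodes[e2, , drop = FALSE])^2))
  g <- igraph::graph_from_data_frame(
    data.frame(from = e1, to = e2, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(nv)))
  g <- igraph::mst(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- cbind(as.integer(el[, 1]), as.integer(el[, 2]))
  # soma node: skeleton voxel closest to the seed
  seed_um <- c(soma_seed[1] * voxel_size_um[1], soma_seed[2] * voxel_size_um[2],
               soma_seed[3] * voxel_size_um[3])
  soma_q <- which.min(rowSums((nodes -
    matrix(seed_um, nv, 3, byrow = TRUE))^2))
  # prune leaf spurs of at most prune_len voxels (never across the soma)
  repeat {
    deg <- tabulate(edges, nbins = nv)
    adj <- vector("list", nv)
    for (r in seq_len(nrow(edges))) {
      adj[[edges[r, 1]]] <- c(adj[[edges[r, 1]]], edges[r, 2])
      adj[[edges[r, 2]]] <- c(adj[[edges[r, 2]]], edges[r, 1])
    }
    drop <- integer(0)
    for (lf in which(deg == 1)) {
      if (lf == soma_q) next
      path <- lf; cur <- lf
      while (TRUE) {
        nb <- setdiff(adj[[cur]], path)
        if (length(nb) != 1L) break
        if (deg[nb] > 2L || nb == soma_q) break
        cur <- nb
        path <- c(path, cur)
      }
      if (length(path) <= prune_len) drop <- union(drop, path)
    }
    if (!length(drop)) break
    keep <- setdiff(seq_len(nv), drop)
    remap <- integer(nv); remap[keep] <- seq_along(keep)
    edges <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
    nodes <- nodes[keep, , drop = FALSE]
    nv <- nrow(nodes)
    soma_q <- which.min(rowSums((nodes -
      matrix(seed_um, nv, 3, byrow = TRUE))^2))
  }
  skeleton(nodes, edges, soma = soma_q)
}

#' Motility index of a cell mask movie
#'
#' For each consecutive frame pair, the additions (pixels newly occupied at
#' t+1) are normalized to the cell size, giving a motility measure that is
#' comparable across cells of different sizes. The normalization frame is
#' configurable because cell size itself changes over time.
#'
#' @param masks binary [image_series()]
#' @param normalize cell-size frame: `"t1"` (size at t+1, default), `"t"`
#'   or `"mean"` of both
#' @return a `motility_result`: list with `per_frame` (index per interval)
#'   and `mean`
#' @export
motility_index <- function(masks, normalize = c("t1", "t", "mean")) {
  stopifnot(inherits(masks, "image_series"))
  normalize <- match.arg(normalize)
  nt <- n_frames(masks)
  if (nt < 2) stop("motility_index: need at least two frames")
  per <- numeric(nt - 1L)
  for (t in seq_len(nt - 1L)) {
    a <- masks$data[t, , ] > 0
    b <- masks$data[t + 1L, , ] > 0
    if (!any(a) || !any(b)) stop("motility_index: empty frame at interval ", t)
    additions <- sum(b & !a)
    size <- switch(normalize, t1 = sum(b), t = sum(a),
                   mean = (sum(a) + sum(b)) / 2)
    per[t] <- additions / size
  }
  structure(list(per_frame = per, mean = mean(per)), class = "motility_result")
}

#' Process track of a branch tip over time
#'
#' @param positions numeric T x 2 or T x 3 matrix of tip positions in um
#' @param soma numeric soma reference position in um
#' @param frame_interval_s time between points in seconds
#' @return a `process_track` object
#' @export
process_track <- function(positions, soma, frame_interval_s = 60) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("process_track: need >= 2 time points")
  if (ncol(positions) == 2L) positions <- cbind(positions, 0)
  if (length(soma) == 2L) soma <- c(soma, 0)
  structure(list(positions = positions, soma = as.numeric(soma),
                 frame_interval_s = frame_interval_s),
            class = "process_track")
}

#' Extension / retraction events of a tracked process
#'
#' The radial distance from the tip to the soma is computed per time point;
#' maximal monotone runs qualify as events when they last at least two
#' steps or change the distance by at least `min_excursion` um. Event speed
#' is |net distance change| / run duration, in um/min.
#'
#' @param track a [process_track()]
#' @param min_excursion minimum net distance change for single-step events
#' @return data.frame with columns `event` ("extension"/"retraction"),
#'   `start`, `end` (time-point indices), `speed_um_min`
#' @export
process_speeds <- function(track, min_excursion = 0.5) {
  stopifnot(inherits(track, "process_track"))
  d <- sqrt(rowSums((track$positions -
    matrix(track$soma, nrow(track$positions), 3, byrow = TRUE))^2))
  dd <- diff(d)
  sgn <- sign(dd)
  out <- data.frame(event = character(0), start = integer(0), end = integer(0),
                    speed_um_min = numeric(0))
  i <- 1L
  while (i <= length(dd)) {
    if (sgn[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < length(dd) && sgn[j + 1L] == sgn[i]) j <- j + 1L
    net <- abs(d[j + 1L] - d[i])
    n_steps <- j - i + 1L
    if (n_steps >= 2L || net >= min_excursion) {
      dur_min <- n_steps * track$frame_interval_s / 60
      out <- rbind(out, data.frame(
        event = if (sgn[i] > 0) "extension" else "retraction",
        start = i, end = j + 1L, speed_um_min = net / dur_min))
    }
    i <- j + 1L
  }
  out
}
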