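# Minimal baseline TIFF support: uncompressed, little-endian, grayscale,
# multi-page, 8/16-bit unsigned or 32-bit float, single strip per page.
# Calibration and provenance travel in the ImageDescription tag as JSON.
# This is deliberately narrow -- enough to round-trip every image this
# package produces and to interoperate with standard scientific readers.

packUShort <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
packUInt <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

#' Write an image series (or matrix) as a grayscale TIFF
#'
#' @param x an [image_series()], matrix or T x Y x X array
#' @param path output path
#' @param bits 8 or 16 (unsigned integer) or 32 (IEEE float)
#' @param metadata optional list stored as JSON in ImageDescription (an
#'   `image_series` contributes pixel size / interval / channel
#'   automatically)
#' @return the path, invisibly
#' @export
write_tiff <- function(x, path, bits = 32L, metadata = list()) {
  if (inherits(x, "image_series")) {
    metadata <- utils::modifyList(list(
      pixel_size_nm = x$pixel_size_nm, frame_interval_s = x$frame_interval_s,
      channel = x$channel, seed = attr(x, "seed")), metadata)
    x <- x$data
  }
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  stopifnot(length(dim(x)) == 3L, bits %in% c(8L, 16L, 32L))
  nt <- dim(x)[1]; ny <- dim(x)[2]; nx <- dim(x)[3]
  metadata <- metadata[!vapply(metadata, is.null, logical(1))]
  metadata <- utils::modifyList(list(writer = "cytodyn"), metadata)
  desc <- charToRaw(jsonlite::toJSON(metadata, auto_unbox = TRUE, digits = NA))
  desc <- c(desc, as.raw(0))
  bytes_px <- bits %/% 8L
  strip_bytes <- ny * nx * bytes_px
  sample_format <- if (bits == 32L) 3L else 1L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.raw(c(42, 0)), con)
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  # layout: 8-byte header | desc | per page: strip then IFD
  desc_off <- 8L
  page_off <- desc_off + length(desc)
  writeBin(packUInt(page_off + strip_bytes), con)  # offset of first IFD
  writeBin(desc, con)
  for (t in seq_len(nt)) {
    fr <- x[t, , ]
    v <- as.vector(t(fr))                  # row-major pixel order
    if (bits == 32L) {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(pmax(pmin(v, 2^bits - 1), 0)))
      writeBin(v, con, size = bytes_px, endian = "little")
    }
    ifd_off <- page_off + strip_bytes
    next_page <- ifd_off + ifd_size
    writeBin(packUShort(n_tags), con)
    wtag <- function(id, type, count, val) {
      writeBin(packUShort(id), con); writeBin(packUShort(type), con)
      writeBin(packUInt(count), con)
      if (type == 3L && count == 1L) {     # SHORT packed left-justified
        writeBin(packUShort(val), con); writeBin(packUShort(0L), con)
      } else writeBin(packUInt(val), con)
    }
    wtag(256L, 3L, 1L, nx)                 # ImageWidth
    wtag(257L, 3L, 1L, ny)                 # ImageLength
    wtag(258L, 3L, 1L, bits)               # BitsPerSample
    wtag(259L, 3L, 1L, 1L)                 # Compression: none
    wtag(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    wtag(270L, 2L, length(desc), desc_off) # ImageDescription
    wtag(273L, 4L, 1L, page_off)           # StripOffsets
    wtag(278L, 3L, 1L, ny)                 # RowsPerStrip
    wtag(279L, 4L, 1L, strip_bytes)        # StripByteCounts
    wtag(339L, 3L, 1L, sample_format)      # SampleFormat
    writeBin(packUInt(if (t < nt) next_page + strip_bytes else 0L), con)
    page_off <- next_page
  }
  invisible(path)
}

#' Read a grayscale TIFF written by [write_tiff()] (or any uncompressed
#' little-endian baseline grayscale TIFF)
#'
#' @param path file path
#' @return list with `data` (T x Y x X array) and `metadata` (parsed JSON
#'   ImageDescription, or empty list)
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  u16 <- function(off) sum(as.integer(raw_all[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw_all[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw_all[1:2]) != "II" || u16(2) != 42L)
    stop("read_tiff: not a little-endian TIFF: ", path)
  ifd <- u32(4)
  frames <- list(); meta <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      e <- ifd + 2 + (k - 1) * 12
      id <- u16(e); type <- u16(e + 2); count <- u32(e + 4)
      val <- if (type == 3L && count == 1L) u16(e + 8) else u32(e + 8)
      tags[[as.character(id)]] <- list(type = type, count = count, val = val)
    }
    need <- c("256", "257", "258", "273", "279")
    if (!all(need %in% names(tags))) stop("read_tiff: missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]]$val != 1L)
      stop("read_tiff: compressed TIFFs are not supported")
    nx <- tags[["256"]]$val; ny <- tags[["257"]]$val
    bits <- tags[["258"]]$val
    fmt <- if (!is.null(tags[["339"]])) tags[["339"]]$val else 1L
    off <- tags[["273"]]$val
    npx <- nx * ny
    v <- if (bits == 32L && fmt == 3L) {
      readBin(raw_all[(off + 1):(off + npx * 4)], numeric(), n = npx,
              size = 4, endian = "little")
    } else if (bits %in% c(8L, 16L)) {
      readBin(raw_all[(off + 1):(off + npx * bits / 8)], integer(), n = npx,
              size = bits / 8, endian = "little", signed = FALSE)
    } else stop("read_tiff: unsupported bit depth / sample format")
    frames[[length(frames) + 1L]] <- matrix(v, ny, nx, byrow = TRUE)
    if (!length(meta) && !is.null(tags[["270"]])) {
      dsc <- tags[["270"]]
      bytes <- raw_all[(dsc$val + 1):(dsc$val + dsc$count)]
      txt <- rawToChar(bytes[bytes != as.raw(0)])
      meta <- tryCatch(jsonlite::fromJSON(txt), error = function(e) list())
    }
    ifd <- u32(ifd + 2 + n * 12)
  }
  arr <- array(0, dim = c(length(frames), dim(frames[[1]])))
  for (t in seq_along(frames)) arr[t, , ] <- frames[[t]]
  list(data = arr, metadata = meta)
}

#' Read an image series from TIFF with calibration resolution
#'
#' Calibration is taken from the embedded metadata; explicit arguments win
#' over the file (with a warning on conflict). Missing calibration is an
#' error naming the field.
#'
#' @param path TIFF path
#' @param pixel_size_nm,frame_interval_s overrides / fallbacks
#' @return an [image_series()]
#' @export
read_image_series <- function(path, pixel_size_nm = NULL,
                              frame_interval_s = NULL) {
  tf <- read_tiff(path)
  meta <- tf$metadata
  pick <- function(arg, field) {
    filev <- meta[[field]]
    if (!is.null(arg)) {
      if (!is.null(filev) && is.finite(filev) && abs(filev - arg) > 1e-9)
        warning(sprintf("read_image_series: %s: config value %g overrides file value %g",
                        field, arg, filev))
      return(arg)
    }
    filev
  }
  px <- pick(pixel_size_nm, "pixel_size_nm")
  if (is.null(px)) stop("read_image_series: missing calibration: pixel_size_nm")
  iv <- pick(frame_interval_s, "frame_interval_s")
  image_series(tf$data, pixel_size_nm = px,
               frame_interval_s = if (is.null(iv)) NA_real_ else iv,
               channel = if (is.null(meta$channel)) "" else meta$channel)
}

#' Write an SWC skeleton file
#'
#' Standard 7-column SWC (index, type, x, y, z, radius, parent). The soma
#' gets type 1 and parent -1; the tree is rooted at the soma. Cyclic
#' skeletons cannot be written.
#'
#' @param skel a [skeleton()]
#' @param path output path
#' @param radius constant node radius to record
#' @return the path, invisibly
#' @export
write_swc <- function(skel, path, radius = 0.5) {
  stopifnot(inherits(skel, "skeleton"))
  if (!skel$is_tree) stop("write_swc: skeleton is not a tree")
  n <- nrow(skel$nodes)
  g <- igraph::graph_from_edgelist(skel$edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  parent <- rep(-1L, n)
  if (n > 1) {
    bfs <- igraph::bfs(g, root = skel$soma, father = TRUE)
    f <- as.integer(bfs$father)
    ord <- as.integer(bfs$order)
    parent[ord[-1]] <- f[ord[-1]]
  }
  # SWC requires parents to precede children: write in BFS order
  ord <- if (n > 1) as.integer(igraph::bfs(g, root = skel$soma)$order) else 1L
  newid <- integer(n); newid[ord] <- seq_len(n)
  lines <- vapply(seq_len(n), function(k) {
    v <- ord[k]
    sprintf("%d %d %.6f %.6f %.6f %.3f %d", k,
            if (v == skel$soma) 1L else 3L,
            skel$nodes[v, 1], skel$nodes[v, 2], skel$nodes[v, 3], radius,
            if (parent[v] < 0) -1L else newid[parent[v]])
  }, character(1))
  writeLines(c("# generated by cytodyn; units um", lines), path)
  invisible(path)
}

#' Read an SWC skeleton file
#'
#' @param path SWC path
#' @return a [skeleton()]; the soma is the type-1 node (or the root)
#' @export
read_swc <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  idx <- match(tab$parent, tab$id)
  edges <- cbind(which(!is.na(idx)), idx[!is.na(idx)])
  soma <- which(tab$type == 1L)[1]
  if (is.na(soma)) soma <- which(tab$parent == -1L)[1]
  skeleton(as.matrix(tab[, c("x", "y", "z")]), edges, soma = soma)
}

#' Write result tables with a provenance sidecar
#'
#' Each table becomes `<name>.csv` (header + optional units row); the full
#' run configuration, including the seed, goes to `run_config.json` next to
#' them so any run can be reproduced from its sidecar alone.
#'
#' @param tables named list of data.frames
#' @param outdir output directory (created if needed)
#' @param config named list describing the run (subcommand, inputs,
#'   parameters, seed)
#' @param units optional named list: character vector of per-column units
#'   for a table of the same name
#' @return character vector of written paths, invisibly
#' @export
write_results <- function(tables, outdir, config = list(), units = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    tab <- tables[[nm]]
    con <- file(p, "w")
    writeLines(paste(colnames(tab), collapse = ","), con)
    if (!is.null(units[[nm]]))
      writeLines(paste(units[[nm]], collapse = ","), con)
    if (nrow(tab))
      utils::write.table(tab, con, sep = ",", row.names = FALSE,
                         col.names = FALSE, qmethod = "double")
    close(con)
    paths <- c(paths, p)
  }
  sp <- file.path(outdir, "run_config.json")
  jsonlite::write_json(config, sp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, sp))
}

#' Reload a run-config sidecar
#'
#' @param path path to `run_config.json`
#' @return the configuration list
#' @export
read_run_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
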