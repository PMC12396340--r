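#' Multi-frame image series
#'
#' The common container of every pipeline: a T x Y x X array of non-negative
#' intensities with physical calibration. `scan` carries raster timing for
#' RICS; for time-lapse movies `pixel_size_nm` and `frame_interval_s` are
#' enough.
#'
#' @param data numeric array, T x Y x X (a single frame Y x X is promoted)
#' @param pixel_size_nm physical pixel size in nm (taken from `scan` if given)
#' @param frame_interval_s time between frames in seconds
#' @param scan optional [raster_scan_config()]
#' @param channel free-text channel label
#' @return an `image_series` object
#' @export
image_series <- function(data, pixel_size_nm = NULL, frame_interval_s = NA_real_,
                         scan = NULL, channel = "") {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  if (length(dim(data)) != 3L)
    stop("image_series: data must be T x Y x X")
  if (any(!is.finite(data)))
    stop("image_series: non-finite intensities")
  if (!is.null(scan)) {
    stopifnot(inherits(scan, "raster_scan_config"))
    if (!all(dim(data)[2:3] == scan$image_size))
      stop("image_series: frame shape does not match scan$image_size")
    if (is.null(pixel_size_nm)) pixel_size_nm <- scan$delta_r * 1e9
    if (is.na(frame_interval_s)) frame_interval_s <- scan$tau_frame
  }
  if (is.null(pixel_size_nm))
    stop("image_series: missing calibration: pixel_size_nm")
  structure(list(
    data = data,
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    scan = scan,
    channel = channel
  ), class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_series: %d frame(s) of %d x %d px, pixel %.1f nm, interval %s s%s\n",
              d[1], d[2], d[3], x$pixel_size_nm,
              format(x$frame_interval_s),
              if (nzchar(x$channel)) paste0(" [", x$channel, "]") else ""))
  invisible(x)
}

#' @export
dim.image_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[1]

frame_of <- function(series, t) series$data[t, , ]

#' Region-of-interest mask
#'
#' A boolean Y x X mask selecting the pixels that enter an analysis (for
#' RICS, the cytosolic region; the nucleus is excluded by leaving it FALSE).
#' A fit is only attempted when at least 64 pixels are included.
#'
#' @param mask logical matrix (numeric is coerced via `> 0`)
#' @param label free-text region label, e.g. "actin-rich"
#' @param min_pixels minimum included pixel count
#' @return a `region_mask` object
#' @export
region_mask <- function(mask, label = "", min_pixels = 64L) {
  if (!is.matrix(mask)) stop("region_mask: mask must be a matrix")
  mask <- if (is.logical(mask)) mask else mask > 0
  if (sum(mask) < min_pixels)
    stop(sprintf("region_mask: only %d pixels included, need >= %d",
                 sum(mask), min_pixels))
  structure(list(mask = mask, label = label), class = "region_mask")
}
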