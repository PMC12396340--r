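#' Raster-scan acquisition geometry and timing
#'
#' Bundles the physical parameters of a confocal raster scan that enter the
#' RICS diffusion model: pixel size \eqn{\delta_r}, pixel dwell time
#' \eqn{\tau_p}, line time \eqn{\tau_l}, frame time, lateral waist of the
#' excitation focus \eqn{\omega_r} and the 2D-Gaussian shape factor
#' \eqn{\gamma = 2^{-3/2}}.
#'
#' Defaults reproduce a typical photon-counting confocal RICS acquisition:
#' 256 x 256 pixels at 50 nm pixel size, 8.19 us pixel dwell, 4.92 ms line
#' time and 1.26 s frame time. The waist must come from a calibration
#' measurement (e.g. a freely diffusing dye standard); 250 nm is a realistic
#' value for a 1.2 NA water objective at 488 nm and is used by the synthetic
#' generators.
#'
#' @param pixel_size_nm pixel size \eqn{\delta_r} in nm
#' @param dwell_us pixel dwell time \eqn{\tau_p} in microseconds
#' @param line_ms line time \eqn{\tau_l} in milliseconds
#' @param frame_s frame time in seconds
#' @param waist_nm lateral \eqn{1/e^2} PSF waist \eqn{\omega_r} in nm
#' @param gamma shape factor; \eqn{2^{-3/2}} for a 2D Gaussian focus
#' @param image_size integer (ny, nx) image dimensions in pixels
#' @return an object of class `raster_scan_config`
#' @export
raster_scan_config <- function(pixel_size_nm = 50,
                               dwell_us = 8.19,
                               line_ms = 4.92,
                               frame_s = 1.26,
                               waist_nm = 250,
                               gamma = 2^(-3 / 2),
                               image_size = c(256L, 256L)) {
  vals <- c(pixel_size_nm = pixel_size_nm, dwell_us = dwell_us,
            line_ms = line_ms, frame_s = frame_s, waist_nm = waist_nm,
            gamma = gamma)
  bad <- names(vals)[!is.finite(vals) | vals <= 0]
  if (length(bad))
    stop("raster_scan_config: non-positive or non-finite field(s): ",
         paste(bad, collapse = ", "))
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 2L))
    stop("raster_scan_config: image_size must be two integers >= 2")
  ny <- image_size[1]; nx <- image_size[2]
  tau_p <- dwell_us * 1e-6
  tau_l <- line_ms * 1e-3
  if (tau_p * nx > tau_l + 1e-12)
    stop("raster_scan_config: dwell * nx exceeds the line time")
  if (tau_l * ny > frame_s + 1e-9)
    stop("raster_scan_config: line time * ny exceeds the frame time")
  structure(list(
    delta_r = pixel_size_nm * 1e-9,   # m
    tau_p = tau_p,                    # s
    tau_l = tau_l,                    # s
    tau_frame = frame_s,              # s
    omega_r = waist_nm * 1e-9,        # m
    gamma = gamma,
    image_size = image_size
  ), class = "raster_scan_config")
}

#' @export
print.raster_scan_config <- function(x, ...) {
  cat(sprintf(
    "raster_scan_config: %d x %d px, pixel %.1f nm, dwell %.2f us, line %.2f ms, frame %.3f s, waist %.0f nm, gamma %.5f\n",
    x$image_size[1], x$image_size[2], x$delta_r * 1e9, x$tau_p * 1e6,
    x$tau_l * 1e3, x$tau_frame, x$omega_r * 1e9, x$gamma))
  invisible(x)
}
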