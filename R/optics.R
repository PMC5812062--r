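#' Optical configuration of an in-line holographic channel
#'
#' Describes the collimated-beam in-line holography geometry: a coherent
#' source of wavelength `wavelength` illuminates a `path_length`-long sample
#' volume imaged at `pixel_pitch` per pixel on a square sensor. Numerical
#' refocusing steps through the volume in increments of `z_step`; planes
#' within `window_margin` of either sampling window are discarded to avoid
#' window boundary-layer effects.
#'
#' Defaults correspond to a 660 nm source, 4.59 um/pixel magnification,
#' 2048 x 2048 sensor and a 4 cm path refocused every 500 um with 2.5 mm
#' margins, i.e. 70 retained planes and a 3.53 mL sample volume per frame.
#'
#' @param wavelength illumination wavelength (m).
#' @param pixel_pitch sensor pixel pitch referred to the sample (m).
#' @param sensor_px integer vector of length 2, sensor size in pixels.
#' @param path_length sample path length along the optical axis (m).
#' @param z_step refocusing increment (m).
#' @param window_margin margin discarded at each window (m).
#' @return an object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' length(plane_offsets(opt))   # 70
#' hologram_volume_ml(opt)      # 3.53
#' @export
optical_config <- function(wavelength = 660e-9,
                           pixel_pitch = 4.59e-6,
                           sensor_px = c(2048L, 2048L),
                           path_length = 0.04,
                           z_step = 500e-6,
                           window_margin = 2.5e-3) {
  sensor_px <- as.integer(rep(sensor_px, length.out = 2L))
  stopifnot(wavelength > 0, pixel_pitch > 0, path_length > 0,
            z_step > 0, window_margin > 0)
  if (any(sensor_px < 64L))
    stop("sensor must be at least 64 px in each dimension")
  if (z_step >= path_length)
    stop("z_step must be smaller than the path length")
  if (2 * window_margin >= path_length)
    stop("window margins leave no usable path")
  usable <- path_length - 2 * window_margin
  if (abs(usable / z_step - round(usable / z_step)) > 1e-9)
    stop("z_step must divide the usable path (path_length - 2*window_margin); ",
         "adjust z_step or window_margin")
  structure(list(wavelength = wavelength, pixel_pitch = pixel_pitch,
                 sensor_px = sensor_px, path_length = path_length,
                 z_step = z_step, window_margin = window_margin),
            class = "optical_config")
}

#' Retained reconstruction plane offsets
#'
#' Depths (m) of the refocusing planes kept for analysis, measured from the
#' sensor-side sampling window into the volume. Planes within
#' `window_margin` of either window are excluded, so the count equals
#' `(path_length - 2*window_margin) / z_step`.
#'
#' @param optics an [optical_config()].
#' @return numeric vector of strictly increasing plane depths (m).
#' @export
plane_offsets <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  seq(optics$window_margin + optics$z_step,
      optics$path_length - optics$window_margin,
      by = optics$z_step)
}

#' Sample volume of one hologram
#'
#' @param optics an [optical_config()].
#' @return imaged volume in mL (field of view x full path length).
#' @export
hologram_volume_ml <- function(optics) {
  stopifnot(inherits(optics, "optical_config"))
  fov <- optics$sensor_px * optics$pixel_pitch
  fov[1] * fov[2] * optics$path_length * 1e6
}

#' @export
print.optical_config <- function(x, ...) {
  fov_mm <- x$sensor_px * x$pixel_pitch * 1e3
  cat("In-line holography configuration\n")
  cat(sprintf("  wavelength : %.0f nm\n", x$wavelength * 1e9))
  cat(sprintf("  pixel pitch: %.2f um  (%d x %d px, FOV %.1f x %.1f mm)\n",
              x$pixel_pitch * 1e6, x$sensor_px[1], x$sensor_px[2],
              fov_mm[1], fov_mm[2]))
  cat(sprintf("  path       : %.1f mm, step %.0f um, margins %.1f mm -> %d planes\n",
              x$path_length * 1e3, x$z_step * 1e6, x$window_margin * 1e3,
              length(plane_offsets(x))))
  cat(sprintf("  volume     : %.2f mL per hologram\n", hologram_volume_ml(x)))
  invisible(x)
}
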