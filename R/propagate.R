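#' Angular-spectrum field propagation
#'
#' Propagates a complex scalar field over a distance `z` using the
#' angular-spectrum transfer function
#' `H(fx, fy) = exp(2i pi z sqrt(1/lambda^2 - fx^2 - fy^2))`,
#' the exact scalar propagator, which reduces to the Fresnel kernel in the
#' paraxial regime and is unitary for propagating components (evanescent
#' components are suppressed). Negative `z` back-propagates, so
#' `propagate_field(propagate_field(u, z, opt), -z, opt)` recovers `u` to
#' numerical precision.
#'
#' @param field complex (or numeric) matrix, the field in the source plane.
#' @param z propagation distance (m); may be negative.
#' @param optics an [optical_config()] supplying wavelength and pixel pitch.
#' @return complex matrix of the propagated field.
#' @export
propagate_field <- function(field, z, optics) {
  stopifnot(inherits(optics, "optical_config"))
  nr <- nrow(field); nc <- ncol(field)
  if (z == 0) return(field + 0i)
  fx <- fft_freq(nc, optics$pixel_pitch)   # along columns (x)
  fy <- fft_freq(nr, optics$pixel_pitch)   # along rows (y)
  arg <- 1 / optics$wavelength^2 -
    outer(fy^2, fx^2, `+`)
  kz <- sqrt(pmax(arg, 0))
  H <- exp(2i * pi * z * kz)
  H[arg < 0] <- 0+0i           # evanescent cut-off
  ft <- stats::fft(field)
  stats::fft(ft * H, inverse = TRUE) / (nr * nc)
}

# FFT sample frequencies (cycles per metre) in R's fft ordering
fft_freq <- function(n, pitch) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * pitch)
}
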