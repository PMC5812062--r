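# Synthetic turbulence and stratification inputs with known ground truth.

#' Configuration for synthetic inertial-subrange velocity series
#'
#' Describes a vertical-velocity time series whose one-sided spectral
#' density follows the Kolmogorov inertial-subrange law
#' `S(kappa) = C eps^{2/3} kappa^{-5/3}` with wavenumber mapped to
#' frequency by Taylor's frozen-turbulence hypothesis,
#' `kappa = 2 pi f / U`.
#'
#' @param epsilon_true turbulent kinetic energy dissipation rate
#'   (m^2 s^-3).
#' @param mean_speed advection speed U past the sensor (m/s).
#' @param sample_rate sampling frequency (Hz, default 16 as for a
#'   point velocimeter).
#' @param duration record length (s); `duration * sample_rate` must be at
#'   least 256, the minimum number of points for a usable spectrum.
#' @param spectral_constant Kolmogorov one-dimensional constant; 0.65 for
#'   the vertical component, 0.49 for horizontal components.
#' @param seed integer seed.
#' @return an object of class `flow_synth_config`.
#' @export
flow_synth_config <- function(epsilon_true = 1e-7,
                              mean_speed = 0.05,
                              sample_rate = 16,
                              duration = 60,
                              spectral_constant = 0.65,
                              seed = NULL) {
  stopifnot(epsilon_true > 0, mean_speed > 0, sample_rate > 0, duration > 0)
  if (!spectral_constant %in% c(0.49, 0.65))
    stop("spectral_constant must be 0.49 (horizontal) or 0.65 (vertical)")
  structure(list(epsilon_true = epsilon_true, mean_speed = mean_speed,
                 sample_rate = sample_rate, duration = duration,
                 spectral_constant = spectral_constant, seed = seed),
            class = "flow_synth_config")
}

#' Model inertial-subrange frequency spectrum
#'
#' The one-sided frequency spectrum implied by the Kolmogorov wavenumber
#' law under Taylor's hypothesis:
#' `S(f) = C eps^{2/3} (2 pi / U)^{-2/3} f^{-5/3}` (m^2 s^-2 / Hz).
#'
#' @param f frequencies (Hz, > 0).
#' @param epsilon dissipation rate (m^2 s^-3).
#' @param U mean advection speed (m/s).
#' @param C spectral constant (0.49 or 0.65).
#' @return spectral density at `f`.
#' @export
model_spectrum <- function(f, epsilon, U, C = 0.65) {
  stopifnot(all(f > 0), epsilon > 0, U > 0, C > 0)
  C * epsilon^(2 / 3) * (2 * pi / U)^(-2 / 3) * f^(-5 / 3)
}

#' Synthesize a velocity series with a -5/3 inertial subrange
#'
#' Builds the series from Fourier modes whose amplitudes follow
#' [model_spectrum()] and whose phases are uniformly random, so the
#' one-sided spectral density of the output matches
#' `C eps^{2/3} kappa^{-5/3}` across the synthesized band (all resolved
#' frequencies up to Nyquist). The series has zero mean; variance equals
#' the band-integrated model spectrum by Parseval's theorem.
#'
#' @param cfg a [flow_synth_config()].
#' @return numeric vector of length `duration * sample_rate` (m/s), with
#'   attributes `fs` and `cfg`.
#' @export
synth_velocity <- function(cfg) {
  stopifnot(inherits(cfg, "flow_synth_config"))
  N <- round(cfg$duration * cfg$sample_rate)
  if (N < 256)
    stop("duration * sample_rate = ", N,
         " < 256: at least 256 instantaneous sampling points are required ",
         "for a usable spectrum")
  with_seed(cfg$seed, {
    df <- cfg$sample_rate / N
    kmax <- floor((N - 1) / 2)     # positive-frequency bins below Nyquist
    f <- (1:kmax) * df
    S <- model_spectrum(f, cfg$epsilon_true, cfg$mean_speed,
                        cfg$spectral_constant)
    amp <- N * sqrt(S * df / 2)
    ph <- stats::runif(kmax, 0, 2 * pi)
    X <- rep(0 + 0i, N)
    X[2:(kmax + 1)] <- amp * exp(1i * ph)
    X[N:(N - kmax + 1)] <- Conj(X[2:(kmax + 1)])
    x <- Re(stats::fft(X, inverse = TRUE)) / N
    structure(x, fs = cfg$sample_rate, cfg = cfg)
  })
}

#' Piecewise-linear two-layer density profile
#'
#' A density-anomaly profile `sigma_t(z)` that is constant above
#' `pycnocline_top`, ramps linearly to `pycnocline_bottom`, and is constant
#' below: the canonical two-layer stratification with a pycnocline. Depth
#' is positive downward, and the profile is monotone non-decreasing with
#' depth (statically stable); inverted inputs are an error.
#'
#' @param surface_sigma density anomaly above the pycnocline (kg/m^3).
#' @param deep_sigma density anomaly below the pycnocline (kg/m^3);
#'   must be >= `surface_sigma`.
#' @param pycnocline_top,pycnocline_bottom pycnocline bounds (m, 0 < top < bottom).
#' @param max_depth profile extent (m).
#' @param dz depth resolution (m).
#' @return data frame with columns `depth_m`, `sigma_t`.
#' @export
synth_density <- function(surface_sigma, deep_sigma,
                          pycnocline_top, pycnocline_bottom,
                          max_depth = 25, dz = 0.05) {
  if (deep_sigma < surface_sigma)
    stop("deep_sigma < surface_sigma: statically unstable profile not modeled")
  stopifnot(pycnocline_top > 0, pycnocline_bottom > pycnocline_top, dz > 0)
  depth <- seq(0, max_depth, by = dz)
  frac <- pmin(pmax((depth - pycnocline_top) /
                      (pycnocline_bottom - pycnocline_top), 0), 1)
  data.frame(depth_m = depth,
             sigma_t = surface_sigma + frac * (deep_sigma - surface_sigma))
}
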