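# Turbulence and stratification diagnostics: Welch spectra,
# inertial-subrange dissipation, microscales, shear, Richardson number.

#' Split a velocity series into depth bins
#'
#' @param series data frame carrying at least a `depth_m` column (plus any
#'   velocity columns).
#' @param bin_height bin height (m), default 3 (needed to accumulate the
#'   256-sample minimum at typical descent rates).
#' @param min_samples minimum samples for a bin to be usable (default 256).
#' @return list of bins; each element has `depth` (bin centre), `data`
#'   (the rows), `n`, `usable`.
#' @export
bin_series_by_depth <- function(series, bin_height = 3, min_samples = 256L) {
  stopifnot("depth_m" %in% names(series))
  if (nrow(series) == 0L) return(list())
  b <- floor(series$depth_m / bin_height)
  lapply(sort(unique(b)), function(k) {
    rows <- series[b == k, , drop = FALSE]
    list(depth = (k + 0.5) * bin_height, data = rows, n = nrow(rows),
         usable = nrow(rows) >= min_samples)
  })
}

#' One-sided velocity spectrum (Welch's method)
#'
#' Averaged modified periodogram: Hann-windowed segments of `nfft` samples
#' with 50% overlap, scaled so that the integral of the spectral density
#' over frequency recovers the series variance (Parseval).
#'
#' @param x numeric velocity series (m/s); at least 256 samples.
#' @param fs sampling frequency (Hz); taken from `attr(x, "fs")` if absent.
#' @param nfft segment length (default 256).
#' @return object of class `velocity_spectrum`: list with `f` (Hz,
#'   excludes 0) and `S` (m^2 s^-2 / Hz), `fs`, `n_segments`.
#' @export
estimate_spectrum <- function(x, fs = NULL, nfft = 256L) {
  if (is.null(fs)) fs <- attr(x, "fs")
  stopifnot(!is.null(fs), fs > 0)
  x <- as.numeric(x)
  N <- length(x)
  if (N < 256L)
    stop("at least 256 samples are required to estimate a spectrum (got ",
         N, ")")
  nfft <- min(nfft, N)
  step <- max(1L, nfft %/% 2L)
  starts <- seq(1L, N - nfft + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))  # Hann
  U <- sum(w^2)
  nf <- nfft %/% 2L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    P <- Mod(X[2:(nf + 1L)])^2 / (fs * U)
    P <- 2 * P
    if (nfft %% 2L == 0L) P[nf] <- P[nf] / 2   # Nyquist bin is not doubled
    acc <- acc + P
  }
  S <- acc / length(starts)
  f <- (1:nf) * fs / nfft
  structure(list(f = f, S = S, fs = fs, n_segments = length(starts)),
            class = "velocity_spectrum")
}

#' @export
print.velocity_spectrum <- function(x, ...) {
  cat(sprintf("velocity spectrum: %d frequencies up to %.2f Hz, %d segment(s)\n",
              length(x$f), max(x$f), x$n_segments))
  invisible(x)
}

#' Dissipation rate from an inertial-subrange fit
#'
#' Inverts the Kolmogorov inertial-subrange law under Taylor's hypothesis:
#' per-frequency estimates `eps(f) = (S(f) f^{5/3} / C)^{3/2} * (2 pi / U)`
#' are averaged over the fit band. The fit is rejected (no estimate) when
#' the log-log slope of `S(f)` over the band deviates from -5/3 by more
#' than `slope_tol`, as for spectra with no discernible inertial subrange.
#'
#' The default band is the upper 40% of resolved frequencies below
#' Nyquist/1.5, where the inertial subrange emerges in slowly advected
#' profiling records.
#'
#' @param spectrum a `velocity_spectrum` (or list with `f`, `S`).
#' @param U mean advection speed (m/s).
#' @param C spectral constant: 0.65 for the vertical component (default),
#'   0.49 for horizontal.
#' @param band `c(f_lo, f_hi)` fit band (Hz); default as above.
#' @param slope_tol tolerated deviation of the local log-log slope from
#'   -5/3 (default 0.3).
#' @return object of class `epsilon_fit`: `epsilon` (m^2 s^-3, `NA` if
#'   rejected), `accepted`, `slope`, `band`, `U`, `C`.
#' @export
fit_epsilon <- function(spectrum, U, C = 0.65, band = NULL,
                        slope_tol = 0.3) {
  stopifnot(U > 0, C > 0)
  f <- spectrum$f; S <- spectrum$S
  if (is.null(band)) {
    f_hi <- max(f) / 1.5
    band <- c(0.6 * f_hi, f_hi)
  }
  sel <- f >= band[1] & f <= band[2] & S > 0
  if (sum(sel) < 2L)
    stop("fit band contains fewer than 2 spectral estimates")
  # the -5/3 acceptance guard needs about a decade of bandwidth for a
  # stable slope, so the local slope is estimated on a log-bin-averaged
  # spectrum over a band extended 4x toward low frequencies (the epsilon
  # average itself stays on `band`); averaging within log-spaced bins
  # suppresses periodogram scatter that would otherwise trip the guard
  gsel <- f >= max(min(f), band[1] / 4) & f <= band[2] & S > 0
  nb <- min(10L, max(2L, sum(gsel) %/% 6L))
  lb <- seq(log(min(f[gsel])), log(band[2]), length.out = nb + 1L)
  grp <- cut(log(f[gsel]), breaks = lb, include.lowest = TRUE)
  mf <- tapply(f[gsel], grp, mean)
  mS <- tapply(S[gsel], grp, mean)
  okb <- !is.na(mf) & !is.na(mS) & mS > 0
  slope <- stats::coef(stats::lm(log(mS[okb]) ~ log(mf[okb])))[[2]]
  accepted <- abs(slope + 5 / 3) <= slope_tol
  eps <- if (accepted) {
    mean((S[sel] * f[sel]^(5 / 3) / C)^(3 / 2)) * (2 * pi / U)
  } else NA_real_
  structure(list(epsilon = eps, accepted = accepted, slope = slope,
                 band = band, U = U, C = C, n = sum(sel)),
            class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, ...) {
  if (x$accepted)
    cat(sprintf("epsilon = %.3g m^2 s^-3  (slope %.2f, band %.2f-%.2f Hz, U = %.3f m/s, C = %.2f)\n",
                x$epsilon, x$slope, x$band[1], x$band[2], x$U, x$C))
  else
    cat(sprintf("fit rejected: log-log slope %.2f deviates from -5/3 beyond tolerance\n",
                x$slope))
  invisible(x)
}

#' Kolmogorov length scale
#'
#' `eta = (nu^3 / eps)^{1/4}`, the size of the smallest turbulent eddies;
#' particles smaller than `eta` experience laminar shear.
#'
#' @param epsilon dissipation rate (m^2 s^-3, > 0).
#' @param nu kinematic viscosity (m^2/s, default 1.1e-6 for seawater).
#' @return eta (m).
#' @export
kolmogorov_scale <- function(epsilon, nu = 1.1e-6) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0")
  (nu^3 / epsilon)^(1 / 4)
}

#' Batchelor length scale
#'
#' `lambda_B = (nu D^2 / eps)^{1/4}` with `D` the molecular diffusivity:
#' the scale where scalar diffusion balances turbulent strain. The ratio
#' `lambda_B / eta = sqrt(D / nu)` is independent of epsilon.
#'
#' @param epsilon dissipation rate (m^2 s^-3, > 0).
#' @param nu kinematic viscosity (m^2/s).
#' @param diffusivity molecular diffusivity (m^2/s, default 1e-9).
#' @return lambda_B (m).
#' @export
batchelor_scale <- function(epsilon, nu = 1.1e-6, diffusivity = 1e-9) {
  if (any(epsilon <= 0)) stop("epsilon must be > 0")
  (nu * diffusivity^2 / epsilon)^(1 / 4)
}

#' Vertical shear of the horizontal velocity
#'
#' Bin-mean horizontal velocities per depth bin, differentiated over depth
#' by centred finite differences (one-sided at the profile ends).
#'
#' @param series data frame with `depth_m`, `u_ms`, `v_ms`.
#' @param bin_height depth bin height (m).
#' @return data frame with `depth_m` (bin centres), `dudz`, `dvdz` (1/s)
#'   and `S2 = dudz^2 + dvdz^2` (s^-2).
#' @export
shear_profile <- function(series, bin_height = 3) {
  stopifnot(all(c("depth_m", "u_ms", "v_ms") %in% names(series)))
  bins <- bin_series_by_depth(series, bin_height, min_samples = 1L)
  if (length(bins) < 2L) stop("at least 2 depth bins are required for shear")
  z <- vapply(bins, `[[`, numeric(1), "depth")
  u <- vapply(bins, function(b) mean(b$data$u_ms), numeric(1))
  v <- vapply(bins, function(b) mean(b$data$v_ms), numeric(1))
  dudz <- centered_gradient(u, z)
  dvdz <- centered_gradient(v, z)
  data.frame(depth_m = z, dudz = dudz, dvdz = dvdz,
             S2 = dudz^2 + dvdz^2)
}

# centred differences, one-sided at the ends
centered_gradient <- function(y, x) {
  n <- length(y)
  if (n == 2L) return(rep(diff(y) / diff(x), 2L))
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

#' Squared buoyancy (Brunt-Vaisala) frequency from a density profile
#'
#' `N^2 = (g / rho0) * d(sigma_t)/d(depth)` on a binned profile (depth
#' positive downward, density increasing downward gives N^2 > 0). The
#' profile is binned to `dz_bin` and differentiated by centred
#' differences without sorting or overturning removal.
#'
#' @param density data frame with `depth_m`, `sigma_t`.
#' @param dz_bin bin height (m, default 0.25).
#' @param g gravitational acceleration (m/s^2).
#' @param rho0 reference density (kg/m^3, default 1025).
#' @return data frame with `depth_m` (bin centres) and `N2` (s^-2).
#' @export
buoyancy_frequency <- function(density, dz_bin = 0.25, g = 9.81,
                               rho0 = 1025) {
  stopifnot(all(c("depth_m", "sigma_t") %in% names(density)))
  b <- floor(density$depth_m / dz_bin)
  ub <- sort(unique(b))
  z <- (ub + 0.5) * dz_bin
  s <- vapply(ub, function(k) mean(density$sigma_t[b == k]), numeric(1))
  data.frame(depth_m = z, N2 = (g / rho0) * centered_gradient(s, z))
}

#' Gradient Richardson number
#'
#' `Ri = N^2 / S^2` on aligned depth bins; `Ri >= 0.25` flags stable
#' stratification. Bins with zero shear are flagged undefined (`Ri = NA`).
#'
#' @param N2 squared buoyancy frequency (s^-2), vector.
#' @param S2 squared shear (s^-2), vector aligned with `N2`.
#' @return data frame with `Ri`, `stable` (Ri >= 0.25), `undefined`
#'   (S2 == 0).
#' @export
richardson <- function(N2, S2) {
  stopifnot(length(N2) == length(S2))
  undef <- S2 == 0
  Ri <- ifelse(undef, NA_real_, N2 / S2)
  data.frame(Ri = Ri, stable = !undef & Ri >= 0.25, undefined = undef)
}

#' Reynolds number of the descending platform
#'
#' `Re = w D_H / nu` with the descent rate as velocity scale and the
#' instrument-tower diameter as length scale; ~9000 at the standard
#' slow-drop configuration (0.05 m/s, 0.2 m tower).
#'
#' @param descent_rate w (m/s).
#' @param tower_diameter D_H (m).
#' @param nu kinematic viscosity (m^2/s).
#' @return Reynolds number (dimensionless).
#' @export
platform_reynolds <- function(descent_rate = 0.05, tower_diameter = 0.2,
                              nu = 1.1e-6) {
  stopifnot(descent_rate > 0, tower_diameter > 0, nu > 0)
  descent_rate * tower_diameter / nu
}

#' Dissipation profile from a binned velocity series
#'
#' Convenience wrapper: bins the series by depth, estimates a Welch
#' spectrum of the vertical velocity per usable bin and fits the
#' dissipation rate; unusable bins (fewer than 256 samples) and rejected
#' fits yield `NA`.
#'
#' @param series data frame with `depth_m`, `w_ms` and optionally
#'   `u_ms`, `v_ms`.
#' @param fs sampling frequency (Hz).
#' @param U mean advection speed (m/s); defaults to the mean descent rate
#'   inferred from depth vs time if a `t_s` column exists, else must be
#'   given.
#' @param bin_height depth bin height (m).
#' @param C spectral constant (0.65 vertical).
#' @param ... passed to [fit_epsilon()].
#' @return data frame with `depth_m`, `n`, `epsilon`, `eta_m`,
#'   `batchelor_m`, `accepted`.
#' @export
dissipation_profile <- function(series, fs, U = NULL, bin_height = 3,
                                C = 0.65, ...) {
  stopifnot(all(c("depth_m", "w_ms") %in% names(series)))
  if (is.null(U)) {
    if (!"t_s" %in% names(series))
      stop("supply U or a t_s column to infer the descent rate")
    U <- abs(stats::coef(stats::lm(depth_m ~ t_s, data = series))[[2]])
  }
  bins <- bin_series_by_depth(series, bin_height)
  rows <- lapply(bins, function(b) {
    if (!b$usable)
      return(data.frame(depth_m = b$depth, n = b$n, epsilon = NA_real_,
                        eta_m = NA_real_, batchelor_m = NA_real_,
                        accepted = FALSE))
    sp <- estimate_spectrum(b$data$w_ms, fs = fs)
    fit <- fit_epsilon(sp, U = U, C = C, ...)
    eps <- fit$epsilon
    data.frame(depth_m = b$depth, n = b$n, epsilon = eps,
               eta_m = if (fit$accepted) kolmogorov_scale(eps) else NA_real_,
               batchelor_m = if (fit$accepted) batchelor_scale(eps) else NA_real_,
               accepted = fit$accepted)
  })
  do.call(rbind, rows)
}
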