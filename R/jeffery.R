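# Jeffery-orbit dynamics of a spheroid in constant laminar shear, and the
# orientation PDFs it predicts.

#' Jeffery angular velocity
#'
#' For a spheroid of aspect ratio `r` in laminar shear `S`, the in-plane
#' orientation angle theta (0 = flow-aligned/horizontal) evolves at
#' `omega(theta) = S / (r^2 + 1) * (r^2 sin^2 theta + cos^2 theta)`:
#' slowest when flow-aligned, fastest perpendicular to the flow
#' (`omega(90)/omega(0) = r^2`), so elongated particles dwell near the
#' flow direction and flip rapidly through the vertical.
#'
#' @param theta orientation angle(s), degrees.
#' @param S shear rate (1/s, > 0).
#' @param r aspect ratio (>= 1).
#' @return angular velocity (rad/s, same length as `theta`).
#' @export
jeffery_angular_velocity <- function(theta, S, r) {
  stopifnot(S > 0, r >= 1)
  th <- deg2rad(theta)
  S / (r^2 + 1) * (r^2 * sin(th)^2 + cos(th)^2)
}

#' Jeffery rotation period
#'
#' `T = (2 pi / S) (r + 1/r)`: the time for one complete rotation,
#' increasing with aspect ratio at fixed shear (a sphere tumbles at the
#' constant rate S/2, giving `T = 4 pi / S`).
#'
#' @param S shear rate (1/s, > 0).
#' @param r aspect ratio (>= 1).
#' @return period (s).
#' @export
jeffery_period <- function(S, r) {
  stopifnot(all(S > 0), all(r >= 1))
  (2 * pi / S) * (r + 1 / r)
}

#' Integrate a Jeffery orbit
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' `d theta / dt = omega(theta)` over one rotation period (by default),
#' starting from `theta0`. The step must resolve the orbit:
#' `dt <= T/1000` is enforced. The closed-form orbit is
#' `tan(theta(t)) = tan(2 pi t / T + phi0) / r`; the numerical series
#' matches it to a small fraction of a degree and is used for the
#' occupancy-based PDF.
#'
#' @param S shear rate (1/s).
#' @param r aspect ratio (>= 1).
#' @param theta0 initial orientation (deg), default 0 (horizontal).
#' @param n_steps number of steps over one period (default 10000).
#' @param dt time step (s); default `T / n_steps`.
#' @param duration total integration time (s); default one period.
#' @return object of class `jeffery_orbit`: data frame columns `t_s`,
#'   `theta_deg` (wrapped to (-90, 90]) plus attributes `S`, `r`,
#'   `period`, `theta_unwrapped`.
#' @export
jeffery_orbit <- function(S, r, theta0 = 0, n_steps = 10000L, dt = NULL,
                          duration = NULL) {
  stopifnot(S > 0, r >= 1, n_steps >= 100L)
  Tp <- jeffery_period(S, r)
  if (is.null(duration)) duration <- Tp
  if (is.null(dt)) dt <- duration / n_steps
  if (dt > Tp / 1000)
    stop("dt = ", signif(dt, 3), " s too coarse: must be <= T/1000 = ",
         signif(Tp / 1000, 3), " s to resolve the flipping motion")
  n <- ceiling(duration / dt)
  th <- numeric(n + 1L)
  th[1] <- deg2rad(theta0)
  f <- function(x) S / (r^2 + 1) * (r^2 * sin(x)^2 + cos(x)^2)
  x <- th[1]
  for (i in seq_len(n)) {
    k1 <- f(x)
    k2 <- f(x + dt * k1 / 2)
    k3 <- f(x + dt * k2 / 2)
    k4 <- f(x + dt * k3)
    x <- x + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    th[i + 1L] <- x
  }
  out <- data.frame(t_s = (0:n) * dt,
                    theta_deg = wrap_angle(rad2deg(th)))
  class(out) <- c("jeffery_orbit", "data.frame")
  attr(out, "S") <- S; attr(out, "r") <- r; attr(out, "period") <- Tp
  attr(out, "theta_unwrapped") <- rad2deg(th)
  out
}

#' Closed-form Jeffery orbit angle
#'
#' `theta(t) = atan(tan(2 pi t / T + phi0) / r)` (continuously unwrapped),
#' the analytic solution used as the oracle for the numerical integrator.
#'
#' @param t time(s) (s).
#' @param S shear rate (1/s).
#' @param r aspect ratio.
#' @param theta0 initial orientation (deg).
#' @return orientation (deg) wrapped to (-90, 90].
#' @export
jeffery_orbit_exact <- function(t, S, r, theta0 = 0) {
  Tp <- jeffery_period(S, r)
  phi0 <- atan(r * tan(deg2rad(theta0)))
  phi <- 2 * pi * t / Tp + phi0
  wrap_angle(rad2deg(atan(tan(phi) / r)))
}

#' Modeled orientation PDF over one Jeffery rotation
#'
#' The occupancy-time distribution of the orientation angle over one full
#' rotation, segregated into nine 20-degree bins on (-90, +90] and
#' normalized to a density per degree. Computed from the fixed-step
#' integration of the orbit, apportioning each step's duration across the
#' angle bins it traverses; the analytic occupancy law
#' `p(theta) proportional to 1 / omega(theta)` is available as
#' [jeffery_pdf_analytic()] and agrees closely at the default resolution.
#'
#' The PDF depends only on the aspect ratio: shear rescales time but not
#' the fraction of the period spent at each angle, and the initial angle
#' drops out after a full period.
#'
#' @param r aspect ratio (>= 1).
#' @param S shear rate (1/s); affects nothing but the internal time scale.
#' @param n_steps integration steps per period (default 10000).
#' @param theta0 initial orientation (deg).
#' @return object of class `jeffery_pdf`: list with `angle_deg` (bin
#'   centres), `pdf` (density per degree; `sum(pdf) * 20 == 1`), `prob`
#'   (bin probabilities), `r`, `S`, `n_steps`, `method`.
#' @export
jeffery_pdf <- function(r, S = 0.1, n_steps = 10000L, theta0 = 0) {
  orb <- jeffery_orbit(S, r, theta0 = theta0, n_steps = n_steps)
  thu <- attr(orb, "theta_unwrapped")       # monotone increasing, degrees
  dt <- diff(orb$t_s)
  edges <- seq(-90, 90, by = 20)
  occ <- numeric(9)
  for (i in seq_along(dt)) {
    a <- thu[i]; b <- thu[i + 1L]
    occ <- occ + segment_occupancy(a, b, edges) * dt[i]
  }
  prob <- occ / sum(occ)
  structure(list(angle_deg = (edges[-1] + edges[-10]) / 2,
                 pdf = prob / 20, prob = prob, r = r, S = S,
                 n_steps = n_steps, method = "occupancy"),
            class = "jeffery_pdf")
}

# fraction of the (short, monotone) angular segment [a, b] (degrees,
# unwrapped) falling in each bin of `edges` modulo 180, assuming constant
# rate within the segment
segment_occupancy <- function(a, b, edges) {
  len <- b - a
  out <- numeric(length(edges) - 1L)
  if (len <= 0) return(out)
  # map to the fundamental domain (-90, 90] by shifting multiples of 180
  shift <- floor((a + 90) / 180) * 180
  a <- a - shift; b <- b - shift
  for (i in seq_len(length(edges) - 1L)) {
    lo <- edges[i]; hi <- edges[i + 1L]
    out[i] <- max(0, min(b, hi) - max(a, lo)) +
      max(0, min(b, hi + 180) - max(a, lo + 180))
  }
  out / len
}

#' Analytic Jeffery orientation PDF
#'
#' Exact occupancy law: the time spent near an angle is inversely
#' proportional to the angular speed, `p(theta) ∝ 1/omega(theta)`, which
#' integrates in closed form to bin probabilities
#' `(atan(r tan b) - atan(r tan a)) / pi` per bin `(a, b]`.
#'
#' @param r aspect ratio (>= 1).
#' @return a `jeffery_pdf` object with `method = "analytic"`.
#' @export
jeffery_pdf_analytic <- function(r) {
  stopifnot(r >= 1)
  edges <- seq(-90, 90, by = 20)
  G <- function(th) atan(r * tan(deg2rad(th)))
  ge <- numeric(10)
  ge[1] <- -pi / 2; ge[10] <- pi / 2
  ge[2:9] <- G(edges[2:9])
  prob <- diff(ge) / pi
  structure(list(angle_deg = (edges[-1] + edges[-10]) / 2,
                 pdf = prob / 20, prob = prob, r = r, S = NA_real_,
                 n_steps = NA_integer_, method = "analytic"),
            class = "jeffery_pdf")
}

#' @export
print.jeffery_pdf <- function(x, ...) {
  cat(sprintf("Jeffery orientation PDF (r = %.3g, %s)\n", x$r, x$method))
  df <- data.frame(angle = sprintf("%+d..%+d", x$angle_deg - 10,
                                   x$angle_deg + 10),
                   pdf_per_deg = signif(x$pdf, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.jeffery_pdf <- function(x, ...) {
  graphics::barplot(x$pdf, names.arg = x$angle_deg,
                    xlab = "orientation (deg)", ylab = "PDF (per degree)",
                    main = sprintf("Jeffery PDF, r = %.3g", x$r), ...)
}

#' Draw orientation angles from the Jeffery occupancy distribution
#'
#' Samples the stationary (occupancy) distribution by evaluating the
#' closed-form orbit at uniformly random phases: `theta =
#' atan(tan(phi)/r)` with `phi ~ U(-pi/2, pi/2)`.
#'
#' @param n number of draws.
#' @param r aspect ratio(s); recycled to length `n`.
#' @return angles in degrees on (-90, 90].
#' @export
sample_jeffery_angles <- function(n, r) {
  r <- rep_len(r, n)
  phi <- stats::runif(n, -pi / 2, pi / 2)
  wrap_angle(rad2deg(atan(tan(phi) / r)))
}
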