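# Spectra, dissipation fitting, microscales, shear, stratification.

test_that("depth binning honours the 256-sample minimum", {
  # 23 m cast at 5 cm/s, 16 Hz
  t <- seq(0, 460, by = 1 / 16)
  series <- data.frame(depth_m = 0.05 * t, w_ms = 0)
  bins <- bin_series_by_depth(series, 3)
  usable <- Filter(function(b) b$usable, bins)
  expect_gte(length(usable), 7L)
  expect_equal(usable[[1]]$n, 960, tolerance = 2 / 960)
  short <- data.frame(depth_m = rep(1, 200), w_ms = 0)
  expect_false(bin_series_by_depth(short, 3)[[1]]$usable)
  expect_length(bin_series_by_depth(series[0, ], 3), 0L)
})

test_that("spectrum estimation finds tones and satisfies Parseval", {
  fs <- 16
  t <- seq(0, 64 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  sp <- estimate_spectrum(x, fs)
  expect_equal(sp$f[which.max(sp$S)], 2, tolerance = 0.05 / 2)
  for (s in 1:50) {
    withr::with_seed(s, { w <- rnorm(4096, 0, 0.3) })
    spw <- estimate_spectrum(w, fs)
    ratio <- sum(spw$S) * diff(spw$f[1:2]) / var(w)
    expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
  }
  expect_error(estimate_spectrum(rnorm(100), fs), "256")
})

test_that("dissipation fitting exactly inverts the model spectrum", {
  f <- seq(0.5, 8, by = 0.05)
  for (eps in c(1e-8, 1e-7, 1e-6))
    for (U in c(0.03, 0.05, 0.1))
      for (C in c(0.49, 0.65)) {
        fit <- fit_epsilon(list(f = f, S = model_spectrum(f, eps, U, C)),
                           U = U, C = C)
        expect_true(fit$accepted)
        expect_equal(fit$epsilon, eps, tolerance = 1e-12)
      }
})

test_that("white-noise spectra are rejected by the slope guard", {
  withr::with_seed(2L, { x <- rnorm(1024) })
  fit <- fit_epsilon(estimate_spectrum(x, 16), U = 0.05)
  expect_false(fit$accepted)
  expect_true(is.na(fit$epsilon))
})

test_that("dissipation estimates are scale-equivariant (a^3)", {
  w <- synth_velocity(flow_synth_config(epsilon_true = 1e-7, duration = 60,
                                        seed = 4L))
  e1 <- fit_epsilon(estimate_spectrum(w, 16), U = 0.05)$epsilon
  e2 <- fit_epsilon(estimate_spectrum(2 * w, 16), U = 0.05)$epsilon
  expect_equal(e2 / e1, 8, tolerance = 1e-9)
})

test_that("synthesized turbulence is recovered within 30% (median, 50 seeds)", {
  rec <- vapply(1:50, function(s) {
    w <- synth_velocity(flow_synth_config(epsilon_true = 1e-7,
                                          mean_speed = 0.05,
                                          duration = 60, seed = s))
    fit_epsilon(estimate_spectrum(w, 16), U = 0.05)$epsilon
  }, numeric(1))
  expect_lt(mean(is.na(rec)), 0.2)
  expect_lt(abs(median(rec, na.rm = TRUE) / 1e-7 - 1), 0.3)
})

test_that("microscales follow their closed forms", {
  expect_equal(kolmogorov_scale(1e-6), ((1.1e-6)^3 / 1e-6)^0.25)
  expect_equal(kolmogorov_scale(1e-6) * 1e3, 1.07, tolerance = 0.01 / 1.07)
  expect_equal(batchelor_scale(3e-7) * 1e6, 43.8, tolerance = 0.01)
  for (eps in c(1e-8, 1e-7, 1e-6))
    expect_equal(batchelor_scale(eps) / kolmogorov_scale(eps),
                 sqrt(1e-9 / 1.1e-6), tolerance = 1e-12)
  # monotone decreasing in epsilon
  eps <- 10^seq(-9, -5, by = 0.5)
  expect_true(all(diff(kolmogorov_scale(eps)) < 0))
  expect_true(all(diff(batchelor_scale(eps)) < 0))
  expect_error(kolmogorov_scale(0), "epsilon")
})

test_that("shear profiles recover linear and piecewise gradients", {
  z <- rep(seq(0.05, 20.95, by = 0.1), each = 5)
  lin <- data.frame(depth_m = z, u_ms = 0.02 * z, v_ms = 0.1)
  sp <- shear_profile(lin, bin_height = 3)
  expect_equal(sp$dudz, rep(0.02, nrow(sp)), tolerance = 1e-9)
  expect_equal(sp$dvdz, rep(0, nrow(sp)), tolerance = 1e-12)
  # piecewise slopes recovered away from the break
  u <- ifelse(z < 10, 0.03 * z, 0.3 + 0.01 * (z - 10))
  pw <- shear_profile(data.frame(depth_m = z, u_ms = u, v_ms = 0), 1)
  in1 <- pw$depth_m > 2 & pw$depth_m < 8     # interior bins of each segment
  in2 <- pw$depth_m > 12 & pw$depth_m < 19
  expect_equal(pw$dudz[in1], rep(0.03, sum(in1)), tolerance = 0.01)
  expect_equal(pw$dudz[in2], rep(0.01, sum(in2)), tolerance = 0.01)
  expect_error(shear_profile(lin[lin$depth_m < 3, ], 3), "2 depth bins")
})

test_that("Richardson numbers and stability flags follow Ri = N2/S2", {
  r <- richardson(c(1e-4, 0, 2.5e-6, 1e-5), c(1e-5, 1e-5, 1e-5, 0))
  expect_equal(r$Ri[1], 10)
  expect_true(r$stable[1])
  expect_equal(r$Ri[2], 0)
  expect_false(r$stable[2])
  expect_equal(r$Ri[3], 0.25)
  expect_true(r$stable[3])       # boundary counts as stable
  expect_true(r$undefined[4])
  expect_true(is.na(r$Ri[4]))
})

test_that("platform Reynolds number matches the slow-drop configuration", {
  expect_equal(platform_reynolds(), 9090.909, tolerance = 1e-6)
  expect_equal(platform_reynolds(0.06), 10909.09, tolerance = 1e-6)
  expect_equal(platform_reynolds(0.1) / platform_reynolds(0.05), 2)
})

test_that("the dissipation profile wrapper flags unusable bins", {
  withr::with_seed(3L, {
    t <- seq(0, 180 - 1 / 16, by = 1 / 16)
    w <- synth_velocity(flow_synth_config(epsilon_true = 1e-7, duration = 180,
                                          seed = 3L))
    series <- data.frame(t_s = t, depth_m = 0.05 * t, w_ms = as.numeric(w))
  })
  prof <- dissipation_profile(series, fs = 16, U = 0.05)
  expect_true(any(prof$accepted))
  expect_true(all(is.na(prof$epsilon[!prof$accepted])))
  expect_true(all(prof$eta_m[prof$accepted] > 0))
})
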