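# Sub-sampling, concentration profiles, PSDs, orientation PDFs.

test_that("cast sub-sampling applies the documented strides", {
  expect_identical(subsample_cast(1:9, "down"), c(1L, 4L, 7L))
  expect_identical(subsample_cast(1:6, "up"), c(1L, 3L, 5L))
  df <- data.frame(i = 1:10)
  expect_identical(subsample_cast(df, "down")$i, c(1L, 4L, 7L, 10L))
  # stride rationale: frame advance at 15 Hz and 5-6 cm/s vs the 9.4 mm FOV
  adv <- c(0.05, 0.06) / 15 * 1e3
  expect_equal(adv, c(3.33, 4.0), tolerance = 2e-3)
  expect_true(all(3 * adv > 9.4))
})

test_that("concentration follows Pv = P/(nV)", {
  holos <- data.frame(depth_m = rep(5.05, 10))
  parts <- data.frame(depth_m = rep(5.1, 100))
  cp <- concentration_profile(parts, holos)
  expect_identical(nrow(cp), 1L)
  expect_equal(cp$Pv, 100 / (10 * 3.53), tolerance = 1e-12)
  expect_equal(round(cp$Pv, 2), 2.83)
  # bins without holograms are absent
  parts2 <- rbind(parts, data.frame(depth_m = 9))
  expect_identical(nrow(concentration_profile(parts2, holos)), 1L)
})

test_that("uniform synthetic scenes give a flat profile at the true concentration", {
  opt <- optical_config()
  withr::with_seed(31L, {
    depths <- seq(1, 6.999, by = 0.02)
    counts <- rpois(length(depths), 20 * hologram_volume_ml(opt))
  })
  holos <- data.frame(depth_m = depths)
  parts <- data.frame(depth_m = rep(depths, counts))
  cp <- concentration_profile(parts, holos, volume_ml = hologram_volume_ml(opt))
  expect_equal(mean(cp$Pv), 20, tolerance = 0.03)
  expect_lt(stats::sd(cp$Pv), 2)
})

test_that("aspect-ratio breakdown columns sum to 100%", {
  withr::with_seed(8L, {
    parts <- data.frame(depth_m = runif(2000, 0, 10),
                        aspect_ratio = exp(runif(2000, 0, 3)))
  })
  ca <- concentration_by_aspect(parts)
  expect_equal(unname(colSums(ca$percent)), rep(100, 4), tolerance = 1e-9)
  # all particles in one depth bin -> 100% there in every occupied class
  one <- data.frame(depth_m = 2.05, aspect_ratio = c(2, 4, 8, 20))
  ca1 <- concentration_by_aspect(one)
  expect_true(all(ca1$percent == 100))
  # an empty class is flagged and all-zero
  lo <- data.frame(depth_m = runif(50), aspect_ratio = rep(2, 50))
  ca2 <- concentration_by_aspect(lo)
  expect_true(ca2$empty_class[["(10,Inf]"]])
  expect_true(all(ca2$percent[, "(10,Inf]"] == 0))
})

test_that("PSD densities are per volume per bin width", {
  psd <- build_psd(100, volume_l = 1)
  k <- findInterval(100, psd$breaks)
  expect_equal(psd$density[k], 1 / psd$width[k])
  expect_equal(sum(psd$counts), 1)
  psd2 <- build_psd(100, volume_l = 2)
  expect_equal(psd2$density[k], psd$density[k] / 2)
  # out-of-range particles are excluded and logged
  psd3 <- build_psd(c(100, 5, 2000), volume_l = 1)
  expect_identical(psd3$n_excluded, 2L)
})

test_that("Junge fits are exact on noiseless power laws", {
  for (g in c(0.5, 1, 1.8, 3.3, 5.9, 7)) {
    psd <- build_psd(numeric(0), volume_l = 1)
    psd$density <- psd$centers^(-g)
    fit <- fit_junge(psd)
    expect_equal(fit$gamma, g, tolerance = 1e-9)
  }
  # insufficient occupied bins -> typed no-fit
  psd <- build_psd(c(20, 30, 400), volume_l = 1)
  nofit <- fit_junge(psd, c(11.6, 40))
  expect_false(nofit$ok)
  expect_true(is.na(nofit$gamma))
})

test_that("sampled size distributions recover single and segmented slopes", {
  withr::with_seed(11L, { D <- sample_junge(50000, 1.8, c(11.6, 1000)) })
  expect_equal(fit_junge(build_psd(D, 1))$gamma, 1.8, tolerance = 0.05 / 1.8)
  withr::with_seed(12L, {
    D2 <- c(sample_junge(50000, 1.8, c(11.6, 250)),
            sample_junge(50000, 5.9, c(250, 1000)))
  })
  seg <- fit_junge_segmented(build_psd(D2, 1), knee_um = 250)
  expect_equal(seg$below$gamma, 1.8, tolerance = 0.1 / 1.8)
  expect_equal(seg$above$gamma, 5.9, tolerance = 0.1 / 5.9)
})

test_that("orientation PDFs normalize, localize and flag low counts", {
  withr::with_seed(13L, {
    parts <- data.frame(depth_m = runif(5000, 0, 6),
                        theta_deg = runif(5000, -90, 90),
                        aspect_ratio = runif(5000, 3.01, 12))
  })
  pm <- orientation_pdf(parts, bin_height = 3)
  for (d in unique(pm$depth_m))
    expect_equal(sum(pm$pdf[pm$depth_m == d]) * 20, 1, tolerance = 1e-9)
  expect_true(all(abs(pm$pdf - 1 / 180) < 0.2 / 180))
  # delta distribution: all mass in the central bin
  delta <- data.frame(depth_m = 1, theta_deg = 0, aspect_ratio = 5)
  pd <- orientation_pdf(delta)
  expect_equal(pd$pdf[pd$angle_deg == 0], 1 / 20)
  expect_true(all(pd$pdf[pd$angle_deg != 0] == 0))
  expect_true(all(pd$low_count_flag))
  # r filter removes near-round particles
  round_only <- data.frame(depth_m = 1, theta_deg = 10, aspect_ratio = 2)
  expect_identical(nrow(orientation_pdf(round_only)), 0L)
})

test_that("angles sampled from the Jeffery occupancy law reproduce the model PDF", {
  model <- jeffery_pdf(6)
  pvals <- vapply(1:10, function(s) {
    withr::with_seed(s, { th <- sample_jeffery_angles(4000, 6) })
    cnt <- hist(th, breaks = seq(-90, 90, 20), plot = FALSE)$counts
    suppressWarnings(stats::chisq.test(cnt, p = model$prob)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
  expect_gt(median(pvals), 0.05)
})

test_that("sub-sampled concentration agrees with the full-sequence estimate", {
  withr::with_seed(17L, {
    depths <- seq(1, 8.999, by = 0.01)
    counts <- rpois(length(depths), 30)
  })
  holos <- data.frame(depth_m = depths)
  parts <- data.frame(depth_m = rep(depths, counts))
  full <- concentration_profile(parts, holos)
  keep <- subsample_cast(seq_along(depths), "down")
  sub_h <- holos[keep, , drop = FALSE]
  sub_p <- data.frame(depth_m = rep(depths[keep], counts[keep]))
  sub <- concentration_profile(sub_p, sub_h)
  common <- intersect(full$depth_m, sub$depth_m)
  a <- full$Pv[match(common, full$depth_m)]
  b <- sub$Pv[match(common, sub$depth_m)]
  expect_equal(mean(b), mean(a), tolerance = 0.05)
})
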