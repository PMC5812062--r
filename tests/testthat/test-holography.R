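# Background handling, angular-spectrum reconstruction, focus
# consolidation, overlap separation.

test_that("ensemble background is the pixel mean and rejects bad input", {
  f <- matrix(runif(64), 8, 8)
  expect_equal(ensemble_background(list(f, f)), f)
  expect_error(ensemble_background(list(f)), "at least 2")
  expect_error(ensemble_background(list(f, matrix(0, 4, 4))), "dimensions")
})

test_that("background averaging recovers a fixed vignette under random particles", {
  nr <- 64L
  vign <- outer(seq(0.8, 1, length.out = nr), seq(0.9, 1, length.out = nr))
  withr::with_seed(21L, {
    frames <- lapply(1:500, function(i) {
      f <- vign
      r0 <- sample(5:55, 1); c0 <- sample(5:55, 1)
      f[r0:(r0 + 4), c0:(c0 + 4)] <- 0.1   # a dark particle somewhere
      f
    })
  })
  bg <- ensemble_background(frames)
  expect_lt(max(abs(bg - vign)), 0.05)   # particle residual averages out
})

test_that("normalization removes background structure and re-centres", {
  bg <- outer(seq(0.8, 1, length.out = 32), rep(1, 32))
  expect_equal(normalize_hologram(bg, bg), matrix(mean(bg), 32, 32))
  h <- bg + 0.02
  res <- normalize_hologram(h, bg)
  expect_equal(res, matrix(mean(bg) + 0.02, 32, 32))
  expect_error(normalize_hologram(matrix(0, 4, 4), bg), "dimensions")
})

test_that("angular-spectrum propagation is unitary (forward then back)", {
  opt <- optical_config(sensor_px = c(64L, 64L))
  withr::with_seed(5L, {
    u <- matrix(complex(real = rnorm(64^2), imaginary = rnorm(64^2)), 64, 64)
  })
  for (z in c(1e-3, 10e-3, 37e-3)) {
    v <- propagate_field(propagate_field(u, z, opt), -z, opt)
    expect_lt(max(Mod(v - u)), 1e-9)
  }
})

test_that("reconstruction yields the configured plane count and geometry", {
  opt <- small_optics(128L)
  st <- reconstruct_stack(matrix(1, 128, 128), opt)
  expect_length(st$planes, 70L)
  expect_true(all(diff(st$z) > 0))
  expect_equal(diff(st$z)[1], 500e-6)
  expect_equal(min(st$z), opt$window_margin + opt$z_step)
  expect_error(reconstruct_stack(matrix(1, 64, 64), opt), "dimensions")
})

test_that("a rendered particle reconstructs sharpest at its own depth", {
  opt <- small_optics()
  sc <- scene_row(0.587e-3, 0.587e-3, 18e-3, 100e-6, 100e-6, 90)
  h <- render_hologram(sc, opt)
  st <- reconstruct_stack(h)
  ctr <- 118:138
  prof <- vapply(st$planes, function(P) mean(P[ctr, ctr]), numeric(1))
  expect_lt(abs(st$z[which.min(prof)] - 18e-3), 0.5e-3)
})

test_that("consolidation picks the in-focus plane per sub-window", {
  opt <- small_optics()
  sc <- scene_row(0.3e-3, 0.3e-3, 21e-3, 150e-6, 60e-6, 60)
  h <- render_hologram(sc, opt)
  st <- reconstruct_stack(h)
  comp <- consolidate(st, window_size = 64L)
  expect_identical(dim(comp$depth_index), c(4L, 4L))
  # particle centred at (col, row-from-bottom) = (65, 65) -> window [4, 2]
  chosen <- st$z[comp$depth_index[4, 2]]
  expect_lt(abs(chosen - 21e-3), 1e-3)
  # sub-window grid arithmetic at the instrument scale
  expect_identical(prod(dim(matrix(0, 2048 / 128, 2048 / 128))), 256)
})

test_that("consolidating a stack of identical planes returns that plane", {
  opt <- small_optics(128L)
  withr::with_seed(2L, { P <- matrix(runif(128^2, 0.5, 1), 128, 128) })
  st <- structure(list(z = plane_offsets(opt),
                       planes = rep(list(P), 70), optics = opt),
                  class = "reconstruction_stack")
  comp <- consolidate(st, window_size = 32L)
  expect_equal(comp$image, P)
  expect_equal(consolidate(st, mode = "minimum")$image, P)
})

test_that("focus localization holds over seeded single-particle trials", {
  res <- do.call(rbind, lapply(1:15, function(s)
    roundtrip_trial(s, n_particles = 1L)))
  expect_true(all(res$matched))
  dz <- abs(res$meas_z_mm - res$true_z_mm)
  expect_true(all(dz <= 0.5))
})

test_that("non-overlapping particles are conserved through the pipeline", {
  opt <- optical_config(sensor_px = c(512L, 512L))
  n_disc_total <- 0L
  for (s in 1:2) {
    sc <- make_test_scene(10L, opt, major_range = c(150e-6, 300e-6),
                          aspect_range = c(2, 4), margin = 100e-6, seed = s)
    h <- render_hologram(sc, opt)
    f <- process_hologram(h, window_size = 64L)
    matched <- vapply(seq_len(nrow(sc)), function(i) {
      d <- sqrt((f$x_um - sc$x[i] * 1e6)^2 + (f$y_um - sc$y[i] * 1e6)^2)
      any(d < sc$major[i] * 1e6 / 2)
    }, logical(1))
    expect_true(all(matched))
    expect_lte(nrow(f), nrow(sc) + 1L)   # at most one stray halo fragment
    n_disc_total <- n_disc_total + attr(f, "n_discarded")
  }
  expect_lte(n_disc_total, 1L)   # overlap discards are rare on sparse scenes
})

test_that("crossing rods at distinct depths are split; single-depth crosses are discarded", {
  opt <- small_optics()
  rods <- rbind(scene_row(0.587e-3, 0.587e-3, 8e-3, 350e-6, 45e-6, 60),
                scene_row(0.587e-3, 0.587e-3, 22e-3, 350e-6, 45e-6, 120))
  rods$id <- 1:2
  f <- process_hologram(render_hologram(rods, opt), window_size = 64L)
  expect_identical(nrow(f), 2L)
  expect_true(all(f$overlap_flag))
  expect_equal(sort(f$z_mm), c(8, 22), tolerance = 0.5 / 8)
  expect_lt(angle_diff(f$theta_deg[which.min(f$z_mm)], 30), 3)
  expect_lt(angle_diff(f$theta_deg[which.max(f$z_mm)], -30), 3)
  # same two rods collapsed to one depth: an X-shaped single region with a
  # high hull ratio and a single focus signature -> eliminated
  x1 <- rods; x1$z <- 15e-3; x1$minor <- 30e-6
  f2 <- process_hologram(render_hologram(x1, opt), window_size = 64L)
  expect_identical(nrow(f2), 0L)
  expect_identical(attr(f2, "n_discarded"), 1L)
})

test_that("convex particles pass the overlap triage unchanged", {
  opt <- small_optics()
  sc <- scene_row(0.587e-3, 0.587e-3, 15e-3, 200e-6, 80e-6, 60)
  h <- render_hologram(sc, opt)
  st <- reconstruct_stack(h)
  comp <- consolidate(st, window_size = 64L)
  regs <- segment_composite(lowpass_2x2(comp$image), min_px = 5L)
  rg <- regs[[which.max(vapply(regs, function(r) nrow(r$px), numeric(1)))]]
  res <- resolve_overlaps(rg, st, hull_ratio_threshold = 1.5)
  expect_identical(res$status, "kept")
  expect_false(res$records$overlap_flag)
})
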