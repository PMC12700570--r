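test_that("an empty scene produces all-zero signals", {
  sc <- scatter_scene(data.frame(x_um = numeric(0), y_um = numeric(0),
                                 z_um = numeric(0), intensity = numeric(0)))
  rec <- simulate_signals(sc, cfg4(), crosstalk_model("diagonal"),
                          duration = 20 * scan_period(cfg4()))
  expect_true(all(rec$signals == 0))
  expect_equal(dim(rec$signals), c(4L, 20L * 64L))
})

test_that("a single scatterer matches the closed-form signal model", {
  cfg <- cfg4()
  w <- cfg$beam_waist_w
  j <- 3
  x0 <- 1.7; y0 <- 0.9
  sc <- point_scene(cfg, j, x = x0, y = y0, intensity = 2.5)
  rec <- simulate_signals(sc, cfg, crosstalk_model("diagonal"))
  n <- ncol(rec$signals)
  t <- (seq_len(n) - 1) / cfg$sample_rate
  vy_um <- cfg$flow_speed_vy * 1e6
  expected <- 2.5 *
    exp(-2 * ((rec$y_origin + vy_um * t) - y0)^2 / w^2) *
    exp(-2 * (x0 - beam_position(t, cfg))^2 / w^2)
  expect_equal(rec$signals[j, ], expected, tolerance = 1e-9)
  # only the channel of the scatterer's plane responds (diagonal crosstalk)
  expect_true(all(rec$signals[-j, ] == 0))
  # per-scan maximum occurs where the beam is closest to x0
  S <- samples_per_scan(cfg)
  mid <- which.max(rec$signals[j, ])
  scan0 <- (mid - 1) %/% S
  seg <- rec$signals[j, scan0 * S + seq_len(S)]
  xseg <- beam_position(t[scan0 * S + seq_len(S)], cfg)
  expect_equal(which.max(seg), which.min(abs(xseg - x0)))
  # envelope across scans is Gaussian in the flow offset, evaluated at the
  # within-scan time when the beam crosses the scatterer
  scan_max <- vapply(seq_len(n %/% S) - 1, function(s) {
    max(rec$signals[j, s * S + seq_len(S)])
  }, numeric(1))
  cross_frac <- (x0 + cfg$scan_range / 2) / cfg$scan_range
  y_scan <- rec$y_origin +
    vy_um * (seq_along(scan_max) - 1 + cross_frac) * scan_period(cfg)
  ratio <- scan_max / max(scan_max)
  model <- exp(-2 * (y_scan - y0)^2 / w^2)
  expect_equal(ratio, model / max(model), tolerance = 0.05)
})

test_that("the forward model is linear and scales with intensity", {
  cfg <- cfg4()
  xt <- xt_nn(0.2)
  a <- point_scene(cfg, 1, x = -2, y = 0)
  b <- point_scene(cfg, 3, x = 3, y = 4)
  both <- scatter_scene(rbind(a$centers, b$centers))
  dur <- 40 * scan_period(cfg)
  ra <- simulate_signals(a, cfg, xt, duration = dur, y_origin = -10)
  rb <- simulate_signals(b, cfg, xt, duration = dur, y_origin = -10)
  rab <- simulate_signals(both, cfg, xt, duration = dur, y_origin = -10)
  expect_equal(rab$signals, ra$signals + rb$signals, tolerance = 1e-12)
  r3 <- simulate_signals(
    scatter_scene(transform(both$centers, intensity = intensity * 3.7)),
    cfg, xt, duration = dur, y_origin = -10)
  expect_equal(r3$signals, 3.7 * rab$signals, tolerance = 1e-12)
  expect_true(all(rab$signals >= 0))
})

test_that("too-short durations and invalid scenes are refused", {
  cfg <- cfg4()
  sc <- grid_phantom(1, n_planes = 4, xy_extent = 20, min_separation = 2,
                     seed = 1)
  expect_error(simulate_signals(sc, cfg, xt_nn(), duration = 1e-5),
               class = "fsc_validation_error")
  bad <- sc
  bad$centers$x_um[1] <- NaN
  expect_error(simulate_signals(bad, cfg, xt_nn()),
               class = "fsc_validation_error")
})

test_that("dense operator reproduces the simulator and shifts along flow", {
  cfg <- cfg4()
  xt <- xt_nn(0.2)
  dx <- cfg$scan_range / samples_per_scan(cfg)
  dy <- cfg$flow_speed_vy * 1e6 * scan_period(cfg)
  grid <- list(x = dx * (-3:2), y = dy * (0:4), z = z_planes(cfg)[2:3])
  op <- build_dense_operator(grid, cfg, xt, frozen_y = TRUE)
  vals <- array(runif(6 * 5 * 2), c(6, 5, 2))
  vox <- voxel_scene(grid, vals)
  rec <- simulate_signals(vox$scene, cfg, xt, duration = op$duration,
                          frozen_y = TRUE, y_origin = op$y_origin)
  p <- as.vector(op$A %*% vox$vector)
  expect_equal(p, as.vector(rec$signals), tolerance = 1e-12)
  expect_equal(as.vector(op$A %*% numeric(ncol(op$A))),
               numeric(nrow(op$A)))
  # voxels differing only in y give sample-shifted operator columns
  S <- samples_per_scan(cfg) * cfg$n_channels
  i1 <- which(op$voxels$x_um == grid$x[2] & op$voxels$y_um == grid$y[1] &
                op$voxels$z_um == grid$z[1])
  i2 <- which(op$voxels$x_um == grid$x[2] & op$voxels$y_um == grid$y[3] &
                op$voxels$z_um == grid$z[1])
  c1 <- op$A[, i1]; c2 <- op$A[, i2]
  shift <- 2L * S   # two scan periods, channel-major flattening
  expect_equal(c2[(shift + 1):length(c2)], c1[1:(length(c1) - shift)],
               tolerance = 1e-12)
  expect_error(build_dense_operator(list(x = 1:100, y = 1:100, z = 1:10),
                                    cfg, xt),
               class = "fsc_numerical_error")
})

test_that("noise is seeded, optional and leaves the input untouched", {
  cfg <- cfg4()
  sc <- point_scene(cfg, 2)
  rec <- simulate_signals(sc, cfg, crosstalk_model("diagonal"))
  same <- add_noise(rec, poisson_scale = 0, gaussian_sigma = 0)
  expect_equal(same$signals, rec$signals)
  n1 <- add_noise(rec, poisson_scale = 50, gaussian_sigma = 0.02, seed = 3)
  n2 <- add_noise(rec, poisson_scale = 50, gaussian_sigma = 0.02, seed = 3)
  n3 <- add_noise(rec, poisson_scale = 50, gaussian_sigma = 0.02, seed = 4)
  expect_identical(n1$signals, n2$signals)
  expect_false(identical(n1$signals, n3$signals))
  expect_equal(rec$signals,
               simulate_signals(sc, cfg, crosstalk_model("diagonal"))$signals)
  expect_error(add_noise(rec, poisson_scale = -1),
               class = "fsc_validation_error")

  # additive-noise standard deviation converges on a zero record
  zero <- with_signals(rec, matrix(0, 4, 6e4))
  sig <- add_noise(zero, gaussian_sigma = 0.37, seed = 8)$signals
  expect_equal(sd(sig), 0.37, tolerance = 3 * 0.37 / sqrt(length(sig)) * 3)
})

test_that("axial Gaussian response spreads a scatterer over adjacent planes", {
  cfg <- fsc_config(n_channels = 4, axial_psf_sigma = 1.5)
  z_mid <- mean(z_planes(cfg)[2:3])    # halfway between two planes
  sc <- scatter_scene(data.frame(x_um = 0, y_um = 0, z_um = z_mid,
                                 intensity = 1))
  rec <- simulate_signals(sc, cfg, crosstalk_model("diagonal"))
  ch_max <- apply(rec$signals, 1, max)
  expect_equal(ch_max[2], ch_max[3], tolerance = 1e-9)
  expect_gt(ch_max[2], ch_max[1])
  expect_gt(min(ch_max), 0)
})
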