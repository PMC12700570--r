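test_that("demultiplexing maps samples to the scan/flow pixel grid", {
  cfg <- cfg4()
  S <- samples_per_scan(cfg)
  sc <- point_scene(cfg, 2, x = 0, y = 0)
  rec <- simulate_signals(sc, cfg, crosstalk_model("diagonal"))
  # a partial trailing scan is discarded
  rec105 <- with_signals(rec, rec$signals[, seq_len(10 * S + S %/% 2)])
  st <- demultiplex(rec105, cfg)
  expect_equal(dim(st$images), c(10L, S, 4L))
  expect_equal(st$pixel_size_y, 0.8)       # vy * T at the defaults
  expect_equal(st$pixel_size_x, cfg$scan_range / S)
  # mid-scan sample lands in the x = 0 column
  xs <- st$origin[["x"]] + (seq_len(S) - 1) * st$pixel_size_x
  expect_equal(xs[S / 2 + 1], 0)
  # row n, column k holds sample k of scan n
  st_full <- demultiplex(rec, cfg)
  expect_equal(st_full$images[3, 5, 2], rec$signals[2, 2 * S + 5])
  short <- with_signals(rec, rec$signals[, seq_len(S + 3)])
  expect_error(demultiplex(short, cfg), class = "fsc_validation_error")
  wrong <- fsc_config(n_channels = 8)
  expect_error(demultiplex(rec, wrong), class = "fsc_validation_error")
})

test_that("beam deconvolution sharpens rows and has an identity limit", {
  cfg <- cfg4()
  n_x <- 64; dx <- 0.625; w <- 3
  xs <- (seq_len(n_x) - n_x / 2) * dx
  blurred <- exp(-2 * (xs - 0.3)^2 / w^2)
  img <- array(rep(blurred, each = 4), c(4, n_x, 1))  # 4 identical rows
  st <- make_stack(img, dx, 0.8, cfg)

  # w -> 0: the filter tends to 1 and the data pass through unchanged
  tiny <- deconvolve_x(st, w = 1e-9, params = deconv_params(epsilon = 1e-6))
  expect_equal(tiny$images, st$images, tolerance = 1e-12)

  dec <- deconvolve_x(st, w = w, params = deconv_params(epsilon = 1e-6))
  expect_gte(fwhm(blurred) / fwhm(dec$images[1, , 1]), 3)
  peak_col <- which.max(dec$images[1, , 1])
  expect_equal(xs[peak_col], 0.3, tolerance = dx)

  # two impulses blurred by the beam merge, and are resolved afterwards
  two <- exp(-2 * (xs + 1.4)^2 / w^2) + exp(-2 * (xs - 1.4)^2 / w^2)
  n_max <- function(v) sum(v > c(-Inf, head(v, -1)) & v > c(v[-1], -Inf) &
                             v > 0.2 * max(v))
  expect_equal(n_max(two), 1)
  st2 <- make_stack(array(two, c(1, n_x, 1)), dx, 0.8, cfg)
  dec2 <- deconvolve_x(st2, w = w, params = deconv_params(epsilon = 1e-6))
  expect_equal(n_max(dec2$images[1, , 1]), 2)
})

test_that("the exact inverse is refused on broadband data and allowed in band", {
  cfg <- cfg4()
  n_x <- 64; dx <- 0.625
  impulse <- numeric(n_x); impulse[20] <- 1
  st <- make_stack(array(impulse, c(1, n_x, 1)), dx, 0.8, cfg)
  expect_error(deconvolve_x(st, w = 3, params = deconv_params(epsilon = 0)),
               class = "fsc_numerical_error")
  xs <- (seq_len(n_x) - n_x / 2) * dx
  smooth <- exp(-xs^2 / (2 * 9))
  sts <- make_stack(array(smooth, c(1, n_x, 1)), dx, 0.8, cfg)
  dec <- deconvolve_x(sts, w = 3, params = deconv_params(epsilon = 0))
  expect_true(all(is.finite(dec$images)))
})

test_that("U spectrum matches the closed-form Gaussian transform", {
  w <- 3
  U <- build_u_spectrum(crosstalk_model("diagonal"), w, y_window = 51.2,
                        n_y = 64, n_channels = 3)
  for (j in 1:3) {
    analytic <- w * sqrt(pi / 2) * exp(-pi^2 * w^2 * U$ky_grid^2 / 2)
    expect_equal(Re(U$values[j, j, ]), analytic, tolerance = 1e-6)
    expect_true(all(Mod(U$values[j, j, ] - analytic) < 1e-6))
  }
  off <- U$values[1, 2, ]
  expect_true(all(Mod(off) == 0))
  # U at k_y = 0 equals the quadrature of the kernel
  dy <- 51.2 / 64
  yy <- seq(-25.6, 25.6 - dy, by = dy)
  expect_equal(Re(U$values[1, 1, 1]), sum(exp(-2 * yy^2 / w^2)) * dy,
               tolerance = 1e-9)
  expect_error(build_u_spectrum(crosstalk_model("diagonal"), w,
                                y_window = 10, n_y = 16, n_channels = 3),
               class = "fsc_validation_error")
})

test_that("a zero crosstalk table yields a zero U spectrum", {
  yg <- seq(-10, 10, by = 0.5)
  tab <- array(0, c(3, 3, length(yg)))
  U <- build_u_spectrum(crosstalk_model("tabulated", table = tab,
                                        y_grid = yg),
                        w = 3, y_window = 40, n_y = 64, n_channels = 3)
  expect_true(all(Mod(U$values) == 0))
})

test_that("axial unmixing recovers a fabricated multiplication oracle", {
  # y-dependent tabulated crosstalk exercises the general Tikhonov path
  cfg <- cfg4()
  n <- 4; n_pad <- 64; dy <- 0.8
  yg <- seq(-12, 12, by = 0.4)
  tab <- array(0, c(n, n, length(yg)))
  for (k in seq_along(yg)) {
    m <- diag(n)
    eps_y <- 0.25 * exp(-yg[k]^2 / 18)    # smoothly varying coupling
    idx <- seq_len(n - 1)
    m[cbind(idx, idx + 1)] <- eps_y
    m[cbind(idx + 1, idx)] <- eps_y
    tab[, , k] <- m
  }
  xt <- crosstalk_model("tabulated", table = tab, y_grid = yg)
  U <- build_u_spectrum(xt, w = 3, y_window = n_pad * dy, n_y = n_pad,
                        n_channels = n)
  expect_null(U$separable)
  # forward-convolve a known field through U, then invert
  f <- array(0, c(n_pad, 6, n))
  set.seed(42)
  for (j in seq_len(n)) {
    base <- exp(-((seq_len(n_pad) - 20 - 4 * j)^2) / 18)
    for (x in 1:6) f[, x, j] <- base * runif(1, 0.5, 1.5)
  }
  img <- array(0, c(n_pad, 6, n))
  for (i in seq_len(n)) {
    acc <- matrix(0i, n_pad, 6)
    for (j in seq_len(n)) {
      acc <- acc + U$values[i, j, ] * stats::mvfft(f[, , j])
    }
    img[, , i] <- Re(stats::mvfft(acc, inverse = TRUE)) / n_pad
  }
  st <- make_stack(img, 0.625, dy, cfg)
  vol <- invert_axial(st, U, ridge = 1e-12)
  expect_lt(rel_l2(vol$intensities, f), 1e-6)
})

test_that("diagonal unmixing with zero ridge is a per-channel division", {
  cfg <- cfg4()
  n_pad <- 64; dy <- 0.8
  U <- build_u_spectrum(crosstalk_model("diagonal"), w = 3,
                        y_window = n_pad * dy, n_y = n_pad, n_channels = 4)
  prof <- exp(-((seq_len(n_pad) - 25)^2) / 8)
  img <- array(0, c(n_pad, 5, 4))
  img[, 3, 2] <- prof                      # only channel 2, one column
  st <- make_stack(img, 0.625, dy, cfg)
  vol <- invert_axial(st, U, ridge = 0)
  on <- max(abs(vol$intensities[, , 2]))
  off <- max(abs(vol$intensities[, , -2]))
  expect_lt(off / on, 1e-9)
})

test_that("crosstalk ghosts are measured before and removed after unmixing", {
  cfg <- cfg4()
  truth <- point_scene(cfg, 3)
  for (eps in c(0.1, 0.2, 0.3)) {
    rec <- simulate_signals(truth, cfg, xt_nn(eps))
    st <- demultiplex(rec)
    vol <- reconstruct_volume(rec)
    rep <- crosstalk_suppression(vol, st, truth)
    expect_equal(rep$before_ratio, eps, tolerance = 1e-6)
    expect_lt(rep$after_ratio, 0.02)
    # suppression is monotone: always better than no unmixing
    expect_lt(rep$after_ratio, eps)
  }
})

test_that("the full pipeline is linear in the recorded signals", {
  cfg <- cfg4()
  xt <- xt_nn(0.2)
  dur <- 40 * scan_period(cfg)
  r1 <- simulate_signals(point_scene(cfg, 2, x = -3, y = 0), cfg, xt,
                         duration = dur, y_origin = -10)
  r2 <- simulate_signals(point_scene(cfg, 4, x = 5, y = 3), cfg, xt,
                         duration = dur, y_origin = -10)
  v1 <- reconstruct_volume(r1)
  v2 <- reconstruct_volume(r2)
  mix <- with_signals(r1, 2.5 * r1$signals + 0.75 * r2$signals)
  vmix <- reconstruct_volume(mix)
  expect_lt(rel_l2(vmix$intensities,
                   2.5 * v1$intensities + 0.75 * v2$intensities), 1e-9)
})

test_that("delaying a scene by whole scan periods shifts the volume rows", {
  cfg <- cfg4()
  xt <- xt_nn(0.15)
  dy <- cfg$flow_speed_vy * 1e6 * scan_period(cfg)
  m <- 4L
  sc <- grid_phantom(1, n_planes = 4, xy_extent = 16, min_separation = 2,
                     seed = 6)
  shifted <- scatter_scene(transform(sc$centers, y_um = y_um + m * dy))
  dur <- 60 * scan_period(cfg)
  r0 <- simulate_signals(sc, cfg, xt, duration = dur, y_origin = -16)
  r1 <- simulate_signals(shifted, cfg, xt, duration = dur, y_origin = -16)
  v0 <- reconstruct_volume(r0)$intensities
  v1 <- reconstruct_volume(r1)$intensities
  interior <- 8:(dim(v0)[1] - 8)
  expect_lt(rel_l2(v1[interior + m, , ], v0[interior, , ]), 1e-6)
})

test_that("an all-zero record reconstructs to an all-zero volume", {
  cfg <- cfg4()
  rec <- simulate_signals(point_scene(cfg, 1), cfg, xt_nn())
  zero <- with_signals(rec, rec$signals * 0)
  vol <- reconstruct_volume(zero)
  expect_true(all(vol$intensities == 0))
})

test_that("volume resampling preserves shape contracts and total intensity", {
  cfg <- cfg4()
  rec <- simulate_signals(bead_shell_phantom(12, n_surface_points = 150,
                                             seed = 3), cfg, xt_nn())
  vol <- reconstruct_volume(rec)
  d <- dim(vol$intensities)
  same <- resample_volume(vol, c(d[2], d[1], d[3]))
  expect_equal(same$intensities, vol$intensities, tolerance = 1e-12)

  big <- resample_volume(vol, c(200, 200, 100))
  expect_equal(dim(big$intensities), c(200L, 200L, 100L))
  # physical extent preserved
  expect_equal(big$voxel_size[["x"]] * 200, vol$voxel_size[["x"]] * d[2])
  expect_equal(big$voxel_size[["z"]] * 100, vol$voxel_size[["z"]] * d[3])
  # integrated intensity preserved for this smooth volume
  int_old <- sum(vol$intensities) * prod(vol$voxel_size)
  int_new <- sum(big$intensities) * prod(big$voxel_size)
  expect_equal(int_new, int_old, tolerance = 0.01)

  const <- volume3d(array(2.5, c(6, 6, 4)), c(x = 1, y = 1, z = 1),
                    c(x = 0, y = 0, z = 0))
  up <- resample_volume(const, c(11, 13, 7))
  expect_equal(range(up$intensities), c(2.5, 2.5))
  expect_error(resample_volume(vol, c(200, 1, 100)),
               class = "fsc_validation_error")
})

test_that("flow-speed compensation restores the aspect ratio of a sphere", {
  xt <- crosstalk_model("diagonal")
  sc <- bead_shell_phantom(diameter = 15, n_surface_points = 250,
                           interior_density = 0, seed = 2)
  cfg_act <- fsc_config(flow_speed_vy = 0.08)
  cfg_nom <- fsc_config(flow_speed_vy = 0.16)
  rec <- simulate_signals(sc, cfg_act, xt)
  rec$config <- cfg_nom
  st <- demultiplex(rec, cfg_nom)    # wrong speed assumed at demultiplexing
  extent_ratio <- function(stack) {
    img <- apply(pmax(stack$images, 0), c(1, 2), sum)
    m <- img >= 0.2 * max(img)
    y_ext <- (diff(range(which(rowSums(m) > 0))) + 1) * stack$pixel_size_y
    x_ext <- (diff(range(which(colSums(m) > 0))) + 1) * stack$pixel_size_x
    y_ext / x_ext
  }
  expect_gt(extent_ratio(st), 1.6)           # distorted by ~2x
  fixed <- compensate_flow_speed(st, vy_actual = 0.08, vy_nominal = 0.16)
  expect_equal(extent_ratio(fixed), 1, tolerance = 0.1)
  # identity and smooth reciprocal round trip
  expect_identical(compensate_flow_speed(st, 0.16, 0.16), st)
  ys <- (0:79) * 0.8
  smooth <- array(exp(-(ys - 32)^2 / 250), c(80, 3, 2))
  sts <- make_stack(smooth, 0.625, 0.8, cfg_nom)
  back <- compensate_flow_speed(compensate_flow_speed(sts, 0.144, 0.16),
                                0.16, 0.144)
  n <- min(dim(back$images)[1], 80)
  expect_lt(rel_l2(back$images[1:n, , ], sts$images[1:n, , ]), 1e-3)
  expect_error(compensate_flow_speed(st, -1, 0.16),
               class = "fsc_validation_error")
})

test_that("thresholding clips negatives and obeys its limits", {
  v <- array(c(-0.5, runif(30), 2), c(4, 4, 2))
  vol <- volume3d(v, c(x = 1, y = 1, z = 1), c(x = 0, y = 0, z = 0))
  full <- threshold_volume(vol, 0)
  expect_true(all(full$mask))
  top <- threshold_volume(vol, 1)
  expect_equal(sum(top$mask), 1)
  expect_equal(which(top$mask), which.max(v))
  mid <- threshold_volume(vol, 0.5)
  expect_true(all(mid$masked$intensities[!mid$mask] == 0))
  expect_true(all(mid$masked$intensities >= 0))
  expect_error(threshold_volume(vol, 1.5), class = "fsc_validation_error")
})
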