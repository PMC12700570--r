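# Spatiotemporal reconstruction: demultiplex the PMT time series into
# per-channel (x, y) images, deconvolve the Gaussian beam along the scan axis,
# unmix axial crosstalk per flow-axis spatial frequency, and assemble the 3D
# volume.
#
# Fourier convention: ordinary frequency (kernel exp(-2*pi*i*k*x)), under
# which the continuous transform of exp(-2 x^2 / w^2) is
# w*sqrt(pi/2) * exp(-pi^2 w^2 k^2 / 2); the inverse beam filter
# exp(+pi^2 w^2 k^2 / 2) is its exact phase-free inverse up to that constant
# amplitude, which is folded into the final intensity calibration.

#' Deconvolution parameters
#'
#' @param epsilon Wiener regularization: the ideal inverse gain `1/H` is
#'   replaced by `H / (H^2 + epsilon * max(H)^2)`. Default 1e-3. A value
#'   `<= 0` requests the exact inverse, which is refused on data with energy
#'   at frequencies where the ideal gain exceeds `max_gain`.
#' @param max_gain hard cap on the ideal inverse gain (default 1e3).
#' @param clip_negative clip negative deconvolved values at zero
#'   (default `FALSE`; negatives are kept internally and only clipped at
#'   rendering / thresholding time).
#' @return a list of class `deconv_params`.
#' @export
deconv_params <- function(epsilon = 1e-3, max_gain = 1e3,
                          clip_negative = FALSE) {
  structure(list(epsilon = epsilon, max_gain = max_gain,
                 clip_negative = isTRUE(clip_negative)),
            class = "deconv_params")
}

#' Reconstruction parameters
#'
#' @inheritParams deconv_params
#' @param ridge Tikhonov ridge for the axial unmixing, relative to the largest
#'   squared singular value of `U(k_y)` (default 1e-6).
#' @param calibrate apply the intensity calibration
#'   `dx * dy / (w * sqrt(pi/2))` so reconstructed amplitudes are in
#'   scene-intensity units (default `TRUE`).
#' @return a list of class `recon_params`.
#' @export
recon_params <- function(epsilon = 1e-3, max_gain = 1e3, ridge = 1e-6,
                         clip_negative = FALSE, calibrate = TRUE) {
  structure(list(epsilon = epsilon, max_gain = max_gain, ridge = ridge,
                 clip_negative = isTRUE(clip_negative),
                 calibrate = isTRUE(calibrate)),
            class = "recon_params")
}

#' Demultiplex a PMT record into per-channel images
#'
#' Sample `k` of scan `n` on channel `i` maps to pixel (row `n`, column `k`)
#' with `x` the beam position at that sample time and `y = vy * n * T` (the
#' frozen-y convention). A trailing partial scan is discarded; flyback-blanked
#' samples (when `dead_time_frac > 0`) are dropped from the columns.
#'
#' @param record a `pmt_record`.
#' @param config an [fsc_config()]; defaults to the record's own snapshot and
#'   must agree with the record on channel count and sample rate.
#' @return an object of class `channel_stack`: `images`
#'   (`n_y x n_x x n_channels`), `pixel_size_x = scan_range /
#'   samples_per_scan`, `pixel_size_y = vy * T` (micrometres), and the
#'   `origin` (x, y) of pixel (1, 1).
#' @export
demultiplex <- function(record, config = NULL) {
  if (is.null(config)) config <- record$config
  if (nrow(record$signals) != config$n_channels) {
    stop_validation("record has ", nrow(record$signals),
                    " channels but config expects ", config$n_channels)
  }
  if (abs(record$sample_rate - config$sample_rate) >
      1e-9 * config$sample_rate) {
    stop_validation("record and config sample rates differ")
  }
  S <- samples_per_scan(config)
  n_total <- ncol(record$signals)
  n_y <- n_total %/% S
  if (n_y < 2) stop_validation("record holds fewer than 2 complete scans")
  active <- which((seq_len(S) - 1) < S * (1 - config$dead_time_frac))
  n_x <- length(active)
  images <- array(0, c(n_y, n_x, config$n_channels))
  for (i in seq_len(config$n_channels)) {
    m <- matrix(record$signals[i, seq_len(n_y * S)], nrow = S)  # S x n_y
    images[, , i] <- t(m[active, , drop = FALSE])
  }
  dx <- config$scan_range / S
  x0 <- config$scan_range * ((active[1] - 1) / S - 0.5)
  # within-scan flow displacement of each column's samples relative to the
  # frozen-y row coordinate vy*n*T; zero if the record itself froze y per scan
  col_y_offset <- if (isTRUE(record$frozen_y)) {
    rep(0, n_x)
  } else {
    config$flow_speed_vy * 1e6 * (active - 1) / config$sample_rate
  }
  structure(
    list(images = images,
         pixel_size_x = dx,
         pixel_size_y = config$flow_speed_vy * 1e6 * scan_period(config),
         origin = c(x = x0, y = record$y_origin %||% 0),
         col_y_offset = col_y_offset,
         config = config),
    class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<channel_stack: %d x %d pixels x %d channels (%.3g x %.3g um px)>\n",
              d[1], d[2], d[3], x$pixel_size_x, x$pixel_size_y))
  invisible(x)
}

# Beam transfer function along the scan axis on an n-point grid of pitch dx:
# the DFT of the pixel-sampled profile exp(-2 x^2 / w^2), normalized to unit
# DC gain. For a well-sampled beam this equals the analytic
# exp(-pi^2 w^2 k^2 / 2) (ordinary-frequency convention) to within aliasing
# that is negligible at the shipped defaults; for coarse sampling it stays the
# exact discrete transfer, and it tends to 1 as w -> 0.
beam_transfer_x <- function(n, dx, w) {
  if (w <= 0) return(rep(1, n))
  m <- 0:(n - 1)
  x <- ifelse(m < n / 2, m, m - n) * dx
  h <- exp(-2 * x^2 / w^2)
  Re(stats::fft(h)) / sum(h)
}

# Wiener (or guarded exact) inverse gain for the beam transfer H; spectra is
# an optional matrix of data spectra used to check the exact inverse is safe.
inverse_beam_gain <- function(H, params, spectra = NULL) {
  if (params$epsilon > 0) {
    # Wiener inverse, normalized to unit gain at DC (H = 1) so in-band
    # amplitudes are unbiased and the w -> 0 limit is the exact identity
    return((1 + params$epsilon) * H / (H^2 + params$epsilon))
  }
  unstable <- H < 1 / params$max_gain
  if (any(unstable) && !is.null(spectra)) {
    total <- sum(Mod(spectra)^2)
    bad <- sum(Mod(spectra[unstable, , drop = FALSE])^2)
    if (total > 0 && bad > 1e-20 * total) {
      stop_numerical(
        "exact inverse refused: data has energy at frequencies where the ",
        "ideal gain exceeds max_gain = ", params$max_gain,
        "; use epsilon > 0")
    }
  }
  pmin(1 / H, params$max_gain)
}

#' Deconvolve the Gaussian beam along the scan axis
#'
#' Per image row, multiplies the x spectrum by the regularized inverse of the
#' beam transfer function `H(k_x)` (the ideal gain `exp(+pi^2 w^2 k_x^2 / 2)`
#' in Wiener form) and returns the real part. `H` is computed as the
#' unit-DC-normalized DFT of the pixel-sampled beam profile, which equals the
#' analytic `exp(-pi^2 w^2 k_x^2 / 2)` for well-sampled beams and remains the
#' exact discrete transfer under coarse sampling.
#'
#' @param stack a `channel_stack`.
#' @param w beam waist, micrometres; defaults to the stack's configuration.
#' @param params a [deconv_params()].
#' @return a `channel_stack` with deconvolved images.
#' @export
deconvolve_x <- function(stack, w = NULL, params = deconv_params()) {
  if (is.null(w)) w <- stack$config$beam_waist_w
  w <- check_scalar(w, "w", nonnegative = TRUE)
  d <- dim(stack$images)
  n_x <- d[2]
  H <- beam_transfer_x(n_x, stack$pixel_size_x, w)
  out <- stack
  for (i in seq_len(d[3])) {
    img_i <- matrix(stack$images[, , i], d[1], d[2])
    spec <- stats::mvfft(t(img_i))                      # n_x x n_y, per row
    gain <- inverse_beam_gain(H, params, spectra = spec)
    spec <- spec * gain
    rec <- Re(stats::mvfft(spec, inverse = TRUE)) / n_x
    if (params$clip_negative) rec <- pmax(rec, 0)
    out$images[, , i] <- t(rec)
  }
  out
}

#' Flow-axis spectrum of the crosstalk-weighted beam kernel
#'
#' For each channel/plane pair (i, j), the discrete Fourier transform along y
#' of `M_ij(y) * exp(-2 y^2 / w^2)`, sampled on an `n_y`-point periodic grid
#' of total length `y_window` and scaled by the sample spacing so it
#' approximates the continuous (ordinary-frequency) transform. For diagonal
#' crosstalk `U_jj(k_y) = w * sqrt(pi/2) * exp(-pi^2 w^2 k_y^2 / 2)` up to
#' discretization.
#'
#' @param crosstalk a [crosstalk_model()].
#' @param w beam waist, micrometres.
#' @param y_window total window length, micrometres; must be at least `6 w`
#'   to capture the Gaussian support.
#' @param n_y number of samples in the window.
#' @param n_channels channel count.
#' @return an object of class `u_spectrum`: `values`
#'   (`n_channels x n_channels x n_y` complex), `ky_grid` (1/um, unshifted
#'   DFT order) and the sample `spacing`.
#' @export
build_u_spectrum <- function(crosstalk, w, y_window, n_y, n_channels) {
  w <- check_scalar(w, "w", positive = TRUE)
  check_scalar(y_window, "y_window", positive = TRUE)
  if (y_window < 6 * w) {
    stop_validation("y_window must be >= 6 w to capture the beam support")
  }
  n_y <- as.integer(n_y)
  dy <- y_window / n_y
  m <- 0:(n_y - 1)
  y <- ifelse(m < n_y / 2, m, m - n_y) * dy       # wrapped, kernel at index 0
  K <- crosstalk_kernel(crosstalk, y, w, n_channels)
  U <- array(0i, dim(K))
  for (i in seq_len(n_channels)) {
    for (j in seq_len(n_channels)) {
      U[i, j, ] <- stats::fft(K[i, j, ]) * dy
    }
  }
  # y-independent crosstalk factorizes as U(k_y) = M * g(k_y) with g the
  # transform of the beam profile alone; record the factors so the unmixing
  # can invert M exactly and regularize only the scalar deconvolution
  separable <- if (crosstalk$mode != "tabulated") {
    list(M = evaluate_crosstalk(crosstalk, 0, n_channels),
         g = stats::fft(exp(-2 * y^2 / w^2)) * dy)
  } else NULL
  structure(list(values = U, ky_grid = fft_freqs(n_y, dy), spacing = dy,
                 w = w, separable = separable),
            class = "u_spectrum")
}

#' Unmix axial crosstalk per flow-axis spatial frequency
#'
#' Takes the y-FFT of the beam-deconvolved channel images, solves the
#' `n_channels`-dimensional linear system at every `(x, k_y)` by
#' Tikhonov-regularized least squares
#' `(U^H U + ridge * sigma_max^2 I) f = U^H V`, and inverse-transforms along
#' `k_y`. With `ridge = 0` a `U(k_y)` that is singular to machine precision
#' is an error naming the offending frequency.
#'
#' @param stack_deconvolved a beam-deconvolved `channel_stack`.
#' @param U a [build_u_spectrum()] whose grid length is at least the stack's
#'   row count (rows are zero-padded to the grid length).
#' @param ridge relative Tikhonov ridge (>= 0).
#' @param y_offsets optional per-column flow-axis offsets (micrometres)
#'   compensated in the Fourier domain before unmixing: samples in column `k`
#'   of a continuously flowing record sit at `y = vy (n T + t_k)`, a known
#'   sub-row shear that is removed exactly (for band-limited content) by a
#'   per-frequency phase. Defaults to the stack's own `col_y_offset`.
#' @return an object of class `volume3d`: `intensities` (`n_y x n_x x n_z`),
#'   physical `voxel_size` and `origin`, planes ordered by ascending z.
#' @export
invert_axial <- function(stack_deconvolved, U, ridge = 1e-6,
                         y_offsets = NULL) {
  stopifnot(inherits(U, "u_spectrum"))
  check_scalar(ridge, "ridge", nonnegative = TRUE)
  img <- stack_deconvolved$images
  d <- dim(img)
  n_y <- d[1]; n_x <- d[2]; nch <- d[3]
  n_pad <- length(U$ky_grid)
  if (n_pad < n_y) {
    stop_validation("U grid (", n_pad, ") is shorter than the stack (", n_y,
                    " rows)")
  }
  if (abs(U$spacing - stack_deconvolved$pixel_size_y) >
      1e-9 * U$spacing) {
    stop_validation("U sample spacing does not match the stack's y pixel size")
  }
  if (is.null(y_offsets)) y_offsets <- stack_deconvolved$col_y_offset
  V <- array(0i, c(n_pad, n_x, nch))
  for (i in seq_len(nch)) {
    padded <- matrix(0, n_pad, n_x)
    padded[seq_len(n_y), ] <- img[, , i]
    V[, , i] <- stats::mvfft(padded)
  }
  if (!is.null(y_offsets) && any(y_offsets != 0)) {
    if (length(y_offsets) != n_x) {
      stop_validation("y_offsets must have one entry per image column")
    }
    shear <- exp(-2i * pi * outer(U$ky_grid, y_offsets))
    for (i in seq_len(nch)) V[, , i] <- V[, , i] * shear
  }
  Fhat <- array(0i, c(n_pad, n_x, nch))
  if (!is.null(U$separable)) {
    # U(k_y) = M * g(k_y): invert the channel mixing exactly (as the bare
    # U^-1 reconstruction formula does) and regularize only the scalar
    # flow-axis deconvolution in Wiener form. Exact unmixing avoids the
    # eigencomponent-dependent shrinkage of a full-matrix ridge, which would
    # leak a fraction of the coupling into ghost planes near the cutoff.
    M <- U$separable$M
    g <- U$separable$g
    gmax2 <- max(Mod(g))^2
    if (ridge == 0 && min(Mod(g)) < 1e3 * .Machine$double.eps * max(Mod(g))) {
      k_bad <- which.min(Mod(g))
      stop_numerical(sprintf(
        "U is singular to machine precision at k_y = %.6g 1/um (index %d); use ridge > 0",
        U$ky_grid[k_bad], k_bad))
    }
    if (rcond(M) < 1e3 * .Machine$double.eps) {
      stop_numerical("crosstalk matrix M is singular; cannot unmix channels")
    }
    Minv <- solve(M)
    greg <- Conj(g) / (Mod(g)^2 + ridge * gmax2)
    for (i in seq_len(nch)) {
      for (j in seq_len(nch)) {
        if (Minv[i, j] != 0) {
          Fhat[, , i] <- Fhat[, , i] + Minv[i, j] * V[, , j]
        }
      }
    }
    for (i in seq_len(nch)) Fhat[, , i] <- Fhat[, , i] * greg
  } else {
    # general (possibly y-dependent) U: Tikhonov-regularized least squares
    # per k_y, ridge relative to the global largest singular value of U (not
    # per-frequency: the Gaussian envelope vanishes at high k_y, where a
    # per-frequency relative ridge would amplify model mismatch)
    sv_all <- vapply(seq_len(n_pad), function(k) {
      svd(matrix(U$values[, , k], nch, nch), nu = 0, nv = 0)$d
    }, numeric(nch))
    smax_global <- max(sv_all)
    eye <- diag(nch)
    for (k in seq_len(n_pad)) {
      A <- matrix(U$values[, , k], nch, nch)
      sv <- if (nch > 1) sv_all[, k] else sv_all[k]
      if (ridge == 0 &&
          (max(sv) == 0 || min(sv) < 1e3 * .Machine$double.eps * max(sv))) {
        stop_numerical(sprintf(
          "U is singular to machine precision at k_y = %.6g 1/um (index %d); use ridge > 0",
          U$ky_grid[k], k))
      }
      Ah <- Conj(t(A))
      lhs <- Ah %*% A + (ridge * smax_global^2) * eye
      rhs <- Ah %*% t(matrix(V[k, , ], n_x, nch))
      Fhat[k, , ] <- t(solve(lhs, rhs))
    }
  }
  vol <- array(0, c(n_y, n_x, nch))
  for (j in seq_len(nch)) {
    f <- Re(stats::mvfft(matrix(Fhat[, , j], n_pad, n_x),
                         inverse = TRUE)) / n_pad
    vol[, , j] <- f[seq_len(n_y), ]
  }
  cfg <- stack_deconvolved$config
  volume3d(vol,
           voxel_size = c(x = stack_deconvolved$pixel_size_x,
                          y = stack_deconvolved$pixel_size_y,
                          z = cfg$plane_spacing),
           origin = c(x = stack_deconvolved$origin[["x"]],
                      y = stack_deconvolved$origin[["y"]],
                      z = z_planes(cfg)[1]),
           provenance = list(ridge = ridge))
}

#' 3D reconstructed volume container
#'
#' @param intensities numeric array `n_y x n_x x n_z` (row = flow axis y,
#'   column = scan axis x, slice = ascending plane z).
#' @param voxel_size named numeric vector `c(x=, y=, z=)`, micrometres.
#' @param origin named numeric vector `c(x=, y=, z=)`: physical position of
#'   voxel (1, 1, 1), micrometres.
#' @param provenance named list echoing configuration and parameters.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(intensities, voxel_size, origin,
                     provenance = list()) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_validation("intensities must be a 3-d array")
  }
  if (any(!is.finite(intensities))) {
    stop_validation("volume intensities must be finite")
  }
  voxel_size <- voxel_size[c("x", "y", "z")]
  origin <- origin[c("x", "y", "z")]
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop_validation("voxel sizes must be positive")
  }
  structure(list(intensities = intensities, voxel_size = voxel_size,
                 origin = origin, provenance = provenance),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume3d: %d x %d x %d (y,x,z), voxels %.3g x %.3g x %.3g um>\n",
              d[1], d[2], d[3], x$voxel_size[["y"]], x$voxel_size[["x"]],
              x$voxel_size[["z"]]))
  invisible(x)
}

# physical coordinates of voxel centers along one axis
volume_axis <- function(vol, axis) {
  d <- dim(vol$intensities)
  n <- switch(axis, x = d[2], y = d[1], z = d[3])
  vol$origin[[axis]] + (seq_len(n) - 1) * vol$voxel_size[[axis]]
}

#' Full reconstruction pipeline
#'
#' Composition demultiplex -> beam deconvolution along x -> flow-axis FFT ->
#' per-frequency axial unmixing -> inverse FFT; deterministic given its
#' inputs. Rows are zero-padded to the next power of two past the kernel
#' support before the y-FFT to control circular-convolution wraparound. When
#' `params$calibrate` is `TRUE` the volume is scaled by
#' `dx * dy / (w * sqrt(pi/2))` so that an isolated unit-intensity scatterer
#' integrates to approximately one.
#'
#' @param record a `pmt_record`.
#' @param config an [fsc_config()]; defaults to the record's snapshot.
#' @param crosstalk a [crosstalk_model()]; defaults to the record's snapshot.
#' @param params a [recon_params()].
#' @return a `volume3d` with provenance embedded.
#' @examples
#' sc <- grid_phantom(k_per_plane = 2, n_planes = 4, seed = 2)
#' cfg <- fsc_config(n_channels = 4)
#' xt <- crosstalk_model("nearest_neighbor", epsilon = 0.2)
#' rec <- simulate_signals(sc, cfg, xt)
#' vol <- reconstruct_volume(rec)
#' dim(vol$intensities)
#' @export
reconstruct_volume <- function(record, config = NULL, crosstalk = NULL,
                               params = recon_params()) {
  if (is.null(config)) config <- record$config
  if (is.null(crosstalk)) crosstalk <- record$crosstalk
  stack <- demultiplex(record, config)
  w <- config$beam_waist_w
  dec <- deconvolve_x(stack, w,
                      deconv_params(params$epsilon, params$max_gain,
                                    clip_negative = FALSE))
  n_y <- dim(dec$images)[1]
  dy <- dec$pixel_size_y
  kernel_rows <- ceiling(6 * w / dy)
  n_pad <- next_pow2(n_y + kernel_rows)
  U <- build_u_spectrum(crosstalk, w, y_window = n_pad * dy, n_y = n_pad,
                        n_channels = config$n_channels)
  vol <- invert_axial(dec, U, ridge = params$ridge)
  if (params$calibrate) {
    # x-deconvolved rows carry the sampled beam's DC gain; the y division by
    # the continuous-scaled kernel transform carries 1/dy
    n_x <- dim(dec$images)[2]
    m <- 0:(n_x - 1)
    xw <- ifelse(m < n_x / 2, m, m - n_x) * dec$pixel_size_x
    scale <- dy / sum(exp(-2 * xw^2 / w^2))
    vol$intensities <- vol$intensities * scale
  }
  if (params$clip_negative) vol$intensities <- pmax(vol$intensities, 0)
  vol$provenance <- c(vol$provenance,
                      list(config = config_as_list(config),
                           crosstalk_mode = crosstalk$mode,
                           epsilon = params$epsilon, ridge = params$ridge,
                           calibrated = params$calibrate, n_pad = n_pad))
  vol
}

# linear interpolation of an array along one axis onto n_new equispaced
# samples spanning the same physical extent (voxel-center convention)
axis_interp <- function(arr, axis, n_new) {
  d <- dim(arr)
  n_old <- d[axis]
  if (n_new == n_old) return(arr)
  # new voxel centers expressed in old index coordinates
  pos <- ((seq_len(n_new) - 0.5) / n_new) * n_old + 0.5
  lo <- pmin(pmax(floor(pos), 1), n_old)
  hi <- pmin(lo + 1, n_old)
  fr <- pmin(pmax(pos - lo, 0), 1)
  take <- function(idx) {
    switch(axis,
           `1` = arr[idx, , , drop = FALSE],
           `2` = arr[, idx, , drop = FALSE],
           `3` = arr[, , idx, drop = FALSE])
  }
  a_lo <- take(lo)
  a_hi <- take(hi)
  fshape <- switch(axis,
                   `1` = array(fr, c(n_new, d[2], d[3])),
                   `2` = aperm(array(fr, c(n_new, d[1], d[3])), c(2, 1, 3)),
                   `3` = aperm(array(fr, c(n_new, d[1], d[2])), c(2, 3, 1)))
  a_lo * (1 - fshape) + a_hi * fshape
}

#' Resample a volume onto a target grid
#'
#' Trilinear (separable linear) interpolation onto `target_shape` voxels per
#' axis; voxel sizes are rescaled so the physical extent is preserved. The
#' standard rendering size for these volumes is 200 x 200 x 100
#' (x, y, z).
#'
#' @param vol a `volume3d`.
#' @param target_shape integer vector `c(nx, ny, nz)`, each >= 2.
#' @return a resampled `volume3d`.
#' @export
resample_volume <- function(vol, target_shape) {
  if (length(target_shape) != 3 || any(target_shape < 2) ||
      any(target_shape != round(target_shape))) {
    stop_validation("target_shape must be three integers >= 2 (nx, ny, nz)")
  }
  tn <- as.integer(target_shape)        # (nx, ny, nz)
  arr <- vol$intensities                # (y, x, z)
  arr <- axis_interp(arr, 1L, tn[2])
  arr <- axis_interp(arr, 2L, tn[1])
  arr <- axis_interp(arr, 3L, tn[3])
  d_old <- dim(vol$intensities)
  vs_old <- vol$voxel_size
  vs_new <- c(x = vs_old[["x"]] * d_old[2] / tn[1],
              y = vs_old[["y"]] * d_old[1] / tn[2],
              z = vs_old[["z"]] * d_old[3] / tn[3])
  org_new <- c(
    x = vol$origin[["x"]] - vs_old[["x"]] / 2 + vs_new[["x"]] / 2,
    y = vol$origin[["y"]] - vs_old[["y"]] / 2 + vs_new[["y"]] / 2,
    z = vol$origin[["z"]] - vs_old[["z"]] / 2 + vs_new[["z"]] / 2)
  volume3d(arr, vs_new, org_new,
           provenance = c(vol$provenance, list(resampled_from = d_old)))
}

#' Correct images acquired at an off-nominal flow speed
#'
#' A record demultiplexed assuming `vy_nominal` while the object actually
#' flowed at `vy_actual` has its y axis compressed or stretched by
#' `vy_actual / vy_nominal`. This rescales the y axis (data resampled onto the
#' nominal pixel grid) so the object recovers its true aspect ratio. Plain
#' linear rescaling along y; an approximation to a full resampling treatment
#' of speed variation.
#'
#' @param stack a `channel_stack`.
#' @param vy_actual true flow speed, m/s.
#' @param vy_nominal flow speed assumed at demultiplexing, m/s.
#' @return a `channel_stack` on the nominal y grid.
#' @export
compensate_flow_speed <- function(stack, vy_actual, vy_nominal) {
  vy_actual <- check_scalar(vy_actual, "vy_actual", positive = TRUE)
  vy_nominal <- check_scalar(vy_nominal, "vy_nominal", positive = TRUE)
  ratio <- vy_actual / vy_nominal
  if (ratio == 1) return(stack)
  d <- dim(stack$images)
  n_y <- d[1]
  dy <- stack$pixel_size_y
  y_true <- (seq_len(n_y) - 1) * dy * ratio     # true physical row positions
  n_new <- max(2L, as.integer(floor(y_true[n_y] / dy)) + 1L)
  y_new <- (seq_len(n_new) - 1) * dy
  out <- stack
  out$images <- array(0, c(n_new, d[2], d[3]))
  for (i in seq_len(d[3])) {
    for (cx in seq_len(d[2])) {
      out$images[, cx, i] <- stats::approx(y_true, stack$images[, cx, i],
                                           xout = y_new, rule = 2)$y
    }
  }
  out
}

#' Threshold a volume at a fraction of its maximum
#'
#' Negative intensities are clipped at zero before thresholding (they are kept
#' internally through the pipeline and only removed at rendering time). The
#' standard display convention is a low threshold to show the overall volume
#' and a high threshold to reveal internal scattering features.
#'
#' @param vol a `volume3d`.
#' @param level fraction of the maximum in `[0, 1]`.
#' @return a list with `mask` (logical array), `masked` (a `volume3d` of the
#'   clipped intensities with sub-threshold voxels zeroed) and `level`.
#' @export
threshold_volume <- function(vol, level) {
  level <- check_scalar(level, "level")
  if (level < 0 || level > 1) stop_validation("level must lie in [0, 1]")
  v <- pmax(vol$intensities, 0)
  mx <- max(v)
  mask <- if (mx > 0) v >= level * mx else array(FALSE, dim(v))
  masked <- vol
  masked$intensities <- v * mask
  list(mask = mask, masked = masked, level = level)
}
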