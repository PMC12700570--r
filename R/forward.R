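# Forward model: a scatter scene flowing along y at vy through the scanned
# Gaussian needle beam produces one time series per PMT channel,
#
#   P_i(t) = sum_j sum_c M_ij(dy) exp(-2 dy^2 / w^2) * I_c *
#            exp(-2 (x_c - x_n(t))^2 / w^2) * a_j(z_c),
#
# where dy is the offset between the center's instantaneous flow position and
# the beam line, x_n(t) the sawtooth beam position, and a_j the axial
# assignment of the scatterer to plane j (nearest plane, or a Gaussian axial
# response of width axial_psf_sigma). The model is linear and incoherent.

# Flow geometry shared by simulate_signals and build_dense_operator: the lead
# distance is rounded up to a whole number of scan periods' worth of flow so
# that grid-aligned scenes land exactly on demultiplexed rows.
flow_geometry <- function(scene_y, config) {
  w <- config$beam_waist_w
  dy <- config$flow_speed_vy * 1e6 * scan_period(config)  # um per scan
  y_lead <- ceiling(2 * w / dy) * dy
  y_min <- if (length(scene_y)) min(scene_y) else 0
  y_max <- if (length(scene_y)) max(scene_y) else 0
  list(dy = dy, y_lead = y_lead, y_min = y_min, y_extent = y_max - y_min)
}

#' Simulate multi-channel PMT time series from a scatter scene
#'
#' Evaluates the forward model at every digitizer sample time. The default
#' duration covers the full transit of the scene through the beam plus a lead
#' and tail of about two beam waists on either side.
#'
#' @param scene a [scatter_scene()].
#' @param config an [fsc_config()].
#' @param crosstalk a [crosstalk_model()].
#' @param duration recording length in seconds; default auto-computed from the
#'   scene's flow-axis extent. A duration shorter than
#'   `(y_extent + 4 w) / vy` is refused.
#' @param noise optional list with elements `poisson_scale`, `gaussian_sigma`
#'   and `seed`, applied via [add_noise()] after the noiseless evaluation.
#' @param frozen_y if `TRUE`, each object's flow position is frozen at the
#'   start of every scan (the approximation the reconstruction relies on);
#'   default `FALSE` simulates exact continuous motion.
#' @param y_origin override the scene y coordinate that crosses the beam at
#'   t = 0 (micrometres); used to give several simulations a common timebase.
#' @return an object of class `pmt_record` with fields `signals`
#'   (`n_channels x n_samples`), `sample_rate`, `t0`, the configuration and
#'   crosstalk echo, `y_origin` and `noise_spec`.
#' @examples
#' sc <- grid_phantom(k_per_plane = 1, n_planes = 2, seed = 3)
#' rec <- simulate_signals(sc, fsc_config(), crosstalk_model("diagonal"))
#' dim(rec$signals)
#' @export
simulate_signals <- function(scene, config, crosstalk,
                             duration = NULL, noise = NULL,
                             frozen_y = FALSE, y_origin = NULL) {
  stopifnot(inherits(scene, "scatter_scene"), inherits(config, "fsc_config"),
            inherits(crosstalk, "crosstalk_model"))
  cen <- scene$centers
  if (nrow(cen) > 0 && any(!is.finite(as.matrix(cen)))) {
    stop_validation("scene contains non-finite values")
  }
  w <- config$beam_waist_w
  vy_um <- config$flow_speed_vy * 1e6
  Tp <- scan_period(config)
  geom <- flow_geometry(cen$y_um, config)
  if (is.null(y_origin)) y_origin <- geom$y_min - geom$y_lead
  if (is.null(duration)) {
    span <- (geom$y_min - y_origin) + geom$y_extent + geom$y_lead
    n_scans <- max(2L, as.integer(ceiling(span / geom$dy)))
    duration <- n_scans * Tp
  } else {
    duration <- check_scalar(duration, "duration", positive = TRUE)
    if (nrow(cen) > 0 && duration < (geom$y_extent + 4 * w) / vy_um) {
      stop_validation(sprintf(
        "duration %.3g s is too short for the scene to transit the beam (need >= %.3g s)",
        duration, (geom$y_extent + 4 * w) / vy_um))
    }
  }
  n_samples <- as.integer(floor(duration * config$sample_rate))
  if (n_samples < 2 * samples_per_scan(config)) {
    stop_validation("duration yields fewer than two complete scans")
  }
  t <- (seq_len(n_samples) - 1) / config$sample_rate
  t_flow <- if (frozen_y) floor(t / Tp) * Tp else t
  xbeam <- beam_position(t, config)
  zp <- z_planes(config)
  nch <- config$n_channels

  signals <- matrix(0, nch, n_samples)
  if (nrow(cen) > 0) {
    m_const <- if (crosstalk$mode != "tabulated") {
      evaluate_crosstalk(crosstalk, 0, nch)
    } else NULL
    for (c_idx in seq_len(nrow(cen))) {
      ic <- cen$intensity[c_idx]
      if (ic == 0) next
      dyc <- (y_origin + vy_um * t_flow) - cen$y_um[c_idx]
      gy <- exp(-2 * dyc^2 / w^2)
      gx <- exp(-2 * (cen$x_um[c_idx] - xbeam)^2 / w^2)
      aw <- axial_weights(cen$z_um[c_idx], zp, config$axial_psf_sigma)
      base <- ic * gy * gx
      if (is.null(m_const)) {
        for (j in which(aw > 0)) {
          for (i in seq_len(nch)) {
            mij <- stats::approx(crosstalk$y_grid, crosstalk$table[i, j, ],
                                 xout = dyc, rule = 1)$y
            mij[is.na(mij)] <- 0
            signals[i, ] <- signals[i, ] + aw[j] * mij * base
          }
        }
      } else {
        mcol <- as.numeric(m_const %*% aw)    # channel gains for this center
        signals <- signals + tcrossprod(mcol, base)
      }
    }
  }
  if (config$dead_time_frac > 0) {
    S <- samples_per_scan(config)
    k <- (seq_len(n_samples) - 1) %% S
    signals[, k >= S * (1 - config$dead_time_frac)] <- 0
  }
  rec <- structure(
    list(signals = signals, sample_rate = config$sample_rate, t0 = 0,
         config = config, crosstalk = crosstalk, y_origin = y_origin,
         frozen_y = frozen_y, noise_spec = NULL),
    class = "pmt_record")
  if (!is.null(noise)) {
    rec <- add_noise(rec,
                     poisson_scale = noise$poisson_scale %||% 0,
                     gaussian_sigma = noise$gaussian_sigma %||% 0,
                     seed = noise$seed %||% 1L)
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

axial_weights <- function(z, zp, sigma) {
  if (is.null(sigma)) {
    aw <- numeric(length(zp))
    aw[which.min(abs(z - zp))] <- 1
    aw
  } else {
    exp(-(z - zp)^2 / (2 * sigma^2))
  }
}

#' @export
print.pmt_record <- function(x, ...) {
  cat(sprintf("<pmt_record: %d channels x %d samples @ %.4g MHz%s%s>\n",
              nrow(x$signals), ncol(x$signals), x$sample_rate / 1e6,
              if (isTRUE(x$frozen_y)) ", frozen-y" else "",
              if (!is.null(x$noise_spec)) ", noisy" else ""))
  invisible(x)
}

#' Apply detection noise to a PMT record
#'
#' Optional Poisson shot noise (the signal is interpreted as a mean photon
#' count of `poisson_scale * value`, resampled and rescaled) followed by
#' additive Gaussian read noise. The input record is not modified.
#'
#' @param record a `pmt_record`.
#' @param poisson_scale counts per signal unit (0 disables shot noise).
#' @param gaussian_sigma additive noise standard deviation in signal units
#'   (0 disables).
#' @param seed integer RNG seed.
#' @return a new `pmt_record` with `noise_spec` recorded.
#' @export
add_noise <- function(record, poisson_scale = 0, gaussian_sigma = 0,
                      seed = 1L) {
  check_scalar(poisson_scale, "poisson_scale", nonnegative = TRUE)
  check_scalar(gaussian_sigma, "gaussian_sigma", nonnegative = TRUE)
  out <- record
  if (poisson_scale > 0 || gaussian_sigma > 0) {
    s <- record$signals
    out$signals <- with_seed(seed, {
      if (poisson_scale > 0) {
        s <- matrix(stats::rpois(length(s), lambda = s * poisson_scale),
                    nrow(s), ncol(s)) / poisson_scale
      }
      if (gaussian_sigma > 0) {
        s <- s + matrix(stats::rnorm(length(s), sd = gaussian_sigma),
                        nrow(s), ncol(s))
      }
      s
    })
  }
  out$noise_spec <- list(poisson_scale = poisson_scale,
                         gaussian_sigma = gaussian_sigma, seed = seed)
  out
}

#' Materialize the forward model as a dense matrix
#'
#' Brute-force reference operator: column `v` is the flattened (channel-major)
#' signal of a unit scatterer in voxel `v` of `scene_grid`, so applying the
#' matrix to a voxelized scene reproduces [simulate_signals()] by linearity.
#' Intended as an independent oracle on small grids; the entry count is capped.
#'
#' @param scene_grid list with numeric vectors `x`, `y`, `z`: voxel center
#'   coordinates in micrometres. Voxels are ordered x-fastest, then y, then z
#'   (matching `expand.grid(x, y, z)`).
#' @param config an [fsc_config()].
#' @param crosstalk a [crosstalk_model()].
#' @param duration recording length (seconds); default auto-computed from the
#'   grid's y extent.
#' @param frozen_y passed to [simulate_signals()] (default `TRUE`: the dense
#'   operator is normally used to cross-check the reconstruction, which
#'   assumes frozen flow positions within a scan).
#' @param max_entries guard on `n_rows * n_voxels` (default 5e7).
#' @return a list with the matrix `A` (`(n_channels * n_samples) x n_voxels`),
#'   the voxel coordinate table `voxels`, `y_origin`, `duration` and
#'   `n_samples`.
#' @export
build_dense_operator <- function(scene_grid, config, crosstalk,
                                 duration = NULL, frozen_y = TRUE,
                                 max_entries = 5e7) {
  stopifnot(is.list(scene_grid),
            all(c("x", "y", "z") %in% names(scene_grid)))
  vox <- expand.grid(x_um = scene_grid$x, y_um = scene_grid$y,
                     z_um = scene_grid$z, KEEP.OUT.ATTRS = FALSE)
  geom <- flow_geometry(scene_grid$y, config)
  y_origin <- geom$y_min - geom$y_lead
  if (is.null(duration)) {
    n_scans <- max(2L, as.integer(ceiling((geom$y_extent + 2 * geom$y_lead) /
                                            geom$dy)))
    duration <- n_scans * scan_period(config)
  }
  n_samples <- as.integer(floor(duration * config$sample_rate))
  n_rows <- config$n_channels * n_samples
  if (as.numeric(n_rows) * nrow(vox) > max_entries) {
    stop_numerical("dense operator would hold ",
                   format(as.numeric(n_rows) * nrow(vox), big.mark = ","),
                   " entries; the guard is ", format(max_entries))
  }
  A <- matrix(0, n_rows, nrow(vox))
  for (v in seq_len(nrow(vox))) {
    sc <- scatter_scene(data.frame(x_um = vox$x_um[v], y_um = vox$y_um[v],
                                   z_um = vox$z_um[v], intensity = 1))
    rec <- simulate_signals(sc, config, crosstalk, duration = duration,
                            frozen_y = frozen_y, y_origin = y_origin)
    A[, v] <- as.vector(rec$signals)
  }
  list(A = A, voxels = vox, y_origin = y_origin, duration = duration,
       n_samples = n_samples, frozen_y = frozen_y)
}

#' Voxelized scene on a regular grid
#'
#' Convenience constructor pairing [build_dense_operator()]: turns a 3-d value
#' array on the grid into a [scatter_scene()] of point scatterers at the voxel
#' centers (zero-valued voxels are kept so the scene vector and the operator
#' columns stay aligned).
#'
#' @param scene_grid list with vectors `x`, `y`, `z` of voxel centers (um).
#' @param values array of nonnegative intensities, dim
#'   `c(length(x), length(y), length(z))`.
#' @return a list with the `scatter_scene` and the flattened `vector`
#'   (x-fastest ordering, matching the dense operator's columns).
#' @export
voxel_scene <- function(scene_grid, values) {
  dims <- c(length(scene_grid$x), length(scene_grid$y), length(scene_grid$z))
  if (!all(dim(values) == dims)) {
    stop_validation("values must have dim c(length(x), length(y), length(z))")
  }
  if (any(values < 0)) stop_validation("voxel intensities must be >= 0")
  vox <- expand.grid(x_um = scene_grid$x, y_um = scene_grid$y,
                     z_um = scene_grid$z, KEEP.OUT.ATTRS = FALSE)
  vec <- as.vector(values)
  centers <- data.frame(x_um = vox$x_um, y_um = vox$y_um, z_um = vox$z_um,
                        intensity = vec)
  list(scene = scatter_scene(centers), vector = vec)
}
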