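# Synthetic ground-truth scatter scenes. Scatterers are ideal incoherent
# points: the forward model integrates an intensity field, and point sets are
# its natural quadrature at this scale. Every generator is deterministic for a
# fixed seed.

#' Construct a scatter scene
#'
#' A scene is a set of point scatterers `(x, y, z, intensity)` in object-frame
#' micrometres (y measured along the flow axis) together with its bounding
#' extent and generator metadata.
#'
#' @param centers data.frame with columns `x_um`, `y_um`, `z_um`, `intensity`.
#' @param extent optional 3 x 2 matrix (rows x/y/z, columns min/max); computed
#'   from the centers when omitted.
#' @param metadata named list of generator provenance.
#' @return an object of class `scatter_scene`.
#' @export
scatter_scene <- function(centers, extent = NULL, metadata = list()) {
  req <- c("x_um", "y_um", "z_um", "intensity")
  if (!is.data.frame(centers) || !all(req %in% names(centers))) {
    stop_validation("centers must be a data.frame with columns ",
                    paste(req, collapse = ", "))
  }
  centers <- centers[, req, drop = FALSE]
  if (nrow(centers) > 0) {
    vals <- as.matrix(centers)
    if (any(!is.finite(vals))) {
      stop_validation("scene contains non-finite coordinates or intensities")
    }
    if (any(centers$intensity < 0)) {
      stop_validation("scatter intensities must be >= 0")
    }
  }
  if (is.null(extent)) {
    extent <- if (nrow(centers) > 0) {
      rbind(x = range(centers$x_um), y = range(centers$y_um),
            z = range(centers$z_um))
    } else {
      matrix(0, 3, 2, dimnames = list(c("x", "y", "z"), NULL))
    }
  }
  extent <- matrix(as.numeric(extent), 3, 2,
                   dimnames = list(c("x", "y", "z"), c("min", "max")))
  if (nrow(centers) > 0) {
    pos <- as.matrix(centers[, c("x_um", "y_um", "z_um")])
    tol <- 1e-9
    inside <- pos[, 1] >= extent[1, 1] - tol & pos[, 1] <= extent[1, 2] + tol &
      pos[, 2] >= extent[2, 1] - tol & pos[, 2] <= extent[2, 2] + tol &
      pos[, 3] >= extent[3, 1] - tol & pos[, 3] <= extent[3, 2] + tol
    if (!all(inside)) stop_validation("all centers must lie inside the extent")
  }
  structure(list(centers = centers, extent = extent, metadata = metadata),
            class = "scatter_scene")
}

#' @export
print.scatter_scene <- function(x, ...) {
  cat(sprintf("<scatter_scene: %d centers", nrow(x$centers)))
  if (!is.null(x$metadata$generator)) cat(", generator=", x$metadata$generator,
                                          sep = "")
  cat(">\n")
  if (nrow(x$centers) > 0) {
    e <- x$extent
    cat(sprintf("  extent x [%g, %g], y [%g, %g], z [%g, %g] um\n",
                e[1, 1], e[1, 2], e[2, 1], e[2, 2], e[3, 1], e[3, 2]))
  }
  invisible(x)
}

# rejection-sample k points in a square with a pairwise minimum separation
sample_separated_xy <- function(k, half_extent, min_sep, max_attempts = 5000L) {
  pts <- matrix(numeric(0), 0, 2)
  attempts <- 0L
  while (nrow(pts) < k) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop_validation("could not place ", k, " centers with separation >= ",
                      min_sep, " um inside a ", 2 * half_extent,
                      " um square after ", max_attempts, " attempts")
    }
    cand <- stats::runif(2, -half_extent, half_extent)
    if (nrow(pts) == 0 ||
        all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2,
                                       byrow = TRUE))^2)) >= min_sep)) {
      pts <- rbind(pts, cand)
    }
  }
  pts
}

#' Grid-of-planes point phantom
#'
#' Places `k_per_plane` point scatterers on each of `n_planes` focal planes
#' (planes centered about z = 0 at `plane_spacing`), with all pairwise in-plane
#' distances at least `min_separation`. This reproduces the standard
#' multi-plane validation objects: two equal scatterers per plane on eight
#' planes, or five scatterers of graded intensities per plane.
#'
#' @param k_per_plane scatterers per plane (>= 1).
#' @param n_planes number of planes.
#' @param plane_spacing axial plane spacing, micrometres.
#' @param xy_extent side length of the square in-plane placement region,
#'   micrometres (centered on the origin).
#' @param min_separation minimum in-plane pairwise distance, micrometres.
#' @param intensities `"equal"` (all ones) or a numeric vector of length
#'   `k_per_plane`, reused on every plane.
#' @param seed integer RNG seed.
#' @return a [scatter_scene()].
#' @examples
#' sc <- grid_phantom(k_per_plane = 2, n_planes = 8, seed = 1)
#' table(sc$centers$z_um)
#' @export
grid_phantom <- function(k_per_plane, n_planes = 8L, plane_spacing = 2.5,
                         xy_extent = 30, min_separation = 6,
                         intensities = "equal", seed = 1L) {
  if (!is.numeric(k_per_plane) || k_per_plane < 1 ||
      k_per_plane != round(k_per_plane)) {
    stop_validation("k_per_plane must be a positive integer")
  }
  k <- as.integer(k_per_plane)
  n_planes <- as.integer(n_planes)
  if (n_planes < 1) stop_validation("n_planes must be >= 1")
  check_scalar(xy_extent, "xy_extent", positive = TRUE)
  check_scalar(min_separation, "min_separation", nonnegative = TRUE)
  if (identical(intensities, "equal")) {
    ints <- rep(1, k)
  } else {
    ints <- as.numeric(intensities)
    if (length(ints) != k || any(ints < 0)) {
      stop_validation("intensities must be 'equal' or a nonnegative vector ",
                      "of length k_per_plane")
    }
  }
  zs <- plane_spacing * ((seq_len(n_planes) - 1) - (n_planes - 1) / 2)
  centers <- with_seed(seed, {
    do.call(rbind, lapply(zs, function(z) {
      xy <- sample_separated_xy(k, xy_extent / 2, min_separation)
      data.frame(x_um = xy[, 1], y_um = xy[, 2], z_um = z, intensity = ints)
    }))
  })
  half <- xy_extent / 2
  extent <- rbind(x = c(-half, half), y = c(-half, half), z = range(zs))
  scatter_scene(centers, extent,
                metadata = list(generator = "grid_phantom", seed = seed,
                                k_per_plane = k, n_planes = n_planes,
                                plane_spacing = plane_spacing,
                                xy_extent = xy_extent,
                                min_separation = min_separation,
                                intensities = ints))
}

#' Terraced microstructure phantom
#'
#' Emulates a 3D-printed staircase test target: `n_terraces` rectangular
#' terraces of area `terrace_area` stacked along the flow axis, each one
#' `step_height` higher than the last, with small rectangular bumps on every
#' terrace. Scatter arises at terrace edges and at the bumps; each bump is
#' represented by one point scatterer at its center. Terrace z levels are
#' offset so that the staircase is centered about z = 0, matching the
#' centered-plane convention; the terrace-to-z mapping is returned in the
#' scene metadata.
#'
#' @param terrace_area length-2 vector, terrace x and y size in micrometres
#'   (default `c(35, 8)`).
#' @param step_height z increment between consecutive terraces, micrometres
#'   (default 2.5).
#' @param n_terraces number of terraces (default 8).
#' @param bump_size length-3 vector, bump x/y/z dimensions in micrometres
#'   (default `c(1.5, 1, 1)`), recorded as metadata.
#' @param bumps_per_terrace bumps per terrace (default 2), evenly spaced
#'   along x at the terrace mid-line.
#' @param edge_spacing spacing of the edge scatterers along terrace
#'   boundaries, micrometres (default 2).
#' @param edge_intensity intensity of edge scatterers relative to the unit
#'   bump intensity (default 0.5).
#' @return a [scatter_scene()].
#' @export
terrace_phantom <- function(terrace_area = c(35, 8), step_height = 2.5,
                            n_terraces = 8L, bump_size = c(1.5, 1, 1),
                            bumps_per_terrace = 2L, edge_spacing = 2,
                            edge_intensity = 0.5) {
  if (length(terrace_area) != 2 || any(terrace_area <= 0)) {
    stop_validation("terrace_area must be two positive lengths (x, y)")
  }
  check_scalar(step_height, "step_height", positive = TRUE)
  if (length(bump_size) != 3 || any(bump_size <= 0)) {
    stop_validation("bump_size must be three positive lengths")
  }
  n_terraces <- as.integer(n_terraces)
  if (n_terraces < 1) stop_validation("n_terraces must be >= 1")
  bumps_per_terrace <- as.integer(bumps_per_terrace)
  if (bumps_per_terrace < 0) stop_validation("bumps_per_terrace must be >= 0")

  lx <- terrace_area[1]
  ly <- terrace_area[2]
  z0 <- step_height * (n_terraces - 1) / 2   # center staircase on z = 0
  zs <- step_height * (seq_len(n_terraces) - 1) - z0

  rows <- list()
  for (m in seq_len(n_terraces)) {
    z <- zs[m]
    ylo <- (m - 1) * ly - n_terraces * ly / 2
    yhi <- ylo + ly
    # bump centers: evenly spaced along x at terrace mid-y
    if (bumps_per_terrace > 0) {
      bx <- seq(-lx / 2, lx / 2,
                length.out = bumps_per_terrace + 2)[-c(1, bumps_per_terrace + 2)]
      rows[[length(rows) + 1]] <-
        data.frame(x_um = bx, y_um = (ylo + yhi) / 2, z_um = z, intensity = 1)
    }
    # edge scatterers along the leading and trailing terrace edges
    ex <- seq(-lx / 2, lx / 2, by = edge_spacing)
    rows[[length(rows) + 1]] <-
      data.frame(x_um = rep(ex, 2), y_um = rep(c(ylo, yhi), each = length(ex)),
                 z_um = z, intensity = edge_intensity)
  }
  centers <- do.call(rbind, rows)
  extent <- rbind(x = c(-lx / 2, lx / 2),
                  y = range(centers$y_um), z = range(zs))
  scatter_scene(centers, extent,
                metadata = list(generator = "terrace_phantom",
                                terrace_area = terrace_area,
                                step_height = step_height,
                                n_terraces = n_terraces,
                                bump_size = bump_size,
                                bumps_per_terrace = bumps_per_terrace,
                                terrace_z_um = zs))
}

# uniform points on a sphere surface via normalized Gaussians
runif_sphere_surface <- function(n, radius) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2)) * radius
}

# uniform points inside a sphere
runif_sphere_interior <- function(n, radius) {
  v <- runif_sphere_surface(n, 1)
  v * stats::runif(n)^(1 / 3) * radius
}

#' Porous bead phantom (hollow shell plus interior pores)
#'
#' Emulates a spherical porous hydrogel bead: `n_surface_points` scatterers
#' uniformly distributed on the sphere surface plus a Poisson number of
#' interior "pore" scatterers at density `interior_density`.
#'
#' @param diameter bead diameter, micrometres (default 25).
#' @param n_surface_points surface scatterer count (default 300).
#' @param interior_density interior pore density per cubic micrometre
#'   (default 0.005; 0 gives a hollow shell).
#' @param surface_intensity,interior_intensity scatter strengths (defaults 1
#'   and 0.6).
#' @param seed integer RNG seed.
#' @return a [scatter_scene()].
#' @export
bead_shell_phantom <- function(diameter = 25, n_surface_points = 300L,
                               interior_density = 0.005,
                               surface_intensity = 1,
                               interior_intensity = 0.6, seed = 1L) {
  check_scalar(diameter, "diameter", positive = TRUE)
  n_surface_points <- as.integer(n_surface_points)
  if (n_surface_points < 1) stop_validation("n_surface_points must be >= 1")
  check_scalar(interior_density, "interior_density", nonnegative = TRUE)
  r <- diameter / 2
  centers <- with_seed(seed, {
    surf <- runif_sphere_surface(n_surface_points, r)
    n_int <- if (interior_density > 0) {
      stats::rpois(1, interior_density * 4 / 3 * pi * r^3)
    } else 0L
    intr <- if (n_int > 0) runif_sphere_interior(n_int, r) else
      matrix(numeric(0), 0, 3)
    data.frame(
      x_um = c(surf[, 1], intr[, 1]),
      y_um = c(surf[, 2], intr[, 2]),
      z_um = c(surf[, 3], intr[, 3]),
      intensity = c(rep(surface_intensity, nrow(surf)),
                    rep(interior_intensity, nrow(intr))))
  })
  extent <- rbind(x = c(-r, r), y = c(-r, r), z = c(-r, r))
  scatter_scene(centers, extent,
                metadata = list(generator = "bead_shell_phantom",
                                diameter = diameter,
                                n_surface_points = n_surface_points,
                                interior_density = interior_density,
                                seed = seed))
}

#' Cell phantom with optional surface beads
#'
#' A spherical cell filled with `n_internal` weak cytoplasmic scatterers plus
#' `n_beads` strong scatterers on the membrane, emulating polystyrene
#' microbeads bound to the cell surface. Bead scatter exceeds cytoplasmic
#' scatter because of the refractive-index contrast; the ratio is a free
#' parameter. Bead positions are returned separately in the metadata so
#' recovery can be scored against them.
#'
#' @param cell_diameter cell diameter, micrometres (default 15).
#' @param n_internal number of cytoplasmic scatterers (default 120).
#' @param n_beads number of surface beads (default 4).
#' @param bead_intensity_ratio bead / mean cytoplasmic intensity (>= 1,
#'   default 5).
#' @param seed integer RNG seed.
#' @return a [scatter_scene()]; `metadata$bead_centers` holds the bead
#'   positions and intensities.
#' @export
cell_phantom <- function(cell_diameter = 15, n_internal = 120L, n_beads = 4L,
                         bead_intensity_ratio = 5, seed = 1L) {
  check_scalar(cell_diameter, "cell_diameter", positive = TRUE)
  n_internal <- as.integer(n_internal)
  n_beads <- as.integer(n_beads)
  if (n_internal < 0 || n_beads < 0) {
    stop_validation("n_internal and n_beads must be >= 0")
  }
  check_scalar(bead_intensity_ratio, "bead_intensity_ratio")
  if (bead_intensity_ratio < 1) {
    stop_validation("bead_intensity_ratio must be >= 1")
  }
  r <- cell_diameter / 2
  out <- with_seed(seed, {
    intr <- if (n_internal > 0) runif_sphere_interior(n_internal, r) else
      matrix(numeric(0), 0, 3)
    # mild lognormal spread around unit mean for cytoplasmic scatter
    i_int <- if (n_internal > 0) {
      v <- stats::rlnorm(n_internal, meanlog = -0.045, sdlog = 0.3)
      v / mean(v)
    } else numeric(0)
    beads <- if (n_beads > 0) runif_sphere_surface(n_beads, r) else
      matrix(numeric(0), 0, 3)
    list(intr = intr, i_int = i_int, beads = beads)
  })
  mean_int <- if (n_internal > 0) mean(out$i_int) else 1
  bead_int <- bead_intensity_ratio * mean_int
  centers <- data.frame(
    x_um = c(out$intr[, 1], out$beads[, 1]),
    y_um = c(out$intr[, 2], out$beads[, 2]),
    z_um = c(out$intr[, 3], out$beads[, 3]),
    intensity = c(out$i_int, rep(bead_int, n_beads)))
  bead_df <- data.frame(x_um = out$beads[, 1], y_um = out$beads[, 2],
                        z_um = out$beads[, 3],
                        intensity = rep(bead_int, n_beads))
  extent <- rbind(x = c(-r, r), y = c(-r, r), z = c(-r, r))
  scatter_scene(centers, extent,
                metadata = list(generator = "cell_phantom",
                                cell_diameter = cell_diameter,
                                n_internal = n_internal, n_beads = n_beads,
                                bead_intensity_ratio = bead_intensity_ratio,
                                seed = seed, bead_centers = bead_df))
}
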