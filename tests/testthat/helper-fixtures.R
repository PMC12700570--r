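# Shared fixtures: small configurations and scenes built in code.

cfg4 <- function(...) fsc_config(n_channels = 4, ...)

xt_nn <- function(eps = 0.2) crosstalk_model("nearest_neighbor", epsilon = eps)

# a single unit scatterer exactly on plane j of a config
point_scene <- function(config, j = 1, x = 0, y = 0, intensity = 1) {
  scatter_scene(data.frame(x_um = x, y_um = y, z_um = z_planes(config)[j],
                           intensity = intensity))
}

# channel stack built directly (for stage-level tests without a record)
make_stack <- function(images, dx, dy, config) {
  structure(list(images = images, pixel_size_x = dx, pixel_size_y = dy,
                 origin = c(x = 0, y = 0),
                 col_y_offset = rep(0, dim(images)[2]), config = config),
            class = "channel_stack")
}

# record with replaced signal matrix (for linearity tests)
with_signals <- function(record, signals) {
  record$signals <- signals
  record
}

# full width at half maximum of a 1-d profile, in sample units
fwhm <- function(v) {
  v <- v / max(v)
  above <- which(v >= 0.5)
  diff(range(above)) + 1
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

# smooth windowed test blobs on a voxel grid (for oracle comparisons)
windowed_blobs <- function(xs, ys, n_planes) {
  hx <- sin(pi * ((xs - min(xs)) / (max(xs) - min(xs))))^2
  hy <- sin(pi * ((ys - min(ys)) / (max(ys) - min(ys))))^2
  win <- outer(hx, hy)
  blob <- function(cx, cy, s) {
    outer(xs, ys, function(x, y) exp(-((x - cx)^2 + (y - cy)^2) / (2 * s^2))) *
      win
  }
  spanx <- max(xs) - min(xs)
  spany <- max(ys) - min(ys)
  cx0 <- mean(range(xs)); cy0 <- mean(range(ys))
  vals <- array(0, c(length(xs), length(ys), n_planes))
  specs <- list(list(c(-0.2, 0.05, 1), c(0.15, 0.2, 0.7)),
                list(c(0.05, 0, 0.9)),
                list(c(-0.13, 0.1, 1), c(0.2, -0.2, 0.5)),
                list(c(0.08, -0.1, 0.8)))
  for (p in seq_len(n_planes)) {
    for (b in specs[[((p - 1) %% length(specs)) + 1]]) {
      vals[, , p] <- vals[, , p] +
        b[3] * blob(cx0 + b[1] * spanx, cy0 + b[2] * spany, 1.4)
    }
  }
  vals
}
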