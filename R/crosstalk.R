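# Inter-plane crosstalk: the matrix M_ij(y) coupling light scattered at focal
# plane z_j to detector channel i. It never depends on the scan position x
# (the micro-mirrors span the whole scan line); a y-dependence can arise from
# the mirror geometry and is supported through the tabulated mode.

#' Crosstalk model between focal planes and PMT channels
#'
#' Three modes are available:
#' \describe{
#'   \item{`"diagonal"`}{no crosstalk, `M = I` at every y.}
#'   \item{`"nearest_neighbor"`}{unit diagonal with coupling `epsilon` to the
#'     two adjacent channels, independent of y.}
#'   \item{`"tabulated"`}{an `n x n x length(y_grid)` array of measured or
#'     ray-traced values, linearly interpolated in y.}
#' }
#'
#' @param mode one of `"diagonal"`, `"nearest_neighbor"`, `"tabulated"`.
#' @param epsilon nearest-neighbour coupling in `[0, 1)`.
#' @param table numeric array `n_channels x n_channels x length(y_grid)` of
#'   nonnegative couplings (tabulated mode only).
#' @param y_grid strictly increasing y sample positions, micrometres
#'   (tabulated mode only).
#' @return an object of class `crosstalk_model`.
#' @examples
#' m <- crosstalk_model("nearest_neighbor", epsilon = 0.2)
#' evaluate_crosstalk(m, y = 0, n_channels = 3)
#' @export
crosstalk_model <- function(mode = c("diagonal", "nearest_neighbor",
                                     "tabulated"),
                            epsilon = 0.1, table = NULL, y_grid = NULL) {
  mode <- match.arg(mode)
  if (mode == "nearest_neighbor") {
    epsilon <- check_scalar(epsilon, "epsilon", nonnegative = TRUE)
    if (epsilon >= 1) stop_validation("epsilon must lie in [0, 1)")
  }
  if (mode == "tabulated") {
    if (is.null(table) || is.null(y_grid)) {
      stop_validation("tabulated mode requires both `table` and `y_grid`")
    }
    if (!is.array(table) || length(dim(table)) != 3L) {
      stop_validation("`table` must be a 3-d array (n x n x length(y_grid))")
    }
    d <- dim(table)
    if (d[1] != d[2] || d[3] != length(y_grid)) {
      stop_validation("`table` dimensions must be n_channels x n_channels x ",
                      "length(y_grid)")
    }
    if (any(!is.finite(table)) || any(table < 0)) {
      stop_validation("crosstalk table entries must be finite and >= 0")
    }
    if (length(y_grid) < 2 || any(diff(y_grid) <= 0)) {
      stop_validation("`y_grid` must be strictly increasing with >= 2 points")
    }
  }
  structure(list(mode = mode, epsilon = epsilon, table = table,
                 y_grid = y_grid),
            class = "crosstalk_model")
}

#' @export
print.crosstalk_model <- function(x, ...) {
  cat("<crosstalk_model mode=", x$mode, sep = "")
  if (x$mode == "nearest_neighbor") cat(" epsilon=", x$epsilon, sep = "")
  if (x$mode == "tabulated") {
    cat(sprintf(" %dx%d over y in [%g, %g] um", dim(x$table)[1],
                dim(x$table)[2], min(x$y_grid), max(x$y_grid)))
  }
  cat(">\n")
  invisible(x)
}

#' Evaluate the crosstalk matrix at a flow offset y
#'
#' @param model a [crosstalk_model()].
#' @param y flow-axis offset from the beam line, micrometres (scalar).
#' @param n_channels number of channels the matrix must have.
#' @return an `n_channels x n_channels` nonnegative matrix.
#' @export
evaluate_crosstalk <- function(model, y, n_channels) {
  y <- check_scalar(y, "y")
  n <- as.integer(n_channels)
  switch(model$mode,
    diagonal = diag(n),
    nearest_neighbor = {
      m <- diag(n)
      if (n > 1) {
        idx <- seq_len(n - 1)
        m[cbind(idx, idx + 1)] <- model$epsilon
        m[cbind(idx + 1, idx)] <- model$epsilon
      }
      m
    },
    tabulated = {
      if (dim(model$table)[1] != n) {
        stop_validation("crosstalk table is for ", dim(model$table)[1],
                        " channels, not ", n)
      }
      if (y < min(model$y_grid) || y > max(model$y_grid)) {
        stop_validation("y = ", y, " um outside tabulated range [",
                        min(model$y_grid), ", ", max(model$y_grid), "]")
      }
      interp_table(model, y, n)
    })
}

# Linear interpolation of the tabulated matrix at offsets y; positions beyond
# the table are returned as zero coupling when clamp_zero (used by the forward
# model and build_u_spectrum, whose Gaussian envelope vanishes there anyway).
interp_table <- function(model, y, n, clamp_zero = FALSE) {
  g <- model$y_grid
  out <- matrix(0, n, n)
  inside <- y >= min(g) & y <= max(g)
  if (!inside && !clamp_zero) {
    stop_validation("y outside tabulated range")
  }
  if (inside) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        out[i, j] <- stats::approx(g, model$table[i, j, ], xout = y,
                                   rule = 1)$y
      }
    }
  }
  out
}

# Crosstalk-weighted beam kernel K_ij(y) = M_ij(y) * exp(-2 y^2 / w^2),
# vectorized over y, returned as an n x n x length(y) array. This is the
# kernel whose flow-axis Fourier transform is the U spectrum.
crosstalk_kernel <- function(model, y, w, n_channels) {
  n <- as.integer(n_channels)
  env <- exp(-2 * y^2 / w^2)
  out <- array(0, c(n, n, length(y)))
  if (model$mode == "tabulated") {
    g <- model$y_grid
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        v <- stats::approx(g, model$table[i, j, ], xout = y, rule = 1)$y
        v[is.na(v)] <- 0
        out[i, j, ] <- v * env
      }
    }
  } else {
    m <- evaluate_crosstalk(model, 0, n)
    for (k in seq_along(y)) out[, , k] <- m * env[k]
  }
  out
}
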