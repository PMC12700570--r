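# Classed conditions shared across the package. The CLI maps these classes to
# exit codes, so every user-facing failure should go through one of them.

stop_usage <- function(...) {
  stop(errorCondition(paste0(...), class = c("fsc_usage_error", "error")))
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("fsc_validation_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("fsc_io_error", "error")))
}

stop_numerical <- function(...) {
  stop(errorCondition(paste0(...), class = c("fsc_numerical_error", "error")))
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop_validation(name, " must be > 0")
  if (nonnegative && x < 0) stop_validation(name, " must be >= 0")
  as.numeric(x)
}

# Atomic file write: stream to a sibling temp file, then rename into place so a
# failed run never leaves a partial output.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path)))
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop_io("could not move temporary file into place at ", path)
  }
  ok <- TRUE
  invisible(path)
}

write_json_file <- function(x, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  })
}

fft_freqs <- function(n, spacing) {
  # Unshifted DFT sample frequencies (cycles per unit), numpy fftfreq layout.
  k <- c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L)
  k / (n * spacing)
}

next_pow2 <- function(n) 2^ceiling(log2(max(1, n)))
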