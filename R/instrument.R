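# Acquisition geometry and timing shared by the forward simulator and the
# reconstructor. Units at the API boundary: lengths in micrometres, times in
# seconds, speeds in metres per second; conversions are internal.

#' Instrument configuration
#'
#' Describes the scanned needle-beam acquisition: an acousto-optic deflector
#' sweeps a Gaussian beam of waist `beam_waist_w` (the `w` of
#' `exp(-2 r^2 / w^2)`) across `scan_range` micrometres at `scan_rate` scans
#' per second, while the object flows along y at `flow_speed_vy`. A micro-mirror
#' array maps `n_channels` focal planes, spaced `plane_spacing` apart and
#' centered on z = 0, onto the PMT channels.
#'
#' @param scan_rate scan repetition rate in Hz (default 200 kHz).
#' @param scan_range scan sweep length in micrometres (default 40).
#' @param beam_waist_w Gaussian beam waist parameter in micrometres (default 3).
#' @param flow_speed_vy flow speed along y in m/s (default 0.16).
#' @param n_channels number of detection planes / PMT channels (default 8).
#' @param plane_spacing axial spacing between focal planes, micrometres
#'   (default 2.5).
#' @param sample_rate digitizer rate in samples/s; default `64 * scan_rate`
#'   so every scan yields 64 samples.
#' @param axial_psf_sigma optional Gaussian axial response width (micrometres);
#'   when `NULL` a scatterer is assigned entirely to its nearest plane.
#' @param magnification optical magnification, metadata only (default 50).
#' @param dead_time_frac fraction of each scan period blanked for flyback
#'   (default 0, ideal sawtooth).
#' @param seed optional integer seed recorded with the configuration.
#' @return an object of class `fsc_config`.
#' @examples
#' cfg <- fsc_config()
#' scan_speed(cfg)       # 8 m/s
#' scan_period(cfg) * 1e6  # 5 microseconds
#' z_planes(cfg)
#' @export
fsc_config <- function(scan_rate = 200e3,
                       scan_range = 40,
                       beam_waist_w = 3,
                       flow_speed_vy = 0.16,
                       n_channels = 8L,
                       plane_spacing = 2.5,
                       sample_rate = NULL,
                       axial_psf_sigma = NULL,
                       magnification = 50,
                       dead_time_frac = 0,
                       seed = NULL) {
  scan_rate <- check_scalar(scan_rate, "scan_rate", positive = TRUE)
  scan_range <- check_scalar(scan_range, "scan_range", nonnegative = TRUE)
  beam_waist_w <- check_scalar(beam_waist_w, "beam_waist_w", positive = TRUE)
  flow_speed_vy <- check_scalar(flow_speed_vy, "flow_speed_vy", positive = TRUE)
  plane_spacing <- check_scalar(plane_spacing, "plane_spacing", positive = TRUE)
  magnification <- check_scalar(magnification, "magnification", positive = TRUE)
  dead_time_frac <- check_scalar(dead_time_frac, "dead_time_frac",
                                 nonnegative = TRUE)
  if (dead_time_frac >= 1) stop_validation("dead_time_frac must be < 1")
  if (!is.numeric(n_channels) || length(n_channels) != 1L ||
      n_channels < 1 || n_channels != round(n_channels)) {
    stop_validation("n_channels must be a positive integer")
  }
  n_channels <- as.integer(n_channels)
  if (is.null(sample_rate)) sample_rate <- 64 * scan_rate
  sample_rate <- check_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (!is.null(axial_psf_sigma)) {
    axial_psf_sigma <- check_scalar(axial_psf_sigma, "axial_psf_sigma",
                                    positive = TRUE)
  }

  period <- 1 / scan_rate
  spp <- round(sample_rate * period)
  if (spp < 8) {
    stop_validation("sample_rate yields ", spp,
                    " samples per scan; at least 8 are required")
  }
  vx <- scan_range * 1e-6 / period   # m/s
  if (scan_range > 0 && vx / flow_speed_vy < 10) {
    warning(sprintf(paste0(
      "scan speed (%.3g m/s) is less than 10x the flow speed (%.3g m/s); ",
      "the frozen-y approximation underlying the reconstruction degrades"),
      vx, flow_speed_vy), call. = FALSE)
  }

  structure(
    list(scan_rate = scan_rate, scan_range = scan_range,
         beam_waist_w = beam_waist_w, flow_speed_vy = flow_speed_vy,
         n_channels = n_channels, plane_spacing = plane_spacing,
         sample_rate = sample_rate, axial_psf_sigma = axial_psf_sigma,
         magnification = magnification, dead_time_frac = dead_time_frac,
         seed = seed),
    class = "fsc_config")
}

#' @export
print.fsc_config <- function(x, ...) {
  cat("<fsc_config>\n")
  cat(sprintf("  scan: %.3g kHz over %.3g um  (vx = %.3g m/s, T = %.3g us)\n",
              x$scan_rate / 1e3, x$scan_range, scan_speed(x),
              scan_period(x) * 1e6))
  cat(sprintf("  beam waist w = %.3g um; flow vy = %.3g m/s\n",
              x$beam_waist_w, x$flow_speed_vy))
  cat(sprintf("  %d channels, plane spacing %.3g um (axial FOV %.3g um)\n",
              x$n_channels, x$plane_spacing, axial_fov(x)))
  cat(sprintf("  sample rate %.4g MHz (%d samples per scan)\n",
              x$sample_rate / 1e6, samples_per_scan(x)))
  invisible(x)
}

#' Scan period in seconds
#' @param config an [fsc_config()].
#' @return scan period T = 1 / scan_rate, seconds.
#' @export
scan_period <- function(config) 1 / config$scan_rate

#' Lateral scan speed in m/s
#'
#' The beam sweeps `scan_range` micrometres every scan period, so
#' `vx = scan_range / T`; at 200 kHz over 40 um this is 8 m/s.
#'
#' @param config an [fsc_config()].
#' @return scan speed in m/s.
#' @export
scan_speed <- function(config) {
  config$scan_range * 1e-6 * config$scan_rate
}

#' Samples digitized per scan period
#' @param config an [fsc_config()].
#' @return integer sample count per scan.
#' @export
samples_per_scan <- function(config) {
  as.integer(round(config$sample_rate * scan_period(config)))
}

#' Focal-plane z positions
#'
#' Planes are spaced `plane_spacing` apart and centered symmetrically about
#' z = 0: `z_j = plane_spacing * (j - (n_channels - 1) / 2)`.
#'
#' @param config an [fsc_config()].
#' @return numeric vector of plane positions (micrometres), ascending.
#' @export
z_planes <- function(config) {
  j <- seq_len(config$n_channels) - 1
  config$plane_spacing * (j - (config$n_channels - 1) / 2)
}

#' Axial field of view in micrometres
#' @param config an [fsc_config()].
#' @return `n_channels * plane_spacing`.
#' @export
axial_fov <- function(config) config$n_channels * config$plane_spacing

#' Instantaneous beam position along the scan axis
#'
#' The ideal sawtooth scan law: within scan `n` (i.e. `nT < t < (n+1)T`) the
#' beam position is `x_n(t) = vx * (t - T/2 - n T)`, a centered linear ramp
#' from `-scan_range/2` to `+scan_range/2`.
#'
#' @param t time(s) in seconds, nonnegative; vectorized.
#' @param config an [fsc_config()].
#' @return beam x position(s) in micrometres.
#' @export
beam_position <- function(t, config) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop_validation("beam_position requires finite t >= 0")
  }
  Tp <- scan_period(config)
  n <- floor(t / Tp)
  vx_um <- config$scan_range / Tp      # um/s
  vx_um * (t - Tp / 2 - n * Tp)
}

#' Event throughput from flow parameters
#'
#' Cells per second given a volumetric sample flow and a cell concentration,
#' e.g. 12 ul/min at 2000 cells/ul gives 400 cells/s.
#'
#' @param volumetric_flow_ul_min sample volumetric flow, microlitres / minute.
#' @param concentration_cells_ul cell concentration, cells / microlitre.
#' @return throughput in cells per second.
#' @export
throughput_cells_per_s <- function(volumetric_flow_ul_min,
                                   concentration_cells_ul) {
  check_scalar(volumetric_flow_ul_min, "volumetric_flow_ul_min",
               nonnegative = TRUE)
  check_scalar(concentration_cells_ul, "concentration_cells_ul",
               nonnegative = TRUE)
  volumetric_flow_ul_min * concentration_cells_ul / 60
}

#' Per-cell light exposure
#'
#' Energy deposited on a cell while it resides in the illuminated region:
#' `power * residence time`; 1.5 mW for 0.2 ms gives 0.3 uJ.
#'
#' @param power_mw laser power at the sample, milliwatts.
#' @param residence_ms residence time in the scanning region, milliseconds.
#' @return exposure in microjoules.
#' @export
exposure_dose_uj <- function(power_mw, residence_ms) {
  check_scalar(power_mw, "power_mw", nonnegative = TRUE)
  check_scalar(residence_ms, "residence_ms", nonnegative = TRUE)
  power_mw * residence_ms
}

#' Residence time of a flowing object in the scan region
#' @param region_um illuminated region length along the flow axis, micrometres.
#' @param flow_speed_vy flow speed, m/s.
#' @return residence time in milliseconds.
#' @export
residence_time_ms <- function(region_um, flow_speed_vy) {
  check_scalar(region_um, "region_um", nonnegative = TRUE)
  check_scalar(flow_speed_vy, "flow_speed_vy", positive = TRUE)
  region_um * 1e-6 / flow_speed_vy * 1e3
}

#' Read an instrument configuration from a YAML file
#'
#' Flat key/value YAML using the [fsc_config()] argument names. Unknown keys
#' are an error; missing keys take the documented defaults. The raw file text
#' is attached as attribute `"source_text"` so it can be echoed verbatim into
#' output metadata.
#'
#' @param path path to the YAML file.
#' @return an [fsc_config()].
#' @export
read_instrument_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  # YAML 1.1 leaves forms like "200e3" as strings; coerce numeric-looking
  # scalars so engineering notation works in config files
  vals <- lapply(vals, function(v) {
    if (is.character(v) && length(v) == 1L &&
        !is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
  })
  known <- names(formals(fsc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_validation("unknown configuration key(s): ",
                    paste(unknown, collapse = ", "))
  }
  cfg <- do.call(fsc_config, vals)
  attr(cfg, "source_text") <- paste(readLines(path, warn = FALSE),
                                    collapse = "\n")
  cfg
}

config_as_list <- function(config) {
  out <- unclass(config)
  out[!vapply(out, is.null, logical(1))]
}
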