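# File formats: scatter scenes as CSV + JSON sidecar, PMT records as a
# CSV signal matrix + JSON metadata sidecar, volumes as multi-page 32-bit
# float TIFF with voxel-size metadata in a JSON sidecar, peak tables as CSV.
# All writes are atomic (temp file + rename).

SCHEMA_VERSION <- "1.0"

pkg_version <- function() {
  as.character(utils::packageVersion("fsc3d"))
}

full_precision <- function(x) {
  # shortest decimal strings that round-trip doubles exactly
  vapply(x, function(v) format(v, digits = 17, scientific = TRUE),
         character(1))
}

#' Write a scatter scene to CSV + JSON sidecar
#'
#' `<stem>.csv` holds the centers (columns `x_um`, `y_um`, `z_um`,
#' `intensity`); `<stem>.json` holds the extent, generator metadata and schema
#' version.
#'
#' @param scene a [scatter_scene()].
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_scene <- function(scene, stem) {
  atomic_write(paste0(stem, ".csv"), function(tmp) {
    df <- scene$centers
    df[] <- lapply(df, full_precision)
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
  meta <- list(schema_version = SCHEMA_VERSION,
               package_version = pkg_version(),
               n_centers = nrow(scene$centers),
               extent = list(x = scene$extent[1, ], y = scene$extent[2, ],
                             z = scene$extent[3, ]),
               metadata = scene$metadata)
  write_json_file(meta, paste0(stem, ".json"))
  invisible(stem)
}

#' Read a scatter scene written by [write_scene()]
#' @param stem path stem (no extension).
#' @return a [scatter_scene()].
#' @export
read_scene <- function(stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  if (!file.exists(csv)) stop_io("scene file not found: ", csv)
  centers <- utils::read.csv(csv)
  meta <- if (file.exists(js)) jsonlite::read_json(js, simplifyVector = TRUE)
          else list()
  extent <- if (!is.null(meta$extent)) {
    rbind(x = unlist(meta$extent$x), y = unlist(meta$extent$y),
          z = unlist(meta$extent$z))
  } else NULL
  md <- meta$metadata
  if (is.null(md)) md <- list()
  scatter_scene(centers, extent, metadata = md)
}

#' Write a PMT record
#'
#' `<stem>.csv` holds the signal matrix (one row per sample, one column per
#' channel, full double precision); `<stem>.json` carries `sample_rate_hz`,
#' `t0_s`, `y_origin_um`, the configuration and crosstalk echo, the noise
#' description and the schema version.
#'
#' @param record a `pmt_record`.
#' @param stem output path without extension.
#' @return the stem, invisibly.
#' @export
write_pmt_record <- function(record, stem) {
  sig <- t(record$signals)   # samples x channels
  atomic_write(paste0(stem, ".csv"), function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste(paste0("ch", seq_len(ncol(sig))), collapse = ","), con)
    txt <- apply(sig, 2, full_precision)
    writeLines(do.call(paste, c(split(txt, col(txt)), sep = ",")), con)
  })
  xt <- record$crosstalk
  meta <- list(
    schema_version = SCHEMA_VERSION,
    package_version = pkg_version(),
    sample_rate_hz = record$sample_rate,
    t0_s = record$t0,
    n_channels = nrow(record$signals),
    n_samples = ncol(record$signals),
    y_origin_um = record$y_origin,
    frozen_y = isTRUE(record$frozen_y),
    config = config_as_list(record$config),
    crosstalk = list(mode = xt$mode, epsilon = xt$epsilon,
                     y_grid = xt$y_grid,
                     table = if (!is.null(xt$table)) as.vector(xt$table),
                     table_dim = if (!is.null(xt$table)) dim(xt$table)),
    noise = record$noise_spec)
  write_json_file(meta, paste0(stem, ".json"))
  invisible(stem)
}

#' Read a PMT record written by [write_pmt_record()]
#' @param stem path stem (no extension).
#' @return a `pmt_record`.
#' @export
read_pmt_record <- function(stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop_io("record files not found at stem: ", stem)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(meta$schema_version, SCHEMA_VERSION)) {
    stop_validation("record schema version ", meta$schema_version,
                    " does not match supported version ", SCHEMA_VERSION)
  }
  sig <- as.matrix(utils::read.csv(csv))
  cfg_args <- meta$config
  cfg_args <- cfg_args[names(cfg_args) %in% names(formals(fsc_config))]
  config <- do.call(fsc_config, cfg_args)
  xt <- meta$crosstalk
  crosstalk <- if (identical(xt$mode, "tabulated")) {
    crosstalk_model("tabulated",
                    table = array(unlist(xt$table), unlist(xt$table_dim)),
                    y_grid = unlist(xt$y_grid))
  } else {
    crosstalk_model(xt$mode, epsilon = xt$epsilon %||% 0.1)
  }
  structure(
    list(signals = t(unname(sig)), sample_rate = meta$sample_rate_hz,
         t0 = meta$t0_s, config = config, crosstalk = crosstalk,
         y_origin = meta$y_origin_um, frozen_y = isTRUE(meta$frozen_y),
         noise_spec = meta$noise),
    class = "pmt_record")
}

#' Write a volume as multi-page float TIFF with a JSON sidecar
#'
#' One 32-bit float page per z plane (rows = y, columns = x), axis order
#' z-y-x across the file. Values are stored min/max-normalized to [0, 1];
#' the affine intensity scale, physical voxel sizes, origin and provenance go
#' to `<path>.json` so [read_volume_tiff()] restores physical values.
#'
#' @param vol a `volume3d`.
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_volume_tiff <- function(vol, path) {
  v <- vol$intensities
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) (v[, , k] - lo) / scale)
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 32, compression = "none",
                    reduce = FALSE)
  })
  meta <- list(schema_version = SCHEMA_VERSION,
               package_version = pkg_version(),
               axis_order = "zyx",
               shape_yxz = dim(v),
               voxel_size_um = as.list(vol$voxel_size),
               origin_um = as.list(vol$origin),
               intensity_offset = lo, intensity_scale = scale,
               provenance = vol$provenance)
  write_json_file(meta, paste0(path, ".json"))
  invisible(path)
}

#' Read a volume written by [write_volume_tiff()]
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return a `volume3d`.
#' @export
read_volume_tiff <- function(path) {
  js <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(js)) {
    stop_io("volume files not found: ", path)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr <- arr * meta$intensity_scale + meta$intensity_offset
  prov <- meta$provenance
  if (is.null(prov)) prov <- list()
  volume3d(arr,
           voxel_size = unlist(meta$voxel_size_um)[c("x", "y", "z")],
           origin = unlist(meta$origin_um)[c("x", "y", "z")],
           provenance = prov)
}

#' Write a binary mask as 8-bit multi-page TIFF
#' @param mask logical 3-d array (y, x, z).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  pages <- lapply(seq_len(dim(mask)[3]),
                  function(k) mask[, , k] * 1.0)
  atomic_write(path, function(tmp) {
    tiff::writeTIFF(pages, tmp, bits.per.sample = 8, compression = "none")
  })
  invisible(path)
}

#' Write a peak table as CSV
#' @param peaks a `peak_set`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(peaks$peaks, tmp, row.names = FALSE)
  })
  invisible(path)
}
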