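#' Write an image stack as a multi-page 16-bit TIFF with a geometry sidecar
#'
#' Intensities are rounded and clipped to the unsigned 16-bit range. The
#' voxel geometry is written to a JSON sidecar next to the TIFF; the
#' sidecar is required to read the stack back, so physical units can never
#' be silently lost.
#'
#' @param stack an [image_stack()].
#' @param path destination `.tif` path.
#' @param sidecar geometry sidecar path; default `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  vals <- pmin(pmax(round(stack$data), 0), 65535)
  pages <- lapply(seq_len(d[3]), function(z) vals[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size_um = stack$voxel_size, shape = d,
         axes = "y,x,z", z_origin = "coverslip"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Single-plane (2D) TIFFs are promoted to stacks with `nz = 1`.
#' Multi-channel pages are refused unless a channel is selected; geometry
#' is never assumed, so a missing sidecar is an error.
#'
#' @param path TIFF path.
#' @param sidecar geometry sidecar path; default `<path>.json`.
#' @param channel optional 1-based channel index for multi-channel input.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json"), channel = NULL) {
  if (!file.exists(path)) stop("stack not found: ", path, call. = FALSE)
  if (!file.exists(sidecar))
    stop("geometry sidecar not found: ", sidecar,
         " (voxel size is required; isotropy is never assumed)", call. = FALSE)
  geom <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel))
        stop("multi-channel TIFF: pass `channel` to select one", call. = FALSE)
      p <- p[, , channel]
    }
    p
  })
  d2 <- dim(pages[[1]])
  data <- array(0, c(d2[1], d2[2], length(pages)))
  for (z in seq_along(pages)) data[, , z] <- pages[[z]]
  image_stack(data, geom$voxel_size_um)
}

# 32-bit label TIFFs: the tiff package stores 32-bit samples as value/(2^32-1)
.LAB_SCALE <- 2^32 - 1

#' Write an integer label volume as a multi-page 32-bit TIFF
#' @param labels integer array `(ny, nx, nz)` or matrix; 0 = background.
#' @param path destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (is.matrix(labels)) labels <- array(labels, c(dim(labels), 1L))
  stopifnot(length(dim(labels)) == 3L, all(labels >= 0))
  pages <- lapply(seq_len(dim(labels)[3]),
                  function(z) labels[, , z] / .LAB_SCALE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path TIFF path.
#' @return integer array `(ny, nx, nz)`.
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d2 <- dim(pages[[1]])
  out <- array(0L, c(d2[1], d2[2], length(pages)))
  for (z in seq_along(pages))
    out[, , z] <- as.integer(round(pages[[z]] * .LAB_SCALE))
  out
}

#' Write per-aggregate records, metrics, and a run manifest
#'
#' Emits `aggregates.csv` (one row per aggregate), `metrics.json`, and
#' `manifest.json` (config hash, seed, package version, timestamp) into
#' `dir`. The CSV and metrics JSON are byte-deterministic for identical
#' inputs; the timestamp lives only in the manifest.
#'
#' @param set an [aggregate_set][segment_stack()].
#' @param metrics a `metrics_report` from [aggregate_metrics()]; its volume
#'   list must match the records in `set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(set, metrics, dir) {
  stopifnot(inherits(set, "aggregate_set"), inherits(metrics, "metrics_report"))
  if (!isTRUE(all.equal(sort(metrics$volumes), sort(set$records$volume_um3))))
    stop("metrics volume list does not match the aggregate records",
         call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- set$records[, c("id", "voxel_count", "volume_um3",
                         "centroid_x_um", "centroid_y_um", "centroid_z_um",
                         "z_min", "z_max", "max_xsection_area_um2")]
  write.csv(rec, file.path(dir, "aggregates.csv"), row.names = FALSE)
  m <- unclass(metrics)
  m$weighted_mean_volume_um3 <- if (is.null(m$weighted_mean_volume_um3))
    NULL else m$weighted_mean_volume_um3
  jsonlite::write_json(m, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_json <- jsonlite::toJSON(unclass(set$config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  tf <- tempfile()
  writeLines(as.character(cfg_json), tf)
  manifest <- list(config_hash = unname(tools::md5sum(tf)),
                   rng_seed = set$config$rng_seed,
                   package_version = as.character(packageVersion("aggscan")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
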