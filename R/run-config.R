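#' Segmentation run configuration
#'
#' Bundles every tunable of the segmentation pipeline. Within an analysis
#' all parameters are held fixed; a config is attached to every result so
#' the provenance of a segmentation is always recoverable. Size cutoffs are
#' given in physical units (um^3) and converted to voxels internally.
#'
#' @param intensity_threshold global intensity threshold; voxels with
#'   intensity >= threshold are foreground. No per-plane adaptation.
#' @param min_object_volume minimum 3D object volume in um^3; smaller
#'   reconstructed objects are discarded (removes planktonic cells and
#'   shot-noise specks). The value is a pipeline default, not a published
#'   constant.
#' @param max_cluster_volume optional upper volume cutoff in um^3, used in
#'   the high-magnification "cluster" mode; `NULL` disables it.
#' @param rmsd_cutoff convexity-deviation cutoff above which a 2D object is
#'   considered a merged pair and bisected. The default 0.2 flags objects
#'   whose solidity falls below 0.96 (see [score_convexity()]); it was
#'   calibrated on synthetic scenes, where clean convex footprints score 0
#'   and abutting-pair footprints score above 0.23.
#' @param split logical; apply convexity-driven bisection at all.
#' @param split_max_iterations maximum recursion depth when re-splitting
#'   children that still exceed the cutoff.
#' @param overlap_min_voxels minimum (y, x) footprint overlap, in pixels,
#'   for two objects in adjacent planes to be linked into one 3D aggregate.
#' @param connectivity_2d pixel connectivity for 2D labeling, 4 or 8.
#' @param convexity_method `"deficit_fraction"` (normalized; default) or
#'   `"raw_deficit"` (convex area minus area, in pixels); see
#'   [score_convexity()].
#' @param quadrant_frame `"image"` (axis-aligned quadrants; default) or
#'   `"principal"` (quadrants aligned to the object's principal axes).
#' @param rng_seed integer seed recorded in run manifests.
#' @return an object of class `run_config`.
#' @seealso [run_preset()] for the objective-specific defaults.
#' @export
run_config <- function(intensity_threshold = 70,
                       min_object_volume = 50,
                       max_cluster_volume = NULL,
                       rmsd_cutoff = 0.2,
                       split = TRUE,
                       split_max_iterations = 3L,
                       overlap_min_voxels = 1L,
                       connectivity_2d = 8L,
                       convexity_method = c("deficit_fraction", "raw_deficit"),
                       quadrant_frame = c("image", "principal"),
                       rng_seed = 1L) {
  convexity_method <- match.arg(convexity_method)
  quadrant_frame <- match.arg(quadrant_frame)
  if (intensity_threshold < 0) stop("intensity_threshold must be >= 0", call. = FALSE)
  if (min_object_volume < 0) stop("min_object_volume must be >= 0", call. = FALSE)
  if (!is.null(max_cluster_volume)) {
    if (max_cluster_volume <= 0)
      stop("max_cluster_volume must be positive or NULL", call. = FALSE)
    if (min_object_volume > max_cluster_volume)
      stop("min_object_volume exceeds max_cluster_volume", call. = FALSE)
  }
  if (rmsd_cutoff < 0) stop("rmsd_cutoff must be >= 0", call. = FALSE)
  if (split_max_iterations < 0) stop("split_max_iterations must be >= 0", call. = FALSE)
  if (overlap_min_voxels < 1) stop("overlap_min_voxels must be >= 1", call. = FALSE)
  if (!connectivity_2d %in% c(4L, 8L)) stop("connectivity_2d must be 4 or 8", call. = FALSE)
  structure(list(intensity_threshold = intensity_threshold,
                 min_object_volume = min_object_volume,
                 max_cluster_volume = max_cluster_volume,
                 rmsd_cutoff = rmsd_cutoff,
                 split = isTRUE(split),
                 split_max_iterations = as.integer(split_max_iterations),
                 overlap_min_voxels = as.integer(overlap_min_voxels),
                 connectivity_2d = as.integer(connectivity_2d),
                 convexity_method = convexity_method,
                 quadrant_frame = quadrant_frame,
                 rng_seed = as.integer(rng_seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  threshold %.4g; min volume %.4g um^3; max volume %s\n",
              x$intensity_threshold, x$min_object_volume,
              if (is.null(x$max_cluster_volume)) "none"
              else sprintf("%.4g um^3", x$max_cluster_volume)))
  cat(sprintf("  split: %s (cutoff %.4g, max depth %d, %s quadrants, %s)\n",
              if (x$split) "on" else "off", x$rmsd_cutoff,
              x$split_max_iterations, x$quadrant_frame, x$convexity_method))
  cat(sprintf("  link overlap >= %d px; 2D connectivity %d\n",
              x$overlap_min_voxels, x$connectivity_2d))
  invisible(x)
}

#' Objective-specific run presets
#'
#' `"10x"` is the aggregate regime (large field of view, 2 um z step);
#' `"63x"` is the cluster regime, which additionally applies an upper
#' cluster size cutoff; `"small"` mirrors `"10x"` parameters for the small
#' synthetic test grids. Threshold and cutoff values are pipeline defaults
#' calibrated on synthetic scenes.
#'
#' @param name one of `"10x"`, `"63x"`, `"small"`.
#' @param ... overrides passed on to [run_config()].
#' @return a `run_config`.
#' @export
run_preset <- function(name = c("10x", "63x", "small"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "10x"   = list(intensity_threshold = 70, min_object_volume = 100),
    "63x"   = list(intensity_threshold = 70, min_object_volume = 5,
                   max_cluster_volume = 500),
    "small" = list(intensity_threshold = 70, min_object_volume = 50))
  args <- utils::modifyList(base, list(...))
  do.call(run_config, args)
}

#' Read a run configuration from YAML or JSON
#' @param path file ending in `.yaml`, `.yml` or `.json`.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Write a run configuration
#' @param cfg a `run_config`.
#' @param path destination ending in `.yaml`, `.yml` or `.json`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  vals <- unclass(cfg)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(vals, path)
  else jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                            null = "null", pretty = TRUE)
  invisible(path)
}
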