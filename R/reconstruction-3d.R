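#' Link 2D objects across adjacent planes into 3D aggregates
#'
#' Two objects in adjacent z-planes belong to the same aggregate when
#' their (y, x) footprints share at least `overlap_min_voxels` pixels.
#' Merging is transitive (union-find), so two objects in plane z joined
#' through a single object in plane z+1 become one aggregate. 3D
#' connectivity is defined only through this inter-plane footprint
#' overlap. Final labels are renumbered by (first plane, raster position
#' of the first pixel in that plane), so the labeling is deterministic.
#'
#' @param planes a `plane_labels` object from [segment_planes()], or a
#'   plain list of integer label matrices of identical shape.
#' @param overlap_min_voxels minimum footprint overlap in pixels.
#' @return integer array `(ny, nx, nz)` of 3D labels.
#' @export
link_planes <- function(planes, overlap_min_voxels = 1L) {
  if (inherits(planes, "plane_labels")) planes <- planes$planes
  stopifnot(is.list(planes), length(planes) >= 1L)
  d2 <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d2), TRUE)))
    stop("all planes must share the same (ny, nx) shape", call. = FALSE)
  nz <- length(planes)
  counts <- vapply(planes, function(p) as.integer(max(p)), 0L)
  offset <- c(0L, cumsum(counts))[seq_len(nz)]
  total <- sum(counts)
  if (total == 0L) return(array(0L, c(d2, nz)))

  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  for (z in seq_len(nz - 1L)) {
    a <- planes[[z]]; b <- planes[[z + 1L]]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    ov <- table(a[sel], b[sel])
    hits <- which(ov >= overlap_min_voxels, arr.ind = TRUE)
    if (!nrow(hits)) next
    ia <- as.integer(rownames(ov))[hits[, 1]] + as.integer(offset[z])
    ib <- as.integer(colnames(ov))[hits[, 2]] + as.integer(offset[z + 1L])
    for (k in seq_len(nrow(hits))) union(ia[k], ib[k])
  }
  roots <- vapply(seq_len(total), find, 0L)

  # order components by (first z, raster position of first pixel)
  first_z <- rep(NA_integer_, total)
  first_pos <- rep(NA_real_, total)
  for (z in seq_len(nz)) {
    p <- planes[[z]]
    k <- max(p)
    if (k == 0L) next
    for (i in seq_len(k)) {
      r <- roots[i + offset[z]]
      if (is.na(first_z[r])) {
        idx <- which(p == i, arr.ind = TRUE)
        pos <- min((idx[, 1] - 1) * d2[2] + idx[, 2])  # raster (row-major)
        first_z[r] <- z
        first_pos[r] <- pos
      }
    }
  }
  comp <- sort(unique(roots))
  ord <- comp[order(first_z[comp], first_pos[comp])]
  newid <- integer(total)
  newid[ord] <- seq_along(ord)

  out <- array(0L, c(d2, nz))
  for (z in seq_len(nz)) {
    p <- planes[[z]]
    sel <- p > 0L
    if (!any(sel)) next
    q <- p
    q[sel] <- newid[roots[p[sel] + offset[z]]]
    out[, , z] <- q
  }
  out
}

# per-label summary of a 3D label volume
.label_records <- function(vol, voxel_size) {
  d <- dim(vol)
  n <- max(vol)
  if (n == 0L)
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), centroid_x_um = numeric(0),
                      centroid_y_um = numeric(0), centroid_z_um = numeric(0),
                      z_min = integer(0), z_max = integer(0),
                      z_extent = integer(0),
                      max_xsection_area_um2 = numeric(0)))
  idx <- which(vol > 0L)
  lab <- vol[idx]
  iy <- ((idx - 1L) %% d[1]) + 1L
  ixz <- (idx - 1L) %/% d[1]
  ix <- (ixz %% d[2]) + 1L
  iz <- (ixz %/% d[2]) + 1L
  vvol <- prod(voxel_size)
  cnt <- tabulate(lab, n)
  f <- factor(lab, levels = seq_len(n))
  per_plane <- tapply(seq_along(lab), list(f, iz), length)
  max_fp <- apply(per_plane, 1, max, na.rm = TRUE)
  zmin <- as.integer(tapply(iz, f, min))
  zmax <- as.integer(tapply(iz, f, max))
  data.frame(
    id = seq_len(n),
    voxel_count = cnt,
    volume_um3 = cnt * vvol,
    centroid_x_um = as.numeric(tapply((ix - 0.5) * voxel_size[1], f, mean)),
    centroid_y_um = as.numeric(tapply((iy - 0.5) * voxel_size[2], f, mean)),
    centroid_z_um = as.numeric(tapply((iz - 0.5) * voxel_size[3], f, mean)),
    z_min = zmin,
    z_max = zmax,
    z_extent = zmax - zmin + 1L,
    max_xsection_area_um2 = as.numeric(max_fp) * voxel_size[1] * voxel_size[2])
}

#' Apply physical-unit size cutoffs to a 3D label volume
#'
#' Aggregates below `min_object_volume` are removed (this is what excludes
#' planktonic cells and noise specks); when `max_cluster_volume` is set
#' (cluster mode) aggregates above it are removed as well. Survivors are
#' re-indexed 1..K in their original order; every removal is logged with
#' its reason, so no voxel disappears silently.
#'
#' @param vol integer label array `(ny, nx, nz)`.
#' @param voxel_size `(dx, dy, dz)` um.
#' @param min_object_volume minimum volume, um^3.
#' @param max_cluster_volume optional maximum volume, um^3.
#' @param sample_id,replicate_id,timepoint_h optional provenance fields.
#' @param config optional `run_config` recorded in the result.
#' @param cuts optional chord log carried through from [segment_planes()].
#' @return an object of class `aggregate_set`: `records` (per-aggregate
#'   table), `removed` (log of filtered objects), `label_volume`,
#'   `imaged_volume_um3`, `voxel_size`.
#' @export
filter_by_size <- function(vol, voxel_size, min_object_volume,
                           max_cluster_volume = NULL, sample_id = NA,
                           replicate_id = NA, timepoint_h = NA,
                           config = NULL, cuts = NULL) {
  if (!is.null(max_cluster_volume) && min_object_volume > max_cluster_volume)
    stop("min_object_volume exceeds max_cluster_volume", call. = FALSE)
  rec <- .label_records(vol, voxel_size)
  too_small <- rec$volume_um3 < min_object_volume
  too_big <- if (is.null(max_cluster_volume)) rep(FALSE, nrow(rec))
             else rec$volume_um3 > max_cluster_volume
  removed <- rec[too_small | too_big, c("id", "voxel_count", "volume_um3")]
  removed$reason <- ifelse(rec$volume_um3[too_small | too_big] <
                             min_object_volume, "below_min_volume",
                           "above_max_volume")
  keep <- rec[!(too_small | too_big), , drop = FALSE]
  remap <- integer(nrow(rec))
  remap[keep$id] <- seq_len(nrow(keep))
  newvol <- vol
  sel <- vol > 0L
  newvol[sel] <- remap[vol[sel]]
  keep$id <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  rownames(removed) <- NULL
  structure(list(records = keep, removed = removed, label_volume = newvol,
                 imaged_volume_um3 = prod(dim(vol)) * prod(voxel_size),
                 voxel_size = voxel_size, sample_id = sample_id,
                 replicate_id = replicate_id, timepoint_h = timepoint_h,
                 config = config,
                 cuts = if (is.null(cuts)) data.frame() else cuts),
            class = "aggregate_set")
}

#' Segment a 3D stack into aggregates
#'
#' The full pipeline: global intensity threshold on every plane, 2D
#' connected-component labeling, convexity-driven bisection of merged
#' objects, linking of overlapping 2D regions across planes into 3D
#' aggregates, and physical-unit size filtering. Fully deterministic for a
#' fixed `(stack, cfg)`.
#'
#' @param stack an [image_stack()].
#' @param cfg a [run_config()].
#' @param sample_id,replicate_id,timepoint_h optional provenance fields
#'   stored in the result.
#' @return an `aggregate_set`; see [filter_by_size()].
#' @examples
#' sc <- generate_scene(scene_config(grid_shape = c(64, 64, 10),
#'                                   n_aggregates = 2, n_planktonic = 5,
#'                                   volume_range = c(200, 500),
#'                                   noise_sd = 0, blur_sigma = 0))
#' segment_stack(sc$stack, run_config(min_object_volume = 50))
#' @export
segment_stack <- function(stack, cfg, sample_id = NA, replicate_id = NA,
                          timepoint_h = NA) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "run_config"))
  pl <- segment_planes(stack, cfg)
  vol <- link_planes(pl, cfg$overlap_min_voxels)
  filter_by_size(vol, stack$voxel_size, cfg$min_object_volume,
                 cfg$max_cluster_volume, sample_id = sample_id,
                 replicate_id = replicate_id, timepoint_h = timepoint_h,
                 config = cfg, cuts = pl$cuts)
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf("<aggregate_set> %d aggregates (%d removed by size filter)\n",
              nrow(x$records), nrow(x$removed)))
  cat(sprintf("  imaged volume %.4g um^3; volume fraction %.4g\n",
              x$imaged_volume_um3, volume_fraction(x)))
  if (nrow(x$records)) {
    v <- x$records$volume_um3
    cat(sprintf("  volumes [um^3]: min %.4g, median %.4g, max %.4g; weighted mean %.4g\n",
                min(v), stats::median(v), max(v), weighted_mean_volume(v)))
  }
  invisible(x)
}

#' @export
summary.aggregate_set <- function(object, ...) {
  out <- list(n_aggregates = nrow(object$records),
              n_removed = nrow(object$removed),
              volume_fraction = volume_fraction(object),
              weighted_mean_volume_um3 = if (nrow(object$records))
                weighted_mean_volume(object$records$volume_um3) else NULL,
              imaged_volume_um3 = object$imaged_volume_um3)
  class(out) <- "summary.aggregate_set"
  out
}

#' @export
print.summary.aggregate_set <- function(x, ...) {
  cat(sprintf("aggregates: %d (removed: %d)\n", x$n_aggregates, x$n_removed))
  cat(sprintf("volume fraction: %.6g\n", x$volume_fraction))
  cat(sprintf("weighted mean volume: %s um^3\n",
              if (is.null(x$weighted_mean_volume_um3)) "undefined (no aggregates)"
              else sprintf("%.6g", x$weighted_mean_volume_um3)))
  invisible(x)
}

#' Histogram of aggregate volumes
#'
#' @param x an `aggregate_set`.
#' @param log plot volumes on a log10 axis (default).
#' @param ... passed to [graphics::hist()].
#' @export
plot.aggregate_set <- function(x, log = TRUE, ...) {
  v <- x$records$volume_um3
  if (!length(v)) {
    warning("no aggregates to plot")
    return(invisible(NULL))
  }
  if (log) {
    hist(log10(v), xlab = "log10 aggregate volume [um^3]",
         main = "Aggregate volume distribution", ...)
    abline(v = log10(weighted_mean_volume(v)), col = 2, lwd = 2)
  } else {
    hist(v, xlab = "aggregate volume [um^3]",
         main = "Aggregate volume distribution", ...)
    abline(v = weighted_mean_volume(v), col = 2, lwd = 2)
  }
  legend("topright", legend = "volume-weighted mean", col = 2, lwd = 2,
         bty = "n")
  invisible(x)
}
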