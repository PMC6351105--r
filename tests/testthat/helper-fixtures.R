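# shared fixture builders and small oracles, all generated in code

# (y, x) coordinates of a filled disk on an ny x nx grid
disk_coords <- function(cy, cx, r, ny, nx) {
  g <- as.matrix(expand.grid(y = seq_len(ny), x = seq_len(nx)))
  g[(g[, 1] - cy)^2 + (g[, 2] - cx)^2 <= r^2, , drop = FALSE]
}

coords_to_mask <- function(coords, ny, nx) {
  m <- matrix(FALSE, ny, nx)
  m[coords] <- TRUE
  m
}

# pixel-set Jaccard index
jaccard <- function(a, b) {
  ka <- paste(a[, 1], a[, 2])
  kb <- paste(b[, 1], b[, 2])
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# 3D Jaccard on voxel index sets
jaccard_idx <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# greedy truth-to-prediction matching at a Jaccard floor; returns counts
match_objects <- function(truth_lab, pred_lab, truth_ids, jmin = 0.5) {
  pred_ids <- setdiff(unique(as.vector(pred_lab)), 0L)
  used <- integer(0)
  tp <- 0L
  for (t in truth_ids) {
    tv <- which(truth_lab == t)
    cand <- setdiff(unique(pred_lab[tv]), c(0L, used))
    best <- 0
    bestp <- NA_integer_
    for (p in cand) {
      j <- jaccard_idx(tv, which(pred_lab == p))
      if (j > best) {
        best <- j
        bestp <- p
      }
    }
    if (best >= jmin) {
      tp <- tp + 1L
      used <- c(used, bestp)
    }
  }
  list(tp = tp, n_truth = length(truth_ids), n_pred = length(pred_ids))
}

# independent convex-hull-raster oracle: a pixel is in the hull iff its
# center is on the inner side of every hull edge (half-plane test) —
# a different algorithm from the scanline fill used by the package
hull_pixels_oracle <- function(coords) {
  h <- grDevices::chull(coords[, 2], coords[, 1])
  hv <- coords[h, , drop = FALSE]
  if (nrow(hv) < 3L) return(coords)
  g <- as.matrix(expand.grid(y = min(coords[, 1]):max(coords[, 1]),
                             x = min(coords[, 2]):max(coords[, 2])))
  n <- nrow(hv)
  jn <- c(2:n, 1)
  # polygon orientation from the signed area (in (x, y) coordinates)
  area2 <- sum(hv[, 2] * hv[jn, 1] - hv[jn, 2] * hv[, 1])
  inside <- rep(TRUE, nrow(g))
  for (i in seq_len(n)) {
    j <- jn[i]
    ey <- hv[j, 1] - hv[i, 1]
    ex <- hv[j, 2] - hv[i, 2]
    cr <- ex * (g[, 1] - hv[i, 1]) - ey * (g[, 2] - hv[i, 2])
    inside <- inside & (if (area2 > 0) cr >= -1e-9 else cr <= 1e-9)
  }
  g[inside, , drop = FALSE]
}

# exhaustive two-sample ECDF supremum-difference oracle
ks_D_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
}

# quick clean (noise/blur-free) scene config for exactness tests
clean_scene_config <- function(seed, grid = c(128L, 128L, 16L),
                               n_aggregates = 5L, n_planktonic = 10L,
                               touching = 0, vr = c(200, 1500),
                               noise_sd = 0, blur_sigma = 0, ...) {
  scene_config(grid_shape = grid, voxel_size = c(1, 1, 2),
               n_aggregates = n_aggregates, n_planktonic = n_planktonic,
               touching_pair_fraction = touching, volume_range = vr,
               noise_sd = noise_sd, blur_sigma = blur_sigma,
               depth_attenuation = 0, rng_seed = seed, ...)
}
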