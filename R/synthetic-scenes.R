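#' Synthetic scene configuration
#'
#' Describes a simulated confocal acquisition of a liquid-phase bacterial
#' culture: bright, roughly convex aggregates (rendered as solid
#' ellipsoids), dim planktonic single cells, a uniform background, optical
#' blur, linear depth attenuation, and additive Gaussian and/or Poisson
#' noise. A controllable fraction of aggregates is placed in abutting
#' pairs whose merged 2D footprints are non-convex dumbbells — the fixture
#' that exercises convexity-driven bisection.
#'
#' All geometry is specified in micrometers; placement is done in physical
#' coordinates, so the same seed reproduces the same physical scene at any
#' voxel resolution.
#'
#' @param grid_shape integer `(ny, nx, nz)` voxel counts.
#' @param voxel_size `(dx, dy, dz)` in um.
#' @param n_aggregates number of aggregates to place.
#' @param volume_distribution list with `name = "lognormal"`, `meanlog`,
#'   `sdlog`; aggregate volumes in um^3 (in 2D mosaic mode the same
#'   parameters are read as cross-sectional areas in um^2). The default is
#'   a stand-in for real aggregate size spectra, not a measured
#'   distribution.
#' @param volume_range optional `(lo, hi)` truncation for sampled volumes
#'   (resampling), um^3.
#' @param aspect_ratio_range `(lo, hi)` for the two ellipsoid axis ratios;
#'   `(1, 1)` gives spheres.
#' @param touching_pair_fraction fraction in `[0, 1]` of aggregates placed
#'   in contact with a partner (rounded down to whole pairs).
#' @param n_planktonic number of single-cell-sized blobs (radius 0.8 um).
#' @param aggregate_intensity,planktonic_intensity,background_level mean
#'   intensity levels (arbitrary units); must be strictly decreasing in
#'   that order.
#' @param noise_sd additive Gaussian noise standard deviation (0 = none).
#' @param poisson_noise logical; replace intensities by Poisson draws
#'   before Gaussian noise.
#' @param blur_sigma isotropic Gaussian blur sigma in um (0 = none).
#' @param depth_attenuation fractional intensity loss per um of depth
#'   (0 = none); plane 1 sits at the coverslip and is unattenuated.
#' @param rng_seed integer seed; identical config + seed gives
#'   bit-identical scenes.
#' @return an object of class `scene_config`.
#' @seealso [scene_preset()], [generate_scene()], [generate_mosaic()]
#' @export
scene_config <- function(grid_shape = c(256L, 256L, 25L),
                         voxel_size = c(1, 1, 2),
                         n_aggregates = 15L,
                         volume_distribution = list(name = "lognormal",
                                                    meanlog = log(1000),
                                                    sdlog = 0.5),
                         volume_range = NULL,
                         aspect_ratio_range = c(1, 1.5),
                         touching_pair_fraction = 0,
                         n_planktonic = 50L,
                         aggregate_intensity = 120,
                         planktonic_intensity = 60,
                         background_level = 20,
                         noise_sd = 10,
                         poisson_noise = FALSE,
                         blur_sigma = 0.5,
                         depth_attenuation = 0.001,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive voxel counts (ny, nx, nz)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive um values", call. = FALSE)
  if (background_level < 0 || planktonic_intensity < 0 || aggregate_intensity < 0)
    stop("intensities must be >= 0", call. = FALSE)
  if (!(aggregate_intensity > planktonic_intensity &&
        planktonic_intensity > background_level))
    stop("require aggregate_intensity > planktonic_intensity > background_level",
         call. = FALSE)
  if (touching_pair_fraction < 0 || touching_pair_fraction > 1)
    stop("touching_pair_fraction must be in [0, 1]", call. = FALSE)
  if (n_aggregates < 0 || n_planktonic < 0)
    stop("object counts must be >= 0", call. = FALSE)
  if (noise_sd < 0 || blur_sigma < 0 || depth_attenuation < 0)
    stop("noise_sd, blur_sigma and depth_attenuation must be >= 0", call. = FALSE)
  if (!is.list(volume_distribution) ||
      !identical(volume_distribution$name, "lognormal"))
    stop("volume_distribution must be list(name = 'lognormal', meanlog, sdlog)",
         call. = FALSE)
  if (!is.null(volume_range) &&
      (length(volume_range) != 2L || volume_range[1] > volume_range[2]))
    stop("volume_range must be (lo, hi)", call. = FALSE)
  if (aspect_ratio_range[1] < 1 || aspect_ratio_range[2] < aspect_ratio_range[1])
    stop("aspect_ratio_range must satisfy 1 <= lo <= hi", call. = FALSE)
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 n_aggregates = as.integer(n_aggregates),
                 volume_distribution = volume_distribution,
                 volume_range = volume_range,
                 aspect_ratio_range = as.numeric(aspect_ratio_range),
                 touching_pair_fraction = touching_pair_fraction,
                 n_planktonic = as.integer(n_planktonic),
                 aggregate_intensity = aggregate_intensity,
                 planktonic_intensity = planktonic_intensity,
                 background_level = background_level,
                 noise_sd = noise_sd, poisson_noise = isTRUE(poisson_noise),
                 blur_sigma = blur_sigma,
                 depth_attenuation = depth_attenuation,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Imaging-regime presets for the synthetic generator
#'
#' `"10x"` emulates a low-magnification aggregate acquisition: 2048 x 2048
#' pixels over a 1163 x 1163 um field (0.568 um/px) with 50 planes at a
#' 2 um step. `"63x"` emulates the high-magnification cluster regime:
#' 1984 x 1984 px at 1 um/px with 50 planes at a 1 um step. `"small"` is a
#' fast 256 x 256 x 25 grid at (1, 1, 2) um for tests and examples.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [scene_config()].
#' @return a `scene_config`.
#' @export
scene_preset <- function(name = c("small", "10x", "63x"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "small" = list(grid_shape = c(256L, 256L, 25L), voxel_size = c(1, 1, 2)),
    "10x" = list(grid_shape = c(2048L, 2048L, 50L),
                 voxel_size = c(0.568, 0.568, 2), n_aggregates = 60L,
                 n_planktonic = 2000L),
    "63x" = list(grid_shape = c(1984L, 1984L, 50L), voxel_size = c(1, 1, 1),
                 n_aggregates = 80L,
                 volume_distribution = list(name = "lognormal",
                                            meanlog = log(150), sdlog = 0.5),
                 n_planktonic = 2000L))
  do.call(scene_config, utils::modifyList(base, list(...)))
}

# sample truncated lognormal volumes
.sample_volumes <- function(n, dist, range) {
  if (n == 0L) return(numeric(0))
  v <- rlnorm(n, dist$meanlog, dist$sdlog)
  if (!is.null(range)) {
    for (i in seq_len(1000)) {
      bad <- v < range[1] | v > range[2]
      if (!any(bad)) break
      v[bad] <- rlnorm(sum(bad), dist$meanlog, dist$sdlog)
    }
    if (any(v < range[1] | v > range[2]))
      stop("could not sample volumes inside volume_range; widen volume_range ",
           "or adjust volume_distribution", call. = FALSE)
  }
  v
}

# semi-axes (ax, ay, az) um for an ellipsoid of given volume
.sample_semiaxes <- function(volume, ar_range) {
  q <- runif(2, ar_range[1], ar_range[2])
  s <- sample(c(1, q))
  s <- s / prod(s)^(1 / 3)
  r0 <- (3 * volume / (4 * pi))^(1 / 3)
  r0 * s
}

# do physical bounding boxes (rows: lo/hi per axis) intersect?
.bbox_overlap <- function(lo1, hi1, lo2, hi2) {
  all(lo1 <= hi2 & lo2 <= hi1)
}

# voxel indices (linear) whose centers fall inside an ellipsoid
.ellipsoid_voxels <- function(center, semi, grid, vox) {
  rng <- lapply(1:3, function(k) {
    axk <- c(2, 1, 3)[k]  # center/semi are (x, y, z); grid is (ny, nx, nz)
    lo <- max(1L, floor((center[k] - semi[k]) / vox[k] + 0.5))
    hi <- min(grid[axk], ceiling((center[k] + semi[k]) / vox[k] + 0.5))
    if (lo > hi) integer(0) else lo:hi
  })
  ix <- rng[[1]]; iy <- rng[[2]]; iz <- rng[[3]]
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  xs <- ((ix - 0.5) * vox[1] - center[1]) / semi[1]
  ys <- ((iy - 0.5) * vox[2] - center[2]) / semi[2]
  zs <- ((iz - 0.5) * vox[3] - center[3]) / semi[3]
  m <- outer(ys^2, xs^2, "+")
  keep <- outer(m, zs^2, "+") <= 1          # (ny', nx', nz')
  if (!any(keep)) return(integer(0))
  idx <- which(keep, arr.ind = TRUE)
  (iy[idx[, 1]]) + (ix[idx[, 2]] - 1L) * grid[1] +
    (iz[idx[, 3]] - 1L) * grid[1] * grid[2]
}

# are two linear-index voxel sets 6-connected (face) adjacent?
.face_adjacent <- function(a, b, grid) {
  if (!length(a) || !length(b)) return(FALSE)
  ny <- grid[1]; nplane <- grid[1] * grid[2]
  for (off in c(1L, -1L, ny, -ny, nplane, -nplane))
    if (any((a + off) %in% b)) return(TRUE)
  FALSE
}

#' Generate a seeded synthetic z-stack with ground truth
#'
#' Places ellipsoidal aggregates (and abutting pairs), planktonic blobs,
#' renders intensities, then applies blur, depth attenuation and noise.
#' Ground-truth labels record the pre-blur, pre-noise voxel memberships.
#' Placement uses rejection sampling in physical coordinates with a 3 um
#' clearance between distinct (non-partner) objects, so non-touching
#' objects can never share or abut voxels.
#'
#' @param config a [scene_config()].
#' @return a list of class `scene` with elements `stack` (an
#'   [image_stack()]) and `truth` (class `scene_truth`: `objects` table and
#'   integer `label_volume`).
#' @examples
#' sc <- generate_scene(scene_config(grid_shape = c(64, 64, 10),
#'                                   n_aggregates = 2, n_planktonic = 5,
#'                                   volume_range = c(200, 500)))
#' sc$truth$objects
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$rng_seed, .generate_scene_impl(config))
}

.generate_scene_impl <- function(cfg) {
  grid <- cfg$grid_shape; vox <- cfg$voxel_size
  L <- c(grid[2] * vox[1], grid[1] * vox[2], grid[3] * vox[3])  # (Lx, Ly, Lz)
  clearance <- 3  # um between non-partner objects
  n_pairs <- floor(cfg$n_aggregates * cfg$touching_pair_fraction / 2)
  n_single <- cfg$n_aggregates - 2L * n_pairs

  vols <- .sample_volumes(cfg$n_aggregates, cfg$volume_distribution,
                          cfg$volume_range)
  objs <- list()           # per object: center (x,y,z), semi (x,y,z), class
  boxes_lo <- list(); boxes_hi <- list()
  add_box <- function(center, semi, pad) {
    boxes_lo[[length(boxes_lo) + 1L]] <<- center - semi - pad
    boxes_hi[[length(boxes_hi) + 1L]] <<- center + semi + pad
  }
  clash <- function(lo, hi) {
    for (i in seq_along(boxes_lo))
      if (.bbox_overlap(lo, hi, boxes_lo[[i]], boxes_hi[[i]])) return(TRUE)
    FALSE
  }
  sample_center <- function(semi, extra_lo = c(0, 0, 0), extra_hi = c(0, 0, 0)) {
    lo <- semi + vox + extra_lo
    hi <- L - semi - vox - extra_hi
    if (any(lo > hi)) return(NULL)
    c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
  }

  vi <- 1L
  # abutting pairs first: partner shares the anchor's z center and abuts
  # along a lateral axis, so the contact plane is constant in z and the
  # merged footprint there is a dumbbell
  for (p in seq_len(n_pairs)) {
    va <- vols[vi]; vp <- vols[vi + 1L] * runif(1, 0.7, 1)
    sa <- .sample_semiaxes(va, cfg$aspect_ratio_range)
    sp <- .sample_semiaxes(vp, cfg$aspect_ratio_range)
    axis <- sample(1:2, 1)                 # abut along x or y
    sgn <- sample(c(-1, 1), 1)
    delta <- vox[axis] / 2                 # initial interpenetration
    placed <- FALSE
    for (try in seq_len(200)) {
      extra <- c(0, 0, 0)
      extra[axis] <- sa[axis] + 2 * sp[axis]
      ca <- if (sgn > 0) sample_center(sa, extra_hi = extra)
            else sample_center(sa, extra_lo = extra)
      if (is.null(ca)) break
      cp <- ca
      cp[axis] <- ca[axis] + sgn * (sa[axis] + sp[axis] - delta)
      half <- clearance / 2
      lo <- pmin(ca - sa, cp - sp) - half; hi <- pmax(ca + sa, cp + sp) + half
      if (clash(lo, hi)) next
      objs[[length(objs) + 1L]] <- list(center = ca, semi = sa,
                                        class = "aggregate",
                                        partner = length(objs) + 2L,
                                        pair_axis = axis, pair_sgn = sgn,
                                        analytic = 4 / 3 * pi * prod(sa))
      objs[[length(objs) + 1L]] <- list(center = cp, semi = sp,
                                        class = "aggregate",
                                        partner = length(objs),
                                        pair_axis = axis, pair_sgn = sgn,
                                        analytic = 4 / 3 * pi * prod(sp))
      add_box(ca, sa, clearance / 2); add_box(cp, sp, clearance / 2)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place touching pair ", p, " after 200 tries; reduce ",
           "n_aggregates or volume_distribution scale, or enlarge grid_shape",
           call. = FALSE)
    vi <- vi + 2L
  }
  for (s in seq_len(n_single)) {
    semi <- .sample_semiaxes(vols[vi], cfg$aspect_ratio_range)
    placed <- FALSE
    for (try in seq_len(200)) {
      ctr <- sample_center(semi)
      if (is.null(ctr)) break
      lo <- ctr - semi - clearance / 2; hi <- ctr + semi + clearance / 2
      if (clash(lo, hi)) next
      objs[[length(objs) + 1L]] <- list(center = ctr, semi = semi,
                                        class = "aggregate", partner = NA,
                                        analytic = 4 / 3 * pi * prod(semi))
      add_box(ctr, semi, clearance / 2)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place aggregate ", s, " after 200 tries; reduce ",
           "n_aggregates or volume_distribution scale, or enlarge grid_shape",
         call. = FALSE)
    vi <- vi + 1L
  }
  r_cell <- 0.8  # um; a single bacterium rendered as a small sphere
  for (s in seq_len(cfg$n_planktonic)) {
    semi <- rep(r_cell, 3)
    placed <- FALSE
    for (try in seq_len(200)) {
      ctr <- sample_center(semi)
      if (is.null(ctr)) break
      if (clash(ctr - semi, ctr + semi)) next
      objs[[length(objs) + 1L]] <- list(center = ctr, semi = semi,
                                        class = "planktonic", partner = NA,
                                        analytic = 4 / 3 * pi * prod(semi))
      add_box(ctr, semi, 0)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place planktonic cell ", s, "; reduce n_planktonic ",
           "or enlarge grid_shape", call. = FALSE)
  }

  # voxelize in placement order; keep-first assignment carves the small
  # designed interpenetration out of the pair partner
  lab <- array(0L, grid)
  voxsets <- vector("list", length(objs))
  for (i in seq_along(objs)) {
    o <- objs[[i]]
    idx <- .ellipsoid_voxels(o$center, o$semi, grid, vox)
    idx <- idx[lab[idx] == 0L]
    if (!length(idx)) {
      # guarantee every object owns at least the voxel containing its center
      ctr_idx <- min(max(1L, round(o$center[2] / vox[2] + 0.5)), grid[1]) +
        (min(max(1L, round(o$center[1] / vox[1] + 0.5)), grid[2]) - 1L) * grid[1] +
        (min(max(1L, round(o$center[3] / vox[3] + 0.5)), grid[3]) - 1L) *
          grid[1] * grid[2]
      if (lab[ctr_idx] == 0L) idx <- ctr_idx
    }
    lab[idx] <- i
    voxsets[[i]] <- idx
    # pull a pair partner closer until the carved sets share a face
    if (!is.na(o$partner) && o$partner < i) {
      a <- voxsets[[o$partner]]
      for (nudge in seq_len(6)) {
        if (.face_adjacent(a, voxsets[[i]], grid)) break
        lab[voxsets[[i]]] <- 0L
        o$center[o$pair_axis] <- o$center[o$pair_axis] -
          o$pair_sgn * vox[o$pair_axis] / 2
        idx <- .ellipsoid_voxels(o$center, o$semi, grid, vox)
        idx <- idx[lab[idx] == 0L]
        lab[idx] <- i
        voxsets[[i]] <- idx
        objs[[i]] <- o
      }
    }
  }

  classes <- vapply(objs, `[[`, "", "class")
  img <- array(cfg$background_level, grid)
  for (i in seq_along(objs))
    img[voxsets[[i]]] <- if (classes[i] == "aggregate")
      cfg$aggregate_intensity else cfg$planktonic_intensity

  if (cfg$blur_sigma > 0)
    img <- .gaussian_blur_3d(img, cfg$blur_sigma / vox[c(2, 1, 3)])
  if (cfg$depth_attenuation > 0) {
    zf <- pmax(0, 1 - cfg$depth_attenuation * ((seq_len(grid[3]) - 1) * vox[3]))
    img <- sweep(img, 3, zf, "*")
  }
  if (cfg$poisson_noise)
    img <- array(rpois(length(img), lambda = img), grid)
  if (cfg$noise_sd > 0)
    img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img <- pmax(img, 0)

  vvol <- prod(vox)
  objects <- data.frame(
    id = seq_along(objs),
    class = classes,
    center_x_um = vapply(objs, function(o) o$center[1], 0),
    center_y_um = vapply(objs, function(o) o$center[2], 0),
    center_z_um = vapply(objs, function(o) o$center[3], 0),
    semi_x_um = vapply(objs, function(o) o$semi[1], 0),
    semi_y_um = vapply(objs, function(o) o$semi[2], 0),
    semi_z_um = vapply(objs, function(o) o$semi[3], 0),
    volume_analytic_um3 = vapply(objs, `[[`, 0, "analytic"),
    voxel_count = vapply(voxsets, length, 0L),
    volume_voxel_um3 = vapply(voxsets, length, 0L) * vvol,
    touching_partner = vapply(objs, function(o)
      if (is.na(o$partner)) NA_integer_ else as.integer(o$partner), 0L))

  truth <- structure(list(objects = objects, label_volume = lab,
                          voxel_size = vox), class = "scene_truth")
  structure(list(stack = image_stack(img, vox), truth = truth,
                 config = cfg), class = "scene")
}

# separable Gaussian blur; sigma in voxels per array dimension (y, x, z)
.gaussian_blur_3d <- function(arr, sigma) {
  d <- dim(arr)
  kernel_mat <- function(n, s) {
    if (s < 0.05) return(NULL)
    r <- ceiling(3 * s)
    off <- -r:r
    w <- exp(-off^2 / (2 * s^2))
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + off
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- w[ok] / sum(w[ok])
    }
    K
  }
  K1 <- kernel_mat(d[1], sigma[1])
  if (!is.null(K1)) arr <- array(K1 %*% matrix(arr, d[1]), d)
  K2 <- kernel_mat(d[2], sigma[2])
  if (!is.null(K2)) {
    arr <- aperm(arr, c(2, 1, 3))
    arr <- aperm(array(K2 %*% matrix(arr, d[2]), d[c(2, 1, 3)]), c(2, 1, 3))
  }
  K3 <- kernel_mat(d[3], sigma[3])
  if (!is.null(K3)) {
    arr <- aperm(arr, c(3, 1, 2))
    arr <- aperm(array(K3 %*% matrix(arr, d[3]), d[c(3, 1, 2)]), c(2, 3, 1))
  }
  arr
}

#' @export
print.scene <- function(x, ...) {
  tab <- table(x$truth$objects$class)
  cat(sprintf("<scene> %s aggregates, %s planktonic cells\n",
              if ("aggregate" %in% names(tab)) tab[["aggregate"]] else 0,
              if ("planktonic" %in% names(tab)) tab[["planktonic"]] else 0))
  print(x$stack)
  invisible(x)
}

#' Signal-to-noise estimate of a rendered scene
#'
#' Contrast-to-noise of aggregate voxels against background:
#' `(mean(foreground) - mean(background)) / sd(background)`, using the
#' ground-truth labels to locate each compartment.
#'
#' @param scene a `scene` from [generate_scene()].
#' @return a single number; larger is cleaner.
#' @export
estimate_snr <- function(scene) {
  stopifnot(inherits(scene, "scene"))
  lab <- scene$truth$label_volume
  agg_ids <- scene$truth$objects$id[scene$truth$objects$class == "aggregate"]
  fg <- scene$stack$data[lab %in% agg_ids]
  bg <- scene$stack$data[lab == 0L]
  (mean(fg) - mean(bg)) / sd(bg)
}

#' Generate a seeded 2D mosaic scene cut into tiles
#'
#' Renders a single full-well 2D image (disk-shaped aggregates and
#' planktonic cells; sizes drawn from `volume_distribution` read in um^2)
#' and partitions it row-major into non-overlapping tiles, emulating a
#' tile-scanned acquisition. Re-assembling the tiles reproduces the full
#' image exactly.
#'
#' @param config a [scene_config()]; only the first two entries of
#'   `grid_shape` are used, and `voxel_size[1]` must equal `voxel_size[2]`.
#' @param tiles integer `(rows, cols)`; must divide the image shape.
#' @return list of class `mosaic_scene`: `tiles` (row-major list of
#'   matrices), `full` (the full image), `truth` (`objects` table and
#'   `label_image`), `pixel_size`, `layout`.
#' @export
generate_mosaic <- function(config, tiles = c(2L, 2L)) {
  stopifnot(inherits(config, "scene_config"))
  tiles <- as.integer(tiles)
  if (length(tiles) != 2L || any(tiles < 1L))
    stop("tiles must be positive (rows, cols)", call. = FALSE)
  ny <- config$grid_shape[1]; nx <- config$grid_shape[2]
  if (ny %% tiles[1] != 0L || nx %% tiles[2] != 0L)
    stop("tile grid ", tiles[1], "x", tiles[2], " does not divide the ",
         ny, "x", nx, " image", call. = FALSE)
  if (abs(config$voxel_size[1] - config$voxel_size[2]) > 1e-12)
    stop("mosaic mode requires square pixels (dx == dy)", call. = FALSE)
  withr::with_seed(config$rng_seed, .generate_mosaic_impl(config, tiles))
}

.generate_mosaic_impl <- function(cfg, tiles) {
  ny <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]; px <- cfg$voxel_size[1]
  L <- c(nx * px, ny * px)
  clearance <- 3
  areas <- .sample_volumes(cfg$n_aggregates, cfg$volume_distribution,
                           cfg$volume_range)
  radii <- sqrt(areas / pi)
  lab <- matrix(0L, ny, nx)
  boxes <- list()
  objects <- list()
  place_disk <- function(r, class, id) {
    for (try in seq_len(200)) {
      lo <- r + px; hix <- L[1] - r - px; hiy <- L[2] - r - px
      if (lo > hix || lo > hiy) return(FALSE)
      ctr <- c(runif(1, lo, hix), runif(1, lo, hiy))
      box <- c(ctr - r - clearance / 2, ctr + r + clearance / 2)
      ok <- TRUE
      for (b in boxes)
        if (all(box[1:2] <= b[3:4] & b[1:2] <= box[3:4])) { ok <- FALSE; break }
      if (!ok) next
      ix <- max(1L, floor((ctr[1] - r) / px)):min(nx, ceiling((ctr[1] + r) / px + 1))
      iy <- max(1L, floor((ctr[2] - r) / px)):min(ny, ceiling((ctr[2] + r) / px + 1))
      xs <- (ix - 0.5) * px - ctr[1]; ys <- (iy - 0.5) * px - ctr[2]
      m <- outer(ys^2, xs^2, "+") <= r^2
      sel <- which(m, arr.ind = TRUE)
      if (nrow(sel)) {
        lin <- iy[sel[, 1]] + (ix[sel[, 2]] - 1L) * ny
        lin <- lin[lab[lin] == 0L]
        lab[lin] <<- id
        npx <- length(lin)
      } else npx <- 0L
      boxes[[length(boxes) + 1L]] <<- box
      objects[[id]] <<- data.frame(id = id, class = class,
                                   center_x_um = ctr[1], center_y_um = ctr[2],
                                   radius_um = r, area_analytic_um2 = pi * r^2,
                                   pixel_count = npx,
                                   area_pixel_um2 = npx * px^2)
      return(TRUE)
    }
    FALSE
  }
  id <- 0L
  for (i in seq_len(cfg$n_aggregates)) {
    id <- id + 1L
    if (!place_disk(radii[i], "aggregate", id))
      stop("could not place mosaic aggregate ", i, "; reduce n_aggregates or ",
           "volume_distribution scale, or enlarge grid_shape", call. = FALSE)
  }
  for (i in seq_len(cfg$n_planktonic)) {
    id <- id + 1L
    if (!place_disk(0.8, "planktonic", id))
      stop("could not place mosaic planktonic cell ", i, call. = FALSE)
  }
  img <- matrix(cfg$background_level, ny, nx)
  agg_ids <- which(vapply(objects, function(o) o$class == "aggregate", TRUE))
  img[lab %in% agg_ids] <- cfg$aggregate_intensity
  img[lab > 0L & !(lab %in% agg_ids)] <- cfg$planktonic_intensity
  if (cfg$blur_sigma > 0) {
    arr <- .gaussian_blur_3d(array(img, c(ny, nx, 1L)),
                             c(cfg$blur_sigma / px, cfg$blur_sigma / px, 0))
    img <- arr[, , 1]
  }
  if (cfg$poisson_noise) img <- matrix(rpois(length(img), img), ny, nx)
  if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img <- pmax(img, 0)
  th <- ny / tiles[1]; tw <- nx / tiles[2]
  tl <- list()
  for (r in seq_len(tiles[1]))
    for (cc in seq_len(tiles[2]))
      tl[[length(tl) + 1L]] <- img[((r - 1) * th + 1):(r * th),
                                   ((cc - 1) * tw + 1):(cc * tw)]
  structure(list(tiles = tl, full = img,
                 truth = list(objects = do.call(rbind, objects),
                              label_image = lab),
                 pixel_size = px, layout = tiles),
            class = "mosaic_scene")
}

#' Write a scene to disk
#'
#' Writes the intensity stack (16-bit TIFF + geometry sidecar), the truth
#' label volume (32-bit TIFF) and the truth object table (CSV).
#'
#' @param scene a `scene`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_stack(scene$stack, file.path(dir, "stack.tif"))
  write_labels(scene$truth$label_volume, file.path(dir, "truth_labels.tif"))
  write.csv(scene$truth$objects, file.path(dir, "truth_objects.csv"),
            row.names = FALSE)
  invisible(dir)
}
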