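#' Threshold one z-plane of a stack
#'
#' A single global intensity threshold is applied to every plane; there is
#' deliberately no per-plane or local adaptation, so a segmentation is a
#' pure function of the stack and the configured threshold.
#'
#' @param stack an [image_stack()].
#' @param z plane index, `1 <= z <= n_planes(stack)`.
#' @param threshold intensity; pixels with intensity `>= threshold` are
#'   foreground.
#' @return logical `(ny, nx)` mask.
#' @export
threshold_plane <- function(stack, z, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  if (z < 1 || z > n_planes(stack)) stop("plane index out of range", call. = FALSE)
  stack$data[, , z] >= threshold
}

#' Label connected components of a binary mask
#'
#' Maximal connected components under 4- or 8-connectivity. Labels are
#' assigned in raster-scan order of each component's first pixel, so the
#' labeling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, standard for bright blobs).
#' @return integer matrix of labels; 0 is background.
#' @export
label_plane <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  cc_label_cpp(mask, as.integer(connectivity))
}

# pixel coordinate matrix (y, x) of a label, in raster order
.label_coords <- function(labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  colnames(idx) <- c("y", "x")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Rasterized convex hull of a pixel set
#'
#' Pixels whose centers lie inside (or on) the convex hull of the input
#' pixel centers, computed by scanline filling of the hull polygon. The
#' result always contains the input pixels. Degenerate (collinear) sets
#' are returned unchanged.
#'
#' @param coords integer matrix `(n, 2)` of (y, x) pixel coordinates.
#' @return integer matrix of hull pixel coordinates.
#' @export
convex_hull_pixels <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) return(coords)
  h <- chull(coords[, 2], coords[, 1])
  hv <- coords[h, , drop = FALSE]
  if (nrow(hv) < 3L) return(coords)     # collinear
  ys <- hv[, 1]; xs <- hv[, 2]
  # signed polygon area; zero means collinear vertices
  n <- nrow(hv)
  j <- c(2:n, 1)
  if (abs(sum(xs * ys[j] - xs[j] * ys)) < 1e-9) return(coords)
  eps <- 1e-7
  rows <- vector("list", max(ys) - min(ys) + 1L)
  for (k in seq_along(rows)) {
    y <- min(ys) + k - 1L
    xint <- numeric(0)
    for (i in seq_len(n)) {
      y1 <- ys[i]; y2 <- ys[j[i]]; x1 <- xs[i]; x2 <- xs[j[i]]
      if (y1 == y2) {
        if (y == y1) xint <- c(xint, x1, x2)
      } else if (y >= min(y1, y2) - eps && y <= max(y1, y2) + eps) {
        xint <- c(xint, x1 + (y - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    if (!length(xint)) next
    xr <- ceiling(min(xint) - eps):floor(max(xint) + eps)
    if (length(xr)) rows[[k]] <- cbind(y = y, x = xr)
  }
  do.call(rbind, rows)
}

#' Convexity-deviation score of a 2D object
#'
#' Flags merged (under-segmented) objects by how far they fall short of
#' their own convex hull. The default score is the root mean square of the
#' per-hull-pixel deficit indicator: with object area `A` and rasterized
#' convex-hull area `H` (both in pixels),
#' `score = sqrt((H - A) / H) = sqrt(1 - solidity)`. It is 0 exactly for
#' objects that fill their hull and is comparable across object sizes.
#' `method = "raw_deficit"` instead returns `H - A` in pixels, an
#' unnormalized variant of the same idea. Degenerate objects (fewer than 3
#' pixels, or collinear) score 0 by convention.
#'
#' @param coords integer matrix `(n, 2)` of (y, x) pixel coordinates.
#' @param method `"deficit_fraction"` (default) or `"raw_deficit"`.
#' @return non-negative scalar.
#' @export
score_convexity <- function(coords, method = c("deficit_fraction", "raw_deficit")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  A <- nrow(coords)
  if (A < 3L) return(0)
  hull <- convex_hull_pixels(coords)
  H <- nrow(hull)
  if (H <= A) return(0)
  if (method == "raw_deficit") H - A else sqrt((H - A) / H)
}

# quadrant membership of each boundary pixel relative to the centroid.
# frame = "image": quadrants bounded by axis-aligned lines through the
# centroid; "principal": same after rotating into the object's principal
# axes. Membership is band-inclusive: a pixel within half a pixel of a
# dividing line belongs to both adjacent quadrants, so a neck lying
# exactly on a centroid axis still yields opposite-quadrant endpoints.
# Returns an (n, 4) logical matrix; opposite pairs are (1, 3) and (2, 4).
.quadrants <- function(coords, centroid, frame = "image") {
  dy <- coords[, 1] - centroid[1]
  dx <- coords[, 2] - centroid[2]
  if (frame == "principal") {
    cv <- cbind(dy, dx)
    ev <- eigen(stats::cov(cv) + diag(1e-9, 2), symmetric = TRUE)$vectors
    rot <- cv %*% ev
    dy <- rot[, 1]; dx <- rot[, 2]
  }
  cbind(q1 = dx >= -0.5 & dy <= 0.5,   # upper right
        q2 = dx <= 0.5 & dy <= 0.5,    # upper left
        q3 = dx <= 0.5 & dy >= -0.5,   # lower left
        q4 = dx >= -0.5 & dy >= -0.5)  # lower right
}

# boundary pixels: object pixels with at least one 4-neighbour outside
.boundary_pixels <- function(coords, ny, nx) {
  key <- coords[, 1] + (coords[, 2] - 1L) * ny
  inside <- logical(ny * nx)
  inside[key] <- TRUE
  on_edge <- coords[, 1] == 1L | coords[, 1] == ny |
             coords[, 2] == 1L | coords[, 2] == nx
  nb <- rep(TRUE, nrow(coords))
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    yy <- coords[, 1] + off[1]; xx <- coords[, 2] + off[2]
    valid <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    has <- valid & inside[pmin(pmax(yy, 1L), ny) + (pmin(pmax(xx, 1L), nx) - 1L) * ny]
    nb <- nb & has
  }
  coords[!nb | on_edge, , drop = FALSE]
}

#' Bisect an under-segmented 2D object along its shortest cross-quadrant chord
#'
#' Implements the splitting heuristic for touching aggregates: boundary
#' pixels are assigned to quadrants around the object centroid (membership
#' is band-inclusive within half a pixel of the dividing lines, so a neck
#' lying exactly on a centroid axis still spans quadrants). Candidate cuts
#' are straight pixel chords between boundary pixels that span different
#' quadrants — the chord crosses at least one centroid axis, which is what
#' carries it through the neck of a merged pair rather than along an edge.
#' A candidate is valid when its 8-connected rasterization lies entirely
#' inside the object and removing its pixels bisects the object into
#' exactly two discrete components, each of at least 6 pixels (rejecting
#' degenerate corner shaves). The shortest valid chord (ties broken by
#' raster order of the endpoints) is applied; each child whose convexity
#' deviation still exceeds the cutoff is split again, up to
#' `max_iterations` levels. An object with no valid chord is returned
#' unchanged.
#'
#' @param coords integer matrix `(n, 2)` of (y, x) pixel coordinates.
#' @param ny,nx dimensions of the parent plane.
#' @param rmsd_cutoff convexity-deviation cutoff (see [score_convexity()]).
#' @param max_iterations recursion depth; 0 disables splitting.
#' @param connectivity connectivity used to relabel the remainder.
#' @param method convexity score variant.
#' @param frame quadrant frame, `"image"` or `"principal"`.
#' @return list with `pieces` (list of coordinate matrices) and `cuts`
#'   (data.frame of chord endpoints and removed pixel counts; the removed
#'   chord pixels are accounted for there, never silently dropped).
#' @export
bisect_object <- function(coords, ny, nx, rmsd_cutoff = sqrt(0.1),
                          max_iterations = 3L, connectivity = 8L,
                          method = "deficit_fraction", frame = "image") {
  coords <- as.matrix(coords)
  cuts <- list()
  recurse <- function(cc, depth) {
    if (depth <= 0L || nrow(cc) < 6L) return(list(cc))
    if (score_convexity(cc, method) <= rmsd_cutoff) return(list(cc))
    # work on the tight bounding box: boundary status and connectivity of
    # the object are unchanged, and the chord search stays cheap
    ylo <- min(cc[, 1]); xlo <- min(cc[, 2])
    cs <- cbind(cc[, 1] - ylo + 1L, cc[, 2] - xlo + 1L)
    nys <- max(cs[, 1]); nxs <- max(cs[, 2])
    centroid <- c(mean(cs[, 1]), mean(cs[, 2]))
    bnd <- .boundary_pixels(cs, nys, nxs)
    q <- .quadrants(bnd, centroid, frame)
    mask <- matrix(FALSE, nys, nxs)
    mask[cs] <- TRUE
    best <- shortest_cut_cpp(mask, bnd, q, as.integer(connectivity))
    if (!isTRUE(best$found)) return(list(cc))
    cut_px <- best$pixels
    mask[cut_px] <- FALSE
    lab <- cc_label_cpp(mask, as.integer(connectivity))
    ids <- seq_len(max(lab))
    if (length(ids) != 2L) return(list(cc))
    cuts[[length(cuts) + 1L]] <<- data.frame(
      y0 = best$y0 + ylo - 1L, x0 = best$x0 + xlo - 1L,
      y1 = best$y1 + ylo - 1L, x1 = best$x1 + xlo - 1L,
      length_px = best$length, n_cut_pixels = nrow(cut_px))
    children <- lapply(ids, function(i) {
      ch <- .label_coords(lab, i)
      cbind(ch[, 1] + ylo - 1L, ch[, 2] + xlo - 1L)
    })
    out <- list()
    for (ch in children) out <- c(out, recurse(ch, depth - 1L))
    out
  }
  pieces <- recurse(coords, as.integer(max_iterations))
  list(pieces = pieces,
       cuts = if (length(cuts)) do.call(rbind, cuts)
              else data.frame(y0 = integer(0), x0 = integer(0),
                              y1 = integer(0), x1 = integer(0),
                              length_px = numeric(0), n_cut_pixels = integer(0)))
}

#' Segment every plane of a stack in 2D
#'
#' For each z-plane: global threshold, connected-component labeling,
#' convexity scoring, and bisection of objects exceeding the cutoff. No
#' size filtering happens here; size cutoffs are applied in 3D after
#' reconstruction. Final labels per plane are renumbered in raster order
#' of each object's first pixel.
#'
#' @param stack an [image_stack()].
#' @param cfg a [run_config()].
#' @return list of class `plane_labels`: `planes` (list of integer label
#'   matrices) and `cuts` (data.frame of applied chords, with plane index).
#' @export
segment_planes <- function(stack, cfg) {
  stopifnot(inherits(stack, "image_stack"), inherits(cfg, "run_config"))
  d <- dim(stack$data)
  planes <- vector("list", d[3])
  all_cuts <- list()
  for (z in seq_len(d[3])) {
    mask <- threshold_plane(stack, z, cfg$intensity_threshold)
    lab <- label_plane(mask, cfg$connectivity_2d)
    k <- max(lab)
    if (k > 0L && cfg$split && cfg$split_max_iterations > 0L) {
      pieces <- list()
      for (i in seq_len(k)) {
        cc <- .label_coords(lab, i)
        bi <- bisect_object(cc, d[1], d[2], cfg$rmsd_cutoff,
                            cfg$split_max_iterations, cfg$connectivity_2d,
                            cfg$convexity_method, cfg$quadrant_frame)
        pieces <- c(pieces, bi$pieces)
        if (nrow(bi$cuts)) all_cuts[[length(all_cuts) + 1L]] <-
            cbind(z = z, bi$cuts)
      }
      # rebuild plane labels, ordered by raster position of first pixel
      first <- vapply(pieces, function(p) p[1, 1] + (p[1, 2] - 1) * d[1], 0)
      pieces <- pieces[order(first)]
      lab <- matrix(0L, d[1], d[2])
      for (i in seq_along(pieces)) lab[pieces[[i]]] <- i
    }
    planes[[z]] <- lab
  }
  structure(list(planes = planes,
                 cuts = if (length(all_cuts)) do.call(rbind, all_cuts)
                        else data.frame(z = integer(0), y0 = integer(0),
                                        x0 = integer(0), y1 = integer(0),
                                        x1 = integer(0), length_px = numeric(0),
                                        n_cut_pixels = integer(0))),
            class = "plane_labels")
}
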