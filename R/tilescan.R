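#' Assemble tile-scanned images into a full-well mosaic
#'
#' Tiles are abutted row-major (left to right, then top to bottom) with no
#' overlap and no blending; synthetic tiles are exact partitions of the
#' well, so assembly is a deterministic inverse of the tiling.
#'
#' @param tiles list of numeric matrices, all the same shape, in row-major
#'   order; length must equal `prod(layout)`.
#' @param layout integer `(rows, cols)`.
#' @param pixel_size pixel pitch in um (square pixels).
#' @return object of class `mosaic_image`: `data`, `pixel_size`, `layout`.
#' @export
assemble_tiles <- function(tiles, layout, pixel_size = 1) {
  layout <- as.integer(layout)
  if (length(layout) != 2L || any(layout < 1L))
    stop("layout must be positive (rows, cols)", call. = FALSE)
  if (length(tiles) != prod(layout))
    stop("expected ", prod(layout), " tiles for a ", layout[1], "x",
         layout[2], " layout, got ", length(tiles), call. = FALSE)
  d <- dim(tiles[[1]])
  if (!all(vapply(tiles, function(t) identical(dim(t), d), TRUE)))
    stop("all tiles must have the same shape", call. = FALSE)
  full <- matrix(0, d[1] * layout[1], d[2] * layout[2])
  k <- 0L
  for (r in seq_len(layout[1]))
    for (cc in seq_len(layout[2])) {
      k <- k + 1L
      full[((r - 1) * d[1] + 1):(r * d[1]),
           ((cc - 1) * d[2] + 1):(cc * d[2])] <- tiles[[k]]
    }
  structure(list(data = full, pixel_size = pixel_size, layout = layout),
            class = "mosaic_image")
}

#' @export
print.mosaic_image <- function(x, ...) {
  cat(sprintf("<mosaic_image> %d x %d px (%d x %d tiles), %.4g um/px\n",
              nrow(x$data), ncol(x$data), x$layout[1], x$layout[2],
              x$pixel_size))
  invisible(x)
}

#' Segment a whole-well mosaic and measure cross-sectional areas
#'
#' Intensity threshold, 2D connected-component labeling (8-connectivity)
#' and a minimum object-area cutoff, applied to the assembled mosaic.
#' Because assembly precedes segmentation, an aggregate spanning a tile
#' seam is measured as one object. Convexity-driven bisection is off by
#' default in mosaic mode but can be enabled.
#'
#' @param mosaic a `mosaic_image` (or plain matrix, with `pixel_size`).
#' @param threshold intensity threshold.
#' @param min_object_area minimum cross-sectional area in um^2.
#' @param pixel_size pixel pitch in um; taken from the mosaic if present.
#' @param split apply convexity bisection to merged objects.
#' @param rmsd_cutoff,split_max_iterations bisection controls, as in
#'   [run_config()].
#' @return numeric vector of surviving cross-sectional areas in um^2, with
#'   the label matrix attached as attribute `labels`.
#' @export
segment_mosaic <- function(mosaic, threshold, min_object_area,
                           pixel_size = NULL, split = FALSE,
                           rmsd_cutoff = sqrt(0.1),
                           split_max_iterations = 3L) {
  if (inherits(mosaic, "mosaic_image")) {
    img <- mosaic$data
    pixel_size <- mosaic$pixel_size
  } else {
    img <- mosaic
    if (is.null(pixel_size))
      stop("pixel_size required for a plain matrix", call. = FALSE)
  }
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  mask <- img >= threshold
  lab <- label_plane(mask, 8L)
  k <- max(lab)
  if (k > 0L && split && split_max_iterations > 0L) {
    pieces <- list()
    for (i in seq_len(k)) {
      cc <- .label_coords(lab, i)
      bi <- bisect_object(cc, nrow(img), ncol(img), rmsd_cutoff,
                          split_max_iterations)
      pieces <- c(pieces, bi$pieces)
    }
    first <- vapply(pieces, function(p) p[1, 1] + (p[1, 2] - 1) * nrow(img), 0)
    pieces <- pieces[order(first)]
    lab <- matrix(0L, nrow(img), ncol(img))
    for (i in seq_along(pieces)) lab[pieces[[i]]] <- i
    k <- length(pieces)
  }
  if (k == 0L) {
    out <- numeric(0)
    attr(out, "labels") <- lab
    return(out)
  }
  areas_px <- tabulate(lab[lab > 0L], k)
  areas <- areas_px * pixel_size^2
  keep <- areas >= min_object_area
  remap <- integer(k)
  remap[keep] <- seq_len(sum(keep))
  sel <- lab > 0L
  lab[sel] <- remap[lab[sel]]
  out <- areas[keep]
  attr(out, "labels") <- lab
  out
}
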