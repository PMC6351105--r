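#' Construct an image stack
#'
#' An `image_stack` couples a 3D grid of fluorescence intensities with its
#' physical voxel geometry. The grid is stored as a numeric array indexed
#' `[y, x, z]`; plane `z = 1` sits just above the coverslip and `z`
#' increases into the sample. Physical geometry always travels with the
#' data so that all downstream size cutoffs can be stated in micrometers
#' and converted internally, making results independent of the pixel pitch
#' of a particular objective.
#'
#' @param data numeric array with dimensions `(ny, nx, nz)`, or a matrix
#'   (promoted to a single-plane stack). All values must be non-negative.
#' @param voxel_size numeric length-3 vector `(dx, dy, dz)` in micrometers
#'   per voxel along x, y and z.
#' @return an object of class `image_stack`.
#' @examples
#' st <- image_stack(array(0, c(8, 8, 4)), voxel_size = c(1, 1, 2))
#' imaged_volume(st) # 8*8*4 * 2 um^3
#' @export
image_stack <- function(data, voxel_size) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (ny, nx, nz) or a matrix", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive values (dx, dy, dz) in um",
         call. = FALSE)
  if (any(data < 0)) stop("intensities must be non-negative", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d pixels, %d planes\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel: %.4g x %.4g x %.4g um; imaged volume %.4g um^3\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              imaged_volume(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Physical voxel volume of a stack, in cubic micrometers
#' @param x an `image_stack` or a length-3 voxel-size vector.
#' @return voxel volume dx*dy*dz in um^3.
#' @export
voxel_volume <- function(x) {
  vs <- if (inherits(x, "image_stack")) x$voxel_size else as.numeric(x)
  prod(vs)
}

#' Total imaged volume of a stack, in cubic micrometers
#' @param x an `image_stack`.
#' @return nx*ny*nz * voxel volume, in um^3.
#' @export
imaged_volume <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  prod(dim(x$data)) * voxel_volume(x)
}

#' Number of z planes
#' @param x an `image_stack`.
#' @export
n_planes <- function(x) {
  stopifnot(inherits(x, "image_stack"))
  dim(x$data)[3]
}
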