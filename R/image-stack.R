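#' Calibrated fluorescence image stack
#'
#' Container for a multi-slice 16-bit widefield acquisition. Voxels are stored
#' as a 3D array indexed `[y, x, z]` (one matrix per z-slice); coordinates
#' reported by all ramfish functions are 0-based pixel indices with pixel
#' centres at integer positions. Calibration follows the acquisition used
#' throughout: 100 nm xy pixels and 0.2 um z-sections.
#'
#' @param voxels 3D numeric array `[y, x, z]` (or a matrix, treated as a
#'   single slice) of non-negative intensities.
#' @param pixel_size_xy Lateral pixel size in um (default 0.1).
#' @param z_step Axial section spacing in um (default 0.2).
#' @param bit_depth Camera bit depth; intensities must lie in
#'   `[0, 2^bit_depth - 1]` (default 16).
#' @return An `image_stack` object.
#' @examples
#' st <- image_stack(array(100, dim = c(8, 8, 4)))
#' n_slices(st)
#' @export
image_stack <- function(voxels, pixel_size_xy = 0.1, z_step = 0.2,
                        bit_depth = 16) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a matrix or 3D array [y, x, z]", call. = FALSE)
  }
  if (dim(voxels)[3] < 1L) stop("stack must contain at least one slice", call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    stop("stack intensities must be finite", call. = FALSE)
  }
  if (any(voxels < 0) || any(voxels > 2^bit_depth - 1)) {
    stop("intensities must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  }
  stopifnot(pixel_size_xy > 0, z_step > 0)
  structure(
    list(voxels = voxels, pixel_size_xy = pixel_size_xy, z_step = z_step,
         bit_depth = bit_depth),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d px, %d slices | %.3f um/px, %.2f um z-step, %d-bit\n",
    d[1], d[2], d[3], x$pixel_size_xy, x$z_step, x$bit_depth))
  invisible(x)
}

#' @rdname image_stack
#' @param stack An `image_stack`.
#' @export
n_slices <- function(stack) dim(stack$voxels)[3]

#' Single-channel 2D image with calibration
#'
#' A plain numeric matrix carrying the lateral pixel size as an attribute.
#' Most image operations accept either a `fish_image` or a bare matrix
#' (assumed 0.1 um pixels).
#'
#' @param pixels Numeric matrix `[y, x]`, non-negative and finite.
#' @param pixel_size_xy Lateral pixel size in um.
#' @return A `fish_image` (matrix subclass).
#' @export
fish_image <- function(pixels, pixel_size_xy = 0.1) {
  stopifnot(is.matrix(pixels), pixel_size_xy > 0)
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    stop("image pixels must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) stop("image pixels must be non-negative", call. = FALSE)
  structure(pixels, pixel_size_xy = pixel_size_xy,
            class = c("fish_image", "matrix", "array"))
}

pixel_size_of <- function(image, default = 0.1) {
  ps <- attr(image, "pixel_size_xy")
  if (is.null(ps)) default else ps
}

as_pixel_matrix <- function(image) {
  m <- unclass(image)
  attr(m, "pixel_size_xy") <- NULL
  m
}

#' Maximum z-projection
#'
#' Collapses a stack to a 2D image whose each pixel is the maximum intensity
#' over z at that xy position. This is the first step of the widefield
#' quantification chain; calibration metadata is preserved.
#'
#' @param stack An `image_stack` (or 3D array `[y, x, z]`).
#' @return A `fish_image` matrix.
#' @examples
#' st <- image_stack(array(c(5, 7), dim = c(2, 2, 2)))
#' max_z_project(st)
#' @export
max_z_project <- function(stack) {
  if (is.array(stack) && !inherits(stack, "image_stack")) {
    stack <- image_stack(stack)
  }
  if (!inherits(stack, "image_stack")) stop("`stack` must be an image_stack", call. = FALSE)
  v <- stack$voxels
  d <- dim(v)
  proj <- v[, , 1L]
  if (d[3] > 1L) {
    for (k in 2:d[3]) proj <- pmax(proj, v[, , k])
  }
  fish_image(matrix(proj, nrow = d[1]), pixel_size_xy = stack$pixel_size_xy)
}

#' Read / write multi-page TIFF stacks
#'
#' Reads a single-channel, multi-page 16-bit grayscale TIFF into an
#' [image_stack()]. TIFF files rarely carry voxel calibration reliably, so
#' pixel size and z-step are supplied by the caller (or a sidecar config; see
#' [read_run_config()]).
#'
#' @param path TIFF file path.
#' @param pixel_size_xy,z_step Calibration in um.
#' @param bit_depth Camera bit depth recorded on the stack (values are read
#'   as raw integer grey levels).
#' @return An `image_stack`.
#' @export
read_stack <- function(path, pixel_size_xy = 0.1, z_step = 0.2, bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("empty TIFF: ", path, call. = FALSE)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # first channel only
    p
  })
  voxels <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) voxels[, , k] <- pages[[k]]
  image_stack(voxels, pixel_size_xy = pixel_size_xy, z_step = z_step,
              bit_depth = bit_depth)
}

#' @rdname read_stack
#' @param stack An `image_stack` to write.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- 2^stack$bit_depth - 1
  pages <- lapply(seq_len(n_slices(stack)), function(k) {
    matrix(stack$voxels[, , k] / scale, nrow = dim(stack$voxels)[1])
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
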