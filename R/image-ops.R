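#' Spherical-cap structuring element for rolling-ball background estimation
#'
#' Offsets and heights of a ball (spherical cap) of the given pixel radius:
#' all `(dy, dx)` with `dy^2 + dx^2 <= r^2`, height `sqrt(r^2 - dy^2 - dx^2)`.
#'
#' @param radius_px Ball radius in pixels (>= 1).
#' @return A tibble with columns `dy`, `dx`, `h`.
#' @export
ball_element <- function(radius_px) {
  stopifnot(radius_px >= 1)
  d <- seq(-radius_px, radius_px)
  g <- expand.grid(dy = d, dx = d)
  g <- g[g$dy^2 + g$dx^2 <= radius_px^2, ]
  tibble::tibble(dy = g$dy, dx = g$dx,
                 h = sqrt(radius_px^2 - g$dy^2 - g$dx^2))
}

# shift so that out[y, x] = m[y + dy, x + dx]; out-of-range cells get `fill`
shift_matrix <- function(m, dy, dx, fill) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  if (max(1, 1 + dy) > min(ny, ny + dy) || max(1, 1 + dx) > min(nx, nx + dx)) {
    return(out)
  }
  out[ys - dy, xs - dx] <- m[ys, xs]
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' opening of the intensity surface with a spherical-cap (ball) structuring
#' element, then subtracts it, clipping at zero. A ball of radius r cannot
#' enter structures narrower than ~2r pixels, so diffraction-limited spots
#' survive subtraction while autofluorescence and shading are removed. The
#' default radius of 3 px matches the quantification chain used throughout
#' the package.
#'
#' Grayscale opening with a non-flat element `b`:
#' erosion `e(p) = min_u f(p + u) - b(u)` then dilation
#' `g(p) = max_u e(p - u) + b(u)`; out-of-bounds offsets are ignored. Opening
#' is anti-extensive, so the background never exceeds the image and the
#' result is always non-negative. Adding a constant c to the image shifts the
#' background estimate by exactly c and leaves the subtracted image unchanged.
#'
#' @param image Numeric matrix or `fish_image`.
#' @param radius_px Ball radius in pixels (default 3).
#' @return Background-subtracted image of the same class, with the background
#'   estimate attached as attribute `"background"`.
#' @examples
#' img <- matrix(0, 9, 9); img[5, 5] <- 1000
#' sub <- rolling_ball_subtract(img, 3)
#' @export
rolling_ball_subtract <- function(image, radius_px = 3L) {
  m <- as_pixel_matrix(image)
  stopifnot(is.matrix(m))
  if (anyNA(m) || any(!is.finite(m))) stop("image must be finite", call. = FALSE)
  if (radius_px < 1) stop("`radius_px` must be >= 1", call. = FALSE)
  if (radius_px >= min(dim(m))) {
    stop("`radius_px` (", radius_px, ") exceeds the image extent", call. = FALSE)
  }
  el <- ball_element(radius_px)
  ero <- matrix(Inf, nrow(m), ncol(m))
  for (k in seq_len(nrow(el))) {
    ero <- pmin(ero, shift_matrix(m, el$dy[k], el$dx[k], Inf) - el$h[k])
  }
  bg <- matrix(-Inf, nrow(m), ncol(m))
  for (k in seq_len(nrow(el))) {
    bg <- pmax(bg, shift_matrix(ero, -el$dy[k], -el$dx[k], -Inf) + el$h[k])
  }
  out <- pmax(m - bg, 0)
  res <- if (inherits(image, "fish_image")) {
    fish_image(out, pixel_size_of(image))
  } else {
    out
  }
  attr(res, "background") <- bg
  res
}

#' Prominence-based local-maxima spot calling
#'
#' Finds the regional maxima of an image whose topographic prominence -- the
#' height of the peak above the highest saddle connecting it to any higher
#' maximum -- is at least `prominence`. This reproduces, from primitives, the
#' "find maxima" step used to call diffraction-limited smFISH spots on
#' background-subtracted maximum projections; the default prominence of 1700
#' grey values is the spot-calling threshold of the quantification chain.
#'
#' A connected plateau of maxima yields one candidate at the plateau centroid
#' (rounded to the nearest pixel, ties toward smaller y then x). The global
#' maximum is always emitted for a non-constant image. Border maxima are
#' emitted and flagged via `on_border`; set `exclude_edges = TRUE` to drop
#' them.
#'
#' @param image Numeric matrix or `fish_image`; must be finite.
#' @param prominence Minimum prominence in grey values (> 0; default 1700).
#' @param exclude_edges Drop maxima whose representative pixel lies on the
#'   image border (default `FALSE`).
#' @return A tibble of spot candidates sorted by decreasing `peak_value`:
#'   columns `y`, `x` (0-based pixel coordinates), `peak_value`,
#'   `prominence_value`, `on_border`, `is_global`.
#' @examples
#' img <- matrix(0, 10, 10); img[3, 3] <- 2000; img[8, 8] <- 1900
#' find_maxima(img, prominence = 1700)
#' @export
find_maxima <- function(image, prominence = 1700, exclude_edges = FALSE) {
  m <- as_pixel_matrix(image)
  stopifnot(is.matrix(m))
  if (anyNA(m) || any(!is.finite(m))) {
    stop("image contains non-finite pixels", call. = FALSE)
  }
  if (!is.numeric(prominence) || prominence <= 0) {
    stop("`prominence` must be > 0", call. = FALSE)
  }
  out <- tibble::as_tibble(find_maxima_cpp(m, prominence))
  if (exclude_edges) out <- out[!out$on_border, ]
  out
}

#' Mean grey value of the 3x3 spot ROI
#'
#' Measures the 3x3 pixel block centred on a spot candidate: at the 100 nm
#' pixel calibration this is the 0.09 um^2 ROI used for per-spot intensity
#' and background sampling. Candidates on the image border are measured over
#' the clipped block and flagged.
#'
#' @param image Numeric matrix or `fish_image`.
#' @param y,x 0-based pixel coordinates of the spot centre (vectorised).
#' @param half Half-width of the square ROI in pixels (default 1, i.e. 3x3).
#' @return A tibble with one row per spot: `y`, `x`, `mean_grey`,
#'   `raw_integrated_density`, `area_px`, `area_um2`, `clipped`.
#' @export
spot_roi_mean <- function(image, y, x, half = 1L) {
  m <- as_pixel_matrix(image)
  ps <- pixel_size_of(image)
  stopifnot(length(y) == length(x))
  ny <- nrow(m); nx <- ncol(m)
  if (any(y < 0 | y > ny - 1 | x < 0 | x > nx - 1)) {
    stop("spot centre outside image bounds", call. = FALSE)
  }
  res <- purrr::map2(y, x, function(yy, xx) {
    ys <- max(0, yy - half):min(ny - 1, yy + half)
    xs <- max(0, xx - half):min(nx - 1, xx + half)
    block <- m[ys + 1, xs + 1, drop = FALSE]
    list(mean_grey = mean(block), rid = sum(block), area = length(block),
         clipped = length(block) < (2 * half + 1)^2)
  })
  tibble::tibble(
    y = as.integer(y), x = as.integer(x),
    mean_grey = purrr::map_dbl(res, "mean_grey"),
    raw_integrated_density = purrr::map_dbl(res, "rid"),
    area_px = purrr::map_int(res, ~ as.integer(.x$area)),
    area_um2 = purrr::map_dbl(res, "area") * ps^2,
    clipped = purrr::map_lgl(res, "clipped")
  )
}

#' Even-odd point-in-polygon test
#'
#' Vectorised ray-casting containment test (even-odd rule) for pixel centres
#' against a polygon in pixel coordinates. Points exactly on an edge follow
#' the half-open crossing convention; cell outlines drawn between pixel
#' centres (half-integer vertices) avoid the ambiguity entirely.
#'
#' @param px,py Point coordinates (0-based pixel units).
#' @param vx,vy Polygon vertex coordinates (>= 3 vertices, implicit closure).
#' @return Logical vector, `TRUE` when the point is inside.
#' @export
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  stopifnot(n >= 3, length(vy) == n, length(px) == length(py))
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Mean grey value and area inside a polygonal cell ROI
#'
#' Rasterises a manually-outlined cell polygon (even-odd rule over pixel
#' centres) and reports the mean grey value, pixel area, physical area and
#' raw integrated density -- the per-cell measurements collected on the
#' maximum projection.
#'
#' @param image Numeric matrix or `fish_image`.
#' @param vertices Two-column matrix or data frame of polygon vertices
#'   `(x, y)` in 0-based pixel coordinates, at least 3 rows.
#' @return A one-row tibble: `mean_grey`, `area_px`, `area_um2`,
#'   `raw_integrated_density`.
#' @export
mean_grey_in_polygon <- function(image, vertices) {
  m <- as_pixel_matrix(image)
  ps <- pixel_size_of(image)
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  vx <- v[, 1]; vy <- v[, 2]
  xs <- max(0, floor(min(vx))):min(ncol(m) - 1, ceiling(max(vx)))
  ys <- max(0, floor(min(vy))):min(nrow(m) - 1, ceiling(max(vy)))
  g <- expand.grid(y = ys, x = xs)
  keep <- points_in_polygon(g$x, g$y, vx, vy)
  if (!any(keep)) {
    stop("polygon encloses no pixel centres", call. = FALSE)
  }
  vals <- m[cbind(g$y[keep] + 1, g$x[keep] + 1)]
  tibble::tibble(
    mean_grey = mean(vals),
    area_px = sum(keep),
    area_um2 = sum(keep) * ps^2,
    raw_integrated_density = sum(vals)
  )
}
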