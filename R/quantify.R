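#' Assign detected spots to cell ROIs
#'
#' Each spot belongs to the cell polygon containing its centre (even-odd
#' rule); spots inside no polygon are returned with `cell_id = NA`. ROIs are
#' expected to be non-overlapping (manual outlines); overlap triggers a
#' warning and the first containing ROI (table order) wins.
#'
#' @param spots Tibble with 0-based `y`, `x` columns (e.g. from
#'   [find_maxima()]).
#' @param rois A `roi_tbl` (see [cell_roi()]).
#' @return `spots` with `cell_id` and `group` columns added.
#' @export
assign_spots_to_cells <- function(spots, rois) {
  stopifnot(is.data.frame(spots), all(c("y", "x") %in% names(spots)))
  n <- nrow(spots)
  cell <- rep(NA_character_, n)
  grp <- rep(NA_character_, n)
  hits <- rep(0L, n)
  for (i in seq_len(nrow(rois))) {
    v <- rois$vertices[[i]]
    inside <- points_in_polygon(spots$x, spots$y, v[, 1], v[, 2])
    hits <- hits + inside
    take <- inside & is.na(cell)
    cell[take] <- rois$cell_id[i]
    grp[take] <- rois$group[i]
  }
  if (any(hits > 1L)) {
    warning(sum(hits > 1L), " spot(s) fall in overlapping ROIs; ",
            "first ROI in table order kept", call. = FALSE)
  }
  dplyr::mutate(spots, cell_id = cell, group = grp)
}

#' Cell volume from projected area and z-extent
#'
#' Approximates the cell volume as the product of the projected cell area,
#' the number of z-slices the cell spans, and the z-section size:
#' `V = area_um2 * n_slices * z_step_um`.
#'
#' @param area_um2 Projected cell area in um^2 (> 0).
#' @param n_slices Number of z-slices spanned (> 0).
#' @param z_step_um z-section size in um (default 0.2).
#' @return Volume in um^3.
#' @examples
#' cell_volume(100, 10)  # 200 um^3
#' @export
cell_volume <- function(area_um2, n_slices, z_step_um = 0.2) {
  if (any(area_um2 <= 0) || any(n_slices <= 0) || any(z_step_um <= 0)) {
    stop("area, n_slices and z_step must all be > 0", call. = FALSE)
  }
  area_um2 * n_slices * z_step_um
}

#' Transcript concentration per cell
#'
#' mRNA count divided by the estimated cell volume, in molecules per um^3.
#'
#' @param spot_count Non-negative transcript count.
#' @param volume_um3 Cell volume in um^3 (> 0).
#' @return Concentration in mRNA um^-3.
#' @export
concentration <- function(spot_count, volume_um3) {
  if (any(volume_um3 <= 0)) stop("volume must be > 0", call. = FALSE)
  if (any(spot_count < 0)) stop("spot_count must be >= 0", call. = FALSE)
  spot_count / volume_um3
}

#' Sample spot-free intracellular background ROIs
#'
#' Draws `n` 3x3 background ROIs uniformly at random from pixels that lie
#' inside a cell polygon and at least `min_dist_px` from every detected spot
#' centre, and returns their mean grey values. This reproduces the manual
#' "background fluorescence" sampling (20 spot-free 0.09 um^2 intracellular
#' ROIs) as a seeded, reproducible procedure.
#'
#' @param image Numeric matrix or `fish_image` (maximum projection).
#' @param rois `roi_tbl` of cell outlines.
#' @param spots Tibble with `y`, `x` of detected spots (may be empty).
#' @param n Number of background ROIs (default 20).
#' @param min_dist_px Minimum distance from any spot centre (default 5).
#' @param seed Integer seed; required for reproducibility.
#' @return A list of class `background_sample`: `values` (n mean grey
#'   values), `mean_background`, `n`, `positions` (tibble of y, x).
#' @export
sample_background <- function(image, rois, spots = NULL, n = 20L,
                              min_dist_px = 5, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  m <- as_pixel_matrix(image)
  ny <- nrow(m); nx <- ncol(m)
  inside <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(rois))) {
    v <- rois$vertices[[i]]
    xs <- max(0, floor(min(v[, 1]))):min(nx - 1, ceiling(max(v[, 1])))
    ys <- max(0, floor(min(v[, 2]))):min(ny - 1, ceiling(max(v[, 2])))
    g <- expand.grid(y = ys, x = xs)
    keep <- points_in_polygon(g$x, g$y, v[, 1], v[, 2])
    inside[cbind(g$y[keep] + 1, g$x[keep] + 1)] <- TRUE
  }
  # keep the 3x3 block fully inside the image
  inside[c(1, ny), ] <- FALSE
  inside[, c(1, nx)] <- FALSE
  idx <- which(inside, arr.ind = TRUE)
  if (!is.null(spots) && nrow(spots) > 0) {
    py <- idx[, 1] - 1; px <- idx[, 2] - 1
    ok <- rep(TRUE, nrow(idx))
    for (k in seq_len(nrow(spots))) {
      d2 <- (py - spots$y[k])^2 + (px - spots$x[k])^2
      ok <- ok & d2 >= min_dist_px^2
    }
    idx <- idx[ok, , drop = FALSE]
  }
  if (nrow(idx) < n) {
    stop("insufficient spot-free intracellular area: only ", nrow(idx),
         " eligible pixels for ", n, " background ROIs", call. = FALSE)
  }
  pick <- withr::with_seed(seed, sample.int(nrow(idx), n))
  sel <- idx[pick, , drop = FALSE]
  meas <- spot_roi_mean(image, y = sel[, 1] - 1, x = sel[, 2] - 1)
  structure(
    list(values = meas$mean_grey, mean_background = mean(meas$mean_grey),
         n = n, positions = tibble::tibble(y = sel[, 1] - 1, x = sel[, 2] - 1)),
    class = "background_sample"
  )
}

#' @export
print.background_sample <- function(x, ...) {
  cat(sprintf("<background_sample> n = %d, mean = %.2f grey values\n",
              x$n, x$mean_background))
  invisible(x)
}

#' Total corrected cellular fluorescence per spot
#'
#' TCCF for a measured region is its integrated density minus the region
#' area times the mean background fluorescence:
#' `tccf = raw_integrated_density - area_px * mean_background`.
#' Computed per spot over its 3x3 ROI (so `area_px = 9` for unclipped
#' spots). Negative values are retained and flagged; border-clipped spots
#' are dropped by default because their area differs from the others.
#'
#' @param spot_measurements Tibble from [spot_roi_mean()] (columns
#'   `raw_integrated_density`, `area_px`, `clipped`).
#' @param background A `background_sample`, or a single mean background grey
#'   value.
#' @param include_clipped Keep border-clipped spots (flagged) instead of
#'   dropping them.
#' @return The measurement tibble with `mean_background`, `tccf` and
#'   `tccf_negative` columns; clipped rows removed unless requested.
#' @examples
#' m <- tibble::tibble(raw_integrated_density = 4500, area_px = 9L,
#'                     clipped = FALSE)
#' tccf(m, background = 100)  # 4500 - 9 * 100 = 3600
#' @export
tccf <- function(spot_measurements, background, include_clipped = FALSE) {
  bg <- if (inherits(background, "background_sample")) {
    background$mean_background
  } else {
    as.numeric(background)
  }
  stopifnot(length(bg) == 1L, is.finite(bg))
  out <- spot_measurements
  if (!"clipped" %in% names(out)) out$clipped <- FALSE
  if (!include_clipped) out <- out[!out$clipped, , drop = FALSE]
  dplyr::mutate(out,
                mean_background = bg,
                tccf = .data$raw_integrated_density - .data$area_px * bg,
                tccf_negative = .data$tccf < 0)
}

#' Integrated density over a fixed-area nuclear ROI
#'
#' Sums pixel intensities over a fixed physical area centred on a nucleus,
#' guaranteeing an identical pixel count for every measured nucleus so that
#' integrated densities are directly comparable across experimental groups.
#' The target area (default 59.94 um^2, i.e. 5994 pixels at 100 nm pixels)
#' is realised as the `round(area_um2 / pixel_size^2)` pixels nearest the
#' centre (a disc-like mask), which hits the requested pixel count exactly.
#'
#' @param image Numeric matrix or `fish_image`.
#' @param centre Length-2 vector `c(y, x)`, 0-based pixel coordinates.
#' @param area_um2 ROI area in um^2 (default 59.94).
#' @return A one-row tibble: `y`, `x`, `area_um2`, `area_px`,
#'   `integrated_density`, `mean_grey`.
#' @export
nuclear_integrated_density <- function(image, centre, area_um2 = 59.94) {
  m <- as_pixel_matrix(image)
  ps <- pixel_size_of(image)
  n_px <- round(area_um2 / ps^2)
  cy <- centre[1]; cx <- centre[2]
  r <- ceiling(sqrt(n_px / pi)) + 2
  ys <- (cy - r):(cy + r)
  xs <- (cx - r):(cx + r)
  if (min(ys) < 0 || max(ys) > nrow(m) - 1 || min(xs) < 0 || max(xs) > ncol(m) - 1) {
    stop("nuclear ROI extends outside the image", call. = FALSE)
  }
  g <- expand.grid(y = ys, x = xs)
  d2 <- (g$y - cy)^2 + (g$x - cx)^2
  # deterministic: nearest pixels first, ties by (y, x)
  ord <- order(d2, g$y, g$x)
  sel <- g[ord[seq_len(n_px)], ]
  vals <- m[cbind(sel$y + 1, sel$x + 1)]
  tibble::tibble(y = cy, x = cx, area_um2 = n_px * ps^2, area_px = n_px,
                 integrated_density = sum(vals), mean_grey = mean(vals))
}

#' Per-cell quantification table
#'
#' Combines assigned spots and cell ROIs into the per-cell record: spot
#' count, projected area, volume (`area x n_slices x z_step`) and
#' concentration (`count / volume`).
#'
#' @param assigned_spots Tibble from [assign_spots_to_cells()].
#' @param rois `roi_tbl` of cell outlines.
#' @param image Maximum projection used for area measurement.
#' @param z_step_um z-section size in um (default 0.2).
#' @return A tibble with one row per cell: `cell_id`, `group`, `spot_count`,
#'   `area_um2`, `n_slices`, `volume_um3`, `concentration_per_um3`.
#' @export
quantify_cells <- function(assigned_spots, rois, image, z_step_um = 0.2) {
  counts <- assigned_spots |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$cell_id, name = "spot_count")
  areas <- purrr::map_dbl(rois$vertices,
                          ~ mean_grey_in_polygon(image, .x)$area_um2)
  rois |>
    dplyr::mutate(area_um2 = areas) |>
    dplyr::left_join(counts, by = "cell_id") |>
    dplyr::mutate(
      spot_count = dplyr::coalesce(.data$spot_count, 0L),
      volume_um3 = cell_volume(.data$area_um2, .data$n_slices, z_step_um),
      concentration_per_um3 = concentration(.data$spot_count, .data$volume_um3)
    ) |>
    dplyr::select("cell_id", "group", "spot_count", "area_um2", "n_slices",
                  "volume_um3", "concentration_per_um3")
}
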