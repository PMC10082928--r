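#' Cell ROI tables
#'
#' Cell regions of interest are kept in a tibble with one row per cell:
#' `cell_id`, `group` (probe-set label), `n_slices` (z-extent used for the
#' volume estimate) and `vertices`, a list-column of two-column `(x, y)`
#' matrices in 0-based pixel coordinates. `cell_roi()` builds a one-row
#' table; `bind_rois()` stacks several.
#'
#' @param cell_id Cell identifier.
#' @param vertices Two-column `(x, y)` matrix (>= 3 rows).
#' @param group Probe-set label (e.g. `"MON1"`, `"no-probe"`).
#' @param n_slices z-slices spanned by the cell (>= 1).
#' @return A tibble with class `roi_tbl`.
#' @export
cell_roi <- function(cell_id, vertices, group = NA_character_, n_slices = 1L) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3L) stop("ROI polygon needs >= 3 vertices", call. = FALSE)
  if (n_slices < 1L) stop("`n_slices` must be >= 1", call. = FALSE)
  colnames(v) <- c("x", "y")
  out <- tibble::tibble(cell_id = as.character(cell_id),
                        group = as.character(group),
                        n_slices = as.integer(n_slices),
                        vertices = list(v))
  class(out) <- c("roi_tbl", class(out))
  out
}

#' @rdname cell_roi
#' @param ... `roi_tbl` tables to combine.
#' @export
bind_rois <- function(...) {
  out <- dplyr::bind_rows(rlang::list2(...))
  if (!inherits(out, "roi_tbl")) class(out) <- c("roi_tbl", class(out))
  out
}

#' Read and write the JSON cell-ROI dialect
#'
#' The on-disk polygon dialect is a JSON array of objects with fields
#' `cell_id`, `group`, `n_slices` and `vertices` (an array of `[x, y]` pairs
#' in 0-based pixel coordinates). Round-trips losslessly at full double
#' precision.
#'
#' @param path File path.
#' @return `read_rois_json()` returns a `roi_tbl`; `write_rois_json()`
#'   returns `path` invisibly.
#' @export
read_rois_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rois <- purrr::map(raw, function(r) {
    v <- do.call(rbind, lapply(r$vertices, function(p) as.numeric(unlist(p))))
    cell_roi(r$cell_id, v,
             group = r$group %||% NA_character_,
             n_slices = r$n_slices %||% 1L)
  })
  bind_rois(!!!rois)
}

#' @rdname read_rois_json
#' @param rois A `roi_tbl`.
#' @export
write_rois_json <- function(rois, path) {
  recs <- purrr::pmap(rois, function(cell_id, group, n_slices, vertices, ...) {
    list(cell_id = cell_id, group = group, n_slices = n_slices,
         vertices = purrr::map(seq_len(nrow(vertices)),
                               ~ c(vertices[.x, 1], vertices[.x, 2])))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ImageJ .roi polygon files
#'
#' Minimal reader for the binary ImageJ ROI format, covering polygon,
#' freehand and traced outlines (the types produced by manual cell
#' outlining). Vertex coordinates are converted to 0-based pixels.
#' `read_rois_imagej_zip()` reads a RoiSet zip as saved by the ROI manager;
#' cell ids default to the entry names.
#'
#' @param path Path to a `.roi` file (or `.zip` for the zip reader).
#' @param cell_id,group,n_slices Metadata attached to the resulting ROI.
#' @return A `roi_tbl`.
#' @export
read_roi_imagej <- function(path, cell_id = NULL, group = NA_character_,
                            n_slices = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", n = file.info(path)$size)
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout") {
    stop("not an ImageJ ROI file: ", path, call. = FALSE)
  }
  be_i2 <- function(off) {  # signed big-endian short at 0-based byte offset
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  }
  type <- as.integer(raw[7])  # 0 polygon, 3 freeline, 4 traced, 7 freehand
  if (!type %in% c(0L, 3L, 4L, 7L)) {
    stop("unsupported ImageJ ROI type ", type, " (need a polygon outline)",
         call. = FALSE)
  }
  top <- be_i2(8); left <- be_i2(10)
  n <- be_i2(16)
  if (n < 3L) stop("ROI has fewer than 3 vertices", call. = FALSE)
  xs <- vapply(seq_len(n), function(i) be_i2(64 + 2 * (i - 1)), integer(1))
  ys <- vapply(seq_len(n), function(i) be_i2(64 + 2 * n + 2 * (i - 1)), integer(1))
  v <- cbind(x = xs + left, y = ys + top)
  if (is.null(cell_id)) cell_id <- sub("\\.roi$", "", basename(path))
  cell_roi(cell_id, v, group = group, n_slices = n_slices)
}

#' @rdname read_roi_imagej
#' @export
read_rois_imagej_zip <- function(path, group = NA_character_, n_slices = 1L) {
  tmp <- tempfile("roiset")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  files <- utils::unzip(path, exdir = tmp)
  files <- sort(files[grepl("\\.roi$", files)])
  if (length(files) == 0L) stop("no .roi entries in ", path, call. = FALSE)
  rois <- purrr::map(files, read_roi_imagej, group = group, n_slices = n_slices)
  bind_rois(!!!rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
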