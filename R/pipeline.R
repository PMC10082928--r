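#' Default analysis parameters
#'
#' The parameter set of the quantification chain: 100 nm pixels, 0.2 um
#' z-sections, rolling-ball radius 3 px, maxima prominence 1700, 20
#' background ROIs at >= 5 px from any spot, 2 px co-localization radius.
#' A seed is required wherever sampling occurs.
#'
#' @param ... Named overrides.
#' @return Named list of parameters.
#' @export
run_params <- function(...) {
  p <- list(
    pixel_size_xy = 0.1,
    z_step = 0.2,
    rolling_ball_radius = 3L,
    prominence = 1700,
    exclude_edges = FALSE,
    n_background = 20L,
    background_min_dist_px = 5,
    coloc_max_dist_px = 2,
    seed = NULL
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(p))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p <- modifyList(p, over)
  }
  p
}

#' Read a YAML run configuration
#'
#' Loads analysis parameters (and optional input paths / column mappings)
#' from a YAML file, filling unspecified values with the [run_params()]
#' defaults. The returned list records which parameters were user-set
#' versus defaulted (attribute `"provenance"`).
#'
#' @param path YAML file path.
#' @return A parameter list as from [run_params()], plus any extra fields
#'   (`inputs`, `column_map`, `output_dir`) found in the file.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(run_params())
  p <- do.call(run_params, raw[intersect(names(raw), known)])
  extra <- raw[setdiff(names(raw), known)]
  out <- c(p, extra)
  attr(out, "provenance") <- tibble::tibble(
    parameter = known,
    source = ifelse(known %in% names(raw), "user", "default")
  )
  out
}

#' Run the full per-field quantification chain
#'
#' Executes the widefield pipeline on one image stack and its cell
#' outlines: maximum z-projection, rolling-ball background subtraction,
#' prominence-based spot calling, spot-to-cell assignment, per-cell
#' count/area/volume/concentration, spot-free background sampling and
#' per-spot TCCF. Deterministic given `params$seed`.
#'
#' @param stack An [image_stack()] (or path to a TIFF readable by
#'   [read_stack()]).
#' @param rois A `roi_tbl` (or path to a JSON ROI file).
#' @param params Parameter list from [run_params()]; `seed` must be set
#'   (used for background ROI sampling).
#' @return A list of class `fish_quant`: `cells` (per-cell tibble),
#'   `spots` (per-spot tibble with TCCF), `background`
#'   (`background_sample`), `params`.
#' @export
run_quantify <- function(stack, rois, params = run_params()) {
  if (is.character(stack)) {
    stack <- read_stack(stack, pixel_size_xy = params$pixel_size_xy,
                        z_step = params$z_step)
  }
  if (is.character(rois)) rois <- read_rois_json(rois)
  if (is.null(params$seed)) {
    stop("params$seed must be set for background sampling", call. = FALSE)
  }
  proj <- max_z_project(stack)
  sub <- rolling_ball_subtract(proj, params$rolling_ball_radius)
  spots <- find_maxima(sub, prominence = params$prominence,
                       exclude_edges = params$exclude_edges)
  if (nrow(rois) == 0L) {
    warning("empty ROI set: zero-row output", call. = FALSE)
    return(structure(list(
      cells = tibble::tibble(cell_id = character(0), group = character(0),
                             spot_count = integer(0), area_um2 = numeric(0),
                             n_slices = integer(0), volume_um3 = numeric(0),
                             concentration_per_um3 = numeric(0)),
      spots = tibble::tibble(), background = NULL, params = params),
      class = "fish_quant"))
  }
  assigned <- assign_spots_to_cells(spots, rois)
  cells <- quantify_cells(assigned, rois, proj, z_step_um = params$z_step)
  in_cell <- assigned[!is.na(assigned$cell_id), , drop = FALSE]
  spot_tbl <- tibble::tibble()
  background <- NULL
  if (nrow(in_cell) > 0) {
    background <- sample_background(
      proj, rois, spots = in_cell, n = params$n_background,
      min_dist_px = params$background_min_dist_px, seed = params$seed)
    meas <- spot_roi_mean(proj, in_cell$y, in_cell$x)
    meas$cell_id <- in_cell$cell_id
    meas$group <- in_cell$group
    meas$prominence_value <- in_cell$prominence_value
    spot_tbl <- tccf(meas, background)
    spot_tbl$spot_id <- sprintf("s%05d", seq_len(nrow(spot_tbl)))
  }
  structure(list(cells = cells, spots = spot_tbl, background = background,
                 params = params),
            class = "fish_quant")
}

#' @export
print.fish_quant <- function(x, ...) {
  cat(sprintf("<fish_quant> %d cells, %d spots (seed %s)\n",
              nrow(x$cells), nrow(x$spots),
              if (is.null(x$params$seed)) "unset" else x$params$seed))
  invisible(x)
}

#' Quantify a simulated experiment field by field
#'
#' Runs [run_quantify()] over every field of a [simulate_experiment()]
#' result and binds the per-cell and per-spot tables.
#'
#' @param sim A `sim_experiment`.
#' @param params Parameter list; seeds per field are derived from
#'   `params$seed`.
#' @return A `fish_quant` with combined tables.
#' @export
quantify_experiment <- function(sim, params = run_params(seed = 1L)) {
  results <- purrr::map(sim$fields, function(f) {
    p <- params
    p$seed <- params$seed + f$field_id
    run_quantify(f$stack, f$rois, p)
  })
  structure(
    list(cells = purrr::map_dfr(results, "cells"),
         spots = purrr::map_dfr(results, "spots"),
         background = results[[1]]$background, params = params),
    class = "fish_quant"
  )
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching (closest pairs first) of detected spots to
#' true positions within `max_dist_px`, giving recall, precision and the
#' matched pair table.
#'
#' @param detected Tibble with `y`, `x` (detections).
#' @param truth Tibble with `y`, `x` (ground truth).
#' @param max_dist_px Matching radius (default 2).
#' @return Tibble with `n_true`, `n_detected`, `n_matched`, `recall`,
#'   `precision`.
#' @export
score_detection <- function(detected, truth, max_dist_px = 2) {
  m <- match_spots_greedy(truth$y, truth$x, detected$y, detected$x,
                          max_dist_px)
  n_matched <- if (length(m) == 0L) 0L else sum(!is.na(m))
  tibble::tibble(
    n_true = nrow(truth), n_detected = nrow(detected), n_matched = n_matched,
    recall = if (nrow(truth) == 0) NA_real_ else n_matched / nrow(truth),
    precision = if (nrow(detected) == 0) NA_real_ else n_matched / nrow(detected)
  )
}

#' Recompute the study's summary statistics from a measurement table
#'
#' Takes a per-cell table (and optionally a per-spot table) -- either
#' in-memory data frames, a `study_table`, or CSV/XLSX paths -- and
#' recomputes the quantities the analysis reports: per-group median counts,
#' mean volumes and concentrations, Pearson R^2/p of count versus volume,
#' spot/background intensity means, TCCF means with relative-intensity
#' percentages, the no-probe false detection rate, and the ANOVA-Tukey
#' comparison of TCCF across probe sets.
#'
#' Column names are mapped through `column_map` (defaults assume the
#' package's own schema), never hard-coded to an external file's headers.
#'
#' @param cells Per-cell table, `study_table`, or file path.
#' @param spots Optional per-spot table or file path.
#' @param column_map Named list mapping the required names (`cell_id`,
#'   `group`, `spot_count`, `volume_um3`, and for spots `tccf`,
#'   `spot_mean_grey`, `background_mean`) to the input's column names.
#' @param no_probe_group Label of the probe-omission control group
#'   (default `"no-probe"`).
#' @return A list of class `fish_report`: tibbles `group_summary`,
#'   `correlations`, `relative_tccf` (NULL without spots), `false_detection`
#'   (NULL without a no-probe group), `tukey` (a `fish_tukey` or NULL).
#' @export
run_reproduce <- function(cells, spots = NULL, column_map = list(),
                          no_probe_group = "no-probe") {
  if (inherits(cells, "study_table")) {
    spots <- cells$spots
    cells <- cells$cells
  }
  cells <- read_any_table(cells)
  spots <- if (!is.null(spots)) read_any_table(spots)
  cmap <- modifyList(
    list(cell_id = "cell_id", group = "group", spot_count = "spot_count",
         volume_um3 = "volume_um3", tccf = "tccf",
         spot_mean_grey = "spot_mean_grey", background_mean = "background_mean"),
    column_map)
  need <- c("group", "spot_count", "volume_um3")
  missing_cols <- setdiff(unlist(cmap[need]), names(cells))
  if (length(missing_cols)) {
    stop("unmapped column(s): ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(names(cells), collapse = ", "), call. = FALSE)
  }
  cl <- tibble::tibble(
    group = as.character(cells[[cmap$group]]),
    spot_count = cells[[cmap$spot_count]],
    volume_um3 = cells[[cmap$volume_um3]]
  )
  cl$concentration_per_um3 <- cl$spot_count / cl$volume_um3
  probe_groups <- setdiff(unique(cl$group), no_probe_group)

  group_summary <- cl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_count = median(.data$spot_count),
      mean_volume_um3 = mean(.data$volume_um3),
      sd_volume_um3 = sd(.data$volume_um3),
      mean_concentration_per_um3 = mean(.data$concentration_per_um3),
      .groups = "drop")

  correlations <- purrr::map_dfr(probe_groups, function(g) {
    sub <- cl[cl$group == g, ]
    ct <- pearson(sub$volume_um3, sub$spot_count)
    tibble::tibble(group = g, n = ct$n, r = ct$r, r2 = ct$r2,
                   p_value = ct$p_value)
  })

  relative_tccf <- NULL
  tukey <- NULL
  if (!is.null(spots) && nrow(spots) > 0) {
    sp <- tibble::tibble(
      group = as.character(spots[[cmap$group]]),
      tccf = spots[[cmap$tccf]]
    )
    if (cmap$spot_mean_grey %in% names(spots)) {
      sp$spot_mean_grey <- spots[[cmap$spot_mean_grey]]
    }
    if (cmap$background_mean %in% names(spots)) {
      sp$background_mean <- spots[[cmap$background_mean]]
    }
    sp_probe <- sp[sp$group %in% probe_groups, , drop = FALSE]
    relative_tccf <- relative_intensity(sp_probe, value = "tccf")
    if (length(unique(sp_probe$group)) >= 2L) {
      tukey <- anova_tukey(sp_probe, value = "tccf", group = "group")
    }
  }

  false_detection <- NULL
  if (no_probe_group %in% cl$group) {
    false_detection <- false_detection_rate(cl[cl$group == no_probe_group, ])
  }

  structure(list(group_summary = group_summary, correlations = correlations,
                 relative_tccf = relative_tccf, tukey = tukey,
                 false_detection = false_detection),
            class = "fish_report")
}

#' @export
print.fish_report <- function(x, ...) {
  cat("<fish_report>\n-- group summary --\n")
  print(x$group_summary)
  cat("-- count~volume correlations --\n")
  print(x$correlations)
  if (!is.null(x$relative_tccf)) {
    cat("-- relative TCCF --\n")
    print(x$relative_tccf)
  }
  if (!is.null(x$false_detection)) {
    cat("-- false detection (no-probe) --\n")
    print(x$false_detection)
  }
  invisible(x)
}

read_any_table <- function(x) {
  if (is.data.frame(x)) return(tibble::as_tibble(x))
  if (!is.character(x)) stop("expected a data frame or file path", call. = FALSE)
  ext <- tolower(tools::file_ext(x))
  if (ext %in% c("csv", "tsv")) {
    readr::read_delim(x, delim = if (ext == "csv") "," else "\t",
                      show_col_types = FALSE)
  } else if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the readxl package", call. = FALSE)
    }
    tibble::as_tibble(readxl::read_excel(x))
  } else {
    stop("unsupported table format: .", ext, call. = FALSE)
  }
}

#' Write quantification results as tidy CSV
#'
#' Writes `cells.csv` and `spots.csv` (one row per cell / per spot) plus a
#' `run_log.txt` echoing every parameter, into `dir`.
#'
#' @param result A `fish_quant`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_quant_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$cells, file.path(dir, "cells.csv"))
  if (nrow(result$spots) > 0) {
    readr::write_csv(result$spots, file.path(dir, "spots.csv"))
  }
  log <- c(
    paste0("ramfish ", as.character(utils::packageVersion("ramfish"))),
    paste0(names(result$params), " = ",
           vapply(result$params, function(v) paste(format(v), collapse = ","),
                  character(1)))
  )
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Write a reproduce report as CSV files
#'
#' @param report A `fish_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$group_summary, file.path(dir, "group_summary.csv"))
  readr::write_csv(report$correlations, file.path(dir, "correlations.csv"))
  if (!is.null(report$relative_tccf)) {
    readr::write_csv(report$relative_tccf, file.path(dir, "relative_tccf.csv"))
  }
  if (!is.null(report$false_detection)) {
    readr::write_csv(report$false_detection,
                     file.path(dir, "false_detection.csv"))
  }
  if (!is.null(report$tukey)) {
    readr::write_csv(tidy(report$tukey), file.path(dir, "tukey.csv"))
  }
  invisible(dir)
}
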