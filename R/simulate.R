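#' Simulation configuration for synthetic smFISH experiments
#'
#' Returns the default study-like simulation parameters: six experimental
#' groups (five reference probe sets plus a no-probe control) whose cell
#' volume distributions, transcript concentrations, count overdispersion and
#' fluorescence levels emulate the root-apical-meristem data set the package
#' is designed around, plus the imaging model (100 nm pixels, 0.2 um
#' z-sections, ~250 nm FWHM diffraction-limited spots, autofluorescent
#' background, Poisson shot noise and Gaussian read noise, 16-bit camera).
#'
#' Per-group defaults: truncated-normal cell volumes with the printed group
#' means/SDs (e.g. 1191 +/- 536 um^3 for MON1), true concentrations kappa of
#' 0.021-0.039 mRNA um^-3, and a gamma-mixed Poisson count model whose
#' overdispersion `phi` is calibrated in closed form (see [phi_for_r2()]) so
#' the expected count-volume R^2 matches the study-like targets
#' (0.761/0.662/0.734/0.513/0.778). The no-probe group draws spurious spots
#' at 0.29 per cell (one per ~3.4 cells). Spot and background grey levels
#' are chosen so the brightest set (TIP41) reads 100% relative corrected
#' fluorescence and the others 40/38/34/26%.
#'
#' @param ... Named overrides of top-level defaults (e.g. `n_slices = 20`,
#'   `groups = <tibble>`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  groups <- tibble::tibble(
    group     = c("MON1", "TIP41", "AP2M", "NRPB1", "PP2A", "no-probe"),
    n_cells   = c(93L, 93L, 93L, 93L, 93L, 68L),
    vol_mean  = c(1191, 1233, 1278, 996, 1204, 1204),
    vol_sd    = c(536, 506, 604, 495, 544, 601),
    kappa     = c(0.021, 0.023, 0.0288, 0.0390, 0.0391, 0),
    r2_target = c(0.761, 0.662, 0.734, 0.513, 0.778, NA),
    false_rate = c(0, 0, 0, 0, 0, 0.29),
    bg_grey   = c(200, 900, 550, 600, 850, 150),
    spot_delta = c(1600, 4000, 1520, 1360, 1040, 2000)
  )
  groups$phi <- purrr::pmap_dbl(groups, function(kappa, r2_target, vol_mean,
                                                 vol_sd, ...) {
    if (is.na(r2_target) || kappa <= 0) 0 else
      phi_for_r2(r2_target, kappa, vol_mean, vol_sd)
  })
  cfg <- list(
    groups = groups,
    pixel_size_xy = 0.1,      # um
    z_step = 0.2,             # um
    n_slices = 25L,
    cells_per_field = 4L,
    margin_px = 6,
    psf_sigma_xy_px = 1.06,   # FWHM ~ 250 nm at 100 nm pixels
    psf_sigma_z_slices = 1.5, # ~300 nm axial sigma at 0.2 um sections
    amp_mean = 6000,
    amp_sd = 800,
    amp_min = 3400,           # 2 x the 1700 detection prominence
    background = 300,
    autofluor_scale = 0.15,
    autofluor_grain_px = 16,
    read_noise_sd = 30,
    shot_noise = TRUE,
    bit_depth = 16L,
    spot_grey_cv = 0.15,
    bg_cv = 0.05,
    n_background = 20L,
    dye_efficiency = 0.77,
    coloc_jitter_px = 0.5
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim_config field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg <- modifyList(cfg, over)
  }
  stopifnot(cfg$pixel_size_xy > 0, cfg$z_step > 0, cfg$n_slices >= 1)
  structure(cfg, class = "sim_config")
}

# moments of N(mu, sd) truncated to (0, Inf)
truncnorm_moments <- function(mu, sd) {
  alpha <- -mu / sd
  lambda <- dnorm(alpha) / (1 - pnorm(alpha))
  list(mean = mu + sd * lambda,
       var = sd^2 * (1 + alpha * lambda - lambda^2))
}

#' Expected count-volume R^2 under the generative model
#'
#' For volumes V ~ N(mu, sd) truncated above zero and counts
#' N | V ~ Poisson(kappa V G) with gamma multiplier G (mean 1, variance
#' `phi`), the squared Pearson correlation between N and V is
#' `kappa^2 Var(V) / Var(N)` with
#' `Var(N) = kappa E(V) + kappa^2 Var(V) + phi E((kappa V)^2)`.
#' `phi_for_r2()` inverts this for the overdispersion that yields a target
#' R^2 (0 when pure Poisson already falls at or below the target).
#'
#' @param kappa True concentration (mRNA um^-3).
#' @param vol_mean,vol_sd Volume distribution parameters (um^3).
#' @param phi Gamma overdispersion (variance of the mean multiplier).
#' @param r2 Target R^2 in (0, 1).
#' @return A number: expected R^2, or the required `phi`.
#' @export
expected_count_volume_r2 <- function(kappa, vol_mean, vol_sd, phi = 0) {
  tm <- truncnorm_moments(vol_mean, vol_sd)
  S <- kappa^2 * tm$var
  m1 <- kappa * tm$mean
  e2 <- m1^2 + S
  S / (S + m1 + phi * e2)
}

#' @rdname expected_count_volume_r2
#' @export
phi_for_r2 <- function(r2, kappa, vol_mean, vol_sd) {
  stopifnot(r2 > 0, r2 < 1)
  tm <- truncnorm_moments(vol_mean, vol_sd)
  S <- kappa^2 * tm$var
  m1 <- kappa * tm$mean
  e2 <- m1^2 + S
  max(0, (S / r2 - S - m1) / e2)
}

# star-shaped random polygon with the exact target area (pixel^2 units)
random_cell_polygon <- function(area_px, n_vertices = 14) {
  th <- sort(2 * pi * (seq_len(n_vertices) - 1) / n_vertices +
               runif(n_vertices, -0.5, 0.5) * pi / n_vertices)
  rad <- 1 + runif(n_vertices, -0.25, 0.25)
  x <- rad * cos(th); y <- rad * sin(th)
  a0 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  s <- sqrt(area_px / a0)
  cbind(x = s * x, y = s * y)
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Generate study-like cell outlines with known volumes
#'
#' Samples per-cell volumes from the group's truncated-normal distribution,
#' converts them to projected areas (`area = V / (n_slices * z_step)`), and
#' lays out star-shaped random polygons with exactly those areas on
#' non-overlapping grid slots, grouped into square imaging fields of
#' `cells_per_field` cells. Fields are sized to their largest member, so
#' packing never overlaps; a cell too large for any field is a hard error.
#'
#' @param config A [sim_config()].
#' @param group Group label (must appear in `config$groups`).
#' @param n_cells Number of cells (default: the group's configured n).
#' @param seed Integer seed (`NULL` to consume the current RNG stream).
#' @return A tibble (class `sim_cells`): `cell_id`, `group`, `field_id`,
#'   `volume_um3`, `area_um2`, `n_slices`, `centre_y`, `centre_x`,
#'   `vertices` (list-column); attribute `"fields"` holds per-field pixel
#'   sizes.
#' @export
generate_cells <- function(config, group = "MON1", n_cells = NULL, seed = NULL) {
  grow <- config$groups[config$groups$group == group, ]
  if (nrow(grow) != 1L) stop("unknown group '", group, "'", call. = FALSE)
  if (is.null(n_cells)) n_cells <- grow$n_cells
  run <- function() {
    vols <- numeric(n_cells)
    for (i in seq_len(n_cells)) {
      v <- rnorm(1, grow$vol_mean, grow$vol_sd)
      tries <- 0L
      while (v <= 0 && tries < 1000L) {
        v <- rnorm(1, grow$vol_mean, grow$vol_sd)
        tries <- tries + 1L
      }
      if (v <= 0) stop("could not sample a positive volume", call. = FALSE)
      vols[i] <- v
    }
    area_um2 <- vols / (config$n_slices * config$z_step)
    area_px <- area_um2 / config$pixel_size_xy^2
    polys <- purrr::map(area_px, random_cell_polygon)
    bbox <- purrr::map_dbl(polys, ~ 2 * max(abs(.x)) )
    # big cells first so each field's slot is as tight as possible
    ord <- order(bbox, decreasing = TRUE)
    k <- config$cells_per_field
    grid_k <- ceiling(sqrt(k))
    field_of <- ceiling(seq_len(n_cells) / k)
    placed <- vector("list", n_cells)
    centres <- matrix(0, n_cells, 2)
    fields <- tibble::tibble(field_id = integer(0), field_px = integer(0))
    for (f in unique(field_of)) {
      members <- ord[field_of == f]
      slot <- ceiling(max(bbox[members]) + 2 * config$margin_px)
      field_px <- slot * grid_k
      if (field_px > 8192) {
        stop("cell packing infeasible: needed a ", field_px,
             " px field for a cell of bbox ", max(bbox[members]),
             " px; reduce volumes or raise n_slices", call. = FALSE)
      }
      for (j in seq_along(members)) {
        i <- members[j]
        cy <- ((j - 1) %/% grid_k + 0.5) * slot
        cx <- ((j - 1) %% grid_k + 0.5) * slot
        placed[[i]] <- cbind(x = polys[[i]][, 1] + cx,
                             y = polys[[i]][, 2] + cy)
        centres[i, ] <- c(cy, cx)
      }
      fields <- dplyr::bind_rows(fields,
                                 tibble::tibble(field_id = f,
                                                field_px = as.integer(field_px)))
    }
    out <- tibble::tibble(
      cell_id = sprintf("%s_c%03d", group, seq_len(n_cells)),
      group = group,
      field_id = field_of[match(seq_len(n_cells), ord)],
      volume_um3 = purrr::map_dbl(placed, shoelace_area) *
        config$pixel_size_xy^2 * config$n_slices * config$z_step,
      area_um2 = purrr::map_dbl(placed, shoelace_area) * config$pixel_size_xy^2,
      n_slices = as.integer(config$n_slices),
      centre_y = centres[, 1],
      centre_x = centres[, 2],
      vertices = placed
    )
    attr(out, "fields") <- fields
    class(out) <- c("sim_cells", class(out))
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Sample per-cell transcript counts
#'
#' Counts are Poisson around `kappa * V`, optionally gamma-mixed
#' (negative-binomial-like) with overdispersion `phi` to push the
#' count-volume R^2 below the pure-Poisson limit (see
#' [expected_count_volume_r2()]).
#'
#' @param volumes Cell volumes in um^3.
#' @param kappa True concentration (mRNA um^-3, >= 0).
#' @param phi Gamma overdispersion (>= 0; 0 = pure Poisson).
#' @param seed Integer seed (`NULL` to consume the current stream).
#' @return Integer vector of counts.
#' @export
sample_counts <- function(volumes, kappa, phi = 0, seed = NULL) {
  stopifnot(kappa >= 0, phi >= 0)
  run <- function() {
    mult <- if (phi > 0) rgamma(length(volumes), shape = 1 / phi, rate = 1 / phi) else 1
    rpois(length(volumes), kappa * volumes * mult)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# uniform points inside a polygon shrunk toward its centroid
sample_points_in_polygon <- function(v, n, shrink = 0.9) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  cx <- mean(v[, 1]); cy <- mean(v[, 2])
  sv <- cbind(cx + shrink * (v[, 1] - cx), cy + shrink * (v[, 2] - cy))
  out <- matrix(0, n, 2)
  got <- 0L
  guard <- 0L
  while (got < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("spot placement failed", call. = FALSE)
    m <- (n - got) * 3L
    px <- runif(m, min(sv[, 1]), max(sv[, 1]))
    py <- runif(m, min(sv[, 2]), max(sv[, 2]))
    keep <- points_in_polygon(px, py, sv[, 1], sv[, 2])
    take <- min(sum(keep), n - got)
    if (take > 0) {
      out[(got + 1):(got + take), ] <- cbind(px[keep], py[keep])[seq_len(take), ]
      got <- got + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

# slowly varying multiplicative autofluorescence texture (bilinear upsample
# of a coarse Gaussian grid)
smooth_texture <- function(ny, nx, grain, scale) {
  ncy <- max(1L, ceiling(ny / grain)) + 1L
  ncx <- max(1L, ceiling(nx / grain)) + 1L
  g <- matrix(rnorm(ncy * ncx), ncy, ncx)
  fy <- (seq_len(ny) - 1) / grain
  fx <- (seq_len(nx) - 1) / grain
  iy <- pmin(floor(fy), ncy - 2L); ty <- fy - iy
  ix <- pmin(floor(fx), ncx - 2L); tx <- fx - ix
  G11 <- g[iy + 1, ix + 1, drop = FALSE]; G12 <- g[iy + 1, ix + 2, drop = FALSE]
  G21 <- g[iy + 2, ix + 1, drop = FALSE]; G22 <- g[iy + 2, ix + 2, drop = FALSE]
  tex <- (1 - ty) %o% (1 - tx) * G11 + (1 - ty) %o% tx * G12 +
    ty %o% (1 - tx) * G21 + ty %o% tx * G22
  pmax(1 + scale * tex, 0.2)
}

#' Render a synthetic smFISH z-stack
#'
#' Renders each true spot as a 3D Gaussian (default sigma 1.06 px laterally,
#' ~250 nm FWHM; 1.5 slices axially) on an autofluorescent background,
#' applies Poisson shot noise and Gaussian read noise if configured, and
#' quantizes to the camera bit depth. Warns if more than 1% of voxels
#' saturate.
#'
#' @param truth Tibble of true spots: columns `y`, `x`, `z` (0-based, may be
#'   fractional) and `amplitude` (peak grey value above background).
#' @param field_px Field side length in pixels.
#' @param config A [sim_config()].
#' @param noise Apply shot/read noise (default `TRUE`; `FALSE` gives the
#'   noiseless expectation, still quantized).
#' @param quantize Round and clip to the camera bit depth (default `TRUE`).
#' @return An [image_stack()].
#' @export
render_stack <- function(truth, field_px, config, noise = TRUE,
                         quantize = TRUE) {
  ny <- nx <- as.integer(field_px)
  nz <- config$n_slices
  tex <- smooth_texture(ny, nx, config$autofluor_grain_px,
                        config$autofluor_scale)
  vox <- array(rep(config$background * tex, nz), dim = c(ny, nx, nz))
  sxy <- config$psf_sigma_xy_px
  sz <- config$psf_sigma_z_slices
  wxy <- ceiling(5 * sxy)
  wz <- ceiling(5 * sz)
  for (i in seq_len(nrow(truth))) {
    y0 <- truth$y[i]; x0 <- truth$x[i]; z0 <- truth$z[i]
    A <- truth$amplitude[i]
    ys <- max(0, floor(y0) - wxy):min(ny - 1, ceiling(y0) + wxy)
    xs <- max(0, floor(x0) - wxy):min(nx - 1, ceiling(x0) + wxy)
    zs <- max(0, floor(z0) - wz):min(nz - 1, ceiling(z0) + wz)
    gy <- exp(-(ys - y0)^2 / (2 * sxy^2))
    gx <- exp(-(xs - x0)^2 / (2 * sxy^2))
    gz <- exp(-(zs - z0)^2 / (2 * sz^2))
    patch <- gy %o% gx
    for (k in seq_along(zs)) {
      vox[ys + 1, xs + 1, zs[k] + 1] <- vox[ys + 1, xs + 1, zs[k] + 1] +
        A * gz[k] * patch
    }
  }
  if (noise) {
    n <- length(vox)
    v <- rpois(n, as.vector(vox))
    if (config$read_noise_sd > 0) v <- v + rnorm(n, 0, config$read_noise_sd)
    vox <- array(v, dim = dim(vox))
  }
  cap <- 2^config$bit_depth - 1
  if (quantize) {
    vox <- round(vox)
    sat <- mean(vox >= cap)
    if (sat > 0.01) warning(sprintf("%.1f%% of voxels saturate", 100 * sat),
                            call. = FALSE)
    vox <- pmin(pmax(vox, 0), cap)
  }
  image_stack(vox, pixel_size_xy = config$pixel_size_xy,
              z_step = config$z_step, bit_depth = config$bit_depth)
}

# truncated-normal spot amplitudes (peak grey above background)
sample_amplitudes <- function(n, config) {
  a <- rnorm(n, config$amp_mean, config$amp_sd)
  bad <- a < config$amp_min
  guard <- 0L
  while (any(bad)) {
    guard <- guard + 1L
    if (guard > 1000L) stop("amplitude sampling failed", call. = FALSE)
    a[bad] <- rnorm(sum(bad), config$amp_mean, config$amp_sd)
    bad <- a < config$amp_min
  }
  a
}

#' Simulate a complete imaging experiment with ground truth
#'
#' Generates cells ([generate_cells()]), samples true counts
#' ([sample_counts()]) and spot positions inside each cell, renders every
#' field ([render_stack()]) and returns stacks, ROIs and ground truth
#' together. The no-probe group draws spurious spots at its configured
#' per-cell rate instead of volume-scaled counts.
#'
#' @param config A [sim_config()].
#' @param group Group label.
#' @param n_cells Number of cells (default: group's configured n).
#' @param seed Integer seed (required: the whole experiment is reproducible).
#' @param noise Passed to [render_stack()].
#' @return A list of class `sim_experiment`: `cells` (the `sim_cells`
#'   tibble), `truth` (tibble of true spots with cell and field ids) and
#'   `fields`, a list with per-field `stack`, `rois` and `truth`.
#' @export
simulate_experiment <- function(config, group = "MON1", n_cells = NULL, seed,
                                noise = TRUE) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  grow <- config$groups[config$groups$group == group, ]
  if (nrow(grow) != 1L) stop("unknown group '", group, "'", call. = FALSE)
  withr::with_seed(seed, {
    cells <- generate_cells(config, group = group, n_cells = n_cells)
    counts <- if (grow$kappa > 0) {
      sample_counts(cells$volume_um3, grow$kappa, grow$phi)
    } else {
      rpois(nrow(cells), grow$false_rate)
    }
    truth <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      n <- counts[i]
      if (n == 0L) return(NULL)
      pts <- sample_points_in_polygon(cells$vertices[[i]], n)
      tibble::tibble(
        cell_id = cells$cell_id[i], group = group,
        field_id = cells$field_id[i],
        x = pts[, 1], y = pts[, 2],
        z = runif(n, 3, config$n_slices - 4),
        amplitude = sample_amplitudes(n, config)
      )
    })
    fields_tbl <- attr(cells, "fields")
    fields <- purrr::map(fields_tbl$field_id, function(f) {
      ft <- truth[truth$field_id == f, , drop = FALSE]
      stack <- render_stack(ft, fields_tbl$field_px[fields_tbl$field_id == f],
                            config, noise = noise)
      in_field <- cells$field_id == f
      rois <- bind_rois(!!!purrr::map(which(in_field), function(i) {
        cell_roi(cells$cell_id[i], cells$vertices[[i]], group = group,
                 n_slices = cells$n_slices[i])
      }))
      list(field_id = f, stack = stack, rois = rois, truth = ft)
    })
    structure(list(config = config, group = group, cells = cells,
                   truth = truth, fields = fields),
              class = "sim_experiment")
  })
}

#' Simulate a dual-dye (odd/even probe set) co-localization experiment
#'
#' True transcript positions are drawn per cell; each dye channel observes
#' every transcript independently with probability `dye_efficiency` and
#' localizes it with isotropic Gaussian jitter (`coloc_jitter_px`). The
#' defaults emulate splitting one probe set into interleaved odd/even halves
#' with different dyes.
#'
#' @param config A [sim_config()].
#' @param n_cells Number of cells (default 20).
#' @param mean_spots Mean true transcripts per cell (default 26).
#' @param seed Integer seed.
#' @return List with `spots_a`, `spots_b` (tibbles: `cell_id`, `y`, `x`) and
#'   `truth`.
#' @export
simulate_dual_dye <- function(config, n_cells = 20L, mean_spots = 26, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(seed, {
    truth <- purrr::map_dfr(seq_len(n_cells), function(i) {
      n <- rpois(1, mean_spots)
      tibble::tibble(cell_id = sprintf("c%03d", i),
                     y = runif(n, 0, 200), x = runif(n, 0, 200))
    })
    observe <- function() {
      keep <- runif(nrow(truth)) < config$dye_efficiency
      tibble::tibble(
        cell_id = truth$cell_id[keep],
        y = truth$y[keep] + rnorm(sum(keep), 0, config$coloc_jitter_px),
        x = truth$x[keep] + rnorm(sum(keep), 0, config$coloc_jitter_px)
      )
    }
    list(spots_a = observe(), spots_b = observe(), truth = truth)
  })
}

#' Generate a study-like per-cell and per-spot measurement table
#'
#' Emits the tabular form of a full six-group experiment without rendering
#' images: per-cell rows (count, area, volume, concentration) for all five
#' probe sets and the no-probe control, and per-spot rows (mean grey,
#' background, TCCF over the 3x3 spot ROI) drawn from the group fluorescence
#' defaults. With default parameters the table is statistically consistent
#' with the study-like design centres (median counts 26/29/37/37/46,
#' MON1 mean volume ~1191 um^3, concentrations ~0.021-0.039 um^-3, relative
#' TCCF 40/38/34/26% of TIP41, ~0.29 spurious spots per no-probe cell).
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `study_table`: `cells`, `spots`, `background`
#'   tibbles.
#' @export
generate_study_table <- function(config, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  withr::with_seed(seed, {
    cells_all <- list(); spots_all <- list(); bg_all <- list()
    for (gi in seq_len(nrow(config$groups))) {
      g <- config$groups[gi, ]
      vols <- numeric(g$n_cells)
      for (i in seq_len(g$n_cells)) {
        v <- rnorm(1, g$vol_mean, g$vol_sd)
        while (v <= 0) v <- rnorm(1, g$vol_mean, g$vol_sd)
        vols[i] <- v
      }
      counts <- if (g$kappa > 0) {
        sample_counts(vols, g$kappa, g$phi)
      } else {
        rpois(g$n_cells, g$false_rate)
      }
      cell_ids <- sprintf("%s_c%03d", g$group, seq_len(g$n_cells))
      cells_all[[gi]] <- tibble::tibble(
        cell_id = cell_ids, group = g$group, spot_count = counts,
        area_um2 = vols / (config$n_slices * config$z_step),
        n_slices = as.integer(config$n_slices),
        volume_um3 = vols,
        concentration_per_um3 = counts / vols
      )
      bg_vals <- rnorm(config$n_background, g$bg_grey, config$bg_cv * g$bg_grey)
      bg_mean <- mean(bg_vals)
      bg_all[[gi]] <- tibble::tibble(group = g$group,
                                     sample = seq_len(config$n_background),
                                     mean_grey = bg_vals)
      n_spots <- sum(counts)
      if (n_spots > 0) {
        spot_grey <- rnorm(n_spots, g$bg_grey + g$spot_delta,
                           config$spot_grey_cv * g$spot_delta)
        spots_all[[gi]] <- tibble::tibble(
          spot_id = sprintf("%s_s%05d", g$group, seq_len(n_spots)),
          cell_id = rep(cell_ids, counts),
          group = g$group,
          spot_mean_grey = spot_grey,
          raw_integrated_density = 9 * spot_grey,
          area_px = 9L,
          background_mean = bg_mean,
          tccf = 9 * spot_grey - 9 * bg_mean
        )
      }
    }
    structure(list(cells = dplyr::bind_rows(cells_all),
                   spots = dplyr::bind_rows(spots_all),
                   background = dplyr::bind_rows(bg_all)),
              class = "study_table")
  })
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d cells, %d spots, %d groups\n",
              nrow(x$cells), nrow(x$spots), length(unique(x$cells$group))))
  invisible(x)
}

#' Write a study table to CSV files
#'
#' Writes `cells.csv`, `spots.csv` and `background.csv` into `dir`.
#' Deterministic input gives byte-identical files.
#'
#' @param table A `study_table`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(table$cells, file.path(dir, "cells.csv"))
  readr::write_csv(table$spots, file.path(dir, "spots.csv"))
  readr::write_csv(table$background, file.path(dir, "background.csv"))
  invisible(dir)
}
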