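cfg <- sim_config()

test_that("generated cells satisfy the volume identity and are reproducible", {
  one <- generate_cells(cfg, "MON1", n_cells = 1, seed = 3)
  expect_equal(one$volume_um3,
               one$area_um2 * one$n_slices * cfg$z_step, tolerance = 1e-10)

  a <- generate_cells(cfg, "TIP41", n_cells = 6, seed = 12)
  b <- generate_cells(cfg, "TIP41", n_cells = 6, seed = 12)
  expect_identical(a$vertices, b$vertices)
  c2 <- generate_cells(cfg, "TIP41", n_cells = 6, seed = 13)
  expect_false(identical(a$vertices, c2$vertices))

  expect_error(generate_cells(cfg, "NOPE", 3, seed = 1), "unknown group")
})

test_that("sampled cell volumes match the configured group distribution", {
  cells <- generate_cells(cfg, "MON1", n_cells = 200, seed = 77)
  se <- 536 / sqrt(200)
  expect_lt(abs(mean(cells$volume_um3) - 1191), 3 * se)
  expect_gt(sd(cells$volume_um3), 536 * 0.8)
  expect_lt(sd(cells$volume_um3), 536 * 1.2)
})

test_that("cell polygons stay inside their fields and never overlap", {
  cells <- generate_cells(cfg, "AP2M", n_cells = 8, seed = 31)
  fields <- attr(cells, "fields")
  for (f in fields$field_id) {
    sub <- cells[cells$field_id == f, ]
    fpx <- fields$field_px[fields$field_id == f]
    for (i in seq_len(nrow(sub))) {
      v <- sub$vertices[[i]]
      expect_true(all(v >= 0 & v <= fpx))
      if (i > 1) {
        for (j in 1:(i - 1)) {
          w <- sub$vertices[[j]]
          expect_false(any(points_in_polygon(v[, 1], v[, 2], w[, 1], w[, 2])))
        }
      }
    }
  }
})

test_that("count sampling follows the Poisson-gamma model", {
  expect_true(all(sample_counts(c(100, 1000, 2000), 0, seed = 1) == 0))
  withr::with_seed(17, {
    n <- 20000
    cnt <- sample_counts(rep(1191, n), 0.021, phi = 0)
    expect_lt(abs(mean(cnt) - 0.021 * 1191), 3 * sqrt(25 / n))
  })
})

test_that("closed-form count-volume R^2 matches a Monte-Carlo oracle", {
  withr::with_seed(19, {
    n <- 60000
    mu <- 1191; sdv <- 536; kappa <- 0.021
    v <- rnorm(n, mu, sdv)
    while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), mu, sdv)
    for (phi in c(0, 0.02, 0.1)) {
      cnt <- sample_counts(v, kappa, phi)
      expect_equal(cor(v, cnt)^2,
                   expected_count_volume_r2(kappa, mu, sdv, phi),
                   tolerance = 0.04)
    }
    # phi_for_r2 inverts the closed form
    for (r2 in c(0.5, 0.661, 0.761)) {
      phi <- phi_for_r2(r2, kappa, mu, sdv)
      expect_equal(expected_count_volume_r2(kappa, mu, sdv, phi), r2,
                   tolerance = 1e-10)
    }
  })
})

test_that("rendering is deterministic, conserves photons and places peaks truly", {
  quiet <- sim_config(autofluor_scale = 0, shot_noise = FALSE,
                      read_noise_sd = 0)
  # no spots, no noise -> constant stack at the background level
  empty <- tibble::tibble(y = numeric(0), x = numeric(0), z = numeric(0),
                          amplitude = numeric(0))
  st0 <- withr::with_seed(1, render_stack(empty, 40, quiet, noise = FALSE))
  expect_true(all(st0$voxels == quiet$background))

  # single spot, no noise: the projection argmax is the true position
  tr <- tibble::tibble(y = 21, x = 13, z = 12, amplitude = 5000)
  st1 <- withr::with_seed(1, render_stack(tr, 40, quiet, noise = FALSE))
  proj <- max_z_project(st1)
  pk <- which(proj == max(proj), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(22, 14))  # 1-based matrix indices

  # photon conservation of the noiseless, unquantized render
  tr3 <- tibble::tibble(y = c(10.2, 30.7, 20.1), x = c(12.5, 8.3, 30.8),
                        z = c(10, 12, 14), amplitude = c(5000, 6000, 4500))
  st3 <- withr::with_seed(1, render_stack(tr3, 48, quiet, noise = FALSE,
                                          quantize = FALSE))
  spot_sum <- sum(st3$voxels) - quiet$background * 48 * 48 * quiet$n_slices
  mass <- sum(tr3$amplitude) * 2 * pi * quiet$psf_sigma_xy_px^2 *
    sqrt(2 * pi) * quiet$psf_sigma_z_slices
  expect_equal(spot_sum, mass, tolerance = 1e-3)

  # full render determinism under an identical seed
  sa <- simulate_experiment(cfg, "MON1", n_cells = 2, seed = 5)
  sb <- simulate_experiment(cfg, "MON1", n_cells = 2, seed = 5)
  expect_identical(sa$fields[[1]]$stack$voxels, sb$fields[[1]]$stack$voxels)
  expect_identical(sa$truth, sb$truth)
})

test_that("ground-truth spots lie inside their cell polygons", {
  sim <- simulate_experiment(cfg, "PP2A", n_cells = 3, seed = 8)
  for (cid in unique(sim$truth$cell_id)) {
    v <- sim$cells$vertices[[match(cid, sim$cells$cell_id)]]
    tr <- sim$truth[sim$truth$cell_id == cid, ]
    expect_true(all(points_in_polygon(tr$x, tr$y, v[, 1], v[, 2])))
  }
  expect_equal(nrow(sim$truth),
               sum(purrr::map_int(unique(sim$truth$cell_id), ~ sum(sim$truth$cell_id == .x))))
})

test_that("study table is seeded, consistent and hits its design centres", {
  t1 <- generate_study_table(cfg, seed = 14)
  t2 <- generate_study_table(cfg, seed = 14)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study_table(t1, d1); write_study_table(t2, d2)
  expect_identical(readLines(file.path(d1, "cells.csv")),
                   readLines(file.path(d2, "cells.csv")))
  expect_identical(readLines(file.path(d1, "spots.csv")),
                   readLines(file.path(d2, "spots.csv")))

  # internal consistency of the schema
  expect_equal(t1$cells$concentration_per_um3,
               t1$cells$spot_count / t1$cells$volume_um3)
  expect_equal(t1$cells$volume_um3,
               t1$cells$area_um2 * t1$cells$n_slices * cfg$z_step)
  expect_equal(nrow(t1$spots[t1$spots$group == "MON1", ]),
               sum(t1$cells$spot_count[t1$cells$group == "MON1"]))
  expect_equal(t1$spots$tccf,
               t1$spots$raw_integrated_density -
                 t1$spots$area_px * t1$spots$background_mean)

  # stochastic design centres at the configured n (generous sampling bands)
  med <- median_counts(t1$cells, "MON1")
  expect_gt(med, 21); expect_lt(med, 31)
  fdr <- false_detection_rate(t1$cells[t1$cells$group == "no-probe", ])
  expect_gt(fdr$spots_per_cell, 0.1); expect_lt(fdr$spots_per_cell, 0.55)
  rel <- relative_intensity(t1$spots[t1$spots$group != "no-probe", ])
  expect_equal(rel$relative_pct[rel$group == "TIP41"], 100)
  expect_equal(rel$relative_pct[rel$group == "MON1"], 40, tolerance = 0.05)
  expect_equal(rel$relative_pct[rel$group == "PP2A"], 26, tolerance = 0.06)
})

test_that("dual-dye simulation co-localizes near the configured efficiency", {
  dd <- simulate_dual_dye(cfg, n_cells = 40, seed = 22)
  got <- colocalization(dd$spots_a, dd$spots_b, max_dist_px = 2)
  expect_gt(got$fraction, 0.70)
  expect_lt(got$fraction, 0.85)
})
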