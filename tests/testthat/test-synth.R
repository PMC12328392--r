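test_that("peak libraries have the requested composition and placement", {
  g <- default_sim_grid()
  lib <- simulate_peak_library(1, 10, 5, 3, g)
  expect_equal(nrow(lib), 20)
  expect_equal(sum(lib$active), 3)
  act <- lib[lib$active, ]
  expect_true(all(act$retention_min >= 20 & act$retention_min <= 35))
  expect_true(all(lib$retention_min > g$start_min & lib$retention_min < g$end_min))
  # shared peaks have equal amplitudes; specific peaks are zero elsewhere
  for (i in seq_len(nrow(lib))) {
    a <- lib$amplitude[[i]]
    if (lib$class[i] == "shared") {
      expect_equal(a[["species_A"]], a[["species_B"]])
    } else {
      other <- setdiff(names(a), lib$class[i])
      expect_identical(unname(a[other]), 0)
    }
  }
})

test_that("peak libraries are deterministic in the seed", {
  g <- default_sim_grid()
  expect_identical(
    simulate_peak_library(1, 10, 5, 3, g),
    simulate_peak_library(1, 10, 5, 3, g)
  )
  expect_false(isTRUE(all.equal(
    simulate_peak_library(1, 10, 5, 3, g)$retention_min,
    simulate_peak_library(2, 10, 5, 3, g)$retention_min
  )))
})

test_that("impossible library requests are rejected", {
  g <- default_sim_grid()
  expect_error(simulate_peak_library(1, 2, 1, 4, g), "n_active")
  narrow <- make_time_grid(0, 10, 30)
  expect_error(simulate_peak_library(1, 3, 1, 1, narrow), "active-peak window")
  expect_silent(simulate_peak_library(1, 3, 1, 0, narrow))
})

test_that("a noiseless single-peak chromatogram has its apex at the planted height", {
  grid <- make_time_grid(20, 40, 0.4)
  lib <- test_library(retention = 30, sigma = 0.1, amp_a = 1)
  cfg <- noiseless_cfg()
  ch <- simulate_chromatogram(lib, "species_A", "A_E01", 1, grid, cfg)
  a <- ch$absorbance[[1]]
  expect_equal(max(a), 1.0, tolerance = 1e-12)  # 30 min lies on the grid
  expect_equal(grid$points[which.max(a)], 30)
  # all-zero amplitude map leaves drift + noise only (here: exactly zero)
  lib0 <- test_library(amp_a = 0, amp_b = 0)
  ch0 <- simulate_chromatogram(lib0, "species_A", "A_E01", 1, grid, cfg)
  expect_equal(max(abs(ch0$absorbance[[1]])), 0)
  expect_error(
    simulate_chromatogram(lib, "species_C", "A_E01", 1, grid, cfg),
    "absent"
  )
})

test_that("the integral of a noiseless simulated peak matches the Gaussian area", {
  grid <- make_time_grid(20, 40, 0.4)
  cfg <- noiseless_cfg()
  for (sg in c(0.08, 0.12, 0.18)) {
    lib <- test_library(retention = 30, sigma = sg, amp_a = 0.7)
    ch <- simulate_chromatogram(lib, "species_A", "A_E01", 1, grid, cfg)
    riemann <- sum(ch$absorbance[[1]]) * grid$spacing_s / 60
    expect_equal(riemann, 0.7 * sg * sqrt(2 * pi), tolerance = 0.01)
  }
})

test_that("duplicate injections share extract structure and correlate above the gate", {
  grid <- default_sim_grid()
  cfg <- sim_config(seed = 3)
  lib <- simulate_peak_library(7, 12, 10, 3, grid)
  r1 <- simulate_chromatogram(lib, "species_B", "B_E01", 1, grid, cfg)
  r2 <- simulate_chromatogram(lib, "species_B", "B_E01", 2, grid, cfg)
  expect_gte(cor(r1$absorbance[[1]], r2$absorbance[[1]]), 0.93)
  # determinism: the exact same call reproduces byte-identical traces
  r1b <- simulate_chromatogram(lib, "species_B", "B_E01", 1, grid, cfg)
  expect_identical(r1$absorbance[[1]], r1b$absorbance[[1]])
})

test_that("blanks carry drift and noise but no peak structure", {
  grid <- default_sim_grid()
  bl0 <- simulate_blank(grid, noiseless_cfg())
  expect_true(bl0$blank[1])
  expect_equal(max(abs(bl0$absorbance[[1]])), 0)
  cfg <- sim_config(seed = 5)
  bl <- simulate_blank(grid, cfg)
  expect_true(bl$blank[1])
  # peak-scan oracle: after baseline removal nothing peak-like remains
  corrected <- estimate_baseline(bl)$corrected
  expect_lte(max(abs(corrected)), 5 * cfg$noise_sd)
})

test_that("assay panels are driven by the latent activity", {
  cfg <- sim_config(seed = 2)
  lib <- simulate_peak_library(
    11, cfg$n_shared, cfg$n_specific_per_species, cfg$n_active
  )
  truth <- simulate_truth(lib, cfg)
  expect_setequal(truth$active_peak_ids, lib$peak_id[lib$active])
  expect_gt(truth$species_effect, 0)

  # zero assay noise: all four columns are perfectly rank-correlated
  cfg0 <- sim_config(seed = 2, assay_noise_fraction = 0)
  p0 <- simulate_assay_panel(truth, cfg0)
  cols <- c("tp_mg_gae_g", "dpph_mg_te_g", "abts_mg_te_g", "frap_mg_te_g")
  for (a in cols) {
    for (b in cols) {
      expect_equal(cor(p0[[a]], p0[[b]], method = "spearman"), 1)
    }
  }

  # default noise: planted group ordering holds in every assay
  p <- simulate_assay_panel(truth, cfg)
  for (a in cols) {
    mns <- tapply(p[[a]], p$species, mean)
    expect_gt(mns[["species_B"]], mns[["species_A"]])
  }
  expect_identical(p, simulate_assay_panel(truth, cfg))
})

test_that("datasets have the study-design sample counts", {
  ds_small <- simulate_dataset(small_cfg(seed = 4))
  expect_equal(nrow(ds_small$chromatograms), 2 * 6 * 2)
  expect_equal(nrow(ds_small$blanks), 1)
  expect_equal(nrow(ds_small$assay_panel), 12)

  # degenerate single-sample design still renders
  cfg1 <- sim_config(
    n_species = 1, n_extracts_per_species = 1, n_injection_replicates = 1,
    wavelengths_nm = 280L
  )
  ds1 <- simulate_dataset(cfg1)
  expect_equal(nrow(ds1$chromatograms), 1)

  # default study design: 80 chromatograms per wavelength
  ds <- default_ds()
  counts <- table(ds$chromatograms$wavelength_nm)
  expect_true(all(counts == 80))
  expect_setequal(ds$truth$active_peak_ids,
    ds$peak_library$peak_id[ds$peak_library$active]
  )
  # standards table names the active peaks at their true retentions
  expect_equal(nrow(ds$standards), 3)
  expect_setequal(ds$standards$compound,
    c("vitexin", "tannic acid", "chlorogenic acid")
  )
  expect_true(all(
    ds$standards$retention_min %in%
      ds$peak_library$retention_min[ds$peak_library$active]
  ))
})

test_that("identical configurations reproduce identical datasets", {
  cfg <- small_cfg(seed = 9)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$chromatograms$absorbance, d2$chromatograms$absorbance)
  expect_identical(d1$assay_panel, d2$assay_panel)
  expect_identical(d1$truth$latent, d2$truth$latent)
})

test_that("species are separable in correlation distance", {
  ds <- simulate_dataset(small_cfg(seed = 6))
  fm <- preprocess_dataset(ds, 280)
  D <- correlation_distance(fm)$D
  same <- outer(fm$species, fm$species, "==")
  ut <- upper.tri(D)
  expect_gt(mean(D[ut & !same]), mean(D[ut & same]))
})
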