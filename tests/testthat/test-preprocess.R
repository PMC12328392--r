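make_chrom <- function(a, id = "x", wl = 280L, t = NULL, blank = FALSE,
                       species = "species_A", extract = "E01", rep_ = 1L) {
  if (is.null(t)) t <- seq(0, by = 1 / 150, length.out = length(a))
  tibble::tibble(
    sample_id = id, species = species, extract_id = extract,
    replicate = rep_, wavelength_nm = wl, blank = blank,
    time_min = list(t), absorbance = list(a)
  )
}

test_that("blank subtraction is exact, linear and metadata-preserving", {
  set.seed(1)
  a <- rnorm(300)
  b <- rnorm(300)
  blank <- make_chrom(a, id = "bl", blank = TRUE)
  # chrom == blank -> zero trace
  out <- subtract_blank(make_chrom(a), blank)
  expect_equal(out$absorbance[[1]], rep(0, 300))
  # zero blank -> identity
  out <- subtract_blank(make_chrom(a), make_chrom(rep(0, 300), blank = TRUE))
  expect_equal(out$absorbance[[1]], a)
  # linearity: subtract(a + b, blank) = subtract(a, blank) + b
  s_ab <- subtract_blank(make_chrom(a + b), blank)$absorbance[[1]]
  s_a <- subtract_blank(make_chrom(a), blank)$absorbance[[1]]
  expect_equal(s_ab, s_a + b)
  expect_identical(out$sample_id, "x")
  expect_false(out$blank)
})

test_that("blank subtraction validates grids, wavelengths and flags", {
  a <- rnorm(100)
  expect_error(
    subtract_blank(make_chrom(a), make_chrom(a[1:50], blank = TRUE)),
    "Grid mismatch"
  )
  expect_error(
    subtract_blank(make_chrom(a), make_chrom(a, wl = 330L, blank = TRUE)),
    "No blank supplied"
  )
  expect_error(
    subtract_blank(make_chrom(a), make_chrom(a, blank = FALSE)),
    "blank = TRUE"
  )
})

test_that("subtracting a shared drift leaves only detector noise", {
  grid <- make_time_grid(10, 30, 2)
  cfg <- sim_config(seed = 8, noise_sd = 0)
  drift_only <- simulate_blank(grid, cfg)$absorbance[[1]]
  noise_sd <- 0.005
  set.seed(42)
  noise <- rnorm(length(drift_only), 0, noise_sd)
  chrom <- make_chrom(drift_only + noise, t = grid$points)
  blank <- make_chrom(drift_only, t = grid$points, blank = TRUE)
  resid <- subtract_blank(chrom, blank)$absorbance[[1]]
  expect_equal(sd(resid), noise_sd, tolerance = 0.15)
  expect_lte(max(abs(resid)), 4 * noise_sd)
})

test_that("replicate correlation handles exact, inverted and constant traces", {
  set.seed(2)
  x <- rnorm(200)
  two <- dplyr::bind_rows(
    make_chrom(x, id = "r1", rep_ = 1L),
    make_chrom(x, id = "r2", rep_ = 2L)
  )
  expect_equal(replicate_correlation(two)$min_r, 1.0)
  anti <- dplyr::bind_rows(
    make_chrom(x, id = "r1", rep_ = 1L),
    make_chrom(-x, id = "r2", rep_ = 2L)
  )
  expect_equal(replicate_correlation(anti)$min_r, -1.0)
  const <- dplyr::bind_rows(
    make_chrom(x, id = "r1", rep_ = 1L),
    make_chrom(rep(1, 200), id = "flat", rep_ = 2L)
  )
  expect_error(replicate_correlation(const), "flat")
  expect_error(replicate_correlation(make_chrom(x)), "at least 2")
})

test_that("the reproducibility gate partitions extracts and warns on failures", {
  rs <- tibble::tibble(
    wavelength_nm = 280L, extract_id = c("a", "b"),
    species = "species_A", n_replicates = 2L, min_r = c(0.95, 0.90)
  )
  expect_warning(out <- gate_reproducibility(rs, 0.93), "b@280nm")
  expect_identical(out$extract_id[out$pass], "a")
  expect_identical(out$extract_id[!out$pass], "b")
  expect_silent(out0 <- gate_reproducibility(rs, 0))
  expect_true(all(out0$pass))
  rs$min_r <- c(1, 1)
  expect_silent(out1 <- gate_reproducibility(rs))
  expect_true(all(out1$pass))
})

test_that("consolidation averages replicates pointwise", {
  x <- rnorm(100)
  # identical replicates: idempotence
  two <- dplyr::bind_rows(
    make_chrom(x, id = "r1", rep_ = 1L), make_chrom(x, id = "r2", rep_ = 2L)
  )
  cons <- consolidate_replicates(two)
  expect_equal(cons$absorbance[[1]], x)
  expect_identical(cons$sample_id, "E01")
  # {0, 2} -> 1
  pair <- dplyr::bind_rows(
    make_chrom(rep(0, 100), id = "r1", rep_ = 1L),
    make_chrom(rep(2, 100), id = "r2", rep_ = 2L)
  )
  expect_equal(consolidate_replicates(pair)$absorbance[[1]], rep(1, 100))
  expect_equal(
    consolidate_replicates(pair, "median")$absorbance[[1]], rep(1, 100)
  )
})

test_that("consolidating k noisy copies shrinks noise like 1/sqrt(k)", {
  k <- 4
  sds <- replicate(200, {
    reps <- dplyr::bind_rows(lapply(seq_len(k), function(r) {
      make_chrom(rnorm(50), id = paste0("r", r), rep_ = r)
    }))
    sd(consolidate_replicates(reps)$absorbance[[1]])
  })
  expect_equal(mean(sds), 1 / sqrt(k), tolerance = 0.05)
})

test_that("group medians are robust pointwise summaries", {
  # a single-member group is returned unchanged
  one <- make_chrom(rnorm(60), id = "a", extract = "a")
  m1 <- group_median(one)
  expect_equal(m1$absorbance[[1]], one$absorbance[[1]])
  # {0, 1, 100} -> 1: the outlier is ignored
  tri <- dplyr::bind_rows(
    make_chrom(rep(0, 60), id = "a", extract = "a"),
    make_chrom(rep(1, 60), id = "b", extract = "b"),
    make_chrom(rep(100, 60), id = "c", extract = "c")
  )
  expect_equal(group_median(tri)$absorbance[[1]], rep(1, 60))
  # matches a sort-based oracle on random input
  set.seed(3)
  traces <- lapply(1:5, function(i) rnorm(20))
  five <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_chrom(traces[[i]], id = letters[i], extract = letters[i])
  }))
  oracle <- apply(do.call(rbind, traces), 2, function(v) sort(v)[3])
  expect_equal(group_median(five)$absorbance[[1]], oracle)
})

test_that("window cropping is inclusive, idempotent and guarded", {
  grid <- default_sim_grid()
  ch <- make_chrom(rnorm(length(grid$points)), t = grid$points)
  full <- crop_window(ch, grid$start_min, grid$end_min)
  expect_equal(full$absorbance[[1]], ch$absorbance[[1]])
  cropped <- crop_window(ch)
  expect_length(cropped$time_min[[1]], 7696)
  expect_equal(range(cropped$time_min[[1]]), c(13.2, 64.5))
  again <- crop_window(cropped)
  expect_identical(again$absorbance[[1]], cropped$absorbance[[1]])
  expect_error(crop_window(ch, 100, 110), "no points")
})

test_that("fingerprint matrices mirror their source traces", {
  set.seed(4)
  a1 <- rnorm(80)
  a2 <- rnorm(80)
  set <- dplyr::bind_rows(
    make_chrom(a1, id = "s1", extract = "s1"),
    make_chrom(a2, id = "s2", extract = "s2", species = "species_B")
  )
  fm <- build_fingerprint_matrix(set, 280L)
  expect_equal(dim(fm$X), c(2, 80))
  expect_equal(fm$X["s1", ], a1, ignore_attr = TRUE)
  expect_equal(fm$species, c("species_A", "species_B"))
  single <- build_fingerprint_matrix(set[1, ], 280L)
  expect_equal(dim(single$X), c(1, 80))
  bad <- dplyr::bind_rows(
    make_chrom(a1, id = "s1", extract = "s1"),
    make_chrom(a2[1:40], id = "s2", extract = "s2")
  )
  expect_error(build_fingerprint_matrix(bad, 280L), "heterogeneous")
})

test_that("baseline-then-crop and crop-then-baseline differ near the window edge", {
  ds <- simulate_dataset(small_cfg(seed = 5))
  sub <- subtract_blank(ds$chromatograms, ds$blanks)
  cons <- consolidate_replicates(sub)[1, ]
  a <- crop_window(correct_baseline(cons))$absorbance[[1]]
  b <- correct_baseline(crop_window(cons))$absorbance[[1]]
  expect_length(a, length(b))
  expect_gt(max(abs(a - b)), 1e-12)  # a real, documented difference
  expect_lt(median(abs(a - b)), 0.01)  # but small away from the edges
})

test_that("preprocessing preserves planted apex positions within one grid step", {
  ds <- default_ds()
  fm <- default_fm(280)
  lib <- ds$peak_library
  act <- lib[lib$active & lib$class == "species_B", ]
  spacing <- 0.4 / 60
  sample_b <- which(fm$species == "species_B")[1]
  for (i in seq_len(nrow(act))) {
    win <- which(abs(fm$time_min - act$retention_min[i]) < 0.5)
    apex <- fm$time_min[win[which.max(fm$X[sample_b, win])]]
    expect_lte(abs(apex - act$retention_min[i]), 2 * spacing)
  }
})
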