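# Shared fixtures. The default-condition dataset is expensive enough to be
# worth computing once per test run; anything smaller is built inline.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# full default-condition dataset (seed 1, all three wavelengths)
default_ds <- function() cached("ds1", simulate_dataset(sim_config(seed = 1)))

default_fm <- function(wl) {
  cached(paste0("fm", wl), preprocess_dataset(default_ds(), wl))
}

default_index <- function() {
  cached("idx1", antioxidant_index(default_ds()$assay_panel))
}

# small, fast dataset: 2 species x 6 extracts x 2 injections at 280 nm only
small_cfg <- function(seed = 1, ...) {
  sim_config(
    seed = seed, n_extracts_per_species = 6L, wavelengths_nm = 280L, ...
  )
}

# hand-built single-peak library for controlled chromatogram tests; the peak
# is flagged active so its detector response factor is exactly 1
test_library <- function(retention = 30, sigma = 0.1, amp_a = 1, amp_b = 1,
                         active = TRUE) {
  lib <- tibble::tibble(
    peak_id = "P01",
    class = "shared",
    retention_min = retention,
    width_sigma_min = sigma,
    active = active,
    amplitude = list(c(species_A = amp_a, species_B = amp_b))
  )
  attr(lib, "species_labels") <- c("species_A", "species_B")
  attr(lib, "lib_seed") <- 99L
  class(lib) <- c("peak_library", class(lib))
  lib
}

# deterministic configuration: every stochastic component switched off
noiseless_cfg <- function(...) {
  sim_config(
    noise_sd = 0, drift_amplitude = 0, injection_scale_sd = 0,
    extract_log_sd = 0, assay_noise_fraction = 0, ...
  )
}
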