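#' Simulation configuration for the synthetic fingerprint study
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode the
#' study design the analysis assumes: 2 species x 20 extracts x duplicate
#' injections (80 chromatograms per wavelength), detection at 254, 280 and
#' 330 nm, extract-to-extract lognormal amplitude variability (sd 0.2 on the
#' log scale), a 1% injection-scale factor, 0.005 AU detector noise, a slow
#' drifting baseline at 5% of the typical peak height, and four antioxidant
#' assays that read a common latent activity with 10% method noise.
#'
#' @param n_species Number of species (the study design uses 2).
#' @param n_extracts_per_species Extracts per species.
#' @param n_injection_replicates Injections per extract.
#' @param wavelengths_nm Detection wavelengths recorded by the simulated DAD.
#' @param noise_sd Detector noise standard deviation, in absorbance units.
#' @param drift_amplitude Baseline drift amplitude, AU.
#' @param drift_period_min Period of the slow sinusoidal drift component, min.
#' @param drift_curvature Relative weight of the quadratic drift component.
#' @param injection_scale_sd Standard deviation (log scale) of the
#'   per-injection intensity factor.
#' @param extract_log_sd Standard deviation (log scale) of the per-extract
#'   peak-amplitude factor.
#' @param assay_noise_fraction Assay noise as a fraction of the standard
#'   deviation of the latent antioxidant activity.
#' @param n_shared,n_specific_per_species,n_active Peak-library composition:
#'   peaks common to both species, peaks unique to each species, and peaks
#'   whose amplitude drives the latent antioxidant activity.
#' @param species_labels Labels for the two species; the second is the
#'   high-activity one.
#' @param seed Master seed fixing every random draw in the module.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 2L,
                       n_extracts_per_species = 20L,
                       n_injection_replicates = 2L,
                       wavelengths_nm = c(254L, 280L, 330L),
                       noise_sd = 0.005,
                       drift_amplitude = 0.05,
                       drift_period_min = 35,
                       drift_curvature = 0.5,
                       injection_scale_sd = 0.01,
                       extract_log_sd = 0.2,
                       assay_noise_fraction = 0.1,
                       n_shared = 12L,
                       n_specific_per_species = 10L,
                       n_active = 3L,
                       species_labels = c("species_A", "species_B"),
                       seed = 1L) {
  stopifnot(
    n_species >= 1, n_extracts_per_species >= 1, n_injection_replicates >= 1,
    length(wavelengths_nm) >= 1, noise_sd >= 0, injection_scale_sd >= 0,
    extract_log_sd >= 0, assay_noise_fraction >= 0
  )
  if (!n_species %in% c(1L, 2L)) {
    stop("`n_species` must be 1 (single-species runs) or 2 (the study design).",
      call. = FALSE
    )
  }
  if (length(species_labels) != 2L) {
    stop("`species_labels` must name exactly two species.", call. = FALSE)
  }
  structure(
    list(
      n_species = as.integer(n_species),
      n_extracts_per_species = as.integer(n_extracts_per_species),
      n_injection_replicates = as.integer(n_injection_replicates),
      wavelengths_nm = as.integer(wavelengths_nm),
      noise_sd = noise_sd,
      drift_amplitude = drift_amplitude,
      drift_period_min = drift_period_min,
      drift_curvature = drift_curvature,
      injection_scale_sd = injection_scale_sd,
      extract_log_sd = extract_log_sd,
      assay_noise_fraction = assay_noise_fraction,
      n_shared = as.integer(n_shared),
      n_specific_per_species = as.integer(n_specific_per_species),
      n_active = as.integer(n_active),
      species_labels = species_labels,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Default simulation time grid
#'
#' The simulated run covers 10--66 min at the detector's 0.4 s sampling
#' interval, wide enough that cropping to the 13.2--64.5 min analysis window
#' is a genuine operation (and lands exactly on grid points).
#'
#' @return A `time_grid`.
#' @export
default_sim_grid <- function() make_time_grid(10, 66, 0.4)

#' Simulate a Gaussian peak library
#'
#' Draws a library of chromatographic peaks: `n_shared` peaks with equal
#' amplitude in both species, `n_specific_per_species` peaks unique to each
#' species, and `n_active` peaks flagged as drivers of the latent antioxidant
#' activity. Active peaks are placed in the 20--35 min region where the
#' antioxidant-related compounds (tannic acid, chlorogenic acid, vitexin)
#' elute; the first active peak is taken from the shared pool (present in both
#' species, vitexin-like) and the rest from the high-activity species'
#' specific pool.
#'
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param n_shared Number of peaks common to both species.
#' @param n_specific_per_species Peaks unique to each species.
#' @param n_active Number of activity-driving peaks.
#' @param grid A `time_grid` delimiting the chromatographic run.
#' @param species_labels Two species labels; the second is the high-activity
#'   species.
#' @param active_window Retention window (min) for active peaks.
#'
#' @return A tibble of class `peak_library` with columns `peak_id`, `class`
#'   (`"shared"` or a species label), `retention_min`, `width_sigma_min`,
#'   `active`, and `amplitude` (list-column of named per-species amplitudes).
#' @export
simulate_peak_library <- function(seed,
                                  n_shared = 12L,
                                  n_specific_per_species = 10L,
                                  n_active = 3L,
                                  grid = default_sim_grid(),
                                  species_labels = c("species_A", "species_B"),
                                  active_window = c(20, 35)) {
  stopifnot(n_shared >= 0, n_specific_per_species >= 0, n_active >= 0)
  if (n_active > n_shared + n_specific_per_species) {
    stop("`n_active` cannot exceed n_shared + n_specific_per_species.",
      call. = FALSE
    )
  }
  lo <- grid$start_min + 1
  hi <- grid$end_min - 1
  if (n_active > 0 &&
    (grid$start_min > active_window[1] || grid$end_min < active_window[2])) {
    stop(sprintf(
      "Grid [%g, %g] min does not cover the active-peak window [%g, %g] min.",
      grid$start_min, grid$end_min, active_window[1], active_window[2]
    ), call. = FALSE)
  }

  sp_a <- species_labels[1]
  sp_b <- species_labels[2]
  classes <- c(
    rep("shared", n_shared),
    rep(sp_a, n_specific_per_species),
    rep(sp_b, n_specific_per_species)
  )
  n_peaks <- length(classes)

  # active assignment: one shared peak (if any), remainder from the
  # high-activity species' specific pool, overflow back to shared
  active <- logical(n_peaks)
  n_left <- n_active
  if (n_left > 0 && n_shared > 0) {
    active[1] <- TRUE
    n_left <- n_left - 1
  }
  if (n_left > 0 && n_specific_per_species > 0) {
    take <- min(n_left, n_specific_per_species)
    idx_b <- n_shared + n_specific_per_species + seq_len(take)
    active[idx_b] <- TRUE
    n_left <- n_left - take
  }
  if (n_left > 0) {
    active[seq(2, 1 + n_left)] <- TRUE
  }

  with_seed(seed, {
    retention <- numeric(n_peaks)
    for (i in seq_len(n_peaks)) {
      rng <- if (active[i]) {
        c(max(active_window[1], lo), min(active_window[2], hi))
      } else {
        c(lo, hi)
      }
      # keep apices at least 0.7 min apart so peaks stay resolvable
      for (try in 1:500) {
        cand <- stats::runif(1, rng[1], rng[2])
        if (i == 1 || min(abs(cand - retention[seq_len(i - 1)])) > 0.7) break
      }
      retention[i] <- cand
    }
    width <- stats::runif(n_peaks, 0.07, 0.18)
    amp <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      a <- if (active[i]) stats::runif(1, 0.5, 1) else stats::runif(1, 0.2, 1)
      amp[[i]] <- switch(classes[i],
        shared = stats::setNames(c(a, a), species_labels),
        stats::setNames(
          c(if (classes[i] == sp_a) a else 0, if (classes[i] == sp_b) a else 0),
          species_labels
        )
      )
    }
  })

  lib <- tibble::tibble(
    peak_id = sprintf("P%02d", seq_len(n_peaks)),
    class = classes,
    retention_min = retention,
    width_sigma_min = width,
    active = active,
    amplitude = amp
  )
  attr(lib, "species_labels") <- species_labels
  attr(lib, "lib_seed") <- as.integer(seed)
  class(lib) <- c("peak_library", class(lib))
  lib
}

# Per-extract lognormal amplitude factors, shared by both injections of one
# extract (and by the assay panel's latent activity).
extract_factors <- function(library, cfg, extract_index) {
  with_seed(
    mix_seed(cfg$seed, 11, extract_index),
    stats::rlnorm(nrow(library), meanlog = 0, sdlog = cfg$extract_log_sd)
  )
}

# Deterministic per-(peak, wavelength) detector response factor. Active peaks
# respond fully at every analysis wavelength so markers are recoverable at
# both 280 and 330 nm.
wavelength_response <- function(library, wavelength_nm) {
  lib_seed <- attr(library, "lib_seed")
  if (is.null(lib_seed)) lib_seed <- 0L
  f <- with_seed(
    mix_seed(lib_seed, 29, wavelength_nm),
    stats::runif(nrow(library), 0.5, 1)
  )
  f[library$active] <- 1
  f
}

baseline_drift <- function(t, cfg, phase) {
  span <- max(t) - min(t)
  mid <- (max(t) + min(t)) / 2
  cfg$drift_amplitude * (
    0.5 + 0.5 * sin(2 * pi * (t - t[1]) / cfg$drift_period_min + phase) +
      cfg$drift_curvature * ((t - mid) / (span / 2))^2
  )
}

new_chromatogram <- function(sample_id, species, extract_id, replicate,
                             wavelength_nm, time_min, absorbance,
                             blank = FALSE) {
  tibble::tibble(
    sample_id = sample_id,
    species = species,
    extract_id = extract_id,
    replicate = as.integer(replicate),
    wavelength_nm = as.integer(wavelength_nm),
    blank = blank,
    time_min = list(time_min),
    absorbance = list(absorbance)
  )
}

#' Simulate one chromatogram
#'
#' Renders a single detector trace: the sum of the library's Gaussian peaks
#' (species amplitude x extract-level lognormal factor x wavelength response x
#' per-injection scale factor), a smooth drifting baseline, and i.i.d.
#' detector noise. Both injections of one extract share the extract-level
#' factors and differ only in noise, drift phase and a small injection-scale
#' factor.
#'
#' @param library A `peak_library`.
#' @param species Species label; must appear in the library amplitude maps.
#' @param extract_id Extract identifier (carried into metadata).
#' @param replicate Injection replicate index.
#' @param grid A `time_grid`.
#' @param cfg A `sim_config`.
#' @param wavelength_nm Detection wavelength.
#' @param extract_index Integer identifying the extract's random stream;
#'   parsed from trailing digits of `extract_id` when omitted.
#'
#' @return A one-row chromatogram tibble (columns `sample_id`, `species`,
#'   `extract_id`, `replicate`, `wavelength_nm`, `blank`, `time_min`,
#'   `absorbance`).
#' @export
simulate_chromatogram <- function(library, species, extract_id, replicate,
                                  grid, cfg, wavelength_nm = 280L,
                                  extract_index = NULL) {
  sp_names <- names(library$amplitude[[1]])
  if (!species %in% sp_names) {
    stop(sprintf(
      "Species '%s' absent from library amplitude maps (%s).",
      species, paste(sp_names, collapse = ", ")
    ), call. = FALSE)
  }
  if (is.null(extract_index)) {
    digits <- gsub("\\D", "", extract_id)
    extract_index <- if (nzchar(digits)) {
      as.integer(substr(digits, max(1, nchar(digits) - 6), nchar(digits)))
    } else {
      sum(utf8ToInt(extract_id))
    }
  }
  t <- grid$points
  fac <- extract_factors(library, cfg, extract_index)
  wlf <- wavelength_response(library, wavelength_nm)
  amp <- vapply(library$amplitude, function(a) a[[species]], numeric(1)) *
    fac * wlf

  signal <- numeric(length(t))
  for (i in which(amp > 0)) {
    rt <- library$retention_min[i]
    sg <- library$width_sigma_min[i]
    idx <- which(t >= rt - 6 * sg & t <= rt + 6 * sg)
    if (length(idx)) {
      signal[idx] <- signal[idx] + amp[i] * exp(-(t[idx] - rt)^2 / (2 * sg^2))
    }
  }

  inj_seed <- mix_seed(cfg$seed, 13, extract_index, replicate, wavelength_nm)
  with_seed(inj_seed, {
    inj <- exp(stats::rnorm(1, 0, cfg$injection_scale_sd))
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(length(t), 0, cfg$noise_sd)
  })
  absorbance <- inj * signal + baseline_drift(t, cfg, phase) + noise

  new_chromatogram(
    sample_id = sprintf("%s_r%d", extract_id, replicate),
    species = species, extract_id = extract_id, replicate = replicate,
    wavelength_nm = wavelength_nm, time_min = t, absorbance = absorbance
  )
}

#' Simulate a blank injection
#'
#' A blank carries only baseline drift and detector noise; its `blank` flag is
#' always `TRUE`.
#'
#' @inheritParams simulate_chromatogram
#' @param blank_id Sample identifier for the blank.
#' @return A one-row chromatogram tibble flagged `blank = TRUE`.
#' @export
simulate_blank <- function(grid, cfg, wavelength_nm = 280L,
                           blank_id = "blank") {
  t <- grid$points
  with_seed(mix_seed(cfg$seed, 17, wavelength_nm), {
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(length(t), 0, cfg$noise_sd)
  })
  new_chromatogram(
    sample_id = sprintf("%s_%dnm", blank_id, wavelength_nm),
    species = NA_character_, extract_id = blank_id, replicate = 1L,
    wavelength_nm = wavelength_nm, time_min = t,
    absorbance = baseline_drift(t, cfg, phase) + noise, blank = TRUE
  )
}

sample_frame <- function(cfg) {
  sp <- cfg$species_labels[seq_len(cfg$n_species)]
  letters_ <- sub("^species_", "", sp)
  tidyr::expand_grid(
    species_idx = seq_along(sp),
    extract_num = seq_len(cfg$n_extracts_per_species)
  ) |>
    dplyr::mutate(
      species = sp[.data$species_idx],
      extract_id = sprintf(
        "%s_E%02d", letters_[.data$species_idx], .data$extract_num
      ),
      extract_index = (.data$species_idx - 1L) * cfg$n_extracts_per_species +
        .data$extract_num
    )
}

#' Ground-truth latent antioxidant activity
#'
#' Computes, without rendering any chromatogram, the latent antioxidant
#' activity of every extract: the sum over active peaks of species amplitude
#' times the extract-level lognormal factor (unit weights). The same random
#' streams drive [simulate_dataset()], so the truth matches the rendered
#' traces exactly.
#'
#' @param library A `peak_library`.
#' @param cfg A `sim_config`.
#' @return A list of class `ground_truth` with `latent` (tibble `sample_id`,
#'   `species`, `latent`), `active_peak_ids`, and `species_effect` (difference
#'   in mean latent activity, high minus low species).
#' @export
simulate_truth <- function(library, cfg) {
  frame <- sample_frame(cfg)
  act <- which(library$active)
  latent <- vapply(seq_len(nrow(frame)), function(i) {
    fac <- extract_factors(library, cfg, frame$extract_index[i])
    amp <- vapply(
      library$amplitude, function(a) a[[frame$species[i]]], numeric(1)
    )
    sum(amp[act] * fac[act])
  }, numeric(1))
  lat <- tibble::tibble(
    sample_id = frame$extract_id,
    species = frame$species,
    latent = latent
  )
  means <- tapply(lat$latent, lat$species, mean)
  eff <- if (cfg$n_species == 2L) {
    unname(means[cfg$species_labels[2]] - means[cfg$species_labels[1]])
  } else {
    NA_real_
  }
  structure(
    list(
      latent = lat,
      active_peak_ids = library$peak_id[act],
      species_effect = eff
    ),
    class = "ground_truth"
  )
}

# method-specific affine maps from latent activity to assay readouts
assay_maps <- list(
  tp_mg_gae_g   = c(intercept = 30, slope = 60),
  dpph_mg_te_g  = c(intercept = 10, slope = 35),
  abts_mg_te_g  = c(intercept = 15, slope = 45),
  frap_mg_te_g  = c(intercept = 8,  slope = 30)
)

#' Simulate the four-assay antioxidant panel
#'
#' Each assay column (total polyphenols in mg GAE/g DW; DPPH, ABTS and FRAP in
#' mg TE/g DW) is a method-specific affine map of the latent antioxidant
#' activity plus Gaussian noise with standard deviation
#' `assay_noise_fraction * sd(latent)`.
#'
#' @param truth A `ground_truth` from [simulate_truth()].
#' @param cfg A `sim_config`.
#' @return A tibble with columns `sample_id`, `species`, `tp_mg_gae_g`,
#'   `dpph_mg_te_g`, `abts_mg_te_g`, `frap_mg_te_g`.
#' @export
simulate_assay_panel <- function(truth, cfg) {
  lat <- truth$latent
  n <- nrow(lat)
  sd_lat <- stats::sd(lat$latent)
  if (!is.finite(sd_lat)) sd_lat <- 0  # single-sample designs carry no spread
  noise_sd <- cfg$assay_noise_fraction * sd_lat
  panel <- tibble::tibble(sample_id = lat$sample_id, species = lat$species)
  with_seed(mix_seed(cfg$seed, 19), {
    for (col in names(assay_maps)) {
      m <- assay_maps[[col]]
      panel[[col]] <- m[["intercept"]] + m[["slope"]] * lat$latent +
        stats::rnorm(n, 0, m[["slope"]] * noise_sd)
    }
  })
  panel
}

#' Simulate a complete synthetic fingerprint study
#'
#' Generates everything the analysis pipeline consumes: one chromatogram per
#' species x extract x injection x wavelength, one blank per wavelength, the
#' four-assay antioxidant panel, a standards retention-time table naming the
#' active peaks, and the ground truth used by parameter-recovery tests. With
#' the default configuration this yields 80 chromatograms per wavelength
#' (2 species x 20 extracts x duplicate injections).
#'
#' @param cfg A `sim_config`.
#' @param grid A `time_grid`; defaults to [default_sim_grid()].
#' @return A list of class `sim_dataset` with elements `chromatograms`,
#'   `blanks`, `assay_panel`, `standards`, `truth`, `peak_library`, `grid`,
#'   `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(), grid = default_sim_grid()) {
  library <- simulate_peak_library(
    seed = mix_seed(cfg$seed, 23),
    n_shared = cfg$n_shared,
    n_specific_per_species = cfg$n_specific_per_species,
    n_active = cfg$n_active,
    grid = grid,
    species_labels = cfg$species_labels
  )
  frame <- sample_frame(cfg)
  rows <- list()
  for (wl in cfg$wavelengths_nm) {
    for (i in seq_len(nrow(frame))) {
      for (r in seq_len(cfg$n_injection_replicates)) {
        rows[[length(rows) + 1L]] <- simulate_chromatogram(
          library, frame$species[i], frame$extract_id[i], r, grid, cfg,
          wavelength_nm = wl, extract_index = frame$extract_index[i]
        )
      }
    }
  }
  chroms <- dplyr::bind_rows(rows)
  blanks <- dplyr::bind_rows(lapply(
    cfg$wavelengths_nm, function(wl) simulate_blank(grid, cfg, wl)
  ))
  truth <- simulate_truth(library, cfg)
  panel <- simulate_assay_panel(truth, cfg)
  standards <- standards_from_library(library)
  structure(
    list(
      chromatograms = chroms,
      blanks = blanks,
      assay_panel = panel,
      standards = standards,
      truth = truth,
      peak_library = library,
      grid = grid,
      config = cfg
    ),
    class = "sim_dataset"
  )
}

# Name the active peaks after the phenolic standards whose retention regions
# they emulate: the shared active peak plays vitexin (330 nm), the
# species-specific ones tannic and chlorogenic acid (280 nm).
standards_from_library <- function(library) {
  act <- library[library$active, , drop = FALSE]
  if (nrow(act) == 0) {
    return(tibble::tibble(
      compound = character(), retention_min = numeric(),
      wavelength_nm = integer()
    ))
  }
  shared_first <- order(act$class != "shared", act$retention_min)
  act <- act[shared_first, , drop = FALSE]
  base_names <- c("vitexin", "tannic acid", "chlorogenic acid")
  base_wl <- c(330L, 280L, 280L)
  k <- nrow(act)
  compound <- c(
    base_names[seq_len(min(3, k))],
    if (k > 3) sprintf("synthetic_standard_%02d", seq_len(k - 3))
  )
  wl <- c(base_wl[seq_len(min(3, k))], rep(280L, max(0, k - 3)))
  tibble::tibble(
    compound = compound,
    retention_min = act$retention_min,
    wavelength_nm = wl
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d chromatograms (%d wavelengths), %d blanks, %d assay samples\n",
    nrow(x$chromatograms), length(x$config$wavelengths_nm), nrow(x$blanks),
    nrow(x$assay_panel)
  ))
  invisible(x)
}
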