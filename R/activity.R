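#' Fit an assay calibration curve
#'
#' Ordinary least-squares line of instrument response on standard
#' concentration (e.g. the gallic-acid or Trolox dilution series).
#'
#' @param concentrations Standard concentrations, mg/mL (>= 3 distinct values).
#' @param responses Instrument responses (absorbance units).
#' @param standard_name Label for the standard compound.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` and the input series.
#' @export
fit_calibration <- function(concentrations, responses,
                            standard_name = "standard") {
  stopifnot(length(concentrations) == length(responses))
  if (length(concentrations) < 3) {
    stop("Need at least 3 calibration points.", call. = FALSE)
  }
  if (stats::sd(concentrations) == 0) {
    stop("Calibration concentrations are constant.", call. = FALSE)
  }
  fit <- stats::lm(responses ~ concentrations)
  r2 <- if (stats::sd(responses) == 0) {
    1  # a flat response line is fitted exactly by its mean
  } else {
    stats::cor(concentrations, responses)^2
  }
  structure(
    list(
      standard_name = standard_name,
      concentrations = concentrations,
      responses = responses,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: response = %.4g + %.4g * conc (r^2 = %.4f, n = %d)\n",
    x$standard_name, x$intercept, x$slope, x$r_squared,
    length(x$concentrations)
  ))
  invisible(x)
}

#' Convert a raw assay response to equivalents per g dry weight
#'
#' Inverts the calibration line and scales by dilution and dry-weight
#' concentration: `((raw - intercept) / slope) * dilution_factor /
#' dry_weight_g_per_mL`, in mg equivalents (GAE or TE) per g dry drug weight.
#'
#' @param raw_response Raw instrument response(s).
#' @param curve A `calibration_curve`.
#' @param dilution_factor Dilution applied to the extract before reading.
#' @param dry_weight_g_per_mL Dry drug weight per mL of assayed solution.
#' @return Equivalents in mg per g DW (vectorised over `raw_response`).
#' @export
to_equivalents <- function(raw_response, curve, dilution_factor = 1,
                           dry_weight_g_per_mL = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("Calibration slope is zero.", call. = FALSE)
  if (dry_weight_g_per_mL <= 0) {
    stop("`dry_weight_g_per_mL` must be positive.", call. = FALSE)
  }
  ((raw_response - curve$intercept) / curve$slope) * dilution_factor /
    dry_weight_g_per_mL
}

assay_columns <- function(panel) {
  canonical <- c("tp_mg_gae_g", "dpph_mg_te_g", "abts_mg_te_g", "frap_mg_te_g")
  if (all(canonical %in% names(panel))) {
    return(canonical)
  }
  setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
    c("replicate", "wavelength_nm")
  )
}

#' Column-wise z-score matrix of an assay panel
#'
#' Standardises each assay column to mean 0 and sample (n-1) standard
#' deviation 1, putting methods with different units and scales on a common
#' footing.
#'
#' @param panel An assay-panel tibble (columns `tp_mg_gae_g`, `dpph_mg_te_g`,
#'   `abts_mg_te_g`, `frap_mg_te_g`, or any numeric assay columns), or a
#'   numeric matrix.
#' @return A samples x assays matrix of z-scores; row names are sample ids
#'   when available.
#' @export
zscore_matrix <- function(panel) {
  if (is.data.frame(panel)) {
    cols <- assay_columns(panel)
    M <- as.matrix(panel[, cols])
    if ("sample_id" %in% names(panel)) rownames(M) <- panel$sample_id
  } else {
    M <- as.matrix(panel)
  }
  if (nrow(M) < 2) stop("Need at least 2 samples.", call. = FALSE)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf(
      "Constant assay column(s): %s.",
      paste(colnames(M)[sds == 0], collapse = ", ")
    ), call. = FALSE)
  }
  sweep(sweep(M, 2, colMeans(M)), 2, sds, "/")
}

#' RACI as the mean of standard scores
#'
#' The relative antioxidant capacity index of each sample: the row mean of
#' its per-assay z-scores. Centred at zero over the sample set by
#' construction.
#'
#' @param z A z-score matrix from [zscore_matrix()].
#' @return A numeric vector (named by sample when `z` has row names).
#' @export
raci_mean <- function(z) {
  rowMeans(as.matrix(z))
}

#' RACI variant from the first principal component
#'
#' Scores on the first principal component of the z-scored assay matrix:
#' loadings are the first right-singular vector (unit norm, oriented so the
#' loading sum is positive), scores are `z %*% loadings`. A weighted
#' alternative to the plain z-score mean.
#'
#' @param z A z-score matrix from [zscore_matrix()] with more samples than
#'   assays.
#' @return A list with `scores` and `loadings`.
#' @export
raci_pc1 <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) <= ncol(z)) {
    stop("Need more samples than assay columns.", call. = FALSE)
  }
  sv <- svd(z)
  if (sv$d[1] <= 0) stop("Rank-0 input.", call. = FALSE)
  loadings <- sv$v[, 1]
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(z)
  scores <- drop(z %*% loadings)
  list(scores = scores, loadings = loadings)
}

#' Agreement between the two RACI variants
#'
#' Coefficient of determination of the OLS regression of the PC1 index on the
#' z-score-mean index.
#'
#' @param raci z-score-mean index vector.
#' @param pc1 PC1-score index vector (same length, >= 3).
#' @return R-squared (scalar).
#' @export
compare_indices <- function(raci, pc1) {
  stopifnot(length(raci) == length(pc1))
  if (length(raci) < 3) stop("Need at least 3 samples.", call. = FALSE)
  if (stats::sd(raci) == 0 || stats::sd(pc1) == 0) {
    stop("Constant index vector; R^2 undefined.", call. = FALSE)
  }
  # R^2 of the simple OLS regression of pc1 on raci
  stats::cor(raci, pc1)^2
}

#' Composite antioxidant index of an assay panel
#'
#' One-stop wrapper: z-scores the panel, computes both RACI variants (z-score
#' mean and PC1 scores) and their agreement.
#'
#' @param panel An assay-panel tibble.
#' @return An object of class `antioxidant_index` with fields `samples`
#'   (tibble: `sample_id`, `species`, `raci_mean`, `pc1_score`), `z_matrix`,
#'   `pc1_loadings` and `r_squared_mean_vs_pc1`.
#' @export
antioxidant_index <- function(panel) {
  z <- zscore_matrix(panel)
  rm_ <- raci_mean(z)
  pc <- raci_pc1(z)
  samples <- tibble::tibble(
    sample_id = if ("sample_id" %in% names(panel)) panel$sample_id else rownames(z),
    species = if ("species" %in% names(panel)) panel$species else NA_character_,
    raci_mean = unname(rm_),
    pc1_score = unname(pc$scores)
  )
  structure(
    list(
      samples = samples,
      z_matrix = z,
      pc1_loadings = pc$loadings,
      r_squared_mean_vs_pc1 = compare_indices(rm_, pc$scores)
    ),
    class = "antioxidant_index"
  )
}

#' @export
print.antioxidant_index <- function(x, ...) {
  cat(sprintf(
    "<antioxidant_index> %d samples; PC1 loadings: %s; R^2(mean, PC1) = %.4f\n",
    nrow(x$samples),
    paste(sprintf("%s %.2f", names(x$pc1_loadings), x$pc1_loadings),
      collapse = ", "
    ),
    x$r_squared_mean_vs_pc1
  ))
  invisible(x)
}

#' Drug-extract ratio
#'
#' Mass of dried plant drug per unit mass of native extract, the "X" in the
#' conventional X:1 notation.
#'
#' @param drug_mass_g Dried drug mass, g.
#' @param extract_mass_g Native extract mass, g.
#' @return The ratio (scalar).
#' @export
compute_der <- function(drug_mass_g, extract_mass_g) {
  if (any(drug_mass_g <= 0) || any(extract_mass_g <= 0)) {
    stop("Masses must be positive.", call. = FALSE)
  }
  drug_mass_g / extract_mass_g
}

#' Species contrast of an antioxidant index
#'
#' Group means of an index for a two-species design, reporting which species
#' scores higher and, when the expected high-activity species is supplied,
#' whether the observed direction matches.
#'
#' @param index Numeric index vector (e.g. `raci_mean`).
#' @param species Species label per sample (exactly 2 distinct labels, >= 2
#'   samples each).
#' @param expected_high Optional label of the species planted as more active.
#' @return A one-row tibble: `species_high`, `mean_high`, `species_low`,
#'   `mean_low`, `difference`, and `direction_correct` when `expected_high`
#'   is given.
#' @export
species_contrast <- function(index, species, expected_high = NULL) {
  stopifnot(length(index) == length(species))
  labs <- unique(species)
  if (length(labs) != 2) {
    stop("Exactly two species labels are required.", call. = FALSE)
  }
  if (any(table(species) < 2)) {
    stop("Need at least 2 samples per species.", call. = FALSE)
  }
  means <- tapply(index, species, mean)
  hi <- names(which.max(means))
  lo <- setdiff(labs, hi)
  out <- tibble::tibble(
    species_high = hi,
    mean_high = unname(means[hi]),
    species_low = lo,
    mean_low = unname(means[lo]),
    difference = unname(means[hi] - means[lo])
  )
  if (!is.null(expected_high)) {
    out$direction_correct <- identical(hi, expected_high)
  }
  out
}
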