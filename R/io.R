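# Plain-text interchange: wide CSV per wavelength (time_min + one column per
# sample) with a JSON metadata sidecar, plus assay-panel and standards CSVs.

#' Write a chromatogram set to wide CSV files with a JSON sidecar
#'
#' One `chromatograms_<wl>nm.csv` per wavelength (column 1 `time_min`, one
#' column per sample id, blanks included) and one `samples.json` holding the
#' per-sample metadata (`species`, `extract_id`, `replicate`,
#' `wavelength_nm`, `blank`).
#'
#' @param set A chromatogram tibble (samples and blanks may be mixed).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_chromatograms <- function(set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (wl in unique(set$wavelength_nm)) {
    sub <- set[set$wavelength_nm == wl, , drop = FALSE]
    t0 <- sub$time_min[[1]]
    for (i in seq_len(nrow(sub))) {
      if (!same_grid(sub$time_min[[i]], t0)) {
        stop("All chromatograms at one wavelength must share a grid.",
          call. = FALSE
        )
      }
    }
    wide <- c(list(time_min = t0), stats::setNames(sub$absorbance, sub$sample_id))
    readr::write_csv(
      tibble::as_tibble(wide),
      file.path(dir, sprintf("chromatograms_%dnm.csv", wl))
    )
  }
  meta <- set[, c(
    "sample_id", "species", "extract_id", "replicate", "wavelength_nm", "blank"
  )]
  jsonlite::write_json(
    meta, file.path(dir, "samples.json"),
    dataframe = "rows", na = "null", auto_unbox = FALSE, digits = NA
  )
  invisible(dir)
}

#' Read a chromatogram set written by [write_chromatograms()]
#'
#' @param dir Directory holding `chromatograms_<wl>nm.csv` files and
#'   `samples.json`.
#' @param wavelengths_nm Optional subset of wavelengths to read.
#' @return A chromatogram tibble.
#' @export
read_chromatograms <- function(dir, wavelengths_nm = NULL) {
  meta_path <- file.path(dir, "samples.json")
  if (!file.exists(meta_path)) {
    stop(sprintf("No samples.json found in '%s'.", dir), call. = FALSE)
  }
  meta <- tibble::as_tibble(jsonlite::fromJSON(meta_path))
  meta$replicate <- as.integer(meta$replicate)
  meta$wavelength_nm <- as.integer(meta$wavelength_nm)
  files <- list.files(dir, pattern = "^chromatograms_\\d+nm\\.csv$")
  wls <- as.integer(gsub("\\D", "", files))
  if (!is.null(wavelengths_nm)) {
    keep <- wls %in% wavelengths_nm
    files <- files[keep]
    wls <- wls[keep]
  }
  rows <- list()
  for (f in seq_along(files)) {
    wide <- readr::read_csv(
      file.path(dir, files[f]),
      show_col_types = FALSE, progress = FALSE
    )
    t0 <- wide$time_min
    for (sid in setdiff(names(wide), "time_min")) {
      m <- meta[meta$sample_id == sid & meta$wavelength_nm == wls[f], , drop = FALSE]
      if (nrow(m) != 1) {
        stop(sprintf("Metadata missing or duplicated for sample '%s'.", sid),
          call. = FALSE
        )
      }
      rows[[length(rows) + 1L]] <- new_chromatogram(
        sample_id = sid, species = m$species, extract_id = m$extract_id,
        replicate = m$replicate, wavelength_nm = wls[f],
        time_min = t0, absorbance = wide[[sid]], blank = m$blank
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read the assay-panel CSV
#'
#' Columns: `sample_id`, `species`, `tp_mg_gae_g`, `dpph_mg_te_g`,
#' `abts_mg_te_g`, `frap_mg_te_g`.
#'
#' @param panel Assay-panel tibble.
#' @param path CSV path.
#' @return `path` invisibly (write); the panel tibble (read).
#' @export
write_assay_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' @rdname write_assay_panel
#' @export
read_assay_panel <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write / read the standards retention-time table
#'
#' Columns: `compound`, `retention_min`, `wavelength_nm`.
#'
#' @param standards Standards tibble.
#' @param path CSV path.
#' @return `path` invisibly (write); the standards tibble (read).
#' @export
write_standards <- function(standards, path) {
  readr::write_csv(standards, path)
  invisible(path)
}

#' @rdname write_standards
#' @export
read_standards <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$wavelength_nm <- as.integer(out$wavelength_nm)
  out
}
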