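#' Subtract blank injections from chromatograms
#'
#' Subtracts, pointwise, the blank trace recorded at the same wavelength from
#' every non-blank chromatogram. Negative values are retained. Metadata is
#' preserved.
#'
#' @param chroms A chromatogram tibble (any mix of wavelengths).
#' @param blanks A chromatogram tibble of blanks, one per wavelength present
#'   in `chroms`.
#' @return `chroms` with blank-subtracted absorbance.
#' @export
subtract_blank <- function(chroms, blanks) {
  if (!all(blanks$blank)) {
    stop("All rows of `blanks` must be flagged blank = TRUE.", call. = FALSE)
  }
  out <- chroms
  for (i in seq_len(nrow(out))) {
    wl <- out$wavelength_nm[i]
    j <- which(blanks$wavelength_nm == wl)
    if (length(j) == 0) {
      stop(sprintf("No blank supplied for wavelength %d nm.", wl), call. = FALSE)
    }
    if (length(j) > 1) {
      stop(sprintf("Multiple blanks supplied for wavelength %d nm.", wl),
        call. = FALSE
      )
    }
    tb <- blanks$time_min[[j]]
    tc <- out$time_min[[i]]
    if (!same_grid(tc, tb)) {
      stop(sprintf(
        "Grid mismatch between sample '%s' (%d points) and blank (%d points).",
        out$sample_id[i], length(tc), length(tb)
      ), call. = FALSE)
    }
    out$absorbance[[i]] <- out$absorbance[[i]] - blanks$absorbance[[j]]
  }
  out
}

#' Replicate-injection reproducibility
#'
#' For every extract (at each wavelength), computes the minimum pairwise
#' Pearson correlation over its replicate traces. Intended to run on
#' blank-subtracted traces, before consolidation.
#'
#' @param set A chromatogram tibble with >= 2 replicates per extract.
#' @return A tibble with columns `wavelength_nm`, `extract_id`, `species`,
#'   `n_replicates`, `min_r`.
#' @export
replicate_correlation <- function(set) {
  set <- set[!set$blank, , drop = FALSE]
  keys <- unique(set[, c("wavelength_nm", "extract_id")])
  res <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    idx <- which(set$wavelength_nm == keys$wavelength_nm[k] &
      set$extract_id == keys$extract_id[k])
    if (length(idx) < 2) {
      stop(sprintf(
        "Extract '%s' at %d nm has %d replicate(s); need at least 2.",
        keys$extract_id[k], keys$wavelength_nm[k], length(idx)
      ), call. = FALSE)
    }
    traces <- set$absorbance[idx]
    for (i in idx) {
      if (stats::sd(set$absorbance[[i]]) == 0) {
        stop(sprintf(
          "Sample '%s' has a constant trace; correlation undefined.",
          set$sample_id[i]
        ), call. = FALSE)
      }
    }
    pairs <- utils::combn(length(traces), 2)
    rs <- apply(pairs, 2, function(p) {
      stats::cor(traces[[p[1]]], traces[[p[2]]])
    })
    res[[k]] <- tibble::tibble(
      wavelength_nm = keys$wavelength_nm[k],
      extract_id = keys$extract_id[k],
      species = set$species[idx[1]],
      n_replicates = length(idx),
      min_r = min(rs)
    )
  }
  dplyr::bind_rows(res)
}

#' Gate extracts on replicate reproducibility
#'
#' Partitions extracts by whether their minimum replicate correlation reaches
#' the threshold. Failures raise a warning (never an error): as in the
#' underlying workflow, no peak alignment is attempted in either case.
#'
#' @param rs A tibble from [replicate_correlation()].
#' @param threshold Minimum acceptable Pearson r (default 0.93).
#' @return `rs` with an added logical `pass` column.
#' @export
gate_reproducibility <- function(rs, threshold = 0.93) {
  rs$pass <- rs$min_r >= threshold
  if (any(!rs$pass)) {
    bad <- rs[!rs$pass, , drop = FALSE]
    warning(sprintf(
      "%d extract(s) below the replicate-correlation threshold %.3g: %s",
      nrow(bad), threshold,
      paste(sprintf("%s@%dnm (r=%.3f)", bad$extract_id, bad$wavelength_nm,
        bad$min_r
      ), collapse = ", ")
    ), call. = FALSE)
  }
  rs
}

# pointwise summary across a list of equal-grid traces
combine_traces <- function(traces, method) {
  if (method == "mean") {
    Reduce(`+`, traces) / length(traces)
  } else {
    apply(do.call(rbind, traces), 2, stats::median)
  }
}

#' Consolidate replicate injections into one trace per extract
#'
#' Averages (default) or takes the pointwise median of the replicate traces
#' of each extract, yielding the per-extract mean chromatogram used for
#' fingerprint analysis.
#'
#' @param set A chromatogram tibble.
#' @param method `"mean"` (default) or `"median"`.
#' @return A chromatogram tibble with one row per extract and wavelength;
#'   `sample_id` becomes the extract id.
#' @export
consolidate_replicates <- function(set, method = c("mean", "median")) {
  method <- match.arg(method)
  set <- set[!set$blank, , drop = FALSE]
  keys <- unique(set[, c("wavelength_nm", "extract_id")])
  rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    idx <- which(set$wavelength_nm == keys$wavelength_nm[k] &
      set$extract_id == keys$extract_id[k])
    t0 <- set$time_min[[idx[1]]]
    for (i in idx[-1]) {
      if (!same_grid(set$time_min[[i]], t0)) {
        stop(sprintf(
          "Replicates of extract '%s' are on different grids.",
          keys$extract_id[k]
        ), call. = FALSE)
      }
    }
    rows[[k]] <- new_chromatogram(
      sample_id = keys$extract_id[k],
      species = set$species[idx[1]],
      extract_id = keys$extract_id[k],
      replicate = NA_integer_,
      wavelength_nm = keys$wavelength_nm[k],
      time_min = t0,
      absorbance = combine_traces(set$absorbance[idx], method)
    )
  }
  dplyr::bind_rows(rows)
}

#' Pointwise median chromatogram per group
#'
#' Computes the median trace over all chromatograms sharing a grouping label
#' (typically the species), one per wavelength. A visualisation-oriented
#' summary; the analysis pipeline itself consolidates by extract-level means.
#'
#' @param set A chromatogram tibble (typically consolidated).
#' @param by Name of the grouping column (default `"species"`).
#' @return A chromatogram tibble with one row per group and wavelength.
#' @export
group_median <- function(set, by = "species") {
  set <- set[!set$blank, , drop = FALSE]
  keys <- unique(set[, c("wavelength_nm", by)])
  names(keys)[2] <- "group"
  keys <- keys[!is.na(keys$group), , drop = FALSE]
  if (nrow(keys) == 0) stop("No non-empty groups found.", call. = FALSE)
  rows <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    idx <- which(set$wavelength_nm == keys$wavelength_nm[k] &
      set[[by]] == keys$group[k])
    if (length(idx) == 0) {
      stop(sprintf("Empty group '%s'.", keys$group[k]), call. = FALSE)
    }
    rows[[k]] <- new_chromatogram(
      sample_id = sprintf("%s_median", keys$group[k]),
      species = if (by == "species") keys$group[k] else NA_character_,
      extract_id = sprintf("%s_median", keys$group[k]),
      replicate = NA_integer_,
      wavelength_nm = keys$wavelength_nm[k],
      time_min = set$time_min[[idx[1]]],
      absorbance = combine_traces(set$absorbance[idx], "median")
    )
  }
  dplyr::bind_rows(rows)
}

#' Crop chromatograms to an analysis window
#'
#' Retains the points with `start_min <= t <= end_min`, inclusive. The default
#' window is the 13.2--64.5 min fingerprint-analysis interval.
#'
#' @param set A chromatogram tibble.
#' @param start_min,end_min Window endpoints in minutes.
#' @return The cropped chromatogram tibble.
#' @export
crop_window <- function(set, start_min = 13.2, end_min = 64.5) {
  for (i in seq_len(nrow(set))) {
    t <- set$time_min[[i]]
    keep <- t >= start_min - 1e-9 & t <= end_min + 1e-9
    if (!any(keep)) {
      stop(sprintf(
        "Cropping sample '%s' to [%g, %g] min leaves no points.",
        set$sample_id[i], start_min, end_min
      ), call. = FALSE)
    }
    set$time_min[[i]] <- t[keep]
    set$absorbance[[i]] <- set$absorbance[[i]][keep]
  }
  set
}

#' Assemble the fingerprint matrix at one wavelength
#'
#' Stacks consolidated, baseline-corrected traces into a samples x timepoints
#' matrix, rows ordered by sample id, with species labels carried through.
#'
#' @param set A chromatogram tibble on a common grid (one row per sample).
#' @param wavelength_nm Wavelength to extract.
#' @param window Optional `c(start, end)` window (minutes) to crop to first.
#' @return An object of class `fingerprint_matrix`: list with `X` (matrix),
#'   `sample_ids`, `species`, `wavelength_nm`, `time_min`.
#' @export
build_fingerprint_matrix <- function(set, wavelength_nm, window = NULL) {
  set <- set[!set$blank & set$wavelength_nm == wavelength_nm, , drop = FALSE]
  if (nrow(set) == 0) {
    stop(sprintf("No chromatograms at %d nm.", wavelength_nm), call. = FALSE)
  }
  if (!is.null(window)) {
    set <- crop_window(set, window[1], window[2])
  }
  set <- set[order(set$sample_id), , drop = FALSE]
  t0 <- set$time_min[[1]]
  for (i in seq_len(nrow(set))) {
    if (!same_grid(set$time_min[[i]], t0)) {
      stop(paste0(
        "Chromatograms are on heterogeneous grids; resample to a common ",
        "grid (see `resample_chromatograms()`) before building the matrix."
      ), call. = FALSE)
    }
  }
  X <- do.call(rbind, set$absorbance)
  rownames(X) <- set$sample_id
  structure(
    list(
      X = X,
      sample_ids = set$sample_id,
      species = set$species,
      wavelength_nm = as.integer(wavelength_nm),
      time_min = t0
    ),
    class = "fingerprint_matrix"
  )
}

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf(
    "<fingerprint_matrix> %d samples x %d timepoints at %d nm (%.4g-%.4g min)\n",
    nrow(x$X), ncol(x$X), x$wavelength_nm, min(x$time_min), max(x$time_min)
  ))
  invisible(x)
}

#' Linearly resample chromatograms onto a common grid
#'
#' Provided for externally supplied data recorded on heterogeneous grids; the
#' simulator always emits a common grid. Linear interpolation only -- no
#' retention-time warping or peak alignment is ever performed.
#'
#' @param set A chromatogram tibble.
#' @param grid Target `time_grid`.
#' @return The set resampled onto `grid`.
#' @export
resample_chromatograms <- function(set, grid) {
  for (i in seq_len(nrow(set))) {
    a <- stats::approx(
      set$time_min[[i]], set$absorbance[[i]],
      xout = grid$points, rule = 2
    )$y
    set$time_min[[i]] <- grid$points
    set$absorbance[[i]] <- a
  }
  set
}

#' Run the full preprocessing pipeline on a synthetic dataset
#'
#' Blank subtraction, replicate-reproducibility gating (warning on failures),
#' consolidation into per-extract mean chromatograms, fill-peaks baseline
#' correction, and cropping to the analysis window, returning the fingerprint
#' matrix at the requested wavelength.
#'
#' @param ds A `sim_dataset`, or a list with `chromatograms` and `blanks`.
#' @param wavelength_nm Analysis wavelength.
#' @param window Analysis window, minutes.
#' @param threshold Replicate-correlation gate threshold.
#' @param consolidate `"mean"` or `"median"`.
#' @param half_window_min,iterations,smooth_window_min Baseline parameters,
#'   see [estimate_baseline()].
#' @return A `fingerprint_matrix`.
#' @export
preprocess_dataset <- function(ds, wavelength_nm = 280L,
                               window = c(13.2, 64.5),
                               threshold = 0.93,
                               consolidate = "mean",
                               half_window_min = 2, iterations = 8L,
                               smooth_window_min = 0.2) {
  chroms <- ds$chromatograms
  chroms <- chroms[chroms$wavelength_nm == wavelength_nm, , drop = FALSE]
  if (nrow(chroms) == 0) {
    stop(sprintf("Dataset has no chromatograms at %d nm.", wavelength_nm),
      call. = FALSE
    )
  }
  sub <- subtract_blank(chroms, ds$blanks)
  rs <- replicate_correlation(sub)
  gate_reproducibility(rs, threshold)
  cons <- consolidate_replicates(sub, consolidate)
  corr <- correct_baseline(
    cons,
    half_window_min = half_window_min, iterations = iterations,
    smooth_window_min = smooth_window_min
  )
  cropped <- crop_window(corr, window[1], window[2])
  build_fingerprint_matrix(cropped, wavelength_nm)
}
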