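#' Locate antioxidant-marker intervals from regression coefficients
#'
#' Scans the retention-time-aligned regression coefficients for maximal runs
#' of coefficients exceeding `rel_threshold * max(B)`. Only positive
#' coefficients are considered: peaks whose concentration rises with the
#' antioxidant index. Runs narrower than `min_width_min` are discarded. An
#' all-nonpositive coefficient vector yields an empty report, not an error.
#'
#' @param model Either a fitted `pls_model` (with grid metadata) or a numeric
#'   vector of retention times.
#' @param coefficients Coefficient vector aligned with `model` when `model`
#'   is a time vector; ignored otherwise.
#' @param rel_threshold Fraction of the maximum positive coefficient a run
#'   must exceed (default 0.1).
#' @param min_width_min Minimum run width in minutes (default 0.1).
#' @param wavelength_nm Wavelength tag for the report (taken from the model
#'   when available).
#' @return An object of class `marker_report`: list with `intervals` (tibble
#'   `start_min`, `end_min`, `apex_min`, `peak_coefficient`), an empty
#'   `matches` tibble, and `wavelength_nm`.
#' @export
find_marker_intervals <- function(model, coefficients = NULL,
                                  rel_threshold = 0.1, min_width_min = 0.1,
                                  wavelength_nm = NA_integer_) {
  if (inherits(model, "pls_model")) {
    rc <- regression_coefficients(model)
    time_min <- rc$time_min
    B <- rc$coefficient
    if (is.na(wavelength_nm)) wavelength_nm <- model$wavelength_nm
  } else {
    time_min <- as.numeric(model)
    B <- as.numeric(coefficients)
  }
  stopifnot(length(time_min) == length(B))
  empty <- tibble::tibble(
    start_min = numeric(), end_min = numeric(),
    apex_min = numeric(), peak_coefficient = numeric()
  )
  report <- structure(
    list(intervals = empty, matches = empty_matches(),
         wavelength_nm = as.integer(wavelength_nm),
         rel_threshold = rel_threshold, min_width_min = min_width_min),
    class = "marker_report"
  )
  bmax <- max(B)
  if (!is.finite(bmax) || bmax <= 0) {
    return(report)
  }
  above <- B > rel_threshold * bmax
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- list()
  for (k in keep) {
    i0 <- starts[k]
    i1 <- ends[k]
    width <- time_min[i1] - time_min[i0]
    if (width < min_width_min) next
    apex_rel <- which.max(B[i0:i1])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      start_min = time_min[i0],
      end_min = time_min[i1],
      apex_min = time_min[i0 + apex_rel - 1L],
      peak_coefficient = B[i0 + apex_rel - 1L]
    )
  }
  if (length(rows)) report$intervals <- dplyr::bind_rows(rows)
  report
}

empty_matches <- function() {
  tibble::tibble(
    apex_min = numeric(), compound = character(),
    retention_min = numeric(), delta_min = numeric()
  )
}

#' Match marker intervals to retention-time standards
#'
#' Attaches to each marker interval the injected standards whose retention
#' time lies within `tolerance_min` of the interval apex, at the report's
#' wavelength. Unmatched intervals are retained with no match row.
#'
#' @param report A `marker_report`.
#' @param standards Standards tibble (`compound`, `retention_min`,
#'   `wavelength_nm`).
#' @param tolerance_min Maximum |apex - standard| gap, minutes (default 0.5).
#' @return The report with its `matches` tibble filled in.
#' @export
match_standards <- function(report, standards, tolerance_min = 0.5) {
  stopifnot(inherits(report, "marker_report"))
  std <- standards
  if (!is.na(report$wavelength_nm) && "wavelength_nm" %in% names(std)) {
    std <- std[std$wavelength_nm == report$wavelength_nm, , drop = FALSE]
  }
  rows <- list()
  for (i in seq_len(nrow(report$intervals))) {
    apex <- report$intervals$apex_min[i]
    if (nrow(std)) {
      delta <- std$retention_min - apex
      hit <- which(abs(delta) <= tolerance_min)
      for (j in hit) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          apex_min = apex,
          compound = std$compound[j],
          retention_min = std$retention_min[j],
          delta_min = abs(delta[j])
        )
      }
    }
  }
  report$matches <- if (length(rows)) dplyr::bind_rows(rows) else empty_matches()
  report$tolerance_min <- tolerance_min
  report
}

#' @export
print.marker_report <- function(x, ...) {
  cat(sprintf(
    "<marker_report> %s nm: %d interval(s), %d standard match(es)\n",
    x$wavelength_nm, nrow(x$intervals), nrow(x$matches)
  ))
  if (nrow(x$intervals)) {
    print(x$intervals)
  }
  invisible(x)
}
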