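# Rolling-window primitives (vectorised van Herk/Gil-Werman scheme) and the
# iterative fill-peaks baseline estimator built on them.

# centred moving average; window truncated at the edges
rolling_mean <- function(x, half_window) {
  n <- length(x)
  h <- as.integer(half_window)
  if (h <= 0) {
    return(x)
  }
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# centred running min/max over window 2*h+1, edges truncated
rolling_extreme <- function(x, half_window, which = c("min", "max")) {
  which <- match.arg(which)
  n <- length(x)
  h <- as.integer(half_window)
  if (h <= 0) {
    return(x)
  }
  w <- 2L * h + 1L
  pad_val <- if (which == "min") Inf else -Inf
  xp <- c(rep(pad_val, h), x, rep(pad_val, h))
  len <- length(xp)
  nb <- ceiling(len / w)
  xp <- c(xp, rep(pad_val, nb * w - len))
  mat <- matrix(xp, nrow = w)
  cfun <- if (which == "min") cummin else cummax
  pref <- as.vector(apply(mat, 2, cfun))
  suff <- as.vector(apply(mat[w:1, , drop = FALSE], 2, cfun)[w:1, , drop = FALSE])
  # sliding extreme with left edge at i over the padded vector
  i <- seq_len(n)
  ext <- if (which == "min") {
    pmin(suff[i], pref[i + w - 1L])
  } else {
    pmax(suff[i], pref[i + w - 1L])
  }
  ext
}

# morphological opening: erosion then dilation with the same window
rolling_open <- function(x, half_window) {
  rolling_extreme(
    rolling_extreme(x, half_window, "min"), half_window, "max"
  )
}

#' Estimate a chromatographic baseline by iterative peak filling
#'
#' Estimates the slowly varying baseline under a chromatogram and returns the
#' baseline-corrected trace. The trace is first lightly smoothed, then peaks
#' are suppressed by taking, at every point, the minimum of the current value
#' and its moving-window opening (running minimum followed by running
#' maximum), with window widths shrinking geometrically from `half_window_min`
#' across the iterations; a final moving average yields the baseline. The
#' corrected trace is `absorbance - baseline`, never clipped at zero. With
#' `smooth_window_min = 0` the estimator is exactly idempotent on noiseless
#' input: re-correcting a corrected trace changes nothing.
#'
#' @param absorbance Numeric trace (AU), or a one-row chromatogram tibble.
#' @param spacing_min Sampling interval in minutes (ignored when a
#'   chromatogram row is supplied).
#' @param half_window_min Initial suppression half-window, minutes. Must be
#'   wider than the widest genuine peak and narrower than the trace.
#' @param iterations Number of window-shrinking iterations (>= 1).
#' @param smooth_window_min Half-window of the pre/post smoothing moving
#'   average, minutes; 0 disables smoothing.
#'
#' @return A list of class `baseline_result` with `baseline`, `corrected` and
#'   `params`.
#' @export
estimate_baseline <- function(absorbance, spacing_min = NULL,
                              half_window_min = 2, iterations = 8L,
                              smooth_window_min = 0.2) {
  if (is.data.frame(absorbance)) {
    chrom <- absorbance
    stopifnot(nrow(chrom) == 1L)
    t <- chrom$time_min[[1]]
    spacing_min <- t[2] - t[1]
    absorbance <- chrom$absorbance[[1]]
  }
  stopifnot(is.numeric(absorbance), is.numeric(spacing_min))
  if (half_window_min <= 0) stop("`half_window_min` must be positive.", call. = FALSE)
  if (iterations < 1) stop("`iterations` must be >= 1.", call. = FALSE)
  n <- length(absorbance)
  h0 <- max(1L, as.integer(round(half_window_min / spacing_min)))
  if (2L * h0 + 1L > n) {
    stop(sprintf(
      "Suppression window (%d points) is wider than the trace (%d points).",
      2L * h0 + 1L, n
    ), call. = FALSE)
  }
  hs <- max(0L, as.integer(round(smooth_window_min / spacing_min)))

  cur <- rolling_mean(absorbance, hs)
  h_final <- max(1L, as.integer(round(0.1 / spacing_min)))
  ratio <- if (iterations > 1) (h_final / h0)^(1 / (iterations - 1)) else 1
  for (k in seq_len(iterations)) {
    hk <- max(1L, as.integer(round(h0 * ratio^(k - 1))))
    cur <- pmin(cur, rolling_open(cur, hk))
  }
  baseline <- rolling_mean(cur, hs)
  structure(
    list(
      baseline = baseline,
      corrected = absorbance - baseline,
      params = list(
        half_window_min = half_window_min, iterations = iterations,
        smooth_window_min = smooth_window_min, spacing_min = spacing_min
      )
    ),
    class = "baseline_result"
  )
}

#' Baseline-correct every chromatogram in a set
#'
#' Applies [estimate_baseline()] row-wise and replaces each `absorbance` trace
#' with its corrected version.
#'
#' @param set A chromatogram tibble.
#' @inheritParams estimate_baseline
#' @return The set with corrected absorbance traces.
#' @export
correct_baseline <- function(set, half_window_min = 2, iterations = 8L,
                             smooth_window_min = 0.2) {
  set$absorbance <- lapply(seq_len(nrow(set)), function(i) {
    t <- set$time_min[[i]]
    estimate_baseline(
      set$absorbance[[i]],
      spacing_min = t[2] - t[1],
      half_window_min = half_window_min,
      iterations = iterations,
      smooth_window_min = smooth_window_min
    )$corrected
  })
  set
}
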