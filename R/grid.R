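#' Construct a uniform retention-time grid
#'
#' Builds the uniform time axis on which chromatograms are sampled. Endpoints
#' are inclusive, so a 13.2--64.5 min window sampled every 0.4 s contains
#' exactly 7696 points.
#'
#' @param start_min First retention time, in minutes.
#' @param end_min Last retention time, in minutes. Must exceed `start_min`.
#' @param spacing_s Detector sampling interval, in seconds.
#'
#' @return An object of class `time_grid`: a list with fields `start_min`,
#'   `end_min`, `spacing_s` and `points` (the time axis in minutes).
#'
#' @examples
#' g <- make_time_grid(13.2, 64.5, 0.4)
#' length(g$points)  # 7696
#' @export
make_time_grid <- function(start_min, end_min, spacing_s) {
  stopifnot(is.numeric(start_min), is.numeric(end_min), is.numeric(spacing_s))
  if (end_min <= start_min) {
    stop("`end_min` must be greater than `start_min`.", call. = FALSE)
  }
  if (spacing_s <= 0) {
    stop("`spacing_s` must be positive.", call. = FALSE)
  }
  span_s <- (end_min - start_min) * 60
  n_steps <- span_s / spacing_s
  residual <- abs(n_steps - round(n_steps))
  if (residual > 1e-6) {
    stop(sprintf(
      "Time span (%.6g s) is not divisible by spacing %.6g s (residual %.3g steps).",
      span_s, spacing_s, residual
    ), call. = FALSE)
  }
  n_points <- as.integer(round(n_steps)) + 1L
  points <- seq(start_min, end_min, length.out = n_points)
  structure(
    list(
      start_min = start_min,
      end_min = end_min,
      spacing_s = spacing_s,
      points = points
    ),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %.6g to %.6g min, spacing %.6g s, %d points\n",
    x$start_min, x$end_min, x$spacing_s, length(x$points)
  ))
  invisible(x)
}

#' @export
length.time_grid <- function(x) length(x$points)

# grid spacing in minutes
grid_spacing_min <- function(grid) grid$spacing_s / 60

# check that two time axes coincide
same_grid <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && max(abs(a - b)) <= tol
}
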