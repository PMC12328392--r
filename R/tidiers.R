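# broom-style tidiers for the package's fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a PLS/OPLS model into a coefficient table
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `time_min` (when available) and `estimate`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  if (!is.null(x$time_min)) {
    tibble::tibble(
      term = sprintf("t%.4f", x$time_min),
      time_min = x$time_min,
      estimate = x$B / x$x_scale
    )
  } else {
    tibble::tibble(
      term = sprintf("x%d", seq_along(x$B)),
      estimate = x$B / x$x_scale
    )
  }
}

#' Glance at a PLS/OPLS model
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return A one-row tibble with the calibration summary (`kind`,
#'   `n_components`, `n_orthogonal`, `r2x_total`, `r2y`, `rmsec`, `rpd_cal`).
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  fit_metrics(x, NULL, x$y, cv = NULL) |>
    dplyr::select(
      "kind", "n_components", "n_orthogonal", "r2x_total", "r2y",
      "mse_cal", "rmsec", "rpd_cal"
    )
}

#' Tidy an antioxidant index
#'
#' @param x An `antioxidant_index`.
#' @param ... Unused.
#' @return The per-sample tibble (`sample_id`, `species`, `raci_mean`,
#'   `pc1_score`).
#' @method tidy antioxidant_index
#' @export
tidy.antioxidant_index <- function(x, ...) x$samples

#' Glance at an antioxidant index
#'
#' @param x An `antioxidant_index`.
#' @param ... Unused.
#' @return A one-row tibble with the four PC1 loadings and the RACI-PC1
#'   agreement R-squared.
#' @method glance antioxidant_index
#' @export
glance.antioxidant_index <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(
    x$pc1_loadings, paste0("loading_", names(x$pc1_loadings))
  )))
  out$r_squared_mean_vs_pc1 <- x$r_squared_mean_vs_pc1
  out
}

#' Tidy a marker report
#'
#' @param x A `marker_report`.
#' @param ... Unused.
#' @return The interval tibble joined with any standard matches.
#' @method tidy marker_report
#' @export
tidy.marker_report <- function(x, ...) {
  if (nrow(x$matches) == 0) {
    out <- x$intervals
    out$compound <- rep(NA_character_, nrow(out))
    out$delta_min <- rep(NA_real_, nrow(out))
    return(out)
  }
  dplyr::left_join(
    x$intervals,
    x$matches[, c("apex_min", "compound", "delta_min")],
    by = "apex_min"
  )
}

#' Tidy a distance matrix into pair rows
#'
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @return A tibble with `id_1`, `id_2`, `distance` (upper triangle).
#' @method tidy dist_matrix
#' @export
tidy.dist_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$D), arr.ind = TRUE)
  tibble::tibble(
    id_1 = x$ids[ut[, 1]],
    id_2 = x$ids[ut[, 2]],
    distance = x$D[ut]
  )
}

#' Tidy a linkage tree into its merge table
#'
#' @param x A `linkage_tree`.
#' @param ... Unused.
#' @return A tibble with `step`, `node_1`, `node_2`, `height` (negative
#'   entries index leaves, positive entries earlier merges, as in
#'   [stats::hclust()]).
#' @method tidy linkage_tree
#' @export
tidy.linkage_tree <- function(x, ...) {
  tibble::tibble(
    step = seq_len(nrow(x$merge)),
    node_1 = x$merge[, 1],
    node_2 = x$merge[, 2],
    height = x$height
  )
}
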