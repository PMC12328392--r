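# ggplot2 graphics for the main result types

#' Plot chromatogram traces
#'
#' Overlays the traces of a chromatogram set, one facet per wavelength,
#' coloured by species.
#'
#' @param set A chromatogram tibble.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_chromatograms <- function(set, alpha = 0.5) {
  long <- tidyr::unnest(
    set[, c("sample_id", "species", "wavelength_nm", "time_min", "absorbance")],
    cols = c("time_min", "absorbance")
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$time_min, y = .data$absorbance,
      group = .data$sample_id, colour = .data$species
    )
  ) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::facet_wrap(~wavelength_nm, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Retention time (min)", y = "Absorbance (AU)") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_chromatograms Autoplot method for fingerprint matrices:
#'   overlaid baseline-corrected fingerprints coloured by species.
#' @param object A `fingerprint_matrix`.
#' @param ... Unused.
#' @method autoplot fingerprint_matrix
#' @export
autoplot.fingerprint_matrix <- function(object, ...) {
  long <- tibble::tibble(
    sample_id = rep(object$sample_ids, each = length(object$time_min)),
    species = rep(object$species, each = length(object$time_min)),
    time_min = rep(object$time_min, times = nrow(object$X)),
    absorbance = as.vector(t(object$X))
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$time_min, y = .data$absorbance,
      group = .data$sample_id, colour = .data$species
    )
  ) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::labs(
      x = "Retention time (min)", y = "Absorbance (AU)",
      title = sprintf("Fingerprints at %d nm", object$wavelength_nm)
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot an antioxidant index
#'
#' Both RACI variants per sample, sorted by the z-score-mean index, coloured
#' by species.
#'
#' @param object An `antioxidant_index`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot antioxidant_index
#' @export
autoplot.antioxidant_index <- function(object, ...) {
  s <- object$samples
  s <- s[order(s$raci_mean), ]
  s$rank <- seq_len(nrow(s))
  long <- tidyr::pivot_longer(
    s,
    cols = c("raci_mean", "pc1_score"),
    names_to = "index", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$rank, y = .data$value,
      colour = .data$species, shape = .data$index
    )
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Sample (sorted by RACI)", y = "Index value",
      shape = "Variant"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot PLS/OPLS regression coefficients
#'
#' Coefficient trace over retention time; optionally shades marker intervals
#' and flags matched standards.
#'
#' @param object A `pls_model` fitted on a `fingerprint_matrix`.
#' @param markers Optional `marker_report` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pls_model
#' @export
autoplot.pls_model <- function(object, markers = NULL, ...) {
  rc <- regression_coefficients(object)
  p <- ggplot2::ggplot(rc, ggplot2::aes(x = .data$time_min, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "Retention time (min)", y = "Regression coefficient",
      title = sprintf(
        "%s coefficients%s", toupper(object$kind),
        if (!is.na(object$wavelength_nm)) {
          sprintf(" at %d nm", object$wavelength_nm)
        } else {
          ""
        }
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(markers) && nrow(markers$intervals)) {
    p <- p + ggplot2::geom_rect(
      data = markers$intervals,
      ggplot2::aes(
        xmin = .data$start_min, xmax = .data$end_min,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "orange", alpha = 0.2
    )
  }
  p
}

#' Plot a Ward dendrogram
#'
#' Simple segment-based dendrogram with leaves coloured by a label vector
#' (typically the species).
#'
#' @param tree A `linkage_tree`.
#' @param labels Optional named vector (by sample id) of leaf labels.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, labels = NULL) {
  n <- length(tree$labels)
  # x position of each leaf in plotting order
  leaf_x <- stats::setNames(seq_len(n), tree$labels[tree$order])
  node_x <- numeric(n - 1)
  node_h <- tree$height
  seg <- list()
  pos <- function(id) {
    if (id < 0) {
      c(leaf_x[[tree$labels[-id]]], 0)
    } else {
      c(node_x[id], node_h[id])
    }
  }
  for (i in seq_len(n - 1)) {
    a <- pos(tree$merge[i, 1])
    b <- pos(tree$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    h <- node_h[i]
    seg[[length(seg) + 1L]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], h, h),
      yend = c(h, h, b[2])
    )
  }
  segs <- dplyr::bind_rows(seg)
  leaves <- tibble::tibble(
    x = unname(leaf_x),
    sample_id = names(leaf_x),
    label = if (!is.null(labels)) unname(labels[names(leaf_x)]) else names(leaf_x)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend),
      linewidth = 0.3
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.02 * max(segs$y), label = .data$label),
      angle = 90, hjust = 1, size = 2.5
    ) +
    ggplot2::labs(x = NULL, y = "Merge height") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}
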