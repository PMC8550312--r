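#' Plot labeled vs unlabeled DNA concentration profiles
#'
#' Density-profile comparison of a labeled/unlabeled sample pair, the
#' view used to place the light/middle/heavy bin boundaries.
#'
#' @param fractions Validated fraction tibble.
#' @param design Design tibble (used to label samples by role).
#' @param boundaries Optional [bin_boundaries()] drawn as vertical
#'   lines.
#' @return A ggplot object.
#' @export
plot_density_profiles <- function(fractions, design, boundaries = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  dat <- dplyr::inner_join(
    fractions, dplyr::select(design, "sample_id", "role", "week"),
    by = "sample_id"
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$density, y = .data$dna_conc,
    colour = .data$role, group = .data$sample_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~week) +
    ggplot2::labs(
      x = "buoyant density (g/ml)", y = "DNA concentration (ng/µl)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    p <- p + ggplot2::geom_vline(
      xintercept = c(boundaries$light_max, boundaries$middle_max),
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}

#' Plot the rank-APE curve with the detection threshold
#'
#' @param enrichment Ranked enrichment tibble (with `labeled` flags if
#'   available).
#' @param threshold Optional threshold result from
#'   [detect_labeling_threshold()] or the `threshold` tibble of
#'   [run_qsip_pipeline()]; draws the breakpoint and APE cutoff.
#' @return A ggplot object.
#' @export
plot_rank_ape <- function(enrichment, threshold = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  p <- ggplot2::ggplot(enrichment, ggplot2::aes(
    x = .data$rank, y = .data$ape,
    colour = .data$taxon_class
  )) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(
      x = "rank (ascending APE)", y = "atom percent excess (%)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    tr <- if (is.data.frame(threshold)) threshold else
      tibble::tibble(
        threshold_rank = threshold$threshold_rank,
        ape_cutoff = threshold$ape_cutoff
      )
    p <- p +
      ggplot2::geom_vline(
        xintercept = tr$threshold_rank,
        linetype = "dashed", colour = "grey40"
      ) +
      ggplot2::geom_hline(
        yintercept = tr$ape_cutoff,
        linetype = "dotted", colour = "grey40"
      )
  }
  p
}
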