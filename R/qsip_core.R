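#' Taxon abundance in one gradient fraction
#'
#' The qSIP abundance metric: relative coverage of the taxon in the
#' fraction library times the total DNA concentration of the fraction.
#' Relative coverage apportions the fraction's DNA among taxa; the
#' concentration scales it to DNA amount.
#'
#' @param p Relative coverage (dimensionless, >= 0).
#' @param f Total DNA concentration of the fraction (ng/ul).
#' @return Abundance y on the ng/ul scale.
#' @export
#' @examples
#' taxon_fraction_abundance(0.2, 50) # 10
taxon_fraction_abundance <- function(p, f) {
  if (any(p < 0) || any(f < 0)) stop("`p` and `f` must be >= 0", call. = FALSE)
  p * f
}

#' Abundance-weighted mean buoyant density of a taxon
#'
#' The taxon's center of mass in the gradient: each fraction's density
#' weighted by the taxon's abundance there.
#'
#' @param y Abundances per fraction (see [taxon_fraction_abundance()]).
#' @param x Fraction buoyant densities (g/ml), same length as `y`.
#' @return The weighted mean density, or `NA_real_` when the taxon is
#'   undetected (all-zero `y`) - absence of signal, not a density of
#'   zero.
#' @export
#' @examples
#' weighted_mean_density(c(10, 10, 20), c(1.70, 1.72, 1.74)) # 1.725
weighted_mean_density <- function(y, x) {
  stopifnot(length(y) == length(x), length(y) >= 1)
  if (any(y < 0)) stop("`y` must be >= 0", call. = FALSE)
  total <- sum(y)
  if (total == 0) {
    return(NA_real_)
  }
  sum(x * y) / total
}

#' Estimate per-taxon isotope enrichment for one timepoint
#'
#' For every taxon present in both treatments at the given week, the
#' abundance-weighted mean density is computed per sample, averaged over
#' replicates within each treatment, and the labeled-vs-unlabeled
#' density shift is converted to 13C atom percent excess via the isotope
#' substitution model. Taxa undetected in either treatment are reported
#' separately with a reason rather than being assigned zero enrichment.
#'
#' @param design Validated design tibble (see [validate_design()]).
#' @param fractions Validated fraction tibble (or pseudo-fractions from
#'   [combine_fractions()]).
#' @param coverage Coverage tibble (taxon_id, sample_id, fraction_id,
#'   rel_coverage); may carry a `taxon_class` column, which is passed
#'   through.
#' @param week Week of the timepoint to analyze.
#' @param constants A [qsip_constants()] object.
#' @return A list with `enrichment` - tibble (taxon_id, taxon_class,
#'   week, w_light, w_lab, ape, rank) ranked ascending by APE - and
#'   `skipped` - tibble (taxon_id, reason).
#' @export
estimate_enrichment <- function(design, fractions, coverage, week,
                                constants = qsip_constants()) {
  wk <- week
  lab_samples <- design$sample_id[design$role == "labeled" & design$week == wk]
  unl_samples <- design$sample_id[design$role == "unlabeled" & design$week == wk]
  if (length(lab_samples) == 0) {
    stop("no labeled sample at week ", wk, call. = FALSE)
  }
  if (length(unl_samples) == 0) {
    stop("week ", wk, " has no paired unlabeled (bulk) sample", call. = FALSE)
  }

  classes <- if ("taxon_class" %in% names(coverage)) {
    dplyr::distinct(coverage, .data$taxon_id, .data$taxon_class)
  } else {
    dplyr::distinct(coverage, .data$taxon_id) |>
      dplyr::mutate(taxon_class = NA_character_)
  }

  dat <- coverage |>
    dplyr::filter(.data$sample_id %in% c(lab_samples, unl_samples)) |>
    dplyr::inner_join(
      dplyr::select(fractions, "sample_id", "fraction_id", "density", "dna_conc"),
      by = c("sample_id", "fraction_id")
    ) |>
    dplyr::mutate(y = taxon_fraction_abundance(.data$rel_coverage, .data$dna_conc))

  # per-sample weighted densities, then replicate means per treatment
  per_sample <- dat |>
    dplyr::group_by(.data$taxon_id, .data$sample_id) |>
    dplyr::summarise(w = weighted_mean_density(.data$y, .data$density), .groups = "drop") |>
    dplyr::mutate(role = ifelse(.data$sample_id %in% lab_samples, "labeled", "unlabeled"))

  per_taxon <- per_sample |>
    dplyr::group_by(.data$taxon_id, .data$role) |>
    dplyr::summarise(w = mean(.data$w, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "w")
  for (col in c("labeled", "unlabeled")) {
    if (!col %in% names(per_taxon)) per_taxon[[col]] <- NA_real_
  }

  all_taxa <- dplyr::left_join(classes, per_taxon, by = "taxon_id")
  skipped <- all_taxa |>
    dplyr::filter(is.na(.data$labeled) | is.nan(.data$labeled) |
      is.na(.data$unlabeled) | is.nan(.data$unlabeled)) |>
    dplyr::mutate(reason = dplyr::case_when(
      (is.na(.data$labeled) | is.nan(.data$labeled)) &
        (is.na(.data$unlabeled) | is.nan(.data$unlabeled)) ~
        "undetected in both treatments",
      is.na(.data$labeled) | is.nan(.data$labeled) ~ "undetected in labeled treatment",
      TRUE ~ "undetected in unlabeled treatment"
    )) |>
    dplyr::select("taxon_id", "reason")

  kept <- dplyr::anti_join(all_taxa, skipped, by = "taxon_id")
  enrichment <- kept |>
    dplyr::mutate(
      week = wk,
      w_light = .data$unlabeled,
      w_lab = .data$labeled,
      ape = 100 * as.numeric(afe_from_densities(.data$unlabeled, .data$labeled, constants))
    ) |>
    dplyr::select("taxon_id", "taxon_class", "week", "w_light", "w_lab", "ape") |>
    rank_by_ape()

  list(enrichment = enrichment, skipped = skipped)
}

#' Rank taxa by atom percent excess
#'
#' Ascending stable sort on APE; ties are broken by taxon id so ranks
#' are reproducible.
#'
#' @param enrichment Tibble with `taxon_id` and `ape` columns.
#' @return The tibble sorted ascending by APE with a 1-based `rank`
#'   column.
#' @export
rank_by_ape <- function(enrichment) {
  out <- dplyr::arrange(enrichment, .data$ape, .data$taxon_id)
  out$rank <- seq_len(nrow(out))
  out
}
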