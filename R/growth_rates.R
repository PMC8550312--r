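#' Growth model configuration
#'
#' @param u Fraction of carbon in newly synthesized DNA that originates
#'   from labeled substrates. In a rhizosphere labeling experiment all
#'   new DNA carbon can come from labeled root inputs, hence the default
#'   1.0.
#' @param a_source Atom fraction excess 13C of the assimilated carbon
#'   pool (0-1]. Gross growth estimates scale by `1/a_source`, so it is
#'   exposed rather than guessed; default 1.0.
#' @param t_days Elapsed time in days.
#' @return A `growth_config` list.
#' @export
growth_config <- function(u = 1.0, a_source = 1.0, t_days) {
  stopifnot(u > 0, u <= 1, a_source > 0, a_source <= 1, t_days > 0)
  structure(list(u = u, a_source = a_source, t_days = t_days),
    class = "growth_config"
  )
}

#' Taxon total abundance in the soil
#'
#' Scales a taxon's whole-sample relative abundance by the sample's DNA
#' yield per gram of dry soil. When not measured directly, the relative
#' abundance is the taxon's share of summed fraction abundances,
#' `sum_k y_ik / sum_taxa sum_k y`.
#'
#' @param p_total Whole-sample relative abundance in `[0, 1]`.
#' @param dna_yield Total DNA extracted per gram of dry soil (ng/g).
#' @return Abundance in ng DNA per g dry soil.
#' @export
#' @examples
#' taxon_total_abundance(0.02, 2000) # 40 ng/g
taxon_total_abundance <- function(p_total, dna_yield) {
  if (any(p_total < 0 | p_total > 1)) {
    stop("`p_total` must lie in [0, 1]", call. = FALSE)
  }
  if (any(dna_yield <= 0)) stop("`dna_yield` must be positive", call. = FALSE)
  p_total * dna_yield
}

#' Whole-sample relative abundances from fraction-level coverage
#'
#' @param fractions Validated fraction tibble for the sample(s).
#' @param coverage Coverage tibble keyed to those fractions.
#' @return Tibble (taxon_id, sample_id, p_total) with p_total summing to
#'   1 per sample over the tracked taxa.
#' @export
whole_sample_abundance <- function(fractions, coverage) {
  coverage |>
    dplyr::inner_join(
      dplyr::select(fractions, "sample_id", "fraction_id", "dna_conc"),
      by = c("sample_id", "fraction_id")
    ) |>
    dplyr::mutate(y = taxon_fraction_abundance(.data$rel_coverage, .data$dna_conc)) |>
    dplyr::group_by(.data$sample_id, .data$taxon_id) |>
    dplyr::summarise(y = sum(.data$y), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(p_total = .data$y / sum(.data$y)) |>
    dplyr::ungroup() |>
    dplyr::select("taxon_id", "sample_id", "p_total")
}

#' Net growth rate under the linear growth model
#'
#' `N_t = N_0 + r*t`, so the net rate is the abundance change per day.
#' Negative values (population decline) are reported as-is.
#'
#' @param n_t,n_0 Total abundance (ng DNA per g dry soil) at time t and
#'   time zero.
#' @param t_days Elapsed days.
#' @return Net growth rate in ng DNA g^-1 day^-1.
#' @export
#' @examples
#' net_growth_rate(100, 40, 42) # ~1.43
net_growth_rate <- function(n_t, n_0, t_days) {
  if (any(t_days <= 0)) stop("`t_days` must be positive", call. = FALSE)
  (n_t - n_0) / t_days
}

#' Gross growth rate on labeled carbon
#'
#' Under linear growth with new DNA built from a carbon pool of
#' enrichment `a_source`, a taxon whose DNA measures atom fraction
#' excess A has new-DNA fraction `phi = A / (a_source * u)`; the DNA
#' produced over the incubation is `N_t * phi`, giving the gross rate
#' per day. `phi` is capped at 1 (all DNA new) with a warning, and a
#' negative APE - measurement noise, not negative growth - yields a rate
#' of exactly 0.
#'
#' @param n_t Total abundance at time t (ng DNA per g dry soil).
#' @param ape_percent Measured atom percent excess (100 x atom fraction
#'   excess).
#' @param cfg A [growth_config()].
#' @return Gross growth rate in ng DNA g^-1 day^-1; never negative and
#'   never above `n_t / t_days`.
#' @export
#' @examples
#' gross_growth_rate(100, 45, growth_config(a_source = 0.9, t_days = 42))
gross_growth_rate <- function(n_t, ape_percent, cfg) {
  stopifnot(inherits(cfg, "growth_config"))
  if (any(!is.finite(ape_percent))) stop("`ape_percent` must be finite", call. = FALSE)
  phi <- pmax(0, ape_percent / 100) / (cfg$a_source * cfg$u)
  if (any(phi > 1)) {
    warning(sum(phi > 1), " taxa with labeled fraction > 1; capped (all DNA new)",
      call. = FALSE
    )
    phi <- pmin(phi, 1)
  }
  n_t * phi / cfg$t_days
}

#' Per-taxon growth estimates for one timepoint
#'
#' Combines time-zero and time-t total abundances with the enrichment
#' estimates: net rate from the abundance change, gross rate from the
#' labeled fraction of the time-t DNA pool.
#'
#' @param enrichment Enrichment tibble for the timepoint (taxon_id, week,
#'   ape).
#' @param n0 Tibble (taxon_id, n_total) at time zero.
#' @param nt Tibble (taxon_id, n_total) at the timepoint.
#' @param cfg A [growth_config()]; its `t_days` must match the timepoint
#'   (7 days per week).
#' @return Tibble (taxon_id, week, ape, n_total_0, n_total_t, r_net,
#'   r_gross). Taxa missing an abundance at either time are dropped.
#' @export
estimate_growth <- function(enrichment, n0, nt, cfg) {
  stopifnot(inherits(cfg, "growth_config"))
  enrichment |>
    dplyr::inner_join(
      dplyr::rename(n0, n_total_0 = "n_total"),
      by = "taxon_id"
    ) |>
    dplyr::inner_join(
      dplyr::rename(nt, n_total_t = "n_total"),
      by = "taxon_id"
    ) |>
    dplyr::mutate(
      r_net = net_growth_rate(.data$n_total_t, .data$n_total_0, cfg$t_days),
      r_gross = gross_growth_rate(.data$n_total_t, .data$ape, cfg)
    ) |>
    dplyr::select(dplyr::any_of(c(
      "taxon_id", "taxon_class", "week", "ape",
      "n_total_0", "n_total_t", "r_net", "r_gross"
    )))
}
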