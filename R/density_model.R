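#' Constants of the isotope-substitution-in-DNA model
#'
#' The closed-form qSIP model relating GC content, buoyant density,
#' average nucleotide molecular weight, and 13C atom fraction excess is
#' parameterized by a small set of empirical constants. They are held in
#' one object so an alternative parameterization (e.g. for a different
#' isotope) can be supplied to every model function without touching
#' callers.
#'
#' @param density_intercept Buoyant density (g/ml) of DNA with GC = 0.
#' @param density_slope Increase in buoyant density (g/ml) per unit GC
#'   fraction.
#' @param mw_intercept Average nucleotide molecular weight (g/mol) at
#'   GC = 0, natural isotope abundance.
#' @param mw_gc_slope Increase in average nucleotide weight (g/mol) per
#'   unit GC fraction.
#' @param dmw_max_intercept Maximum possible mass gain (g/mol) of the
#'   average nucleotide under full 13C substitution, at GC = 0.
#' @param dmw_max_gc_slope Change of that maximum gain per unit GC
#'   fraction (negative: GC pairs carry slightly less carbon per
#'   nucleotide pair).
#' @param nat_abund_13c Natural 13C atom fraction.
#'
#' @return A named list of class `qsip_constants`.
#' @export
#' @examples
#' cst <- qsip_constants()
#' cst$density_slope
qsip_constants <- function(density_intercept = 1.646057,
                           density_slope = 0.083506,
                           mw_intercept = 307.691,
                           mw_gc_slope = 0.496,
                           dmw_max_intercept = 9.974564,
                           dmw_max_gc_slope = -0.4987282,
                           nat_abund_13c = 0.01111233) {
  cst <- list(
    density_intercept = density_intercept,
    density_slope = density_slope,
    mw_intercept = mw_intercept,
    mw_gc_slope = mw_gc_slope,
    dmw_max_intercept = dmw_max_intercept,
    dmw_max_gc_slope = dmw_max_gc_slope,
    nat_abund_13c = nat_abund_13c
  )
  stopifnot(vapply(cst, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1)))
  structure(cst, class = "qsip_constants")
}

# density bounds outside which a weighted mean density is physically implausible
.density_lo <- 1.55
.density_hi <- 1.85

#' GC content inferred from unlabeled buoyant density
#'
#' Inverts the linear density-GC relationship: the buoyant density of
#' unlabeled (natural-abundance) DNA is determined by its GC content, so
#' the taxon's mean weighted density in the unlabeled treatment yields
#' its genome-wide GC fraction without consulting the sequence.
#'
#' @param w_light Mean weighted buoyant density (g/ml) in the unlabeled
#'   treatment. Must lie in (1.55, 1.85).
#' @param constants A [qsip_constants()] object.
#'
#' @return Numeric vector of GC fractions. Values outside `[0, 1]`
#'   (possible under noisy density estimates) are returned unclamped and
#'   carry an attribute `out_of_range` marking them, so downstream QC can
#'   drop the taxon explicitly.
#' @export
#' @examples
#' gc_from_light_density(1.70) # ~0.646
gc_from_light_density <- function(w_light, constants = qsip_constants()) {
  if (any(!is.finite(w_light))) {
    stop("`w_light` must be finite", call. = FALSE)
  }
  if (any(w_light <= .density_lo | w_light >= .density_hi)) {
    stop("`w_light` outside the physically plausible range (1.55, 1.85) g/ml",
      call. = FALSE
    )
  }
  g <- (w_light - constants$density_intercept) / constants$density_slope
  tol <- 1e-9 # rounding slack so exact endpoints are not flagged
  oor <- g < -tol | g > 1 + tol
  if (any(oor)) {
    attr(g, "out_of_range") <- oor
  }
  g
}

#' Average nucleotide molecular weight of unlabeled DNA
#'
#' @param gc GC fraction.
#' @inheritParams gc_from_light_density
#' @return Molecular weight in g/mol per average nucleotide.
#' @export
mw_light <- function(gc, constants = qsip_constants()) {
  stopifnot(is.finite(gc))
  constants$mw_gc_slope * gc + constants$mw_intercept
}

#' Maximum average nucleotide weight under full 13C substitution
#'
#' @param gc GC fraction.
#' @param m_light Unlabeled molecular weight; computed from `gc` when
#'   missing.
#' @inheritParams gc_from_light_density
#' @return Molecular weight in g/mol of the fully 13C-substituted
#'   average nucleotide.
#' @export
mw_heavy_max_13c <- function(gc, m_light = mw_light(gc, constants),
                             constants = qsip_constants()) {
  m_light + constants$dmw_max_intercept + constants$dmw_max_gc_slope * gc
}

#' Atom fraction excess 13C from a buoyant density shift
#'
#' The core qSIP conversion. GC content (hence the unlabeled molecular
#' weight and the fully labeled maximum weight) is inferred from the
#' unlabeled density; the labeled density is converted to a labeled
#' molecular weight by proportional scaling; the excess mass, as a
#' fraction of the maximum possible gain, gives atom fraction excess
#' after discounting the natural 13C background. Because GC enters only
#' through the paired unlabeled density, the GC/enrichment confound of
#' raw buoyant density cancels.
#'
#' @param w_light,w_lab Mean weighted densities (g/ml) in the unlabeled
#'   and labeled treatments.
#' @inheritParams gc_from_light_density
#' @return Atom fraction excess on the 0-1 scale (multiply by 100 for
#'   APE). Negative values (labeled density below unlabeled, pure noise)
#'   are returned as-is, not clamped.
#' @export
#' @examples
#' afe_from_densities(1.70, 1.726937) # ~0.5
afe_from_densities <- function(w_light, w_lab, constants = qsip_constants()) {
  if (any(!is.finite(w_lab))) stop("`w_lab` must be finite", call. = FALSE)
  gc <- gc_from_light_density(w_light, constants)
  m_light <- mw_light(as.numeric(gc), constants)
  m_heavy <- mw_heavy_max_13c(as.numeric(gc), m_light, constants)
  m_lab <- m_light * (w_lab / w_light)
  a <- ((m_lab - m_light) / (m_heavy - m_light)) * (1 - constants$nat_abund_13c)
  if (!is.null(attr(gc, "out_of_range"))) {
    attr(a, "gc_out_of_range") <- attr(gc, "out_of_range")
  }
  a
}

#' Buoyant density implied by a known atom fraction excess
#'
#' Exact inverse of [afe_from_densities()]; the forward model used by
#' the gradient simulator to place a taxon of known GC and enrichment in
#' the gradient.
#'
#' @param gc GC fraction.
#' @param afe Atom fraction excess 13C on the 0-1 scale; must lie in
#'   `[0, 1 - nat_abund_13c]`.
#' @param w_light Unlabeled buoyant density; computed from `gc` when
#'   missing.
#' @inheritParams gc_from_light_density
#' @return Labeled buoyant density (g/ml).
#' @export
#' @examples
#' density_from_afe(0.5, 0) # == unlabeled density at GC 0.5
density_from_afe <- function(gc, afe,
                             w_light = NULL,
                             constants = qsip_constants()) {
  stopifnot(is.finite(gc), is.finite(afe))
  amax <- 1 - constants$nat_abund_13c
  if (any(afe < 0 | afe > amax)) {
    stop("`afe` outside the physical range [0, ", signif(amax, 8), "]",
      call. = FALSE
    )
  }
  if (is.null(w_light)) {
    w_light <- constants$density_intercept + constants$density_slope * gc
  }
  m_light <- mw_light(gc, constants)
  m_heavy <- mw_heavy_max_13c(gc, m_light, constants)
  m_lab <- m_light + (afe / amax) * (m_heavy - m_light)
  w_light * m_lab / m_light
}
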