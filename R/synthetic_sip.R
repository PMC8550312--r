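#' Gradient simulation configuration
#'
#' Defaults emulate a CsCl gradient spun to equilibrium and drawn into
#' ~32 fractions spanning the density range where soil community DNA
#' bands.
#'
#' @param density_min,density_max Density range (g/ml) covered by the
#'   collected fractions.
#' @param n_fractions Number of equal-width fractions.
#' @param sigma_density Gaussian spread (g/ml) of one taxon's DNA about
#'   its buoyant density, lumping diffusion and fragment-length effects.
#'   The 0.005 default lets a 32-fraction gradient resolve labeled from
#'   unlabeled DNA at roughly 20 APE.
#' @param reads_per_library Expected reads per fraction library for the
#'   multinomial sequencing-noise model; 0 (default) means noiseless.
#' @param volume_ul Fraction volume (ul).
#' @param bin_mode `"per_fraction"` (emit every fraction) or
#'   `"three_bins"` (combine into light/middle/heavy before emitting,
#'   as when pooled bins are sequenced).
#' @param seed Integer seed making a simulation reproducible; NULL uses
#'   the current RNG state.
#' @return A `gradient_config` list.
#' @export
gradient_config <- function(density_min = 1.692, density_max = 1.765,
                            n_fractions = 32, sigma_density = 0.005,
                            reads_per_library = 0, volume_ul = 144,
                            bin_mode = c("per_fraction", "three_bins"),
                            seed = NULL) {
  bin_mode <- match.arg(bin_mode)
  stopifnot(
    density_min < density_max, n_fractions >= 3, sigma_density > 0,
    reads_per_library >= 0, volume_ul > 0
  )
  structure(
    list(
      density_min = density_min, density_max = density_max,
      n_fractions = n_fractions, sigma_density = sigma_density,
      reads_per_library = reads_per_library, volume_ul = volume_ul,
      bin_mode = bin_mode, seed = seed
    ),
    class = "gradient_config"
  )
}

#' Synthetic taxa table
#'
#' @param taxon_id Identifiers.
#' @param taxon_class One of bacterial_bin, phage, eukaryote_scaffold
#'   per taxon.
#' @param g_true True GC fraction in `[0, 1]`.
#' @param ape_true True 13C atom percent excess in `[0, 98.9]`.
#' @param mass_ng Total DNA mass of the taxon in the tube (ng); when
#'   time courses are simulated this is also the abundance in ng per g
#'   dry soil at time zero.
#' @param r_true True net growth rate (ng g^-1 day^-1), used by
#'   [simulate_timepoints()].
#' @return A validated tibble of synthetic taxa.
#' @export
synthetic_taxa <- function(taxon_id, taxon_class, g_true, ape_true, mass_ng,
                           r_true = 0) {
  stopifnot(
    all(taxon_class %in% c("bacterial_bin", "phage", "eukaryote_scaffold")),
    all(g_true >= 0 & g_true <= 1),
    all(ape_true >= 0 & ape_true <= 98.9),
    all(mass_ng > 0)
  )
  if (anyDuplicated(taxon_id)) stop("duplicate taxon_id", call. = FALSE)
  tibble::tibble(
    taxon_id = as.character(taxon_id), taxon_class = taxon_class,
    g_true = g_true, ape_true = ape_true, mass_ng = mass_ng,
    r_true = r_true
  )
}

# Distribute each taxon's DNA mass over the fraction grid: Gaussian
# (center = buoyant density at its GC and APE, sd = sigma_density)
# integrated over each fraction's density interval.
.fraction_masses <- function(taxa, cfg, ape) {
  edges <- seq(cfg$density_min, cfg$density_max, length.out = cfg$n_fractions + 1)
  centers <- density_from_afe(taxa$g_true, ape / 100)
  m <- vapply(seq_len(cfg$n_fractions), function(k) {
    taxa$mass_ng *
      (pnorm(edges[k + 1], centers, cfg$sigma_density) -
        pnorm(edges[k], centers, cfg$sigma_density))
  }, numeric(nrow(taxa)))
  m <- matrix(m, nrow = nrow(taxa))
  truncated <- 1 - rowSums(m) / taxa$mass_ng
  if (any(truncated > 0.01)) {
    warning(
      "more than 1% of DNA mass outside the density range for taxa: ",
      paste(taxa$taxon_id[truncated > 0.01], collapse = ", "),
      call. = FALSE
    )
  }
  list(mass = m, edges = edges)
}

.simulate_sample <- function(taxa, cfg, sample_id, ape) {
  fm <- .fraction_masses(taxa, cfg, ape)
  m <- fm$mass
  mids <- (head(fm$edges, -1) + tail(fm$edges, -1)) / 2
  frac_ids <- sprintf("F%02d", seq_len(cfg$n_fractions))
  f <- colSums(m) / cfg$volume_ul

  if (cfg$reads_per_library > 0) {
    shares <- apply(m, 2, function(col) {
      tot <- sum(col)
      if (tot == 0) {
        return(rep(0, length(col)))
      }
      counts <- rmultinom(1, size = cfg$reads_per_library, prob = col / tot)[, 1]
      counts / cfg$reads_per_library
    })
    shares <- matrix(shares, nrow = nrow(taxa))
    total_reads <- rep(cfg$reads_per_library, cfg$n_fractions)
  } else {
    shares <- apply(m, 2, function(col) {
      tot <- sum(col)
      if (tot == 0) rep(0, length(col)) else col / tot
    })
    shares <- matrix(shares, nrow = nrow(taxa))
    total_reads <- rep(1e6, cfg$n_fractions)
  }

  fractions <- tibble::tibble(
    sample_id = sample_id, fraction_id = frac_ids,
    density = mids, dna_conc = f, volume_ul = cfg$volume_ul,
    density_bin = "unassigned"
  )
  coverage <- tibble::tibble(
    taxon_id = rep(taxa$taxon_id, times = cfg$n_fractions),
    taxon_class = rep(taxa$taxon_class, times = cfg$n_fractions),
    sample_id = sample_id,
    fraction_id = rep(frac_ids, each = nrow(taxa)),
    rel_coverage = as.vector(shares)
  )
  libraries <- tibble::tibble(
    library_id = paste(sample_id, frac_ids, sep = "_"),
    sample_id = sample_id, fraction_or_bin_id = frac_ids,
    total_reads = total_reads
  )
  list(fractions = fractions, coverage = coverage, libraries = libraries)
}

#' Simulate one labeled/unlabeled gradient pair
#'
#' Forward-simulates the density separation of a labeled (rhizosphere)
#' and an unlabeled (bulk) sample of the same community: each taxon's
#' DNA bands at the buoyant density implied by its GC content and (for
#' the labeled sample) its true enrichment, spreads as a Gaussian, and
#' is discretized into fractions. Relative coverage is each taxon's
#' share of a fraction's DNA, optionally resampled multinomially to
#' emulate sequencing noise. With `bin_mode = "three_bins"` the
#' fractions are combined into light/middle/heavy bins using boundaries
#' derived from the simulated concentration profiles, as when pooled
#' bins rather than single fractions are sequenced.
#'
#' @param taxa A [synthetic_taxa()] tibble.
#' @param cfg A [gradient_config()].
#' @param week Week recorded in the design table (default 6).
#' @return A list of tibbles: `fractions`, `coverage`, `libraries`,
#'   `design`, `truth` (plus `boundaries` in three-bin mode), using the
#'   same schemas the pipeline reads.
#' @export
simulate_gradient <- function(taxa, cfg = gradient_config(), week = 6) {
  stopifnot(inherits(cfg, "gradient_config"), nrow(taxa) > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lab_id <- sprintf("rhizo_w%d", week)
  unl_id <- sprintf("bulk_w%d", week)
  lab <- .simulate_sample(taxa, cfg, lab_id, taxa$ape_true)
  unl <- .simulate_sample(taxa, cfg, unl_id, rep(0, nrow(taxa)))

  out <- list(
    fractions = dplyr::bind_rows(lab$fractions, unl$fractions),
    coverage = dplyr::bind_rows(lab$coverage, unl$coverage),
    libraries = dplyr::bind_rows(lab$libraries, unl$libraries),
    design = tibble::tibble(
      sample_id = c(lab_id, unl_id),
      habitat = c("rhizosphere", "bulk"),
      week = week,
      role = c("labeled", "unlabeled"),
      replicate = 1L
    ),
    truth = taxa
  )
  if (cfg$bin_mode == "three_bins") {
    bounds <- derive_bin_boundaries(lab$fractions, unl$fractions)
    binned <- combine_fractions(
      assign_density_bins(out$fractions, bounds),
      out$coverage
    )
    out$fractions <- binned$fractions
    out$coverage <- binned$coverage
    out$libraries <- tibble::tibble(
      library_id = paste(out$fractions$sample_id, out$fractions$fraction_id, sep = "_"),
      sample_id = out$fractions$sample_id,
      fraction_or_bin_id = out$fractions$fraction_id,
      total_reads = if (cfg$reads_per_library > 0) cfg$reads_per_library else 1e6
    )
    out$boundaries <- bounds
  }
  out
}

#' Simulate a labeled time course
#'
#' Taxon abundances (ng DNA per g dry soil) evolve linearly,
#' `N(t) = N(0) + r_true * t` with `t = 7 * week` days. DNA synthesized
#' during the incubation carries the enrichment of the source carbon
#' pool, so a taxon's measured enrichment at week w is its new-DNA
#' fraction times `a_source`; bulk (unlabeled) communities stay at
#' natural abundance. Week 0 contributes the single time-zero bulk
#' sample; later weeks contribute a labeled/unlabeled pair each.
#'
#' @inheritParams simulate_gradient
#' @param weeks Weeks to simulate; must include 0.
#' @param a_source Atom fraction excess of the assimilated carbon pool
#'   (0-1], default 1.
#' @return A list of tibbles `fractions`, `coverage`, `libraries`,
#'   `design`, `yields` (sample_id, week, role, dna_yield in ng/g), and
#'   `truth` with per-week columns `week`, `n_total_true` and
#'   `ape_week_true`.
#' @export
simulate_timepoints <- function(taxa, cfg = gradient_config(),
                                weeks = c(0, 6, 9), a_source = 1) {
  stopifnot(0 %in% weeks, a_source > 0, a_source <= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg_noseed <- cfg
  cfg_noseed$seed <- NULL # one seeding for the whole time course

  pieces <- lapply(sort(weeks), function(w) {
    t_days <- 7 * w
    n_t <- taxa$mass_ng + taxa$r_true * t_days
    if (any(n_t < 0)) {
      stop("negative abundance at week ", w, " under the supplied r_true",
        call. = FALSE
      )
    }
    phi <- ifelse(n_t > 0, pmax(0, taxa$r_true * t_days) / n_t, 0)
    ape_w <- 100 * a_source * phi
    taxa_w <- taxa
    taxa_w$mass_ng <- n_t
    truth_w <- tibble::tibble(
      taxon_id = taxa$taxon_id, taxon_class = taxa$taxon_class,
      g_true = taxa$g_true, r_true = taxa$r_true, week = w,
      n_total_true = n_t, ape_week_true = ape_w
    )

    if (w == 0) {
      unl <- .simulate_sample(taxa_w, cfg_noseed, "bulk_w0", rep(0, nrow(taxa)))
      list(
        fractions = unl$fractions, coverage = unl$coverage,
        libraries = unl$libraries,
        design = tibble::tibble(
          sample_id = "bulk_w0", habitat = "bulk", week = 0,
          role = "unlabeled", replicate = 1L
        ),
        yields = tibble::tibble(
          sample_id = "bulk_w0", week = 0, role = "unlabeled",
          dna_yield = sum(n_t)
        ),
        truth = truth_w
      )
    } else {
      taxa_w$ape_true <- ape_w
      sim <- simulate_gradient(taxa_w, cfg_noseed, week = w)
      sim$yields <- tibble::tibble(
        sample_id = sim$design$sample_id, week = w,
        role = sim$design$role, dna_yield = sum(n_t)
      )
      sim$truth <- truth_w
      sim[c("fractions", "coverage", "libraries", "design", "yields", "truth")]
    }
  })

  list(
    fractions = dplyr::bind_rows(lapply(pieces, `[[`, "fractions")),
    coverage = dplyr::bind_rows(lapply(pieces, `[[`, "coverage")),
    libraries = dplyr::bind_rows(lapply(pieces, `[[`, "libraries")),
    design = dplyr::bind_rows(lapply(pieces, `[[`, "design")),
    yields = dplyr::bind_rows(lapply(pieces, `[[`, "yields")),
    truth = dplyr::bind_rows(lapply(pieces, `[[`, "truth"))
  )
}

#' Rhizosphere-like community preset
#'
#' A 92-taxon community shaped like a labeled rhizosphere soil
#' metagenome: 55 bacterial genome bins of which roughly 78% carry
#' detectable label, 10 strongly labeled phage genomes (the most labeled
#' taxa in the community), and 27 eukaryote 18S scaffolds that are at
#' most weakly labeled. True APE values are laid out so the rank-APE
#' curve has a flat low-rank segment followed by a rise - the hinge
#' shape the breakpoint detection stage needs. True growth rates are
#' chosen so that, under linear growth over a 6-week incubation with a
#' fully labeled carbon pool, each taxon's new-DNA fraction reproduces
#' its true APE.
#'
#' @param seed Seed stored in the returned config (default 42).
#' @return A list with `taxa` (a [synthetic_taxa()] tibble) and `cfg`
#'   (a [gradient_config()]).
#' @export
rhizosphere_preset <- function(seed = 42) {
  n_bact <- 55
  n_phage <- 10
  n_euk <- 27
  n_bact_unl <- 12 # 43/55 = 78% of bacteria labeled

  bact_ape <- c(
    seq(0, 1.1, length.out = n_bact_unl),
    seq(4, 60, length.out = n_bact - n_bact_unl)
  )
  phage_ape <- seq(62, 90, length.out = n_phage)
  euk_ape <- c(seq(0, 1.0, length.out = n_euk - 3), 3.0, 3.8, 4.5)

  taxa <- synthetic_taxa(
    taxon_id = c(
      sprintf("bin_%02d", seq_len(n_bact)),
      sprintf("phage_%02d", seq_len(n_phage)),
      sprintf("euk_%02d", seq_len(n_euk))
    ),
    taxon_class = rep(
      c("bacterial_bin", "phage", "eukaryote_scaffold"),
      c(n_bact, n_phage, n_euk)
    ),
    g_true = c(
      seq(0.35, 0.70, length.out = n_bact),
      seq(0.38, 0.55, length.out = n_phage),
      seq(0.40, 0.60, length.out = n_euk)
    ),
    ape_true = c(bact_ape, phage_ape, euk_ape),
    mass_ng = exp(seq(log(20), log(200), length.out = n_bact + n_phage + n_euk))
  )
  # linear-growth rate consistent with the taxon's APE at week 6 under a
  # fully labeled pool: phi = APE/100, r = phi*N0 / (t*(1-phi))
  t_days <- 42
  phi <- taxa$ape_true / 100
  taxa$r_true <- phi * taxa$mass_ng / (t_days * (1 - phi))

  # gradient wide enough that every taxon's band (GC 0.35-0.70, up to 90
  # APE) lies well inside the collected range
  list(
    taxa = taxa,
    cfg = gradient_config(density_min = 1.65, density_max = 1.80, seed = seed)
  )
}
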