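#' @importFrom rlang .data
#' @importFrom stats approx coef lm median pnorm quantile rmultinom sd setNames vcov
#' @importFrom utils head tail
NULL

.required_cols <- list(
  fractions = c("sample_id", "fraction_id", "density_g_ml", "dna_conc_ng_ul"),
  coverage  = c("library_id", "scaffold_id", "length_bp", "mean_depth"),
  binmap    = c("scaffold_id", "taxon_id"),
  design    = c("sample_id", "habitat", "week", "role", "replicate"),
  libraries = c("library_id", "sample_id", "fraction_or_bin_id", "total_reads")
)

.check_cols <- function(df, table) {
  missing <- setdiff(.required_cols[[table]], names(df))
  if (length(missing) > 0) {
    stop(
      sprintf(
        "%s table is missing required column(s): %s",
        table, paste(missing, collapse = ", ")
      ),
      call. = FALSE
    )
  }
  invisible(df)
}

.read_tsv_quiet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, comment = "#")
}

#' Read and validate the qSIP input tables
#'
#' Reads the five tab-delimited inputs (gradient fraction metadata,
#' per-scaffold coverage, scaffold-to-taxon bin map, sample design, and
#' sequencing library metadata), checks the schema of each, and
#' cross-references identifiers across tables.
#'
#' Expected columns: `fractions.tsv` (sample_id, fraction_id,
#' density_g_ml, dna_conc_ng_ul, optional volume_ul), `coverage.tsv`
#' (library_id, scaffold_id, length_bp, mean_depth), `binmap.tsv`
#' (scaffold_id, taxon_id), `design.tsv` (sample_id, habitat, week,
#' role, replicate), `libraries.tsv` (library_id, sample_id,
#' fraction_or_bin_id, total_reads).
#'
#' @param fraction_path,coverage_path,binmap_path,design_path,libraries_path
#'   Paths to the TSV files.
#' @return A named list of validated tibbles: `fractions` (with density
#'   and dna_conc renamed to bare units-free names and volume_ul filled
#'   with its 144 ul default), `coverage`, `binmap`, `design`,
#'   `libraries`.
#' @export
read_qsip_tables <- function(fraction_path, coverage_path, binmap_path,
                             design_path, libraries_path) {
  fractions <- .check_cols(.read_tsv_quiet(fraction_path), "fractions")
  coverage <- .check_cols(.read_tsv_quiet(coverage_path), "coverage")
  binmap <- .check_cols(.read_tsv_quiet(binmap_path), "binmap")
  design <- .check_cols(.read_tsv_quiet(design_path), "design")
  libraries <- .check_cols(.read_tsv_quiet(libraries_path), "libraries")

  fractions <- validate_fractions(fractions)
  design <- validate_design(design)

  if (any(coverage$mean_depth < 0 | !is.finite(coverage$mean_depth))) {
    stop("coverage table contains negative or non-finite mean_depth", call. = FALSE)
  }
  if (any(coverage$length_bp < 1)) {
    stop("coverage table contains non-positive scaffold lengths", call. = FALSE)
  }
  dup <- duplicated(coverage[c("library_id", "scaffold_id")])
  if (any(dup)) {
    k <- coverage[which(dup)[1], ]
    stop(
      sprintf(
        "duplicate coverage row for (library '%s', scaffold '%s')",
        k$library_id, k$scaffold_id
      ),
      call. = FALSE
    )
  }

  orphans <- !(binmap$scaffold_id %in% coverage$scaffold_id)
  if (any(orphans)) {
    warning(
      sum(orphans), " bin-map scaffold(s) have no coverage rows; dropped",
      call. = FALSE
    )
    binmap <- binmap[!orphans, ]
  }
  if (anyDuplicated(binmap$scaffold_id)) {
    stop("bin map assigns some scaffold to more than one taxon", call. = FALSE)
  }

  if (any(libraries$total_reads <= 0)) {
    stop("libraries table contains non-positive total_reads", call. = FALSE)
  }
  unknown <- setdiff(libraries$sample_id, design$sample_id)
  if (length(unknown) > 0) {
    stop(
      "libraries reference sample_id(s) absent from design: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }

  message(sprintf(
    "read %d fractions, %d coverage rows, %d bin-map rows, %d samples, %d libraries",
    nrow(fractions), nrow(coverage), nrow(binmap), nrow(design), nrow(libraries)
  ))
  list(
    fractions = fractions, coverage = coverage, binmap = binmap,
    design = design, libraries = libraries
  )
}

#' Validate a gradient fraction table
#'
#' @param fractions Tibble with sample_id, fraction_id, density_g_ml,
#'   dna_conc_ng_ul, optional volume_ul.
#' @return Tibble with columns sample_id, fraction_id, density, dna_conc,
#'   volume_ul, density_bin (initialized "unassigned").
#' @export
validate_fractions <- function(fractions) {
  .check_cols(fractions, "fractions")
  if (any(!is.finite(fractions$density_g_ml))) {
    stop("non-finite density in fraction table", call. = FALSE)
  }
  if (any(fractions$density_g_ml <= .density_lo | fractions$density_g_ml >= .density_hi)) {
    stop("fraction density outside the plausible CsCl range (1.55, 1.85) g/ml",
      call. = FALSE
    )
  }
  if (any(fractions$dna_conc_ng_ul < 0)) {
    stop("negative DNA concentration in fraction table", call. = FALSE)
  }
  dup <- duplicated(fractions[c("sample_id", "fraction_id")])
  if (any(dup)) {
    k <- fractions[which(dup)[1], ]
    stop(
      sprintf(
        "duplicate fraction row for (sample '%s', fraction '%s')",
        k$sample_id, k$fraction_id
      ),
      call. = FALSE
    )
  }
  if (!("volume_ul" %in% names(fractions))) fractions$volume_ul <- 144
  fractions$volume_ul[is.na(fractions$volume_ul)] <- 144

  # collection order (file order) should sweep the gradient monotonically
  mono <- vapply(split(fractions$density_g_ml, fractions$sample_id), function(d) {
    length(d) < 3 || all(diff(d) > 0) || all(diff(d) < 0)
  }, logical(1))
  if (!all(mono)) {
    warning(
      "fraction densities not monotone in collection order for sample(s): ",
      paste(names(mono)[!mono], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    sample_id = fractions$sample_id,
    fraction_id = as.character(fractions$fraction_id),
    density = fractions$density_g_ml,
    dna_conc = fractions$dna_conc_ng_ul,
    volume_ul = fractions$volume_ul,
    density_bin = "unassigned"
  )
}

#' Validate a sample design table
#'
#' Checks factor levels and the labeled/unlabeled pairing: every week
#' with a labeled sample must also have at least one unlabeled sample to
#' serve as its density reference.
#'
#' @param design Tibble with sample_id, habitat, week, role, replicate.
#' @return The validated tibble.
#' @export
validate_design <- function(design) {
  .check_cols(design, "design")
  if (!all(design$habitat %in% c("bulk", "rhizosphere"))) {
    stop("design habitat must be 'bulk' or 'rhizosphere'", call. = FALSE)
  }
  if (!all(design$role %in% c("labeled", "unlabeled"))) {
    stop("design role must be 'labeled' or 'unlabeled'", call. = FALSE)
  }
  if (any(design$week < 0) || any(design$week != floor(design$week))) {
    stop("design week must be a nonnegative integer", call. = FALSE)
  }
  if (any(design$replicate < 1)) {
    stop("design replicate must be >= 1", call. = FALSE)
  }
  lab_weeks <- unique(design$week[design$role == "labeled"])
  unl_weeks <- unique(design$week[design$role == "unlabeled"])
  unpaired <- setdiff(lab_weeks, unl_weeks)
  if (length(unpaired) > 0) {
    stop(
      "labeled sample(s) at week(s) ", paste(unpaired, collapse = ", "),
      " have no unlabeled sample at the same week",
      call. = FALSE
    )
  }
  design
}

#' Length-weighted bin coverage from scaffold coverage
#'
#' Aggregates per-scaffold read depths into one mean depth per genome
#' bin and library. The bin depth is the scaffold-length-weighted mean,
#' which equals the depth obtained by mapping against all scaffolds of
#' the bin at once.
#'
#' @param scaffold_cov Tibble (library_id, scaffold_id, length_bp,
#'   mean_depth).
#' @param bin_map Tibble (scaffold_id, taxon_id); each scaffold may
#'   belong to at most one taxon.
#' @param min_scaffold_length Scaffolds shorter than this are excluded
#'   (default 1000 bp).
#' @return Tibble (library_id, taxon_id, mean_depth).
#' @export
#' @examples
#' cov <- tibble::tibble(
#'   library_id = "L1", scaffold_id = c("s1", "s2"),
#'   length_bp = c(1000, 3000), mean_depth = c(10, 20)
#' )
#' bm <- tibble::tibble(scaffold_id = c("s1", "s2"), taxon_id = "bin1")
#' aggregate_bin_coverage(cov, bm) # depth 17.5
aggregate_bin_coverage <- function(scaffold_cov, bin_map,
                                   min_scaffold_length = 1000) {
  if (anyDuplicated(bin_map$scaffold_id)) {
    stop("bin map assigns some scaffold to more than one taxon", call. = FALSE)
  }
  kept <- dplyr::filter(scaffold_cov, .data$length_bp >= min_scaffold_length)
  joined <- dplyr::inner_join(kept, bin_map, by = "scaffold_id")
  out <- joined |>
    dplyr::group_by(.data$library_id, .data$taxon_id) |>
    dplyr::summarise(
      total_len = sum(.data$length_bp),
      mean_depth = sum(.data$mean_depth * .data$length_bp) / sum(.data$length_bp),
      .groups = "drop"
    )
  if (any(out$total_len == 0)) {
    stop("genome bin with zero total scaffold length", call. = FALSE)
  }
  dplyr::select(out, "library_id", "taxon_id", "mean_depth")
}

#' Depth-normalized relative coverage
#'
#' Scales a read depth by the size of its library so coverages are
#' comparable across fraction libraries of very different sequencing
#' depth. The dialect is depth per million mapped reads; any per-library
#' constant would do, since relative coverage enters the qSIP estimates
#' only through products and ratios that cancel it.
#'
#' @param depth Mean read depth (reads/bp).
#' @param library_total_reads Total mapped reads of the library.
#' @return Relative coverage (depth per million reads).
#' @export
#' @examples
#' normalize_coverage(10, 2e6) # 5
normalize_coverage <- function(depth, library_total_reads) {
  if (any(library_total_reads <= 0)) {
    stop("`library_total_reads` must be positive", call. = FALSE)
  }
  if (any(depth < 0)) stop("`depth` must be >= 0", call. = FALSE)
  depth / (library_total_reads / 1e6)
}

#' Assemble per-taxon relative coverage records
#'
#' Convenience chain over [aggregate_bin_coverage()] and
#' [normalize_coverage()]: scaffold depths are pooled into bins,
#' normalized per million reads of the owning library, and keyed to
#' (taxon, sample, fraction) via the library table.
#'
#' @inheritParams aggregate_bin_coverage
#' @param libraries Tibble (library_id, sample_id, fraction_or_bin_id,
#'   total_reads).
#' @return Tibble (taxon_id, sample_id, fraction_id, rel_coverage).
#' @export
coverage_records <- function(scaffold_cov, bin_map, libraries,
                             min_scaffold_length = 1000) {
  bins <- aggregate_bin_coverage(scaffold_cov, bin_map, min_scaffold_length)
  out <- bins |>
    dplyr::inner_join(libraries, by = "library_id") |>
    dplyr::mutate(rel_coverage = normalize_coverage(.data$mean_depth, .data$total_reads)) |>
    dplyr::transmute(
      taxon_id = .data$taxon_id,
      sample_id = .data$sample_id,
      fraction_id = as.character(.data$fraction_or_bin_id),
      rel_coverage = .data$rel_coverage
    )
  if (anyDuplicated(out[c("taxon_id", "sample_id", "fraction_id")])) {
    stop("more than one library maps to the same (taxon, sample, fraction)",
      call. = FALSE
    )
  }
  out
}

#' Density bin boundaries
#'
#' @param light_max Upper density bound (g/ml, inclusive) of the light
#'   bin.
#' @param middle_max Upper density bound (g/ml, inclusive) of the middle
#'   bin; everything denser is heavy.
#' @param source `"fixed"` (user-supplied, e.g. a published range) or
#'   `"derived"` (from [derive_bin_boundaries()]).
#' @return A `bin_boundaries` list.
#' @export
bin_boundaries <- function(light_max, middle_max, source = "fixed") {
  stopifnot(
    is.finite(light_max), is.finite(middle_max),
    source %in% c("fixed", "derived")
  )
  if (light_max >= middle_max) {
    stop("`light_max` must be below `middle_max`", call. = FALSE)
  }
  structure(
    list(light_max = light_max, middle_max = middle_max, source = source),
    class = "bin_boundaries"
  )
}

#' Derive density bin boundaries from paired concentration profiles
#'
#' The heavy bin starts where the unlabeled (bulk) DNA concentration
#' profile has decayed to effectively zero: denser DNA there can only be
#' isotopically labeled. The middle bin spans from the density at which
#' the labeled and unlabeled concentration curves cross (labeled rising
#' above unlabeled as label shifts mass to heavier fractions) up to the
#' start of the heavy bin.
#'
#' @param labeled_fractions,unlabeled_fractions Validated fraction
#'   tibbles (see [validate_fractions()]) for one labeled and one
#'   unlabeled sample.
#' @param eps Concentration (ng/ul) below which the unlabeled profile is
#'   considered to have reached zero; fluorometry rarely returns exact
#'   zeros. Default 0.05.
#' @return A `bin_boundaries` object with `source = "derived"`.
#' @export
derive_bin_boundaries <- function(labeled_fractions, unlabeled_fractions,
                                  eps = 0.05) {
  lab <- dplyr::arrange(labeled_fractions, .data$density)
  unl <- dplyr::arrange(unlabeled_fractions, .data$density)
  if (nrow(lab) < 5 || nrow(unl) < 5) {
    stop("need at least 5 fractions per profile to derive boundaries", call. = FALSE)
  }

  # middle_max: lowest density at/above which the unlabeled profile stays <= eps
  below <- rev(cumprod(rev(unl$dna_conc <= eps))) == 1
  if (!any(below)) {
    stop(
      "unlabeled DNA concentration never drops to ", eps,
      " ng/ul; supply fixed boundaries instead",
      call. = FALSE
    )
  }
  middle_max <- unl$density[which(below)[1]]

  # light_max: highest crossing of the two concentration curves below middle_max
  grid <- sort(unique(c(lab$density, unl$density)))
  grid <- grid[grid >= max(min(lab$density), min(unl$density)) &
    grid <= min(max(lab$density), max(unl$density))]
  diff_curve <- approx(lab$density, lab$dna_conc, xout = grid)$y -
    approx(unl$density, unl$dna_conc, xout = grid)$y
  if (all(abs(diff_curve) < 1e-12)) {
    stop(
      "labeled and unlabeled concentration profiles are identical; no crossing",
      call. = FALSE
    )
  }
  sign_change <- which(diff_curve[-1] * diff_curve[-length(diff_curve)] < 0)
  crossings <- vapply(sign_change, function(i) {
    d <- diff_curve[c(i, i + 1)]
    grid[i] + (0 - d[1]) / (d[2] - d[1]) * (grid[i + 1] - grid[i])
  }, numeric(1))
  crossings <- c(crossings, grid[diff_curve == 0])
  crossings <- crossings[crossings < middle_max]
  if (length(crossings) == 0) {
    stop(
      "labeled and unlabeled concentration profiles do not cross below the heavy bin",
      call. = FALSE
    )
  }
  bin_boundaries(max(crossings), middle_max, source = "derived")
}

#' Assign fractions to light/middle/heavy density bins
#'
#' Upper bounds are inclusive: a fraction exactly at `light_max` is
#' light, one exactly at `middle_max` is middle.
#'
#' @param fractions Validated fraction tibble.
#' @param boundaries A [bin_boundaries()] object.
#' @return The fraction tibble with `density_bin` filled in.
#' @export
assign_density_bins <- function(fractions, boundaries) {
  stopifnot(inherits(boundaries, "bin_boundaries"))
  dplyr::mutate(fractions, density_bin = dplyr::case_when(
    .data$density <= boundaries$light_max ~ "light",
    .data$density <= boundaries$middle_max ~ "middle",
    TRUE ~ "heavy"
  ))
}

#' Combine fractions into density-bin pseudo-fractions
#'
#' Collapses each sample's light/middle/heavy bin into one
#' pseudo-fraction, mirroring the laboratory practice of pooling
#' fractions before sequencing. The pseudo-fraction density is the
#' DNA-mass-weighted mean of the member densities (the expected buoyant
#' density of the DNA actually sequenced from the bin); its
#' concentration is total member DNA mass over total member volume, so
#' DNA mass is conserved exactly.
#'
#' When per-fraction coverage records are supplied they are aggregated
#' to the bin: each taxon's per-fraction DNA mass (y times volume) is
#' summed over the bin and converted back to a within-bin relative
#' share. Coverage already keyed to bin ids (sequenced per bin) passes
#' through unchanged.
#'
#' @param fractions Fraction tibble with `density_bin` assigned.
#' @param coverage Optional coverage tibble (taxon_id, sample_id,
#'   fraction_id, rel_coverage) keyed to the same fraction ids.
#' @return A list with `fractions` (pseudo-fractions, fraction_id =
#'   bin name) and `coverage` (NULL if not supplied).
#' @export
combine_fractions <- function(fractions, coverage = NULL) {
  if (all(fractions$density_bin == "unassigned")) {
    stop("assign density bins before combining fractions", call. = FALSE)
  }
  mass <- dplyr::mutate(fractions, dna_mass = .data$dna_conc * .data$volume_ul)
  empty <- mass |>
    dplyr::group_by(.data$sample_id, .data$density_bin) |>
    dplyr::summarise(m = sum(.data$dna_mass), .groups = "drop") |>
    dplyr::filter(.data$m <= 0)
  if (nrow(empty) > 0) {
    warning(
      "dropping ", nrow(empty), " bin(s) with zero total DNA: ",
      paste(paste(empty$sample_id, empty$density_bin, sep = "/"), collapse = ", "),
      call. = FALSE
    )
    mass <- dplyr::anti_join(mass, empty,
      by = c("sample_id", "density_bin")
    )
  }
  pseudo <- mass |>
    dplyr::group_by(.data$sample_id, .data$density_bin) |>
    dplyr::summarise(
      density = sum(.data$density * .data$dna_mass) / sum(.data$dna_mass),
      dna_conc = sum(.data$dna_mass) / sum(.data$volume_ul),
      volume_ul = sum(.data$volume_ul),
      .groups = "drop"
    ) |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      fraction_id = .data$density_bin,
      density = .data$density,
      dna_conc = .data$dna_conc,
      volume_ul = .data$volume_ul,
      density_bin = .data$density_bin
    )

  comb_cov <- NULL
  if (!is.null(coverage)) {
    if (all(coverage$fraction_id %in% pseudo$fraction_id)) {
      comb_cov <- coverage # already keyed per bin
    } else {
      key <- dplyr::select(
        mass, "sample_id", "fraction_id", "density_bin",
        "volume_ul", "dna_conc"
      )
      comb_cov <- coverage |>
        dplyr::inner_join(key, by = c("sample_id", "fraction_id")) |>
        dplyr::mutate(taxon_mass = .data$rel_coverage * .data$dna_conc * .data$volume_ul) |>
        dplyr::group_by(.data$taxon_id, .data$sample_id, .data$density_bin) |>
        dplyr::summarise(taxon_mass = sum(.data$taxon_mass), .groups = "drop") |>
        dplyr::group_by(.data$sample_id, .data$density_bin) |>
        dplyr::mutate(rel_coverage = .data$taxon_mass / sum(.data$taxon_mass)) |>
        dplyr::ungroup() |>
        dplyr::transmute(
          taxon_id = .data$taxon_id,
          sample_id = .data$sample_id,
          fraction_id = .data$density_bin,
          rel_coverage = .data$rel_coverage
        )
    }
  }
  list(fractions = pseudo, coverage = comb_cov)
}
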