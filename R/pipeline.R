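#' Run the full qSIP analysis pipeline
#'
#' Orchestrates enrichment estimation, breakpoint threshold detection,
#' and growth-rate estimation over one or more timepoints, starting
#' either from a simulation (see [simulate_timepoints()]) or from tables
#' read with [read_qsip_tables()]. Enrichment is estimated separately
#' per week (each week's bulk sample is its unlabeled reference); for
#' the detection threshold the per-week APE values are pooled, re-ranked
#' and fitted once, so a single APE cutoff is applied across weeks.
#'
#' @param tables A named list with tibbles `fractions`, `coverage`,
#'   `design`, and optionally `yields` (sample_id, week, role,
#'   dna_yield) to enable growth estimation.
#' @param weeks Weeks to analyze; defaults to every week with a labeled
#'   sample.
#' @param rank_hi Breakpoint fitting window (default 90).
#' @param se_mult Threshold standard-error multiplier m (default 3).
#' @param u,a_source Growth model parameters, see [growth_config()].
#' @param outdir Directory to write `enrichment.tsv`, `threshold.tsv`,
#'   `growth.tsv`, and `summary.tsv` into; NULL (default) writes
#'   nothing.
#' @param seed Recorded in output headers (the pipeline itself draws no
#'   random numbers).
#' @param constants A [qsip_constants()] object.
#' @return A list: `enrichment` (all weeks, with `labeled` flags),
#'   `skipped`, `threshold` (psi, psi_se, slopes, davies_p,
#'   threshold_rank, ape_cutoff, window), `growth` (NULL without
#'   yields), and `summary` (flat named list).
#' @export
run_qsip_pipeline <- function(tables, weeks = NULL, rank_hi = 90, se_mult = 3,
                              u = 1, a_source = 1, outdir = NULL, seed = NA,
                              constants = qsip_constants()) {
  design <- validate_design(tables$design)
  fractions <- tables$fractions
  coverage <- tables$coverage
  if (is.null(weeks)) {
    weeks <- sort(unique(design$week[design$role == "labeled"]))
  }
  if (length(weeks) == 0) stop("no labeled weeks to analyze", call. = FALSE)

  message("estimating enrichment for week(s) ", paste(weeks, collapse = ", "))
  per_week <- lapply(weeks, function(w) {
    estimate_enrichment(design, fractions, coverage, w, constants)
  })
  enrichment <- dplyr::bind_rows(lapply(per_week, `[[`, "enrichment"))
  skipped <- dplyr::bind_rows(lapply(per_week, `[[`, "skipped"))

  # pooled ranking across weeks for a single detection threshold
  pooled <- rank_by_ape(enrichment)
  message("fitting rank-APE breakpoint on ", nrow(pooled), " taxon-week records")
  thr <- tryCatch(
    detect_labeling_threshold(pooled, rank_hi = rank_hi, m = se_mult),
    error = function(e) {
      warning("labeling threshold not determined: ", conditionMessage(e),
        call. = FALSE
      )
      NULL
    }
  )
  if (is.null(thr)) {
    enrichment <- dplyr::mutate(pooled, labeled = NA)
    threshold <- tibble::tibble(
      psi = NA_real_, psi_se = NA_real_,
      beta0 = NA_real_, beta1 = NA_real_, beta2 = NA_real_,
      davies_p = NA_real_, threshold_rank = NA_real_,
      ape_cutoff = NA_real_, m = se_mult,
      window_lo = NA_real_, window_hi = NA_real_
    )
  } else {
    enrichment <- thr$enrichment
    threshold <- tibble::tibble(
      psi = thr$fit$psi, psi_se = thr$fit$psi_se,
      beta0 = thr$fit$beta0, beta1 = thr$fit$beta1, beta2 = thr$fit$beta2,
      davies_p = thr$davies_p, threshold_rank = thr$threshold_rank,
      ape_cutoff = thr$ape_cutoff, m = se_mult,
      window_lo = thr$window[1], window_hi = thr$window[2]
    )
  }

  growth <- NULL
  if (!is.null(tables$yields)) {
    message("estimating growth rates")
    p_total <- whole_sample_abundance(fractions, coverage)
    yields <- tables$yields
    abund <- p_total |>
      dplyr::inner_join(yields, by = "sample_id") |>
      dplyr::mutate(n_total = taxon_total_abundance(.data$p_total, .data$dna_yield))
    zero_sample <- design$sample_id[design$week == 0 & design$role == "unlabeled"]
    if (length(zero_sample) == 0) {
      warning("no week-0 unlabeled sample; growth rates not estimated", call. = FALSE)
    } else {
      n0 <- abund |>
        dplyr::filter(.data$sample_id %in% zero_sample) |>
        dplyr::group_by(.data$taxon_id) |>
        dplyr::summarise(n_total = mean(.data$n_total), .groups = "drop")
      growth <- dplyr::bind_rows(lapply(weeks, function(w) {
        lab_samples <- design$sample_id[design$week == w & design$role == "labeled"]
        nt <- abund |>
          dplyr::filter(.data$sample_id %in% lab_samples) |>
          dplyr::group_by(.data$taxon_id) |>
          dplyr::summarise(n_total = mean(.data$n_total), .groups = "drop")
        cfg <- growth_config(u = u, a_source = a_source, t_days = 7 * w)
        estimate_growth(
          dplyr::filter(enrichment, .data$week == w), n0, nt, cfg
        )
      }))
    }
  }

  lab_counts <- enrichment |>
    dplyr::filter(!is.na(.data$labeled) & .data$labeled) |>
    dplyr::count(.data$taxon_class)
  summary <- c(
    list(
      n_taxa = nrow(pooled), n_skipped = nrow(skipped),
      psi = threshold$psi, psi_se = threshold$psi_se,
      davies_p = threshold$davies_p,
      threshold_rank = threshold$threshold_rank,
      ape_cutoff = threshold$ape_cutoff,
      n_labeled = sum(enrichment$labeled, na.rm = TRUE)
    ),
    if (nrow(lab_counts) > 0) {
      setNames(
        as.list(lab_counts$n),
        paste0("n_labeled_", lab_counts$taxon_class)
      )
    },
    if (!is.null(growth)) {
      gm <- growth |>
        dplyr::group_by(.data$taxon_class) |>
        dplyr::summarise(m = mean(.data$r_gross), .groups = "drop")
      setNames(as.list(gm$m), paste0("mean_r_gross_", gm$taxon_class))
    }
  )

  out <- list(
    enrichment = enrichment, skipped = skipped, threshold = threshold,
    growth = growth, summary = summary
  )
  if (!is.null(outdir)) {
    .write_outputs(out, outdir, seed)
  }
  out
}

.write_outputs <- function(out, outdir, seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf(
    "# qsipr %s | seed %s | config %s",
    as.character(utils::packageVersion("qsipr")), seed,
    rlang::hash(out$threshold)
  )
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    writeLines(stamp, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  }
  wr(out$enrichment, "enrichment.tsv")
  wr(out$threshold, "threshold.tsv")
  if (!is.null(out$growth)) wr(out$growth, "growth.tsv")
  wr(
    tibble::tibble(
      key = names(out$summary),
      value = vapply(out$summary, function(v) format(v, digits = 10), character(1))
    ),
    "summary.tsv"
  )
  invisible(out)
}
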