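test_that("simulated fraction masses conserve total DNA mass", {
  taxa <- toy_community(n = 15, ape = seq(0, 85, length.out = 15),
                        mass = seq(10, 150, length.out = 15))
  sim <- simulate_gradient(taxa, wide_gradient(seed = 1))
  for (s in unique(sim$fractions$sample_id)) {
    fr <- sim$fractions[sim$fractions$sample_id == s, ]
    expect_equal(
      sum(fr$dna_conc * fr$volume_ul), sum(taxa$mass_ng),
      tolerance = 1e-9
    )
  }
})

test_that("emitted abundances reconstruct per-fraction taxon mass up to a constant", {
  taxa <- toy_community(n = 5, ape = c(0, 20, 40, 60, 80))
  sim <- simulate_gradient(taxa, wide_gradient(seed = 2))
  lab <- dplyr::inner_join(
    sim$coverage, sim$fractions,
    by = c("sample_id", "fraction_id")
  ) |>
    dplyr::filter(startsWith(.data$sample_id, "rhizo")) |>
    dplyr::mutate(y = rel_coverage * dna_conc)
  # y summed over fractions recovers each taxon's mass share
  per_taxon <- tapply(lab$y, lab$taxon_id, sum)
  expect_equal(
    as.numeric(per_taxon[taxa$taxon_id] / sum(per_taxon)),
    taxa$mass_ng / sum(taxa$mass_ng),
    tolerance = 1e-6
  )
})

test_that("simulation is deterministic under a fixed seed", {
  taxa <- toy_community(n = 8, ape = seq(0, 70, length.out = 8))
  cfg <- wide_gradient(reads_per_library = 1e5, seed = 42)
  a <- simulate_gradient(taxa, cfg)
  b <- simulate_gradient(taxa, cfg)
  expect_identical(a$coverage, b$coverage)
  expect_identical(a$fractions, b$fractions)
})

test_that("an unenriched taxon produces identical labeled and unlabeled profiles", {
  taxa <- toy_community(n = 1, ape = 0, gc = 0.5)
  sim <- simulate_gradient(taxa, wide_gradient(seed = 4))
  lab <- sim$fractions[startsWith(sim$fractions$sample_id, "rhizo"), ]
  unl <- sim$fractions[startsWith(sim$fractions$sample_id, "bulk"), ]
  expect_equal(lab$dna_conc, unl$dna_conc, tolerance = 1e-12)
})

test_that("mass escaping the collected density range triggers a warning", {
  taxa <- toy_community(n = 1, ape = 90, gc = 0.7)
  cfg <- gradient_config(density_min = 1.692, density_max = 1.73, seed = 1)
  expect_warning(simulate_gradient(taxa, cfg), "outside the density range")
})

test_that("multinomial read noise keeps APE approximately unbiased", {
  taxa <- toy_community(n = 6, ape = seq(0, 50, length.out = 6))
  bias <- vapply(1:5, function(s) {
    sim <- simulate_gradient(taxa, wide_gradient(reads_per_library = 1e6, seed = s))
    res <- estimate_enrichment(sim$design, sim$fractions, sim$coverage, 6)
    m <- dplyr::inner_join(res$enrichment, sim$truth, by = "taxon_id")
    mean(m$ape - m$ape_true)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 1)
})

test_that("three-bin coarsening preserves the true APE rank order", {
  p <- rhizosphere_preset()
  cfg <- p$cfg
  cfg$bin_mode <- "three_bins"
  sim <- simulate_gradient(p$taxa, cfg)
  expect_setequal(unique(sim$fractions$fraction_id), c("light", "middle", "heavy"))
  res <- estimate_enrichment(sim$design, sim$fractions, sim$coverage, 6)
  m <- dplyr::inner_join(res$enrichment, sim$truth, by = "taxon_id")
  rho <- cor(m$ape, m$ape_true, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("time courses evolve abundance linearly and label only new DNA", {
  taxa <- toy_community(n = 3, ape = rep(0, 3), mass = c(50, 80, 100))
  taxa$r_true <- c(0, 0.5, 1)
  sim <- simulate_timepoints(taxa, wide_gradient(seed = 6), weeks = c(0, 6, 9))
  tr <- sim$truth
  expect_equal(
    tr$n_total_true[tr$week == 9],
    taxa$mass_ng + taxa$r_true * 63
  )
  expect_equal(tr$ape_week_true[tr$week == 0], rep(0, 3))
  # zero-rate taxon stays unlabeled at every week
  expect_equal(tr$ape_week_true[tr$taxon_id == "t001"], rep(0, 3))
  # yields equal the summed community abundance
  y9 <- sim$yields$dna_yield[sim$yields$week == 9][1]
  expect_equal(y9, sum(taxa$mass_ng + taxa$r_true * 63))

  shrink <- taxa
  shrink$r_true <- c(-10, 0, 0)
  expect_error(
    simulate_timepoints(shrink, wide_gradient(seed = 6), weeks = c(0, 6)),
    "negative abundance"
  )
})

test_that("the rhizosphere preset has the intended composition and hinge shape", {
  p <- rhizosphere_preset()
  counts <- table(p$taxa$taxon_class)
  expect_equal(unname(counts[["bacterial_bin"]]), 55)
  expect_equal(unname(counts[["phage"]]), 10)
  expect_equal(unname(counts[["eukaryote_scaffold"]]), 27)
  # ~78% of bacteria above the 2.5-APE hinge
  bact <- p$taxa[p$taxa$taxon_class == "bacterial_bin", ]
  expect_equal(mean(bact$ape_true > 2.5), 43 / 55)
  # the two most labeled taxa are phage
  top2 <- p$taxa$taxon_class[order(-p$taxa$ape_true)][1:2]
  expect_equal(top2, c("phage", "phage"))
  # flat low-rank segment then a rise
  ape_sorted <- sort(p$taxa$ape_true)
  expect_lt(max(ape_sorted[1:36]), 2.5)
  expect_gt(min(ape_sorted[37:92]), 2.5)
})
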