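make_toy_tables <- function() {
  list(
    fractions = tibble::tibble(
      sample_id = "s1", fraction_id = c("f1", "f2", "f3"),
      density_g_ml = c(1.70, 1.72, 1.74), dna_conc_ng_ul = c(10, 20, 5),
      volume_ul = 144
    ),
    coverage = tibble::tibble(
      library_id = rep(c("L1", "L2", "L3"), each = 2),
      scaffold_id = rep(c("sc1", "sc2"), 3),
      length_bp = rep(c(2000, 3000), 3),
      mean_depth = c(10, 20, 1, 2, 5, 5)
    ),
    binmap = tibble::tibble(scaffold_id = c("sc1", "sc2"), taxon_id = c("A", "B")),
    design = tibble::tibble(
      sample_id = "s1", habitat = "rhizosphere", week = 6L,
      role = "labeled", replicate = 1L
    ),
    libraries = tibble::tibble(
      library_id = c("L1", "L2", "L3"), sample_id = "s1",
      fraction_or_bin_id = c("f1", "f2", "f3"), total_reads = 2e6
    )
  )
}

test_that("well-formed tables read back with identical content", {
  tb <- make_toy_tables()
  # add the unlabeled pair so the design validates
  tb$design <- dplyr::bind_rows(tb$design, tibble::tibble(
    sample_id = "s2", habitat = "bulk", week = 6L,
    role = "unlabeled", replicate = 1L
  ))
  paths <- write_table_set(tb)
  got <- suppressMessages(read_qsip_tables(
    paths$fractions, paths$coverage, paths$binmap, paths$design, paths$libraries
  ))
  expect_equal(nrow(got$fractions), 3)
  expect_equal(got$fractions$density, c(1.70, 1.72, 1.74))
  expect_equal(got$fractions$dna_conc, c(10, 20, 5))
  expect_equal(nrow(got$coverage), 6)
  expect_s3_class(got$design, "tbl_df")
})

test_that("schema and key violations are rejected with informative errors", {
  tb <- make_toy_tables()
  tb$design <- dplyr::bind_rows(tb$design, tibble::tibble(
    sample_id = "s2", habitat = "bulk", week = 6L,
    role = "unlabeled", replicate = 1L
  ))

  bad <- tb
  bad$fractions <- dplyr::select(bad$fractions, -"density_g_ml")
  paths <- write_table_set(bad)
  expect_error(
    suppressMessages(read_qsip_tables(
      paths$fractions, paths$coverage, paths$binmap, paths$design, paths$libraries
    )),
    "density_g_ml"
  )

  bad <- tb
  bad$coverage <- dplyr::bind_rows(bad$coverage, bad$coverage[1, ])
  paths <- write_table_set(bad)
  expect_error(
    suppressMessages(read_qsip_tables(
      paths$fractions, paths$coverage, paths$binmap, paths$design, paths$libraries
    )),
    "duplicate.*L1.*sc1"
  )

  bad <- tb
  bad$fractions$dna_conc_ng_ul[1] <- -1
  paths <- write_table_set(bad)
  expect_error(
    suppressMessages(read_qsip_tables(
      paths$fractions, paths$coverage, paths$binmap, paths$design, paths$libraries
    )),
    "negative"
  )
})

test_that("bin-map scaffolds without coverage are dropped with a warning", {
  tb <- make_toy_tables()
  tb$design <- dplyr::bind_rows(tb$design, tibble::tibble(
    sample_id = "s2", habitat = "bulk", week = 6L,
    role = "unlabeled", replicate = 1L
  ))
  tb$binmap <- dplyr::bind_rows(
    tb$binmap,
    tibble::tibble(scaffold_id = "ghost", taxon_id = "C")
  )
  paths <- write_table_set(tb)
  expect_warning(
    got <- suppressMessages(read_qsip_tables(
      paths$fractions, paths$coverage, paths$binmap, paths$design, paths$libraries
    )),
    "no coverage"
  )
  expect_equal(nrow(got$binmap), 2)
})

test_that("bin coverage is the scaffold-length-weighted mean depth", {
  cov <- tibble::tibble(
    library_id = "L1", scaffold_id = c("s1", "s2"),
    length_bp = c(1000, 3000), mean_depth = c(10, 20)
  )
  bm <- tibble::tibble(scaffold_id = c("s1", "s2"), taxon_id = "bin1")
  expect_equal(aggregate_bin_coverage(cov, bm)$mean_depth, 17.5)

  # single-scaffold bin is the scaffold's own depth; zero depths give zero
  expect_equal(aggregate_bin_coverage(cov[1, ], bm[1, ])$mean_depth, 10)
  cov$mean_depth <- 0
  expect_equal(aggregate_bin_coverage(cov, bm)$mean_depth, 0)
})

test_that("bin coverage is invariant to splitting a scaffold at equal depth", {
  cov <- tibble::tibble(
    library_id = "L1", scaffold_id = c("s1", "s2"),
    length_bp = c(4000, 2000), mean_depth = c(12, 7)
  )
  bm <- tibble::tibble(scaffold_id = c("s1", "s2"), taxon_id = "bin1")
  whole <- aggregate_bin_coverage(cov, bm)$mean_depth

  split_cov <- tibble::tibble(
    library_id = "L1", scaffold_id = c("s1a", "s1b", "s2"),
    length_bp = c(2500, 1500, 2000), mean_depth = c(12, 12, 7)
  )
  split_bm <- tibble::tibble(
    scaffold_id = c("s1a", "s1b", "s2"), taxon_id = "bin1"
  )
  expect_equal(aggregate_bin_coverage(split_cov, split_bm)$mean_depth, whole)
})

test_that("short scaffolds are excluded by the length filter", {
  cov <- tibble::tibble(
    library_id = "L1", scaffold_id = c("s1", "s2"),
    length_bp = c(500, 3000), mean_depth = c(100, 20)
  )
  bm <- tibble::tibble(scaffold_id = c("s1", "s2"), taxon_id = "bin1")
  expect_equal(aggregate_bin_coverage(cov, bm)$mean_depth, 20)
  expect_equal(
    aggregate_bin_coverage(cov, bm, min_scaffold_length = 100)$mean_depth,
    (100 * 500 + 20 * 3000) / 3500
  )
})

test_that("coverage normalization is depth per million reads", {
  expect_equal(normalize_coverage(10, 2e6), 5)
  expect_equal(normalize_coverage(0, 5e6), 0)
  expect_equal(normalize_coverage(7, 1e6), 7)
  expect_error(normalize_coverage(1, 0), "positive")
})

test_that("bin boundaries derive from the zero point and the profile crossing", {
  # constructed so the bulk profile reaches 0 at exactly 1.747 and the
  # curves cross at exactly 1.738
  dens <- c(1.692, 1.700, 1.710, 1.720, 1.730, 1.738, 1.747, 1.755, 1.765)
  unl_conc <- c(5, 15, 30, 25, 10, 2, 0, 0, 0)
  lab_conc <- c(3, 10, 20, 18, 8, 2, 5, 9, 4)
  unl <- tibble::tibble(
    sample_id = "bulk", fraction_id = as.character(seq_along(dens)),
    density = dens, dna_conc = unl_conc, volume_ul = 144, density_bin = "unassigned"
  )
  lab <- dplyr::mutate(unl, sample_id = "rhizo", dna_conc = lab_conc)
  b <- derive_bin_boundaries(lab, unl)
  expect_s3_class(b, "bin_boundaries")
  expect_identical(b$source, "derived")
  expect_equal(b$middle_max, 1.747)
  expect_equal(b$light_max, 1.738)

  # an interpolated crossing between fractions is located between them
  lab2 <- lab
  lab2$dna_conc[6] <- 4 # now crosses strictly between 1.730 and 1.738
  b2 <- derive_bin_boundaries(lab2, unl)
  expect_gt(b2$light_max, 1.730)
  expect_lt(b2$light_max, 1.738)

  # identical profiles never cross; flat profiles never reach zero
  expect_error(derive_bin_boundaries(unl, unl), "identical")
  flat <- dplyr::mutate(unl, dna_conc = 5)
  expect_error(derive_bin_boundaries(flat, flat), "never drops")
})

test_that("density bins partition the fractions with inclusive upper bounds", {
  b <- bin_boundaries(1.737, 1.746)
  fr <- tibble::tibble(
    sample_id = "s", fraction_id = as.character(1:5),
    density = c(1.70, 1.737, 1.740, 1.746, 1.75),
    dna_conc = 1, volume_ul = 144, density_bin = "unassigned"
  )
  got <- assign_density_bins(fr, b)
  expect_equal(got$density_bin, c("light", "light", "middle", "middle", "heavy"))
  expect_true(all(got$density_bin %in% c("light", "middle", "heavy")))
})

test_that("combining fractions pools DNA mass-weighted and conserves mass", {
  fr <- tibble::tibble(
    sample_id = "s", fraction_id = c("f1", "f2"),
    density = c(1.740, 1.744), dna_conc = c(10, 30),
    volume_ul = 144, density_bin = "middle"
  )
  got <- combine_fractions(fr)
  expect_equal(got$fractions$density, (1.740 * 10 + 1.744 * 30) / 40)
  # total DNA mass conserved to machine precision
  expect_equal(
    got$fractions$dna_conc * got$fractions$volume_ul,
    sum(fr$dna_conc * fr$volume_ul),
    tolerance = 1e-12
  )

  # one fraction per bin passes through unchanged
  single <- fr[1, ]
  got1 <- combine_fractions(single)
  expect_equal(got1$fractions$density, 1.740)
  expect_equal(got1$fractions$dna_conc, 10)

  # an all-zero bin is dropped with a warning
  fr$dna_conc <- 0
  expect_warning(got0 <- combine_fractions(fr), "zero total DNA")
  expect_equal(nrow(got0$fractions), 0)
})
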