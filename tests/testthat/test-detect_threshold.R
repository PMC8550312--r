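test_that("a noiseless hinge is recovered exactly", {
  x <- 1:90
  y <- hinge_response(x, psi = 70, slope = 0.5)
  fit <- fit_segmented(x, y)
  expect_true(fit$converged)
  expect_false(fit$no_breakpoint)
  expect_equal(fit$psi, 70, tolerance = 1e-6)
  expect_equal(fit$beta2, 0.5, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
  # matches the exhaustive grid-search oracle
  oracle <- grid_search_breakpoint(x, y)
  expect_equal(fit$psi, oracle$psi, tolerance = 0.01)
})

test_that("an exactly linear response raises the no-breakpoint flag", {
  x <- 1:60
  fit <- fit_segmented(x, 2 * x)
  expect_true(fit$no_breakpoint)
  expect_error(
    ape_cutoff(tibble::tibble(taxon_id = "a", ape = 1, rank = 1), fit),
    "no breakpoint"
  )
})

test_that("converged fits match the grid-search oracle RSS on random hinges", {
  set.seed(2024)
  for (i in 1:8) {
    psi_true <- runif(1, 25, 65)
    slope <- runif(1, 0.2, 1.5)
    x <- 1:90
    y <- hinge_response(x, psi_true, slope) + rnorm(90, sd = runif(1, 0.5, 3))
    fit <- fit_segmented(x, y)
    expect_true(fit$converged)
    oracle <- grid_search_breakpoint(x, y)
    expect_lte(fit$rss, oracle$rss * (1 + 1e-6))
  }
})

test_that("breakpoint estimates are equivariant under shift and scale of y", {
  set.seed(7)
  x <- 1:90
  y <- hinge_response(x, 55, 0.8) + rnorm(90, sd = 1)
  base <- fit_segmented(x, y)
  shifted <- fit_segmented(x, y + 100)
  expect_equal(shifted$psi, base$psi, tolerance = 1e-6)
  expect_equal(shifted$beta0, base$beta0 + 100, tolerance = 1e-6)
  expect_equal(shifted$beta1, base$beta1, tolerance = 1e-8)

  scaled <- fit_segmented(x, 10 * y)
  expect_equal(scaled$psi, base$psi, tolerance = 1e-6)
  expect_equal(scaled$beta2, 10 * base$beta2, tolerance = 1e-6)
  # the Davies decision is scale-free
  expect_equal(davies_test(x, y), davies_test(x, 10 * y), tolerance = 1e-10)
})

test_that("Davies test rejects a clear hinge and agrees with a permutation null", {
  set.seed(31)
  x <- 1:60
  y <- hinge_response(x, 40, 0.5) + rnorm(60, sd = 1e-6)
  p_davies <- davies_test(x, y)
  expect_lt(p_davies, 0.001)

  stat_fn <- max_wald_stat_fn(x)
  observed <- stat_fn(y)
  perm <- replicate(1000, stat_fn(sample(y)))
  p_perm <- (1 + sum(perm >= observed)) / 1001
  expect_lt(p_perm, 0.005) # resolution floor of 1000 shuffles
})

test_that("Davies p-values are proper and degenerate input gives p = 1", {
  set.seed(5)
  x <- 1:40
  for (i in 1:20) {
    p <- davies_test(x, rnorm(40))
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  expect_equal(davies_test(x, rep(3, 40)), 1)
})

test_that("the +m*SE rule and APE interpolation follow the stated arithmetic", {
  # printed breakpoint arithmetic: 71.1 + 3 * 0.6 = 72.9
  fit <- structure(
    list(
      psi = 71.1, psi_se = 0.6, beta0 = 0, beta1 = 0, beta2 = 0.1,
      rss = 0, window = c(1, 90), converged = TRUE, no_breakpoint = FALSE,
      boundary_warning = FALSE, n = 90
    ),
    class = "breakpoint_fit"
  )
  apes <- c(seq(0, 2.3, length.out = 72), 2.522, seq(2.6, 40, length.out = 20))
  enr <- tibble::tibble(
    taxon_id = sprintf("t%03d", seq_along(apes)),
    ape = apes, rank = seq_along(apes)
  )
  out <- ape_cutoff(enr, fit, m = 3)
  expect_equal(out$threshold_rank, 72.9)
  # linear interpolation between APE(72) = 2.3 and APE(73) = 2.522
  expect_equal(out$ape_cutoff, 2.3 + 0.9 * (2.522 - 2.3), tolerance = 1e-12)
  expect_equal(out$ape_cutoff, 2.5, tolerance = 1e-3)
  expect_equal(sum(out$enrichment$labeled), sum(apes > out$ape_cutoff))

  # m = 0 thresholds at the breakpoint itself
  expect_equal(ape_cutoff(enr, fit, m = 0)$threshold_rank, 71.1)

  # threshold is nondecreasing in m, cutoff nondecreasing in threshold
  ms <- c(0, 1, 2, 3, 5)
  res <- lapply(ms, function(m) ape_cutoff(enr, fit, m))
  tr <- vapply(res, `[[`, numeric(1), "threshold_rank")
  co <- vapply(res, `[[`, numeric(1), "ape_cutoff")
  expect_true(all(diff(tr) >= 0))
  expect_true(all(diff(co) >= 0))
})

test_that("a threshold beyond the largest rank labels nothing, with a warning", {
  fit <- structure(
    list(
      psi = 9, psi_se = 2, beta0 = 0, beta1 = 0, beta2 = 0.1,
      rss = 0, window = c(1, 10), converged = TRUE, no_breakpoint = FALSE,
      boundary_warning = FALSE, n = 10
    ),
    class = "breakpoint_fit"
  )
  enr <- tibble::tibble(taxon_id = letters[1:10], ape = 1:10, rank = 1:10)
  expect_warning(out <- ape_cutoff(enr, fit), "beyond")
  expect_false(any(out$enrichment$labeled))
})

test_that("the fitting window keeps the lowest ranks and warns when short", {
  enr <- tibble::tibble(
    taxon_id = sprintf("t%03d", 1:120), ape = sort(rnorm(120)), rank = 1:120
  )
  w <- restrict_window(enr, 90)
  expect_length(w$x, 90)
  expect_equal(w$x, as.numeric(1:90))

  short <- enr[1:60, ]
  expect_warning(w2 <- restrict_window(short, 90), "reduced")
  expect_length(w2$x, 60)
  expect_error(restrict_window(enr, 0), ">= 1")
})
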