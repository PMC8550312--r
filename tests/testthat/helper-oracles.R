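# Independent oracles used to check the package's estimators.

# Exhaustive RSS grid search for the single-breakpoint model, at the
# given resolution. Deliberately independent of fit_segmented: plain
# least squares at every candidate breakpoint.
grid_search_breakpoint <- function(x, y, resolution = 0.01, margin = 1) {
  grid <- seq(min(x) + margin, max(x) - margin, by = resolution)
  rss <- vapply(grid, function(p) {
    X <- cbind(1, x, pmax(x - p, 0))
    fit <- .lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  best <- which.min(rss)
  list(psi = grid[best], rss = rss[best])
}

# Max Wald statistic over candidate breakpoints, as a closure so a
# permutation null can re-evaluate it cheaply on shuffled responses.
max_wald_stat_fn <- function(x, k = 10, interior_margin = 2) {
  xs <- sort(x)
  cand <- seq(xs[1 + interior_margin], xs[length(xs) - interior_margin],
    length.out = k
  )
  pre <- lapply(cand, function(p) {
    X <- cbind(1, x, pmax(x - p, 0))
    xtxinv <- solve(crossprod(X))
    list(X = X, xtxinv = xtxinv, proj = xtxinv %*% t(X))
  })
  n <- length(x)
  function(y) {
    max(vapply(pre, function(pc) {
      beta <- pc$proj %*% y
      res <- y - pc$X %*% beta
      sigma2 <- sum(res^2) / (n - 3)
      abs(beta[3] / sqrt(sigma2 * pc$xtxinv[3, 3]))
    }, numeric(1)))
  }
}

# Noiseless hinge response: flat at 0 up to the breakpoint, then rising.
hinge_response <- function(x, psi = 70, slope = 0.5) {
  pmax(x - psi, 0) * slope
}

# Small community spanning the GC and enrichment ranges of interest,
# with a gradient wide enough to hold every band.
toy_community <- function(n = 10, ape = seq(0, 90, length.out = n),
                          gc = seq(0.30, 0.75, length.out = n),
                          mass = rep(50, n)) {
  synthetic_taxa(
    taxon_id = sprintf("t%03d", seq_len(n)),
    taxon_class = rep("bacterial_bin", n),
    g_true = gc, ape_true = ape, mass_ng = mass
  )
}

wide_gradient <- function(...) {
  gradient_config(density_min = 1.64, density_max = 1.80, ...)
}

# Write a table set to temp TSVs and return the paths.
write_table_set <- function(tables, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list()
  for (nm in names(tables)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tables[[nm]], paths[[nm]])
  }
  paths
}
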