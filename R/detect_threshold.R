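#' Restrict the rank-APE curve to the low-enrichment window
#'
#' The breakpoint is fitted on the lowest-APE ranks only (default ranks
#' 1-90). Above the window the rank-APE relationship flattens again, and
#' including those highly enriched taxa pulls the fitted breakpoint
#' toward zero APE, inflating the set called labeled; restricting to the
#' region around the visually obvious slope change gives a more
#' conservative detection threshold.
#'
#' @param enrichment Ranked enrichment tibble (see [rank_by_ape()]).
#' @param rank_hi Highest rank included (default 90). Adjusted down with
#'   a warning when fewer taxa are available.
#' @return A list with numeric vectors `x` (ranks) and `y` (APE).
#' @export
restrict_window <- function(enrichment, rank_hi = 90) {
  if (rank_hi < 1) stop("`rank_hi` must be >= 1", call. = FALSE)
  n <- nrow(enrichment)
  if (n < rank_hi) {
    warning(
      "only ", n, " taxa available; fitting window reduced from ",
      rank_hi, " to ", n,
      call. = FALSE
    )
    rank_hi <- n
  }
  keep <- enrichment$rank <= rank_hi
  list(x = as.numeric(enrichment$rank[keep]), y = enrichment$ape[keep])
}

.hinge <- function(x, psi) pmax(x - psi, 0)

#' Fit a single-breakpoint segmented regression
#'
#' Fits `y = b0 + b1*x + b2*(x - psi)+` by iterative linearization: at
#' the current breakpoint estimate the hinge is locally expanded with
#' the working covariate `V = -1(x > psi)`, the linear model is refitted,
#' and the breakpoint is updated by `psi <- psi + gamma/b2` where
#' `gamma` is the coefficient of `V`. At convergence `gamma` vanishes
#' and its standard error, scaled by the slope change, gives the
#' standard error of the breakpoint. If the iteration diverges, an
#' exhaustive residual-sum-of-squares grid search over candidate
#' breakpoints (0.1-rank resolution) restarts it from the global
#' minimum; if multiple candidates tie, the smallest breakpoint (the
#' most conservative threshold) is used.
#'
#' @param x Strictly increasing predictor (ranks).
#' @param y Response (APE values).
#' @param psi0 Starting breakpoint; defaults to the median of `x`.
#' @param max_iter,tol Iteration cap and convergence tolerance on
#'   `gamma`.
#' @return An object of class `breakpoint_fit`: list with `psi`,
#'   `psi_se`, `beta0`, `beta1` (left slope), `beta2` (slope change),
#'   `rss`, `window` (range of `x`), `converged`, `no_breakpoint`
#'   (TRUE when the slope change is indistinguishable from zero) and
#'   `boundary_warning` (TRUE when fewer than 3 points fall on either
#'   side of the estimate).
#' @export
fit_segmented <- function(x, y, psi0 = NULL, max_iter = 50, tol = 1e-8) {
  stopifnot(length(x) == length(y))
  if (length(x) < 8) stop("need at least 8 points to fit a breakpoint", call. = FALSE)
  if (any(diff(x) <= 0)) stop("`x` must be strictly increasing", call. = FALSE)

  lo <- min(x)
  hi <- max(x)
  # keep psi strictly interior so both segments retain support
  clamp <- function(psi) min(max(psi, lo + 1e-6), hi - 1e-6)
  if (is.null(psi0)) psi0 <- median(x)
  psi <- clamp(psi0)

  one_step <- function(psi) {
    u <- .hinge(x, psi)
    v <- -as.numeric(x > psi)
    fit <- lm(y ~ x + u + v)
    cf <- coef(fit)
    cf[is.na(cf)] <- 0
    list(
      fit = fit, beta0 = cf[["(Intercept)"]], beta1 = cf[["x"]],
      beta2 = cf[["u"]], gamma = cf[["v"]],
      # suppressWarnings: a perfect (zero-residual) fit is legitimate here
      se_gamma = tryCatch(suppressWarnings(sqrt(vcov(fit)["v", "v"])),
        error = function(e) NA_real_
      ),
      rss = sum(fit$residuals^2)
    )
  }

  iterate <- function(psi) {
    st <- NULL
    for (it in seq_len(max_iter)) {
      st <- one_step(psi)
      if (abs(st$beta2) < 1e-10) {
        return(list(psi = psi, st = st, converged = TRUE))
      }
      if (abs(st$gamma) < tol) {
        return(list(psi = psi, st = st, converged = TRUE))
      }
      step <- st$gamma / st$beta2
      if (!is.finite(step)) {
        return(list(psi = psi, st = st, converged = FALSE))
      }
      psi <- clamp(psi + step)
    }
    list(psi = psi, st = st, converged = FALSE)
  }

  method <- "iterative"
  res <- iterate(psi)

  # the iteration can stall in a local RSS minimum (the profile RSS over
  # psi is piecewise smooth with kinks at the data points); verify
  # against a grid scan and restart from the global basin if needed.
  # smallest psi on ties = most conservative detection threshold.
  grid <- seq(lo + 1, hi - 1, by = 0.1)
  grid_rss <- vapply(grid, function(p) {
    sum(.lm.fit(cbind(1, x, .hinge(x, p)), y)$residuals^2)
  }, numeric(1))
  psi_grid <- min(grid[grid_rss <= min(grid_rss) + 1e-12])
  if (!res$converged || res$st$rss > min(grid_rss) * (1 + 1e-9) + 1e-12) {
    polished <- iterate(psi_grid)
    if (polished$converged && polished$st$rss <= min(grid_rss) + 1e-12) {
      res <- polished
      method <- "grid+iterative"
    } else {
      # iteration cannot settle (kinked RSS profile): refine the grid
      # locally instead
      fine <- seq(max(lo + 1, psi_grid - 0.1), min(hi - 1, psi_grid + 0.1),
        by = 0.001
      )
      fine_rss <- vapply(fine, function(p) {
        sum(.lm.fit(cbind(1, x, .hinge(x, p)), y)$residuals^2)
      }, numeric(1))
      psi_fine <- min(fine[fine_rss <= min(fine_rss) + 1e-12])
      res <- list(psi = psi_fine, st = one_step(psi_fine), converged = TRUE)
      method <- "grid"
    }
  }
  psi <- res$psi
  st <- res$st

  no_breakpoint <- abs(st$beta2) < 1e-10
  psi_se <- if (no_breakpoint) NA_real_ else st$se_gamma / abs(st$beta2)
  structure(
    list(
      psi = psi, psi_se = psi_se,
      beta0 = st$beta0, beta1 = st$beta1, beta2 = st$beta2,
      rss = st$rss, window = c(lo, hi), method = method,
      converged = res$converged || no_breakpoint,
      no_breakpoint = no_breakpoint,
      boundary_warning = sum(x <= psi) < 3 || sum(x > psi) < 3,
      n = length(x)
    ),
    class = "breakpoint_fit"
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat("Segmented (single-breakpoint) fit\n")
  if (x$no_breakpoint) {
    cat("  no detectable slope change (beta2 ~ 0)\n")
  } else {
    cat(sprintf("  breakpoint psi = %.3f (SE %.3f)\n", x$psi, x$psi_se))
    cat(sprintf(
      "  left slope %.4f, slope change %.4f, RSS %.4g, n = %d\n",
      x$beta1, x$beta2, x$rss, x$n
    ))
  }
  invisible(x)
}

#' Davies test for the existence of a slope change
#'
#' Tests the null of a straight line against a broken-line alternative
#' when the breakpoint is not identified under the null. The Wald
#' statistic for the slope-change coefficient is evaluated at `k`
#' equally spaced interior candidate breakpoints and the p-value is the
#' Davies (1987) upper bound for the maximum of the correlated
#' statistics: `p = Phi(-M) + V * exp(-M^2/2) / sqrt(8*pi)`, where `M`
#' is the largest statistic and `V` the total variation of the statistic
#' sequence. The bound makes the test conservative. The default
#' alternative is a positive slope change (APE rising with rank);
#' `"two.sided"` doubles the bound on the absolute statistics.
#'
#' @inheritParams fit_segmented
#' @param k Number of candidate breakpoints (default 10, minimum 5).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param interior_margin Candidates are placed between the
#'   `interior_margin`-th smallest and largest x (default 2) so each
#'   candidate leaves support on both sides.
#' @return p-value in `[0, 1]`.
#' @export
davies_test <- function(x, y, k = 10, alternative = c("greater", "two.sided"),
                        interior_margin = 2) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), length(x) >= 8)
  if (k < 5) stop("`k` must be >= 5", call. = FALSE)
  if (sd(y) == 0) {
    return(1)
  }
  xs <- sort(x)
  lo <- xs[1 + interior_margin]
  hi <- xs[length(xs) - interior_margin]
  cand <- seq(lo, hi, length.out = k)
  stat <- vapply(cand, function(p) {
    f <- lm(y ~ x + .hinge(x, p))
    cf <- suppressWarnings(summary(f))$coefficients
    if (nrow(cf) < 3 || !is.finite(cf[3, 3])) 0 else cf[3, 3]
  }, numeric(1))
  if (alternative == "two.sided") stat <- abs(stat)
  m <- max(stat)
  v <- sum(abs(diff(stat)))
  p <- pnorm(-m) + v * exp(-m^2 / 2) / sqrt(8 * pi)
  if (alternative == "two.sided") p <- 2 * p
  min(max(p, 0), 1)
}

#' Convert a breakpoint fit into an APE labeling cutoff
#'
#' The detection threshold is the breakpoint plus `m` standard errors
#' (with the default `m = 3`, the upper 99.7% confidence limit of the
#' breakpoint estimate). The APE value at that - generally fractional -
#' rank is read off the sorted APE sequence by linear interpolation, and
#' every taxon strictly above the cutoff is flagged as detectably
#' labeled.
#'
#' @param enrichment Ranked enrichment tibble covering ranks 1..n.
#' @param fit A converged [fit_segmented()] result.
#' @param m Standard-error multiplier (default 3).
#' @return A list with `threshold_rank`, `ape_cutoff`, `m`, the input
#'   `fit`, and `enrichment` with a logical `labeled` column added.
#' @export
ape_cutoff <- function(enrichment, fit, m = 3) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  if (fit$no_breakpoint) {
    stop("no breakpoint was detected; an APE cutoff is undefined", call. = FALSE)
  }
  if (!fit$converged) stop("breakpoint fit did not converge", call. = FALSE)
  threshold_rank <- fit$psi + m * fit$psi_se
  enr <- dplyr::arrange(enrichment, .data$rank)
  if (threshold_rank > max(enr$rank)) {
    warning("threshold rank ", round(threshold_rank, 1),
      " beyond the largest rank; no taxon called labeled",
      call. = FALSE
    )
    cutoff <- Inf
  } else {
    cutoff <- approx(enr$rank, enr$ape, xout = threshold_rank, rule = 2)$y
  }
  enr$labeled <- enr$ape > cutoff
  list(
    threshold_rank = threshold_rank,
    ape_cutoff = cutoff,
    m = m,
    fit = fit,
    enrichment = enr
  )
}

#' Rank-APE breakpoint detection threshold, end to end
#'
#' Convenience wrapper: restricts the ranked enrichment table to the
#' low-APE window, fits the segmented regression, runs the Davies test,
#' and applies the +m*SE threshold rule.
#'
#' @inheritParams restrict_window
#' @inheritParams ape_cutoff
#' @param k Candidate count for [davies_test()].
#' @return A list as from [ape_cutoff()] plus `davies_p` and `window`.
#' @export
detect_labeling_threshold <- function(enrichment, rank_hi = 90, m = 3, k = 10) {
  w <- restrict_window(enrichment, rank_hi)
  fit <- fit_segmented(w$x, w$y)
  p <- davies_test(w$x, w$y, k = k)
  out <- ape_cutoff(enrichment, fit, m = m)
  out$davies_p <- p
  out$window <- range(w$x)
  out
}
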