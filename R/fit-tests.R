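#' Tests of fit of the Leunbach model
#'
#' Runs the three tests of fit of the model to the two-way score table:
#' (1) a conditional likelihood ratio test comparing observed counts to the
#' expected counts given each total score, (2) a comparison of the observed
#' Goodman-Kruskal gamma correlation of the two scores with its expected
#' value under the full fitted model (score parameters plus a latent
#' mixing distribution estimated from the total scores), and (3) a count of
#' persons whose two scores differ
#' significantly at the 5% level under the fitted conditional distribution.
#' The score tables are typically large and sparse, so p-values for (1) and
#' (2) are obtained by parametric bootstrap: tables are simulated from the
#' full fitted model (see [parametric_bootstrap_tables()]), each replicate
#' is refitted, and the statistics are recomputed. (3) uses an asymptotic
#' chi-square comparison of the flagged proportion with the nominal 5%.
#'
#' Following the reporting convention for these tests, only p-values at or
#' below 0.01 are strong evidence against fit on their own; p-values in
#' (0.01, 0.05] are moderate evidence, regarded as conclusive only when more
#' than one of the three tests is significant.
#'
#' @param fit A converged [fit_leunbach()] object.
#' @param n_boot Number of parametric bootstrap replicates (default 1000).
#' @param seed Optional integer seed making the bootstrap reproducible.
#' @param level Critical level for the person-wise test (default 0.05).
#' @param boot_tol Convergence tolerance for the bootstrap refits. The
#'   default (1e-7 on the conditional split probabilities) perturbs the
#'   bootstrap statistics by far less than their sampling noise while
#'   keeping the refits fast.
#' @param misfit_method Construction of the person-wise two-sided exact
#'   test: `"mid_p"` (default) sums the conditional probabilities of splits
#'   strictly less probable than the observed one plus half the probability
#'   of equally probable splits; `"prob_ordering"` sums all splits no more
#'   probable than the observed one (more conservative on small supports).
#' @return An object of class `leunbach_fit_report`; see [tidy()] and
#'   [glance()] methods.
#' @export
fit_tests <- function(fit, n_boot = 1000, seed = NULL, level = 0.05,
                      misfit_method = c("mid_p", "prob_ordering"),
                      boot_tol = 1e-7) {
  misfit_method <- match.arg(misfit_method)
  stopifnot(inherits(fit, "leunbach_fit"))
  if (!fit$converged) {
    warn("Fit tests on a non-converged fit are unreliable.")
  }
  counts <- unclass(fit$table)
  attributes(counts) <- attributes(counts)["dim"]
  g1 <- fit$params_a$gamma
  g2 <- fit$params_b$gamma
  nr <- total_score_counts(counts)

  g2_obs <- conditional_lrt(fit)
  gam_obs <- goodman_kruskal_gamma(counts)
  mix <- latent_mixture(g1, g2, nr)
  gam_exp <- goodman_kruskal_gamma(model_expected_table(g1, g2, nr, mix),
                                   warn_ties = FALSE)
  gam_diff <- gam_obs - gam_exp

  boot_fun <- function() {
    tabs <- parametric_bootstrap_tables(fit, n_tables = n_boot)
    stats <- vapply(tabs, function(tb) {
      eng <- ipf_engine(tb, tol = boot_tol, max_iter = 10000,
                        g1 = g1, g2 = g2)
      nr_b <- total_score_counts(tb)
      e <- gamma_expected_counts(eng$g1, eng$g2, nr_b)
      gam_b <- goodman_kruskal_gamma(tb, warn_ties = FALSE)
      mix_b <- latent_mixture(eng$g1, eng$g2, nr_b, grid = mix$grid)
      gam_e <- goodman_kruskal_gamma(
        model_expected_table(eng$g1, eng$g2, nr_b, mix_b), warn_ties = FALSE)
      c(g2 = g2_statistic(tb, e), gamma = gam_b, gamma_diff = gam_b - gam_e)
    }, numeric(3))
    tibble(g2 = stats["g2", ], gamma = stats["gamma", ],
           gamma_diff = stats["gamma_diff", ])
  }
  boot <- if (is.null(seed)) boot_fun() else withr::with_seed(seed, boot_fun())

  lrt_p <- bootstrap_p(g2_obs, boot$g2, direction = "upper")
  gamma_p <- bootstrap_p(gam_diff, boot$gamma_diff[!is.na(boot$gamma_diff)],
                         direction = "two_sided")
  mis <- person_misfit_test(fit, level = level, method = misfit_method)

  structure(
    list(
      lrt_statistic = g2_obs, lrt_p = lrt_p,
      gamma_observed = gam_obs, gamma_expected = gam_exp, gamma_p = gamma_p,
      misfit_count = mis$count, misfit_proportion = mis$proportion,
      misfit_ci = mis$ci, misfit_p = mis$p_value,
      n = fit$n, n_bootstrap = n_boot, seed = seed, level = level,
      misfit_method = misfit_method,
      verdict = fit_verdict(c(lrt_p, gamma_p, mis$p_value)),
      boot_stats = boot
    ),
    class = "leunbach_fit_report"
  )
}

fit_verdict <- function(ps) {
  ps <- ps[!is.na(ps)]
  if (any(ps <= 0.01) || sum(ps <= 0.05) > 1) return("strong_evidence_against")
  if (sum(ps > 0.01 & ps <= 0.05) == 1) return("moderate_evidence")
  "fit"
}

#' Conditional likelihood ratio statistic
#'
#' `G2 = 2 * sum(obs * log(obs / exp))` over observed cells, where the
#' expected count of a split `(x, r - x)` is the observed count of total
#' score `r` times the fitted conditional split probability.
#'
#' @inheritParams conditional_loglik
#' @return The non-negative statistic.
#' @export
conditional_lrt <- function(fit, data = NULL) {
  counts <- unclass(if (is.null(data)) fit$table else as_score_table(data))
  g2_statistic(counts, expected_counts(fit, counts = counts))
}

g2_statistic <- function(counts, expected) {
  obs <- counts > 0
  2 * sum(counts[obs] * log(counts[obs] / expected[obs]))
}

#' Goodman-Kruskal gamma of a two-way table
#'
#' Ordinal association `(C - D) / (C + D)` over concordant and discordant
#' pairs. Defined for any non-negative cell weights, so it applies to both
#' observed and model-expected tables.
#'
#' @param counts A [score_table()] or counts matrix (weights allowed).
#' @param warn_ties Warn (and return `NA`) when every pair is tied.
#' @return A number in `[-1, 1]`, or `NA` if all pairs are tied.
#' @export
goodman_kruskal_gamma <- function(counts, warn_ties = TRUE) {
  N <- as.matrix(unclass(counts))
  nr <- nrow(N)
  nc <- ncol(N)
  if (sum(N) < 2) abort("Gamma needs at least two observations.")
  if (nr < 2 || nc < 2) {
    if (warn_ties) warn("All pairs tied: gamma undefined.")
    return(NA_real_)
  }
  # suffix/prefix sums via triangular ones-matrices (fast dense matmuls):
  # br[i,j] = sum over i' >= i, j' >= j; bl[i,j] = sum over i' >= i, j' <= j
  ur <- upper.tri(diag(nr), diag = TRUE) * 1
  lc <- lower.tri(diag(nc), diag = TRUE) * 1
  rowsuf <- ur %*% N
  br <- rowsuf %*% lc
  bl <- rowsuf %*% t(lc)
  C <- sum(N[-nr, -nc] * br[-1, -1])
  D <- sum(N[-nr, -1] * bl[-1, -nc])
  if (C + D == 0) {
    if (warn_ties) warn("All pairs tied: gamma undefined.")
    return(NA_real_)
  }
  (C - D) / (C + D)
}

# Latent estimates for several target scores at once (vectorised Newton with
# per-target bisection brackets); targets must be interior to the support.
newton_thetas <- function(lg, targets, tol = 1e-8, max_iter = 100) {
  xs <- seq_along(lg) - 1
  lo <- rep(-745, length(targets))
  hi <- rep(745, length(targets))
  theta <- rep(0, length(targets))
  for (i in seq_len(max_iter)) {
    lw <- outer(xs, theta) + lg
    lw <- sweep(lw, 2, apply(lw, 2, max))
    w <- exp(lw)
    p <- sweep(w, 2, colSums(w), "/")
    mu <- colSums(xs * p)
    err <- mu - targets
    if (all(abs(err) <= tol)) break
    v <- colSums(xs^2 * p) - mu^2
    hi <- ifelse(err > 0, pmin(hi, theta), hi)
    lo <- ifelse(err < 0, pmax(lo, theta), lo)
    cand <- theta - err / pmax(v, 1e-12)
    mid <- 0.5 * (lo + hi)
    theta <- ifelse(cand > lo & cand < hi, cand, mid)
  }
  theta
}

# Discrete latent mixing distribution reproducing the observed total-score
# counts: a fixed theta grid spanning the raw-score latent estimates, with
# weights estimated by EM against n_r (a nonparametric marginal-likelihood
# route). Used only where a person distribution is unavoidable:
# the model-expected joint table (the gamma test's reference) and the
# model-based parametric bootstrap generator. Conditional estimation and
# equating never touch it.
latent_mixture <- function(g1, g2, nr, grid_size = 61, em_iter = 200,
                           grid = NULL) {
  lom <- log(convolve_gamma(g1, g2))
  robs <- which(nr > 0) - 1L
  if (is.null(grid)) {
    sup <- range(which(is.finite(lom)) - 1L)
    interior <- robs[robs > sup[1] & robs < sup[2]]
    if (length(interior) == 0) {
      interior <- sup[1] + (sup[2] - sup[1]) / 2
    }
    th <- newton_thetas(lom, interior)
    grid <- seq(min(th) - 1.5, max(th) + 1.5, length.out = grid_size)
  }
  pom <- vapply(grid, function(t) pmf_engine(lom, t), numeric(length(lom)))
  a_obs <- pom[robs + 1L, , drop = FALSE]
  nr_obs <- nr[robs + 1L]
  n <- sum(nr_obs)
  w <- rep(1 / grid_size, grid_size)
  for (i in seq_len(em_iter)) {
    lik <- as.vector(a_obs %*% w) + 1e-300
    w <- w * as.vector(crossprod(a_obs, nr_obs / lik)) / n
  }
  list(grid = grid, weights = w)
}

# Expected joint score table under the full fitted model: the latent values
# follow the mixture estimated from the total scores, and the two scores
# are drawn independently given the latent value. Unlike the conditional
# expectation given r, this table carries the between-scale association a
# shared trait implies, so its gamma is the model-expected correlation.
model_expected_table <- function(g1, g2, nr, mix = NULL) {
  mix <- mix %||% latent_mixture(g1, g2, nr)
  p1 <- vapply(mix$grid, function(t) pmf_engine(log(g1), t),
               numeric(length(g1)))
  p2 <- vapply(mix$grid, function(t) pmf_engine(log(g2), t),
               numeric(length(g2)))
  sum(nr) * (p1 %*% (mix$weights * t(p2)))
}

#' Parametric bootstrap score tables
#'
#' Simulates tables from the fitted model. With `type = "model"` (the
#' default used by [fit_tests()]) each observed person sits at the latent
#' estimate of their total score and both scale scores are drawn
#' independently given it -- the full fitted model, which carries the
#' between-scale association a shared trait implies. With
#' `type = "conditional"` the observed count of each total score is kept
#' fixed and only the splits are drawn from the fitted conditional split
#' distribution (purely conditional inference; such tables cannot contradict
#' the fitted association structure, so they serve the likelihood ratio
#' statistic but carry no information about the correlation of the scores).
#'
#' @inheritParams fit_tests
#' @param n_tables Number of tables to generate.
#' @param type `"model"` or `"conditional"` (see above).
#' @return A list of `n_tables` count matrices; for `"conditional"`, each
#'   has exactly the total-score margins of the fitted table.
#' @export
parametric_bootstrap_tables <- function(fit, n_tables, seed = NULL,
                                        type = c("model", "conditional")) {
  type <- match.arg(type)
  run <- function() {
    counts <- unclass(fit$table)
    m1 <- nrow(counts) - 1L
    m2 <- ncol(counts) - 1L
    nr <- total_score_counts(counts)
    g1 <- fit$params_a$gamma
    g2 <- fit$params_b$gamma
    if (n_tables == 0) return(list())
    if (type == "model") {
      mix <- latent_mixture(g1, g2, nr)
      p1 <- vapply(mix$grid, function(t) pmf_engine(log(g1), t),
                   numeric(m1 + 1L))
      p2 <- vapply(mix$grid, function(t) pmf_engine(log(g2), t),
                   numeric(m2 + 1L))
      n <- sum(counts)
      return(lapply(seq_len(n_tables), function(s) {
        ng <- as.vector(rmultinom(1, n, mix$weights))
        acc <- numeric((m1 + 1L) * (m2 + 1L))
        for (gidx in which(ng > 0)) {
          acc <- acc + rmultinom(1, ng[gidx],
                                 as.vector(outer(p1[, gidx], p2[, gidx])))
        }
        matrix(acc, m1 + 1L, m2 + 1L)
      }))
    }
    cell_idx <- integer(0)
    draw_list <- list()
    for (r in which(nr > 0) - 1L) {
      xs <- max(0, r - m2):min(r, m1)
      p <- g1[xs + 1L] * g2[r - xs + 1L]
      keep <- p > 0
      xs <- xs[keep]
      p <- p[keep] / sum(p[keep])
      cell_idx <- c(cell_idx, xs + 1L + (r - xs) * (m1 + 1L))
      draw_list[[length(draw_list) + 1L]] <-
        if (length(p) == 1) matrix(nr[r + 1L], 1, n_tables)
        else rmultinom(n_tables, nr[r + 1L], p)
    }
    draws <- do.call(rbind, draw_list)
    lapply(seq_len(n_tables), function(s) {
      v <- numeric((m1 + 1L) * (m2 + 1L))
      v[cell_idx] <- draws[, s]
      matrix(v, m1 + 1L, m2 + 1L)
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Bootstrap p-value from a reference distribution
#'
#' Counts bootstrap statistics at least as extreme as the observed one with
#' the `+1 / (S + 1)` convention, so a p-value is never exactly zero. For
#' two-sided use, extremeness is distance from the bootstrap mean.
#'
#' @param observed Observed statistic.
#' @param boot_stats Vector of bootstrap statistics.
#' @param direction `"upper"` for statistics large under misfit (the
#'   likelihood ratio), `"two_sided"` for centred statistics (gamma).
#' @return A p-value in `(0, 1]`.
#' @export
bootstrap_p <- function(observed, boot_stats,
                        direction = c("upper", "two_sided")) {
  direction <- match.arg(direction)
  if (length(boot_stats) < 1) abort("Need at least one bootstrap statistic.")
  s <- length(boot_stats)
  eps <- 1e-12 * (1 + abs(observed))
  k <- switch(direction,
    upper = sum(boot_stats >= observed - eps),
    two_sided = {
      ctr <- mean(boot_stats)
      sum(abs(boot_stats - ctr) >= abs(observed - ctr) - eps)
    }
  )
  (1 + k) / (s + 1)
}

#' Person-wise misfit test
#'
#' For every person (cell), a two-sided conditional exact test of the
#' observed split of the total score between the two scales under the fitted
#' conditional distribution. Persons whose split has tail probability at or
#' below `level` are flagged; the flagged proportion is compared with the
#' nominal level by the one-degree-of-freedom chi-square statistic
#' `n * (p - level)^2 / (level * (1 - level))` with an upper-tail p-value.
#'
#' @inheritParams fit_tests
#' @param method See `misfit_method` in [fit_tests()].
#' @return A list with `count`, `proportion`, `ci` (95% Wald interval for
#'   the proportion), and the chi-square `p_value`. Total scores admitting a
#'   single split contribute no flags but stay in the denominator.
#' @export
person_misfit_test <- function(fit, level = 0.05,
                               method = c("mid_p", "prob_ordering")) {
  method <- match.arg(method)
  counts <- unclass(fit$table)
  m1 <- nrow(counts) - 1L
  m2 <- ncol(counts) - 1L
  nr <- total_score_counts(counts)
  g1 <- fit$params_a$gamma
  g2 <- fit$params_b$gamma
  count <- 0
  for (r in which(nr > 0) - 1L) {
    xs <- max(0, r - m2):min(r, m1)
    p <- g1[xs + 1L] * g2[r - xs + 1L]
    keep <- p > 0
    xs <- xs[keep]
    p <- p[keep] / sum(p[keep])
    if (length(p) < 2) next
    tails <- vapply(p, function(px) {
      lo <- p < px * (1 - 1e-9)
      eq <- !lo & p <= px * (1 + 1e-9)
      if (method == "mid_p") sum(p[lo]) + 0.5 * sum(p[eq]) else sum(p[lo | eq])
    }, numeric(1))
    flagged <- xs[tails <= level]
    if (length(flagged) > 0) {
      count <- count + sum(counts[flagged + 1L, , drop = FALSE][
        cbind(seq_along(flagged), r - flagged + 1L)])
    }
  }
  n <- sum(counts)
  phat <- count / n
  half <- qnorm(0.975) * sqrt(phat * (1 - phat) / n)
  ci <- c(max(0, phat - half), min(1, phat + half))
  x2 <- n * (phat - level)^2 / (level * (1 - level))
  p_value <- pchisq(x2, df = 1, lower.tail = FALSE)
  list(count = count, proportion = phat, ci = ci, p_value = p_value)
}

#' @export
print.leunbach_fit_report <- function(x, ...) {
  cat("<Leunbach model fit tests>\n")
  cat(sprintf("  conditional LRT: G2 = %.3f, bootstrap p = %.4f\n",
              x$lrt_statistic, x$lrt_p))
  cat(sprintf("  gamma: observed %.3f, expected %.3f, bootstrap p = %.4f\n",
              x$gamma_observed, x$gamma_expected, x$gamma_p))
  cat(sprintf(
    "  persons with significant score differences: %d (%.1f%%) [%.1f, %.1f], p = %.4f\n",
    x$misfit_count, 100 * x$misfit_proportion,
    100 * x$misfit_ci[1], 100 * x$misfit_ci[2], x$misfit_p))
  cat(sprintf("  bootstrap replicates: %d; verdict: %s\n",
              x$n_bootstrap, x$verdict))
  invisible(x)
}

#' @rdname fit_tests
#' @param x A `leunbach_fit_report` object.
#' @param ... Unused.
#' @export
tidy.leunbach_fit_report <- function(x, ...) {
  tibble(
    test = c("conditional_lrt", "gamma", "person_misfit"),
    statistic = c(x$lrt_statistic, x$gamma_observed, x$misfit_proportion),
    expected = c(0, x$gamma_expected, x$level),
    p_value = c(x$lrt_p, x$gamma_p, x$misfit_p)
  )
}

#' @rdname fit_tests
#' @export
glance.leunbach_fit_report <- function(x, ...) {
  tibble(
    lrt_statistic = x$lrt_statistic, lrt_p = x$lrt_p,
    gamma_observed = x$gamma_observed, gamma_expected = x$gamma_expected,
    gamma_p = x$gamma_p, misfit_count = x$misfit_count,
    misfit_proportion = x$misfit_proportion,
    misfit_ci_lower = x$misfit_ci[1], misfit_ci_upper = x$misfit_ci[2],
    misfit_p = x$misfit_p, n = x$n, n_bootstrap = x$n_bootstrap,
    verdict = x$verdict
  )
}
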