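#' Fit Leunbach's model to a two-way score table
#'
#' Estimates the score parameters of both scales by conditional maximum
#' likelihood: the likelihood of the observed score splits given each
#' person's total score, which is free of the person parameters. The
#' estimate is computed by iterative proportional fitting of the expected
#' row and column margins (the total-score margins are matched by
#' construction), the same estimating equations solved for item parameters
#' in Rasch models.
#'
#' Scores never observed on a scale have no information in the conditional
#' likelihood; their parameters are fixed at zero and equating is restricted
#' to the observed score range.
#'
#' @param data A [score_table()], a counts matrix, or a per-person data
#'   frame (passed on to [score_table()]).
#' @param scale_a,scale_b,range_a,range_b Passed to [score_table()] when
#'   `data` is a data frame.
#' @param tol Convergence tolerance: the largest absolute change in any
#'   fitted conditional split probability over one fitting cycle.
#' @param max_iter Maximum number of fitting cycles.
#' @param normalization Identifiability convention for the fitted gammas.
#'   The conditional likelihood determines them only up to a constant per
#'   scale and a common geometric tilt. `"theta_centered"` (default) sets the
#'   first observed gamma of each scale to 1 and tilts so that the mean
#'   latent estimate over observed interior total scores is 0;
#'   `"none"` keeps the raw fitted values. All conditional and equating
#'   output is invariant to this choice.
#' @param start Optional list with elements `gamma_a`, `gamma_b` used as a
#'   warm start.
#' @return An object of class `leunbach_fit` with fitted [score_params()]
#'   for both scales, their convolution `omega`, the table, the
#'   log conditional likelihood, and convergence/identifiability diagnostics.
#' @examples
#' tab <- matrix(10, 3, 2)
#' fit <- fit_leunbach(tab)
#' glance(fit)
#' @export
fit_leunbach <- function(data, scale_a = NULL, scale_b = NULL,
                         range_a = NULL, range_b = NULL,
                         tol = 1e-9, max_iter = 10000,
                         normalization = c("theta_centered", "none"),
                         start = NULL) {
  normalization <- match.arg(normalization)
  tab <- as_score_table(data, scale_a = scale_a, scale_b = scale_b,
                        range_a = range_a, range_b = range_b)
  counts <- unclass(tab)
  attributes(counts) <- attributes(counts)["dim"]

  eng <- ipf_engine(counts, tol = tol, max_iter = max_iter,
                    g1 = start$gamma_a, g2 = start$gamma_b)
  g1 <- eng$g1
  g2 <- eng$g2
  if (normalization == "theta_centered") {
    tilt <- center_tilt(g1, g2, counts)
    g1 <- tilt$g1
    g2 <- tilt$g2
  } else {
    tilt <- list(delta = 0)
  }
  sc <- attr(tab, "scales")
  fit <- structure(
    list(
      params_a = score_params(g1, name = sc[1]),
      params_b = score_params(g2, name = sc[2]),
      omega = score_params(convolve_gamma(g1, g2)),
      table = tab,
      n = sum(counts),
      converged = eng$converged,
      iterations = eng$iterations,
      max_change = eng$max_change,
      identifiable = eng$identifiable,
      observed_range_a = range(which(rowSums(counts) > 0) - 1L),
      observed_range_b = range(which(colSums(counts) > 0) - 1L),
      normalization = list(method = normalization, tilt = tilt$delta),
      tol = tol
    ),
    class = "leunbach_fit"
  )
  fit$loglik <- conditional_loglik(fit)
  if (!eng$converged) {
    warn(sprintf(
      "CML estimation did not converge in %d cycles (max change %.2e).",
      eng$iterations, eng$max_change))
  }
  if (!eng$identifiable) {
    warn(paste("Every observed total score admits a single split:",
               "the conditional likelihood is constant and the fit is",
               "not identifiable."))
  }
  fit
}

# Iterative proportional fitting of the conditional model (compiled inner
# loop, see src/ipf.cpp). The fitted expected counts are n_r * P(split | r);
# diagonal (total-score) margins match by construction, and the row/column
# margins are matched alternately through multiplicative updates of the
# gammas. Convergence is monitored as the largest change in any fitted
# conditional split probability on the observed total scores over one cycle.
ipf_engine <- function(counts, tol = 1e-9, max_iter = 10000,
                       g1 = NULL, g2 = NULL) {
  row_obs <- rowSums(counts)
  col_obs <- colSums(counts)
  if (!any(row_obs > 0) || !any(col_obs > 0)) {
    abort("Empty table: no observed scores.")
  }
  if (is.null(g1)) g1 <- as.numeric(row_obs > 0)
  if (is.null(g2)) g2 <- as.numeric(col_obs > 0)

  out <- cpp_ipf(counts, g1, g2, tol, max_iter)

  # identifiable only if some observed total score admits >= 2 splits
  dvec <- as.vector(outer(seq_len(nrow(counts)), seq_len(ncol(counts)), "+")) - 1L
  nr <- total_score_counts(counts)
  cell_sup <- as.vector(outer(row_obs > 0, col_obs > 0, "&"))
  rpos <- which(nr > 0)
  conv_r <- match(dvec[cell_sup & dvec %in% rpos], rpos)
  out$identifiable <- any(tabulate(conv_r, length(rpos)) > 1)
  out
}

# Tilt gamma_ix -> gamma_ix * exp(delta * x) so the mean latent estimate over
# observed interior total scores is zero, then scale each gamma vector so its
# first positive entry is 1. Both transformations leave all conditional and
# equating quantities unchanged.
center_tilt <- function(g1, g2, counts) {
  om <- convolve_gamma(g1, g2)
  nr <- total_score_counts(counts)
  sup <- param_support(score_params(om))
  interior <- which(nr > 0) - 1L
  interior <- interior[interior > min(sup) & interior < max(sup)]
  delta <- 0
  if (length(interior) > 0) {
    lg <- log(om)
    thetas <- vapply(interior, function(r) theta_solve(lg, r), numeric(1))
    delta <- mean(thetas)
  }
  tilt_one <- function(g) {
    g <- g * exp(delta * (seq_along(g) - 1))
    g / g[which(g > 0)[1]]
  }
  list(g1 = tilt_one(g1), g2 = tilt_one(g2), delta = delta)
}

#' Conditional log-likelihood of a fitted model
#'
#' Sum over persons of the log conditional probability of the observed score
#' split given the person's total score. Invariant to the identifiability
#' normalization of the gammas.
#'
#' @param fit A [fit_leunbach()] object.
#' @param data Optional table to evaluate on; defaults to the fitted table.
#' @return A single non-positive number; `-Inf` (with a warning) if any
#'   observed cell is impossible under the fitted parameters.
#' @export
conditional_loglik <- function(fit, data = NULL) {
  tab <- if (is.null(data)) fit$table else as_score_table(data)
  counts <- unclass(tab)
  if (nrow(counts) - 1L != fit$params_a$max_score ||
      ncol(counts) - 1L != fit$params_b$max_score) {
    abort("Table dimensions do not match the fitted score ranges.")
  }
  lg1 <- log(fit$params_a$gamma)
  lg2 <- log(fit$params_b$gamma)
  lom <- log(fit$omega$gamma)
  nr <- total_score_counts(counts)
  didx <- outer(seq_along(lg1) - 1L, seq_along(lg2) - 1L, "+") + 1L
  lcell <- outer(lg1, lg2, "+")
  obs <- counts > 0
  if (any(obs & !is.finite(lcell))) {
    warn("Observed cells are impossible under the fitted parameters.")
    return(-Inf)
  }
  sum(counts[obs] * lcell[obs]) - sum(nr[nr > 0] * lom[nr > 0])
}

#' Latent person value whose expected score matches a target score
#'
#' Solves `expected_score(params, theta) = score` by Newton-Raphson on the
#' log scale with a bisection fallback; this is the raw-score maximum
#' likelihood estimate of the person parameter. Real-valued interior targets
#' are allowed. The minimum and maximum attainable scores have no finite
#' estimate and raise a condition of class `psq_extreme_score`; equating
#' applies its endpoint convention instead of calling this function.
#'
#' @inheritParams score_pmf
#' @param score Target score, strictly between the smallest and largest
#'   attainable score.
#' @param tol Convergence tolerance on the expected score.
#' @return A list with elements `theta` and `xi`.
#' @examples
#' person_mle(c(1, 2, 1), 4 / 3)
#' @export
person_mle <- function(params, score, tol = 1e-10) {
  params <- as_score_params(params)
  sup <- param_support(params)
  if (length(score) != 1 || is.na(score)) abort("`score` must be one number.")
  if (score <= min(sup) || score >= max(sup)) {
    abort(sprintf(
      "Score %.3g is at or outside the attainable range [%d, %d]: no finite estimate.",
      score, min(sup), max(sup)), class = "psq_extreme_score")
  }
  theta <- theta_solve(log(params$gamma), score, tol = tol)
  list(theta = theta, xi = exp(theta))
}

theta_solve <- function(lg, score, tol = 1e-10, max_iter = 200) {
  # bracket the root
  lo <- -1
  hi <- 1
  while (score_moments(lg, lo)[["mu"]] > score && lo > -745) lo <- lo * 2
  while (score_moments(lg, hi)[["mu"]] < score && hi < 745) hi <- hi * 2
  theta <- 0.5 * (lo + hi)
  for (i in seq_len(max_iter)) {
    mo <- score_moments(lg, theta)
    err <- mo[["mu"]] - score
    if (abs(err) <= tol) return(theta)
    if (err > 0) hi <- theta else lo <- theta
    step <- if (mo[["var"]] > 0) -err / mo[["var"]] else 0
    cand <- theta + step
    theta <- if (step != 0 && cand > lo && cand < hi) cand else 0.5 * (lo + hi)
  }
  theta
}

# fitted expected counts n_r * P(x, r - x | r)
expected_counts <- function(fit, counts = NULL) {
  counts <- counts %||% unclass(fit$table)
  gamma_expected_counts(fit$params_a$gamma, fit$params_b$gamma,
                        total_score_counts(counts))
}

gamma_expected_counts <- function(g1, g2, nr) {
  didx <- outer(seq_along(g1) - 1L, seq_along(g2) - 1L, "+") + 1L
  w <- outer(g1, g2)
  om <- convolve_gamma(g1, g2)
  scale <- ifelse(om > 0, nr / om, 0)
  w * scale[didx]
}

#' @export
print.leunbach_fit <- function(x, ...) {
  sc <- c(x$params_a$name, x$params_b$name)
  cat(sprintf("<Leunbach model fit: '%s' x '%s', n = %d>\n", sc[1], sc[2], x$n))
  cat(sprintf("  conditional log-likelihood: %.4f\n", x$loglik))
  cat(sprintf("  converged: %s (%d cycles, max change %.2e)\n",
              x$converged, x$iterations, x$max_change))
  if (!x$identifiable) cat("  NOTE: fit is not identifiable (degenerate splits)\n")
  cat(sprintf("  observed ranges: %s %d-%d, %s %d-%d\n",
              sc[1], x$observed_range_a[1], x$observed_range_a[2],
              sc[2], x$observed_range_b[1], x$observed_range_b[2]))
  invisible(x)
}

#' @rdname fit_leunbach
#' @param x A `leunbach_fit` object.
#' @param ... Unused.
#' @export
tidy.leunbach_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(scale = x$params_a$name %||% "a",
           score = 0:x$params_a$max_score,
           gamma = x$params_a$gamma),
    tibble(scale = x$params_b$name %||% "b",
           score = 0:x$params_b$max_score,
           gamma = x$params_b$gamma)
  ) |>
    dplyr::mutate(log_gamma = log(.data$gamma),
                  observed = .data$gamma > 0)
}

#' @rdname fit_leunbach
#' @export
glance.leunbach_fit <- function(x, ...) {
  tibble(n = x$n, loglik = x$loglik, converged = x$converged,
         iterations = x$iterations, max_change = x$max_change,
         identifiable = x$identifiable)
}
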