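#' Round an expected score to an equated integer score
#'
#' Equated scores are reported as integers: the expected target score is
#' rounded to the nearest integer, with halves rounded away from zero (a
#' declared convention; only non-half values occur in practice).
#'
#' @param expected Numeric vector of expected target scores.
#' @return Integer vector.
#' @examples
#' round_expected(c(1.9, 4.4, 2.5))
#' @export
round_expected <- function(expected) {
  as.integer(sign(expected) * floor(abs(expected) + 0.5))
}

#' Direct score-to-score equating table (point estimates)
#'
#' For each observed score on the source scale: estimate the latent person
#' value whose expected source score equals it, then compute the expected
#' score on the target scale at that value, and round. The smallest and
#' largest observed source scores have no finite person estimate and map to
#' the smallest and largest observed target scores (the limits of the test
#' characteristic curve restricted to the observed ranges).
#'
#' @param fit A converged [fit_leunbach()] object.
#' @param source Which scale is the source: `"a"`, `"b"`, or a scale name.
#' @return A tibble of class `psq_equating` with one row per observed source
#'   score: `source_score`, `theta` (person estimate; `-Inf`/`Inf` at the
#'   endpoints), `expected_target`, `equated_target`, and `weight` (observed
#'   relative frequency of the source score).
#' @export
equate_direct <- function(fit, source = "a") {
  stopifnot(inherits(fit, "leunbach_fit"))
  side <- match_source(fit, source)
  par_s <- if (side == "a") fit$params_a else fit$params_b
  par_t <- if (side == "a") fit$params_b else fit$params_a
  counts <- unclass(fit$table)
  freq <- if (side == "a") rowSums(counts) else colSums(counts)

  sup_s <- param_support(par_s)
  sup_t <- param_support(par_t)
  scores <- sup_s
  rows <- purrr::map(scores, function(s) {
    if (s == min(sup_s)) {
      list(theta = -Inf, expected = as.numeric(min(sup_t)))
    } else if (s == max(sup_s)) {
      list(theta = Inf, expected = as.numeric(max(sup_t)))
    } else {
      th <- person_mle(par_s, s)$theta
      list(theta = th, expected = expected_score(par_t, theta = th))
    }
  })
  out <- tibble(
    source_score = scores,
    theta = vapply(rows, `[[`, numeric(1), "theta"),
    expected_target = vapply(rows, `[[`, numeric(1), "expected"),
    weight = unname(freq[scores + 1L]) / sum(freq)
  )
  out$equated_target <- round_expected(out$expected_target)
  new_equating(out[, c("source_score", "theta", "expected_target",
                       "equated_target", "weight")],
               source = par_s$name %||% side,
               target = par_t$name %||% setdiff(c("a", "b"), side))
}

match_source <- function(fit, source) {
  nms <- c(fit$params_a$name %||% "a", fit$params_b$name %||% "b")
  if (identical(source, "a") || identical(source, nms[1])) return("a")
  if (identical(source, "b") || identical(source, nms[2])) return("b")
  abort(sprintf("`source` must be 'a', 'b', '%s' or '%s'.", nms[1], nms[2]))
}

new_equating <- function(df, source, target, ...) {
  extra <- list(...)
  out <- as_tibble(df)
  class(out) <- c("psq_equating", setdiff(class(out), "psq_equating"))
  attr(out, "source") <- source
  attr(out, "target") <- target
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.psq_equating <- function(x, ...) {
  cat(sprintf("# Equating table: %s -> %s\n",
              attr(x, "source"), attr(x, "target")))
  if (!is.null(attr(x, "weighted_see_mean"))) {
    cat(sprintf("# weighted SEE mean: %.3f (%s; %d bootstrap replicates)\n",
                attr(x, "weighted_see_mean"),
                if (attr(x, "see_acceptable")) "acceptable, < 0.91"
                else "NOT acceptable, >= 0.91",
                attr(x, "n_boot")))
  }
  NextMethod()
}

#' Standard Error of Equating from an error distribution
#'
#' Applies the SEE arithmetic used to summarise bootstrap error
#' distributions: the square root of the frequency-weighted mean squared
#' deviation of the equating errors from their mean. With `n` supplied, the
#' small-sample `n/(n-1)` correction matching the bootstrap SEE formula is
#' applied.
#'
#' @param frequencies Relative frequencies (normalised if they do not sum
#'   to 1 exactly).
#' @param errors Error values the frequencies refer to; defaults to
#'   `-2, -1, 0, 1, 2` for five frequencies.
#' @param n Optional number of replicates behind the frequencies.
#' @return The SEE in score points.
#' @examples
#' see_from_error_distribution(c(0.05, 0.9, 0.05), errors = -1:1)
#' @export
see_from_error_distribution <- function(frequencies, errors = NULL, n = NULL) {
  if (is.null(errors)) {
    if (length(frequencies) != 5) {
      abort("Supply `errors` unless `frequencies` has the five default bins.")
    }
    errors <- -2:2
  }
  if (length(errors) != length(frequencies) || any(frequencies < 0)) {
    abort("`frequencies` must be non-negative and match `errors` in length.")
  }
  f <- frequencies / sum(frequencies)
  mu <- sum(f * errors)
  v <- sum(f * (errors - mu)^2)
  if (!is.null(n)) v <- v * n / (n - 1)
  sqrt(v)
}

#' Weighted mean of per-score SEEs
#'
#' The per-score SEEs are averaged with the observed score frequencies as
#' weights, so sparsely observed scores do not inflate the summary. A
#' weighted mean strictly below 0.91 score points is regarded as acceptable
#' equating error.
#'
#' @param see Numeric vector of per-score SEEs.
#' @param weights Non-negative weights (observed relative frequencies).
#' @return A list with `mean` and logical `acceptable`.
#' @export
weighted_see_mean <- function(see, weights) {
  if (length(see) != length(weights)) abort("Lengths differ.")
  keep <- !is.na(see)
  if (any(weights < 0) || sum(weights[keep]) <= 0) {
    abort("Weights must be non-negative with a positive sum.")
  }
  m <- sum(weights[keep] * see[keep]) / sum(weights[keep])
  list(mean = m, acceptable = m < 0.91)
}

#' Direct equating with bootstrap Standard Error of Equating
#'
#' Resamples the observed contingency table nonparametrically (`n` persons
#' drawn multinomially over the observed cells), refits the model and
#' replays the equating on each of `n_boot` replicates. The SEE of each
#' source score is the standard deviation (with `S - 1` denominator, around
#' the bootstrap mean) of the bootstrapped equated scores; the weighted SEE
#' mean uses the observed source-score frequencies as weights.
#'
#' @inheritParams equate_direct
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @param boot_tol Convergence tolerance for the bootstrap refits (see
#'   [fit_tests()]).
#' @return A `psq_equating` tibble as in [equate_direct()], with an extra
#'   `see` column and attributes `weighted_see_mean`, `see_acceptable`,
#'   `error_distribution` (relative frequencies of equated-score errors of
#'   -2 or less, -1, 0, +1, +2 or more per source score), `n_boot`, `seed`
#'   and `n_failed` (replicates whose refit did not converge; a warning is
#'   raised when more than 5% fail).
#' @export
see_bootstrap <- function(fit, source = "a", n_boot = 1000, seed = NULL,
                          boot_tol = 1e-7) {
  stopifnot(inherits(fit, "leunbach_fit"))
  point <- equate_direct(fit, source = source)
  counts <- unclass(fit$table)
  run <- function() {
    reps <- replicate(n_boot,
                      boot_equate_once(counts, fit, source, boot_tol),
                      simplify = FALSE)
    summarize_boot(point, reps, n_boot, seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# one nonparametric replicate: resample cells, refit, re-equate;
# returns named vector of equated scores (NA for scores absent from the
# replicate) or NULL if the refit failed
boot_equate_once <- function(counts, fit, source, boot_tol = 1e-7) {
  bfit <- boot_refit(counts, fit, boot_tol)
  if (is.null(bfit)) return(NULL)
  eq <- equate_direct(bfit, source = source)
  setNames(eq$equated_target, eq$source_score)
}

summarize_boot <- function(point, reps, n_boot, seed) {
  failed <- vapply(reps, is.null, logical(1))
  if (mean(failed) > 0.05) {
    warn(sprintf("%d of %d bootstrap refits failed.", sum(failed), n_boot))
  }
  reps <- reps[!failed]
  scores <- point$source_score
  mat <- matrix(NA_real_, length(reps), length(scores),
                dimnames = list(NULL, scores))
  for (i in seq_along(reps)) {
    common <- intersect(names(reps[[i]]), colnames(mat))
    mat[i, common] <- reps[[i]][common]
  }
  see <- apply(mat, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else sd(v)
  })
  err_dist <- purrr::map_dfr(seq_along(scores), function(j) {
    e <- mat[, j] - point$equated_target[j]
    e <- e[!is.na(e)]
    bins <- c(sum(e <= -2), sum(e == -1), sum(e == 0),
              sum(e == 1), sum(e >= 2))
    tibble(source_score = scores[j],
           err_m2 = bins[1], err_m1 = bins[2], err_0 = bins[3],
           err_p1 = bins[4], err_p2 = bins[5]) |>
      dplyr::mutate(dplyr::across(dplyr::starts_with("err_"),
                                  ~ .x / max(1, length(e))))
  })
  point$see <- unname(see)
  wm <- weighted_see_mean(point$see, point$weight)
  new_equating(point, source = attr(point, "source"),
               target = attr(point, "target"),
               weighted_see_mean = wm$mean, see_acceptable = wm$acceptable,
               error_distribution = err_dist,
               n_boot = n_boot, seed = seed, n_failed = sum(failed))
}

#' Indirect (common-scale) equating
#'
#' Equates scale B to scale C through a common scale A administered in both
#' samples: B is equated to A in sample 1, A to C in sample 2, and the two
#' steps are composed. The expected A score for a B score is generally not
#' an integer; the expected C score is linearly interpolated between the
#' expected C scores of the neighbouring integer A scores. Expected A scores
#' outside A's observed range in sample 2 are clamped with a warning.
#'
#' @param fit_source_via Fit of (source scale, common scale) on sample 1.
#' @param fit_via_target Fit of (common scale, target scale) on sample 2.
#'   The common scale is identified by its name appearing in both fits.
#' @return A `psq_equating` tibble from source to target scores.
#' @export
equate_indirect <- function(fit_source_via, fit_via_target) {
  link <- indirect_link(fit_source_via, fit_via_target)
  tab1 <- equate_direct(fit_source_via, source = link$source)
  tab2 <- equate_direct(fit_via_target, source = link$via)
  expected_c <- interpolate_expected_target(tab1$expected_target, tab2)
  out <- tibble(
    source_score = tab1$source_score,
    theta = tab1$theta,
    expected_via = tab1$expected_target,
    expected_target = expected_c,
    equated_target = round_expected(expected_c),
    weight = tab1$weight
  )
  new_equating(out, source = attr(tab1, "source"),
               target = attr(tab2, "target"),
               via = link$via)
}

indirect_link <- function(fit1, fit2) {
  nms1 <- c(fit1$params_a$name %||% "a", fit1$params_b$name %||% "b")
  nms2 <- c(fit2$params_a$name %||% "a", fit2$params_b$name %||% "b")
  via <- intersect(nms1, nms2)
  if (length(via) != 1) {
    abort("The two fits must share exactly one scale name (the common scale).")
  }
  list(source = setdiff(nms1, via), via = via, target = setdiff(nms2, via))
}

#' Interpolate expected target scores through the common scale
#'
#' Given a (possibly fractional) expected score `s` on the common scale and
#' the direct equating table of the common scale to the target, the expected
#' target score is `(1 - f) * e(k) + f * e(k + 1)` with `k = floor(s)` and
#' `f = s - k`, where `e(.)` are the expected target scores at the observed
#' integer common-scale scores. Values outside the observed common-scale
#' range are clamped with a warning.
#'
#' @param s Numeric vector of expected common-scale scores.
#' @param via_target_table Equating table from [equate_direct()] with the
#'   common scale as source.
#' @return Numeric vector of expected target scores.
#' @examples
#' tab <- tibble::tibble(source_score = 4:5, expected_target = c(3.5, 5.3))
#' interpolate_expected_target(4.5, tab)
#' @export
interpolate_expected_target <- function(s, via_target_table) {
  x <- via_target_table$source_score
  y <- via_target_table$expected_target
  if (any(s < min(x) - 1e-9 | s > max(x) + 1e-9)) {
    warn("Expected common-scale scores outside the observed range were clamped.")
  }
  approx(x, y, xout = pmin(pmax(s, min(x)), max(x)), rule = 2)$y
}

#' Indirect equating with bootstrap Standard Error of Equating
#'
#' Both observed tables are resampled independently, both fits and the full
#' three-step indirect procedure are replayed on every replicate, and the
#' SEE is summarised exactly as in [see_bootstrap()] with the source-score
#' frequencies of sample 1 as weights.
#'
#' @inheritParams equate_indirect
#' @inheritParams see_bootstrap
#' @return A `psq_equating` tibble as in [see_bootstrap()].
#' @export
see_bootstrap_indirect <- function(fit_source_via, fit_via_target,
                                   n_boot = 1000, seed = NULL,
                                   boot_tol = 1e-7) {
  point <- suppressWarnings(equate_indirect(fit_source_via, fit_via_target))
  c1 <- unclass(fit_source_via$table)
  c2 <- unclass(fit_via_target$table)
  run <- function() {
    reps <- replicate(n_boot, {
      b1 <- boot_refit(c1, fit_source_via, boot_tol)
      b2 <- boot_refit(c2, fit_via_target, boot_tol)
      if (is.null(b1) || is.null(b2)) NULL
      else {
        eq <- suppressWarnings(equate_indirect(b1, b2))
        setNames(eq$equated_target, eq$source_score)
      }
    }, simplify = FALSE)
    summarize_boot(point, reps, n_boot, seed)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

boot_refit <- function(counts, fit, boot_tol = 1e-7) {
  tb <- matrix(as.numeric(rmultinom(1, sum(counts),
                                    as.vector(counts) / sum(counts))),
               nrow(counts), ncol(counts))
  eng <- try(ipf_engine(tb, tol = boot_tol, max_iter = 10000,
                        g1 = fit$params_a$gamma, g2 = fit$params_b$gamma),
             silent = TRUE)
  if (inherits(eng, "try-error") || !eng$converged) return(NULL)
  bfit <- fit
  bfit$params_a <- score_params(eng$g1, name = fit$params_a$name)
  bfit$params_b <- score_params(eng$g2, name = fit$params_b$name)
  bfit$omega <- score_params(convolve_gamma(eng$g1, eng$g2))
  bfit$table <- new_score_table(tb, scales = attr(fit$table, "scales"))
  bfit
}
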