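#' Simulation scenario for two (or three) scales sharing a latent trait
#'
#' Describes the population the synthetic-data generator draws from: score
#' parameters for each scale, a normal distribution for the latent trait on
#' the log (`theta`) scale, the number of persons, and two controlled model
#' violations — a trait correlation below 1 (each scale responds to its own
#' trait) and a unit scale factor on the second scale's trait (latent
#' values measured in different logit units).
#'
#' The defaults emulate the study design the model targets: a
#' cross-sectional sample of self-reported scale totals from a mid-sized
#' clinical cohort (722 persons), with scale shapes like 8 items scored 0-3
#' (range 0-24) and 6 items scored 0-4. The normal trait distribution is a
#' generator choice only; conditional estimation makes no use of it.
#'
#' @param gamma_a,gamma_b Score parameters ([score_params()] or bare
#'   vectors) of the two scales. Defaults: the parameters implied by 8
#'   uniform items scored 0-3 and 6 uniform items scored 0-4.
#' @param gamma_c Optional third scale, for indirect-equating workflows.
#' @param n Number of persons (default 722).
#' @param theta_mean,theta_sd Latent trait distribution on the log scale.
#' @param trait_correlation Correlation of the traits driving the two
#'   scales; 1 (default) reproduces the model exactly, values below 1
#'   violate unidimensionality.
#' @param theta_scale_b Multiplier applied to the second scale's trait
#'   (1 = same units).
#' @param seed Default seed used by the generators for this scenario.
#' @return An object of class `psq_scenario`.
#' @export
sim_scenario <- function(gamma_a = NULL, gamma_b = NULL, gamma_c = NULL,
                         n = 722, theta_mean = 0, theta_sd = 1,
                         trait_correlation = 1, theta_scale_b = 1,
                         seed = NULL) {
  gamma_a <- as_score_params(
    gamma_a %||% rasch_score_params(rep(list(rep(0, 3)), 8))$gamma, name = "a")
  gamma_b <- as_score_params(
    gamma_b %||% rasch_score_params(rep(list(rep(0, 4)), 6))$gamma, name = "b")
  if (!is.null(gamma_c)) gamma_c <- as_score_params(gamma_c, name = "c")
  if (n < 1) abort("`n` must be at least 1.")
  if (theta_sd < 0) abort("`theta_sd` must be non-negative.")
  if (trait_correlation < 0 || trait_correlation > 1) {
    abort("`trait_correlation` must be in [0, 1].")
  }
  structure(
    list(gamma_a = gamma_a, gamma_b = gamma_b, gamma_c = gamma_c,
         n = as.integer(n), theta_mean = theta_mean, theta_sd = theta_sd,
         trait_correlation = trait_correlation,
         theta_scale_b = theta_scale_b, seed = seed),
    class = "psq_scenario"
  )
}

#' @export
print.psq_scenario <- function(x, ...) {
  cat(sprintf(
    "<simulation scenario: n = %d, theta ~ N(%.2f, %.2f), rho = %.2f%s>\n",
    x$n, x$theta_mean, x$theta_sd^2, x$trait_correlation,
    if (x$theta_scale_b != 1) sprintf(", unit factor %.2f", x$theta_scale_b)
    else ""))
  invisible(x)
}

# vectorized sampling of one score per person from a power-series pmf
sample_scores <- function(gamma, theta) {
  lg <- log(gamma)
  m <- length(gamma) - 1L
  lw <- outer(0:m, theta) + lg           # (m+1) x n log-weights
  lw <- sweep(lw, 2, apply(lw, 2, max))
  w <- exp(lw)
  cw <- apply(w, 2, cumsum)
  cw <- sweep(cw, 2, cw[m + 1L, ], "/")
  u <- runif(length(theta))
  colSums(cw < rep(u, each = m + 1L))
}

#' Simulate person-level scores under the scenario
#'
#' Draws a latent trait per person and then each scale score independently
#' given the trait(s): the exact data-generating process of the model when
#' `trait_correlation = 1`, a controlled violation otherwise.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Seed; defaults to the scenario's.
#' @return A tibble with columns `person`, `theta` (the first trait),
#'   `a`, `b`, and `c` when the scenario has a third scale.
#' @export
simulate_scores <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "psq_scenario"))
  run <- function() {
    n <- scenario$n
    rho <- scenario$trait_correlation
    t1 <- rnorm(n, scenario$theta_mean, scenario$theta_sd)
    t2 <- if (rho == 1) t1 else {
      scenario$theta_mean + rho * (t1 - scenario$theta_mean) +
        sqrt(1 - rho^2) * rnorm(n, 0, scenario$theta_sd)
    }
    t2 <- scenario$theta_mean +
      scenario$theta_scale_b * (t2 - scenario$theta_mean)
    out <- tibble(
      person = seq_len(n),
      theta = t1,
      a = sample_scores(scenario$gamma_a$gamma, t1),
      b = sample_scores(scenario$gamma_b$gamma, t2)
    )
    if (!is.null(scenario$gamma_c)) {
      out$c <- sample_scores(scenario$gamma_c$gamma, t1)
    }
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a two-way score table under the model
#'
#' [simulate_scores()] collapsed to the contingency table of the first two
#' scales, with the full theoretical score ranges as dimensions. Requires
#' `trait_correlation = 1` (use [simulate_misfit_table()] otherwise).
#'
#' @inheritParams simulate_scores
#' @return A [score_table()].
#' @export
simulate_table <- function(scenario, seed = scenario$seed) {
  if (scenario$trait_correlation != 1) {
    abort("Use simulate_misfit_table() when trait_correlation < 1.")
  }
  scenario_table(scenario, seed)
}

#' Simulate a score table violating unidimensionality
#'
#' As [simulate_table()] but with the two scales driven by traits with the
#' scenario's correlation (and/or unit scale factor). As the correlation
#' approaches 1 and the unit factor 1, the distribution converges to the
#' model's.
#'
#' @inheritParams simulate_scores
#' @return A [score_table()].
#' @export
simulate_misfit_table <- function(scenario, seed = scenario$seed) {
  if (scenario$trait_correlation >= 1 && scenario$theta_scale_b == 1) {
    abort("Scenario has no model violation; use simulate_table().")
  }
  scenario_table(scenario, seed)
}

scenario_table <- function(scenario, seed) {
  d <- simulate_scores(scenario, seed = seed)
  score_table(d, "a", "b",
              range_a = scenario$gamma_a$max_score,
              range_b = scenario$gamma_b$max_score)
}

#' Simulate a score table from item-level partial-credit responses
#'
#' Samples each item of each scale from a partial-credit (polytomous Rasch)
#' model given the person's trait and sums the items to scale totals. The
#' resulting totals follow the power-series model by construction, with
#' score parameters equal to [rasch_score_params()] of the thresholds.
#'
#' @param thresholds_a,thresholds_b Lists of per-item threshold vectors.
#' @param n Number of persons.
#' @param theta_mean,theta_sd Latent trait distribution.
#' @param seed Optional seed.
#' @return A [score_table()].
#' @export
simulate_from_rasch_items <- function(thresholds_a, thresholds_b, n = 722,
                                      theta_mean = 0, theta_sd = 1,
                                      seed = NULL) {
  if (!is.list(thresholds_a)) thresholds_a <- list(thresholds_a)
  if (!is.list(thresholds_b)) thresholds_b <- list(thresholds_b)
  run <- function() {
    theta <- rnorm(n, theta_mean, theta_sd)
    scale_total <- function(thresholds) {
      item_scores <- lapply(thresholds, function(tau) {
        sample_scores(c(1, exp(-cumsum(tau))), theta)
      })
      Reduce(`+`, item_scores)
    }
    d <- tibble(a = scale_total(thresholds_a), b = scale_total(thresholds_b))
    score_table(d, "a", "b",
                range_a = sum(lengths(thresholds_a)),
                range_b = sum(lengths(thresholds_b)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
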