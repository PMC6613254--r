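test_that("conditional LRT is zero on perfectly fitting tables", {
  # forced splits: each total score has a single possible cell
  tab <- matrix(c(5, 0, 0, 7), 2, 2)
  fit <- suppressWarnings(fit_leunbach(tab))
  expect_equal(conditional_lrt(fit), 0, tolerance = 1e-10)
  # a table equal to its own fitted expectation (uniform splits)
  tab2 <- matrix(c(0, 3, 3, 0), 2, 2)
  fit2 <- fit_leunbach(tab2)
  expect_equal(conditional_lrt(fit2), 0, tolerance = 1e-8)
})

test_that("conditional LRT matches the naive double-loop oracle", {
  withr::with_seed(111, {
    for (i in 1:5) {
      tb <- matrix(rpois(16, 7) + 1, 4, 4)
      fit <- fit_leunbach(tb, tol = 1e-11)
      expect_equal(conditional_lrt(fit),
                   oracle_g2(fit$params_a$gamma, fit$params_b$gamma, tb),
                   tolerance = 1e-10)
    }
  })
})

test_that("Goodman-Kruskal gamma reproduces its defining cases", {
  expect_equal(goodman_kruskal_gamma(matrix(c(10, 0, 0, 10), 2, 2)), 1)
  expect_equal(goodman_kruskal_gamma(matrix(c(0, 10, 10, 0), 2, 2)), -1)
  expect_equal(goodman_kruskal_gamma(matrix(10, 2, 2)), 0)
  expect_warning(g <- goodman_kruskal_gamma(matrix(c(5, 5), 1, 2)), "tied")
  expect_true(is.na(g))
  # concordant/discordant pair counting against a naive loop
  withr::with_seed(112, {
    tb <- matrix(rpois(12, 5), 3, 4)
    conc <- disc <- 0
    for (i1 in 1:3) for (j1 in 1:4) for (i2 in 1:3) for (j2 in 1:4) {
      if (i2 > i1 && j2 > j1) conc <- conc + tb[i1, j1] * tb[i2, j2]
      if (i2 > i1 && j2 < j1) disc <- disc + tb[i1, j1] * tb[i2, j2]
    }
    expect_equal(goodman_kruskal_gamma(tb), (conc - disc) / (conc + disc))
  })
})

test_that("parametric bootstrap preserves total-score counts exactly", {
  withr::with_seed(113, {
    sc <- sim_scenario(gamma_a = c(1, 2, 2, 1), gamma_b = c(1, 2, 1), n = 400)
    fit <- fit_leunbach(simulate_table(sc, seed = 3))
    nr <- psequate:::total_score_counts(unclass(fit$table))
    tabs <- parametric_bootstrap_tables(fit, 25, seed = 4,
                                        type = "conditional")
    expect_length(tabs, 25)
    for (tb in tabs) {
      expect_equal(psequate:::total_score_counts(tb), nr)
    }
    # model-based tables keep the sample size but let the margins vary
    mtabs <- parametric_bootstrap_tables(fit, 10, seed = 4, type = "model")
    expect_true(all(vapply(mtabs, sum, numeric(1)) == sum(fit$table)))
    expect_identical(parametric_bootstrap_tables(fit, 0), list())
    expect_identical(parametric_bootstrap_tables(fit, 5, seed = 9),
                     parametric_bootstrap_tables(fit, 5, seed = 9))
  })
})

test_that("bootstrap p-values follow the +1/(S+1) counting rule", {
  boots <- as.numeric(1:999)
  expect_equal(bootstrap_p(1000, boots, "upper"), 1 / 1000)
  expect_equal(bootstrap_p(0, boots, "upper"), 1)
  expect_equal(bootstrap_p(500, boots, "upper"), (1 + 500) / 1000)
  # two-sided: extremeness is distance from the bootstrap mean
  expect_equal(bootstrap_p(500, boots, "two_sided"), 1)
  expect_equal(bootstrap_p(2000, boots, "two_sided"), 1 / 1000)
  expect_error(bootstrap_p(1, numeric(0)), "at least one")
})

test_that("person misfit test flags nothing when every split is forced", {
  tab <- matrix(c(5, 0, 0, 7), 2, 2)
  fit <- suppressWarnings(fit_leunbach(tab))
  mis <- person_misfit_test(fit)
  expect_equal(mis$count, 0)
  expect_equal(mis$proportion, 0)
  expect_equal(mis$p_value, pchisq(12 * 0.05 / 0.95, 1, lower.tail = FALSE))
})

test_that("misfit chi-square reproduces the published arithmetic", {
  # a flagged proportion of 5.7% among n = 2228 persons gives p ~ 0.13
  n <- 2228
  x2 <- n * (127 / n - 0.05)^2 / (0.05 * 0.95)
  expect_equal(pchisq(x2, 1, lower.tail = FALSE), 0.129, tolerance = 0.01)
})

test_that("fit tests are reproducible under a fixed seed", {
  withr::with_seed(121, {
    sc <- sim_scenario(gamma_a = c(1, 2, 2, 1), gamma_b = c(1, 3, 1), n = 300)
    fit <- fit_leunbach(simulate_table(sc, seed = 12))
    r1 <- fit_tests(fit, n_boot = 49, seed = 99)
    r2 <- fit_tests(fit, n_boot = 49, seed = 99)
    expect_identical(glance(r1), glance(r2))
    expect_identical(r1$boot_stats, r2$boot_stats)
  })
})

test_that("the verdict follows the strong/moderate evidence convention", {
  verdict <- psequate:::fit_verdict
  expect_equal(verdict(c(0.005, 0.5, 0.5)), "strong_evidence_against")
  expect_equal(verdict(c(0.03, 0.04, 0.5)), "strong_evidence_against")
  expect_equal(verdict(c(0.03, 0.5, 0.5)), "moderate_evidence")
  expect_equal(verdict(c(0.2, 0.5, 0.9)), "fit")
  expect_equal(verdict(c(0.011, 0.051, 0.9)), "moderate_evidence")
})

test_that("a reversed-keyed scale is flagged by the gamma test", {
  sc <- sim_scenario(gamma_a = rasch_score_params(rep(list(0), 10))$gamma,
                     gamma_b = rasch_score_params(rep(list(0), 12))$gamma,
                     n = 1000, theta_scale_b = -1)
  fit <- fit_leunbach(simulate_misfit_table(sc, seed = 403))
  rep <- fit_tests(fit, n_boot = 199, seed = 404)
  # no latent mixing distribution can imply a negative association
  expect_lt(rep$gamma_observed, -0.3)
  expect_gte(rep$gamma_expected, -0.05)
  expect_lte(rep$gamma_p, 0.01)
  expect_equal(rep$verdict, "strong_evidence_against")
})

test_that("subgroups with different score couplings break the conditional fit", {
  # two subpopulations whose second score tracks the first along different
  # lines: the split of each total score is bimodal, which the
  # quasi-independence structure given r cannot reproduce
  withr::with_seed(411, {
    ga <- rasch_score_params(rep(list(0), 10))$gamma
    n <- 1200
    th <- rnorm(n)
    x1 <- psequate:::sample_scores(ga, th)
    grp <- rbinom(n, 1, 0.5)
    x2 <- ifelse(grp == 1, pmin(12, round(1.8 * x1)), pmax(0, round(0.6 * x1)))
    x2 <- pmin(12, pmax(0, x2 + rbinom(n, 2, 0.3) - 1))
    tab <- score_table(data.frame(a = x1, b = x2), range_a = 10, range_b = 12)
  })
  fit <- fit_leunbach(tab)
  rep <- fit_tests(fit, n_boot = 199, seed = 412)
  expect_lte(rep$lrt_p, 0.01)
  expect_lte(rep$misfit_p, 0.01)
  expect_equal(rep$verdict, "strong_evidence_against")
})

test_that("pure trait-correlation violations are absorbed by the model", {
  # with free score parameters (which absorb any margins) and a free latent
  # mixing distribution (which absorbs the strength of association), data
  # whose only violation is a trait correlation below 1 stay inside the
  # model family; the fitted expected gamma tracks the observed one and no
  # test is expected to flag the table. This is a documented limitation.
  sc <- sim_scenario(gamma_a = rasch_score_params(rep(list(0), 10))$gamma,
                     gamma_b = rasch_score_params(rep(list(0), 12))$gamma,
                     n = 2000, trait_correlation = 0.3)
  fit <- fit_leunbach(simulate_misfit_table(sc, seed = 77))
  rep <- fit_tests(fit, n_boot = 199, seed = 78)
  expect_lt(rep$gamma_observed, 0.3) # association far below the rho = 1 case
  expect_equal(rep$gamma_expected, rep$gamma_observed, tolerance = 0.05)
  expect_gt(rep$gamma_p, 0.05)
})

test_that("expected gamma sits inside the bootstrap distribution under fit", {
  withr::with_seed(131, {
    sc <- sim_scenario(gamma_a = c(1, 2, 2, 1), gamma_b = c(1, 2, 2, 2, 1),
                       n = 800)
    fit <- fit_leunbach(simulate_table(sc, seed = 13))
    rep <- fit_tests(fit, n_boot = 199, seed = 14)
    qs <- quantile(rep$boot_stats$gamma, c(0.025, 0.975), na.rm = TRUE)
    expect_gte(rep$gamma_expected, qs[[1]])
    expect_lte(rep$gamma_expected, qs[[2]])
  })
})
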