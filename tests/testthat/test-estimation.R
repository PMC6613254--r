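test_that("CML via proportional fitting matches brute-force maximization", {
  # fixed small example: 3x2 table with all cells equal
  tab <- matrix(10, 3, 2)
  fit <- fit_leunbach(tab, tol = 1e-12)
  oracle <- oracle_cml_fit(tab)
  expect_equal(fit$loglik,
               oracle_conditional_loglik(oracle$g1, oracle$g2, tab),
               tolerance = 1e-8)
  for (r in 0:3) {
    expect_equal(unname(conditional_split_pmf(fit$params_a, fit$params_b, r)),
                 unname(conditional_split_pmf(oracle$g1, oracle$g2, r)),
                 tolerance = 1e-6)
  }

  # random all-positive tables up to 6x6, compared on the log-gamma scale
  # after applying the same identifiability normalization to both solutions
  withr::with_seed(61, {
    for (i in 1:5) {
      nr <- sample(3:6, 1)
      nc <- sample(2:6, 1)
      tb <- matrix(rpois(nr * nc, 20) + 1, nr, nc)
      fit <- fit_leunbach(tb, tol = 1e-12)
      oracle <- oracle_cml_fit(tb)
      norm <- psequate:::center_tilt(oracle$g1, oracle$g2, tb)
      expect_lt(max(abs(log(fit$params_a$gamma) - log(norm$g1))), 1e-6)
      expect_lt(max(abs(log(fit$params_b$gamma) - log(norm$g2))), 1e-6)
      expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-9)
    }
  })
})

test_that("fitted margins match observed margins within total-score diagonals", {
  withr::with_seed(62, {
    tb <- matrix(rpois(20, 8), 5, 4)
    tb[1, 1] <- tb[1, 1] + 5
    fit <- fit_leunbach(tb, tol = 1e-12)
    e <- psequate:::expected_counts(fit)
    expect_equal(rowSums(e), rowSums(tb), tolerance = 1e-6)
    expect_equal(colSums(e), colSums(tb), tolerance = 1e-6)
    expect_equal(psequate:::total_score_counts(e),
                 psequate:::total_score_counts(tb), tolerance = 1e-9)
  })
})

test_that("a diagonal table with forced splits is flagged non-identifiable", {
  tab <- matrix(c(5, 0, 0, 7), 2, 2)
  expect_warning(fit <- fit_leunbach(tab), "not identifiable")
  expect_false(fit$identifiable)
})

test_that("unobserved scores get zero gamma and restrict the range", {
  withr::with_seed(63, {
    sc <- sim_scenario(gamma_a = c(1, 2, 2, 1), gamma_b = c(1, 2, 1), n = 300)
    tb <- unclass(simulate_table(sc, seed = 5))
    tb[2, ] <- 0 # remove score 1 on scale a entirely
    fit <- fit_leunbach(psequate:::new_score_table(tb))
    expect_equal(fit$params_a$gamma[2], 0)
    eq <- equate_direct(fit, "a")
    expect_false(1 %in% eq$source_score)
  })
})

test_that("conditional log-likelihood matches hand and oracle values", {
  # uniform-split model: every person with r = 1 contributes log(0.5)
  tab <- matrix(c(0, 3, 4, 0), 2, 2) # 7 persons, all with total score 1
  fit <- fake_fit(c(1, 1), c(1, 1), counts = tab)
  expect_equal(conditional_loglik(fit), 7 * log(0.5))
  # doubling the counts doubles the log-likelihood
  fit2 <- fake_fit(c(1, 1), c(1, 1), counts = 2 * tab)
  expect_equal(conditional_loglik(fit2), 2 * conditional_loglik(fit))
  # oracle equivalence on a random 4x5 table
  withr::with_seed(71, {
    tb <- matrix(rpois(20, 6), 4, 5)
    g1 <- random_gamma(3)
    g2 <- random_gamma(4)
    ff <- fake_fit(g1, g2, counts = tb)
    expect_equal(conditional_loglik(ff),
                 oracle_conditional_loglik(g1, g2, tb), tolerance = 1e-10)
  })
})

test_that("log-likelihood is -Inf with warning for impossible cells", {
  tab <- matrix(c(1, 1, 1, 1), 2, 2)
  fit <- fake_fit(c(1, 1), c(1, 1))
  fit$table <- psequate:::new_score_table(tab)
  fit$params_a <- score_params(c(1, 0), name = "a") # score 1 impossible
  expect_warning(ll <- conditional_loglik(fit), "impossible")
  expect_identical(ll, -Inf)
})

test_that("person estimation inverts the expected-score curve", {
  expect_equal(person_mle(c(1, 2, 1), 1)$theta, 0, tolerance = 1e-8)
  expect_equal(person_mle(c(1, 2, 1), 4 / 3)$xi, 2, tolerance = 1e-8)
  expect_error(person_mle(c(1, 2, 1), 0), class = "psq_extreme_score")
  expect_error(person_mle(c(1, 2, 1), 2), class = "psq_extreme_score")
  withr::with_seed(81, {
    for (i in 1:10) {
      g <- random_gamma(sample(3:10, 1))
      sup <- which(g > 0) - 1
      target <- runif(1, min(sup) + 0.05, max(sup) - 0.05)
      est <- person_mle(g, target)
      expect_equal(expected_score(g, theta = est$theta), target,
                   tolerance = 1e-8)
    }
  })
})

test_that("the normalization convention does not change conditional output", {
  withr::with_seed(91, {
    sc <- sim_scenario(gamma_a = c(1, 3, 3, 1), gamma_b = c(1, 2, 2, 2, 1),
                       n = 600)
    tab <- simulate_table(sc, seed = 9)
    f1 <- fit_leunbach(tab, normalization = "theta_centered", tol = 1e-11)
    f2 <- fit_leunbach(tab, normalization = "none", tol = 1e-11)
    expect_false(isTRUE(all.equal(f1$params_a$gamma, f2$params_a$gamma)))
    expect_equal(conditional_loglik(f1), conditional_loglik(f2),
                 tolerance = 1e-9)
    for (r in which(f1$omega$gamma > 0) - 1L) {
      expect_equal(conditional_split_pmf(f1$params_a, f1$params_b, r),
                   conditional_split_pmf(f2$params_a, f2$params_b, r),
                   tolerance = 1e-9)
    }
    e1 <- equate_direct(f1, "a")
    e2 <- equate_direct(f2, "a")
    expect_equal(e1$expected_target, e2$expected_target, tolerance = 1e-7)
    expect_identical(e1$equated_target, e2$equated_target)
  })
})

test_that("simulated data recover the conditional split distributions", {
  sc <- sim_scenario(gamma_a = rasch_score_params(rep(list(0), 6))$gamma,
                     gamma_b = rasch_score_params(rep(list(c(-0.5, 0.5)), 4))$gamma,
                     n = 5000)
  tab <- simulate_table(sc, seed = 101)
  fit <- fit_leunbach(tab)
  nr <- psequate:::total_score_counts(unclass(tab))
  truth_a <- sc$gamma_a$gamma
  truth_b <- sc$gamma_b$gamma
  for (r in which(nr >= 300) - 1L) {
    est <- conditional_split_pmf(fit$params_a, fit$params_b, r)
    truth <- conditional_split_pmf(truth_a, truth_b, r)
    common <- intersect(names(est), names(truth))
    expect_lt(tv_dist(est[common], truth[common]), 0.05)
  }
})

test_that("tidy and glance expose the fitted parameters and diagnostics", {
  fit <- fit_leunbach(matrix(10, 3, 2))
  td <- tidy(fit)
  expect_equal(nrow(td), 3 + 2)
  expect_named(td, c("scale", "score", "gamma", "log_gamma", "observed"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, 60)
})
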