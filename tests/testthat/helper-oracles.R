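# Independent brute-force oracles and small fixtures, deliberately written
# without reusing the package's vectorised internals.

# conditional log-likelihood by naive double loops over cells
oracle_conditional_loglik <- function(g1, g2, counts) {
  m1 <- nrow(counts) - 1L
  m2 <- ncol(counts) - 1L
  omega <- numeric(m1 + m2 + 1L)
  for (x in 0:m1) {
    for (y in 0:m2) {
      omega[x + y + 1L] <- omega[x + y + 1L] + g1[x + 1L] * g2[y + 1L]
    }
  }
  ll <- 0
  for (x in 0:m1) {
    for (y in 0:m2) {
      n <- counts[x + 1L, y + 1L]
      if (n > 0) {
        ll <- ll + n * log(g1[x + 1L] * g2[y + 1L] / omega[x + y + 1L])
      }
    }
  }
  ll
}

# direct numeric maximisation of the conditional log-likelihood over the
# log-gammas (first entry of each scale fixed at 0); assumes all margins
# observed
oracle_cml_fit <- function(counts) {
  m1 <- nrow(counts) - 1L
  m2 <- ncol(counts) - 1L
  obj <- function(par) {
    g1 <- exp(c(0, par[seq_len(m1)]))
    g2 <- exp(c(0, par[m1 + seq_len(m2)]))
    -oracle_conditional_loglik(g1, g2, counts)
  }
  fit <- optim(rep(0, m1 + m2), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  list(g1 = exp(c(0, fit$par[seq_len(m1)])),
       g2 = exp(c(0, fit$par[m1 + seq_len(m2)])),
       loglik = -fit$value)
}

# naive G2 double loop given a table and the fitted gammas
oracle_g2 <- function(g1, g2, counts) {
  m1 <- nrow(counts) - 1L
  m2 <- ncol(counts) - 1L
  omega <- numeric(m1 + m2 + 1L)
  nr <- numeric(m1 + m2 + 1L)
  for (x in 0:m1) {
    for (y in 0:m2) {
      omega[x + y + 1L] <- omega[x + y + 1L] + g1[x + 1L] * g2[y + 1L]
      nr[x + y + 1L] <- nr[x + y + 1L] + counts[x + 1L, y + 1L]
    }
  }
  g2stat <- 0
  for (x in 0:m1) {
    for (y in 0:m2) {
      n <- counts[x + 1L, y + 1L]
      if (n > 0) {
        e <- nr[x + y + 1L] * g1[x + 1L] * g2[y + 1L] / omega[x + y + 1L]
        g2stat <- g2stat + 2 * n * log(n / e)
      }
    }
  }
  g2stat
}

# total-variation distance between two probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# a ready-made fit object with known gammas (uniform weights unless counts
# are given), bypassing estimation
fake_fit <- function(g1, g2, counts = NULL, scales = c("a", "b")) {
  if (is.null(counts)) {
    counts <- outer(as.numeric(g1 > 0), as.numeric(g2 > 0)) * 10
  }
  tab <- psequate:::new_score_table(counts, scales = scales)
  structure(
    list(
      params_a = score_params(g1, name = scales[1]),
      params_b = score_params(g2, name = scales[2]),
      omega = omega_convolution(g1, g2),
      table = tab, n = sum(counts), converged = TRUE, iterations = 0L,
      max_change = 0, identifiable = TRUE,
      observed_range_a = range(which(g1 > 0) - 1L),
      observed_range_b = range(which(g2 > 0) - 1L),
      normalization = list(method = "none", tilt = 0),
      tol = 1e-9, loglik = NA_real_
    ),
    class = "leunbach_fit"
  )
}

# small random gamma vectors for property loops
random_gamma <- function(m, zero_prob = 0) {
  g <- exp(rnorm(m + 1, 0, 1))
  if (zero_prob > 0) {
    z <- runif(m + 1) < zero_prob
    z[1] <- FALSE
    g[z] <- 0
  }
  g
}
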