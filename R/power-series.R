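#' Power-series score distribution
#'
#' Probability of each total score `0..m` for a person with latent value
#' `xi` (equivalently `theta = log(xi)`). Computed on the log scale, so large
#' score ranges and extreme latent values do not overflow. `xi = 0` and
#' `xi = Inf` are supported as limits and return point masses at the lowest
#' and highest attainable score.
#'
#' @param params A [score_params()] object or a bare gamma vector.
#' @param xi Non-negative latent value (multiplicative scale). Supply either
#'   `xi` or `theta`.
#' @param theta Latent value on the log scale; `theta = log(xi)`.
#' @return Numeric vector of probabilities named by score; sums to 1.
#' @examples
#' score_pmf(c(1, 2, 1), xi = 2)
#' @export
score_pmf <- function(params, xi = NULL, theta = NULL) {
  params <- as_score_params(params)
  theta <- resolve_theta(xi, theta)
  p <- pmf_engine(log(params$gamma), theta)
  setNames(p, 0:params$max_score)
}

resolve_theta <- function(xi, theta) {
  if (is.null(theta) == is.null(xi)) {
    abort("Supply exactly one of `xi` or `theta`.")
  }
  if (!is.null(xi)) {
    if (length(xi) != 1 || is.na(xi) || xi < 0) {
      abort("`xi` must be a single non-negative number.")
    }
    theta <- log(xi)
  }
  if (length(theta) != 1 || is.na(theta)) {
    abort("`theta` must be a single number (may be -Inf or Inf).")
  }
  theta
}

# log-gamma parameterized pmf; lg may contain -Inf for unattainable scores
pmf_engine <- function(lg, theta) {
  m <- length(lg) - 1L
  support <- which(is.finite(lg))
  p <- numeric(m + 1L)
  if (identical(theta, -Inf)) {
    p[support[1]] <- 1
    return(p)
  }
  if (identical(theta, Inf)) {
    p[support[length(support)]] <- 1
    return(p)
  }
  lw <- (0:m) * theta + lg
  lw <- lw - max(lw[support])
  w <- exp(lw)
  p[support] <- w[support] / sum(w[support])
  p
}

#' Convolution of two score-parameter vectors
#'
#' The total score over two scales driven by the same latent value has
#' power-series parameters `omega[r] = sum_x gamma_a[x] * gamma_b[r - x]`,
#' the discrete convolution of the two gamma vectors.
#'
#' @param params_a,params_b [score_params()] objects or bare gamma vectors.
#' @return A [score_params()] object of length `m_a + m_b + 1` holding omega.
#' @examples
#' omega_convolution(c(1, 2, 1), c(1, 1))
#' @export
omega_convolution <- function(params_a, params_b) {
  a <- as_score_params(params_a)
  b <- as_score_params(params_b)
  score_params(convolve_gamma(a$gamma, b$gamma),
               name = paste(a$name %||% "a", b$name %||% "b", sep = "+"))
}

# exact O(m1*m2) convolution (no FFT round-off)
convolve_gamma <- function(g1, g2) {
  m1 <- length(g1) - 1L
  m2 <- length(g2) - 1L
  idx <- as.vector(outer(0:m1, 0:m2, "+")) + 1L
  out <- numeric(m1 + m2 + 1L)
  acc <- rowsum(as.vector(outer(g1, g2)), idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Distribution of the total score over two scales
#'
#' @param omega A [score_params()] object for the combined scale, typically
#'   from [omega_convolution()], or a bare omega vector.
#' @inheritParams score_pmf
#' @return Numeric probability vector over total scores `0..(m_a + m_b)`.
#' @examples
#' total_score_pmf(omega_convolution(c(1, 1), c(1, 1)), xi = 1)
#' @export
total_score_pmf <- function(omega, xi = NULL, theta = NULL) {
  score_pmf(omega, xi = xi, theta = theta)
}

#' Conditional distribution of the score split given the total score
#'
#' Given the total score `r` over two scales, the probability that the first
#' scale contributed `x` is `gamma_a[x] * gamma_b[r - x] / omega[r]`,
#' independent of the latent person value: the total score is a sufficient
#' statistic. This distribution carries all the information used for
#' conditional estimation and the fit tests.
#'
#' @inheritParams omega_convolution
#' @param r Total score, `0 <= r <= m_a + m_b`.
#' @return Named probability vector over the possible first-scale scores
#'   `max(0, r - m_b) .. min(r, m_a)`.
#' @examples
#' conditional_split_pmf(c(1, 2, 1), c(1, 1), r = 2)
#' @export
conditional_split_pmf <- function(params_a, params_b, r) {
  a <- as_score_params(params_a)
  b <- as_score_params(params_b)
  if (length(r) != 1 || is.na(r) || r != round(r) || r < 0 ||
      r > a$max_score + b$max_score) {
    abort("`r` must be a single total score between 0 and m_a + m_b.")
  }
  xs <- max(0, r - b$max_score):min(r, a$max_score)
  lw <- log(a$gamma[xs + 1L]) + log(b$gamma[r - xs + 1L])
  if (all(lw == -Inf)) {
    abort(sprintf("Total score r = %d has zero probability (omega_r = 0).", r),
          class = "psq_unsupported_total")
  }
  lw <- lw - max(lw)
  w <- exp(lw)
  setNames(w / sum(w), xs)
}

#' Expected score (test characteristic curve)
#'
#' The expected total score of a scale at a given latent value; a strictly
#' increasing function of `xi` on non-degenerate scales, with limits at the
#' lowest and highest attainable score.
#'
#' @inheritParams score_pmf
#' @return A single number in `[0, m]`.
#' @examples
#' expected_score(c(1, 2, 1), xi = 2)
#' @export
expected_score <- function(params, xi = NULL, theta = NULL) {
  params <- as_score_params(params)
  theta <- resolve_theta(xi, theta)
  p <- pmf_engine(log(params$gamma), theta)
  sum((0:params$max_score) * p)
}

# mean and variance of the score at theta, for Newton steps
score_moments <- function(lg, theta) {
  p <- pmf_engine(lg, theta)
  xs <- seq_along(p) - 1
  mu <- sum(xs * p)
  c(mu = mu, var = sum((xs - mu)^2 * p))
}
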