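#' Score parameters of a power-series score distribution
#'
#' A scale with maximum total score `m` is represented by a vector of
#' non-negative score parameters `gamma[0..m]`, one per attainable total
#' score. The probability of scoring `x` for a person with latent value
#' `xi >= 0` is proportional to `xi^x * gamma[x]`. A zero entry marks a score
#' that can never be attained (for fitted objects, a score never observed).
#'
#' @param gamma Numeric vector of length `m + 1`, the weight of each score
#'   `0, 1, ..., m`. All entries must be non-negative and at least one must be
#'   positive.
#' @param name Optional scale label.
#' @return An object of class `psq_params` with fields `gamma`, `max_score`
#'   and `name`.
#' @examples
#' score_params(c(1, 2, 1), name = "toy")
#' @export
score_params <- function(gamma, name = NULL) {
  gamma <- as.numeric(gamma)
  if (length(gamma) < 1 || anyNA(gamma)) {
    abort("`gamma` must be a numeric vector without missing values.",
          class = "psq_invalid_parameter")
  }
  if (any(gamma < 0)) {
    abort("All score parameters must be non-negative.",
          class = "psq_invalid_parameter")
  }
  if (all(gamma == 0)) {
    abort("At least one score parameter must be positive.",
          class = "psq_invalid_parameter")
  }
  structure(
    list(gamma = gamma, max_score = length(gamma) - 1L, name = name),
    class = "psq_params"
  )
}

#' @export
print.psq_params <- function(x, ...) {
  lbl <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("<score parameters%s: scores 0-%d>\n", lbl, x$max_score))
  print(setNames(x$gamma, 0:x$max_score))
  invisible(x)
}

as_score_params <- function(x, name = NULL) {
  if (inherits(x, "psq_params")) x else score_params(x, name = name)
}

# scores with positive gamma; range of the attainable (or observed) scores
param_support <- function(params) {
  which(params$gamma > 0) - 1L
}

#' Score parameters implied by partial-credit items
#'
#' The total score over conditionally independent polytomous Rasch
#' (partial-credit) items follows a power-series distribution; its score
#' parameters are the convolution of the per-item parameters
#' `gamma_x = exp(-sum(tau[1:x]))`, where `tau` are the item thresholds.
#'
#' @param thresholds A numeric vector of thresholds for a single item, or a
#'   list of such vectors (one per item).
#' @inheritParams score_params
#' @return A [score_params()] object for the scale total score.
#' @examples
#' rasch_score_params(list(c(-1, 1), c(0, 0.5)))
#' @export
rasch_score_params <- function(thresholds, name = NULL) {
  if (!is.list(thresholds)) thresholds <- list(thresholds)
  item_gamma <- lapply(thresholds, function(tau) {
    if (length(tau) < 1 || anyNA(tau)) {
      abort("Each item needs at least one finite threshold.",
            class = "psq_invalid_parameter")
    }
    c(1, exp(-cumsum(tau)))
  })
  gamma <- Reduce(convolve_gamma, item_gamma)
  score_params(gamma, name = name)
}
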