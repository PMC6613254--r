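#' Two-way score contingency table
#'
#' Collapses person-level scores on two scales into the joint table of
#' observed counts that drives conditional estimation: rows index the score
#' on the first scale, columns the score on the second. Persons with a
#' missing score on either scale are dropped (pairwise complete cases).
#'
#' @param data A data frame with one row per person, or a numeric matrix of
#'   counts (rows = scores `0..m_a` on the first scale).
#' @param scale_a,scale_b Column names of the two score variables. Defaults
#'   to the first two numeric columns.
#' @param range_a,range_b Optional theoretical maximum score of each scale
#'   (or a `c(0, max)` range); defaults to the largest observed score. Scores
#'   outside a declared range raise an error naming the offending rows.
#' @return An object of class `psq_score_table`: a counts matrix with the
#'   scale names, total `n` and score ranges attached.
#' @examples
#' d <- data.frame(ess = c(0, 1, 2, 2), mos = c(1, 1, 2, 3))
#' score_table(d, "ess", "mos")
#' @export
score_table <- function(data, scale_a = NULL, scale_b = NULL,
                        range_a = NULL, range_b = NULL) {
  if (is.matrix(data)) {
    return(new_score_table(data,
                           scales = c(scale_a %||% "a", scale_b %||% "b")))
  }
  data <- as.data.frame(data)
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  scale_a <- scale_a %||% num_cols[1]
  scale_b <- scale_b %||% num_cols[2]
  for (s in c(scale_a, scale_b)) {
    if (!s %in% names(data)) {
      abort(sprintf("Column '%s' not found in `data`.", s))
    }
  }
  a <- data[[scale_a]]
  b <- data[[scale_b]]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0) abort("No persons with both scores non-missing.")
  check_scores <- function(x, scale, range) {
    if (any(x != round(x) | x < 0)) {
      bad <- which(x != round(x) | x < 0)
      abort(sprintf("Scale '%s' has non-integer or negative scores in rows: %s",
                    scale, paste(utils::head(bad, 5), collapse = ", ")))
    }
    if (!is.null(range)) {
      mx <- max(range)
      if (any(x > mx)) {
        bad <- which(x > mx)
        abort(sprintf(
          "Scale '%s' has scores above the declared maximum %d in rows: %s",
          scale, mx, paste(utils::head(bad, 5), collapse = ", ")),
          class = "psq_out_of_range")
      }
      mx
    } else {
      max(x)
    }
  }
  m1 <- check_scores(a, scale_a, range_a)
  m2 <- check_scores(b, scale_b, range_b)
  counts <- matrix(0L, m1 + 1L, m2 + 1L)
  for (i in seq_along(a)) {
    counts[a[i] + 1L, b[i] + 1L] <- counts[a[i] + 1L, b[i] + 1L] + 1L
  }
  new_score_table(counts, scales = c(scale_a, scale_b))
}

new_score_table <- function(counts, scales = c("a", "b")) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts)) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(counts) == 0) abort("Empty table: total count is zero.")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(0:(nrow(counts) - 1L), 0:(ncol(counts) - 1L))
  structure(counts, class = c("psq_score_table", "matrix", "array"),
            scales = scales, n = sum(counts))
}

as_score_table <- function(x, ...) {
  if (inherits(x, "psq_score_table")) x else score_table(x, ...)
}

#' @export
print.psq_score_table <- function(x, ...) {
  sc <- attr(x, "scales")
  cat(sprintf("<score table: '%s' (rows, 0-%d) x '%s' (cols, 0-%d), n = %d>\n",
              sc[1], nrow(x) - 1L, sc[2], ncol(x) - 1L, sum(x)))
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' @export
as_tibble.psq_score_table <- function(x, ...) {
  sc <- attr(x, "scales")
  out <- expand.grid(a = 0:(nrow(x) - 1L), b = 0:(ncol(x) - 1L))
  out$n <- as.vector(unclass(x))
  names(out) <- c(sc[1], sc[2], "n")
  as_tibble(out)
}

# counts of each total score r = 0..(m1+m2)
total_score_counts <- function(counts) {
  m1 <- nrow(counts) - 1L
  m2 <- ncol(counts) - 1L
  idx <- as.vector(outer(0:m1, 0:m2, "+")) + 1L
  out <- numeric(m1 + m2 + 1L)
  acc <- rowsum(as.vector(counts), idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
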