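#' Plot an equating table
#'
#' Step plot of the equated target score against the source score, with the
#' expected (unrounded) target score as a line and, when a bootstrap SEE is
#' present, a ribbon of plus/minus one SEE around the expected score.
#'
#' @param object A `psq_equating` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psq_equating <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$source_score)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_target),
                       colour = "grey50") +
    ggplot2::geom_step(ggplot2::aes(y = .data$equated_target)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$equated_target)) +
    ggplot2::labs(
      x = sprintf("%s score", attr(object, "source")),
      y = sprintf("equated %s score", attr(object, "target")),
      title = sprintf("Equating %s to %s", attr(object, "source"),
                      attr(object, "target")),
      subtitle = if (!is.null(attr(object, "weighted_see_mean"))) {
        sprintf("weighted SEE mean %.2f (%s)",
                attr(object, "weighted_see_mean"),
                if (attr(object, "see_acceptable")) "acceptable"
                else "not acceptable")
      }
    )
  if ("see" %in% names(object) && any(!is.na(object$see))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$expected_target - .data$see,
                   ymax = .data$expected_target + .data$see),
      alpha = 0.2)
  }
  p
}

#' Plot observed vs expected counts of a fitted model
#'
#' Tile plot of the observed two-way score table next to the fitted
#' expected counts given the total scores.
#'
#' @param object A `leunbach_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leunbach_fit <- function(object, ...) {
  sc <- attr(object$table, "scales")
  obs <- as_tibble(object$table)
  names(obs) <- c("score_a", "score_b", "count")
  obs$type <- "observed"
  e <- expected_counts(object)
  exp_df <- obs
  exp_df$count <- as.vector(e)
  exp_df$type <- "expected"
  dplyr::bind_rows(obs, exp_df) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$score_a, y = .data$score_b,
                                 fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~type) +
    ggplot2::labs(x = sprintf("%s score", sc[1]),
                  y = sprintf("%s score", sc[2]), fill = "count")
}

#' Plot the bootstrap reference distributions of the fit tests
#'
#' Histograms of the bootstrapped likelihood-ratio and gamma statistics
#' with the observed values marked.
#'
#' @param object A `leunbach_fit_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.leunbach_fit_report <- function(object, ...) {
  boot <- tidyr::pivot_longer(object$boot_stats, dplyr::everything(),
                              names_to = "statistic", values_to = "value")
  obs <- tibble(statistic = c("g2", "gamma"),
                value = c(object$lrt_statistic, object$gamma_observed))
  ggplot2::ggplot(boot, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "bootstrap statistic", y = "replicates")
}
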