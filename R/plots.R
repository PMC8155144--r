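#' Plot perceived stress against glutamate change
#'
#' Scatter of percent-change glutamate against PSS with per-group linear
#' trends and, optionally, the pooled quadratic curve over every
#' stress-condition participant.
#'
#' @param changes Output of [score_metabolite_changes()] (included rows
#'   are plotted).
#' @param participants Participant table with `id`, `group`, `pss`.
#' @param quadratic Overlay the pooled centered-quadratic fit (default
#'   TRUE).
#' @return A ggplot object.
#' @export
plot_pss_glu <- function(changes, participants, quadratic = TRUE) {
  d <- changes
  if ("included" %in% names(d)) d <- filter(d, .data$included)
  d <- inner_join(d, select(as_tibble(participants), "id", "group", "pss"),
                  by = "id")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pss, y = .data$pct_change_glu,
                                       colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = "Perceived Stress Scale (PSS)",
                  y = "% change Glu/Cr", colour = "group") +
    ggplot2::theme_minimal()
  if (quadratic && nrow(d) >= 4) {
    p <- p + ggplot2::geom_smooth(
      ggplot2::aes(group = 1), method = "lm",
      formula = y ~ poly(x, 2), se = FALSE, colour = "black",
      linewidth = 0.8)
  }
  p
}

#' Plot a calibration model with out-of-sample residuals
#'
#' Draws the fitted expected-change line and, when scored MGR records are
#' supplied, the observed points with vertical segments to their expected
#' values (the segments are the maladaptive glutamate responses).
#'
#' @param object A [fit_calibration()] model.
#' @param mgr Optional output of [score_mgr()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.glu_calibration <- function(object, mgr = NULL, ...) {
  rng <- range(object$fit$model$pss)
  if (!is.null(mgr)) rng <- range(c(rng, mgr$pss))
  line <- tibble(pss = seq(rng[1], rng[2], length.out = 50)) |>
    mutate(expected = expected_change(object, .data$pss))
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$pss, y = .data$expected)) +
    ggplot2::geom_line(colour = "black", linewidth = 0.8) +
    ggplot2::labs(x = "Perceived Stress Scale (PSS)",
                  y = "% change Glu/Cr",
                  title = sprintf("expected = %.3f %+.3f * PSS",
                                  object$intercept, object$slope)) +
    ggplot2::theme_minimal()
  if (!is.null(mgr)) {
    p <- p +
      ggplot2::geom_segment(
        data = mgr,
        ggplot2::aes(x = .data$pss, xend = .data$pss,
                     y = .data$pct_change_glu_expected,
                     yend = .data$pct_change_glu_observed),
        colour = "grey60", linetype = "dashed") +
      ggplot2::geom_point(
        data = mgr,
        ggplot2::aes(x = .data$pss, y = .data$pct_change_glu_observed),
        colour = "steelblue")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot EMA summary group means
#'
#' Mean and standard error of each per-participant EMA summary variable by
#' diagnostic group.
#'
#' @param summaries Output of [summarize_ema()] (included rows are used).
#' @param participants Participant table with `id` and `group`.
#' @return A ggplot object.
#' @export
plot_ema_group_means <- function(summaries, participants) {
  vars <- c("expected_outcome", "experienced_outcome", "inaccuracy",
            "pessimistic_mean", "optimistic_mean", "pos_affect", "neg_affect")
  d <- summaries |>
    filter(.data$included) |>
    inner_join(select(as_tibble(participants), "id", "group"), by = "id") |>
    mutate(diag = if_else(.data$group == "mdd", "MDD", "HC")) |>
    tidyr::pivot_longer(dplyr::all_of(vars), names_to = "variable") |>
    filter(!is.na(.data$value)) |>
    group_by(.data$diag, .data$variable) |>
    summarise(mean = mean(.data$value),
              se = sd(.data$value) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$variable, y = .data$mean,
                                  fill = .data$diag)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "group mean ± SE", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}
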