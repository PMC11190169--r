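# ggplot2 views of the result objects.

#' Forest plot of detected signals
#'
#' One row per event, point estimate with its lower/upper bound where the
#' statistic has both (ROR) or its lower bound (EBGM, IC), on a log scale
#' with the null value marked.
#'
#' @param object A `faers_signals` tibble.
#' @param statistic Which estimator to draw: `"ror"` (with full CI),
#'   `"ebgm"` or `"ic"` (with lower bound).
#' @param max_events Cap on the number of events drawn (top of the ranking).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, statistic = c("ror", "ebgm", "ic"),
                                   max_events = 30, ...) {
  statistic <- match.arg(statistic)
  df <- as_tibble(head(object, max_events))
  df$event <- factor(df$event, levels = rev(df$event))
  null_at <- if (statistic == "ic") 0 else 1
  p <- switch(statistic,
    ror = ggplot(df, aes(x = .data$ror, y = .data$event)) +
      geom_errorbarh(aes(xmin = .data$ror_low, xmax = .data$ror_high),
                     height = 0.25) +
      scale_x_log10() + labs(x = "ROR (95% CI)"),
    ebgm = ggplot(df, aes(x = .data$ebgm, y = .data$event)) +
      geom_errorbarh(aes(xmin = .data$ebgm_low, xmax = .data$ebgm),
                     height = 0.25) +
      scale_x_log10() + labs(x = "EBGM (EBGM05 to point)"),
    ic = ggplot(df, aes(x = .data$ic, y = .data$event)) +
      geom_errorbarh(aes(xmin = .data$ic_low, xmax = .data$ic),
                     height = 0.25) +
      labs(x = "IC (IC025 to point)")
  )
  p + geom_point() +
    geom_vline(xintercept = null_at, linetype = "dashed") +
    labs(y = NULL) + theme_minimal()
}

#' Bar-chart view of a report profile
#'
#' @param object A `faers_profile`.
#' @param blocks Which blocks to draw (default all).
#' @param ... Unused.
#' @return A ggplot object faceted by block.
#' @method autoplot faers_profile
#' @export
autoplot.faers_profile <- function(object, blocks = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(blocks)) df <- filter(df, .data$block %in% blocks)
  df <- mutate(df, category = factor(.data$category, levels = unique(.data$category)))
  ggplot(df, aes(x = .data$category, y = .data$n)) +
    geom_col() +
    facet_wrap(~block, scales = "free") +
    labs(x = NULL, y = "reports") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.faers_signals
#' @param signals A `faers_signals` tibble.
#' @export
plot_signal_forest <- function(signals, statistic = "ror", max_events = 30) {
  autoplot.faers_signals(signals, statistic = statistic, max_events = max_events)
}
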