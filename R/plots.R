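#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_line
#'   geom_hline geom_vline labs coord_polar facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Scree plot of a fitted decomposition
#'
#' Explained-variance share per latent vector, with the cumulative share
#' overlaid, in variance-rank order.
#'
#' @param object An `olsa_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.olsa_fit <- function(object, ...) {
  df <- tidy(object, matrix = "variance")
  df$rank <- seq_len(nrow(df))
  df$cumulative <- cumsum(df$explained_variance)
  ggplot(df, aes(x = .data$rank)) +
    geom_col(aes(y = .data$explained_variance), fill = "grey60") +
    geom_line(aes(y = .data$cumulative), colour = "steelblue") +
    geom_hline(yintercept = object$threshold, linetype = "dashed") +
    labs(x = "latent vector (variance rank)", y = "variance share",
         title = sprintf("%d vectors retained at %.0f%% cumulative variance",
                         object$n_components, 100 * object$threshold)) +
    theme_minimal()
}

#' Score distribution of a selection report
#'
#' Per-compound scores coloured by category, with the moderate and high
#' median + m*IQR cutoffs marked.
#'
#' @param object A `selection_report` from [categorize()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.selection_report <- function(object, ...) {
  df <- as_tibble(object)
  df <- dplyr::arrange(df, .data$score)
  df$rank <- seq_len(nrow(df))
  cuts <- attr(object, "cutoffs")
  ggplot(df, aes(x = .data$rank, y = .data$score,
                 colour = .data$category)) +
    geom_point() +
    geom_hline(yintercept = cuts[["moderate"]], linetype = "dashed") +
    geom_hline(yintercept = cuts[["high"]], linetype = "dotted") +
    labs(x = "compound (score rank)", y = "response score",
         colour = "category") +
    theme_minimal()
}

#' Radar-style plot of compound response scores
#'
#' Response scores of selected compounds over all latent vectors on a
#' polar layout (vectors clockwise from P1V at the top), one panel per
#' compound, with the zero-score baseline drawn.
#'
#' @param fit An `olsa_fit`.
#' @param compounds Character vector of compound ids.
#' @return A ggplot.
#' @export
plot_radar <- function(fit, compounds) {
  df <- radar_data(fit, compounds)
  df$vector <- factor(df$vector, levels = colnames(fit$scores))
  ggplot(df, aes(x = .data$vector, y = .data$score, group = .data$compound_id)) +
    geom_hline(yintercept = 0, colour = "black") +
    geom_line(colour = "steelblue") +
    geom_point(size = 0.6, colour = "steelblue") +
    coord_polar(start = 0, direction = 1) +
    facet_wrap(~compound_id) +
    labs(x = NULL, y = "response score") +
    theme_minimal()
}

#' Indicator comparison bar data plot
#'
#' Hit counts per indicator and IQR multiplier, split into flagged
#' (previously reported) and unflagged compounds.
#'
#' @param object An indicator-comparison tibble from
#'   [compare_indicators()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_indicator_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object, "indicator", "m", "n_flagged", "n_unflagged"),
    c("n_flagged", "n_unflagged"),
    names_to = "status", values_to = "count")
  ggplot(long, aes(x = factor(.data$m), y = .data$count,
                   fill = .data$status)) +
    geom_col() +
    facet_wrap(~indicator) +
    labs(x = "IQR multiplier m", y = "compounds at or above cutoff",
         fill = NULL) +
    theme_minimal()
}
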