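#' Plot a metagene profile
#'
#' Promoter and 3'-end segments on their bp axes, the scaled body on its bin
#' axis, as the usual three-panel composite profile.
#'
#' @param object a `metagene_profile` from [metagene_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metagene_profile <- function(object, ...) {
  df <- as_tibble(object)
  df$segment <- factor(df$segment, levels = c("promoter", "body", "tes"),
                       labels = c("TSS", "gene body (scaled)", "TES"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$rpm)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$segment), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RPM") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the permuted statistics with the observed value marked.
#'
#' @param object a `perm_enrichment` object.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble(statistic = object$null_values),
                  ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = object$statistic_name, y = "permutations",
                  subtitle = sprintf("observed = %.4g, p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Bar chart of positional transitions by response class
#'
#' @param transitions tibble from [classify_transitions()].
#' @return A ggplot object.
#' @export
plot_transitions <- function(transitions) {
  df <- filter(transitions, .data$response %in% c("induced", "repressed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$transition, fill = .data$response)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = NULL, y = "anchor genes", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Boxplot of pause ratios by response class
#'
#' @param pause tibble from [pause_ratio()].
#' @param response response table (`gene_id`, `label`).
#' @return A ggplot object (log10 y axis).
#' @export
plot_pause_ratios <- function(pause, response) {
  df <- pause %>%
    inner_join(response, by = "gene_id") %>%
    filter(!.data$flagged, is.finite(.data$pause_ratio),
           .data$label %in% c("induced", "repressed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$pause_ratio)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "pause ratio (TSS / gene body)") +
    ggplot2::theme_minimal()
}
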