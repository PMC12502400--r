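#' Volcano plot of a differential table
#'
#' log2 fold change against \eqn{-\log_{10} q} for one comparison of a
#' differential tibble (e.g. from [kruskal_dunn()] or [differential_ko()]).
#'
#' @param diff differential tibble.
#' @param comparison comparison label to plot (default: first non-omnibus).
#' @param q_threshold significance line (default 0.05).
#' @return a ggplot object.
#' @export
plot_volcano <- function(diff, comparison = NULL, q_threshold = 0.05) {
  cmp <- comparison %||% setdiff(unique(diff$comparison), "omnibus")[1]
  df <- diff |>
    dplyr::filter(.data$comparison == cmp, !is.na(.data$effect), !is.na(.data$q)) |>
    dplyr::mutate(significant = .data$q < q_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = -log10(.data$q))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10](q)), title = cmp) +
    ggplot2::theme_minimal()
}

#' Bar plot of the most central nodes
#'
#' @param object a `centrality_report` from [betweenness_centrality()].
#' @param top_n number of nodes to show (default 20).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.centrality_report <- function(object, top_n = 20, ...) {
  df <- object |>
    dplyr::arrange(dplyr::desc(.data$bc_norm)) |>
    head(top_n) |>
    dplyr::mutate(node = factor(.data$node, levels = rev(.data$node)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bc_norm, y = .data$node)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "normalized betweenness centrality", y = NULL) +
    ggplot2::theme_minimal()
}
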