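#' Plot per-rule pass counts of a candidate screen
#'
#' @param object A `candidate_screen`.
#' @param ... Unused.
#' @return A ggplot: one bar per rule, the candidate-gate rules highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.candidate_screen <- function(object, ...) {
  s <- object$rule_summary
  s$gate <- s$rule %in% c("hia", "bioavailability")
  ggplot2::ggplot(s, ggplot2::aes(x = stats::reorder(.data$rule, .data$n_pass),
                                  y = .data$n_pass, fill = .data$gate)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = s$n_total[1], linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#2166ac"),
                               name = "candidate gate") +
    ggplot2::labs(x = NULL, y = "compounds passing",
                  title = sprintf("Candidate screen: %d / %d compounds",
                                  length(object$candidates), s$n_total[1]))
}

#' Bubble plot of the top enriched terms
#'
#' @param object An `enrichment` object.
#' @param k Number of top terms to show (default 15).
#' @param ... Unused.
#' @return A ggplot: enrichment factor on x, terms on y, bubble size = hit
#'   count, colour = -log10 q.
#' @exportS3Method ggplot2::autoplot
autoplot.enrichment <- function(object, k = 15, ...) {
  tt <- top_terms(object, k)
  tt$mlq <- -log10(pmax(tt$q, 1e-300))
  ggplot2::ggplot(tt, ggplot2::aes(x = .data$ef,
                                   y = stats::reorder(.data$term_name, -.data$log10_p),
                                   size = .data$k, colour = .data$mlq)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_viridis_c(name = expression(-log[10] * q)) +
    ggplot2::labs(x = "enrichment factor", y = NULL, size = "hit genes",
                  title = sprintf("Top %d %s terms", nrow(tt), object$category))
}

#' Heatmap of pairwise shared-target counts between compound classes
#'
#' @param object A `class_overlap`.
#' @param ... Unused.
#' @return A ggplot tile map; the diagonal holds per-class totals.
#' @exportS3Method ggplot2::autoplot
autoplot.class_overlap <- function(object, ...) {
  d <- tidy(object)
  d$class_a <- factor(d$class_a, levels = object$classes)
  d$class_b <- factor(d$class_b, levels = rev(object$classes))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class_a, y = .data$class_b,
                                  fill = .data$n_shared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_shared), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b",
                                 name = "shared targets") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Target overlap by %s", object$level)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Degree distribution of a tripartite network by layer
#'
#' Node positions are not drawn (layout is out of scope); the plot shows
#' how connectivity is distributed within each layer.
#'
#' @param object A `tripartite_network`.
#' @param ... Unused.
#' @return A ggplot of per-layer degree distributions.
#' @exportS3Method ggplot2::autoplot
autoplot.tripartite_network <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(object$nodes, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30, fill = "#2166ac") +
    ggplot2::facet_wrap(~layer, scales = "free") +
    ggplot2::labs(x = "degree", y = "nodes",
                  title = sprintf("%d nodes, %d edges", g$n_nodes, g$n_edges))
}
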