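#' Screen disease terms for the network stage
#'
#' Keeps disease terms that are both extremely enriched
#' (`log10(p) < max_log10_p`) and broadly matched (more than
#' `min_hit_genes` hit genes), ranks the survivors by p-value ascending,
#' and truncates to the `top_k` most significant.
#'
#' @param x A disease `enrichment` object or its tidy tibble.
#' @param top_k Number of diseases to keep (default 40).
#' @param max_log10_p Upper bound (strict `<`) on log10 p (default -70).
#' @param min_hit_genes Lower bound (strict `>`) on the hit-gene count
#'   (default 100).
#' @return Tibble of the selected disease rows (with their `hit_genes`
#'   list-column), sorted by significance.
#' @export
screen_diseases <- function(x, top_k = 40, max_log10_p = -70, min_hit_genes = 100) {
  if (top_k < 1) abort("`top_k` must be >= 1")
  res <- if (inherits(x, "enrichment")) tidy(x) else x
  assert_cols(res, c("term_id", "log10_p", "k"), "disease enrichment table")
  sel <- res %>%
    filter(.data$log10_p < max_log10_p, .data$k > min_hit_genes) %>%
    arrange(.data$log10_p, desc(.data$k), .data$term_id) %>%
    slice_head(n = top_k)
  if (nrow(sel) == 0) {
    abort(paste0("no disease term passes log10(p) < ", max_log10_p,
                 " and hit genes > ", min_hit_genes,
                 "; consider relaxing the thresholds"))
  }
  sel
}

#' Build the compound-target-disease network
#'
#' A tripartite, undirected, simple graph: one compound-target edge per
#' (compound, gene) pair of the target map, and one target-disease edge per
#' (gene, disease) with the gene among that disease's hit genes. Targets
#' with no disease edge are retained as isolated-in-the-upper-layer nodes.
#' Edges never connect nodes of the same layer and never skip the target
#' layer.
#'
#' @param map A `target_map` from [aggregate_targets()].
#' @param diseases Tibble of selected diseases from [screen_diseases()]
#'   (columns `term_id` and `hit_genes`).
#' @return A `tripartite_network`: `nodes` (tibble `id`, `layer`, `degree`)
#'   and `edges` (tibble `from`, `to`, `type` with type `"ct"` or `"td"`).
#'   `tidy()` returns the node table, `glance()` the node/edge counts per
#'   layer.
#' @export
build_network <- function(map, diseases) {
  if (nrow(map) == 0) abort("target map is empty")
  assert_cols(diseases, c("term_id", "hit_genes"), "disease table")
  if (nrow(diseases) == 0) abort("at least one selected disease is required")

  genes <- unique(map$gene)
  ct <- tibble(from = map$compound_id, to = map$gene, type = "ct")
  td <- diseases %>%
    select("term_id", "hit_genes") %>%
    tidyr::unnest_longer("hit_genes", values_to = "gene") %>%
    filter(.data$gene %in% genes) %>%
    distinct(.data$gene, .data$term_id) %>%
    transmute_edges()
  edges <- bind_rows(ct, td) %>%
    distinct(.data$from, .data$to, .data$type) %>%
    arrange(.data$type, .data$from, .data$to)
  nodes <- bind_rows(
    tibble(id = unique(map$compound_id), layer = "compound"),
    tibble(id = genes, layer = "target"),
    tibble(id = unique(diseases$term_id), layer = "disease")
  )
  if (anyDuplicated(nodes$id) > 0) {
    abort("node identifiers collide across layers; disambiguate term ids")
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$degree <- as.integer(deg[nodes$id])
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

transmute_edges <- function(x) {
  tibble(from = x$gene, to = x$term_id, type = "td")
}

#' @exportS3Method generics::tidy
tidy.tripartite_network <- function(x, ...) x$nodes

#' @exportS3Method generics::glance
glance.tripartite_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_compounds = sum(x$nodes$layer == "compound"),
    n_targets = sum(x$nodes$layer == "target"),
    n_diseases = sum(x$nodes$layer == "disease"),
    n_edges = nrow(x$edges),
    n_ct_edges = sum(x$edges$type == "ct"),
    n_td_edges = sum(x$edges$type == "td")
  )
}

#' @export
print.tripartite_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<tripartite_network> %d nodes (%d compounds, %d targets, %d diseases), %d edges\n",
              g$n_nodes, g$n_compounds, g$n_targets, g$n_diseases, g$n_edges))
  invisible(x)
}

#' Degree and content-weighted node scores
#'
#' Reports every node's degree and, for compounds with a known content
#' fraction, the content-weighted importance `degree x content_fraction`.
#' Compounds without content data keep `weighted_score = NA` and are ranked
#' by raw degree.
#'
#' @param network A `tripartite_network`.
#' @param catalog Compound catalog tibble (for `content_fraction`).
#' @return Tibble `id`, `layer`, `degree`, `content_fraction`,
#'   `weighted_score`, sorted within layer by weighted score (where
#'   available) then degree.
#' @export
score_nodes <- function(network, catalog = NULL) {
  stopifnot(inherits(network, "tripartite_network"))
  out <- network$nodes
  out$content_fraction <- NA_real_
  if (!is.null(catalog)) {
    assert_cols(catalog, c("compound_id", "content_fraction"), "catalog")
    idx <- match(out$id, catalog$compound_id)
    out$content_fraction <- ifelse(out$layer == "compound",
                                   catalog$content_fraction[idx], NA_real_)
  }
  out %>%
    mutate(weighted_score = if_else(.data$layer == "compound" &
                                      !is.na(.data$content_fraction),
                                    .data$degree * .data$content_fraction,
                                    NA_real_)) %>%
    arrange(.data$layer, desc(!is.na(.data$weighted_score)),
            desc(.data$weighted_score), desc(.data$degree), .data$id)
}

#' Induced subnetwork for a subset of compounds
#'
#' Keeps the given compounds, every target adjacent to at least one kept
#' compound, and every disease adjacent to at least one kept target;
#' degrees are recomputed on the induced graph.
#'
#' @param network A `tripartite_network`.
#' @param compounds Non-empty character vector of compound node ids.
#' @return A `tripartite_network`.
#' @export
subnetwork <- function(network, compounds) {
  stopifnot(inherits(network, "tripartite_network"))
  if (length(compounds) == 0) abort("compound subset must be non-empty")
  all_compounds <- network$nodes$id[network$nodes$layer == "compound"]
  unknown <- setdiff(compounds, all_compounds)
  if (length(unknown) > 0) {
    abort(sprintf("unknown compound node(s): %s", paste(unknown, collapse = ", ")))
  }
  ct <- filter(network$edges, .data$type == "ct", .data$from %in% compounds)
  kept_targets <- unique(ct$to)
  td <- filter(network$edges, .data$type == "td", .data$from %in% kept_targets)
  kept_diseases <- unique(td$to)
  edges <- bind_rows(ct, td) %>% arrange(.data$type, .data$from, .data$to)
  nodes <- bind_rows(
    tibble(id = intersect(all_compounds, compounds), layer = "compound"),
    tibble(id = kept_targets, layer = "target"),
    tibble(id = kept_diseases, layer = "disease")
  )
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$id))
  nodes$degree <- as.integer(deg[nodes$id])
  structure(list(nodes = nodes, edges = edges), class = "tripartite_network")
}

#' Export a network to Cytoscape-compatible files
#'
#' Writes SIF (interaction labels `ct` and `td`), GraphML (with `layer`,
#' `degree`, and `weighted_score` node attributes), or a sorted edge list
#' (CSV). Exports are deterministic: edges are written in
#' (type, from, to) lexicographic order.
#'
#' @param network A `tripartite_network`.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"`, or `"edgelist"`.
#' @param scores Optional node-score tibble from [score_nodes()]; its
#'   `weighted_score` is attached to GraphML nodes.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("sif", "graphml", "edgelist"),
                           scores = NULL) {
  stopifnot(inherits(network, "tripartite_network"))
  format <- match.arg(format)
  edges <- arrange(network$edges, .data$type, .data$from, .data$to)
  if (format == "sif") {
    readr::write_lines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to), path)
  } else if (format == "edgelist") {
    readr::write_csv(edges, path, progress = FALSE)
  } else {
    g <- as_igraph(network, scores)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a tripartite network to an igraph object
#'
#' @param network A `tripartite_network`.
#' @param scores Optional node scores from [score_nodes()].
#' @return An undirected `igraph` graph with `layer`, `degree`, and
#'   `weighted_score` vertex attributes and a `type` edge attribute.
#' @export
as_igraph <- function(network, scores = NULL) {
  stopifnot(inherits(network, "tripartite_network"))
  nodes <- network$nodes
  nodes$weighted_score <- NA_real_
  if (!is.null(scores)) {
    nodes$weighted_score <- scores$weighted_score[match(nodes$id, scores$id)]
  }
  igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = as.data.frame(nodes[, c("id", "layer", "degree", "weighted_score")])
  )
}
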