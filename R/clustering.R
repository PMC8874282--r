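#' Kappa-similarity clustering of enriched terms
#'
#' Groups the significant terms of an enrichment result by the similarity
#' of their hit-gene memberships. Pairwise Cohen's kappa is computed over
#' the union of hit genes across significant terms, the terms are
#' agglomerated hierarchically (average linkage by default) on distance
#' `1 - kappa`, and every maximal sub-tree whose merges all happen at
#' similarity strictly above the cut becomes one cluster. Singletons are
#' allowed. Each cluster is represented by its most significant member
#' (minimum p; ties broken by larger hit count, then term id).
#'
#' @param x An `enrichment` object with at least one significant term.
#' @param kappa_cut Similarity cut in (-1, 1); defaults to the value stored
#'   in the enrichment's config (0.3).
#' @param linkage Agglomeration rule: `"average"` (default), `"complete"`,
#'   or `"single"`.
#' @return A `term_clusters` object: `clusters` (tibble with `term_id`,
#'   `term_name`, `cluster`, `p`, `k`, `representative`), `kappa` (the
#'   symmetric similarity matrix), `kappa_cut`, `linkage`. `tidy()` returns
#'   the cluster tibble; `glance()` the cluster count.
#' @export
cluster_terms <- function(x, kappa_cut = NULL,
                          linkage = c("average", "complete", "single")) {
  stopifnot(inherits(x, "enrichment"))
  linkage <- match.arg(linkage)
  kappa_cut <- kappa_cut %||% x$config$kappa_cut
  res <- filter(tidy(x), .data$significant)
  if (nrow(res) == 0) abort("no significant terms to cluster")

  sets <- res$hit_genes
  names(sets) <- res$term_id
  kuni <- unique(unlist(sets))
  km <- kappa_matrix(sets, kuni)

  if (nrow(res) == 1) {
    groups <- setNames(1L, res$term_id)
  } else {
    # merge height = 1 - kappa; a merge at similarity > cut happens at
    # height < 1 - cut, so cut just below that height (strict ">")
    tree <- hclust(as.dist(1 - km), method = linkage)
    groups <- cutree(tree, h = (1 - kappa_cut) - 1e-9)
  }
  cl <- res %>%
    mutate(cluster = unname(groups[.data$term_id])) %>%
    group_by(.data$cluster) %>%
    mutate(representative = dplyr::row_number() ==
             order(.data$p, -.data$k, .data$term_id)[1]) %>%
    ungroup() %>%
    arrange(.data$cluster, .data$p, desc(.data$k), .data$term_id) %>%
    select("term_id", "term_name", "cluster", "p", "k", "representative")
  structure(
    list(clusters = cl, kappa = km, kappa_cut = kappa_cut, linkage = linkage),
    class = "term_clusters"
  )
}

# symmetric kappa matrix with unit diagonal over a fixed universe
kappa_matrix <- function(sets, universe) {
  m <- length(sets)
  km <- matrix(1, m, m, dimnames = list(names(sets), names(sets)))
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      km[i, j] <- km[j, i] <- kappa_similarity(sets[[i]], sets[[j]], universe)
    }
  }
  km
}

#' @exportS3Method generics::tidy
tidy.term_clusters <- function(x, ...) x$clusters

#' @exportS3Method generics::glance
glance.term_clusters <- function(x, ...) {
  tibble(n_terms = nrow(x$clusters),
         n_clusters = dplyr::n_distinct(x$clusters$cluster),
         kappa_cut = x$kappa_cut, linkage = x$linkage)
}

#' @export
print.term_clusters <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<term_clusters> %d terms in %d clusters (kappa > %.2f, %s linkage)\n",
              g$n_terms, g$n_clusters, g$kappa_cut, g$linkage))
  invisible(x)
}

#' Representative terms of each cluster
#'
#' @param x A `term_clusters` object.
#' @return Tibble of one row per cluster, its representative term.
#' @export
cluster_representatives <- function(x) {
  stopifnot(inherits(x, "term_clusters"))
  filter(x$clusters, .data$representative)
}
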