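#' Aggregate multi-source target predictions into a compound-to-gene map
#'
#' Restricts a prediction table to one species and to the candidate
#' compounds, then pools targets per compound as a union across prediction
#' sources (no consensus vote; a `min_sources` larger than 1 gives a
#' stricter variant). Provenance — which sources contributed each
#' (compound, gene) pair — is retained.
#'
#' @param predictions Prediction tibble from [read_target_predictions()].
#' @param candidates Character vector of candidate compound ids (from
#'   [screen_candidates()]).
#' @param species Taxon label to keep, matched exactly after whitespace
#'   normalization. Default `"Homo sapiens"`.
#' @param min_sources Minimum number of distinct sources required to keep a
#'   (compound, gene) pair. Default 1 (pure union).
#' @return A `target_map`: tibble with columns `compound_id`, `gene`,
#'   `n_sources`, `sources` (list-column), plus attributes `species` and
#'   `n_distinct_targets`. `glance()` gives the headline counts.
#' @export
aggregate_targets <- function(predictions, candidates,
                              species = "Homo sapiens", min_sources = 1) {
  assert_cols(predictions, c("compound_id", "gene", "source", "species"),
              "prediction table")
  if (length(candidates) == 0) abort("candidate set is empty")
  species <- normalize_species(species)
  kept <- predictions %>%
    mutate(species = normalize_species(.data$species),
           gene = normalize_gene(.data$gene)) %>%
    filter(.data$species == !!species)
  if (nrow(kept) == 0) {
    abort(sprintf("no predictions with species '%s'; check species labels", species))
  }
  map <- kept %>%
    filter(.data$compound_id %in% candidates) %>%
    group_by(.data$compound_id, .data$gene) %>%
    summarise(sources = list(sort(unique(.data$source))), .groups = "drop") %>%
    mutate(n_sources = lengths(.data$sources)) %>%
    filter(.data$n_sources >= min_sources) %>%
    arrange(.data$compound_id, .data$gene) %>%
    select("compound_id", "gene", "n_sources", "sources")
  structure(map,
            class = c("target_map", class(map)),
            species = species,
            n_distinct_targets = n_distinct(map$gene))
}

#' @exportS3Method generics::glance
glance.target_map <- function(x, ...) {
  tibble(
    n_compounds = n_distinct(x$compound_id),
    n_distinct_targets = n_distinct(x$gene),
    n_pairs = nrow(x),
    species = attr(x, "species")
  )
}

#' @export
print.target_map <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<target_map> %d compounds -> %d distinct targets (%d pairs, %s)\n",
              g$n_compounds, g$n_distinct_targets, g$n_pairs, g$species))
  NextMethod()
}

#' Per-class target sets and their pairwise overlaps
#'
#' Pools each class's targets (union over its compounds) and counts how many
#' targets every pair of classes shares. At `level = "flavone_subclass"`
#' only flavone compounds are partitioned; other classes are ignored.
#'
#' @param map A `target_map` from [aggregate_targets()].
#' @param catalog Compound catalog tibble.
#' @param level `"chem_class"` (default) or `"flavone_subclass"`.
#' @return A `class_overlap` object: `classes`, `target_sets` (named list),
#'   `totals`, and `shared` (symmetric matrix whose diagonal equals the
#'   totals). `tidy()` returns the pairwise counts in long form.
#' @export
class_overlap <- function(map, catalog, level = c("chem_class", "flavone_subclass")) {
  level <- match.arg(level)
  if (nrow(map) == 0) abort("target map is empty")
  assert_cols(catalog, c("compound_id", "chem_class", "flavone_subclass"),
              "catalog")
  if (level == "chem_class") {
    lab <- setNames(catalog$chem_class, catalog$compound_id)
    classes <- intersect(chem_classes(), unique(catalog$chem_class))
  } else {
    fl <- catalog[catalog$chem_class == "flavone" & !is.na(catalog$flavone_subclass), ]
    lab <- setNames(fl$flavone_subclass, fl$compound_id)
    classes <- intersect(flavone_subclasses(), unique(fl$flavone_subclass))
  }
  sets <- lapply(classes, function(cl) {
    ids <- names(lab)[lab == cl]
    sort(unique(map$gene[map$compound_id %in% ids]))
  })
  names(sets) <- classes
  k <- length(classes)
  shared <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    shared[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  structure(
    list(classes = classes, target_sets = sets,
         totals = setNames(lengths(sets), classes), shared = shared,
         level = level),
    class = "class_overlap"
  )
}

#' @exportS3Method generics::tidy
tidy.class_overlap <- function(x, ...) {
  as_tibble(as.data.frame(as.table(x$shared), stringsAsFactors = FALSE)) %>%
    setNames(c("class_a", "class_b", "n_shared")) %>%
    mutate(n_shared = as.integer(.data$n_shared))
}

#' @exportS3Method generics::glance
glance.class_overlap <- function(x, ...) {
  tibble(level = x$level, n_classes = length(x$classes),
         n_targets_union = length(unique(unlist(x$target_sets))))
}

#' @export
print.class_overlap <- function(x, ...) {
  cat(sprintf("<class_overlap> level=%s, %d classes, totals: %s\n", x$level,
              length(x$classes),
              paste(sprintf("%s=%d", x$classes, x$totals), collapse = ", ")))
  invisible(x)
}

#' Count per-class targets that fall in keyword-tagged enriched terms
#'
#' Tags every enriched term whose name matches any keyword
#' (case-insensitive substring), then counts, per compound class, how many
#' of the class's targets appear among the hit genes of at least one tagged
#' term. Used e.g. to ask what fraction of each class's targets sit in
#' brain-related disease terms.
#'
#' @param map A `target_map`.
#' @param catalog Compound catalog tibble.
#' @param enrichment An `enrichment` result (see [enrich()]); only
#'   significant terms are considered.
#' @param keywords Non-empty character vector of keywords.
#' @param level Class level passed to [class_overlap()].
#' @return A tibble with one row per class: `class`, `n_targets`,
#'   `n_tagged`, `fraction_tagged`.
#' @export
subset_by_term_tags <- function(map, catalog, enrichment, keywords,
                                level = c("chem_class", "flavone_subclass")) {
  level <- match.arg(level)
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    abort("keyword list must be non-empty")
  }
  res <- tidy(enrichment) %>% filter(.data$significant)
  pattern <- paste(vapply(keywords, function(k)
    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k), character(1)), collapse = "|")
  tagged <- res[grepl(pattern, res$term_name, ignore.case = TRUE), ]
  if (nrow(tagged) == 0) {
    warn("no enriched term name matches any keyword; all tagged counts are 0")
    tagged_genes <- character(0)
  } else {
    tagged_genes <- unique(unlist(tagged$hit_genes))
  }
  ov <- class_overlap(map, catalog, level)
  tibble(
    class = ov$classes,
    n_targets = as.integer(ov$totals),
    n_tagged = vapply(ov$target_sets,
                      function(s) length(intersect(s, tagged_genes)), integer(1)),
  ) %>%
    mutate(fraction_tagged = if_else(.data$n_targets > 0,
                                     .data$n_tagged / .data$n_targets, 0))
}
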