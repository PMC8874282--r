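#' Pipeline run configuration
#'
#' Collects every stage's configuration: input paths (or a synthetic-study
#' spec), the drug-likeness rules, the per-library enrichment settings, the
#' disease-screen thresholds, the output directory and the seed. The
#' configuration round-trips through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for every random draw.
#' @param synthetic `NULL`, or a (possibly empty) list of arguments for
#'   [synthetic_study()]; when set, inputs are generated rather than read.
#' @param paths Named list of input paths (`compounds`, `descriptors`,
#'   `predictions`, `disease_gmt`, `go_bp_gmt`, `go_mf_gmt`, `go_cc_gmt`,
#'   `kegg_gmt`) used when `synthetic` is `NULL`.
#' @param rules A [druglikeness_rules()] configuration.
#' @param disease_config [enrichment_config()] for the disease library.
#' @param go_config [enrichment_config()] for GO/KEGG libraries (default:
#'   BH-corrected p < 0.05).
#' @param screen List with `top_k`, `max_log10_p`, `min_hit_genes` for
#'   [screen_diseases()].
#' @param species Species retained during target aggregation.
#' @param top_k_terms How many top GO/KEGG terms to report (default 15).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, synthetic = list(), paths = NULL,
                       rules = druglikeness_rules(),
                       disease_config = enrichment_config(p_max = 0.01),
                       go_config = enrichment_config(p_max = 0.05,
                                                     use_adjusted = TRUE),
                       screen = list(top_k = 40, max_log10_p = -70,
                                     min_hit_genes = 100),
                       species = "Homo sapiens", top_k_terms = 15) {
  if (is.null(synthetic) && is.null(paths)) {
    abort("either `synthetic` or `paths` must be given")
  }
  if (!is.null(paths)) {
    need <- c("compounds", "descriptors", "predictions", "disease_gmt")
    missing <- setdiff(need, names(paths))
    if (length(missing) > 0) {
      abort(sprintf("paths is missing: %s", paste(missing, collapse = ", ")))
    }
    gone <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(gone) > 0) {
      abort(sprintf("input path(s) do not exist: %s", paste(gone, collapse = ", ")))
    }
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
         paths = paths, rules = rules, disease_config = disease_config,
         go_config = go_config, screen = screen, species = species,
         top_k_terms = top_k_terms),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' Threshold-bearing sub-configurations are stored as plain key-value maps;
#' reading reconstructs the typed objects.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- do.call(druglikeness_rules, y$rules %||% list())
  args <- list(
    out_dir = y$out_dir, seed = y$seed %||% 1,
    synthetic = y$synthetic, paths = y$paths, rules = rules,
    disease_config = do.call(enrichment_config, y$disease_config %||% list()),
    go_config = do.call(enrichment_config,
                        y$go_config %||% list(p_max = 0.05, use_adjusted = TRUE)),
    species = y$species %||% "Homo sapiens",
    top_k_terms = y$top_k_terms %||% 15
  )
  if (!is.null(y$screen)) args$screen <- y$screen
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  y <- list(
    out_dir = config$out_dir, seed = config$seed,
    synthetic = config$synthetic, paths = config$paths,
    rules = unclass(config$rules),
    disease_config = unclass(config$disease_config),
    go_config = unclass(config$go_config),
    screen = config$screen, species = config$species,
    top_k_terms = config$top_k_terms
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes catalog parsing, the candidate screen, target aggregation,
#' disease enrichment with kappa clustering, GO/KEGG enrichment on the same
#' hit genes, the disease screen, tripartite-network construction and
#' scoring, and the content-weighted subnetwork of the quantified
#' compounds. Every stage writes its table(s) under `out_dir` so any
#' downstream stage can be resumed from disk, and a plain-text summary
#' `report.txt` records the headline counts. Identical config and seed give
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return A `pipeline_report` list: per-stage counts, top terms, top
#'   nodes, and the paths of everything written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    inform(sprintf("[%s seed=%d] %s", stage, config$seed, sprintf(...)))
  }

  # --- inputs ---------------------------------------------------------
  if (!is.null(config$synthetic)) {
    study <- do.call(synthetic_study, c(list(seed = config$seed), config$synthetic))
    catalog <- study$catalog; profiles <- study$profiles
    predictions <- study$predictions; libraries <- study$libraries
    write_table(catalog, file.path(out, "catalog.csv"))
    write_table(profiles, file.path(out, "descriptors.csv"))
    write_table(predictions, file.path(out, "predictions.csv"))
    for (nm in names(libraries)) {
      write_gmt(libraries[[nm]], file.path(out, paste0(tolower(nm), ".gmt")))
    }
    log_stage("inputs", "generated synthetic study: %d compounds, %d prediction rows",
              nrow(catalog), nrow(predictions))
  } else {
    p <- config$paths
    catalog <- read_compound_table(p$compounds)
    profiles <- read_descriptor_table(p$descriptors)
    predictions <- read_target_predictions(p$predictions)
    libraries <- list(disease = read_gmt(p$disease_gmt, "disease"))
    for (nm in c("go_bp", "go_mf", "go_cc", "kegg")) {
      key <- paste0(nm, "_gmt")
      if (!is.null(p[[key]])) {
        libraries[[toupper(sub("go", "GO", nm))]] <-
          read_gmt(p[[key]], toupper(sub("go", "GO", nm)))
      }
    }
    names(libraries) <- sub("GO_BP", "GO_BP", names(libraries))
    digests <- tools::md5sum(unlist(p))
    log_stage("inputs", "read %d input file(s); md5: %s", length(digests),
              paste(basename(names(digests)), unname(digests), sep = "=",
                    collapse = ", "))
  }

  # --- candidate screen ----------------------------------------------
  scr <- screen_candidates(profiles, config$rules)
  write_table(scr$verdicts, file.path(out, "verdicts.csv"))
  write_table(scr$rule_summary, file.path(out, "rule_summary.csv"))
  readr::write_lines(scr$candidates, file.path(out, "candidates.txt"))
  log_stage("druglikeness", "%d / %d compounds pass the candidate gate",
            length(scr$candidates), nrow(profiles))

  # --- target aggregation --------------------------------------------
  map <- aggregate_targets(predictions, scr$candidates, config$species)
  write_table(
    map %>% mutate(sources = vapply(.data$sources, paste, "", collapse = ";")) %>%
      as_tibble(),
    file.path(out, "target_map.csv")
  )
  n_targets <- attr(map, "n_distinct_targets")
  log_stage("targets", "%d distinct targets over %d candidate compounds",
            n_targets, n_distinct(map$compound_id))
  hits <- unique(map$gene)

  # --- enrichment -----------------------------------------------------
  enr <- list()
  for (nm in names(libraries)) {
    cfg <- if (nm == "disease") config$disease_config else config$go_config
    enr[[nm]] <- enrich(hits, libraries[[nm]], cfg)
    res_out <- tidy(enr[[nm]]) %>%
      mutate(hit_genes = vapply(.data$hit_genes, paste, "", collapse = ";"))
    write_table(res_out, file.path(out, paste0("enrichment_", tolower(nm), ".csv")))
    log_stage("enrichment", "%s: %d significant of %d terms with hits", nm,
              sum(tidy(enr[[nm]])$significant), nrow(tidy(enr[[nm]])))
  }
  clusters <- NULL
  if (sum(tidy(enr$disease)$significant) > 0) {
    clusters <- cluster_terms(enr$disease)
    write_table(tidy(clusters), file.path(out, "disease_clusters.csv"))
  }
  top_go <- purrr::imap(enr[setdiff(names(enr), "disease")], function(e, nm) {
    top_terms(e, config$top_k_terms, significant_only = TRUE) %>%
      select(-"hit_genes") %>%
      mutate(library = nm, .before = 1)
  })
  if (length(top_go) > 0) {
    write_table(bind_rows(top_go), file.path(out, "top_terms.csv"))
  }

  # --- disease screen and network ------------------------------------
  sel <- screen_diseases(enr$disease, top_k = config$screen$top_k,
                         max_log10_p = config$screen$max_log10_p,
                         min_hit_genes = config$screen$min_hit_genes)
  write_table(select(sel, -"hit_genes"), file.path(out, "selected_diseases.csv"))
  log_stage("network", "%d diseases selected for the network", nrow(sel))

  net <- build_network(map, sel)
  scores <- score_nodes(net, catalog)
  write_table(scores, file.path(out, "network_nodes.csv"))
  write_table(net$edges, file.path(out, "network_edges.csv"))
  export_network(net, file.path(out, "network.sif"), "sif")
  export_network(net, file.path(out, "network.graphml"), "graphml", scores = scores)

  content_ids <- catalog$compound_id[!is.na(catalog$content_fraction) &
                                       catalog$compound_id %in% scr$candidates]
  sub <- NULL; sub_scores <- NULL
  if (length(content_ids) > 0) {
    sub <- subnetwork(net, content_ids)
    sub_scores <- score_nodes(sub, catalog)
    write_table(sub_scores, file.path(out, "subnetwork_nodes.csv"))
    export_network(sub, file.path(out, "subnetwork.sif"), "sif")
    log_stage("network", "content-weighted subnetwork: %d compounds, %d nodes",
              length(content_ids), nrow(sub$nodes))
  }

  report <- structure(
    list(
      seed = config$seed,
      counts = tibble(
        n_compounds = nrow(catalog),
        n_candidates = length(scr$candidates),
        n_distinct_targets = n_targets,
        n_significant_diseases = sum(tidy(enr$disease)$significant),
        n_disease_clusters = if (is.null(clusters)) 0L else
          glance(clusters)$n_clusters,
        n_selected_diseases = nrow(sel),
        n_network_nodes = glance(net)$n_nodes,
        n_network_edges = glance(net)$n_edges,
        n_subnetwork_nodes = if (is.null(sub)) NA_integer_ else
          glance(sub)$n_nodes,
        n_subnetwork_edges = if (is.null(sub)) NA_integer_ else
          glance(sub)$n_edges
      ),
      screen = scr, target_map = map, enrichment = enr, clusters = clusters,
      selected_diseases = sel, network = net, scores = scores,
      subnetwork = sub, subnetwork_scores = sub_scores,
      out_dir = out
    ),
    class = "pipeline_report"
  )
  write_report_text(report, file.path(out, "report.txt"))
  report
}

write_report_text <- function(report, path) {
  c0 <- report$counts
  lines <- c(
    "network-pharmacology pipeline report",
    sprintf("seed: %d", report$seed),
    sprintf("compounds cataloged: %d", c0$n_compounds),
    sprintf("candidate compounds (HIA & bioavailability gate): %d", c0$n_candidates),
    sprintf("distinct predicted targets: %d", c0$n_distinct_targets),
    sprintf("significant disease terms: %d", c0$n_significant_diseases),
    sprintf("disease term clusters: %d", c0$n_disease_clusters),
    sprintf("diseases selected for the network: %d", c0$n_selected_diseases),
    sprintf("network nodes: %d", c0$n_network_nodes),
    sprintf("network edges: %d", c0$n_network_edges),
    if (!is.na(c0$n_subnetwork_nodes)) {
      sprintf("content-weighted subnetwork nodes: %d / edges: %d",
              c0$n_subnetwork_nodes, c0$n_subnetwork_edges)
    },
    "top compounds by degree:",
    report_top_lines(report$scores, "compound"),
    "top targets by degree:",
    report_top_lines(report$scores, "target")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

report_top_lines <- function(scores, layer, k = 10) {
  s <- scores[scores$layer == layer, ]
  s <- head(s[order(-s$degree, s$id), ], k)
  sprintf("  %s degree=%d%s", s$id, s$degree,
          ifelse(is.na(s$weighted_score), "",
                 sprintf(" weighted=%.3f", s$weighted_score)))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$counts)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.pipeline_report <- function(x, ...) x$counts
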