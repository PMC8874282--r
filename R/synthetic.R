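#' Generate a synthetic compound catalog
#'
#' Emulates the catalog of a multi-compound herbal extract: nine chemical
#' classes in proportions matching a flavone-rich plant extract (roughly
#' half flavones, then phenylpropanoids and phenols), six flavone
#' subclasses, placeholder SMILES strings, and a small set of
#' high-content compounds carrying most of the extract mass.
#'
#' @param n Number of compounds (default 131).
#' @param seed Integer seed; identical seeds give identical catalogs.
#' @param n_content Number of compounds with a known content fraction
#'   (default 10).
#' @param content_total Total extract mass fraction carried by the
#'   quantified compounds (default 0.7).
#' @return A list with `catalog` (tibble) and `truth` (list with
#'   `content_ids` and the per-class counts).
#' @export
gen_compound_catalog <- function(n = 131, seed = 1, n_content = 10,
                                 content_total = 0.7) {
  base <- c(phenylpropanoid = 17, phenol = 11, polyacetylene = 7,
            terpenoid = 6, steroid = 4, alkaloid = 2, phenylethanoid = 1,
            anthraquinone = 5, flavone = 57)
  counts <- largest_remainder(base, n)
  sub_base <- c(chalcone = 11, flavanone = 24, flavone = 6, flavonol = 9,
                flavanol = 2, aurone = 5)
  sub_counts <- largest_remainder(sub_base, counts[["flavone"]])
  withr::with_seed(seed, {
    classes <- rep(names(counts), counts)
    subclasses <- rep(NA_character_, n)
    subclasses[classes == "flavone"] <- rep(names(sub_counts), sub_counts)
    frags <- c("C1=CC=CC=C1", "CC(=O)O", "OC1=CC=CC=C1O", "C=CC#C",
               "CC1CCC2CCCCC2C1", "COC1=CC=CC=C1")
    smiles <- paste0(sample(frags, n, replace = TRUE),
                     sample(frags, n, replace = TRUE))
    catalog <- tibble(
      compound_id = sprintf("C%03d", seq_len(n)),
      name = sprintf("compound-%03d", seq_len(n)),
      smiles = smiles,
      chem_class = classes,
      flavone_subclass = subclasses,
      content_fraction = NA_real_
    )
    # the quantified compounds are flavones (plus one flavonol stand-in for
    # a quercetin-like constituent), as in a flavone-dominated extract
    flavone_ids <- catalog$compound_id[catalog$chem_class == "flavone"]
    content_ids <- sample(flavone_ids, min(n_content, length(flavone_ids)))
    w <- runif(length(content_ids), 0.5, 2)
    catalog$content_fraction[match(content_ids, catalog$compound_id)] <-
      content_total * w / sum(w)
    list(catalog = catalog,
         truth = list(seed = seed, content_ids = sort(content_ids),
                      class_counts = counts, subclass_counts = sub_counts))
  })
}

# integer allocation proportional to weights, exact total
largest_remainder <- function(weights, total) {
  q <- weights / sum(weights) * total
  fl <- floor(q)
  rem <- total - sum(fl)
  if (rem > 0) {
    add <- order(q - fl, decreasing = TRUE)[seq_len(rem)]
    fl[add] <- fl[add] + 1
  }
  setNames(as.integer(fl), names(weights))
}

#' Generate a descriptor table with a planted candidate-gate outcome
#'
#' Exactly `n_pass` rows satisfy the candidate gate (HIA > 25 and
#' bioavailability > 0.15); every failing row violates at least one of the
#' two gates. Physicochemical descriptors are drawn uniformly over windows
#' extending 20% beyond each drug-likeness rule window on both sides, so
#' individual physicochemical flags fail independently of the gate.
#'
#' @param n_total Number of compounds (default 131).
#' @param n_pass Number of gate-passing compounds (default 110).
#' @param seed Integer seed.
#' @param compound_ids Optional explicit ids (defaults to `C001`...).
#' @return A list with `profiles` (descriptor tibble) and `truth` (list
#'   with `pass_ids` and `fail_ids`).
#' @export
gen_descriptor_table <- function(n_total = 131, n_pass = 110, seed = 1,
                                 compound_ids = NULL) {
  if (n_pass < 0 || n_pass > n_total) abort("need 0 <= n_pass <= n_total")
  ids <- compound_ids %||% sprintf("C%03d", seq_len(n_total))
  stopifnot(length(ids) == n_total)
  withr::with_seed(seed, {
    pass <- sort(sample(seq_len(n_total), n_pass))
    is_pass <- seq_len(n_total) %in% pass
    hia <- numeric(n_total); bio <- numeric(n_total)
    hia[is_pass] <- runif(n_pass, 26, 99)
    bio[is_pass] <- runif(n_pass, 0.17, 0.85)
    n_fail <- n_total - n_pass
    if (n_fail > 0) {
      # failure mode: 1 = low HIA, 2 = low bioavailability, 3 = both
      mode <- sample(1:3, n_fail, replace = TRUE)
      hia[!is_pass] <- ifelse(mode != 2, runif(n_fail, 0, 24),
                              runif(n_fail, 26, 99))
      bio[!is_pass] <- ifelse(mode != 1, runif(n_fail, 0.01, 0.14),
                              runif(n_fail, 0.17, 0.85))
    }
    profiles <- tibble(
      compound_id = ids,
      xlogp3 = runif(n_total, -1.84, 6.14),
      mw = runif(n_total, 80, 570),
      tpsa = runif(n_total, 0, 152),
      log_s = runif(n_total, -7.4, 0.5),
      n_rot_bonds = sample(0:12, n_total, replace = TRUE),
      fsp3 = runif(n_total, 0, 1),
      hia = hia,
      bbb = runif(n_total, -1.6, 1.2),
      bioavailability = bio,
      pgp_substrate = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      cyp1a2 = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      cyp2c19 = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      cyp2c9 = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      cyp2d6 = sample(c(TRUE, FALSE), n_total, replace = TRUE),
      cyp3a4 = sample(c(TRUE, FALSE), n_total, replace = TRUE)
    )
    list(profiles = profiles,
         truth = list(seed = seed, pass_ids = ids[is_pass],
                      fail_ids = ids[!is_pass]))
  })
}

#' Generate class-structured target predictions with planted ground truth
#'
#' Each chemical class draws its targets from a class pool; pools share a
#' common overlap pool covering roughly `overlap` of the distinct-target
#' union. The union of genes over the candidate compounds is exactly
#' `distinct_total`. Optionally a set of hub genes is attached to every
#' candidate so the highest-degree targets are known, and decoy rows (other
#' species, non-candidate compounds) exercise the downstream filters.
#'
#' @param catalog Compound catalog tibble.
#' @param candidates Character vector of candidate compound ids.
#' @param distinct_total Exact number of distinct genes over candidates
#'   (default 1011).
#' @param targets_per_compound Targets drawn per candidate (default 25).
#' @param overlap Fraction of the union placed in the shared pool, in
#'   \[0, 1\] (default 0.25); 0 gives pairwise-disjoint class pools, 1 gives
#'   identical pools.
#' @param n_hubs Number of hub genes attached to every candidate
#'   (default 0).
#' @param seed Integer seed.
#' @param decoys Add other-species and non-candidate rows (default `TRUE`).
#' @return A list with `predictions` (tibble) and `truth` (pools, shared
#'   pool, hub genes, per-compound assignments).
#' @export
gen_target_predictions <- function(catalog, candidates, distinct_total = 1011,
                                   targets_per_compound = 25, overlap = 0.25,
                                   n_hubs = 0, seed = 1, decoys = TRUE) {
  cand <- catalog[catalog$compound_id %in% candidates, ]
  if (nrow(cand) == 0) abort("no catalog rows match the candidate set")
  withr::with_seed(seed, {
    genes <- sprintf("G%06d", seq_len(distinct_total))
    classes <- unique(cand$chem_class)
    n_shared <- round(overlap * distinct_total)
    shared <- genes[seq_len(n_shared)]
    rest <- setdiff(genes, shared)
    cls_n <- table(cand$chem_class)[classes]
    alloc <- largest_remainder(as.numeric(cls_n), length(rest))
    names(alloc) <- classes
    pools <- list(); used <- 0
    for (cl in classes) {
      part <- rest[seq_len(alloc[[cl]]) + used]
      used <- used + alloc[[cl]]
      pools[[cl]] <- c(part, shared)
    }
    short <- classes[vapply(pools, length, integer(1)) < targets_per_compound]
    if (length(short) > 0) {
      abort(sprintf("distinct_total too small: class pool(s) %s have fewer than %d genes",
                    paste(short, collapse = ", "), targets_per_compound))
    }
    hubs <- if (n_hubs > 0) {
      if (n_hubs > length(shared)) abort("n_hubs exceeds the shared pool size")
      shared[seq_len(n_hubs)]
    } else character(0)
    assign <- lapply(seq_len(nrow(cand)), function(i) {
      pool <- pools[[cand$chem_class[i]]]
      unique(c(sample(pool, targets_per_compound), hubs))
    })
    names(assign) <- cand$compound_id
    # coverage fix: every gene of the union must be hit by >= 1 candidate
    uncovered <- setdiff(genes, unique(unlist(assign)))
    for (g in uncovered) {
      host <- names(pools)[vapply(pools, function(p) g %in% p, logical(1))]
      pick <- sample(cand$compound_id[cand$chem_class %in% host], 1)
      assign[[pick]] <- c(assign[[pick]], g)
    }
    rows <- purrr::map2_dfr(names(assign), assign, function(id, gs) {
      n_src <- sample(1:3, length(gs), replace = TRUE)
      tibble(compound_id = id, gene = rep(gs, n_src)) %>%
        group_by(.data$compound_id, .data$gene) %>%
        mutate(source = sample(target_sources(), dplyr::n())) %>%
        ungroup()
    })
    rows$species <- "Homo sapiens"
    if (decoys) {
      non_cand <- setdiff(catalog$compound_id, candidates)
      decoy <- bind_rows(
        if (length(non_cand) > 0) tibble(
          compound_id = sample(non_cand, min(5, length(non_cand))),
          gene = sample(genes, min(5, length(non_cand))),
          source = "SEA", species = "Homo sapiens"),
        tibble(compound_id = sample(cand$compound_id, 5),
               gene = sample(genes, 5),
               source = "STITCH", species = "Rattus norvegicus")
      )
      rows <- bind_rows(rows, decoy)
    }
    rows <- arrange(rows, .data$compound_id, .data$gene, .data$source)
    list(predictions = rows,
         truth = list(seed = seed, pools = pools, shared_pool = shared,
                      hub_genes = hubs, assignments = assign,
                      distinct_total = distinct_total))
  })
}

#' Generate a gene-set library with planted structure
#'
#' Builds a GMT-ready library of random terms over a synthetic universe,
#' optionally with (a) planted terms biased toward a supplied gene pool
#' (for enrichment-recovery experiments) and (b) term families sharing a
#' common core (within-family Jaccard around `core / (core + 2 * extra)`,
#' across-family near zero) for clustering-recovery experiments.
#'
#' @param n_terms Total number of terms (default 200), including any
#'   planted or family terms.
#' @param size_range Inclusive term-size range (default `c(10, 50)`).
#' @param universe_size Universe size when `universe` is not supplied
#'   (default 2000).
#' @param universe Optional explicit gene universe (character vector).
#' @param planted Optional list `list(n, size_range, pool, pool_fraction)`:
#'   `n` terms draw `pool_fraction` of their genes from `pool`.
#' @param n_families,terms_per_family,family_core,family_extra Family
#'   structure: each family has a random core of `family_core` genes and
#'   each member term adds `family_extra` private genes.
#' @param category Library category label.
#' @param seed Integer seed.
#' @return A list with `library` (a `gene_set_library`) and `truth`
#'   (planted term ids, family membership, universe).
#' @export
gen_geneset_library <- function(n_terms = 200, size_range = c(10, 50),
                                universe_size = 2000, universe = NULL,
                                planted = NULL, n_families = 0,
                                terms_per_family = 4, family_core = 32,
                                family_extra = 4,
                                category = "disease", seed = 1) {
  uni <- universe %||% sprintf("G%06d", seq_len(universe_size))
  if (length(uni) < max(size_range)) {
    abort("universe too small for the requested term sizes")
  }
  n_family_terms <- n_families * terms_per_family
  n_planted <- if (is.null(planted)) 0 else planted$n
  if (n_family_terms + n_planted > n_terms) {
    abort("family and planted terms exceed n_terms")
  }
  withr::with_seed(seed, {
    ids <- sprintf("%s%04d", substr(toupper(category), 1, 1), seq_len(n_terms))
    sets <- vector("list", n_terms)
    names(sets) <- ids
    i <- 1
    family_members <- list()
    if (n_families > 0) {
      if (length(uni) < family_core + family_extra) {
        abort("universe too small for the family core size")
      }
      for (f in seq_len(n_families)) {
        core <- sample(uni, family_core)
        members <- character(terms_per_family)
        for (m in seq_len(terms_per_family)) {
          extra <- sample(setdiff(uni, core), family_extra)
          sets[[i]] <- sort(c(core, extra))
          members[m] <- ids[i]
          i <- i + 1
        }
        family_members[[paste0("family", f)]] <- members
      }
    }
    planted_ids <- character(0)
    if (n_planted > 0) {
      pr <- planted$size_range %||% size_range
      frac <- planted$pool_fraction %||% 0.7
      pool <- intersect(planted$pool, uni)
      if (length(pool) == 0) abort("planted pool has no genes in the universe")
      for (p in seq_len(n_planted)) {
        sz <- sample(seq(pr[1], pr[2]), 1)
        n_pool <- min(round(frac * sz), length(pool))
        sets[[i]] <- sort(unique(c(sample(pool, n_pool),
                                   sample(setdiff(uni, pool), sz - n_pool))))
        planted_ids <- c(planted_ids, ids[i])
        i <- i + 1
      }
    }
    while (i <= n_terms) {
      sz <- sample(seq(size_range[1], size_range[2]), 1)
      sets[[i]] <- sort(sample(uni, sz))
      i <- i + 1
    }
    lib <- gene_set_library(
      category = category, sets = sets,
      term_names = setNames(sprintf("%s term %04d", category, seq_len(n_terms)), ids),
      universe = uni
    )
    list(library = lib,
         truth = list(seed = seed, planted_ids = planted_ids,
                      family_members = family_members, universe = uni))
  })
}

#' Generate a hit-gene list with a planted enrichment signal
#'
#' Draws `ceiling(effect * n_hits)` genes without replacement from the
#' union of the planted terms' gene sets and the remainder uniformly from
#' the rest of the universe. `effect = 0` gives a pure null list.
#'
#' @param library A `gene_set_library`.
#' @param planted_terms Character vector of term ids whose union supplies
#'   the signal genes (may be empty when `effect = 0`).
#' @param effect Fraction of hits drawn from the planted union, in \[0, 1\].
#' @param n_hits Number of hit genes.
#' @param seed Integer seed.
#' @return A list with `hits` (character vector) and `truth`.
#' @export
gen_hit_list <- function(library, planted_terms = character(0), effect = 0,
                         n_hits = 100, seed = 1) {
  stopifnot(inherits(library, "gene_set_library"))
  if (effect < 0 || effect > 1) abort("effect must be in [0, 1]")
  pool <- unique(unlist(library$sets[planted_terms], use.names = FALSE))
  n_signal <- ceiling(effect * n_hits)
  if (n_signal > length(pool)) {
    abort("planted-term union is smaller than the required signal draw")
  }
  if (n_hits > length(library$universe)) {
    abort("n_hits exceeds the universe size")
  }
  withr::with_seed(seed, {
    signal <- if (n_signal > 0) sample(pool, n_signal) else character(0)
    rest <- sample(setdiff(library$universe, signal), n_hits - n_signal)
    hits <- sample(c(signal, rest))  # shuffle so order carries no signal
    list(hits = hits,
         truth = list(seed = seed, planted_terms = planted_terms,
                      effect = effect, signal_genes = sort(signal)))
  })
}

#' Generate a complete synthetic study
#'
#' Produces every input of the pipeline at the scale of a flavone-rich
#' extract study — 131 cataloged compounds of which 110 pass the candidate
#' gate, 1,011 distinct human targets, a disease library in which at least
#' `top_k` terms are overwhelmingly enriched for the target pool over a
#' genome-sized background, and GO/KEGG-style libraries with planted
#' signal — together with the full ground truth.
#'
#' @param seed Integer seed driving every draw.
#' @param n_compounds,n_pass Catalog size and planted gate passers.
#' @param distinct_targets Distinct-target union over candidates.
#' @param genome_size Background universe for disease/GO/KEGG libraries.
#' @param n_disease_terms,n_strong_diseases Disease-library size and the
#'   number of terms planted to pass the network disease screen.
#' @return A list with `catalog`, `profiles`, `predictions`, `libraries`
#'   (disease, GO_BP, GO_MF, GO_CC, KEGG), and `truth`.
#' @export
synthetic_study <- function(seed = 1, n_compounds = 131, n_pass = 110,
                            distinct_targets = 1011, genome_size = 20000,
                            n_disease_terms = 120, n_strong_diseases = 48) {
  cat_gen <- gen_compound_catalog(n_compounds, seed = seed)
  desc_gen <- gen_descriptor_table(n_compounds, n_pass, seed = seed + 1,
                                   compound_ids = cat_gen$catalog$compound_id)
  pred_gen <- gen_target_predictions(
    cat_gen$catalog, desc_gen$truth$pass_ids,
    distinct_total = distinct_targets, targets_per_compound = 25,
    overlap = 0.25, n_hubs = 10, seed = seed + 2
  )
  target_genes <- sprintf("G%06d", seq_len(distinct_targets))
  genome <- c(target_genes,
              sprintf("B%06d", seq_len(genome_size - distinct_targets)))
  disease_gen <- gen_geneset_library(
    n_terms = n_disease_terms, size_range = c(60, 200), universe = genome,
    planted = list(n = n_strong_diseases, size_range = c(220, 320),
                   pool = target_genes, pool_fraction = 0.7),
    category = "disease", seed = seed + 3
  )
  go_bp <- gen_geneset_library(
    n_terms = 150, size_range = c(20, 150), universe = genome,
    planted = list(n = 25, size_range = c(40, 150), pool = target_genes,
                   pool_fraction = 0.5),
    category = "GO_BP", seed = seed + 4
  )
  go_mf <- gen_geneset_library(
    n_terms = 80, size_range = c(15, 120), universe = genome,
    planted = list(n = 15, size_range = c(30, 120), pool = target_genes,
                   pool_fraction = 0.5),
    category = "GO_MF", seed = seed + 5
  )
  go_cc <- gen_geneset_library(
    n_terms = 80, size_range = c(15, 120), universe = genome,
    planted = list(n = 15, size_range = c(30, 120), pool = target_genes,
                   pool_fraction = 0.5),
    category = "GO_CC", seed = seed + 6
  )
  kegg <- gen_geneset_library(
    n_terms = 100, size_range = c(20, 150), universe = genome,
    planted = list(n = 20, size_range = c(40, 150), pool = target_genes,
                   pool_fraction = 0.5),
    category = "KEGG", seed = seed + 7
  )
  list(
    catalog = cat_gen$catalog,
    profiles = desc_gen$profiles,
    predictions = pred_gen$predictions,
    libraries = list(disease = disease_gen$library, GO_BP = go_bp$library,
                     GO_MF = go_mf$library, GO_CC = go_cc$library,
                     KEGG = kegg$library),
    truth = list(seed = seed, catalog = cat_gen$truth,
                 descriptors = desc_gen$truth, predictions = pred_gen$truth,
                 disease = disease_gen$truth,
                 go_bp = go_bp$truth, go_mf = go_mf$truth,
                 go_cc = go_cc$truth, kegg = kegg$truth)
  )
}
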