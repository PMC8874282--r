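toy_predictions <- function() {
  tibble::tibble(
    compound_id = c("C001", "C001", "C001", "C002", "C999"),
    gene = c("AKT1", "akt1", "TNF", "VEGFA", "EGFR"),
    source = c("SEA", "STITCH", "SwissTargetPrediction", "SEA", "SEA"),
    species = c("Homo sapiens", "Homo  sapiens", "Homo sapiens",
                "Rattus norvegicus", "Homo sapiens")
  )
}

test_that("aggregation unions sources per compound after the species filter", {
  map <- aggregate_targets(toy_predictions(), candidates = c("C001", "C002"))
  expect_equal(sort(map$gene[map$compound_id == "C001"]), c("AKT1", "TNF"))
  expect_equal(map$n_sources[map$gene == "AKT1"], 2L)
  # C002's only row is another species; C999 is not a candidate
  expect_false("C002" %in% map$compound_id)
  expect_false("C999" %in% map$compound_id)
  expect_equal(attr(map, "n_distinct_targets"), 2L)

  expect_error(aggregate_targets(toy_predictions(), "C001", species = "Mus musculus"),
               "species")
  strict <- aggregate_targets(toy_predictions(), c("C001", "C002"), min_sources = 2)
  expect_equal(strict$gene, "AKT1")
})

test_that("a planted prediction table yields the planted distinct-target union", {
  catalog <- gen_compound_catalog(131, seed = 1)$catalog
  cand <- gen_descriptor_table(131, 110, seed = 2,
                               compound_ids = catalog$compound_id)$truth$pass_ids
  gen <- gen_target_predictions(catalog, cand, distinct_total = 1011,
                                targets_per_compound = 25, seed = 3)
  map <- aggregate_targets(gen$predictions, cand)
  expect_equal(attr(map, "n_distinct_targets"), 1011L)
  expect_equal(dplyr::n_distinct(map$gene), 1011L)
  # union monotonicity: an extra row can only add pairs
  extra <- dplyr::bind_rows(gen$predictions,
                            tibble::tibble(compound_id = cand[1], gene = "ZNEW",
                                           source = "SEA", species = "Homo sapiens"))
  map2 <- aggregate_targets(extra, cand)
  expect_true(all(paste(map$compound_id, map$gene) %in%
                    paste(map2$compound_id, map2$gene)))
})

test_that("class overlap counts shared targets with a symmetric matrix", {
  catalog <- toy_catalog()
  map <- aggregate_targets(tibble::tibble(
    compound_id = c("C001", "C001", "C001", "C003", "C003", "C003"),
    gene = c("A", "B", "C", "B", "C", "D"),
    source = "SEA", species = "Homo sapiens"
  ), candidates = catalog$compound_id)
  ov <- class_overlap(map, catalog)
  expect_equal(unname(ov$shared["flavone", "polyacetylene"]), 2L)
  expect_equal(unname(ov$totals[c("flavone", "polyacetylene")]), c(3L, 3L))
  # a class with no compounds in the map has zero totals and shares
  expect_equal(unname(ov$totals["phenol"]), 0L)
  expect_true(all(ov$shared[, "phenol"] == 0))
  expect_true(isSymmetric(ov$shared))
  expect_equal(unname(diag(ov$shared)), unname(ov$totals))

  # subclass level partitions flavones only; an aurone with no mapped
  # targets keeps a zero total
  sub <- class_overlap(map, catalog, level = "flavone_subclass")
  expect_setequal(sub$classes, c("chalcone", "aurone"))
  expect_equal(unname(sub$totals[["aurone"]]), 0L)
  expect_error(class_overlap(map, catalog, level = "nope"))
})

test_that("disjoint planted class pools give an all-zero off-diagonal", {
  catalog <- gen_compound_catalog(30, seed = 4)$catalog
  gen <- gen_target_predictions(catalog, catalog$compound_id,
                                distinct_total = 300, targets_per_compound = 10,
                                overlap = 0, seed = 5, decoys = FALSE)
  ov <- class_overlap(aggregate_targets(gen$predictions, catalog$compound_id),
                      catalog)
  off <- ov$shared; diag(off) <- 0L
  expect_true(all(off == 0))

  # full overlap with identical pools exhausted by every compound:
  # every class carries the same target set, so shared counts equal totals
  gen1 <- gen_target_predictions(catalog, catalog$compound_id,
                                 distinct_total = 60, targets_per_compound = 60,
                                 overlap = 1, seed = 6, decoys = FALSE)
  ov1 <- class_overlap(aggregate_targets(gen1$predictions, catalog$compound_id),
                       catalog)
  expect_true(all(ov1$shared == 60L))
  expect_equal(unname(diag(ov1$shared)), unname(ov1$totals))
})

test_that("keyword tagging counts per-class targets inside tagged terms", {
  catalog <- gen_compound_catalog(20, seed = 8)$catalog
  gen <- gen_target_predictions(catalog, catalog$compound_id,
                                distinct_total = 120, targets_per_compound = 12,
                                seed = 9, decoys = FALSE)
  map <- aggregate_targets(gen$predictions, catalog$compound_id)
  ov <- class_overlap(map, catalog)
  # one disease term per class holding >= 2/3 of that class's targets
  sets <- lapply(ov$target_sets, function(s) s[seq_len(ceiling(2 / 3 * length(s)) + 1)])
  names(sets) <- sprintf("BR%02d", seq_along(sets))
  nms <- setNames(sprintf("brain disease of class %s", ov$classes), names(sets))
  filler <- sprintf("F%04d", 1:500)
  lib <- gene_set_library("disease", sets, term_names = nms,
                          universe = c(map$gene, filler))
  enr <- enrich(unique(map$gene), lib,
                enrichment_config(p_max = 0.01, min_count = 3, ef_min = 1.5))
  tagged <- subset_by_term_tags(map, catalog, enr, keywords = c("brain", "memory"))
  expect_true(all(tagged$fraction_tagged >= 2 / 3))

  expect_error(subset_by_term_tags(map, catalog, enr, keywords = character(0)),
               "non-empty")
  expect_warning(z <- subset_by_term_tags(map, catalog, enr, "xyzzy"), "keyword")
  expect_true(all(z$n_tagged == 0))
})
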