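test_that("generators are byte-deterministic given the seed", {
  a <- gen_descriptor_table(50, 30, seed = 7)
  b <- gen_descriptor_table(50, 30, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$profiles,
                         gen_descriptor_table(50, 30, seed = 8)$profiles))

  cat_ <- gen_compound_catalog(30, seed = 7)
  expect_identical(cat_, gen_compound_catalog(30, seed = 7))

  p1 <- gen_target_predictions(cat_$catalog, cat_$catalog$compound_id,
                               distinct_total = 100, targets_per_compound = 8,
                               seed = 7)
  p2 <- gen_target_predictions(cat_$catalog, cat_$catalog$compound_id,
                               distinct_total = 100, targets_per_compound = 8,
                               seed = 7)
  expect_identical(p1$predictions, p2$predictions)

  g1 <- withr::local_tempfile(fileext = ".gmt")
  g2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gen_geneset_library(n_terms = 30, seed = 9)$library, g1)
  write_gmt(gen_geneset_library(n_terms = 30, seed = 9)$library, g2)
  expect_identical(readr::read_file(g1), readr::read_file(g2))
})

test_that("planted gate outcomes are exactly reproduced by the screen", {
  gen <- gen_descriptor_table(131, 110, seed = 7)
  expect_length(screen_candidates(gen$profiles)$candidates, 110)
  # every failing row violates at least one gate
  fails <- gen$profiles[gen$profiles$compound_id %in% gen$truth$fail_ids, ]
  expect_true(all(fails$hia <= 25 | fails$bioavailability <= 0.15))

  none <- gen_descriptor_table(10, 0, seed = 3)
  expect_length(screen_candidates(none$profiles)$candidates, 0)
  expect_error(gen_descriptor_table(10, 11))
})

test_that("catalog generator allocates the nine classes and content compounds", {
  gen <- gen_compound_catalog(131, seed = 2)
  expect_equal(nrow(gen$catalog), 131)
  expect_setequal(unique(gen$catalog$chem_class), chem_classes())
  # largest-remainder allocation of the class proportions at n = 131
  expect_equal(sum(gen$catalog$chem_class == "flavone"), 68)
  expect_equal(sum(unlist(gen$truth$class_counts)), 131L)
  with_content <- gen$catalog[!is.na(gen$catalog$content_fraction), ]
  expect_equal(nrow(with_content), 10)
  expect_equal(sum(with_content$content_fraction), 0.7, tolerance = 1e-12)
  sub <- gen$catalog$flavone_subclass
  expect_true(all(is.na(sub[gen$catalog$chem_class != "flavone"])))
  expect_true(all(sub[gen$catalog$chem_class == "flavone"] %in%
                    flavone_subclasses()))
})

test_that("prediction generator honours distinct totals and pool feasibility", {
  catalog <- gen_compound_catalog(40, seed = 5)$catalog
  gen <- gen_target_predictions(catalog, catalog$compound_id,
                                distinct_total = 250, targets_per_compound = 12,
                                seed = 6)
  human <- gen$predictions[gen$predictions$species == "Homo sapiens", ]
  expect_equal(dplyr::n_distinct(human$gene[human$compound_id %in%
                                              catalog$compound_id]), 250)
  expect_error(
    gen_target_predictions(catalog, catalog$compound_id, distinct_total = 20,
                           targets_per_compound = 12, overlap = 0, seed = 6),
    "distinct_total too small")
})

test_that("gene-set generator respects sizes, families, and the universe", {
  gen <- gen_geneset_library(n_terms = 40, size_range = c(10, 50),
                             universe_size = 1000, n_families = 5,
                             terms_per_family = 4, seed = 11)
  lib <- gen$library
  expect_length(lib$sets, 40)
  expect_true(all(unlist(lib$sets) %in% lib$universe))
  non_family <- setdiff(names(lib$sets), unlist(gen$truth$family_members))
  expect_true(all(lengths(lib$sets[non_family]) >= 10 &
                    lengths(lib$sets[non_family]) <= 50))
  expect_length(unlist(gen$truth$family_members), 20)
  # within-family Jaccard is high, across-family near zero
  fam1 <- lib$sets[gen$truth$family_members$family1]
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  expect_gt(jac(fam1[[1]], fam1[[2]]), 0.7)
  fam2 <- lib$sets[gen$truth$family_members$family2]
  expect_lt(jac(fam1[[1]], fam2[[1]]), 0.2)
  expect_error(gen_geneset_library(n_terms = 10, size_range = c(10, 50),
                                   universe_size = 20), "universe too small")
})

test_that("hit-list generator plants the requested signal fraction", {
  lib <- gen_geneset_library(n_terms = 50, size_range = c(20, 40),
                             universe_size = 800, seed = 3)$library
  planted <- names(lib$sets)[1:2]
  pool <- unique(unlist(lib$sets[planted]))

  hl <- gen_hit_list(lib, planted, effect = 1, n_hits = 20, seed = 4)
  expect_true(all(hl$hits %in% pool))
  expect_length(hl$hits, 20)
  expect_equal(anyDuplicated(hl$hits), 0L)

  null <- gen_hit_list(lib, effect = 0, n_hits = 30, seed = 5)
  expect_length(null$hits, 30)
  expect_identical(null$hits, gen_hit_list(lib, effect = 0, n_hits = 30,
                                           seed = 5)$hits)
  expect_error(gen_hit_list(lib, planted[1], effect = 1, n_hits = 500, seed = 1),
               "smaller than")
})

test_that("null hit lists give superuniform (valid) enrichment p-values", {
  # the exact test is discrete, so P(p <= t) can fall below t but must not
  # exceed it beyond sampling noise at any threshold
  lib <- gen_geneset_library(n_terms = 100, size_range = c(10, 50),
                             universe_size = 2000, seed = 17)$library
  ps <- unlist(lapply(1:30, function(s) {
    hl <- gen_hit_list(lib, effect = 0, n_hits = 100, seed = 9000 + s)
    res <- suppressMessages(tidy(enrich(hl$hits, lib)))
    # terms with no hits have p = 1; include them so the distribution is
    # over all tested terms
    c(res$p, rep(1, 100 - nrow(res)))
  }))
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    se <- sqrt(t * (1 - t) / length(ps))
    expect_lte(mean(ps <= t), t + 3 * se)
  }
})

test_that("the full synthetic study reproduces its planted scale", {
  study <- synthetic_study(seed = 12, n_compounds = 50, n_pass = 35,
                           distinct_targets = 300, genome_size = 4000,
                           n_disease_terms = 50, n_strong_diseases = 15)
  expect_equal(nrow(study$catalog), 50)
  scr <- screen_candidates(study$profiles)
  expect_length(scr$candidates, 35)
  map <- aggregate_targets(study$predictions, scr$candidates)
  expect_equal(attr(map, "n_distinct_targets"), 300L)
  expect_setequal(names(study$libraries),
                  c("disease", "GO_BP", "GO_MF", "GO_CC", "KEGG"))
})
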