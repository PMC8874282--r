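test_that("the accumulative hypergeometric tail matches brute-force pmf summation", {
  expect_equal(hypergeom_upper_tail(0, K = 10, n = 5, N = 100), 1.0)
  expect_equal(hypergeom_upper_tail(5, K = 5, n = 5, N = 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, K = 10, n = 5, N = 100),
               oracle_upper_tail(3, 10, 5, 100), tolerance = 1e-12)

  # random grid against the oracle and against stats::phyper
  withr::with_seed(99, {
    for (i in 1:50) {
      N <- sample(10:500, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
      k <- sample(0:min(n, K), 1)
      p <- hypergeom_upper_tail(k, K, n, N)
      expect_equal(p, oracle_upper_tail(k, K, n, N), tolerance = 1e-12)
      expect_equal(p, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })

  # monotone non-increasing in k at fixed (K, n, N)
  tails <- hypergeom_upper_tail(0:10, K = 20, n = 10, N = 200)
  expect_true(all(diff(tails) <= 0))

  # log-space route survives far below double underflow
  lp <- hypergeom_upper_tail(300, K = 320, n = 1011, N = 20000, log10 = TRUE)
  expect_lt(lp, -250)
  expect_true(is.finite(lp))

  expect_error(hypergeom_upper_tail(6, K = 5, n = 5, N = 20), "invalid")
  expect_error(hypergeom_upper_tail(1, K = 30, n = 5, N = 20), "invalid")
})

test_that("BH adjustment reproduces the hand step-up and never lowers p", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(1.0), 1.0)
  withr::with_seed(5, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(q >= p))
      expect_true(all(q <= 1))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("kappa similarity is Cohen's kappa over the membership vectors", {
  u <- sprintf("G%02d", 1:10)
  expect_equal(kappa_similarity(u[1:4], u[1:4], u), 1.0)
  expect_equal(kappa_similarity(u[1:5], u[6:10], u), -1.0)
  # hand value: |A|=4, |B|=3, both=2 over N=10 -> p_o=0.7, p_e=0.54
  expect_equal(kappa_similarity(u[1:4], u[3:5], u),
               (0.7 - 0.54) / (1 - 0.54), tolerance = 1e-12)
  withr::with_seed(21, {
    for (i in 1:20) {
      a <- sample(u, sample(0:10, 1)); b <- sample(u, sample(0:10, 1))
      expect_equal(kappa_similarity(a, b, u), kappa_similarity(b, a, u))
    }
  })
  # degenerate-marginal cases: both-empty and both-full agree perfectly;
  # empty vs non-empty has zero chance-corrected agreement
  expect_equal(kappa_similarity(u, u, u), 1)
  expect_equal(kappa_similarity(character(0), character(0), u), 1)
  expect_equal(kappa_similarity(character(0), u[1:5], u), 0)
  expect_error(kappa_similarity(c("ZZ"), u[1:2], u), "subsets")
})

test_that("enrich computes k, expected counts, EF, and the significance gate", {
  u <- sprintf("G%03d", 1:100)
  lib <- gene_set_library("disease", sets = list(T1 = u[1:10]), universe = u)
  hits <- c(u[1:5], u[90:94])  # k=5, n=10, K=10, N=100
  res <- tidy(enrich(hits, lib))
  expect_equal(res$expected, 1.0)
  expect_equal(res$ef, 5.0)
  expect_equal(res$k, 5L)
  expect_equal(res$p, oracle_upper_tail(5, 10, 10, 100), tolerance = 1e-12)

  # minimum count 3 blocks a tiny but extreme term
  lib2 <- gene_set_library("disease", sets = list(TINY = u[1:2], BULK = u[1:50]),
                           universe = u)
  res2 <- tidy(enrich(u[1:2], lib2))
  tiny <- res2[res2$term_id == "TINY", ]
  expect_lt(tiny$p, 1e-3)
  expect_false(tiny$significant)

  # hits outside the universe are dropped with a message; all-out errors
  expect_message(enrich(c(u[1:3], "XX"), lib), "dropped")
  expect_error(suppressMessages(enrich("XX", lib)), "no hit genes")

  # genome-size universe override enters N
  res3 <- tidy(enrich(hits, lib, enrichment_config(universe_size = 20000)))
  expect_equal(res3$N, 20000L)
  expect_equal(res3$ef, 5 / (10 * 10 / 20000))
})

test_that("q-values are computed over all tested terms of the library", {
  u <- sprintf("G%03d", 1:60)
  lib <- gene_set_library("KEGG",
                          sets = list(A = u[1:10], B = u[11:20], C = u[21:30]),
                          universe = u)
  res <- tidy(enrich(u[1:12], lib))
  # term C has no hits and is absent from the rows, but counted in BH (m=3)
  expect_equal(nrow(res), 2)
  ps <- setNames(res$p, res$term_id)
  m <- 3
  expect_equal(unname(res$q[res$term_id == "A"]),
               min(oracle_bh(c(ps[["A"]], ps[["B"]], 1))[1], 1))
})

test_that("planted terms dominate the top p-ranks in a recovery experiment", {
  lib <- gen_geneset_library(n_terms = 200, size_range = c(10, 50),
                             universe_size = 2000, seed = 42)$library
  sizes <- lengths(lib$sets)
  planted <- names(sort(sizes, decreasing = TRUE))[1:3]
  hitrate <- 0
  n_runs <- 20
  for (s in 1:n_runs) {
    hl <- gen_hit_list(lib, planted, effect = 0.6, n_hits = 100, seed = 1000 + s)
    res <- tidy(enrich(hl$hits, lib))
    hitrate <- hitrate + setequal(res$term_id[1:3], planted)
  }
  expect_gte(hitrate / n_runs, 0.95)
})

test_that("top_terms ranks by p, then larger count, then term id", {
  res <- tibble::tibble(
    term_id = c("T3", "T1", "T2", "T4"),
    term_name = term_id, k = c(5L, 9L, 9L, 2L),
    log10_p = log10(c(0.01, 0.001, 0.001, 0.5)),
    p = c(0.01, 0.001, 0.001, 0.5), significant = TRUE
  )
  top <- top_terms(res, 3)
  expect_equal(top$term_id, c("T1", "T2", "T3"))
  expect_equal(nrow(top_terms(res, 10)), 4)
  expect_error(top_terms(res, 0))

  many <- tibble::tibble(term_id = sprintf("T%02d", 1:20),
                         term_name = term_id, k = 5L,
                         p = seq(0.001, 0.02, length.out = 20),
                         log10_p = log10(p), significant = TRUE)
  expect_equal(nrow(top_terms(many, 15)), 15)
})
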