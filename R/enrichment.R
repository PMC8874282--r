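#' Accumulative hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more hits, `P[X >= k]`, for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a universe of `N`
#' of which `K` are annotated to the term. Computed exactly as a log-space
#' sum over the point masses (no normal approximation), so it stays
#' accurate deep in the tail.
#'
#' @param k Observed hit count(s), `0 <= k <= min(n, K)`.
#' @param K Term size(s).
#' @param n Hit-list size(s).
#' @param N Universe size(s).
#' @param log10 Return log10 of the probability instead (useful when the
#'   probability underflows double precision).
#' @return Numeric vector of upper-tail probabilities (or their log10).
#' @examples
#' hypergeom_upper_tail(5, K = 5, n = 5, N = 20)  # 1 / choose(20, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N, log10 = FALSE) {
  args <- vctrs_recycle(k = k, K = K, n = n, N = N)
  lt <- mapply(hyper_tail_log, args$k, args$K, args$n, args$N)
  if (log10) lt / log(10) else pmin(exp(lt), 1)
}

# scalar log upper tail; log-sum-exp over dhyper log point masses
hyper_tail_log <- function(k, K, n, N) {
  if (any(!is.finite(c(k, K, n, N)))) abort("hypergeometric arguments must be finite")
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K)) {
    abort(sprintf(
      "invalid hypergeometric arguments: k=%g, K=%g, n=%g, N=%g (need 0<=K<=N, 0<=n<=N, 0<=k<=min(n,K))",
      k, K, n, N))
  }
  lo <- max(0, n + K - N)
  if (k <= lo) return(0)  # P[X >= lower support bound] = 1
  j <- seq(k, min(n, K))
  lp <- dhyper(j, K, N - K, n, log = TRUE)
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  bad <- lengths(args) != len & lengths(args) != 1
  if (any(bad)) abort("arguments must have length 1 or a common length")
  lapply(args, rep_len, len)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment: the i-th smallest
#' p-value maps to `min over j >= i of m * p_(j) / j`, capped at 1, returned
#' in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cohen's kappa similarity between two gene sets
#'
#' Chance-corrected agreement of the two binary membership vectors over a
#' reference universe: `kappa = (p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed agreement fraction and `p_e` the agreement expected by chance
#' from the marginal set sizes. Identical sets give 1; complementary halves
#' of the universe give -1.
#'
#' @param a,b Character vectors of genes, both subsets of `universe`.
#' @param universe Character vector (length >= 2) over which membership is
#'   compared.
#' @return A single kappa value in \[-1, 1\].
#' @export
kappa_similarity <- function(a, b, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N < 2) abort("kappa universe must contain at least 2 genes")
  a <- unique(a); b <- unique(b)
  if (length(setdiff(a, universe)) > 0 || length(setdiff(b, universe)) > 0) {
    abort("both gene sets must be subsets of the kappa universe")
  }
  both <- length(intersect(a, b))
  na <- length(a); nb <- length(b)
  neither <- N - (na + nb - both)
  p_o <- (both + neither) / N
  p_e <- (na * nb + (N - na) * (N - nb)) / N^2
  if (p_e >= 1) {
    if (setequal(a, b)) return(1)
    abort("kappa undefined: chance agreement is 1 but the sets differ")
  }
  (p_o - p_e) / (1 - p_e)
}

#' Enrichment analysis configuration
#'
#' Thresholds of the significance call and the term-clustering cut. The
#' defaults are the disease-library settings (raw p < 0.01, minimum count
#' 3, enrichment factor > 1.5, kappa cut 0.3); for GO and KEGG libraries
#' use `p_max = 0.05, use_adjusted = TRUE` so the call is on the
#' BH-corrected value.
#'
#' @param p_max Significance threshold (strict `<`) on p, or on q when
#'   `use_adjusted` is `TRUE`.
#' @param min_count Minimum observed hit count (`k >= min_count`).
#' @param ef_min Minimum enrichment factor (strict `>`).
#' @param kappa_cut Similarity above which terms merge into one cluster
#'   (strict `>`), in (-1, 1).
#' @param use_adjusted Apply `p_max` to the BH-adjusted q instead of raw p.
#' @param universe_size Optional background size override (e.g. 20000 for a
#'   whole-genome background); genes beyond the library's annotated union
#'   are then counted as unannotated background.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(p_max = 0.01, min_count = 3, ef_min = 1.5,
                              kappa_cut = 0.3, use_adjusted = FALSE,
                              universe_size = NULL) {
  assert_scalar_number(p_max, "p_max", lo = 1e-300, hi = 1)
  assert_scalar_number(min_count, "min_count", lo = 1)
  assert_scalar_number(ef_min, "ef_min", lo = 1e-12)
  assert_scalar_number(kappa_cut, "kappa_cut", lo = -1 + 1e-9, hi = 1 - 1e-9)
  structure(list(p_max = p_max, min_count = min_count, ef_min = ef_min,
                 kappa_cut = kappa_cut, use_adjusted = use_adjusted,
                 universe_size = universe_size),
            class = "enrichment_config")
}

#' Gene-set enrichment by the accumulative hypergeometric test
#'
#' Tests every term of a library against a hit-gene list. For each term the
#' observed hit count `k`, the count expected by chance `n*K/N`, the
#' enrichment factor `EF = k / expected`, the exact hypergeometric
#' upper-tail p-value and the BH q-value are reported. The q-values are
#' computed over all terms tested in the library (terms the hit list never
#' touches contribute p = 1); only terms with `k >= 1` appear in the result
#' rows. A term is flagged significant when it clears the p (or q)
#' threshold, the minimum count, and the enrichment-factor floor.
#'
#' Hit genes outside the universe are dropped with a message; an empty hit
#' list after that intersection is an error.
#'
#' @param hit_genes Character vector of gene symbols.
#' @param library A `gene_set_library`.
#' @param config An [enrichment_config()].
#' @param universe Optional character vector overriding the library
#'   universe.
#' @return An `enrichment` object. `tidy()` returns the per-term tibble
#'   (sorted by p ascending) with columns `term_id`, `term_name`,
#'   `category`, `k`, `K`, `n`, `N`, `expected`, `ef`, `p`, `q`, `log10_p`,
#'   `significant`, `hit_genes` (list-column); `glance()` the headline
#'   counts.
#' @export
enrich <- function(hit_genes, library, config = enrichment_config(),
                   universe = NULL) {
  stopifnot(inherits(library, "gene_set_library"))
  stopifnot(inherits(config, "enrichment_config"))
  uni <- unique(normalize_gene(universe %||% library$universe))
  hits_raw <- unique(normalize_gene(hit_genes))
  hits <- intersect(hits_raw, uni)
  n_dropped <- length(hits_raw) - length(hits)
  if (n_dropped > 0) {
    inform(sprintf("%d hit gene(s) outside the universe were dropped", n_dropped))
  }
  if (length(hits) == 0) abort("no hit genes remain after universe intersection")

  N <- if (!is.null(config$universe_size)) {
    if (config$universe_size < length(uni)) {
      abort("universe_size override is smaller than the annotated-gene union")
    }
    as.integer(config$universe_size)
  } else {
    length(uni)
  }
  n <- length(hits)

  sets <- lapply(library$sets, intersect, y = uni)
  Ks <- unname(lengths(sets))
  hit_sets <- lapply(sets, intersect, y = hits)
  ks <- unname(lengths(hit_sets))

  log_p_all <- vapply(seq_along(sets), function(i) {
    if (ks[i] == 0) 0 else hyper_tail_log(ks[i], Ks[i], n, N)
  }, numeric(1))
  p_all <- pmin(exp(log_p_all), 1)
  q_all <- bh_adjust(p_all)

  res <- tibble(
    term_id = names(sets),
    term_name = unname(library$term_names[names(sets)]),
    category = library$category,
    k = as.integer(ks),
    K = as.integer(Ks),
    n = as.integer(n),
    N = as.integer(N),
    expected = n * Ks / N,
    ef = ifelse(Ks > 0, ks / (n * Ks / N), 0),
    p = p_all,
    q = q_all,
    log10_p = log_p_all / log(10),
    hit_genes = unname(hit_sets)
  ) %>%
    filter(.data$k >= 1)
  stat <- if (config$use_adjusted) res$q else res$p
  res$significant <- stat < config$p_max &
    res$k >= config$min_count & res$ef > config$ef_min
  res <- res %>%
    arrange(.data$log10_p, desc(.data$k), .data$term_id) %>%
    select("term_id", "term_name", "category", "k", "K", "n", "N",
           "expected", "ef", "p", "q", "log10_p", "significant", "hit_genes")
  structure(
    list(results = res, config = config, category = library$category,
         n_hits = n, n_hits_dropped = n_dropped, universe_size = N),
    class = "enrichment"
  )
}

#' @exportS3Method generics::tidy
tidy.enrichment <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.enrichment <- function(x, ...) {
  tibble(category = x$category, n_terms_hit = nrow(x$results),
         n_significant = sum(x$results$significant),
         n_hits = x$n_hits, universe_size = x$universe_size)
}

#' @export
print.enrichment <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<enrichment> %s: %d terms with hits, %d significant (n=%d, N=%d)\n",
              g$category, g$n_terms_hit, g$n_significant, g$n_hits,
              g$universe_size))
  invisible(x)
}

#' Top enriched terms
#'
#' Ranks terms by p-value ascending, breaking ties by larger hit count and
#' then lexicographic term id, and returns the first `k`.
#'
#' @param x An `enrichment` object or a tidy enrichment tibble.
#' @param k Number of terms to keep (default 15). Fewer rows than `k`
#'   returns the full ranked list.
#' @param significant_only Restrict to significant terms first.
#' @return A tibble of at most `k` rows.
#' @export
top_terms <- function(x, k = 15, significant_only = FALSE) {
  if (k < 1) abort("`k` must be >= 1")
  res <- if (inherits(x, "enrichment")) tidy(x) else x
  if (significant_only) res <- filter(res, .data$significant)
  res %>%
    arrange(.data$log10_p, desc(.data$k), .data$term_id) %>%
    slice_head(n = k)
}
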