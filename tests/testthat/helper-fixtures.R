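# small in-code fixtures shared across test files

toy_catalog <- function() {
  tibble::tibble(
    compound_id = c("C001", "C002", "C003", "C004"),
    name = c("okanin-like", "marein-like", "coreopsin-like", "acid-like"),
    smiles = c("OC1=CC=CC=C1", "COC1=CC=CC=C1", "C=CC#CC#C", "CC(=O)O"),
    chem_class = c("flavone", "flavone", "polyacetylene", "phenol"),
    flavone_subclass = c("chalcone", "aurone", NA, NA),
    content_fraction = c(0.30, 0.10, NA, NA)
  )
}

# a descriptor row with every field comfortably mid-window
mid_profile <- function(compound_id = "C001", ...) {
  base <- tibble::tibble(
    compound_id = compound_id, xlogp3 = 2, mw = 300, tpsa = 75, log_s = -3,
    n_rot_bonds = 4L, fsp3 = 0.5, hia = 80, bbb = 0, bioavailability = 0.55,
    pgp_substrate = FALSE, cyp1a2 = FALSE, cyp2c19 = FALSE, cyp2c9 = FALSE,
    cyp2d6 = FALSE, cyp3a4 = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}

toy_library <- function() {
  gene_set_library(
    category = "disease",
    sets = list(T1 = c("A", "B", "C"), T2 = c("B", "C", "D")),
    term_names = c(T1 = "memory impairment", T2 = "fatty liver disease")
  )
}

# brute-force upper tail from binomial coefficients, independent of the
# implementation's dhyper/log-sum-exp route
oracle_upper_tail <- function(k, K, n, N) {
  j <- k:min(n, K)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# hand step-up BH, independent of stats::p.adjust
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}
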