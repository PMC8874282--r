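`%||%` <- rlang::`%||%`

#' Chemical class vocabulary
#'
#' The nine compound classes recognised in a catalog, and the six flavone
#' subclasses.
#'
#' @return Character vector of class labels.
#' @export
chem_classes <- function() {
  c("phenylpropanoid", "phenol", "polyacetylene", "terpenoid", "steroid",
    "alkaloid", "phenylethanoid", "anthraquinone", "flavone")
}

#' @rdname chem_classes
#' @export
flavone_subclasses <- function() {
  c("chalcone", "flavanone", "flavone", "flavonol", "flavanol", "aurone")
}

target_sources <- function() {
  c("SEA", "SwissTargetPrediction", "STITCH", "experimental")
}

assert_cols <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(x)
}

# gene symbols are uppercased and whitespace-stripped so joins across
# prediction sources are case-insensitive
normalize_gene <- function(x) {
  toupper(gsub("\\s+", "", as.character(x)))
}

normalize_species <- function(x) {
  gsub("\\s+", " ", trimws(as.character(x)))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lo), format(hi)))
  }
  invisible(x)
}
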