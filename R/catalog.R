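#' Read a compound catalog table
#'
#' Parses a delimited text file describing the compounds of an extract: one
#' row per compound with its identifier, name, SMILES string, chemical class
#' (one of the nine classes in [chem_classes()]), an optional flavone
#' subclass, and an optional content fraction (share of extract mass).
#'
#' Content may be supplied either as a fraction in \[0, 1\] or as a percent in
#' \[0, 100\] (column `content_percent`, or `content = "percent"`); it is
#' always stored internally as a fraction.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @param content How to interpret the content column: `"auto"` (percent if
#'   the column is named `content_percent`, fraction otherwise), `"fraction"`,
#'   or `"percent"`.
#' @return A tibble with columns `compound_id`, `name`, `smiles`,
#'   `chem_class`, `flavone_subclass`, `content_fraction`, in file order.
#' @export
read_compound_table <- function(path, delim = ",", content = c("auto", "fraction", "percent")) {
  content <- match.arg(content)
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, trim_ws = TRUE)
  assert_cols(x, c("compound_id", "name", "smiles", "chem_class"), "compound table")

  percent_col <- "content_percent" %in% names(x)
  if (percent_col && content == "auto") content <- "percent"
  if (percent_col) x <- rename(x, content_fraction = "content_percent")
  if (!"content_fraction" %in% names(x)) x$content_fraction <- NA_real_
  if (!"flavone_subclass" %in% names(x)) x$flavone_subclass <- NA_character_

  x <- x %>%
    mutate(
      compound_id = as.character(.data$compound_id),
      name = as.character(.data$name),
      smiles = as.character(.data$smiles),
      chem_class = as.character(.data$chem_class),
      flavone_subclass = as.character(.data$flavone_subclass),
      content_fraction = as.numeric(.data$content_fraction)
    ) %>%
    select("compound_id", "name", "smiles", "chem_class",
           "flavone_subclass", "content_fraction")
  if (content == "percent") {
    x$content_fraction <- x$content_fraction / 100
  }
  validate_catalog(x)
}

validate_catalog <- function(x) {
  bad_id <- which(is.na(x$compound_id) | x$compound_id == "")
  if (length(bad_id) > 0) {
    abort(sprintf("missing compound_id in row(s): %s",
                  paste(bad_id, collapse = ", ")))
  }
  dup <- unique(x$compound_id[duplicated(x$compound_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated compound_id: %s", paste(dup, collapse = ", ")))
  }
  bad <- which(!x$chem_class %in% chem_classes())
  if (length(bad) > 0) {
    abort(sprintf("unknown chem_class %s in row(s): %s",
                  paste(unique(x$chem_class[bad]), collapse = ", "),
                  paste(bad, collapse = ", ")))
  }
  bad_sub <- which(!is.na(x$flavone_subclass) & x$chem_class != "flavone")
  if (length(bad_sub) > 0) {
    abort(sprintf("flavone_subclass set for non-flavone row(s): %s",
                  paste(bad_sub, collapse = ", ")))
  }
  bad_sub2 <- which(!is.na(x$flavone_subclass) &
                      !x$flavone_subclass %in% flavone_subclasses())
  if (length(bad_sub2) > 0) {
    abort(sprintf("unknown flavone_subclass in row(s): %s",
                  paste(bad_sub2, collapse = ", ")))
  }
  cf <- x$content_fraction
  bad_cf <- which(!is.na(cf) & (cf < 0 | cf > 1))
  if (length(bad_cf) > 0) {
    abort(sprintf("content_fraction outside [0, 1] in row(s): %s",
                  paste(bad_cf, collapse = ", ")))
  }
  bad_smiles <- which(is.na(x$smiles) | x$smiles == "")
  if (length(bad_smiles) > 0) {
    abort(sprintf("empty SMILES in row(s): %s", paste(bad_smiles, collapse = ", ")))
  }
  x
}

#' Read a per-compound descriptor table
#'
#' Parses physicochemical and ADME descriptors: XLOGP3, molecular weight
#' (g/mol), TPSA (squared angstroms), log S, rotatable-bond count, Fsp3,
#' HIA (percent), BBB (log BB), bioavailability score, the P-gp substrate
#' flag and the five CYP450 inhibition flags.
#'
#' @inheritParams read_compound_table
#' @return A tibble with one row per compound, in file order.
#' @export
read_descriptor_table <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, trim_ws = TRUE)
  assert_cols(x, descriptor_columns(), "descriptor table")
  x <- x %>%
    mutate(
      compound_id = as.character(.data$compound_id),
      across(c("xlogp3", "mw", "tpsa", "log_s", "fsp3", "hia", "bbb",
               "bioavailability"), as.numeric),
      n_rot_bonds = as.integer(.data$n_rot_bonds),
      across(c("pgp_substrate", "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6",
               "cyp3a4"), as.logical)
    ) %>%
    select(dplyr::all_of(descriptor_columns()))
  validate_descriptors(x)
}

descriptor_columns <- function() {
  c("compound_id", "xlogp3", "mw", "tpsa", "log_s", "n_rot_bonds", "fsp3",
    "hia", "bbb", "bioavailability", "pgp_substrate",
    "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4")
}

validate_descriptors <- function(x) {
  dup <- unique(x$compound_id[duplicated(x$compound_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated compound_id in descriptor table: %s",
                  paste(dup, collapse = ", ")))
  }
  bad <- which(!is.na(x$fsp3) & (x$fsp3 < 0 | x$fsp3 > 1))
  if (length(bad) > 0) {
    abort(sprintf("fsp3 outside [0, 1] in row(s): %s", paste(bad, collapse = ", ")))
  }
  bad <- which(!is.na(x$hia) & (x$hia < 0 | x$hia > 100))
  if (length(bad) > 0) {
    abort(sprintf("hia outside [0, 100] in row(s): %s", paste(bad, collapse = ", ")))
  }
  x
}

#' Read a compound-to-target prediction table
#'
#' One row per (compound, gene, source) prediction. Gene symbols are
#' uppercased and whitespace-stripped at parse time; species labels are
#' whitespace-normalized. Rows are kept per-species; filtering to one
#' species happens in [aggregate_targets()].
#'
#' @inheritParams read_compound_table
#' @return A tibble with columns `compound_id`, `gene`, `source`, `species`,
#'   in file order.
#' @export
read_target_predictions <- function(path, delim = ",") {
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, trim_ws = TRUE)
  assert_cols(x, c("compound_id", "gene", "source", "species"), "prediction table")
  x <- x %>%
    mutate(
      compound_id = as.character(.data$compound_id),
      gene = normalize_gene(.data$gene),
      source = as.character(.data$source),
      species = normalize_species(.data$species)
    ) %>%
    select("compound_id", "gene", "source", "species")
  bad <- which(is.na(x$gene) | x$gene == "" | x$gene == "NA")
  if (length(bad) > 0) {
    abort(sprintf("empty gene symbol in row(s): %s", paste(bad, collapse = ", ")))
  }
  bad_src <- which(!x$source %in% target_sources())
  if (length(bad_src) > 0) {
    abort(sprintf("unknown source %s in row(s): %s",
                  paste(unique(x$source[bad_src]), collapse = ", "),
                  paste(bad_src, collapse = ", ")))
  }
  x
}

#' Write a pipeline table to delimited text
#'
#' Writes any of the package's tabular objects (catalog, descriptor table,
#' prediction table, verdicts, enrichment rows) with a stable column order so
#' that a read of the written file reproduces the original table.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = ",") {
  readr::write_delim(x, path, delim = delim, na = "", progress = FALSE)
  invisible(path)
}

#' Read a gene-set library in GMT format
#'
#' Standard GMT dialect: `term_id TAB description TAB gene TAB gene ...`.
#' Genes are uppercased and deduplicated within each term. Unless an
#' explicit universe is supplied the universe is the union of all genes
#' annotated in the library.
#'
#' @param path Path to a GMT file.
#' @param category Library category, one of `"disease"`, `"GO_BP"`,
#'   `"GO_MF"`, `"GO_CC"`, `"KEGG"`.
#' @param universe Optional character vector of genes to use as the
#'   enrichment background instead of the annotated-gene union.
#' @return A `gene_set_library`: list with `category`, `sets` (named list of
#'   gene vectors), `term_names` (named character), and `universe`.
#' @export
read_gmt <- function(path, category = c("disease", "GO_BP", "GO_MF", "GO_CC", "KEGG"),
                     universe = NULL) {
  category <- match.arg(category)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(bad, collapse = ", ")))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicated term_id in GMT: %s", paste(dup, collapse = ", ")))
  }
  names_ <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(normalize_gene(f[-(1:2)])))
  empty <- which(vapply(sets, function(s) length(s) == 0 || all(s == ""), logical(1)))
  if (length(empty) > 0) {
    abort(sprintf("empty gene set on GMT line(s): %s", paste(empty, collapse = ", ")))
  }
  names(sets) <- ids
  names(names_) <- ids
  gene_set_library(category = category, sets = sets, term_names = names_,
                   universe = universe)
}

#' Construct a gene-set library object
#'
#' @param category Library category label.
#' @param sets Named list of character gene vectors (term_id -> genes).
#' @param term_names Named character vector of human-readable term names;
#'   defaults to the term ids.
#' @param universe Optional background gene vector; defaults to the union of
#'   all term genes.
#' @return A `gene_set_library` object.
#' @export
gene_set_library <- function(category, sets, term_names = NULL, universe = NULL) {
  if (length(sets) == 0) abort("a gene-set library needs at least one term")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list keyed by term_id")
  }
  sets <- lapply(sets, function(s) unique(normalize_gene(s)))
  annotated <- sort(unique(unlist(sets, use.names = FALSE)))
  universe <- if (is.null(universe)) annotated else sort(unique(normalize_gene(universe)))
  outside <- setdiff(annotated, universe)
  if (length(outside) > 0) {
    abort(sprintf("%d annotated gene(s) are outside the supplied universe (e.g. %s)",
                  length(outside), outside[1]))
  }
  term_names <- term_names %||% setNames(names(sets), names(sets))
  structure(
    list(category = category, sets = sets,
         term_names = term_names[names(sets)], universe = universe),
    class = "gene_set_library"
  )
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("<gene_set_library> category=%s, %d terms, universe of %d genes\n",
              x$category, length(x$sets), length(x$universe)))
  invisible(x)
}

#' Write a gene-set library to GMT
#'
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(id) {
    paste(c(id, unname(library$term_names[id]), library$sets[[id]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a plain-text gene universe (one symbol per line)
#'
#' @param path Path to a text file.
#' @return Character vector of normalized gene symbols.
#' @export
read_gene_universe <- function(path) {
  g <- readr::read_lines(path, progress = FALSE)
  unique(normalize_gene(g[nzchar(g)]))
}
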