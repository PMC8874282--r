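#' Drug-likeness and ADME rule thresholds
#'
#' Bundles the six physicochemical drug-likeness windows (lipophilicity,
#' size, polarity, solubility, flexibility, saturation) and the ADME gates
#' (HIA, BBB, bioavailability). "Between a and b" windows are inclusive at
#' both ends; "larger than" gates are strict.
#'
#' The solubility rule deserves a note: log S is conventionally negative,
#' with the insoluble edge of the bioavailability radar at -6, so the
#' default rule is `log_s >= -6`. Set `log_s_literal_max` to a number to
#' instead apply a literal upper bound `log_s <= log_s_literal_max`.
#'
#' @param xlogp3_range Inclusive XLOGP3 window (default -0.7 to 5.0).
#' @param mw_range Inclusive molecular-weight window in g/mol (150 to 500).
#' @param tpsa_range Inclusive TPSA window in squared angstroms (20 to 130).
#' @param log_s_min Lower bound on log S (default -6, inclusive).
#' @param log_s_literal_max If non-`NULL`, replaces the solubility rule with
#'   `log_s <= log_s_literal_max`.
#' @param max_rot_bonds Maximum rotatable bonds, inclusive (9).
#' @param fsp3_min Minimum Fsp3, inclusive (0.25).
#' @param hia_min HIA gate in percent, strict `>` (25).
#' @param bbb_min BBB gate in log BB, strict `>` (-1).
#' @param bioavailability_min Bioavailability-score gate, strict `>` (0.15).
#' @param gate Which rules form the candidate gate: `"hia_bioavailability"`
#'   (default; the screen that takes 131 compounds to 110) or
#'   `"hia_bioavailability_bbb"` to also require BBB permeation.
#' @return A `druglikeness_rules` list.
#' @export
druglikeness_rules <- function(xlogp3_range = c(-0.7, 5.0),
                               mw_range = c(150, 500),
                               tpsa_range = c(20, 130),
                               log_s_min = -6,
                               log_s_literal_max = NULL,
                               max_rot_bonds = 9,
                               fsp3_min = 0.25,
                               hia_min = 25,
                               bbb_min = -1,
                               bioavailability_min = 0.15,
                               gate = c("hia_bioavailability",
                                        "hia_bioavailability_bbb")) {
  gate <- match.arg(gate)
  for (r in list(xlogp3_range = xlogp3_range, mw_range = mw_range,
                 tpsa_range = tpsa_range)) {
    if (length(r) != 2 || !all(is.finite(r)) || r[1] > r[2]) {
      abort("ranges must be finite length-2 vectors with low <= high")
    }
  }
  assert_scalar_number(log_s_min, "log_s_min")
  assert_scalar_number(max_rot_bonds, "max_rot_bonds", lo = 0)
  assert_scalar_number(fsp3_min, "fsp3_min", lo = 0, hi = 1)
  assert_scalar_number(hia_min, "hia_min", lo = 0, hi = 100)
  assert_scalar_number(bbb_min, "bbb_min")
  assert_scalar_number(bioavailability_min, "bioavailability_min", lo = 0, hi = 1)
  structure(
    list(xlogp3_range = xlogp3_range, mw_range = mw_range,
         tpsa_range = tpsa_range, log_s_min = log_s_min,
         log_s_literal_max = log_s_literal_max, max_rot_bonds = max_rot_bonds,
         fsp3_min = fsp3_min, hia_min = hia_min, bbb_min = bbb_min,
         bioavailability_min = bioavailability_min, gate = gate),
    class = "druglikeness_rules"
  )
}

#' Read drug-likeness rules from a YAML file
#'
#' Any threshold of [druglikeness_rules()] may be overridden; unspecified
#' fields keep their defaults.
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [druglikeness_rules()].
#' @return A `druglikeness_rules` list.
#' @export
read_druglikeness_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(druglikeness_rules))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown rule field(s) in %s: %s", path,
                  paste(unknown, collapse = ", ")))
  }
  do.call(druglikeness_rules, cfg)
}

physchem_rules <- function() {
  c("lipophilicity", "size", "polarity", "solubility", "flexibility", "saturation")
}

#' Evaluate drug-likeness and ADME rules per compound
#'
#' Applies every rule of a [druglikeness_rules()] configuration to a
#' descriptor table and returns one verdict row per compound: a logical flag
#' per rule, the number of physicochemical rules passed (0-6), and the
#' candidate gate decision.
#'
#' In strict mode (default) a missing value in a gated field is an error
#' naming the compound and field; in permissive mode the affected rule is
#' treated as failed and a warning reports how many values were missing.
#'
#' @param profiles Descriptor tibble as returned by [read_descriptor_table()].
#' @param rules A `druglikeness_rules` configuration.
#' @param strict Error on missing descriptor values (default `TRUE`).
#' @return A tibble with columns `compound_id`, the nine rule flags,
#'   `n_physchem_passed`, and `is_candidate`, one row per input row in input
#'   order.
#' @export
evaluate_rules <- function(profiles, rules = druglikeness_rules(), strict = TRUE) {
  stopifnot(inherits(rules, "druglikeness_rules"))
  assert_cols(profiles, setdiff(descriptor_columns(), c("pgp_substrate",
              "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4")),
              "descriptor table")
  gated <- c("xlogp3", "mw", "tpsa", "log_s", "n_rot_bonds", "fsp3",
             "hia", "bbb", "bioavailability")
  na_counts <- vapply(gated, function(f) sum(is.na(profiles[[f]])), integer(1))
  if (any(na_counts > 0)) {
    if (strict) {
      f <- gated[which(na_counts > 0)[1]]
      id <- profiles$compound_id[which(is.na(profiles[[f]]))[1]]
      abort(sprintf("missing value in gated field `%s` for compound %s (strict mode)",
                    f, id))
    }
    warn(sprintf("%d missing descriptor value(s); affected rules treated as failed",
                 sum(na_counts)))
  }
  in_range <- function(x, r) !is.na(x) & x >= r[1] & x <= r[2]
  solubility <- if (is.null(rules$log_s_literal_max)) {
    !is.na(profiles$log_s) & profiles$log_s >= rules$log_s_min
  } else {
    !is.na(profiles$log_s) & profiles$log_s <= rules$log_s_literal_max
  }
  v <- tibble(
    compound_id = profiles$compound_id,
    lipophilicity = in_range(profiles$xlogp3, rules$xlogp3_range),
    size = in_range(profiles$mw, rules$mw_range),
    polarity = in_range(profiles$tpsa, rules$tpsa_range),
    solubility = solubility,
    flexibility = !is.na(profiles$n_rot_bonds) &
      profiles$n_rot_bonds <= rules$max_rot_bonds,
    saturation = !is.na(profiles$fsp3) & profiles$fsp3 >= rules$fsp3_min,
    hia = !is.na(profiles$hia) & profiles$hia > rules$hia_min,
    bbb = !is.na(profiles$bbb) & profiles$bbb > rules$bbb_min,
    bioavailability = !is.na(profiles$bioavailability) &
      profiles$bioavailability > rules$bioavailability_min
  )
  v$n_physchem_passed <- rowSums(v[physchem_rules()])
  v$is_candidate <- v$hia & v$bioavailability
  if (rules$gate == "hia_bioavailability_bbb") {
    v$is_candidate <- v$is_candidate & v$bbb
  }
  v
}

#' Screen a descriptor table for candidate compounds
#'
#' Applies the candidate gate (HIA > `hia_min` AND bioavailability >
#' `bioavailability_min`) to every compound and summarises, per rule, how
#' many compounds pass. The physicochemical windows and the BBB rule are
#' evaluated and reported as flags but do not gate under the default
#' configuration.
#'
#' @inheritParams evaluate_rules
#' @return A `candidate_screen` object with elements `verdicts` (the
#'   per-compound rule flags), `candidates` (character vector of passing
#'   compound ids, input order), `rule_summary` (tibble of per-rule pass
#'   counts), and `rules`. `tidy()` returns the verdicts, `glance()` the
#'   headline counts, `autoplot()` a per-rule pass-count chart.
#' @examples
#' prof <- gen_descriptor_table(20, 12, seed = 1)$profiles
#' scr <- screen_candidates(prof)
#' glance(scr)
#' @export
screen_candidates <- function(profiles, rules = druglikeness_rules(), strict = TRUE) {
  if (nrow(profiles) == 0) abort("descriptor table is empty")
  v <- evaluate_rules(profiles, rules, strict = strict)
  rule_cols <- c(physchem_rules(), "hia", "bbb", "bioavailability")
  summary <- tibble(
    rule = rule_cols,
    n_pass = vapply(rule_cols, function(r) sum(v[[r]]), numeric(1),
                    USE.NAMES = FALSE),
    n_total = nrow(v)
  )
  structure(
    list(verdicts = v,
         candidates = v$compound_id[v$is_candidate],
         rule_summary = summary,
         rules = rules),
    class = "candidate_screen"
  )
}

#' @export
print.candidate_screen <- function(x, ...) {
  cat(sprintf("<candidate_screen> %d / %d compounds pass the candidate gate\n",
              length(x$candidates), nrow(x$verdicts)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.candidate_screen <- function(x, ...) x$verdicts

#' @exportS3Method generics::glance
glance.candidate_screen <- function(x, ...) {
  tibble(
    n_compounds = nrow(x$verdicts),
    n_candidates = length(x$candidates),
    n_pass_all_physchem = sum(x$verdicts$n_physchem_passed == 6),
    gate = x$rules$gate
  )
}
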