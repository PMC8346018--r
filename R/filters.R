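#' Fixed vocabulary of filter rule names
#'
#' Every violation reported by [eligibility_check()] and [apply_filters()]
#' is one of these names; `"unparseable"` is reserved for structures the
#' chemistry backend cannot read.
#'
#' @return character vector of the 13 rule names.
#' @export
filter_rule_vocabulary <- function() {
  c("mw_range", "element_whitelist", "heavy_atoms", "ring_count",
    "fused_rings", "rotatable_bonds", "hbd", "hba", "charged_carbon",
    "no_N_or_O", "exclusion_smarts", "tosyl", "unparseable")
}

#' Default property filter configuration
#'
#' Bounds of the drug-likeness filter cascade applied to the candidate pool:
#' molecular weight 250-900 Da; elements restricted to C, H, O, N, P, S, F,
#' Cl, Br, I; 18-30 heavy atoms; 1-4 rings (SSSR); at most 3 fused rings per
#' ring system; at most 8 rotatable bonds; at most 3 hydrogen-bond donors;
#' at most 7 acceptors; no formally charged carbon atoms; at least one N or
#' O atom; no match to the exclusion SMARTS (structural alerts) nor to the
#' built-in tosyl pattern `S(=O)(=O)O`.
#'
#' @param ... named overrides of individual bounds.
#' @return named list of filter bounds.
#' @export
default_filter_config <- function(...) {
  config <- list(
    mw_min = 250, mw_max = 900,
    elements = c("C", "H", "O", "N", "P", "S", "F", "Cl", "Br", "I"),
    heavy_min = 18L, heavy_max = 30L,
    rings_min = 1L, rings_max = 4L,
    fused_max = 3L,
    rot_max = 8L,
    hbd_max = 3L,
    hba_max = 7L
  )
  overrides <- list(...)
  stopifnot(all(names(overrides) %in% names(config)))
  config[names(overrides)] <- overrides
  config
}

#' @keywords internal
filter_verdict <- function(ids, violated) {
  vocab <- filter_rule_vocabulary()
  stopifnot(all(unlist(violated) %in% vocab))
  data.frame(
    id = ids,
    passed = lengths(violated) == 0L,
    violated_rules = I(violated),
    stringsAsFactors = FALSE
  )
}

#' Apply the property filters to a profile
#'
#' Evaluates every property rule (not short-circuited) so the verdict lists
#' all violated rules of each compound. Eligibility rules (molecular weight,
#' element whitelist) are checked separately by [eligibility_check()].
#'
#' @param profile data.frame from [property_profile()].
#' @param config filter bounds, see [default_filter_config()].
#' @return verdict data.frame: `id`, `passed`, list-column `violated_rules`.
#' @export
apply_filters <- function(profile, config = default_filter_config()) {
  rules <- lapply(seq_len(nrow(profile)), function(i) {
    p <- profile[i, ]
    if (!is.null(profile$ok) && !p$ok) return("unparseable")
    v <- character()
    if (p$heavy_atoms < config$heavy_min || p$heavy_atoms > config$heavy_max)
      v <- c(v, "heavy_atoms")
    if (p$rings < config$rings_min || p$rings > config$rings_max)
      v <- c(v, "ring_count")
    if (p$max_fused_system_rings > config$fused_max)
      v <- c(v, "fused_rings")
    if (p$rotatable_bonds > config$rot_max)
      v <- c(v, "rotatable_bonds")
    if (p$hbd > config$hbd_max)
      v <- c(v, "hbd")
    if (p$hba > config$hba_max)
      v <- c(v, "hba")
    if (p$has_charged_carbon)
      v <- c(v, "charged_carbon")
    if (!p$has_N_or_O)
      v <- c(v, "no_N_or_O")
    matched <- p$matched_exclusion_patterns[[1]]
    if (length(setdiff(matched, "tosyl")) > 0)
      v <- c(v, "exclusion_smarts")
    if ("tosyl" %in% matched)
      v <- c(v, "tosyl")
    v
  })
  filter_verdict(profile$id, rules)
}

#' Curate a candidate compound pool from raw SMILES
#'
#' End-to-end pool curation: standardization, duplicate merging,
#' eligibility checks and property filters. The union of violated rules
#' (eligibility + property) forms each compound's verdict.
#'
#' @param raw data.frame with columns `id` and `smiles` (e.g. from
#'   [read_smiles()]).
#' @param patterns optional structural-alert table (`name`, `smarts`).
#' @param config filter bounds, see [default_filter_config()].
#' @return list with elements `pass` (data.frame `id`, `smiles_std` plus the
#'   property profile columns of the surviving compounds, with Morgan
#'   fingerprints of the passing compounds as attribute `"fingerprints"`),
#'   `rejected` (data.frame `id`, `smiles`, list-column `violated_rules`)
#'   and `verdicts` (one verdict per deduplicated record).
#' @export
filter_pool <- function(raw, patterns = NULL,
                        config = default_filter_config()) {
  check_columns(raw, c("id", "smiles"), "raw compound table")
  std <- standardize_compounds(raw$smiles, raw$id)
  bad <- std[!std$ok, , drop = FALSE]
  good <- dedupe_compounds(std[std$ok, , drop = FALSE])

  elig <- eligibility_check(good, config)
  profile <- property_profile(good, patterns = patterns)
  prop <- apply_filters(profile, config)
  violated <- Map(function(a, b) unique(c(a, b)),
                  elig$violated_rules, prop$violated_rules)
  verdicts <- filter_verdict(good$id, violated)

  pass_idx <- which(verdicts$passed)
  pass <- cbind(good[pass_idx, c("id", "smiles_std"), drop = FALSE],
                profile[pass_idx, setdiff(names(profile), c("id", "ok")),
                        drop = FALSE])
  rownames(pass) <- NULL
  attr(pass, "fingerprints") <-
    attr(profile, "fingerprints")[pass_idx, , drop = FALSE]

  rejected <- rbind(
    data.frame(id = bad$id, smiles = bad$smiles,
               violated_rules = I(rep(list("unparseable"), nrow(bad))),
               stringsAsFactors = FALSE),
    data.frame(id = good$id[!verdicts$passed],
               smiles = good$smiles[!verdicts$passed],
               violated_rules = I(verdicts$violated_rules[!verdicts$passed]),
               stringsAsFactors = FALSE)
  )
  rownames(rejected) <- NULL
  list(pass = pass, rejected = rejected, verdicts = verdicts)
}
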