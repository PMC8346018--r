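#' Configuration of the synthetic annotation-tier generator
#'
#' Defaults emulate the statistical shape of a realistic candidate pool:
#' about half of the filtered compounds are dark chemical matter (no
#' predictable targets), active compounds carry a skewed (zero-truncated
#' negative-binomial) number of predicted targets averaging around three,
#' target popularity and family sizes follow power-law weights, and family
#' novelty scores follow a Beta law centered near 0.7 with most mass on
#' the recent side.
#'
#' @param n_compounds number of pool compounds.
#' @param n_targets number of protein targets.
#' @param n_families number of Pfam families.
#' @param promiscuity mean predicted targets per active compound.
#' @param dark_fraction share of compounds with no predictions.
#' @param novelty_shape Beta shape parameters of family novelty.
#' @param year_range inclusive calendar range of record years.
#' @param cutoff_year novelty cutoff year.
#' @param multi_family_fraction share of targets assigned two families.
#' @param unmapped_fraction share of targets with no family (dummy).
#' @param missing_year_fraction share of records without a date.
#' @param records_per_target_mu,records_per_target_size negative-binomial
#'   parameters of the per-target reference record count (plus one).
#' @param seed integer RNG seed.
#' @return named list of generator settings.
#' @export
fixture_config <- function(n_compounds = 10000L, n_targets = 300L,
                           n_families = 120L, promiscuity = 3,
                           dark_fraction = 0.49,
                           novelty_shape = c(3.5, 1.5),
                           year_range = c(1995L, 2020L),
                           cutoff_year = 2010L,
                           multi_family_fraction = 0.10,
                           unmapped_fraction = 0.02,
                           missing_year_fraction = 0.04,
                           records_per_target_mu = 9,
                           records_per_target_size = 0.7,
                           seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_targets = as.integer(n_targets),
              n_families = as.integer(n_families),
              promiscuity = promiscuity,
              dark_fraction = dark_fraction,
              novelty_shape = novelty_shape,
              year_range = as.integer(year_range),
              cutoff_year = as.integer(cutoff_year),
              multi_family_fraction = multi_family_fraction,
              unmapped_fraction = unmapped_fraction,
              missing_year_fraction = missing_year_fraction,
              records_per_target_mu = records_per_target_mu,
              records_per_target_size = records_per_target_size,
              seed = as.integer(seed))
  stopifnot(cfg$n_compounds > 0, cfg$n_targets > 0, cfg$n_families > 0,
            cfg$promiscuity >= 1,
            cfg$dark_fraction >= 0, cfg$dark_fraction <= 1,
            cfg$multi_family_fraction >= 0, cfg$multi_family_fraction <= 1,
            cfg$unmapped_fraction >= 0, cfg$unmapped_fraction <= 1,
            cfg$missing_year_fraction >= 0, cfg$missing_year_fraction <= 1,
            length(cfg$novelty_shape) == 2, all(cfg$novelty_shape > 0),
            cfg$year_range[1] < cfg$cutoff_year,
            cfg$cutoff_year <= cfg$year_range[2])
  cfg
}

#' Generate a synthetic annotated candidate pool
#'
#' Deterministic (seeded) generator of everything the optimizer consumes
#' downstream of chemistry: a compound pool with dark-matter flags, target
#' predictions with supporting similarities, a target-to-family mapping
#' with multi-family and unmapped targets, and dated bioactivity records
#' whose realized family novelty follows the configured Beta law. The
#' novelty table included in the result is recomputed from the emitted
#' records through [novelty_table()], so it is self-consistent by
#' construction.
#'
#' @param cfg a [fixture_config()].
#' @return list with `pool` (data.frame `compound_id`, `in_pcc`),
#'   `predictions`, `family_map`, `bioactivities`, `assignment`,
#'   `novelty` and `config`.
#' @export
synth_annotation_pool <- function(cfg = fixture_config()) {
  set.seed(cfg$seed)
  targets <- sprintf("T%04d", seq_len(cfg$n_targets))
  families <- sprintf("FAM%04d", seq_len(cfg$n_families))

  # family sizes: power-law weights so a few families hold many targets
  fam_w <- 1 / seq_len(cfg$n_families)
  n_unmapped <- floor(cfg$unmapped_fraction * cfg$n_targets)
  unmapped <- if (n_unmapped > 0) sample(targets, n_unmapped) else character()
  mapped <- setdiff(targets, unmapped)
  primary <- sample(families, length(mapped), replace = TRUE, prob = fam_w)
  names(primary) <- mapped
  n_multi <- floor(cfg$multi_family_fraction * length(mapped))
  multi <- if (n_multi > 0) sample(mapped, n_multi) else character()
  second <- vapply(multi, function(t) {
    sample_vec(setdiff(families, primary[[t]]), 1L)
  }, character(1))
  family_map <- rbind(
    data.frame(target_id = mapped, family_id = unname(primary),
               stringsAsFactors = FALSE),
    data.frame(target_id = multi, family_id = unname(second),
               stringsAsFactors = FALSE))
  family_map <- family_map[order(family_map$target_id,
                                 family_map$family_id), , drop = FALSE]
  rownames(family_map) <- NULL
  assignment <- assign_families(targets, family_map)

  # dated reference records per target; year recency driven by the
  # (primary) family's Beta-distributed novelty propensity
  fam_p <- stats::setNames(
    stats::rbeta(cfg$n_families + 1L,
                 cfg$novelty_shape[1], cfg$novelty_shape[2]),
    c(families, dummy_family()))
  n_rec <- 1L + stats::rnbinom(cfg$n_targets,
                               size = cfg$records_per_target_size,
                               mu = cfg$records_per_target_mu)
  rec_target <- rep(targets, n_rec)
  rec_primary <- vapply(rec_target, function(t) {
    if (t %in% mapped) primary[[t]] else dummy_family()
  }, character(1))
  recent <- stats::runif(length(rec_target)) < fam_p[rec_primary]
  year <- integer(length(rec_target))
  year[recent] <- sample(seq.int(cfg$cutoff_year, cfg$year_range[2]),
                         sum(recent), replace = TRUE)
  year[!recent] <- sample(seq.int(cfg$year_range[1], cfg$cutoff_year - 1L),
                          sum(!recent), replace = TRUE)
  year[stats::runif(length(year)) < cfg$missing_year_fraction] <- NA_integer_
  bioactivities <- data.frame(target_id = rec_target, year = year,
                              stringsAsFactors = FALSE)
  rownames(bioactivities) <- NULL

  # compounds: dark matter plus skewed per-compound target counts
  compound_id <- sprintf("C%06d", seq_len(cfg$n_compounds))
  n_dark <- round(cfg$dark_fraction * cfg$n_compounds)
  dark <- rep(FALSE, cfg$n_compounds)
  if (n_dark > 0) dark[sample.int(cfg$n_compounds, n_dark)] <- TRUE
  tgt_w <- 1 / seq_len(cfg$n_targets)^0.8  # promiscuous targets are shared
  pred_targets <- vector("list", cfg$n_compounds)
  max_sim <- numeric(cfg$n_compounds)
  for (i in seq_len(cfg$n_compounds)) {
    if (dark[i]) {
      pred_targets[[i]] <- character()
      max_sim[i] <- stats::runif(1, 0.05, 0.4999)
    } else {
      k <- 1L + stats::rnbinom(1L, size = 0.9, mu = cfg$promiscuity - 1)
      k <- min(k, cfg$n_targets)
      pred_targets[[i]] <- sort(sample(targets, k, prob = tgt_w))
      max_sim[i] <- stats::runif(1, 0.5, 1)
    }
  }
  predictions <- data.frame(compound_id = compound_id,
                            max_similarity = max_sim,
                            n_targets = lengths(pred_targets),
                            targets = I(pred_targets),
                            dark = dark,
                            stringsAsFactors = FALSE)
  list(pool = data.frame(compound_id = compound_id, in_pcc = !dark,
                         stringsAsFactors = FALSE),
       predictions = predictions,
       family_map = family_map,
       bioactivities = bioactivities,
       assignment = assignment,
       novelty = novelty_table(bioactivities, assignment,
                               cutoff_year = cfg$cutoff_year),
       config = cfg)
}

# -- chemistry-tier fixtures --------------------------------------------------

# substituted two-ring amide/amine templates whose every substituent
# combination stays inside all property-filter bounds
pass_templates <- function() {
  c("COc1ccc(C(=O)Nc2ccc(N3CCOCC3)cc2%s)cc1%s",
    "Cc1ccc(S(=O)(=O)Nc2ccc(N3CCOCC3)cc2%s)cc1%s",
    "O=C(Nc1ccc(N2CCOCC2)cc1%s)c1ccc2ccccc2c1%s",
    "CN1CCN(c2ccc(NC(=O)c3ccc(C)c(C)c3%s)cc2%s)CC1",
    "COc1ccc(CNC(=O)c2ccc(-c3ccc(C)cc3%s)cc2%s)cc1",
    "Cc1cc(C)c(C(=O)Nc2ccc(OCC3CCOC3)cc2%s)c(C)c1%s")
}

pass_substituents <- function() c("", "C", "F", "Cl", "OC", "CC")

#' Generate a synthetic chemistry-tier compound pool
#'
#' Enumerates substituted heteroaromatic amide/sulfonamide structures from
#' a fixed template grammar whose every substituent combination satisfies
#' all eligibility and property filters, and mixes in deliberate
#' single-rule violators from [filter_rule_fixture()] plus salt/charged
#' input forms that standardize onto the drug-like grammar. The pass
#' fraction is controlled by `pass_fraction`.
#'
#' @param n number of records to generate.
#' @param seed integer RNG seed.
#' @param pass_fraction share of records drawn from the pass-designed
#'   grammar (default 0.75).
#' @return data.frame with columns `id`, `smiles` and `designed`
#'   (`"pass"`, `"salt_form"`, or the name of the designed violated rule).
#' @export
synth_chemistry_pool <- function(n, seed = 1L, pass_fraction = 0.75) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  templates <- pass_templates()
  subs <- pass_substituents()
  violators <- filter_rule_fixture()
  violators <- violators[violators$rule != "none", , drop = FALSE]

  n_pass <- round(pass_fraction * n)
  n_salt <- min(round(0.05 * n), n - n_pass)
  n_bad <- n - n_pass - n_salt
  rows <- vector("list", n)
  draw_pass <- function() {
    sprintf(sample_vec(templates, 1L), sample_vec(subs, 1L),
            sample_vec(subs, 1L))
  }
  for (i in seq_len(n)) {
    if (i <= n_pass) {
      rows[[i]] <- c(draw_pass(), "pass")
    } else if (i <= n_pass + n_salt) {
      rows[[i]] <- c(paste0(draw_pass(), ".Cl"), "salt_form")
    } else {
      j <- ((i - n_pass - n_salt - 1L) %% nrow(violators)) + 1L
      rows[[i]] <- c(violators$smiles[j], violators$rule[j])
    }
  }
  out <- data.frame(id = sprintf("Z%05d", seq_len(n)),
                    smiles = vapply(rows, `[`, character(1), 1L),
                    designed = vapply(rows, `[`, character(1), 2L),
                    stringsAsFactors = FALSE)
  out
}

#' Single-rule violator suite for the property filters
#'
#' A fixed panel of hand-designed structures, one per filter rule, each
#' violating exactly that rule after standardization, plus one compliant
#' control (`rule = "none"`). The `exclusion_smarts` violator carries a
#' nitro group and is meant to be screened with
#' [example_exclusion_patterns()].
#'
#' @return data.frame with columns `id`, `smiles`, `rule`.
#' @export
filter_rule_fixture <- function() {
  data.frame(
    id = c("FX_CONTROL", "FX_MW", "FX_ELEMENT", "FX_HEAVY", "FX_RINGS",
           "FX_FUSED", "FX_ROT", "FX_HBD", "FX_HBA", "FX_CHARGED_C",
           "FX_NO_NO", "FX_ALERT", "FX_TOSYL", "FX_BAD"),
    smiles = c(
      # compliant control: methoxy-benzanilide with a morpholine
      "COc1ccc(C(=O)Nc2ccc(N3CCOCC3)cc2)cc1",
      # below 250 Da but 18 heavy atoms: methyl-diphenylfuran
      "Cc1cc(-c2ccccc2)oc1-c1ccccc1",
      # boron outside the element whitelist (pinacol boronate)
      "CC1(C)OB(OC1(C)C)c1ccc(C(=O)Nc2ccccc2)cc1",
      # 31 heavy atoms: di-tert-butyl benzanilide with morpholine
      "CC(C)(C)c1cc(C(C)(C)C)cc(C(=O)Nc2ccc(N3CCOCC3)cc2C)c1C",
      # five rings, none fused: tetraphenylfuran
      "c1ccc(-c2oc(-c3ccccc3)c(-c3ccccc3)c2-c2ccccc2)cc1",
      # four fused rings: 1-pyrenebutyric acid
      "OC(=O)CCCc1ccc2ccc3cccc4ccc1c2c34",
      # nine rotatable bonds: dialkoxy ether chain
      "COc1ccc(OCCCCCCN2CCOCC2)cc1",
      # four hydrogen-bond donors: catechol bis-amide
      "NC(=O)c1ccc(NC(=O)c2ccc(O)c(O)c2)cc1C",
      # eight acceptors: tetramethoxybenzamide on aminopyridine-morpholine
      "COc1cc(OC)c(OC)c(OC)c1C(=O)Nc1ccc(N2CCOCC2)cn1",
      # formally charged carbon: aryl isocyanide
      "[C-]#[N+]c1ccc(C(=O)Nc2ccc(N3CCOCC3)cc2)cc1",
      # no nitrogen or oxygen: chloro-methyl-terphenyl
      "Cc1ccc(-c2ccc(-c3ccc(Cl)cc3)cc2)cc1",
      # nitro group (matches the example exclusion alert)
      "O=[N+]([O-])c1ccc(C(=O)Nc2ccc(N3CCOCC3)cc2)cc1",
      # tosylate ester (matches the built-in tosyl SMARTS)
      "Cc1ccc(S(=O)(=O)OCCc2ccc(OC)cc2)cc1",
      # unparseable SMILES (unclosed ring)
      "C1CC("),
    rule = c("none", "mw_range", "element_whitelist", "heavy_atoms",
             "ring_count", "fused_rings", "rotatable_bonds", "hbd", "hba",
             "charged_carbon", "no_N_or_O", "exclusion_smarts", "tosyl",
             "unparseable"),
    stringsAsFactors = FALSE
  )
}

#' Example structural-alert table
#'
#' A minimal exclusion SMARTS table (a nitro alert) in the format expected
#' by [property_profile()] and [filter_pool()]: one named SMARTS per row.
#' Production use should supply the full curated alert lists in the same
#' format.
#'
#' @return data.frame with columns `name`, `smarts`.
#' @export
example_exclusion_patterns <- function() {
  data.frame(name = "nitro", smarts = "[N+](=O)[O-]",
             stringsAsFactors = FALSE)
}
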