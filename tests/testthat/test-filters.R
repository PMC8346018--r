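test_that("eligibility check enforces molecular weight range and element whitelist", {
  std <- standardize_compounds(c("CCO", "COc1ccc(C(=O)Nc2ccc(CN3CCOCC3)cc2)cc1",
                                 "CC1(C)OB(OC1(C)C)c1ccc(C(=O)Nc2ccccc2)cc1"),
                               ids = c("ethanol", "amide", "boronate"))
  v <- eligibility_check(std)
  expect_equal(v$violated_rules[[1]], "mw_range")      # MW 46 < 250
  expect_true(v$passed[2])                             # ~340 Da, CHNO only
  expect_equal(v$violated_rules[[3]], "element_whitelist")
})

test_that("property profile counts descriptors and matches SMARTS alerts", {
  prof <- property_profile(
    c(caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      tosylate = "CCOS(=O)(=O)c1ccc(C)cc1",
      isocyanide = "[C-]#[N+]c1ccccc1"),
    patterns = example_exclusion_patterns())
  expect_equal(prof$heavy_atoms[1], 14L)
  expect_equal(prof$rings[1], 2L)
  expect_equal(prof$hbd[1], 0L)
  expect_true(prof$has_N_or_O[1])
  expect_true(prof$qed[1] > 0 && prof$qed[1] < 1)
  expect_true("tosyl" %in% prof$matched_exclusion_patterns[[2]])
  expect_true(prof$has_charged_carbon[3])
  expect_false(any(prof$has_charged_carbon[1:2]))
  expect_true(all(prof$max_fused_system_rings <= prof$rings))
  fps <- attr(prof, "fingerprints")
  expect_equal(dim(fps), c(3L, 2048L))
  expect_true(all(rowSums(fps[1:2, ]) > 0))
})

test_that("apply_filters reports every violated rule, not just the first", {
  base <- data.frame(id = "x", ok = TRUE, heavy_atoms = 24L, rings = 3L,
                     max_fused_system_rings = 2L, rotatable_bonds = 6L,
                     hbd = 1L, hba = 4L, has_charged_carbon = FALSE,
                     has_N_or_O = TRUE,
                     matched_exclusion_patterns = I(list(character())),
                     stringsAsFactors = FALSE)
  expect_true(apply_filters(base)$passed)

  cases <- list(
    list(heavy_atoms = 31L, rule = "heavy_atoms"),
    list(heavy_atoms = 17L, rule = "heavy_atoms"),
    list(rings = 0L, rule = "ring_count"),
    list(rings = 5L, rule = "ring_count"),
    list(max_fused_system_rings = 4L, rings = 4L, rule = "fused_rings"),
    list(rotatable_bonds = 9L, rule = "rotatable_bonds"),
    list(hbd = 4L, rule = "hbd"),
    list(hba = 8L, rule = "hba"),
    list(has_charged_carbon = TRUE, rule = "charged_carbon"),
    list(has_N_or_O = FALSE, rule = "no_N_or_O"))
  for (case in cases) {
    p <- base
    for (field in setdiff(names(case), "rule")) p[[field]] <- case[[field]]
    expect_equal(apply_filters(p)$violated_rules[[1]], case$rule)
  }

  multi <- base
  multi$heavy_atoms <- 31L
  multi$rotatable_bonds <- 9L
  multi$matched_exclusion_patterns <- I(list(c("nitro", "tosyl")))
  expect_setequal(apply_filters(multi)$violated_rules[[1]],
                  c("heavy_atoms", "rotatable_bonds", "exclusion_smarts",
                    "tosyl"))
})

test_that("the single-rule violator suite is classified exactly as designed", {
  fx <- filter_rule_fixture()
  res <- filter_pool(fx[, c("id", "smiles")],
                     patterns = example_exclusion_patterns())
  for (i in seq_len(nrow(fx))) {
    id <- fx$id[i]
    rule <- fx$rule[i]
    if (rule == "none") {
      expect_true(id %in% res$pass$id, label = id)
    } else if (rule == "unparseable") {
      j <- match(id, res$rejected$id)
      expect_equal(res$rejected$violated_rules[[j]], "unparseable")
    } else {
      j <- match(id, res$verdicts$id)
      expect_equal(res$verdicts$violated_rules[[j]], rule,
                   label = paste("verdict for", id))
    }
  }
})

test_that("filter_pool standardizes salts onto the pass grammar and keeps fingerprints aligned", {
  pool <- synth_chemistry_pool(40, seed = 3)
  res <- filter_pool(pool[, c("id", "smiles")],
                     patterns = example_exclusion_patterns())
  designed_pass <- pool$id[pool$designed %in% c("pass", "salt_form")]
  # designed-pass records are never rejected: they either pass or were
  # merged into a passing duplicate during deduplication
  expect_length(intersect(designed_pass, res$rejected$id), 0L)
  surviving <- intersect(designed_pass, res$verdicts$id)
  expect_true(all(res$verdicts$passed[match(surviving, res$verdicts$id)]))
  fps <- attr(res$pass, "fingerprints")
  expect_equal(rownames(fps), res$pass$id)
  expect_true(all(rowSums(fps) > 0))
})
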