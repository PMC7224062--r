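mk_variant <- function(consequence = "missense", maf = NA_real_,
                       verdict = "unavailable", db_class = NA_character_,
                       seg = 0L, gene = "PKD1", hgvs = "c.1A>G") {
  tibble::tibble(gene = gene, hgvs = hgvs, consequence = consequence,
                 maf = maf, verdict = verdict, db_class = db_class,
                 seg_affected_carriers = seg)
}

test_that("frequency filter keeps rare alleles and logs removals", {
  v <- dplyr::bind_rows(mk_variant(maf = 0.05, hgvs = "common"),
                        mk_variant(maf = 0, hgvs = "absent"),
                        mk_variant(maf = NA, hgvs = "missing"))
  kept <- filter_by_frequency(v)
  expect_setequal(kept$hgvs, c("absent", "missing"))
  expect_equal(attr(kept, "removed")$hgvs, "common")
  expect_equal(nrow(filter_by_frequency(v, maf_cutoff = 1)), 3)
})

test_that("headline classification examples", {
  expect_equal(classify_variants(mk_variant("nonsense"))$category, "P")
  expect_equal(classify_variants(mk_variant("frameshift", maf = 0.3))$category,
               "P")  # truncating dominates frequency
  expect_equal(
    classify_variants(mk_variant("missense", maf = 0,
                                 verdict = "pathogenic_lean"))$category, "LP")
  expect_equal(
    classify_variants(mk_variant("missense", maf = 0.004,
                                 verdict = "pathogenic_lean"))$category, "VUS")
  expect_equal(
    classify_variants(mk_variant("missense", maf = 0.004,
                                 verdict = "conflicting"))$category, "VUS")
  expect_equal(classify_variants(mk_variant("missense", maf = 0.02))$category,
               "LB")
  expect_equal(classify_variants(mk_variant("missense", maf = 0.2))$category,
               "B")
  expect_equal(
    classify_variants(mk_variant("missense", db_class = "H"))$category, "H")
  expect_equal(
    classify_variants(mk_variant("missense", seg = 2L))$category, "LP")
  expect_error(classify_variants(mk_variant("weird")), "unknown consequence")
})

test_that("exhaustive rule-table enumeration: one category, truncating => P", {
  grid <- expand.grid(
    consequence = c("frameshift", "nonsense", "canonical_splice",
                    "large_rearrangement", "missense", "synonymous",
                    "inframe_indel", "intronic"),
    maf = c(NA, 0, 0.004, 0.006, 0.02, 0.08),
    verdict = c("pathogenic_lean", "benign_lean", "conflicting",
                "unavailable"),
    db_class = c(NA, "P", "LP", "H"),
    seg = c(0L, 1L, 2L, 3L),
    stringsAsFactors = FALSE)
  grid$gene <- "PKD1"
  grid$hgvs <- sprintf("v%d", seq_len(nrow(grid)))
  names(grid)[names(grid) == "seg"] <- "seg_affected_carriers"
  out <- classify_variants(tibble::as_tibble(grid))
  expect_equal(nrow(out), nrow(grid))
  expect_true(all(out$category %in% c("P", "LP", "VUS", "LB", "B", "H")))
  expect_true(all(nchar(out$category) > 0))
  # truncating dominance, with no exception
  trunc <- out$consequence %in% c("frameshift", "nonsense",
                                  "canonical_splice", "large_rearrangement")
  expect_identical(out$truncating, trunc)
  expect_true(all(out$category[trunc] == "P"))
  # frequency invariant: common alleles are LB/B unless a prior overrides
  common <- !trunc & !is.na(out$maf) & out$maf > 0.01 & is.na(out$db_class)
  expect_true(all(out$category[common] %in% c("LB", "B")))
  # audit completeness: rules are non-empty and reconstruct the category
  expect_true(all(lengths(out$applied_rules) > 0))
  final_rule <- vapply(out$applied_rules, function(r) r[length(r)],
                       character(1))
  rule_to_cat <- c(PT_TRUNCATING_P = "P", DB_PRIOR_P = "P", DB_PRIOR_LP = "LP",
                   DB_PRIOR_H = "H", MAF_COMMON_B = "B",
                   MAF_ABOVE_CUTOFF_LB = "LB", INSILICO_PATH_ABSENT_LP = "LP",
                   INSILICO_PATH_RARE_VUS = "VUS",
                   INSILICO_BENIGN_NEARCUTOFF_LB = "LB", DEFAULT_VUS = "VUS",
                   SEGREGATION_UPGRADE_LP = "LP")
  expect_identical(unname(rule_to_cat[final_rule]), out$category)
  # determinism
  expect_identical(out$category,
                   classify_variants(tibble::as_tibble(grid))$category)
})

test_that("hypomorphic reclassification requires trans (or de novo main
           with transmission from an unaffected parent) and early onset", {
  two <- classify_variants(dplyr::bind_rows(
    mk_variant("frameshift", hgvs = "main"),
    mk_variant("missense", maf = 0.004, hgvs = "extra")))
  h <- reclassify_hypomorphic(two, "extra", "main", onset_class = "EO",
                              phase = "trans")
  expect_equal(h$category[h$hgvs == "extra"], "H")
  expect_true("HYPOMORPHIC_TRANS_EARLY_ONSET" %in%
                h$applied_rules[[which(h$hgvs == "extra")]])
  # cis -> unchanged; adult onset -> unchanged
  expect_equal(reclassify_hypomorphic(two, "extra", "main", "EO",
                                      "cis")$category[2], "VUS")
  expect_equal(reclassify_hypomorphic(two, "extra", "main", "adult",
                                      "trans")$category[2], "VUS")
  # de novo main + transmission from unaffected parent qualifies
  dn <- reclassify_hypomorphic(two, "extra", "main", "EO",
                               phase = "de_novo_unknown",
                               main_de_novo = TRUE,
                               from_unaffected_parent = TRUE)
  expect_equal(dn$category[2], "H")
  expect_error(reclassify_hypomorphic(two, "main", "main", "EO", "trans"),
               "main variant itself")
  vus_main <- classify_variants(dplyr::bind_rows(
    mk_variant("missense", hgvs = "weak_main"),
    mk_variant("missense", maf = 0.004, hgvs = "extra")))
  expect_error(reclassify_hypomorphic(vus_main, "extra", "weak_main", "EO",
                                      "trans"), "P/LP")
  tr <- classify_variants(dplyr::bind_rows(
    mk_variant("frameshift", hgvs = "main"),
    mk_variant("nonsense", hgvs = "extra")))
  expect_error(reclassify_hypomorphic(tr, "extra", "main", "EO", "trans"),
               "non-truncating")
})

test_that("nosology labels follow the main variant", {
  lab <- function(v) assign_nosology(classify_variants(v))$label
  expect_equal(lab(mk_variant("frameshift")), "ADPKD-PKD1-T")
  expect_equal(lab(mk_variant("missense", maf = 0,
                              verdict = "pathogenic_lean")), "ADPKD-PKD1-NT")
  expect_equal(lab(mk_variant("nonsense", gene = "PKD2")), "ADPKD-PKD2")
  expect_equal(lab(mk_variant("missense")), "PKD-VUS-only")
  expect_equal(lab(mk_variant("missense", maf = 0.02)), "negative")
  expect_equal(assign_nosology(NULL)$label, "negative")
  # main-variant rule: P truncating + H additional -> T label
  both <- classify_variants(dplyr::bind_rows(
    mk_variant("nonsense", hgvs = "a"),
    mk_variant("missense", db_class = "H", hgvs = "b")))
  nos <- assign_nosology(both)
  expect_equal(nos$label, "ADPKD-PKD1-T")
  expect_equal(nos$main_hgvs, "a")
  expect_equal(nos$n_additional, 1L)
})
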