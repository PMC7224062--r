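states <- c("carrier", "non_carrier", "unknown")

test_that("phase inference matches the brute-force transmission oracle
           on all 81 parental-state combinations", {
  grid <- expand.grid(v1m = states, v1f = states, v2m = states, v2f = states,
                      stringsAsFactors = FALSE)
  got <- mapply(infer_phase, grid$v1m, grid$v1f, grid$v2m, grid$v2f)
  want <- mapply(phase_oracle, grid$v1m, grid$v1f, grid$v2m, grid$v2f)
  expect_identical(unname(got), unname(want))
  expect_equal(nrow(grid), 81)
})

test_that("canonical phase examples", {
  expect_equal(infer_phase("carrier", "non_carrier",
                           "non_carrier", "carrier"), "trans")
  expect_equal(infer_phase("carrier", "non_carrier",
                           "carrier", "non_carrier"), "cis")
  expect_equal(infer_phase("non_carrier", "non_carrier",
                           "carrier", "non_carrier"), "de_novo_unknown")
  expect_equal(infer_phase("unknown", "unknown",
                           "carrier", "non_carrier"), "unknown")
})

test_that("de novo detection and its mosaicism caveat", {
  got <- detect_de_novo("carrier", "non_carrier", "non_carrier")
  expect_true(isTRUE(got$de_novo))
  expect_match(got$caveat, "mosaicism")
  expect_false(detect_de_novo("carrier", "carrier", "non_carrier")$de_novo)
  expect_equal(detect_de_novo("carrier", "non_carrier", "unknown")$de_novo,
               "indeterminate")
  expect_false(detect_de_novo("non_carrier", "unknown", "unknown")$de_novo)
})

test_that("family categorization covers every documented category", {
  v <- function(gene, category, origin, homozygous = FALSE) {
    tibble::tibble(gene = gene, category = category, origin = origin,
                   homozygous = homozygous)
  }
  expect_equal(categorize_family(v("PKD1", "P", "maternal")), "monoallelic")
  expect_equal(categorize_family(v("PKD1", "P", "unknown", TRUE)), "biallelic")
  expect_equal(categorize_family(
    v(c("PKD1", "PKD1"), c("P", "VUS"), c("maternal", "paternal")),
    phase = "trans"), "biallelic")
  expect_equal(categorize_family(
    v(c("PKD2", "PKD1"), c("P", "H"), c("maternal", "paternal"))),
    "bilineal")
  expect_equal(categorize_family(
    v(c("PKD2", "PKD1"), c("P", "VUS"), c("maternal", "unknown"))),
    "digenic")
  expect_equal(categorize_family(v("PKD1", "P", "maternal"),
                                 parent_vaf = 0.04), "mosaic_parent")
  expect_equal(categorize_family(v("PKD1", "LB", "maternal")), "unresolved")
})

test_that("Table 5 scenarios reproduce the published phase labels", {
  # 17016: main from the affected mother, additional from the father -> trans
  expect_equal(infer_phase("carrier", "non_carrier",
                           "non_carrier", "carrier"), "trans")
  # 16533 / 17474: main variant absent in both parents -> de novo, pair
  # phase unresolvable
  expect_equal(infer_phase("non_carrier", "non_carrier",
                           "non_carrier", "carrier"), "de_novo_unknown")
  # 15686 / 16051 / 16813: no parental data -> unknown, never guessed
  expect_equal(infer_phase("unknown", "unknown", "unknown", "unknown"),
               "unknown")
  # 17045: homozygous hypomorphic PKD1 variant -> biallelic
  expect_equal(categorize_family(
    tibble::tibble(gene = "PKD1", category = "H", origin = "unknown",
                   homozygous = TRUE)), "biallelic")
  # 18287: de novo PKD2 P on the maternal line plus a paternal PKD1
  # hypomorphic variant -> bilineal
  expect_equal(categorize_family(
    tibble::tibble(gene = c("PKD2", "PKD1"), category = c("P", "H"),
                   origin = c("maternal", "paternal")), phase = "trans"),
    "bilineal")
})

test_that("no category is emitted without its preconditions (fuzz)", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:3, 1)
    vars <- tibble::tibble(
      gene = sample(c("PKD1", "PKD2"), n, replace = TRUE),
      category = sample(c("P", "LP", "VUS", "H", "LB", "B"), n,
                        replace = TRUE),
      origin = sample(c("maternal", "paternal", "de_novo", "unknown"), n,
                      replace = TRUE),
      homozygous = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.2, .8)))
    phase <- sample(c(NA, "trans", "cis", "unknown"), 1)
    cat <- categorize_family(vars, phase = if (is.na(phase)) NULL else phase)
    focal <- vars[vars$category %in% c("P", "LP", "VUS", "H"), ]
    if (cat == "biallelic") {
      expect_true(any(focal$homozygous) ||
                    (length(unique(focal$gene)) == 1 && nrow(focal) >= 2 &&
                       identical(phase, "trans")))
    }
    if (cat == "bilineal") {
      expect_true(length(unique(focal$gene)) == 2)
    }
    if (cat == "monoallelic") {
      expect_true(nrow(focal) == 1 && focal$category[1] %in% c("P", "LP"))
    }
    if (cat == "unresolved") {
      expect_true(nrow(focal) == 0 || !any(focal$homozygous))
    }
  }
})

test_that("PED files round-trip and drive family_findings end to end", {
  ped <- tibble::tibble(
    fid = "F1", iid = c("fa", "mo", "kid"),
    pat = c("0", "0", "fa"), mat = c("0", "0", "mo"),
    sex = c(1L, 2L, 2L), phenotype = c(1L, 2L, 2L),
    var1 = c("non_carrier", "carrier", "carrier"),
    var2 = c("carrier", "non_carrier", "carrier"))
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)
  expect_equal(back$var1, ped$var1)
  expect_equal(back$var2, ped$var2)
  raw <- utils::read.table(path)
  expect_true(all(unlist(raw[, 7:8]) %in% 0:2))

  info <- tibble::tibble(variant_id = c("var1", "var2"),
                         gene = c("PKD1", "PKD1"),
                         category = c("P", "VUS"))
  out <- family_findings(back, info)
  expect_equal(nrow(out), 1)
  expect_equal(out$phase, "trans")
  expect_equal(out$family_category, "biallelic")
  expect_true(is.na(out$de_novo))
})

test_that("family_findings reports de novo carriers", {
  ped <- tibble::tibble(
    fid = "F2", iid = c("fa", "mo", "kid"),
    pat = c("0", "0", "fa"), mat = c("0", "0", "mo"),
    sex = c(1L, 2L, 1L), phenotype = c(1L, 1L, 2L),
    var1 = c("non_carrier", "non_carrier", "carrier"))
  out <- family_findings(ped, tibble::tibble(variant_id = "var1",
                                             gene = "PKD1", category = "P"))
  expect_equal(out$de_novo, "var1")
  expect_true(is.na(out$phase))
})
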