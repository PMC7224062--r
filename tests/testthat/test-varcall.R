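test_that("pileup allele counts sum to depth and match injected reads", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  pos <- amps$start[1] + 350L
  refb <- substr(loc$gene_sequence, pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  reads <- simulate_reads(loc, amps, variant_scenario(pos, refb, altb),
                          depth = 120, error_model = read_error_model(0, 0),
                          contamination = 0, seed = 31)
  g <- locus_genome(loc)
  ref <- build_masked_reference(g$sequence, g$target)
  pu <- build_pileup(align_reads(reads, ref), ref)
  by_pos <- dplyr::summarise(dplyr::group_by(pu, pos),
                             total = sum(count), depth = depth[1],
                             .groups = "drop")
  expect_true(all(by_pos$total == by_pos$depth))
  site <- pu[pu$pos == pos, ]
  expect_setequal(site$allele, c(refb, altb))
  expect_true(all(site$fwd + site$rev == site$count))
})

test_that("call_germline genotype bands behave as documented", {
  mk <- function(alt, depth) {
    pileup_from_counts(100, "A", ref_count = depth - alt, alt_allele = "G",
                       alt_count = alt)
  }
  expect_equal(call_germline(mk(50, 100))$genotype, "het")
  expect_equal(call_germline(mk(95, 100))$genotype, "hom")
  expect_equal(call_germline(mk(15, 100))$genotype, "mosaic_candidate")
  amb <- call_germline(mk(85, 100))
  expect_equal(amb$genotype, "ambiguous")
  expect_true("suspect_fp_unbalanced" %in% amb$qc_flags[[1]])
  expect_equal(nrow(call_germline(mk(5, 100))), 0)   # below threshold
  expect_equal(nrow(call_germline(mk(8, 15))), 0)    # below min depth
  expect_error(call_germline(mk(50, 100), call_threshold = 0.5),
               "thresholds")
})

test_that("indel alleles are emitted in VCF anchored notation", {
  pu <- pileup_from_counts(c(100, 200), c("A", "C"),
                           ref_count = c(120, 130),
                           alt_allele = c("-TG", "+T"),
                           alt_count = c(80, 70))
  calls <- call_germline(pu)
  del <- calls[calls$pos == 100, ]
  expect_equal(del$ref, "ATG")
  expect_equal(del$alt, "A")
  ins <- calls[calls$pos == 200, ]
  expect_equal(ins$ref, "C")
  expect_equal(ins$alt, "CT")
})

test_that("the 10% threshold hides a 7.1% mosaic from the germline caller", {
  pu <- pileup_from_counts(100, "A", ref_count = 2193 - 156,
                           alt_allele = "-TG", alt_count = 156)
  expect_equal(nrow(call_germline(pu)), 0)
  mos <- scan_mosaic(pu)
  expect_equal(nrow(mos), 1)
  expect_equal(mos$vaf_pct, 7.1)
})

test_that("scan_mosaic p values match a direct binomial-tail oracle", {
  pu <- pileup_from_counts(c(10, 20), c("A", "C"),
                           ref_count = c(400, 960),
                           alt_allele = c("G", "T"),
                           alt_count = c(30, 40))
  mos <- scan_mosaic(pu)
  expect_equal(nrow(mos), 2)
  expect_equal(mos$mosaic_p[mos$pos == 10],
               binom_tail_oracle(30, 430, 0.01), tolerance = 1e-10)
  expect_equal(mos$mosaic_p[mos$pos == 20],
               binom_tail_oracle(40, 1000, 0.01), tolerance = 1e-10)
})

test_that("scan_mosaic doubles the null rate in flagged contexts", {
  base <- scan_mosaic(pileup_from_counts(1, "A", 470, "G", 30))
  hp <- scan_mosaic(pileup_from_counts(1, "A", 470, "G", 30, hp_len = 6))
  expect_gt(hp$mosaic_p, base$mosaic_p)
  expect_equal(hp$mosaic_p, binom_tail_oracle(30, 500, 0.02),
               tolerance = 1e-10)
  off <- scan_mosaic(pileup_from_counts(1, "A", 470, "G", 30, hp_len = 6),
                     context_doubling = FALSE)
  expect_equal(off$mosaic_p, base$mosaic_p)
})

test_that("scan_mosaic applies Bonferroni over scanned positions and filters", {
  # marginal candidate: significant alone, not after correction over many sites
  k <- 11; n <- 500
  p1 <- binom_tail_oracle(k, n, 0.01)
  expect_true(p1 < 0.05 && p1 * 400 > 0.05)
  many <- pileup_from_counts(1:400, "A", ref_count = n - k,
                             alt_allele = "G",
                             alt_count = c(k, rep(0L, 399)))
  got <- scan_mosaic(many)
  expect_equal(nrow(got), 0)
  expect_equal(attr(got, "n_tests"), 400L)
  one <- scan_mosaic(pileup_from_counts(1, "A", n - k, "G", k))
  expect_equal(nrow(one), 1)
  # min_alt floor
  few <- scan_mosaic(pileup_from_counts(1, "A", 100, "G", 9))
  expect_equal(nrow(few), 0)
  expect_error(scan_mosaic(one, error_rate = 0.2), "scan window")
})

test_that("scan_mosaic returns a clean empty result when nothing qualifies", {
  pu <- pileup_from_counts(1, "A", ref_count = 500, alt_allele = "G",
                           alt_count = 1)
  got <- scan_mosaic(pu)
  expect_equal(nrow(got), 0)
  expect_s3_class(got, "pkd_calls")
})

test_that("qc_allele_balance flags unbalanced hets and context", {
  pu <- pileup_from_counts(c(1, 2), c("A", "C"),
                           ref_count = c(120, 100),
                           alt_allele = c("G", "T"),
                           alt_count = c(80, 100), hp_len = c(1L, 6L),
                           gc_frac = c(0.5, 0.8))
  calls <- qc_allele_balance(call_germline(pu))
  f1 <- calls$qc_flags[[which(calls$pos == 1)]]
  f2 <- calls$qc_flags[[which(calls$pos == 2)]]
  expect_false("suspect_fp_unbalanced" %in% f1)  # VAF 0.4 within band
  expect_true("homopolymer_context" %in% f2 || "gc_rich_context" %in% f2)
})

test_that("allele dropout is detected from overlapping-amplicon discordance", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  scen <- sample_dropout_scenario(loc, amps, seed = 41)
  reads <- simulate_reads(loc, amps, scen, depth = 150, seed = 42)
  g <- locus_genome(loc)
  ref <- build_masked_reference(g$sequence, g$target)
  aln <- align_reads(reads, ref)
  by_amp <- call_by_amplicon(aln, ref, amps)
  rep <- detect_allele_dropout(by_amp, amps)
  expect_true(scen$position %in% rep$pos)
  expect_true(all(rep$finding %in% c("allele_dropout_suspect", "vaf_shift")))
  expect_true(isTRUE(attr(rep, "possible")))
})

test_that("no dropout report without overlap or without discordance", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  # concordant calls in both amplicons -> nothing reported
  ovl <- amplicon_overlaps(amps)
  pos <- ovl$ov_start[1] + 5L
  calls <- call_germline(pileup_from_counts(pos, "A", 60, "G", 55))
  rep <- detect_allele_dropout(list(AMP1 = calls, AMP2 = calls), amps)
  expect_equal(nrow(rep), 0)
  # no overlaps at all -> warning and attr possible = FALSE
  amps2 <- amps
  attr(amps2, "overlaps") <- attr(amps, "overlaps")[0, ]
  expect_warning(rep2 <- detect_allele_dropout(list(), amps2), "not possible")
  expect_false(isTRUE(attr(rep2, "possible")))
})

test_that("VCF writer output is read back identically by VariantAnnotation", {
  pu <- pileup_from_counts(c(150, 300, 450), c("A", "C", "G"),
                           ref_count = c(100, 120, 90),
                           alt_allele = c("T", "-AG", "+TT"),
                           alt_count = c(95, 60, 50))
  calls <- call_germline(pu)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(calls, path, contig = "GENE", contig_length = 2000L)
  vcf <- VariantAnnotation::readVcf(path)
  expect_equal(unname(BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))),
               calls$pos)
  expect_equal(as.character(VariantAnnotation::ref(vcf)), calls$ref)
  expect_equal(unname(vapply(VariantAnnotation::alt(vcf), function(a) {
    as.character(a[[1]])
  }, character(1))), calls$alt)
  expect_equal(unname(VariantAnnotation::info(vcf)$DP), calls$depth)
})
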