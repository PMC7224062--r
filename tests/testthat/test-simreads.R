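test_that("variant_scenario validates its inputs", {
  s <- variant_scenario(100, "A", "C", "het")
  expect_equal(s$position, 100L)
  expect_error(variant_scenario(100, "A", "A"), "ref != alt")
  expect_error(variant_scenario(100, "A", "C", "mosaic"), "mosaic_fraction")
  expect_error(variant_scenario(100, "A", "C", "het", mosaic_fraction = 0.2),
               "only applies")
  m <- variant_scenario(100, "A", "C", "mosaic", mosaic_fraction = 0.07)
  expect_equal(m$mosaic_fraction, 0.07)
})

test_that("sampled scenarios sit outside primers, spaced, ref matching gene", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  scen <- sample_variant_scenarios(loc, amps, n = 4, min_spacing = 200,
                                   seed = 11)
  expect_equal(nrow(scen), 4)
  g <- strsplit(loc$gene_sequence, "")[[1]]
  expect_identical(scen$ref, g[scen$position])
  expect_true(all(diff(sort(scen$position)) > 200))
  for (i in seq_len(nrow(amps))) {
    expect_false(any(scen$position >= amps$fwd_start[i] &
                       scen$position <= amps$fwd_end[i]))
    expect_false(any(scen$position >= amps$rev_start[i] &
                       scen$position <= amps$rev_end[i]))
  }
  # paralog mimics carry a genuine paralog base
  mim <- scen[scen$paralog_mimic, ]
  if (nrow(mim) > 0) {
    hit <- vapply(seq_len(nrow(mim)), function(i) {
      any(vapply(seq_along(loc$paralogs), function(k) {
        substr(loc$paralogs[[k]], mim$position[i], mim$position[i]) == mim$alt[i]
      }, logical(1)))
    }, logical(1))
    expect_true(all(hit))
  }
})

test_that("dropout scenario lands in an amplicon overlap", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 3)
  scen <- sample_dropout_scenario(loc, amps, seed = 5)
  ov <- amplicon_overlaps(amps)
  pair <- ov[ov$a == scen$dropout_amplicon, ]
  expect_equal(nrow(pair), 1)
  expect_true(scen$position >= pair$ov_start && scen$position <= pair$ov_end)
})

test_that("homopolymer indel rate follows r(L) = min(r0 * 2^(L-3), cap)", {
  m <- read_error_model()
  expect_equal(pkdpanel:::hp_indel_rate(2, m), 0)
  expect_equal(pkdpanel:::hp_indel_rate(3, m), 0.002)
  expect_equal(pkdpanel:::hp_indel_rate(4, m), 0.004)
  expect_equal(pkdpanel:::hp_indel_rate(5, m), 0.008)
  expect_equal(pkdpanel:::hp_indel_rate(15, m), 0.2)  # capped
})

test_that("apply_variants edits sequences and maps coordinates", {
  seq <- "AACCGGTT"
  # SNV at 3 (C->T), deletion of base 6 (anchored at 5: ref GG alt G)
  vars <- dplyr::bind_rows(
    variant_scenario(3, "C", "T"),
    variant_scenario(5, "GG", "G"))
  ed <- pkdpanel:::apply_variants(seq, vars)
  expect_equal(ed$seq, "AATCGTT")
  expect_equal(ed$map(c(1, 3, 5, 7, 8)), c(1L, 3L, 5L, 6L, 7L))
})

test_that("error-free reads reproduce haplotype substrings exactly", {
  loc <- test_locus(length = 2000)
  amps <- design_amplicons(loc, n_amplicons = 2)
  scen <- variant_scenario(amps$start[1] + 300L,
                           substr(loc$gene_sequence, amps$start[1] + 300L,
                                  amps$start[1] + 300L),
                           setdiff(c("A", "C", "G", "T"),
                                   substr(loc$gene_sequence,
                                          amps$start[1] + 300L,
                                          amps$start[1] + 300L))[1])
  reads <- simulate_reads(loc, amps, scen, depth = 30,
                          error_model = read_error_model(0, 0),
                          contamination = 0, seed = 2)
  gene <- loc$gene_sequence
  fwd <- reads[reads$strand == "+" & reads$hap == "A", ]
  # haplotype A carries no het variant; + strand reads are plain substrings
  expect_true(all(vapply(seq_len(nrow(fwd)), function(i) {
    substr(gene, fwd$start[i], fwd$start[i] + nchar(fwd$seq[i]) - 1L) ==
      fwd$seq[i]
  }, logical(1))))
  rev <- reads[reads$strand == "-" & reads$hap == "A", ][1, ]
  expect_equal(pkdpanel:::revcomp_chr(rev$seq),
               substr(gene, rev$start, rev$start + nchar(rev$seq) - 1L))
})

test_that("het variants appear in reads at a binomial fraction", {
  loc <- test_locus(length = 2000)
  amps <- design_amplicons(loc, n_amplicons = 2)
  pos <- amps$start[1] + 400L
  refb <- substr(loc$gene_sequence, pos, pos)
  altb <- setdiff(c("A", "C", "G", "T"), refb)[1]
  reads <- simulate_reads(loc, amps, variant_scenario(pos, refb, altb),
                          depth = 300,
                          error_model = read_error_model(0, 0),
                          contamination = 0, seed = 9)
  cover <- reads[reads$start <= pos &
                   reads$start + nchar(reads$seq) - 1L >= pos, ]
  base_at <- vapply(seq_len(nrow(cover)), function(i) {
    s <- if (cover$strand[i] == "-") pkdpanel:::revcomp_chr(cover$seq[i])
         else cover$seq[i]
    substr(s, pos - cover$start[i] + 1L, pos - cover$start[i] + 1L)
  }, character(1))
  k <- sum(base_at == altb)
  n <- nrow(cover)
  # two-sided binomial check at p = 0.5 (hap B carries the variant)
  p <- stats::binom.test(k, n, 0.5)$p.value
  expect_gt(p, 1e-6)
  expect_true(all(base_at %in% c(refb, altb)))
})

test_that("dropout amplicon emits only the variant haplotype", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  scen <- sample_dropout_scenario(loc, amps, seed = 3)
  reads <- simulate_reads(loc, amps, scen, depth = 50, contamination = 0,
                          seed = 4)
  inside <- reads[reads$amplicon == scen$dropout_amplicon, ]
  expect_true(all(inside$hap == "B"))
  other <- reads[reads$amplicon != scen$dropout_amplicon, ]
  expect_true(all(c("A", "B") %in% other$hap))
})

test_that("contamination fraction of paralog reads is as configured", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  reads <- simulate_reads(loc, amps, NULL, depth = 400,
                          contamination = 0.05, seed = 6)
  frac <- mean(reads$origin != "gene")
  expect_gt(stats::binom.test(sum(reads$origin != "gene"),
                              nrow(reads), 0.05)$p.value, 1e-6)
  expect_true(frac > 0.02 && frac < 0.09)
})

test_that("simulate_reads is deterministic under a fixed seed", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  r1 <- simulate_reads(loc, amps, NULL, depth = 40, seed = 10)
  r2 <- simulate_reads(loc, amps, NULL, depth = 40, seed = 10)
  expect_identical(r1, r2)
})

test_that("FASTQ output round-trips", {
  loc <- test_locus()
  amps <- design_amplicons(loc, n_amplicons = 2)
  reads <- simulate_reads(loc, amps, NULL, depth = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(unname(back$read_id), reads$read_id)
  expect_equal(unname(back$seq), reads$seq)
})
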