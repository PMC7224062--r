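---
title: "Masked-reference analysis of a duplicated disease locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Masked-reference analysis of a duplicated disease locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdpanel)
```

## Why masking

About 70% of *PKD1* is duplicated in six pseudogenes at roughly 98%
nucleotide identity. A read sequenced from the gene therefore has six
near-perfect alternative homes in an ordinary reference, and a mapper will
happily use them: reads carrying a true variant drift to a pseudogene
contig (false negatives), while pseudogene-contaminating reads that do map
to the gene deposit their divergent bases as false calls. Masking
everything except the target locus removes the alternative homes — every
read competes only for target positions, and paralog divergence becomes
visible as mismatches that the confidence filter and the caller can
reason about.

This vignette walks the full chain on simulated data with known truth.

## Simulating a duplicated locus

```{r locus}
loc <- generate_locus(seed = 7, n_paralogs = 6, identity = 0.98,
                      length = 2000)
loc
amps <- design_amplicons(loc, n_amplicons = 2)
amps
```

`design_amplicons()` anchors each primer on locus-specific bases (sites
where the gene differs from every paralog), mimicking long-range PCR
primer design, and leaves the two amplicons overlapping so allele-dropout
checks are possible later.

## Sequencing a known variant through the noise

```{r reads}
refb <- substr(loc$gene_sequence, 760, 760)
scen <- variant_scenario(760, refb,
                         setdiff(c("A", "C", "G", "T"), refb)[1],
                         zygosity = "het")
reads <- simulate_reads(loc, amps, scen, depth = 200,
                        contamination = 0.05, seed = 8)
nrow(reads)
```

The error model scales indel rates with homopolymer length and inflates
errors in GC-rich windows, and 5% of reads are drawn from a random
paralog instead of the gene — the contamination that defeats unmasked
mapping.

## Masked alignment and calling

```{r call}
g <- locus_genome(loc)
ref <- build_masked_reference(g$sequence, g$target)
aln <- align_reads(reads, ref)
calls <- call_germline(build_pileup(aln, ref))
calls[, c("pos", "ref", "alt", "alt_depth", "depth", "vaf", "genotype")]
```

The injected heterozygote comes back at its position with a balanced VAF.
Alignments carry a mapping confidence from the margin between the best
and second-best placement; ambiguous reads are dropped before pileup.

## What masking buys

`run_masking_benchmark()` injects a pseudogene gene-conversion tract — the
worst case, where a stretch of the patient's gene carries every divergent
base of one paralog — and scores the same reads against the masked and
the unmasked reference:

```{r masking-benchmark}
bench <- run_masking_benchmark(seeds = 1:2, depth = 500,
                               compare_unmasked = TRUE)
bench[, c("seed", "arm", "n_truth", "n_called", "missed", "spurious",
          "n_false")]
```

On the masked reference every injected variant is recovered; on the
unmasked reference the conversion-tract reads are captured by the
pseudogene contig and the variants vanish.

## Sub-threshold mosaicism and allele dropout

```{r mosaic}
scan_mosaic(pileup_from_counts(1189, "A", ref_count = 2193 - 156,
                               alt_allele = "-TG", alt_count = 156))
```

A 7.1% allele fraction is invisible to the 10% germline threshold, but
the binomial scan — Bonferroni-corrected over every scanned position, with
the null error rate doubled in homopolymer and GC-rich contexts — flags
it. Overlapping amplicons give an orthogonal check: a variant het in one
amplicon but absent in the overlapping one suggests allele dropout, which
`detect_allele_dropout()` reports.

## Dosage, classification, families, cohorts

```{r mlpa}
panel <- mlpa_panel()
pk <- simulate_mlpa(c(ex08 = 1, ex09 = 1), panel, noise_sd = 0.05,
                    seed = 3)
dq <- normalize_dosage(pk[pk$sample == "case", ],
                       pk[pk$sample != "case", ], panel)
dosage_events(call_rearrangements(dq, panel))
```

```{r classify}
v <- tibble::tibble(
  gene = c("PKD1", "PKD1"), hgvs = c("c.11364del", "c.9829C>T"),
  consequence = c("frameshift", "missense"), maf = c(NA, 0.004),
  verdict = c("unavailable", "pathogenic_lean"),
  db_class = NA_character_, seg_affected_carriers = 0L)
cl <- classify_variants(v)
cl[, c("hgvs", "category", "truncating")]
assign_nosology(cl)
```

Every classification records the rule chain that produced it in
`applied_rules`, so each call is auditable. Trio phase comes from
parental carrier states, and `family_findings()` ties genotypes,
phase and de novo status into a per-family category:

```{r pedigree}
ped <- tibble::tibble(
  fid = "F1", iid = c("fa", "mo", "kid"),
  pat = c("0", "0", "fa"), mat = c("0", "0", "mo"),
  sex = c(1L, 2L, 2L), phenotype = c(1L, 2L, 2L),
  v_main  = c("non_carrier", "carrier", "carrier"),
  v_extra = c("carrier", "non_carrier", "carrier"))
family_findings(ped, tibble::tibble(variant_id = c("v_main", "v_extra"),
                                    gene = "PKD1",
                                    category = c("P", "VUS")))
```

Cohort-level reporting reproduces the standard summary layout:

```{r cohort}
co <- simulate_cohort(n = 212, seed = 1)
yield_table(tibble::tibble(nosology = co$nosology))
anova_onset(co)
```

## Running everything at once

The configured pipeline executes the whole chain deterministically and
writes a checksummed manifest:

```{r pipeline, eval = FALSE}
res <- run_pipeline(output_dir = "demo_run")
res$manifest
```

Re-running with the same configuration reproduces identical MD5 sums for
every output file.
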