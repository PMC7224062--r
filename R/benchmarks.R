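#' Gene-conversion-tract variant scenarios
#'
#' Builds the canonical stress case for masked-reference alignment: a
#' contiguous tract in which every gene-vs-paralog divergent position
#' carries the paralog's base as a heterozygous variant, mimicking a gene
#' conversion event between the gene and one of its pseudogenes. Reads
#' from the variant haplotype inside such a tract are locally identical to
#' the pseudogene, so on an unmasked multi-copy reference they map to the
#' pseudogene (or are discarded as ambiguous) and the variants vanish; on
#' a masked reference they can only map to the gene and the variants are
#' called. The tract is chosen deterministically: the first window (by
#' paralog, then position) lying fully outside primer windows whose
#' central segment — the positions every covering read fits inside the
#' tract — contains at least one divergent site.
#'
#' @param locus A `pkd_locus` with at least one paralog.
#' @param amplicons A `pkd_amplicons`.
#' @param tract_length Tract length in bases (default 3 read lengths, so
#'   the central segment is one read length long).
#' @param read_length Read length the simulation will use.
#' @return Scenario tibble (one het row per divergent site in the tract)
#'   with a `paralog_mimic` column and a `tract` attribute (tibble:
#'   `paralog`, `start`, `end`, `n_sites`, `n_central`).
#' @export
conversion_tract_scenarios <- function(locus, amplicons, tract_length = 600,
                                       read_length = 200) {
  stopifnot(inherits(locus, "pkd_locus"), length(locus$paralogs) > 0,
            tract_length >= 2 * read_length)
  eligible <- rep(FALSE, locus$length)
  for (i in seq_len(nrow(amplicons))) {
    eligible[amplicons$start[i]:amplicons$end[i]] <- TRUE
  }
  for (i in seq_len(nrow(amplicons))) {
    eligible[amplicons$fwd_start[i]:amplicons$fwd_end[i]] <- FALSE
    eligible[amplicons$rev_start[i]:amplicons$rev_end[i]] <- FALSE
  }
  run <- rle(eligible)
  run_end <- cumsum(run$lengths)
  run_start <- run_end - run$lengths + 1L
  open <- which(run$values & run$lengths >= tract_length)
  if (length(open) == 0) {
    stop("no primer-free stretch of ", tract_length, " bases exists; ",
         "reduce tract_length", call. = FALSE)
  }
  for (k in seq_along(locus$paralogs)) {
    div <- paralog_divergent_sites(locus, k)
    for (r in open) {
      for (t in seq(run_start[r], run_end[r] - tract_length + 1L, by = 50L)) {
        e <- t + tract_length - 1L
        central <- div$pos[div$pos >= t + read_length - 1L &
                             div$pos <= e - read_length + 1L]
        if (length(central) == 0) next
        sites <- div[div$pos >= t & div$pos <= e, , drop = FALSE]
        scen <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
          variant_scenario(sites$pos[i], sites$gene_base[i],
                           sites$paralog_base[i], zygosity = "het")
        })) |>
          dplyr::mutate(paralog_mimic = TRUE)
        attr(scen, "tract") <- tibble::tibble(
          paralog = names(locus$paralogs)[k], start = t, end = e,
          n_sites = nrow(sites), n_central = length(central))
        return(scen)
      }
    }
  }
  stop("no qualifying conversion tract found; increase locus length or ",
       "identity divergence", call. = FALSE)
}

# internal: scenario set for the masking benchmark — one conversion tract
# plus a few ordinary het SNVs away from it
masking_scenarios <- function(locus, amplicons, n_plain = 2,
                              tract_length = 600, read_length = 200,
                              min_spacing = 150, seed = NULL) {
  tract_scen <- conversion_tract_scenarios(locus, amplicons, tract_length,
                                           read_length)
  tract <- attr(tract_scen, "tract")
  with_seed(seed, {
    g <- strsplit(locus$gene_sequence, "")[[1]]
    eligible <- rep(FALSE, locus$length)
    for (i in seq_len(nrow(amplicons))) {
      eligible[amplicons$start[i]:amplicons$end[i]] <- TRUE
    }
    for (i in seq_len(nrow(amplicons))) {
      eligible[amplicons$fwd_start[i]:amplicons$fwd_end[i]] <- FALSE
      eligible[amplicons$rev_start[i]:amplicons$rev_end[i]] <- FALSE
    }
    block <- max(1L, tract$start - min_spacing):
      min(locus$length, tract$end + min_spacing)
    eligible[block] <- FALSE
    chosen <- integer(0)
    pool <- which(eligible)
    for (i in seq_len(n_plain)) {
      pool <- setdiff(pool, unlist(lapply(chosen, function(p) {
        (p - min_spacing):(p + min_spacing)
      })))
      if (length(pool) == 0) break
      chosen <- c(chosen, pool[sample.int(length(pool), 1)])
    }
    plain <- dplyr::bind_rows(lapply(chosen, function(p) {
      variant_scenario(p, g[p], sample(setdiff(c("A", "C", "G", "T"), g[p]), 1),
                       zygosity = "het")
    }))
    if (nrow(plain) > 0) plain$paralog_mimic <- FALSE
    out <- dplyr::bind_rows(tract_scen, plain) |>
      dplyr::arrange(.data$position)
    attr(out, "tract") <- tract
    out
  })
}

#' Compare a call set against injected variant scenarios
#'
#' Tallies the three ways a call set can disagree with the simulation
#' truth: spurious calls at positions never injected, injected variants
#' never called (false negatives), and injected variants called with the
#' wrong genotype. Their sum is the false-call count used by the masking
#' comparison.
#'
#' @param calls A `pkd_calls` tibble (restricted to the gene contig).
#' @param scenarios The injected scenario tibble (het/hom rows).
#' @return One-row tibble: `n_truth`, `n_called`, `missed`, `spurious`,
#'   `wrong_genotype`, `n_false`.
#' @export
count_call_discrepancies <- function(calls, scenarios) {
  truth_key <- paste(scenarios$position, scenarios$alt)
  call_key <- paste(calls$pos, calls$alt)
  spurious <- sum(!call_key %in% truth_key)
  hit <- match(truth_key, call_key)
  missed <- sum(is.na(hit))
  expected <- ifelse(scenarios$zygosity == "hom", "hom", "het")
  wrong <- sum(calls$genotype[hit[!is.na(hit)]] != expected[!is.na(hit)])
  tibble::tibble(n_truth = nrow(scenarios), n_called = sum(!is.na(hit)),
                 missed = missed, spurious = spurious,
                 wrong_genotype = wrong,
                 n_false = missed + spurious + wrong)
}

# internal: align, pile up and call one reference arm, restricted to the
# gene contig, and score against truth
run_masking_arm <- function(reads, ref, locus, scenarios, params) {
  aln <- align_reads(reads, ref, params)
  calls <- call_germline(build_pileup(aln, ref))
  calls <- calls[calls$pos <= locus$length, , drop = FALSE]
  count_call_discrepancies(calls, scenarios)
}

#' Masking-benefit benchmark
#'
#' For each seed, simulates a duplicated locus (by default 6 paralogs at
#' 98% identity), injects a pseudogene conversion tract plus ordinary
#' heterozygous SNVs, sequences it with paralog contamination, and runs
#' the identical alignment + calling pipeline against (i) the masked
#' reference and optionally (ii) the unmasked multi-copy reference. The
#' per-arm false-call counts quantify what masking buys: the conversion
#' variants are invisible on the unmasked reference because their reads
#' belong equally or better to a pseudogene contig.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param depth Mean per-base depth (default 500).
#' @param compare_unmasked Also run the unmasked comparator arm?
#' @param locus_length,n_paralogs,identity Locus parameters.
#' @param contamination Paralog read contamination fraction.
#' @param n_amplicons Amplicons tiling the locus.
#' @param read_length Read length.
#' @param params [alignment_params()].
#' @return Tibble with one row per seed and arm: `seed`, `arm`
#'   (`"masked"`/`"unmasked"`), plus the [count_call_discrepancies()]
#'   columns.
#' @export
run_masking_benchmark <- function(seeds, depth = 500,
                                  compare_unmasked = FALSE,
                                  locus_length = 2400, n_paralogs = 6,
                                  identity = 0.98, contamination = 0.05,
                                  n_amplicons = 2, read_length = 200,
                                  params = alignment_params()) {
  dplyr::bind_rows(lapply(seeds, function(seed) {
    locus <- generate_locus(seed, n_paralogs = n_paralogs,
                            identity = identity, length = locus_length)
    amps <- design_amplicons(locus, n_amplicons = n_amplicons)
    scen <- masking_scenarios(locus, amps, read_length = read_length,
                              seed = seed + 1000000L)
    reads <- simulate_reads(locus, amps, scen, depth = depth,
                            contamination = contamination,
                            seed = seed + 2000000L,
                            read_length = read_length)
    genome <- locus_genome(locus)
    masked <- build_masked_reference(genome$sequence, genome$target,
                                     source_name = "masked")
    out <- dplyr::mutate(
      run_masking_arm(reads, masked, locus, scen, params),
      seed = seed, arm = "masked", .before = 1)
    if (compare_unmasked) {
      unmasked <- build_masked_reference(
        genome$sequence,
        tibble::tibble(start = 1L, end = nchar(genome$sequence)),
        source_name = "unmasked")
      out <- dplyr::bind_rows(out, dplyr::mutate(
        run_masking_arm(reads, unmasked, locus, scen, params),
        seed = seed, arm = "unmasked", .before = 1))
    }
    out
  }))
}

#' Allele-dropout detection benchmark
#'
#' For each seed, simulates a locus with overlapping amplicons, injects a
#' heterozygous variant whose non-variant haplotype fails to amplify in
#' one amplicon of an overlapping pair, runs the masked-reference pipeline
#' with per-amplicon calling, and records whether
#' [detect_allele_dropout()] flags the site.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param depth Mean per-base depth (default 100).
#' @param locus_length,n_paralogs,identity,contamination,n_amplicons,read_length
#'   Simulation parameters as in [run_masking_benchmark()].
#' @param params [alignment_params()].
#' @return Tibble: `seed`, `position`, `detected`.
#' @export
run_dropout_benchmark <- function(seeds, depth = 100, locus_length = 2000,
                                  n_paralogs = 6, identity = 0.98,
                                  contamination = 0.05, n_amplicons = 2,
                                  read_length = 200,
                                  params = alignment_params()) {
  dplyr::bind_rows(lapply(seeds, function(seed) {
    locus <- generate_locus(seed, n_paralogs = n_paralogs,
                            identity = identity, length = locus_length)
    amps <- design_amplicons(locus, n_amplicons = n_amplicons)
    scen <- sample_dropout_scenario(locus, amps, seed = seed + 1000000L)
    reads <- simulate_reads(locus, amps, scen, depth = depth,
                            contamination = contamination,
                            seed = seed + 2000000L,
                            read_length = read_length)
    genome <- locus_genome(locus)
    masked <- build_masked_reference(genome$sequence, genome$target,
                                     source_name = "masked")
    aln <- align_reads(reads, masked, params)
    by_amp <- call_by_amplicon(aln, masked, amps)
    report <- detect_allele_dropout(by_amp, amps)
    tibble::tibble(seed = seed, position = scen$position,
                   detected = scen$position %in% report$pos)
  }))
}

#' Standard MLPA rearrangement cases
#'
#' The six canonical events: heterozygous deletion and duplication of a
#' single mid-gene exon, of the exon 8-9 pair, and of the whole gene.
#'
#' @param panel An [mlpa_panel()].
#' @return Named list of copy-state vectors for [simulate_mlpa()].
#' @export
mlpa_benchmark_cases <- function(panel = mlpa_panel()) {
  exons <- unique(panel$exon[!panel$is_reference])
  mid <- exons[ceiling(length(exons) / 2)]
  pair <- exons[seq(min(8L, length(exons) - 1L), length.out = 2)]
  list(
    single_exon_del = stats::setNames(1L, mid),
    single_exon_dup = stats::setNames(3L, mid),
    two_exon_del = stats::setNames(c(1L, 1L), pair),
    two_exon_dup = stats::setNames(c(3L, 3L), pair),
    whole_gene_del = stats::setNames(rep(1L, length(exons)), exons),
    whole_gene_dup = stats::setNames(rep(3L, length(exons)), exons))
}

#' MLPA rearrangement recovery benchmark
#'
#' For each seed and each case in [mlpa_benchmark_cases()], simulates peak
#' tables at the given noise level, normalizes, calls rearrangements, and
#' checks that exactly one event with the correct state and exon span
#' (and whole-gene flag) is reported.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param noise_sd Multiplicative peak noise SD (default 0.05).
#' @param panel An [mlpa_panel()].
#' @param n_controls Control samples per run.
#' @return Tibble: `seed`, `case`, `correct`.
#' @export
run_mlpa_benchmark <- function(seeds, noise_sd = 0.05, panel = mlpa_panel(),
                               n_controls = 3) {
  cases <- mlpa_benchmark_cases(panel)
  exons <- unique(panel$exon[!panel$is_reference])
  dplyr::bind_rows(lapply(seeds, function(seed) {
    dplyr::bind_rows(lapply(seq_along(cases), function(ci) {
      cs <- cases[[ci]]
      pk <- simulate_mlpa(cs, panel, noise_sd = noise_sd,
                          n_controls = n_controls,
                          seed = seed * 10L + ci)
      dq <- normalize_dosage(pk[pk$sample == "case", ],
                             pk[pk$sample != "case", ], panel)
      ev <- dosage_events(call_rearrangements(dq, panel))
      want_state <- if (cs[1] < 2) "deletion" else "duplication"
      want_from <- names(cs)[1]
      want_to <- names(cs)[length(cs)]
      ok <- nrow(ev) == 1 && ev$state == want_state &&
        ev$exon_from == want_from && ev$exon_to == want_to &&
        ev$whole_gene == (length(cs) == length(exons))
      tibble::tibble(seed = seed, case = names(cases)[ci], correct = ok)
    }))
  }))
}

#' ANOVA power benchmark for onset-age group differences
#'
#' Simulates cohorts with the configured class onset-age means and SD and
#' records, per seed, whether [anova_onset()] rejects equality of means at
#' `alpha`, and whether the recovered group means reproduce the injected
#' ordering (PKD1-truncating earliest, PKD2 latest).
#'
#' @param seeds Integer vector of simulation seeds.
#' @param n_per_group Probands per genotype class.
#' @param means Named onset-age means for `PKD1_T`, `PKD1_NT`, `PKD2`.
#' @param sd Common onset-age SD.
#' @param alpha Significance level.
#' @return Tibble: `seed`, `p_value`, `rejected`, `ordering_recovered`.
#' @export
run_anova_power <- function(seeds, n_per_group = 50,
                            means = c(PKD1_T = 27, PKD1_NT = 38, PKD2 = 47),
                            sd = 8, alpha = 0.05) {
  classes <- names(means)
  dplyr::bind_rows(lapply(seeds, function(seed) {
    with_seed(seed, {
      records <- tibble::tibble(
        genotype_class = rep(classes, each = n_per_group),
        onset_age = stats::rnorm(n_per_group * length(classes),
                                 rep(means, each = n_per_group), sd))
      fit <- anova_onset(records)
      gm <- fit$group_means
      ord <- gm$mean[match(classes, gm$group)]
      tibble::tibble(seed = seed, p_value = fit$p_value,
                     rejected = fit$p_value < alpha,
                     ordering_recovered = !is.unsorted(ord))
    })
  }))
}
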