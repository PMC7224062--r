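#' Build a pileup from alignments
#'
#' Walks every accepted alignment and tallies, per reference position, the
#' allele each read presents there: the read base under `M`, a left-aligned
#' `-<seq>` deletion allele at the anchor base, `*` inside deletions, or a
#' left-aligned `+<seq>` insertion allele at the anchor base. Each read
#' contributes exactly one allele per consumed position, so allele counts
#' sum to depth by construction. Local sequence context (homopolymer run
#' length, GC fraction in a +/-25 bp window) is annotated for the
#' context-aware QC downstream.
#'
#' @param alignments A `pkd_alignments` tibble (only `status == "aligned"`
#'   rows are used).
#' @param ref A `pkd_masked_ref`.
#' @return A `pkd_pileup` tibble: `pos`, `ref_base`, `allele`, `count`,
#'   `fwd`, `rev`, `depth`, `hp_len`, `gc_frac`.
#' @export
build_pileup <- function(alignments, ref) {
  stopifnot(inherits(ref, "pkd_masked_ref"))
  aln <- alignments[alignments$status == "aligned", , drop = FALSE]
  raw <- if (nrow(aln) > 0) {
    cpp_pileup(ref$sequence, aln$pos, aln$cigar, aln$aligned_seq, aln$strand)
  } else {
    data.frame(pos = integer(0), allele = character(0),
               strand = character(0), count = integer(0))
  }
  refb <- strsplit(ref$sequence, "")[[1]]
  hp <- homopolymer_lengths(ref$sequence)
  gc <- gc_window(ref$sequence)

  out <- tibble::as_tibble(raw) |>
    tidyr::pivot_wider(names_from = "strand", values_from = "count",
                       values_fill = 0L) |>
    dplyr::rename(fwd = dplyr::any_of("+"), rev = dplyr::any_of("-"))
  if (!"fwd" %in% names(out)) out$fwd <- 0L
  if (!"rev" %in% names(out)) out$rev <- 0L
  out <- out |>
    dplyr::mutate(count = .data$fwd + .data$rev) |>
    dplyr::group_by(.data$pos) |>
    dplyr::mutate(depth = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(ref_base = refb[.data$pos],
                  hp_len = hp[.data$pos],
                  gc_frac = gc[.data$pos]) |>
    dplyr::select("pos", "ref_base", "allele", "count", "fwd", "rev",
                  "depth", "hp_len", "gc_frac") |>
    dplyr::arrange(.data$pos, dplyr::desc(.data$count))
  class(out) <- c("pkd_pileup", class(out))
  out
}

#' Call germline variants at a VAF threshold
#'
#' A site yields a call when an alternate allele reaches the calling
#' threshold (default 10% — the pipeline's germline variant-calling
#' threshold, below which real mutations are invisible to the caller and
#' only the mosaic scan can recover them) at sufficient depth. Genotype
#' assignment: heterozygous inside the het band, homozygous above the hom
#' threshold, `mosaic_candidate` between the calling threshold and the het
#' band (the regime in which a true somatic mosaic presents, e.g. a 2 bp
#' deletion carried by 40 of 252 reads, 15.9%), and `ambiguous` between
#' the het band and the hom threshold.
#'
#' @param pileup A `pkd_pileup`.
#' @param call_threshold Minimum VAF to emit a call (default 0.10).
#' @param het_band VAF interval called heterozygous (default `[0.20, 0.80]`).
#' @param hom_threshold VAF at or above which a call is homozygous (0.90).
#' @param min_depth Minimum depth to call (default 20).
#' @return A `pkd_calls` tibble: `pos`, `ref`, `alt`, `alt_depth`, `depth`,
#'   `vaf`, `vaf_pct` (half-up, one decimal), `genotype`, `qc_flags`
#'   (list-column), `mosaic_p` (NA here; filled by [scan_mosaic()]).
#' @export
call_germline <- function(pileup, call_threshold = 0.10,
                          het_band = c(0.20, 0.80), hom_threshold = 0.90,
                          min_depth = 20) {
  if (!(call_threshold < het_band[1] && het_band[1] <= het_band[2] &&
        het_band[2] < hom_threshold)) {
    stop("thresholds must satisfy call_threshold < het_band[1] <= ",
         "het_band[2] < hom_threshold", call. = FALSE)
  }
  alt <- pileup |>
    dplyr::filter(.data$allele != .data$ref_base, .data$allele != "*",
                  .data$depth >= min_depth) |>
    dplyr::mutate(vaf = .data$count / .data$depth) |>
    dplyr::filter(.data$vaf >= call_threshold)
  if (nrow(alt) == 0) return(empty_calls())

  out <- alt |>
    dplyr::mutate(
      genotype = dplyr::case_when(
        .data$vaf >= hom_threshold ~ "hom",
        .data$vaf >= het_band[1] & .data$vaf <= het_band[2] ~ "het",
        .data$vaf < het_band[1] ~ "mosaic_candidate",
        TRUE ~ "ambiguous"),
      vaf_pct = round_half_up(100 * .data$vaf, 1)) |>
    dplyr::rowwise() |>
    dplyr::mutate(vcf = list(allele_to_vcf(.data$pos, .data$allele,
                                           .data$ref_base))) |>
    dplyr::ungroup() |>
    tidyr::unnest_wider("vcf") |>
    dplyr::transmute(
      pos = .data$vcf_pos, ref = .data$vcf_ref, alt = .data$vcf_alt,
      alt_depth = .data$count, depth = .data$depth, vaf = .data$vaf,
      vaf_pct = .data$vaf_pct, genotype = .data$genotype,
      hp_len = .data$hp_len, gc_frac = .data$gc_frac,
      qc_flags = lapply(seq_len(dplyr::n()), function(i) character(0)),
      mosaic_p = NA_real_)
  out$qc_flags[out$genotype == "ambiguous"] <-
    lapply(which(out$genotype == "ambiguous"), function(i) "suspect_fp_unbalanced")
  class(out) <- c("pkd_calls", class(out))
  out
}

# internal: convert a pileup allele at pos to VCF-style (pos, ref, alt);
# here `ref_base` is the base at the pileup position
allele_to_vcf <- function(pos, allele, ref_base) {
  if (startsWith(allele, "-")) {
    del <- substring(allele, 2)
    list(vcf_pos = pos, vcf_ref = paste0(ref_base, del), vcf_alt = ref_base)
  } else if (startsWith(allele, "+")) {
    ins <- substring(allele, 2)
    list(vcf_pos = pos, vcf_ref = ref_base, vcf_alt = paste0(ref_base, ins))
  } else {
    list(vcf_pos = pos, vcf_ref = ref_base, vcf_alt = allele)
  }
}

#' Allele-balance and sequence-context QC
#'
#' The false positives of semiconductor amplicon sequencing concentrate in
#' GC-rich regions and homopolymers, and typically show unbalanced allele
#' fractions; this annotator adds the corresponding advisory flags without
#' deleting any call (every reported variant is expected to be orthogonally
#' confirmed).
#'
#' @param calls A `pkd_calls` tibble (with `hp_len`, `gc_frac` context).
#' @param balance_band Het calls with VAF outside this interval are flagged
#'   `suspect_fp_unbalanced` (default `[0.30, 0.70]`).
#' @param hp_min Homopolymer run length flagged as context (default 5).
#' @param gc_min GC fraction flagged as context (default 0.75).
#' @return The calls with updated `qc_flags`.
#' @export
qc_allele_balance <- function(calls, balance_band = c(0.30, 0.70),
                              hp_min = 5, gc_min = 0.75) {
  add_flag <- function(flags, idx, flag) {
    flags[idx] <- lapply(flags[idx], function(f) union(f, flag))
    flags
  }
  f <- calls$qc_flags
  unb <- calls$genotype %in% c("het", "mosaic_candidate") &
    (calls$vaf < balance_band[1] | calls$vaf > balance_band[2])
  f <- add_flag(f, which(unb), "suspect_fp_unbalanced")
  f <- add_flag(f, which(calls$hp_len >= hp_min), "homopolymer_context")
  f <- add_flag(f, which(calls$gc_frac >= gc_min), "gc_rich_context")
  calls$qc_flags <- f
  calls
}

#' Scan for sub-threshold somatic mosaicism
#'
#' Sites whose alternate allele sits below the germline calling threshold
#' are tested against the sequencing error rate with a one-sided binomial
#' tail, Bonferroni-corrected over all scanned positions: the regime of a
#' true mosaic carried by 156 of 2,193 reads (7.1%), invisible to the
#' germline caller at its 10% threshold yet plainly non-random.
#'
#' @param pileup A `pkd_pileup`.
#' @param error_rate Per-base error rate under the null (default 0.01;
#'   doubled at homopolymer/GC-flagged positions when
#'   `context_doubling = TRUE`).
#' @param germline_threshold The germline calling threshold (default 0.10);
#'   must exceed `error_rate`.
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_alt Minimum alternate reads for a candidate (default 10).
#' @param min_depth Minimum depth scanned (default 20).
#' @param context_doubling Double the null error rate at homopolymer
#'   (run >= 5) or GC-rich (>= 0.75) positions?
#' @return A `pkd_calls` tibble of mosaic candidates with genotype
#'   `"mosaic_candidate"` and `mosaic_p` the uncorrected binomial tail
#'   probability; attribute `n_tests` records the Bonferroni family size.
#' @export
scan_mosaic <- function(pileup, error_rate = 0.01, germline_threshold = 0.10,
                        alpha = 0.05, min_alt = 10, min_depth = 20,
                        context_doubling = TRUE) {
  if (error_rate <= 0 || error_rate >= germline_threshold) {
    stop("error_rate must lie strictly between 0 and the germline ",
         "threshold; otherwise the scan window is empty", call. = FALSE)
  }
  n_tests <- length(unique(pileup$pos[pileup$depth > 0]))
  cand <- pileup |>
    dplyr::filter(.data$allele != .data$ref_base, .data$allele != "*",
                  .data$depth >= min_depth, .data$count >= min_alt) |>
    dplyr::mutate(vaf = .data$count / .data$depth) |>
    dplyr::filter(.data$vaf < germline_threshold) |>
    dplyr::mutate(
      rate = ifelse(context_doubling &
                      (.data$hp_len >= 5 | .data$gc_frac >= 0.75),
                    pmin(2 * error_rate, 1), error_rate),
      p = stats::pbinom(.data$count - 1L, .data$depth, .data$rate,
                        lower.tail = FALSE)) |>
    dplyr::filter(.data$p * n_tests < alpha)

  out <- if (nrow(cand) > 0) {
    cand |>
      dplyr::rowwise() |>
      dplyr::mutate(vcf = list(allele_to_vcf(.data$pos, .data$allele,
                                             .data$ref_base))) |>
      dplyr::ungroup() |>
      tidyr::unnest_wider("vcf") |>
      dplyr::transmute(
        pos = .data$vcf_pos, ref = .data$vcf_ref, alt = .data$vcf_alt,
        alt_depth = .data$count, depth = .data$depth, vaf = .data$vaf,
        vaf_pct = round_half_up(100 * .data$vaf, 1),
        genotype = "mosaic_candidate",
        hp_len = .data$hp_len, gc_frac = .data$gc_frac,
        qc_flags = lapply(seq_len(dplyr::n()), function(i) character(0)),
        mosaic_p = .data$p)
  } else {
    empty_calls()
  }
  attr(out, "n_tests") <- n_tests
  class(out) <- c("pkd_calls", class(out))
  out
}

#' Construct a pileup directly from allele counts
#'
#' Convenience constructor for working through reported read counts (e.g. a
#' site with 156 variant reads among 2,193) without simulating alignments.
#'
#' @param pos Position(s).
#' @param ref_base Reference base per position.
#' @param ref_count,alt_count Reference/alternate read counts per position.
#' @param alt_allele Alternate allele per position (pileup notation: a base,
#'   `-<seq>` deletion, or `+<seq>` insertion).
#' @param hp_len,gc_frac Sequence context annotations.
#' @return A `pkd_pileup` tibble.
#' @export
#' @examples
#' pileup_from_counts(100, "A", ref_count = 2037, alt_allele = "-TG",
#'                    alt_count = 156)
pileup_from_counts <- function(pos, ref_base, ref_count, alt_allele,
                               alt_count, hp_len = 1L, gc_frac = 0.5) {
  base <- tibble::tibble(pos = as.integer(pos), ref_base = ref_base,
                         ref_count = as.integer(ref_count),
                         alt_allele = alt_allele,
                         alt_count = as.integer(alt_count),
                         hp_len = as.integer(hp_len), gc_frac = gc_frac)
  out <- base |>
    tidyr::pivot_longer(c("ref_count", "alt_count"), names_to = "which",
                        values_to = "count") |>
    dplyr::mutate(allele = ifelse(.data$which == "ref_count",
                                  .data$ref_base, .data$alt_allele)) |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$pos) |>
    dplyr::mutate(depth = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fwd = .data$count %/% 2L,
                  rev = .data$count - .data$count %/% 2L) |>
    dplyr::select("pos", "ref_base", "allele", "count", "fwd", "rev",
                  "depth", "hp_len", "gc_frac")
  class(out) <- c("pkd_pileup", class(out))
  out
}

# internal: zero-row calls tibble with the full schema
empty_calls <- function() {
  out <- tibble::tibble(
    pos = integer(0), ref = character(0), alt = character(0),
    alt_depth = integer(0), depth = integer(0), vaf = numeric(0),
    vaf_pct = numeric(0), genotype = character(0), hp_len = integer(0),
    gc_frac = numeric(0), qc_flags = list(), mosaic_p = numeric(0))
  class(out) <- c("pkd_calls", class(out))
  out
}

#' Detect allele dropout across overlapping amplicons
#'
#' A variant under a primer site suppresses amplification of one haplotype,
#' so the site looks homozygous in the affected amplicon while an
#' overlapping amplicon, amplified with independent primers, still shows
#' the heterozygote. Calls are made per amplicon and compared over the
#' overlap: hom-vs-het discordance flags the hom call as
#' `allele_dropout_suspect`; additionally any site het in at least one
#' amplicon whose VAF shifts by more than `vaf_shift` between amplicons is
#' reported.
#'
#' @param calls_by_amplicon Named list of `pkd_calls`, one per amplicon
#'   (e.g. from [call_by_amplicon()]).
#' @param amplicons A `pkd_amplicons` (its overlap table drives the
#'   comparison).
#' @param vaf_shift Report het sites with a VAF difference above this.
#' @return A `pkd_dropout` tibble: `pos`, `ref`, `alt`, `amplicon_a`,
#'   `amplicon_b`, `vaf_a`, `vaf_b`, `genotype_a`, `genotype_b`, `finding`
#'   (`"allele_dropout_suspect"` or `"vaf_shift"`). Attribute `possible`
#'   records whether any overlap existed.
#' @export
detect_allele_dropout <- function(calls_by_amplicon, amplicons,
                                  vaf_shift = 0.35) {
  ov <- amplicon_overlaps(amplicons)
  empty <- tibble::tibble(pos = integer(0), ref = character(0),
                          alt = character(0), amplicon_a = character(0),
                          amplicon_b = character(0), vaf_a = numeric(0),
                          vaf_b = numeric(0), genotype_a = character(0),
                          genotype_b = character(0), finding = character(0))
  if (is.null(ov) || nrow(ov) == 0) {
    warning("no overlapping amplicons: dropout detection not possible",
            call. = FALSE)
    attr(empty, "possible") <- FALSE
    class(empty) <- c("pkd_dropout", class(empty))
    return(empty)
  }
  rows <- list()
  for (i in seq_len(nrow(ov))) {
    a <- calls_by_amplicon[[ov$a[i]]]
    b <- calls_by_amplicon[[ov$b[i]]]
    if (is.null(a) || is.null(b)) next
    j <- dplyr::full_join(
      dplyr::select(tibble::as_tibble(a), "pos", "ref", "alt", "vaf", "genotype"),
      dplyr::select(tibble::as_tibble(b), "pos", "ref", "alt", "vaf", "genotype"),
      by = c("pos", "ref", "alt"), suffix = c("_a", "_b")) |>
      dplyr::filter(.data$pos >= ov$ov_start[i], .data$pos <= ov$ov_end[i])
    if (nrow(j) == 0) next
    j$genotype_a[is.na(j$genotype_a)] <- "none"
    j$genotype_b[is.na(j$genotype_b)] <- "none"
    disc <- (j$genotype_a == "hom" & j$genotype_b %in% c("het", "none")) |
            (j$genotype_b == "hom" & j$genotype_a %in% c("het", "none"))
    shift <- !disc & !is.na(j$vaf_a) & !is.na(j$vaf_b) &
      (j$genotype_a == "het" | j$genotype_b == "het") &
      abs(j$vaf_a - j$vaf_b) > vaf_shift
    k <- j[disc | shift, , drop = FALSE]
    if (nrow(k) == 0) next
    k$finding <- ifelse(disc[disc | shift], "allele_dropout_suspect", "vaf_shift")
    k$amplicon_a <- ov$a[i]
    k$amplicon_b <- ov$b[i]
    rows[[length(rows) + 1]] <- k
  }
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)[, names(empty)]
  } else empty
  attr(out, "possible") <- TRUE
  class(out) <- c("pkd_dropout", class(out))
  out
}

#' Per-amplicon germline calling
#'
#' Splits alignments by their amplicon of origin (carried as provenance on
#' simulated reads, or inferred from the aligned span), builds one pileup
#' per amplicon and calls each, for use by [detect_allele_dropout()].
#'
#' @param alignments A `pkd_alignments` tibble with an `amplicon` column,
#'   or without one (then spans are intersected with `amplicons`).
#' @param ref A `pkd_masked_ref`.
#' @param amplicons A `pkd_amplicons`.
#' @param ... Passed to [call_germline()].
#' @return Named list of `pkd_calls`, one per amplicon.
#' @export
call_by_amplicon <- function(alignments, ref, amplicons, ...) {
  aln <- alignments[alignments$status == "aligned", , drop = FALSE]
  if (!"amplicon" %in% names(aln)) {
    mid <- aln$pos + cigar_ref_span(aln$cigar) %/% 2
    idx <- vapply(mid, function(p) {
      w <- which(amplicons$start <= p & amplicons$end >= p)
      if (length(w) == 0) NA_integer_ else w[1]
    }, integer(1))
    aln$amplicon <- amplicons$name[idx]
  }
  stats::setNames(lapply(amplicons$name, function(a) {
    call_germline(build_pileup(aln[!is.na(aln$amplicon) & aln$amplicon == a, ,
                                   drop = FALSE], ref), ...)
  }), amplicons$name)
}
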