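#' Build a masked reference
#'
#' Replaces every base outside the target intervals with `N`, the
#' pseudogene-aware reference strategy: reads can then anchor only inside
#' the target locus, because the aligner never scores a match against `N`.
#'
#' @param genome Reference sequence as a single character string (A/C/G/T/N).
#' @param target_intervals Data frame with 1-based inclusive `start`, `end`
#'   columns; must be disjoint and within bounds.
#' @param source_name Identifier for the reference.
#' @return A `pkd_masked_ref` object: list with `sequence`,
#'   `target_intervals` (sorted tibble) and `source_name`.
#' @export
#' @examples
#' ref <- build_masked_reference(strrep("ACGT", 25),
#'                               data.frame(start = 11, end = 40))
build_masked_reference <- function(genome, target_intervals,
                                   source_name = "reference") {
  stopifnot(is.character(genome), length(genome) == 1)
  n <- nchar(genome)
  ti <- check_intervals(tibble::as_tibble(target_intervals), n, "target interval")
  b <- strsplit(genome, "")[[1]]
  keep <- rep(FALSE, n)
  for (i in seq_len(nrow(ti))) keep[ti$start[i]:ti$end[i]] <- TRUE
  bad <- keep & !b %in% c("A", "C", "G", "T")
  if (any(bad)) {
    # spacer Ns may fall inside a caller-supplied interval; treat them as
    # masked rather than erroring so whole-genome "no masking" calls work
    keep[bad] <- FALSE
  }
  b[!keep] <- "N"
  structure(list(sequence = paste(b, collapse = ""),
                 target_intervals = ti[, c("start", "end")],
                 source_name = source_name),
            class = "pkd_masked_ref")
}

#' @export
print.pkd_masked_ref <- function(x, ...) {
  tw <- sum(x$target_intervals$end - x$target_intervals$start + 1)
  cat("<pkd_masked_ref> '", x$source_name, "': ", nchar(x$sequence),
      " bp, ", nrow(x$target_intervals), " target interval(s) totalling ",
      tw, " bp unmasked\n", sep = "")
  invisible(x)
}

#' Default alignment scoring parameters
#'
#' Match/mismatch/gap scores for the banded local aligner, the seeding
#' parameters, and the acceptance filters: a minimum score as a fraction of
#' the maximum attainable (amplicon reads are near-exact) and a minimum
#' mapping confidence. Mapping confidence is the score gap between the best
#' and second-best placement, scaled by 3 and capped at 60 (so one
#' additional mismatch of separation is worth 15 points); ties at distinct
#' locations give confidence 0 and the leftmost placement is reported.
#'
#' @param match,mismatch,gap Alignment scores (mismatch/gap negative);
#'   an `N` reference base always scores as a mismatch.
#' @param band Band half-width of the banded dynamic program.
#' @param k,stride K-mer length and sampling stride for seeding.
#' @param max_candidates Maximum candidate placements scored per read.
#' @param min_score_frac Reject alignments scoring below this fraction of
#'   `match * read_length`.
#' @param min_confidence Reject alignments with mapping confidence below
#'   this value (0-60 scale).
#' @return List of parameters.
#' @export
alignment_params <- function(match = 2, mismatch = -3, gap = -4, band = 16,
                             k = 13, stride = 6, max_candidates = 12,
                             min_score_frac = 0.6, min_confidence = 20) {
  stopifnot(match > 0, mismatch < 0, gap < 0, band >= 4, k >= 8)
  list(match = match, mismatch = mismatch, gap = gap, band = band, k = k,
       stride = stride, max_candidates = max_candidates,
       min_score_frac = min_score_frac, min_confidence = min_confidence)
}

#' Align reads to a (masked) reference
#'
#' Banded local alignment with exact k-mer seeding. Each read (and its
#' reverse complement) is placed at its best-scoring location; the mapping
#' confidence encodes how much better that location is than the
#' second-best one, so reads that fit several reference copies equally
#' well are rejected — the behaviour masking exploits.
#'
#' @param reads A `pkd_reads` tibble (or any tibble with `read_id`, `seq`).
#' @param ref A `pkd_masked_ref`.
#' @param params [alignment_params()].
#' @param keep_unmapped Keep rejected reads in the output (status column)?
#' @return A `pkd_alignments` tibble: `read_id`, `pos` (1-based), `score`,
#'   `second_score`, `confidence` (0-60), `nm` (edit distance), `cigar`,
#'   `strand`, `aligned_seq` (reference orientation), `status`
#'   (`"aligned"`, `"low_score"`, `"low_confidence"`, `"unmapped"`), plus
#'   any provenance columns of `reads` (e.g. `amplicon`).
#' @export
align_reads <- function(reads, ref, params = alignment_params(),
                        keep_unmapped = FALSE) {
  stopifnot(inherits(ref, "pkd_masked_ref"))
  res <- cpp_align_batch(ref$sequence, reads$seq,
                         params$match, params$mismatch, params$gap,
                         params$band, params$k, params$stride,
                         params$max_candidates)
  conf <- ifelse(res$n_ties > 0, 0L,
                 pmin(60L, pmax(0L, 3L * (res$score - res$second_score))))
  min_score <- params$min_score_frac * params$match * nchar(reads$seq)
  status <- dplyr::case_when(
    !res$mapped ~ "unmapped",
    res$score < min_score ~ "low_score",
    conf < params$min_confidence ~ "low_confidence",
    TRUE ~ "aligned")
  out <- tibble::tibble(
    read_id = reads$read_id,
    pos = ifelse(res$mapped, res$pos, NA_integer_),
    score = res$score,
    second_score = res$second_score,
    confidence = ifelse(res$mapped, conf, NA_integer_),
    nm = ifelse(res$mapped, res$nm, NA_integer_),
    cigar = res$cigar,
    strand = res$strand,
    aligned_seq = ifelse(res$mapped, res$aligned_seq, reads$seq),
    status = status)
  extra <- setdiff(names(reads), c(names(out), "seq"))
  if (length(extra) > 0) out <- dplyr::bind_cols(out, reads[, extra])
  if (!keep_unmapped) out <- out[out$status == "aligned", , drop = FALSE]
  class(out) <- c("pkd_alignments", class(out))
  out
}

#' Align a single read
#'
#' @param read Read sequence (character scalar, >= 30 bases, A/C/G/T only).
#' @param ref A `pkd_masked_ref`.
#' @param params [alignment_params()].
#' @return One-row `pkd_alignments` tibble (status column tells whether the
#'   read was accepted).
#' @export
align_read <- function(read, ref, params = alignment_params()) {
  stopifnot(is.character(read), length(read) == 1)
  if (nchar(read) < 30) stop("reads shorter than 30 bp are not supported", call. = FALSE)
  align_reads(tibble::tibble(read_id = "read", seq = read), ref,
              params = params, keep_unmapped = TRUE)
}

# internal: reference span consumed by a cigar string
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0L)
    len <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(len[op %in% c("M", "D", "X", "=")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Per-base coverage over the target, with low-coverage flagging
#'
#' Positions below the depth threshold are exactly the regions a diagnostic
#' pipeline refers to orthogonal (Sanger) confirmation.
#'
#' @param alignments A `pkd_alignments` tibble.
#' @param ref A `pkd_masked_ref`.
#' @param threshold Depth below which a target position is flagged (default
#'   20, the usual Sanger-fallback cutoff).
#' @return A `pkd_coverage` tibble (`pos`, `depth` over target positions)
#'   with attributes `summary` (mean depth, fraction >= threshold) and
#'   `low_coverage` (tibble of maximal sub-threshold intervals).
#' @export
coverage_profile <- function(alignments, ref, threshold = 20) {
  stopifnot(inherits(ref, "pkd_masked_ref"))
  n <- nchar(ref$sequence)
  aln <- alignments[alignments$status == "aligned", , drop = FALSE]
  cov <- if (nrow(aln) > 0) {
    spans <- cigar_ref_span(aln$cigar)
    as.integer(IRanges::coverage(
      IRanges::IRanges(start = aln$pos, width = spans), width = n))
  } else integer(n) # all zero
  if (length(cov) < n) cov <- c(cov, integer(n - length(cov)))

  ti <- ref$target_intervals
  tpos <- unlist(lapply(seq_len(nrow(ti)), function(i) ti$start[i]:ti$end[i]))
  depth <- cov[tpos]
  out <- tibble::tibble(pos = as.integer(tpos), depth = depth)

  low <- out[out$depth < threshold, , drop = FALSE]
  low_iv <- if (nrow(low) > 0) {
    r <- IRanges::reduce(IRanges::IRanges(start = low$pos, width = 1))
    tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
  } else tibble::tibble(start = integer(0), end = integer(0))

  attr(out, "summary") <- tibble::tibble(
    mean_depth = mean(depth),
    frac_ge_threshold = mean(depth >= threshold),
    threshold = threshold)
  attr(out, "low_coverage") <- low_iv
  class(out) <- c("pkd_coverage", class(out))
  out
}

#' Low-coverage intervals of a coverage profile
#' @param coverage A `pkd_coverage`.
#' @return Tibble of maximal intervals with depth below the threshold.
#' @export
low_coverage_intervals <- function(coverage) attr(coverage, "low_coverage")

#' Coverage summary (mean depth, fraction at or above threshold)
#' @param coverage A `pkd_coverage`.
#' @return One-row tibble.
#' @export
coverage_summary <- function(coverage) attr(coverage, "summary")

#' Write alignments as a minimal SAM file
#'
#' Emits a valid 11-column SAM with the fields this pipeline populates
#' (QNAME/FLAG/RNAME/POS/MAPQ/CIGAR/SEQ; RNEXT/PNEXT/TLEN/QUAL are
#' placeholders) plus an NM tag.
#'
#' @param alignments A `pkd_alignments` tibble.
#' @param ref A `pkd_masked_ref`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, ref, path) {
  aln <- alignments[alignments$status == "aligned", , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", ref$source_name, "\tLN:", nchar(ref$sequence)))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  body <- paste(aln$read_id, flag, ref$source_name, aln$pos,
                aln$confidence, aln$cigar, "*", 0L, 0L,
                aln$aligned_seq, "*", paste0("NM:i:", aln$nm), sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write a coverage profile as BEDGRAPH, and low-coverage intervals as BED
#'
#' @param coverage A `pkd_coverage`.
#' @param path Output BEDGRAPH path; the low-coverage BED takes the same
#'   path with extension `.low.bed`.
#' @param chrom Contig name.
#' @return `path`, invisibly.
#' @export
write_coverage_bedgraph <- function(coverage, path, chrom = "GENE") {
  r <- rle(coverage$depth)
  ends <- coverage$pos[cumsum(r$lengths)]
  starts <- coverage$pos[cumsum(r$lengths) - r$lengths + 1]
  readr::write_tsv(tibble::tibble(chrom = chrom, start = starts - 1L,
                                  end = ends, depth = r$values),
                   path, col_names = FALSE)
  low <- low_coverage_intervals(coverage)
  readr::write_tsv(tibble::tibble(chrom = chrom, start = low$start - 1L,
                                  end = low$end),
                   paste0(tools::file_path_sans_ext(path), ".low.bed"),
                   col_names = FALSE)
  invisible(path)
}
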