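#' Generate a synthetic duplicated locus (gene plus pseudogene paralogs)
#'
#' Emulates a disease gene embedded in a family of high-identity pseudogenes,
#' the situation that makes conventional read mapping fail for PKD1. The gene
#' is a random sequence; each paralog is derived from it by substituting a
#' controlled number of positions so that pairwise identity matches
#' `identity`. A set of *anchor sites* — positions where the gene differs
#' from **every** paralog — is guaranteed; long-range PCR primers are
#' anchored on such sites to obtain locus-specific amplicons.
#'
#' @param seed Integer seed; the locus is fully deterministic given it.
#' @param n_paralogs Number of pseudogene paralogs (0 allowed; PKD1 has 6).
#' @param identity Target pairwise gene-vs-paralog identity, in `[0.8, 1)`.
#' @param length Locus length in bases (>= 2000).
#' @param n_anchors Number of anchor sites; default one per ~250 bp, dense
#'   enough that every primer window can be anchored.
#' @param n_exons Number of exon intervals laid out across the locus.
#' @return A `pkd_locus` object: list with `gene_sequence`, `paralogs`
#'   (named character vector), `identity`, `anchor_sites` (1-based
#'   positions), `exon_intervals` (tibble of 1-based inclusive intervals),
#'   `length` and `seed`.
#' @export
#' @examples
#' loc <- generate_locus(seed = 1, n_paralogs = 6, identity = 0.98, length = 3000)
#' paralog_identity(loc)
generate_locus <- function(seed, n_paralogs = 6, identity = 0.98,
                           length = 6000, n_anchors = NULL, n_exons = 8) {
  stopifnot(length >= 2000, n_paralogs >= 0, n_exons >= 1)
  if (identity >= 1) {
    stop("identity must be < 1: fully identical paralogs admit no anchor sites",
         call. = FALSE)
  }
  if (identity < 0.8) stop("identity must be >= 0.8", call. = FALSE)
  if (is.null(n_anchors)) n_anchors <- max(8L, round(length / 250))

  with_seed(seed, {
    gene <- random_dna(length)

    # anchors: quasi-evenly spaced with jitter, spanning beyond the exon area
    # so that terminal primer windows can be anchored
    ideal <- seq(50, length - 50, length.out = n_anchors)
    spacing <- diff(ideal[1:2])
    jitter <- sample(seq(-floor(spacing / 4), floor(spacing / 4)),
                     n_anchors, replace = TRUE)
    anchors <- sort(unique(pmin(pmax(round(ideal + jitter), 2L), length - 1L)))

    # exons: evenly spaced blocks within the anchored span
    exon_area <- c(150L, length - 150L)
    exon_frac <- 0.6
    span <- exon_area[2] - exon_area[1] + 1L
    exon_len <- max(50L, floor(span * exon_frac / n_exons))
    gap <- floor((span - n_exons * exon_len) / max(1L, n_exons - 1L))
    starts <- exon_area[1] + (seq_len(n_exons) - 1L) * (exon_len + gap)
    exons <- tibble::tibble(
      exon = sprintf("ex%02d", seq_len(n_exons)),
      start = as.integer(starts),
      end = as.integer(starts + exon_len - 1L)
    )
    check_intervals(exons, length, "exon interval")

    gene_b <- strsplit(gene, "")[[1]]
    bases <- c("A", "C", "G", "T")
    n_diff <- max(length(anchors), round((1 - identity) * length))
    paralogs <- character(0)
    if (n_paralogs > 0) {
      paralogs <- vapply(seq_len(n_paralogs), function(k) {
        extra <- sample(setdiff(seq_len(length), anchors),
                        n_diff - length(anchors))
        sites <- c(anchors, extra)
        pb <- gene_b
        pb[sites] <- vapply(sites, function(s) {
          sample(setdiff(bases, gene_b[s]), 1)
        }, character(1))
        paste(pb, collapse = "")
      }, character(1))
      names(paralogs) <- sprintf("PSEUDO%d", seq_len(n_paralogs))
    }

    structure(
      list(gene_sequence = gene, paralogs = paralogs, identity = identity,
           anchor_sites = anchors, exon_intervals = exons,
           length = length, seed = seed),
      class = "pkd_locus")
  })
}

#' @export
print.pkd_locus <- function(x, ...) {
  cat("<pkd_locus> ", x$length, " bp gene, ", length(x$paralogs),
      " paralog(s) at ", round(100 * x$identity, 1), "% identity, ",
      length(x$anchor_sites), " anchor sites, ",
      nrow(x$exon_intervals), " exons\n", sep = "")
  invisible(x)
}

#' Observed gene-vs-paralog identity
#'
#' @param locus A `pkd_locus`.
#' @return Named numeric vector: fraction of positions identical to the gene
#'   for each paralog.
#' @export
paralog_identity <- function(locus) {
  stopifnot(inherits(locus, "pkd_locus"))
  g <- strsplit(locus$gene_sequence, "")[[1]]
  vapply(locus$paralogs, function(p) {
    mean(strsplit(p, "")[[1]] == g)
  }, numeric(1))
}

# internal: positions where the gene differs from paralog k, with the
# paralog's base (used to construct pseudogene-homologous variant scenarios)
paralog_divergent_sites <- function(locus, k) {
  g <- strsplit(locus$gene_sequence, "")[[1]]
  p <- strsplit(locus$paralogs[[k]], "")[[1]]
  idx <- which(g != p)
  tibble::tibble(pos = idx, gene_base = g[idx], paralog_base = p[idx])
}

#' Design anchored long-range PCR amplicons over a synthetic locus
#'
#' Amplicon boundaries are placed on anchor sites so that each primer window
#' contains at least one position discriminating the gene from every
#' paralog, mirroring locus-specific LR-PCR design. Consecutive amplicons
#' overlap, which the allele-dropout detector requires.
#'
#' @param locus A `pkd_locus`.
#' @param n_amplicons Number of amplicons (>= 2 so that overlaps exist).
#' @param primer_length Primer window length in bases.
#' @return A `pkd_amplicons` tibble with columns `name`, `start`, `end`,
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end` (1-based inclusive), and
#'   an `overlaps` attribute listing overlapping pairs.
#' @export
design_amplicons <- function(locus, n_amplicons = 4, primer_length = 25) {
  stopifnot(inherits(locus, "pkd_locus"))
  if (n_amplicons < 2) {
    stop("need >= 2 amplicons so that at least one pair overlaps", call. = FALSE)
  }
  a <- locus$anchor_sites
  K <- length(a)
  if (K < n_amplicons + 1) stop("too few anchor sites for that many amplicons", call. = FALSE)

  bnd <- round(seq(1, K, length.out = n_amplicons + 1))
  fwd_idx <- c(bnd[1], pmax(1, bnd[2:n_amplicons] - 1))
  rev_idx <- c(bnd[2:n_amplicons], bnd[n_amplicons + 1])
  amp <- tibble::tibble(
    name = sprintf("AMP%d", seq_len(n_amplicons)),
    start = a[fwd_idx],
    end = pmin(locus$length, a[rev_idx] + primer_length - 1L),
    fwd_start = a[fwd_idx],
    fwd_end = pmin(locus$length, a[fwd_idx] + primer_length - 1L),
    rev_start = a[rev_idx],
    rev_end = pmin(locus$length, a[rev_idx] + primer_length - 1L)
  )

  ex <- locus$exon_intervals
  if (amp$start[1] > min(ex$start) || amp$end[n_amplicons] < max(ex$end)) {
    stop("amplicons do not cover the exon span; increase n_anchors or ",
         "reduce n_amplicons", call. = FALSE)
  }
  ov <- tibble::tibble(a = amp$name[-n_amplicons], b = amp$name[-1],
                       ov_start = amp$start[-1],
                       ov_end = amp$end[-n_amplicons])
  if (any(ov$ov_start > ov$ov_end)) {
    stop("consecutive amplicons fail to overlap; increase n_anchors", call. = FALSE)
  }
  structure(amp, class = c("pkd_amplicons", class(amp)), overlaps = ov)
}

#' Overlapping amplicon pairs
#' @param amplicons A `pkd_amplicons` tibble.
#' @return Tibble of overlapping pairs with the overlap interval.
#' @export
amplicon_overlaps <- function(amplicons) attr(amplicons, "overlaps")

#' Assemble the locus into a reference genome string
#'
#' Concatenates the gene and its paralogs (separated by runs of `N`) into a
#' single reference, returning the contig map and the gene target interval.
#' Masking this genome outside the target with [build_masked_reference()]
#' reproduces the pseudogene-aware reference strategy; leaving it unmasked
#' gives the conventional multi-copy reference used as a comparator.
#'
#' @param locus A `pkd_locus`.
#' @param spacer Number of `N` bases between contigs.
#' @return List with `sequence`, `contigs` (tibble: name, start, end) and
#'   `target` (tibble: start, end of the gene contig).
#' @export
locus_genome <- function(locus, spacer = 60) {
  stopifnot(inherits(locus, "pkd_locus"))
  seqs <- c(GENE = locus$gene_sequence, locus$paralogs)
  lens <- nchar(seqs)
  starts <- cumsum(c(1, head(lens + spacer, -1)))
  genome <- paste(seqs, collapse = strrep("N", spacer))
  contigs <- tibble::tibble(name = names(seqs),
                            start = as.integer(starts),
                            end = as.integer(starts + lens - 1))
  list(sequence = genome, contigs = contigs,
       target = tibble::tibble(start = contigs$start[1], end = contigs$end[1]))
}

#' Write locus sequences to a FASTA file
#' @param locus A `pkd_locus`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(locus, path) {
  stopifnot(inherits(locus, "pkd_locus"))
  seqs <- Biostrings::DNAStringSet(c(GENE = locus$gene_sequence, locus$paralogs))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write exon, amplicon and anchor annotations to BED files
#'
#' BED output is 0-based half-open as the format requires; all package
#' internals are 1-based inclusive.
#'
#' @param locus A `pkd_locus`.
#' @param amplicons Optional `pkd_amplicons`.
#' @param dir Output directory.
#' @param chrom Contig name used in the BED records.
#' @return Character vector of files written, invisibly.
#' @export
write_locus_bed <- function(locus, amplicons = NULL, dir = ".", chrom = "GENE") {
  stopifnot(inherits(locus, "pkd_locus"))
  files <- character(0)
  bed <- function(df, name_col, path) {
    readr::write_tsv(
      tibble::tibble(chrom = chrom, start = df$start - 1L, end = df$end,
                     name = df[[name_col]]),
      path, col_names = FALSE)
    path
  }
  ex <- locus$exon_intervals
  files <- c(files, bed(ex, "exon", file.path(dir, "exons.bed")))
  anc <- tibble::tibble(start = locus$anchor_sites, end = locus$anchor_sites,
                        name = sprintf("anchor%03d", seq_along(locus$anchor_sites)))
  files <- c(files, bed(anc, "name", file.path(dir, "anchors.bed")))
  if (!is.null(amplicons)) {
    files <- c(files, bed(amplicons, "name", file.path(dir, "amplicons.bed")))
  }
  invisible(files)
}
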