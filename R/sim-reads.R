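#' Semiconductor-sequencing read error model
#'
#' Captures the artifact profile of ion semiconductor amplicon sequencing:
#' baseline substitution miscalls, single-base insertion/deletion errors at
#' homopolymer runs whose rate grows with run length
#' (`r(L) = min(r0 * 2^(L-3), cap)` for runs of length `L >= 3`), and a
#' substitution-rate multiplier inside GC-rich windows.
#'
#' @param substitution_rate Per-base substitution miscall rate.
#' @param homopolymer_r0 Indel rate at a homopolymer run of length 3.
#' @param homopolymer_cap Upper bound on the per-run indel rate.
#' @param gc_multiplier Substitution-rate multiplier at GC-rich positions.
#' @param gc_threshold GC fraction (in a +/-25 bp window) above which a
#'   position counts as GC-rich.
#' @return A `pkd_error_model` list.
#' @export
#' @examples
#' read_error_model()                       # defaults
#' read_error_model(0, 0)                   # error-free sequencing
read_error_model <- function(substitution_rate = 0.005,
                             homopolymer_r0 = 0.002,
                             homopolymer_cap = 0.2,
                             gc_multiplier = 2,
                             gc_threshold = 0.75) {
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            homopolymer_r0 >= 0, homopolymer_r0 < 1,
            homopolymer_cap >= 0, homopolymer_cap < 1,
            gc_multiplier >= 1)
  structure(list(substitution_rate = substitution_rate,
                 homopolymer_r0 = homopolymer_r0,
                 homopolymer_cap = homopolymer_cap,
                 gc_multiplier = gc_multiplier,
                 gc_threshold = gc_threshold),
            class = "pkd_error_model")
}

# internal: homopolymer indel rate as a function of run length
hp_indel_rate <- function(L, model) {
  ifelse(L >= 3, pmin(model$homopolymer_r0 * 2^(L - 3), model$homopolymer_cap), 0)
}

# internal: apply VCF-anchored variants to a sequence; returns the edited
# sequence and a vectorized map from gene coordinates to edited coordinates
apply_variants <- function(seq, vars) {
  if (is.null(vars) || nrow(vars) == 0) {
    return(list(seq = seq, map = identity))
  }
  vars <- vars[order(vars$position), ]
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(vars))) {
    p <- vars$position[i]
    pieces <- c(pieces, substr(seq, cursor, p - 1L), vars$alt[i])
    cursor <- p + nchar(vars$ref[i])
  }
  pieces <- c(pieces, substr(seq, cursor, nchar(seq)))
  edited <- paste(pieces, collapse = "")
  var_end <- vars$position + nchar(vars$ref) - 1L
  cumdelta <- c(0L, cumsum(nchar(vars$alt) - nchar(vars$ref)))
  map <- function(g) {
    idx <- findInterval(g, var_end + 1L)
    as.integer(g + cumdelta[idx + 1L])
  }
  list(seq = edited, map = map)
}

#' Simulate amplicon sequencing reads
#'
#' Draws fragment reads uniformly within each amplicon (read count
#' proportional to amplicon length, emulating equimolar pooling of LR-PCR
#' products), injects the variant scenarios on two haplotypes (mosaic
#' variants hit each read independently with probability
#' `mosaic_fraction`), mixes in a fraction of reads drawn from random
#' paralogs (pseudogene carry-over surviving anchored PCR), applies the
#' error model, and reverse-complements a random half of the reads.
#'
#' For an amplicon named as a scenario's `dropout_amplicon`, only the
#' variant-carrying haplotype is emitted there, so the variant appears
#' homozygous in that amplicon.
#'
#' @param locus A `pkd_locus`.
#' @param amplicons A `pkd_amplicons`.
#' @param scenarios Scenario tibble ([variant_scenario()]), or `NULL`.
#' @param depth Mean per-base read depth per amplicon.
#' @param error_model A [read_error_model()].
#' @param contamination Fraction of reads drawn from paralogs, in `[0, 1)`.
#' @param seed Integer seed.
#' @param read_length Read length in bases (fragmented LR-PCR, ~200 bp).
#' @return A `pkd_reads` tibble: `read_id`, `amplicon`, `origin`, `hap`,
#'   `mosaic`, `start` (gene coordinate of the fragment), `strand`, `seq`.
#' @export
simulate_reads <- function(locus, amplicons, scenarios = NULL, depth = 100,
                           error_model = read_error_model(),
                           contamination = 0.05, seed = NULL,
                           read_length = 200) {
  stopifnot(inherits(locus, "pkd_locus"), depth >= 1,
            contamination >= 0, contamination < 1, read_length >= 30)
  check_scenarios(scenarios, locus, amplicons)

  if (is.null(scenarios)) scenarios <- variant_scenario(1, "A", "C")[0, ]
  mos <- scenarios[scenarios$zygosity == "mosaic", ]
  if (nrow(mos) > 1) {
    stop("at most one mosaic scenario per simulation", call. = FALSE)
  }
  germ <- scenarios[scenarios$zygosity != "mosaic", ]
  hapA_vars <- germ[germ$zygosity == "hom", ]
  hapB_vars <- germ
  hapA <- apply_variants(locus$gene_sequence, hapA_vars)
  hapB <- apply_variants(locus$gene_sequence, hapB_vars)
  hapAm <- apply_variants(locus$gene_sequence, dplyr::bind_rows(hapA_vars, mos))
  hapBm <- apply_variants(locus$gene_sequence, dplyr::bind_rows(germ, mos))
  haps <- list(A = hapA, B = hapB, Am = hapAm, Bm = hapBm)

  drop_amp <- stats::na.omit(scenarios$dropout_amplicon)

  with_seed(seed, {
    # fragment layout: equimolar pooling
    amp_len <- amplicons$end - amplicons$start + 1L
    n_per_amp <- pmax(1L, round(depth * amp_len / read_length))
    amp_idx <- rep(seq_len(nrow(amplicons)), n_per_amp)
    n <- length(amp_idx)
    max_start <- pmax(amplicons$start[amp_idx],
                      amplicons$end[amp_idx] - read_length + 1L)
    g <- amplicons$start[amp_idx] +
      floor(stats::runif(n) * (max_start - amplicons$start[amp_idx] + 1L))
    g <- as.integer(g)

    contam <- stats::runif(n) < contamination & length(locus$paralogs) > 0
    par_k <- if (length(locus$paralogs) > 0) {
      sample.int(length(locus$paralogs), n, replace = TRUE)
    } else rep(1L, n)
    hap <- ifelse(stats::runif(n) < 0.5, "A", "B")
    if (length(drop_amp) > 0) {
      hap[amplicons$name[amp_idx] %in% drop_amp] <- "B"
    }
    mosaic_hit <- if (nrow(mos) == 1) stats::runif(n) < mos$mosaic_fraction
                  else rep(FALSE, n)
    strand <- ifelse(stats::runif(n) < 0.5, "+", "-")

    seqs <- character(n)
    hap_key <- paste0(hap, ifelse(mosaic_hit, "m", ""))
    for (key in unique(hap_key)) {
      i <- which(hap_key == key & !contam)
      if (length(i) == 0) next
      h <- haps[[key]]
      hs <- h$map(g[i])
      seqs[i] <- substring(h$seq, hs, hs + read_length - 1L)
    }
    if (any(contam)) {
      for (k in unique(par_k[contam])) {
        i <- which(contam & par_k == k)
        seqs[i] <- substring(locus$paralogs[[k]], g[i], g[i] + read_length - 1L)
      }
    }

    seqs <- apply_sequencing_errors(seqs, g, locus$gene_sequence, error_model)

    neg <- strand == "-"
    if (any(neg)) {
      seqs[neg] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
    }

    out <- tibble::tibble(
      read_id = sprintf("read%06d", seq_len(n)),
      amplicon = amplicons$name[amp_idx],
      origin = ifelse(contam, names(locus$paralogs)[par_k], "gene"),
      hap = ifelse(contam, NA_character_, hap),
      mosaic = mosaic_hit & !contam,
      start = g,
      strand = strand,
      seq = seqs)
    class(out) <- c("pkd_reads", class(out))
    out
  })
}

# internal: apply the error model to read sequences laid out at gene
# coordinates g (sequence context is taken from the gene; haplotype edits
# and paralog differences shift it negligibly at the rates modelled)
apply_sequencing_errors <- function(seqs, g, gene, error_model) {
  n <- length(seqs)
  len <- nchar(seqs)
  if (n == 0) return(seqs)
  m <- error_model
  bases <- c("A", "C", "G", "T")

  # GC-rich positions of the gene
  gc_flag <- gc_window(gene) >= m$gc_threshold
  gc_cum <- cumsum(c(0L, as.integer(gc_flag)))
  n_gc <- gc_cum[pmin(g + len, length(gc_cum))] - gc_cum[pmax(g, 1L)]

  n_sub <- stats::rbinom(n, len, m$substitution_rate)
  p_extra <- min(1, (m$gc_multiplier - 1) * m$substitution_rate)
  n_sub_gc <- stats::rbinom(n, pmax(0L, n_gc), p_extra)

  # homopolymer runs of the gene
  hp <- homopolymer_runs(gene)
  hp$rate <- hp_indel_rate(hp$length, m)
  hp <- hp[hp$rate > 0, , drop = FALSE]
  hit_read <- integer(0); hit_off <- integer(0)
  if (nrow(hp) > 0) {
    first_j <- findInterval(g - 1L, hp$start) + 1L
    last_j <- findInterval(g + len - 2L, hp$start)
    counts <- pmax(0L, last_j - first_j + 1L)
    if (sum(counts) > 0) {
      read_idx <- rep(seq_len(n), counts)
      run_idx <- sequence(counts, from = first_j)
      hits <- stats::runif(length(run_idx)) < hp$rate[run_idx]
      hit_read <- read_idx[hits]
      hit_off <- hp$start[run_idx[hits]] - g[hit_read] + 1L
    }
  }

  needs <- which(n_sub + n_sub_gc > 0 | seq_len(n) %in% hit_read)
  for (i in needs) {
    ch <- strsplit(seqs[i], "")[[1]]
    L <- length(ch)
    if (n_sub[i] > 0) {
      pos <- sample.int(L, min(n_sub[i], L))
      ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1), character(1))
    }
    if (n_sub_gc[i] > 0) {
      flag_off <- which(gc_flag[g[i]:(g[i] + L - 1L)])
      if (length(flag_off) > 0) {
        pos <- flag_off[sample.int(length(flag_off), min(n_sub_gc[i], length(flag_off)))]
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1), character(1))
      }
    }
    offs <- sort(hit_off[hit_read == i], decreasing = TRUE)
    for (o in offs) {
      if (o < 1 || o > length(ch)) next
      if (stats::runif(1) < 0.5) {
        ch <- ch[-o]                         # homopolymer contraction
      } else {
        ch <- append(ch, ch[o], after = o)   # homopolymer expansion
      }
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

# internal: homopolymer runs (start, length) of a sequence
homopolymer_runs <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  r <- rle(b)
  ends <- cumsum(r$lengths)
  tibble::tibble(start = ends - r$lengths + 1L, length = r$lengths)
}

#' Write reads to a FASTQ file
#'
#' @param reads A `pkd_reads` tibble (or any tibble with `read_id`, `seq`).
#' @param path Output path (uncompressed FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#' @param path FASTQ path.
#' @return Tibble with `read_id` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub(" .*", "", names(x)), seq = as.character(x))
}
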