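#' Construct a variant scenario
#'
#' A scenario describes one variant to inject into simulated reads: a
#' germline heterozygote or homozygote, a sub-heterozygous somatic mosaic, or
#' a heterozygote subject to allele dropout in a named amplicon. Alleles use
#' VCF-style anchored notation: for a deletion `ref` is the anchor base plus
#' the deleted bases and `alt` the anchor base; for an insertion `ref` is the
#' anchor base and `alt` the anchor base plus the insertion.
#'
#' @param position 1-based position on the gene (the anchor base for indels).
#' @param ref,alt Reference and alternate alleles.
#' @param zygosity One of `"het"`, `"hom"`, `"mosaic"`.
#' @param mosaic_fraction Expected fraction of reads carrying a mosaic
#'   variant; required (in `(0, 1)`) iff `zygosity = "mosaic"`.
#' @param dropout_amplicon Name of the amplicon in which the non-variant
#'   haplotype fails to amplify, or `NA` for no dropout.
#' @param truth_category Optional intended classification label carried
#'   through for bookkeeping.
#' @return One-row tibble.
#' @export
variant_scenario <- function(position, ref, alt,
                             zygosity = c("het", "hom", "mosaic"),
                             mosaic_fraction = NA_real_,
                             dropout_amplicon = NA_character_,
                             truth_category = NA_character_) {
  zygosity <- match.arg(zygosity)
  if (zygosity == "mosaic") {
    if (is.na(mosaic_fraction) || mosaic_fraction <= 0 || mosaic_fraction >= 1) {
      stop("mosaic scenarios need mosaic_fraction in (0, 1)", call. = FALSE)
    }
  } else if (!is.na(mosaic_fraction)) {
    stop("mosaic_fraction only applies to mosaic scenarios", call. = FALSE)
  }
  stopifnot(nchar(ref) >= 1, nchar(alt) >= 1, ref != alt)
  tibble::tibble(position = as.integer(position), ref = ref, alt = alt,
                 zygosity = zygosity, mosaic_fraction = mosaic_fraction,
                 dropout_amplicon = dropout_amplicon,
                 truth_category = truth_category)
}

# internal: validate a scenario table against locus + amplicons
check_scenarios <- function(scenarios, locus, amplicons) {
  if (is.null(scenarios) || nrow(scenarios) == 0) return(invisible(NULL))
  g <- strsplit(locus$gene_sequence, "")[[1]]
  for (i in seq_len(nrow(scenarios))) {
    s <- scenarios[i, ]
    covered <- any(s$position >= amplicons$start & s$position <= amplicons$end)
    if (!covered) {
      stop("scenario ", i, " at position ", s$position,
           " lies outside every amplicon", call. = FALSE)
    }
    obs <- paste(g[s$position:(s$position + nchar(s$ref) - 1)], collapse = "")
    if (obs != s$ref) {
      stop("scenario ", i, ": ref allele '", s$ref,
           "' does not match the gene sequence ('", obs, "') at position ",
           s$position, call. = FALSE)
    }
    if (!is.na(s$dropout_amplicon) && !s$dropout_amplicon %in% amplicons$name) {
      stop("scenario ", i, ": dropout amplicon '", s$dropout_amplicon,
           "' does not exist", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Sample germline SNV scenarios across a locus
#'
#' Positions are drawn inside amplicon interiors (primer windows excluded),
#' spaced apart so pileups of distinct variants do not interact. A fraction
#' of variants is placed at paralog-divergent sites with the paralog's base
#' as the alternate allele: such *pseudogene-homologous* variants are the
#' alleles a multi-copy reference silently loses, and the reason the masked
#' reference exists.
#'
#' @param locus A `pkd_locus`.
#' @param amplicons A `pkd_amplicons`.
#' @param n Number of scenarios.
#' @param p_paralog_mimic Fraction of variants mimicking a paralog base
#'   (rounded to a count; requires paralogs).
#' @param zygosity Zygosity for all sampled variants.
#' @param min_spacing Minimum distance between sampled positions.
#' @param seed Integer seed.
#' @return Scenario tibble as from [variant_scenario()].
#' @export
sample_variant_scenarios <- function(locus, amplicons, n = 5,
                                     p_paralog_mimic = 0.3,
                                     zygosity = "het",
                                     min_spacing = 250, seed = NULL) {
  stopifnot(inherits(locus, "pkd_locus"))
  with_seed(seed, {
    g <- strsplit(locus$gene_sequence, "")[[1]]
    in_primer <- rep(FALSE, locus$length)
    for (i in seq_len(nrow(amplicons))) {
      in_primer[amplicons$fwd_start[i]:amplicons$fwd_end[i]] <- TRUE
      in_primer[amplicons$rev_start[i]:amplicons$rev_end[i]] <- TRUE
    }
    covered <- rep(FALSE, locus$length)
    for (i in seq_len(nrow(amplicons))) {
      covered[amplicons$start[i]:amplicons$end[i]] <- TRUE
    }
    eligible <- which(covered & !in_primer)

    n_mimic <- if (length(locus$paralogs) > 0) round(n * p_paralog_mimic) else 0L
    chosen <- integer(0)
    alts <- character(0)
    mimic_flag <- logical(0)

    take <- function(pool) {
      pool <- setdiff(pool, unlist(lapply(chosen, function(p) (p - min_spacing):(p + min_spacing))))
      if (length(pool) == 0) return(NA_integer_)
      pool[sample.int(length(pool), 1)]
    }

    if (n_mimic > 0) {
      div <- dplyr::bind_rows(lapply(seq_along(locus$paralogs), function(k) {
        dplyr::mutate(paralog_divergent_sites(locus, k), paralog = k)
      }))
      div <- div[div$pos %in% eligible, ]
      for (i in seq_len(n_mimic)) {
        p <- take(unique(div$pos))
        if (is.na(p)) break
        row <- div[div$pos == p, ][1, ]
        chosen <- c(chosen, p)
        alts <- c(alts, row$paralog_base)
        mimic_flag <- c(mimic_flag, TRUE)
      }
    }
    while (length(chosen) < n) {
      p <- take(eligible)
      if (is.na(p)) break
      chosen <- c(chosen, p)
      alts <- c(alts, sample(setdiff(c("A", "C", "G", "T"), g[p]), 1))
      mimic_flag <- c(mimic_flag, FALSE)
    }
    if (length(chosen) < n) {
      stop("could not place ", n, " variants at spacing ", min_spacing,
           "; reduce n or min_spacing", call. = FALSE)
    }
    o <- order(chosen)
    dplyr::bind_rows(lapply(seq_along(chosen), function(i) {
      variant_scenario(chosen[i], g[chosen[i]], alts[i], zygosity)
    }))[o, ] |>
      dplyr::mutate(paralog_mimic = mimic_flag[o])
  })
}

#' Sample an allele-dropout scenario in an amplicon overlap
#'
#' Places a heterozygous SNV inside the overlap of two amplicons and marks
#' one of them as dropping the non-variant haplotype, so the variant appears
#' homozygous there but heterozygous in the overlapping amplicon — the
#' discordance the dropout detector looks for.
#'
#' @param locus A `pkd_locus`.
#' @param amplicons A `pkd_amplicons`.
#' @param seed Integer seed.
#' @return One-row scenario tibble.
#' @export
sample_dropout_scenario <- function(locus, amplicons, seed = NULL) {
  ov <- amplicon_overlaps(amplicons)
  stopifnot(nrow(ov) >= 1)
  with_seed(seed, {
    g <- strsplit(locus$gene_sequence, "")[[1]]
    pair <- ov[sample.int(nrow(ov), 1), ]
    in_primer <- rep(FALSE, locus$length)
    for (i in seq_len(nrow(amplicons))) {
      in_primer[amplicons$fwd_start[i]:amplicons$fwd_end[i]] <- TRUE
      in_primer[amplicons$rev_start[i]:amplicons$rev_end[i]] <- TRUE
    }
    pool <- setdiff(seq(pair$ov_start, pair$ov_end), which(in_primer))
    pos <- pool[sample.int(length(pool), 1)]
    variant_scenario(pos, g[pos], sample(setdiff(c("A", "C", "G", "T"), g[pos]), 1),
                     zygosity = "het", dropout_amplicon = pair$a)
  })
}
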