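GENO_STATES <- c("carrier", "non_carrier", "unknown")

# internal: parental origin of one proband variant from trio carrier states
variant_origin <- function(mother, father) {
  stopifnot(mother %in% GENO_STATES, father %in% GENO_STATES)
  if (mother == "carrier" && father == "non_carrier") return("maternal")
  if (father == "carrier" && mother == "non_carrier") return("paternal")
  if (mother == "non_carrier" && father == "non_carrier") return("de_novo")
  if (mother == "carrier" && father == "carrier") return("either")
  "unknown"
}

#' Infer the phase of two heterozygous proband variants from a trio
#'
#' With unphased carrier states only, phase follows from transmission: one
#' variant maternal-only and the other paternal-only means *trans*; both
#' carried only by the same single parent means *cis* (the proband
#' received a single haplotype from that parent); a variant absent from
#' both parents is de novo and leaves the pair phase unknown
#' (`de_novo_unknown`); missing or ambiguous parental data give
#' `unknown`. Carriers are assumed heterozygous, the usual situation for
#' rare dominant-disease alleles.
#'
#' @param v1_mother,v1_father,v2_mother,v2_father Parental carrier states
#'   for the two variants: `"carrier"`, `"non_carrier"` or `"unknown"`.
#' @return One of `"trans"`, `"cis"`, `"de_novo_unknown"`, `"unknown"`.
#' @export
#' @examples
#' infer_phase("carrier", "non_carrier", "non_carrier", "carrier") # trans
infer_phase <- function(v1_mother, v1_father, v2_mother, v2_father) {
  o1 <- variant_origin(v1_mother, v1_father)
  o2 <- variant_origin(v2_mother, v2_father)
  if (o1 == "de_novo" || o2 == "de_novo") return("de_novo_unknown")
  if (o1 == "unknown" || o2 == "unknown" ||
      o1 == "either" || o2 == "either") return("unknown")
  if (o1 != o2) return("trans")
  "cis"
}

#' Detect a de novo variant in a trio
#'
#' @param proband,mother,father Carrier states (`"carrier"`,
#'   `"non_carrier"`, `"unknown"`).
#' @return List with `de_novo` (`TRUE`, `FALSE` or `"indeterminate"` when
#'   a parental genotype is missing) and a `caveat` reminding that an
#'   apparently de novo variant may reflect parental somatic or germline
#'   mosaicism below the calling threshold.
#' @export
detect_de_novo <- function(proband, mother, father) {
  stopifnot(proband %in% GENO_STATES, mother %in% GENO_STATES,
            father %in% GENO_STATES)
  caveat <- paste("an apparently de novo variant can reflect parental",
                  "somatic/germline mosaicism below the calling threshold")
  if (proband != "carrier") return(list(de_novo = FALSE, caveat = caveat))
  if (mother == "unknown" || father == "unknown") {
    return(list(de_novo = "indeterminate", caveat = caveat))
  }
  list(de_novo = mother == "non_carrier" && father == "non_carrier",
       caveat = caveat)
}

#' Categorize a family from its proband's variants and their segregation
#'
#' Categories: `mosaic_parent` when a parent carries the proband's variant
#' at sub-germline VAF; `biallelic` for a homozygous variant or two
#' same-gene variants in trans; `bilineal` for variants in two genes
#' demonstrably inherited from both parental lines (a de novo variant in
#' an affected parent's line counts as that line); `digenic` for two genes
#' without proof of both lines; `monoallelic` for a single P/LP variant;
#' otherwise `unresolved`.
#'
#' @param variants Tibble with one row per relevant proband variant:
#'   `gene`, `category` (P/LP/VUS/H/...), `origin` (`"maternal"`,
#'   `"paternal"`, `"de_novo"`, `"unknown"`), optional `homozygous`
#'   (logical).
#' @param phase Pair phase from [infer_phase()] when two variants are
#'   present (`NULL` otherwise).
#' @param parent_vaf Optional numeric vector of parental VAFs for the
#'   proband's main variant (e.g. from re-sequencing a parent); any value
#'   below `mosaic_threshold` triggers `mosaic_parent`.
#' @param mosaic_threshold Germline calling threshold (default 0.10).
#' @return Family category string.
#' @export
categorize_family <- function(variants, phase = NULL, parent_vaf = NULL,
                              mosaic_threshold = 0.10) {
  if (!"homozygous" %in% names(variants)) variants$homozygous <- FALSE
  if (!is.null(parent_vaf) && any(parent_vaf > 0 & parent_vaf < mosaic_threshold,
                                  na.rm = TRUE)) {
    return("mosaic_parent")
  }
  focal <- variants[variants$category %in% c("P", "LP", "VUS", "H"), ,
                    drop = FALSE]
  if (nrow(focal) == 0) return("unresolved")
  if (any(focal$homozygous)) return("biallelic")
  if (nrow(focal) >= 2) {
    genes <- unique(focal$gene)
    if (length(genes) == 1) {
      if (!is.null(phase) && phase == "trans") return("biallelic")
    } else {
      lines <- unique(focal$origin[focal$origin %in% c("maternal", "paternal")])
      if (length(lines) == 2 || (!is.null(phase) && phase == "trans")) {
        return("bilineal")
      }
      return("digenic")
    }
    return("unresolved")
  }
  if (focal$category[1] %in% c("P", "LP")) return("monoallelic")
  "unresolved"
}

#' Read a PED file with per-variant genotype columns
#'
#' Standard 6-column PED (family, individual, father, mother, sex,
#' phenotype) followed by one column per variant coded 0 = missing,
#' 1 = non-carrier, 2 = carrier.
#'
#' @param path PED path (whitespace-separated).
#' @param variant_ids Names for the genotype columns; defaults to
#'   `var1, var2, ...`.
#' @return Tibble with character genotype states per variant column.
#' @export
read_ped <- function(path, variant_ids = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  base <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  nv <- ncol(raw) - 6
  if (nv < 0) stop("PED file needs at least 6 columns", call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- sprintf("var%d", seq_len(nv))
  names(raw) <- c(base, variant_ids)
  out <- tibble::as_tibble(raw)
  for (v in variant_ids) {
    out[[v]] <- c("unknown", "non_carrier", "carrier")[out[[v]] + 1L]
  }
  out
}

#' Write a PED file with per-variant genotype columns
#' @param ped Tibble as returned by [read_ped()] (carrier-state columns) or
#'   with numeric 0/1/2 codes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  out <- ped
  for (v in setdiff(names(out), c("fid", "iid", "pat", "mat", "sex", "phenotype"))) {
    if (is.character(out[[v]])) {
      out[[v]] <- match(out[[v]], c("unknown", "non_carrier", "carrier")) - 1L
    }
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Phase, de novo status and family category for each trio in a pedigree
#'
#' For every family whose proband (an individual with both parents in the
#' file) carries at least one of the tabulated variants, reports the
#' parental origin of each carried variant, the pair phase when two are
#' carried, de novo findings, and the family category.
#'
#' @param ped Tibble from [read_ped()]: 6 pedigree columns plus one
#'   carrier-state column per variant.
#' @param variant_info Tibble keyed by `variant_id` with `gene` and
#'   `category` for each genotype column of `ped`.
#' @return Tibble: `fid`, `proband`, `variants` (comma-joined), `phase`,
#'   `de_novo` (comma-joined ids), `family_category`.
#' @export
family_findings <- function(ped, variant_info) {
  vcols <- setdiff(names(ped), c("fid", "iid", "pat", "mat", "sex", "phenotype"))
  fams <- unique(ped$fid)
  rows <- lapply(fams, function(f) {
    fam <- ped[ped$fid == f, , drop = FALSE]
    pro <- fam[fam$pat != "0" & fam$mat != "0", , drop = FALSE]
    if (nrow(pro) == 0) return(NULL)
    pro <- pro[1, ]
    mo <- fam[fam$iid == pro$mat, , drop = FALSE]
    fa <- fam[fam$iid == pro$pat, , drop = FALSE]
    carried <- vcols[vapply(vcols, function(v) pro[[v]] == "carrier", logical(1))]
    if (length(carried) == 0) return(NULL)
    state <- function(ind, v) if (nrow(ind) == 0) "unknown" else ind[[v]][1]
    origin <- vapply(carried, function(v) {
      variant_origin(state(mo, v), state(fa, v))
    }, character(1))
    origin_lab <- dplyr::recode(origin, maternal = "maternal",
                                paternal = "paternal", de_novo = "de_novo",
                                .default = "unknown")
    dn <- carried[vapply(carried, function(v) {
      isTRUE(detect_de_novo(pro[[v]], state(mo, v), state(fa, v))$de_novo)
    }, logical(1))]
    phase <- if (length(carried) >= 2) {
      infer_phase(state(mo, carried[1]), state(fa, carried[1]),
                  state(mo, carried[2]), state(fa, carried[2]))
    } else NA_character_
    vi <- variant_info[match(carried, variant_info$variant_id), , drop = FALSE]
    cat <- categorize_family(
      tibble::tibble(gene = vi$gene, category = vi$category,
                     origin = unname(origin_lab)),
      phase = if (is.na(phase)) NULL else phase)
    tibble::tibble(fid = f, proband = pro$iid,
                   variants = paste(carried, collapse = ","),
                   phase = phase,
                   de_novo = if (length(dn) > 0) paste(dn, collapse = ",")
                             else NA_character_,
                   family_category = cat)
  })
  dplyr::bind_rows(rows)
}
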