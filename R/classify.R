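TRUNCATING_CONSEQUENCES <- c("frameshift", "nonsense", "canonical_splice",
                             "large_rearrangement")
NON_TRUNCATING_CONSEQUENCES <- c("missense", "synonymous", "inframe_indel",
                                 "intronic")
CATEGORY_LEVELS <- c("P", "LP", "VUS", "LB", "B", "H")

#' Filter variants by population frequency
#'
#' Retains only rare alleles (minor allele frequency at or below the
#' cutoff, default 1%); a missing MAF is treated as 0 (absent from the
#' population databases). Removed variants stay available in the
#' `removed` attribute for auditing.
#'
#' @param variants Annotated variant tibble with a `maf` column.
#' @param maf_cutoff Maximum MAF retained (default 0.01).
#' @return The retained rows, with attribute `removed`.
#' @export
filter_by_frequency <- function(variants, maf_cutoff = 0.01) {
  maf <- ifelse(is.na(variants$maf), 0, variants$maf)
  keep <- maf <= maf_cutoff
  out <- variants[keep, , drop = FALSE]
  attr(out, "removed") <- variants[!keep, , drop = FALSE]
  out
}

#' Classify variants with a deterministic ACMG-style rule table
#'
#' Protein-truncating consequences (frameshift, nonsense, canonical splice
#' site, large gene rearrangement) are pathogenic outright. Non-truncating
#' variants pass through an ordered rule list: adopt a curated database
#' prior of P/LP/H when present; common alleles (MAF above the cutoff) are
#' benign or likely benign; otherwise a pathogenic-leaning computational
#' verdict on an allele absent from the population gives likely
#' pathogenic, a pathogenic-leaning verdict on a merely rare allele gives
#' uncertain significance, a benign-leaning verdict near the frequency
#' cutoff gives likely benign, and everything else is uncertain.
#' Segregation in two or more affected relatives upgrades an uncertain
#' call to likely pathogenic. Every decision appends a rule identifier, so
#' the category is fully reconstructible from `applied_rules`.
#'
#' @param variants Tibble with columns `gene`, `hgvs`, `consequence`,
#'   `maf` (NA = absent), `verdict` (one of `pathogenic_lean`,
#'   `benign_lean`, `conflicting`, `unavailable`), optional `db_class`
#'   (prior category or NA) and `seg_affected_carriers` (number of
#'   affected relatives carrying the variant).
#' @param maf_cutoff Frequency cutoff shared with [filter_by_frequency()].
#' @param common_benign_maf MAF above which a variant is outright benign
#'   rather than likely benign.
#' @param near_cutoff_maf MAF at or above which a benign-leaning verdict
#'   gives likely benign (default half the cutoff).
#' @return The input with `truncating` (logical), `category` (factor-like
#'   character in `P, LP, VUS, LB, B, H`) and `applied_rules`
#'   (list-column of rule identifiers) added.
#' @export
#' @examples
#' classify_variants(tibble::tibble(
#'   gene = "PKD1", hgvs = "p.Glu2954*", consequence = "nonsense",
#'   maf = NA, verdict = "unavailable"))
classify_variants <- function(variants, maf_cutoff = 0.01,
                              common_benign_maf = 0.05,
                              near_cutoff_maf = maf_cutoff / 2) {
  cons <- variants$consequence
  bad <- setdiff(unique(cons), c(TRUNCATING_CONSEQUENCES,
                                 NON_TRUNCATING_CONSEQUENCES))
  if (length(bad) > 0) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!"db_class" %in% names(variants)) variants$db_class <- NA_character_
  if (!"seg_affected_carriers" %in% names(variants)) {
    variants$seg_affected_carriers <- 0L
  }
  maf <- ifelse(is.na(variants$maf), 0, variants$maf)
  seg <- ifelse(is.na(variants$seg_affected_carriers), 0L,
                variants$seg_affected_carriers)
  db <- variants$db_class

  n <- nrow(variants)
  category <- character(n)
  rules <- vector("list", n)
  truncating <- cons %in% TRUNCATING_CONSEQUENCES

  for (i in seq_len(n)) {
    r <- character(0)
    if (truncating[i]) {
      category[i] <- "P"
      r <- c(r, "PT_TRUNCATING_P")
    } else if (!is.na(db[i]) && db[i] %in% c("P", "LP", "H")) {
      category[i] <- db[i]
      r <- c(r, paste0("DB_PRIOR_", db[i]))
    } else if (maf[i] > maf_cutoff) {
      if (maf[i] > common_benign_maf) {
        category[i] <- "B"; r <- c(r, "MAF_COMMON_B")
      } else {
        category[i] <- "LB"; r <- c(r, "MAF_ABOVE_CUTOFF_LB")
      }
    } else {
      v <- variants$verdict[i]
      if (v == "pathogenic_lean" && maf[i] == 0) {
        category[i] <- "LP"; r <- c(r, "INSILICO_PATH_ABSENT_LP")
      } else if (v == "pathogenic_lean") {
        category[i] <- "VUS"; r <- c(r, "INSILICO_PATH_RARE_VUS")
      } else if (v == "benign_lean" && maf[i] >= near_cutoff_maf) {
        category[i] <- "LB"; r <- c(r, "INSILICO_BENIGN_NEARCUTOFF_LB")
      } else {
        category[i] <- "VUS"; r <- c(r, "DEFAULT_VUS")
      }
      if (category[i] == "VUS" && seg[i] >= 2) {
        category[i] <- "LP"; r <- c(r, "SEGREGATION_UPGRADE_LP")
      }
    }
    rules[[i]] <- r
  }
  out <- variants
  out$truncating <- truncating
  out$category <- category
  out$applied_rules <- rules
  class(out) <- unique(c("pkd_classified", class(out)))
  out
}

#' Re-classify an additional variant as hypomorphic
#'
#' In early-onset probands carrying a pathogenic main variant, an
#' additional non-truncating variant in *trans* (or inherited from an
#' unaffected parent when the main variant is de novo) is re-classified as
#' a hypomorphic allele — a partially functional allele that aggravates
#' the phenotype of the pathogenic allele it accompanies.
#'
#' @param classified A `pkd_classified` tibble of one proband's variants.
#' @param variant_id Row index (or `hgvs` value) of the additional variant
#'   to consider; it must not be the main variant.
#' @param main_id Row index (or `hgvs`) of the proband's main variant,
#'   which must be P or LP.
#' @param onset_class Proband onset class: `"VEO"` (in utero or before 18
#'   months), `"EO"` (before 15 years), `"adult"`.
#' @param phase Phase of the additional variant relative to the main one:
#'   `"trans"`, `"cis"`, `"unknown"`, `"de_novo_unknown"`.
#' @param main_de_novo Is the main variant de novo?
#' @param from_unaffected_parent Was the additional variant inherited from
#'   an unaffected parent?
#' @return `classified` with the additional variant possibly re-classified
#'   `H` (rule `HYPOMORPHIC_TRANS_EARLY_ONSET`).
#' @export
reclassify_hypomorphic <- function(classified, variant_id, main_id,
                                   onset_class = c("adult", "EO", "VEO"),
                                   phase = c("unknown", "trans", "cis",
                                             "de_novo_unknown"),
                                   main_de_novo = FALSE,
                                   from_unaffected_parent = FALSE) {
  onset_class <- match.arg(onset_class)
  phase <- match.arg(phase)
  idx <- function(id) {
    if (is.character(id)) match(id, classified$hgvs) else as.integer(id)
  }
  vi <- idx(variant_id); mi <- idx(main_id)
  if (is.na(vi) || is.na(mi)) stop("variant not found", call. = FALSE)
  if (vi == mi) {
    stop("the main variant itself cannot be re-classified hypomorphic",
         call. = FALSE)
  }
  if (!classified$category[mi] %in% c("P", "LP")) {
    stop("hypomorphic re-classification requires a P/LP main variant",
         call. = FALSE)
  }
  if (classified$truncating[vi]) {
    stop("only non-truncating additional variants can be hypomorphic",
         call. = FALSE)
  }
  qualifies <- (phase == "trans" ||
                  (main_de_novo && from_unaffected_parent)) &&
    onset_class %in% c("VEO", "EO")
  if (qualifies) {
    classified$category[vi] <- "H"
    classified$applied_rules[[vi]] <- c(classified$applied_rules[[vi]],
                                        "HYPOMORPHIC_TRANS_EARLY_ONSET")
  }
  classified
}

#' Assign a proband's nosology label from its classified variants
#'
#' The main variant is the highest-ranked one (category order
#' P > LP > VUS > H > LB > B; then truncating before non-truncating; then
#' lower MAF; then gene PKD1 before PKD2; then position/order). The label
#' follows the gene and truncating status of the main variant when it is
#' P/LP (`ADPKD-PKD1-T`, `ADPKD-PKD1-NT`, `ADPKD-PKD2`), is
#' `PKD-VUS-only` when the best variant is a VUS, and `negative`
#' otherwise.
#'
#' @param classified A `pkd_classified` tibble of one proband's variants
#'   (possibly empty).
#' @return One-row tibble: `label`, `main_hgvs`, `main_gene`,
#'   `main_category`, `n_additional`.
#' @export
assign_nosology <- function(classified) {
  if (is.null(classified) || nrow(classified) == 0) {
    return(tibble::tibble(label = "negative", main_hgvs = NA_character_,
                          main_gene = NA_character_,
                          main_category = NA_character_, n_additional = 0L))
  }
  maf <- ifelse(is.na(classified$maf), 0, classified$maf)
  rank <- order(match(classified$category, CATEGORY_LEVELS),
                !classified$truncating,
                maf,
                match(classified$gene, c("PKD1", "PKD2")),
                seq_len(nrow(classified)))
  main <- classified[rank[1], ]
  label <- if (main$category %in% c("P", "LP")) {
    if (main$gene == "PKD2") "ADPKD-PKD2"
    else if (main$truncating) "ADPKD-PKD1-T"
    else "ADPKD-PKD1-NT"
  } else if (main$category == "VUS") {
    "PKD-VUS-only"
  } else {
    "negative"
  }
  tibble::tibble(label = label, main_hgvs = main$hgvs, main_gene = main$gene,
                 main_category = main$category,
                 n_additional = nrow(classified) - 1L)
}
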