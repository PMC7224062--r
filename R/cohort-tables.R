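NOSOLOGY_LABELS <- c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2",
                     "PKD-VUS-only", "negative")

#' Diagnostic yield table
#'
#' Partitions probands by nosology label into the standard reporting
#' layout: positives (P/LP in PKD1 or PKD2) as a fraction of all probands,
#' the PKD1/PKD2 split among positives, the truncating/non-truncating
#' split among PKD1 positives, negatives, and the VUS-only stratum with
#' its gene split. Percentages are half-up to one decimal.
#'
#' @param records Cohort tibble with a `nosology` column (labels among
#'   `ADPKD-PKD1-T`, `ADPKD-PKD1-NT`, `ADPKD-PKD2`, `PKD-VUS-only`,
#'   `negative`) and optionally `arm`.
#' @param by_arm Also produce one sub-table per study arm?
#' @return Tibble: `arm`, `group`, `n`, `denominator`, `pct`.
#' @export
#' @examples
#' rec <- tibble::tibble(nosology = rep(
#'   c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2", "PKD-VUS-only",
#'     "negative"),
#'   c(92, 26, 20, 24, 50)))
#' yield_table(rec)
yield_table <- function(records, by_arm = FALSE) {
  if (nrow(records) == 0) stop("empty cohort", call. = FALSE)
  bad <- setdiff(unique(records$nosology), NOSOLOGY_LABELS)
  if (length(bad) > 0) {
    stop("unknown nosology label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  one <- function(df, arm_label) {
    lab <- df$nosology
    n_all <- nrow(df)
    n <- function(x) sum(lab %in% x)
    pos <- n(c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2"))
    pkd1 <- n(c("ADPKD-PKD1-T", "ADPKD-PKD1-NT"))
    vus <- n("PKD-VUS-only")
    rows <- tibble::tribble(
      ~group, ~n, ~denominator,
      "positive", pos, n_all,
      "PKD1", pkd1, pos,
      "PKD1_T", n("ADPKD-PKD1-T"), pkd1,
      "PKD1_NT", n("ADPKD-PKD1-NT"), pkd1,
      "PKD2", n("ADPKD-PKD2"), pos,
      "negative", n(c("negative", "PKD-VUS-only")), n_all,
      "VUS_only", vus, n_all)
    rows$pct <- ifelse(rows$denominator > 0,
                       percent_of(rows$n, pmax(rows$denominator, 1)), NA_real_)
    rows$arm <- arm_label
    rows[, c("arm", "group", "n", "denominator", "pct")]
  }
  out <- one(records, "all")
  if (by_arm && "arm" %in% names(records)) {
    out <- dplyr::bind_rows(
      out,
      dplyr::bind_rows(lapply(split(records, records$arm), function(df) {
        one(df, df$arm[1])
      })))
  }
  out
}

#' Variant spectrum table
#'
#' Summary of distinct variants in the style of a mutation-spectrum table:
#' counts and percentages of novel/known, de novo, truncating vs
#' non-truncating, category, and consequence class, overall and per gene.
#'
#' @param variants Tibble of distinct variants: `gene`, `consequence`,
#'   `category`, logical `novel` and `de_novo`.
#' @return Tibble: `row`, `scope` (`all`/`PKD1`/`PKD2`), `n`,
#'   `denominator`, `pct` (percent of the scope's variants, half-up one
#'   decimal).
#' @export
variant_spectrum <- function(variants) {
  if (nrow(variants) == 0) stop("no variants", call. = FALSE)
  truncating <- variants$consequence %in% TRUNCATING_CONSEQUENCES
  scopes <- list(all = rep(TRUE, nrow(variants)),
                 PKD1 = variants$gene == "PKD1",
                 PKD2 = variants$gene == "PKD2")
  dplyr::bind_rows(lapply(names(scopes), function(s) {
    i <- scopes[[s]]
    d <- sum(i)
    row <- function(name, k) {
      tibble::tibble(row = name, scope = s, n = k, denominator = d,
                     pct = if (d > 0) percent_of(k, d) else NA_real_)
    }
    dplyr::bind_rows(
      row("all", d),
      row("novel", sum(variants$novel[i])),
      row("known", sum(!variants$novel[i])),
      row("de_novo", sum(variants$de_novo[i])),
      row("truncating", sum(truncating[i])),
      row("non_truncating", sum(!truncating[i])),
      dplyr::bind_rows(lapply(c("P", "LP", "VUS", "H"), function(cat) {
        row(cat, sum(variants$category[i] == cat))
      })),
      dplyr::bind_rows(lapply(
        c("missense", "nonsense", "frameshift", "canonical_splice",
          "large_rearrangement", "inframe_indel"),
        function(cq) row(cq, sum(variants$consequence[i] == cq)))))
  }))
}

#' Family-history table
#'
#' Breakdown of probands lacking an apparent family history: their share
#' of the cohort, the fraction with PKD1/PKD2 variants (and the gene/type
#' split among those), plus de novo, mosaic, multi-variant and negative
#' strata when the columns are present.
#'
#' @param records Cohort tibble with `nosology` and logical
#'   `family_history`; optional logicals `de_novo`, `mosaic`,
#'   `multi_variant`.
#' @return Tibble: `row`, `n`, `denominator`, `pct`.
#' @export
family_history_table <- function(records) {
  nh <- records[!records$family_history, , drop = FALSE]
  n_nh <- nrow(nh)
  pos_lab <- c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2")
  with_var <- sum(nh$nosology %in% pos_lab)
  row <- function(name, k, d) {
    tibble::tibble(row = name, n = k, denominator = d,
                   pct = if (d > 0) percent_of(k, d) else NA_real_)
  }
  out <- dplyr::bind_rows(
    row("no_family_history", n_nh, nrow(records)),
    row("with_PKD1_PKD2_variant", with_var, n_nh),
    row("PKD1_T", sum(nh$nosology == "ADPKD-PKD1-T"), with_var),
    row("PKD1_NT", sum(nh$nosology == "ADPKD-PKD1-NT"), with_var),
    row("PKD2", sum(nh$nosology == "ADPKD-PKD2"), with_var),
    row("negative", sum(!nh$nosology %in% pos_lab), n_nh))
  for (col in c("de_novo", "mosaic", "multi_variant")) {
    if (col %in% names(records)) {
      out <- dplyr::bind_rows(out, row(col, sum(nh[[col]]), with_var))
    }
  }
  out
}

#' Concordance of test calls against a gold standard
#'
#' Computes sensitivity, the false-positive rate among test positives,
#' and (when a site universe is supplied) specificity and accuracy,
#' comparing a call set against orthogonally confirmed (gold) calls.
#' Percentages are reported as integers (half-up), the precision at which
#' such validation figures are conventionally quoted.
#'
#' @param test_positive,gold_positive Character vectors of site
#'   identifiers called positive by the test and the gold standard.
#' @param universe Optional character vector of all sites examined
#'   (needed for specificity and accuracy).
#' @return One-row tibble: `confirmed`, `unconfirmed`, `missed`,
#'   `sensitivity_pct`, `fp_rate_pct`, and when `universe` is given,
#'   `specificity_pct`, `accuracy_pct`.
#' @export
#' @examples
#' concordance_metrics(test_positive = sprintf("s%03d", 1:221),
#'                     gold_positive = sprintf("s%03d", 1:199))
concordance_metrics <- function(test_positive, gold_positive,
                                universe = NULL) {
  if (length(gold_positive) == 0) {
    stop("empty gold-positive set: sensitivity undefined", call. = FALSE)
  }
  confirmed <- length(intersect(test_positive, gold_positive))
  unconfirmed <- length(setdiff(test_positive, gold_positive))
  missed <- length(setdiff(gold_positive, test_positive))
  out <- tibble::tibble(
    confirmed = confirmed, unconfirmed = unconfirmed, missed = missed,
    sensitivity_pct = percent_of(confirmed, confirmed + missed, digits = 0),
    fp_rate_pct = if (confirmed + unconfirmed > 0) {
      percent_of(unconfirmed, confirmed + unconfirmed, digits = 0)
    } else NA_real_)
  if (!is.null(universe)) {
    neg <- setdiff(universe, gold_positive)
    tn <- length(setdiff(neg, test_positive))
    out$specificity_pct <- percent_of(tn, length(neg), digits = 0)
    out$accuracy_pct <- percent_of(confirmed + tn, length(universe), digits = 0)
  }
  out
}
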