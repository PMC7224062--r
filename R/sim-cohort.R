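#' Simulate an ADPKD proband cohort with genotype-dependent phenotypes
#'
#' Generates per-proband records whose structure mirrors the clinical
#' tables of LR-PCR panel studies: a genotype class (PKD1 truncating, PKD1
#' non-truncating, PKD2, or negative), study arm, family-history flag,
#' onset/diagnosis/ESRD ages drawn from class-specific normal
#' distributions, and early-event flags. Default effect sizes follow the
#' reported gradient: PKD1-truncating carriers start disease earliest and
#' reach ESRD earliest, PKD2 carriers latest (onset means 27/38/47 years,
#' ESRD means 54/63/68 years).
#'
#' @param n Number of probands (>= 10).
#' @param class_mix Named proportions over
#'   `c("PKD1_T", "PKD1_NT", "PKD2", "negative")`; must sum to 1.
#' @param onset_mean,onset_sd Class onset-age means (named as `class_mix`)
#'   and common SD in years.
#' @param diagnosis_lag_mean,diagnosis_lag_sd Mean/SD of the onset-to-
#'   diagnosis lag (years, truncated at 0).
#' @param esrd_gap_mean,esrd_gap_sd Class means / common SD of the
#'   onset-to-ESRD gap (years).
#' @param esrd_prob Probability that ESRD age is observed, per class.
#' @param no_history_prob Probability of absent family history, per class.
#' @param vus_fraction_of_negative Fraction of genotype-negative probands
#'   carrying only a variant of uncertain significance.
#' @param arm_mix Named proportions over validation/confirmation/discovery.
#' @param seed Integer seed.
#' @return A `pkd_cohort` tibble with one row per proband and a `pedigree`
#'   attribute holding trio PED records (see [cohort_pedigree()]).
#' @export
simulate_cohort <- function(
    n = 212,
    class_mix = c(PKD1_T = 92, PKD1_NT = 26, PKD2 = 20, negative = 74) / 212,
    onset_mean = c(PKD1_T = 27, PKD1_NT = 38, PKD2 = 47, negative = 40),
    onset_sd = 8,
    diagnosis_lag_mean = 4, diagnosis_lag_sd = 3,
    esrd_gap_mean = c(PKD1_T = 27, PKD1_NT = 25, PKD2 = 21, negative = 25),
    esrd_gap_sd = 6,
    esrd_prob = c(PKD1_T = 0.55, PKD1_NT = 0.45, PKD2 = 0.35, negative = 0.25),
    no_history_prob = c(PKD1_T = 0.17, PKD1_NT = 0.38, PKD2 = 0.25, negative = 0.19),
    vus_fraction_of_negative = 24 / 74,
    arm_mix = c(validation = 21, confirmation = 36, discovery = 155) / 212,
    seed = NULL) {
  classes <- c("PKD1_T", "PKD1_NT", "PKD2", "negative")
  if (n < 1) stop("n must be positive", call. = FALSE)
  if (n < 10) stop("cohorts below 10 probands are not supported", call. = FALSE)
  stopifnot(setequal(names(class_mix), classes),
            abs(sum(class_mix) - 1) < 1e-8)
  if (onset_sd < 0 || diagnosis_lag_sd < 0 || esrd_gap_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }

  with_seed(seed, {
    cls <- sample(classes, n, replace = TRUE, prob = class_mix[classes])
    arm <- sample(names(arm_mix), n, replace = TRUE, prob = arm_mix)
    onset <- pmax(1, stats::rnorm(n, onset_mean[cls], onset_sd))
    diagnosis <- onset + pmax(0, stats::rnorm(n, diagnosis_lag_mean, diagnosis_lag_sd))
    esrd <- onset + pmax(1, stats::rnorm(n, esrd_gap_mean[cls], esrd_gap_sd))
    esrd[stats::runif(n) >= esrd_prob[cls]] <- NA_real_
    no_hist <- stats::runif(n) < no_history_prob[cls]
    vus <- cls == "negative" & stats::runif(n) < vus_fraction_of_negative
    nosology <- dplyr::case_when(
      cls == "PKD1_T" ~ "ADPKD-PKD1-T",
      cls == "PKD1_NT" ~ "ADPKD-PKD1-NT",
      cls == "PKD2" ~ "ADPKD-PKD2",
      vus ~ "PKD-VUS-only",
      TRUE ~ "negative")
    htn <- stats::runif(n) <
      c(PKD1_T = 0.50, PKD1_NT = 0.30, PKD2 = 0.15, negative = 0.20)[cls]
    uro <- stats::runif(n) <
      c(PKD1_T = 0.30, PKD1_NT = 0.20, PKD2 = 0.10, negative = 0.10)[cls]
    transplant <- !is.na(esrd) & stats::runif(n) < 0.6

    out <- tibble::tibble(
      proband_id = sprintf("P%04d", seq_len(n)),
      arm = arm,
      genotype_class = cls,
      nosology = nosology,
      family_history = !no_hist,
      onset_age = round(onset, 1),
      diagnosis_age = round(diagnosis, 1),
      esrd_age = round(esrd, 1),
      htn_before_35 = htn,
      uro_before_35 = uro,
      transplant = transplant)

    # trio PED records: one parent affected when family history is present
    ped <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      id <- out$proband_id[i]
      aff_parent <- if (out$family_history[i]) sample(c("father", "mother"), 1) else "none"
      tibble::tibble(
        fid = id,
        iid = c(paste0(id, "_F"), paste0(id, "_M"), id),
        pat = c("0", "0", paste0(id, "_F")),
        mat = c("0", "0", paste0(id, "_M")),
        sex = c(1L, 2L, sample(1:2, 1)),
        phenotype = c(ifelse(aff_parent == "father", 2L, 1L),
                      ifelse(aff_parent == "mother", 2L, 1L),
                      ifelse(out$genotype_class[i] == "negative" &&
                               out$nosology[i] == "negative", 1L, 2L)))
    }))
    attr(out, "pedigree") <- ped
    class(out) <- c("pkd_cohort", class(out))
    out
  })
}

#' Trio pedigree records attached to a simulated cohort
#' @param cohort A `pkd_cohort` from [simulate_cohort()].
#' @return PED-style tibble (fid, iid, pat, mat, sex, phenotype).
#' @export
cohort_pedigree <- function(cohort) attr(cohort, "pedigree")
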