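#' Normalize MLPA peaks to dosage quotients
#'
#' Standard dosage-quotient computation: each probe's peak is first scaled
#' by the sample's median reference-probe peak (intra-sample
#' normalization), then divided by the same ratio in each control sample
#' and averaged over controls. A copy-number-2 probe has expected quotient
#' 1, a heterozygous deletion ~0.5, a duplication ~1.5. The quotient is
#' invariant to rescaling all peaks of any one sample.
#'
#' @param peaks Case-sample peak tibble: `sample`, `probe`, `exon`, `peak`
#'   (a single sample).
#' @param controls Control peak tibble (one or more samples, same probes).
#' @param panel The [mlpa_panel()] used.
#' @return Tibble: `probe`, `exon`, `is_reference`, `dq` (dosage quotient).
#' @export
normalize_dosage <- function(peaks, controls, panel) {
  stopifnot(length(unique(peaks$sample)) == 1)
  if (nrow(controls) == 0) stop("at least one control sample is required", call. = FALSE)
  missing_case <- setdiff(panel$probe, peaks$probe)
  if (length(missing_case) > 0) {
    stop("case sample lacks panel probe(s): ",
         paste(missing_case, collapse = ", "), call. = FALSE)
  }
  ref_probes <- panel$probe[panel$is_reference]

  rel <- function(df) {
    med <- stats::median(df$peak[df$probe %in% ref_probes])
    if (!is.finite(med) || med == 0) {
      stop("reference-probe median is zero; cannot normalize", call. = FALSE)
    }
    dplyr::mutate(df, rel = .data$peak / med)
  }
  case_rel <- rel(peaks)
  ctrl_rel <- controls |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_modify(~ rel(.x)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$probe) |>
    dplyr::summarise(ctrl_rel = mean(.data$rel), .groups = "drop")

  panel |>
    dplyr::select("probe", "exon", "is_reference") |>
    dplyr::left_join(dplyr::select(case_rel, "probe", "rel"), by = "probe") |>
    dplyr::left_join(ctrl_rel, by = "probe") |>
    dplyr::mutate(dq = .data$rel / .data$ctrl_rel) |>
    dplyr::select("probe", "exon", "is_reference", "dq")
}

#' Call exon-level rearrangements from dosage quotients
#'
#' Each exon's state is decided by thresholding the median quotient over
#' its probes (deletion below `low`, duplication above `high`); adjacent
#' exons sharing a state merge into one event, and an event spanning every
#' gene exon is flagged whole-gene. A single aberrant probe within an
#' otherwise normal multi-probe exon is reported as a single-probe anomaly
#' rather than an event.
#'
#' @param quotients Output of [normalize_dosage()].
#' @param panel The [mlpa_panel()].
#' @param low,high Deletion / duplication thresholds (defaults 0.70 / 1.30,
#'   standard MLPA practice).
#' @return A `pkd_dosage` tibble of per-exon states (`exon`, `dq`,
#'   `state`), with attributes `events` (merged event spans with
#'   `whole_gene` flag) and `single_probe_anomalies`.
#' @export
#' @examples
#' pk <- simulate_mlpa(c(ex08 = 1, ex09 = 1), noise_sd = 0, seed = 1)
#' dq <- normalize_dosage(dplyr::filter(pk, sample == "case"),
#'                        dplyr::filter(pk, sample != "case"), mlpa_panel())
#' call_rearrangements(dq)
call_rearrangements <- function(quotients, panel = mlpa_panel(),
                                low = 0.70, high = 1.30) {
  stopifnot(low > 0, low < 1, high > 1)
  exon_order <- unique(panel$exon[!panel$is_reference])
  gene <- quotients[!quotients$is_reference, , drop = FALSE]

  per_exon <- gene |>
    dplyr::group_by(.data$exon) |>
    dplyr::summarise(dq = stats::median(.data$dq), n_probes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(state = dplyr::case_when(
      .data$dq < low ~ "deletion",
      .data$dq > high ~ "duplication",
      TRUE ~ "normal")) |>
    dplyr::arrange(match(.data$exon, exon_order))

  # events: maximal runs of identical non-normal state
  r <- rle(per_exon$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- tibble::tibble(state = r$values,
                       exon_from = per_exon$exon[starts],
                       exon_to = per_exon$exon[ends],
                       n_exons = r$lengths,
                       mean_dq = vapply(seq_along(starts), function(i) {
                         mean(per_exon$dq[starts[i]:ends[i]])
                       }, numeric(1))) |>
    dplyr::filter(.data$state != "normal") |>
    dplyr::mutate(whole_gene = .data$n_exons == length(exon_order))

  anomalies <- gene |>
    dplyr::left_join(dplyr::select(per_exon, "exon", exon_state = "state"),
                     by = "exon") |>
    dplyr::group_by(.data$exon) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$exon_state == "normal",
                  .data$dq < low | .data$dq > high) |>
    dplyr::select("probe", "exon", "dq")

  out <- per_exon
  attr(out, "events") <- ev
  attr(out, "single_probe_anomalies") <- anomalies
  class(out) <- c("pkd_dosage", class(out))
  out
}

#' Rearrangement events of a dosage call
#' @param dosage A `pkd_dosage` from [call_rearrangements()].
#' @return Tibble of merged events (state, exon span, mean quotient,
#'   whole-gene flag).
#' @export
dosage_events <- function(dosage) attr(dosage, "events")

#' Single-probe anomalies of a dosage call
#' @param dosage A `pkd_dosage`.
#' @return Tibble of lone aberrant probes inside otherwise normal exons.
#' @export
dosage_anomalies <- function(dosage) attr(dosage, "single_probe_anomalies")
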