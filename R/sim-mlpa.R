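#' Construct an MLPA probe panel
#'
#' Abstracts a commercial MLPA probemix: a set of probes targeting each gene
#' exon plus reference probes in copy-number-stable regions used for
#' intra-sample normalization.
#'
#' @param n_exons Number of gene exons covered.
#' @param probes_per_exon Probes per exon (>= 1).
#' @param n_reference Number of reference probes (>= 2).
#' @return A `pkd_mlpa_panel` tibble: `probe`, `exon`, `is_reference`.
#' @export
mlpa_panel <- function(n_exons = 15, probes_per_exon = 2, n_reference = 8) {
  stopifnot(n_exons >= 1, probes_per_exon >= 1, n_reference >= 2)
  exon <- sprintf("ex%02d", seq_len(n_exons))
  panel <- dplyr::bind_rows(
    tibble::tibble(
      probe = sprintf("%s_p%d", rep(exon, each = probes_per_exon),
                      rep(seq_len(probes_per_exon), n_exons)),
      exon = rep(exon, each = probes_per_exon),
      is_reference = FALSE),
    tibble::tibble(
      probe = sprintf("ref_p%d", seq_len(n_reference)),
      exon = "reference",
      is_reference = TRUE))
  class(panel) <- c("pkd_mlpa_panel", class(panel))
  panel
}

#' Simulate MLPA probe peak intensities
#'
#' Each probe's peak is proportional to a probe-specific amplification
#' efficiency (shared across samples in the run, as in a real probemix)
#' times the target copy number over 2, with multiplicative log-normal
#' noise. Reference probes and all control samples are copy-number 2.
#'
#' @param copy_state Named integer vector mapping exon labels to copy
#'   numbers in `{0, 1, 2, 3}` for the case sample; exons omitted default
#'   to 2. Unknown exon labels are an error.
#' @param panel A [mlpa_panel()].
#' @param noise_sd Standard deviation of the multiplicative noise on the
#'   log scale (fraction, e.g. 0.05).
#' @param n_controls Number of control samples.
#' @param seed Integer seed.
#' @return Tibble of peaks: `sample`, `probe`, `exon`, `peak`; the case
#'   sample is named `"case"`, controls `"control1"`, ...
#' @export
#' @examples
#' pk <- simulate_mlpa(c(ex08 = 1, ex09 = 1), mlpa_panel(), noise_sd = 0, seed = 1)
simulate_mlpa <- function(copy_state = integer(0), panel = mlpa_panel(),
                          noise_sd = 0.05, n_controls = 3, seed = NULL) {
  stopifnot(noise_sd >= 0, n_controls >= 1)
  exons <- unique(panel$exon[!panel$is_reference])
  unknown <- setdiff(names(copy_state), exons)
  if (length(unknown) > 0) {
    stop("unknown exon(s) in copy_state: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(copy_state) > 0 && !all(copy_state %in% 0:3)) {
    stop("copy numbers must be in {0, 1, 2, 3}", call. = FALSE)
  }
  cn <- stats::setNames(rep(2L, length(exons)), exons)
  cn[names(copy_state)] <- as.integer(copy_state)

  with_seed(seed, {
    eff <- stats::runif(nrow(panel), 0.5, 1.5) * 1000
    samples <- c("case", sprintf("control%d", seq_len(n_controls)))
    dplyr::bind_rows(lapply(samples, function(s) {
      copies <- ifelse(panel$is_reference, 2L,
                       if (s == "case") cn[panel$exon] else 2L)
      noise <- if (noise_sd > 0) exp(stats::rnorm(nrow(panel), 0, noise_sd)) else 1
      tibble::tibble(sample = s, probe = panel$probe, exon = panel$exon,
                     peak = eff * (copies / 2) * noise)
    }))
  })
}
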