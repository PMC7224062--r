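#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; diagnostic tables in this field
#' are conventionally printed with halves rounded up, so all human-readable
#' percentages in pkdpanel go through this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round() gives 0.12
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count over a denominator
#'
#' @param n Numerator count(s).
#' @param d Denominator count(s).
#' @param digits Decimal places (half-up); tables use 1, concordance uses 0.
#' @return Numeric percentage(s) on the 0-100 scale.
#' @export
#' @examples
#' percent_of(138, 212) # 65.1
#' percent_of(22, 221, digits = 0) # 10
percent_of <- function(n, d, digits = 1) {
  stopifnot(all(d > 0))
  round_half_up(100 * n / d, digits)
}

# internal: sample a random DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# internal: reverse complement of a plain character string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# internal: validate a tibble of 1-based inclusive intervals against a
# sequence length; requires sortedness and disjointness
check_intervals <- function(intervals, seq_length, what = "interval") {
  stopifnot(is.data.frame(intervals), all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) return(invisible(intervals))
  if (any(intervals$start > intervals$end)) {
    stop(what, "s must have start <= end", call. = FALSE)
  }
  if (any(intervals$start < 1) || any(intervals$end > seq_length)) {
    stop(what, "s fall outside the sequence bounds [1, ", seq_length, "]", call. = FALSE)
  }
  o <- order(intervals$start)
  s <- intervals$start[o]; e <- intervals$end[o]
  if (nrow(intervals) > 1 && any(s[-1] <= e[-nrow(intervals)])) {
    stop(what, "s overlap; they must be disjoint", call. = FALSE)
  }
  invisible(intervals[o, , drop = FALSE])
}

# internal: per-position homopolymer run length of a sequence
homopolymer_lengths <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  r <- rle(b)
  rep(r$lengths, r$lengths)
}

# internal: per-position GC fraction in a +/- flank window
gc_window <- function(seq, flank = 25) {
  b <- strsplit(seq, "")[[1]]
  gc <- as.integer(b %in% c("G", "C"))
  cs <- cumsum(c(0, gc))
  n <- length(gc)
  lo <- pmax(1, seq_len(n) - flank)
  hi <- pmin(n, seq_len(n) + flank)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# internal: run code under a local RNG seed without disturbing the caller's
# RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}
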