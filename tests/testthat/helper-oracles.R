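# Independent oracles used by the property tests. Everything here is
# deliberately naive (quadratic DP, double loops, exhaustive enumeration)
# so that agreement with the package implementations is meaningful.

# Full (unbanded, unseeded) local Smith-Waterman score, linear gap penalty.
sw_score_oracle <- function(ref, read, match = 2, mismatch = -3, gap = -4) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(read, "")[[1]]
  n <- length(r); m <- length(q)
  H <- matrix(0, nrow = m + 1, ncol = n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (r[j] != "N" && q[i] == r[j]) match else mismatch
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + s,
                             H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Naive chi-square statistic by explicit double loop over cells.
chisq_stat_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / N
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  unname(stat)
}

# Hand-computed one-way ANOVA decomposition.
anova_oracle <- function(y, g) {
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  df1 <- length(means) - 1
  df2 <- length(y) - length(means)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       ss = c(between = ssb, within = ssw))
}

# Brute-force phase oracle: enumerate every consistent placement of the two
# proband variants on the transmitted haplotypes. A parent marked carrier is
# assumed heterozygous and may or may not have transmitted; a definite
# non-carrier cannot have; an unknown parent admits both, and de novo is a
# possible placement exactly when no parent definitely carries the variant.
# The phase is reported only when every consistent placement agrees.
phase_oracle <- function(v1_mother, v1_father, v2_mother, v2_father) {
  placements <- function(mo, fa) {
    s <- character(0)
    if (mo != "non_carrier") s <- c(s, "M")
    if (fa != "non_carrier") s <- c(s, "F")
    if (mo != "carrier" && fa != "carrier") s <- c(s, "D")
    s
  }
  s1 <- placements(v1_mother, v1_father)
  s2 <- placements(v2_mother, v2_father)
  outcomes <- unique(unlist(lapply(s1, function(p1) {
    vapply(s2, function(p2) {
      if (p1 == "D" || p2 == "D") "de_novo_unknown"
      else if (p1 != p2) "trans"
      else "cis"
    }, character(1))
  })))
  if (length(outcomes) == 1) outcomes else "unknown"
}

# Binomial upper-tail probability by direct summation (mosaic-scan oracle).
binom_tail_oracle <- function(k, n, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), numeric(1)))
}

# Small deterministic locus/amplicon fixture shared by several tests.
test_locus <- function(seed = 42L, length = 2000L, n_paralogs = 6L,
                       identity = 0.98) {
  generate_locus(seed, n_paralogs = n_paralogs, identity = identity,
                 length = length)
}
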