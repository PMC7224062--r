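#' Association between a categorical phenotype and genotype groups
#'
#' Builds the contingency table and tests it with Pearson's goodness-of-fit
#' chi-square, computed from first principles as `sum((O - E)^2 / E)`
#' against the chi-square distribution with `(r-1)(c-1)` degrees of
#' freedom. When any cell is below 5 the Fisher exact test is used
#' instead; for a 2x2 table the two-sided p value is obtained by direct
#' hypergeometric enumeration (summing all tables with probability not
#' exceeding the observed one), for larger tables it delegates to
#' [stats::fisher.test()]. The small-cell trigger examines observed counts
#' by default and can be switched to expected counts.
#'
#' @param records Cohort tibble.
#' @param outcome Name of the categorical/logical outcome column.
#' @param group Name of the grouping column (e.g. genotype class).
#' @param small_cell_rule Use `"observed"` (default) or `"expected"`
#'   counts for the Fisher trigger.
#' @return A `pkd_assoc` object: list with `table`, `expected`, `method`,
#'   `statistic`, `df`, `p_value`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
categorical_association <- function(records, outcome, group,
                                    small_cell_rule = c("observed", "expected")) {
  small_cell_rule <- match.arg(small_cell_rule)
  tab <- table(records[[group]], records[[outcome]])
  if (nrow(tab) < 2) stop("need at least two groups", call. = FALSE)
  if (ncol(tab) < 2) stop("outcome has a single level", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  trigger <- if (small_cell_rule == "observed") any(tab < 5) else any(expected < 5)

  if (trigger) {
    if (all(dim(tab) == c(2, 2))) {
      p <- fisher_2x2_p(tab)
    } else {
      p <- stats::fisher.test(tab)$p.value
    }
    out <- list(table = tab, expected = expected, method = "fisher",
                statistic = NA_real_, df = NA_integer_, p_value = p)
  } else {
    stat <- sum((tab - expected)^2 / expected)
    df <- (nrow(tab) - 1) * (ncol(tab) - 1)
    out <- list(table = tab, expected = expected, method = "chi_square",
                statistic = stat, df = df,
                p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  structure(out, class = "pkd_assoc")
}

# internal: two-sided Fisher exact p for a 2x2 table by hypergeometric
# enumeration (sum of probabilities of all tables at the observed margins
# with probability <= that of the observed table)
fisher_2x2_p <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' @export
print.pkd_assoc <- function(x, ...) {
  cat("<pkd_assoc> ", x$method,
      if (x$method == "chi_square") {
        sprintf(": X2 = %.3f, df = %d,", x$statistic, x$df)
      } else ":",
      sprintf(" p = %.4g\n", x$p_value), sep = "")
  invisible(x)
}

#' One-way ANOVA of an age variable across genotype groups
#'
#' Classical between/within decomposition: the F statistic is the ratio of
#' the between-group to within-group mean squares, with group means
#' reported so the clinical ordering (PKD1-truncating earliest) can be
#' read off directly.
#'
#' @param records Cohort tibble.
#' @param age Name of the numeric age column (NAs dropped).
#' @param group Name of the grouping column.
#' @return A `pkd_anova` object: list with `group_means` (tibble),
#'   `statistic` (F), `df` (c(between, within)), `p_value`, `ss`
#'   (c(between, within)). Has `tidy()` and `glance()` methods.
#' @export
anova_onset <- function(records, age = "onset_age", group = "genotype_class") {
  df <- records[!is.na(records[[age]]), c(age, group)]
  names(df) <- c("y", "g")
  counts <- table(df$g)
  counts <- counts[counts > 0]
  if (length(counts) < 2) stop("need at least two groups", call. = FALSE)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  gm <- df |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                     sd = stats::sd(.data$y), .groups = "drop") |>
    dplyr::rename(group = "g")
  grand <- mean(df$y)
  ssb <- sum(gm$n * (gm$mean - grand)^2)
  ssw <- sum((df$y - gm$mean[match(df$g, gm$group)])^2)
  df1 <- nrow(gm) - 1
  df2 <- nrow(df) - nrow(gm)
  f <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(group_means = gm, statistic = f, df = c(df1, df2),
                 p_value = p, ss = c(between = ssb, within = ssw)),
            class = "pkd_anova")
}

#' @export
print.pkd_anova <- function(x, ...) {
  cat(sprintf("<pkd_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p_value))
  print(x$group_means)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pkd_anova <- function(x, ...) {
  x$group_means
}

#' @export
glance.pkd_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df_between = x$df[1],
                 df_within = x$df[2], p_value = x$p_value,
                 ss_between = x$ss[["between"]], ss_within = x$ss[["within"]])
}

#' @export
tidy.pkd_assoc <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$table)) |>
    stats::setNames(c("group", "outcome", "n"))
}

#' @export
glance.pkd_assoc <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value)
}
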