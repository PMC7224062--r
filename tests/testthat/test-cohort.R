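table2_fixture <- function() {
  tibble::tibble(nosology = rep(
    c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2", "PKD-VUS-only",
      "negative"),
    c(92, 26, 20, 24, 50)))
}

test_that("yield_table partitions counts and errors on bad input", {
  yt <- yield_table(table2_fixture())
  n <- function(g) yt$n[yt$group == g]
  expect_equal(n("positive") + n("negative"), 212)
  expect_equal(n("PKD1") + n("PKD2"), n("positive"))
  expect_equal(n("PKD1_T") + n("PKD1_NT"), n("PKD1"))
  expect_error(yield_table(table2_fixture()[0, ]), "empty")
  expect_error(yield_table(tibble::tibble(nosology = "nope")), "unknown")
})

test_that("complementary yield percentages sum to 100 within rounding", {
  set.seed(31)
  for (i in 1:20) {
    rec <- tibble::tibble(nosology = sample(
      c("ADPKD-PKD1-T", "ADPKD-PKD1-NT", "ADPKD-PKD2", "PKD-VUS-only",
        "negative"), sample(20:300, 1), replace = TRUE))
    yt <- yield_table(rec)
    p <- function(g) yt$pct[yt$group == g]
    expect_equal(p("positive") + p("negative"), 100, tolerance = 0.101)
    if (yt$n[yt$group == "PKD1"] > 0) {
      expect_equal(p("PKD1_T") + p("PKD1_NT"), 100, tolerance = 0.101)
    }
  }
})

test_that("concordance metrics follow their definitions", {
  t1 <- concordance_metrics(test_positive = sprintf("s%d", 1:221),
                            gold_positive = sprintf("s%d", 1:199))
  expect_equal(t1$unconfirmed, 22)
  expect_equal(t1$fp_rate_pct, 10)
  expect_equal(t1$sensitivity_pct, 100)
  t2 <- concordance_metrics(letters[1:5], letters[1:5])
  expect_equal(t2$sensitivity_pct, 100)
  expect_equal(t2$fp_rate_pct, 0)
  expect_error(concordance_metrics(letters, character(0)), "gold")
  u <- sprintf("u%d", 1:100)
  t3 <- concordance_metrics(u[1:40], u[1:30], universe = u)
  expect_equal(t3$specificity_pct, round_half_up(100 * 60 / 70))
  expect_equal(t3$accuracy_pct, 90)
  # accuracy symmetric under test<->gold relabeling, sensitivity not
  t4 <- concordance_metrics(u[1:30], u[1:40], universe = u)
  expect_equal(t3$accuracy_pct, t4$accuracy_pct)
  expect_false(t3$sensitivity_pct == t4$sensitivity_pct)
})

test_that("chi-square is used for large cells and matches the naive oracle", {
  set.seed(32)
  rec <- tibble::tibble(
    group = sample(c("g1", "g2"), 400, replace = TRUE),
    flag = sample(c("yes", "no", "maybe"), 400, replace = TRUE))
  got <- categorical_association(rec, "flag", "group")
  expect_equal(got$method, "chi_square")
  expect_equal(got$statistic, chisq_stat_oracle(got$table))
  ref <- suppressWarnings(stats::chisq.test(got$table, correct = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))
  expect_equal(got$df, 2L)
})

test_that("identical group proportions give statistic ~0, p ~1", {
  rec <- tibble::tibble(group = rep(c("a", "b"), each = 200),
                        flag = rep(rep(c(TRUE, FALSE), each = 100), 2))
  got <- categorical_association(rec, "flag", "group")
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
})

test_that("a small observed cell triggers Fisher; 2x2 enumeration matches
           stats::fisher.test", {
  rec <- tibble::tibble(
    group = rep(c("a", "b"), c(20, 20)),
    flag = c(rep(TRUE, 3), rep(FALSE, 17), rep(TRUE, 12), rep(FALSE, 8)))
  got <- categorical_association(rec, "flag", "group")
  expect_equal(got$method, "fisher")
  expect_equal(got$p_value,
               stats::fisher.test(got$table)$p.value, tolerance = 1e-9)
  # expected-cell rule is configurable and can differ from the observed rule
  rec2 <- tibble::tibble(
    group = rep(c("a", "b"), c(100, 8)),
    flag = c(rep(TRUE, 50), rep(FALSE, 50), rep(TRUE, 4), rep(FALSE, 4)))
  obs <- categorical_association(rec2, "flag", "group",
                                 small_cell_rule = "observed")
  expc <- categorical_association(rec2, "flag", "group",
                                  small_cell_rule = "expected")
  expect_equal(obs$method, "fisher")
  expect_equal(expc$method, "fisher")
  expect_error(categorical_association(
    tibble::tibble(group = "a", flag = TRUE), "flag", "group"), "two groups")
})

test_that("fisher_2x2_p equals stats::fisher.test across random tables", {
  set.seed(33)
  for (i in 1:25) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(pkdpanel:::fisher_2x2_p(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("anova_onset matches the hand decomposition and stats::aov", {
  toy <- tibble::tibble(
    genotype_class = rep(c("PKD1_T", "PKD1_NT", "PKD2"), each = 3),
    onset_age = c(20, 25, 30, 35, 38, 41, 44, 47, 52))
  got <- anova_onset(toy)
  want <- anova_oracle(toy$onset_age, toy$genotype_class)
  expect_equal(got$statistic, want$statistic)
  expect_equal(got$p_value, want$p_value)
  expect_equal(unname(got$ss), unname(want$ss))
  ref <- summary(stats::aov(onset_age ~ genotype_class, data = toy))[[1]]
  expect_equal(got$statistic, ref[["F value"]][1])
  expect_equal(got$p_value, ref[["Pr(>F)"]][1])
  expect_equal(got$df, c(2L, 6L))
  # identical values across and within groups -> F = 0
  flat <- tibble::tibble(genotype_class = rep(c("a", "b"), each = 3),
                         onset_age = rep(10, 6))
  expect_equal(anova_onset(flat)$statistic, 0)
  expect_error(anova_onset(tibble::tibble(
    genotype_class = c("a", "a", "b"), onset_age = c(1, 2, 3))), "b")
})

test_that("tidy and glance methods return well-formed tibbles", {
  toy <- tibble::tibble(
    genotype_class = rep(c("x", "y"), each = 4),
    onset_age = c(1, 2, 3, 4, 7, 8, 9, 10))
  a <- anova_onset(toy)
  expect_named(glance(a), c("statistic", "df_between", "df_within",
                            "p_value", "ss_between", "ss_within"))
  expect_equal(nrow(tidy(a)), 2)
  rec <- tibble::tibble(group = rep(c("a", "b"), each = 50),
                        flag = rep(c(TRUE, FALSE), 50))
  s <- categorical_association(rec, "flag", "group")
  expect_named(glance(s), c("method", "statistic", "df", "p_value"))
  expect_equal(sum(tidy(s)$n), 100)
})

test_that("simulate_cohort recovers its injected structure", {
  co <- simulate_cohort(n = 400, seed = 51)
  expect_equal(nrow(co), 400)
  expect_true(all(co$onset_age > 0))
  both <- !is.na(co$esrd_age)
  expect_true(all(co$esrd_age[both] >= co$onset_age[both]))
  # onset-age gaps recovered within ~2 SE
  m <- tapply(co$onset_age, co$genotype_class, mean)
  n_t <- sum(co$genotype_class == "PKD1_T")
  expect_lt(abs(m[["PKD1_T"]] - 27), 2.5 * 8 / sqrt(n_t))
  expect_true(m[["PKD1_T"]] < m[["PKD1_NT"]])
  expect_true(m[["PKD1_NT"]] < m[["PKD2"]])
  ped <- cohort_pedigree(co)
  expect_equal(nrow(ped), 3 * 400)
  expect_error(simulate_cohort(n = 5), "10")
  expect_identical(simulate_cohort(50, seed = 9), simulate_cohort(50, seed = 9))
})

test_that("family_history_table and variant_spectrum report coherent splits", {
  co <- simulate_cohort(n = 300, seed = 61)
  fh <- family_history_table(co)
  n_nh <- fh$n[fh$row == "no_family_history"]
  expect_equal(fh$denominator[fh$row == "with_PKD1_PKD2_variant"], n_nh)
  expect_equal(fh$n[fh$row == "with_PKD1_PKD2_variant"] +
                 fh$n[fh$row == "negative"], n_nh)
  vs <- variant_spectrum(tibble::tibble(
    gene = c("PKD1", "PKD1", "PKD2"),
    consequence = c("frameshift", "missense", "nonsense"),
    category = c("P", "VUS", "P"),
    novel = c(TRUE, FALSE, TRUE),
    de_novo = c(FALSE, FALSE, TRUE)))
  all_scope <- vs[vs$scope == "all", ]
  expect_equal(all_scope$n[all_scope$row == "truncating"] +
                 all_scope$n[all_scope$row == "non_truncating"], 3)
  expect_equal(all_scope$n[all_scope$row == "novel"], 2)
})
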