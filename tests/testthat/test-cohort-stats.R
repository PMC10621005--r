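test_that("uncorrected chi-squared reproduces printed cohort p-values", {
  # hypertension: CAD- 10/38, CAD+ 40/79
  expect_equal(round(chi2_2x2_uncorrected(10, 28, 40, 39)$p, 3), 0.013)
  # statin: closed-form statistic and printed p
  st <- chi2_2x2_uncorrected(7, 31, 31, 48)
  expect_equal(st$statistic, 5.07, tolerance = 0.002)
  expect_equal(round(st$p, 3), 0.024)
})

test_that("chi-squared is zero for proportional tables and matches stats::chisq.test", {
  prop <- chi2_2x2_uncorrected(10, 20, 30, 60) # a/b = c/d
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)
  set.seed(1)
  for (i in 1:20) {
    t <- rpois(4, 20) + 1
    ours <- chi2_2x2_uncorrected(t[1], t[2], t[3], t[4])
    ref <- suppressWarnings(
      chisq.test(matrix(t, 2, 2, byrow = TRUE), correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("chi-squared is invariant to row/column swaps and transposition", {
  t <- c(7, 31, 31, 48)
  base <- chi2_2x2_uncorrected(t[1], t[2], t[3], t[4])$statistic
  expect_equal(chi2_2x2_uncorrected(t[3], t[4], t[1], t[2])$statistic, base)
  expect_equal(chi2_2x2_uncorrected(t[2], t[1], t[4], t[3])$statistic, base)
  expect_equal(chi2_2x2_uncorrected(t[1], t[3], t[2], t[4])$statistic, base)
})

test_that("chi-squared equals the squared pooled two-proportion z statistic", {
  set.seed(2)
  for (i in 1:10) {
    t <- rpois(4, 15) + 1
    n1 <- t[1] + t[2]; n2 <- t[3] + t[4]
    phat <- (t[1] + t[3]) / (n1 + n2)
    z <- (t[1] / n1 - t[3] / n2) /
      sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
    expect_equal(chi2_2x2_uncorrected(t[1], t[2], t[3], t[4])$statistic,
                 z^2, tolerance = 1e-10)
  }
})

test_that("degenerate tables raise a degenerate-table error", {
  expect_error(chi2_2x2_uncorrected(0, 0, 5, 5), "degenerate")
})

test_that("Fisher exact test matches hypergeometric enumeration", {
  # diabetes-like table: the observed table is modal, so p = 1
  expect_equal(fisher_exact_2x2(2, 36, 6, 73)$p, 1.0, tolerance = 1e-9)
  # fully crossed extreme table
  expect_equal(fisher_exact_2x2(0, 5, 5, 0)$p, 2 / choose(10, 5),
               tolerance = 1e-9)
  set.seed(3)
  for (i in 1:25) {
    t <- rpois(4, sample(3:40, 1))
    if (sum(t) > 200 || sum(t) == 0) next
    expect_equal(fisher_exact_2x2(t[1], t[2], t[3], t[4])$p,
                 fisher_enum_p(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-7)
  }
})

test_that("Wilcoxon rank-sum covers exact, approximate and degenerate cases", {
  # exact enumeration: most extreme labeling of {1,2} vs {3,4}
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p, 1 / 3, tolerance = 1e-12)
  # same multiset: symmetric, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(3, 1, 2))$p, 1)
  # strong shift at n = 200 per group: overwhelming evidence
  set.seed(4)
  x <- rnorm(200); y <- rnorm(200, mean = 2)
  expect_lt(wilcoxon_rank_sum(x, y)$p, 1e-6)
  # all values identical: degenerate with warning note
  deg <- wilcoxon_rank_sum(rep(1, 5), rep(1, 5))
  expect_equal(deg$p, 1)
  expect_match(deg$note, "degenerate")
})

test_that("the characteristics table reproduces the printed p column", {
  m <- read_margins(system.file("extdata", "discovery_margins.csv",
                                package = "cadimmune"))
  rec <- records_from_margins(m)
  t1 <- build_table1(rec, rule = "chi2_always")
  p <- setNames(round(t1$p, 3), t1$variable)
  expect_equal(p[["sex_male"]], 0.010)
  expect_equal(p[["hypertension"]], 0.013)
  expect_equal(p[["hyperlipidaemia"]], 0.042)
  expect_equal(p[["smurfless"]], 0.024)
  expect_equal(p[["statin"]], 0.024)
  expect_equal(p[["ace_arb"]], 0.028)
  expect_equal(p[["diabetes"]], 0.640)
  expect_equal(p[["family_history"]], 0.902)
  expect_equal(p[["current_smoking"]], 0.625)
  expect_true(all(t1$test_used[t1$variable %in% c("age", "bmi")] == "wilcoxon"))
})

test_that("the footnote rule routes small expected counts to Fisher", {
  m <- read_margins(system.file("extdata", "discovery_margins.csv",
                                package = "cadimmune"))
  rec <- records_from_margins(m)
  t1 <- build_table1(rec, rule = "paper_footnote")
  dia <- t1[t1$variable == "diabetes", ]
  expect_equal(dia$test_used, "fisher_exact")
  expect_equal(dia$p, 1.0, tolerance = 1e-9) # diverges from chi-squared 0.640
  # large expected counts keep chi-squared
  expect_equal(t1$test_used[t1$variable == "hypertension"], "chi2_uncorrected")
})

test_that("zero-prevalence variables are reported as not applicable", {
  rec <- make_patients(30, gensini = rep(c(0, 5), 15))
  rec$diabetes <- FALSE
  t1 <- build_table1(rec)
  dia <- t1[t1$variable == "diabetes", ]
  expect_true(is.na(dia$p))
  expect_match(dia$note, "degenerate")
})
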