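test_that("single binary predictor recovers the cross-product odds ratio", {
  # trait-by-CAD table (10, 28; 40, 39): OR = (40*28)/(10*39)
  y <- rep(c(FALSE, TRUE), c(38, 79))
  x <- c(rep(c(1, 0), c(10, 28)), rep(c(1, 0), c(40, 39)))
  fit <- fit_logistic(y, cbind(trait = x))
  expect_equal(exp(fit$coef[["trait"]]), (40 * 28) / (10 * 39),
               tolerance = 1e-6)
  expect_equal(sqrt(fit$vcov["trait", "trait"]),
               sqrt(1 / 10 + 1 / 28 + 1 / 40 + 1 / 39), tolerance = 1e-6)
})

test_that("cross-product oracle holds over random 2x2 designs", {
  set.seed(10)
  for (i in 1:50) {
    t <- rpois(4, 15) + 2
    y <- rep(c(0, 0, 1, 1), t)
    x <- rep(c(1, 0, 1, 0), t)
    fit <- fit_logistic(y, cbind(x = x))
    expect_equal(exp(fit$coef[["x"]]), (t[3] * t[2]) / (t[1] * t[4]),
                 tolerance = 1e-5)
  }
})

test_that("outcome-balanced predictors give a zero coefficient", {
  # x distributed identically within both outcome strata
  y <- rep(c(0, 1), each = 10)
  x <- rep(c(1, 2, 3, 4, 5), 4)
  fit <- fit_logistic(y, cbind(x = x))
  expect_equal(fit$coef[["x"]], 0, tolerance = 1e-8)
})

test_that("an orthogonal covariate leaves the focal coefficient unchanged", {
  # balanced 2x2 design in (x, z) with identical y rates across z within x
  x <- rep(c(0, 0, 1, 1), each = 25)
  z <- rep(c(0, 1, 0, 1), each = 25)
  y <- c(rep(c(1, 0), c(10, 15)), rep(c(1, 0), c(10, 15)),
         rep(c(1, 0), c(15, 10)), rep(c(1, 0), c(15, 10)))
  b1 <- fit_logistic(y, cbind(x = x))$coef[["x"]]
  b2 <- fit_logistic(y, cbind(x = x, z = z))$coef[["x"]]
  expect_equal(b1, b2, tolerance = 1e-6)
})

test_that("predictor rescaling rescales beta and se but not p", {
  set.seed(11)
  x <- rnorm(80); y <- runif(80) < plogis(0.5 * x)
  f1 <- fit_logistic(y, cbind(x = x))
  f2 <- fit_logistic(y, cbind(x = 10 * x))
  se1 <- sqrt(f1$vcov["x", "x"]); se2 <- sqrt(f2$vcov["x", "x"])
  expect_equal(f2$coef[["x"]], f1$coef[["x"]] / 10, tolerance = 1e-8)
  expect_equal(se2, se1 / 10, tolerance = 1e-8)
  expect_equal(f1$coef[["x"]] / se1, f2$coef[["x"]] / se2, tolerance = 1e-8)
})

test_that("separation and degenerate predictors are flagged", {
  y <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(y, cbind(x = y * 100)), "separation")
  expect_error(fit_logistic(y, cbind(x = rep(1, 40))), "constant")
})

test_that("association panels carry matching schemas and tiers", {
  cfg <- sim_config(n_discovery = 80, n_validation = 0, seed = 21)
  coh <- generate_cohort(cfg)
  un <- run_panel(coh$proportions, coh$records, adjust = FALSE)
  ad <- run_panel(coh$proportions, coh$records, adjust = TRUE)
  expect_identical(un$subset_id, ad$subset_id)
  expect_identical(names(un), names(ad))
  expect_true(all(un$model == "unadjusted"))
  expect_true(all(ad$model == "age_sex_adjusted"))
  expect_equal(un$or_, exp(un$beta))
  expect_true(all(un$ci_low < un$or_ & un$or_ < un$ci_high))
  bh <- run_panel(coh$proportions[, 1:5], coh$records, bh = TRUE)
  expect_true("p_bh" %in% names(bh))
  expect_true(all(bh$p_bh >= bh$p))
})

test_that("zero-variance subsets are flagged untestable, not dropped", {
  cfg <- sim_config(n_discovery = 60, n_validation = 0, seed = 22)
  coh <- generate_cohort(cfg)
  prop <- coh$proportions[, 1:4]
  prop[, 2] <- 50
  panel <- run_panel(prop, coh$records)
  expect_equal(nrow(panel), 4)
  expect_match(panel$note[2], "zero variance")
  expect_true(is.na(panel$p[2]))
})

test_that("significance tiers map p-values to the figure glyphs", {
  cfg <- sim_config(n_discovery = 60, n_validation = 0, seed = 23)
  coh <- generate_cohort(cfg)
  panel <- run_panel(coh$proportions[, 1:3], coh$records)
  panel$p <- c(0.03, 0.2, 0.0005)
  panel$tier <- cadimmune:::tier_glyph(panel$p)
  ft <- forest_table(panel, coh$catalog)
  expect_equal(ft$tier[match(panel$subset_id, ft$subset_id)],
               c("*", "", "***"))
  expect_equal(cadimmune:::tier_glyph(c(0.09, 0.04, 0.009, 0.0009, 0.5)),
               c("°", "*", "**", "***", ""))
})

test_that("adjustment changes nothing when age and sex are independent", {
  # no age trend on the subset, no age/sex effect on the label
  devs <- vapply(1:15, function(s) {
    cfg <- one_subset_config(delta = 0.4, n = 1500, seed = 400 + s)
    coh <- generate_cohort(cfg)
    un <- run_panel(coh$proportions, coh$records, adjust = FALSE)
    ad <- run_panel(coh$proportions, coh$records, adjust = TRUE)
    ad$beta[1] - un$beta[1]
  }, 0)
  expect_lt(abs(mean(devs)), 3 * sd(devs) / sqrt(length(devs)) + 1e-3)
})
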