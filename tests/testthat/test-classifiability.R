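test_that("cross-validation plans partition patients and stratify classes", {
  y <- rep(c(TRUE, FALSE), c(34, 16))
  plan <- cv_plan(y, folds = 5, repeats = 10, seed = 50)
  expect_equal(dim(plan$assignment), c(10, 50))
  for (r in 1:10) {
    expect_equal(sort(unique(plan$assignment[r, ])), 1:5)
    # every patient appears in exactly one fold per repeat (by construction
    # of the assignment vector) and every fold holds both classes
    for (f in 1:5) {
      expect_setequal(unique(y[plan$assignment[r, ] == f]), c(TRUE, FALSE))
    }
  }
  expect_identical(cv_plan(y, 5, 10, seed = 50)$assignment, plan$assignment)
  expect_false(identical(cv_plan(y, 5, 10, seed = 51)$assignment,
                         plan$assignment))
})

test_that("AUC screening ranks by distance from 0.5 with stable ties", {
  set.seed(51)
  y <- rep(c(TRUE, FALSE), each = 20)
  X <- cbind(noise1 = rnorm(40), label = as.numeric(y), noise2 = rnorm(40))
  expect_equal(screen_by_auc(X, y, 1), 2)
  # an anti-predictive feature outranks a mildly predictive one
  n <- 40
  x_anti <- ifelse(y, rnorm(n, -2), rnorm(n, 0))   # AUC well below 0.5
  x_mild <- ifelse(y, rnorm(n, 0.2), rnorm(n, 0))  # AUC slightly above
  X2 <- cbind(mild = x_mild, anti = x_anti)
  expect_equal(screen_by_auc(X2, y, 1, rank_key = "abs"), 2)
  expect_equal(screen_by_auc(X2, y, 1, rank_key = "raw"), 1)
  # ties break by original column order
  X3 <- cbind(a = x_mild, b = x_mild)
  expect_equal(screen_by_auc(X3, y, 2), c(1, 2))
  expect_error(screen_by_auc(X, rep(TRUE, 40), 1), "both classes")
})

test_that("screening sees only the training split", {
  set.seed(52)
  y <- rep(c(TRUE, FALSE), each = 20)
  train <- c(1:10, 21:30)
  X <- cbind(test_only = ifelse(seq_len(40) %in% train, rnorm(40),
                                as.numeric(y) * 10),
             weak = as.numeric(y) + rnorm(40, sd = 2))
  # on training rows the leaky feature is pure noise and must lose
  sel <- screen_by_auc(X[train, ], y[train], 1)
  expect_equal(sel, 2)
})

test_that("a perfectly separating feature gives classifiability 1", {
  set.seed(53)
  n <- 40
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(signal = as.numeric(y) * 10 + rnorm(n, sd = 0.01),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("n", 1:5))))
  plan <- cv_plan(y, folds = 5, repeats = 3, seed = 53)
  prof <- compute_classifiability(X, y, plan, m = 2)
  expect_true(all(prof$score == 1))
})

test_that("classifiability scores obey the structural identities", {
  cfg <- sim_config(n_discovery = 60, n_validation = 0, seed = 54)
  coh <- generate_cohort(cfg)
  y <- cad_status(coh$records)
  plan <- cv_plan(y, folds = 5, repeats = 4, seed = 54)
  prof <- compute_classifiability(coh$proportions, y, plan, m = 10)
  expect_true(all(prof$score >= 0 & prof$score <= 1))
  expect_lte(length(unique(prof$score)), plan$repeats + 1)
  # mean classifiability equals overall repeated-CV accuracy, exactly
  expect_identical(mean(prof$score), mean(prof$correct))
  # determinism
  prof2 <- compute_classifiability(coh$proportions, y, plan, m = 10)
  expect_identical(prof$score, prof2$score)
})

test_that("all-noise features yield majority-class-level accuracy", {
  set.seed(55)
  accs <- vapply(1:5, function(s) {
    n <- 117
    y <- rep(c(TRUE, FALSE), c(79, 38))[sample.int(n)]
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("f", 1:20)))
    plan <- cv_plan(y, folds = 5, repeats = 4, seed = 600 + s)
    mean(compute_classifiability(X, y, plan, m = 10)$score)
  }, 0)
  # binomial CI around the majority-class rate 79/117
  p0 <- 79 / 117
  half <- qnorm(0.9995) * sqrt(p0 * (1 - p0) / (117 * 5))
  expect_lt(abs(mean(accs) - p0), half + 0.05)
})

test_that("modifier regressions recover a planted age slope", {
  rec <- make_patients(117, gensini = rep(c(0, 5), length.out = 117),
                       age = runif(117, 40, 80))
  firsts <- vapply(1:100, function(s) {
    set.seed(700 + s)
    ci <- 0.3 + 0.006 * (rec$age - 40) + rnorm(117, sd = 0.05)
    mods <- find_modifiers(pmin(pmax(ci, 0), 1), rec)
    mods$covariate[1] == "age" && mods$coefficient[1] > 0
  }, TRUE)
  expect_gte(mean(firsts), 0.95)
})

test_that("null modifier p-values are uniform", {
  rec <- make_patients(100, gensini = rep(c(0, 5), 50),
                       age = runif(100, 40, 80))
  ps <- vapply(1:200, function(s) {
    set.seed(800 + s)
    ci <- runif(100, 0.4, 0.9) # independent of every covariate
    mods <- find_modifiers(ci, rec, covariates = "age")
    mods$p[1]
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("constant inputs to modifier regression are flagged", {
  rec <- make_patients(30, gensini = rep(c(0, 5), 15))
  mods <- find_modifiers(rep(0.7, 30), rec, covariates = c("age", "diabetes"))
  expect_true(all(grepl("degenerate|untestable", mods$note)))
  rec$diabetes <- FALSE
  mods2 <- find_modifiers(runif(30), rec, covariates = c("age", "diabetes"))
  expect_match(mods2$note[mods2$covariate == "diabetes"], "untestable")
})

test_that("sub-cohort selection is boundary-inclusive", {
  rec <- make_patients(3, age = c(54, 55, 56))
  idx <- select_subcohort(rec, 55)
  expect_equal(idx, c(2L, 3L), ignore_attr = TRUE)
  expect_equal(length(select_subcohort(rec, 20)), 3)
  expect_error(select_subcohort(rec, 100), "empty")
})

test_that("cut-off scanning recovers a planted step at 55", {
  set.seed(905)
  age <- sample(35:85, 117, replace = TRUE) # ages recorded in whole years
  hits <- vapply(1:100, function(s) {
    set.seed(900 + s)
    ci <- 0.6 + 0.2 * (age >= 55) + rnorm(117, sd = 0.08)
    scan_age_cutoff(ci, age)$cutoff
  }, 0)
  expect_gte(mean(hits == 55), 0.90)
})
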