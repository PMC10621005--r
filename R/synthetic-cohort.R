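# Synthetic cohort generator.
#
# Emulates the data structure of a two-cohort mass-cytometry CAD study:
# a ~117-patient discovery and ~58-patient validation cohort, CAD
# prevalence near 68%, ages ~ Normal(61, 12) truncated to [30, 95],
# 82 subset proportions nested in 11 major populations, per-subset
# CAD effects on the logit scale, age/sex confounding of the CAD label,
# and an additive logit-scale batch shift in the validation cohort.
#
# Proportions follow a logit-normal model: for subset k,
#   z_k ~ Normal(mu_k + delta_k * CAD + gamma_k * (age - age_mean)/10
#                + batch_shift * is_validation, sigma_k^2)
#   p_k = 100 * plogis(z_k)
# which respects the [0, 100] bounds and makes planted effects tractable.

logit <- stats::qlogis
invlogit <- stats::plogis

# Convert a (mean %, SD %) pair on the percent scale to logit-scale
# (mu, sigma) by the delta method: sd_p ~= sigma * p * (1 - p).
logit_params <- function(mean_pct, sd_pct) {
  p <- mean_pct / 100
  c(mu = logit(p), sigma = (sd_pct / 100) / (p * (1 - p)))
}

# The 18 headline subsets with their CAD-/CAD+ group means and SDs (percent)
# as reported for the discovery cohort: 5 conventional CD4 T-cell subsets,
# 7 Treg subsets, 3 CD8 subsets, plasmacytoid DCs and 2 B-cell subsets.
headline_subset_table <- function() {
  tab <- rbind(
    # subset_id,            label,                       population,   m0,   s0,   m1,   s1
    c("tconv_naive",        "Tconv naive",               "CD4 Tconv", 45.4, 15.4, 37.9, 14.0),
    c("tconv_tem",          "Tconv TEM",                 "CD4 Tconv", 24.7, 11.6, 31.7, 12.9),
    c("tconv_ccr2",         "Tconv CCR2+",               "CD4 Tconv", 20.8,  8.7, 24.2,  9.5),
    c("tconv_ccr4",         "Tconv CCR4+",               "CD4 Tconv", 24.2,  8.6, 28.4,  8.7),
    c("tconv_klrg1_cd27n",  "Tconv KLRG1+CD27-",         "CD4 Tconv",  7.3,  7.4, 13.4, 13.0),
    c("treg_ccr2",          "Treg CCR2+",                "Treg",      14.7,  5.9, 17.9,  5.3),
    c("treg_ccr4",          "Treg CCR4+",                "Treg",      64.1, 14.1, 73.7,  9.2),
    c("treg_ccr6",          "Treg CCR6+",                "Treg",      10.1,  5.7, 13.1,  6.8),
    c("treg_cd38_cd45ro",   "Treg CD38+CD45RO+",         "Treg",       9.7,  3.6, 11.5,  4.3),
    c("treg_cd39",          "Treg CD39+",                "Treg",      43.2, 21.6, 53.8, 20.5),
    c("treg_hladr",         "Treg HLA-DR+",              "Treg",      12.3,  6.7, 15.1,  7.1),
    c("treg_ki67",          "Treg Ki67+",                "Treg",       7.0,  2.9,  9.2,  4.2),
    c("cd8_naive",          "CD8 naive",                 "CD8 T",     21.1, 14.2, 13.7, 10.7),
    c("cd8_cd56",           "CD8 CD56+",                 "CD8 T",      8.8,  7.6, 12.7,  8.9),
    c("cd8_klrg1_cd27n",    "CD8 KLRG1+CD27-",           "CD8 T",     30.2, 16.4, 38.7, 20.5),
    c("pdc_total",          "pDC",                       "pDC",        2.8,  2.1,  2.0,  1.3),
    c("b_cxcr3",            "B CXCR3+",                  "B cells",    4.0,  3.1,  5.5,  4.0),
    c("b_ki67",             "B Ki67+",                   "B cells",    0.5,  0.3,  0.8,  0.7)
  )
  data.frame(subset_id = tab[, 1], label = tab[, 2], major_population = tab[, 3],
             m0 = as.numeric(tab[, 4]), s0 = as.numeric(tab[, 5]),
             m1 = as.numeric(tab[, 6]), s1 = as.numeric(tab[, 7]),
             stringsAsFactors = FALSE)
}

#' Default per-subset generative parameters (82 subsets, 11 populations)
#'
#' Builds the default subset parameter table: the 11 major populations
#' measured as a percentage of total live cells, the 18 headline subsets
#' whose group means and SDs are taken from the discovery-cohort results
#' (logit-scale baseline and CAD shift back-solved by the delta method),
#' and null filler subsets with population-typical baselines bringing the
#' total to 82. Differentiated/memory subsets carry positive age trends and
#' naive subsets negative ones, creating the age confounding that the
#' adjusted models must remove.
#'
#' @return A data.frame with columns subset_id, label, major_population,
#'   denominator, mu, sigma, delta, gamma (logit scale; gamma per decade).
#' @export
default_subset_params <- function() {
  majors <- major_populations()
  # %total means for the 11 major populations (typical PBMC composition, %)
  major_mean <- c(28, 4, 18, 10, 9, 2.5, 3, 14, 3, 1.5, 2.8)
  major_sd <- pmax(major_mean * 0.35, 0.4)
  head_tab <- headline_subset_table()

  rows <- list()
  for (i in seq_along(majors)) {
    mp <- logit_params(major_mean[i], major_sd[i])
    is_pdc <- majors[i] == "pDC"
    hl <- if (is_pdc) head_tab[head_tab$subset_id == "pdc_total", ] else NULL
    if (is_pdc) {
      # the pDC major population itself is a headline feature (%total)
      mp <- logit_params(hl$m0, hl$s0)
      delta <- logit(hl$m1 / 100) - logit(hl$m0 / 100)
    } else {
      delta <- 0
    }
    rows[[length(rows) + 1]] <- data.frame(
      subset_id = paste0("maj_", gsub("[^a-z0-9]+", "_", tolower(majors[i]))),
      label = majors[i], major_population = majors[i],
      denominator = "total_live",
      mu = unname(mp["mu"]), sigma = unname(mp["sigma"]),
      delta = delta, gamma = if (is_pdc) -0.05 else 0,
      stringsAsFactors = FALSE)
  }

  for (j in seq_len(nrow(head_tab))) {
    h <- head_tab[j, ]
    if (h$subset_id == "pdc_total") next # already placed as a major row
    mp <- logit_params(h$m0, h$s0)
    delta <- logit(h$m1 / 100) - logit(h$m0 / 100)
    naive <- grepl("naive", h$subset_id)
    rows[[length(rows) + 1]] <- data.frame(
      subset_id = h$subset_id, label = h$label,
      major_population = h$major_population, denominator = "parent_population",
      mu = unname(mp["mu"]), sigma = unname(mp["sigma"]),
      delta = delta, gamma = if (naive) -0.15 else 0.10,
      stringsAsFactors = FALSE)
  }

  # null fillers to reach 82 subsets; deterministic baselines spread over
  # plausible marker-positivity ranges, mild age trends on a third of them
  filler_counts <- c("CD4 Tconv" = 10, "Treg" = 6, "CD8 T" = 10,
                     "B cells" = 8, "NK cells" = 7, "NKT cells" = 3,
                     "gd T cells" = 2, "Classical monocytes" = 3,
                     "Non-classical monocytes" = 3, "mDC" = 2)
  k <- 0
  for (pop in names(filler_counts)) {
    for (i in seq_len(filler_counts[[pop]])) {
      k <- k + 1
      mean_pct <- 1.5 + ((k * 17) %% 53) * 0.8   # 1.5% .. ~43%
      sd_pct <- pmax(mean_pct * 0.45, 0.25)
      mp <- logit_params(mean_pct, sd_pct)
      rows[[length(rows) + 1]] <- data.frame(
        subset_id = sprintf("%s_s%02d", gsub("[^a-z0-9]+", "_", tolower(pop)), i),
        label = sprintf("%s subset %d", pop, i), major_population = pop,
        denominator = "parent_population",
        mu = unname(mp["mu"]), sigma = unname(mp["sigma"]),
        delta = 0, gamma = if (k %% 3 == 0) 0.05 else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 82)
  out
}

#' Identifiers of the 18 headline subsets
#'
#' The 15 T-cell subsets plus plasmacytoid DCs and the 2 B-cell subsets
#' that carry planted CAD effects in the default configuration — the
#' synthetic analogue of a study's significant signature populations.
#'
#' @return Character vector of 18 subset ids.
#' @export
headline_subsets <- function() {
  ids <- headline_subset_table()$subset_id
  ids[ids == "pdc_total"] <- "maj_pdc"
  ids
}

#' Catalog view of a subset parameter table
#' @param params Subset parameter data.frame (see [default_subset_params()]).
#' @return A subset catalog data.frame.
#' @export
params_to_catalog <- function(params) {
  validate_catalog(params[, c("subset_id", "label", "major_population",
                              "denominator")])
}

#' Simulation configuration
#'
#' Defaults mirror the study the package emulates: a discovery cohort of
#' 117 and validation cohort of 58 patients, age ~ Normal(61, 12) truncated
#' to [30, 95], 49% male, CAD prevalence 68% driven by age and sex
#' (slopes back-solved from the reported CAD+/CAD- contrasts of
#' 64 +/- 10 vs 53 +/- 13 years and 59% vs 34% male), and a logit-scale
#' batch shift of 0.25 applied to every subset in the validation cohort.
#'
#' @param n_discovery,n_validation Cohort sizes (>= 10 each; validation may
#'   be 0 to simulate a single-cohort study).
#' @param age_mean,age_sd,age_bounds Truncated-normal age model (years).
#' @param p_male Probability of male sex.
#' @param subsets Per-subset parameter table with columns subset_id, label,
#'   major_population, denominator, mu, sigma, delta, gamma.
#' @param beta_age Log-odds of CAD per decade of age.
#' @param beta_sex Log-odds shift for male sex.
#' @param prevalence Target marginal CAD prevalence; the label-model
#'   intercept is solved from it by quadrature over the age/sex model.
#' @param batch_shift Additive logit-scale shift applied to all subsets in
#'   the validation cohort (emulates a between-experiment batch effect).
#' @param effect_age_knot Optional age (years). When set, the per-subset
#'   CAD shifts `delta` apply only to patients at or above this age,
#'   planting a classifiability step: the immune signature is informative
#'   only in the older sub-cohort.
#' @param seed Integer seed for this configuration.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_discovery = 117L, n_validation = 58L,
                       age_mean = 61, age_sd = 12, age_bounds = c(30, 95),
                       p_male = 0.49,
                       subsets = default_subset_params(),
                       beta_age = 0.86, beta_sex = 1.03,
                       prevalence = 0.68,
                       batch_shift = 0.25,
                       effect_age_knot = NULL,
                       seed = 1L) {
  stopifnot(n_discovery >= 10, n_validation == 0 || n_validation >= 10,
            age_sd > 0, p_male > 0, p_male < 1,
            prevalence > 0, prevalence < 1)
  if (any(subsets$sigma <= 0)) {
    stop("sim_config: all subset sigma values must be positive", call. = FALSE)
  }
  cfg <- list(
    n_discovery = as.integer(n_discovery),
    n_validation = as.integer(n_validation),
    age_mean = age_mean, age_sd = age_sd, age_bounds = age_bounds,
    p_male = p_male, subsets = subsets,
    beta_age = beta_age, beta_sex = beta_sex,
    prevalence = prevalence, batch_shift = batch_shift,
    effect_age_knot = effect_age_knot,
    seed = as.integer(seed)
  )
  cfg$beta0 <- solve_label_intercept(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Quadrature nodes/weights for the truncated-normal age distribution.
age_quadrature <- function(cfg, n = 201) {
  ages <- seq(cfg$age_bounds[1], cfg$age_bounds[2], length.out = n)
  w <- stats::dnorm(ages, cfg$age_mean, cfg$age_sd)
  list(ages = ages, w = w / sum(w))
}

# Solve the label-model intercept so the marginal CAD prevalence over the
# age/sex distribution equals the target.
solve_label_intercept <- function(cfg) {
  aq <- age_quadrature(cfg)
  marg <- function(b0) {
    lin <- b0 + cfg$beta_age * (aq$ages - cfg$age_mean) / 10
    p <- (1 - cfg$p_male) * invlogit(lin) +
      cfg$p_male * invlogit(lin + cfg$beta_sex)
    sum(aq$w * p) - cfg$prevalence
  }
  stats::uniroot(marg, c(-20, 20), tol = 1e-10)$root
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd),
                    stats::pnorm(upper, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Age-dependent risk factor / medication prevalence models: target marginal
# prevalence near the discovery-cohort margins, log-odds slope per decade.
risk_factor_models <- function() {
  data.frame(
    field = c("hypertension", "diabetes", "hyperlipidaemia", "current_smoking",
              "smoking_history_gt10py", "family_history", "statin", "ace_arb",
              "antiplatelet", "beta_blocker"),
    prev = c(0.43, 0.07, 0.53, 0.11, 0.20, 0.28, 0.33, 0.35, 0.20, 0.16),
    slope = c(0.5, 0.3, 0.4, -0.3, 0.2, 0.0, 0.6, 0.5, 0.4, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic two-cohort study
#'
#' Draws patient demographics, risk factors, CAD labels and subset
#' proportions from the generative model described in [sim_config()].
#' The CAD label is drawn conditional on age and sex; subset shifts are
#' applied conditional on the label, producing the confounding structure
#' that age/sex-adjusted models must undo. Major-population percent-of-total
#' values are proportionally rescaled when a draw would exceed a 100% sum.
#' Gensini scores are log-normal with median 7.5 in CAD+ patients and
#' exactly 0 in CAD- patients, so derived CAD status matches the label.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"synthetic_cohort"` with elements `records`
#'   (validated patient table), `proportions` (validated matrix),
#'   `catalog`, and `truth` (the config, for recomputing planted effects).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(cfg$seed, "generate_cohort"))

  n <- cfg$n_discovery + cfg$n_validation
  cohort <- rep(c("discovery", "validation"),
                c(cfg$n_discovery, cfg$n_validation))
  age <- rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                    cfg$age_bounds[1], cfg$age_bounds[2])
  male <- stats::runif(n) < cfg$p_male
  lin <- cfg$beta0 + cfg$beta_age * (age - cfg$age_mean) / 10 +
    cfg$beta_sex * male
  cad <- stats::runif(n) < invlogit(lin)

  # risk factors and medications, age-dependent
  rf <- risk_factor_models()
  booleans <- matrix(FALSE, n, nrow(rf), dimnames = list(NULL, rf$field))
  for (i in seq_len(nrow(rf))) {
    b0 <- logit(rf$prev[i])
    p <- invlogit(b0 + rf$slope[i] * (age - cfg$age_mean) / 10)
    booleans[, i] <- stats::runif(n) < p
  }

  gensini <- ifelse(cad, stats::rlnorm(n, log(7.5), 1), 0)
  bmi <- stats::rnorm(n, 27.1, 4.8)

  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = age, sex = ifelse(male, "male", "female"),
    as.data.frame(booleans),
    bmi = bmi, gensini = gensini, cohort = cohort,
    stringsAsFactors = FALSE
  )

  sub <- cfg$subsets
  z <- matrix(stats::rnorm(n * nrow(sub)), n, nrow(sub))
  z <- sweep(z, 2, sub$sigma, `*`)
  cad_active <- if (is.null(cfg$effect_age_knot)) cad
                else cad & age >= cfg$effect_age_knot
  shift <- outer(cad_active, sub$delta) +
    outer((age - cfg$age_mean) / 10, sub$gamma) +
    outer(cohort == "validation", rep(cfg$batch_shift, nrow(sub)))
  z <- z + shift + matrix(sub$mu, n, nrow(sub), byrow = TRUE)
  props <- 100 * invlogit(z)
  colnames(props) <- sub$subset_id
  rownames(props) <- records$patient_id

  # compositional bound on %total major populations
  catalog <- params_to_catalog(sub)
  total_cols <- major_populations_ids(catalog)
  if (length(total_cols) > 1) {
    sums <- rowSums(props[, total_cols, drop = FALSE])
    over <- sums > 100
    if (any(over)) {
      props[over, total_cols] <- props[over, total_cols, drop = FALSE] *
        (100 / sums[over])
    }
  }

  records <- validate_patients(records)
  props <- validate_proportions(props, catalog)
  structure(list(records = records, proportions = props,
                 catalog = catalog, truth = cfg),
            class = "synthetic_cohort")
}

#' Large-sample per-percent odds ratio planted in a subset
#'
#' Computes, by numerical quadrature over the generative distribution, the
#' slope the population logistic regression of CAD status on the subset's
#' percentage (the only covariate) converges to, and returns its
#' exponential: the per-unit-percent odds ratio a large-sample
#' single-predictor fit will estimate. Accounts for the label model and the
#' subset's age trend; the validation batch shift is excluded (the planted
#' OR is a discovery-cohort quantity).
#'
#' @param cfg A [sim_config()].
#' @param subset_id Subset identifier present in `cfg$subsets`.
#' @return The implied odds ratio (numeric scalar).
#' @export
planted_or <- function(cfg, subset_id) {
  stopifnot(inherits(cfg, "sim_config"))
  i <- match(subset_id, cfg$subsets$subset_id)
  if (is.na(i)) stop("unknown subset: ", subset_id, call. = FALSE)
  s <- cfg$subsets[i, ]
  if (s$delta == 0 && s$gamma == 0) return(1)

  # joint quadrature over age x sex x CAD x z
  aq <- age_quadrature(cfg, 101)
  gh <- 41
  zq <- seq(-6, 6, length.out = gh)
  zw <- stats::dnorm(zq); zw <- zw / sum(zw)

  cells <- expand.grid(ai = seq_along(aq$ages), male = c(0, 1), zi = seq_len(gh))
  adec <- (aq$ages[cells$ai] - cfg$age_mean) / 10
  pcad <- invlogit(cfg$beta0 + cfg$beta_age * adec + cfg$beta_sex * cells$male)
  wbase <- aq$w[cells$ai] *
    ifelse(cells$male == 1, cfg$p_male, 1 - cfg$p_male) * zw[cells$zi]

  # per CAD status, subset percent at each node; the CAD shift respects an
  # effect-modification knot when one is configured
  delta_eff <- if (is.null(cfg$effect_age_knot)) s$delta
               else s$delta * (aq$ages[cells$ai] >= cfg$effect_age_knot)
  p0 <- 100 * invlogit(s$mu + s$gamma * adec + s$sigma * zq[cells$zi])
  p1 <- 100 * invlogit(s$mu + delta_eff + s$gamma * adec + s$sigma * zq[cells$zi])
  x <- c(p0, p1)
  y <- rep(c(0, 1), each = nrow(cells))
  w <- c(wbase * (1 - pcad), wbase * pcad)

  # population logistic score equations solved by Newton iterations
  beta <- c(logit(sum(w * y)), 0)
  X <- cbind(1, x)
  for (iter in 1:50) {
    eta <- drop(X %*% beta)
    mu_ <- invlogit(eta)
    score <- drop(crossprod(X, w * (y - mu_)))
    info <- crossprod(X, X * (w * mu_ * (1 - mu_)))
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(score)) < 1e-12) break
  }
  unname(exp(beta[2]))
}

#' Solve the logit shift that plants a target per-percent odds ratio
#'
#' Root-finds the CAD logit shift `delta` for one subset such that
#' [planted_or()] equals the target odds ratio, holding every other
#' configuration parameter fixed.
#'
#' @param cfg A [sim_config()].
#' @param subset_id Subset to modify.
#' @param target_or Desired per-unit-percent odds ratio.
#' @return The configuration with the subset's `delta` replaced.
#' @export
plant_target_or <- function(cfg, subset_id, target_or) {
  stopifnot(target_or > 0)
  i <- match(subset_id, cfg$subsets$subset_id)
  if (is.na(i)) stop("unknown subset: ", subset_id, call. = FALSE)
  f <- function(d) {
    cfg$subsets$delta[i] <- d
    log(planted_or(cfg, subset_id)) - log(target_or)
  }
  d <- stats::uniroot(f, c(-8, 8), tol = 1e-9)$root
  cfg$subsets$delta[i] <- d
  cfg
}
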