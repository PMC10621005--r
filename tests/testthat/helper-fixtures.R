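# Shared fixture builders and independent brute-force oracles.

# minimal valid patient table
make_patients <- function(n = 6, gensini = rep(c(0, 7.5), length.out = n),
                          age = seq(40, 75, length.out = n),
                          cohort = "discovery") {
  df <- data.frame(
    patient_id = sprintf("PT%03d", seq_len(n)),
    age = age,
    sex = rep(c("male", "female"), length.out = n),
    hypertension = rep(c(TRUE, FALSE), length.out = n),
    diabetes = FALSE,
    hyperlipidaemia = rep(c(FALSE, TRUE), length.out = n),
    current_smoking = FALSE,
    smoking_history_gt10py = FALSE,
    family_history = FALSE,
    statin = rep(c(TRUE, FALSE), length.out = n),
    ace_arb = FALSE,
    antiplatelet = FALSE,
    beta_blocker = FALSE,
    bmi = 27,
    gensini = gensini,
    cohort = rep(cohort, length.out = n),
    stringsAsFactors = FALSE
  )
  validate_patients(df)
}

make_catalog <- function(ids, pop = "Treg") {
  validate_catalog(data.frame(
    subset_id = ids, label = ids, major_population = pop,
    denominator = "parent_population", stringsAsFactors = FALSE))
}

# single-subset simulation config: convenient for planted-effect studies
one_subset_config <- function(delta = 0, gamma = 0, mu = qlogis(0.15),
                              sigma = 0.4, n = 2000, beta_age = 0,
                              beta_sex = 0, prevalence = 0.5, seed = 1) {
  sub <- data.frame(subset_id = "s1", label = "Treg test subset",
                    major_population = "Treg",
                    denominator = "parent_population",
                    mu = mu, sigma = sigma, delta = delta, gamma = gamma,
                    stringsAsFactors = FALSE)
  sim_config(n_discovery = n, n_validation = 0, subsets = sub,
             beta_age = beta_age, beta_sex = beta_sex,
             prevalence = prevalence, batch_shift = 0, seed = seed)
}

# Fisher two-sided p by full hypergeometric enumeration over all tables
# with the observed margins (probability-ordering convention).
fisher_enum_p <- function(a, b, c, d, rel_tol = 1e-7) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# O(n^3) brute-force agglomerative clustering, complete linkage, Euclidean.
# Returns merge heights (ascending) and the partition (set of clusters,
# each a sorted index vector) recorded after each merge.
brute_complete_linkage <- function(X) {
  d <- as.matrix(stats::dist(X))
  clusters <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    clusters <- c(clusters[-c(i, j)], list(merged))
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# cophenetic distances implied by the brute-force agglomeration
brute_cophenetic <- function(X) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(X)
  res <- brute_complete_linkage(X)
  coph <- matrix(0, n, n)
  assigned <- matrix(FALSE, n, n)
  clusters <- lapply(seq_len(n), identity)
  for (step in seq_along(res$heights)) {
    part <- res$partitions[[step]]
    for (cl in part) {
      for (i in cl) for (j in cl) {
        if (i != j && !assigned[i, j]) {
          coph[i, j] <- res$heights[step]
          assigned[i, j] <- TRUE
        }
      }
    }
  }
  coph
}
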