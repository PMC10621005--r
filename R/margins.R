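# Reconstruction of a patient-level table from published group margins.
# Group comparisons on 2x2 tables depend only on the per-variable counts,
# so a cohort re-encoded from a characteristics table reproduces its
# categorical p-values exactly.

#' Read a group-margins table
#'
#' A margins table gives, for each categorical variable, the count of
#' trait-positive patients in the CAD- and CAD+ groups, with a `patients`
#' row holding the group sizes. The package ships the margins of a
#' 117-patient discovery cohort as
#' `system.file("extdata", "discovery_margins.csv", package = "cadimmune")`.
#'
#' @param path CSV with columns variable, cad_neg, cad_pos.
#' @return A data.frame of margins.
#' @export
read_margins <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variable", "cad_neg", "cad_pos") %in% names(df)),
            "patients" %in% df$variable)
  df
}

margin_count <- function(margins, variable, group) {
  i <- match(variable, margins$variable)
  if (is.na(i)) stop("margins table lacks variable: ", variable, call. = FALSE)
  margins[[group]][i]
}

# Deterministic age sequences matching a target mean/SD via normal quantiles.
quantile_ages <- function(n, mean, sd) {
  q <- stats::qnorm((seq_len(n) - 0.5) / n, mean, sd)
  pmax(q, 18)
}

#' Re-encode group margins as a patient-level table
#'
#' Builds a synthetic patient table whose per-variable 2x2 tables against
#' CAD status reproduce the margins exactly. Risk factors are packed
#' round-robin among the non-SMuRFless patients of each group (so the
#' derived SMuRFless count matches its margin), medications and other
#' traits fill from the top of each group, ages follow deterministic
#' normal quantile sequences per group, and Gensini scores are 0 (CAD-)
#' or 7.5 (CAD+). Joint distributions between variables are arbitrary:
#' only the margins are meaningful.
#'
#' @param margins Margins data.frame from [read_margins()].
#' @param age_neg,age_pos `c(mean, sd)` of the age quantile sequence per group.
#' @return A validated patient table (cohort tag `"discovery"`).
#' @export
records_from_margins <- function(margins, age_neg = c(53, 13),
                                 age_pos = c(64, 10)) {
  smurf_fields <- c("hypertension", "diabetes", "hyperlipidaemia",
                    "current_smoking", "smoking_history_gt10py")
  other_fields <- c("family_history", "antiplatelet", "statin",
                    "beta_blocker", "ace_arb")
  build_group <- function(group, gensini, age_ms) {
    n <- margin_count(margins, "patients", group)
    s <- margin_count(margins, "smurfless", group)
    flags <- matrix(FALSE, n, length(c(smurf_fields, other_fields)),
                    dimnames = list(NULL, c(smurf_fields, other_fields)))
    # risk factors only among the n - s non-SMuRFless patients (rows s+1..n)
    risky <- (s + 1):n
    total_flags <- sum(vapply(smurf_fields, margin_count, 0,
                              margins = margins, group = group))
    if (total_flags < length(risky)) {
      stop("margins infeasible: fewer risk-factor flags than non-SMuRFless ",
           "patients in ", group, call. = FALSE)
    }
    ptr <- 0
    for (f in smurf_fields) {
      k <- margin_count(margins, f, group)
      if (k > length(risky)) {
        stop("margins infeasible: ", f, " count exceeds non-SMuRFless size",
             call. = FALSE)
      }
      idx <- risky[(ptr + seq_len(k) - 1) %% length(risky) + 1]
      flags[idx, f] <- TRUE
      ptr <- ptr + k
    }
    for (f in other_fields) {
      k <- margin_count(margins, f, group)
      flags[seq_len(k), f] <- TRUE
    }
    n_male <- margin_count(margins, "sex_male", group)
    data.frame(
      patient_id = sprintf("%s%03d", toupper(substr(group, 5, 5)), seq_len(n)),
      age = quantile_ages(n, age_ms[1], age_ms[2]),
      sex = rep(c("male", "female"), c(n_male, n - n_male)),
      as.data.frame(flags), bmi = 27.1, gensini = gensini,
      cohort = "discovery", stringsAsFactors = FALSE)
  }
  out <- rbind(build_group("cad_neg", 0, age_neg),
               build_group("cad_pos", 7.5, age_pos))
  out <- validate_patients(out)
  target_s <- margin_count(margins, "smurfless", "cad_neg") +
    margin_count(margins, "smurfless", "cad_pos")
  stopifnot(sum(smurfless(out)) == target_s)
  out
}
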