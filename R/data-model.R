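# Shared data model: patient metadata tables, subset catalogs and
# patient x subset proportion matrices, plus the analysis configuration
# and the seed-splitting helper every stochastic stage draws from.

PATIENT_BOOL_FIELDS <- c(
  "hypertension", "diabetes", "hyperlipidaemia", "current_smoking",
  "smoking_history_gt10py", "family_history", "statin", "ace_arb",
  "antiplatelet", "beta_blocker"
)

PATIENT_REQUIRED_FIELDS <- c(
  "patient_id", "age", "sex", PATIENT_BOOL_FIELDS, "gensini", "cohort"
)

#' Major immune population names used by the default catalog
#'
#' The closed list of 11 major circulating immune populations that subset
#' definitions must reference. Each is gated as a percentage of total live
#' cells; finer subsets are percentages of their parent population.
#'
#' @return Character vector of length 11.
#' @export
major_populations <- function() {
  c("CD4 Tconv", "Treg", "CD8 T", "B cells", "NK cells",
    "NKT cells", "gd T cells", "Classical monocytes",
    "Non-classical monocytes", "mDC", "pDC")
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. Defaults follow the
#' study design the package emulates: stratified repeated 5-fold
#' cross-validation with 20 repeats, 18 features screened by AUC per fold,
#' an age cut-off of 55 years for the sub-cohort, and significance tiers at
#' 0.1 / 0.05 / 0.01 / 0.001.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param cv_folds Number of cross-validation folds (>= 2).
#' @param cv_repeats Number of cross-validation repeats (>= 1).
#' @param screen_top_m Features retained by per-fold AUC screening.
#' @param age_cutoff Sub-cohort age threshold in years (inclusive).
#' @param alpha_tiers Decreasing significance thresholds for tier glyphs.
#' @param table1_test_rule `"chi2_always"` applies uncorrected chi-squared to
#'   every categorical variable; `"paper_footnote"` routes tables with any
#'   expected cell below 5 to Fisher's exact test.
#' @param fold_change_scale Scale for the concordance correlation:
#'   `"raw"` fold changes or their `"log"`.
#' @param screen_rank_key Ranking key for AUC screening: distance from 0.5
#'   (`"abs"`, so an AUC of 0.2 is as informative as 0.8) or `"raw"` AUC.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(seed = 1L,
                            cv_folds = 5L,
                            cv_repeats = 20L,
                            screen_top_m = 18L,
                            age_cutoff = 55,
                            alpha_tiers = c(0.1, 0.05, 0.01, 0.001),
                            table1_test_rule = c("chi2_always", "paper_footnote"),
                            fold_change_scale = c("raw", "log"),
                            screen_rank_key = c("abs", "raw")) {
  stopifnot(cv_folds >= 2, cv_repeats >= 1, screen_top_m >= 1)
  cfg <- list(
    seed = as.integer(seed),
    cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    screen_top_m = as.integer(screen_top_m),
    age_cutoff = age_cutoff,
    alpha_tiers = sort(alpha_tiers, decreasing = TRUE),
    table1_test_rule = match.arg(table1_test_rule),
    fold_change_scale = match.arg(fold_change_scale),
    screen_rank_key = match.arg(screen_rank_key)
  )
  class(cfg) <- "analysis_config"
  cfg
}

#' Derive a child seed from a master seed and a stage label
#'
#' Every stochastic stage consumes a seed derived deterministically from the
#' master seed and its own label, so stages are reproducible independently
#' of execution order. The derivation is a 31-bit multiplicative string hash.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h) + 1L
}

parse_bool <- function(x, field = "value") {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  map <- c("0" = FALSE, "1" = TRUE, "true" = TRUE, "false" = FALSE,
           "yes" = TRUE, "no" = FALSE)
  out <- unname(map[key])
  if (anyNA(out[!is.na(key)])) {
    bad <- which(is.na(out) & !is.na(key))[1]
    stop(sprintf("field '%s': unrecognised boolean value '%s' (row %d)",
                 field, x[bad], bad), call. = FALSE)
  }
  out
}

parse_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  map <- c(male = "male", m = "male", female = "female", f = "female",
           "1" = "male", "0" = "female")
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("field 'sex': unrecognised value '%s' (row %d)", x[bad], bad),
         call. = FALSE)
  }
  out
}

#' Validate a patient metadata table
#'
#' Checks schema and invariants: all required columns present, ages >= 18
#' (study eligibility), non-negative Gensini scores, recognised sex and
#' cohort codes, parseable booleans. CAD status is never stored: it is
#' derived as Gensini score > 0 (a zero score defines the CAD- group).
#'
#' @param df A data.frame of patient records.
#' @return The validated data.frame with canonical column types.
#' @export
validate_patients <- function(df) {
  missing <- setdiff(PATIENT_REQUIRED_FIELDS, names(df))
  if (length(missing) > 0) {
    stop("patient table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id values in patient table", call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  if (any(is.na(df$age))) stop("non-numeric age values", call. = FALSE)
  if (any(df$age < 18)) {
    stop(sprintf("age below 18 at row %d (eligibility requires age >= 18)",
                 which(df$age < 18)[1]), call. = FALSE)
  }
  df$sex <- parse_sex(df$sex)
  for (f in PATIENT_BOOL_FIELDS) df[[f]] <- parse_bool(df[[f]], f)
  df$gensini <- as.numeric(df$gensini)
  if (any(is.na(df$gensini))) stop("non-numeric gensini values", call. = FALSE)
  if (any(df$gensini < 0)) {
    stop(sprintf("negative Gensini score at row %d", which(df$gensini < 0)[1]),
         call. = FALSE)
  }
  df$cohort <- tolower(trimws(as.character(df$cohort)))
  if (!all(df$cohort %in% c("discovery", "validation"))) {
    stop("cohort must be 'discovery' or 'validation'", call. = FALSE)
  }
  if (!"bmi" %in% names(df)) df$bmi <- NA_real_ else df$bmi <- as.numeric(df$bmi)
  df
}

#' Derived CAD status of patient records
#'
#' @param records Validated patient data.frame.
#' @return Logical vector: `TRUE` where Gensini score > 0 (CAD+).
#' @export
cad_status <- function(records) {
  records$gensini > 0
}

#' SMuRFless indicator
#'
#' A patient is SMuRFless when free of all standard modifiable risk factors:
#' hypertension, diabetes, hyperlipidaemia, and smoking (current or a
#' significant > 10 pack-year history). Family history and medications do
#' not count against SMuRFless status.
#'
#' @param records Validated patient data.frame.
#' @return Logical vector.
#' @export
smurfless <- function(records) {
  !(records$hypertension | records$diabetes | records$hyperlipidaemia |
      records$current_smoking | records$smoking_history_gt10py)
}

#' Read a patient metadata table from delimited text
#'
#' Comma-delimited UTF-8 with a header row naming the patient fields.
#' Booleans accept 0/1, true/false, yes/no (case-insensitive); sex accepts
#' male/female, m/f or 1/0.
#'
#' @param path Path to the CSV file.
#' @return A validated patient data.frame.
#' @export
read_patient_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  validate_patients(df)
}

#' Write a patient metadata table as delimited text
#'
#' Booleans are emitted as 0/1 so a write/read round trip is the identity.
#'
#' @param records Validated patient data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_table <- function(records, path) {
  out <- records
  for (f in PATIENT_BOOL_FIELDS) out[[f]] <- as.integer(out[[f]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a subset catalog
#'
#' The catalog lists each gated subset with a human-readable marker label,
#' its major population (one of the closed list of 11) and its denominator:
#' `total_live` (percentage of total live cells) or `parent_population`.
#'
#' @param path CSV with columns subset_id, label, major_population, denominator.
#' @return A validated catalog data.frame.
#' @export
read_subset_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_catalog(df)
}

#' Validate a subset catalog
#' @param df Catalog data.frame.
#' @return The validated data.frame.
#' @export
validate_catalog <- function(df) {
  need <- c("subset_id", "label", "major_population", "denominator")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$subset_id)) {
    stop("duplicate subset_id in catalog", call. = FALSE)
  }
  if (!all(df$major_population %in% major_populations())) {
    bad <- setdiff(unique(df$major_population), major_populations())
    stop("unknown major population(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$denominator %in% c("total_live", "parent_population"))) {
    stop("denominator must be 'total_live' or 'parent_population'",
         call. = FALSE)
  }
  df
}

#' Validate a proportions matrix against a catalog
#'
#' All values must lie in [0, 100] with no missing entries, and the
#' per-patient sum of the total-live major-population percentages must not
#' exceed 100 (compositional bound).
#'
#' @param mat Numeric matrix, patients in rows (rownames = patient ids),
#'   subsets in columns (colnames = subset ids).
#' @param catalog Subset catalog data.frame.
#' @return The validated matrix, columns ordered as in the catalog.
#' @export
validate_proportions <- function(mat, catalog) {
  if (is.null(colnames(mat)) || is.null(rownames(mat))) {
    stop("proportions matrix needs patient rownames and subset colnames",
         call. = FALSE)
  }
  unknown <- setdiff(colnames(mat), catalog$subset_id)
  if (length(unknown) > 0) {
    stop("unknown subset column(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(catalog$subset_id, colnames(mat))
  if (length(missing) > 0) {
    stop("proportions matrix missing subset(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat <- mat[, catalog$subset_id, drop = FALSE]
  if (anyNA(mat)) {
    stop("proportions matrix contains missing values", call. = FALSE)
  }
  if (any(mat < 0) || any(mat > 100)) {
    bad <- which(mat < 0 | mat > 100, arr.ind = TRUE)[1, ]
    stop(sprintf("proportion out of [0, 100] at patient '%s', subset '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]), call. = FALSE)
  }
  total_cols <- catalog$subset_id[catalog$denominator == "total_live" &
                                    catalog$subset_id %in% major_populations_ids(catalog)]
  if (length(total_cols) > 1) {
    sums <- rowSums(mat[, total_cols, drop = FALSE])
    if (any(sums > 100 + 1e-8)) {
      stop(sprintf("total-live major population percentages sum to %.2f > 100 for patient '%s'",
                   max(sums), rownames(mat)[which.max(sums)]), call. = FALSE)
    }
  }
  mat
}

# subset ids that represent a major population measured as %total
major_populations_ids <- function(catalog) {
  catalog$subset_id[catalog$denominator == "total_live" &
                      catalog$label %in% major_populations()]
}

#' Read a proportions matrix from delimited text
#'
#' First column must be `patient_id`; remaining columns are subset ids
#' matching the catalog. Rows are aligned to `records` by patient id when
#' supplied.
#'
#' @param path CSV path.
#' @param catalog Subset catalog data.frame.
#' @param records Optional validated patient table used to align row order.
#' @return Validated numeric matrix (patients x subsets).
#' @export
read_proportions <- function(path, catalog, records = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(patient_id = "character"))
  if (!"patient_id" %in% names(df)) {
    stop("proportions file is missing the patient_id column", call. = FALSE)
  }
  mat <- as.matrix(df[, setdiff(names(df), "patient_id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df$patient_id
  mat <- validate_proportions(mat, catalog)
  if (!is.null(records)) {
    missing <- setdiff(records$patient_id, rownames(mat))
    if (length(missing) > 0) {
      stop("proportions missing for patient(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    mat <- mat[records$patient_id, , drop = FALSE]
  }
  mat
}

#' Write a proportions matrix as delimited text
#' @param mat Proportions matrix with patient rownames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(mat, path) {
  df <- data.frame(patient_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a subset catalog as delimited text
#' @param catalog Catalog data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subset_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
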