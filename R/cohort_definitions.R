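#' Assign diabetes status labels by the cohort rules
#'
#' Classifies every subject into exactly one of
#' `CONTROL`, `T2D`, `SAID`, `EXCLUDED_PREDIABETES`, `EXCLUDED_GESTATIONAL`,
#' `EXCLUDED_INCOMPLETE`.
#'
#' Evaluation order:
#' 1. `EXCLUDED_INCOMPLETE` if any required field is missing
#'    (`hba1c`, `random_glucose`, or any of the five self-report flags);
#' 2. `EXCLUDED_GESTATIONAL` if `flag_gestational` (applies regardless of any
#'    other criterion);
#' 3. diabetes if any of: physician diagnosis flag, diabetes-medication flag,
#'    HbA1c > 6.5%, random glucose > 200 mg/dL (strict inequalities, as
#'    printed); within diabetes, `SAID` if self-reported type 1 diabetes or
#'    (C-peptide < 0.5 nmol/L and on insulin treatment), otherwise `T2D`;
#' 4. among non-diabetics, `EXCLUDED_PREDIABETES` if 5.7 <= HbA1c <= 6.4;
#' 5. `CONTROL` only if all four control conditions hold: no physician
#'    diagnosis, no diabetes medication, HbA1c < 5.7% and glucose < 200 mg/dL.
#'
#' A missing `c_peptide` never triggers `EXCLUDED_INCOMPLETE`: the C-peptide
#' arm of the SAID rule simply evaluates to false.
#'
#' @param subjects Data frame with at least columns `hba1c` (percent),
#'   `random_glucose` (mg/dL), `c_peptide` (nmol/L, may be `NA`), and logical
#'   flags `flag_physician_diagnosis`, `flag_diabetes_medication`,
#'   `flag_insulin_treatment`, `flag_self_report_t1d`, `flag_gestational`.
#' @return Factor of status labels, one per row, levels in a fixed order.
#' @export
classify_status <- function(subjects) {
  req_flags <- c("flag_physician_diagnosis", "flag_diabetes_medication",
                 "flag_insulin_treatment", "flag_self_report_t1d",
                 "flag_gestational")
  req <- c("hba1c", "random_glucose", req_flags)
  missing_cols <- setdiff(req, names(subjects))
  if (length(missing_cols) > 0) {
    stop("subjects table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(subjects)
  incomplete <- Reduce(`|`, lapply(subjects[req], is.na), rep(FALSE, n))

  hba1c <- subjects$hba1c
  glu <- subjects$random_glucose
  cpep <- if ("c_peptide" %in% names(subjects)) subjects$c_peptide else rep(NA_real_, n)

  diabetes <- subjects$flag_physician_diagnosis |
    subjects$flag_diabetes_medication |
    (hba1c > 6.5) | (glu > 200)
  said <- subjects$flag_self_report_t1d |
    (!is.na(cpep) & cpep < 0.5 & subjects$flag_insulin_treatment)
  prediab <- hba1c >= 5.7 & hba1c <= 6.4
  control <- !subjects$flag_physician_diagnosis &
    !subjects$flag_diabetes_medication & (hba1c < 5.7) & (glu < 200)

  lab <- rep("EXCLUDED_INCOMPLETE", n)
  done <- incomplete
  gest <- !done & subjects$flag_gestational
  lab[gest] <- "EXCLUDED_GESTATIONAL"; done <- done | gest
  d <- !done & diabetes
  lab[d & said] <- "SAID"
  lab[d & !said] <- "T2D"
  done <- done | d
  p <- !done & prediab
  lab[p] <- "EXCLUDED_PREDIABETES"; done <- done | p
  c0 <- !done & control
  lab[c0] <- "CONTROL"; done <- done | c0
  # Non-diabetic, non-prediabetic rows failing a control rule (e.g. glucose
  # exactly at a boundary with HbA1c < 5.7) cannot occur under the rule set:
  # any such residual is labelled incomplete-for-analysis.
  lab[!done] <- "EXCLUDED_INCOMPLETE"
  factor(lab, levels = status_levels())
}

#' Status label levels
#' @return Character vector of the six possible status labels.
#' @export
status_levels <- function() {
  c("CONTROL", "T2D", "SAID", "EXCLUDED_PREDIABETES",
    "EXCLUDED_GESTATIONAL", "EXCLUDED_INCOMPLETE")
}

#' HOMA2 indices from glucose and C-peptide
#'
#' Computes beta-cell function (HOMA2-B, percent) and insulin resistance
#' (HOMA2-IR, dimensionless) from fasting glucose (mmol/L) and C-peptide
#' (nmol/L) via a pluggable estimator. The default estimator
#' [homa2_approximation()] is a documented monotone parametric approximation of
#' the homeostasis model, calibrated so that the reference input
#' (glucose 5.0 mmol/L, C-peptide 0.55 nmol/L) maps to exactly (100%, 1.0).
#' Externally computed indices can be injected by supplying a custom
#' `estimator`; downstream clustering never depends on the estimator's
#' absolute calibration.
#'
#' Inputs outside the estimator's declared valid range (glucose 3.5-25 mmol/L,
#' C-peptide 0.2-3.5 nmol/L, mirroring the ranges accepted by standard HOMA2
#' software) are clamped to the range and flagged in the result.
#'
#' @param glucose Numeric vector, mmol/L (convert mg/dL by dividing by
#'   18.016). Must be positive.
#' @param c_peptide Numeric vector, nmol/L. Must be positive.
#' @param estimator Function `(glucose, c_peptide) -> list(homa2_b, homa2_ir)`.
#' @return Data frame with columns `homa2_b`, `homa2_ir`, `clamped` (logical).
#' @export
compute_homa2 <- function(glucose, c_peptide, estimator = homa2_approximation) {
  if (any(!is.finite(glucose)) || any(!is.finite(c_peptide))) {
    stop("glucose and c_peptide must be finite")
  }
  if (any(glucose <= 0) || any(c_peptide <= 0)) {
    stop("glucose and c_peptide must be positive")
  }
  g <- pmin(pmax(glucose, 3.5), 25)
  cp <- pmin(pmax(c_peptide, 0.2), 3.5)
  clamped <- (g != glucose) | (cp != c_peptide)
  est <- estimator(g, cp)
  data.frame(homa2_b = est$homa2_b, homa2_ir = est$homa2_ir, clamped = clamped)
}

#' Default parametric HOMA2 approximation
#'
#' A monotone closed-form stand-in for the homeostasis model assessment
#' computer model:
#' \deqn{HOMA2B = 100 \cdot \frac{c}{0.55} \cdot \frac{5 - 2.5}{g - 2.5},
#'       \qquad HOMA2IR = \frac{g \cdot c}{5 \cdot 0.55}}
#' with glucose \eqn{g} in mmol/L and C-peptide \eqn{c} in nmol/L. HOMA2-B is
#' increasing in C-peptide and decreasing in glucose; HOMA2-IR is increasing
#' in both, matching the qualitative behavior of the homeostasis model. The
#' reference input (5.0, 0.55) maps to (100%, 1.0).
#'
#' @param glucose Numeric, mmol/L (assumed already range-clamped).
#' @param c_peptide Numeric, nmol/L.
#' @return List with `homa2_b` and `homa2_ir`.
#' @export
homa2_approximation <- function(glucose, c_peptide) {
  list(homa2_b = 100 * (c_peptide / 0.55) * (5 - 2.5) / (glucose - 2.5),
       homa2_ir = (glucose * c_peptide) / (5 * 0.55))
}

#' Stratified training/testing split
#'
#' Splits subjects into disjoint, exhaustive training and testing sets,
#' stratified on a status column so prevalence matches across splits within
#' one subject per stratum. Deterministic given `seed`.
#'
#' @param subjects Data frame with a `subject_id` column.
#' @param fraction Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @param strata Optional vector (length `nrow(subjects)`) to stratify on;
#'   defaults to the `status` column if present, else a single stratum.
#' @return List with character vectors `training` and `testing` of subject ids.
#' @export
split_cohort <- function(subjects, fraction = 0.5, seed = 1L, strata = NULL) {
  if (nrow(subjects) == 0) stop("empty subject table")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)")
  }
  if (is.null(strata)) {
    strata <- if ("status" %in% names(subjects)) subjects$status else rep(1L, nrow(subjects))
  }
  ids <- as.character(subjects$subject_id)
  set.seed(seed)
  train <- character(0)
  for (s in unique(strata)) {
    sids <- ids[strata == s]
    n_tr <- round(length(sids) * fraction)
    train <- c(train, sample(sids, n_tr))
  }
  list(training = sort(train), testing = sort(setdiff(ids, train)))
}
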