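# Physical-unit affine map for the five clustering variables. Magnitudes are
# loosely patterned on the demographics of a Middle-Eastern diabetes cohort
# (means/SDs of the diabetes group); they are preset constants of the
# generator, not estimates from any real data set.
CLINICAL_AFFINE <- data.frame(
  variable = c("age_at_diagnosis", "bmi", "hba1c", "homa2_b", "homa2_ir"),
  mean = c(45, 32, 7.5, 75, 2.5),
  sd = c(9, 6, 1.5, 30, 1.0)
)

# Standardized-space center pattern of the SAID (autoimmune) group: young,
# lean, very poor glycemic control, severely insulin deficient.
SAID_CENTER <- c(age_at_diagnosis = -1.0, bmi = -0.8, hba1c = 2.5,
                 homa2_b = -2.0, homa2_ir = -0.5)

#' Default subtype centers in standardized units
#'
#' A 4 x 5 matrix (rows SIDD, SIRD, MOD, MARD; columns the five clustering
#' variables) whose sign pattern follows the canonical subtype phenotypes:
#' SIDD has high HbA1c and low HOMA2-B, SIRD high HOMA2-IR and high BMI, MOD
#' high BMI at young age of onset, and MARD the highest age at onset with
#' near-zero values elsewhere.
#'
#' @return Numeric matrix with dimnames.
#' @export
default_subtype_centers <- function() {
  m <- rbind(
    SIDD = c(-0.5, -0.7,  2.0, -1.2, -0.3),
    SIRD = c( 0.3,  0.8, -0.3,  0.6,  2.2),
    MOD  = c(-1.2,  1.2, -0.2,  0.5, -0.2),
    MARD = c( 1.0, -0.3, -0.3,  0.0, -0.4)
  )
  colnames(m) <- CLUSTER_VARS
  m
}

#' Default per-drug, per-group medication usage probabilities
#'
#' Rows are active molecules from the packaged toy ATC dictionary, columns the
#' six subject groups (`CONTROL`, the four T2D subtypes, `SAID`). Diabetes
#' drugs are frequent in cases and rare in controls; a few drugs are planted
#' with subtype-differential usage (insulin and sulfonylureas in SIDD,
#' losartan in SIRD, lisinopril and esomeprazole in MOD, perindopril in MARD).
#'
#' @return Numeric matrix of Bernoulli probabilities.
#' @export
default_med_usage_probs <- function() {
  groups <- c("CONTROL", SUBTYPES, "SAID")
  p <- rbind(
    metformin     = c(0.02, 0.75, 0.60, 0.60, 0.55, 0.30),
    `insulin human` = c(0.00, 0.50, 0.20, 0.15, 0.10, 0.90),
    glibenclamide = c(0.01, 0.30, 0.10, 0.12, 0.10, 0.02),
    sitagliptin   = c(0.01, 0.25, 0.10, 0.10, 0.08, 0.02),
    pioglitazone  = c(0.00, 0.12, 0.05, 0.04, 0.03, 0.01),
    losartan      = c(0.05, 0.12, 0.35, 0.12, 0.12, 0.05),
    lisinopril    = c(0.05, 0.10, 0.12, 0.30, 0.10, 0.05),
    perindopril   = c(0.04, 0.08, 0.08, 0.08, 0.20, 0.04),
    esomeprazole  = c(0.08, 0.10, 0.10, 0.25, 0.10, 0.08),
    atorvastatin  = c(0.08, 0.40, 0.40, 0.40, 0.40, 0.20),
    aspirin       = c(0.10, 0.30, 0.30, 0.30, 0.30, 0.15),
    bisoprolol    = c(0.03, 0.15, 0.15, 0.15, 0.15, 0.05),
    paracetamol   = c(0.25, 0.30, 0.30, 0.30, 0.30, 0.25),
    ibuprofen     = c(0.15, 0.15, 0.15, 0.15, 0.15, 0.15)
  )
  colnames(p) <- groups
  p
}

#' Simulation parameters for the synthetic cohort generator
#'
#' Bundles and validates all knobs of the synthetic-data module. The default
#' preset emulates the statistical structure the subtyping analysis assumes:
#' four Gaussian subtype clusters in standardized 5-variable space with the
#' canonical center sign patterns, subtype fractions patterned on the reported
#' cluster sizes (SIRD smallest at 4%), an autoimmune (SAID) sliver of
#' 109/1160 of diabetes rows, log-normal omics baselines with disjoint planted
#' subtype-specific shifts, case-control shifts, missing-at-random omics
#' entries, and group-differential medication usage.
#'
#' @param n_cases Number of diabetes rows (T2D + SAID).
#' @param n_controls Number of control rows.
#' @param subtype_fractions Four proportions (SIDD, SIRD, MOD, MARD) summing
#'   to 1.
#' @param subtype_centers 4 x 5 matrix of standardized cluster centers.
#' @param within_cluster_sd Positive within-cluster standard deviation per
#'   clustering variable (standardized units), length 1 or 5.
#' @param n_proteins,n_metabolites Number of omics features per platform.
#' @param n_specific_per_subtype Planted subtype-specific features per subtype
#'   and platform (disjoint across subtypes).
#' @param n_case_control_features Features shifted in all diabetes cases.
#' @param effect_size Planted subtype-specific shift on the log scale, in
#'   units of the feature's log-SD (Cohen's d).
#' @param case_control_effect Planted case-control shift (same units).
#' @param missing_rate Missing-at-random proportion in `[0, 1)`.
#' @param said_fraction Fraction of diabetes rows that are SAID.
#' @param med_usage_probs Drug x group probability matrix, see
#'   [default_med_usage_probs()].
#' @param seed Integer master seed.
#' @return Object of class `simulation_params` (a validated list).
#' @export
simulation_params <- function(n_cases = 1000L,
                              n_controls = 1735L,
                              subtype_fractions = c(SIDD = 0.25, SIRD = 0.04,
                                                    MOD = 0.24, MARD = 0.47),
                              subtype_centers = default_subtype_centers(),
                              within_cluster_sd = 0.3,
                              n_proteins = 1305L,
                              n_metabolites = 1159L,
                              n_specific_per_subtype = 5L,
                              n_case_control_features = 50L,
                              effect_size = 2,
                              case_control_effect = 0.5,
                              missing_rate = 0.05,
                              said_fraction = 109 / 1160,
                              med_usage_probs = default_med_usage_probs(),
                              seed = 1L) {
  counts <- c(n_cases = n_cases, n_controls = n_controls,
              n_proteins = n_proteins, n_metabolites = n_metabolites,
              n_specific_per_subtype = n_specific_per_subtype,
              n_case_control_features = n_case_control_features)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all counts must be finite and >= 0")
  }
  if (!is.null(names(subtype_fractions)) && setequal(names(subtype_fractions), SUBTYPES)) {
    subtype_fractions <- subtype_fractions[SUBTYPES]
  }
  if (length(subtype_fractions) != 4 ||
      abs(sum(subtype_fractions) - 1) > 1e-9 || any(subtype_fractions < 0)) {
    stop("subtype_fractions must be 4 non-negative proportions summing to 1")
  }
  if (!is.matrix(subtype_centers) || !all(dim(subtype_centers) == c(4, 5)) ||
      any(!is.finite(subtype_centers))) {
    stop("subtype_centers must be a finite 4 x 5 matrix")
  }
  if (length(within_cluster_sd) == 1) within_cluster_sd <- rep(within_cluster_sd, 5)
  if (length(within_cluster_sd) != 5 || any(within_cluster_sd <= 0) ||
      any(!is.finite(within_cluster_sd))) {
    stop("within_cluster_sd must be positive, length 1 or 5")
  }
  if (!is.finite(effect_size) || !is.finite(case_control_effect)) {
    stop("effect sizes must be finite")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (said_fraction < 0 || said_fraction >= 1) stop("said_fraction must be in [0, 1)")
  if (any(med_usage_probs < 0) || any(med_usage_probs > 1)) {
    stop("med_usage_probs must be probabilities in [0, 1]")
  }
  rownames(subtype_centers) <- SUBTYPES
  colnames(subtype_centers) <- CLUSTER_VARS
  out <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              subtype_fractions = subtype_fractions,
              subtype_centers = subtype_centers,
              within_cluster_sd = within_cluster_sd,
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              n_specific_per_subtype = as.integer(n_specific_per_subtype),
              n_case_control_features = as.integer(n_case_control_features),
              effect_size = effect_size,
              case_control_effect = case_control_effect,
              missing_rate = missing_rate,
              said_fraction = said_fraction,
              med_usage_probs = med_usage_probs,
              seed = as.integer(seed))
  class(out) <- "simulation_params"
  out
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("simulation_params:", x$n_cases, "cases /", x$n_controls, "controls;",
      x$n_proteins, "proteins,", x$n_metabolites, "metabolites; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic clinical cohort with ground truth
#'
#' Draws diabetes cases from the four-subtype Gaussian mixture in standardized
#' 5-variable space, maps them to physical units by the documented affine
#' transform, adds an autoimmune (SAID) sliver satisfying the SAID rule
#' (C-peptide < 0.5 nmol/L on insulin treatment), and draws controls that
#' satisfy all four control rules (no diagnosis, no diabetes medication,
#' HbA1c < 5.7%, glucose < 200 mg/dL). HOMA2-B / HOMA2-IR are emitted directly
#' so downstream stages do not depend on any HOMA2 estimator's calibration.
#'
#' @param params A [simulation_params()] object.
#' @return List with `subjects` (one row per subject) and `truth`
#'   (class `synthetic_truth`: group and subtype per subject, the affine
#'   constants, and the subtype centers used).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)

  n_said <- as.integer(round(params$n_cases * params$said_fraction))
  n_t2d <- params$n_cases - n_said
  n_total <- params$n_cases + params$n_controls
  ids <- sprintf("S%05d", seq_len(n_total))
  id_t2d <- head(ids, n_t2d)
  id_said <- ids[seq_len(n_said) + n_t2d]
  id_ctrl <- ids[seq_len(params$n_controls) + params$n_cases]

  draw_std <- function(center, n) {
    m <- matrix(rnorm(n * 5), n, 5)
    m <- sweep(m, 2, params$within_cluster_sd, `*`)
    sweep(m, 2, center, `+`)
  }
  to_physical <- function(z) {
    x <- sweep(z, 2, CLINICAL_AFFINE$sd, `*`)
    x <- sweep(x, 2, CLINICAL_AFFINE$mean, `+`)
    colnames(x) <- CLUSTER_VARS
    x
  }

  # --- T2D cases ---
  subtype <- if (n_t2d > 0) {
    sample(SUBTYPES, n_t2d, replace = TRUE, prob = params$subtype_fractions)
  } else character(0)
  z <- matrix(numeric(0), 0, 5)
  if (n_t2d > 0) {
    z <- matrix(NA_real_, n_t2d, 5)
    for (s in SUBTYPES) {
      idx <- which(subtype == s)
      if (length(idx)) z[idx, ] <- draw_std(params$subtype_centers[s, ], length(idx))
    }
  }
  x_t2d <- to_physical(z)

  make_case_rows <- function(id, x, said) {
    n <- length(id)
    if (n == 0) return(NULL)
    tsd <- rgamma(n, shape = 2, scale = 3)                 # time since diagnosis, years
    cpep <- if (said) runif(n, 0.05, 0.45) else pmax(rlnorm(n, log(1.0), 0.35), 0.5)
    insulin_flag <- if (said) rep(TRUE, n) else runif(n) < 0.24
    data.frame(
      subject_id = id,
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.42, 0.58)),
      age = x[, "age_at_diagnosis"] + tsd,
      age_at_diagnosis = x[, "age_at_diagnosis"],
      time_since_diagnosis = tsd,
      bmi = x[, "bmi"],
      hba1c = x[, "hba1c"],
      random_glucose = pmax(rnorm(n, 160, 50), 80),
      c_peptide = cpep,
      insulin = cpep * 120 * exp(rnorm(n, 0, 0.2)),
      fasting_minutes = round(rgamma(n, shape = 4, scale = 120)),
      homa2_b = x[, "homa2_b"],
      homa2_ir = x[, "homa2_ir"],
      flag_physician_diagnosis = TRUE,
      flag_diabetes_medication = runif(n) < 0.7,
      flag_insulin_treatment = insulin_flag,
      flag_self_report_t1d = if (said) runif(n) < 0.5 else FALSE,
      flag_gestational = FALSE,
      flag_hypertension_medication = runif(n) < 0.35,
      stringsAsFactors = FALSE
    )
  }
  t2d_rows <- make_case_rows(id_t2d, x_t2d, said = FALSE)
  x_said <- to_physical(draw_std(SAID_CENTER, n_said))
  said_rows <- make_case_rows(id_said, x_said, said = TRUE)

  # --- Controls (satisfy all four control rules by construction) ---
  nc <- params$n_controls
  ctrl_rows <- NULL
  if (nc > 0) {
    cpep_c <- rlnorm(nc, log(0.8), 0.3)
    hba1c_c <- pmin(rnorm(nc, 5.2, 0.25), 5.65)
    ctrl_rows <- data.frame(
      subject_id = id_ctrl,
      sex = sample(c("male", "female"), nc, replace = TRUE, prob = c(0.345, 0.655)),
      age = pmax(rnorm(nc, 35, 10), 18),
      age_at_diagnosis = NA_real_,
      time_since_diagnosis = 0,
      bmi = pmax(rnorm(nc, 28.2, 5.8), 15),
      hba1c = hba1c_c,
      random_glucose = pmin(pmax(rnorm(nc, 90.2, 10.3), 60), 199),
      c_peptide = cpep_c,
      insulin = cpep_c * 110 * exp(rnorm(nc, 0, 0.2)),
      fasting_minutes = round(rgamma(nc, shape = 4, scale = 110)),
      homa2_b = rnorm(nc, 105, 20),
      homa2_ir = pmax(rnorm(nc, 1.2, 0.5), 0.1),
      flag_physician_diagnosis = FALSE,
      flag_diabetes_medication = FALSE,
      flag_insulin_treatment = FALSE,
      flag_self_report_t1d = FALSE,
      flag_gestational = FALSE,
      flag_hypertension_medication = runif(nc) < 0.1,
      stringsAsFactors = FALSE
    )
  }

  subjects <- do.call(rbind, Filter(Negate(is.null),
                                    list(t2d_rows, said_rows, ctrl_rows)))
  rownames(subjects) <- NULL

  truth <- list(
    group = setNames(c(rep("T2D", n_t2d), rep("SAID", n_said),
                       rep("CONTROL", nc)),
                     c(id_t2d, id_said, id_ctrl)),
    subtype = setNames(subtype, id_t2d),
    clinical_affine = CLINICAL_AFFINE,
    subtype_centers = params$subtype_centers,
    features = NULL,
    drugs = NULL
  )
  class(truth) <- "synthetic_truth"
  list(subjects = subjects, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$group), "subjects (",
      sum(x$group == "T2D"), "T2D,", sum(x$group == "SAID"), "SAID,",
      sum(x$group == "CONTROL"), "controls )\n")
  if (!is.null(x$features)) {
    cat("  planted features:", sum(!is.na(x$features$target_subtype)),
        "subtype-specific,", sum(x$features$case_control), "case-control\n")
  }
  invisible(x)
}

#' Generate a synthetic omics matrix with planted effects
#'
#' Positive relative abundances with a log-normal baseline per feature
#' (per-feature log-mean, unit log-SD). Planted subtype-specific features are
#' shifted by `effect_size` log-SD units in their target subtype only, with
#' alternating sign; planted case-control features are shifted by
#' `case_control_effect` in all diabetes cases (T2D and SAID). Entries are
#' masked missing-at-random at `missing_rate`. Technical covariates (cell
#' lysis proxy, collection week, fasting minutes, tube number) are emitted
#' alongside as independent draws.
#'
#' @param truth A `synthetic_truth` from [generate_cohort()]; updated feature
#'   truth is recorded in the returned object's `truth` element.
#' @param params The same [simulation_params()].
#' @param platform `"protein"` or `"metabolite"`.
#' @return List with `omics` (class `omics_matrix`: `values` samples x
#'   features, `platform`, `covariates`) and the updated `truth`.
#' @export
generate_omics <- function(truth, params, platform = c("protein", "metabolite")) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "simulation_params"))
  platform <- match.arg(platform)
  n_feat <- if (platform == "protein") params$n_proteins else params$n_metabolites
  prefix <- if (platform == "protein") "PROT" else "MET"
  set.seed(params$seed + if (platform == "protein") 101L else 202L)

  ids <- names(truth$group)
  n <- length(ids)
  feat <- sprintf("%s_%04d", prefix, seq_len(n_feat))

  # planted structure: first 4 * n_specific features are subtype-specific
  # (disjoint blocks), the following n_case_control_features are case-control.
  n_spec <- params$n_specific_per_subtype
  target <- rep(NA_character_, n_feat)
  shift <- rep(0, n_feat)
  if (4 * n_spec > 0 && n_feat >= 4 * n_spec) {
    for (i in seq_along(SUBTYPES)) {
      idx <- ((i - 1) * n_spec + 1):(i * n_spec)
      target[idx] <- SUBTYPES[i]
      shift[idx] <- params$effect_size * rep_len(c(1, -1), n_spec)
    }
  }
  cc <- rep(FALSE, n_feat)
  cc_from <- 4 * n_spec + 1
  cc_to <- min(4 * n_spec + params$n_case_control_features, n_feat)
  if (params$n_case_control_features > 0 && cc_from <= cc_to) {
    cc[cc_from:cc_to] <- TRUE
  }

  mu <- rnorm(n_feat, mean = 2, sd = 0.5)
  logx <- matrix(rnorm(n * n_feat), n, n_feat)
  logx <- sweep(logx, 2, mu, `+`)

  is_case <- truth$group %in% c("T2D", "SAID")
  if (any(cc)) {
    logx[is_case, cc] <- logx[is_case, cc] +
      matrix(params$case_control_effect, sum(is_case), sum(cc))
  }
  for (j in which(!is.na(target))) {
    in_target <- !is.na(truth$subtype[ids]) & truth$subtype[ids] == target[j]
    logx[in_target, j] <- logx[in_target, j] + shift[j]
  }

  values <- exp(logx)
  dimnames(values) <- list(ids, feat)
  if (params$missing_rate > 0) {
    values[matrix(runif(n * n_feat) < params$missing_rate, n, n_feat)] <- NA
  }

  covariates <- data.frame(
    subject_id = ids,
    lysis_proxy = rnorm(n),
    collection_week = sample(1:52, n, replace = TRUE),
    fasting_minutes = round(rgamma(n, shape = 4, scale = 120)),
    tube_number = factor(sample(1:8, n, replace = TRUE)),
    stringsAsFactors = FALSE
  )

  feature_truth <- data.frame(feature = feat, platform = platform,
                              target_subtype = target, shift = shift,
                              case_control = cc, stringsAsFactors = FALSE)
  truth$features <- rbind(truth$features, feature_truth)

  omics <- structure(list(values = values, platform = platform,
                          covariates = covariates),
                     class = "omics_matrix")
  list(omics = omics, truth = truth)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("omics_matrix (", x$platform, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " features; ",
      round(100 * mean(is.na(x$values)), 1), "% missing\n", sep = "")
  invisible(x)
}

#' Generate free-text medication entries by group-specific usage
#'
#' Per subject, each drug in `params$med_usage_probs` is used with the
#' probability of the subject's group (control, T2D subtype, or SAID); a used
#' drug contributes one free-text entry built from a dictionary synonym with
#' randomized case, punctuation, and occasional dosage suffix.
#'
#' @param truth A `synthetic_truth` (with subtype assignments).
#' @param params The [simulation_params()].
#' @param dictionary Synonym dictionary, defaults to [atc_dictionary()].
#' @return List with `entries` (data frame `subject_id`, `entry`) and the
#'   updated `truth` (drug usage probabilities recorded).
#' @export
generate_medications <- function(truth, params, dictionary = atc_dictionary()) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(params, "simulation_params"))
  probs <- params$med_usage_probs
  if (any(probs < 0 | probs > 1)) stop("usage probabilities must be in [0, 1]")
  set.seed(params$seed + 303L)

  ids <- names(truth$group)
  grp <- ifelse(truth$group == "T2D", truth$subtype[ids], truth$group)
  grp[truth$group == "CONTROL"] <- "CONTROL"
  missing_groups <- setdiff(unique(grp), colnames(probs))
  if (length(missing_groups)) {
    stop("med_usage_probs lacks columns for groups: ",
         paste(missing_groups, collapse = ", "))
  }

  scramble <- function(mol) {
    syns <- dictionary$synonym[dictionary$molecule == mol]
    s <- if (length(syns)) sample(syns, 1) else mol
    style <- sample(1:4, 1)
    s <- switch(style,
                s,
                toupper(s),
                paste0(toupper(substring(s, 1, 1)), substring(s, 2)),
                paste0(s, "."))
    if (runif(1) < 0.3) s <- paste0(s, " ", sample(c("500mg", "10 mg", "850 mg", "5mg"), 1))
    s
  }

  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    p <- probs[, grp[i]]
    used <- rownames(probs)[runif(length(p)) < p]
    if (length(used)) {
      out[[i]] <- data.frame(subject_id = ids[i],
                             entry = vapply(used, scramble, character(1)),
                             stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(entries)) {
    entries <- data.frame(subject_id = character(0), entry = character(0))
  }
  rownames(entries) <- NULL
  truth$drugs <- probs
  list(entries = entries, truth = truth)
}
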