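PIPELINE_DEFAULTS <- list(
  seed = 1L,
  alpha = 0.05,
  k = 4L,
  k_range = c(2L, 15L),
  n_restarts = 100L,
  n_stability_reruns = 500L,
  fasting_reference_minutes = 480,
  training_fraction = 0.5,
  select_k_enabled = TRUE,
  synthetic = list(n_cases = 1000L, n_controls = 1735L,
                   n_proteins = 1305L, n_metabolites = 1159L),
  out_dir = NULL
)

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills documented defaults, and checks
#' every constraint, returning the complete list of violations rather than
#' failing on the first.
#'
#' @param config Path to a YAML file or a named list.
#' @return List with `config` (validated, defaults filled; `NULL` when
#'   invalid) and `errors` (character vector, empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      return(list(config = NULL, errors = paste("config file not found:", config)))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    return(list(config = NULL, errors = "config must be a YAML mapping / named list"))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, config)
  errors <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)

  chk(is.numeric(cfg$alpha) && length(cfg$alpha) == 1 &&
        cfg$alpha > 0 && cfg$alpha < 1, "alpha: must be in (0, 1)")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "seed: must be a single integer")
  chk(is.numeric(cfg$k) && cfg$k >= 2, "k: must be >= 2")
  chk(is.numeric(cfg$k_range) && length(cfg$k_range) == 2 &&
        cfg$k_range[1] >= 2 && cfg$k_range[2] <= 15 &&
        cfg$k_range[1] <= cfg$k_range[2],
      "k_range: must be two values within [2, 15]")
  chk(is.numeric(cfg$n_restarts) && cfg$n_restarts >= 1, "n_restarts: must be >= 1")
  chk(is.numeric(cfg$n_stability_reruns) && cfg$n_stability_reruns >= 1,
      "n_stability_reruns: must be >= 1")
  chk(is.numeric(cfg$fasting_reference_minutes) && cfg$fasting_reference_minutes >= 0,
      "fasting_reference_minutes: must be >= 0")
  chk(is.numeric(cfg$training_fraction) && cfg$training_fraction > 0 &&
        cfg$training_fraction < 1, "training_fraction: must be in (0, 1)")
  for (p in c("subjects_path", "proteins_path", "metabolites_path", "medications_path")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      errors <- c(errors, paste0(p, ": file does not exist: ", cfg[[p]]))
    }
  }
  if (length(errors)) return(list(config = NULL, errors = errors))
  cfg$seed <- as.integer(cfg$seed)
  list(config = cfg, errors = character(0))
}

# per-stage child seeds derived deterministically from the master seed
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 0L, split = 11L, fit = 23L, select_k = 37L,
               stability = 53L, sensitivity = 71L, omics = 89L,
               signatures = 107L, medications = 131L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full subtyping pipeline on a synthetic cohort
#'
#' Executes every stage end to end: cohort synthesis, status classification,
#' stratified train/test split, subtype-model fitting on the training T2D
#' cases (with optional cluster-count voting and bootstrap stability),
#' nearest-centroid assignment of the testing cases, sensitivity analyses
#' (fasting-state correction, sex-specific re-clustering), case-control
#' omics association on both platforms, two-criteria subtype signatures, and
#' medication enrichment. All stage outputs are written as TSV/JSON under
#' `config$out_dir` (when set) and a machine-readable summary is returned.
#'
#' @param config A validated configuration from [validate_config()] (the
#'   `config` element), or a list/path accepted by it.
#' @return List `summary` with per-stage counts plus `results` holding the
#'   main in-memory objects.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) || is.null(config$seed)) {
    v <- validate_config(config)
    if (length(v$errors)) stop("invalid config:\n", paste(v$errors, collapse = "\n"))
    config <- v$config
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(x, name) {
    if (!is.null(out_dir)) write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
  }
  log_lines <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  # --- stage: synthesize / load ---
  syn_args <- config$synthetic[intersect(names(config$synthetic),
                                         names(formals(simulation_params)))]
  syn_args$seed <- stage_seed(config$seed, "cohort")
  params <- do.call(simulation_params, syn_args)
  note("stage cohort: synthesizing ", params$n_cases, " cases / ",
       params$n_controls, " controls (seed ", params$seed, ")")
  coh <- generate_cohort(params)
  subjects <- coh$subjects
  truth <- coh$truth

  # --- stage: classify ---
  subjects$status <- as.character(classify_status(subjects))
  emit(subjects, "subjects")

  # --- stage: split ---
  sp <- split_cohort(subjects, fraction = config$training_fraction,
                     seed = stage_seed(config$seed, "split"))
  train_t2d <- subjects[subjects$subject_id %in% sp$training &
                          subjects$status == "T2D", ]
  test_t2d <- subjects[subjects$subject_id %in% sp$testing &
                         subjects$status == "T2D", ]
  note("stage split: ", length(sp$training), " training / ",
       length(sp$testing), " testing (",
       nrow(train_t2d), "/", nrow(test_t2d), " T2D)")

  # --- stage: cluster ---
  std <- standardize(train_t2d)
  kvote <- NULL
  if (isTRUE(config$select_k_enabled)) {
    kvote <- select_k(std$X, k_range = config$k_range[1]:config$k_range[2],
                      seed = stage_seed(config$seed, "select_k"))
    note("stage select_k: chosen k = ", kvote$k, " (votes: ",
         paste(names(kvote$votes), kvote$votes, sep = "=", collapse = ", "), ")")
  }
  model <- fit_cluster_model(std$X, k = config$k, restarts = config$n_restarts,
                             seed = stage_seed(config$seed, "fit"),
                             standardization = std$params)
  if (!is.null(out_dir)) write_cluster_model(model, file.path(out_dir, "cluster_model.json"))
  stab <- jaccard_stability(std$X, model,
                            n_reruns = config$n_stability_reruns,
                            seed = stage_seed(config$seed, "stability"))
  note("stage stability: per-cluster Jaccard ",
       paste(names(stab$per_cluster), round(stab$per_cluster, 3),
             sep = "=", collapse = ", "))

  X_test <- apply_standardization(test_t2d, std$params)
  assign_test <- assign_by_centers(X_test, model)
  emit(assign_test, "assignments_testing")

  # --- stage: sensitivity ---
  sens_seed <- stage_seed(config$seed, "sensitivity")
  corrected <- correct_for_fasting(test_t2d, config$fasting_reference_minutes)
  assign_corr <- assign_by_centers(apply_standardization(corrected, std$params), model)
  fasting_agreement <- compare_partitions(
    setNames(assign_test$subtype, assign_test$subject_id),
    setNames(assign_corr$subtype, assign_corr$subject_id))$agreement

  sex_agreement <- NA_real_
  sex_parts <- list()
  for (sx in c("male", "female")) {
    rows <- test_t2d$sex == sx
    if (sum(rows) > 8) {
      std_s <- standardize(test_t2d[rows, ])
      m_s <- fit_cluster_model(std_s$X, k = config$k, restarts = config$n_restarts,
                               seed = sens_seed, standardization = std_s$params)
      a_s <- assign_by_centers(std_s$X, m_s)
      sex_parts[[sx]] <- setNames(a_s$subtype, a_s$subject_id)
    }
  }
  if (length(sex_parts)) {
    joint <- unlist(unname(sex_parts))
    pooled <- setNames(assign_test$subtype, assign_test$subject_id)[names(joint)]
    sex_agreement <- compare_partitions(pooled, joint)$agreement
  }
  note("stage sensitivity: fasting-corrected agreement ",
       round(fasting_agreement, 1), "%, sex-specific agreement ",
       round(sex_agreement, 1), "%")

  # --- stage: omics case-control ---
  omx_p <- generate_omics(truth, params, "protein")
  truth <- omx_p$truth
  omx_m <- generate_omics(truth, params, "metabolite")
  truth <- omx_m$truth
  test_ids <- intersect(sp$testing, names(truth$group))
  prep_p <- preprocess_features(omx_p$omics)
  prep_m <- preprocess_features(omx_m$omics)

  cc_ids <- subjects$subject_id[subjects$status %in% c("CONTROL", "T2D")]
  covar <- data.frame(age = subjects$age, sex = subjects$sex,
                      bmi = subjects$bmi, row.names = subjects$subject_id)
  tech <- omx_p$omics$covariates[, c("lysis_proxy", "collection_week",
                                     "fasting_minutes", "tube_number")]
  rownames(tech) <- omx_p$omics$covariates$subject_id
  status_by_id <- setNames(subjects$status, subjects$subject_id)

  assoc_p <- associate_case_control(
    prep_p$omics$values[cc_ids, , drop = FALSE], status_by_id[cc_ids],
    covariates = cbind(covar[cc_ids, c("age", "sex")], tech[cc_ids, ]),
    model = "logistic")
  assoc_m <- associate_case_control(
    prep_m$omics$values[cc_ids, , drop = FALSE], status_by_id[cc_ids],
    covariates = cbind(covar[cc_ids, c("age", "sex", "bmi")], tech[cc_ids, ]),
    model = "linear")
  emit(assoc_p, "association_proteins")
  emit(assoc_m, "association_metabolites")
  thr_p <- bonferroni_threshold(config$alpha, nrow(assoc_p))
  thr_m <- bonferroni_threshold(config$alpha, nrow(assoc_m))
  n_sig_p <- sum(assoc_p$p < thr_p, na.rm = TRUE)
  n_sig_m <- sum(assoc_m$p < thr_m, na.rm = TRUE)
  note("stage omics: ", n_sig_p, " proteins and ", n_sig_m,
       " metabolites associated at the Bonferroni level")

  # --- stage: subtype signatures (testing-set T2D cases) ---
  sig_ids <- intersect(assign_test$subject_id, rownames(prep_p$omics$values))
  assign_named <- setNames(assign_test$subtype, assign_test$subject_id)[sig_ids]
  sig_p <- cluster_specific_features(prep_p$omics$values[sig_ids, , drop = FALSE],
                                     assign_named, alpha = config$alpha)
  sig_m <- cluster_specific_features(prep_m$omics$values[sig_ids, , drop = FALSE],
                                     assign_named, alpha = config$alpha)
  emit(sig_p, "signatures_proteins")
  emit(sig_m, "signatures_metabolites")
  note("stage signatures: ", sum(sig_p$specific), " protein and ",
       sum(sig_m$specific), " metabolite subtype-specific records")

  # --- stage: medications ---
  med <- generate_medications(truth, params)
  truth <- med$truth
  annot <- annotate_medications(med$entries)
  grp_cc <- status_by_id[cc_ids]
  scan_cc <- enrichment_scan(annot, grp_cc, level = "atc2")
  grp_cl <- assign_named
  scan_cl <- enrichment_scan(annot, grp_cl, level = "molecule")
  emit(scan_cc, "enrichment_case_control")
  emit(scan_cl, "enrichment_clusters")
  note("stage medications: ", nrow(scan_cc), " case-control and ",
       nrow(scan_cl), " cluster enrichment records")

  summary <- list(
    n_subjects = nrow(subjects),
    status_counts = as.list(table(subjects$status)),
    k_selected = if (is.null(kvote)) NA else kvote$k,
    k_votes = if (is.null(kvote)) NULL else as.list(kvote$votes),
    cluster_sizes = as.list(table(assign_test$subtype)),
    jaccard = as.list(round(stab$per_cluster, 4)),
    fasting_agreement = fasting_agreement,
    sex_agreement = sex_agreement,
    n_significant_proteins = n_sig_p,
    n_significant_metabolites = n_sig_m,
    n_specific_protein_records = sum(sig_p$specific),
    n_specific_metabolite_records = sum(sig_m$specific),
    n_enrichment_case_control = nrow(scan_cc),
    n_enrichment_clusters = nrow(scan_cl),
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(list(summary = summary,
                 results = list(model = model, stability = stab,
                                assignments = assign_test, k_vote = kvote,
                                association_proteins = assoc_p,
                                association_metabolites = assoc_m,
                                signatures_proteins = sig_p,
                                signatures_metabolites = sig_m,
                                enrichment_case_control = scan_cc,
                                enrichment_clusters = scan_cl,
                                truth = truth)))
}
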