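#' Clusterwise bootstrap Jaccard stability
#'
#' For each of `n_reruns` bootstrap re-runs, rows are resampled with
#' replacement and k-means is refit; each original cluster is scored by its
#' maximum Jaccard similarity over the new clusters, where
#' `Jaccard(A, B) = |A intersect B| / |A union B|` over subject-id sets
#' restricted to the (unique) resampled ids. Per-cluster means over re-runs
#' are reported; values above roughly 0.75 are conventionally read as stable
#' clusters.
#'
#' @param X_std Standardized matrix with subject-id rownames.
#' @param model The fitted `cluster_model`.
#' @param n_reruns Number of bootstrap re-runs (>= 1).
#' @param seed Integer seed.
#' @param restarts k-means restarts per re-run.
#' @return Object of class `stability_result`: `per_cluster` (named mean
#'   Jaccard per original cluster), `n_reruns`, `scheme`.
#' @export
jaccard_stability <- function(X_std, model, n_reruns = 500L, seed = 1L,
                              restarts = 10L) {
  if (n_reruns < 1) stop("n_reruns must be >= 1")
  orig <- assign_by_centers(X_std, model)$cluster
  n <- nrow(X_std)
  k <- model$k
  set.seed(seed)
  sums <- numeric(k)
  for (r in seq_len(n_reruns)) {
    idx <- sample.int(n, n, replace = TRUE)
    uniq <- unique(idx)
    km <- kmeans(X_std[idx, , drop = FALSE], centers = k,
                 nstart = restarts, iter.max = 100L)
    # new cluster membership of each unique resampled row (first occurrence)
    new_cl <- km$cluster[match(uniq, idx)]
    for (ci in seq_len(k)) {
      a <- uniq[orig[uniq] == ci]
      if (length(a) == 0) { sums[ci] <- sums[ci] + 0; next }
      best <- 0
      for (cj in seq_len(k)) {
        b <- uniq[new_cl == cj]
        j <- length(intersect(a, b)) / length(union(a, b))
        if (j > best) best <- j
      }
      sums[ci] <- sums[ci] + best
    }
  }
  per_cluster <- sums / n_reruns
  names(per_cluster) <- if (!is.null(model$label_map)) model$label_map else as.character(seq_len(k))
  structure(list(per_cluster = per_cluster, n_reruns = as.integer(n_reruns),
                 scheme = "bootstrap"),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("clusterwise bootstrap Jaccard stability (", x$n_reruns, " re-runs):\n", sep = "")
  print(round(x$per_cluster, 3))
  invisible(x)
}

#' Correct HOMA2 indices for fasting state
#'
#' Regresses each HOMA2 variable on self-reported fasting minutes (linear
#' model over the supplied rows, typically the T2D cases) and replaces it by
#' its residual plus the model prediction at `reference_minutes`, i.e. the
#' value expected had every subject fasted the reference duration (default
#' 480 minutes, the 8-hour convention).
#'
#' @param subjects Data frame with `homa2_b`, `homa2_ir`, `fasting_minutes`.
#' @param reference_minutes Reference fasting duration in minutes.
#' @return The data frame with corrected `homa2_b` / `homa2_ir` columns. If
#'   `fasting_minutes` is constant the regression is undefined and the data
#'   are passed through with a warning.
#' @export
correct_for_fasting <- function(subjects, reference_minutes = 480) {
  if (!"fasting_minutes" %in% names(subjects)) stop("fasting_minutes column required")
  if (sd(subjects$fasting_minutes) == 0) {
    warning("fasting_minutes is constant; returning data unchanged")
    return(subjects)
  }
  for (v in c("homa2_b", "homa2_ir")) {
    fit <- lm(subjects[[v]] ~ subjects$fasting_minutes)
    pred_ref <- coef(fit)[1] + coef(fit)[2] * reference_minutes
    subjects[[v]] <- residuals(fit) + pred_ref
  }
  subjects
}

#' Classify subjects with externally derived cluster centers
#'
#' Standardizes the subjects with the supplied (receiving-cohort)
#' standardization parameters, picks the center set matching each subject's
#' sex when sex-specific centers are given, and assigns each subject to the
#' nearest center by Euclidean distance.
#'
#' @param subjects Data frame with the clustering variables, `subject_id`,
#'   and `sex` (required when `centers_by_sex` has sex-specific entries).
#' @param centers_by_sex Either a single k x 5 matrix (sex-pooled; rownames
#'   are used as cluster labels) or a named list with elements `male` and
#'   `female`.
#' @param standardization Standardization parameters from [standardize()].
#' @return Assignment data frame as from [assign_by_centers()], with a
#'   `subtype` column taken from the center rownames when present.
#' @export
transfer_centers <- function(subjects, centers_by_sex, standardization) {
  X <- apply_standardization(subjects, standardization)
  as_model <- function(centers) {
    structure(list(feature_names = CLUSTER_VARS,
                   centers = centers[, CLUSTER_VARS, drop = FALSE],
                   k = nrow(centers),
                   label_map = rownames(centers),
                   standardization = standardization,
                   fit_meta = list()),
              class = "cluster_model")
  }
  if (is.matrix(centers_by_sex)) {
    return(assign_by_centers(X, as_model(centers_by_sex)))
  }
  if (!all(c("male", "female") %in% names(centers_by_sex))) {
    stop("centers_by_sex must be a matrix or a list with 'male' and 'female'")
  }
  if (!"sex" %in% names(subjects) || anyNA(subjects$sex)) {
    stop("sex column required for sex-specific centers")
  }
  parts <- lapply(c("male", "female"), function(sx) {
    rows <- subjects$sex == sx
    if (!any(rows)) return(NULL)
    assign_by_centers(X[rows, , drop = FALSE], as_model(centers_by_sex[[sx]]))
  })
  out <- do.call(rbind, Filter(Negate(is.null), parts))
  out[match(as.character(subjects$subject_id), out$subject_id), , drop = FALSE]
}

#' Compare two partitions of the same subjects
#'
#' Reports the percent agreement maximized over one-to-one relabelings of the
#' second partition, and the adjusted Rand index computed from the
#' contingency table.
#'
#' @param a,b Cluster assignments: named vectors (names = subject ids) or
#'   plain vectors of equal length in the same order.
#' @return List: `agreement` (percent, 0-100), `ari`, `matching` (label of
#'   `b` matched to each label of `a`), `table` (contingency).
#' @export
compare_partitions <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stop("subject ids differ between partitions")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stop("partitions must cover the same subjects")
  }
  tab <- table(a = as.character(a), b = as.character(b))
  la <- rownames(tab); lb <- colnames(tab)
  # pad to square so one-to-one matching is defined
  k <- max(length(la), length(lb))
  M <- matrix(0, k, k)
  M[seq_along(la), seq_along(lb)] <- tab
  best <- -Inf; best_perm <- NULL
  for (p in permutations_of(k)) {
    s <- sum(M[cbind(seq_len(k), p)])
    if (s > best) { best <- s; best_perm <- p }
  }
  agreement <- 100 * best / length(a)
  matching <- setNames(rep(NA_character_, length(la)), la)
  for (i in seq_along(la)) {
    j <- best_perm[i]
    if (j <= length(lb)) matching[i] <- lb[j]
  }
  list(agreement = agreement, ari = adjusted_rand_index(tab),
       matching = matching, table = tab)
}

#' Adjusted Rand index from a contingency table
#'
#' Chance-corrected agreement between two partitions; 1 for identical
#' partitions (up to relabeling), approximately 0 for independent ones.
#'
#' @param tab Contingency table of two partitions.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(tab) {
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Confounder association and corrected re-clustering
#'
#' Tests each candidate confounder against cluster membership (chi-square for
#' categorical, one-way ANOVA for continuous), residualizes the five
#' clustering variables on the significant confounders, re-standardizes and
#' re-clusters, and reports (i) the per-confounder association p-values,
#' (ii) the assignment agreement between original and corrected clusterings,
#' and (iii) the ANOVA p-value of each clustering variable across the
#' corrected clusters.
#'
#' @param subjects Data frame of the clustered subjects (T2D cases) holding
#'   the five clustering variables and the confounder columns.
#' @param assignments Cluster assignment vector aligned with `subjects` rows.
#' @param confounders Character vector of confounder column names.
#' @param alpha Significance level for calling a confounder significant.
#' @param k,restarts,seed Passed to the corrected re-fit.
#' @return List: `confounder_p` (named), `significant`, `agreement` (percent),
#'   `ari`, `post_correction_p` (ANOVA p per clustering variable).
#' @export
confounder_sensitivity <- function(subjects, assignments, confounders,
                                   alpha = 0.05, k = 4L, restarts = 100L,
                                   seed = 1L) {
  cl <- factor(assignments)
  conf_p <- setNames(rep(NA_real_, length(confounders)), confounders)
  for (cf in confounders) {
    v <- subjects[[cf]]
    if (is.null(v)) stop("confounder column not found: ", cf)
    if (is.numeric(v)) {
      conf_p[cf] <- anova(aov(v ~ cl))[["Pr(>F)"]][1]
    } else {
      v <- factor(v)
      if (nlevels(v) < 2) stop("confounder with a single level: ", cf)
      conf_p[cf] <- suppressWarnings(chisq.test(table(v, cl))$p.value)
    }
  }
  signif_conf <- names(conf_p)[conf_p < alpha]

  corrected <- subjects
  if (length(signif_conf) > 0) {
    rhs <- paste(signif_conf, collapse = " + ")
    for (v in CLUSTER_VARS) {
      fit <- lm(as.formula(paste(v, "~", rhs)), data = subjects)
      corrected[[v]] <- residuals(fit) + mean(subjects[[v]])
    }
  }
  std <- standardize(corrected)
  model2 <- fit_cluster_model(std$X, k = k, restarts = restarts, seed = seed,
                              standardization = std$params)
  new_cl <- assign_by_centers(std$X, model2)$cluster
  cmp <- compare_partitions(as.integer(cl), new_cl)

  post_p <- setNames(rep(NA_real_, length(CLUSTER_VARS)), CLUSTER_VARS)
  for (v in CLUSTER_VARS) {
    post_p[v] <- anova(aov(corrected[[v]] ~ factor(new_cl)))[["Pr(>F)"]][1]
  }
  list(confounder_p = conf_p, significant = signif_conf,
       agreement = cmp$agreement, ari = cmp$ari, post_correction_p = post_p)
}
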