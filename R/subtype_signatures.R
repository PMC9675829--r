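#' Two-criteria subtype-specific feature selection
#'
#' A feature is declared specific to a subtype cluster iff (1) its mean in
#' that cluster differs from all other clusters combined at the Bonferroni
#' level `alpha / m` (one-vs-rest linear model without covariates), and
#' (2) it differs from every other cluster individually at nominal
#' significance (pairwise linear models, p < 0.05). Only T2D cases enter the
#' tests; the Bonferroni denominator `m` defaults to the number of features
#' on the platform.
#'
#' @param values Processed numeric matrix (T2D cases x features) or an
#'   `omics_matrix` restricted to T2D cases.
#' @param assignments Subtype label per row of `values`.
#' @param alpha Family-wise level for criterion 1 (default 0.05).
#' @param m Bonferroni denominator; defaults to `ncol(values)`.
#' @param pairwise_alpha Nominal level for criterion 2 (default 0.05).
#' @return Data frame with one record per feature x cluster: `feature`,
#'   `cluster`, `p_one_vs_rest`, `p_pair_<cluster>` columns, `mean_<cluster>`
#'   and `se_<cluster>` columns, `direction` (`up`/`down`), `specific`.
#' @export
cluster_specific_features <- function(values, assignments, alpha = 0.05,
                                      m = NULL, pairwise_alpha = 0.05) {
  if (inherits(values, "omics_matrix")) values <- values$values
  assignments <- as.character(assignments)
  if (length(assignments) != nrow(values)) {
    stop("assignments must have one entry per row of values")
  }
  clusters <- intersect(SUBTYPES, unique(assignments))
  if (length(clusters) < 2) stop("need at least two clusters")
  if (is.null(m)) m <- ncol(values)
  thr1 <- bonferroni_threshold(alpha, m)

  small <- names(which(table(assignments)[clusters] < 2))

  feats <- colnames(values)
  rec <- vector("list", length(feats) * length(clusters))
  ri <- 0L
  for (f in feats) {
    x <- values[, f]
    grp_mean <- vapply(clusters, function(cl) mean(x[assignments == cl], na.rm = TRUE),
                       numeric(1))
    grp_se <- vapply(clusters, function(cl) {
      xx <- x[assignments == cl & !is.na(x)]
      if (length(xx) < 2) NA_real_ else sd(xx) / sqrt(length(xx))
    }, numeric(1))
    for (cl in clusters) {
      ri <- ri + 1L
      p_ovr <- NA_real_
      p_pair <- setNames(rep(NA_real_, length(clusters)), clusters)
      if (!(cl %in% small)) {
        cc <- !is.na(x)
        p_ovr <- ovr_lm_p(x[cc], assignments[cc] == cl)
        for (other in setdiff(clusters, cl)) {
          if (other %in% small) next
          rows <- cc & assignments %in% c(cl, other)
          p_pair[other] <- ovr_lm_p(x[rows], assignments[rows] == cl)
        }
      }
      others <- setdiff(clusters, c(cl, small))
      pair_ok <- length(others) > 0 && !any(is.na(p_pair[others])) &&
        all(p_pair[others] < pairwise_alpha)
      specific <- !is.na(p_ovr) && p_ovr < thr1 && pair_ok
      rest_mean <- mean(x[assignments != cl & assignments %in% clusters], na.rm = TRUE)
      row <- data.frame(feature = f, cluster = cl, p_one_vs_rest = p_ovr,
                        direction = ifelse(grp_mean[cl] >= rest_mean, "up", "down"),
                        specific = specific, stringsAsFactors = FALSE)
      for (o in clusters) row[[paste0("p_pair_", o)]] <- unname(p_pair[o])
      for (o in clusters) row[[paste0("mean_", o)]] <- unname(grp_mean[o])
      for (o in clusters) row[[paste0("se_", o)]] <- unname(grp_se[o])
      rec[[ri]] <- row
    }
  }
  out <- do.call(rbind, rec)
  rownames(out) <- NULL
  out
}

# Wald p-value of the group indicator in a one-predictor linear model
# (equivalent to the equal-variance two-sample t-test).
ovr_lm_p <- function(x, in_group) {
  if (length(unique(in_group)) < 2) return(NA_real_)
  sm <- summary(lm(x ~ in_group))$coefficients
  if (nrow(sm) < 2) return(NA_real_)
  sm[2, 4]
}

#' Normalized per-group mean profiles with 95% confidence intervals
#'
#' Per feature and group (the four subtypes plus any display-only groups such
#' as SAID and controls), computes the group mean divided by the reference
#' cluster's mean, with the 95% CI `(mean +/- 1.96 SE) / reference mean`.
#' The reference cluster's normalized mean is exactly 1.
#'
#' @param values Numeric matrix (samples x features), typically raw
#'   abundances.
#' @param groups Group label per row (subtypes, `SAID`, `CONTROL`, ...).
#' @param reference_cluster The normalizing group (nonempty, nonzero mean).
#' @param features Optional subset of feature names.
#' @return Data frame: `feature`, `group`, `n`, `normalized_mean`, `ci_lower`,
#'   `ci_upper`, `reference`.
#' @export
normalized_cluster_profiles <- function(values, groups, reference_cluster,
                                        features = colnames(values)) {
  if (inherits(values, "omics_matrix")) values <- values$values
  groups <- as.character(groups)
  if (!reference_cluster %in% groups) stop("reference cluster is empty")
  glev <- unique(groups)
  out <- list()
  for (f in features) {
    x <- values[, f]
    ref <- mean(x[groups == reference_cluster], na.rm = TRUE)
    if (!is.finite(ref) || ref == 0) stop("reference mean is zero for feature ", f)
    for (g in glev) {
      xx <- x[groups == g & !is.na(x)]
      n <- length(xx)
      mu <- mean(xx)
      se <- if (n > 1) sd(xx) / sqrt(n) else 0
      out[[length(out) + 1L]] <- data.frame(
        feature = f, group = g, n = n,
        normalized_mean = mu / ref,
        ci_lower = (mu - 1.96 * se) / ref,
        ci_upper = (mu + 1.96 * se) / ref,
        reference = reference_cluster, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Variance of omics principal components explained by cluster membership
#'
#' Runs PCA over the (T2D) samples of a processed matrix (missing entries are
#' mean-filled for the decomposition only) and regresses each component's
#' scores on cluster-membership indicators, reporting the per-component R^2.
#'
#' @param values Processed matrix (samples x features) or `omics_matrix`.
#' @param assignments Cluster label per row.
#' @param n_components Number of leading components (must not exceed rank).
#' @return Data frame: `component`, `variance_fraction` (share of total
#'   variance), `r_squared`.
#' @export
pc_variance_explained <- function(values, assignments, n_components = 10L) {
  if (inherits(values, "omics_matrix")) values <- values$values
  if (anyNA(values)) {
    mu <- colMeans(values, na.rm = TRUE)
    idx <- which(is.na(values), arr.ind = TRUE)
    values[idx] <- mu[idx[, 2]]
  }
  pc <- prcomp(values, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$x)) stop("n_components exceeds the rank of the matrix")
  cl <- factor(assignments)
  r2 <- vapply(seq_len(n_components), function(i) {
    summary(lm(pc$x[, i] ~ cl))$r.squared
  }, numeric(1))
  data.frame(component = paste0("PC", seq_len(n_components)),
             variance_fraction = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
             r_squared = r2)
}

#' Correlations between cluster-specific proteins and metabolites
#'
#' Pairwise Pearson correlations over shared (T2D) samples between the
#' selected protein and metabolite signatures, with two-sided p-values from
#' the t distribution on pairwise-complete observations.
#'
#' @param proteins,metabolites Numeric matrices (samples x features) or
#'   `omics_matrix` objects with overlapping sample rownames.
#' @param protein_ids,metabolite_ids Feature subsets (default: all columns).
#' @return Data frame: `protein`, `metabolite`, `r`, `n`, `p`.
#' @export
correlate_signature_features <- function(proteins, metabolites,
                                         protein_ids = NULL,
                                         metabolite_ids = NULL) {
  if (inherits(proteins, "omics_matrix")) proteins <- proteins$values
  if (inherits(metabolites, "omics_matrix")) metabolites <- metabolites$values
  shared <- intersect(rownames(proteins), rownames(metabolites))
  if (length(shared) < 3) stop("fewer than 3 shared samples")
  P <- proteins[shared, protein_ids %||% colnames(proteins), drop = FALSE]
  M <- metabolites[shared, metabolite_ids %||% colnames(metabolites), drop = FALSE]
  r <- cor(P, M, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(P), !is.na(M))
  tstat <- r * sqrt(pmax(n - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(n - 2, 1))
  data.frame(protein = rep(rownames(r), times = ncol(r)),
             metabolite = rep(colnames(r), each = nrow(r)),
             r = as.vector(r), n = as.vector(n), p = as.vector(p),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
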