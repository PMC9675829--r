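#' Preprocess an omics matrix for association analysis
#'
#' Applies the standard preprocessing chain: features with more than 90%
#' missingness are excluded; observed values are natural-log transformed,
#' z-scored per feature over the observed entries, and winsorized by clipping
#' to \[-5, +5\] standard deviations. Missing entries stay missing.
#' Non-positive observed values cannot be log-transformed and are converted
#' to missing with a logged warning.
#'
#' @param omics An `omics_matrix` (see [generate_omics()]) or a bare numeric
#'   samples x features matrix.
#' @param max_missing Exclusion threshold on the per-feature missing fraction
#'   (strictly greater than; default 0.9).
#' @param winsor_sd Clipping bound in SD units (default 5).
#' @return List: `omics` (processed, same class as input), `excluded`
#'   (character vector of dropped features), `log` (data frame of per-feature
#'   actions).
#' @export
preprocess_features <- function(omics, max_missing = 0.9, winsor_sd = 5) {
  values <- if (inherits(omics, "omics_matrix")) omics$values else omics
  log_rows <- list()

  nonpos <- !is.na(values) & values <= 0
  if (any(nonpos)) {
    bad_feats <- colnames(values)[colSums(nonpos) > 0]
    warning(sum(nonpos), " non-positive observed value(s) in ",
            length(bad_feats), " feature(s) treated as missing")
    values[nonpos] <- NA
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      feature = bad_feats, action = "nonpositive_to_missing",
      stringsAsFactors = FALSE)
  }

  miss_frac <- colMeans(is.na(values))
  excluded <- colnames(values)[miss_frac > max_missing]
  if (length(excluded)) {
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      feature = excluded, action = "excluded_missingness",
      stringsAsFactors = FALSE)
    values <- values[, setdiff(colnames(values), excluded), drop = FALSE]
  }

  lv <- log(values)
  mu <- colMeans(lv, na.rm = TRUE)
  sdv <- apply(lv, 2, sd, na.rm = TRUE)
  sdv[sdv == 0 | is.na(sdv)] <- 1   # constant feature: centered to all-zero
  z <- sweep(sweep(lv, 2, mu, `-`), 2, sdv, `/`)
  z[z > winsor_sd] <- winsor_sd
  z[z < -winsor_sd] <- -winsor_sd

  out <- omics
  if (inherits(omics, "omics_matrix")) out$values <- z else out <- z
  list(omics = out, excluded = excluded,
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(feature = character(0), action = character(0)))
}

#' Case-control association of omics features
#'
#' Per feature, on complete cases: for proteins a logistic model
#' `status ~ feature + covariates` (two-sided Wald p on the feature
#' coefficient); for metabolites a linear model
#' `feature ~ status + covariates` (Wald p on the case indicator). Perfect
#' separation in the logistic model is flagged by a non-finite estimate with
#' the p-value set missing.
#'
#' @param omics Processed `omics_matrix` or numeric matrix (samples in rows).
#' @param status Factor/character per sample with levels `CONTROL` and `T2D`
#'   (rows with other values are dropped).
#' @param covariates Optional data frame of covariates aligned with the rows
#'   of `omics` (e.g. age, sex, BMI, technical covariates).
#' @param model `"logistic"` (proteins) or `"linear"` (metabolites).
#' @return Data frame: `feature`, `model`, `beta`, `se`, `p`, `n`.
#' @export
associate_case_control <- function(omics, status,
                                   covariates = NULL,
                                   model = c("logistic", "linear")) {
  model <- match.arg(model)
  values <- if (inherits(omics, "omics_matrix")) omics$values else omics
  status <- as.character(status)
  keep <- status %in% c("CONTROL", "T2D")
  values <- values[keep, , drop = FALSE]
  status <- status[keep]
  if (length(unique(status)) < 2) stop("status has no contrast (constant)")
  y <- as.integer(status == "T2D")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
    if (anyNA(covariates)) stop("covariate columns must be complete for used rows")
  }

  feats <- colnames(values)
  res <- data.frame(feature = feats, model = model, beta = NA_real_,
                    se = NA_real_, p = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(feats)) {
    x <- values[, j]
    cc <- !is.na(x)
    n_used <- sum(cc)
    res$n[j] <- n_used
    if (n_used < 3 || length(unique(y[cc])) < 2) next
    dat <- data.frame(y = y[cc], x = x[cc])
    if (!is.null(covariates)) dat <- cbind(dat, covariates[cc, , drop = FALSE])
    if (model == "logistic") {
      sep <- FALSE
      fit <- withCallingHandlers(
        glm(y ~ ., data = dat, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
            sep <<- TRUE
          }
          invokeRestart("muffleWarning")
        })
      sm <- summary(fit)$coefficients
      if (sep || !"x" %in% rownames(sm)) {
        res$beta[j] <- if ("x" %in% rownames(sm)) sign(sm["x", 1]) * Inf else NA_real_
        res$p[j] <- NA_real_
      } else {
        res$beta[j] <- sm["x", 1]
        res$se[j] <- sm["x", 2]
        res$p[j] <- sm["x", 4]
      }
    } else {
      fit <- lm(x ~ ., data = dat)
      sm <- summary(fit)$coefficients
      if ("y" %in% rownames(sm)) {
        res$beta[j] <- sm["y", 1]
        res$se[j] <- sm["y", 2]
        res$p[j] <- sm["y", 4]
      }
    }
  }
  res
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Replication and directional concordance of association results
#'
#' Restricts to features significant in the primary analysis at the primary
#' Bonferroni level (`alpha` / number of primary features) that are also
#' present in the replication set; among those, counts features replicating
#' at `alpha / n_shared` and features whose effect signs agree.
#'
#' @param primary,replication Association tables from
#'   [associate_case_control()] (columns `feature`, `beta`, `p`).
#' @param alpha Family-wise level (default 0.05).
#' @return List: `summary` (n_tested, n_replicated, n_concordant,
#'   threshold), `table` (per-feature detail).
#' @export
replication_concordance <- function(primary, replication, alpha = 0.05) {
  prim_thr <- bonferroni_threshold(alpha, nrow(primary))
  sig <- primary[!is.na(primary$p) & primary$p < prim_thr, , drop = FALSE]
  shared <- merge(sig, replication, by = "feature",
                  suffixes = c("_primary", "_replication"))
  if (nrow(shared) == 0) stop("no shared features between primary and replication")
  rep_thr <- bonferroni_threshold(alpha, nrow(shared))
  shared$replicated <- !is.na(shared$p_replication) & shared$p_replication < rep_thr
  shared$concordant <- sign(shared$beta_primary) == sign(shared$beta_replication)
  list(summary = list(n_tested = nrow(shared),
                      n_replicated = sum(shared$replicated),
                      n_concordant = sum(shared$concordant, na.rm = TRUE),
                      threshold = rep_thr),
       table = shared)
}
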