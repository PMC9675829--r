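#' Standardize the five clustering variables on a fitting set
#'
#' Centers each clustering variable to mean 0 and scales to SD 1 using the
#' moments of the fitting subset only; the stored parameters can be applied to
#' held-out subjects with [apply_standardization()].
#'
#' @param subjects Data frame containing the five clustering variables and a
#'   `subject_id` column.
#' @param fit_ids Subject ids forming the fitting set; defaults to all rows.
#' @return List with `X` (standardized matrix of the fitting rows, rownames =
#'   subject ids) and `params` (data frame `variable`, `mean`, `sd`).
#' @export
standardize <- function(subjects, fit_ids = NULL) {
  if (is.null(fit_ids)) fit_ids <- as.character(subjects$subject_id)
  if (length(fit_ids) == 0) stop("fit_ids must be nonempty")
  miss <- setdiff(CLUSTER_VARS, names(subjects))
  if (length(miss)) stop("missing clustering variables: ", paste(miss, collapse = ", "))
  rows <- match(fit_ids, as.character(subjects$subject_id))
  if (anyNA(rows)) stop("fit_ids not all present in subjects")
  X <- as.matrix(subjects[rows, CLUSTER_VARS])
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    stop("zero-variance clustering variable(s): ",
         paste(CLUSTER_VARS[zero], collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`)
  rownames(Xs) <- fit_ids
  list(X = Xs,
       params = data.frame(variable = CLUSTER_VARS, mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Apply stored standardization parameters to new subjects
#'
#' @param subjects Data frame with the five clustering variables and
#'   `subject_id`, or a numeric matrix with those columns.
#' @param params Standardization parameters from [standardize()].
#' @return Standardized numeric matrix (rownames = subject ids if available).
#' @export
apply_standardization <- function(subjects, params) {
  if (is.data.frame(subjects)) {
    X <- as.matrix(subjects[, CLUSTER_VARS])
    if ("subject_id" %in% names(subjects)) {
      rownames(X) <- as.character(subjects$subject_id)
    }
  } else {
    X <- subjects[, CLUSTER_VARS, drop = FALSE]
  }
  mu <- params$mean[match(CLUSTER_VARS, params$variable)]
  sdv <- params$sd[match(CLUSTER_VARS, params$variable)]
  sweep(sweep(X, 2, mu, `-`), 2, sdv, `/`)
}

#' Fit the k-means subtype cluster model
#'
#' Runs seeded k-means on standardized data, keeping the best-inertia solution
#' over `restarts` initializations. When `k = 4` the clusters are named
#' SIDD/SIRD/MOD/MARD by [label_clusters()].
#'
#' @param X_std Standardized matrix (rows = subjects, columns the five
#'   clustering variables).
#' @param k Number of clusters (>= 2).
#' @param restarts Number of random initializations (best inertia kept).
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param standardization Optional standardization parameter frame to embed in
#'   the model (needed for transfer to new subjects).
#' @return Object of class `cluster_model`: `feature_names`, `centers`
#'   (k x 5, standardized units), `k`, `label_map`, `standardization`,
#'   `fit_meta`.
#' @export
fit_cluster_model <- function(X_std, k = 4L, restarts = 100L, seed = 1L,
                              standardization = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (nrow(X_std) < k) stop("k exceeds the number of rows")
  if (nrow(X_std) == k) {
    # degenerate exact solution: every point is its own center
    centers <- unname(as.matrix(X_std))
    inertia <- 0
  } else {
    set.seed(seed)
    km <- kmeans(X_std, centers = k, nstart = restarts, iter.max = 100L)
    centers <- unname(km$centers)
    inertia <- km$tot.withinss
  }
  colnames(centers) <- colnames(X_std)
  model <- structure(list(
    feature_names = colnames(X_std),
    centers = centers,
    k = as.integer(k),
    label_map = NULL,
    standardization = standardization,
    fit_meta = list(restarts = as.integer(restarts), seed = as.integer(seed),
                    inertia = inertia)
  ), class = "cluster_model")
  if (k == 4) model$label_map <- label_clusters(model)
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, "on", paste(x$feature_names, collapse = ", "), "\n")
  if (!is.null(x$label_map)) {
    cat("  labels:", paste(sprintf("%d=%s", seq_along(x$label_map), x$label_map),
                           collapse = ", "), "\n")
  }
  cat("  inertia:", signif(x$fit_meta$inertia, 6), "(", x$fit_meta$restarts,
      "restarts, seed", x$fit_meta$seed, ")\n")
  invisible(x)
}

# Subtype prototype sign patterns in the order of CLUSTER_VARS
# (age_at_diagnosis, bmi, hba1c, homa2_b, homa2_ir).
SUBTYPE_PROTOTYPES <- rbind(
  SIDD = c(0, 0, 1, -1, 0),   # poor glycemic control, insulin deficient
  SIRD = c(0, 1, 0, 0, 1),    # insulin resistant, high BMI
  MOD  = c(-1, 1, 0, 0, 0),   # obese, young onset
  MARD = c(1, 0, 0, 0, 0)     # old onset, mild otherwise
)

#' Name the four clusters as SIDD / SIRD / MOD / MARD
#'
#' Assigns subtype names to cluster indices by maximizing the total agreement
#' between the cluster center sign patterns and fixed prototype patterns
#' (SIDD: high HbA1c, low HOMA2-B; SIRD: high HOMA2-IR, high BMI; MOD: high
#' BMI, young onset; MARD: late onset with small magnitudes elsewhere) over
#' all one-to-one matchings.
#'
#' @param model A `cluster_model` with `k = 4` (or a bare 4 x 5 center matrix).
#' @return Character vector: `label_map[i]` is the subtype name of cluster `i`.
#' @export
label_clusters <- function(model) {
  centers <- if (inherits(model, "cluster_model")) model$centers else model
  if (nrow(centers) != 4) stop("cluster labeling requires k = 4")
  centers <- centers[, CLUSTER_VARS, drop = FALSE]
  # score of assigning cluster i the subtype s: prototype dot product, with a
  # mildness penalty for MARD (small magnitudes outside age at diagnosis)
  score <- matrix(NA_real_, 4, 4, dimnames = list(NULL, SUBTYPES))
  for (i in 1:4) {
    for (s in SUBTYPES) {
      sc <- sum(SUBTYPE_PROTOTYPES[s, ] * centers[i, ])
      if (s == "MARD") sc <- sc - 0.5 * mean(abs(centers[i, -1]))
      score[i, s] <- sc
    }
  }
  perms <- permutations_of(4)
  best <- NULL
  best_score <- -Inf
  for (p in perms) {
    tot <- sum(score[cbind(1:4, p)])
    if (tot > best_score) {
      best_score <- tot
      best <- p
    }
  }
  SUBTYPES[best]
}

# all permutations of 1..n (small n)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in permutations_of(n - 1)) {
      tail <- seq_len(n)[-i][rest]
      out[[length(out) + 1L]] <- c(i, tail)
    }
  }
  out
}

#' Assign subjects to the nearest cluster center
#'
#' Each row is assigned to the center with minimum Euclidean distance; ties
#' are broken toward the lowest cluster index. All per-center distances are
#' returned.
#'
#' @param X_std Matrix standardized with the model's parameters.
#' @param model A `cluster_model`.
#' @return Data frame: `subject_id`, `cluster`, `subtype` (if the model is
#'   labelled), `dist_own`, and one `dist_<i>` column per center.
#' @export
assign_by_centers <- function(X_std, model) {
  centers <- model$centers
  if (ncol(X_std) != ncol(centers)) stop("dimension mismatch with centers")
  D <- distances_to_centers(X_std, centers)
  cl <- max.col(-D, ties.method = "first")
  out <- data.frame(
    subject_id = if (is.null(rownames(X_std))) as.character(seq_len(nrow(X_std))) else rownames(X_std),
    cluster = cl,
    subtype = if (!is.null(model$label_map)) model$label_map[cl] else NA_character_,
    dist_own = D[cbind(seq_len(nrow(D)), cl)],
    stringsAsFactors = FALSE
  )
  colnames(D) <- paste0("dist_", seq_len(ncol(D)))
  cbind(out, as.data.frame(D))
}

distances_to_centers <- function(X, centers) {
  # direct differences per center: numerically exact at centers and for ties,
  # unlike the ||x||^2 - 2x.c + ||c||^2 expansion
  D <- matrix(NA_real_, nrow(X), nrow(centers))
  for (i in seq_len(nrow(centers))) {
    diff <- sweep(X, 2, centers[i, ], `-`)
    D[, i] <- sqrt(rowSums(diff^2))
  }
  D
}

#' Choose the number of clusters by BIC plus validity-index voting
#'
#' For each candidate `k`, fits (i) Gaussian mixture models scored by BIC
#' (via \pkg{mclust}, EM initialized by model-based hierarchical clustering)
#' and (ii) a k-means solution scored by mean silhouette width,
#' Calinski-Harabasz index, Davies-Bouldin index, and the within-SS elbow
#' (largest second difference). Each of the five criteria casts one vote for
#' its optimal `k`; the majority-vote `k` wins, with ties broken toward the
#' smaller `k`.
#'
#' @param X_std Standardized data matrix.
#' @param k_range Candidate cluster counts, within 2..15.
#' @param restarts k-means restarts per candidate `k`.
#' @param seed Integer seed.
#' @return List with `k` (chosen), `votes` (named integer vector, one vote per
#'   criterion), and `indices` (per-`k` table of all criterion values).
#' @export
select_k <- function(X_std, k_range = 2:15, restarts = 20L, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > 15) stop("k_range must lie within [2, 15]")
  if (nrow(X_std) <= max(k_range)) stop("degenerate data: n <= max k")

  set.seed(seed)
  bic <- mclust::mclustBIC(X_std, G = k_range, verbose = FALSE)
  bic_best <- apply(bic, 1, max, na.rm = TRUE)
  vote_bic <- k_range[which.max(bic_best)]

  n <- nrow(X_std)
  d <- dist(X_std)
  wss <- sil <- ch <- db <- setNames(rep(NA_real_, length(k_range)), k_range)
  total_ss <- sum(scale(X_std, scale = FALSE)^2)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    km <- kmeans(X_std, centers = k, nstart = restarts, iter.max = 100L)
    wss[i] <- km$tot.withinss
    sil[i] <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    bss <- total_ss - km$tot.withinss
    ch[i] <- (bss / (k - 1)) / (km$tot.withinss / (n - k))
    db[i] <- davies_bouldin(X_std, km$cluster, km$centers)
  }
  vote_sil <- k_range[which.max(sil)]
  vote_ch <- k_range[which.max(ch)]
  vote_db <- k_range[which.min(db)]
  vote_elbow <- if (length(k_range) >= 3) {
    second_diff <- wss[1:(length(k_range) - 2)] - 2 * wss[2:(length(k_range) - 1)] +
      wss[3:length(k_range)]
    k_range[which.max(second_diff) + 1L]
  } else k_range[1]

  votes <- c(bic = vote_bic, silhouette = vote_sil, calinski_harabasz = vote_ch,
             davies_bouldin = vote_db, elbow = vote_elbow)
  list(k = majority_vote(votes),
       votes = votes,
       indices = data.frame(k = k_range, bic = bic_best[as.character(k_range)],
                            wss = wss, silhouette = sil, calinski_harabasz = ch,
                            davies_bouldin = db))
}

#' Majority vote over per-criterion cluster counts, ties to the smaller k
#' @param votes Named integer vector of per-criterion chosen `k`s.
#' @return The winning `k`.
#' @export
majority_vote <- function(votes) {
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

davies_bouldin <- function(X, cl, centers) {
  k <- nrow(centers)
  s <- vapply(seq_len(k), function(i) {
    rows <- cl == i
    if (sum(rows) == 0) return(0)
    mean(sqrt(rowSums((X[rows, , drop = FALSE] -
                         matrix(centers[i, ], sum(rows), ncol(X), byrow = TRUE))^2)))
  }, numeric(1))
  M <- as.matrix(dist(centers))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / M[i, j], numeric(1)))
  }, numeric(1))
  mean(r)
}
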