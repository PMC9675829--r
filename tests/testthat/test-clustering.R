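test_that("standardization centers and scales the fitting set and transfers to new rows", {
  coh <- generate_cohort(small_params(seed = 41))
  t2d <- coh$subjects[classify_status(coh$subjects) == "T2D", ]
  std <- standardize(t2d)
  expect_lt(max(abs(colMeans(std$X))), 1e-9)
  expect_lt(max(abs(apply(std$X, 2, sd) - 1)), 1e-9)

  mean_row <- t2d[1, ]
  mean_row[clustering_variables()] <- as.list(std$params$mean)
  expect_lt(max(abs(apply_standardization(mean_row, std$params))), 1e-12)

  t2d$hba1c <- 7.5
  expect_error(standardize(t2d), "hba1c")
})

test_that("k-means fit is exact on trivial data and deterministic", {
  X <- rbind(c(0, 0, 0, 0, 0), c(4, 4, 4, 4, 4))
  colnames(X) <- clustering_variables()
  m <- fit_cluster_model(X, k = 2, restarts = 5, seed = 1)
  expect_equal(sort(m$centers[, 1]), c(0, 4))
  expect_equal(m$fit_meta$inertia, 0)
  b <- make_blobs(default_subtype_centers(), 60, seed = 3)
  m1 <- fit_cluster_model(b$X, 4, 20, seed = 9)
  m2 <- fit_cluster_model(b$X, 4, 20, seed = 9)
  expect_identical(m1$centers, m2$centers)
  expect_error(fit_cluster_model(X, k = 3), "exceeds")
})

test_that("nearest-center assignment matches a brute-force oracle and breaks ties low", {
  b <- make_blobs(default_subtype_centers(), 50, seed = 13)
  m <- fit_cluster_model(b$X, 4, 20, seed = 2)
  a <- assign_by_centers(b$X, m)
  # oracle: exhaustive per-row distance comparison
  oracle <- apply(b$X, 1, function(x) {
    d <- apply(m$centers, 1, function(ct) sqrt(sum((x - ct)^2)))
    which.min(d)
  })
  expect_equal(a$cluster, unname(oracle))
  expect_equal(a$dist_own, apply(b$X, 1, function(x) {
    min(apply(m$centers, 1, function(ct) sqrt(sum((x - ct)^2))))
  }), tolerance = 1e-12, ignore_attr = TRUE)

  # a point exactly at a center
  at_center <- matrix(m$centers[3, ], 1, dimnames = list("z", colnames(b$X)))
  a3 <- assign_by_centers(at_center, m)
  expect_equal(a3$cluster, 3)
  expect_equal(a3$dist_own, 0)

  # equidistant point between centers 1 and 2 goes to the lower index
  mid_model <- m
  mid_model$centers <- rbind(rep(0, 5), rep(2, 5), rep(10, 5), rep(-10, 5))
  colnames(mid_model$centers) <- colnames(b$X)
  mid <- matrix(rep(1, 5), 1, dimnames = list("m", colnames(b$X)))
  expect_equal(assign_by_centers(mid, mid_model)$cluster, 1)

  # refitting assignment reproduces the fit's own partition
  expect_equal(assign_by_centers(b$X, m)$cluster,
               assign_by_centers(b$X, m)$cluster)
})

test_that("cluster labeling is the identity on prototypes and equivariant to permutation", {
  proto <- rbind(
    SIDD = c(0, 0, 1, -1, 0),
    SIRD = c(0, 1, 0, 0, 1),
    MOD  = c(-1, 1, 0, 0, 0),
    MARD = c(1, 0, 0, 0, 0))
  colnames(proto) <- clustering_variables()
  expect_equal(label_clusters(proto), subtype_names())
  perm <- c(3, 1, 4, 2)
  expect_equal(label_clusters(proto[perm, ]), subtype_names()[perm])
  expect_equal(label_clusters(default_subtype_centers()), subtype_names())
  expect_error(label_clusters(proto[1:3, ]), "k = 4")
})

test_that("fitted subtype labels recover the generative subtypes", {
  p <- small_params(n_cases = 400L, n_controls = 0L, seed = 17)
  coh <- generate_cohort(p)
  t2d <- coh$subjects[classify_status(coh$subjects) == "T2D", ]
  std <- standardize(t2d)
  m <- fit_cluster_model(std$X, 4, 50, seed = 5, standardization = std$params)
  a <- assign_by_centers(std$X, m)
  truth <- coh$truth$subtype[a$subject_id]
  expect_gt(mean(a$subtype == truth), 0.95)
})

test_that("partition comparison scores identity, relabeling, and independence correctly", {
  x <- sample(subtype_names(), 300, replace = TRUE)
  names(x) <- sprintf("i%03d", 1:300)
  cmp <- compare_partitions(x, x)
  expect_equal(cmp$agreement, 100)
  expect_equal(cmp$ari, 1)

  relabel <- c(SIDD = "c4", SIRD = "c2", MOD = "c1", MARD = "c3")
  cmp2 <- compare_partitions(x, setNames(relabel[x], names(x)))
  expect_equal(cmp2$agreement, 100)
  expect_equal(cmp2$ari, 1)

  set.seed(99)
  aris <- replicate(20, {
    a <- sample(1:4, 1000, replace = TRUE)
    b <- sample(1:4, 1000, replace = TRUE)
    compare_partitions(a, b)$ari
  })
  expect_lt(abs(mean(aris)), 3 * sd(aris) / sqrt(20))
  # cross-check the ARI formula against the reference implementation
  set.seed(5)
  for (i in 1:5) {
    a <- sample(1:3, 80, replace = TRUE)
    b <- sample(1:5, 80, replace = TRUE)
    expect_equal(compare_partitions(a, b)$ari,
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(compare_partitions(setNames(1:3, c("a", "b", "c")),
                                  setNames(1:3, c("a", "b", "d"))), "ids differ")
})

test_that("bootstrap Jaccard is high for separated clusters, low for forced splits", {
  b <- make_blobs(default_subtype_centers(), 80, seed = 23)
  m <- fit_cluster_model(b$X, 4, 30, seed = 1)
  st <- jaccard_stability(b$X, m, n_reruns = 60, seed = 2)
  expect_true(all(st$per_cluster >= 0 & st$per_cluster <= 1))
  expect_true(all(st$per_cluster > 0.95))

  set.seed(7)
  iso <- matrix(rnorm(320 * 5), 320)
  colnames(iso) <- clustering_variables()
  rownames(iso) <- sprintf("g%03d", 1:320)
  m0 <- fit_cluster_model(iso, 4, 30, seed = 1)
  st0 <- jaccard_stability(iso, m0, n_reruns = 60, seed = 3)
  expect_lt(min(st0$per_cluster), 0.75)
})

test_that("fasting correction removes a planted linear dependence and nothing else", {
  set.seed(55)
  n <- 1000
  fasting <- runif(n, 0, 960)
  indep <- data.frame(homa2_b = rnorm(n, 80, 10), homa2_ir = rnorm(n, 2, 0.5),
                      fasting_minutes = fasting)
  corr <- correct_for_fasting(indep)
  expect_lt(max(abs(corr$homa2_b - indep$homa2_b)), 1.5)
  expect_gt(cor(corr$homa2_b, indep$homa2_b), 0.99)

  dep <- indep
  dep$homa2_ir <- 2 + 0.004 * fasting + rnorm(n, 0, 0.3)
  corr2 <- correct_for_fasting(dep)
  expect_lt(abs(cor(corr2$homa2_ir, fasting)), 0.05)
  # corrected values sit at the reference-time prediction on average
  fit <- lm(dep$homa2_ir ~ fasting)
  expect_equal(mean(corr2$homa2_ir), unname(coef(fit)[1] + coef(fit)[2] * 480),
               tolerance = 1e-8)

  cst <- indep
  cst$fasting_minutes <- 480
  expect_warning(out <- correct_for_fasting(cst), "constant")
  expect_identical(out$homa2_b, cst$homa2_b)
})

test_that("clustering is insensitive to fasting correction when HOMA2 is fasting-independent", {
  p <- small_params(n_cases = 400L, n_controls = 0L, seed = 61)
  coh <- generate_cohort(p)
  t2d <- coh$subjects[classify_status(coh$subjects) == "T2D", ]
  std <- standardize(t2d)
  m <- fit_cluster_model(std$X, 4, 50, seed = 3, standardization = std$params)
  before <- assign_by_centers(std$X, m)
  corrected <- correct_for_fasting(t2d)
  after <- assign_by_centers(apply_standardization(corrected, std$params), m)
  expect_gte(mean(before$cluster == after$cluster), 0.98)
})

test_that("transfer classification honors external centers and degrades with noise", {
  p <- small_params(n_cases = 350L, n_controls = 0L, seed = 71)
  coh <- generate_cohort(p)
  t2d <- coh$subjects[classify_status(coh$subjects) == "T2D", ]
  std <- standardize(t2d)
  m <- fit_cluster_model(std$X, 4, 50, seed = 2, standardization = std$params)
  own <- assign_by_centers(std$X, m)

  centers <- m$centers
  rownames(centers) <- m$label_map
  tr <- transfer_centers(t2d, centers, std$params)
  expect_equal(tr$subtype, own$subtype)

  swapped <- centers[c(2, 1, 3, 4), ]
  tr2 <- transfer_centers(t2d, swapped, std$params)
  expect_equal(compare_partitions(setNames(tr2$subtype, tr2$subject_id),
                                  setNames(own$subtype, own$subject_id))$agreement, 100)

  # sex-specific centers: identical per-sex sets reproduce the pooled result
  by_sex <- list(male = centers, female = centers)
  tr3 <- transfer_centers(t2d, by_sex, std$params)
  expect_equal(tr3$subtype, own$subtype)

  noise_levels <- c(0, 0.5, 1, 2, 4)
  agree <- sapply(noise_levels, function(ns) {
    mean(sapply(1:10, function(s) {
      set.seed(s)
      pert <- centers + matrix(rnorm(20, sd = ns), 4)
      trn <- transfer_centers(t2d, pert, std$params)
      compare_partitions(setNames(trn$subtype, trn$subject_id),
                         setNames(own$subtype, own$subject_id))$agreement
    }))
  })
  expect_lt(cor(noise_levels, agree, method = "spearman"), 0)
  expect_equal(agree[1], 100)
})

test_that("confounder screening is calibrated and correction preserves clean clusterings", {
  p <- small_params(n_cases = 350L, n_controls = 0L, seed = 81)
  coh <- generate_cohort(p)
  t2d <- coh$subjects[classify_status(coh$subjects) == "T2D", ]
  std <- standardize(t2d)
  m <- fit_cluster_model(std$X, 4, 50, seed = 4, standardization = std$params)
  cl <- assign_by_centers(std$X, m)$cluster

  set.seed(6)
  t2d$noise_confounder <- rnorm(nrow(t2d))
  res <- confounder_sensitivity(t2d, cl, c("noise_confounder", "sex",
                                           "time_since_diagnosis"),
                                k = 4, restarts = 50, seed = 5)
  expect_gte(res$agreement, 95)
  expect_true(all(res$post_correction_p < 0.05))

  # null calibration: p of an independent continuous confounder is uniform
  set.seed(10)
  pvals <- replicate(100, {
    v <- rnorm(length(cl))
    anova(aov(v ~ factor(cl)))[["Pr(>F)"]][1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(confounder_sensitivity(t2d, cl, "missing_col"), "not found")
  t2d$onelevel <- "x"
  expect_error(confounder_sensitivity(t2d, cl, "onelevel"), "single level")
})
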