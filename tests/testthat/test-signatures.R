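make_cluster_matrix <- function(n_per = 100, n_feat = 30, seed = 101) {
  set.seed(seed)
  assignments <- rep(subtype_names(), each = n_per)
  X <- matrix(rnorm(length(assignments) * n_feat), length(assignments), n_feat,
              dimnames = list(sprintf("t%04d", seq_along(assignments)),
                              sprintf("f%03d", seq_len(n_feat))))
  list(X = X, assignments = assignments)
}

test_that("a feature elevated in one cluster only is selected as specific and up", {
  hit <- replicate(10, {
    d <- make_cluster_matrix(seed = sample.int(1e6, 1))
    d$X[d$assignments == "MOD", 1] <- d$X[d$assignments == "MOD", 1] + 2
    sig <- cluster_specific_features(d$X, d$assignments, m = ncol(d$X))
    rec <- sig[sig$feature == "f001" & sig$cluster == "MOD", ]
    rec$specific && rec$direction == "up"
  })
  expect_gte(mean(hit), 0.9)
})

test_that("null and two-cluster-elevated features are never called specific", {
  d <- make_cluster_matrix(n_feat = 200, seed = 103)
  sig <- cluster_specific_features(d$X, d$assignments, m = ncol(d$X))
  # null: selection rate bounded by the Bonferroni level
  expect_lte(sum(sig$specific), 3)

  d2 <- make_cluster_matrix(seed = 104)
  shift <- d2$assignments %in% c("SIDD", "SIRD")
  d2$X[shift, 2] <- d2$X[shift, 2] + 2
  sig2 <- cluster_specific_features(d2$X, d2$assignments, m = ncol(d2$X))
  both <- sig2[sig2$feature == "f002" & sig2$cluster %in% c("SIDD", "SIRD"), ]
  expect_false(any(both$specific))
  # the pairwise criterion between the two elevated clusters is what fails
  expect_gt(both$p_pair_SIRD[both$cluster == "SIDD"], 0.05)
})

test_that("one-vs-rest linear-model p equals the equal-variance t-test p", {
  d <- make_cluster_matrix(n_per = 40, n_feat = 10, seed = 105)
  sig <- cluster_specific_features(d$X, d$assignments, m = ncol(d$X))
  for (i in 1:10) {
    f <- sample(colnames(d$X), 1)
    cl <- sample(subtype_names(), 1)
    rec <- sig[sig$feature == f & sig$cluster == cl, ]
    tt <- t.test(d$X[d$assignments == cl, f], d$X[d$assignments != cl, f],
                 var.equal = TRUE)
    expect_equal(rec$p_one_vs_rest, tt$p.value, tolerance = 1e-12)
  }
})

test_that("dropping a pairwise criterion can only grow the specific set", {
  d <- make_cluster_matrix(n_feat = 60, seed = 106)
  for (s in subtype_names()) {
    rows <- d$assignments == s
    idx <- which(subtype_names() == s)
    d$X[rows, idx] <- d$X[rows, idx] + 1.2   # moderate shifts, borderline calls
  }
  sig <- cluster_specific_features(d$X, d$assignments, m = ncol(d$X))
  thr <- bonferroni_threshold(0.05, ncol(d$X))
  full <- sig$specific
  pair_cols <- paste0("p_pair_", subtype_names())
  for (drop_col in pair_cols) {
    kept <- setdiff(pair_cols, drop_col)
    relaxed <- !is.na(sig$p_one_vs_rest) & sig$p_one_vs_rest < thr
    for (pc in kept) {
      other <- sub("p_pair_", "", pc)
      applicable <- sig$cluster != other
      relaxed <- relaxed & (!applicable | (!is.na(sig[[pc]]) & sig[[pc]] < 0.05))
    }
    expect_true(all(relaxed[full]))   # full criterion set is a subset
  }
})

test_that("clusters with fewer than two members are flagged missing, not tested", {
  d <- make_cluster_matrix(n_per = 30, seed = 107)
  keep <- d$assignments != "SIRD" | seq_along(d$assignments) %in% which(d$assignments == "SIRD")[1]
  sig <- cluster_specific_features(d$X[keep, ], d$assignments[keep], m = ncol(d$X))
  sird <- sig[sig$cluster == "SIRD", ]
  expect_true(all(is.na(sird$p_one_vs_rest)))
  expect_false(any(sird$specific))
})

test_that("normalized profiles anchor the reference at exactly 1 with sane CIs", {
  set.seed(108)
  groups <- rep(c(subtype_names(), "SAID", "CONTROL"), each = 40)
  X <- matrix(rlnorm(length(groups) * 3), length(groups), 3,
              dimnames = list(NULL, c("a", "b", "c")))
  prof <- normalized_cluster_profiles(X, groups, reference_cluster = "MOD")
  ref_rows <- prof[prof$group == "MOD", ]
  expect_true(all(ref_rows$normalized_mean == 1))
  expect_true(all(prof$ci_lower <= prof$normalized_mean &
                    prof$normalized_mean <= prof$ci_upper))

  # constant group: normalized mean v / r with a zero-width interval
  Xc <- X
  Xc[groups == "SAID", "a"] <- 7
  pc <- normalized_cluster_profiles(Xc, groups, "MOD", features = "a")
  said <- pc[pc$group == "SAID", ]
  r <- mean(Xc[groups == "MOD", "a"])
  expect_equal(said$normalized_mean, 7 / r)
  expect_equal(said$ci_lower, said$ci_upper)

  Xz <- X
  Xz[groups == "MOD", "b"] <- 0
  expect_error(normalized_cluster_profiles(Xz, groups, "MOD", features = "b"),
               "reference mean is zero")
})

test_that("PC variance explained by cluster is bounded and exact on constructed data", {
  d <- make_cluster_matrix(n_per = 50, n_feat = 20, seed = 109)
  pcr <- pc_variance_explained(d$X, d$assignments, n_components = 10)
  expect_true(all(pcr$r_squared >= 0 & pcr$r_squared <= 1))

  # build data whose dominant component IS the cluster index
  idx <- as.numeric(factor(d$assignments, levels = subtype_names()))
  X2 <- outer(idx, rnorm(20)) * 5 + matrix(rnorm(length(idx) * 20, sd = 0.01),
                                           length(idx))
  rownames(X2) <- rownames(d$X)
  pcr2 <- pc_variance_explained(X2, d$assignments, n_components = 2)
  expect_gt(pcr2$r_squared[1], 0.99)
  expect_error(pc_variance_explained(d$X, d$assignments, n_components = 100),
               "rank")
})

test_that("signature cross-correlations behave at the identity, null, and planted cases", {
  set.seed(110)
  n <- 400
  ids <- sprintf("s%04d", 1:n)
  P <- matrix(rnorm(n * 6), n, 6, dimnames = list(ids, paste0("P", 1:6)))
  M <- matrix(rnorm(n * 5), n, 5, dimnames = list(ids, paste0("M", 1:5)))
  M[, 1] <- P[, 1] + rnorm(n, sd = 0.5)   # planted correlation

  self <- correlate_signature_features(P, P, "P2", "P2")
  expect_equal(self$r, 1)

  ct <- correlate_signature_features(P, M)
  planted <- ct[ct$protein == "P1" & ct$metabolite == "M1", ]
  expect_gt(planted$r, 0.5)
  expect_lt(planted$p, 1e-10)

  null_pairs <- ct[!(ct$protein == "P1" & ct$metabolite == "M1"), ]
  expect_gte(mean(abs(null_pairs$r) < 0.15), 0.95)
  expect_error(correlate_signature_features(P[1:2, ], M[1:2, ]), "3 shared")
})
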