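test_that("preprocessing drops high-missingness features, z-scores and winsorizes", {
  set.seed(91)
  X <- matrix(rlnorm(200 * 5), 200, 5,
              dimnames = list(sprintf("s%03d", 1:200), paste0("F", 1:5)))
  X[sample(200, 190), 2] <- NA            # 95% missing -> excluded
  X[1, 3] <- exp(mean(log(X[-1, 3])) + 50)  # extreme outlier -> clipped to +5
  pp <- preprocess_features(X)
  expect_true("F2" %in% pp$excluded)
  expect_true("F2" %in% pp$log$feature[pp$log$action == "excluded_missingness"])
  expect_false("F2" %in% colnames(pp$omics))
  expect_lte(max(pp$omics, na.rm = TRUE), 5)
  expect_gte(min(pp$omics, na.rm = TRUE), -5)
  expect_equal(pp$omics[1, "F3"], 5)

  # a value at the feature's geometric mean maps to z = 0
  Y <- X[, 4, drop = FALSE]
  Y[1, 1] <- exp(mean(log(Y[-1, 1])))
  ppy <- preprocess_features(Y)
  # after centering on the full column the geometric-mean row is ~0
  expect_lt(abs(ppy$omics[1, 1]), 0.05)

  Xn <- X[, 1, drop = FALSE]
  Xn[2, 1] <- -1
  expect_warning(ppn <- preprocess_features(Xn), "non-positive")
  expect_true(is.na(ppn$omics[2, 1]))
})

test_that("missing entries stay missing and preprocessing is idempotent for downstream calls", {
  p <- small_params(seed = 92, missing_rate = 0.1)
  coh <- generate_cohort(p)
  om <- generate_omics(coh$truth, p, "protein")
  pp <- preprocess_features(om$omics)
  expect_identical(is.na(pp$omics$values), is.na(om$omics$values))

  status <- coh$truth$group[rownames(pp$omics$values)]
  keep <- status %in% c("CONTROL", "T2D")
  a1 <- associate_case_control(pp$omics$values[keep, ], status[keep], model = "linear")
  pp2 <- preprocess_features(exp(pp$omics$values))   # re-run on already-scaled data
  a2 <- associate_case_control(pp2$omics[keep, ], status[keep], model = "linear")
  thr <- bonferroni_threshold(0.05, nrow(a1))
  expect_identical(a1$p < thr, a2$p < thr)
})

test_that("case-control association recovers planted effects with the right sign", {
  set.seed(93)
  n <- 600
  status <- rep(c("CONTROL", "T2D"), each = n / 2)
  hits <- replicate(20, {
    x <- rnorm(n) + (status == "T2D") * 0.8
    X <- matrix(x, ncol = 1, dimnames = list(NULL, "f"))
    a <- associate_case_control(X, status, model = "logistic")
    a$beta > 0 & a$p < 0.05
  })
  expect_gte(mean(hits), 0.99)
  lin <- associate_case_control(
    matrix(rnorm(n) + (status == "T2D") * 0.8, ncol = 1,
           dimnames = list(NULL, "f")), status, model = "linear")
  expect_gt(lin$beta, 0)
  expect_lt(lin$p, 1e-6)
  expect_error(associate_case_control(matrix(rnorm(10), ncol = 1),
                                      rep("T2D", 10)), "contrast")
})

test_that("null feature p-values are uniform and affine rescaling changes nothing", {
  set.seed(94)
  n <- 300
  status <- rep(c("CONTROL", "T2D"), each = n / 2)
  X <- matrix(rlnorm(n * 300), n, 300,
              dimnames = list(NULL, sprintf("f%03d", 1:300)))
  pp <- preprocess_features(X)
  a <- associate_case_control(pp$omics, status, model = "linear")
  expect_gt(ks.test(a$p, "punif")$p.value, 0.01)

  # scale/translation invariance: multiplying raw abundances by a constant
  # shifts the log and leaves z-scores, hence p-values, unchanged
  pp_scaled <- preprocess_features(X * 1000)
  a_scaled <- associate_case_control(pp_scaled$omics, status, model = "linear")
  expect_equal(a$p, a_scaled$p, tolerance = 1e-9)
})

test_that("perfect separation is flagged rather than reported as a finite effect", {
  status <- rep(c("CONTROL", "T2D"), each = 20)
  x <- c(rnorm(20, -5), rnorm(20, 5))   # perfectly separates the groups
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "sep"))
  a <- associate_case_control(X, status, model = "logistic")
  expect_true(is.na(a$p))
  expect_false(is.finite(a$beta))
})

test_that("Bonferroni threshold is alpha over m with strict validation", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 20), 5e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})

test_that("replication concordance counts identity, sign flips, and effect-size trends", {
  set.seed(95)
  prim <- data.frame(feature = sprintf("f%02d", 1:40),
                     beta = rnorm(40, 2, 0.2), p = 10^runif(40, -12, -6))
  rc <- replication_concordance(prim, prim)
  expect_equal(rc$summary$n_tested, 40)
  expect_equal(rc$summary$n_replicated, 40)
  expect_equal(rc$summary$n_concordant, 40)

  flipped <- prim
  flipped$beta <- -flipped$beta
  rcf <- replication_concordance(prim, flipped)
  expect_equal(rcf$summary$n_concordant, 0)

  # replication rate increases with planted effect size
  n <- 400
  status <- rep(c("CONTROL", "T2D"), each = n / 2)
  frac <- sapply(c(0.2, 0.5, 1.0), function(d) {
    X1 <- sapply(1:30, function(i) rnorm(n) + (status == "T2D") * d)
    X2 <- sapply(1:30, function(i) rnorm(n / 2) +
                   (status[seq(1, n, 2)] == "T2D") * d)
    colnames(X1) <- colnames(X2) <- sprintf("g%02d", 1:30)
    a1 <- associate_case_control(X1, status, model = "linear")
    a2 <- associate_case_control(X2, status[seq(1, n, 2)], model = "linear")
    sig <- a1$p < bonferroni_threshold(0.05, nrow(a1))
    if (!any(sig)) return(0)
    rc <- replication_concordance(a1, a2)
    rc$summary$n_replicated / rc$summary$n_tested
  })
  expect_true(all(diff(frac) >= 0))
  expect_error(replication_concordance(prim, data.frame(feature = "zz", beta = 1, p = 0.5)),
               "no shared")
})
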