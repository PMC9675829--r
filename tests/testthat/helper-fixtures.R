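# Shared fixtures built in code.

# Small default-structured preset for fast unit tests.
small_params <- function(seed = 11L, ...) {
  args <- list(n_cases = 300L, n_controls = 300L, n_proteins = 60L,
               n_metabolites = 50L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(simulation_params, args)
}

# Minimal subject row for status-rule tests; override fields as needed.
subject_row <- function(...) {
  base <- data.frame(
    subject_id = "X1", sex = "female", age = 50, age_at_diagnosis = NA_real_,
    bmi = 28, hba1c = 5.4, random_glucose = 90, c_peptide = 0.8,
    insulin = 80, fasting_minutes = 480, homa2_b = 100, homa2_ir = 1.2,
    flag_physician_diagnosis = FALSE, flag_diabetes_medication = FALSE,
    flag_insulin_treatment = FALSE, flag_self_report_t1d = FALSE,
    flag_gestational = FALSE, stringsAsFactors = FALSE)
  ov <- list(...)
  base[names(ov)] <- ov
  base
}

# Standardized-space Gaussian blobs with known memberships.
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  colnames(X) <- clustering_variables()[seq_len(ncol(centers))]
  rownames(X) <- sprintf("B%04d", seq_len(nrow(X)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Independent brute-force Fisher oracle: enumerate all tables with the
# observed margins, probabilities from choose() products.
fisher_oracle_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(N, c1)
  obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(N, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
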