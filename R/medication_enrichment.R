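#' Packaged toy ATC drug dictionary
#'
#' A small synthetic dictionary mapping free-text medication synonyms to a
#' unique active molecule and a 7-character ATC code, spanning the drug
#' classes relevant to diabetes cohorts (A10 diabetes drugs, C07 beta
#' blockers, C09 renin-angiotensin agents, C10 lipid modifiers, B01
#' antithrombotics, N02 analgesics, M01 anti-inflammatories, and others).
#' It is a deliberately small stand-in for a full drug-repository export.
#'
#' @param path Path to a dictionary TSV (`synonym`, `molecule`, `atc`);
#'   defaults to the packaged file.
#' @return Data frame with columns `synonym`, `molecule`, `atc`.
#' @export
atc_dictionary <- function(path = system.file("extdata", "atc_dictionary.tsv",
                                              package = "t2dsubtypes")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("synonym", "molecule", "atc") %in% names(d))) {
    stop("malformed dictionary: needs columns synonym, molecule, atc")
  }
  bad <- !grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", d$atc)
  if (any(bad)) {
    stop("malformed ATC code(s): ", paste(unique(d$atc[bad]), collapse = ", "))
  }
  d$synonym <- normalize_drug_string(d$synonym)
  d
}

#' Normalize a free-text drug string
#'
#' Lower-cases, strips punctuation, and drops dosage tokens (bare numbers and
#' number-unit tokens such as `500mg`, `10 ml`, `5 iu`), so that matching
#' against dictionary synonyms is exact after normalization.
#'
#' @param x Character vector of raw entries.
#' @return Normalized character vector.
#' @export
normalize_drug_string <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]+", " ", x)
  vapply(strsplit(x, "[[:space:]]+"), function(tok) {
    tok <- tok[nzchar(tok)]
    drop <- grepl("^[0-9]+([.][0-9]+)?(mg|mcg|g|ml|iu|units?|tabs?|tablets?)?$", tok) |
      tok %in% c("mg", "mcg", "g", "ml", "iu", "unit", "units", "tab", "tabs",
                 "tablet", "tablets", "capsule", "capsules", "daily")
    paste(tok[!drop], collapse = " ")
  }, character(1))
}

#' Annotate free-text medication entries with molecules and ATC codes
#'
#' Matches each entry against the dictionary synonyms,
#' case/punctuation/dosage-insensitively (exact after normalization). A
#' subject-molecule pair is recorded once regardless of repeated entries;
#' unmatched strings are kept with a flag.
#'
#' @param entries Data frame with columns `subject_id` and `entry`.
#' @param dictionary Dictionary as from [atc_dictionary()].
#' @return Object of class `medication_table`: `medications` (data frame
#'   `subject_id`, `molecule`, `atc`), `unmatched` (data frame `subject_id`,
#'   `entry`).
#' @export
annotate_medications <- function(entries, dictionary = atc_dictionary()) {
  stopifnot(all(c("subject_id", "entry") %in% names(entries)))
  norm <- normalize_drug_string(entries$entry)
  hit <- match(norm, dictionary$synonym)
  matched <- !is.na(hit)
  meds <- data.frame(subject_id = entries$subject_id[matched],
                     molecule = dictionary$molecule[hit[matched]],
                     atc = dictionary$atc[hit[matched]],
                     stringsAsFactors = FALSE)
  meds <- unique(meds)
  rownames(meds) <- NULL
  unmatched <- data.frame(subject_id = entries$subject_id[!matched],
                          entry = entries$entry[!matched],
                          stringsAsFactors = FALSE)
  structure(list(medications = meds, unmatched = unmatched),
            class = "medication_table")
}

#' @export
print.medication_table <- function(x, ...) {
  cat("medication_table:", nrow(x$medications), "annotated subject-molecule pairs (",
      length(unique(x$medications$molecule)), "molecules ),",
      nrow(x$unmatched), "unmatched entries\n")
  invisible(x)
}

#' Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-ordering definition: the sum of
#' hypergeometric probabilities of all tables (with the observed margins) at
#' most as probable as the observed one. The odds ratio is the conditional
#' maximum-likelihood estimate under the noncentral hypergeometric model.
#' A zero row or column margin yields p = 1 with an undefined (NA) odds
#' ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List: `odds_ratio`, `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  x <- tab[1, 1]
  m <- sum(tab[1, ])           # row-1 margin
  n2 <- sum(tab[2, ])          # row-2 margin
  k <- sum(tab[, 1])           # column-1 margin
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  support <- lo:hi
  dens <- dhyper(support, m, n2, k)
  d_obs <- dhyper(x, m, n2, k)
  # relative tolerance guards against ties lost to floating-point noise
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  list(odds_ratio = conditional_mle_or(x, m, n2, k), p_value = min(p, 1))
}

# Conditional MLE of the odds ratio: solve E[X | psi] = x under the
# noncentral hypergeometric distribution on the table's support.
conditional_mle_or <- function(x, m, n2, k) {
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  if (x == lo) return(0)
  if (x == hi) return(Inf)
  support <- lo:hi
  logdc <- lchoose(m, support) + lchoose(n2, k - support)
  mean_x <- function(log_psi) {
    logw <- logdc + support * log_psi
    w <- exp(logw - max(logw))
    sum(support * w) / sum(w) - x
  }
  exp(uniroot(mean_x, lower = -35, upper = 35, tol = 1e-12)$root)
}

#' Scan medication usage for group enrichment
#'
#' For every code at the chosen level (active molecule, ATC therapeutic
#' subgroup = first three characters, or ATC anatomical main group = first
#' letter), builds a users/non-users by in-group/out-group 2x2 table from
#' distinct-subject counts for each group, runs [fisher_exact_2x2()], and
#' returns the records sorted by p with a Bonferroni-adjusted column. Codes
#' used by nobody are excluded.
#'
#' @param med_table A `medication_table` from [annotate_medications()].
#' @param groups Named vector (names = subject ids) giving each tested
#'   subject's group (e.g. `T2D`/`CONTROL`, or subtype labels). All named
#'   subjects count as tested, whether or not they have medications.
#' @param level `"molecule"`, `"atc2"` or `"atc_main"`.
#' @return Data frame: `code`, `group`, the four 2x2 counts
#'   (`users_in`, `nonusers_in`, `users_out`, `nonusers_out`), `odds_ratio`,
#'   `p`, `p_bonferroni`.
#' @export
enrichment_scan <- function(med_table, groups,
                            level = c("molecule", "atc2", "atc_main")) {
  level <- match.arg(level)
  stopifnot(inherits(med_table, "medication_table"))
  groups <- groups[!is.na(groups)]
  if (length(groups) == 0) stop("no subjects in groups")
  glev <- unique(as.character(groups))
  if (any(table(groups) == 0)) stop("a group with zero subjects")

  meds <- med_table$medications
  meds <- meds[meds$subject_id %in% names(groups), , drop = FALSE]
  code <- switch(level,
                 molecule = meds$molecule,
                 atc2 = substr(meds$atc, 1, 3),
                 atc_main = substr(meds$atc, 1, 1))
  usage <- unique(data.frame(subject_id = meds$subject_id, code = code,
                             stringsAsFactors = FALSE))
  codes <- sort(unique(usage$code))
  if (length(codes) == 0) {
    return(data.frame(code = character(0), group = character(0),
                      users_in = integer(0), nonusers_in = integer(0),
                      users_out = integer(0), nonusers_out = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0)))
  }
  n_by_group <- table(factor(as.character(groups), levels = glev))
  out <- list()
  for (cd in codes) {
    users <- unique(usage$subject_id[usage$code == cd])
    ug <- table(factor(as.character(groups[users]), levels = glev))
    for (g in glev) {
      users_in <- ug[[g]]
      users_out <- sum(ug) - users_in
      nonusers_in <- n_by_group[[g]] - users_in
      nonusers_out <- (length(groups) - n_by_group[[g]]) - users_out
      ft <- fisher_exact_2x2(matrix(c(users_in, users_out,
                                      nonusers_in, nonusers_out), 2, byrow = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        code = cd, group = g, users_in = users_in, nonusers_in = nonusers_in,
        users_out = users_out, nonusers_out = nonusers_out,
        odds_ratio = ft$odds_ratio, p = ft$p_value, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(res$p * length(codes), 1)
  res[order(res$p), , drop = FALSE]
}
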