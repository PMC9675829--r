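#' Write a cluster model to JSON
#'
#' Serializes feature order, standardization parameters, centers, label map
#' and fit metadata so a model can be reloaded and applied to new cohorts.
#'
#' @param model A `cluster_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  obj <- list(
    feature_names = model$feature_names,
    standardization = model$standardization,
    centers = unname(apply(model$centers, 1, as.list)),
    k = model$k,
    label_map = model$label_map,
    fit_meta = model$fit_meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cluster model from JSON
#'
#' @param path Path written by [write_cluster_model()].
#' @return A `cluster_model`.
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- do.call(rbind, lapply(seq_len(obj$k), function(i) {
    unlist(obj$centers[i, obj$feature_names])
  }))
  colnames(centers) <- obj$feature_names
  structure(list(feature_names = obj$feature_names,
                 centers = centers,
                 k = as.integer(obj$k),
                 label_map = obj$label_map,
                 standardization = as.data.frame(obj$standardization),
                 fit_meta = obj$fit_meta),
            class = "cluster_model")
}

#' Write a data frame as a TSV with header
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an omics matrix (samples x features) as TSV
#'
#' The first column `subject_id` holds the sample ids; remaining columns are
#' features.
#'
#' @param omics An `omics_matrix` or bare matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omics_tsv <- function(omics, path) {
  values <- if (inherits(omics, "omics_matrix")) omics$values else omics
  df <- data.frame(subject_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an omics TSV written by [write_omics_tsv()]
#' @param path Input path.
#' @param platform Platform tag to attach.
#' @return An `omics_matrix` (without technical covariates).
#' @export
read_omics_tsv <- function(path, platform = "protein") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(values = values, platform = platform, covariates = NULL),
            class = "omics_matrix")
}
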