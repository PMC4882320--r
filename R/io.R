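# Delimited-text interchange: tab-separated tables with header rows for
# panels and square matrices, JSON for metadata. Everything written here is
# diff-able and language-neutral.

#' Write a subject panel to delimited files
#'
#' Writes two tab-separated files: the values matrix (one row per subject,
#' header = region abbreviations, first column `subject_id`) and the
#' covariate table (`subject_id`, `group`, `age`, `sex`, `glucose`).
#'
#' @param panel A `subject_panel`.
#' @param values_path,covariates_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_panel <- function(panel, values_path, covariates_path) {
  stopifnot(inherits(panel, "subject_panel"))
  vals <- data.frame(subject_id = panel$subject_ids, panel$values,
                     check.names = FALSE)
  utils::write.table(vals, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cov <- data.frame(subject_id = panel$subject_ids, group = panel$group,
                    panel$covariates, check.names = FALSE)
  utils::write.table(cov, covariates_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(values_path, covariates_path))
}

#' Read a subject panel from delimited files
#'
#' @param values_path,covariates_path Files as written by [write_panel()].
#' @return A `subject_panel`.
#' @export
read_panel <- function(values_path, covariates_path) {
  vals <- utils::read.delim(values_path, check.names = FALSE)
  cov <- utils::read.delim(covariates_path, check.names = FALSE)
  if (!"subject_id" %in% names(vals) || !"subject_id" %in% names(cov)) {
    stop("panel files must carry a subject_id column")
  }
  if (!identical(as.character(vals$subject_id),
                 as.character(cov$subject_id))) {
    stop("subject_id mismatch between values and covariates files")
  }
  m <- as.matrix(vals[, setdiff(names(vals), "subject_id"), drop = FALSE])
  subject_panel(m, cov, group = cov$group[1],
                subject_ids = as.character(vals$subject_id))
}

#' Write a square matrix with region-abbreviation headers
#'
#' @param m Square matrix (correlation or adjacency).
#' @param path Output TSV path.
#' @param labels Optional row/column labels (defaults to existing dimnames).
#' @param metadata Optional named list written to a `.json` sidecar
#'   (`paste0(path, ".json")`), e.g. group, density, realized cutoff.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, labels = NULL, metadata = NULL) {
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(colnames(m))) {
    colnames(m) <- rownames(m) <- sprintf("R%03d", seq_len(ncol(m)))
  }
  df <- data.frame(region = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path.
#' @return A labelled square matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "region"), drop = FALSE])
  rownames(m) <- df$region
  if (!identical(rownames(m), colnames(m))) {
    stop("matrix file is not square with matching labels")
  }
  m
}
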