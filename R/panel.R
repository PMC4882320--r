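#' Construct a subject panel
#'
#' A subject panel holds the subjects-by-regions matrix of mean regional
#' metabolism values for one group, together with per-subject covariates
#' (age in years, sex as a 0/1 indicator, fasting blood glucose in mmol/L)
#' and a group label.
#'
#' @param values Numeric matrix, subjects in rows, regions in columns;
#'   strictly positive, no missing entries. Column names are region
#'   abbreviations (hemisphere-suffixed), row order defines subject order.
#' @param covariates Data frame with one row per subject and columns `age`,
#'   `sex`, `glucose`.
#' @param group Group label (single string).
#' @param subject_ids Optional subject identifiers (default `S001`, ...).
#' @return An object of class `subject_panel`.
#' @export
subject_panel <- function(values, covariates, group = "group",
                          subject_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (anyNA(values)) stop("`values` must not contain missing entries")
  if (any(values <= 0)) stop("`values` must be strictly positive")
  if (!is.data.frame(covariates) ||
      !all(c("age", "sex", "glucose") %in% names(covariates))) {
    stop("`covariates` must be a data frame with columns age, sex, glucose")
  }
  if (nrow(covariates) != nrow(values)) {
    stop("covariate rows must align with value rows")
  }
  if (anyNA(covariates[c("age", "sex", "glucose")])) {
    stop("missing covariate values are not allowed")
  }
  if (!all(covariates$sex %in% c(0, 1))) stop("`sex` must be coded 0/1")
  if (is.null(subject_ids)) {
    subject_ids <- sprintf("S%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("R%03d", seq_len(ncol(values)))
  }
  rownames(values) <- subject_ids
  structure(list(values = values,
                 covariates = covariates[c("age", "sex", "glucose")],
                 group = as.character(group)[1],
                 subject_ids = subject_ids),
            class = "subject_panel")
}

#' @export
print.subject_panel <- function(x, ...) {
  cat(sprintf("Subject panel '%s': %d subjects x %d regions\n",
              x$group, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Extract the subjects-by-regions value matrix from a panel-like object
#'
#' @param panel A `subject_panel`, `residual_panel`, or plain matrix.
#' @return Numeric matrix, subjects in rows.
#' @export
panel_values <- function(panel) {
  if (inherits(panel, "subject_panel")) return(panel$values)
  if (inherits(panel, "residual_panel")) return(panel$residuals)
  if (is.matrix(panel) && is.numeric(panel)) return(panel)
  stop("cannot extract values from object of class ",
       paste(class(panel), collapse = "/"))
}
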