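#' Global-mean normalization of regional metabolism values
#'
#' Divides each subject's regional values by that subject's whole-brain mean
#' (the mean over all regions in the panel), so every output row has mean 1.
#' This removes the per-subject global scaling of PET uptake (injected dose,
#' weight, scanner gain) before inter-regional correlation.
#'
#' @param panel A `subject_panel` with strictly positive values.
#' @return A `subject_panel` whose rows each have mean 1.
#' @export
global_normalize <- function(panel) {
  stopifnot(inherits(panel, "subject_panel"))
  v <- panel$values
  gm <- rowMeans(v)
  if (any(!is.finite(gm)) || any(gm <= 0)) {
    stop("non-positive whole-brain mean for subject(s): ",
         paste(panel$subject_ids[gm <= 0], collapse = ", "))
  }
  out <- panel
  out$values <- v / gm
  out
}

#' Regress covariates out of regional values
#'
#' Fits, for every region, an ordinary-least-squares regression of the
#' (normalized) regional value on an intercept plus the selected per-subject
#' covariates, and keeps the residuals. The residuals replace the regional
#' values in all downstream correlation analysis, so age, sex and blood
#' glucose cannot induce spurious inter-regional correlation.
#'
#' Fitting is per panel (per group) by default: each group's network is
#' built from its own subjects only.
#'
#' @param panel A `subject_panel` (normalize first with
#'   [global_normalize()]).
#' @param covariates Character vector naming the covariates to remove, a
#'   subset of `c("age", "sex", "glucose")`.
#' @return An object of class `residual_panel`: `residuals`
#'   (subjects-by-regions matrix, per-region mean 0), `coefficients`
#'   (regions-by-terms matrix of fitted coefficients), `design` (the model
#'   matrix used), `group`, `subject_ids`.
#' @export
residualize <- function(panel, covariates = c("age", "sex", "glucose")) {
  stopifnot(inherits(panel, "subject_panel"))
  covariates <- match.arg(covariates, c("age", "sex", "glucose"),
                          several.ok = TRUE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(panel$covariates[, covariates, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dropped, collapse = ", "))
  }
  coef <- qr.coef(qrX, panel$values)
  res <- qr.resid(qrX, panel$values)
  colnames(res) <- colnames(panel$values)
  structure(list(residuals = res,
                 coefficients = t(coef),
                 design = X,
                 covariates = covariates,
                 group = panel$group,
                 subject_ids = panel$subject_ids),
            class = "residual_panel")
}

#' @export
print.residual_panel <- function(x, ...) {
  cat(sprintf("Residual panel '%s': %d subjects x %d regions (covariates: %s)\n",
              x$group, nrow(x$residuals), ncol(x$residuals),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

# Normalize + residualize in one step; the standard preprocessing chain.
#' Standard preprocessing chain
#'
#' [global_normalize()] followed by [residualize()].
#'
#' @inheritParams residualize
#' @return A `residual_panel`.
#' @export
preprocess_panel <- function(panel, covariates = c("age", "sex", "glucose")) {
  residualize(global_normalize(panel), covariates = covariates)
}
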