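#' Construct an expression matrix object
#'
#' Thin container for a genes x samples expression matrix with an optional
#' per-sample RNA quality score (RIN analogue) used for sample QC.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param quality optional numeric vector of per-sample quality scores,
#'   length `ncol(values)` (named or positional).
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `quality`.
#' @export
expr_matrix <- function(values, quality = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop2("duplicate gene ids: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop2("duplicate sample ids: ",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  if (!is.null(quality)) {
    if (length(quality) != ncol(values))
      stop2("quality must have one score per sample")
    quality <- stats::setNames(as.numeric(quality), colnames(values))
  }
  structure(list(values = values, quality = quality), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$quality)) "" else " (with quality scores)"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

gene_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

#' Retain samples exceeding a quality threshold
#'
#' Keeps samples whose quality score is strictly greater than `min_quality`
#' (so `min_quality = 6` emulates a "RIN > 6" rule). Sample order is
#' preserved.
#'
#' @param expr an [expr_matrix] with quality scores.
#' @param min_quality numeric threshold; samples with quality strictly above
#'   it are retained.
#' @return a filtered [expr_matrix].
#' @export
filter_by_quality <- function(expr, min_quality) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$quality))
    stop2("filter_by_quality: expression matrix has no quality scores")
  keep <- expr$quality > min_quality
  if (!any(keep))
    stop2("filter_by_quality: no sample passes quality > ", min_quality)
  expr_matrix(expr$values[, keep, drop = FALSE], expr$quality[keep])
}

# Expand a covariate data.frame to a full-rank numeric design matrix with
# intercept; categorical columns become treatment contrasts (drop first
# level). Errors name collinear/constant columns.
covariate_design <- function(covars) {
  covars <- as.data.frame(covars)
  if (ncol(covars) == 0L) stop2("empty covariate table")
  for (nm in names(covars)) {
    v <- covars[[nm]]
    if (is.character(v) || is.logical(v)) covars[[nm]] <- factor(v)
    if (is.factor(covars[[nm]]) && nlevels(droplevels(covars[[nm]])) < 2L)
      stop2("covariate '", nm, "' is constant")
    if (is.numeric(v) && stats::var(v) == 0)
      stop2("covariate '", nm, "' is constant")
  }
  X <- stats::model.matrix(~ ., data = covars)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop2("rank-deficient covariate design; collinear columns: ",
          paste(bad, collapse = ", "))
  }
  X
}

#' Residualize expression on covariates
#'
#' Replaces each gene's expression by the residuals of an ordinary
#' least-squares fit on an intercept plus all covariate columns, removing
#' confounding variation (demographics and similar) before network
#' construction. Genes containing missing values are dropped with a logged
#' count; missing values are not imputed.
#'
#' @param expr an [expr_matrix].
#' @param covars data.frame of covariates, rows aligned with (or named by)
#'   the samples of `expr`. Categorical columns are expanded to indicator
#'   contrasts dropping one level.
#' @return an [expr_matrix] of residuals (each gene has mean zero and is
#'   orthogonal to every covariate column).
#' @export
residualize <- function(expr, covars) {
  stopifnot(inherits(expr, "expr_matrix"))
  covars <- as.data.frame(covars)
  if (!is.null(rownames(covars)) &&
      all(sample_ids(expr) %in% rownames(covars))) {
    covars <- covars[sample_ids(expr), , drop = FALSE]
  } else if (nrow(covars) != ncol(expr$values)) {
    stop2("covariate rows do not match expression samples")
  }
  X <- covariate_design(covars)
  Y <- t(expr$values)                       # samples x genes
  miss <- colSums(is.na(Y)) > 0
  if (any(miss)) {
    log_note("dropped_genes_with_missing", count = sum(miss))
    Y <- Y[, !miss, drop = FALSE]
  }
  if (ncol(Y) == 0L) stop2("no complete genes left to residualize")
  fit <- stats::lm.fit(X, Y)
  res <- t(fit$residuals)
  dimnames(res) <- list(colnames(Y), rownames(Y))
  expr_matrix(res, expr$quality)
}
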