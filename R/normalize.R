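#' Library-size log-normalization
#'
#' Scales each cell to `scale_factor` total counts and applies
#' `log1p` (natural log): `value(g,c) = log1p(count(g,c) / total(c) *
#' scale_factor)`. All-zero cells map to all-zero columns. For any
#' non-empty cell, `sum(expm1(values))` equals `scale_factor`.
#'
#' @param m genes x cells count matrix (post QC).
#' @param scale_factor target per-cell total (default 10000).
#' @return sparse genes x cells matrix of log-normalized values with
#'   attribute `scale_factor`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  tot <- Matrix::colSums(m)
  sf <- ifelse(tot > 0, scale_factor / tot, 0)
  nm <- as_dgc(m) %*% Matrix::Diagonal(x = sf)
  nm <- log1p(nm)
  nm <- as_dgc(nm)
  dimnames(nm) <- dimnames(m)
  attr(nm, "scale_factor") <- scale_factor
  nm
}

#' Regress technical covariates out of normalized expression and scale
#'
#' For each gene, fits ordinary least squares of the log-normalized values
#' on an intercept plus the supplied per-cell covariates (factors expanded
#' to treatment-coded dummies, e.g. the 10x chemistry; numeric covariates
#' such as the number of genes detected taken as-is), replaces the values
#' with the residuals, and standardizes each gene to unit sample variance,
#' clipping at `clip` standard deviations. Constant covariates are dropped
#' with a warning; a rank-deficient design degrades gracefully by dropping
#' the pivoted-out columns.
#'
#' @param nm normalized matrix from [log_normalize()] (genes x cells).
#' @param covariates data.frame with one row per cell, in matrix column
#'   order (typically `chemistry` and `n_genes_detected`).
#' @param clip symmetric bound on standardized values (default 10).
#' @param standardize divide residuals by their sample SD (default TRUE);
#'   set FALSE to inspect raw residuals.
#' @return dense genes x cells matrix of scaled residuals with attribute
#'   `covariates_used` (the retained design columns).
#' @export
regress_covariates <- function(nm, covariates, clip = 10, standardize = TRUE) {
  n <- ncol(nm)
  if (n < 2) stop("need at least 2 cells")
  if (nrow(covariates) != n)
    stop("covariates must have one row per cell")
  covariates <- as.data.frame(covariates)
  for (j in names(covariates))
    if (is.character(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  const <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(const)) {
    warning("dropping constant covariate(s): ",
            paste(names(covariates)[const], collapse = ", "))
    covariates <- covariates[, !const, drop = FALSE]
  }
  X <- if (ncol(covariates))
    stats::model.matrix(~ ., data = covariates)
  else matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning("rank-deficient design; dropping column(s): ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Y <- t(as.matrix(nm))                      # cells x genes
  R <- t(qr.resid(qx, Y))                    # genes x cells residuals
  if (standardize) {
    sds <- sqrt(rowSums(R^2) / (n - 1))
    ok <- sds > 1e-12
    R[ok, ] <- R[ok, , drop = FALSE] / sds[ok]
    R[!ok, ] <- 0
    R[R > clip] <- clip
    R[R < -clip] <- -clip
  }
  dimnames(R) <- dimnames(nm)
  attr(R, "covariates_used") <- setdiff(colnames(X), "(Intercept)")
  R
}

#' Select the top-N most variable genes of a normalized matrix
#'
#' Simple variance ranking on log-normalized values; an optional
#' pre-clustering reduction.
#'
#' @param nm normalized matrix (genes x cells).
#' @param n number of genes to keep.
#' @return character vector of gene symbols, ordered by decreasing
#'   variance.
#' @export
top_variable_genes <- function(nm, n = 2000) {
  mu <- Matrix::rowMeans(nm)
  ex2 <- Matrix::rowMeans(nm^2)
  v <- ex2 - mu^2
  rownames(nm)[order(v, decreasing = TRUE)][seq_len(min(n, nrow(nm)))]
}
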