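#' Differential-expression parameters
#'
#' @param min_pct minimum expressing fraction required of at least one of
#'   the two groups (default 0.25).
#' @param lfc_threshold minimum absolute log2 fold-change (default 0.25).
#' @param alpha FDR level for calling significance (default 0.05).
#' @param pseudocount pseudocount added to delogged means before the
#'   fold-change ratio (default 1).
#' @param pct_side `"either"` gates on the larger of the two groups'
#'   expressing fractions (workflow convention); `"focal"` gates on the
#'   focal group only.
#' @param bh_universe `"all"` corrects over every gene of the matrix,
#'   mirroring the adjusted p-values of the standard single-cell
#'   workflow, which corrects over the full dataset rather than the
#'   handful of genes surviving the fold-change gate; `"gated"` corrects
#'   over the tested genes only. Gating selects extreme genes, so the
#'   narrow universe does not control the false discovery rate.
#' @return list of class `deg_params`.
#' @export
deg_params <- function(min_pct = 0.25, lfc_threshold = 0.25, alpha = 0.05,
                       pseudocount = 1, pct_side = c("either", "focal"),
                       bh_universe = c("all", "gated")) {
  if (min_pct < 0 || min_pct > 1) stop("min_pct must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  structure(list(min_pct = min_pct, lfc_threshold = lfc_threshold,
                 alpha = alpha, pseudocount = pseudocount,
                 pct_side = match.arg(pct_side),
                 bh_universe = match.arg(bh_universe)),
            class = "deg_params")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Computes the Mann-Whitney U statistic from midranks. For small
#' tie-free samples (combined size at most 12) the p-value is exact from
#' the Wilcoxon distribution; otherwise the normal approximation with tie
#' correction and continuity correction is used, the same formulation as
#' `stats::wilcox.test`. When the tie-corrected variance vanishes (all
#' values identical) the p-value is 1.
#'
#' @param x,y non-empty numeric samples.
#' @return list with elements `statistic` (U for `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty")
  z <- c(x, y)
  r <- rank(z)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(z) > 0
  if (!ties && nx + ny <= 12) {
    p <- if (U > nx * ny / 2)
      2 * stats::pwilcox(U - 1, nx, ny, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, nx, ny)
    p <- min(1, p)
  } else {
    mu <- nx * ny / 2
    nt <- table(r)
    n <- nx + ny
    sigma2 <- (nx * ny / 12) * ((n + 1) - sum(nt^3 - nt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- U - mu
      zstat <- (d - sign(d) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(zstat)))
    }
  }
  list(statistic = unname(U), p_value = p)
}

#' Log2 fold-change of delogged mean normalized expression
#'
#' `log2((mean(expm1(group)) + pseudocount) /
#' (mean(expm1(reference)) + pseudocount))`, i.e. the ratio of mean
#' linear-scale normalized expression with a stabilizing pseudocount.
#'
#' @param group,reference non-empty vectors of log1p-normalized values.
#' @param pseudocount positive stabilizer (default 1).
#' @return log2 fold-change (positive = up in `group`).
#' @export
log2_fold_change <- function(group, reference, pseudocount = 1) {
  if (length(group) == 0 || length(reference) == 0)
    stop("both groups must be non-empty")
  log2((mean(expm1(group)) + pseudocount) /
         (mean(expm1(reference)) + pseudocount))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvals p-values in [0, 1].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (length(pvals) && (any(!is.finite(pvals)) ||
                        any(pvals < 0) || any(pvals > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

group_indices <- function(labels, group, reference) {
  labels <- as.character(labels)
  gi <- which(labels == group)
  if (length(gi) == 0) stop("unknown or empty group label: ", group)
  ri <- if (identical(reference, "rest")) which(labels != group)
  else which(labels == reference)
  if (length(ri) == 0)
    stop("unknown or empty reference label: ", reference)
  list(gi = gi, ri = ri)
}

#' Wilcoxon marker detection between a group and a reference
#'
#' Computes per-gene expressing fractions and log2 fold-changes of
#' delogged means, gates genes on the expressing-fraction and
#' fold-change thresholds, tests surviving genes with the Wilcoxon
#' rank-sum test on the log-normalized values, and corrects p-values
#' with Benjamini-Hochberg over the universe set by
#' `bh_universe` (all genes of the matrix by default). Records are
#' sorted by decreasing log2 fold-change.
#'
#' @param nm normalized matrix (genes x cells) from [log_normalize()].
#' @param labels cluster/cell-type label per cell, aligned to columns.
#' @param group focal label.
#' @param reference `"rest"` (all other cells) or an explicit label.
#' @param params a [deg_params()].
#' @return data.frame with columns `gene`, `group`, `reference`,
#'   `avg_log2fc`, `pct_in`, `pct_out`, `p_value`, `q_value`.
#' @export
find_markers <- function(nm, labels, group, reference = "rest",
                         params = deg_params()) {
  if (length(labels) != ncol(nm))
    stop("labels must align to matrix columns")
  ix <- group_indices(labels, group, reference)
  A <- nm[, ix$gi, drop = FALSE]
  B <- nm[, ix$ri, drop = FALSE]
  pct_in <- as.numeric(Matrix::rowSums(A > 0)) / ncol(A)
  pct_out <- as.numeric(Matrix::rowSums(B > 0)) / ncol(B)
  mA <- as.numeric(Matrix::rowMeans(expm1(A)))
  mB <- as.numeric(Matrix::rowMeans(expm1(B)))
  lfc <- log2((mA + params$pseudocount) / (mB + params$pseudocount))
  pct_gate <- if (params$pct_side == "either") pmax(pct_in, pct_out) else pct_in
  gate <- pct_gate >= params$min_pct & abs(lfc) > params$lfc_threshold
  idx <- which(gate)
  empty <- data.frame(gene = character(0), group = character(0),
                      reference = character(0), avg_log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(idx) == 0) return(empty)
  Ad <- as.matrix(A[idx, , drop = FALSE])
  Bd <- as.matrix(B[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(i)
    wilcoxon_rank_sum(Ad[i, ], Bd[i, ])$p_value, numeric(1))
  m_tests <- if (params$bh_universe == "all") nrow(nm) else length(p)
  out <- data.frame(gene = rownames(nm)[idx], group = group,
                    reference = if (identical(reference, "rest")) "rest"
                    else reference,
                    avg_log2fc = lfc[idx], pct_in = pct_in[idx],
                    pct_out = pct_out[idx], p_value = p,
                    q_value = stats::p.adjust(p, "BH", n = m_tests),
                    stringsAsFactors = FALSE)
  out[order(out$avg_log2fc, decreasing = TRUE), , drop = FALSE]
}

#' One-vs-rest marker detection for every cluster
#'
#' Applies [find_markers()] with reference `"rest"` to each label in
#' turn. A matrix with a single label yields an empty table (there is no
#' rest to compare against).
#'
#' @inheritParams find_markers
#' @return data.frame keyed by (`group`, `gene`).
#' @export
find_all_markers <- function(nm, labels, params = deg_params()) {
  groups <- unique(as.character(labels))
  if (length(groups) < 2)
    return(data.frame(gene = character(0), group = character(0),
                      reference = character(0), avg_log2fc = numeric(0),
                      pct_in = numeric(0), pct_out = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE))
  res <- lapply(sort(groups), function(g)
    find_markers(nm, labels, g, "rest", params))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Dot-plot statistics: mean expression and expressing fraction
#'
#' For each (cluster, gene), the mean log-normalized expression over all
#' cells of the cluster and the fraction of those cells with non-zero
#' expression. Genes absent from the matrix are dropped with a warning.
#'
#' @inheritParams find_markers
#' @param genes gene symbols to summarize.
#' @return data.frame with columns `cluster`, `gene`, `mean_expr`,
#'   `pct_expr`.
#' @export
dotplot_stats <- function(nm, labels, genes) {
  missing <- setdiff(genes, rownames(nm))
  if (length(missing)) {
    warning("gene(s) absent from matrix, omitted: ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  clusters <- sort(unique(as.character(labels)))
  out <- expand.grid(cluster = clusters, gene = genes,
                     stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)[, c("cluster", "gene")]
  out$mean_expr <- NA_real_
  out$pct_expr <- NA_real_
  for (cl in clusters) {
    cells <- which(labels == cl)
    sub <- nm[genes, cells, drop = FALSE]
    rows <- out$cluster == cl
    out$mean_expr[rows] <- as.numeric(Matrix::rowMeans(sub))[
      match(out$gene[rows], genes)]
    out$pct_expr[rows] <- (as.numeric(Matrix::rowSums(sub > 0)) /
                             length(cells))[match(out$gene[rows], genes)]
  }
  out
}
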