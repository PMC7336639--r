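#' Receptors differentially expressed in a focal population
#'
#' Gates the receptor universe of a ligand-receptor table on one-vs-rest
#' differential expression in the focal population: a receptor is kept
#' when it passes [find_markers()] with `q_value < alpha` and positive
#' log2 fold-change. With `pairwise_all = TRUE` the receptor must instead
#' be significantly up in the focal population against every other
#' population individually.
#'
#' @param nm normalized matrix (genes x cells).
#' @param labels cell-type label per cell.
#' @param focal focal (receptor-side) population.
#' @param receptor_universe receptor gene symbols from the pair table.
#' @param params a [deg_params()].
#' @param pairwise_all require a win in every pairwise comparison rather
#'   than a single one-vs-rest test (default FALSE).
#' @return character vector of gated receptor symbols.
#' @export
de_receptors <- function(nm, labels, focal, receptor_universe,
                         params = deg_params(), pairwise_all = FALSE) {
  universe <- intersect(unique(toupper(receptor_universe)), rownames(nm))
  if (length(universe) == 0) {
    warning("no receptor of the universe is present in the matrix")
    return(character(0))
  }
  pass_set <- function(deg) {
    hit <- deg$gene %in% universe & deg$q_value < params$alpha &
      deg$avg_log2fc > 0
    deg$gene[hit]
  }
  if (!pairwise_all)
    return(pass_set(find_markers(nm, labels, focal, "rest", params)))
  others <- setdiff(unique(as.character(labels)), focal)
  sets <- lapply(others, function(o)
    pass_set(find_markers(nm, labels, focal, o, params)))
  Reduce(intersect, sets, universe)
}

#' Score ligand-receptor interactions against every sending cell type
#'
#' For each ligand-receptor pair whose receptor passed the differential-
#' expression gate in the focal population, and for each other
#' (ligand-sending) cell type, the raw interaction score is the product
#' of the mean receptor expression over focal cells and the mean ligand
#' expression over sender cells (means of log1p-normalized values).
#'
#' @param nm normalized matrix (genes x cells).
#' @param labels cell-type label per cell.
#' @param focal receptor-side population.
#' @param gated_receptors receptors retained by [de_receptors()].
#' @param pairs pair table from [read_lr_table()].
#' @param include_autocrine also score the focal population as its own
#'   sender (default FALSE: the model considers ligands from other cell
#'   types).
#' @param all_pairs score every pair with both genes present, not only
#'   gated receptors; the `receptor_de` column then records gate
#'   membership (default FALSE).
#' @return data.frame with columns `pair_name`, `ligand`, `receptor`,
#'   `focal`, `sender`, `raw_score`, `z_score` (NA until
#'   [zscore_rows()]), `ligand_de` (NA until
#'   [flag_ligand_specificity()]), `receptor_de`.
#' @export
score_interactions <- function(nm, labels, focal, gated_receptors, pairs,
                               include_autocrine = FALSE,
                               all_pairs = FALSE) {
  labels <- as.character(labels)
  if (!focal %in% labels) stop("unknown focal population: ", focal)
  keep <- pairs$ligand %in% rownames(nm) & pairs$receptor %in% rownames(nm)
  pairs <- pairs[keep, , drop = FALSE]
  if (!all_pairs)
    pairs <- pairs[pairs$receptor %in% gated_receptors, , drop = FALSE]
  empty <- data.frame(pair_name = character(0), ligand = character(0),
                      receptor = character(0), focal = character(0),
                      sender = character(0), raw_score = numeric(0),
                      z_score = numeric(0), ligand_de = logical(0),
                      receptor_de = logical(0), stringsAsFactors = FALSE)
  senders <- unique(labels)
  if (!include_autocrine) senders <- setdiff(senders, focal)
  senders <- sort(senders)
  if (nrow(pairs) == 0 || length(senders) == 0) return(empty)

  need <- unique(c(pairs$ligand, pairs$receptor))
  sub <- nm[need, , drop = FALSE]
  type_means <- vapply(c(focal, senders), function(ct)
    as.numeric(Matrix::rowMeans(sub[, labels == ct, drop = FALSE])),
    numeric(length(need)))
  if (length(need) == 1)
    type_means <- matrix(type_means, nrow = 1,
                         dimnames = list(need, c(focal, senders)))
  else rownames(type_means) <- need

  rec_mean <- type_means[pairs$receptor, focal]
  out <- do.call(rbind, lapply(senders, function(s)
    data.frame(pair_name = pairs$pair_name, ligand = pairs$ligand,
               receptor = pairs$receptor, focal = focal, sender = s,
               raw_score = rec_mean * type_means[pairs$ligand, s],
               z_score = NA_real_, ligand_de = NA,
               receptor_de = pairs$receptor %in% gated_receptors,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$pair_name, out$sender), , drop = FALSE]
}

#' Row-standardize interaction scores across senders
#'
#' Within each (pair, focal population) row of the interaction table, the
#' z-score is `(raw - row mean) / row sample SD` (divisor n - 1) across
#' the sending cell types. Constant or singleton rows get z-score 0
#' everywhere.
#'
#' @param table interaction table from [score_interactions()].
#' @return The table with `z_score` filled.
#' @export
zscore_rows <- function(table) {
  if (nrow(table) == 0) return(table)
  key <- paste(table$pair_name, table$focal, sep = "\r")
  for (k in unique(key)) {
    i <- which(key == k)
    x <- table$raw_score[i]
    s <- stats::sd(x)
    table$z_score[i] <- if (length(i) < 2 || !is.finite(s) || s == 0)
      0 else (x - mean(x)) / s
  }
  table
}

#' Flag ligand specificity of scored interactions
#'
#' Marks an interaction's `ligand_de` TRUE when the sending cell type
#' expresses the ligand differentially: the ligand passes
#' [find_markers()] (sender vs rest) with `q_value < alpha` and positive
#' fold-change. Such interactions are likely cell-type specific.
#'
#' @param table interaction table from [score_interactions()].
#' @param nm normalized matrix (genes x cells).
#' @param labels cell-type label per cell.
#' @param params a [deg_params()].
#' @return The table with `ligand_de` filled.
#' @export
flag_ligand_specificity <- function(table, nm, labels,
                                    params = deg_params()) {
  if (nrow(table) == 0) return(table)
  for (s in unique(table$sender)) {
    deg <- find_markers(nm, labels, s, "rest", params)
    up <- deg$gene[deg$q_value < params$alpha & deg$avg_log2fc > 0]
    i <- table$sender == s
    table$ligand_de[i] <- table$ligand[i] %in% up
  }
  table
}

#' Rank differentially expressed receptors between two subpopulations
#'
#' Intersects a two-group differential-expression table (e.g. MuSC1 vs
#' MuSC2) with the receptor universe and ranks by log2 fold-change,
#' flagging FDR significance. Positive fold-changes are up in the first
#' (focal A) group.
#'
#' @param deg output of [find_markers()] between exactly two populations.
#' @param receptor_universe receptor gene symbols.
#' @param alpha FDR significance cutoff (default 0.05).
#' @return data.frame with columns `gene`, `avg_log2fc`, `q_value`,
#'   `significant`, sorted by decreasing fold-change.
#' @export
rank_de_receptors <- function(deg, receptor_universe, alpha = 0.05) {
  universe <- unique(toupper(receptor_universe))
  out <- deg[deg$gene %in% universe,
             c("gene", "avg_log2fc", "q_value"), drop = FALSE]
  out <- out[order(out$avg_log2fc, decreasing = TRUE), , drop = FALSE]
  out$significant <- out$q_value < alpha
  rownames(out) <- NULL
  out
}

#' Export chord-diagram edges for scored interaction tables
#'
#' Flattens one or more interaction tables (typically one per focal
#' population, optionally scored with `all_pairs = TRUE` so interactions
#' not involving a gated receptor can be drawn in gray) into a single
#' edge list for chord-diagram rendering. The `significant` column marks
#' edges whose receptor passed the differential-expression gate.
#'
#' @param tables one interaction table or a list of them.
#' @param path optional output TSV path.
#' @return data.frame with columns `sender`, `receiver`, `ligand`,
#'   `receptor`, `raw_score`, `z_score`, `significant`.
#' @export
export_chord_edges <- function(tables, path = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  edges <- do.call(rbind, lapply(tables, function(tb)
    data.frame(sender = tb$sender, receiver = tb$focal, ligand = tb$ligand,
               receptor = tb$receptor, raw_score = tb$raw_score,
               z_score = tb$z_score, significant = tb$receptor_de,
               stringsAsFactors = FALSE)))
  if (is.null(edges))
    edges <- data.frame(sender = character(0), receiver = character(0),
                        ligand = character(0), receptor = character(0),
                        raw_score = numeric(0), z_score = numeric(0),
                        significant = logical(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edges
}

#' Full ligand-receptor analysis for one focal population
#'
#' Convenience wrapper: gate receptors by differential expression in the
#' focal population, score all pairs with gated receptors against every
#' sender, row-standardize, and flag ligand specificity.
#'
#' @inheritParams score_interactions
#' @param pairs pair table from [read_lr_table()].
#' @param params a [deg_params()].
#' @return list with `receptors` (gated set) and `scores` (completed
#'   interaction table).
#' @export
lr_analysis <- function(nm, labels, focal, pairs, params = deg_params(),
                        include_autocrine = FALSE) {
  gated <- de_receptors(nm, labels, focal, unique(pairs$receptor), params)
  tab <- score_interactions(nm, labels, focal, gated, pairs,
                            include_autocrine = include_autocrine)
  tab <- zscore_rows(tab)
  tab <- flag_ligand_specificity(tab, nm, labels, params)
  list(receptors = gated, scores = tab)
}
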