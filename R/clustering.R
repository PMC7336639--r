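#' Clustering parameters
#'
#' @param n_pcs number of principal components (default 30).
#' @param k_neighbors neighbors per cell, including the cell itself
#'   (default 20).
#' @param snn_prune Jaccard cutoff below or at which shared-nearest-
#'   neighbor edges are removed (default 1/15).
#' @param resolution modularity resolution parameter (default 0.4).
#' @param seed RNG seed for community detection.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(n_pcs = 30, k_neighbors = 20, snn_prune = 1 / 15,
                           resolution = 0.4, seed = 0) {
  if (k_neighbors < 1) stop("k_neighbors must be >= 1")
  if (resolution <= 0) stop("resolution must be > 0")
  if (snn_prune < 0 || snn_prune > 1) stop("snn_prune must be in [0, 1]")
  structure(list(n_pcs = n_pcs, k_neighbors = k_neighbors,
                 snn_prune = snn_prune, resolution = resolution, seed = seed),
            class = "cluster_params")
}

#' Principal-component embedding of cells
#'
#' Computes the top principal components of the cells (rows of the
#' transposed scaled matrix). Component signs are fixed by making the
#' largest-magnitude gene loading positive, so the embedding is
#' reproducible across platforms.
#'
#' @param sm scaled matrix (genes x cells) from [regress_covariates()].
#' @param n_pcs number of components; clamped with a warning when it
#'   exceeds the matrix rank bound.
#' @param seed RNG seed (kept for interface stability; the exact solver
#'   is deterministic).
#' @return cells x n_pcs matrix of component scores.
#' @export
embed_pca <- function(sm, n_pcs = 30, seed = 0) {
  if (ncol(sm) < 2) stop("need at least 2 cells")
  max_pcs <- min(nrow(sm), ncol(sm))
  if (n_pcs > max_pcs) {
    warning("n_pcs clamped from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  set.seed(seed)
  pc <- stats::prcomp(t(as.matrix(sm)), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  emb <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- colnames(sm)
  emb
}

# exact k-nearest neighbors (Euclidean, self included), computed in row
# blocks to bound memory; ties broken by cell index for determinism
knn_indices <- function(emb, k, block = 1024L) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * emb[rows, , drop = FALSE] %*% t(emb)
    for (r in seq_along(rows))
      idx[rows[r], ] <- order(d2[r, ])[seq_len(k)]
  }
  idx
}

#' Shared-nearest-neighbor graph over cells
#'
#' Finds each cell's `k_neighbors` nearest neighbors (Euclidean distance
#' in the embedding; neighbor sets include the cell itself), weights the
#' edge between two cells by the Jaccard overlap of their neighbor sets,
#' and removes edges with weight at or below `snn_prune`.
#'
#' @param embedding cells x components matrix from [embed_pca()].
#' @param params a [cluster_params()].
#' @return weighted undirected `igraph` graph whose vertices are cells.
#' @export
build_snn_graph <- function(embedding, params = cluster_params()) {
  n <- nrow(embedding)
  k <- params$k_neighbors
  if (n < k + 1) stop("need at least k_neighbors + 1 cells")
  nn <- knn_indices(embedding, k)
  N <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn),
                            x = 1, dims = c(n, n))
  S <- Matrix::tcrossprod(N)                 # shared-neighbor counts
  S <- as_dgc(S)
  jac <- S
  methods::slot(jac, "x") <- methods::slot(S, "x") /
    (2 * k - methods::slot(S, "x"))
  jac <- jac * (jac > params$snn_prune)
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  dimnames(jac) <- list(rownames(embedding), rownames(embedding))
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Modularity community detection on the SNN graph
#'
#' Leiden communities under the modularity objective with a resolution
#' parameter. Cluster ids are consecutive integers starting at 1, ordered
#' by decreasing cluster size (ties by first occurrence).
#'
#' @param graph weighted undirected graph from [build_snn_graph()].
#' @param resolution modularity resolution (default 0.4).
#' @param seed RNG seed; fixed before detection so labels are
#'   reproducible.
#' @return integer vector of cluster ids, named by cell when the graph
#'   has vertex names.
#' @export
cluster_graph <- function(graph, resolution = 0.4, seed = 0) {
  nv <- igraph::vcount(graph)
  if (nv == 0) return(integer(0))
  set.seed(seed)
  w <- igraph::E(graph)$weight
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               weights = w, resolution = resolution,
                               n_iterations = 10)
  mem <- as.integer(igraph::membership(cl))
  sizes <- tabulate(mem)
  relabel <- integer(length(sizes))
  relabel[order(-sizes)] <- seq_along(sizes)
  out <- relabel[mem]
  nm <- igraph::V(graph)$name
  if (!is.null(nm)) names(out) <- nm
  out
}

#' End-to-end clustering of a scaled matrix
#'
#' Convenience wrapper chaining [embed_pca()], [build_snn_graph()] and
#' [cluster_graph()].
#'
#' @param sm scaled matrix (genes x cells).
#' @param params a [cluster_params()].
#' @return integer cluster ids named by cell barcode.
#' @export
cluster_cells <- function(sm, params = cluster_params()) {
  emb <- embed_pca(sm, params$n_pcs, params$seed)
  g <- build_snn_graph(emb, params)
  cluster_graph(g, params$resolution, params$seed)
}

#' Read a cell-type marker table
#'
#' TSV with header columns `cell_type` and `markers`, the latter a
#' comma-separated gene-symbol list.
#'
#' @param file path to the marker TSV.
#' @return named list: cell type -> character vector of marker symbols.
#' @export
read_marker_table <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  if (!all(c("cell_type", "markers") %in% names(tab)))
    stop("marker table must have columns 'cell_type' and 'markers'")
  stats::setNames(lapply(strsplit(tab$markers, ","), function(x)
    toupper(trimws(x))), tab$cell_type)
}

#' Annotate clusters with cell-type names via marker expression
#'
#' Scores each cell type in each cluster as the mean over its marker
#' genes of the per-gene mean log-normalized expression in the cluster,
#' and assigns the argmax type. Ties are broken alphabetically with a
#' warning; marker genes absent from the matrix are dropped with a
#' warning, and a cell type with no marker present is an error.
#'
#' @param nm normalized matrix (genes x cells) from [log_normalize()].
#' @param cluster_ids cluster id per cell, aligned to the matrix columns.
#' @param markers named list: cell type -> marker gene symbols.
#' @return named character vector: cluster id -> cell-type name.
#' @export
annotate_clusters <- function(nm, cluster_ids, markers) {
  if (length(markers) == 0) stop("marker set is empty")
  if (length(cluster_ids) != ncol(nm))
    stop("cluster_ids must align to matrix columns")
  markers <- markers[order(names(markers))]
  present <- lapply(names(markers), function(ct) {
    got <- intersect(markers[[ct]], rownames(nm))
    if (length(got) == 0)
      stop("no marker gene of cell type '", ct, "' present in matrix")
    if (length(got) < length(markers[[ct]]))
      warning("missing marker gene(s) for '", ct, "': ",
              paste(setdiff(markers[[ct]], got), collapse = ", "))
    got
  })
  names(present) <- names(markers)
  clusters <- sort(unique(cluster_ids))
  out <- vapply(clusters, function(cl) {
    cells <- which(cluster_ids == cl)
    score <- vapply(present, function(genes)
      mean(Matrix::rowMeans(nm[genes, cells, drop = FALSE])), numeric(1))
    top <- which(score == max(score))
    if (length(top) > 1)
      warning("cluster ", cl, ": tied annotation scores; choosing '",
              names(present)[top[1]], "' alphabetically")
    names(present)[top[1]]
  }, character(1))
  stats::setNames(out, clusters)
}
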