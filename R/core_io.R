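#' Validate a gene-by-cell UMI count matrix
#'
#' A count matrix is a sparse (or dense) genes-by-cells matrix of raw UMI
#' counts with unique uppercase gene symbols as row names and unique cell
#' barcodes as column names. All entries must be non-negative integers.
#'
#' @param m matrix-like object to validate.
#' @return `m` invisibly, if valid; otherwise an error is thrown.
#' @export
validate_counts <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene symbols as rownames and barcodes as colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene symbols in count matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicate cell barcodes in count matrix")
  x <- if (methods::is(m, "sparseMatrix")) methods::slot(as_dgc(m), "x") else as.numeric(m)
  if (length(x)) {
    if (any(x < 0)) stop("negative entry in count matrix")
    if (any(x != round(x))) stop("non-integer entry in count matrix")
  }
  invisible(m)
}

# coerce any Matrix / base matrix to dgCMatrix
as_dgc <- function(m) {
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

#' Read a 10x-style Matrix Market count directory
#'
#' Expects a directory holding a Matrix Market triplet file (`matrix.mtx`),
#' a gene file (`genes.tsv` or `features.tsv`, 1-3 columns; the symbol
#' column is the last of the first two) and a `barcodes.tsv` file. Gene
#' symbols are uppercased; duplicate symbols are collapsed by summing
#' their counts.
#'
#' @param dir_path directory containing `matrix.mtx`, `genes.tsv` (or
#'   `features.tsv`) and `barcodes.tsv`.
#' @return A `dgCMatrix` of raw UMI counts, genes x cells.
#' @export
read_counts_mtx <- function(dir_path) {
  if (!dir.exists(dir_path)) stop("directory not found: ", dir_path)
  mtx <- file.path(dir_path, "matrix.mtx")
  gfile <- file.path(dir_path, "genes.tsv")
  if (!file.exists(gfile)) gfile <- file.path(dir_path, "features.tsv")
  bfile <- file.path(dir_path, "barcodes.tsv")
  for (f in c(mtx, gfile, bfile))
    if (!file.exists(f)) stop("missing file: ", f)

  m <- Matrix::readMM(mtx)
  genes_tab <- utils::read.table(gfile, sep = "\t", header = FALSE,
                                 stringsAsFactors = FALSE, quote = "")
  # CellRanger v2: <id> <symbol>; v3 adds a feature-type column; a bare
  # one-column symbol list is also accepted.
  genes <- toupper(genes_tab[[min(ncol(genes_tab), 2L)]])
  barcodes <- utils::read.table(bfile, sep = "\t", header = FALSE,
                                stringsAsFactors = FALSE, quote = "")[[1]]
  if (nrow(m) != length(genes))
    stop("matrix header reports ", nrow(m), " genes but gene file has ",
         length(genes))
  if (ncol(m) != length(barcodes))
    stop("matrix header reports ", ncol(m), " cells but barcode file has ",
         length(barcodes))
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", bfile)
  x <- methods::slot(as_dgc(m), "x")
  if (length(x) && any(x < 0)) stop("negative entry in ", mtx)
  if (length(x) && any(x != round(x))) stop("non-integer entry in ", mtx)

  m <- as_dgc(m)
  if (anyDuplicated(genes)) {
    keep <- unique(genes)
    fac <- factor(genes, levels = keep)
    ind <- Matrix::sparseMatrix(i = as.integer(fac), j = seq_along(genes),
                                x = 1, dims = c(length(keep), length(genes)))
    m <- as_dgc(ind %*% m)
    genes <- keep
  }
  dimnames(m) <- list(genes, barcodes)
  validate_counts(m)
  m
}

#' Write a count matrix as Matrix Market triplets plus gene/barcode lists
#'
#' Emits `matrix.mtx`, `genes.tsv` (two identical symbol columns, matching
#' the CellRanger v2 layout) and `barcodes.tsv` under `dir_path`, readable
#' back with [read_counts_mtx()].
#'
#' @param m genes x cells count matrix with dimnames.
#' @param dir_path output directory (created if absent).
#' @return `dir_path` invisibly.
#' @export
write_counts_mtx <- function(m, dir_path) {
  validate_counts(m)
  if (!dir.exists(dir_path) &&
      !dir.create(dir_path, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dir_path)
  Matrix::writeMM(as_dgc(m), file.path(dir_path, "matrix.mtx"))
  utils::write.table(data.frame(id = rownames(m), symbol = rownames(m)),
                     file.path(dir_path, "genes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(colnames(m), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a ligand-receptor pair table
#'
#' Accepts tab- or comma-delimited tables with either explicit
#' `ligand`/`receptor` columns (case-insensitive), Ramilowski-style
#' `Ligand.ApprovedSymbol`/`Receptor.ApprovedSymbol` columns, or a
#' `Pair.Name` column in `LIGAND_RECEPTOR` form. Symbols are uppercased
#' and pairs deduplicated; self-pairs are kept as given. Symbols are taken
#' verbatim unless an alias map is supplied (some databases mix synonyms,
#' e.g. TWEAK for TNFSF12).
#'
#' @param file path to the delimited pair table.
#' @param alias_map optional named character vector mapping symbols to
#'   replacements, applied to both columns before deduplication.
#' @return data.frame with columns `ligand`, `receptor`, `pair_name`.
#' @export
read_lr_table <- function(file, alias_map = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  first <- readLines(file, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(file, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = TRUE, comment.char = "")
  lc <- tolower(names(tab))
  if (all(c("ligand", "receptor") %in% lc)) {
    lig <- tab[[match("ligand", lc)]]
    rec <- tab[[match("receptor", lc)]]
  } else if (all(c("ligand.approvedsymbol", "receptor.approvedsymbol") %in% lc)) {
    lig <- tab[[match("ligand.approvedsymbol", lc)]]
    rec <- tab[[match("receptor.approvedsymbol", lc)]]
  } else if ("pair.name" %in% lc) {
    parts <- strsplit(tab[[match("pair.name", lc)]], "_", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed Pair.Name entries: ",
                       paste(utils::head(tab[[match("pair.name", lc)]][bad], 3),
                             collapse = ", "))
    lig <- vapply(parts, `[`, "", 1L)
    rec <- vapply(parts, `[`, "", 2L)
  } else {
    stop("ligand-receptor table must contain 'ligand'/'receptor' columns, ",
         "Ramilowski 'ApprovedSymbol' columns, or a 'Pair.Name' column")
  }
  lig <- toupper(trimws(lig))
  rec <- toupper(trimws(rec))
  if (!is.null(alias_map)) {
    alias_map <- stats::setNames(toupper(alias_map), toupper(names(alias_map)))
    hit <- lig %in% names(alias_map); lig[hit] <- alias_map[lig[hit]]
    hit <- rec %in% names(alias_map); rec[hit] <- alias_map[rec[hit]]
  }
  keep <- !duplicated(paste(lig, rec, sep = "_")) & nzchar(lig) & nzchar(rec)
  out <- data.frame(ligand = lig[keep], receptor = rec[keep],
                    stringsAsFactors = FALSE)
  out$pair_name <- paste(out$ligand, out$receptor, sep = "_")
  out
}
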