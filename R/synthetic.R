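#' Specification for a synthetic multi-donor muscle atlas
#'
#' Describes a negative-binomial UMI count simulation with distinct cell
#' populations, per-population marker genes, mitochondrial genes, donor
#' depth variability, two 10x library chemistries, and optionally planted
#' ligand-receptor circuits. Defaults emulate a ten-donor human muscle
#' atlas: 16 populations including two muscle stem cell (MuSC)
#' subpopulations, roughly 2200 +/- 1900 cells per donor, and v2/v3
#' chemistry split across donors.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor list with `mean` and `sd` of the per-donor cell
#'   count, drawn log-normally (truncated at 0); `sd = 0` gives exactly
#'   `mean` cells per donor.
#' @param n_populations number of cell populations.
#' @param population_names optional character vector of population names;
#'   defaults to muscle cell-type names for up to 16 populations.
#' @param population_proportions simplex vector of expected population
#'   frequencies; defaults to a geometric decay (ratio 0.85) so the atlas
#'   has abundant and rare types, normalized to sum to 1.
#' @param n_genes total number of genes (including mitochondrial genes).
#' @param n_mito_genes number of mitochondrial genes, named with the
#'   `MT-` prefix (13 by default, the protein-coding mtDNA gene count).
#' @param baseline_mean mean UMI per gene per cell on the linear scale.
#' @param nb_dispersion negative-binomial size parameter shared by all
#'   genes.
#' @param marker_genes_per_population markers planted per population.
#' @param marker_log2fc log2 fold elevation of a marker in its population.
#' @param chemistry_effect named multiplicative depth factor per chemistry.
#' @param donor_depth_sd log-scale SD of the per-donor depth factor.
#' @param mito_share share of baseline expression allocated to MT- genes,
#'   so mitochondrial-fraction QC thresholds are exercised on both sides.
#' @param lr_circuits list of circuits, each a list with elements
#'   `ligand`, `receptor` (gene names), `sender`, `receiver` (population
#'   names) and `fold` (multiplicative elevation).
#' @param seed master integer seed; one RNG stream per donor is derived
#'   from it so outputs are stable under donor-count changes.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_donors = 10,
                       cells_per_donor = list(mean = 2206, sd = 1961),
                       n_populations = 16,
                       population_names = NULL,
                       population_proportions = NULL,
                       n_genes = 2000,
                       n_mito_genes = 13,
                       baseline_mean = 1,
                       nb_dispersion = 2,
                       marker_genes_per_population = 5,
                       marker_log2fc = 2,
                       chemistry_effect = c(v2 = 1, v3 = 1.6),
                       donor_depth_sd = 0.3,
                       mito_share = 0.1,
                       lr_circuits = list(),
                       seed = 1) {
  if (is.null(population_names)) {
    defaults <- c("MuSC1", "MuSC2", "Myonuclei", "Fibroblast1", "Fibroblast2",
                  "Fibroblast3", "Adipocyte", "Pericyte", "SmoothMuscle",
                  "Endothelial1", "Endothelial2", "LymphaticEC", "Macrophage",
                  "Tcell", "Bcell", "NKcell")
    population_names <- if (n_populations <= length(defaults))
      defaults[seq_len(n_populations)] else
      sprintf("Pop%02d", seq_len(n_populations))
  }
  if (length(population_names) != n_populations)
    stop("population_names must have length n_populations")
  if (is.null(population_proportions)) {
    population_proportions <- 0.85^(seq_len(n_populations) - 1)
    population_proportions <- population_proportions / sum(population_proportions)
  }
  spec <- list(n_donors = n_donors, cells_per_donor = cells_per_donor,
               n_populations = n_populations,
               population_names = population_names,
               population_proportions = population_proportions,
               n_genes = n_genes, n_mito_genes = n_mito_genes,
               baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
               marker_genes_per_population = marker_genes_per_population,
               marker_log2fc = marker_log2fc,
               chemistry_effect = chemistry_effect,
               donor_depth_sd = donor_depth_sd, mito_share = mito_share,
               lr_circuits = lr_circuits, seed = seed)
  class(spec) <- "synth_spec"
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  with(spec, {
    if (abs(sum(population_proportions) - 1) > 1e-9)
      stop("population_proportions must sum to 1")
    if (any(population_proportions < 0)) stop("negative population proportion")
    if (baseline_mean <= 0) stop("baseline_mean must be > 0")
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
    if (marker_log2fc < 0) stop("marker_log2fc must be >= 0")
    if (n_mito_genes > n_genes) stop("more mitochondrial genes than genes")
    if (n_populations * marker_genes_per_population > n_genes - n_mito_genes)
      stop("more marker genes requested than available genes")
    if (mito_share < 0 || mito_share >= 1) stop("mito_share must be in [0, 1)")
    if (is.null(names(chemistry_effect)))
      stop("chemistry_effect must be a named vector")
  })
  invisible(spec)
}

mito_gene_names <- function(n) {
  canonical <- paste0("MT-", c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6",
                               "CO3", "ND3", "ND4L", "ND4", "ND5", "ND6",
                               "CYB"))
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, sprintf("MT-G%03d", seq_len(n - length(canonical))))
}

#' Elevate marker-gene means in their own population
#'
#' Multiplies each marker gene's mean by `2^marker_log2fc` in its assigned
#' population, leaving all other (gene, population) means unchanged.
#' Marker sets must be disjoint across populations.
#'
#' @param mean_matrix genes x populations matrix of expected means.
#' @param markers named list: population name -> marker gene names.
#' @param marker_log2fc log2 fold elevation.
#' @return The adjusted mean matrix.
#' @export
plant_marker <- function(mean_matrix, markers, marker_log2fc) {
  all_genes <- unlist(markers, use.names = FALSE)
  if (anyDuplicated(all_genes))
    stop("marker gene sets must be disjoint across populations")
  if (!all(all_genes %in% rownames(mean_matrix)))
    stop("marker gene absent from mean matrix")
  if (!all(names(markers) %in% colnames(mean_matrix)))
    stop("marker population absent from mean matrix")
  for (pop in names(markers))
    mean_matrix[markers[[pop]], pop] <-
      mean_matrix[markers[[pop]], pop] * 2^marker_log2fc
  mean_matrix
}

#' Plant a ligand-receptor circuit into a population mean matrix
#'
#' Elevates the ligand mean by `fold` in the sender population and the
#' receptor mean by `fold` in the receiver population. Circuits are applied
#' independently per (gene, population) cell, so repeated elevations of the
#' same cell compound multiplicatively.
#'
#' @param mean_matrix genes x populations matrix of expected means.
#' @param circuit list with `ligand`, `receptor`, `sender`, `receiver`,
#'   `fold`.
#' @return The adjusted mean matrix.
#' @export
plant_lr_circuit <- function(mean_matrix, circuit) {
  need <- c("ligand", "receptor", "sender", "receiver", "fold")
  if (!all(need %in% names(circuit)))
    stop("circuit must have elements ", paste(need, collapse = ", "))
  for (g in c(circuit$ligand, circuit$receptor))
    if (!g %in% rownames(mean_matrix)) stop("unknown circuit gene: ", g)
  for (p in c(circuit$sender, circuit$receiver))
    if (!p %in% colnames(mean_matrix)) stop("unknown circuit population: ", p)
  if (circuit$fold <= 0) stop("circuit fold must be > 0")
  mean_matrix[circuit$ligand, circuit$sender] <-
    mean_matrix[circuit$ligand, circuit$sender] * circuit$fold
  mean_matrix[circuit$receptor, circuit$receiver] <-
    mean_matrix[circuit$receptor, circuit$receiver] * circuit$fold
  mean_matrix
}

# population-level expected mean matrix implied by a spec (before donor
# and chemistry depth factors)
population_mean_matrix <- function(spec) {
  n_mito <- spec$n_mito_genes
  n_other <- spec$n_genes - n_mito
  genes <- c(mito_gene_names(n_mito),
             sprintf("GENE%05d", seq_len(n_other)))
  total <- spec$n_genes * spec$baseline_mean
  mu <- numeric(spec$n_genes)
  if (n_mito > 0) {
    mu[seq_len(n_mito)] <- spec$mito_share * total / n_mito
    mu[(n_mito + 1):spec$n_genes] <- (1 - spec$mito_share) * total / n_other
  } else {
    mu[] <- total / n_other
  }
  M <- matrix(mu, nrow = spec$n_genes, ncol = spec$n_populations,
              dimnames = list(genes, spec$population_names))
  if (spec$marker_genes_per_population > 0) {
    k <- spec$marker_genes_per_population
    markers <- lapply(seq_len(spec$n_populations) - 1L, function(i)
      genes[n_mito + i * k + seq_len(k)])
    names(markers) <- spec$population_names
    M <- plant_marker(M, markers, spec$marker_log2fc)
  } else {
    markers <- stats::setNames(rep(list(character(0)), spec$n_populations),
                               spec$population_names)
  }
  for (circ in spec$lr_circuits) M <- plant_lr_circuit(M, circ)
  list(mean_matrix = M, markers = markers)
}

donor_seed <- function(master, d) (as.integer(master) + 10007L * d) %% 2147483562L

#' Generate a synthetic multi-donor UMI count atlas with ground truth
#'
#' Draws UMI counts from a negative binomial whose mean combines the
#' population baseline, planted markers and ligand-receptor circuits, a
#' log-normal per-donor depth factor, and a per-chemistry depth factor.
#' Each donor has its own RNG stream derived from the master seed, so a
#' given donor's cells are reproducible independently of how many donors
#' are generated.
#'
#' @param spec a [synth_spec()].
#' @return list with elements `counts` (sparse genes x cells matrix),
#'   `meta` (per-cell data.frame: barcode, donor, chemistry, sex, age,
#'   anatomical site) and `truth` (list: `cells` with true population
#'   labels, `markers`, `circuits`, `mean_matrix`).
#' @export
generate_dataset <- function(spec) {
  validate_synth_spec(spec)
  pm <- population_mean_matrix(spec)
  M <- pm$mean_matrix
  genes <- rownames(M)
  chems <- rep(names(spec$chemistry_effect), length.out = max(spec$n_donors, 1))

  sites <- c("quadriceps", "hamstring", "gastrocnemius", "deltoid")
  blocks <- vector("list", spec$n_donors)
  metas <- vector("list", spec$n_donors)
  for (d in seq_len(spec$n_donors)) {
    set.seed(donor_seed(spec$seed, d))
    donor <- sprintf("D%02d", d)
    chem <- chems[d]
    m_cells <- spec$cells_per_donor$mean
    s_cells <- spec$cells_per_donor$sd
    n_cells <- if (m_cells <= 0) 0L else if (s_cells <= 0)
      as.integer(round(m_cells)) else {
      sdlog <- sqrt(log1p((s_cells / m_cells)^2))
      as.integer(round(stats::rlnorm(1, log(m_cells) - sdlog^2 / 2, sdlog)))
    }
    sex <- sample(c("M", "F"), 1)
    age <- sample(20:80, 1)
    site <- sample(sites, 1)
    depth <- stats::rlnorm(1, -spec$donor_depth_sd^2 / 2, spec$donor_depth_sd)
    if (n_cells == 0L) {
      blocks[[d]] <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                          x = numeric(0),
                                          dims = c(spec$n_genes, 0))
      metas[[d]] <- data.frame(barcode = character(0), donor = character(0),
                               chemistry = character(0), sex = character(0),
                               age = integer(0), site = character(0),
                               population = character(0),
                               stringsAsFactors = FALSE)
      next
    }
    pops <- sample(spec$population_names, n_cells, replace = TRUE,
                   prob = spec$population_proportions)
    mu <- M[, pops, drop = FALSE] * depth * spec$chemistry_effect[[chem]]
    cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                 size = spec$nb_dispersion),
                  nrow = spec$n_genes)
    blocks[[d]] <- as_dgc(Matrix::Matrix(cnt, sparse = TRUE))
    barcodes <- sprintf("%s_C%05d", donor, seq_len(n_cells))
    metas[[d]] <- data.frame(barcode = barcodes, donor = donor,
                             chemistry = chem, sex = sex, age = age,
                             site = site, population = pops,
                             stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  rownames(meta) <- NULL
  dimnames(counts) <- list(genes, meta$barcode)

  circuits <- if (length(spec$lr_circuits))
    do.call(rbind, lapply(spec$lr_circuits, function(x)
      data.frame(ligand = x$ligand, receptor = x$receptor,
                 sender = x$sender, receiver = x$receiver, fold = x$fold,
                 stringsAsFactors = FALSE)))
  else data.frame(ligand = character(0), receptor = character(0),
                  sender = character(0), receiver = character(0),
                  fold = numeric(0), stringsAsFactors = FALSE)

  truth <- list(
    cells = meta[, c("barcode", "donor", "chemistry", "population")],
    markers = pm$markers,
    circuits = circuits,
    mean_matrix = M)
  list(counts = counts, meta = meta[, setdiff(names(meta), "population")],
       truth = truth)
}

#' Write a generated dataset to disk
#'
#' Writes the count matrix in the Matrix Market layout of
#' [write_counts_mtx()] plus `meta.tsv`, and the ground truth as
#' `truth_cells.tsv`, `truth_markers.tsv` and `truth_circuits.tsv`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir_path output directory.
#' @return `dir_path` invisibly.
#' @export
write_dataset <- function(dataset, dir_path) {
  write_counts_mtx(dataset$counts, dir_path)
  tsv <- function(x, f) utils::write.table(
    x, file.path(dir_path, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(dataset$meta, "meta.tsv")
  tsv(dataset$truth$cells, "truth_cells.tsv")
  mk <- dataset$truth$markers
  tsv(data.frame(population = rep(names(mk), lengths(mk)),
                 gene = unlist(mk, use.names = FALSE)), "truth_markers.tsv")
  tsv(dataset$truth$circuits, "truth_circuits.tsv")
  invisible(dir_path)
}
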