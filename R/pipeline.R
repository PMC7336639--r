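pipeline_defaults <- function() {
  list(
    input_dir = NULL, lr_table = NULL, marker_file = NULL,
    out_dir = "pipeline_out",
    min_umi = 1000, max_mito_frac = 0.20, min_cells_per_gene = 3,
    mito_prefix = "MT-",
    scale_factor = 10000, clip = 10,
    n_pcs = 30, k_neighbors = 20, snn_prune = 1 / 15, resolution = 0.4,
    min_pct = 0.25, lfc_threshold = 0.25, alpha = 0.05, pseudocount = 1,
    focal = character(0),
    simulate = list(),
    seed = 1)
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML key-value configuration, fills in the documented defaults
#' (UMI cutoff 1000, mitochondrial fraction 0.20, clustering resolution
#' 0.4, expressing-fraction gate 0.25, FDR level 0.05), and range-checks
#' every threshold. Unknown keys are errors.
#'
#' @param file path to a YAML config file; an empty file yields all
#'   defaults.
#' @return validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  user <- yaml::read_yaml(file)
  if (is.null(user)) user <- list()
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  check <- function(ok, key, what)
    if (!ok) stop("config key '", key, "' ", what)
  check(cfg$max_mito_frac >= 0 && cfg$max_mito_frac <= 1,
        "max_mito_frac", "must be in [0, 1]")
  check(cfg$min_umi >= 0, "min_umi", "must be >= 0")
  check(cfg$min_cells_per_gene >= 0, "min_cells_per_gene", "must be >= 0")
  check(cfg$scale_factor > 0, "scale_factor", "must be > 0")
  check(cfg$resolution > 0, "resolution", "must be > 0")
  check(cfg$k_neighbors >= 1, "k_neighbors", "must be >= 1")
  check(cfg$snn_prune >= 0 && cfg$snn_prune <= 1,
        "snn_prune", "must be in [0, 1]")
  check(cfg$min_pct >= 0 && cfg$min_pct <= 1, "min_pct", "must be in [0, 1]")
  check(cfg$alpha > 0 && cfg$alpha < 1, "alpha", "must be in (0, 1)")
  check(cfg$pseudocount > 0, "pseudocount", "must be > 0")
  check(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed",
        "must be a single integer")
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, msg, verbose)
  if (verbose) message(sprintf("[%s] %s", stage, msg))

#' Run the full atlas pipeline
#'
#' Executes load-or-simulate, QC, normalization, covariate scaling,
#' clustering with optional marker annotation, one-vs-rest marker
#' detection (plus a focal-vs-focal comparison when two focal populations
#' are configured), and ligand-receptor scoring for each focal
#' population. Every stage writes its table under `out_dir`, and a
#' `manifest.json` records parameters, seed, per-stage outputs and their
#' MD5 checksums. With `resume = TRUE` a stage whose outputs already
#' exist is loaded from disk instead of recomputed.
#'
#' @param config a `pipeline_config` from [validate_config()], or a list
#'   overriding the documented defaults.
#' @param resume reuse existing stage outputs (default FALSE).
#' @param verbose log stage progress (default TRUE).
#' @return list with `manifest` (also written as JSON) and the in-memory
#'   results (`counts`, `qc`, `clusters`, `markers`, `lr`).
#' @export
run_pipeline <- function(config = list(), resume = FALSE, verbose = TRUE) {
  cfg <- pipeline_defaults()
  if (inherits(config, "pipeline_config")) cfg <- unclass(config)
  else {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
  }
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages_run <- character(0)
  tsv <- function(x, f) utils::write.table(
    x, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)

  # -- stage 1: load or simulate ------------------------------------------
  data_dir <- file.path(out, "counts")
  truth <- NULL
  if (!is.null(cfg$input_dir)) {
    counts <- read_counts_mtx(cfg$input_dir)
    meta_file <- file.path(cfg$input_dir, "meta.tsv")
    meta <- if (file.exists(meta_file))
      utils::read.table(meta_file, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
    else data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
    stage_log("load", sprintf("%d genes x %d cells from %s", nrow(counts),
                              ncol(counts), cfg$input_dir), verbose)
  } else if (resume && dir.exists(data_dir)) {
    counts <- read_counts_mtx(data_dir)
    meta <- utils::read.table(file.path(data_dir, "meta.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    truth_file <- file.path(data_dir, "truth_cells.tsv")
    if (file.exists(truth_file))
      truth <- list(cells = utils::read.table(truth_file, sep = "\t",
                                              header = TRUE,
                                              stringsAsFactors = FALSE))
    stage_log("simulate", "reusing cached synthetic dataset", verbose)
  } else {
    spec <- do.call(synth_spec, c(cfg$simulate,
                                  if (!"seed" %in% names(cfg$simulate))
                                    list(seed = cfg$seed)))
    ds <- generate_dataset(spec)
    write_dataset(ds, data_dir)
    counts <- ds$counts; meta <- ds$meta; truth <- ds$truth
    stages_run <- c(stages_run, "simulate")
    stage_log("simulate", sprintf("%d genes x %d cells, %d donors",
                                  nrow(counts), ncol(counts),
                                  spec$n_donors), verbose)
  }

  # -- stage 2: QC --------------------------------------------------------
  qp <- qc_params(cfg$min_umi, cfg$max_mito_frac, cfg$min_cells_per_gene,
                  cfg$mito_prefix)
  qc <- compute_cell_qc(counts, qp)
  filtered <- apply_qc_filters(counts, qc, qp)
  qc$pass <- qc$barcode %in% colnames(filtered)
  tsv(qc, "qc_report.tsv")
  stages_run <- c(stages_run, "qc")
  stage_log("qc", sprintf("retained %d/%d cells, %d/%d genes",
                          ncol(filtered), ncol(counts), nrow(filtered),
                          nrow(counts)), verbose)

  # -- stage 3: normalize + scale ----------------------------------------
  nm <- log_normalize(filtered, cfg$scale_factor)
  covs <- data.frame(n_genes_detected =
                       qc$n_genes_detected[match(colnames(nm), qc$barcode)])
  if ("chemistry" %in% names(meta))
    covs$chemistry <- meta$chemistry[match(colnames(nm), meta$barcode)]
  sm <- regress_covariates(nm, covs, clip = cfg$clip)
  stages_run <- c(stages_run, "normalize")
  stage_log("normalize", sprintf("scaled %d genes, covariates: %s",
                                 nrow(sm),
                                 paste(attr(sm, "covariates_used"),
                                       collapse = ", ")), verbose)

  # -- stage 4: cluster + annotate ---------------------------------------
  cl_file <- file.path(out, "clusters.tsv")
  if (resume && file.exists(cl_file)) {
    cl_tab <- utils::read.table(cl_file, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    cl_tab <- cl_tab[match(colnames(nm), cl_tab$barcode), , drop = FALSE]
    stage_log("cluster", "reusing cached cluster assignments", verbose)
  } else {
    cp <- cluster_params(cfg$n_pcs, cfg$k_neighbors, cfg$snn_prune,
                         cfg$resolution, cfg$seed)
    ids <- cluster_cells(sm, cp)
    cl_tab <- data.frame(barcode = colnames(nm), cluster = as.integer(ids),
                         stringsAsFactors = FALSE)
    if (!is.null(cfg$marker_file)) {
      markers <- read_marker_table(cfg$marker_file)
      ann <- annotate_clusters(nm, cl_tab$cluster, markers)
      cl_tab$cell_type <- ann[as.character(cl_tab$cluster)]
    } else {
      cl_tab$cell_type <- paste0("C", cl_tab$cluster)
    }
    tsv(cl_tab, "clusters.tsv")
    stages_run <- c(stages_run, "cluster")
    stage_log("cluster", sprintf("%d clusters over %d cells",
                                 length(unique(cl_tab$cluster)),
                                 nrow(cl_tab)), verbose)
  }
  labels <- cl_tab$cell_type

  # -- stage 5: differential expression ----------------------------------
  dp <- deg_params(cfg$min_pct, cfg$lfc_threshold, cfg$alpha,
                   cfg$pseudocount)
  de_file <- file.path(out, "markers_all.tsv")
  if (resume && file.exists(de_file)) {
    markers_all <- utils::read.table(de_file, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
    stage_log("de", "reusing cached marker table", verbose)
  } else {
    markers_all <- find_all_markers(nm, labels, dp)
    tsv(markers_all, "markers_all.tsv")
    if (length(cfg$focal) == 2 && all(cfg$focal %in% labels)) {
      de_focal <- find_markers(nm, labels, cfg$focal[1], cfg$focal[2], dp)
      tsv(de_focal, "de_focal.tsv")
    }
    stages_run <- c(stages_run, "de")
    stage_log("de", sprintf("%d marker records", nrow(markers_all)), verbose)
  }

  # -- stage 6: ligand-receptor scoring ----------------------------------
  lr_results <- NULL
  if (!is.null(cfg$lr_table) && length(cfg$focal)) {
    lr_file <- file.path(out, "chord_edges.tsv")
    if (resume && file.exists(lr_file)) {
      stage_log("lr", "reusing cached interaction tables", verbose)
    } else {
      pairs <- read_lr_table(cfg$lr_table)
      focal_present <- intersect(cfg$focal, labels)
      lr_results <- lapply(focal_present, function(f)
        lr_analysis(nm, labels, f, pairs, dp))
      names(lr_results) <- focal_present
      for (f in focal_present)
        tsv(lr_results[[f]]$scores, sprintf("lr_scores_%s.tsv", f))
      if (length(cfg$focal) == 2 && all(cfg$focal %in% labels)) {
        de_focal <- find_markers(nm, labels, cfg$focal[1], cfg$focal[2], dp)
        panel <- rank_de_receptors(de_focal, unique(pairs$receptor),
                                   cfg$alpha)
        tsv(panel, "receptor_panel.tsv")
      }
      export_chord_edges(lapply(lr_results, `[[`, "scores"), lr_file)
      stages_run <- c(stages_run, "lr")
      stage_log("lr", sprintf("scored %d focal population(s)",
                              length(focal_present)), verbose)
    }
  }

  # -- manifest -----------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "musclecomm",
    version = as.character(utils::packageVersion("musclecomm")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("simulate"))],
    simulate = cfg$simulate,
    stages_run = stages_run,
    n_cells_raw = ncol(counts), n_cells_qc = ncol(filtered),
    n_genes_qc = nrow(filtered),
    n_clusters = length(unique(cl_tab$cluster)),
    outputs = lapply(files, function(f)
      list(path = sub(paste0("^", out, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(manifest = manifest, counts = filtered, qc = qc,
                 normalized = nm, scaled = sm, clusters = cl_tab,
                 markers = markers_all, lr = lr_results, truth = truth))
}
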