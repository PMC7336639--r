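test_that("same seed and spec give bitwise-identical datasets", {
  spec <- flat_spec(4, 50, 200, seed = 11)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("donor RNG streams are stable under donor-count changes", {
  s3 <- synth_spec(n_donors = 3, cells_per_donor = list(mean = 40, sd = 0),
                   n_populations = 3, n_genes = 100,
                   marker_genes_per_population = 3, seed = 5)
  s2 <- synth_spec(n_donors = 2, cells_per_donor = list(mean = 40, sd = 0),
                   n_populations = 3, n_genes = 100,
                   marker_genes_per_population = 3, seed = 5)
  a <- generate_dataset(s3)
  b <- generate_dataset(s2)
  d1 <- a$meta$barcode[a$meta$donor == "D01"]
  expect_identical(as.matrix(a$counts[, d1]), as.matrix(b$counts[, d1]))
})

test_that("zero mean cells per donor yields an empty dataset", {
  spec <- synth_spec(n_donors = 2, cells_per_donor = list(mean = 0, sd = 0),
                     n_populations = 2, n_genes = 50,
                     marker_genes_per_population = 2, seed = 1)
  ds <- generate_dataset(spec)
  expect_equal(ncol(ds$counts), 0L)
  expect_equal(nrow(ds$truth$cells), 0L)
})

test_that("empirical gene means match the negative-binomial expectation", {
  # single population, no depth confounders: every gene mean is exactly 2
  spec <- synth_spec(n_donors = 1, cells_per_donor = list(mean = 500, sd = 0),
                     n_populations = 1, n_genes = 100, n_mito_genes = 0,
                     mito_share = 0, baseline_mean = 2, nb_dispersion = 1,
                     marker_genes_per_population = 0, marker_log2fc = 0,
                     chemistry_effect = c(v2 = 1), donor_depth_sd = 0,
                     seed = 42)
  ds <- generate_dataset(spec)
  mu <- 2
  se <- sqrt((mu + mu^2 / 1) / 500)          # NB variance mu + mu^2/size
  means <- Matrix::rowMeans(ds$counts)
  expect_gte(sum(abs(means - mu) <= 3 * se), 95)
})

test_that("per-cell totals scale with the chemistry depth factor", {
  spec <- synth_spec(n_donors = 2, cells_per_donor = list(mean = 500, sd = 0),
                     n_populations = 1, n_genes = 200, n_mito_genes = 0,
                     mito_share = 0, baseline_mean = 1,
                     marker_genes_per_population = 0, marker_log2fc = 0,
                     chemistry_effect = c(v2 = 1, v3 = 2),
                     donor_depth_sd = 0, seed = 9)
  ds <- generate_dataset(spec)
  tot <- Matrix::colSums(ds$counts)
  chem <- ds$meta$chemistry
  ratio <- mean(tot[chem == "v3"]) / mean(tot[chem == "v2"])
  expect_lt(abs(ratio - 2), 0.1)
})

test_that("metadata carries the donor-level atlas schema", {
  ds <- generate_dataset(flat_spec(3, 30, 100, seed = 2, n_donors = 3))
  expect_true(all(c("barcode", "donor", "chemistry", "sex", "age", "site")
                  %in% names(ds$meta)))
  expect_setequal(unique(ds$meta$chemistry), c("v2", "v3"))
  expect_equal(length(unique(ds$meta$donor)), 3L)
  expect_true(all(startsWith(grep("^MT-", rownames(ds$counts), value = TRUE),
                             "MT-")))
})

test_that("plant_marker elevates means only in the assigned population", {
  M <- matrix(2, 4, 2, dimnames = list(paste0("G", 1:4), c("A", "B")))
  out <- plant_marker(M, list(A = "G1"), 1)
  expect_equal(out["G1", "A"], 4)
  expect_equal(out["G1", "B"], 2)
  expect_equal(out["G2", "A"], 2)
  # log2fc 0 is the identity
  expect_equal(plant_marker(M, list(A = "G1"), 0), M)
  # fractional baseline
  M2 <- matrix(0.5, 2, 1, dimnames = list(c("G1", "G2"), "A"))
  expect_equal(plant_marker(M2, list(A = "G1"), 2)["G1", "A"], 2)
  # overlapping marker sets are rejected
  expect_error(plant_marker(M, list(A = "G1", B = "G1"), 1), "disjoint")
})

test_that("plant_lr_circuit elevates ligand and receptor independently", {
  M <- matrix(0.5, 3, 3, dimnames = list(paste0("G", 1:3),
                                         c("S", "R", "O")))
  circ <- list(ligand = "G1", receptor = "G2", sender = "S",
               receiver = "R", fold = 8)
  out <- plant_lr_circuit(M, circ)
  expect_equal(out["G1", "S"], 4)
  expect_equal(out["G2", "R"], 4)
  expect_equal(out["G1", "R"], 0.5)
  expect_equal(out["G2", "O"], 0.5)
  # fold 1 is the identity
  expect_equal(plant_lr_circuit(M, modifyList(circ, list(fold = 1))), M)
  # two circuits sharing a ligand act on their own cells
  out2 <- plant_lr_circuit(out, list(ligand = "G1", receptor = "G3",
                                     sender = "O", receiver = "R",
                                     fold = 4))
  expect_equal(out2["G1", "S"], 4)
  expect_equal(out2["G1", "O"], 2)
  expect_equal(out2["G3", "R"], 2)
  # unknown references are spec errors
  expect_error(plant_lr_circuit(M, modifyList(circ, list(ligand = "NOPE"))),
               "unknown circuit gene")
  expect_error(plant_lr_circuit(M, modifyList(circ, list(sender = "NOPE"))),
               "unknown circuit population")
})

test_that("infeasible specs are rejected", {
  expect_error(synth_spec(n_populations = 4, n_genes = 10, n_mito_genes = 2,
                          marker_genes_per_population = 5),
               "more marker genes")
  expect_error(synth_spec(population_proportions = c(0.5, 0.6),
                          n_populations = 2), "sum to 1")
  expect_error(synth_spec(baseline_mean = 0), "baseline_mean")
})

test_that("written datasets round trip with their truth tables", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(flat_spec(3, 30, 120, seed = 8))
  write_dataset(ds, dir)
  back <- read_counts_mtx(dir)
  expect_equal(as.matrix(back), as.matrix(ds$counts))
  truth <- read.table(file.path(dir, "truth_cells.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  expect_equal(truth$population, ds$truth$cells$population)
})
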