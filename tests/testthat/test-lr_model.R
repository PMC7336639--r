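toy_pairs <- function(...) {
  tab <- data.frame(...)
  tab$pair_name <- paste(tab$ligand, tab$receptor, sep = "_")
  tab
}

test_that("interaction scores are products of mean expressions", {
  # receptor mean 2.0 in focal; ligand means 1, 2, 3 across senders
  gm <- matrix(c(
    # Focal S1 S2 S3   (delogged means)
    0, 1, 2, 3,        # LIG
    expm1(2), 0, 0, 0),# REC: log-normalized mean exactly 2 in focal
    2, 4, byrow = TRUE,
    dimnames = list(c("LIG", "REC"), c("Focal", "S1", "S2", "S3")))
  labels <- rep(c("Focal", "S1", "S2", "S3"), each = 3)
  nm <- block_nm(gm, labels)
  pairs <- toy_pairs(ligand = "LIG", receptor = "REC")
  tab <- score_interactions(nm, labels, "Focal", "REC", pairs)
  expect_equal(tab$sender, c("S1", "S2", "S3"))
  expect_equal(tab$raw_score, 2 * log1p(1:3), tolerance = 1e-12)
  # ligand absent in a sender scores 0
  gm0 <- gm; gm0["LIG", "S1"] <- 0
  tab0 <- score_interactions(block_nm(gm0, labels), labels, "Focal",
                             "REC", pairs)
  expect_equal(tab0$raw_score[tab0$sender == "S1"], 0)
  # bilinearity: scaling one sender's ligand scales only its raw score
  nm2 <- nm
  nm2["LIG", labels == "S2"] <- 2 * nm2["LIG", labels == "S2"]
  tab2 <- score_interactions(nm2, labels, "Focal", "REC", pairs)
  expect_equal(tab2$raw_score[tab2$sender == "S2"],
               2 * tab$raw_score[tab$sender == "S2"])
  expect_equal(tab2$raw_score[tab2$sender != "S2"],
               tab$raw_score[tab$sender != "S2"])
  # no gated receptors: empty table, not an error
  expect_equal(nrow(score_interactions(nm, labels, "Focal", character(0),
                                       pairs)), 0L)
})

test_that("row z-scores standardize across senders", {
  tab <- data.frame(pair_name = "L_R", ligand = "L", receptor = "R",
                    focal = "F", sender = c("a", "b", "c"),
                    raw_score = c(2, 4, 6), z_score = NA_real_,
                    ligand_de = NA, receptor_de = TRUE,
                    stringsAsFactors = FALSE)
  expect_equal(zscore_rows(tab)$z_score, c(-1, 0, 1))
  tab$raw_score <- c(5, 5, 5)
  expect_equal(zscore_rows(tab)$z_score, c(0, 0, 0))
  tab2 <- tab[1:2, ]; tab2$raw_score <- c(0, 2)
  expect_equal(zscore_rows(tab2)$z_score, c(-1, 1) / sqrt(2),
               tolerance = 1e-9)
  # invariance under positive row rescaling
  tab$raw_score <- c(2, 4, 6)
  scaled <- tab; scaled$raw_score <- 7.3 * scaled$raw_score
  expect_equal(zscore_rows(scaled)$z_score, zscore_rows(tab)$z_score,
               tolerance = 1e-12)
})

test_that("removing a sender only renormalizes that row", {
  tab <- data.frame(pair_name = "L_R", ligand = "L", receptor = "R",
                    focal = "F", sender = c("a", "b", "c", "d"),
                    raw_score = c(1, 2, 3, 10), z_score = NA_real_,
                    ligand_de = NA, receptor_de = TRUE,
                    stringsAsFactors = FALSE)
  full <- zscore_rows(tab)
  dropped <- zscore_rows(tab[tab$sender != "d", ])
  expect_equal(dropped$raw_score, full$raw_score[1:3])
  expect_false(isTRUE(all.equal(dropped$z_score, full$z_score[1:3])))
})

test_that("receptor gating and ligand flags recover a planted circuit", {
  circ <- list(ligand = "GENE00120", receptor = "GENE00121",
               sender = "Fibroblast1", receiver = "MuSC1", fold = 8)
  ds <- generate_dataset(flat_spec(5, 120, 300, seed = 77,
                                   lr_circuits = list(circ)))
  nm <- log_normalize(ds$counts)
  labels <- true_labels(ds)
  pairs <- toy_pairs(ligand = c("GENE00120", "GENE00150"),
                     receptor = c("GENE00121", "GENE00151"))
  gated <- de_receptors(nm, labels, "MuSC1", pairs$receptor)
  expect_true("GENE00121" %in% gated)
  expect_false("GENE00151" %in% gated)
  res <- lr_analysis(nm, labels, "MuSC1", pairs)
  sc <- res$scores
  expect_equal(unique(sc$receptor), "GENE00121")
  planted <- sc[sc$sender == "Fibroblast1", ]
  expect_equal(planted$z_score, max(sc$z_score))
  expect_true(planted$ligand_de)
  expect_false(any(sc$ligand_de[sc$sender != "Fibroblast1"]))
})

test_that("a ligand expressed identically everywhere is never flagged", {
  gm <- matrix(c(1, 1, 1,
                 2, 2, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("LIG", "REC"), c("F", "S1", "S2")))
  labels <- rep(c("F", "S1", "S2"), each = 5)
  nm <- block_nm(gm, labels)
  tab <- score_interactions(nm, labels, "F", "REC",
                            toy_pairs(ligand = "LIG", receptor = "REC"))
  tab <- flag_ligand_specificity(tab, nm, labels)
  expect_false(any(tab$ligand_de))
})

test_that("an empty receptor universe warns and returns nothing", {
  gm <- matrix(1, 1, 2, dimnames = list("G1", c("A", "B")))
  nm <- block_nm(gm, rep(c("A", "B"), each = 4))
  expect_warning(out <- de_receptors(nm, rep(c("A", "B"), each = 4), "A",
                                     c("NOPE1", "NOPE2")),
                 "no receptor")
  expect_equal(out, character(0))
})

test_that("receptor panels rank by fold-change and flag significance", {
  deg <- data.frame(gene = c("R2", "R1", "OTHER"),
                    group = "MuSC1", reference = "MuSC2",
                    avg_log2fc = c(-0.5, 1, 3),
                    pct_in = 1, pct_out = 1,
                    p_value = c(0.15, 0.005, 0.001),
                    q_value = c(0.2, 0.01, 0.003),
                    stringsAsFactors = FALSE)
  panel <- rank_de_receptors(deg, c("R1", "R2"))
  expect_equal(panel$gene, c("R1", "R2"))
  expect_equal(panel$significant, c(TRUE, FALSE))
  expect_equal(nrow(rank_de_receptors(deg[0, ], c("R1"))), 0L)
})

test_that("chord edges flatten scored tables with the gate flag", {
  gm <- matrix(c(0, 1, 2,
                 2, 0, 0,
                 0, 3, 1,
                 1, 0, 0), 4, 3, byrow = TRUE,
               dimnames = list(c("L1", "R1", "L2", "R2"),
                               c("F", "S1", "S2")))
  labels <- rep(c("F", "S1", "S2"), each = 4)
  nm <- block_nm(gm, labels)
  pairs <- toy_pairs(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  tab <- score_interactions(nm, labels, "F", "R1", pairs, all_pairs = TRUE)
  tab <- zscore_rows(tab)
  edges <- export_chord_edges(tab)
  expect_equal(nrow(edges), 4L)              # 2 pairs x 2 senders
  expect_setequal(edges$significant[edges$receptor == "R1"], TRUE)
  expect_setequal(edges$significant[edges$receptor == "R2"], FALSE)
  # significant-edge count equals a brute-force recount:
  # (gated pairs) x (senders)
  brute <- sum(pairs$receptor %in% "R1") * length(c("S1", "S2"))
  expect_equal(sum(edges$significant), brute)
  # empty input gives a header-only frame
  f <- withr::local_tempfile(fileext = ".tsv")
  e0 <- export_chord_edges(list(), f)
  expect_equal(nrow(e0), 0L)
  expect_equal(nrow(read.table(f, header = TRUE, sep = "\t")), 0L)
})
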