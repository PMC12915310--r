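make_occ <- function(rows, genomes = paste0("G", seq_len(ncol(rows)))) {
  m <- rows
  dimnames(m) <- list(paste0("GC", seq_len(nrow(m))), genomes)
  m
}

test_that("occurrence partitioning follows the presence rule", {
  occ <- make_occ(rbind(c(1, 1, 1), c(1, 0, 0), c(1, 1, 0)))
  pt <- partition_occurrence(occ)
  expect_equal(as.character(pt$partition), c("core", "singleton", "accessory"))

  ## presence in every one of 107 genomes makes a cluster core, even with
  ## paralog copy-number variation
  occ107 <- make_occ(matrix(c(rep(1, 107), sample(c(2, 1), 107, TRUE)),
                            nrow = 2, byrow = TRUE),
                     genomes = paste0("G", 1:107))
  pt107 <- partition_occurrence(occ107)
  expect_true(all(pt107$partition == "core"))

  withzero <- make_occ(rbind(c(1, 1, 1), c(0, 0, 0)))
  expect_warning(pt0 <- partition_occurrence(withzero), "all-zero")
  expect_equal(nrow(pt0), 1)
  expect_error(partition_occurrence(withzero, drop_empty = FALSE),
               "all-zero")
})

test_that("partitions are exhaustive and core is monotone in genome removal", {
  ## a cluster core in the full genome set stays core after removing a
  ## genome (presence in all remaining genomes still holds); clusters can
  ## only enter the core, never leave it
  set.seed(42)
  for (rep in 1:20) {
    occ <- matrix(rbinom(8 * 6, 2, 0.6), 8, 6,
                  dimnames = list(paste0("GC", 1:8), paste0("G", 1:6)))
    occ[1, ] <- 1  # guarantee no empty genome column matters
    suppressWarnings({
      full <- partition_occurrence(occ)
      sub <- partition_occurrence(occ[, -3, drop = FALSE])
    })
    expect_equal(nrow(full), sum(rowSums(occ > 0) > 0))
    core_full <- full$cluster_id[full$partition == "core"]
    core_sub <- sub$cluster_id[sub$partition == "core"]
    expect_true(all(core_full %in% core_sub))
  }
})

test_that("gene-to-BGC join distinguishes containment from overlap", {
  genes <- data.frame(genome_id = "G1", contig_id = "c1",
                      gene_id = c("g1", "g2"),
                      start = c(100, 400), stop = c(400, 600),
                      stringsAsFactors = FALSE)
  bgcs <- data.frame(genome_id = "G1", contig_id = "c1", bgc_id = "b1",
                     start = 50, stop = 500, bgc_class = "Terpene",
                     stringsAsFactors = FALSE)
  cont <- bgc_gene_join(genes, bgcs, mode = "containment")
  expect_equal(cont$is_bg, c(TRUE, FALSE))
  ovl <- bgc_gene_join(genes, bgcs, mode = "any-overlap")
  expect_equal(ovl$is_bg, c(TRUE, TRUE))
})

test_that("a BGC spanning genes 3-7 labels exactly those five genes", {
  starts <- seq(100, by = 500, length.out = 10)
  genes <- data.frame(genome_id = "G1", contig_id = "c1",
                      gene_id = sprintf("g%02d", 1:10),
                      start = starts, stop = starts + 300,
                      stringsAsFactors = FALSE)
  bgcs <- data.frame(genome_id = "G1", contig_id = "c1", bgc_id = "b1",
                     start = starts[3], stop = starts[7] + 300,
                     stringsAsFactors = FALSE)
  joined <- bgc_gene_join(genes, bgcs)
  expect_equal(sum(joined$is_bg), 5)
  expect_equal(joined$is_bg, bf_bg_labels(genes, bgcs))
})

test_that("join matches the brute-force double loop on random instances", {
  set.seed(7)
  for (rep in 1:12) {
    ng <- sample(50:150, 1)
    nb <- sample(5:20, 1)
    genes <- data.frame(
      genome_id = sample(c("G1", "G2"), ng, TRUE),
      contig_id = sample(c("c1", "c2"), ng, TRUE),
      gene_id = sprintf("g%03d", 1:ng),
      start = sample(1:10000, ng), stringsAsFactors = FALSE)
    genes$stop <- genes$start + sample(50:800, ng, TRUE)
    bgcs <- data.frame(
      genome_id = sample(c("G1", "G2"), nb, TRUE),
      contig_id = sample(c("c1", "c2"), nb, TRUE),
      bgc_id = sprintf("b%02d", 1:nb),
      start = sample(1:9000, nb), stringsAsFactors = FALSE)
    bgcs$stop <- bgcs$start + sample(200:3000, nb, TRUE)
    for (mode in c("containment", "any-overlap")) {
      expect_equal(bgc_gene_join(genes, bgcs, mode)$is_bg,
                   bf_bg_labels(genes, bgcs, mode))
    }
  }
})

test_that("overlapping BGCs resolve to smallest span then smallest id", {
  genes <- data.frame(genome_id = "G1", contig_id = "c1", gene_id = "g1",
                      start = 200, stop = 300, stringsAsFactors = FALSE)
  bgcs <- data.frame(genome_id = "G1", contig_id = "c1",
                     bgc_id = c("b_wide", "b_narrow", "a_narrow"),
                     start = c(50, 150, 150), stop = c(1000, 350, 350),
                     stringsAsFactors = FALSE)
  joined <- bgc_gene_join(genes, bgcs)
  expect_equal(joined$bgc_id, "a_narrow")

  inv <- data.frame(genome_id = "G1", contig_id = "c1", bgc_id = "bad",
                    start = 500, stop = 100, stringsAsFactors = FALSE)
  expect_warning(j2 <- bgc_gene_join(genes, inv), "inverted")
  expect_false(any(j2$is_bg))
})

test_that("BG partition profile percentages sum to 100 within partitions", {
  pt <- data.frame(cluster_id = c("GC1", "GC2", "GC3"),
                   partition = factor(c("core", "core", "accessory"),
                                      levels = c("core", "accessory",
                                                 "singleton")))
  bg <- data.frame(cluster_id = c(rep("GC1", 7), rep("GC2", 3)),
                   bgc_class = c(rep("Terpene", 7), rep("NRPS", 3)),
                   stringsAsFactors = FALSE)
  prof <- bg_partition_profile(pt, bg)
  core <- prof[prof$partition == "core", ]
  expect_equal(core$pct_within_partition[core$bgc_class == "Terpene"], 70)
  expect_equal(core$pct_within_partition[core$bgc_class == "NRPS"], 30)
  expect_equal(sum(core$pct_within_partition), 100)
  ## empty partition reports zeros, and the class vocabulary stays split out
  acc <- prof[prof$partition == "accessory", ]
  expect_true(all(acc$n_bg == 0) && all(acc$pct_within_partition == 0))
  expect_true(all(c("NI-siderophore", "NAGGN") %in% prof$bgc_class))

  bad <- data.frame(cluster_id = "GC99", bgc_class = "Terpene")
  expect_error(bg_partition_profile(pt, bad), "GC99")
})

test_that("novelty summary counts and fractions are consistent", {
  nv <- summarize_novelty(c(0, 0, 30, 100))
  expect_equal(nv$n_zero, 2)
  expect_equal(nv$n_le50, 3)
  expect_equal(nv$n_eq100, 1)
  expect_equal(nv$mean_similarity, 32.5)
  expect_equal(unname(nv$fractions), c(50, 75, 25))
  expect_lte(nv$fractions["pct_zero"], nv$fractions["pct_le50"])

  expect_error(summarize_novelty(c(bgcX = 150)), "bgcX")

  set.seed(1)
  sims <- runif(500, 0, 100)
  nv2 <- summarize_novelty(sims)
  expect_lte(nv2$fractions["pct_zero"], nv2$fractions["pct_le50"])
  expect_true(all(nv2$fractions >= 0 & nv2$fractions <= 100))
})

test_that("species novelty needs both ANI and dDDH strictly below threshold", {
  ids <- c("Q1", "Q2", "Q3", "R1", "R2")
  ani <- matrix(90, 5, 5, dimnames = list(ids, ids)); diag(ani) <- 100
  ddh <- matrix(50, 5, 5, dimnames = list(ids, ids)); diag(ddh) <- 100
  ani["Q1", "R1"] <- 94.0; ddh["Q1", "R1"] <- 60.0
  ani["Q2", "R1"] <- 96.2; ddh["Q2", "R1"] <- 30.0
  ani["Q3", "R2"] <- 94.9; ddh["Q3", "R2"] <- 70.0
  res <- classify_species_novelty(ani, ddh, c("Q1", "Q2", "Q3"),
                                  c("R1", "R2"))
  expect_equal(res$is_putative_novel, c(TRUE, FALSE, FALSE))
  expect_equal(res$closest_reference, c("R1", "R1", "R2"))
  expect_error(classify_species_novelty(ani, ddh, "missing", c("R1")),
               "absent")
})
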