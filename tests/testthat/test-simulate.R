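test_that("simulated Yule trees are binary, rooted, positive, and seeded", {
  tr <- simulate_tree(3, seed = 1)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 3)
  expect_equal(tr$Nnode, 2)
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))

  expect_error(simulate_tree(2, seed = 1), "n_strains")

  t1 <- simulate_tree(10, seed = 3)
  t2 <- simulate_tree(10, seed = 3)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("patristic distances of a simulated tree form a metric", {
  tr <- simulate_tree(15, seed = 7)
  d <- patristic(tr)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 15))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("GCF evolution freezes at rate zero and is reproducible", {
  tr <- simulate_tree(8, seed = 2)
  m0 <- simulate_gcf_matrix(tr, 40, gain_loss_rate = 0, seed = 5)
  expect_true(all(apply(m0, 2, function(col) length(unique(col)) == 1)))

  m1 <- simulate_gcf_matrix(tr, 40, gain_loss_rate = 0.4, seed = 9)
  m2 <- simulate_gcf_matrix(tr, 40, gain_loss_rate = 0.4, seed = 9)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% 0:1))
  expect_true(all(rowSums(m1) > 0))
  expect_error(simulate_gcf_matrix(tr, 40, gain_loss_rate = -1, seed = 1),
               "gain_loss_rate")
})

test_that("fast gain/loss erases phylogenetic structure toward independence", {
  ## at rate 100 on a depth ~1 tree the chain mixes to its stationary 1/2;
  ## mean pairwise Jaccard should match an iid Bernoulli(1/2) simulation
  tr <- simulate_tree(10, seed = 4)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  m <- simulate_gcf_matrix(tr, 500, gain_loss_rate = 100, seed = 6)
  obs <- mean(jaccard_matrix(m)[upper.tri(diag(10))])
  set.seed(99)
  iid <- matrix(rbinom(10 * 500, 1, 0.5), 10,
                dimnames = list(rownames(m), NULL))
  ref <- mean(jaccard_matrix(iid)[upper.tri(diag(10))])
  expect_lt(abs(obs - ref), 0.05)
})

test_that("phylogenetic signal in GCF content decreases with gain/loss rate", {
  mean_mantel_r <- function(rate) {
    mean(vapply(1:15, function(s) {
      tr <- simulate_tree(10, seed = 100 + s)
      m <- simulate_gcf_matrix(tr, 80, gain_loss_rate = rate, seed = 200 + s)
      cor(patristic(tr)[upper.tri(diag(10))],
          jaccard_matrix(m)[upper.tri(diag(10))])
    }, numeric(1)))
  }
  r_low <- mean_mantel_r(0.2)
  r_mid <- mean_mantel_r(2)
  r_high <- mean_mantel_r(50)
  expect_gt(r_low, r_mid)
  expect_gt(r_mid, r_high)
})

test_that("metabolome variance components behave as designed", {
  tr <- simulate_tree(6, seed = 1)
  truth <- list(tree = tr,
                groups = data.frame(strain = tr$tip.label,
                                    source = rep(c("soil", "host"), 3),
                                    clade = rep(c("clade1", "clade2"), each = 3)))
  zero <- list(sigma_phylo = 0, sigma_medium = 0, sigma_source = 0,
               sigma_noise = 0)
  ft <- simulate_metabolome(truth, zero, n_features = 20, seed = 3)
  expect_equal(nrow(ft$abundance), 12)  # 6 strains x 2 media
  for (i in 2:nrow(ft$abundance))
    expect_equal(unname(ft$abundance[i, ]), unname(ft$abundance[1, ]))

  ## phylogeny-only signal: Bray-Curtis of strain means tracks the tree,
  ## more strongly at larger sigma_phylo (mean over seeds)
  mantel_r <- function(sigma, s) {
    es <- list(sigma_phylo = sigma, sigma_medium = 0, sigma_source = 0,
               sigma_noise = 0.3)
    ft <- simulate_metabolome(truth, es, n_features = 120, seed = s)
    ag <- aggregate_by_strain(normalize_features(ft))
    cor(patristic(tr)[upper.tri(diag(6))],
        bray_curtis_matrix(ag)[upper.tri(diag(6))])
  }
  r_small <- mean(vapply(1:12, function(s) mantel_r(0.2, s), numeric(1)))
  r_big <- mean(vapply(1:12, function(s) mantel_r(1.5, s), numeric(1)))
  expect_gt(r_big, r_small)
  expect_gt(r_big, 0.3)
})

test_that("dominant medium effect separates media on the first PCoA axis", {
  hits <- vapply(1:10, function(s) {
    tr <- simulate_tree(8, seed = 400 + s)
    truth <- list(tree = tr,
                  groups = data.frame(strain = tr$tip.label,
                                      source = rep("soil", 8),
                                      clade = rep("clade1", 8)))
    es <- list(sigma_phylo = 0.1, sigma_medium = 2, sigma_source = 0,
               sigma_noise = 0.3)
    ft <- simulate_metabolome(truth, es, n_features = 150, seed = 500 + s)
    ft <- normalize_features(ft)
    co <- pcoa(bray_curtis_matrix(ft))$coordinates
    ax1 <- co[, 1]
    med <- ft$sample_meta$medium
    max(min(ax1[med == "GYM"]) > max(ax1[med == "V22"]),
        min(ax1[med == "V22"]) > max(ax1[med == "GYM"]))
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("coordinate tables honor containment ground truth and seeding", {
  cfg <- sim_config(n_strains = 5, n_gcfs = 8, genes_per_genome = 50,
                    bgc_per_genome = 3, seed = 11)
  truth <- simulate_dataset(cfg)
  ## every truth-labeled BG is fully contained in a same-contig BGC
  joined <- bgc_gene_join(truth$gene_calls, truth$bgcs)
  expect_identical(joined$is_bg, truth$bg_labels$is_bg)
  expect_true(all(truth$gene_calls$start <= truth$gene_calls$stop))
  expect_true(all(truth$bgcs$start <= truth$bgcs$stop))
  expect_true(all(truth$bgcs$similarity_pct >= 0 &
                    truth$bgcs$similarity_pct <= 100))

  none <- emit_coordinate_tables(truth, genes_per_genome = 20,
                                 bgc_per_genome = 0, seed = 2)
  expect_false(any(none$bg_labels$is_bg))
  expect_equal(nrow(none$bgcs), 0)

  a <- emit_coordinate_tables(truth, 40, 2, seed = 7)
  b <- emit_coordinate_tables(truth, 40, 2, seed = 7)
  expect_identical(a, b)
})

test_that("the whole synthetic bundle is reproducible under one seed", {
  cfg <- sim_config(n_strains = 6, n_gcfs = 15, n_features = 30,
                    genes_per_genome = 60, bgc_per_genome = 4, seed = 21)
  t1 <- simulate_dataset(cfg)
  t2 <- simulate_dataset(cfg)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$gcf_presence, t2$gcf_presence)
  expect_identical(t1$features$abundance, t2$features$abundance)
  expect_identical(t1$gene_calls, t2$gene_calls)
  expect_identical(t1$bgcs, t2$bgcs)
})
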