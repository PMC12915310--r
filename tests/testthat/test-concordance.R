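test_that("cophenetic Pearson pairs by label and is affine invariant", {
  d <- rand_dist(6, seed = 1)
  expect_equal(cophenetic_pearson(d, d), 1)
  expect_equal(cophenetic_pearson(d, 3 * d + 2 * (1 - diag(6))), 1)

  ## label pairing: permuting the representation changes nothing
  p <- sample(6)
  expect_equal(cophenetic_pearson(d, d[p, p]), 1)

  ## fixed 4-leaf matrices against a from-scratch Pearson on the 6 pairs
  a <- rand_dist(4, seed = 2); b <- rand_dist(4, seed = 3)
  rownames(b) <- colnames(b) <- rownames(a)
  x <- a[upper.tri(a)]; y <- b[upper.tri(b)]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cophenetic_pearson(a, b), r_direct, tolerance = 1e-12)

  bad <- rand_dist(4, seed = 4)
  rownames(bad) <- colnames(bad) <- c("L01", "L02", "L03", "ZZ")
  expect_error(cophenetic_pearson(a, bad), "ZZ")
})

test_that("merge levels follow the k-cluster cut definition", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  lev <- merge_levels(tr)
  expect_equal(lev["A", "B"], 2)
  expect_equal(lev["A", "C"], 1)
  expect_equal(lev["B", "C"], 1)

  ## cherry leaves in an n-leaf tree co-occur up to k = n - 1
  d <- rand_dist(7, seed = 9)
  dend <- upgma(d)
  lv <- merge_levels(dend)
  cherry <- dend$labels[-dend$merge[1, ]]
  expect_equal(lv[cherry[1], cherry[2]], 6)

  ## star topology: the only cut shatters everything, all pairs k = 1
  star <- read_newick(text = "(A:1,B:1,C:1,D:1);")
  lvs <- merge_levels(star)
  expect_true(all(lvs[upper.tri(lvs)] == 1))

  ## equal-distance dendrogram degenerates the same way
  deq <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(deq) <- 0
  lvd <- merge_levels(upgma(deq))
  expect_true(all(lvd[upper.tri(lvd)] == 1))
})

test_that("merge levels match the brute-force cut oracles", {
  skip_if_not_installed("igraph")
  for (s in 1:8) {
    dend <- upgma(rand_dist(8, seed = 4000 + s))
    expect_equal(merge_levels(dend), bf_dendro_merge_levels(dend))
  }
  for (s in 1:8) {
    tr <- rand_tree(8, seed = 5000 + s)
    expect_equal(merge_levels(tr),
                 bf_phylo_merge_levels(tr)[tr$tip.label, tr$tip.label])
  }
})

test_that("Baker's Gamma equals 1 on self and -0.5 on the 3-leaf swap", {
  dend <- upgma(rand_dist(8, seed = 21))
  expect_equal(bakers_gamma(dend, dend), 1)

  t1 <- read_newick(text = "((A:1,B:1):1,C:2);")
  t2 <- read_newick(text = "((A:1,C:1):1,B:2);")
  expect_equal(bakers_gamma(t1, t2), -0.5)

  ## invariance to the leaf order of the representation
  tr <- rand_tree(9, seed = 31)
  rot <- ape::rotate(tr, node = 9 + 1)
  expect_equal(bakers_gamma(tr, rot), 1)
})

test_that("leaf-permutation null is seeded, plus-one corrected, monotone", {
  tr <- rand_tree(8, seed = 51)
  dend <- upgma(patristic(tr))

  self <- permutation_null("cophenetic_pearson", tr, tr, n_perm = 199,
                           seed = 3)
  expect_equal(self$observed, 1)
  expect_equal(self$p_value, 1 / 200)

  r1 <- permutation_null("bakers_gamma", tr, dend, n_perm = 99, seed = 7)
  r2 <- permutation_null("bakers_gamma", tr, dend, n_perm = 99, seed = 7)
  expect_identical(r1$null_values, r2$null_values)
  expect_gt(r1$p_value, 0)

  expect_error(permutation_null("bakers_gamma", tr, dend, n_perm = 50,
                                seed = 1), "99")

  ## p is monotone non-increasing in the observed statistic, null fixed
  nulls <- r1$null_values
  obs_grid <- seq(-1, 1, by = 0.25)
  ps <- vapply(obs_grid,
               function(o) (1 + sum(nulls >= o)) / (length(nulls) + 1),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("permuting matrix labels equals recomputing on a relabeled tree", {
  tr <- rand_tree(7, seed = 61)
  dend <- upgma(rand_dist(7, seed = 62))
  set.seed(8)
  p <- sample(7)
  relabeled <- dend
  relabeled$labels <- dend$labels[p]
  lev <- merge_levels(dend)
  lev_perm <- lev
  dimnames(lev_perm) <- list(dend$labels[p], dend$labels[p])
  expect_equal(bakers_gamma(tr, relabeled),
               bakers_gamma(merge_levels(tr), lev_perm), tolerance = 1e-12)
})

test_that("Mantel statistic agrees with vegan and behaves on self", {
  da <- rand_dist(8, seed = 71)
  db <- rand_dist(8, seed = 72)
  self <- mantel_test(da, da, n_perm = 99, seed = 1)
  expect_equal(self$observed, 1)
  expect_equal(self$r_squared, 1)
  expect_equal(mantel_test(da, 2 * da, n_perm = 99, seed = 1)$observed, 1)

  mt <- mantel_test(da, db, n_perm = 99, seed = 2)
  ref <- vegan::mantel(as.dist(da), as.dist(db), permutations = 0)
  expect_equal(mt$observed, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mt$r_squared, mt$observed^2)
})
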