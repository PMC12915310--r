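test_that("Jaccard distances match definition and brute force", {
  m <- rbind(A = c(1, 1, 1, 0), B = c(0, 1, 1, 1))  # {1,2,3} vs {2,3,4}
  expect_equal(jaccard_matrix(m)["A", "B"], 0.5)

  ident <- rbind(A = c(1, 0, 1), B = c(1, 0, 1))
  expect_equal(jaccard_matrix(ident)["A", "B"], 0)

  disj <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  expect_equal(jaccard_matrix(disj)["A", "B"], 1)

  expect_error(jaccard_matrix(rbind(A = c(2, 0), B = c(1, 1))), "binary")

  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    mm <- matrix(rbinom(n * 20, 1, 0.5), n,
                 dimnames = list(sprintf("r%02d", 1:n), NULL))
    mm[1, ] <- pmax(mm[1, ], 1)  # avoid double-zero rows here
    expect_equal(jaccard_matrix(mm), bf_jaccard(mm), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis distances match definition and brute force", {
  m <- rbind(A = c(2, 2), B = c(1, 3))
  expect_equal(bray_curtis_matrix(m)["A", "B"], 0.25)
  expect_equal(bray_curtis_matrix(rbind(A = c(1, 0), B = c(0, 1)))["A", "B"], 1)
  expect_equal(bray_curtis_matrix(rbind(A = c(1, 2), B = c(1, 2)))["A", "B"], 0)
  expect_error(bray_curtis_matrix(rbind(A = c(-1, 0), B = c(0, 1))),
               "negative")

  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    mm <- matrix(rexp(n * 15), n, dimnames = list(sprintf("r%02d", 1:n), NULL))
    expect_equal(bray_curtis_matrix(mm), bf_bray(mm), tolerance = 1e-12)
  }
})

test_that("empty profiles get distance zero by convention, with a warning", {
  m <- rbind(A = c(0, 0), B = c(0, 0), C = c(1, 1))
  expect_warning(d <- jaccard_matrix(m), "convention")
  expect_equal(d["A", "B"], 0)
  expect_equal(d["A", "C"], 1)
  expect_warning(d2 <- bray_curtis_matrix(m), "convention")
  expect_equal(d2["A", "B"], 0)
})

test_that("UPGMA reproduces the hand-worked three-leaf agglomeration", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dend <- upgma(d)
  expect_equal(dend$height, c(1, 3))
  cop <- cophenetic_matrix(dend)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 6)
  expect_equal(cop["B", "C"], 6)
})

test_that("UPGMA handles ties, pairs, and equal-distance stars", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  dd <- upgma(d2)
  expect_equal(dd$height, 1.5)
  expect_equal(cophenetic_matrix(dd)["A", "B"], 3)

  ## all equal distances: deterministic tie-break, flat cophenetic matrix
  labs <- c("D", "B", "A", "C")
  deq <- matrix(4, 4, 4, dimnames = list(labs, labs)); diag(deq) <- 0
  dend <- upgma(deq)
  cop <- cophenetic_matrix(dend)
  expect_true(all(cop[upper.tri(cop)] == 4))
  expect_identical(upgma(deq)$merge, dend$merge)  # reproducible tie-break
  ## first merge joins the lexicographically smallest pair {A, B}
  first <- sort(dend$labels[-dend$merge[1, ]])
  expect_equal(first, c("A", "B"))

  dn <- deq; dn[1, 2] <- NaN; dn[2, 1] <- NaN
  expect_error(upgma(dn), "finite")
})

test_that("UPGMA agrees with stats::hclust average linkage on random input", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    d <- rand_dist(n, seed = 1000 + rep)
    dend <- upgma(d)
    hc <- stats::hclust(as.dist(d), method = "average")
    expect_equal(2 * dend$height, hc$height, tolerance = 1e-12)
    expect_equal(cophenetic_matrix(dend)[rownames(d), rownames(d)],
                 as.matrix(stats::cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-12)
  }
})

test_that("cophenetic matrices are ultrametric and a fixed point of UPGMA", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    dend <- upgma(rand_dist(n, seed = 2000 + rep))
    cop <- cophenetic_matrix(dend)
    ## ultrametric: the max of any triangle's sides is attained twice
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      sides <- sort(c(cop[i, j], cop[i, k], cop[j, k]))
      expect_equal(sides[2], sides[3], tolerance = 1e-12)
    }
    ## UPGMA of an ultrametric matrix reproduces it exactly
    expect_equal(cophenetic_matrix(upgma(cop)), cop, tolerance = 1e-12)
  }
})

test_that("patristic distances equal shortest paths on the tree graph", {
  skip_if_not_installed("igraph")
  cherry <- read_newick(text = "(A:1,B:2);")
  expect_equal(patristic(cherry)["A", "B"], 3)

  star <- read_newick(text = "(A:0,B:0,C:0);")
  expect_true(all(patristic(star) == 0))

  for (s in 1:5) {
    tr <- rand_tree(10, seed = 3000 + s)
    expect_equal(patristic(tr), bf_patristic(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }

  noln <- rand_tree(5, seed = 1); noln$edge.length <- NULL
  expect_error(patristic(noln), "branch lengths")
})

test_that("dendrograms and trees round-trip through Newick", {
  d <- rand_dist(6, seed = 77)
  dend <- upgma(d)
  tr <- read_newick(text = dendro_to_newick(dend))
  expect_setequal(tr$tip.label, rownames(d))
  ## leaf-pair path lengths in the exported tree equal cophenetic distances
  expect_equal(patristic(tr)[rownames(d), rownames(d)],
               cophenetic_matrix(dend), tolerance = 1e-9)

  tr2 <- rand_tree(8, seed = 5)
  tmp <- tempfile(fileext = ".nwk")
  write_newick(tr2, tmp)
  back <- read_newick(tmp)
  expect_identical(ape::write.tree(back), ape::write.tree(tr2))
})
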