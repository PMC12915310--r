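#' Pairwise distance matrix underlying a tree-concordance statistic
#'
#' For the cophenetic Pearson statistic a dendrogram contributes its
#' cophenetic matrix and a phylogram its patristic matrix; a plain labeled
#' distance matrix is passed through.
#' @noRd
stat_matrix <- function(x) {
  if (inherits(x, "dendro")) return(cophenetic_matrix(x))
  if (inherits(x, "phylo")) return(patristic(x))
  check_distance_matrix(x)
  x
}

#' Pearson correlation between two cophenetic/patristic matrices
#'
#' Correlation over the `n(n-1)/2` leaf pairs, paired by leaf label (never
#' by matrix order).
#'
#' @param tree_a_distances,tree_b_distances labeled distance matrices, or
#'   `dendro` / `phylo` objects (converted via their cophenetic or patristic
#'   matrices).
#' @return Pearson correlation in `[-1, 1]`.
#' @export
cophenetic_pearson <- function(tree_a_distances, tree_b_distances) {
  a <- stat_matrix(tree_a_distances)
  b <- stat_matrix(tree_b_distances)
  b <- align_labels(a, b, "trees")
  if (nrow(a) < 4L) stop_invalid("need at least 4 leaves")
  stats::cor(upper_pairs(a), upper_pairs(b))
}

#' Merge levels of every leaf pair
#'
#' For a rooted tree cut into its `k` highest-level clusters, `k(i, j)` is
#' the largest `k` at which leaves i and j still share a cluster. For a
#' dendrogram the cut sequence follows merge heights from the root; for a
#' (possibly non-ultrametric) phylogram, internal nodes are cut in order of
#' increasing distance from the root, which reproduces the height-cut
#' sequence on ultrametric trees. Leaves of a cherry in an n-leaf tree get
#' `k = n - 1`; the root pair gets `k = 1`.
#'
#' @param x a `dendro` object or a rooted [ape::phylo] tree with at least 3
#'   leaves.
#' @return labeled symmetric integer matrix of merge levels (diagonal `NA`).
#' @export
merge_levels <- function(x) UseMethod("merge_levels")

#' @export
merge_levels.dendro <- function(x) {
  n <- length(x$labels)
  if (n < 3L) stop_invalid("need at least 3 leaves")
  ## a height cut just below a pair's lowest common merge breaks that merge
  ## and every strictly higher one; tied heights are broken simultaneously,
  ## so k(i,j) = #{merges strictly higher than the LCA merge} + 1
  lev <- matrix(NA_integer_, n, n, dimnames = list(x$labels, x$labels))
  members <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    side <- function(v) if (v < 0) -v else members[[v]]
    left <- side(x$merge[m, 1]); right <- side(x$merge[m, 2])
    lev[left, right] <- lev[right, left] <-
      sum(x$height > x$height[m]) + 1L
    members[[m]] <- c(left, right)
  }
  lev
}

#' @export
merge_levels.phylo <- function(x) {
  ## a basal polytomy is treated as a rooted star (ape cannot represent a
  ## rooted multifurcation any other way); only leafless input is rejected
  n <- length(x$tip.label)
  if (n < 3L) stop_invalid("need at least 3 leaves")
  tree <- x
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  depths <- ape::node.depth.edgelength(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  ## cutting just below an internal node breaks it and every strictly
  ## shallower node (ties, e.g. a resolved polytomy, break together), so
  ## k(i,j) = #{internal nodes strictly shallower than the MRCA} + 1
  k_of <- integer(max(internal))
  for (v in internal)
    k_of[v] <- sum(depths[internal] < depths[v]) + 1L
  mrca <- ape::mrca(tree)
  lev <- matrix(k_of[mrca], n, n,
                dimnames = list(tree$tip.label, tree$tip.label))
  diag(lev) <- NA_integer_
  lev[x$tip.label, x$tip.label]
}

#' Baker's Gamma index between two trees
#'
#' Rank correlation (Spearman with midranks by default) between the
#' label-paired merge-level vectors of the two trees: 1 for identical
#' hierarchies, values near 0 for unrelated ones.
#'
#' @param tree_a,tree_b `dendro` or rooted `phylo` objects on the same leaf
#'   set (or precomputed merge-level matrices).
#' @param method `"spearman"` (default) or `"pearson"` on the raw levels.
#' @return correlation in `[-1, 1]`.
#' @export
bakers_gamma <- function(tree_a, tree_b,
                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  a <- if (is.matrix(tree_a)) tree_a else merge_levels(tree_a)
  b <- if (is.matrix(tree_b)) tree_b else merge_levels(tree_b)
  b <- align_labels(a, b, "trees")
  stats::cor(upper_pairs(a), upper_pairs(b), method = method)
}

new_concordance <- function(statistic_name, observed, null_values, n_perm,
                            seed, alternative, extra = list()) {
  res <- c(list(statistic_name = statistic_name, observed = observed,
                null_values = null_values,
                p_value = perm_pvalue(observed, null_values, alternative),
                n_perm = n_perm, seed = seed, alternative = alternative),
           extra)
  class(res) <- "concordance"
  res
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("%s = %.4f, permutation P = %.4g (%d label permutations, %s)\n",
              x$statistic_name, x$observed, x$p_value, x$n_perm,
              x$alternative))
  if (!is.null(x$r_squared))
    cat(sprintf("  r^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Leaf-permutation null model for a tree-concordance statistic
#'
#' Holds the topology and heights of both trees fixed and permutes the leaf
#' labels of the second tree `n_perm` times, recomputing the statistic each
#' time. The one-sided (greater) p-value uses the plus-one correction and
#' can therefore never be 0.
#'
#' @param statistic `"cophenetic_pearson"` or `"bakers_gamma"`.
#' @param tree_a,tree_b `dendro` or rooted `phylo` objects with identical
#'   leaf sets.
#' @param n_perm number of permutations, at least 99.
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return object of class `concordance` with the observed statistic, the
#'   null distribution, and the empirical p-value.
#' @export
permutation_null <- function(statistic = c("cophenetic_pearson",
                                           "bakers_gamma"),
                             tree_a, tree_b, n_perm = 999, seed = 1,
                             alternative = c("greater", "two.sided")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  n_perm <- check_count(n_perm, "n_perm", 1L)
  if (n_perm < 99L)
    stop_invalid("n_perm must be at least 99 for usable p resolution")
  a <- if (statistic == "cophenetic_pearson") stat_matrix(tree_a)
  else if (is.matrix(tree_a)) tree_a else merge_levels(tree_a)
  b <- if (statistic == "cophenetic_pearson") stat_matrix(tree_b)
  else if (is.matrix(tree_b)) tree_b else merge_levels(tree_b)
  b <- align_labels(a, b, "trees")
  ## Baker's Gamma is Spearman on merge levels; midranks are computed once,
  ## which is exact because relabeling only permutes the pair vector
  va <- upper_pairs(a)
  bm <- b
  if (statistic == "bakers_gamma") {
    va <- rank(va)
    bm <- rank_matrix(b)
  }
  observed <- stats::cor(va, upper_pairs(bm))
  n <- nrow(a)
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(va, upper_pairs(bm[p, p, drop = FALSE]))
  }, numeric(1)))
  new_concordance(statistic, observed, null_values, n_perm,
                  check_seed(seed), alternative)
}

## Rank the off-diagonal pair values of a symmetric matrix in place,
## preserving symmetry (midranks for ties).
rank_matrix <- function(m) {
  up <- upper.tri(m)
  r <- rank(m[up])
  out <- m
  out[up] <- r
  out <- t(out)
  out[up] <- r
  out
}

#' Mantel test between two distance matrices
#'
#' Observed statistic is the Pearson correlation over the label-paired upper
#' triangles; the null permutes rows and columns of the second matrix
#' simultaneously. Reports both `r` and `r^2`.
#'
#' @param dist_a,dist_b labeled symmetric distance matrices on the same
#'   label set, `n >= 4`.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return object of class `concordance` with fields `observed` (r),
#'   `r_squared`, `null_values`, and `p_value`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n_perm <- check_count(n_perm, "n_perm", 1L)
  check_distance_matrix(dist_a, "dist_a")
  check_distance_matrix(dist_b, "dist_b")
  b <- align_labels(dist_a, dist_b, "distance matrices")
  n <- nrow(dist_a)
  if (n < 4L) stop_invalid("need at least 4 observations")
  va <- upper_pairs(dist_a)
  observed <- stats::cor(va, upper_pairs(b))
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(va, upper_pairs(b[p, p, drop = FALSE]))
  }, numeric(1)))
  new_concordance("mantel_r", observed, null_values, n_perm,
                  check_seed(seed), alternative,
                  extra = list(r_squared = observed^2))
}
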