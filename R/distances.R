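#' Jaccard dissimilarity matrix from a binary presence matrix
#'
#' `d(i, j) = 1 - |intersection| / |union|` over the presence profiles of
#' the two rows. Two all-zero rows, where the index is undefined, are given
#' distance 0 by convention with a warning.
#'
#' @param presence binary matrix, observations in rows, with row names.
#' @return labeled symmetric matrix of distances in `[0, 1]`.
#' @export
jaccard_matrix <- function(presence) {
  if (!is.matrix(presence) || nrow(presence) < 2L)
    stop_invalid("presence must be a matrix with at least 2 rows")
  if (!all(presence %in% c(0, 1)))
    stop_invalid("presence matrix must be binary (0/1)")
  if (is.null(rownames(presence)))
    stop_invalid("presence matrix must have row names")
  d <- as.matrix(quiet_empty_rows(
    vegan::vegdist(presence, method = "jaccard", binary = TRUE)))
  fix_double_zero(d, rowSums(presence) == 0, "Jaccard")
}

#' Bray-Curtis dissimilarity matrix from an abundance matrix
#'
#' `d(i, j) = sum |x - y| / sum (x + y)` over the two rows. Two all-zero
#' rows are given distance 0 by convention with a warning.
#'
#' @param table nonnegative matrix, samples in rows, with row names, or a
#'   [feature_table].
#' @return labeled symmetric matrix of distances in `[0, 1]`.
#' @export
bray_curtis_matrix <- function(table) {
  if (inherits(table, "feature_table")) table <- table$abundance
  if (!is.matrix(table) || nrow(table) < 2L)
    stop_invalid("table must be a matrix with at least 2 rows")
  if (any(table < 0)) stop_invalid("abundance matrix has negative entries")
  if (is.null(rownames(table)))
    stop_invalid("abundance matrix must have row names")
  d <- as.matrix(quiet_empty_rows(vegan::vegdist(table, method = "bray")))
  fix_double_zero(d, rowSums(table) == 0, "Bray-Curtis")
}

## vegdist warns about empty rows and the NaNs they produce; the double-zero
## convention below handles both, so those warnings are muffled in favor of
## our own (fix_double_zero still errors on any NaN it did not expect).
quiet_empty_rows <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("empty rows|missing values in results", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

## Distance between two empty profiles is undefined (0/0); set it to 0.
fix_double_zero <- function(d, empty, what) {
  if (sum(empty) >= 2L) {
    warning(what, " distance between empty profiles set to 0 by convention")
    idx <- which(empty)
    d[idx, idx] <- 0
  }
  diag(d) <- 0
  if (any(!is.finite(d)))
    stop_invalid(what, " produced non-finite distances")
  d
}

#' UPGMA (and flagged alternatives) hierarchical clustering
#'
#' Average-linkage agglomeration with cluster-size weighting. The merge
#' height stored is half the inter-cluster average distance, so the
#' cophenetic distance of a pair (twice the height of their lowest common
#' merge) reproduces the input distance for a two-leaf tree. Ties are broken
#' by the lexicographically smallest member pair.
#'
#' @param dist labeled symmetric distance matrix (or `dist` object).
#' @param linkage `"average"` (UPGMA, default), `"complete"`, or `"ward"`.
#' @return object of class `dendro`: list with hclust-style `merge`
#'   (negative entries index leaves), `height` (merge heights, half the
#'   merge distance), and `labels`.
#' @export
upgma <- function(dist, linkage = c("average", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  check_distance_matrix(dist)
  n <- nrow(dist)
  if (n < 2L) stop_invalid("need at least 2 observations")
  labels <- rownames(dist)
  ## active clusters: id (negative leaf index or positive merge index),
  ## size, and sorted member-label key for tie-breaking
  d <- dist
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  keys <- labels  # smallest member label of each active cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    k <- length(ids)
    ## find the minimal pair; tie-break on smallest member-label pair
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dij <- d[i, j]
      if (dij < best_d - 1e-15) {
        best <- c(i, j); best_d <- dij
      } else if (dij <= best_d + 1e-15 && !is.null(best)) {
        cand <- sort(c(keys[i], keys[j]))
        cur <- sort(c(keys[best[1]], keys[best[2]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
          best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]; best_d <- d[i, j]
    merge[m, ] <- sort(c(ids[i], ids[j]))
    height[m] <- best_d / 2
    ## Lance-Williams update for the new cluster against the rest
    ni <- sizes[i]; nj <- sizes[j]
    newd <- vapply(seq_len(k), function(l) {
      if (l == i || l == j) return(NA_real_)
      switch(linkage,
             average = (ni * d[i, l] + nj * d[j, l]) / (ni + nj),
             complete = max(d[i, l], d[j, l]),
             ward = ((ni + sizes[l]) * d[i, l] + (nj + sizes[l]) * d[j, l] -
                       sizes[l] * d[i, j]) / (ni + nj + sizes[l]))
    }, numeric(1))
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    ids <- c(ids[keep], m)
    sizes <- c(sizes[keep], ni + nj)
    keys <- c(keys[keep], min(keys[i], keys[j]))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage), class = "dendro")
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("%s-linkage dendrogram over %d leaves (heights %.4g .. %.4g)\n",
              x$linkage, length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' Convert a dendro object to base R's hclust representation
#'
#' Heights are doubled so they equal merge distances, matching the
#' convention of [stats::hclust()].
#' @param x a `dendro` object.
#' @param ... unused.
#' @return an `hclust` object.
#' @export
as.hclust.dendro <- function(x, ...) {
  n <- length(x$labels)
  ord <- dendro_leaf_order(x)
  structure(list(merge = x$merge, height = 2 * x$height, order = ord,
                 labels = x$labels, method = x$linkage,
                 call = match.call(), dist.method = "unknown"),
            class = "hclust")
}

dendro_leaf_order <- function(x) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(x$merge[node, 1]), expand(x$merge[node, 2]))
  }
  expand(nrow(x$merge))
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The cophenetic distance of two leaves is twice the height of their lowest
#' common merge; the result is ultrametric by construction.
#'
#' @param dendrogram a `dendro` object from [upgma()].
#' @return labeled symmetric distance matrix.
#' @export
cophenetic_matrix <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "dendro"))
  n <- length(dendrogram$labels)
  d <- matrix(0, n, n, dimnames = list(dendrogram$labels, dendrogram$labels))
  members <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    side <- function(v) if (v < 0) -v else members[[v]]
    left <- side(dendrogram$merge[m, 1])
    right <- side(dendrogram$merge[m, 2])
    d[left, right] <- d[right, left] <- 2 * dendrogram$height[m]
    members[[m]] <- c(left, right)
  }
  d
}

#' Export an ultrametric dendrogram to Newick
#'
#' @param dendrogram a `dendro` object.
#' @return single-element character vector in Newick format; leaf depths
#'   equal the merge heights.
#' @export
dendro_to_newick <- function(dendrogram) {
  stopifnot(inherits(dendrogram, "dendro"))
  build <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%.10g", dendrogram$labels[-node], parent_h))
    h <- dendrogram$height[node]
    sprintf("(%s,%s):%.10g",
            build(dendrogram$merge[node, 1], h),
            build(dendrogram$merge[node, 2], h), parent_h - h)
  }
  root <- nrow(dendrogram$merge)
  h <- dendrogram$height[root]
  paste0("(", build(dendrogram$merge[root, 1], h), ",",
         build(dendrogram$merge[root, 2], h), ");")
}

#' Patristic distance matrix of a phylogenetic tree
#'
#' Sum of branch lengths along the unique path between each pair of leaves.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return labeled symmetric distance matrix.
#' @export
patristic <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(is.na(tree$edge.length)))
    stop_invalid("tree has missing branch lengths")
  ape::cophenetic.phylo(tree)
}

#' Read and write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] keeping
#' input rooting, quoted labels, and branch lengths.
#'
#' @param file path to a Newick file (or, for `read_newick`, a `text=`
#'   string via `...`).
#' @param tree an [ape::phylo] object.
#' @param ... passed through to the ape reader/writer.
#' @return `read_newick` returns a `phylo`; `write_newick` its file path,
#'   invisibly.
#' @export
read_newick <- function(file = "", ...) {
  tree <- ape::read.tree(file, ...)
  if (is.null(tree)) stop_invalid("could not parse Newick input")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, file, ...) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = file, ...)
  invisible(file)
}
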