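## Independent brute-force oracles used to cross-check the package's
## distance, clustering, and merge-level machinery.

bf_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- m[i, ] > 0; b <- m[j, ] > 0
    u <- sum(a | b)
    d[i, j] <- if (u == 0) 0 else 1 - sum(a & b) / u
  }
  d
}

bf_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (s == 0) 0 else sum(abs(m[i, ] - m[j, ])) / s
  }
  d
}

## Gene-in-BGC containment by an all-pairs double loop.
bf_bg_labels <- function(genes, bgcs, mode = "containment") {
  out <- rep(FALSE, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(bgcs))) {
      if (genes$genome_id[i] != bgcs$genome_id[j] ||
          genes$contig_id[i] != bgcs$contig_id[j]) next
      hit <- if (mode == "containment")
        bgcs$start[j] <= genes$start[i] && genes$stop[i] <= bgcs$stop[j]
      else
        bgcs$start[j] <= genes$stop[i] && genes$start[i] <= bgcs$stop[j]
      if (hit) { out[i] <- TRUE; break }
    }
  }
  out
}

## Merge levels of a dendrogram by literally cutting at every k.
bf_dendro_merge_levels <- function(dend) {
  hc <- as.hclust(dend)
  n <- length(dend$labels)
  lev <- matrix(NA_integer_, n, n, dimnames = list(dend$labels, dend$labels))
  for (k in seq_len(n - 1)) {
    ct <- stats::cutree(hc, k = k)[dend$labels]
    same <- outer(ct, ct, "==")
    lev[same] <- k
  }
  diag(lev) <- NA_integer_
  lev
}

## Merge levels of a phylogram by deleting the k-1 shallowest internal
## nodes and reading off graph components.
bf_phylo_merge_levels <- function(tree) {
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  internal <- (n + 1L):(n + tree$Nnode)
  ord <- internal[order(depths[internal], internal)]
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character), directed = FALSE)
  lev <- matrix(NA_integer_, n, n,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (k in seq_len(n - 1)) {
    gk <- igraph::delete_vertices(g, as.character(ord[seq_len(k - 1)]))
    comp <- igraph::components(gk)$membership
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (comp[as.character(i)] == comp[as.character(j)])
        lev[i, j] <- lev[j, i] <- k
    }
  }
  lev
}

## Patristic distances as all-pairs shortest paths on the weighted tree graph.
bf_patristic <- function(tree) {
  g <- igraph::graph_from_edgelist(
    apply(tree$edge, 2, as.character), directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  d <- igraph::distances(g, v = as.character(seq_len(n)),
                         to = as.character(seq_len(n)))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

## Random labeled distance matrix from iid points (Euclidean, no ties a.s.).
rand_dist <- function(n, seed, dim = 3) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("L%02d", 1:n), sprintf("L%02d", 1:n))
  d
}

rand_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$tip.label <- sprintf("L%02d", 1:n)
  tr
}

## Minimal feature table: abundance matrix plus metadata built in code.
toy_feature_table <- function(ab, has_ms2 = NULL, category = NULL,
                              strain = NULL, medium = NULL) {
  ns <- nrow(ab); nf <- ncol(ab)
  if (is.null(rownames(ab))) rownames(ab) <- sprintf("samp%d", 1:ns)
  if (is.null(colnames(ab))) colnames(ab) <- sprintf("F%d", 1:nf)
  fm <- data.frame(feature_id = colnames(ab),
                   has_ms2 = has_ms2 %||% rep(TRUE, nf),
                   category = category %||% rep("unknown", nf),
                   stringsAsFactors = FALSE)
  sm <- data.frame(sample_id = rownames(ab),
                   strain = strain %||% rownames(ab),
                   medium = medium %||% rep("GYM", ns),
                   stringsAsFactors = FALSE)
  feature_table(ab, fm, sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
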