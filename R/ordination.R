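#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of `-d^2 / 2` followed by a symmetric
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of the positive eigenvalues; axes with negative eigenvalues (which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are counted
#' and dropped, with no correction applied.
#'
#' @param dist labeled symmetric distance matrix, `n >= 3`.
#' @return object of class `pcoa_result`: `coordinates` (samples x positive
#'   axes), `eigenvalues` (all, decreasing), `prop_explained` (over positive
#'   eigenvalues, sums to 1), `n_negative_eigenvalues`.
#' @export
pcoa <- function(dist) {
  check_distance_matrix(dist)
  n <- nrow(dist)
  if (n < 3L) stop_invalid("need at least 3 observations")
  a <- -0.5 * dist^2
  centered <- a - outer(rowMeans(a), colMeans(a), `+`) + mean(a)
  eig <- eigen((centered + t(centered)) / 2, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals), 0) * 1e-8 + 1e-12
  pos <- which(vals > tol)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals[pos]), length(pos))
  rownames(coords) <- rownames(dist)
  colnames(coords) <- if (length(pos)) paste0("PCo", seq_along(pos))
  prop <- if (length(pos)) vals[pos] / sum(vals[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = vals,
                 prop_explained = prop,
                 n_negative_eigenvalues = sum(vals < -tol)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d samples, %d positive axes, %d negative eigenvalue(s)\n",
              nrow(x$coordinates), k, x$n_negative_eigenvalues))
  if (k)
    cat(sprintf("  axis 1-%d %% explained: %s\n", min(k, 3),
                paste(sprintf("%.1f", 100 * x$prop_explained[seq_len(min(k, 3))]),
                      collapse = ", ")))
  invisible(x)
}

## PERMANOVA sums of squares for one labeling; D2 is the squared distance
## matrix, idx a list of index vectors per group.
permanova_ss <- function(D2, idx, n) {
  ss_total <- sum(D2[upper.tri(D2)]) / n
  ss_within <- 0
  for (g in idx) {
    if (length(g) > 1L)
      ss_within <- ss_within + sum(D2[g, g][upper.tri(D2[g, g])]) / length(g)
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' PERMANOVA (ADONIS-style) one-way test on a distance matrix
#'
#' Partitions distance-based sums of squares between and within groups:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = (SS_between / (g-1)) / (SS_within / (n-g))`. Significance
#' comes from permuting the group labels, one-sided on F, with the plus-one
#' correction. An optional `strata` factor restricts permutations to within
#' strata.
#'
#' @param dist labeled symmetric distance matrix.
#' @param groups group labels, one per sample (vector or factor), in the
#'   order of `rownames(dist)` or named by sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @param strata optional factor for restricted permutations.
#' @return object of class `permanova_result` with `pseudo_F`, `r_squared`,
#'   `p_value`, `df_between`, `df_within`, `n_perm`, `seed`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1, strata = NULL) {
  check_distance_matrix(dist)
  n <- nrow(dist)
  if (!is.null(names(groups))) groups <- groups[rownames(dist)]
  if (length(groups) != n)
    stop_invalid("groups must have one label per sample")
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop_invalid("need at least 2 groups")
  if (g >= n) stop_invalid("need more samples than groups")
  if (any(table(groups) == n))
    stop_invalid("one group contains every sample")
  n_perm <- check_count(n_perm, "n_perm", 1L)
  D2 <- dist^2
  fstat <- function(lab) {
    ss <- permanova_ss(D2, split(seq_len(n), lab), n)
    if (ss["within"] <= 0) return(Inf)
    (ss["between"] / (g - 1)) / (ss["within"] / (n - g))
  }
  ss_obs <- permanova_ss(D2, split(seq_len(n), groups), n)
  pseudo_F <- unname(if (ss_obs["within"] <= 0) Inf else
    (ss_obs["between"] / (g - 1)) / (ss_obs["within"] / (n - g)))
  r_squared <- unname(ss_obs["between"] / ss_obs["total"])
  null_values <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    perm <- if (is.null(strata)) sample.int(n) else {
      out <- seq_len(n)
      for (s in split(seq_len(n), strata)) out[s] <- s[sample.int(length(s))]
      out
    }
    unname(fstat(groups[perm]))
  }, numeric(1)))
  structure(list(pseudo_F = pseudo_F, r_squared = r_squared,
                 p_value = perm_pvalue(pseudo_F, null_values),
                 df_between = g - 1L, df_within = n - g,
                 ss = ss_obs, null_values = null_values,
                 n_perm = n_perm, seed = check_seed(seed)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(paste0("PERMANOVA: pseudo-F(%d, %d) = %.4g, R2 = %.3f, ",
                     "P = %.4g (%d permutations)\n"),
              x$df_between, x$df_within, x$pseudo_F, x$r_squared,
              x$p_value, x$n_perm))
  invisible(x)
}
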