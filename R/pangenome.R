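#' Partition a gene-cluster occurrence matrix into core/accessory/singleton
#'
#' A gene cluster is *core* when present (count >= 1) in every genome of the
#' analysis set, *singleton* when present in exactly one genome, and
#' *accessory* otherwise. Presence, not copy count, drives the rule: a
#' paralog expansion never ejects a universal cluster from the core.
#'
#' @param matrix occurrence matrix, gene clusters in rows, genomes in
#'   columns, nonnegative integer copy counts, with dimnames.
#' @param drop_empty drop all-zero rows with a warning (default) instead of
#'   erroring.
#' @return data.frame with columns `cluster_id` and `partition` (factor with
#'   levels core, accessory, singleton).
#' @export
partition_occurrence <- function(matrix, drop_empty = TRUE) {
  if (!is.matrix(matrix) || nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop_invalid("occurrence matrix must be a nonempty matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_invalid("occurrence matrix must carry cluster and genome names")
  if (any(matrix < 0)) stop_invalid("occurrence matrix has negative entries")
  n_genomes <- ncol(matrix)
  present <- matrix > 0
  n_present <- rowSums(present)
  empty <- n_present == 0L
  if (any(empty)) {
    if (!drop_empty)
      stop_invalid("all-zero occurrence rows: ",
                   paste(rownames(matrix)[empty], collapse = ", "))
    warning(sum(empty), " all-zero occurrence row(s) dropped")
    present <- present[!empty, , drop = FALSE]
    n_present <- n_present[!empty]
  }
  partition <- ifelse(n_present == n_genomes, "core",
                      ifelse(n_present == 1L, "singleton", "accessory"))
  data.frame(cluster_id = rownames(present),
             partition = factor(partition,
                                levels = c("core", "accessory", "singleton")),
             stringsAsFactors = FALSE)
}

#' Label genes as biosynthetic by coordinate join against BGC intervals
#'
#' Classifies a gene as a biosynthetic gene (BG) when it lies within the
#' boundaries of a BGC on the same genome and contig. In `containment` mode
#' (the default) the gene interval must lie fully inside the BGC interval;
#' `any-overlap` accepts a single shared base. Strand is ignored. A gene
#' matching several BGCs is assigned to the one with the smallest span,
#' ties broken by lexicographically smallest `bgc_id`.
#'
#' @param gene_calls data.frame with `genome_id`, `contig_id`, `gene_id`,
#'   `start`, `stop` (1-based inclusive).
#' @param bgc_records data.frame with `genome_id`, `contig_id`, `bgc_id`,
#'   `start`, `stop`, and optionally `bgc_class`, `similarity_pct`, `gcf_id`.
#' @param mode `"containment"` or `"any-overlap"`.
#' @return `gene_calls` with added columns `is_bg`, `bgc_id`, `bgc_class`.
#' @export
bgc_gene_join <- function(gene_calls, bgc_records,
                          mode = c("containment", "any-overlap")) {
  mode <- match.arg(mode)
  check_columns(gene_calls, c("genome_id", "contig_id", "gene_id",
                              "start", "stop"), "gene_calls")
  check_columns(bgc_records, c("genome_id", "contig_id", "bgc_id",
                               "start", "stop"), "bgc_records")
  bad_gene <- gene_calls$start > gene_calls$stop
  if (any(bad_gene)) {
    warning("rejecting ", sum(bad_gene),
            " gene call(s) with inverted coordinates")
    gene_calls <- gene_calls[!bad_gene, , drop = FALSE]
  }
  bad_bgc <- bgc_records$start > bgc_records$stop
  if (any(bad_bgc)) {
    warning("rejecting ", sum(bad_bgc),
            " BGC record(s) with inverted coordinates")
    bgc_records <- bgc_records[!bad_bgc, , drop = FALSE]
  }
  if (is.null(bgc_records$bgc_class))
    bgc_records$bgc_class <- rep(NA_character_, nrow(bgc_records))

  out <- gene_calls
  out$is_bg <- FALSE
  out$bgc_id <- NA_character_
  out$bgc_class <- NA_character_
  if (nrow(bgc_records) == 0L || nrow(gene_calls) == 0L) return(out)

  key_g <- paste(gene_calls$genome_id, gene_calls$contig_id, sep = "\r")
  key_b <- paste(bgc_records$genome_id, bgc_records$contig_id, sep = "\r")
  span <- bgc_records$stop - bgc_records$start
  for (key in unique(key_g)) {
    bi <- which(key_b == key)
    if (!length(bi)) next
    gi <- which(key_g == key)
    for (i in gi) {
      gs <- gene_calls$start[i]; ge <- gene_calls$stop[i]
      hit <- if (mode == "containment")
        bi[bgc_records$start[bi] <= gs & ge <= bgc_records$stop[bi]]
      else
        bi[bgc_records$start[bi] <= ge & gs <= bgc_records$stop[bi]]
      if (!length(hit)) next
      if (length(hit) > 1L)
        hit <- hit[order(span[hit], bgc_records$bgc_id[hit])][1L]
      out$is_bg[i] <- TRUE
      out$bgc_id[i] <- bgc_records$bgc_id[hit]
      out$bgc_class[i] <- bgc_records$bgc_class[hit]
    }
  }
  out
}

#' Distribution of biosynthetic genes across pan-genome partitions
#'
#' Cross-tabulates BG counts by pan-genome partition and BGC class, with
#' within-partition percentages. All BGC classes in the vocabulary are
#' reported as separate columns; siderophore and NAGGN clusters are never
#' folded into "Others".
#'
#' @param partition_table data.frame from [partition_occurrence()].
#' @param bg_table data.frame of BG genes with `cluster_id` and `bgc_class`
#'   (e.g. the `is_bg` rows of a [bgc_gene_join()] result joined to gene
#'   cluster ids).
#' @return data.frame with one row per (partition, bgc_class): `n_bg` and
#'   `pct_within_partition`.
#' @export
bg_partition_profile <- function(partition_table, bg_table) {
  check_columns(partition_table, c("cluster_id", "partition"),
                "partition_table")
  check_columns(bg_table, c("cluster_id", "bgc_class"), "bg_table")
  unknown <- setdiff(unique(bg_table$cluster_id), partition_table$cluster_id)
  if (length(unknown))
    stop_invalid("BGs reference cluster ids absent from the partition ",
                 "table: ", paste(sort(unknown), collapse = ", "))
  partitions <- levels(factor(partition_table$partition,
                              levels = c("core", "accessory", "singleton")))
  classes <- union(bgc_class_vocabulary(), unique(bg_table$bgc_class))
  part_of <- stats::setNames(as.character(partition_table$partition),
                             partition_table$cluster_id)
  bg_table$partition <- part_of[bg_table$cluster_id]
  counts <- table(factor(bg_table$partition, levels = partitions),
                  factor(bg_table$bgc_class, levels = classes))
  totals <- rowSums(counts)
  out <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(out) <- c("partition", "bgc_class", "n_bg")
  out$pct_within_partition <- ifelse(
    totals[out$partition] > 0, 100 * out$n_bg / totals[out$partition], 0)
  out[order(out$partition, out$bgc_class), , drop = FALSE]
}

#' Summarize BGC novelty from similarity-to-known-cluster scores
#'
#' Counts BGCs with 0% similarity to any known cluster, with similarity at
#' or below 50%, and with exactly 100% similarity, alongside the
#' corresponding full-precision percentages of the total.
#'
#' @param similarities numeric vector of percent similarities in `[0, 100]`,
#'   optionally named by BGC id.
#' @return object of class `novelty_summary` with fields `n_total`,
#'   `n_zero`, `n_le50`, `n_eq100`, `mean_similarity`, and `fractions`
#'   (named percentages `pct_zero`, `pct_le50`, `pct_eq100`).
#' @export
summarize_novelty <- function(similarities) {
  if (length(similarities) == 0L)
    stop_invalid("no similarity values supplied")
  bad <- which(!is.finite(similarities) | similarities < 0 |
                 similarities > 100)
  if (length(bad)) {
    ids <- if (!is.null(names(similarities))) names(similarities)[bad]
    else paste0("#", bad)
    stop_invalid("similarity values outside [0, 100] for BGC(s): ",
                 paste(ids, collapse = ", "))
  }
  n <- length(similarities)
  res <- list(
    n_total = n,
    n_zero = sum(similarities == 0),
    n_le50 = sum(similarities <= 50),
    n_eq100 = sum(similarities == 100),
    mean_similarity = mean(similarities)
  )
  res$fractions <- c(pct_zero = 100 * res$n_zero / n,
                     pct_le50 = 100 * res$n_le50 / n,
                     pct_eq100 = 100 * res$n_eq100 / n)
  class(res) <- "novelty_summary"
  res
}

#' @export
print.novelty_summary <- function(x, ...) {
  cat(sprintf("BGC novelty over %d clusters (mean similarity %.1f%%)\n",
              x$n_total, x$mean_similarity))
  cat(sprintf("  0%% similarity : %5d (%.1f%%)\n", x$n_zero,
              x$fractions["pct_zero"]))
  cat(sprintf("  <= 50%%        : %5d (%.1f%%)\n", x$n_le50,
              x$fractions["pct_le50"]))
  cat(sprintf("  100%% (known)  : %5d (%.1f%%)\n", x$n_eq100,
              x$fractions["pct_eq100"]))
  invisible(x)
}

#' Flag putative novel species from ANI and dDDH matrices
#'
#' A query strain is a putative novel species when its maximum average
#' nucleotide identity (ANI) over all references is strictly below the
#' species delineation threshold (95%) *and* the digital DNA-DNA
#' hybridization (dDDH) value against that closest reference is strictly
#' below 70%. Boundary equality fails the test.
#'
#' @param ani_matrix,ddh_matrix square labeled matrices covering all queries
#'   and references.
#' @param query_ids,reference_ids character vectors of strain labels.
#' @param ani_threshold,ddh_threshold delineation thresholds (default 95, 70).
#' @return data.frame with one row per query: `query`, `closest_reference`,
#'   `max_ani`, `ddh_at_closest`, `is_putative_novel`.
#' @export
classify_species_novelty <- function(ani_matrix, ddh_matrix, query_ids,
                                     reference_ids, ani_threshold = 95,
                                     ddh_threshold = 70) {
  check_square_labeled(ani_matrix, "ANI matrix")
  check_square_labeled(ddh_matrix, "dDDH matrix")
  for (ids in list(query_ids, reference_ids)) {
    miss <- setdiff(ids, rownames(ani_matrix))
    if (length(miss))
      stop_invalid("strain(s) absent from the ANI matrix: ",
                   paste(miss, collapse = ", "))
    miss <- setdiff(ids, rownames(ddh_matrix))
    if (length(miss))
      stop_invalid("strain(s) absent from the dDDH matrix: ",
                   paste(miss, collapse = ", "))
  }
  if (!length(reference_ids)) stop_invalid("no reference strains supplied")
  out <- lapply(query_ids, function(q) {
    refs <- setdiff(reference_ids, q)
    ani <- ani_matrix[q, refs]
    best <- refs[which.max(ani)]
    ddh <- ddh_matrix[q, best]
    data.frame(query = q, closest_reference = best,
               max_ani = unname(max(ani)), ddh_at_closest = unname(ddh),
               is_putative_novel = max(ani) < ani_threshold &&
                 ddh < ddh_threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build an occurrence matrix from gene calls with cluster assignments
#'
#' Counts gene copies per (gene cluster, genome); the substrate for
#' [partition_occurrence()].
#'
#' @param gene_calls data.frame with `genome_id` and `cluster_id`.
#' @return integer matrix, clusters x genomes.
#' @export
occurrence_from_gene_calls <- function(gene_calls) {
  check_columns(gene_calls, c("genome_id", "cluster_id"), "gene_calls")
  tab <- table(gene_calls$cluster_id, gene_calls$genome_id)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}
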