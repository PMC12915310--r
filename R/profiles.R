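#' Metabolite feature table with feature and sample metadata
#'
#' A light container pairing a samples x features abundance matrix with a
#' feature metadata table (m/z, retention time, MS2 flag, pathway category)
#' and a sample metadata table (strain, medium, source, clade).
#'
#' @param abundance numeric matrix, samples in rows, features in columns,
#'   nonnegative, with dimnames.
#' @param feature_meta data.frame with `feature_id` plus any of `mz`, `rt`,
#'   `has_ms2`, `category`; one row per abundance column.
#' @param sample_meta data.frame with `sample_id` plus grouping columns;
#'   one row per abundance row.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(abundance, feature_meta, sample_meta) {
  if (!is.matrix(abundance) || any(abundance < 0))
    stop_invalid("abundance must be a nonnegative matrix")
  check_columns(feature_meta, "feature_id", "feature_meta")
  check_columns(sample_meta, "sample_id", "sample_meta")
  if (anyDuplicated(feature_meta$feature_id))
    stop_invalid("duplicated feature ids")
  if (anyDuplicated(sample_meta$sample_id))
    stop_invalid("duplicated sample ids")
  if (is.null(dimnames(abundance)))
    dimnames(abundance) <- list(sample_meta$sample_id,
                                feature_meta$feature_id)
  if (!identical(rownames(abundance), sample_meta$sample_id))
    stop_invalid("abundance rows must match sample_meta$sample_id")
  if (!identical(colnames(abundance), feature_meta$feature_id))
    stop_invalid("abundance columns must match feature_meta$feature_id")
  structure(list(abundance = abundance, feature_meta = feature_meta,
                 sample_meta = sample_meta), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d samples x %d features\n",
              nrow(x$abundance), ncol(x$abundance)))
  if (!is.null(x$feature_meta$has_ms2))
    cat(sprintf("  %d features with MS2 spectra\n",
                sum(x$feature_meta$has_ms2)))
  for (col in intersect(c("strain", "medium", "source", "clade"),
                        names(x$sample_meta)))
    cat(sprintf("  %s: %s\n", col,
                paste(unique(x$sample_meta[[col]]), collapse = ", ")))
  invisible(x)
}

#' Strain x GCF presence/absence matrix from BGC records
#'
#' An entry is 1 when the strain carries at least one BGC belonging to the
#' gene cluster family, regardless of copy number; families with no member
#' in any strain are absent.
#'
#' @param bgc_records data.frame with `genome_id` and `gcf_id` (every record
#'   must carry a family id).
#' @return binary integer matrix, strains x GCFs.
#' @export
build_presence <- function(bgc_records) {
  check_columns(bgc_records, c("genome_id", "gcf_id"), "bgc_records")
  missing <- is.na(bgc_records$gcf_id) | bgc_records$gcf_id == ""
  if (any(missing)) {
    ids <- if (!is.null(bgc_records$bgc_id)) bgc_records$bgc_id[missing]
    else paste0("row ", which(missing))
    stop_invalid("BGC record(s) without gcf_id: ", paste(ids, collapse = ", "))
  }
  tab <- table(bgc_records$genome_id, bgc_records$gcf_id)
  m <- matrix(as.integer(tab > 0), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  m
}

#' Keep only features with MS2 spectra
#'
#' @param table a [feature_table] whose `feature_meta` has a logical
#'   `has_ms2` column.
#' @return filtered [feature_table]; sample set unchanged.
#' @export
filter_ms2 <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$feature_meta$has_ms2) ||
      any(is.na(table$feature_meta$has_ms2)))
    stop_invalid("has_ms2 must be defined for every feature")
  keep <- table$feature_meta$has_ms2
  if (!any(keep)) warning("no features carry MS2 spectra; empty table")
  feature_table(table$abundance[, keep, drop = FALSE],
                table$feature_meta[keep, , drop = FALSE],
                table$sample_meta)
}

#' Normalize a feature table
#'
#' `tic` scales each sample to unit total abundance (total ion current);
#' `log1p_tic` (default) additionally applies `log1p`, which stabilizes
#' Bray-Curtis distances against single dominant features; `none` is the
#' identity. All-zero samples are left unchanged with a warning.
#'
#' @param table a [feature_table].
#' @param method `"log1p_tic"`, `"tic"`, or `"none"`.
#' @return normalized [feature_table].
#' @export
normalize_features <- function(table,
                               method = c("log1p_tic", "tic", "none")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (method == "none") return(table)
  ab <- table$abundance
  tot <- rowSums(ab)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) left unnormalized")
    tot[zero] <- 1
  }
  ab <- ab / tot
  if (method == "log1p_tic") ab <- log1p(ab)
  feature_table(ab, table$feature_meta, table$sample_meta)
}

#' Collapse a feature table to one row per strain
#'
#' Arithmetic mean of each feature over the strain's samples; needed when a
#' strain-level metabolome is compared against a strain-level tree. Sample
#' metadata is collapsed to strain-level fields (columns constant within a
#' strain are kept).
#'
#' @param table a [feature_table] whose `sample_meta` has a `strain` column.
#' @return [feature_table] with one row per strain (sample ids = strains).
#' @export
aggregate_by_strain <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  check_columns(table$sample_meta, "strain", "sample_meta")
  strains <- unique(table$sample_meta$strain)
  ab <- t(vapply(strains, function(s) {
    idx <- table$sample_meta$strain == s
    if (!any(idx)) stop_invalid("strain ", s, " has no samples")
    colMeans(table$abundance[idx, , drop = FALSE])
  }, numeric(ncol(table$abundance))))
  rownames(ab) <- strains
  meta_cols <- names(table$sample_meta)
  keep <- vapply(meta_cols, function(col) {
    all(vapply(strains, function(s) {
      length(unique(table$sample_meta[[col]][table$sample_meta$strain == s])) == 1L
    }, logical(1)))
  }, logical(1))
  sm <- unique(table$sample_meta[, meta_cols[keep], drop = FALSE])
  sm <- sm[match(strains, sm$strain), , drop = FALSE]
  sm$sample_id <- strains
  rownames(sm) <- NULL
  feature_table(ab, table$feature_meta,
                sm[, c("sample_id", setdiff(names(sm), "sample_id")),
                   drop = FALSE])
}

#' Pathway-category composition of a feature set
#'
#' Counts features per pathway category and computes the percentage of the
#' total at full precision; uncategorized features are assigned to
#' `"unknown"` with a warning.
#'
#' @param feature_meta data.frame with `feature_id` and `category`, or a
#'   [feature_table].
#' @return data.frame with `category`, `n`, `pct`, ordered by decreasing
#'   count; `pct` sums to 100.
#' @export
category_composition <- function(feature_meta) {
  if (inherits(feature_meta, "feature_table"))
    feature_meta <- feature_meta$feature_meta
  check_columns(feature_meta, "feature_id", "feature_meta")
  cat_col <- feature_meta$category
  if (is.null(cat_col)) cat_col <- rep(NA_character_, nrow(feature_meta))
  if (any(is.na(cat_col) | cat_col == "")) {
    warning(sum(is.na(cat_col) | cat_col == ""),
            " uncategorized feature(s) assigned to 'unknown'")
    cat_col[is.na(cat_col) | cat_col == ""] <- "unknown"
  }
  tab <- sort(table(cat_col), decreasing = TRUE)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
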