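## Plain-text readers and writers for the pipeline's table formats.
## All tables are TSV with named columns (order-free); the feature
## quantification table is CSV with samples as columns, MZmine-style.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read and write labeled square distance matrices as TSV
#'
#' @param m labeled symmetric matrix.
#' @param path file path; first column holds the row labels.
#' @return `read_distance_tsv` returns the validated matrix;
#'   `write_distance_tsv` the path, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_square_labeled(m, basename(path))
  m
}

#' Read gene-call and BGC coordinate tables
#'
#' Column order is free; coordinates are 1-based inclusive.
#'
#' @param path TSV with the required named columns (`genome_id`,
#'   `contig_id`, `gene_id`/`bgc_id`, `start`, `stop`, ...).
#' @return data.frame.
#' @export
read_gene_calls <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("genome_id", "contig_id", "gene_id", "start", "stop"),
                basename(path))
  df
}

#' @rdname read_gene_calls
#' @export
read_bgc_table <- function(path) {
  df <- read_tsv(path)
  check_columns(df, c("genome_id", "contig_id", "bgc_id", "start", "stop"),
                basename(path))
  df
}

#' Read an MZmine-style feature quantification CSV with metadata sidecars
#'
#' The quantification CSV has one row per feature (`feature_id`, optional
#' `mz`, `rt`) and one column per sample; `feature_meta` and `sample_meta`
#' TSVs supply the MS2 flags, pathway categories, and sample groupings.
#'
#' @param quant_csv path to the feature x sample abundance CSV.
#' @param feature_meta_tsv TSV with `feature_id`, `has_ms2`, `category`.
#' @param sample_meta_tsv TSV with `sample_id`, `strain`, `medium`, ...
#' @return a [feature_table].
#' @export
read_feature_table <- function(quant_csv, feature_meta_tsv, sample_meta_tsv) {
  quant <- utils::read.csv(quant_csv, check.names = FALSE,
                           stringsAsFactors = FALSE)
  check_columns(quant, "feature_id", basename(quant_csv))
  fm <- read_tsv(feature_meta_tsv)
  sm <- read_tsv(sample_meta_tsv)
  check_columns(sm, "sample_id", basename(sample_meta_tsv))
  samp_cols <- intersect(names(quant), sm$sample_id)
  if (!length(samp_cols))
    stop_invalid("no sample columns of ", basename(quant_csv),
                 " match sample_meta sample ids")
  ab <- t(as.matrix(quant[, samp_cols, drop = FALSE]))
  colnames(ab) <- quant$feature_id
  fm <- fm[match(quant$feature_id, fm$feature_id), , drop = FALSE]
  sm <- sm[match(samp_cols, sm$sample_id), , drop = FALSE]
  feature_table(ab, fm, sm)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits every pipeline input as plain text: Newick tree, gene-call and BGC
#' TSVs, quantification CSV with metadata sidecars, strain/sample metadata,
#' GCF presence matrix, and the ground-truth tables.
#'
#' @param truth a `synthetic_truth` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_newick(truth$tree, p("tree.nwk"))
  write_tsv(truth$gene_calls, p("gene_calls.tsv"))
  write_tsv(truth$bgcs, p("bgcs.tsv"))
  write_tsv(truth$groups, p("strain_metadata.tsv"))
  write_tsv(truth$features$sample_meta, p("sample_metadata.tsv"))
  write_tsv(truth$features$feature_meta, p("feature_metadata.tsv"))
  quant <- data.frame(feature_id = colnames(truth$features$abundance),
                      t(truth$features$abundance), check.names = FALSE)
  utils::write.csv(quant, p("feature_quant.csv"), row.names = FALSE,
                   quote = FALSE)
  write_tsv(data.frame(strain = rownames(truth$gcf_presence),
                       truth$gcf_presence, check.names = FALSE),
            p("gcf_presence.tsv"))
  write_tsv(truth$bg_labels, p("bg_labels_truth.tsv"))
  invisible(c(tree = p("tree.nwk"), gene_calls = p("gene_calls.tsv"),
              bgcs = p("bgcs.tsv"), strain_metadata = p("strain_metadata.tsv"),
              sample_metadata = p("sample_metadata.tsv"),
              feature_metadata = p("feature_metadata.tsv"),
              feature_quant = p("feature_quant.csv"),
              gcf_presence = p("gcf_presence.tsv"),
              bg_labels = p("bg_labels_truth.tsv")))
}
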