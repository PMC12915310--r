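#' Validate a pipeline run configuration
#'
#' Schema-checks a run configuration (and any referenced input files)
#' without computing anything: required fields, exactly one of a `simulate`
#' block or an `inputs` block, table columns, and label cross-consistency
#' between tree leaves, matrices, and metadata. Problems are returned, not
#' raised.
#'
#' @param config a named list, or the path of a YAML file holding one. A
#'   `simulate` block carries [sim_config()] arguments; an `inputs` block
#'   carries file paths (`tree`, `gene_calls`, `bgcs`, `feature_quant`,
#'   `feature_metadata`, `sample_metadata`, `strain_metadata`).
#' @return character vector of problems; empty when the configuration is
#'   runnable.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (!is.list(config)) return("config must be a list or a YAML file path")
  if (is.null(config$seed)) add("seed is required")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    add("exactly one of a 'simulate' block or an 'inputs' block is required")
  if (has_sim && !has_inp) {
    ok <- tryCatch({
      do.call(sim_config, c(config$simulate,
                            list(seed = config$seed %||% 1)))
      TRUE
    }, error = function(e) {
      add(paste("simulate block:", conditionMessage(e)))
      FALSE
    })
    invisible(ok)
  }
  if (has_inp && !has_sim) {
    req <- c("tree", "feature_quant", "feature_metadata", "sample_metadata")
    for (f in req)
      if (is.null(config$inputs[[f]]))
        add(paste0("inputs block is missing '", f, "'"))
    paths <- unlist(config$inputs)
    for (pth in paths)
      if (!file.exists(pth)) add(paste("missing file:", pth))
    if (!length(problems)) {
      tree <- tryCatch(read_newick(config$inputs$tree),
                       error = function(e) NULL)
      if (is.null(tree)) add("tree is not parsable Newick")
      sm <- tryCatch(read_tsv(config$inputs$sample_metadata),
                     error = function(e) NULL)
      if (is.null(sm) || is.null(sm$sample_id) || is.null(sm$strain)) {
        add("sample_metadata needs sample_id and strain columns")
      } else {
        if (anyDuplicated(sm$sample_id))
          add(paste("duplicated sample id(s):",
                    paste(unique(sm$sample_id[duplicated(sm$sample_id)]),
                          collapse = ", ")))
        if (!is.null(tree)) {
          orphan <- setdiff(tree$tip.label, sm$strain)
          for (o in orphan)
            add(paste("tree leaf missing from sample metadata:", o))
        }
      }
    }
  }
  problems
}

pipeline_defaults <- function() {
  list(n_perm = 999, n_trees = 500,
       analyses = list(pangenome = TRUE, concordance = TRUE,
                       permanova = TRUE, rf = TRUE),
       normalize = "log1p_tic", ms2_only = TRUE)
}

#' Run the integrative concordance pipeline
#'
#' Executes the enabled stages in dependency order: obtain inputs (simulate
#' or load), pan-genome partitioning and BG mapping with a novelty summary,
#' GCF and metabolome profiles, Jaccard/Bray-Curtis distances with UPGMA
#' trees, tree-concordance and Mantel tests against the phylogeny, PERMANOVA
#' per grouping, and random-forest variance attribution. Every stage derives
#' its own seed from the global one, so a rerun with the same configuration
#' reproduces all outputs; when `output_dir` is set each stage also writes
#' its tables as TSV.
#'
#' @param config list or YAML path, see [validate_run_config()]. Optional
#'   fields: `n_perm` (default 999), `n_trees` (default 500), `analyses`
#'   toggles (`pangenome`, `concordance`, `permanova`, `rf`), `normalize`
#'   method, `ms2_only` flag.
#' @param output_dir optional directory for stage outputs.
#' @return object of class `run_report`: stage tables plus a `verdict`
#'   ranking the grouping criteria.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  problems <- validate_run_config(config)
  if (length(problems))
    stop_invalid("invalid run configuration:\n  ",
                 paste(problems, collapse = "\n  "))
  defs <- pipeline_defaults()
  for (nm in names(defs)) config[[nm]] <- config[[nm]] %||% defs[[nm]]
  for (nm in names(defs$analyses))
    config$analyses[[nm]] <- config$analyses[[nm]] %||% defs$analyses[[nm]]
  seed <- check_seed(config$seed)
  out <- if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    function(df, f) write_tsv(df, file.path(output_dir, f))
  } else function(df, f) invisible(NULL)
  report <- list(seed = seed, tables = list())

  ## ---- stage: inputs ----
  if (!is.null(config$simulate)) {
    simcfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    truth <- simulate_dataset(simcfg)
    tree <- truth$tree
    gene_calls <- truth$gene_calls
    bgcs <- truth$bgcs
    features <- truth$features
    strain_meta <- truth$groups
  } else {
    inp <- config$inputs
    tree <- read_newick(inp$tree)
    gene_calls <- if (!is.null(inp$gene_calls)) read_gene_calls(inp$gene_calls)
    bgcs <- if (!is.null(inp$bgcs)) read_bgc_table(inp$bgcs)
    features <- read_feature_table(inp$feature_quant, inp$feature_metadata,
                                   inp$sample_metadata)
    strain_meta <- if (!is.null(inp$strain_metadata))
      read_tsv(inp$strain_metadata)
  }
  message(sprintf("[inputs] %d strains, seed %d", length(tree$tip.label),
                  seed))

  ## ---- stage: pangenome ----
  if (isTRUE(config$analyses$pangenome) && !is.null(gene_calls) &&
      !is.null(gene_calls$cluster_id) && !is.null(bgcs) && nrow(bgcs)) {
    occ <- occurrence_from_gene_calls(gene_calls)
    partition <- partition_occurrence(occ)
    joined <- bgc_gene_join(gene_calls, bgcs)
    bg <- joined[joined$is_bg, c("cluster_id", "bgc_class")]
    profile_tab <- bg_partition_profile(partition, bg)
    novelty <- summarize_novelty(
      stats::setNames(bgcs$similarity_pct, bgcs$bgc_id))
    report$tables$partition <- as.data.frame(table(partition$partition))
    names(report$tables$partition) <- c("partition", "n_clusters")
    report$tables$bg_profile <- profile_tab
    report$tables$novelty <- data.frame(
      n_total = novelty$n_total, n_zero = novelty$n_zero,
      n_le50 = novelty$n_le50, n_eq100 = novelty$n_eq100,
      pct_zero = novelty$fractions["pct_zero"],
      pct_le50 = novelty$fractions["pct_le50"],
      pct_eq100 = novelty$fractions["pct_eq100"],
      mean_similarity = novelty$mean_similarity, row.names = NULL)
    out(report$tables$partition, "partition_counts.tsv")
    out(profile_tab, "bg_partition_profile.tsv")
    out(report$tables$novelty, "novelty_summary.tsv")
    message(sprintf("[pangenome] %d clusters, %d BGs, %d BGCs",
                    nrow(partition), sum(joined$is_bg), nrow(bgcs)))
  }

  ## ---- stage: profiles & distances ----
  presence <- if (!is.null(bgcs) && nrow(bgcs) && !is.null(bgcs$gcf_id))
    build_presence(bgcs)
  ft <- features
  if (isTRUE(config$ms2_only)) ft <- filter_ms2(ft)
  ft <- normalize_features(ft, config$normalize)
  strain_ft <- aggregate_by_strain(ft)
  d_metab_strain <- bray_curtis_matrix(strain_ft)
  d_metab_sample <- bray_curtis_matrix(ft)
  d_phylo <- patristic(tree)
  d_gcf <- if (!is.null(presence)) jaccard_matrix(presence)
  report$tables$category_composition <- category_composition(ft)
  out(report$tables$category_composition, "category_composition.tsv")

  ## ---- stage: concordance ----
  if (isTRUE(config$analyses$concordance)) {
    n_perm <- config$n_perm
    dend_metab <- upgma(d_metab_strain)
    pairs <- list(phylogeny_vs_metabolome = dend_metab)
    if (!is.null(d_gcf)) {
      dend_gcf <- upgma(d_gcf)
      pairs$phylogeny_vs_gcf <- dend_gcf
    }
    rows <- list()
    for (nm in names(pairs)) {
      sd1 <- derive_seed(seed, paste0("concord_p_", nm))
      sd2 <- derive_seed(seed, paste0("concord_g_", nm))
      cp <- permutation_null("cophenetic_pearson", tree, pairs[[nm]],
                             n_perm = n_perm, seed = sd1)
      bg <- permutation_null("bakers_gamma", tree, pairs[[nm]],
                             n_perm = n_perm, seed = sd2)
      rows[[nm]] <- data.frame(
        comparison = nm, cophenetic_pearson = cp$observed,
        pearson_p = cp$p_value, bakers_gamma = bg$observed,
        gamma_p = bg$p_value, n_perm = n_perm, stringsAsFactors = FALSE)
    }
    if (!is.null(d_gcf)) {
      mt <- mantel_test(d_phylo, d_gcf, n_perm = n_perm,
                        seed = derive_seed(seed, "mantel_gcf"))
      report$tables$mantel <- data.frame(
        comparison = "patristic_vs_gcf_jaccard", r = mt$observed,
        r_squared = mt$r_squared, p = mt$p_value, n_perm = n_perm)
      out(report$tables$mantel, "mantel.tsv")
    }
    report$tables$concordance <- do.call(rbind, rows)
    rownames(report$tables$concordance) <- NULL
    out(report$tables$concordance, "concordance.tsv")
    message(sprintf("[concordance] %d tree pairs, %d permutations",
                    length(pairs), n_perm))
  }

  ## ---- stage: PERMANOVA ----
  groupings <- intersect(c("medium", "clade", "source"),
                         names(ft$sample_meta))
  groupings <- groupings[vapply(groupings, function(g)
    length(unique(ft$sample_meta[[g]])) > 1, logical(1))]
  if (isTRUE(config$analyses$permanova) && length(groupings)) {
    rows <- lapply(groupings, function(g) {
      pr <- permanova(d_metab_sample,
                      stats::setNames(ft$sample_meta[[g]],
                                      ft$sample_meta$sample_id),
                      n_perm = config$n_perm,
                      seed = derive_seed(seed, paste0("permanova_", g)))
      data.frame(grouping = g, pseudo_F = pr$pseudo_F,
                 r_squared = pr$r_squared, p = pr$p_value,
                 df_between = pr$df_between, df_within = pr$df_within,
                 stringsAsFactors = FALSE)
    })
    report$tables$permanova <- do.call(rbind, rows)
    out(report$tables$permanova, "permanova.tsv")
    report$pcoa <- pcoa(d_metab_sample)
    message(sprintf("[permanova] groupings: %s",
                    paste(groupings, collapse = ", ")))
  }

  ## ---- stage: random forest ----
  if (isTRUE(config$analyses$rf) && length(groupings)) {
    cfg <- forest_config(n_trees = config$n_trees,
                         seed = derive_seed(seed, "forest"))
    cmp <- compare_groupings(ft$abundance, ft$sample_meta, groupings, cfg)
    report$tables$rf <- cmp$table
    report$rf <- cmp
    out(cmp$table, "rf_comparison.tsv")
    message(sprintf("[rf] %d trees per model", cfg$n_trees))
  }

  ## ---- verdict ----
  report$verdict <- pipeline_verdict(report$tables)
  if (!is.null(output_dir) && !is.null(report$verdict))
    out(report$verdict, "verdict.tsv")
  class(report) <- "run_report"
  report
}

## Rank grouping criteria by RF R^2, annotated with PERMANOVA significance.
pipeline_verdict <- function(tables) {
  if (is.null(tables$rf)) return(NULL)
  v <- tables$rf[, c("grouping", "r_squared")]
  if (!is.null(tables$permanova)) {
    m <- match(v$grouping, tables$permanova$grouping)
    v$permanova_p <- tables$permanova$p[m]
    v$significant <- !is.na(v$permanova_p) & v$permanova_p <= 0.05
  }
  v$rank <- seq_len(nrow(v))
  v
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  cat("  stages:", paste(names(x$tables), collapse = ", "), "\n")
  if (!is.null(x$verdict)) {
    cat("  verdict (grouping criteria ranked by RF R2):\n")
    for (i in seq_len(nrow(x$verdict))) {
      sig <- if (isTRUE(x$verdict$significant[i])) " [PERMANOVA significant]"
      else ""
      cat(sprintf("    %d. %-8s R2 = %.3f%s\n", i, x$verdict$grouping[i],
                  x$verdict$r_squared[i], sig))
    }
  }
  invisible(x)
}
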