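#' Simulation configuration for a synthetic strain collection
#'
#' Bundles every knob of the synthetic-data generator: the size of the strain
#' collection, the gain/loss dynamics of gene cluster families (GCFs) on the
#' phylogeny, and the variance components of the metabolome. The defaults
#' describe the study conditions used throughout the package's recovery
#' experiments: 15 strains fermented in two media with a medium-dominated
#' metabolome (`sigma_medium = 1` standard deviations on the log-abundance
#' scale, against `sigma_phylo = 0.3`, `sigma_source = 0`) and slowly evolving
#' GCF content (`gain_loss_rate = 0.3` events per unit branch length, giving
#' strong phylogenetic signal).
#'
#' @param n_strains number of strains (tree leaves), at least 3.
#' @param n_gcfs number of gene cluster families.
#' @param n_features number of metabolite features.
#' @param n_media number of culture media; the first two are named
#'   `"GYM"` and `"V22"`.
#' @param n_sources number of isolation sources (default 4: soil, desert,
#'   water, host).
#' @param n_clades number of phylogenetic clades cut from the tree.
#' @param tree_model tree prior; only `"yule"` (pure birth) is implemented.
#' @param gain_loss_rate symmetric presence/absence transition rate per unit
#'   branch length; 0 freezes every GCF at its root state.
#' @param source_fraction fraction of GCFs whose presence tracks one
#'   isolation source instead of the phylogeny.
#' @param effect_sizes named list with `sigma_phylo`, `sigma_medium`,
#'   `sigma_source`, `sigma_noise`: nonnegative standard deviations on the
#'   log-abundance scale.
#' @param genes_per_genome gene calls emitted per genome.
#' @param bgc_per_genome upper bound on BGC records per genome.
#' @param n_replicates fermentation replicates per strain x medium.
#' @param has_ms2_rate fraction of features flagged as carrying MS2 spectra.
#' @param category_weights named numeric vector of pathway-category sampling
#'   weights; defaults mirror the observed composition of an annotated
#'   650-feature molecular network.
#' @param seed integer seed fixing every downstream draw.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 15, n_gcfs = 40, n_features = 300,
                       n_media = 2, n_sources = 4, n_clades = 4,
                       tree_model = "yule",
                       gain_loss_rate = 0.3, source_fraction = 0,
                       effect_sizes = list(sigma_phylo = 0.3,
                                           sigma_medium = 1.0,
                                           sigma_source = 0.0,
                                           sigma_noise = 0.5),
                       genes_per_genome = 200, bgc_per_genome = 40,
                       n_replicates = 1, has_ms2_rate = 0.95,
                       category_weights = NULL, seed = 1) {
  tree_model <- match.arg(tree_model, "yule")
  cfg <- list(
    n_strains = check_count(n_strains, "n_strains", 3L),
    n_gcfs = check_count(n_gcfs, "n_gcfs", 2L),
    n_features = check_count(n_features, "n_features", 2L),
    n_media = check_count(n_media, "n_media", 2L),
    n_sources = check_count(n_sources, "n_sources", 2L),
    n_clades = check_count(n_clades, "n_clades", 2L),
    tree_model = tree_model,
    gain_loss_rate = check_nonneg(gain_loss_rate, "gain_loss_rate"),
    source_fraction = check_nonneg(source_fraction, "source_fraction"),
    effect_sizes = effect_sizes,
    genes_per_genome = check_count(genes_per_genome, "genes_per_genome", 1L),
    bgc_per_genome = check_count(bgc_per_genome, "bgc_per_genome", 0L),
    n_replicates = check_count(n_replicates, "n_replicates", 1L),
    has_ms2_rate = check_nonneg(has_ms2_rate, "has_ms2_rate"),
    category_weights = category_weights %||% default_category_weights(),
    seed = check_seed(seed)
  )
  if (cfg$source_fraction > 1) stop_invalid("source_fraction must be in [0, 1]")
  for (s in c("sigma_phylo", "sigma_medium", "sigma_source", "sigma_noise")) {
    if (is.null(cfg$effect_sizes[[s]]))
      stop_invalid("effect_sizes must contain ", s)
    check_nonneg(cfg$effect_sizes[[s]], s)
  }
  class(cfg) <- "sim_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic strain-collection configuration\n")
  cat(sprintf("  %d strains, %d GCFs, %d features, %d media x %d replicates\n",
              x$n_strains, x$n_gcfs, x$n_features, x$n_media, x$n_replicates))
  cat(sprintf("  gain/loss rate %.3g, source fraction %.3g\n",
              x$gain_loss_rate, x$source_fraction))
  es <- x$effect_sizes
  cat(sprintf("  sigmas: phylo %.3g, medium %.3g, source %.3g, noise %.3g\n",
              es$sigma_phylo, es$sigma_medium, es$sigma_source, es$sigma_noise))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

## Pathway-category sampling weights; proportions of an annotated molecular
## network of 650 MS2 features (233/164/117/25/11/10/6/84).
default_category_weights <- function() {
  c("alkaloids" = 233, "amino acids and peptides" = 164,
    "fatty acids" = 117, "carbohydrates" = 25, "terpenoids" = 11,
    "polyketides" = 10, "shikimates and phenylpropanoids" = 6,
    "unknown" = 84) / 650
}

bgc_class_vocabulary <- function() {
  c("Terpene", "NRPS", "RiPPs", "Type I PKS", "Other PKSs",
    "PKS-NRP_Hybrids", "NI-siderophore", "NAGGN", "Others")
}

## Class sampling weights loosely following observed genus-level BGC
## composition (Terpene-dominated, large hybrid "Others" fraction).
bgc_class_weights <- function() {
  c("Terpene" = 22.6, "NRPS" = 12.7, "RiPPs" = 12.9, "Type I PKS" = 8.9,
    "Other PKSs" = 11.7, "PKS-NRP_Hybrids" = 9.5, "NI-siderophore" = 0.3,
    "NAGGN" = 0.2, "Others" = 21.2)
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Draws a binary rooted ultrametric tree with exponential waiting times
#' between speciation events (birth rate 1, no extinction) and labels the
#' leaves `S01 ... Snn`.
#'
#' @param n_strains number of leaves, at least 3.
#' @param seed integer seed.
#' @return an [ape::phylo] tree with strictly positive branch lengths.
#' @export
simulate_tree <- function(n_strains, seed) {
  n_strains <- check_count(n_strains, "n_strains", 3L)
  with_seed(seed, {
    tree <- ape::rphylo(n_strains, birth = 1, death = 0)
    tree$tip.label <- sprintf("S%02d", seq_len(n_strains))
    tree
  })
}

#' Assign isolation sources and clades to strains
#'
#' Sources are drawn uniformly (each source guaranteed at least one strain
#' when possible); clades are cut from the tree by average-linkage clustering
#' of patristic distances, so they respect the phylogeny.
#'
#' @param tree a rooted `phylo` tree.
#' @param n_sources,n_clades numbers of groups.
#' @param seed integer seed.
#' @return data.frame with columns `strain`, `source`, `clade`.
#' @export
assign_groups <- function(tree, n_sources = 4, n_clades = 4, seed = 1) {
  strains <- tree$tip.label
  n <- length(strains)
  n_sources <- min(check_count(n_sources, "n_sources", 2L), n)
  n_clades <- min(check_count(n_clades, "n_clades", 2L), n)
  src_levels <- c("soil", "desert", "water", "host",
                  paste0("source", seq_len(max(0, n_sources - 4))))[seq_len(n_sources)]
  with_seed(seed, {
    src <- sample(rep(src_levels, length.out = n))
    pat <- ape::cophenetic.phylo(tree)
    hc <- stats::hclust(stats::as.dist(pat), method = "average")
    ct <- stats::cutree(hc, k = n_clades)
    data.frame(strain = strains, source = src,
               clade = paste0("clade", unname(ct[strains])),
               stringsAsFactors = FALSE)
  })
}

#' Simulate GCF presence/absence on a phylogeny
#'
#' Each gene cluster family evolves as a two-state (present/absent)
#' continuous-time Markov chain along the tree with symmetric transition rate
#' `gain_loss_rate`; the root state is a fair coin flip. Optionally a fraction
#' of GCFs ignore the phylogeny and instead track one randomly chosen
#' isolation source (presence probability 0.8 inside the source group, 0.2
#' outside). Strains left with an empty profile are redrawn.
#'
#' @param tree rooted `phylo` tree whose tips are the strains.
#' @param n_gcfs number of families.
#' @param gain_loss_rate symmetric transition rate per unit branch length.
#' @param source_fraction fraction of source-driven GCFs in `[0, 1]`.
#' @param group_assignments data.frame from [assign_groups()] (required when
#'   `source_fraction > 0`).
#' @param seed integer seed.
#' @return binary matrix strains x GCFs with a `"source_driven"` attribute
#'   marking the non-phylogenetic columns.
#' @export
simulate_gcf_matrix <- function(tree, n_gcfs, gain_loss_rate,
                                source_fraction = 0, group_assignments = NULL,
                                seed = 1) {
  n_gcfs <- check_count(n_gcfs, "n_gcfs", 1L)
  gain_loss_rate <- check_nonneg(gain_loss_rate, "gain_loss_rate")
  if (source_fraction < 0 || source_fraction > 1)
    stop_invalid("source_fraction must be in [0, 1]")
  if (source_fraction > 0 && is.null(group_assignments))
    stop_invalid("group_assignments required when source_fraction > 0")
  strains <- tree$tip.label
  n <- length(strains)
  with_seed(seed, {
    tr <- stats::reorder(tree, "cladewise")  # parents precede children
    n_node <- n + tr$Nnode
    root <- n + 1L
    ## flip probability over a branch of length t under the symmetric chain
    pflip <- 0.5 * (1 - exp(-2 * gain_loss_rate * tr$edge.length))
    states <- matrix(NA_integer_, n_node, n_gcfs)
    states[root, ] <- stats::rbinom(n_gcfs, 1L, 0.5)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      flip <- stats::runif(n_gcfs) < pflip[e]
      states[child, ] <- ifelse(flip, 1L - states[par, ], states[par, ])
    }
    m <- states[seq_len(n), , drop = FALSE]
    rownames(m) <- tr$tip.label
    m <- m[strains, , drop = FALSE]
    colnames(m) <- sprintf("GCF%03d", seq_len(n_gcfs))

    src_cols <- integer(0)
    if (source_fraction > 0) {
      n_src <- round(source_fraction * n_gcfs)
      src_cols <- sort(sample.int(n_gcfs, n_src))
      src <- group_assignments$source[match(strains, group_assignments$strain)]
      for (j in src_cols) {
        g <- sample(unique(src), 1L)
        p <- ifelse(src == g, 0.8, 0.2)
        m[, j] <- stats::rbinom(n, 1L, p)
      }
    }

    ## no strain may have an all-zero profile; redraw its leaf states from
    ## its parent along the pendant branch
    for (i in seq_len(n)) {
      tip_idx <- match(strains[i], tr$tip.label)
      ei <- match(tip_idx, tr$edge[, 2L])
      par_states <- states[tr$edge[ei, 1L], ]
      pf <- pflip[ei]
      tries <- 0L
      while (sum(m[i, ]) == 0L && tries < 50L) {
        flip <- stats::runif(n_gcfs) < pf
        m[i, ] <- ifelse(flip, 1L - par_states, par_states)
        tries <- tries + 1L
      }
      if (sum(m[i, ]) == 0L && gain_loss_rate > 0)
        warning("strain ", strains[i], " has an empty GCF profile")
    }
    attr(m, "source_driven") <- colnames(m)[src_cols]
    storage.mode(m) <- "integer"
    m
  })
}

#' Simulate a metabolite feature table with known variance components
#'
#' Log-abundance of feature f in the sample of strain s grown in medium m is
#' `mu_f + sigma_medium * a[f,m] + sigma_phylo * b_f * z_s +
#' sigma_source * c[f, src(s)] + sigma_noise * eps`, where `z_s` is a
#' Brownian-motion trait on the tree (variance equal to the root-to-leaf path
#' length) and `a`, `b`, `c`, `eps` are independent standard normal draws;
#' abundances are exponentiated. The phylogenetic effect is channelled
#' through the Brownian trait, not through GCF content, so the medium,
#' source, and phylogeny knobs are orthogonal by construction.
#'
#' @param truth list with at least `tree` (phylo) and `groups` (data.frame
#'   `strain`, `source`); typically a partial [simulate_dataset()] result.
#' @param effect_sizes named list of the four sigmas (see [sim_config()]).
#' @param n_features number of metabolite features.
#' @param seed integer seed.
#' @param media character vector of medium names.
#' @param n_replicates samples per strain x medium.
#' @param has_ms2_rate fraction of features flagged `has_ms2`.
#' @param category_weights pathway-category sampling weights.
#' @return a [feature_table] with complete feature and sample metadata.
#' @export
simulate_metabolome <- function(truth, effect_sizes, n_features, seed,
                                media = c("GYM", "V22"), n_replicates = 1,
                                has_ms2_rate = 0.95,
                                category_weights = NULL) {
  n_features <- check_count(n_features, "n_features", 2L)
  tree <- truth$tree
  groups <- truth$groups
  strains <- tree$tip.label
  if (is.null(groups) || any(!strains %in% groups$strain))
    stop_invalid("truth$groups must assign a source to every strain")
  es <- effect_sizes
  for (s in c("sigma_phylo", "sigma_medium", "sigma_source", "sigma_noise"))
    check_nonneg(es[[s]] %||% stop_invalid("effect_sizes must contain ", s), s)
  category_weights <- category_weights %||% default_category_weights()

  samples <- expand.grid(replicate = seq_len(n_replicates), medium = media,
                         strain = strains, stringsAsFactors = FALSE)
  samples <- samples[, c("strain", "medium", "replicate")]
  samples$source <- groups$source[match(samples$strain, groups$strain)]
  samples$clade <- groups$clade[match(samples$strain, groups$strain)]
  if (any(is.na(samples$medium)))
    stop_invalid("every sample needs a medium assignment")
  samples$sample_id <- if (n_replicates > 1)
    sprintf("%s_%s_r%d", samples$strain, samples$medium, samples$replicate)
  else sprintf("%s_%s", samples$strain, samples$medium)

  with_seed(seed, {
    mu <- stats::rnorm(n_features, mean = 8, sd = 1)
    a <- matrix(stats::rnorm(n_features * length(media)), n_features,
                dimnames = list(NULL, media))
    b <- stats::rnorm(n_features)
    sources <- unique(groups$source)
    cc <- matrix(stats::rnorm(n_features * length(sources)), n_features,
                 dimnames = list(NULL, sources))
    z <- ape::rTraitCont(tree, model = "BM", sigma = 1)

    n_samp <- nrow(samples)
    logab <- matrix(NA_real_, n_samp, n_features)
    for (i in seq_len(n_samp)) {
      logab[i, ] <- mu +
        es$sigma_medium * a[, samples$medium[i]] +
        es$sigma_phylo * b * z[samples$strain[i]] +
        es$sigma_source * cc[, samples$source[i]] +
        es$sigma_noise * stats::rnorm(n_features)
    }
    abundance <- exp(logab)
    feat_ids <- sprintf("F%04d", seq_len(n_features))
    dimnames(abundance) <- list(samples$sample_id, feat_ids)

    feature_meta <- data.frame(
      feature_id = feat_ids,
      mz = round(stats::runif(n_features, 100, 1500), 4),
      rt = round(stats::runif(n_features, 0.5, 18), 3),
      has_ms2 = stats::runif(n_features) < has_ms2_rate,
      category = sample(names(category_weights), n_features, replace = TRUE,
                        prob = category_weights),
      stringsAsFactors = FALSE
    )
    sample_meta <- samples[, c("sample_id", "strain", "medium", "source",
                               "clade", "replicate")]
    feature_table(abundance, feature_meta, sample_meta)
  })
}

#' Emit gene-call and BGC coordinate tables with ground-truth labels
#'
#' Fabricates per-genome gene calls (1-based inclusive coordinates,
#' non-overlapping, on two contigs) and BGC intervals, each spanning a
#' contiguous run of at least two genes, so that a gene's ground-truth
#' biosynthetic label is full containment in some BGC interval. Each genome
#' receives one BGC per GCF present in the strain, capped at
#' `bgc_per_genome`. Gene calls carry pan-genome `cluster_id`s with a mix of
#' universally shared, patchily shared, and genome-private clusters.
#'
#' @param truth list with `tree` and `gcf_presence` (strains x GCFs binary).
#' @param genes_per_genome gene calls per genome.
#' @param bgc_per_genome cap on BGC records per genome (0 for none).
#' @param seed integer seed.
#' @return list with `gene_calls`, `bgcs`, and `bg_labels` data.frames.
#' @export
emit_coordinate_tables <- function(truth, genes_per_genome, bgc_per_genome,
                                   seed) {
  genes_per_genome <- check_count(genes_per_genome, "genes_per_genome", 1L)
  bgc_per_genome <- check_count(bgc_per_genome, "bgc_per_genome", 0L)
  strains <- truth$tree$tip.label
  presence <- truth$gcf_presence
  classes <- bgc_class_vocabulary()
  cw <- bgc_class_weights()[classes]

  with_seed(seed, {
    gene_rows <- list(); bgc_rows <- list(); label_rows <- list()
    for (g in strains) {
      n_genes <- genes_per_genome
      ## split genes over two contigs (one if too few genes)
      n_contigs <- if (n_genes >= 8) 2L else 1L
      contig_of <- rep(seq_len(n_contigs), length.out = n_genes)
      contig_of <- sort(contig_of)
      ## coordinates: sequential non-overlapping intervals per contig
      start <- stop <- integer(n_genes)
      pos <- stats::setNames(rep(1L, n_contigs), seq_len(n_contigs))
      for (j in seq_len(n_genes)) {
        ct <- contig_of[j]
        gap <- sample(50:200, 1L)
        len <- sample(300:1500, 1L)
        start[j] <- pos[ct] + gap
        stop[j] <- start[j] + len - 1L
        pos[ct] <- stop[j] + 1L
      }
      ## pan-genome cluster ids: first 30% universal, rest 60% shared / else
      ## genome-private singleton
      n_core <- ceiling(0.3 * n_genes)
      cl <- character(n_genes)
      for (j in seq_len(n_genes)) {
        cl[j] <- if (j <= n_core || stats::runif(1) < 0.6)
          sprintf("GC%04d", j) else sprintf("GC_%s_%03d", g, j)
      }
      genes <- data.frame(
        genome_id = g, contig_id = sprintf("%s_c%d", g, contig_of),
        gene_id = sprintf("%s_g%03d", g, seq_len(n_genes)),
        start = start, stop = stop,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        cluster_id = cl, stringsAsFactors = FALSE
      )

      ## BGC placement: contiguous free runs of genes per contig
      is_bg <- rep(FALSE, n_genes)
      gcfs_here <- colnames(presence)[presence[g, ] == 1L]
      n_bgc <- min(bgc_per_genome, length(gcfs_here))
      gcf_pick <- if (n_bgc > 0) sample(gcfs_here, n_bgc) else character(0)
      free <- lapply(seq_len(n_contigs), function(ct) {
        idx <- which(contig_of == ct)
        if (length(idx)) list(c(min(idx), max(idx))) else list()
      })
      b <- 0L
      for (gcf in gcf_pick) {
        L <- sample(2:4, 1L)
        placed <- FALSE
        for (ct in sample(seq_len(n_contigs))) {
          for (k in seq_along(free[[ct]])) {
            rng <- free[[ct]][[k]]
            if (rng[2] - rng[1] + 1L >= L) {
              off <- sample.int(rng[2] - rng[1] + 2L - L, 1L) - 1L
              lo <- rng[1] + off; hi <- lo + L - 1L
              is_bg[lo:hi] <- TRUE
              b <- b + 1L
              bgc_rows[[length(bgc_rows) + 1L]] <- data.frame(
                genome_id = g, contig_id = sprintf("%s_c%d", g, ct),
                bgc_id = sprintf("%s_bgc%02d", g, b),
                start = start[lo], stop = stop[hi],
                bgc_class = sample(classes, 1L, prob = cw),
                similarity_pct = draw_similarity(),
                gcf_id = gcf, stringsAsFactors = FALSE
              )
              ## carve the used run (plus a one-gene buffer) out of the
              ## free list so BGCs never touch
              newfree <- list()
              if (lo - 1L >= rng[1] + 1L) newfree <- c(newfree, list(c(rng[1], lo - 2L)))
              if (rng[2] >= hi + 2L) newfree <- c(newfree, list(c(hi + 2L, rng[2])))
              free[[ct]] <- c(free[[ct]][-k], newfree)
              placed <- TRUE
              break
            }
          }
          if (placed) break
        }
        if (!placed)
          stop_invalid("genes_per_genome too small to place ",
                       "bgc_per_genome BGC runs in genome ", g,
                       "; raise genes_per_genome")
      }
      genes$is_bg_truth <- is_bg
      gene_rows[[g]] <- genes
      label_rows[[g]] <- data.frame(genome_id = g, gene_id = genes$gene_id,
                                    is_bg = is_bg, stringsAsFactors = FALSE)
    }
    gene_calls <- do.call(rbind, gene_rows)
    rownames(gene_calls) <- NULL
    bgcs <- if (length(bgc_rows)) do.call(rbind, bgc_rows) else
      data.frame(genome_id = character(0), contig_id = character(0),
                 bgc_id = character(0), start = integer(0), stop = integer(0),
                 bgc_class = character(0), similarity_pct = numeric(0),
                 gcf_id = character(0), stringsAsFactors = FALSE)
    rownames(bgcs) <- NULL
    bg_labels <- do.call(rbind, label_rows)
    rownames(bg_labels) <- NULL
    list(gene_calls = gene_calls, bgcs = bgcs, bg_labels = bg_labels)
  })
}

## Similarity-to-known-cluster score mimicking a novelty-heavy genus:
## point masses at 0 (unknown) and 100 (known compound), low-skewed body.
draw_similarity <- function() {
  u <- stats::runif(1)
  if (u < 0.21) return(0)
  if (u > 0.975) return(100)
  round(100 * stats::rbeta(1, 1.2, 3.5), 1)
}

#' Generate a complete synthetic dataset
#'
#' Runs the full generator: Yule tree, group assignments, GCF
#' presence/absence, metabolite feature table, and coordinate tables, all
#' driven by one seed (stage seeds are derived deterministically).
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_truth`: list with `tree`, `groups`,
#'   `gcf_presence`, `features`, `gene_calls`, `bgcs`, `bg_labels`,
#'   `effect_sizes`, and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  tree <- simulate_tree(config$n_strains, derive_seed(seed, "tree"))
  groups <- assign_groups(tree, config$n_sources, config$n_clades,
                          derive_seed(seed, "groups"))
  truth <- list(tree = tree, groups = groups)
  truth$gcf_presence <- simulate_gcf_matrix(
    tree, config$n_gcfs, config$gain_loss_rate, config$source_fraction,
    groups, derive_seed(seed, "gcf"))
  media <- c("GYM", "V22", sprintf("medium%d", seq_len(max(0, config$n_media - 2))))
  truth$features <- simulate_metabolome(
    truth, config$effect_sizes, config$n_features,
    derive_seed(seed, "metabolome"), media = media[seq_len(config$n_media)],
    n_replicates = config$n_replicates, has_ms2_rate = config$has_ms2_rate,
    category_weights = config$category_weights)
  coords <- emit_coordinate_tables(truth, config$genes_per_genome,
                                   config$bgc_per_genome,
                                   derive_seed(seed, "coords"))
  truth$gene_calls <- coords$gene_calls
  truth$bgcs <- coords$bgcs
  truth$bg_labels <- coords$bg_labels
  truth$effect_sizes <- config$effect_sizes
  truth$config <- config
  class(truth) <- "synthetic_truth"
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic strain collection\n")
  cat(sprintf("  %d strains, %d GCFs, %d features, %d samples\n",
              length(x$tree$tip.label), ncol(x$gcf_presence),
              nrow(x$features$feature_meta), nrow(x$features$sample_meta)))
  cat(sprintf("  %d gene calls, %d BGC records\n",
              nrow(x$gene_calls), nrow(x$bgcs)))
  invisible(x)
}
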