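# Synthetic 450K-like cohort generation with known planted structure.
#
# Every downstream stage of the framework (screening, selection, fusion
# classifier, panel selection, network scoring) is exercised against cohorts
# produced here, so the generator carries explicit ground truth: which CpGs
# are differential, which genes are effectors, which network nodes are hubs,
# which gene sets are over-represented.

#' Simulation configuration for a synthetic methylation cohort
#'
#' Defaults mirror the study conditions of the motivating cohort: 94 cases
#' versus 31 controls pooled from three array datasets, with a modest number
#' of truly differential CpGs planted at a group mean beta difference of
#' 0.25.
#'
#' @param n_cases Number of case (OA, label 1) samples.
#' @param n_controls Number of control (label 0) samples.
#' @param n_cpg Total number of CpG probes.
#' @param n_dm Number of planted differentially methylated CpGs
#'   (`n_dm <= n_cpg`).
#' @param delta_beta Target absolute group mean beta difference at planted
#'   sites, on the \[0,1\] beta scale.
#' @param base_alpha,base_beta Shape parameters of the Beta distribution from
#'   which per-CpG baseline mean methylation levels are drawn.
#' @param precision Beta-distribution precision (alpha+beta) of the
#'   within-group sampling distribution around each CpG's mean; larger values
#'   give tighter beta values.
#' @param n_batches Number of batches (emulated source datasets); samples are
#'   assigned round-robin.
#' @param batch_shift_sd Standard deviation of the additive per-(batch, CpG)
#'   Gaussian location shift.
#' @param n_genes Number of annotated genes.
#' @param window_bp TSS window half-width in base pairs used when linking
#'   CpGs to genes.
#' @param n_effectors Number of genes designated as known effector genes.
#' @param effector_dm_frac Fraction of planted DM sites placed inside an
#'   effector gene's TSS window.
#' @param missing_rate Fraction of beta values set missing (`NA`); 0 by
#'   default.
#' @param seed Integer RNG seed; generation is reproducible for a fixed seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cases = 94L, n_controls = 31L, n_cpg = 2000L,
                       n_dm = 100L, delta_beta = 0.25,
                       base_alpha = 2, base_beta = 2, precision = 50,
                       n_batches = 3L, batch_shift_sd = 0.05,
                       n_genes = 300L, window_bp = 2000L,
                       n_effectors = min(40L, n_genes), effector_dm_frac = 0.5,
                       missing_rate = 0, seed = 1L) {
  cfg <- list(
    n_cases = assert_count(n_cases, "n_cases"),
    n_controls = assert_count(n_controls, "n_controls"),
    n_cpg = assert_count(n_cpg, "n_cpg"),
    n_dm = assert_count(n_dm, "n_dm", min = 0L),
    delta_beta = assert_number(delta_beta, "delta_beta", 0, 1,
                               strict_lower = TRUE, strict_upper = TRUE),
    base_alpha = assert_number(base_alpha, "base_alpha", 0, Inf, TRUE),
    base_beta = assert_number(base_beta, "base_beta", 0, Inf, TRUE),
    precision = assert_number(precision, "precision", 1, Inf),
    n_batches = assert_count(n_batches, "n_batches"),
    batch_shift_sd = assert_number(batch_shift_sd, "batch_shift_sd", 0, 1),
    n_genes = assert_count(n_genes, "n_genes"),
    window_bp = assert_count(window_bp, "window_bp"),
    n_effectors = assert_count(n_effectors, "n_effectors"),
    effector_dm_frac = assert_number(effector_dm_frac, "effector_dm_frac", 0, 1),
    missing_rate = assert_number(missing_rate, "missing_rate", 0, 1),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$n_dm > cfg$n_cpg) {
    stop_oam("n_dm (%d) exceeds n_cpg (%d)", cfg$n_dm, cfg$n_cpg)
  }
  if (cfg$n_effectors > cfg$n_genes) {
    stop_oam("n_effectors (%d) exceeds n_genes (%d)", cfg$n_effectors, cfg$n_genes)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic methylation cohort with planted differential sites
#'
#' Draws per-CpG baseline mean methylation from a Beta distribution, samples
#' individual beta values from a Beta distribution around the group mean with
#' fixed precision, shifts the case-group mean by `delta_beta` at the planted
#' sites (half hypermethylated, half hypomethylated), applies additive
#' per-(batch, CpG) Gaussian location shifts, and clips to \[0,1\].
#'
#' Gene annotation is built jointly: genes are laid out along chromosomes
#' chr1..chr22, a configurable fraction of planted DM sites is positioned
#' inside the TSS window of a designated effector gene, and every CpG's gene
#' links are recomputed from the final geometry, so the annotation is
#' internally consistent.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `beta` (a [beta_matrix()]), `annotation`
#'   (a [cpg_annotation()]), and `truth` (list with `dm_cpg_ids`,
#'   `dm_direction`, `effector_genes`, `dm_in_effector`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- config$n_cases + config$n_controls
  labels <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
  sample_ids <- sprintf("S%03d", seq_len(n_samp))
  cpg_ids <- sprintf("cg%08d", seq_len(config$n_cpg))

  # --- gene layout -----------------------------------------------------
  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  gene_chrom <- paste0("chr", ((seq_len(config$n_genes) - 1L) %% 22L) + 1L)
  # genes on the same chromosome are spaced 50 kb apart: windows never overlap
  gene_idx_on_chrom <- ave(seq_len(config$n_genes), gene_chrom, FUN = seq_along)
  gene_tss <- 100000L + (gene_idx_on_chrom - 1L) * 50000L
  gene_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  effector_genes <- sort(sample(gene_ids, config$n_effectors))

  # --- CpG placement ---------------------------------------------------
  # planted DM sites: a controllable fraction inside effector TSS windows
  dm_idx <- sort(sample.int(config$n_cpg, config$n_dm))
  n_in_eff <- round(config$effector_dm_frac * config$n_dm)
  dm_in_eff <- if (n_in_eff > 0) dm_idx[seq_len(n_in_eff)] else integer(0)

  chrom <- character(config$n_cpg)
  pos <- integer(config$n_cpg)
  near_gene <- sample.int(config$n_genes, config$n_cpg, replace = TRUE)
  offset <- as.integer(round(stats::runif(config$n_cpg, -4000, 4000)))
  # ~half of background CpGs are pushed out of any TSS window
  far <- stats::runif(config$n_cpg) < 0.5
  offset[far] <- offset[far] + as.integer(sign(offset[far] + 0.5)) * 8000L
  chrom <- gene_chrom[near_gene]
  pos <- pmax(1L, gene_tss[near_gene] + offset)
  # force the designated DM sites inside an effector window
  if (length(dm_in_eff) > 0) {
    eff_idx <- match(effector_genes, gene_ids)
    host <- sample(eff_idx, length(dm_in_eff), replace = TRUE)
    chrom[dm_in_eff] <- gene_chrom[host]
    pos[dm_in_eff] <- pmax(1L, gene_tss[host] +
      as.integer(round(stats::runif(length(dm_in_eff),
                                    -config$window_bp, config$window_bp))))
  }

  # --- beta values -----------------------------------------------------
  mu <- stats::rbeta(config$n_cpg, config$base_alpha, config$base_beta)
  # planted sites: keep headroom so the shifted mean stays inside (0,1)
  direction <- rep_len(c(1, -1), config$n_dm)
  lo <- ifelse(direction > 0, 0.10, 0.10 + config$delta_beta + 0.05)
  hi <- ifelse(direction > 0, 0.90 - config$delta_beta - 0.05, 0.90)
  if (config$n_dm > 0) {
    mu[dm_idx] <- stats::runif(config$n_dm, lo, hi)
  }
  mu_mat <- matrix(mu, config$n_cpg, n_samp)
  if (config$n_dm > 0) {
    shift <- direction * config$delta_beta
    mu_mat[dm_idx, labels == 1L] <- mu_mat[dm_idx, labels == 1L] + shift
  }
  mu_mat <- pmin(pmax(mu_mat, 1e-4), 1 - 1e-4)
  values <- matrix(
    stats::rbeta(length(mu_mat), mu_mat * config$precision,
                 (1 - mu_mat) * config$precision),
    config$n_cpg, n_samp
  )

  # --- batch structure -------------------------------------------------
  batch <- paste0("B", ((seq_len(n_samp) - 1L) %% config$n_batches) + 1L)
  for (b in unique(batch)) {
    shift_b <- stats::rnorm(config$n_cpg, 0, config$batch_shift_sd)
    values[, batch == b] <- values[, batch == b] + shift_b
  }
  values <- pmin(pmax(values, 0), 1)

  if (config$missing_rate > 0) {
    miss <- stats::runif(length(values)) < config$missing_rate
    values[miss] <- NA_real_
  }
  dimnames(values) <- list(cpg_ids, sample_ids)

  joint <- sample(c("knee", "hip"), n_samp, replace = TRUE)
  bm <- beta_matrix(values, labels = labels, batch = batch, joint = joint)

  annotation <- build_annotation(cpg_ids, chrom, pos, gene_ids, gene_chrom,
                                 gene_tss, gene_strand, config$window_bp)
  truth <- list(
    dm_cpg_ids = cpg_ids[dm_idx],
    dm_direction = ifelse(direction > 0, "hyper", "hypo"),
    effector_genes = effector_genes,
    dm_in_effector = cpg_ids[dm_in_eff]
  )
  list(beta = bm, annotation = annotation, truth = truth)
}

# Recompute gene links from geometry: a CpG is linked to every gene on its
# chromosome whose TSS lies within window_bp (at most 2 links kept, nearest
# first).  Quadratic within chromosome; fine at simulation scale.
build_annotation <- function(cpg_ids, chrom, pos, gene_ids, gene_chrom,
                             gene_tss, gene_strand, window_bp) {
  links <- vector("list", length(cpg_ids))
  for (ch in unique(chrom)) {
    ci <- which(chrom == ch)
    gi <- which(gene_chrom == ch)
    if (length(gi) == 0) next
    for (i in ci) {
      d <- abs(pos[i] - gene_tss[gi])
      hit <- gi[d <= window_bp]
      if (length(hit) > 0) {
        hit <- hit[order(abs(pos[i] - gene_tss[hit]))]
        hit <- hit[seq_len(min(2L, length(hit)))]
        links[[i]] <- data.frame(
          cpg_id = cpg_ids[i], gene = gene_ids[hit],
          tss = gene_tss[hit], strand = gene_strand[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  link_df <- do.call(rbind, links[!vapply(links, is.null, logical(1))])
  if (is.null(link_df)) {
    link_df <- data.frame(cpg_id = character(0), gene = character(0),
                          tss = integer(0), strand = character(0))
  }
  cpg_annotation(
    probes = data.frame(cpg_id = cpg_ids, chrom = chrom, pos = pos,
                        stringsAsFactors = FALSE),
    links = link_df
  )
}

#' Generate a synthetic interaction network with planted hubs
#'
#' Builds a STRING-like undirected edge list in which `n_hubs` designated
#' nodes are wired to a large fraction of the remaining nodes, while
#' non-hub nodes carry only sparse random edges; each edge receives an
#' integer combined score drawn uniformly from `score_range`.
#'
#' @param genes Character vector of node identifiers.
#' @param n_hubs Number of planted high-centrality nodes.
#' @param score_range Integer pair; inclusive range of combined scores
#'   (STRING convention, 0-1000).
#' @param seed Integer RNG seed.
#' @param hub_attach_frac Fraction of non-hub nodes each hub connects to.
#' @return A list with `network` (an [interaction_network()]) and `truth`
#'   (list with `hub_nodes`).
#' @export
generate_interaction_network <- function(genes, n_hubs, score_range = c(400L, 999L),
                                         seed = 1L, hub_attach_frac = 0.6) {
  if (length(genes) == 0) stop_oam("empty gene list")
  n_hubs <- assert_count(n_hubs, "n_hubs", min = 0L)
  if (n_hubs > length(genes)) stop_oam("n_hubs exceeds number of genes")
  set.seed(assert_count(seed, "seed", min = 0L))
  genes <- as.character(genes)
  hubs <- if (n_hubs > 0) sort(sample(genes, n_hubs)) else character(0)
  others <- setdiff(genes, hubs)

  edges <- list()
  for (h in hubs) {
    k <- max(3L, round(hub_attach_frac * length(others)))
    tgt <- sample(others, min(k, length(others)))
    edges[[length(edges) + 1L]] <- data.frame(a = h, b = tgt,
                                              stringsAsFactors = FALSE)
  }
  # sparse background: each non-hub gets 1-2 random partners among non-hubs
  if (length(others) > 1) {
    for (g in others) {
      k <- sample(1:2, 1)
      tgt <- sample(setdiff(others, g), min(k, length(others) - 1L))
      edges[[length(edges) + 1L]] <- data.frame(a = g, b = tgt,
                                                stringsAsFactors = FALSE)
    }
  }
  ed <- do.call(rbind, edges)
  # canonical undirected form, dedup
  key <- ifelse(ed$a < ed$b, paste(ed$a, ed$b), paste(ed$b, ed$a))
  ed <- ed[!duplicated(key), , drop = FALSE]
  ed$combined_score <- as.integer(round(stats::runif(nrow(ed),
                                                     score_range[1], score_range[2])))
  net <- interaction_network(
    edges = data.frame(node_a = pmin(ed$a, ed$b), node_b = pmax(ed$a, ed$b),
                       combined_score = ed$combined_score,
                       stringsAsFactors = FALSE),
    nodes = sort(unique(genes))
  )
  list(network = net, truth = list(hub_nodes = hubs))
}

#' Generate synthetic gene-set collections with planted enrichment
#'
#' A designated query gene list is over-sampled by the planted-enriched
#' sets (a high fraction of their members come from the query list), while
#' the remaining sets draw members uniformly from the full gene universe.
#'
#' @param genes Character vector: the gene universe.
#' @param n_sets Number of gene sets.
#' @param enriched_fraction Fraction of sets with planted enrichment.
#' @param seed Integer RNG seed.
#' @param query_genes Designated query list over-sampled by enriched sets;
#'   defaults to the first tenth of `genes`.
#' @param set_size_range Integer pair; inclusive range of set sizes.
#' @param enriched_overlap Fraction of an enriched set's members drawn from
#'   `query_genes`.
#' @return A list with `sets` (named list of character vectors, class
#'   `gene_set_collection`) and `truth` (list with `enriched_sets`,
#'   `query_genes`).
#' @export
generate_gene_sets <- function(genes, n_sets, enriched_fraction, seed = 1L,
                               query_genes = NULL,
                               set_size_range = c(10L, 50L),
                               enriched_overlap = 0.8) {
  n_sets <- assert_count(n_sets, "n_sets")
  assert_number(enriched_fraction, "enriched_fraction", 0, 1)
  set.seed(assert_count(seed, "seed", min = 0L))
  genes <- as.character(genes)
  if (is.null(query_genes)) {
    query_genes <- genes[seq_len(max(1L, floor(length(genes) / 10)))]
  }
  n_enriched <- round(enriched_fraction * n_sets)
  set_names <- sprintf("SET%03d", seq_len(n_sets))
  enriched <- set_names[seq_len(n_enriched)]
  sets <- vector("list", n_sets)
  names(sets) <- set_names
  for (i in seq_len(n_sets)) {
    sz <- sample(set_size_range[1]:set_size_range[2], 1)
    sz <- min(sz, length(genes))
    if (set_names[i] %in% enriched) {
      n_q <- min(round(enriched_overlap * sz), length(query_genes))
      members <- c(sample(query_genes, n_q),
                   sample(setdiff(genes, query_genes), sz - n_q))
    } else {
      members <- sample(genes, sz)
    }
    sets[[i]] <- sort(unique(members))
  }
  class(sets) <- "gene_set_collection"
  list(sets = sets,
       truth = list(enriched_sets = enriched, query_genes = query_genes))
}

#' Write a gene-set collection to a GMT file
#'
#' GMT format: one set per line, tab-separated as
#' `set name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param sets Named list of character vectors (class `gene_set_collection`
#'   accepted).
#' @param path Output file path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (length(sets) == 0) stop_oam("empty gene-set collection")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file path.
#' @return Named list of character vectors with class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad) > 0) {
    stop_oam("malformed GMT line %d: fewer than 3 fields", bad[1])
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  class(sets) <- "gene_set_collection"
  sets
}
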