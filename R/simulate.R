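#' Simulate a scale-free interaction network with a planted module
#'
#' Draws a Barabasi-Albert preferential-attachment graph over \code{n_genes}
#' labelled genes (approximate mean degree \code{mean_degree}) and selects a
#' connected planted subgraph of \code{planted_size} nodes by breadth-first
#' expansion from a uniformly chosen start node. Starting from a random node
#' rather than a hub keeps recovery of the planted set from being trivially
#' easy.
#'
#' @param n_genes Number of genes (network nodes).
#' @param mean_degree Target mean degree (>= 2). The default 24 matches the
#'   density of curated high-confidence physical interactome resources
#'   (order 150,000 interactions among order 13,000 proteins).
#' @param planted_size Size of the planted connected gene set
#'   (< \code{n_genes}).
#' @param seed Optional integer seed.
#' @return List with \code{network} (igraph, vertex names \code{G0001}, ...)
#'   and \code{planted} (character vector of planted gene ids).
#' @export
simulate_network <- function(n_genes, mean_degree = 24, planted_size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (planted_size >= n_genes) stop("planted_size must be < n_genes", call. = FALSE)
  if (mean_degree < 2) stop("mean_degree must be >= 2", call. = FALSE)
  m <- max(1L, as.integer(round(mean_degree / 2)))
  g <- igraph::sample_pa(n_genes, m = m, directed = FALSE)
  igraph::V(g)$name <- sprintf("G%05d", seq_len(n_genes))
  igraph::graph_attr(g, "provenance") <- "global"

  start <- sample.int(n_genes, 1L)
  ord <- igraph::bfs(g, root = start, unreachable = FALSE, order = TRUE)$order
  ord <- as.integer(ord)
  ord <- ord[!is.na(ord)]
  if (length(ord) < planted_size) {
    stop("network too sparse: reachable component smaller than planted_size",
         call. = FALSE)
  }
  planted <- igraph::V(g)$name[ord[seq_len(planted_size)]]
  list(network = g, planted = planted)
}

#' Simulate gene models and SNP positions on a synthetic genome
#'
#' Genes are placed sequentially on a single synthetic chromosome with random
#' inter-gene gaps wide enough that scoring windows (110 kb upstream / 40 kb
#' downstream by default) never overlap, so each SNP maps to at most one
#' gene. Each gene receives \code{snps_per_gene} SNPs uniformly placed inside
#' its strand-aware window, and \code{n_intergenic} SNPs are placed in the
#' gaps outside every window.
#'
#' @param genes Character vector of gene ids.
#' @param snps_per_gene SNPs placed inside each gene's window.
#' @param n_intergenic SNPs placed outside all windows.
#' @param window_up,window_down Scoring window extents in bp.
#' @param genome_length Optional total chromosome length; an error is raised
#'   if the genes do not fit. Defaults to the required length.
#' @param seed Optional integer seed.
#' @return List with \code{gene_models} (data.frame gene_id, chrom, strand,
#'   tx_start, tx_end) and \code{snps} (data.frame snp_id, chrom, pos,
#'   source_gene with NA for intergenic SNPs).
#' @export
simulate_gene_models_and_snps <- function(genes, snps_per_gene = 5L,
                                          n_intergenic = 500L,
                                          window_up = 110000L,
                                          window_down = 40000L,
                                          genome_length = NULL,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(genes)
  w <- max(window_up, window_down)
  # gap > 2*w guarantees disjoint windows whatever the strands
  gaps <- as.integer(round(runif(n, 2 * w + 10000, 2 * w + 60000)))
  lens <- as.integer(round(runif(n, 2000, 50000)))
  tx_start <- w + 1L + cumsum(gaps) + cumsum(c(0L, lens[-n]))
  tx_end <- tx_start + lens - 1L
  need <- tx_end[n] + w + 1L
  if (is.null(genome_length)) genome_length <- need
  if (genome_length < need) {
    stop("genome_length ", genome_length, " too small; need ", need, call. = FALSE)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_models <- data.frame(gene_id = genes, chrom = "chr1", strand = strand,
                            tx_start = tx_start, tx_end = tx_end,
                            stringsAsFactors = FALSE)

  win_start <- ifelse(strand == "+", tx_start - window_up, tx_start - window_down)
  win_end <- ifelse(strand == "+", tx_end + window_down, tx_end + window_up)

  genic_pos <- unlist(lapply(seq_len(n), function(i) {
    as.integer(round(runif(snps_per_gene, win_start[i], win_end[i])))
  }))
  genic <- data.frame(
    snp_id = sprintf("rs%05d_%d", rep(seq_len(n), each = snps_per_gene),
                     rep(seq_len(snps_per_gene), n)),
    chrom = "chr1",
    pos = genic_pos,
    source_gene = rep(genes, each = snps_per_gene),
    stringsAsFactors = FALSE
  )

  snps <- genic
  if (n_intergenic > 0) {
    # free intervals strictly between consecutive windows (and flanks)
    free_lo <- c(1L, win_end + 1L)
    free_hi <- c(win_start - 1L, genome_length)
    ok <- free_hi - free_lo > 2L
    free_lo <- free_lo[ok] + 1L
    free_hi <- free_hi[ok] - 1L
    widths <- free_hi - free_lo + 1L
    seg <- sample.int(length(widths), n_intergenic, replace = TRUE,
                      prob = widths)
    pos <- free_lo[seg] +
      as.integer(floor(runif(n_intergenic) * widths[seg]))
    inter <- data.frame(
      snp_id = sprintf("rsI%05d", seq_len(n_intergenic)),
      chrom = "chr1", pos = pos, source_gene = NA_character_,
      stringsAsFactors = FALSE
    )
    snps <- rbind(snps, inter)
  }
  list(gene_models = gene_models, snps = snps)
}

#' Simulate paired discovery/validation GWAS summary statistics
#'
#' Standard GWAS asymptotics for a quantitative trait in phenotype-SD units:
#' each SNP gets an effect-allele frequency f ~ Uniform(0.05, 0.5) (common
#' variants only, mirroring the usual MAF < 5\% exclusion), a per-cohort
#' standard error se = 1/sqrt(2 f (1-f) n), an estimate
#' beta_hat ~ Normal(true_effect * causal, se), and a two-sided normal
#' p-value. The causal effect is shared (same sign and size) across the two
#' cohorts; the noise is independent, matching a two-cohort replication
#' design. Allele frequencies and allele labels are shared across cohorts.
#'
#' @param snps Data.frame with snp_id, chrom, pos (e.g. from
#'   [simulate_gene_models_and_snps()]).
#' @param causal_snps Character vector of causal SNP ids.
#' @param true_effect Per-allele causal effect in phenotype-SD units.
#' @param n_discovery,n_validation Cohort sample sizes.
#' @param seed Optional integer seed.
#' @return List with \code{discovery} and \code{validation} summary-stat
#'   data.frames (columns as in [read_summary_stats()]).
#' @export
simulate_summary_stats <- function(snps, causal_snps = character(0),
                                   true_effect = 0, n_discovery = 126L,
                                   n_validation = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(snps)
  f <- runif(n, 0.05, 0.5)
  pair <- t(vapply(seq_len(n),
                   function(i) sample(c("A", "C", "G", "T"), 2L),
                   character(2)))
  causal <- snps$snp_id %in% causal_snps
  mu <- ifelse(causal, true_effect, 0)

  one_cohort <- function(nc) {
    se <- 1 / sqrt(2 * f * (1 - f) * nc)
    beta <- rnorm(n, mean = mu, sd = se)
    p <- 2 * pnorm(-abs(beta / se))
    data.frame(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
               effect_allele = pair[, 1], other_allele = pair[, 2],
               beta = beta, se = se, pvalue = pmax(p, 1e-300), eaf = f,
               stringsAsFactors = FALSE)
  }
  list(discovery = one_cohort(n_discovery),
       validation = one_cohort(n_validation))
}

#' Simulate a per-gene expression summary table
#'
#' A \code{fraction_low} share of the non-planted genes receive a
#' 25th-percentile RPKM from Uniform(0, 1) (below the pruning threshold); all
#' other genes, including every planted gene, receive Uniform(1, 100), so the
#' planted truth always survives expression pruning. Keep-listed genes get no
#' special expression treatment here; their protection operates in
#' [prune_network()].
#'
#' @param genes Character vector of gene ids.
#' @param planted Genes guaranteed expression >= 1.
#' @param fraction_low Share of non-planted genes drawn below the threshold.
#' @param seed Optional integer seed.
#' @return Data.frame with gene_id and rpkm_q25.
#' @export
simulate_expression <- function(genes, planted = character(0),
                                fraction_low = 0.33, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (fraction_low < 0 || fraction_low >= 1) {
    stop("fraction_low must lie in [0, 1)", call. = FALSE)
  }
  rpkm <- runif(length(genes), 1, 100)
  eligible <- !(genes %in% planted)
  low <- eligible & runif(length(genes)) < fraction_low
  rpkm[low] <- runif(sum(low), 0, 1)
  data.frame(gene_id = genes, rpkm_q25 = rpkm, stringsAsFactors = FALSE)
}

#' Simulate a complete two-cohort network-GWAS study
#'
#' Generates, under one seed, every input the pipeline consumes: a scale-free
#' interaction network with a connected planted module, non-overlapping gene
#' models with window-resident SNPs plus an intergenic pool, an expression
#' table in which the planted genes always survive pruning, a transcription
#' factor style keep-list, and paired discovery/validation summary statistics
#' in which one causal SNP per planted gene carries the association signal.
#'
#' Defaults mirror the study design the pipeline targets: discovery n = 126
#' and validation n = 100 individuals, a per-allele effect of 0.65 phenotype
#' SD (calibrated so the median causal discovery p-value is about 1e-5 at
#' n = 126 with allele frequencies uniform on 0.05-0.5), a 2,000-gene
#' network of interactome-like density with a 30-gene planted module, 5
#' SNPs per gene window, and about a third of background genes lowly
#' expressed (the global-to-tissue attrition seen when pruning a
#' whole-organism interaction map to one cell type).
#'
#' @param n_genes,mean_degree,planted_size Network parameters.
#' @param snps_per_gene,n_intergenic SNP placement parameters.
#' @param true_effect Causal per-allele effect (SD units); 0 gives a global
#'   null study.
#' @param n_discovery,n_validation Cohort sizes.
#' @param fraction_low Share of non-planted genes below the expression
#'   threshold.
#' @param n_keep_list Number of lowly-expressed-but-protected genes named on
#'   the keep-list (sampled from non-planted genes).
#' @param seed Integer seed fixing every output byte.
#' @param config Pipeline configuration (window sizes are taken from it).
#' @return List with network, planted, gene_models, snps, expression,
#'   keep_list, discovery, validation, and a \code{truth} record
#'   (planted_genes, causal_snps, true_effect, n_discovery, n_validation).
#' @export
simulate_study <- function(n_genes = 2000L, mean_degree = 24,
                           planted_size = 30L, snps_per_gene = 5L,
                           n_intergenic = 500L, true_effect = 0.65,
                           n_discovery = 126L, n_validation = 100L,
                           fraction_low = 0.33, n_keep_list = 20L,
                           seed = 1L, config = pipeline_config()) {
  set.seed(seed)
  net <- simulate_network(n_genes, mean_degree, planted_size)
  geno <- simulate_gene_models_and_snps(
    igraph::V(net$network)$name, snps_per_gene = snps_per_gene,
    n_intergenic = n_intergenic,
    window_up = config$window_up, window_down = config$window_down
  )
  # one causal SNP per planted gene: its first window SNP
  causal <- vapply(net$planted, function(g) {
    geno$snps$snp_id[which(geno$snps$source_gene == g)[1]]
  }, character(1))
  stats <- simulate_summary_stats(geno$snps, causal_snps = causal,
                                  true_effect = true_effect,
                                  n_discovery = n_discovery,
                                  n_validation = n_validation)
  expression <- simulate_expression(geno$gene_models$gene_id,
                                    planted = net$planted,
                                    fraction_low = fraction_low)
  low_genes <- expression$gene_id[expression$rpkm_q25 < config$rpkm_threshold]
  keep_list <- if (n_keep_list > 0 && length(low_genes) > 0) {
    sample(low_genes, min(n_keep_list, length(low_genes)))
  } else character(0)

  list(network = net$network,
       planted = net$planted,
       gene_models = geno$gene_models,
       snps = geno$snps,
       expression = expression,
       keep_list = keep_list,
       discovery = stats$discovery,
       validation = stats$validation,
       truth = list(planted_genes = net$planted,
                    causal_snps = causal,
                    true_effect = true_effect,
                    n_discovery = n_discovery,
                    n_validation = n_validation))
}

#' Write a simulated study to a fixture directory
#'
#' Emits the full plain-text fixture set: edge-list TSV, gene-model BED,
#' expression TSV, keep-list, discovery and validation summary-stat TSVs, and
#' the ground-truth JSON.
#'
#' @param study List from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    network = write_edge_list(study$network, file.path(dir, "network.tsv")),
    genes = write_gene_models(study$gene_models, file.path(dir, "genes.bed")),
    expression = write_expression(study$expression,
                                  file.path(dir, "expression.tsv")),
    discovery = write_summary_stats(study$discovery,
                                    file.path(dir, "discovery.tsv")),
    validation = write_summary_stats(study$validation,
                                     file.path(dir, "validation.tsv")),
    truth = write_truth(study$truth, file.path(dir, "truth.json"))
  )
  keep_path <- file.path(dir, "keep_list.txt")
  writeLines(study$keep_list, keep_path)
  invisible(c(files, keep_list = keep_path))
}
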