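# Small in-code fixture builders shared across test files.

# igraph from a two-column edge matrix given as c(a1,b1, a2,b2, ...)
toy_graph <- function(pairs, isolated = character(0)) {
  m <- matrix(pairs, ncol = 2, byrow = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = m[, 1], to = m[, 2]),
    directed = FALSE,
    vertices = data.frame(name = unique(c(m[, 1], m[, 2], isolated)))
  )
  igraph::simplify(g)
}

# gene-score table from named z values (p back-computed so p_to_z(p) == z)
toy_scores <- function(z) {
  data.frame(gene_id = names(z),
             p = pnorm(unname(z), lower.tail = FALSE),
             best_snp = paste0("snp_", names(z)),
             z = unname(z),
             stringsAsFactors = FALSE)
}

# minimal consensus_network object for replication tests
toy_consensus <- function(driving_snps) {
  genes <- names(driving_snps)
  structure(list(genes = genes,
                 occurrence = stats::setNames(rep(2L, length(genes)), genes),
                 driving_snps = driving_snps,
                 graph = igraph::make_empty_graph(directed = FALSE) +
                   igraph::vertices(genes),
                 modules = NULL),
            class = "consensus_network")
}

# random summary-stat table with valid invariants
random_stats <- function(n, prefix = "rs", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alleles <- t(vapply(seq_len(n),
                      function(i) sample(c("A", "C", "G", "T"), 2L),
                      character(2)))
  data.frame(snp_id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             pos = sample.int(1e7, n),
             effect_allele = alleles[, 1],
             other_allele = alleles[, 2],
             beta = rnorm(n, 0, 0.2),
             se = runif(n, 0.05, 0.3),
             pvalue = runif(n),
             eaf = runif(n, 0.05, 0.95),
             stringsAsFactors = FALSE)
}

# exhaustive SNP-to-gene window assignment (independent of IRanges)
brute_assign <- function(snps, genes, window_up = 110000, window_down = 40000) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    if (genes$strand[i] == "+") {
      lo <- genes$tx_start[i] - window_up
      hi <- genes$tx_end[i] + window_down
    } else {
      lo <- genes$tx_start[i] - window_down
      hi <- genes$tx_end[i] + window_up
    }
    hit <- snps$snp_id[snps$chrom == genes$chrom[i] &
                         snps$pos >= lo & snps$pos <= hi]
    if (length(hit) > 0) out[[genes$gene_id[i]]] <- sort(unique(hit))
  }
  out
}
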