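#' @importFrom utils read.delim write.table
NULL

SUMMARY_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                  "beta", "se", "pvalue")

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited summary-statistic file with a header naming the
#' columns \code{snp_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{beta}, \code{se}, \code{pvalue} and optionally
#' \code{eaf}. Rows violating the per-SNP invariants (se > 0,
#' 0 < pvalue <= 1, distinct alleles, finite beta) are dropped with a message
#' stating the reason; a duplicated \code{snp_id} is an error because silent
#' last-wins merges are the main corruption risk when combining cohorts.
#'
#' @param path Path to a tab-delimited file.
#' @return A data.frame of per-SNP association records, one row per SNP.
#' @export
read_summary_stats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(SUMMARY_COLS, names(df))
  if (length(missing) > 0) {
    stop("summary-stat file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  df <- df[c(SUMMARY_COLS, "eaf")]
  df$chrom <- as.character(df$chrom)
  df$snp_id <- as.character(df$snp_id)
  df$pos <- as.integer(df$pos)

  bad <- character(0)
  reject <- rep(FALSE, nrow(df))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) bad <<- c(bad, sprintf("%s (%s)", df$snp_id[cond], why))
    reject <<- reject | cond
  }
  flag(!(df$se > 0), "se <= 0")
  flag(!(df$pvalue > 0 & df$pvalue <= 1), "pvalue outside (0,1]")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(!is.finite(df$beta), "non-finite beta")
  if (length(bad) > 0) {
    message("read_summary_stats: rejected ", sum(reject), " row(s): ",
            paste(utils::head(bad, 10), collapse = "; "),
            if (length(bad) > 10) " ..." else "")
  }
  df <- df[!reject, , drop = FALSE]
  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    stop("duplicate snp_id in ", path, ": ",
         paste(unique(df$snp_id[dup]), collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]; the two round-trip exactly.
#'
#' @param stats Data.frame as returned by [read_summary_stats()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_summary_stats <- function(stats, path) {
  cols <- c(SUMMARY_COLS, if ("eaf" %in% names(stats)) "eaf")
  write.table(stats[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED file
#'
#' Expects six columns (chrom, start, end, gene_id, score placeholder,
#' strand) with BED's 0-based half-open coordinates; these are converted at
#' the boundary to the package's internal 1-based inclusive convention, so a
#' BED line \code{chr1 99 200} becomes \code{tx_start = 100, tx_end = 200}.
#' Strand "." is treated as "+" with a warning. The source annotation's
#' coordinate basis is an assumption of this reader, not something the
#' pipeline can check; see the methods vignette.
#'
#' @param path Path to a BED file (no header).
#' @return A data.frame with columns gene_id, chrom, strand, tx_start, tx_end.
#' @export
read_gene_models <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("gene-model BED needs 6 columns", call. = FALSE)
  names(df)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  if (any(df$start >= df$end)) {
    stop("gene-model BED has start >= end for: ",
         paste(df$gene_id[df$start >= df$end], collapse = ", "), call. = FALSE)
  }
  if (any(df$strand == ".")) {
    warning("strand '.' treated as '+' for ", sum(df$strand == "."),
            " gene(s)", call. = FALSE)
    df$strand[df$strand == "."] <- "+"
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("invalid strand value(s): ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(gene_id = as.character(df$gene_id),
                    chrom = as.character(df$chrom),
                    strand = df$strand,
                    tx_start = as.integer(df$start) + 1L,
                    tx_end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    stop("duplicate gene_id: ", paste(unique(out$gene_id[dup]), collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Write gene models as BED
#'
#' Converts the internal 1-based inclusive coordinates back to BED's 0-based
#' half-open convention (the exact inverse of [read_gene_models()]).
#'
#' @param genes Data.frame with gene_id, chrom, strand, tx_start, tx_end.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_models <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = genes$tx_start - 1L,
                    end = genes$tx_end,
                    gene_id = genes$gene_id,
                    score = 0L,
                    strand = genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-delimited gene-id columns (an optional third confidence column is
#' ignored for topology). The result is an undirected simple igraph: the edge
#' pairs (A,B) and (B,A) collapse to one edge, duplicates are merged, and
#' self-loops are dropped with a warning while their node is retained.
#'
#' @param path Path to the edge-list file (no header).
#' @return An undirected simple \code{igraph} with a \code{provenance} graph
#'   attribute set to \code{"global"}.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("edge list needs at least 2 columns", call. = FALSE)
  a <- as.character(df[[1]])
  b <- as.character(df[[2]])
  nodes <- unique(c(a, b))
  loops <- a == b
  if (any(loops)) {
    warning("dropped ", sum(loops), " self-loop(s)", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[!loops], to = b[!loops], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::graph_attr(g, "provenance") <- "global"
  g
}

#' Write a network as a two-column edge list
#'
#' @param network An \code{igraph} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_edge_list <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  write.table(as.data.frame(el), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene expression summary table
#'
#' Tab-delimited with header columns \code{gene_id} and \code{rpkm_q25}
#' (25th-percentile RPKM across samples).
#'
#' @param path Path to the table.
#' @return Data.frame with gene_id and rpkm_q25.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "rpkm_q25") %in% names(df))) {
    stop("expression table needs columns gene_id and rpkm_q25", call. = FALSE)
  }
  if (any(df$rpkm_q25 < 0)) stop("negative rpkm_q25", call. = FALSE)
  df[c("gene_id", "rpkm_q25")]
}

#' Write a per-gene expression summary table
#' @param expression Data.frame with gene_id and rpkm_q25.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(expression, path) {
  write.table(expression[c("gene_id", "rpkm_q25")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a keep-list of genes protected from expression pruning
#'
#' One gene id per line (e.g. tissue transcription factors that must not be
#' removed even when lowly expressed). Blank lines and lines starting with
#' \code{#} are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of gene ids.
#' @export
read_keep_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write the module report and consensus network
#'
#' Writes three files: \code{<prefix>_modules.tsv} (one row per ranked module:
#' rank, size, raw aggregate z, calibrated score, semicolon-joined member
#' genes), \code{<prefix>_consensus.gml} (the consensus network as GML), and
#' \code{<prefix>_consensus.tsv} (one row per consensus gene with its
#' occurrence count among the top second-order modules, driving SNP, and
#' gene-level p and z when \code{gene_scores} is supplied).
#'
#' @param modules Ranked module table from [greedy_search()].
#' @param consensus Consensus network from [second_order_consensus()].
#' @param path_prefix Path prefix for the three output files.
#' @param gene_scores Optional gene-score table to annotate consensus rows.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_module_report <- function(modules, consensus, path_prefix,
                                gene_scores = NULL) {
  if (nrow(modules) == 0) stop("empty module list", call. = FALSE)
  mod_path <- paste0(path_prefix, "_modules.tsv")
  mtab <- data.frame(rank = modules$rank,
                     size = modules$size,
                     z_raw = modules$z_raw,
                     score = modules$score,
                     genes = vapply(modules$genes, paste,
                                    character(1), collapse = ";"))
  write.table(mtab, mod_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gml_path <- paste0(path_prefix, "_consensus.gml")
  igraph::write_graph(consensus$graph, gml_path, format = "gml")

  cons_path <- paste0(path_prefix, "_consensus.tsv")
  genes <- consensus$genes
  ctab <- data.frame(gene_id = genes,
                     occurrence = unname(consensus$occurrence[genes]),
                     best_snp = unname(consensus$driving_snps[genes]),
                     stringsAsFactors = FALSE)
  if (!is.null(gene_scores)) {
    idx <- match(genes, gene_scores$gene_id)
    ctab$p <- gene_scores$p[idx]
    ctab$z <- gene_scores$z[idx]
  }
  write.table(ctab, cons_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(modules = mod_path, gml = gml_path, consensus = cons_path))
}

#' Write simulation ground truth as JSON
#' @param truth Truth list from [simulate_study()].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_truth <- function(truth, path) {
  truth$causal_snps <- as.list(truth$causal_snps)  # keep gene names in JSON
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read simulation ground truth JSON
#' @param path Path written by [write_truth()].
#' @return Truth list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$planted_genes <- as.character(x$planted_genes)
  x$causal_snps <- unlist(x$causal_snps)
  x
}
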