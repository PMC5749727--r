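#' Transform a p-value to a normal quantile score
#'
#' The gene (and SNP) score used throughout: z = Phi^-1(1 - p), the upper
#' normal quantile of the p-value. P-values are clamped to
#' [eps, 1 - eps] first so the score is always finite; p = 0.5 maps to 0 and
#' smaller p maps to larger z (strictly decreasing).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param eps Clamping bound (default 1e-12).
#' @return Numeric vector of z-scores.
#' @export
p_to_z <- function(p, eps = 1e-12) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  qnorm(pmin(pmax(p, eps), 1 - eps), lower.tail = FALSE)
}

#' Assign SNPs to genes by strand-aware scoring windows
#'
#' A SNP maps to a gene when it lies within the gene's scoring window: for a
#' "+" gene \code{[tx_start - window_up, tx_end + window_down]}, for a "-"
#' gene \code{[tx_start - window_down, tx_end + window_up]} (boundaries
#' inclusive, 1-based). The asymmetric window reflects where cis-regulatory
#' variation concentrates relative to the transcribed region. A SNP may map
#' to several genes if windows overlap; SNPs mapping to no window are
#' dropped.
#'
#' @param snps Data.frame with snp_id, chrom, pos.
#' @param genes Data.frame with gene_id, chrom, strand, tx_start, tx_end.
#' @param window_up,window_down Window extents in bp (non-negative).
#' @return Named list: for each gene with at least one mapped SNP, the
#'   character vector of mapped snp_ids. Genes with no SNPs are absent.
#' @export
assign_snps_to_genes <- function(snps, genes, window_up = 110000L,
                                 window_down = 40000L) {
  if (nrow(genes) == 0) stop("empty gene set", call. = FALSE)
  if (window_up < 0 || window_down < 0) {
    stop("windows must be non-negative", call. = FALSE)
  }
  plus <- genes$strand == "+"
  wstart <- ifelse(plus, genes$tx_start - window_up,
                   genes$tx_start - window_down)
  wend <- ifelse(plus, genes$tx_end + window_down,
                 genes$tx_end + window_up)

  out <- stats::setNames(vector("list", nrow(genes)), genes$gene_id)
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    si <- which(snps$chrom == chr)
    if (length(si) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = snps$pos[si], width = 1L),
      IRanges::IRanges(start = wstart[gi], end = wend[gi])
    )
    if (length(hits) == 0) next
    by_gene <- split(snps$snp_id[si][S4Vectors::queryHits(hits)],
                     S4Vectors::subjectHits(hits))
    for (j in names(by_gene)) {
      out[[gi[as.integer(j)]]] <- sort(unique(by_gene[[j]]))
    }
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Score genes by their minimum mapped SNP p-value
#'
#' Each gene is assigned the lowest p-value among the SNPs mapping to its
#' scoring window, the identity of that best SNP (ties broken by
#' lexicographic snp_id, so output is deterministic), and the derived score
#' z = Phi^-1(1 - p). Genes with no mapped SNPs are not scored.
#'
#' @param assignment Named list from [assign_snps_to_genes()].
#' @param snp_stats Summary-stat data.frame covering every assigned SNP.
#' @param eps Clamping bound passed to [p_to_z()].
#' @return Data.frame with gene_id, p, best_snp, z (one row per scored gene).
#' @export
score_genes <- function(assignment, snp_stats, eps = 1e-12) {
  if (length(assignment) == 0) {
    return(data.frame(gene_id = character(0), p = numeric(0),
                      best_snp = character(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pv <- stats::setNames(snp_stats$pvalue, snp_stats$snp_id)
  all_snps <- unique(unlist(assignment, use.names = FALSE))
  miss <- setdiff(all_snps, names(pv))
  if (length(miss) > 0) {
    stop("missing SNP statistics for: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ..." else "", call. = FALSE)
  }
  rows <- lapply(names(assignment), function(g) {
    ids <- sort(assignment[[g]])      # lexicographic order fixes tie-breaks
    p <- pv[ids]
    i <- which.min(p)                 # first minimum = lexicographic winner
    data.frame(gene_id = g, p = unname(p[i]), best_snp = ids[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$z <- p_to_z(out$p, eps = eps)
  rownames(out) <- NULL
  out
}
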