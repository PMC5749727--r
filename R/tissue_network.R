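#' Prune a global interaction network to a tissue-specific subnetwork
#'
#' Removes genes unlikely to be expressed in the target tissue: a gene is
#' removed when its 25th-percentile RPKM falls below \code{rpkm_threshold},
#' unless it appears on the keep-list (e.g. tissue transcription factors that
#' are biologically required but lowly expressed). Genes absent from the
#' expression table are treated as not expressed and removed unless
#' keep-listed, the conservative reading when expression evidence is
#' missing. The result is the induced subgraph on the surviving nodes;
#' isolated survivors are retained by default (they can still seed a module
#' search).
#'
#' @param network Undirected \code{igraph} (e.g. from [read_edge_list()]).
#' @param expression Data.frame with gene_id and rpkm_q25.
#' @param keep_list Character vector of protected gene ids.
#' @param rpkm_threshold Expression threshold (default 1).
#' @param drop_isolated Drop nodes left without edges after pruning
#'   (default FALSE).
#' @return The pruned \code{igraph}, with \code{provenance} attribute
#'   \code{"pruned"}.
#' @export
prune_network <- function(network, expression, keep_list = character(0),
                          rpkm_threshold = 1.0, drop_isolated = FALSE) {
  nodes <- igraph::V(network)$name
  expressed <- expression$gene_id[expression$rpkm_q25 >= rpkm_threshold]
  survivors <- intersect(nodes, union(expressed, keep_list))
  if (length(survivors) == 0) {
    stop("no nodes survive expression pruning", call. = FALSE)
  }
  pruned <- igraph::induced_subgraph(network, survivors)
  if (drop_isolated) {
    iso <- igraph::V(pruned)[igraph::degree(pruned) == 0]
    if (length(iso) > 0) pruned <- igraph::delete_vertices(pruned, iso)
  }
  igraph::graph_attr(pruned, "provenance") <- "pruned"
  message(sprintf(
    "prune_network: %d/%d nodes, %d/%d edges retained (threshold %.3g, %d keep-listed)",
    igraph::vcount(pruned), length(nodes),
    igraph::ecount(pruned), igraph::ecount(network),
    rpkm_threshold, length(keep_list)))
  pruned
}
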