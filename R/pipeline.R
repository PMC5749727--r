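#' Run the discovery stage: scores, pruning, calibration, modules, consensus
#'
#' Chains the discovery pipeline on in-memory inputs: SNP-to-gene assignment
#' and min-p gene scoring from the discovery cohort, expression pruning of
#' the global network, Monte-Carlo score calibration, greedy module search
#' from the top-scoring seeds, and second-order consensus distillation of the
#' top module.
#'
#' @param discovery Discovery summary-stat data.frame.
#' @param gene_models Gene-model data.frame.
#' @param network Global interaction \code{igraph}.
#' @param expression Expression summary data.frame.
#' @param keep_list Genes protected from pruning.
#' @param config Pipeline configuration from [pipeline_config()].
#' @param seed Optional integer seed for the stochastic stages.
#' @return List: assignment, gene_scores, pruned (igraph), calibration,
#'   modules (ranked), top_module (character vector), consensus.
#' @export
run_discovery <- function(discovery, gene_models, network, expression,
                          keep_list = character(0),
                          config = pipeline_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assignment <- assign_snps_to_genes(discovery, gene_models,
                                     window_up = config$window_up,
                                     window_down = config$window_down)
  gene_scores <- score_genes(assignment, discovery, eps = config$p_clamp_eps)
  pruned <- prune_network(network, expression, keep_list,
                          rpkm_threshold = config$rpkm_threshold)
  n_scored <- sum(igraph::V(pruned)$name %in% gene_scores$gene_id)
  max_k <- min(config$max_module_size, n_scored)
  calibration <- calibrate_scores(pruned, gene_scores,
                                  n_samples = config$n_calibration,
                                  max_k = max_k)
  modules <- greedy_search(pruned, gene_scores, calibration,
                           n_seeds = config$n_seeds, max_size = max_k)
  top_module <- modules$genes[[1]]
  consensus <- second_order_consensus(
    pruned, top_module, gene_scores,
    n_modules = config$n_second_order_modules,
    min_occurrence = config$min_occurrence,
    n_seeds = config$n_seeds,
    n_calibration = config$n_calibration
  )
  list(assignment = assignment, gene_scores = gene_scores, pruned = pruned,
       calibration = calibration, modules = modules,
       top_module = top_module, consensus = consensus)
}

#' Run the replication stage on a discovery-stage result
#'
#' Selects the consensus SNPs passing the discovery p-value cut, computes
#' their combined z-score in the validation cohort, tests it against random
#' same-size SNP sets drawn from the best SNPs of all scored network genes,
#' counts directional consistency (after allele alignment) for the sign
#' test, and meta-analyses the selected SNPs across the two cohorts.
#'
#' @param disc Result list from [run_discovery()].
#' @param discovery,validation The two cohorts' summary stats.
#' @param config Pipeline configuration.
#' @param seed Optional integer seed for the empirical null.
#' @return List: snps (selected ids), combined_z, empirical
#'   (\code{"empirical_test"}), n_consistent, n_total, sign_p, meta
#'   (per-SNP meta table), prs_weights (effect-raising discovery weights for
#'   downstream PRS use).
#' @export
run_replication <- function(disc, discovery, validation,
                            config = pipeline_config(), seed = NULL) {
  snps <- select_validation_snps(disc$consensus, discovery,
                                 p_threshold = config$snp_selection_p)
  if (length(snps) == 0) stop("no validation SNPs selected", call. = FALSE)
  combined_z <- combined_zscore(snps, validation, eps = config$p_clamp_eps)

  in_net <- disc$gene_scores$gene_id %in% igraph::V(disc$pruned)$name
  pool <- unique(disc$gene_scores$best_snp[in_net])
  m <- sum(snps %in% validation$snp_id)
  empirical <- empirical_snpset_test(combined_z, pool, m, validation,
                                     n_draws = config$n_empirical,
                                     seed = seed, eps = config$p_clamp_eps)

  aligned <- align_alleles(discovery, validation)
  sel <- aligned[aligned$snp_id %in% snps, , drop = FALSE]
  d_beta <- discovery$beta[match(sel$snp_id, discovery$snp_id)]
  n_consistent <- sum(sign(sel$beta) == sign(d_beta))
  n_total <- nrow(sel)
  sign_p <- sign_test(n_consistent, n_total)

  # genomic control belongs at the genome-wide level: meta-analyse every SNP
  # shared by the cohorts, then report the selected ones
  meta_all <- fixed_effect_meta(list(discovery = discovery,
                                     validation = aligned),
                                double_gc = TRUE)
  meta <- meta_all[meta_all$snp_id %in% snps, , drop = FALSE]
  attr(meta, "lambda_by_study") <- attr(meta_all, "lambda_by_study")
  attr(meta, "lambda_meta") <- attr(meta_all, "lambda_meta")

  # effect-raising orientation: weights are |discovery beta| for the chosen SNPs
  d_sel <- discovery[discovery$snp_id %in% snps, , drop = FALSE]
  prs_weights <- data.frame(snp_id = d_sel$snp_id,
                            weight = abs(d_sel$beta),
                            stringsAsFactors = FALSE)

  list(snps = snps, combined_z = combined_z, empirical = empirical,
       n_consistent = n_consistent, n_total = n_total, sign_p = sign_p,
       meta = meta, prs_weights = prs_weights)
}
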