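#' Pipeline configuration
#'
#' Bundles every tunable parameter of the network-GWAS pipeline with the
#' defaults used throughout: the gene scoring window (110 kb upstream / 40 kb
#' downstream of the transcribed region), the expression-pruning threshold
#' (25th-percentile RPKM < 1), the module search (top 100 seeds, Monte-Carlo
#' calibration with 100,000 random gene sets, 10 permuted-score reference
#' runs, consensus from the top 15 second-order modules with occurrence >= 2),
#' and the replication stage (SNP selection at discovery P < 5e-4, 100,000
#' random SNP sets for the empirical null, LD thresholds r^2 = 0.8).
#'
#' @param window_up Integer, bp upstream of the transcribed region a SNP may
#'   lie and still map to the gene (default 110000).
#' @param window_down Integer, bp downstream (default 40000).
#' @param rpkm_threshold Genes with 25th-percentile RPKM below this are
#'   removed from the tissue network unless keep-listed (default 1).
#' @param n_seeds Number of highest-scoring nodes used as greedy search
#'   starting points (default 100).
#' @param n_calibration Random gene sets per module size for the Monte-Carlo
#'   score calibration (default 100000; analyses at desk scale typically use
#'   10000).
#' @param n_score_permutations Permuted-score reference reruns (default 10).
#' @param n_second_order_modules Second-order modules contributing to the
#'   consensus (default 15).
#' @param min_occurrence Minimum occurrence among top second-order modules for
#'   a gene to enter the consensus (default 2, i.e. "more than once").
#' @param snp_selection_p Discovery p-value cutoff for validation SNPs
#'   (default 5e-4, strict less-than).
#' @param n_empirical Random SNP sets for the empirical combined-z null
#'   (default 100000).
#' @param ld_r2_prune r^2 threshold for greedy LD pruning (keep if below;
#'   default 0.8).
#' @param ld_r2_proxy r^2 threshold above which a proxy SNP extends a locus
#'   for regulatory-element overlap (default 0.8).
#' @param max_module_size Hard cap on greedy module growth and hence on the
#'   calibration table (default 300).
#' @param p_clamp_eps P-values are clamped to [eps, 1 - eps] before the
#'   normal-quantile transform so z stays finite (default 1e-12).
#' @param rng_seed Integer seed recorded with the run (default 1).
#'
#' @return A named list of class \code{"gwasnet_config"}.
#' @export
pipeline_config <- function(window_up = 110000L,
                            window_down = 40000L,
                            rpkm_threshold = 1.0,
                            n_seeds = 100L,
                            n_calibration = 100000L,
                            n_score_permutations = 10L,
                            n_second_order_modules = 15L,
                            min_occurrence = 2L,
                            snp_selection_p = 5e-4,
                            n_empirical = 100000L,
                            ld_r2_prune = 0.8,
                            ld_r2_proxy = 0.8,
                            max_module_size = 300L,
                            p_clamp_eps = 1e-12,
                            rng_seed = 1L) {
  cfg <- list(
    window_up = as.integer(window_up),
    window_down = as.integer(window_down),
    rpkm_threshold = rpkm_threshold,
    n_seeds = as.integer(n_seeds),
    n_calibration = as.integer(n_calibration),
    n_score_permutations = as.integer(n_score_permutations),
    n_second_order_modules = as.integer(n_second_order_modules),
    min_occurrence = as.integer(min_occurrence),
    snp_selection_p = snp_selection_p,
    n_empirical = as.integer(n_empirical),
    ld_r2_prune = ld_r2_prune,
    ld_r2_proxy = ld_r2_proxy,
    max_module_size = as.integer(max_module_size),
    p_clamp_eps = p_clamp_eps,
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("window_up", "window_down", "n_seeds", "n_calibration",
              "n_score_permutations", "n_second_order_modules",
              "min_occurrence", "n_empirical", "max_module_size")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop("config: '", nm, "' must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$rpkm_threshold < 0) stop("config: rpkm_threshold must be >= 0", call. = FALSE)
  if (cfg$snp_selection_p <= 0 || cfg$snp_selection_p > 1) {
    stop("config: snp_selection_p must lie in (0, 1]", call. = FALSE)
  }
  for (nm in c("ld_r2_prune", "ld_r2_proxy")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("config: '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$p_clamp_eps <= 0 || cfg$p_clamp_eps >= 0.5) {
    stop("config: p_clamp_eps must lie in (0, 0.5)", call. = FALSE)
  }
  class(cfg) <- "gwasnet_config"
  cfg
}

#' @export
print.gwasnet_config <- function(x, ...) {
  cat("gwasnet pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
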