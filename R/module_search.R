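#' Aggregate z-score of a node set
#'
#' The module score z_A = sum(z_i)/sqrt(k) over the k member genes, i.e. the
#' normalised sum of gene z-scores. Nodes without a gene score contribute 0
#' (the null-neutral value).
#'
#' @param nodes Character vector of gene ids (non-empty).
#' @param gene_scores Gene-score data.frame from [score_genes()].
#' @return The aggregate score, a single number.
#' @export
module_zscore <- function(nodes, gene_scores) {
  if (length(nodes) == 0) stop("empty node set", call. = FALSE)
  z <- gene_scores$z[match(nodes, gene_scores$gene_id)]
  z[is.na(z)] <- 0
  sum(z) / sqrt(length(nodes))
}

# z vector aligned to network vertices; unscored nodes get 0
node_scores <- function(network, gene_scores) {
  nodes <- igraph::V(network)$name
  z <- gene_scores$z[match(nodes, gene_scores$gene_id)]
  scored <- !is.na(z)
  z[!scored] <- 0
  list(z = z, scored = scored, nodes = nodes)
}

#' Monte-Carlo calibration of aggregate scores by module size
#'
#' Estimates, for every module size k up to \code{max_k}, the mean mu_k and
#' standard deviation sigma_k of the aggregate score z_A over uniformly drawn
#' k-subsets of the network's scored nodes (subsets are not required to be
#' connected). These reference moments turn a raw z_A into the calibrated
#' score (z_A - mu_k)/sigma_k, removing the size dependence that makes raw
#' aggregate scores incomparable across k.
#'
#' Each Monte-Carlo replicate draws one random ordering prefix of length
#' \code{max_k} and accumulates its cumulative sums, so a single replicate
#' yields one uniform k-subset for every k simultaneously; the per-k moment
#' estimates are unchanged and the table costs O(n_samples * max_k).
#'
#' @param network The search graph.
#' @param gene_scores Gene-score data.frame.
#' @param n_samples Monte-Carlo replicates (>= 100; 100000 for full runs).
#' @param max_k Largest module size covered (<= number of scored nodes).
#' @param seed Optional integer seed; the table is deterministic given it.
#' @param sigma_floor Lower bound applied to sigma_k so degenerate score
#'   vectors (e.g. all equal) cannot cause division blow-ups (default 1e-6).
#' @return An object of class \code{"calibration_table"}: list with
#'   \code{table} (data.frame k, mu, sigma, degenerate), \code{n_samples},
#'   and \code{universe} (the scored node ids sampled from).
#' @export
calibrate_scores <- function(network, gene_scores, n_samples = 10000L,
                             max_k, seed = NULL, sigma_floor = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  if (n_samples < 100) stop("n_samples must be >= 100", call. = FALSE)
  ns <- node_scores(network, gene_scores)
  z <- ns$z[ns$scored]
  universe <- ns$nodes[ns$scored]
  N <- length(z)
  if (N == 0) stop("no scored nodes in network", call. = FALSE)
  if (max_k > N) {
    stop("max_k (", max_k, ") exceeds number of scored nodes (", N, ")",
         call. = FALSE)
  }
  s1 <- numeric(max_k)
  s2 <- numeric(max_k)
  for (i in seq_len(n_samples)) {
    cs <- cumsum(z[sample.int(N, max_k)])
    s1 <- s1 + cs
    s2 <- s2 + cs * cs
  }
  ksqrt <- sqrt(seq_len(max_k))
  mean_sum <- s1 / n_samples
  var_sum <- pmax((s2 - n_samples * mean_sum^2) / (n_samples - 1), 0)
  mu <- mean_sum / ksqrt
  sigma <- sqrt(var_sum) / ksqrt
  degenerate <- sigma < sigma_floor
  if (any(degenerate)) {
    message("calibrate_scores: sigma floored at ", sigma_floor, " for ",
            sum(degenerate), " size(s)")
    sigma[degenerate] <- sigma_floor
  }
  structure(list(table = data.frame(k = seq_len(max_k), mu = mu,
                                    sigma = sigma, degenerate = degenerate),
                 n_samples = n_samples, universe = universe),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat("calibration table over", length(x$universe), "scored nodes,",
      x$n_samples, "samples, k up to", nrow(x$table), "\n")
  print(utils::head(x$table), ...)
  invisible(x)
}

#' Size-calibrated module score
#'
#' s_A = (z_A - mu_k) / sigma_k using the Monte-Carlo reference moments for
#' module size k.
#'
#' @param z_a Raw aggregate score(s).
#' @param k Module size(s), each covered by the table.
#' @param table A \code{"calibration_table"}.
#' @return Calibrated score(s).
#' @export
corrected_score <- function(z_a, k, table) {
  tab <- table$table
  if (any(k < 1) || any(k > nrow(tab))) {
    stop("module size ", paste(k[k < 1 | k > nrow(tab)], collapse = ", "),
         " not covered by calibration table", call. = FALSE)
  }
  (z_a - tab$mu[k]) / tab$sigma[k]
}

# Greedy expansion from one seed (integer-index internals).
# Adding the best neighbour means adding the max-z frontier node: with k
# fixed, the calibrated score is increasing in the added node's z.
greedy_one <- function(seed_idx, z, adj, mu, sigma, max_size,
                       keep_trace = FALSE) {
  n <- length(z)
  in_mod <- logical(n)
  in_front <- logical(n)
  mod <- integer(max_size)
  mod[1L] <- seed_idx
  in_mod[seed_idx] <- TRUE
  k <- 1L
  S <- z[seed_idx]
  s <- (S - mu[1L]) / sigma[1L]
  trace <- if (keep_trace) s else NULL
  front <- adj[[seed_idx]]
  front <- front[!in_mod[front]]
  in_front[front] <- TRUE
  while (k < max_size && length(front) > 0L) {
    j <- front[which.max(z[front])]
    k2 <- k + 1L
    S2 <- S + z[j]
    s2 <- (S2 / sqrt(k2) - mu[k2]) / sigma[k2]
    if (s2 <= s) break
    k <- k2
    S <- S2
    s <- s2
    mod[k] <- j
    in_mod[j] <- TRUE
    in_front[j] <- FALSE
    front <- front[front != j]
    nb <- adj[[j]]
    nb <- nb[!in_mod[nb] & !in_front[nb]]
    if (length(nb) > 0L) {
      in_front[nb] <- TRUE
      front <- c(front, nb)
    }
    if (keep_trace) trace <- c(trace, s)
  }
  list(nodes = mod[seq_len(k)], k = k, z_raw = S / sqrt(k), score = s,
       trace = trace)
}

#' Greedy active-module search
#'
#' From each of the \code{n_seeds} highest-scoring nodes, grows a connected
#' module by repeatedly adding the neighbouring node of the current module
#' that maximises the calibrated score, stopping when no addition improves it
#' or the size cap is reached. Unscored nodes (z = 0) cannot seed but may be
#' absorbed when they bridge high-scoring nodes. Identical node sets from
#' different seeds are collapsed when \code{dedup = TRUE}.
#'
#' @param network The search graph.
#' @param gene_scores Gene-score data.frame.
#' @param table Calibration table covering sizes up to \code{max_size}.
#' @param n_seeds Number of top-scoring seed nodes (default 100).
#' @param max_size Module growth cap (default: table coverage).
#' @param n_keep Return at most this many top modules (default all).
#' @param dedup Collapse identical node sets (default TRUE).
#' @param keep_trace Record the calibrated-score trajectory of each module
#'   expansion in \code{attr(, "traces")} (default FALSE).
#' @return Data.frame of class \code{"scored_modules"}, ranked by calibrated
#'   score: columns rank, size, z_raw, score, seed, and list-column genes.
#' @export
greedy_search <- function(network, gene_scores, table, n_seeds = 100L,
                          max_size = NULL, n_keep = Inf, dedup = TRUE,
                          keep_trace = FALSE) {
  ns <- node_scores(network, gene_scores)
  if (!any(ns$scored)) stop("no scored nodes in network", call. = FALSE)
  if (is.null(max_size)) max_size <- nrow(table$table)
  max_size <- min(max_size, nrow(table$table))

  ord <- order(-ns$z, ns$nodes)           # z desc, ties by gene id
  ord <- ord[ns$scored[ord]]
  seeds <- ord[seq_len(min(n_seeds, length(ord)))]

  adj <- lapply(igraph::as_adj_list(network, mode = "all"), as.integer)
  mu <- table$table$mu
  sigma <- table$table$sigma

  res <- lapply(seeds, greedy_one, z = ns$z, adj = adj, mu = mu,
                sigma = sigma, max_size = max_size, keep_trace = keep_trace)
  genes <- lapply(res, function(r) ns$nodes[r$nodes])
  out <- data.frame(
    size = vapply(res, `[[`, integer(1), "k"),
    z_raw = vapply(res, `[[`, numeric(1), "z_raw"),
    score = vapply(res, `[[`, numeric(1), "score"),
    seed = ns$nodes[seeds],
    stringsAsFactors = FALSE
  )
  out$genes <- genes
  o <- order(-out$score, out$seed)
  out <- out[o, , drop = FALSE]
  traces <- if (keep_trace) lapply(res, `[[`, "trace")[o] else NULL
  if (dedup) {
    key <- vapply(out$genes, function(g) paste(sort(g), collapse = "|"),
                  character(1))
    keep <- !duplicated(key)
    out <- out[keep, , drop = FALSE]
    if (keep_trace) traces <- traces[keep]
  }
  if (is.finite(n_keep) && nrow(out) > n_keep) {
    out <- out[seq_len(n_keep), , drop = FALSE]
    if (keep_trace) traces <- traces[seq_len(n_keep)]
  }
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[c("rank", "size", "z_raw", "score", "seed", "genes")]
  class(out) <- c("scored_modules", "data.frame")
  if (keep_trace) attr(out, "traces") <- traces
  out
}

#' Permuted-score significance reference for the top module
#'
#' Reruns the greedy search after shuffling the gene z-scores across the
#' scored nodes (topology fixed) and records each permutation's top
#' calibrated score. Because the calibration table depends only on the
#' multiset of scores, the same table applies to every permutation. The
#' observed top score is reported alongside the permuted mean and its 95%
#' band (mean +/- 1.96 SEM), the reference that accounts for the search's
#' maximisation bias: an observed score merely above 3 can still be typical
#' of a null search, but one above the permuted band is not.
#'
#' @param network,gene_scores,table,n_seeds,max_size As in [greedy_search()].
#' @param n_perm Number of score permutations (default 10).
#' @param seed Optional integer seed.
#' @return List of class \code{"permutation_reference"}: observed top score,
#'   vector of permuted top scores, their mean and 95% band.
#' @export
permutation_reference <- function(network, gene_scores, table, n_perm = 10L,
                                  n_seeds = 100L, max_size = NULL,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  observed <- greedy_search(network, gene_scores, table, n_seeds = n_seeds,
                            max_size = max_size, n_keep = 1L)$score[1]
  in_net <- gene_scores$gene_id %in% igraph::V(network)$name
  permuted <- vapply(seq_len(n_perm), function(i) {
    gs <- gene_scores
    gs$z[in_net] <- sample(gs$z[in_net])
    greedy_search(network, gs, table, n_seeds = n_seeds,
                  max_size = max_size, n_keep = 1L)$score[1]
  }, numeric(1))
  sem <- stats::sd(permuted) / sqrt(n_perm)
  if (is.na(sem)) sem <- 0
  structure(list(observed = observed,
                 permuted = permuted,
                 perm_mean = mean(permuted),
                 perm_lo = mean(permuted) - 1.96 * sem,
                 perm_hi = mean(permuted) + 1.96 * sem),
            class = "permutation_reference")
}

#' @export
print.permutation_reference <- function(x, ...) {
  cat(sprintf(
    "observed top score %.3f vs %d permuted runs: mean %.3f [%.3f, %.3f]\n",
    x$observed, length(x$permuted), x$perm_mean, x$perm_lo, x$perm_hi))
  invisible(x)
}

#' Second-order module search and consensus network
#'
#' Restricts the graph to the top first-order module, recalibrates the score
#' on that reduced node universe (the null changes with the universe), reruns
#' the greedy search from the top-scoring nodes within, and builds the
#' consensus network from genes occurring at least \code{min_occurrence}
#' times among the top \code{n_modules} second-order modules. Occurrences are
#' counted over the ranked per-seed module instances without deduplication:
#' each seed's search contributes one module, so a gene found by several
#' seeds counts several times (if all top modules are the identical set S,
#' the consensus is S).
#'
#' @param network The (pruned) search graph.
#' @param top_module Character vector: node set of the top first-order module
#'   (>= 2 nodes).
#' @param gene_scores Gene-score data.frame.
#' @param n_modules Second-order modules counted (default 15; if fewer are
#'   found, those found are used, with a message).
#' @param min_occurrence Inclusion threshold (default 2, "more than once").
#' @param n_seeds Seeds for the second-order search (default 100, capped at
#'   the submodule size).
#' @param n_calibration Monte-Carlo replicates for the recalibration.
#' @param seed Optional integer seed.
#' @return List of class \code{"consensus_network"}: genes, occurrence
#'   (named integer over all genes seen in top modules), driving_snps (best
#'   SNP per consensus gene), graph (induced subgraph), modules (the ranked
#'   second-order module table).
#' @export
second_order_consensus <- function(network, top_module, gene_scores,
                                   n_modules = 15L, min_occurrence = 2L,
                                   n_seeds = 100L, n_calibration = 10000L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(top_module) < 2) {
    stop("top module must have at least 2 nodes", call. = FALSE)
  }
  sub <- igraph::induced_subgraph(network, top_module)
  ns <- node_scores(sub, gene_scores)
  max_k <- sum(ns$scored)
  tab <- calibrate_scores(sub, gene_scores, n_samples = n_calibration,
                          max_k = max_k)
  mods <- greedy_search(sub, gene_scores, tab,
                        n_seeds = min(n_seeds, max_k),
                        max_size = max_k, dedup = FALSE)
  if (nrow(mods) < n_modules) {
    message("second_order_consensus: only ", nrow(mods),
            " second-order modules found (wanted ", n_modules, ")")
  }
  top <- mods[seq_len(min(n_modules, nrow(mods))), , drop = FALSE]
  occ_tab <- table(unlist(top$genes, use.names = FALSE))
  occurrence <- stats::setNames(as.integer(occ_tab), names(occ_tab))
  genes <- sort(names(occurrence)[occurrence >= min_occurrence])
  if (length(genes) == 0) {
    warning("consensus network is empty at min_occurrence = ",
            min_occurrence, call. = FALSE)
  }
  idx <- match(genes, gene_scores$gene_id)
  driving <- stats::setNames(gene_scores$best_snp[idx], genes)
  structure(list(genes = genes,
                 occurrence = occurrence,
                 driving_snps = driving,
                 graph = igraph::induced_subgraph(network, genes),
                 modules = top),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("consensus network:", length(x$genes), "genes,",
      igraph::ecount(x$graph), "edges,",
      length(unique(stats::na.omit(x$driving_snps))), "driving SNPs\n")
  invisible(x)
}
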