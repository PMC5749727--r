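#' Select validation SNPs from the consensus network
#'
#' The best SNP of each consensus gene is carried to validation when its
#' discovery p-value is strictly below \code{p_threshold}; SNPs shared
#' between genes appear once. Returned in ascending discovery-p order.
#'
#' @param consensus A \code{"consensus_network"}.
#' @param discovery_stats Discovery summary-stat data.frame.
#' @param p_threshold Strict upper bound on discovery p (default 5e-4).
#' @return Character vector of SNP ids (possibly empty, with a warning).
#' @export
select_validation_snps <- function(consensus, discovery_stats,
                                   p_threshold = 5e-4) {
  snps <- unique(stats::na.omit(unname(consensus$driving_snps)))
  p <- discovery_stats$pvalue[match(snps, discovery_stats$snp_id)]
  keep <- !is.na(p) & p < p_threshold
  out <- snps[keep][order(p[keep], snps[keep])]
  if (length(out) == 0) {
    warning("no consensus SNP passes discovery p < ", p_threshold,
            call. = FALSE)
  }
  out
}

#' Combined z-score of a SNP set in a validation cohort
#'
#' z_j = Phi^-1(1 - p_j) from each SNP's two-sided validation p-value, and
#' the combined statistic is sum(z_j)/sqrt(m) over the m SNPs found in the
#' validation stats (the same normalised-sum form as the module score).
#' SNPs absent from the validation cohort (e.g. failing its quality control)
#' are dropped with a message.
#'
#' @param snp_ids SNP set to test.
#' @param validation_stats Validation summary-stat data.frame.
#' @param eps Clamping bound for [p_to_z()].
#' @return The combined z-score.
#' @export
combined_zscore <- function(snp_ids, validation_stats, eps = 1e-12) {
  p <- validation_stats$pvalue[match(snp_ids, validation_stats$snp_id)]
  drop <- is.na(p)
  if (any(drop)) {
    message("combined_zscore: ", sum(drop),
            " SNP(s) absent from validation stats, dropped")
    p <- p[!drop]
  }
  if (length(p) == 0) stop("no SNPs left to combine", call. = FALSE)
  sum(p_to_z(p, eps = eps)) / sqrt(length(p))
}

#' Empirical SNP-set test against random same-size sets
#'
#' Compares an observed combined z-score with the combined z-scores of
#' \code{n_draws} uniformly drawn size-m subsets of a SNP pool (typically
#' the best SNP of every scored gene in the tissue network, i.e. the SNPs
#' that could have been prioritised). Sampling is without replacement within
#' a draw; draws are independent. The empirical p-value uses the
#' (r + 1)/(N + 1) estimator, so it is never zero and lies in
#' [1/(n_draws + 1), 1].
#'
#' @param observed Observed combined z-score.
#' @param snp_pool Character vector of candidate SNP ids.
#' @param m Set size drawn (<= pool size).
#' @param validation_stats Validation summary-stat data.frame covering the
#'   pool (pool SNPs absent from it are dropped with a message).
#' @param n_draws Null draws (default 100000).
#' @param seed Optional integer seed.
#' @param eps Clamping bound for [p_to_z()].
#' @return List of class \code{"empirical_test"}: observed, null_draws,
#'   n_ge (null draws >= observed), empirical_p, null_mean, null_sd.
#' @export
empirical_snpset_test <- function(observed, snp_pool, m, validation_stats,
                                  n_draws = 100000L, seed = NULL,
                                  eps = 1e-12) {
  if (!is.null(seed)) set.seed(seed)
  p <- validation_stats$pvalue[match(snp_pool, validation_stats$snp_id)]
  drop <- is.na(p)
  if (any(drop)) {
    message("empirical_snpset_test: ", sum(drop),
            " pool SNP(s) absent from validation stats, dropped")
    p <- p[!drop]
  }
  zpool <- p_to_z(p, eps = eps)
  N <- length(zpool)
  if (m > N) stop("pool (", N, ") smaller than set size m = ", m, call. = FALSE)
  sqm <- sqrt(m)
  null <- vapply(seq_len(n_draws),
                 function(i) sum(zpool[sample.int(N, m)]) / sqm,
                 numeric(1))
  n_ge <- sum(null >= observed)
  structure(list(observed = observed,
                 null_draws = n_draws,
                 n_ge = n_ge,
                 empirical_p = (n_ge + 1) / (n_draws + 1),
                 null_mean = mean(null),
                 null_sd = stats::sd(null)),
            class = "empirical_test")
}

#' @export
print.empirical_test <- function(x, ...) {
  cat(sprintf(
    "observed combined z = %.3f; %d/%d null draws >= observed; empirical P = %.4g\n",
    x$observed, x$n_ge, x$null_draws, x$empirical_p))
  invisible(x)
}

#' One-sided sign test for directional consistency
#'
#' Tests whether more SNPs than expected by chance have the same effect
#' direction in discovery and validation (after allele alignment):
#' P(X >= n_consistent) with X ~ Binomial(n_total, 1/2), one-sided upper
#' tail. For 14 consistent of 28 this gives 0.57.
#'
#' @param n_consistent SNPs with matching effect sign.
#' @param n_total SNPs tested (> 0).
#' @return The one-sided exact binomial p-value.
#' @export
sign_test <- function(n_consistent, n_total) {
  if (n_total < 1) stop("n_total must be positive", call. = FALSE)
  if (n_consistent < 0 || n_consistent > n_total) {
    stop("n_consistent must lie in [0, n_total]", call. = FALSE)
  }
  stats::pbinom(n_consistent - 1, n_total, 0.5, lower.tail = FALSE)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Align a target cohort's effect alleles to a source cohort
#'
#' Matches rows by snp_id and re-orients each target record to the source's
#' effect allele: when effect/other are swapped the target beta (and eaf)
#' flip; when the target is reported on the opposite strand its alleles are
#' complemented first. Palindromic SNPs (A/T or C/G) cannot be strand
#' resolved and are passed through with a \code{palindromic} flag and a
#' warning. Irreconcilable allele pairs are an error.
#'
#' @param source Summary-stat data.frame providing the reference orientation.
#' @param target Summary-stat data.frame to re-orient (only shared SNPs are
#'   returned).
#' @return The target rows for shared SNPs, alleles set to the source
#'   orientation, beta/eaf flipped where needed, plus a logical
#'   \code{palindromic} column.
#' @export
align_alleles <- function(source, target) {
  shared <- intersect(source$snp_id, target$snp_id)
  src <- source[match(shared, source$snp_id), , drop = FALSE]
  tgt <- target[match(shared, target$snp_id), , drop = FALSE]

  t_ea <- toupper(tgt$effect_allele)
  t_oa <- toupper(tgt$other_allele)
  s_ea <- toupper(src$effect_allele)
  s_oa <- toupper(src$other_allele)

  same <- t_ea == s_ea & t_oa == s_oa
  swapped <- t_ea == s_oa & t_oa == s_ea
  c_ea <- unname(COMPLEMENT[t_ea])
  c_oa <- unname(COMPLEMENT[t_oa])
  comp_same <- !same & !swapped & !is.na(c_ea) & c_ea == s_ea & c_oa == s_oa
  comp_swap <- !same & !swapped & !is.na(c_ea) & c_ea == s_oa & c_oa == s_ea
  bad <- !(same | swapped | comp_same | comp_swap)
  if (any(bad)) {
    stop("irreconcilable alleles for: ",
         paste(utils::head(shared[bad], 5), collapse = ", "), call. = FALSE)
  }
  flip <- swapped | comp_swap
  tgt$beta[flip] <- -tgt$beta[flip]
  if ("eaf" %in% names(tgt)) tgt$eaf[flip] <- 1 - tgt$eaf[flip]
  tgt$effect_allele <- src$effect_allele
  tgt$other_allele <- src$other_allele
  tgt$palindromic <- s_ea == unname(COMPLEMENT[s_oa])
  if (any(tgt$palindromic)) {
    warning(sum(tgt$palindromic),
            " palindromic SNP(s) retained; strand orientation ambiguous",
            call. = FALSE)
  }
  rownames(tgt) <- NULL
  tgt
}

#' Genomic-control inflation factor
#'
#' lambda = median of the 1-df chi-square association statistics divided by
#' the null median 0.4549364; values near 1 indicate no inflation from
#' stratification or cryptic relatedness.
#'
#' @param pvalues Non-empty vector of two-sided p-values.
#' @return The inflation factor lambda.
#' @export
gc_lambda <- function(pvalues) {
  if (length(pvalues) == 0) stop("empty p-value vector", call. = FALSE)
  chisq <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Inverse-variance fixed-effect meta-analysis with double genomic control
#'
#' Combines two or more studies per SNP with inverse-variance weights:
#' beta_meta = sum(beta/se^2)/sum(1/se^2), se_meta = sum(1/se^2)^(-1/2).
#' With \code{double_gc = TRUE}, each study's standard errors are first
#' inflated by sqrt(max(lambda_study, 1)) (lambda computed from that study's
#' supplied p-values), and the meta-analysis chi-square statistics are then
#' deflated by max(lambda_meta, 1) computed over all meta-analysed SNPs —
#' genomic control applied at both levels. Inflation below 1 is never
#' "corrected" upward. Studies must already share allele orientation (see
#' [align_alleles()]).
#'
#' @param study_stats List of >= 2 summary-stat data.frames (snp_id, beta,
#'   se, pvalue), aligned to a common effect allele.
#' @param double_gc Apply double genomic control (default TRUE).
#' @return Data.frame (one row per SNP present in every study) with snp_id,
#'   beta_meta, se_meta, p_meta, plus attributes \code{lambda_by_study} and
#'   \code{lambda_meta}.
#' @export
fixed_effect_meta <- function(study_stats, double_gc = TRUE) {
  if (length(study_stats) < 2) {
    stop("meta-analysis needs at least 2 studies", call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(study_stats, `[[`, "snp_id"))
  if (length(shared) == 0) stop("no SNPs shared by all studies", call. = FALSE)

  lambda_by_study <- vapply(study_stats,
                            function(s) gc_lambda(s$pvalue), numeric(1))
  if (is.null(names(lambda_by_study))) {
    names(lambda_by_study) <- paste0("study", seq_along(study_stats))
  }
  infl <- if (double_gc) sqrt(pmax(lambda_by_study, 1)) else
    rep(1, length(study_stats))

  wsum <- numeric(length(shared))
  wbsum <- numeric(length(shared))
  for (i in seq_along(study_stats)) {
    s <- study_stats[[i]][match(shared, study_stats[[i]]$snp_id), ]
    se <- s$se * infl[i]
    w <- 1 / se^2
    wsum <- wsum + w
    wbsum <- wbsum + w * s$beta
  }
  beta_meta <- wbsum / wsum
  se_meta <- 1 / sqrt(wsum)
  chisq <- (beta_meta / se_meta)^2
  lambda_meta <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  if (double_gc) chisq <- chisq / max(lambda_meta, 1)
  p_meta <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  out <- data.frame(snp_id = shared, beta_meta = beta_meta,
                    se_meta = se_meta, p_meta = p_meta,
                    stringsAsFactors = FALSE)
  attr(out, "lambda_by_study") <- lambda_by_study
  attr(out, "lambda_meta") <- lambda_meta
  out
}

#' Summary-statistic polygenic score association
#'
#' The inverse-variance approximation of regressing a phenotype on a
#' weighted allele score, computed from per-SNP target-cohort effects b_i
#' and standard errors s_i with discovery-derived weights w_i:
#' alpha_hat = sum(w b / s^2) / sum(w^2 / s^2),
#' se(alpha_hat) = sum(w^2 / s^2)^(-1/2), with a two-sided normal p-value.
#' Weights are conventionally the discovery effect sizes oriented to the
#' effect-raising allele (all positive after orientation); alleles must be
#' aligned between weights and target.
#'
#' @param weights Data.frame with snp_id and weight.
#' @param target_stats Target-cohort summary stats (snp_id, beta, se).
#' @return List of class \code{"prs_result"}: alpha, se, p, n_snps.
#' @export
prs_association <- function(weights, target_stats) {
  shared <- intersect(weights$snp_id, target_stats$snp_id)
  if (length(shared) == 0) stop("no overlapping SNPs", call. = FALSE)
  w <- weights$weight[match(shared, weights$snp_id)]
  t <- target_stats[match(shared, target_stats$snp_id), ]
  num <- sum(w * t$beta / t$se^2)
  den <- sum(w^2 / t$se^2)
  alpha <- num / den
  se <- 1 / sqrt(den)
  structure(list(alpha = alpha, se = se,
                 p = 2 * stats::pnorm(-abs(alpha / se)),
                 n_snps = length(shared)),
            class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("PRS association: alpha = %.4g (se %.4g), P = %.3g, %d SNPs\n",
              x$alpha, x$se, x$p, x$n_snps))
  invisible(x)
}

#' Greedy LD pruning of a ranked SNP list
#'
#' Walks the SNPs in ascending p-value order and keeps each SNP iff its r^2
#' with every already-kept SNP is below \code{threshold}. Pairs absent from
#' the r^2 table are treated as unlinked (r^2 = 0).
#'
#' @param snps Data.frame with snp_id and pvalue.
#' @param ld_r2 Data.frame with snp_a, snp_b, r2 (unordered pairs).
#' @param threshold Keep iff r^2 < threshold with all kept SNPs
#'   (default 0.8).
#' @return Character vector of kept SNP ids, in ascending-p order.
#' @export
ld_prune <- function(snps, ld_r2 = NULL, threshold = 0.8) {
  ord <- order(snps$pvalue, snps$snp_id)
  ids <- snps$snp_id[ord]
  if (is.null(ld_r2) || nrow(ld_r2) == 0) return(ids)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  r2 <- stats::setNames(ld_r2$r2, key(ld_r2$snp_a, ld_r2$snp_b))
  kept <- character(0)
  for (s in ids) {
    if (length(kept) == 0) {
      kept <- s
      next
    }
    r <- r2[key(s, kept)]
    r[is.na(r)] <- 0
    if (all(r < threshold)) kept <- c(kept, s)
  }
  kept
}

#' Overlap of SNP loci with regulatory-element classes
#'
#' Each index SNP defines a locus: its own position plus the positions of
#' proxies in high LD (r^2 strictly above \code{r2_threshold}). A locus
#' overlaps a regulatory class iff any of its positions falls inside any
#' interval of that class on the same chromosome. Intervals are taken as
#' half-open \code{[start, end)} with positions compared in the same
#' coordinate space as the BED file (position 150 is inside [100, 200);
#' position 200 is not).
#'
#' @param snps Data.frame of index SNPs (snp_id, chrom, pos).
#' @param elements Data.frame of intervals with chrom, start, end, class.
#' @param proxy_table Optional data.frame of proxies: snp_id (index), chrom,
#'   pos, r2.
#' @param r2_threshold Proxies with r^2 strictly above this extend the locus
#'   (default 0.8).
#' @return Data.frame, one row per index SNP, one logical column per element
#'   class plus \code{any_overlap}.
#' @export
regulatory_overlap <- function(snps, elements, proxy_table = NULL,
                               r2_threshold = 0.8) {
  if (!all(c("chrom", "start", "end", "class") %in% names(elements))) {
    stop("elements need columns chrom, start, end, class", call. = FALSE)
  }
  if (any(elements$start >= elements$end)) {
    stop("malformed interval: start >= end", call. = FALSE)
  }
  pos <- data.frame(locus = snps$snp_id, chrom = snps$chrom, pos = snps$pos,
                    stringsAsFactors = FALSE)
  if (!is.null(proxy_table) && nrow(proxy_table) > 0) {
    px <- proxy_table[proxy_table$r2 > r2_threshold, , drop = FALSE]
    px <- px[px$snp_id %in% snps$snp_id, , drop = FALSE]
    if (nrow(px) > 0) {
      pos <- rbind(pos, data.frame(locus = px$snp_id, chrom = px$chrom,
                                   pos = px$pos, stringsAsFactors = FALSE))
    }
  }
  classes <- sort(unique(elements$class))
  out <- matrix(FALSE, nrow = nrow(snps), ncol = length(classes),
                dimnames = list(snps$snp_id, classes))
  for (chr in unique(pos$chrom)) {
    pi <- which(pos$chrom == chr)
    ei <- which(elements$chrom == chr)
    if (length(ei) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = pos$pos[pi], width = 1L),
      IRanges::IRanges(start = elements$start[ei],
                       end = elements$end[ei] - 1L)  # half-open [start, end)
    )
    if (length(hits) == 0) next
    loci <- pos$locus[pi][S4Vectors::queryHits(hits)]
    cls <- elements$class[ei][S4Vectors::subjectHits(hits)]
    for (i in seq_along(loci)) out[loci[i], cls[i]] <- TRUE
  }
  res <- data.frame(snp_id = snps$snp_id, out, check.names = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$any_overlap <- apply(out, 1, any)
  res
}
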