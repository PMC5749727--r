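test_that("validation SNP selection is strict, deduplicated, and matches brute force", {
  cons <- toy_consensus(c(G1 = "rs1", G2 = "rs2", G3 = "rs2", G4 = "rs4"))
  disc <- data.frame(snp_id = c("rs1", "rs2", "rs4"),
                     pvalue = c(4.9e-4, 1e-5, 5.0e-4),
                     stringsAsFactors = FALSE)
  got <- select_validation_snps(cons, disc, p_threshold = 5e-4)
  expect_equal(got, c("rs2", "rs1"))            # rs4 at the boundary excluded
  expect_equal(sum(got == "rs2"), 1)            # shared SNP appears once

  set.seed(51)
  snps <- sprintf("rs%03d", 1:60)
  cons2 <- toy_consensus(stats::setNames(sample(snps, 40),
                                         sprintf("G%02d", 1:40)))
  disc2 <- data.frame(snp_id = snps, pvalue = runif(60, 0, 2e-3),
                      stringsAsFactors = FALSE)
  want <- unique(unname(cons2$driving_snps))
  want <- want[disc2$pvalue[match(want, disc2$snp_id)] < 5e-4]
  expect_setequal(select_validation_snps(cons2, disc2), want)

  disc3 <- transform(disc, pvalue = pvalue + 1e-2)
  expect_warning(out <- select_validation_snps(cons, disc3), "no consensus")
  expect_length(out, 0)
})

test_that("combined z-score matches quantile arithmetic and the module formula", {
  val1 <- data.frame(snp_id = "a", pvalue = 0.5, stringsAsFactors = FALSE)
  expect_equal(combined_zscore("a", val1), 0)

  val4 <- data.frame(snp_id = letters[1:4], pvalue = rep(0.0227501, 4),
                     stringsAsFactors = FALSE)
  expect_equal(combined_zscore(letters[1:4], val4), 4.0, tolerance = 1e-3)

  set.seed(52)
  val <- data.frame(snp_id = sprintf("rs%02d", 1:20), pvalue = runif(20),
                    stringsAsFactors = FALSE)
  picks <- sample(val$snp_id, 9)
  gs <- data.frame(gene_id = val$snp_id, p = val$pvalue, best_snp = val$snp_id,
                   z = p_to_z(val$pvalue), stringsAsFactors = FALSE)
  expect_equal(combined_zscore(picks, val), module_zscore(picks, gs),
               tolerance = 1e-12)

  expect_message(z <- combined_zscore(c("rs01", "absent"), val), "dropped")
  expect_equal(z, p_to_z(val$pvalue[1]))
  expect_error(combined_zscore("absent", val))
})

test_that("empirical SNP-set test uses the (r+1)/(N+1) estimator deterministically", {
  set.seed(53)
  val <- data.frame(snp_id = sprintf("rs%03d", 1:50), pvalue = runif(50),
                    stringsAsFactors = FALSE)
  pool <- val$snp_id
  res <- empirical_snpset_test(1e9, pool, 5, val, n_draws = 99, seed = 1)
  expect_equal(res$empirical_p, 1 / 100)
  expect_equal(res$n_ge, 0)
  lo <- empirical_snpset_test(-1e9, pool, 5, val, n_draws = 99, seed = 1)
  expect_equal(lo$empirical_p, 1)

  a <- empirical_snpset_test(2, pool, 5, val, n_draws = 500, seed = 7)
  b <- empirical_snpset_test(2, pool, 5, val, n_draws = 500, seed = 7)
  expect_identical(a$n_ge, b$n_ge)
  expect_error(empirical_snpset_test(0, pool, 51, val, n_draws = 10),
               "smaller")
})

test_that("empirical p-values are uniform when the tested set is itself null", {
  set.seed(54)
  val <- data.frame(snp_id = sprintf("rs%04d", 1:400), pvalue = runif(400),
                    stringsAsFactors = FALSE)
  pool <- val$snp_id
  m <- 10
  ps <- vapply(seq_len(200), function(i) {
    obs <- combined_zscore(sample(pool, m), val)
    empirical_snpset_test(obs, pool, m, val, n_draws = 300)$empirical_p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(200))
})

test_that("sign test reproduces the exact binomial upper tail", {
  expect_equal(round(sign_test(14, 28), 2), 0.57)
  expect_equal(sign_test(0, 28), 1.0)
  expect_equal(sign_test(28, 28), 2^-28, tolerance = 1e-12)
  for (n in c(5, 17, 30)) {
    for (k in 0:n) {
      expect_equal(sign_test(k, n), sum(dbinom(k:n, n, 0.5)),
                   tolerance = 1e-12)
    }
  }
  expect_error(sign_test(1, 0), "positive")
  expect_error(sign_test(5, 3), "n_consistent")
})

test_that("allele alignment flips swapped and complements opposite-strand records", {
  src <- data.frame(snp_id = c("s1", "s2"),
                    effect_allele = c("A", "A"), other_allele = c("G", "G"),
                    beta = c(0.1, 0.1), eaf = c(0.3, 0.3),
                    stringsAsFactors = FALSE)
  swap <- data.frame(snp_id = "s1", effect_allele = "G", other_allele = "A",
                     beta = 0.2, eaf = 0.7, stringsAsFactors = FALSE)
  got <- align_alleles(src, swap)
  expect_equal(got$beta, -0.2)
  expect_equal(got$eaf, 0.3, tolerance = 1e-12)
  expect_equal(got$effect_allele, "A")

  strand <- data.frame(snp_id = "s2", effect_allele = "T", other_allele = "C",
                       beta = 0.15, eaf = 0.3, stringsAsFactors = FALSE)
  got2 <- align_alleles(src, strand)
  expect_equal(got2$beta, 0.15)      # complement of T/C is A/G: sign kept

  bad <- data.frame(snp_id = "s1", effect_allele = "A", other_allele = "C",
                    beta = 0.1, eaf = 0.5, stringsAsFactors = FALSE)
  expect_error(align_alleles(src, bad), "irreconcilable")

  pal_src <- data.frame(snp_id = "p1", effect_allele = "A",
                        other_allele = "T", beta = 0.1, eaf = 0.4,
                        stringsAsFactors = FALSE)
  expect_warning(pal <- align_alleles(pal_src, pal_src), "palindromic")
  expect_true(pal$palindromic)
})

test_that("allele alignment is idempotent on a randomised 100-SNP fixture", {
  set.seed(55)
  n <- 100
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  src <- random_stats(n, seed = 56)
  # keep non-palindromic pairs so strand resolution is unambiguous
  pal <- src$effect_allele == comp[src$other_allele]
  src$other_allele[pal] <- ifelse(src$effect_allele[pal] %in% c("A", "T"),
                                  "C", "A")
  tgt <- src
  swap <- runif(n) < 0.5
  tgt[swap, c("effect_allele", "other_allele")] <-
    tgt[swap, c("other_allele", "effect_allele")]
  tgt$beta[swap] <- -tgt$beta[swap]
  tgt$eaf[swap] <- 1 - tgt$eaf[swap]
  flip_strand <- runif(n) < 0.5
  tgt$effect_allele[flip_strand] <- comp[tgt$effect_allele[flip_strand]]
  tgt$other_allele[flip_strand] <- comp[tgt$other_allele[flip_strand]]

  once <- align_alleles(src, tgt)
  expect_equal(once$beta, src$beta[match(once$snp_id, src$snp_id)],
               tolerance = 1e-12)
  twice <- align_alleles(src, once)
  expect_equal(twice$beta, once$beta, tolerance = 1e-12)
  expect_equal(twice$effect_allele, once$effect_allele)
})

test_that("genomic-control lambda is calibrated and scale-equivariant", {
  p_exact <- (seq_len(9999)) / 10000
  expect_equal(gc_lambda(p_exact), 1.0, tolerance = 1e-3)

  set.seed(57)
  expect_true(abs(gc_lambda(runif(10000)) - 1) < 0.05)

  chi <- qchisq(runif(500), df = 1, lower.tail = FALSE)
  p1 <- pchisq(chi, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(gc_lambda(p2), 2 * gc_lambda(p1), tolerance = 1e-9)
  expect_error(gc_lambda(numeric(0)), "empty")
})

test_that("fixed-effect meta matches closed forms", {
  mk <- function(beta, se) {
    data.frame(snp_id = "s1", beta = beta, se = se,
               pvalue = 2 * pnorm(-abs(beta / se)), stringsAsFactors = FALSE)
  }
  eq <- fixed_effect_meta(list(mk(0.3, 0.1), mk(0.3, 0.1)), double_gc = FALSE)
  expect_equal(eq$beta_meta, 0.3, tolerance = 1e-12)
  expect_equal(eq$se_meta, 0.1 / sqrt(2), tolerance = 1e-12)

  hand <- fixed_effect_meta(list(mk(0.3, 0.1), mk(0.0, 0.2)),
                            double_gc = FALSE)
  expect_equal(hand$beta_meta, 0.24, tolerance = 1e-6)
  expect_equal(hand$se_meta, 1 / sqrt(125), tolerance = 1e-6)
  expect_equal(hand$se_meta, 0.0894427, tolerance = 1e-6)

  inert <- fixed_effect_meta(list(mk(0.25, 0.08), mk(1.0, 1e6)),
                             double_gc = FALSE)
  expect_equal(inert$beta_meta, 0.25, tolerance = 1e-4)
  expect_equal(inert$se_meta, 0.08, tolerance = 1e-4)

  expect_error(fixed_effect_meta(list(mk(0.3, 0.1))), "2 studies")
})

test_that("meta p-values are uniform under the null", {
  set.seed(58)
  n <- 2000
  mk_study <- function() {
    beta <- rnorm(n, 0, 0.1)
    data.frame(snp_id = sprintf("s%04d", seq_len(n)), beta = beta, se = 0.1,
               pvalue = 2 * pnorm(-abs(beta / 0.1)), stringsAsFactors = FALSE)
  }
  meta <- fixed_effect_meta(list(mk_study(), mk_study()), double_gc = FALSE)
  ks <- suppressWarnings(stats::ks.test(meta$p_meta, "punif"))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n))
  # double GC never inflates significance when lambda <= 1
  gc <- fixed_effect_meta(list(mk_study(), mk_study()), double_gc = TRUE)
  expect_true(all(gc$p_meta >= 0 & gc$p_meta <= 1))
})

test_that("PRS association reduces, matches hand computation, and is flip-invariant", {
  one <- prs_association(data.frame(snp_id = "s1", weight = 1),
                         data.frame(snp_id = "s1", beta = 0.2, se = 0.1))
  expect_equal(one$alpha, 0.2, tolerance = 1e-12)
  expect_equal(one$se, 0.1, tolerance = 1e-12)
  expect_equal(one$p, 2 * pnorm(-2), tolerance = 1e-12)

  two <- prs_association(
    data.frame(snp_id = c("s1", "s2"), weight = c(1, 1)),
    data.frame(snp_id = c("s1", "s2"), beta = c(0.2, 0.4), se = c(0.1, 0.1)))
  expect_equal(two$alpha, 0.3, tolerance = 1e-6)
  expect_equal(two$se, 0.0707107, tolerance = 1e-6)
  expect_equal(two$n_snps, 2)

  set.seed(59)
  w <- data.frame(snp_id = sprintf("s%02d", 1:12), weight = runif(12, 0.1, 1))
  t <- data.frame(snp_id = w$snp_id, beta = rnorm(12), se = runif(12, 0.05, 0.2))
  base <- prs_association(w, t)
  flip <- sample(c(TRUE, FALSE), 12, replace = TRUE)
  w2 <- transform(w, weight = ifelse(flip, -weight, weight))
  t2 <- transform(t, beta = ifelse(flip, -beta, beta))
  flipped <- prs_association(w2, t2)
  expect_equal(flipped$alpha, base$alpha, tolerance = 1e-12)
  expect_equal(flipped$se, base$se, tolerance = 1e-12)

  expect_error(prs_association(w, data.frame(snp_id = "zz", beta = 1, se = 1)),
               "overlapping")
})

test_that("LD pruning keeps the smaller-p SNP of linked pairs and matches brute force", {
  snps <- data.frame(snp_id = c("a", "b", "c"), pvalue = c(0.2, 0.01, 0.5),
                     stringsAsFactors = FALSE)
  expect_equal(ld_prune(snps, NULL), c("b", "a", "c"))

  ld <- data.frame(snp_a = "a", snp_b = "b", r2 = 1.0)
  expect_equal(ld_prune(snps, ld), c("b", "c"))

  set.seed(60)
  n <- 20
  snps2 <- data.frame(snp_id = sprintf("s%02d", 1:n), pvalue = runif(n),
                      stringsAsFactors = FALSE)
  block <- rep(1:4, each = 5)
  pairs <- t(combn(n, 2))
  ld2 <- data.frame(snp_a = snps2$snp_id[pairs[, 1]],
                    snp_b = snps2$snp_id[pairs[, 2]],
                    r2 = ifelse(block[pairs[, 1]] == block[pairs[, 2]],
                                runif(nrow(pairs), 0.85, 1),
                                runif(nrow(pairs), 0, 0.3)),
                    stringsAsFactors = FALSE)
  got <- ld_prune(snps2, ld2, threshold = 0.8)
  # independent greedy reimplementation
  lookup <- function(x, y) {
    hit <- (ld2$snp_a == x & ld2$snp_b == y) | (ld2$snp_a == y & ld2$snp_b == x)
    if (any(hit)) ld2$r2[hit][1] else 0
  }
  kept <- character(0)
  for (s in snps2$snp_id[order(snps2$pvalue, snps2$snp_id)]) {
    if (all(vapply(kept, function(k) lookup(s, k), numeric(1)) < 0.8)) {
      kept <- c(kept, s)
    }
  }
  expect_equal(got, kept)
  expect_equal(sort(block[match(got, snps2$snp_id)]), 1:4)  # one per block
})

test_that("regulatory overlap honours half-open intervals and LD proxies", {
  elements <- data.frame(chrom = "chr1", start = 100, end = 200,
                         class = "active enhancers", stringsAsFactors = FALSE)
  at <- function(pos) data.frame(snp_id = "s", chrom = "chr1", pos = pos,
                                 stringsAsFactors = FALSE)
  expect_true(regulatory_overlap(at(150), elements)$`active enhancers`)
  expect_false(regulatory_overlap(at(200), elements)$`active enhancers`)
  expect_true(regulatory_overlap(at(100), elements)$`active enhancers`)

  prox_in <- data.frame(snp_id = "s", chrom = "chr1", pos = 150, r2 = 0.9)
  prox_out <- data.frame(snp_id = "s", chrom = "chr1", pos = 150, r2 = 0.8)
  expect_true(regulatory_overlap(at(999), elements, prox_in)$`active enhancers`)
  expect_false(regulatory_overlap(at(999), elements, prox_out)$`active enhancers`)

  bad <- data.frame(chrom = "chr1", start = 200, end = 100, class = "x")
  expect_error(regulatory_overlap(at(1), bad), "malformed")
})

test_that("regulatory overlap of 30 loci matches an exhaustive interval scan", {
  set.seed(61)
  classes <- c("promoters", "inactive enhancers", "active enhancers",
               "clustered active enhancers", "CTCF bound sites", "other")
  elements <- data.frame(
    chrom = sample(c("chr1", "chr2"), 120, replace = TRUE),
    start = sample.int(1e5, 120),
    class = sample(classes, 120, replace = TRUE),
    stringsAsFactors = FALSE)
  elements$end <- elements$start + sample.int(2000, 120)
  snps <- data.frame(snp_id = sprintf("L%02d", 1:30),
                     chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                     pos = sample.int(1.05e5, 30), stringsAsFactors = FALSE)
  proxies <- data.frame(snp_id = sample(snps$snp_id, 50, replace = TRUE),
                        chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                        pos = sample.int(1.05e5, 50),
                        r2 = runif(50, 0.5, 1), stringsAsFactors = FALSE)
  got <- regulatory_overlap(snps, elements, proxies, r2_threshold = 0.8)
  for (i in seq_len(30)) {
    locus <- rbind(
      data.frame(chrom = snps$chrom[i], pos = snps$pos[i]),
      proxies[proxies$snp_id == snps$snp_id[i] & proxies$r2 > 0.8,
              c("chrom", "pos")])
    for (cl in classes) {
      e <- elements[elements$class == cl, ]
      want <- FALSE
      for (j in seq_len(nrow(locus))) {
        want <- want || any(e$chrom == locus$chrom[j] &
                              e$start <= locus$pos[j] & locus$pos[j] < e$end)
      }
      expect_identical(unname(got[i, cl]), want)
    }
  }
})
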