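test_that("Weir-Cockerham components match a longhand 5-vs-5 evaluation", {
  g1 <- matrix(c(0, 1, 1, 2, 2), ncol = 1L)
  g2 <- matrix(c(0, 0, 1, 0, 1), ncol = 1L)
  out <- weir_cockerham_fst(g1, g2)
  # longhand: r=2, n1=n2=5, nbar=5, nc=5
  p1 <- 6 / 10; p2 <- 2 / 10
  h1 <- 2 / 5; h2 <- 2 / 5
  nbar <- 5; nc <- (2 * 5 - (25 + 25) / 10) / 1
  pbar <- (5 * p1 + 5 * p2) / 10
  s2 <- (5 * (p1 - pbar)^2 + 5 * (p2 - pbar)^2) / 5
  hbar <- (5 * h1 + 5 * h2) / 10
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(out$a, a)
  expect_equal(out$b, b)
  expect_equal(out$c, cc)
  expect_equal(out$est_raw, a / (a + b + cc))
})

test_that("FST boundary cases: identical arrays near zero, fixed difference one", {
  set.seed(71)
  G <- matrix(rbinom(50 * 20L, 2L, 0.5), 50L)
  out <- weir_cockerham_fst(G, G)
  # with identical arrays s2 = 0, so the unbiased estimator sits just below
  # zero (order 1/n); the clamped estimate is exactly 0
  expect_lt(max(abs(out$est_raw), na.rm = TRUE), 0.02)
  expect_true(all(out$est_raw < 0))
  expect_true(all(out$est == 0))
  fixed <- weir_cockerham_fst(matrix(2L, 10L, 5L), matrix(0L, 10L, 5L))
  expect_equal(fixed$est, rep(1, 5L))
  mono <- weir_cockerham_fst(matrix(2L, 10L, 2L), matrix(2L, 10L, 2L))
  expect_true(all(is.na(mono$est_raw)))
  expect_error(weir_cockerham_fst(matrix(0L, 1L, 2L), matrix(0L, 5L, 2L)),
               "at least 2")
})

test_that("planted Balding-Nichols drift is recovered by the estimator", {
  mod <- simulate_ancestral_frequencies(1500L, c(EUR = 0.1, AFR = 0.1,
                                                 AMR = 0.1), seed = 72L)
  set.seed(73)
  n <- 150L
  g_eur <- sapply(seq_len(1500L), function(j)
    rbinom(n, 2L, mod$pop_freqs["EUR", j]))
  g_afr <- sapply(seq_len(1500L), function(j)
    rbinom(n, 2L, mod$pop_freqs["AFR", j]))
  out <- weir_cockerham_fst(g_eur, g_afr)
  s <- fst_summary(out)
  # both standard multi-locus summaries recover the planted drift F = 0.1
  expect_lt(abs(s[["weighted"]] - 0.1), 0.02)
  expect_lt(abs(s[["mean"]] - 0.1), 0.03)
})

test_that("genomic PC pruning keeps independent SNPs and halves duplicates", {
  set.seed(74)
  n <- 120L
  G <- matrix(rbinom(n * 30L, 2L, 0.4), n,
              dimnames = list(NULL, sprintf("s%02d", 1:30)))
  panel <- as_panel(G)
  out <- compute_genomic_pcs(panel, window = 30L, step = 10L)
  expect_true(all(out$kept))                 # independent: nothing pruned
  Gdup <- cbind(G, G)
  colnames(Gdup) <- sprintf("s%02d", 1:60)
  out2 <- compute_genomic_pcs(as_panel(Gdup), window = 60L, step = 20L)
  expect_equal(sum(out2$kept), 30L)          # one of each duplicate pair
})

test_that("PC1 separates two simulated populations", {
  mod <- simulate_ancestral_frequencies(300L, 0.1, seed = 75L)
  set.seed(76)
  n <- 80L
  G <- rbind(
    sapply(1:300, function(j) rbinom(n, 2L, mod$pop_freqs["EUR", j])),
    sapply(1:300, function(j) rbinom(n, 2L, mod$pop_freqs["AFR", j])))
  colnames(G) <- sprintf("s%03d", 1:300)
  out <- compute_genomic_pcs(as_panel(G), window = 300L, step = 100L)
  pop <- rep(0:1, each = n)
  expect_gt(abs(cor(out$pcs[, 1L], pop)), 0.9)
})

test_that("LD scores: self term, perfect blocks, and unbiasedness", {
  set.seed(77)
  n <- 1000L
  # a block of 5 identical SNPs plus independents
  base <- rbinom(n, 2L, 0.5)
  G <- cbind(matrix(base, n, 5L), matrix(rbinom(n * 40L, 2L, 0.5), n))
  colnames(G) <- sprintf("s%02d", 1:45)
  panel <- as_panel(G)
  # spread positions so the window covers everything
  panel$variants$cM <- seq(0, 4, length.out = 45L)
  ell <- adjusted_ld_scores(panel, covariates = NULL, window_cm = 20)
  expect_equal(ell[1:5], rep(5, 5L), tolerance = 0.1)
  # independent SNPs: mean score ~ 1 after bias adjustment
  expect_lt(abs(mean(ell[6:45]) - 1), 0.05)
  # single isolated SNP
  iso <- as_panel(matrix(rbinom(n, 2L, 0.4), n, dimnames = list(NULL, "x")))
  expect_equal(adjusted_ld_scores(iso, NULL), 1, tolerance = 1e-12)
})

test_that("FST enrichment flags constructed depletion and returns structure", {
  set.seed(78)
  s <- 4000L
  tab <- data.frame(maf = runif(s, 0.01, 0.5), ld = runif(s, 1, 50),
                    fst = rbeta(s, 0.8, 8))
  # leads = the minimum-FST SNP of 15 random cells -> depleted
  bins <- function(x) cut(x, quantile(x, seq(0, 1, length.out = 21L)),
                          include.lowest = TRUE, labels = FALSE)
  bm <- bins(tab$maf); bl <- bins(tab$ld)
  cells <- unique(data.frame(bm, bl))[1:15, ]
  leads <- vapply(seq_len(15L), function(i) {
    pool <- which(bm == cells$bm[i] & bl == cells$bl[i])
    pool[which.min(tab$fst[pool])]
  }, integer(1L))
  out <- fst_enrichment(tab, leads, n_resamples = 2000L, seed = 1L)
  expect_equal(out$verdict, "low")
  expect_true(out$reliable)
  # degenerate single-resample run still returns a verdict, flagged
  out1 <- fst_enrichment(tab, leads, n_resamples = 1L, seed = 2L)
  expect_true(out1$verdict %in% c("low", "high", "ns"))
  expect_false(out1$reliable)
})

test_that("FST enrichment is calibrated when leads are cell-matched draws", {
  set.seed(79)
  s <- 3000L
  tab <- data.frame(maf = runif(s, 0.01, 0.5), ld = runif(s, 1, 50),
                    fst = rbeta(s, 1, 6))
  rejections <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    leads <- sample.int(s, 12L)              # uniform draws = matched nulls
    out <- fst_enrichment(tab, leads, n_resamples = 400L, seed = 100L + r)
    if (out$verdict != "ns") rejections <- rejections + 1L
  }
  expect_lt(rejections / n_rep, 0.15)        # ~5% nominal two-sided
})

test_that("ancestry-partitioned dosages always sum to the genotype", {
  sim <- small_sim(n_snps = 50L, n_subjects = 50L)
  panel <- sim$panel
  for (j in c(1L, 10L, 25L, 50L)) {
    x <- ancestry_dosages(panel, j)
    expect_equal(unname(rowSums(x)), unname(panel$dosage[, j]))
    expect_true(all(x >= 0L & x <= 2L))
  }
  # both haplotypes EUR with genotype 2 -> (2, 0, 0)
  p2 <- panel
  p2$haplotypes[1L, 1L, ] <- 1L
  p2$hap_ancestry[1L, 1L, ] <- 1L
  expect_equal(unname(ancestry_dosages(p2, 1L)[1L, ]), c(2, 0, 0))
  p2$haplotypes[1L, 1L, 2L] <- 0L
  p2$hap_ancestry[1L, 1L, 2L] <- 2L           # AFR hap carries minor
  expect_equal(unname(ancestry_dosages(p2, 1L)[1L, ]), c(1, 0, 0))
  p3 <- panel; p3$haplotypes <- NULL
  expect_error(ancestry_dosages(p3, 1L), "unphased")
})

test_that("heterogeneity LRT is untestable in a single-ancestry cohort", {
  set.seed(80)
  n <- 100L
  x_eur <- rbinom(n, 2L, 0.4)
  out <- heterogeneity_lrt(rnorm(n), a_eur = rep(2, n), a_afr = rep(0, n),
                           x_eur = x_eur, x_afr = rep(0L, n),
                           x_amr = rep(0L, n), scenario = "3way")
  expect_false(out$testable)
  expect_setequal(out$dropped, c("AFR", "AMR"))
})

test_that("heterogeneity LRT recovers planted ancestry-specific effects", {
  set.seed(81)
  n <- 2000L
  afr_prop <- rbinom(n, 2L, 0.5)
  a_eur <- 2L - afr_prop
  x_eur <- vapply(a_eur, function(k) rbinom(1L, k, 0.4), integer(1L))
  x_afr <- vapply(2L - a_eur, function(k) rbinom(1L, k, 0.4), integer(1L))
  y <- 0.5 * x_eur + 0 * x_afr + rnorm(n)
  out <- heterogeneity_lrt(y, a_eur, 2L - a_eur, x_eur, x_afr,
                           scenario = "2way")
  expect_true(out$testable)
  expect_lt(out$p, 0.001)
  expect_lt(abs(out$betas_full["EUR", 1L] - 0.5), 0.1)
  expect_lt(abs(out$betas_full["AFR", 1L] - 0), 0.1)
  # statistic is invariant to affine rescaling of the phenotype
  out2 <- heterogeneity_lrt(3 * y + 7, a_eur, 2L - a_eur, x_eur, x_afr,
                            scenario = "2way")
  expect_equal(out2$stat, out$stat, tolerance = 1e-8)
  # multivariate df bookkeeping
  Y <- cbind(y, rnorm(n))
  outm <- heterogeneity_lrt(Y, a_eur, 2L - a_eur, x_eur, x_afr,
                            scenario = "2way")
  expect_equal(outm$df, 2L)
})

test_that("constrained and full models coincide when group betas are equal", {
  set.seed(82)
  n <- 500L
  a_eur <- rbinom(n, 2L, 0.5)
  x_eur <- vapply(a_eur, function(k) rbinom(1L, k, 0.4), integer(1L))
  x_afr <- vapply(2L - a_eur, function(k) rbinom(1L, k, 0.4), integer(1L))
  y <- 0.3 * (x_eur + x_afr) + rnorm(n)
  out <- heterogeneity_lrt(y, a_eur, 2L - a_eur, x_eur, x_afr,
                           scenario = "2way")
  expect_gte(out$stat, 0)
  expect_gt(out$p, 0.001)                    # no heterogeneity to find
})
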