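# Permutation-based effective number of tests, study-wide threshold,
# normalized-statistic genomic inflation, and Benjamini-Hochberg FDR.

# p-values of a matrix of genotype columns against one segment, via the
# orthonormal score basis (see .batch_r2).
.perm_pvals <- function(space, G) {
  Q2 <- .score_basis(space$scores)
  K <- ncol(Q2)
  n <- nrow(G)
  r2 <- .batch_r2(Q2, G)
  chi2 <- -(n - 1 - (K + 2) / 2) * log1p(-pmin(r2, 1 - 1e-16))
  pmax(pchisq(chi2, df = K, lower.tail = FALSE), .Machine$double.xmin)
}

#' Permutation estimate of the effective number of independent tests
#'
#' For each probe SNP the genotype vector is permuted `n_perm` times; every
#' permuted genotype is tested against all segment shape spaces and the
#' minimum p across segments retained. The per-SNP effective number of tests
#' is `alpha` divided by the `percentile`-th percentile of those minimum
#' p-values (so perfectly dependent segments give 1 and independent segments
#' give their count).
#'
#' @param spaces list of `segment_shape_space`.
#' @param panel a `genotype_panel` supplying probe SNPs (non-constant).
#' @param n_perm permutations per probe SNP (default 10000, minimum 1000).
#' @param percentile percentile of the minimum-p distribution (default 5).
#' @param n_probe_snps probe SNPs drawn uniformly without replacement
#'   (default 500; all available are used, with a warning, if fewer).
#' @param alpha nominal level (default 0.05).
#' @param seed RNG seed.
#' @param batch internal permutation batch size.
#' @return list with `mean_m_eff`, `sd_m_eff`, `per_snp_m_eff`,
#'   `probe_snps`.
#' @export
effective_tests <- function(spaces, panel, n_perm = 10000L, percentile = 5,
                            n_probe_snps = 500L, alpha = 0.05, seed = 1L,
                            batch = 2000L) {
  if (n_perm < 1000L) stop("n_perm must be at least 1000")
  if (percentile <= 0 || percentile >= 50)
    stop("percentile must be in (0, 50)")
  set.seed(seed)
  ok <- which(apply(panel$dosage, 2L, function(g) sd(g) > 1e-12))
  if (length(ok) == 0L) stop("no non-constant probe SNPs available")
  if (length(ok) < n_probe_snps) {
    warning("only ", length(ok), " probe SNPs available; using all")
    probes <- ok
  } else {
    probes <- sort(sample(ok, n_probe_snps))
  }
  bases <- lapply(spaces, function(sp) .score_basis(sp$scores))
  Ks <- vapply(bases, ncol, integer(1L))
  n <- nrow(panel$dosage)
  m_eff <- numeric(length(probes))
  for (i in seq_along(probes)) {
    g <- panel$dosage[, probes[i]]
    minp <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      b <- min(batch, n_perm - done)
      G <- matrix(0, n, b)
      for (j in seq_len(b)) G[, j] <- g[sample.int(n)]
      Gc <- sweep(G, 2L, colMeans(G))
      ss <- colSums(Gc^2)
      pmat <- matrix(0, b, length(spaces))
      for (si in seq_along(spaces)) {
        r2 <- pmin(pmax(colSums(crossprod(bases[[si]], Gc)^2) / ss, 0), 1)
        chi2 <- -(n - 1 - (Ks[si] + 2) / 2) * log1p(-pmin(r2, 1 - 1e-16))
        pmat[, si] <- pchisq(chi2, df = Ks[si], lower.tail = FALSE)
      }
      minp[done + seq_len(b)] <- do.call(pmin, as.data.frame(pmat))
      done <- done + b
    }
    m_eff[i] <- alpha / quantile(minp, probs = percentile / 100, type = 7)
  }
  list(mean_m_eff = mean(m_eff), sd_m_eff = sd(m_eff),
       per_snp_m_eff = m_eff, probe_snps = probes)
}

#' Study-wide significance threshold
#'
#' Divides the conventional genome-wide threshold 5e-8 by the effective
#' number of independent tests, reported to 3 significant figures.
#'
#' @param m_eff effective number of tests (values below 1 are clamped to 1
#'   with a warning).
#' @return numeric threshold.
#' @examples
#' study_wide_threshold(11.44)  # 4.37e-9
#' @export
study_wide_threshold <- function(m_eff) {
  if (!is.numeric(m_eff) || length(m_eff) != 1L || is.na(m_eff))
    stop("m_eff must be a single number")
  if (m_eff < 1) {
    warning("m_eff < 1 clamped to 1")
    m_eff <- 1
  }
  signif(5e-8 / m_eff, 3L)
}

#' Sample-size-normalized chi-squared statistic
#'
#' `nu = chi2 / (D * (1 + chi2 / N))`, which places chi-squared statistics
#' with different degrees of freedom D and sample sizes N on a common scale
#' so medians can be compared across segments.
#'
#' @param chi2 nonnegative statistic(s).
#' @param D degrees of freedom (>= 1).
#' @param N sample size (>= 2).
#' @return numeric nu.
#' @export
normalized_stat <- function(chi2, D, N) {
  if (any(chi2 < 0)) stop("chi2 must be nonnegative")
  if (any(D < 1) || any(N < 2)) stop("need D >= 1 and N >= 2")
  chi2 / (D * (1 + chi2 / N))
}

#' Genomic inflation factor on normalized statistics
#'
#' Converts each record's best-segment chi-squared to the normalized
#' statistic nu and returns the ratio of the observed median to the
#' empirical-null median (1 indicates no inflation).
#'
#' @param obs,null data.frames with columns `chi2`, `df`, `n` (the best
#'   segment's statistic, degrees of freedom and sample size per SNP) --
#'   e.g. the `by_snp` table of [run_gwas()] renamed, or built directly.
#' @return scalar lambda.
#' @export
genomic_lambda <- function(obs, null) {
  need <- c("chi2", "df", "n")
  if (!all(need %in% names(obs)) || !all(need %in% names(null)))
    stop("obs and null need columns chi2, df, n")
  if (nrow(obs) == 0L || nrow(null) == 0L) stop("empty inputs")
  nu_obs <- normalized_stat(obs$chi2, obs$df, obs$n)
  nu_null <- normalized_stat(null$chi2, null$df, null$n)
  median(nu_obs) / median(nu_null)
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Standard BH at level `q` (via [stats::p.adjust()]); also reports the
#' data-dependent p-value threshold: the largest rejected p-value, or 0 when
#' nothing is rejected.
#'
#' @param p_values p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `reject` (logical mask) and `p_threshold`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value list")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  reject <- p.adjust(p_values, method = "BH") <= q
  list(reject = reject,
       p_threshold = if (any(reject)) max(p_values[reject]) else 0)
}
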