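# Weir-Cockerham FST, genomic PCs with iterative LD pruning,
# covariate-adjusted LD scores, matched-null FST enrichment,
# ancestry-partitioned allelic dosages, and heterogeneity-of-effect LRTs.

#' Weir-Cockerham FST between two populations
#'
#' Per-SNP variance components of the 1984 Weir & Cockerham estimator for a
#' biallelic locus in two populations: `a` (among populations), `b` (among
#' individuals within populations), `c` (within individuals), with the
#' estimate `a / (a + b + c)`. Negative estimates are clamped to 0 for
#' downstream use, with the pre-clamp value retained; SNPs monomorphic in
#' both populations have an undefined (missing) estimate.
#'
#' @param geno_pop1,geno_pop2 genotype dosage matrices (individuals x SNPs,
#'   values 0/1/2; NA allowed) with the same SNP columns.
#' @return data.frame of class `fst_table`: `a`, `b`, `c`, `est_raw`,
#'   `est` (clamped), `clamped`.
#' @export
weir_cockerham_fst <- function(geno_pop1, geno_pop2) {
  G1 <- as.matrix(geno_pop1); G2 <- as.matrix(geno_pop2)
  if (ncol(G1) != ncol(G2)) stop("populations disagree on SNP count")
  if (nrow(G1) < 2L || nrow(G2) < 2L)
    stop("need at least 2 diploid samples per population")
  n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
  p1 <- colMeans(G1, na.rm = TRUE) / 2
  p2 <- colMeans(G2, na.rm = TRUE) / 2
  h1 <- colMeans(G1 == 1L, na.rm = TRUE)
  h2 <- colMeans(G2 == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  den <- a + b + c_
  est_raw <- ifelse(abs(den) < 1e-300, NA_real_, a / den)
  est <- pmin(pmax(est_raw, 0), 1)
  structure(data.frame(a = a, b = b, c = c_, est_raw = est_raw, est = est,
                       clamped = !is.na(est_raw) & est_raw < 0),
            class = c("fst_table", "data.frame"))
}

#' Multi-locus FST summaries
#'
#' Two standard genome-wide summaries of a per-SNP [weir_cockerham_fst()]
#' table: the unweighted mean of the per-SNP (clamped) estimates, and the
#' ratio-of-sums ("weighted") estimate `sum(a) / sum(a + b + c)`, which
#' Weir & Cockerham recommend for combining loci and which is less biased
#' at moderate sample sizes.
#'
#' @param fst an `fst_table`.
#' @return named vector with `mean` and `weighted`.
#' @export
fst_summary <- function(fst) {
  c(mean = mean(fst$est, na.rm = TRUE),
    weighted = sum(fst$a, na.rm = TRUE) /
      sum(fst$a + fst$b + fst$c, na.rm = TRUE))
}

# one LD-pruning pass over the kept SNPs; returns updated keep mask
.prune_pass <- function(G, keep, window, step, r2_cut) {
  idx <- which(keep)
  removed <- FALSE
  start <- 1L
  while (start <= length(idx)) {
    w <- idx[start:min(start + window - 1L, length(idx))]
    w <- w[keep[w]]
    if (length(w) > 1L) {
      Cw <- suppressWarnings(cor(G[, w, drop = FALSE]))^2
      Cw[is.na(Cw)] <- 0
      for (ii in 2:length(w)) {
        if (!keep[w[ii]]) next
        earlier <- which(keep[w[seq_len(ii - 1L)]])
        if (length(earlier) && any(Cw[ii, earlier] > r2_cut)) {
          keep[w[ii]] <- FALSE
          removed <- TRUE
        }
      }
    }
    start <- start + step
  }
  attr(keep, "removed") <- removed
  keep
}

#' Genomic principal components after iterative LD pruning
#'
#' LD-prunes the panel in sliding windows (dropping one SNP of every pair
#' with `r2 > r2_cut`), repeating whole passes until a pass removes nothing,
#' then runs PCA on the standardized retained dosages.
#'
#' @param panel a `genotype_panel`.
#' @param window window size in markers (default 1000).
#' @param step step size in markers (default 50).
#' @param r2_cut pruning threshold (default 0.2).
#' @param n_pcs PCs to return (default 10).
#' @return list with `pcs` (n x n_pcs score matrix) and `kept` (logical
#'   over SNPs).
#' @export
compute_genomic_pcs <- function(panel, window = 1000L, step = 50L,
                                r2_cut = 0.2, n_pcs = 10L) {
  G <- panel$dosage
  if (ncol(G) == 0L) stop("empty panel")
  keep <- apply(G, 2L, function(g) sd(g) > 1e-12)
  repeat {
    keep2 <- .prune_pass(G, keep, window, step, r2_cut)
    if (!attr(keep2, "removed")) { keep <- as.logical(keep2); break }
    keep <- as.logical(keep2)
  }
  if (!any(keep)) stop("all SNPs pruned")
  Gs <- scale(G[, keep, drop = FALSE])
  pc <- prcomp(Gs, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  list(pcs = pc$x[, seq_len(k), drop = FALSE], kept = keep)
}

#' Covariate-adjusted LD scores
#'
#' Dosages are residualized on the covariates (OLS with intercept), then
#' each SNP's LD score is the sum, over all SNPs within `window_cm` on the
#' same chromosome (self included), of the bias-adjusted squared correlation
#' `r2 - (1 - r2) / (n - 2)`.
#'
#' @param panel a `genotype_panel` with cM positions.
#' @param covariates n x c matrix (e.g. 10 genomic PCs), or `NULL`.
#' @param window_cm window half-width in cM (default 20).
#' @param unbiased apply the small-sample adjustment (default `TRUE`).
#' @return numeric vector of LD scores (NA for zero-variance SNPs).
#' @export
adjusted_ld_scores <- function(panel, covariates = NULL, window_cm = 20,
                               unbiased = TRUE) {
  if (is.null(panel$variants$cM) || anyNA(panel$variants$cM))
    stop("cM positions required")
  G <- panel$dosage
  n <- nrow(G)
  if (!is.null(covariates)) {
    X <- cbind(1, as.matrix(covariates))
    G <- G - qr.fitted(qr(X), G)
  }
  sds <- apply(G, 2L, sd)
  ok <- sds > 1e-12
  ell <- rep(NA_real_, ncol(G))
  for (ch in unique(panel$variants$chrom)) {
    on_ch <- which(panel$variants$chrom == ch & ok)
    if (length(on_ch) == 0L) next
    C2 <- suppressWarnings(cor(G[, on_ch, drop = FALSE]))^2
    C2[is.na(C2)] <- 0
    if (unbiased) C2 <- C2 - (1 - C2) / (n - 2)
    cm <- panel$variants$cM[on_ch]
    mask <- abs(outer(cm, cm, `-`)) <= window_cm
    ell[on_ch] <- rowSums(C2 * mask)
  }
  ell
}

# nearest nonempty (MAF, LD) bin by Chebyshev ring search
.nearest_cell <- function(bi, bj, occupancy) {
  nb <- dim(occupancy)
  for (radius in 0:max(nb)) {
    cand <- expand.grid(i = max(1, bi - radius):min(nb[1], bi + radius),
                        j = max(1, bj - radius):min(nb[2], bj + radius))
    cand <- cand[pmax(abs(cand$i - bi), abs(cand$j - bj)) == radius, ,
                 drop = FALSE]
    hit <- cand[occupancy[cbind(cand$i, cand$j)] > 0, , drop = FALSE]
    if (nrow(hit) > 0L) return(c(hit$i[1L], hit$j[1L]))
  }
  stop("no nonempty bin found")
}

#' FST enrichment of lead SNPs against MAF/LD-matched nulls
#'
#' The mean (clamped) FST of the lead SNPs is compared with a null
#' distribution of `n_resamples` means, each formed by drawing, for every
#' lead, one random SNP from the same MAF x LD-score cell of a
#' `n_bins x n_bins` equal-count quantile binning of the genome-wide SNP
#' set. The verdict is `"low"`/`"high"` if the observed mean falls below
#' the `lower_pct` or above the `upper_pct` percentile of the null means.
#'
#' @param snp_table data.frame over genome-wide SNPs with columns `maf`,
#'   `ld`, `fst`.
#' @param leads integer/logical index of lead SNPs in `snp_table`, or a
#'   data.frame with the same three columns (bins are then matched, widening
#'   to the nearest nonempty cell with a warning).
#' @param n_bins quantile bins per axis (default 20).
#' @param n_resamples null resamples (default 10000).
#' @param lower_pct,upper_pct two-sided percentile bounds (2.5/97.5).
#' @param seed RNG seed.
#' @return list with `obs_mean`, `null_means`, `ci` (the two null
#'   percentiles), `verdict` (`"low"`, `"high"`, `"ns"`), `reliable`.
#' @export
fst_enrichment <- function(snp_table, leads, n_bins = 20L,
                           n_resamples = 10000L, lower_pct = 2.5,
                           upper_pct = 97.5, seed = 1L) {
  stopifnot(all(c("maf", "ld", "fst") %in% names(snp_table)), n_bins >= 2L)
  set.seed(seed)
  qbin <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                          type = 7, na.rm = TRUE))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  bin_maf <- qbin(snp_table$maf)
  bin_ld <- qbin(snp_table$ld)
  nb <- c(max(bin_maf, na.rm = TRUE), max(bin_ld, na.rm = TRUE))
  occupancy <- matrix(0L, nb[1], nb[2])
  tab <- table(factor(bin_maf, levels = seq_len(nb[1])),
               factor(bin_ld, levels = seq_len(nb[2])))
  occupancy[] <- as.integer(tab)
  fst_cl <- pmin(pmax(snp_table$fst, 0), 1)
  if (is.data.frame(leads)) {
    lead_fst <- pmin(pmax(leads$fst, 0), 1)
    bm <- as.integer(cut(leads$maf,
                         breaks = unique(quantile(snp_table$maf,
                           seq(0, 1, length.out = n_bins + 1L), type = 7)),
                         include.lowest = TRUE, labels = FALSE))
    bl <- as.integer(cut(leads$ld,
                         breaks = unique(quantile(snp_table$ld,
                           seq(0, 1, length.out = n_bins + 1L), type = 7)),
                         include.lowest = TRUE, labels = FALSE))
    bm[is.na(bm)] <- 1L; bl[is.na(bl)] <- 1L
    cells <- cbind(bm, bl)
    widened <- FALSE
    for (i in seq_len(nrow(cells))) {
      if (occupancy[cells[i, 1L], cells[i, 2L]] == 0L) {
        cells[i, ] <- .nearest_cell(cells[i, 1L], cells[i, 2L], occupancy)
        widened <- TRUE
      }
    }
    if (widened) warning("empty matching cell(s) widened to nearest nonempty")
  } else {
    lead_idx <- if (is.logical(leads)) which(leads) else as.integer(leads)
    lead_fst <- fst_cl[lead_idx]
    cells <- cbind(bin_maf[lead_idx], bin_ld[lead_idx])
  }
  pools <- lapply(seq_len(nrow(cells)), function(i)
    which(bin_maf == cells[i, 1L] & bin_ld == cells[i, 2L]))
  obs_mean <- mean(lead_fst)
  null_means <- vapply(seq_len(n_resamples), function(b)
    mean(fst_cl[vapply(pools, function(p)
      p[sample.int(length(p), 1L)], integer(1L))]), numeric(1L))
  ci <- quantile(null_means, probs = c(lower_pct, upper_pct) / 100, type = 7)
  verdict <- if (obs_mean < ci[1L]) "low" else if (obs_mean > ci[2L]) "high"
             else "ns"
  list(obs_mean = obs_mean, null_means = null_means, ci = unname(ci),
       verdict = verdict, reliable = n_resamples >= 100L)
}

#' Ancestry-partitioned allelic dosages at one SNP
#'
#' Counts, per subject and ancestry, the major alleles carried on haplotypes
#' assigned to that ancestry (Tractor-style partition), so that
#' `x_EUR + x_AFR + x_AMR` equals the total dosage.
#'
#' @param panel a `genotype_panel` carrying phased `haplotypes` and
#'   `hap_ancestry` (as produced by [simulate_admixed_cohort()]).
#' @param snp SNP column index or id.
#' @return n x 3 matrix with columns EUR, AFR, AMR.
#' @export
ancestry_dosages <- function(panel, snp) {
  if (is.null(panel$haplotypes) || is.null(panel$hap_ancestry))
    stop("phased haplotypes with ancestry are required (unphased input)")
  j <- if (is.character(snp)) match(snp, panel$variants$id) else snp
  if (is.na(j)) stop("SNP not found")
  al <- panel$haplotypes[, j, , drop = TRUE]
  an <- panel$hap_ancestry[, j, , drop = TRUE]
  out <- sapply(1:3, function(a) rowSums(al * (an == a)))
  colnames(out) <- ANCESTRIES
  out
}

#' Likelihood-ratio test for ancestry heterogeneity of a SNP effect
#'
#' Fits, by Gaussian maximum likelihood (OLS), a full model in which each
#' ancestry's allelic dosage has its own effect and a constrained model in
#' which the effects are equal (the standard additive GWAS model with local
#' ancestry adjustment):
#' `y = b0 + b1*a_EUR + b2*a_AFR + b3*x_EUR + b4*x_AFR + b5*x_AMR`,
#' with `b2 = b5 = 0` under the 2-way (EUR vs AFR) scenario. The statistic
#' is `n * sum_j log(RSS0_j / RSS1_j)` over phenotype dimensions, referred
#' to a chi-squared with `(k_groups - 1) * m` degrees of freedom. Ancestries
#' with no allele copies are dropped (with df reduced); if fewer than two
#' testable groups remain the result is flagged untestable.
#'
#' @param y phenotype: length-n vector (univariate latent trait) or n x m
#'   matrix (multivariate PC scores), pre-adjusted for global covariates.
#' @param a_eur,a_afr local ancestry dosages at the SNP's window.
#' @param x_eur,x_afr,x_amr ancestry-partitioned allelic dosages (see
#'   [ancestry_dosages()]); `x_amr` ignored under `scenario = "2way"`.
#' @param scenario `"2way"` (EUR vs AFR) or `"3way"`.
#' @return list with `stat`, `df`, `p`, `betas_full` (per kept ancestry,
#'   m columns), `dropped` (ancestries without copies), `testable`.
#' @export
heterogeneity_lrt <- function(y, a_eur, a_afr, x_eur, x_afr, x_amr = NULL,
                              scenario = c("2way", "3way")) {
  scenario <- match.arg(scenario)
  Y <- as.matrix(y)
  n <- nrow(Y); m <- ncol(Y)
  xs <- if (scenario == "2way") list(EUR = x_eur, AFR = x_afr)
        else list(EUR = x_eur, AFR = x_afr, AMR = x_amr)
  if (scenario == "3way" && is.null(x_amr)) stop("x_amr required for 3way")
  anc_cov <- if (scenario == "2way") cbind(1, a_eur)
             else cbind(1, a_eur, a_afr)
  present <- vapply(xs, function(x) sum(x) > 0 && sd(x) > 1e-12, logical(1L))
  dropped <- names(xs)[!present]
  if (sum(present) < 2L) {
    return(list(stat = NA_real_, df = NA_integer_, p = NA_real_,
                betas_full = NULL, dropped = dropped, testable = FALSE))
  }
  Xg <- do.call(cbind, xs[present])
  rss <- function(X) {
    res <- Y - qr.fitted(qr(X), Y)
    colSums(res^2)
  }
  rss1 <- rss(cbind(anc_cov, Xg))
  rss0 <- rss(cbind(anc_cov, rowSums(Xg)))
  stat <- n * sum(log(pmax(rss0, 1e-300) / pmax(rss1, 1e-300)))
  stat <- max(stat, 0)
  df <- (sum(present) - 1L) * m
  p <- pchisq(stat, df = df, lower.tail = FALSE)
  B <- qr.coef(qr(cbind(anc_cov, Xg)), Y)
  betas_full <- B[ncol(anc_cov) + seq_len(sum(present)), , drop = FALSE]
  rownames(betas_full) <- names(xs)[present]
  list(stat = stat, df = df, p = p, betas_full = betas_full,
       dropped = dropped, testable = TRUE)
}

#' Smallest BH-adjusted p across qualifying segments
#'
#' Used by the all-significant-segments heterogeneity scenario: run
#' [heterogeneity_lrt()] in every segment where the SNP is significant and
#' combine with this helper.
#'
#' @param p_values per-segment heterogeneity p-values.
#' @return minimum Benjamini-Hochberg adjusted p.
#' @export
min_bh_p <- function(p_values) min(p.adjust(p_values, method = "BH"))
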