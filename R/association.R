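# Per-SNP, per-segment multivariate association: local-ancestry adjustment
# of PC scores, CCA against the SNP dosage, and the genome-wide scan.

#' Residualize segment scores on local ancestry
#'
#' Ordinary least squares residualization of each PC-score column on an
#' intercept plus the EUR and AFR diploid ancestry dosages of the SNP's
#' window (AMR is the reference complement, since the three dosages sum
#' to 2). Constant ancestry columns (e.g. in a homogeneous cohort) are
#' dropped, leaving plain centering.
#'
#' @param scores n x K matrix of segment PC scores, already adjusted for
#'   global covariates.
#' @param ancestry_dosage n x 3 matrix (EUR, AFR, AMR columns) of diploid
#'   ancestry dosages at the SNP's window, or n x 2 (EUR, AFR).
#' @return n x K matrix of residual scores.
#' @export
adjust_local_ancestry <- function(scores, ancestry_dosage) {
  scores <- as.matrix(scores)
  A <- as.matrix(ancestry_dosage)
  if (nrow(A) != nrow(scores)) stop("ancestry dosages disagree on n")
  A <- A[, seq_len(min(2L, ncol(A))), drop = FALSE]   # EUR, AFR; AMR implied
  keep <- apply(A, 2L, function(col) sd(col) > 1e-12)
  X <- cbind(1, A[, keep, drop = FALSE])
  qr_x <- qr(X)
  scores - qr.fitted(qr_x, scores)
}

#' CCA association test of one SNP against one segment's shape space
#'
#' With a single SNP on one side, the canonical correlation equals the
#' multiple correlation of the OLS regression of the dosage on the K score
#' columns; the loading is the fitted coefficient direction (unit-norm in PC
#' space), the test statistic is Bartlett's
#' `chi2 = -(n - 1 - (K + 2)/2) * log(1 - r^2)` and the p-value its
#' upper-tail chi-squared probability with K degrees of freedom.
#'
#' @param residual_scores n x K matrix (local-ancestry-adjusted scores).
#' @param genotype length-n dosage vector (0/1/2, non-constant); missing
#'   values are mean-imputed.
#' @param snp_id,segment_id identifiers carried into the record.
#' @return list of class `association_record`: `snp_id`, `segment_id`, `r`,
#'   `chi2`, `df`, `p`, `loading`, `n`; or `NULL` with a warning if the
#'   genotype is constant.
#' @export
cca_test <- function(residual_scores, genotype, snp_id = NA,
                     segment_id = NA) {
  S <- as.matrix(residual_scores)
  g <- as.numeric(genotype)
  if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
  n <- length(g)
  if (nrow(S) != n) stop("scores and genotype disagree on n")
  if (sd(g) < 1e-12) {
    warning("constant genotype; SNP skipped")
    return(NULL)
  }
  # drop rank-deficient score directions
  qr_s <- qr(scale(S, scale = FALSE))
  if (qr_s$rank < ncol(S)) {
    S <- S[, qr_s$pivot[seq_len(qr_s$rank)], drop = FALSE]
    message("rank-deficient scores; K reduced to ", ncol(S))
  }
  K <- ncol(S)
  if (n <= K + 3L) stop("need n > K + 3")
  fit <- lm.fit(cbind(1, S), g)
  res <- fit$residuals
  gc_ <- g - mean(g)
  r2 <- 1 - sum(res^2) / sum(gc_^2)
  r2 <- min(max(r2, 0), 1)
  beta <- fit$coefficients[-1L]
  nb <- sqrt(sum(beta^2))
  loading <- if (nb > 0) beta / nb else { b <- rep(0, K); b[1] <- 1; b }
  chi2 <- -(n - 1 - (K + 2) / 2) * log1p(-r2)
  p <- pchisq(chi2, df = K, lower.tail = FALSE)
  p <- max(p, .Machine$double.xmin)
  structure(list(snp_id = snp_id, segment_id = segment_id,
                 r = sqrt(r2), chi2 = chi2, df = K, p = p,
                 loading = unname(loading), n = n),
            class = "association_record")
}

# Orthonormal basis of the centered score space; r^2 of regressing any g on
# the scores (with intercept) is ||Q2' g_c||^2 / ||g_c||^2 with g_c the
# centered genotype. Used by the vectorized scan and the permutation
# machinery.
.score_basis <- function(scores) {
  Sc <- scale(as.matrix(scores), scale = FALSE)
  q <- qr(Sc)
  qr.Q(q)[, seq_len(q$rank), drop = FALSE]
}

# Vectorized r^2 of many genotype columns against one orthonormalized score
# basis. G: n x s matrix.
.batch_r2 <- function(Q2, G) {
  Gc <- sweep(G, 2L, colMeans(G))
  ss <- colSums(Gc^2)
  num <- colSums(crossprod(Q2, Gc)^2)
  r2 <- ifelse(ss > 0, num / ss, NA_real_)
  pmin(pmax(r2, 0), 1)
}

#' Genome-wide multivariate scan across all segments
#'
#' For every SNP x segment pair: the segment scores are residualized on the
#' local ancestry dosages of the SNP's window, and the SNP is tested by
#' [cca_test()]. Monomorphic SNPs (and SNPs whose window lookup fails) are
#' skipped and counted. Returns a long-format table plus the per-SNP minimum
#' p across segments and the corresponding best segment.
#'
#' @param panel a `genotype_panel` (MAF-filtered; see [filter_maf()]).
#' @param ancestry_panel a `local_ancestry_panel`, or `NULL` for a
#'   homogeneous cohort (scores are then only centered).
#' @param spaces named list of `segment_shape_space` (from
#'   [build_all_shape_spaces()]).
#' @return list of class `gwas_result`: `records` (data.frame with one row
#'   per SNP x segment: snp_id, segment_id, r, chi2, df, p), `loadings`
#'   (list over segments of K x n_snps loading matrices), `by_snp`
#'   (data.frame with min_p and best_segment), `skipped` (data.frame of
#'   skipped SNPs with reasons).
#' @export
run_gwas <- function(panel, ancestry_panel, spaces) {
  s <- ncol(panel$dosage)
  n <- nrow(panel$dosage)
  seg_ids <- as.integer(names(spaces))
  skipped <- character(s)
  mono <- apply(panel$dosage, 2L, function(g) sd(g) < 1e-12)
  skipped[mono] <- "monomorphic"
  if (!is.null(ancestry_panel)) {
    n_win <- nrow(ancestry_panel$windows)
    bad_win <- is.na(panel$window_index) | panel$window_index < 1L |
      panel$window_index > n_win
    skipped[!mono & bad_win] <- "window lookup failed"
  }
  test <- which(skipped == "")
  if (length(test) == 0L) {
    return(structure(list(
      records = data.frame(snp_id = character(0), segment_id = integer(0),
                           r = numeric(0), chi2 = numeric(0),
                           df = integer(0), p = numeric(0)),
      loadings = setNames(vector("list", length(spaces)), names(spaces)),
      by_snp = NULL,
      skipped = data.frame(snp_id = panel$variants$id[skipped != ""],
                           reason = skipped[skipped != ""]),
      n = n), class = "gwas_result"))
  }
  rec_list <- vector("list", length(spaces))
  loadings <- vector("list", length(spaces))
  names(loadings) <- names(spaces)
  for (si in seq_along(spaces)) {
    sp <- spaces[[si]]
    K <- sp$K
    r2 <- numeric(length(test))
    load_mat <- matrix(NA_real_, K, s)
    if (is.null(ancestry_panel)) {
      Q2 <- .score_basis(sp$scores)
      r2 <- .batch_r2(Q2, panel$dosage[, test, drop = FALSE])
      # loadings via per-window batch below need residual scores; compute
      # directly here
      Sc <- scale(sp$scores, scale = FALSE)
      B <- qr.coef(qr(Sc), scale(panel$dosage[, test, drop = FALSE],
                                 scale = FALSE))
      B[is.na(B)] <- 0
      nbs <- sqrt(colSums(B^2))
      load_mat[, test] <- sweep(B, 2L, pmax(nbs, 1e-300), `/`)
    } else {
      wins <- panel$window_index[test]
      for (w in unique(wins)) {
        idx <- test[wins == w]
        res_scores <- adjust_local_ancestry(
          sp$scores, ancestry_panel$dosage_by_window[, w, , drop = TRUE])
        Q2 <- .score_basis(res_scores)
        G <- panel$dosage[, idx, drop = FALSE]
        r2[match(idx, test)] <- .batch_r2(Q2, G)
        Sc <- scale(res_scores, scale = FALSE)
        B <- qr.coef(qr(Sc), scale(G, scale = FALSE))
        B[is.na(B)] <- 0
        nbs <- sqrt(colSums(B^2))
        load_mat[, idx] <- sweep(B, 2L, pmax(nbs, 1e-300), `/`)
      }
    }
    chi2 <- -(n - 1 - (K + 2) / 2) * log1p(-pmin(r2, 1 - 1e-16))
    p <- pmax(pchisq(chi2, df = K, lower.tail = FALSE), .Machine$double.xmin)
    rec_list[[si]] <- data.frame(
      snp_id = panel$variants$id[test],
      segment_id = seg_ids[si],
      r = sqrt(r2), chi2 = chi2, df = K, p = p)
    loadings[[si]] <- load_mat
  }
  records <- do.call(rbind, rec_list)
  by_snp <- NULL
  if (length(test)) {
    pm <- sapply(rec_list, function(d) d$p)
    if (is.null(dim(pm))) pm <- matrix(pm, nrow = 1L)
    best <- apply(pm, 1L, which.min)
    by_snp <- data.frame(
      snp_id = panel$variants$id[test],
      chrom = panel$variants$chrom[test],
      bp = panel$variants$bp[test],
      min_p = pm[cbind(seq_len(nrow(pm)), best)],
      best_segment = seg_ids[best],
      best_chi2 = sapply(seq_along(test), function(i) rec_list[[best[i]]]$chi2[i]),
      best_df = sapply(best, function(b) spaces[[b]]$K))
  }
  skip_df <- data.frame(snp_id = panel$variants$id[skipped != ""],
                        reason = skipped[skipped != ""])
  structure(list(records = records, loadings = loadings, by_snp = by_snp,
                 skipped = skip_df, n = n),
            class = "gwas_result")
}

#' Latent shape trait of an association record
#'
#' Maps the CCA loading back to vertex space: the displacement field is
#' `basis %*% loading`, reshaped to k x 3 over the segment's vertices; the
#' per-subject projection scores (`scores %*% loading`) reproduce the
#' canonical variate used for replication and hotspot mapping.
#'
#' @param record an `association_record` (or any list with a unit-norm
#'   `loading`).
#' @param space the matching `segment_shape_space`.
#' @return list with `displacement` (k x 3 matrix), `projection`
#'   (length-n scores), `loading`.
#' @export
latent_shape <- function(record, space) {
  loading <- record$loading
  if (length(loading) != ncol(space$basis))
    stop("loading and PC basis dimensions disagree")
  if (abs(sqrt(sum(loading^2)) - 1) > 1e-6)
    stop("loading must be unit-norm")
  disp <- as.vector(space$basis %*% loading)
  k <- length(space$vertices)
  list(displacement = matrix(disp, k, 3L, byrow = TRUE),
       projection = as.vector(space$scores %*% loading),
       loading = loading)
}
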