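# Out-of-sample replication by latent-trait projection, the transmission
# disequilibrium test, and cross-GWAS genetic-sharing statistics.

#' Map replication shapes into a discovery segment shape space
#'
#' Aligns the replication cohort's segment configurations to the discovery
#' mean shape (translation, unit centroid-size scaling when the discovery
#' space used it, optimal rotation) and projects them onto the discovery PC
#' basis.
#'
#' @param cohort replication [mesh_cohort] on the discovery template
#'   topology.
#' @param space discovery `segment_shape_space`.
#' @param with_scaling match the discovery GPA scaling (default `TRUE`).
#' @return n x K matrix of scores in the discovery space.
#' @export
project_into_space <- function(cohort, space, with_scaling = TRUE) {
  coords <- cohort$coords[, space$vertices, , drop = FALSE]
  n <- dim(coords)[1]
  M <- space$mean_shape
  flat <- matrix(0, n, 3L * length(space$vertices))
  for (i in seq_len(n)) {
    Xi <- scale(coords[i, , ], scale = FALSE)
    if (with_scaling) Xi <- Xi / sqrt(sum(Xi^2))
    Xi <- Xi %*% .procrustes_rotation(Xi, M)
    flat[i, ] <- as.vector(t(Xi))
  }
  sweep(flat, 2L, space$center) %*% space$basis
}

#' Replication test of one discovery latent trait
#'
#' Projects replication-space scores onto the discovery CCA loading and
#' regresses the resulting univariate latent-trait score on the replication
#' dosage; significance is the F statistic with (1, n-2) degrees of freedom.
#'
#' @param repl_scores n x K matrix of replication scores in the discovery
#'   segment space (see [project_into_space()]).
#' @param discovery_loading unit-norm K-vector from the discovery
#'   `association_record`.
#' @param repl_genotype length-n replication dosage.
#' @return list with `f`, `df1`, `df2`, `p`, `slope`, `testable`.
#' @export
project_and_replicate <- function(repl_scores, discovery_loading,
                                  repl_genotype) {
  S <- as.matrix(repl_scores)
  if (ncol(S) != length(discovery_loading))
    stop("loading and score dimensions disagree")
  g <- as.numeric(repl_genotype)
  n <- length(g)
  if (nrow(S) != n) stop("scores and genotype disagree on n")
  if (sd(g) < 1e-12)
    return(list(f = NA_real_, df1 = 1L, df2 = n - 2L, p = NA_real_,
                slope = NA_real_, testable = FALSE))
  score <- as.vector(S %*% discovery_loading)
  gc_ <- g - mean(g); sc <- score - mean(score)
  beta <- sum(gc_ * sc) / sum(gc_^2)
  res <- sc - beta * gc_
  rss <- sum(res^2)
  f <- (sum(sc^2) - rss) / (rss / (n - 2))
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  list(f = f, df1 = 1L, df2 = n - 2L, p = p, slope = beta, testable = TRUE)
}

#' Transmission disequilibrium test
#'
#' Counts transmissions (`b`) and non-transmissions (`c`) of the target
#' allele from heterozygous parents to the affected child and forms
#' McNemar's statistic `(b - c)^2 / (b + c)` on 1 degree of freedom. Counts
#' are derived from the trio genotypes: a homozygous parent's transmission
#' is fixed, so the heterozygous parents' transmitted alleles follow from
#' the child genotype.
#'
#' @param trios a `trio_set` (see [simulate_trios()]).
#' @param snp SNP column index (default 1).
#' @return list with `b`, `c`, `chi2`, `p`, `testable`.
#' @export
tdt <- function(trios, snp = 1L) {
  fa <- trios$father[, snp]; mo <- trios$mother[, snp]
  ch <- trios$child[, snp]
  het_f <- fa == 1L; het_m <- mo == 1L
  # transmitted target alleles from het parents = child dosage minus the
  # fixed contribution of homozygous parents
  fixed <- ifelse(het_f, 0L, fa %/% 2L) + ifelse(het_m, 0L, mo %/% 2L)
  from_het <- ch - fixed
  n_het <- het_f + het_m
  if (any(from_het < 0L | from_het > n_het))
    stop("child genotype inconsistent with Mendelian transmission")
  b <- sum(from_het)
  c_ <- sum(n_het) - b
  if (b + c_ == 0L)
    return(list(b = 0L, c = 0L, chi2 = NA_real_, p = NA_real_,
                testable = FALSE))
  chi2 <- (b - c_)^2 / (b + c_)
  list(b = b, c = c_, chi2 = chi2,
       p = pchisq(chi2, df = 1, lower.tail = FALSE), testable = TRUE)
}

#' Average association score per LD block
#'
#' Assigns SNPs to approximately independent LD blocks (half-open intervals)
#' and averages `-log10(p)` within each block; empty blocks are dropped.
#' Zero p-values are floored at the smallest positive double.
#'
#' @param summary data.frame with `chrom`, `bp`, `p`.
#' @param blocks data.frame with `chrom`, `start`, `end` (half-open bp
#'   intervals, non-overlapping within chromosome).
#' @return data.frame with `block` (row index into `blocks`) and `mean_mlogp`.
#' @export
block_average <- function(summary, blocks) {
  p <- pmax(summary$p, .Machine$double.xmin)
  mlp <- -log10(p)
  block <- rep(NA_integer_, nrow(summary))
  for (bi in seq_len(nrow(blocks))) {
    inb <- summary$chrom == blocks$chrom[bi] &
      summary$bp >= blocks$start[bi] & summary$bp < blocks$end[bi]
    block[inb] <- bi
  }
  keep <- !is.na(block)
  agg <- rowsum(mlp[keep], group = block[keep])
  cnt <- rowsum(rep(1, sum(keep)), group = block[keep])
  data.frame(block = as.integer(rownames(agg)),
             mean_mlogp = as.vector(agg / cnt))
}

#' Spearman genetic-sharing statistic between two GWAS
#'
#' Rank correlation of block-averaged `-log10(p)` over the shared blocks;
#' the standard error comes from bootstrapping blocks (`n_boot` cycles) and
#' the one-tailed p-value from a normal approximation, `P(Z > rho / SE)`.
#'
#' @param blocksA,blocksB outputs of [block_average()] for the two GWAS.
#' @param n_boot bootstrap cycles (default 100).
#' @param seed RNG seed.
#' @return list with `rho`, `se`, `p_one_tailed`, `n_blocks`.
#' @export
spearman_sharing <- function(blocksA, blocksB, n_boot = 100L, seed = 1L) {
  m <- merge(blocksA, blocksB, by = "block", suffixes = c("_a", "_b"))
  if (nrow(m) < 10L) stop("need at least 10 shared blocks")
  rho <- cor(m$mean_mlogp_a, m$mean_mlogp_b, method = "spearman")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(m), replace = TRUE)
    suppressWarnings(cor(m$mean_mlogp_a[idx], m$mean_mlogp_b[idx],
                         method = "spearman"))
  }, numeric(1L))
  se <- sd(boots, na.rm = TRUE)
  p <- if (se < 1e-12) as.numeric(rho <= 0) else
    pnorm(rho / se, lower.tail = FALSE)
  list(rho = rho, se = se, p_one_tailed = p, n_blocks = nrow(m))
}

#' Mutual strongest connections of a correlation matrix
#'
#' Normalizes each row and each column by its maximum (reported alongside)
#' and returns the pairs `(i, j)` such that `j` is the argmax of row `i`
#' and `i` is the argmax of column `j` on the raw matrix. Ties yield all
#' tied pairs, flagged.
#'
#' @param corr_matrix nonnegative matrix.
#' @return list with `pairs` (data.frame row, col, value, tied),
#'   `row_normalized`, `col_normalized`.
#' @export
mutual_strongest <- function(corr_matrix) {
  M <- as.matrix(corr_matrix)
  if (any(M < 0)) stop("matrix must be nonnegative")
  rmax <- apply(M, 1L, max); cmax <- apply(M, 2L, max)
  tol <- 1e-12
  pairs <- NULL
  for (i in seq_len(nrow(M))) {
    js <- which(M[i, ] >= rmax[i] - tol)
    for (j in js) {
      if (M[i, j] >= cmax[j] - tol) {
        tied <- length(js) > 1L || sum(M[, j] >= cmax[j] - tol) > 1L
        pairs <- rbind(pairs, data.frame(row = i, col = j,
                                         value = M[i, j], tied = tied))
      }
    }
  }
  list(pairs = if (is.null(pairs))
         data.frame(row = integer(0), col = integer(0),
                    value = numeric(0), tied = logical(0)) else pairs,
       row_normalized = M / ifelse(rmax > 0, rmax, 1),
       col_normalized = sweep(M, 2L, ifelse(cmax > 0, cmax, 1), `/`))
}

#' LD-based locus overlap between two lead-SNP lists
#'
#' Flags a lead pair as the same signal iff their cohort LD exceeds
#' `r2 > r2_min` (strict). Leads absent from the panel are unevaluable.
#'
#' @param leadsA,leadsB character vectors of SNP ids.
#' @param panel a `genotype_panel` containing the leads.
#' @param r2_min threshold (default 0.2).
#' @return data.frame with one row per A x B pair: `snp_a`, `snp_b`, `r2`,
#'   `shared` (NA when unevaluable).
#' @export
ld_overlap <- function(leadsA, leadsB, panel, r2_min = 0.2) {
  out <- expand.grid(snp_a = leadsA, snp_b = leadsB,
                     stringsAsFactors = FALSE)
  out$r2 <- NA_real_
  for (k in seq_len(nrow(out))) {
    ia <- match(out$snp_a[k], panel$variants$id)
    ib <- match(out$snp_b[k], panel$variants$id)
    if (is.na(ia) || is.na(ib)) next
    gi <- panel$dosage[, ia]; gj <- panel$dosage[, ib]
    if (sd(gi) < 1e-12 || sd(gj) < 1e-12) next
    out$r2[k] <- cor(gi, gj)^2
  }
  out$shared <- out$r2 > r2_min
  out
}
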