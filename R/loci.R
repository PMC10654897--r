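# LD, three-step peak clumping, cross-GWAS locus overlap, frontal/parietal
# locus labeling, and deformation hotspot maps.

#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors, computed from the same
#' cohort genotypes as the discovery GWAS.
#'
#' @param panel a `genotype_panel`.
#' @param snp_i,snp_j SNP ids (character) or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  ix <- if (is.character(snp_i)) match(snp_i, panel$variants$id) else snp_i
  jx <- if (is.character(snp_j)) match(snp_j, panel$variants$id) else snp_j
  if (is.na(ix) || is.na(jx)) stop("SNP not found in panel")
  gi <- panel$dosage[, ix]; gj <- panel$dosage[, jx]
  if (sd(gi) < 1e-12 || sd(gj) < 1e-12)
    stop("LD undefined for a constant SNP")
  cor(gi, gj)^2
}

#' Clumping configuration
#'
#' @param window1_bp distance within which every significant SNP joins the
#'   lead's locus (default 250 kb).
#' @param window2_bp distance within which LD-linked SNPs join (default 1 Mb).
#' @param merge_bp lead-to-lead distance for merging loci (default 10 Mb).
#' @param r2_clump LD threshold for joining/merging (default 0.01, strict
#'   `>`).
#' @param sig_threshold genome-wide significance (default 5e-8).
#' @param study_wide study-wide significance used by the singleton filter
#'   (default 4.37e-9).
#' @param overlap_bp cross-GWAS lead-pairing distance (default 250 kb).
#' @return list of class `clump_config`.
#' @export
clump_config <- function(window1_bp = 250000, window2_bp = 1000000,
                         merge_bp = 10000000, r2_clump = 0.01,
                         sig_threshold = 5e-8, study_wide = 4.37e-9,
                         overlap_bp = 250000) {
  if (!(window1_bp <= window2_bp && window2_bp <= merge_bp))
    stop("need window1_bp <= window2_bp <= merge_bp")
  structure(list(window1_bp = window1_bp, window2_bp = window2_bp,
                 merge_bp = merge_bp, r2_clump = r2_clump,
                 sig_threshold = sig_threshold, study_wide = study_wide,
                 overlap_bp = overlap_bp),
            class = "clump_config")
}

# order by (p, chrom, bp)
.p_order <- function(d) order(d$p, d$chrom, d$bp)

#' Clump significant SNPs into independent loci
#'
#' Three steps. (1) Starting from the most significant unassigned SNP, all
#' SNPs within `window1_bp`, as well as those within `window2_bp` and in LD
#' (`r2 > r2_clump`) with it, are clumped into one locus represented by that
#' SNP; repeat until every significant SNP is assigned. (2) Any two loci
#' whose lead SNPs are within `merge_bp` and in LD (`r2 > r2_clump`) are
#' merged, represented by the lower-p lead; merging is iterated to a
#' fixpoint so the result does not depend on processing order. (3) Any
#' remaining single-SNP locus that does not reach the study-wide threshold
#' is removed. Ties in p are broken by ascending (chrom, bp).
#'
#' @param summary data.frame with columns `snp_id`, `chrom`, `bp`, `p`
#'   (per-SNP minimum p across segments); only rows with
#'   `p < cfg$sig_threshold` are used.
#' @param panel the discovery `genotype_panel` (for LD).
#' @param cfg a [clump_config()].
#' @return list of loci, each a list with `lead_snp`, `chrom`, `bp`,
#'   `best_p`, `members`, `member_p`; plus attribute `"removed_singletons"`.
#' @export
clump <- function(summary, panel, cfg = clump_config()) {
  sig <- summary[summary$p < cfg$sig_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  sig <- sig[.p_order(sig), , drop = FALSE]
  col <- match(sig$snp_id, panel$variants$id)
  if (anyNA(col)) stop("summary SNP absent from panel")
  G <- panel$dosage[, col, drop = FALSE]
  Gs <- scale(G)
  n <- nrow(G)
  r2_with <- function(i, js) {
    if (length(js) == 0L) return(numeric(0))
    (crossprod(Gs[, i], Gs[, js, drop = FALSE]) / (n - 1))^2
  }
  remaining <- seq_len(nrow(sig))
  loci <- list()
  while (length(remaining) > 0L) {
    lead <- remaining[1L]
    same <- remaining[sig$chrom[remaining] == sig$chrom[lead]]
    d <- abs(sig$bp[same] - sig$bp[lead])
    near <- same[d <= cfg$window1_bp]
    mid <- same[d <= cfg$window2_bp & d > cfg$window1_bp]
    if (length(mid) > 0L)
      mid <- mid[as.vector(r2_with(lead, mid)) > cfg$r2_clump]
    mem <- sort(unique(c(lead, near, mid)))
    loci[[length(loci) + 1L]] <- mem
    remaining <- setdiff(remaining, mem)
  }
  # step 2: merge to fixpoint
  lead_of <- function(mem) mem[.p_order(sig[mem, , drop = FALSE])[1L]]
  repeat {
    merged <- FALSE
    leads <- vapply(loci, lead_of, integer(1L))
    nl <- length(loci)
    for (i in seq_len(nl - 1L)) {
      if (merged) break
      for (j in (i + 1L):nl) {
        li <- leads[i]; lj <- leads[j]
        if (sig$chrom[li] == sig$chrom[lj] &&
            abs(sig$bp[li] - sig$bp[lj]) <= cfg$merge_bp &&
            as.vector(r2_with(li, lj)) > cfg$r2_clump) {
          loci[[i]] <- sort(unique(c(loci[[i]], loci[[j]])))
          loci[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  # step 3: drop singletons that miss study-wide significance
  removed <- character(0)
  keep <- vapply(loci, function(mem) {
    if (length(mem) > 1L) return(TRUE)
    sig$p[mem] < cfg$study_wide
  }, logical(1L))
  removed <- vapply(loci[!keep], function(mem) sig$snp_id[mem], character(1L))
  loci <- loci[keep]
  out <- lapply(loci, function(mem) {
    lead <- lead_of(mem)
    list(lead_snp = sig$snp_id[lead], chrom = sig$chrom[lead],
         bp = sig$bp[lead], best_p = sig$p[lead],
         members = sig$snp_id[mem], member_p = sig$p[mem])
  })
  # report loci in genome order
  if (length(out) > 1L)
    out <- out[order(vapply(out, `[[`, numeric(1L), "chrom"),
                     vapply(out, `[[`, numeric(1L), "bp"))]
  attr(out, "removed_singletons") <- removed
  out
}

#' Pair loci between two GWAS by lead-SNP proximity
#'
#' Greedy nearest pairing: among all same-chromosome lead pairs within
#' `overlap_bp`, repeatedly take the closest pair and remove both leads.
#' Unpaired loci are flagged unique to their GWAS; when the other GWAS's
#' summary is supplied, each unique locus is assigned the best (lowest-p)
#' proxy SNP within `overlap_bp` there.
#'
#' @param leadsA,leadsB data.frames with `snp_id`, `chrom`, `bp` (and `p`
#'   if available).
#' @param overlap_bp pairing distance (default 250 kb).
#' @param summaryA,summaryB optional full summaries (`snp_id`, `chrom`,
#'   `bp`, `p`) used for proxy lookup.
#' @return list with `pairs` (data.frame snp_a, snp_b, distance_bp),
#'   `unique_a`, `unique_b` (data.frames with proxy columns when
#'   resolvable).
#' @export
cross_gwas_overlap <- function(leadsA, leadsB, overlap_bp = 250000,
                               summaryA = NULL, summaryB = NULL) {
  cand <- expand.grid(a = seq_len(nrow(leadsA)), b = seq_len(nrow(leadsB)))
  cand <- cand[leadsA$chrom[cand$a] == leadsB$chrom[cand$b], , drop = FALSE]
  cand$dist <- abs(leadsA$bp[cand$a] - leadsB$bp[cand$b])
  cand <- cand[cand$dist <= overlap_bp, , drop = FALSE]
  cand <- cand[order(cand$dist, cand$a, cand$b), , drop = FALSE]
  pairs <- data.frame(snp_a = character(0), snp_b = character(0),
                      distance_bp = numeric(0))
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    pairs <- rbind(pairs, data.frame(snp_a = leadsA$snp_id[top$a],
                                     snp_b = leadsB$snp_id[top$b],
                                     distance_bp = top$dist))
    cand <- cand[cand$a != top$a & cand$b != top$b, , drop = FALSE]
  }
  proxy <- function(lead_row, summary_other) {
    if (is.null(summary_other)) return(NA_character_)
    cnd <- summary_other[summary_other$chrom == lead_row$chrom &
                           abs(summary_other$bp - lead_row$bp) <= overlap_bp, ,
                         drop = FALSE]
    if (nrow(cnd) == 0L) return(NA_character_)
    cnd$snp_id[which.min(cnd$p)]
  }
  ua <- leadsA[!(leadsA$snp_id %in% pairs$snp_a), , drop = FALSE]
  ub <- leadsB[!(leadsB$snp_id %in% pairs$snp_b), , drop = FALSE]
  if (nrow(ua)) ua$proxy_in_b <- vapply(seq_len(nrow(ua)), function(i)
    proxy(ua[i, ], summaryB), character(1L))
  if (nrow(ub)) ub$proxy_in_a <- vapply(seq_len(nrow(ub)), function(i)
    proxy(ub[i, ], summaryA), character(1L))
  list(pairs = pairs, unique_a = ua, unique_b = ub)
}

#' Frontal/parietal labeling of a locus
#'
#' `"most_significant"`: the content label of the segment where the locus is
#' most significant. `"most_specific"`: start from that segment and, while
#' its label is `"both"` and deeper levels exist, descend to the child
#' segment with the smaller p; return the label reached. Labels depend only
#' on the ordering of the p profile, so they are invariant to monotone
#' transforms of p.
#'
#' @param p_profile numeric vector of p-values named/indexed by segment id
#'   (heap order: segment i has children 2i, 2i+1); NA where untested.
#' @param hierarchy a `segment_hierarchy` with content labels set.
#' @param scheme `"most_significant"` or `"most_specific"`.
#' @return one of `"frontal"`, `"parietal"`, `"both"`.
#' @export
label_locus <- function(p_profile, hierarchy,
                        scheme = c("most_significant", "most_specific")) {
  scheme <- match.arg(scheme)
  labs <- hierarchy$content_label
  if (anyNA(labs)) stop("hierarchy content labels are not set")
  n_seg <- length(labs)
  p <- rep(Inf, n_seg)
  idx <- if (!is.null(names(p_profile))) as.integer(names(p_profile))
         else seq_along(p_profile)
  p[idx] <- ifelse(is.na(p_profile), Inf, p_profile)
  if (all(!is.finite(p))) stop("empty association profile")
  cur <- which.min(p)
  if (scheme == "most_significant") return(labs[cur])
  while (labs[cur] == "both" && 2L * cur + 1L <= n_seg) {
    ch <- c(2L * cur, 2L * cur + 1L)
    cur <- ch[which.min(p[ch])]
  }
  labs[cur]
}

#' Deformation hotspot map across SNP latent traits
#'
#' For each SNP's latent displacement field, the absolute normal component
#' (displacement projected on the outward vertex normal of the mean shape)
#' is taken per vertex and the resulting vector is scaled to unit Euclidean
#' norm; the hotspot map is the per-vertex 95th percentile of these
#' normalized magnitudes across SNPs.
#'
#' @param latent_fields list of m x 3 displacement fields (full-vault
#'   latent traits, e.g. from [latent_shape()]).
#' @param mean_shape m x 3 average vault used for the normals.
#' @param template template supplying the faces.
#' @param probs percentile (default 0.95).
#' @return list with `map` (length-m vector) and `per_snp` (m x n_snp
#'   matrix of unit-norm magnitude vectors).
#' @export
hotspots <- function(latent_fields, mean_shape, template, probs = 0.95) {
  if (length(latent_fields) == 0L) stop("need at least one latent field")
  nrm <- vertex_normals(mean_shape, template$faces)
  mags <- vapply(latent_fields, function(f) {
    d <- abs(rowSums(f * nrm))
    d / sqrt(sum(d^2))
  }, numeric(nrow(mean_shape)))
  mags <- as.matrix(mags)
  map <- apply(mags, 1L, quantile, probs = probs, type = 7)
  list(map = map, per_snp = mags)
}
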