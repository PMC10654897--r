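# Shared fixture builders; everything is generated in code at test time.

tiny_template <- function() vault_template(8L, 4L)

# small admixed simulation reused across tests
small_sim <- function(n_snps = 80L, n_subjects = 120L,
                      proportions = c(EUR = 0.6, AFR = 0.3, AMR = 0.1),
                      F_pop = c(EUR = 0.1, AFR = 0.1, AMR = 0.1),
                      g = 8, seed = 7L) {
  mod <- simulate_ancestral_frequencies(n_snps, F_pop, seed = seed)
  cfg <- admixture_config(proportions, generations_g = g, seed = seed + 1L)
  simulate_admixed_cohort(mod, cfg, n_subjects)
}

# independent CCA oracle: first canonical correlation via stats::cancor
oracle_cca_r <- function(X, y) {
  stats::cancor(as.matrix(X), matrix(y, ncol = 1L))$cor[1L]
}

# independent clumping oracle: literal three-rule application with explicit
# set bookkeeping and direct cor()-based LD, structured differently from
# clump()
oracle_clump <- function(summary, G, cfg) {
  sig <- summary[summary$p < cfg$sig_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(list())
  ld <- function(i, j) cor(G[, sig$snp_id[i]], G[, sig$snp_id[j]])^2
  unassigned <- order(sig$p, sig$chrom, sig$bp)
  loci <- list()
  while (length(unassigned)) {
    lead <- unassigned[1L]
    mem <- lead
    for (k in unassigned[-1L]) {
      if (sig$chrom[k] != sig$chrom[lead]) next
      dd <- abs(sig$bp[k] - sig$bp[lead])
      if (dd <= cfg$window1_bp) mem <- c(mem, k)
      else if (dd <= cfg$window2_bp && ld(lead, k) > cfg$r2_clump)
        mem <- c(mem, k)
    }
    loci <- c(loci, list(sort(mem)))
    unassigned <- setdiff(unassigned, mem)
  }
  lead_of <- function(mem) mem[order(sig$p[mem], sig$chrom[mem],
                                     sig$bp[mem])[1L]]
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (i in seq_along(loci)) {
      for (j in seq_along(loci)) {
        if (j <= i) next
        li <- lead_of(loci[[i]]); lj <- lead_of(loci[[j]])
        if (sig$chrom[li] == sig$chrom[lj] &&
            abs(sig$bp[li] - sig$bp[lj]) <= cfg$merge_bp &&
            ld(li, lj) > cfg$r2_clump) {
          loci[[i]] <- sort(union(loci[[i]], loci[[j]]))
          loci <- loci[-j]
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  loci <- Filter(function(mem)
    length(mem) > 1L || sig$p[mem] < cfg$study_wide, loci)
  lapply(loci, function(mem)
    list(lead = sig$snp_id[lead_of(mem)], members = sort(sig$snp_id[mem])))
}

# random small clumping instance: positions in clusters, correlated dosages
random_clump_instance <- function(seed) {
  set.seed(seed)
  s <- sample(5:30, 1L)
  n <- 80L
  chrom <- sample(1:2, s, replace = TRUE)
  bp <- integer(s)
  for (ch in unique(chrom)) {
    k <- sum(chrom == ch)
    m1 <- max(1L, k %/% 2L)
    m2 <- k - m1
    pos <- c(sample.int(2000000L, m1, replace = TRUE),
             if (m2 > 0L) sample.int(30000000L, m2, replace = TRUE))
    # strictly increasing within chromosome
    bp[chrom == ch] <- sort(pos) + seq_len(k)
  }
  base <- matrix(rbinom(n * 4L, 2L, 0.4), n, 4L)
  G <- sapply(seq_len(s), function(j) {
    src <- base[, sample.int(4L, 1L)]
    flip <- runif(n) < 0.2
    g <- src
    g[flip] <- rbinom(sum(flip), 2L, 0.4)
    g
  })
  colnames(G) <- sprintf("s%02d", seq_len(s))
  p <- 10^-runif(s, 7.31, 12)           # all genome-wide significant
  p[sample.int(s, min(2L, s))] <- 10^-runif(min(2L, s), 7.31, 8.3)
  summary <- data.frame(snp_id = colnames(G), chrom = chrom, bp = bp, p = p)
  list(summary = summary, G = G)
}

as_panel <- function(G, chrom = NULL, bp = NULL) {
  s <- ncol(G)
  f <- colMeans(G) / 2
  structure(list(
    dosage = G,
    variants = data.frame(
      chrom = if (is.null(chrom)) rep(1L, s) else chrom,
      bp = if (is.null(bp)) seq_len(s) * 1000L else bp,
      cM = (if (is.null(bp)) seq_len(s) * 1000L else bp) / 1e6,
      id = colnames(G),
      allele_major = "A", allele_minor = "B",
      maf = pmin(f, 1 - f)),
    window_index = rep(1L, s)),
    class = "genotype_panel")
}
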