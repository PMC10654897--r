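# Simulation of three-way admixed genotype cohorts: Balding-Nichols ancestral
# population frequencies, Markov local-ancestry tracts along a genetic map,
# haplotype allele draws within local ancestry, and case-parent trios with
# tunable transmission distortion.

ANCESTRIES <- c("EUR", "AFR", "AMR")

#' Simulate ancestral population allele frequencies (Balding-Nichols)
#'
#' Draws a shared ancestral frequency per SNP and, for each of the EUR, AFR
#' and AMR populations, a derived frequency from the Balding-Nichols model:
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with drift parameter `F`. `F` is the
#' expected Wright fixation index separating the derived population from the
#' ancestral pool, so planted differentiation can be recovered by the
#' Weir-Cockerham estimator downstream.
#'
#' @param n_snps number of SNPs.
#' @param F_pop per-population drift in (0,1); a single value is recycled to
#'   the three ancestries, or supply a named vector over EUR/AFR/AMR.
#' @param p_anc_range range of the uniform ancestral frequency draw, inside
#'   (0,1); default `c(0.05, 0.95)`.
#' @param seed integer RNG seed; the model is byte-reproducible given it.
#' @param n_chrom,spacing_bp,cm_per_mb genetic map: SNPs are laid out evenly
#'   spaced at `spacing_bp` (default 1000 bp) across `n_chrom` chromosomes
#'   with a uniform recombination rate `cm_per_mb` (default 1 cM/Mb).
#' @return An object of class `ancestral_model`: `n_snps`, `p_anc`, `F_pop`,
#'   `pop_freqs` (3 x n_snps, rows EUR/AFR/AMR), and `map`
#'   (data.frame chrom, bp, cM).
#' @export
simulate_ancestral_frequencies <- function(n_snps, F_pop,
                                           p_anc_range = c(0.05, 0.95),
                                           seed = 1L, n_chrom = 1L,
                                           spacing_bp = 1000L,
                                           cm_per_mb = 1) {
  n_snps <- .check_count(n_snps, "n_snps")
  n_chrom <- .check_count(n_chrom, "n_chrom")
  if (length(F_pop) == 1L) F_pop <- setNames(rep(F_pop, 3L), ANCESTRIES)
  if (is.null(names(F_pop))) names(F_pop) <- ANCESTRIES
  F_pop <- F_pop[ANCESTRIES]
  .check_prob(F_pop, "F_pop")
  .check_prob(p_anc_range, "p_anc_range")
  stopifnot(length(p_anc_range) == 2L, p_anc_range[1] < p_anc_range[2])
  set.seed(seed)
  p_anc <- runif(n_snps, p_anc_range[1], p_anc_range[2])
  pop_freqs <- matrix(NA_real_, 3L, n_snps, dimnames = list(ANCESTRIES, NULL))
  for (a in ANCESTRIES) {
    f <- F_pop[[a]]
    pop_freqs[a, ] <- rbeta(n_snps, p_anc * (1 - f) / f,
                            (1 - p_anc) * (1 - f) / f)
  }
  # even split of SNPs across chromosomes, even bp spacing, uniform cM/Mb
  chrom <- rep(seq_len(n_chrom), length.out = n_snps)
  chrom <- sort(chrom)
  idx_in_chrom <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along)
  bp <- idx_in_chrom * spacing_bp
  cM <- bp / 1e6 * cm_per_mb
  structure(list(n_snps = n_snps, p_anc = p_anc, F_pop = F_pop,
                 pop_freqs = pop_freqs,
                 map = data.frame(chrom = chrom, bp = bp, cM = cM)),
            class = "ancestral_model")
}

#' Admixture configuration
#'
#' @param proportions nonnegative EUR/AFR/AMR admixture fractions summing to
#'   one (within 1e-12).
#' @param generations_g positive real: expected ancestry switch events per
#'   Morgan per haplotype (the age of admixture in generations under a
#'   homogeneous Poisson tract model).
#' @param seed RNG seed.
#' @return list of class `admixture_config`.
#' @export
admixture_config <- function(proportions, generations_g = 8, seed = 1L) {
  if (length(proportions) != 3L) stop("proportions must have length 3")
  if (is.null(names(proportions))) names(proportions) <- ANCESTRIES
  proportions <- proportions[ANCESTRIES]
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-12)
    stop("proportions must be nonnegative and sum to 1 within 1e-12")
  if (!is.numeric(generations_g) || generations_g < 0)
    stop("generations_g must be nonnegative")
  structure(list(proportions = proportions, generations_g = generations_g,
                 seed = as.integer(seed)),
            class = "admixture_config")
}

# Ancestry states (1=EUR, 2=AFR, 3=AMR) along one chromosome for `k`
# haplotypes: Markov chain with Poisson(g per Morgan) switch events, each
# switch re-drawing the state from the global proportions.
.simulate_tracts <- function(cM, k, proportions, g) {
  s <- length(cM)
  states <- matrix(0L, k, s)
  states[, 1L] <- sample.int(3L, k, replace = TRUE, prob = proportions)
  if (s > 1L) {
    d_morgan <- diff(cM) / 100
    p_switch <- 1 - exp(-g * d_morgan)
    for (j in 2L:s) {
      sw <- runif(k) < p_switch[j - 1L]
      states[, j] <- states[, j - 1L]
      if (any(sw))
        states[sw, j] <- sample.int(3L, sum(sw), replace = TRUE,
                                    prob = proportions)
    }
  }
  states
}

#' Simulate an admixed genotype cohort with local ancestry
#'
#' For each subject, two haplotypes are generated per chromosome: local
#' ancestry follows a Markov chain along the genetic map (switch events
#' Poisson with rate `generations_g` per Morgan, new state drawn from the
#' global proportions), and each allele is Bernoulli with the frequency of
#' its local ancestral population. Local ancestry is summarized as diploid
#' dosages over fixed 0.2 cM windows (the window's ancestry per haplotype is
#' taken at the SNP nearest the window midpoint), matching MSP-style output
#' of local-ancestry callers.
#'
#' @param model an [ancestral_model].
#' @param admix_cfg an [admixture_config].
#' @param n_subjects cohort size.
#' @param window_cm local-ancestry window width in cM (default 0.2).
#' @return list with components
#'   `panel` (class `genotype_panel`: `dosage` counting the major allele,
#'   `variants`, `window_index`, plus phased `haplotypes` and per-SNP
#'   per-haplotype `hap_ancestry`),
#'   `ancestry` (class `local_ancestry_panel`: `dosage_by_window`
#'   n x n_windows x 3 and `windows`), and
#'   `global_proportions` (genome-wide mean window dosage / 2).
#' @export
simulate_admixed_cohort <- function(model, admix_cfg, n_subjects,
                                    window_cm = 0.2) {
  stopifnot(inherits(model, "ancestral_model"),
            inherits(admix_cfg, "admixture_config"))
  n_subjects <- .check_count(n_subjects, "n_subjects")
  if (nrow(model$map) == 0L) stop("empty genetic map")
  set.seed(admix_cfg$seed)
  s <- model$n_snps
  k <- 2L * n_subjects
  hap_anc <- matrix(0L, k, s)      # haplotype-major: rows 1,2 = subject 1
  for (ch in unique(model$map$chrom)) {
    on_ch <- which(model$map$chrom == ch)
    hap_anc[, on_ch] <- .simulate_tracts(model$map$cM[on_ch], k,
                                         admix_cfg$proportions,
                                         admix_cfg$generations_g)
  }
  hap_allele <- matrix(0L, k, s)
  for (j in seq_len(s)) {
    pj <- model$pop_freqs[, j][hap_anc[, j]]
    hap_allele[, j] <- as.integer(runif(k) < pj)
  }
  # windows: fixed width in cM per chromosome
  win <- do.call(rbind, lapply(unique(model$map$chrom), function(ch) {
    cm <- model$map$cM[model$map$chrom == ch]
    starts <- seq(floor(min(cm) / window_cm) * window_cm, max(cm), by = window_cm)
    data.frame(chrom = ch, cm_start = starts, cm_end = starts + window_cm)
  }))
  win$window <- seq_len(nrow(win))
  window_index <- integer(s)
  win_mid_snp <- integer(nrow(win))
  for (ch in unique(model$map$chrom)) {
    on_ch <- which(model$map$chrom == ch)
    wch <- which(win$chrom == ch)
    window_index[on_ch] <- wch[findInterval(model$map$cM[on_ch],
                                            win$cm_start[wch])]
    mids <- (win$cm_start[wch] + win$cm_end[wch]) / 2
    win_mid_snp[wch] <- on_ch[vapply(mids, function(m)
      which.min(abs(model$map$cM[on_ch] - m)), integer(1L))]
  }
  # diploid ancestry dosage per window: ancestry at the window-midpoint SNP
  hap_win_anc <- hap_anc[, win_mid_snp, drop = FALSE]  # k x n_windows
  n_win <- nrow(win)
  dosage_by_window <- array(0L, dim = c(n_subjects, n_win, 3L),
                            dimnames = list(NULL, NULL, ANCESTRIES))
  h1 <- seq(1L, k, by = 2L); h2 <- h1 + 1L
  for (a in 1:3)
    dosage_by_window[, , a] <- (hap_win_anc[h1, , drop = FALSE] == a) +
                               (hap_win_anc[h2, , drop = FALSE] == a)
  global_proportions <- apply(dosage_by_window, 3L, mean) / 2
  names(global_proportions) <- ANCESTRIES

  # dosage counting the major allele: flip coding where allele 1 is minor
  raw_dosage <- hap_allele[h1, , drop = FALSE] + hap_allele[h2, , drop = FALSE]
  f1 <- colMeans(raw_dosage) / 2
  flip <- f1 < 0.5
  dosage <- raw_dosage
  dosage[, flip] <- 2L - dosage[, flip]
  haplotypes <- array(0L, dim = c(n_subjects, s, 2L))
  haplotypes[, , 1L] <- hap_allele[h1, , drop = FALSE]
  haplotypes[, , 2L] <- hap_allele[h2, , drop = FALSE]
  haplotypes[, flip, ] <- 1L - haplotypes[, flip, ]
  hap_ancestry <- array(0L, dim = c(n_subjects, s, 2L))
  hap_ancestry[, , 1L] <- hap_anc[h1, , drop = FALSE]
  hap_ancestry[, , 2L] <- hap_anc[h2, , drop = FALSE]
  maf <- pmin(f1, 1 - f1)
  variants <- data.frame(
    chrom = model$map$chrom, bp = model$map$bp, cM = model$map$cM,
    id = sprintf("snp%06d", seq_len(s)),
    allele_major = ifelse(flip, "A", "B"),
    allele_minor = ifelse(flip, "B", "A"),
    maf = maf)
  panel <- structure(list(dosage = dosage, variants = variants,
                          window_index = window_index,
                          haplotypes = haplotypes,
                          hap_ancestry = hap_ancestry),
                     class = "genotype_panel")
  ancestry <- structure(list(dosage_by_window = dosage_by_window,
                             windows = win),
                        class = "local_ancestry_panel")
  list(panel = panel, ancestry = ancestry,
       global_proportions = global_proportions)
}

#' Filter a genotype panel on minor allele frequency
#'
#' The simulator retains monomorphic SNPs; GWAS-facing code should filter at
#' MAF >= 0.01 first.
#'
#' @param panel a `genotype_panel`.
#' @param min_maf threshold (default 0.01).
#' @return The panel restricted to SNPs with `maf >= min_maf`.
#' @export
filter_maf <- function(panel, min_maf = 0.01) {
  keep <- panel$variants$maf >= min_maf
  panel$dosage <- panel$dosage[, keep, drop = FALSE]
  panel$variants <- panel$variants[keep, , drop = FALSE]
  panel$window_index <- panel$window_index[keep]
  if (!is.null(panel$haplotypes)) {
    panel$haplotypes <- panel$haplotypes[, keep, , drop = FALSE]
    panel$hap_ancestry <- panel$hap_ancestry[, keep, , drop = FALSE]
  }
  rownames(panel$variants) <- NULL
  panel
}

#' Choose a causal SNP for power simulations
#'
#' Selects the SNP whose minor allele frequency is closest to `target_maf`
#' among SNPs whose dosage is at most weakly explained by local ancestry
#' (R-squared below `max_ancestry_r2`). Power claims for the
#' local-ancestry-adjusted test concern the ancestry-orthogonal dose
#' effect -- the pipeline by construction has no power against
#' ancestry-collinear dosage variance -- so planted effects for power
#' studies are placed on SNPs that are not ancestry proxies.
#'
#' @param panel a `genotype_panel`.
#' @param ancestry matching `local_ancestry_panel`.
#' @param target_maf target frequency (default 0.5, maximizing dosage
#'   variance).
#' @param max_ancestry_r2 admissible ancestry R-squared (default 0.1).
#' @return SNP column index.
#' @export
pick_causal_snp <- function(panel, ancestry, target_maf = 0.5,
                            max_ancestry_r2 = 0.1) {
  s <- ncol(panel$dosage)
  r2a <- vapply(seq_len(s), function(j) {
    g <- panel$dosage[, j]
    if (sd(g) < 1e-12) return(1)
    A <- ancestry$dosage_by_window[, panel$window_index[j], 1:2]
    A <- cbind(1, A[, apply(A, 2L, sd) > 1e-12, drop = FALSE])
    res <- g - qr.fitted(qr(A), g)
    1 - sum(res^2) / sum((g - mean(g))^2)
  }, numeric(1L))
  ok <- which(r2a <= max_ancestry_r2)
  if (length(ok) == 0L) ok <- order(r2a)[1:max(1L, s %/% 10L)]
  ok[which.min(abs(panel$variants$maf[ok] - target_maf))]
}

#' Simulate case-parent trios with transmission distortion
#'
#' Parents are drawn under Hardy-Weinberg equilibrium at the given target
#' allele frequencies; each heterozygous parent transmits the target allele
#' with probability `tau` (0.5 under the null of no transmission
#' disequilibrium), homozygous parents transmit their only allele.
#'
#' @param freqs per-SNP target allele frequency in (0,1).
#' @param tau per-SNP transmission probability in `[0,1]` (recycled).
#' @param n_trios number of trios.
#' @param seed RNG seed.
#' @return list of class `trio_set` with `father`, `mother`, `child`
#'   genotype matrices (n_trios x n_snps, target-allele dosage) and
#'   `transmitted_father`/`transmitted_mother` allele matrices.
#' @export
simulate_trios <- function(freqs, tau = 0.5, n_trios, seed = 1L) {
  n_trios <- .check_count(n_trios, "n_trios")
  .check_prob(freqs, "freqs")
  tau <- rep_len(tau, length(freqs))
  .check_prob(tau, "tau", open = FALSE)
  s <- length(freqs)
  set.seed(seed)
  draw_parent <- function() {
    h1 <- matrix(runif(n_trios * s), n_trios) <
      matrix(freqs, n_trios, s, byrow = TRUE)
    h2 <- matrix(runif(n_trios * s), n_trios) <
      matrix(freqs, n_trios, s, byrow = TRUE)
    list(h1 = h1 + 0L, h2 = h2 + 0L)
  }
  transmit <- function(par) {
    g <- par$h1 + par$h2
    t_all <- matrix(0L, n_trios, s)
    t_all[g == 2L] <- 1L
    het <- g == 1L
    if (any(het)) {
      taum <- matrix(tau, n_trios, s, byrow = TRUE)
      t_all[het] <- as.integer(runif(sum(het)) < taum[het])
    }
    t_all
  }
  fa <- draw_parent(); mo <- draw_parent()
  tf <- transmit(fa); tm <- transmit(mo)
  structure(list(father = fa$h1 + fa$h2, mother = mo$h1 + mo$h2,
                 child = tf + tm,
                 transmitted_father = tf, transmitted_mother = tm,
                 tau = tau),
            class = "trio_set")
}
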