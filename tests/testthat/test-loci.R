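test_that("LD equals hand-computed squared correlation on a 6-subject toy", {
  G <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 2, 0, 2),
             c = c(2, 2, 2, 2, 2, 2))
  panel <- as_panel(G)
  expect_equal(ld_r2(panel, "a", "a"), 1)
  # longhand Pearson correlation
  x <- G[, "a"]; y <- G[, "b"]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ld_r2(panel, "a", "b"), r_hand^2)
  expect_error(ld_r2(panel, "a", "c"), "constant")
})

test_that("independent SNPs show near-zero LD", {
  set.seed(61)
  n <- 1000L
  G <- matrix(rbinom(n * 200L, 2L, 0.4), n,
              dimnames = list(NULL, sprintf("s%03d", 1:200)))
  panel <- as_panel(G)
  r2s <- vapply(1:100, function(k) ld_r2(panel, 2 * k - 1L, 2 * k),
                numeric(1L))
  expect_lt(mean(r2s), 0.01)
})

test_that("single and nearby significant SNPs clump as specified", {
  cfg <- clump_config()
  n <- 60L
  set.seed(62)
  G <- matrix(rbinom(n * 3L, 2L, 0.4), n,
              dimnames = list(NULL, c("s1", "s2", "s3")))
  panel <- as_panel(G, chrom = c(1L, 1L, 1L),
                    bp = c(1000000L, 1100000L, 9000000L))
  # one SNP below study-wide -> kept as singleton
  s1 <- data.frame(snp_id = "s1", chrom = 1L, bp = 1000000L, p = 1e-10)
  out <- clump(s1, panel, cfg)
  expect_length(out, 1L)
  expect_equal(out[[1L]]$lead_snp, "s1")
  # genome-wide but not study-wide singleton -> removed
  s1b <- s1; s1b$p <- 1e-8
  out_b <- clump(s1b, panel, cfg)
  expect_length(out_b, 0L)
  expect_equal(attr(out_b, "removed_singletons"), "s1")
  # two SNPs 100 kb apart always share a locus, led by the smaller p
  s2 <- data.frame(snp_id = c("s1", "s2"), chrom = 1L,
                   bp = c(1000000L, 1100000L), p = c(1e-9, 1e-12))
  out2 <- clump(s2, panel, cfg)
  expect_length(out2, 1L)
  expect_equal(out2[[1L]]$lead_snp, "s2")
  expect_setequal(out2[[1L]]$members, c("s1", "s2"))
})

test_that("two LD-linked clusters 5 Mb apart merge and a weak singleton drops", {
  cfg <- clump_config()
  n <- 500L
  set.seed(63)
  base <- rbinom(n, 2L, 0.5)
  flip <- function(g, rate) {
    i <- runif(n) < rate
    g[i] <- rbinom(sum(i), 2L, 0.5)
    g
  }
  G <- cbind(c1a = base, c1b = flip(base, 0.1),
             c2a = flip(base, 0.2), c2b = flip(base, 0.25),
             iso = rbinom(n, 2L, 0.5))
  panel <- as_panel(G, chrom = rep(1L, 5L),
                    bp = c(1000000L, 1050000L, 6000000L, 6040000L, 40000000L))
  stopifnot(ld_r2(panel, "c1a", "c2a") > 0.5)     # cross-cluster LD planted
  summ <- data.frame(snp_id = colnames(G), chrom = 1L,
                     bp = panel$variants$bp,
                     p = c(1e-12, 1e-10, 1e-11, 1e-9, 2e-8))
  out <- clump(summ, panel, cfg)
  expect_length(out, 1L)                          # clusters merged
  expect_equal(out[[1L]]$lead_snp, "c1a")
  expect_setequal(out[[1L]]$members, c("c1a", "c1b", "c2a", "c2b"))
  expect_equal(attr(out, "removed_singletons"), "iso")
})

test_that("clumping equals exhaustive rule application on random instances", {
  cfg <- clump_config()
  for (s in 1:100) {
    inst <- random_clump_instance(700 + s)
    got <- clump(inst$summary, as_panel(inst$G, chrom = inst$summary$chrom,
                                        bp = inst$summary$bp), cfg)
    want <- oracle_clump(inst$summary, inst$G, cfg)
    expect_equal(length(got), length(want), info = paste("instance", s))
    got_sets <- lapply(got, function(l) paste(sort(l$members), collapse = ","))
    want_sets <- lapply(want, function(l) paste(l$members, collapse = ","))
    expect_setequal(got_sets, want_sets)
    got_leads <- sort(vapply(got, `[[`, character(1L), "lead_snp"))
    want_leads <- sort(vapply(want, `[[`, character(1L), "lead"))
    expect_identical(got_leads, want_leads)
  }
})

test_that("clumping output partitions the significant set and is a fixpoint", {
  cfg <- clump_config()
  inst <- random_clump_instance(999)
  panel <- as_panel(inst$G, chrom = inst$summary$chrom, bp = inst$summary$bp)
  out <- clump(inst$summary, panel, cfg)
  members <- unlist(lapply(out, `[[`, "members"))
  expect_false(any(duplicated(members)))          # uniqueness across loci
  # rerunning on the clumped member set reproduces the same loci (fixpoint)
  summ2 <- data.frame(
    snp_id = members,
    chrom = unlist(lapply(out, function(l) rep(l$chrom, length(l$members)))),
    bp = inst$summary$bp[match(members, inst$summary$snp_id)],
    p = unlist(lapply(out, `[[`, "member_p")))
  out2 <- clump(summ2, panel, cfg)
  expect_identical(
    sort(vapply(out2, `[[`, character(1L), "lead_snp")),
    sort(vapply(out, `[[`, character(1L), "lead_snp")))
  expect_setequal(lapply(out2, function(l) sort(l$members)),
                  lapply(out, function(l) sort(l$members)))
})

test_that("cross-GWAS lead pairing follows greedy nearest assignment", {
  la <- data.frame(snp_id = c("a1", "a2", "a3"), chrom = c(1L, 1L, 2L),
                   bp = c(1000000L, 5000000L, 700000L))
  lb <- data.frame(snp_id = c("b1", "b2"), chrom = c(1L, 2L),
                   bp = c(1100000L, 680000L))
  out <- cross_gwas_overlap(la, lb)
  expect_equal(nrow(out$pairs), 2L)
  expect_setequal(paste(out$pairs$snp_a, out$pairs$snp_b),
                  c("a1 b1", "a3 b2"))
  expect_equal(out$unique_a$snp_id, "a2")
  # identical lists pair at distance zero
  self <- cross_gwas_overlap(la, la)
  expect_true(all(self$pairs$distance_bp == 0))
  expect_equal(nrow(self$unique_a), 0L)
  # 300 kb apart stays unpaired
  far <- cross_gwas_overlap(
    data.frame(snp_id = "x", chrom = 1L, bp = 1000000L),
    data.frame(snp_id = "y", chrom = 1L, bp = 1300000L))
  expect_equal(nrow(far$pairs), 0L)
})

test_that("locus labels follow the two published schemes", {
  h <- structure(list(
    segments = as.list(1:15), level = floor(log2(1:15)) + 1L,
    n_levels = 4L, content_label = rep(NA_character_, 15L)),
    class = "segment_hierarchy")
  # segment contents: 1-3 mixed, 4 parietal-side parent, 5 frontal, 8 parietal
  labs <- c("both", "both", "both", "both", "frontal", "both", "parietal",
            "parietal", "parietal", "frontal", "frontal", "frontal",
            "both", "parietal", "parietal")
  h <- set_segment_labels(h, labs)
  # profile in the style of rs17479393: best in segment 1, strongest children
  # trace 1 -> 2 -> 4 -> 8 (solely parietal)
  p1 <- rep(NA_real_, 15L)
  p1[c(1, 2, 3, 7, 8, 15)] <- c(1e-12, 1e-10, 1e-8, 1e-8, 1e-9, 1e-8)
  p1[4] <- 3e-10; p1[5] <- 1e-6; p1[9] <- 1e-7
  expect_equal(label_locus(p1, h, "most_significant"), "both")
  expect_equal(label_locus(p1, h, "most_specific"), "parietal")
  # rs11609649 style: best in frontal segment 5 -> frontal under both schemes
  p2 <- rep(NA_real_, 15L)
  p2[c(1, 2, 5)] <- c(1e-8, 1e-9, 1e-13)
  expect_equal(label_locus(p2, h, "most_significant"), "frontal")
  expect_equal(label_locus(p2, h, "most_specific"), "frontal")
  # labels invariant to monotone transforms of the profile
  p3 <- p1^0.5
  expect_equal(label_locus(p3, h, "most_specific"),
               label_locus(p1, h, "most_specific"))
})

test_that("hotspot maps are unit-normalized and localize a planted bump", {
  tpl <- vault_template(12L, 6L)
  m <- nrow(tpl$vertices)
  set.seed(64)
  center <- 30L
  bump <- matrix(bump_direction(tpl, center, width = 0.1), m, 3L,
                 byrow = TRUE)
  diffuse <- replicate(20, {
    f <- matrix(rnorm(m * 3L, 0, 0.05), m)
    f
  }, simplify = FALSE)
  out <- hotspots(c(list(bump), diffuse), tpl$vertices, tpl)
  expect_equal(colSums(out$per_snp^2), rep(1, 21L), tolerance = 1e-12,
               ignore_attr = TRUE)
  d <- sqrt(rowSums((tpl$vertices -
                       matrix(tpl$vertices[center, ], m, 3L, byrow = TRUE))^2))
  expect_lt(d[which.max(out$map)], quantile(d, 0.15))
  # single-field map equals that field's normalized magnitudes
  one <- hotspots(list(bump), tpl$vertices, tpl)
  expect_equal(one$map, one$per_snp[, 1L], ignore_attr = TRUE)
})
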