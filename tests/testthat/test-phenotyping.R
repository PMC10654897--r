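test_that("a grossly displaced subject is flagged by the Mahalanobis QC", {
  tpl <- tiny_template()
  pb <- background_basis(tpl, q_smooth = 4L, seed = 1L)
  plan <- shape_effect_plan(tpl, pop_basis = pb, noise_sd = 0.2)
  coh <- simulate_shapes(NULL, NULL, plan, n_subjects = 40L, seed = 2L)
  coh$coords[7L, , ] <- coh$coords[7L, , ] + 50  # ~10+ SD displacement
  keep <- qc_outliers(coh)
  expect_length(keep, 40L)
  expect_false(keep[7L])
  expect_gt(mean(keep), 0.5)
})

test_that("constant distances give zero z-scores and keep everyone", {
  # two symmetric clusters: every subject equidistant from the mean
  X <- rbind(matrix(1, 5, 6), matrix(-1, 5, 6))
  keep <- qc_outliers(X)
  expect_true(all(keep))
})

test_that("PLSR adjustment removes exact linear covariate effects", {
  set.seed(31)
  n <- 60L
  covs <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5), size = rnorm(n))
  B <- matrix(rnorm(3 * 12), 3, 12)
  Y <- covs %*% B
  res <- adjust_covariates_plsr(Y, covs)
  expect_lt(max(abs(res)), 1e-8 * max(abs(Y)))
})

test_that("PLSR residuals are orthogonal to the covariates", {
  set.seed(32)
  n <- 80L
  covs <- cbind(age = rnorm(n), wt = rnorm(n))
  Y <- matrix(rnorm(n * 9), n) + covs[, 1] %*% t(rnorm(9))
  res <- adjust_covariates_plsr(Y, covs)
  expect_lt(max(abs(cor(res, covs[, 1]))), 1e-6)
  expect_lt(max(abs(colMeans(res))), 1e-10)
})

test_that("PLSR with covariates orthogonal to the response just centers", {
  set.seed(33)
  n <- 50L
  Y <- matrix(rnorm(n * 5), n)
  covs <- matrix(rnorm(n * 2), n)
  # force exact orthogonality covariate-by-response
  covs <- covs - qr.fitted(qr(cbind(1, Y)), covs)
  res <- adjust_covariates_plsr(Y, covs)
  expect_equal(res, scale(Y, scale = FALSE), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PLSR residuals agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(35)
  n <- 60L
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("C", 1:4)))
  Y <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("Y", 1:6)))
  Y <- Y + X[, 1] %*% t(rnorm(6)) + X[, 3] %*% t(rnorm(6))
  fit <- mixOmics::pls(X, Y, ncomp = 4L, mode = "regression", scale = FALSE)
  pred <- predict(fit, X)$predict[, , 4L]
  expect_equal(adjust_covariates_plsr(Y, X), unname(Y - pred),
               tolerance = 1e-8)
})

test_that("constant covariate columns are dropped with a warning", {
  set.seed(34)
  Y <- matrix(rnorm(40 * 4), 40)
  covs <- cbind(rnorm(40), rep(2, 40))
  expect_warning(adjust_covariates_plsr(Y, covs), "constant")
})

test_that("similarity matrix matches a hand computation on a 4-vertex toy", {
  # 3 subjects, 4 vertices; work out both terms longhand
  coords <- array(0, c(3L, 4L, 3L))
  coords[1, , ] <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  coords[2, , ] <- rbind(c(0, 0, 1), c(3, 0, 0), c(0, 2, 0), c(2, 2, 0))
  coords[3, , ] <- rbind(c(0, 0, 2), c(4, 0, 0), c(0, 3, 0), c(2, 2, 1))
  mean_shape <- apply(coords, c(2, 3), mean)
  # distance-to-centroid series, then Pearson correlations, by hand
  dc <- matrix(0, 3, 4)
  for (i in 1:3) {
    ctr <- colMeans(coords[i, , ])
    for (v in 1:4) dc[i, v] <- sqrt(sum((coords[i, v, ] - ctr)^2))
  }
  C <- cor(dc)
  D <- as.matrix(dist(mean_shape))
  off <- upper.tri(C)
  mm <- function(M) (M - min(M[off])) / (max(M[off]) - min(M[off]))
  expected <- 0.6 * mm(C) + 0.4 * mm(-D)
  diag(expected) <- 1
  X <- vaultgwas:::flatten_coords(coords)
  S <- build_similarity(X, mean_shape)
  expect_equal(S, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # degenerate weights reduce to the single normalized component
  S_corr <- build_similarity(X, mean_shape, w_corr = 1, w_prox = 0)
  e1 <- mm(C); diag(e1) <- 1
  expect_equal(S_corr, e1, tolerance = 1e-12, ignore_attr = TRUE)
  S_prox <- build_similarity(X, mean_shape, w_corr = 0, w_prox = 1)
  e2 <- mm(-D); diag(e2) <- 1
  expect_equal(S_prox, e2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("similarity output is within [0,1], symmetric, and reproducible", {
  tpl <- tiny_template()
  pb <- background_basis(tpl, q_smooth = 3L, seed = 6L)
  plan <- shape_effect_plan(tpl, pop_basis = pb, noise_sd = 0.3)
  coh <- simulate_shapes(NULL, NULL, plan, n_subjects = 25L, seed = 7L)
  ms <- apply(coh$coords, c(2, 3), mean)
  S1 <- build_similarity(coh, ms)
  S2 <- build_similarity(coh, ms)
  expect_identical(S1, S2)
  expect_true(all(S1 >= 0 & S1 <= 1))
  expect_equal(S1, t(S1))
  expect_true(all(diag(S1) == 1))
})

test_that("four hierarchy levels yield 15 segments partitioning each level", {
  tpl <- vault_template(8L, 8L)
  pb <- background_basis(tpl, q_smooth = 4L, seed = 8L)
  plan <- shape_effect_plan(tpl, pop_basis = pb, noise_sd = 0.4)
  coh <- simulate_shapes(NULL, NULL, plan, n_subjects = 30L, seed = 9L)
  S <- build_similarity(coh, apply(coh$coords, c(2, 3), mean))
  h <- hierarchical_segment(S, 4L)
  expect_length(h$segments, 15L)
  expect_equal(as.vector(table(h$level)), c(1L, 2L, 4L, 8L))
  m <- nrow(S)
  for (lv in 1:4) {
    verts <- sort(unname(unlist(h$segments[h$level == lv])))
    expect_identical(verts, 1:m)           # partition at every level
  }
  for (id in 1:7)                           # children partition the parent
    expect_identical(sort(c(h$segments[[2 * id]], h$segments[[2 * id + 1]])),
                     sort(h$segments[[id]]))
})

test_that("block-structured similarity is recovered exactly", {
  # two disconnected blocks split at level 2
  S2 <- matrix(0.02, 10, 10)
  S2[1:5, 1:5] <- 0.9; S2[6:10, 6:10] <- 0.9
  diag(S2) <- 1
  h2 <- hierarchical_segment(S2, 2L)
  got <- lapply(h2$segments[2:3], sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  list("1,2,3,4,5", "6,7,8,9,10"))
  # 8 planted blocks with a 3-tier hierarchical structure recovered at level 4
  blocks <- split(1:32, rep(1:8, each = 4))
  S8 <- matrix(0.02, 32, 32)
  for (half in list(1:16, 17:32)) S8[half, half] <- 0.10
  for (q in list(1:8, 9:16, 17:24, 25:32)) S8[q, q] <- 0.30
  for (b in blocks) S8[b, b] <- 0.95
  diag(S8) <- 1
  h8 <- hierarchical_segment(S8, 4L)
  level4 <- lapply(h8$segments[h8$level == 4L], function(v)
    paste(sort(v), collapse = ","))
  expect_setequal(level4, lapply(blocks, paste, collapse = ","))
})

test_that("segments too small to split raise an informative error", {
  S <- diag(3)
  expect_error(hierarchical_segment(S, 4L), "fewer levels")
})

test_that("parallel analysis keeps few components for isotropic noise", {
  for (s in c(1L, 2L)) {
    set.seed(100 + s)
    X <- matrix(rnorm(60 * 10), 60)
    expect_lte(parallel_analysis(X, n_reps = 200L, seed = s), 2L)
  }
})

test_that("parallel analysis recovers three strong planted factors", {
  set.seed(41)
  n <- 100L; p <- 20L
  L <- qr.Q(qr(matrix(rnorm(p * 3), p)))[, 1:3]
  X <- matrix(rnorm(n * 3), n) %*% t(L) * sqrt(10) + matrix(rnorm(n * p), n)
  expect_equal(parallel_analysis(X, n_reps = 200L, seed = 1L), 3L)
})

test_that("parallel analysis respects the rank bound", {
  set.seed(42)
  X <- matrix(rnorm(5 * 40), 5)
  expect_lte(parallel_analysis(X, n_reps = 100L, seed = 1L), 4L)
  expect_error(parallel_analysis(X, n_reps = 50L), "at least 100")
})

test_that("a variation-free segment yields zero scores", {
  tpl <- tiny_template()
  coords <- array(0, c(5L, nrow(tpl$vertices), 3L))
  for (i in 1:5) coords[i, , ] <- tpl$vertices
  coh <- mesh_cohort(coords, tpl)
  sp <- build_shape_space(coh, 1:8, pa_reps = 100L)
  expect_true(all(sp$scores == 0))
})

test_that("shape-space identities: score variance and reconstruction error", {
  tpl <- tiny_template()
  pb <- background_basis(tpl, q_smooth = 4L, seed = 10L)
  plan <- shape_effect_plan(tpl, pop_basis = pb, noise_sd = 0.3)
  coh <- simulate_shapes(NULL, NULL, plan, n_subjects = 40L, seed = 11L)
  sp <- build_shape_space(coh, 1:16, pa_reps = 100L)
  expect_equal(apply(sp$scores, 2L, var), sp$eigenvalues[seq_len(sp$K)],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(crossprod(sp$basis), diag(sp$K), tolerance = 1e-10,
               ignore_attr = TRUE)
  flat <- vaultgwas:::flatten_coords(sp$aligned)
  Xc <- sweep(flat, 2L, sp$center)
  resid <- Xc - sp$scores %*% t(sp$basis)
  expect_equal(sum(resid^2) / (sp$n - 1),
               sum(sp$eigenvalues[-seq_len(sp$K)]), tolerance = 1e-10)
})
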