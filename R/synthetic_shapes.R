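# Simulation of vault-like shape cohorts with planted genetic, ancestry,
# and covariate effects on top of a smooth background shape space.

#' Smooth random orthonormal shape basis
#'
#' Draws `q` random per-vertex displacement fields, smooths each with a
#' Gaussian kernel over inter-vertex distances on the template (so background
#' variation is spatially coherent, as real anatomical variation is), and
#' orthonormalizes them. Used as the latent background basis of an effect
#' plan.
#'
#' @param template a [vault_template].
#' @param q number of basis fields.
#' @param bandwidth kernel bandwidth as a fraction of the template's maximum
#'   inter-vertex distance (default 0.25).
#' @param seed RNG seed.
#' @return q x 3m matrix with orthonormal rows (vertex-major x,y,z layout).
#' @export
random_shape_basis <- function(template, q, bandwidth = 0.25, seed = 1L) {
  set.seed(seed)
  V <- template$vertices
  m <- nrow(V)
  D <- as.matrix(stats::dist(V))
  Kmat <- exp(-(D / (bandwidth * max(D)))^2)
  raw <- matrix(rnorm(q * 3L * m), nrow = 3L * m)
  for (d in 0:2) {
    rows <- seq(1L + d, 3L * m, by = 3L)
    raw[rows, ] <- Kmat %*% raw[rows, ]
  }
  qr_d <- qr(raw)
  t(qr.Q(qr_d)[, seq_len(q), drop = FALSE])
}

#' Localized bump displacement direction
#'
#' Unit-norm vertex displacement field pointing along the outward normals,
#' with Gaussian magnitude centered on one vertex -- a localized regional
#' deformation used to plant segment-specific genetic effects. By default
#' the field is projected orthogonal to the template's seven similarity
#' modes (three translations, three infinitesimal rotations, uniform
#' scaling): Procrustes alignment removes exactly those modes, so only
#' their complement is a genuine *shape* deformation that survives GPA.
#'
#' @param template a [vault_template].
#' @param center_vertex index of the bump center.
#' @param width bump width as a fraction of the maximum inter-vertex
#'   distance (default 0.3).
#' @param remove_similarity project out translation/rotation/scaling
#'   components (default `TRUE`).
#' @return length-3m unit vector (vertex-major layout).
#' @export
bump_direction <- function(template, center_vertex, width = 0.3,
                           remove_similarity = TRUE) {
  V <- template$vertices
  m <- nrow(V)
  nrm <- vertex_normals(V, template$faces)
  d <- sqrt(rowSums((V - matrix(V[center_vertex, ], m, 3L, byrow = TRUE))^2))
  w <- exp(-(d / (width * max(d)))^2)
  v <- as.vector(t(nrm * w))
  if (remove_similarity) {
    Vc <- scale(V, scale = FALSE)
    sim_modes <- cbind(
      as.vector(t(cbind(1, 0, 0)[rep(1L, m), ])),   # translations
      as.vector(t(cbind(0, 1, 0)[rep(1L, m), ])),
      as.vector(t(cbind(0, 0, 1)[rep(1L, m), ])),
      as.vector(t(Vc)),                             # uniform scaling
      as.vector(t(cbind(0, -Vc[, 3], Vc[, 2]))),    # rotations about x,y,z
      as.vector(t(cbind(Vc[, 3], 0, -Vc[, 1]))),
      as.vector(t(cbind(-Vc[, 2], Vc[, 1], 0))))
    v <- v - qr.fitted(qr(sim_modes), v)
  }
  v / sqrt(sum(v^2))
}

#' Background shape basis including the causal latent directions
#'
#' Builds the latent background basis of an effect plan from `q_smooth`
#' smooth random modes with a decaying SD spectrum, plus the supplied causal
#' directions as additional modes with a modest SD. Including each causal
#' direction among the segregating background modes reflects that genetic
#' effects act along directions of standing anatomical variation, and keeps
#' the latent trait inside the PC space retained by parallel analysis. The
#' smooth modes are orthonormalized against the causal directions, which are
#' kept exactly.
#'
#' @param template a [vault_template].
#' @param causal_directions list (or matrix rows) of unit-norm 3m vectors.
#' @param q_smooth number of smooth background modes (default 5).
#' @param sd_smooth their SDs in mm (default a 1.2 to 0.4 decay, the
#'   dominant anatomical modes a few-fold above the 0.5 mm vertex noise).
#' @param sd_causal background SD along each causal direction (default
#'   0.55 mm: enough standing variation for the latent trait to be retained
#'   by parallel analysis, while leaving the dose effect detectable).
#' @param bandwidth,seed passed to [random_shape_basis()].
#' @return list with `directions` and `sd`, suitable as `pop_basis`.
#' @export
background_basis <- function(template, causal_directions = NULL,
                             q_smooth = 5L,
                             sd_smooth = seq(1.2, 0.4,
                                             length.out = q_smooth),
                             sd_causal = 0.55, bandwidth = 0.25, seed = 1L) {
  Braw <- random_shape_basis(template, q_smooth, bandwidth = bandwidth,
                             seed = seed)
  if (is.null(causal_directions))
    return(list(directions = Braw, sd = sd_smooth))
  Cd <- if (is.list(causal_directions)) do.call(rbind, causal_directions)
        else as.matrix(causal_directions)
  qd <- qr(t(rbind(Cd, Braw)))
  Q <- t(qr.Q(qd)[, seq_len(nrow(Cd) + q_smooth), drop = FALSE])
  # first rows of Q span the causal directions exactly (up to sign); use the
  # causal vectors themselves there and the orthonormalized smooth remainder
  list(directions = rbind(Cd, Q[-seq_len(nrow(Cd)), , drop = FALSE]),
       sd = c(rep(sd_causal, nrow(Cd)), sd_smooth))
}

#' Plan of planted effects for a simulated shape cohort
#'
#' @param template a [vault_template]; its `mirror_map` must be an involution.
#' @param pop_basis background variation: list with `directions` (q x 3m,
#'   orthonormal rows) and `sd` (length q, mm). `NULL` for none.
#' @param causal_effects list of effects, each a list with `snp` (column
#'   index into the genotype panel), `beta` (mm displacement per dosage
#'   unit), `direction` (length-3m unit vector), and optional `segment` tag.
#' @param ancestry_shift optional list with `window` (local-ancestry window
#'   index) and `directions` (3 x 3m matrix, per-ancestry mean displacement,
#'   rows EUR/AFR/AMR); the shift enters scaled by ancestry dosage / 2.
#' @param covariate_effects optional n_cov x 3m loading matrix.
#' @param noise_sd isotropic per-coordinate Gaussian noise SD in mm
#'   (default 0.5).
#' @return list of class `shape_effect_plan`.
#' @export
shape_effect_plan <- function(template, pop_basis = NULL,
                              causal_effects = list(),
                              ancestry_shift = NULL,
                              covariate_effects = NULL,
                              noise_sd = 0.5) {
  m <- nrow(template$vertices)
  mm <- template$mirror_map
  if (!all(mm[mm] == seq_len(m)))
    stop("template mirror_map must be an involution")
  for (eff in causal_effects) {
    if (length(eff$direction) != 3L * m)
      stop("causal effect direction has wrong length")
    if (abs(sqrt(sum(eff$direction^2)) - 1) > 1e-8)
      stop("causal effect directions must be unit-norm")
  }
  if (!is.null(pop_basis)) {
    stopifnot(ncol(pop_basis$directions) == 3L * m,
              length(pop_basis$sd) == nrow(pop_basis$directions))
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(template = template, pop_basis = pop_basis,
                 causal_effects = causal_effects,
                 ancestry_shift = ancestry_shift,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd),
            class = "shape_effect_plan")
}

#' Label hierarchy segments as frontal/parietal by template geometry
#'
#' On the simulated vault template the anterior half (`y > 0`) stands in for
#' frontal bone content and the posterior half for parietal content. A
#' segment is labeled `"frontal"` if at least `threshold` of its vertices
#' are anterior, `"parietal"` if at most `1 - threshold` are, and `"both"`
#' otherwise.
#'
#' @param hierarchy a `segment_hierarchy`.
#' @param template the [vault_template] the hierarchy was built on.
#' @param threshold majority fraction (default 0.7).
#' @return The hierarchy with `content_label` set.
#' @export
label_segments_by_y <- function(hierarchy, template, threshold = 0.7) {
  anterior <- template$vertices[, 2] > 0
  labs <- vapply(hierarchy$segments, function(vs) {
    f <- mean(anterior[vs])
    if (f >= threshold) "frontal"
    else if (f <= 1 - threshold) "parietal"
    else "both"
  }, character(1L))
  set_segment_labels(hierarchy, unname(labs))
}

#' Simulate a shape cohort with planted effects
#'
#' Each subject's shape is the template plus (i) background variation drawn
#' on the plan's latent basis, (ii) `beta * dosage * direction` for every
#' planted causal SNP, (iii) an optional per-ancestry mean shift scaled by
#' the subject's local ancestry dosage at the designated window, (iv)
#' covariate effects, and (v) isotropic Gaussian vertex noise.
#'
#' @param panel a `genotype_panel` (only needed if causal effects are
#'   planted; may be `NULL` otherwise).
#' @param ancestry_panel a `local_ancestry_panel` (only needed for ancestry
#'   shifts; may be `NULL`).
#' @param effect_plan a [shape_effect_plan].
#' @param covariates optional numeric matrix (n_subjects x n_cov) entering
#'   through the plan's covariate loadings.
#' @param seed RNG seed.
#' @param n_subjects required when no panel is given.
#' @return A [mesh_cohort] whose `"truth"` attribute records every planted
#'   term (background scores, per-effect dosages, shifts, noise SD).
#' @export
simulate_shapes <- function(panel, ancestry_panel, effect_plan,
                            covariates = NULL, seed = 1L,
                            n_subjects = NULL) {
  stopifnot(inherits(effect_plan, "shape_effect_plan"))
  tpl <- effect_plan$template
  m <- nrow(tpl$vertices)
  if (is.null(n_subjects)) {
    if (is.null(panel)) stop("supply n_subjects when panel is NULL")
    n_subjects <- nrow(panel$dosage)
  }
  set.seed(seed)
  base <- as.vector(t(tpl$vertices))
  X <- matrix(base, n_subjects, 3L * m, byrow = TRUE)
  truth <- list(noise_sd = effect_plan$noise_sd)
  if (!is.null(effect_plan$pop_basis)) {
    q <- nrow(effect_plan$pop_basis$directions)
    z <- matrix(rnorm(n_subjects * q), n_subjects, q)
    z <- sweep(z, 2L, effect_plan$pop_basis$sd, `*`)
    X <- X + z %*% effect_plan$pop_basis$directions
    truth$background_scores <- z
  }
  for (eff in effect_plan$causal_effects) {
    if (eff$snp > ncol(panel$dosage)) stop("causal SNP index out of range")
    g <- panel$dosage[, eff$snp]
    X <- X + (eff$beta * g) %*% t(eff$direction)
    truth$causal <- c(truth$causal, list(c(eff, list(dosage = g))))
  }
  if (!is.null(effect_plan$ancestry_shift)) {
    as_ <- effect_plan$ancestry_shift
    dos <- ancestry_panel$dosage_by_window[, as_$window, , drop = TRUE]
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = n_subjects)
    X <- X + (dos / 2) %*% as_$directions
    truth$ancestry_shift <- as_
  }
  if (!is.null(effect_plan$covariate_effects)) {
    if (is.null(covariates)) stop("plan has covariate effects but no covariates given")
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n_subjects) stop("covariates length mismatch")
    if (ncol(covariates) != nrow(effect_plan$covariate_effects))
      stop("covariate loading dimension mismatch")
    X <- X + covariates %*% effect_plan$covariate_effects
    truth$covariate_effects <- effect_plan$covariate_effects
  }
  if (effect_plan$noise_sd > 0)
    X <- X + matrix(rnorm(length(X), 0, effect_plan$noise_sd), nrow(X))
  cohort <- mesh_cohort(unflatten_coords(X, m), tpl)
  attr(cohort, "truth") <- truth
  cohort
}
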