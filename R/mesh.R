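#' Build a vault-like dome template mesh
#'
#' Constructs a triangulated ellipsoidal dome standing in for a registered
#' cranial vault template: `n_theta` latitude rings of `n_phi` vertices each
#' on the upper part of an ellipsoid (longer front-to-back than side-to-side,
#' as a vault is). The mesh is bilaterally symmetric about the midsagittal
#' plane `x = 0`, and `mirror_map` pairs each vertex with its mirror image so
#' that shapes on this topology can be symmetrized.
#'
#' @param n_phi vertices per latitude ring (must be even so that the ring is
#'   closed under reflection); default 16.
#' @param n_theta number of rings between the apex and the dome rim; default 16.
#' @param radius lateral semi-axis in mm (default 70, a plausible half head
#'   breadth at the parietal eminence).
#' @param theta_max polar angle of the dome rim in radians (default `0.45*pi`,
#'   a dome reaching down to roughly the supraorbital/occipital margin).
#' @return A list of class `vault_template` with `vertices` (m x 3 matrix),
#'   `faces` (f x 3 integer matrix, 1-based, counter-clockwise seen from
#'   outside), and `mirror_map` (integer involution of length m).
#' @examples
#' tpl <- vault_template(8, 4)
#' nrow(tpl$vertices)  # 32
#' all(tpl$mirror_map[tpl$mirror_map] == seq_len(32))
#' @export
vault_template <- function(n_phi = 16L, n_theta = 16L, radius = 70,
                           theta_max = 0.45 * pi) {
  n_phi <- .check_count(n_phi, "n_phi", 4L)
  n_theta <- .check_count(n_theta, "n_theta", 2L)
  if (n_phi %% 2L != 0L) stop("'n_phi' must be even for mirror symmetry")
  theta <- seq_len(n_theta) * theta_max / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  grid <- expand.grid(phi = phi, theta = theta)  # phi fastest within ring
  # mildly anisotropic ellipsoid: anteroposterior (y) longest, height (z)
  # slightly flattened
  vertices <- cbind(
    x = radius * sin(grid$theta) * cos(grid$phi),
    y = 1.25 * radius * sin(grid$theta) * sin(grid$phi),
    z = 0.90 * radius * cos(grid$theta))
  # mirror x -> -x maps phi -> pi - phi; with half-offset grid this permutes
  # ring indices j -> n_phi/2 + 1 - j (mod n_phi)
  j <- seq_len(n_phi)
  ring_mirror <- ((n_phi %/% 2L + 1L - j - 1L) %% n_phi) + 1L
  mirror_map <- as.integer(rep((seq_len(n_theta) - 1L) * n_phi,
                               each = n_phi) + ring_mirror)
  faces <- matrix(0L, nrow = 2L * (n_theta - 1L) * n_phi, ncol = 3L)
  k <- 0L
  for (i in seq_len(n_theta - 1L)) {
    a <- (i - 1L) * n_phi + j          # ring i
    b <- (i - 1L) * n_phi + (j %% n_phi) + 1L
    c_ <- i * n_phi + j                # ring i + 1
    d <- i * n_phi + (j %% n_phi) + 1L
    faces[k + j, ] <- cbind(a, c_, b)
    faces[k + n_phi + j, ] <- cbind(b, c_, d)
    k <- k + 2L * n_phi
  }
  structure(list(vertices = vertices, faces = faces, mirror_map = mirror_map),
            class = "vault_template")
}

#' Per-vertex outward normals of a triangle mesh
#'
#' Area-weighted average of incident face normals, normalized to unit length.
#' Degenerate (zero-area) faces contribute nothing; a vertex whose incident
#' faces are all degenerate falls back to the average normal of its ring
#' neighbours, with a warning.
#'
#' @param vertices m x 3 coordinate matrix.
#' @param faces f x 3 integer matrix of 1-based vertex indices.
#' @return m x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces) {
  m <- nrow(vertices)
  e1 <- vertices[faces[, 2], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  e2 <- vertices[faces[, 3], , drop = FALSE] - vertices[faces[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])  # length = 2 * area
  vn <- matrix(0, m, 3L)
  for (c_ in 1:3) {
    rs <- rowsum(fn, group = faces[, c_], reorder = FALSE)
    at <- as.integer(rownames(rs))
    vn[at, ] <- vn[at, ] + rs
  }
  nrm <- sqrt(rowSums(vn^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    warning(sum(bad), " vertex normals degenerate; using neighbourhood average")
    adj <- lapply(seq_len(m), function(i) {
      r <- faces[rowSums(faces == i) > 0, , drop = FALSE]
      setdiff(unique(as.vector(r)), i)
    })
    for (i in which(bad)) {
      nb <- adj[[i]]
      v <- colSums(vn[nb, , drop = FALSE])
      if (sqrt(sum(v^2)) < 1e-12) v <- c(0, 0, 1)
      vn[i, ] <- v
    }
    nrm <- sqrt(rowSums(vn^2))
  }
  vn / nrm
}

#' Assemble a mesh cohort
#'
#' Bundles per-subject vertex coordinates (all on the shared template
#' topology) with the template itself.
#'
#' @param coords n_subjects x n_vertices x 3 array.
#' @param template a [vault_template] (or any list with `vertices`, `faces`,
#'   `mirror_map`).
#' @param subject_ids optional character vector.
#' @return An object of class `mesh_cohort`.
#' @export
mesh_cohort <- function(coords, template, subject_ids = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (anyNA(coords)) stop("coords must not contain NA")
  if (dim(coords)[2] != nrow(template$vertices))
    stop("coords vertex count does not match template")
  n <- dim(coords)[1]
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(n))
  if (length(subject_ids) != n) stop("subject_ids length mismatch")
  structure(list(coords = coords, template = template,
                 subject_ids = subject_ids),
            class = "mesh_cohort")
}

#' @export
print.mesh_cohort <- function(x, ...) {
  cat(sprintf("mesh_cohort: %d subjects x %d vertices\n",
              dim(x$coords)[1], dim(x$coords)[2]))
  invisible(x)
}

#' Symmetrize shapes across the midsagittal plane
#'
#' Replaces each shape by the average of itself and its reflection: mirror
#' the coordinates across the template plane `x = 0` and relabel vertices by
#' the template `mirror_map`. The result is bilaterally symmetric and the
#' operation is idempotent.
#'
#' @param cohort a [mesh_cohort].
#' @return A `mesh_cohort` of symmetrized shapes.
#' @export
symmetrize <- function(cohort) {
  mm <- cohort$template$mirror_map
  m <- dim(cohort$coords)[2]
  if (is.null(mm) || !all(mm[mm] == seq_len(m)))
    stop("template mirror_map must be an involution on the vertex set")
  refl <- cohort$coords[, mm, , drop = FALSE]
  refl[, , 1] <- -refl[, , 1]
  out <- cohort
  out$coords <- (cohort$coords + refl) / 2
  out
}
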