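# Generalized Procrustes analysis.
#
# No multi-configuration Procrustes routine ships with the installed stack
# (vegan::procrustes superimposes exactly two configurations), so the
# classical iterative algorithm is implemented here: center, optionally scale
# to unit centroid size, rotate each configuration onto the current mean by
# the orthogonal (rotation-only) Procrustes solution, update the mean, and
# repeat until the mean stabilizes.

# Optimal rotation of Y onto M (both centered): R = U V' from svd(Y'M),
# constrained to det(R) = +1 (proper rotation, no reflection).
.procrustes_rotation <- function(Y, M) {
  s <- svd(crossprod(Y, M))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

.centroid_size <- function(X) sqrt(sum(scale(X, scale = FALSE)^2))

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively superimposes a set of vertex configurations: each is centered
#' at its centroid, optionally scaled to unit centroid size, and rotated onto
#' the evolving mean shape; iteration stops when the mean shape changes by
#' less than `tol` (Frobenius norm) or after `max_iter` passes.
#'
#' @param configs n x m x 3 array of configurations (or a list of m x 3
#'   matrices).
#' @param with_scaling scale each configuration to unit centroid size
#'   (default `TRUE`: shape, not form, is analyzed; overall cranial size is
#'   handled as a covariate elsewhere).
#' @param tol convergence tolerance on the mean shape (default 1e-10).
#' @param max_iter maximum iterations (default 100).
#' @return list with `aligned` (n x m x 3 array), `mean_shape` (m x 3),
#'   `iterations`.
#' @export
gpa_align <- function(configs, with_scaling = TRUE, tol = 1e-10,
                      max_iter = 100L) {
  if (is.list(configs) && !is.array(configs))
    configs <- aperm(simplify2array(configs), c(3L, 1L, 2L))
  stopifnot(length(dim(configs)) == 3L)
  n <- dim(configs)[1]; m <- dim(configs)[2]; d <- dim(configs)[3]
  if (n < 2L) stop("at least two configurations are required")
  X <- vector("list", n)
  for (i in seq_len(n)) {
    Xi <- scale(configs[i, , ], scale = FALSE)  # center
    cs <- sqrt(sum(Xi^2))
    if (cs < 1e-12)
      stop("degenerate configuration ", i, ": all vertices coincide")
    X[[i]] <- if (with_scaling) Xi / cs else Xi
  }
  M <- X[[1L]]
  if (with_scaling) M <- M / sqrt(sum(M^2))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_len(n)) X[[i]] <- X[[i]] %*% .procrustes_rotation(X[[i]], M)
    M_new <- Reduce(`+`, X) / n
    if (with_scaling) M_new <- M_new / sqrt(sum(M_new^2))
    delta <- sqrt(sum((M_new - M)^2))
    M <- M_new
    if (delta < tol || iter >= max_iter) break
  }
  aligned <- array(0, dim = c(n, m, d))
  for (i in seq_len(n)) aligned[i, , ] <- X[[i]]
  list(aligned = aligned, mean_shape = M, iterations = iter)
}

#' Full Procrustes distance between two configurations
#'
#' Helper used mainly in tests: centers and unit-scales both configurations,
#' applies the optimal rotation, and returns the residual Frobenius distance.
#'
#' @param A,B m x k coordinate matrices.
#' @return nonnegative scalar.
#' @export
procrustes_distance <- function(A, B) {
  A <- scale(A, scale = FALSE); A <- A / sqrt(sum(A^2))
  B <- scale(B, scale = FALSE); B <- B / sqrt(sum(B^2))
  R <- .procrustes_rotation(A, B)
  sqrt(sum((A %*% R - B)^2))
}
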