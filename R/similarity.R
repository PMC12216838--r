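#' Time-dependent RBF similarity kernel
#'
#' `exp(-||chi_i - chi_j||^2 / (2 sigma^2))`. The kernel width `sigma`
#' controls locality: small widths see only near-identical environments,
#' large widths blur the whole reference bank together. During generation
#' `sigma` is annealed from 1 down to about 0.09 (see [force_schedule()]).
#'
#' @param chi_i,chi_j descriptor vectors of equal length (or matrices with
#'   matching column count; then the kernel is computed row-against-row
#'   pairwise via [outer]-style broadcasting is *not* done — use
#'   [kernel_matrix()] for cross products).
#' @param sigma kernel width, > 0 (dimensionless: descriptors are
#'   unit-normalised).
#' @return Similarity in (0, 1].
#' @export
rbf_kernel <- function(chi_i, chi_j, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (length(chi_i) != length(chi_j)) stop("dimension mismatch", call. = FALSE)
  exp(-sum((chi_i - chi_j)^2) / (2 * sigma^2))
}

#' Squared descriptor cross-distances
#'
#' @param X,R numeric matrices with matching column count (rows = vectors).
#' @return Matrix `D2` with `D2[i, j] = ||X[i,] - R[j,]||^2`.
#' @keywords internal
cross_dist2 <- function(X, R) {
  X <- as.matrix(X); R <- as.matrix(R)
  if (ncol(X) != ncol(R)) stop("dimension mismatch", call. = FALSE)
  d2 <- outer(rowSums(X^2), rowSums(R^2), `+`) - 2 * tcrossprod(X, R)
  pmax(d2, 0)
}

#' Kernel matrix between a configuration's descriptors and a reference bank
#'
#' @param X descriptor matrix (atoms x d).
#' @param refset a [reference_set()] or plain descriptor matrix.
#' @param sigma kernel width.
#' @return Matrix of kernel values, atoms x references.
#' @export
kernel_matrix <- function(X, refset, sigma) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  exp(-cross_dist2(X, ref_matrix(refset)) / (2 * sigma^2))
}

#' Per-atom similarity energy
#'
#' The negative log of the summed kernel similarities between one environment
#' and the reference bank -- the negative log-likelihood of the environment
#' under a kernel density estimate centred on the references. Evaluated with
#' log-sum-exp so it never overflows, however far the environment is.
#'
#' @param chi_i a descriptor vector.
#' @param refset a [reference_set()] or descriptor matrix (rows =
#'   references), non-empty.
#' @param sigma kernel width.
#' @return Scalar energy (dimensionless); 0 for an exact unique match.
#' @export
local_similarity_energy <- function(chi_i, refset, sigma) {
  R <- ref_matrix(refset)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  d2 <- cross_dist2(matrix(chi_i, 1L), R)[1L, ]
  -logsumexp(-d2 / (2 * sigma^2))
}

#' Total similarity energy of a configuration
#'
#' Sum of per-atom energies over all atoms, frozen and free alike (a frozen
#' scaffold shapes the landscape but never moves).
#'
#' @param desc descriptor matrix of the configuration (from
#'   [compute_descriptors()]).
#' @param refset a [reference_set()] or descriptor matrix.
#' @param sigma kernel width.
#' @return Scalar total energy.
#' @export
similarity_energy <- function(desc, refset, sigma) {
  R <- ref_matrix(refset)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  if (nrow(desc) == 0L) return(0)
  d2 <- cross_dist2(desc, R) / (2 * sigma^2)
  -sum(apply(-d2, 1L, logsumexp))
}

#' Similarity force
#'
#' Analytic negative gradient of [similarity_energy()] with respect to atomic
#' positions: softmax weights over reference environments, chained through
#' the descriptor Jacobian. Returned both raw and in schedule-factored form
#' (`force = k_sim * force_tilde` with `k_sim = 1/sigma^2`), which is the
#' form the generation loop consumes. The force on frozen atoms is reported;
#' callers zero it in updates.
#'
#' @param config an [atomic_config()].
#' @param refset a [reference_set()] or descriptor matrix.
#' @param sigma kernel width.
#' @param params [descriptor_params()] (must match the reference bank).
#' @return List with `force` and `force_tilde` (n x 3 matrices), `energy`,
#'   `weights` (atoms x references softmax matrix) and `desc`.
#' @export
similarity_force <- function(config, refset, sigma, params = descriptor_params()) {
  R <- ref_matrix(refset)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  check_ref_params(refset, params)
  dj <- descriptor_jacobian(config, params)
  n <- n_atoms(config)
  logk <- -cross_dist2(dj$desc, R) / (2 * sigma^2)
  lse <- apply(logk, 1L, logsumexp)
  W <- exp(logk - lse)                  # softmax weights, rows sum to 1
  G <- (W %*% R - unclass(dj$desc)) / sigma^2   # dE_i/dchi_i = -G[i,]
  force <- matrix(0, n, 3L)
  d <- ncol(R)
  for (i in seq_len(n)) {
    # chain rule: force on all atoms from atom i's environment term
    Ji <- matrix(dj$jac[, , , i], d, 3L * n)
    force <- force + matrix(crossprod(Ji, G[i, ]), n, 3L, byrow = TRUE)
  }
  list(force = force, force_tilde = force * sigma^2, energy = -sum(lse),
       weights = W, desc = dj$desc)
}

#' Inverse-sum similarity energy
#'
#' Swaps the order of summation relative to [similarity_energy()]: the log
#' runs over atoms, the outer sum over references. Minimised when every
#' reference environment finds a match somewhere in the configuration, which
#' makes it the energy of choice for fragment-biased guidance.
#'
#' @param desc descriptor matrix of the configuration (non-empty).
#' @param refset a [reference_set()] or descriptor matrix.
#' @param sigma kernel width.
#' @return Scalar energy.
#' @export
inverse_similarity_energy <- function(desc, refset, sigma) {
  R <- ref_matrix(refset)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  if (is.null(dim(desc)) || nrow(desc) == 0L) {
    stop("empty configuration: inverse-sum energy is undefined (+Inf)",
         call. = FALSE)
  }
  d2 <- cross_dist2(desc, R) / (2 * sigma^2)
  -sum(apply(-d2, 2L, logsumexp))
}

#' Force of the inverse-sum energy
#'
#' @inheritParams similarity_force
#' @return List with `force` (n x 3), `energy` and `desc`.
#' @export
inverse_similarity_force <- function(config, refset, sigma,
                                     params = descriptor_params()) {
  R <- ref_matrix(refset)
  if (nrow(R) == 0L) stop("empty reference set", call. = FALSE)
  check_ref_params(refset, params)
  if (n_atoms(config) == 0L) stop("empty configuration", call. = FALSE)
  dj <- descriptor_jacobian(config, params)
  n <- n_atoms(config)
  logk <- -cross_dist2(dj$desc, R) / (2 * sigma^2)
  lse_j <- apply(logk, 2L, logsumexp)
  W <- exp(sweep(logk, 2L, lse_j))      # columns sum to 1
  # d(-E_inv)/dchi_i = sum_j W[i,j] (R[j,] - chi_i)/sigma^2
  G <- (W %*% R - rowSums(W) * unclass(dj$desc)) / sigma^2
  force <- matrix(0, n, 3L)
  d <- ncol(R)
  for (i in seq_len(n)) {
    Ji <- matrix(dj$jac[, , , i], d, 3L * n)
    force <- force + matrix(crossprod(Ji, G[i, ]), n, 3L, byrow = TRUE)
  }
  list(force = force, energy = -sum(lse_j), desc = dj$desc)
}

#' Soft short-range repulsion
#'
#' `E = sum over unordered pairs of exp(-alpha r_ij)`, the auxiliary term that
#' keeps small spurious minima of the similarity energy from trapping
#' overlapping atoms. Finite for coincident atoms (each coincident pair
#' contributes 1; its pair force is 0 by symmetry).
#'
#' @param config an [atomic_config()].
#' @param alpha inverse range in 1/\enc{Å}{A} (default 4, making repulsion
#'   negligible beyond about 1.5 \enc{Å}{A}).
#' @param strength amplitude prefactor (default 1, the bare pair term
#'   `exp(-alpha r)` per pair). The generation loop uses a larger value
#'   calibrated against the similarity-force scale; see [sampler_config()].
#' @return List with `energy` and `force` (n x 3, Newton's-third-law
#'   antisymmetric pairwise central forces).
#' @export
repulsive_energy_force <- function(config, alpha = 4.0, strength = 1) {
  stopifnot_config(config)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  n <- n_atoms(config)
  force <- matrix(0, n, 3L)
  energy <- 0
  if (n >= 2L) {
    pos <- config$positions
    for (i in seq_len(n - 1L)) {
      dvec <- sweep(pos[(i + 1L):n, , drop = FALSE], 2L, pos[i, ])
      r <- sqrt(rowSums(dvec^2))
      e <- strength * exp(-alpha * r)
      energy <- energy + sum(e)
      ok <- r > 1e-12
      if (any(ok)) {
        f <- (alpha * e[ok] / r[ok]) * dvec[ok, , drop = FALSE]
        force[i, ] <- force[i, ] - colSums(f)
        idx <- ((i + 1L):n)[ok]
        force[idx, ] <- force[idx, , drop = FALSE] + f
      }
    }
  }
  list(energy = energy, force = force)
}
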