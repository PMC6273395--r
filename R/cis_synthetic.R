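# Synthetic CIS wavefunction fixtures: orthonormal orbital sets and CI
# coefficient matrices whose state mixing follows a model Hamiltonian's
# diabatic-to-adiabatic rotation, so OD/DD couplings can be checked against
# the analytic mixing-angle derivative.

# random orthonormal matrix via QR with deterministic sign fix
.random_orthogonal <- function(n) {
  qr_ <- qr(matrix(stats::rnorm(n * n), n))
  Q <- qr.Q(qr_)
  sweep(Q, 2, sign(diag(qr.R(qr_))), `*`)
}

# antisymmetric generator with unit Frobenius norm
.random_antisym <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  A <- (A - t(A)) / 2
  A / sqrt(sum(A^2))
}

# matrix exponential of an antisymmetric matrix via its eigen decomposition
.expm_antisym <- function(A) {
  if (max(abs(A)) == 0) return(diag(nrow(A)))
  ee <- eigen(A * 1i, symmetric = TRUE)   # i*A is Hermitian
  Re(ee$vectors %*% diag(exp(-1i * ee$values), nrow(A)) %*%
       Conj(t(ee$vectors)))
}

#' Synthetic CIS snapshots along a model path
#'
#' For a two-state model, generates at every path point an orthonormal
#' orbital set and normalized CIS coefficient matrices whose *physical*
#' state mixing follows the model's diabatic-to-adiabatic rotation
#' `R(theta(s))`. Two fixed orthonormal reference CI vectors are rotated by
#' the model mixing angle; optionally the orbital basis additionally drifts
#' by smooth seeded rotations within the occupied and virtual blocks, with
#' the CI coefficients co-transformed so the physical states are unchanged.
#' The OD/DD coupling between the two states along the path therefore
#' equals `d theta/d t` regardless of the orbital drift.
#'
#' @param model Two-state [model_hamiltonian()].
#' @param path Matrix of path coordinates (one row per snapshot).
#' @param orbital_dim Total number of orbitals (occupied + virtual); the
#'   occupied count is `floor(orbital_dim/2)`. The CI space
#'   `n_occ * n_virt` must hold at least `n_states` vectors.
#' @param seed Integer seed.
#' @param orbital_drift Magnitude (radians per unit path length) of the
#'   seeded intra-block orbital rotations. Default 0 (frozen orbitals).
#' @param times Optional time stamps per snapshot (defaults to the row
#'   index), returned alongside for coupling tests.
#' @return List with one element per path point: `orbitals`
#'   ([orbital_set()]), `states` (list of [cis_state()]), `theta` (model
#'   mixing angle), `time`.
#' @export
synthetic_cis_along_path <- function(model, path, orbital_dim, seed = 1,
                                     orbital_drift = 0, times = NULL) {
  stopifnot(inherits(model, "model_hamiltonian"))
  path <- as.matrix(path)
  n_occ <- floor(orbital_dim / 2)
  n_virt <- orbital_dim - n_occ
  if (n_occ * n_virt < model$n_states)
    stop("orbital_dim too small: CI space holds ", n_occ * n_virt,
         " vectors, need ", model$n_states)
  if (is.null(times)) times <- seq_len(nrow(path)) - 1
  set.seed(seed)
  basis_dim <- orbital_dim
  O0 <- .random_orthogonal(basis_dim)
  # fixed orthonormal reference CI vectors (columns) in the i->a space
  Tmat <- .random_orthogonal(n_occ * n_virt)[, seq_len(model$n_states),
                                             drop = FALSE]
  Aocc <- .random_antisym(n_occ)
  Avirt <- .random_antisym(n_virt)
  theta <- mixing_angle(model, path)
  # arc length drives the orbital drift
  s <- c(0, cumsum(sqrt(rowSums((path[-1, , drop = FALSE] -
                                   path[-nrow(path), , drop = FALSE])^2))))
  out <- vector("list", nrow(path))
  for (k in seq_len(nrow(path))) {
    Uocc <- .expm_antisym(orbital_drift * s[k] * Aocc)
    Uvirt <- .expm_antisym(orbital_drift * s[k] * Avirt)
    U <- diag(basis_dim)
    U[seq_len(n_occ), seq_len(n_occ)] <- Uocc
    U[n_occ + seq_len(n_virt), n_occ + seq_len(n_virt)] <- Uvirt
    orbs <- orbital_set(O0 %*% U, n_occ)
    # state columns Psi1 = (cos, -sin), Psi2 = (sin, cos) in the reference
    # CI plane, so that <Psi1|dt Psi2> = +dtheta/dt
    R <- matrix(c(cos(theta[k]), -sin(theta[k]),
                  sin(theta[k]), cos(theta[k])), 2, 2)
    states <- vector("list", model$n_states)
    for (m in seq_len(model$n_states)) {
      v <- Tmat %*% R[, m]
      C0 <- matrix(v, n_occ, n_virt)       # i fastest, a across columns
      C <- crossprod(Uocc, C0) %*% Uvirt   # co-transform into drifted basis
      states[[m]] <- cis_state(C / sqrt(sum(C^2)), label = m)
    }
    out[[k]] <- list(orbitals = orbs, states = states, theta = theta[k],
                     time = times[k])
  }
  out
}
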