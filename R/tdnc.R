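# Time-derivative nonadiabatic couplings between CIS-type states from
# wavefunction overlaps between consecutive time steps.
#
# Two routes are implemented:
#  * od_sigma(): the orbital-derivative (OD) contraction, which needs only
#    the molecular-orbital overlap matrix and the CI coefficients and scales
#    as N_occ * N_virt^2;
#  * dd_sigma(): the determinant-derivative (DD) reference, which expands
#    the wavefunction overlap over all pairs of singly excited determinants
#    and evaluates one N_occ x N_occ determinant per pair.
#
# Ordering convention: the virtual orbital of an excitation i -> a occupies
# the *position of i* in the determinant (in-place replacement). With this
# convention the reordering phase attached to the occupied-block term of the
# OD contraction is identically +1, which is verified against the DD route
# in the test suite.

#' Orthonormal orbital set
#'
#' Orbitals are columns of an orthonormal matrix expressed in a common
#' orthonormal basis (so the atomic-orbital overlap of a real interface is
#' the identity). The first `n_occ` columns are occupied.
#'
#' @param coefficients `basis_dim x n_orbitals` matrix with orthonormal
#'   columns (checked to 1e-10).
#' @param n_occ Number of occupied orbitals.
#' @return Object of class `orbital_set`.
#' @export
orbital_set <- function(coefficients, n_occ) {
  coefficients <- as.matrix(coefficients)
  n_orb <- ncol(coefficients)
  stopifnot(n_occ >= 1, n_occ < n_orb)
  gram <- crossprod(coefficients)
  if (max(abs(gram - diag(n_orb))) > 1e-10)
    stop("orbital coefficients are not orthonormal (deviation ",
         format(max(abs(gram - diag(n_orb)))), ")")
  structure(list(coefficients = coefficients, n_occ = n_occ,
                 n_virt = n_orb - n_occ),
            class = "orbital_set")
}

#' CIS state: singly-excited CI coefficient matrix
#'
#' @param coefficients `n_occ x n_virt` matrix `C_ia`, Frobenius-normalized
#'   (checked to 1e-10).
#' @param label State index or tag.
#' @return Object of class `cis_state`.
#' @export
cis_state <- function(coefficients, label = NA) {
  coefficients <- as.matrix(coefficients)
  nrm <- sqrt(sum(coefficients^2))
  if (abs(nrm - 1) > 1e-10)
    stop("CIS coefficients not normalized (norm ", format(nrm), ")")
  structure(list(coefficients = coefficients, label = label),
            class = "cis_state")
}

#' Orbital overlap matrix between consecutive time steps
#'
#' `S = C(t)^T C(t + dt)` in the common orthonormal basis. Phases and
#' reordering are not yet applied; see [phase_match()].
#'
#' @param orbitals_t,orbitals_next [orbital_set()] objects of equal
#'   dimensions.
#' @return Object of class `overlap_data` with fields `S`, `n_occ`,
#'   `matched = FALSE`.
#' @export
orbital_overlap <- function(orbitals_t, orbitals_next) {
  stopifnot(inherits(orbitals_t, "orbital_set"),
            inherits(orbitals_next, "orbital_set"))
  if (!identical(dim(orbitals_t$coefficients),
                 dim(orbitals_next$coefficients)) ||
      orbitals_t$n_occ != orbitals_next$n_occ)
    stop("orbital sets have mismatching dimensions")
  structure(list(S = crossprod(orbitals_t$coefficients,
                               orbitals_next$coefficients),
                 n_occ = orbitals_t$n_occ,
                 n_virt = orbitals_t$n_virt,
                 phases = NULL, perm = NULL, matched = FALSE),
            class = "overlap_data")
}

# greedy maximum-|overlap| assignment within one block; ties within 1e-12
# broken deterministically toward lower indices
.assign_block <- function(S) {
  n <- nrow(S)
  perm <- integer(n)
  rows <- seq_len(n); cols <- seq_len(n)
  A <- abs(S)
  for (step in seq_len(n)) {
    best <- -1; bi <- bj <- 1L
    for (i in rows) for (j in cols) {
      if (A[i, j] > best + 1e-12) { best <- A[i, j]; bi <- i; bj <- j }
    }
    perm[bi] <- bj
    rows <- setdiff(rows, bi); cols <- setdiff(cols, bj)
  }
  perm
}

#' Phase-match and reorder an orbital overlap
#'
#' Orbitals at `t + dt` are reordered by a maximum-|overlap| assignment and
#' sign-flipped so that every diagonal overlap is non-negative, restoring
#' continuity of the orbital basis across the step. The assignment is done
#' separately within the occupied and virtual blocks (orbitals do not cross
#' the Fermi level between steps). The permutation and sign vector are
#' recorded so CI coefficients can be transformed consistently (see
#' [align_cis_states()]).
#'
#' @param overlap An [orbital_overlap()] result.
#' @return The `overlap_data` with `S` replaced by the matched matrix and
#'   `perm`/`phases` filled in; `matched = TRUE`.
#' @export
phase_match <- function(overlap) {
  stopifnot(inherits(overlap, "overlap_data"))
  if (nrow(overlap$S) != ncol(overlap$S))
    stop("phase matching needs a square overlap matrix")
  no <- overlap$n_occ
  nv <- overlap$n_virt
  occ <- seq_len(no); virt <- no + seq_len(nv)
  perm <- integer(no + nv)
  perm[occ] <- .assign_block(overlap$S[occ, occ, drop = FALSE])
  perm[virt] <- no + .assign_block(overlap$S[virt, virt, drop = FALSE])
  Sm <- overlap$S[, perm, drop = FALSE]
  phases <- ifelse(diag(Sm) < 0, -1, 1)
  Sm <- sweep(Sm, 2, phases, `*`)
  out <- overlap
  out$S <- Sm
  out$perm <- perm
  out$phases <- phases
  out$matched <- TRUE
  out
}

#' @export
print.overlap_data <- function(x, ...) {
  cat(sprintf("<overlap_data %dx%d (%d occ), %s>\n", nrow(x$S), ncol(x$S),
              x$n_occ, if (x$matched) "phase-matched" else "raw"))
  invisible(x)
}

#' Transform CIS states at t+dt into the phase-matched orbital labeling
#'
#' Applies the orbital permutation and sign flips recorded by
#' [phase_match()] to the CI coefficient matrices of the later time step,
#' then fixes the CI-vector phase per state by maximizing the overlap
#' `sum(C(t) * C(t+dt))` with the earlier states.
#'
#' @param states_next List of [cis_state()] at `t + dt`.
#' @param overlap Phase-matched [orbital_overlap()].
#' @param states_t Optional list of [cis_state()] at `t` used for CI-phase
#'   continuity (skipped when `NULL`).
#' @return List of aligned `cis_state` objects; attribute `ci_phases` holds
#'   the per-state signs applied.
#' @export
align_cis_states <- function(states_next, overlap, states_t = NULL) {
  if (!isTRUE(overlap$matched))
    stop("overlap must be phase-matched before aligning CI states")
  no <- overlap$n_occ
  occ_perm <- overlap$perm[seq_len(no)]
  virt_perm <- overlap$perm[no + seq_len(overlap$n_virt)] - no
  occ_ph <- overlap$phases[seq_len(no)]
  virt_ph <- overlap$phases[no + seq_len(overlap$n_virt)]
  signs <- numeric(length(states_next))
  out <- vector("list", length(states_next))
  for (m in seq_along(states_next)) {
    C <- states_next[[m]]$coefficients
    Ct <- C[occ_perm, virt_perm, drop = FALSE]
    Ct <- Ct * outer(occ_ph, virt_ph)
    s <- 1
    if (!is.null(states_t)) {
      ov <- sum(states_t[[m]]$coefficients * Ct)
      if (ov < 0) { s <- -1; Ct <- -Ct }
    }
    signs[m] <- s
    out[[m]] <- cis_state(Ct, label = states_next[[m]]$label)
  }
  attr(out, "ci_phases") <- signs
  out
}

#' Time-derivative coupling by the orbital-derivative (OD) contraction
#'
#' Assembles the coupling `sigma_mn = <Psi_m | d/dt Psi_n>` from (i) the
#' CI-coefficient finite-difference term, (ii) the virtual-block orbital
#' derivative term contracted with `S_ab/dt` and (iii) the occupied-block
#' term contracted with `S_ji/dt`, using only the phase-matched orbital
#' overlap matrix. With the in-place determinant ordering convention the
#' occupied-block reordering phase is +1 for all index pairs. The result is
#' antisymmetrized by default, enforcing the skew symmetry of the exact
#' coupling at finite time step.
#'
#' @param states_t List of [cis_state()] at `t`.
#' @param states_next List of [cis_state()] at `t + dt` (aligned
#'   automatically via [align_cis_states()]).
#' @param overlap Phase-matched [orbital_overlap()].
#' @param dt Time step (fs), positive.
#' @param antisymmetrize Return `(sigma - t(sigma))/2`? Default `TRUE`.
#' @return `n_states x n_states` coupling matrix (1/fs). Attribute
#'   `raw` carries the pre-antisymmetrization matrix.
#' @export
od_sigma <- function(states_t, states_next, overlap, dt,
                     antisymmetrize = TRUE) {
  stopifnot(dt > 0)
  if (!isTRUE(overlap$matched))
    stop("od_sigma requires a phase-matched overlap (see phase_match())")
  if (inherits(states_t, "cis_state")) states_t <- list(states_t)
  if (inherits(states_next, "cis_state")) states_next <- list(states_next)
  aligned <- align_cis_states(states_next, overlap, states_t)
  no <- overlap$n_occ
  occ <- seq_len(no); virt <- no + seq_len(overlap$n_virt)
  Soo <- overlap$S[occ, occ, drop = FALSE]; diag(Soo) <- 0
  Svv <- overlap$S[virt, virt, drop = FALSE]; diag(Svv) <- 0
  ns <- length(states_t)
  sig <- matrix(0, ns, ns)
  # orbital-derivative terms are contracted with midpoint-averaged CI
  # coefficients: the finite-difference sigma lives at the step midpoint,
  # and the averaging cancels the second-order error of the contraction
  # under the final antisymmetrization
  mid <- lapply(seq_len(ns), function(m)
    (states_t[[m]]$coefficients + aligned[[m]]$coefficients) / 2)
  for (m in seq_len(ns)) for (n in seq_len(ns)) {
    Cm <- states_t[[m]]$coefficients
    Cn <- states_t[[n]]$coefficients
    Cn_next <- aligned[[n]]$coefficients
    t1 <- sum(Cm * (Cn_next - Cn))
    t2 <- sum(crossprod(mid[[m]], mid[[n]]) * Svv)  # sum_ab [..]_ab S_ab
    t3 <- -sum(tcrossprod(mid[[m]], mid[[n]]) * t(Soo)) # -sum_ij [..] S_ji
    sig[m, n] <- (t1 + t2 + t3) / dt
  }
  raw <- sig
  if (antisymmetrize) sig <- (sig - t(sig)) / 2
  attr(sig, "raw") <- raw
  sig
}

# determinant overlap for the excitation pair (i->a | j->b): occupied block
# of the full orbital overlap with row i replaced by virtual a (bra) and
# column j by virtual b (ket), in place
.dd_det <- function(Sfull, n_occ, i, a, j, b) {
  M <- Sfull[seq_len(n_occ), seq_len(n_occ), drop = FALSE]
  M[i, ] <- Sfull[n_occ + a, seq_len(n_occ)]
  M[, j] <- Sfull[seq_len(n_occ), n_occ + b]
  M[i, j] <- Sfull[n_occ + a, n_occ + b]
  det(M)
}

#' Time-derivative coupling by the determinant (DD) reference method
#'
#' Expands the wavefunction overlap between consecutive steps over all
#' pairs of singly excited determinants,
#' `<Psi_m(t)|Psi_n(t+dt)> = sum_ia sum_jb C_ia^m C_jb^n det(...)`,
#' and forms `sigma = (<Psi_m(t)|Psi_n(t+dt)> - <Psi_n(t)|Psi_m(t+dt)>) /
#' (2 dt)`. No phase matching is needed; determinant algebra absorbs orbital
#' sign and order changes. Serves as the reference for [od_sigma()].
#'
#' @param states_t,states_next Lists of [cis_state()] (or single states).
#' @param orbitals_t,orbitals_next [orbital_set()] at the two steps.
#' @param dt Time step (fs).
#' @return Coupling matrix (1/fs). Attribute `overlap_matrix` holds the
#'   wavefunction overlap `W[m, n] = <Psi_m(t)|Psi_n(t+dt)>`; attribute
#'   `status` is `"ok"` or `"near_singular"` (flagged with a warning when
#'   the occupied-block overlap is numerically singular).
#' @export
dd_sigma <- function(states_t, states_next, orbitals_t, orbitals_next, dt) {
  stopifnot(dt > 0)
  if (inherits(states_t, "cis_state")) states_t <- list(states_t)
  if (inherits(states_next, "cis_state")) states_next <- list(states_next)
  Sfull <- crossprod(orbitals_t$coefficients, orbitals_next$coefficients)
  no <- orbitals_t$n_occ; nv <- orbitals_t$n_virt
  status <- "ok"
  if (rcond(Sfull[seq_len(no), seq_len(no), drop = FALSE]) < 1e-12) {
    warning("occupied-block orbital overlap is near singular; ",
            "DD couplings may be unreliable")
    status <- "near_singular"
  }
  ns <- length(states_t)
  W <- matrix(0, ns, ns)   # W[m, n] = <Psi_m(t) | Psi_n(t+dt)>
  # precompute all determinants det(i->a | j->b)
  D <- array(0, c(no, nv, no, nv))
  for (i in seq_len(no)) for (a in seq_len(nv))
    for (j in seq_len(no)) for (b in seq_len(nv))
      D[i, a, j, b] <- .dd_det(Sfull, no, i, a, j, b)
  Dm <- matrix(aperm(D, c(2, 1, 4, 3)), no * nv, no * nv)  # (a,i) x (b,j)
  for (m in seq_len(ns)) for (n in seq_len(ns)) {
    cm <- as.vector(t(states_t[[m]]$coefficients))        # (a fastest, i)
    cn <- as.vector(t(states_next[[n]]$coefficients))
    W[m, n] <- drop(cm %*% Dm %*% cn)
  }
  sig <- (W - t(W)) / (2 * dt)
  attr(sig, "overlap_matrix") <- W
  attr(sig, "status") <- status
  sig
}

#' Operation-count scaling of the OD and DD contractions
#'
#' Counts the floating-point multiplications of the contraction kernels as
#' implemented: the OD route costs `N_occ N_virt` (CI derivative) plus
#' `N_occ N_virt^2 + N_virt^2` (virtual block) plus `N_occ^2 N_virt +
#' N_occ^2` (occupied block) per state pair; the DD route evaluates
#' `(N_occ N_virt)^2` determinants of size `N_occ` at `N_occ^3/3`
#' multiplications each, plus the final double contraction.
#'
#' @param n_occ_range,n_virt_range Integer vectors of grid values.
#' @return Data frame with columns `n_occ`, `n_virt`, `od_ops`, `dd_ops`.
#' @export
scaling_probe <- function(n_occ_range = 2:6, n_virt_range = 2:6) {
  grid <- expand.grid(n_occ = n_occ_range, n_virt = n_virt_range)
  grid$od_ops <- with(grid, n_occ * n_virt +
                        n_occ * n_virt^2 + n_virt^2 +
                        n_occ^2 * n_virt + n_occ^2)
  grid$dd_ops <- with(grid, (n_occ * n_virt)^2 * (n_occ^3 / 3 + 1) +
                        2 * (n_occ * n_virt)^2)
  grid
}
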