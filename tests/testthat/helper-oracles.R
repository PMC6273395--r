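# Independent oracles used across the suite. These deliberately avoid the
# package's own contraction code paths.

# Brute-force wavefunction overlap between CIS states at two steps:
# explicitly builds the orbital index list of every singly excited
# determinant (virtual in place of the excited-from occupied) and evaluates
# the determinant of the corresponding orbital-overlap block.
brute_force_wf_overlap <- function(Cm, Cn, O_t, O_next, n_occ) {
  n_virt <- ncol(Cm)
  S <- crossprod(O_t, O_next)
  total <- 0
  for (i in seq_len(n_occ)) for (a in seq_len(n_virt)) {
    if (Cm[i, a] == 0) next
    bra <- seq_len(n_occ); bra[i] <- n_occ + a
    for (j in seq_len(n_occ)) for (b in seq_len(n_virt)) {
      if (Cn[j, b] == 0) next
      ket <- seq_len(n_occ); ket[j] <- n_occ + b
      total <- total + Cm[i, a] * Cn[j, b] *
        det(S[bra, ket, drop = FALSE])
    }
  }
  total
}

brute_force_sigma <- function(states_t, states_next, orb_t, orb_next, dt) {
  ns <- length(states_t)
  W <- matrix(0, ns, ns)
  for (m in seq_len(ns)) for (n in seq_len(ns))
    W[m, n] <- brute_force_wf_overlap(states_t[[m]]$coefficients,
                                      states_next[[n]]$coefficients,
                                      orb_t$coefficients,
                                      orb_next$coefficients,
                                      orb_t$n_occ)
  (W - t(W)) / (2 * dt)
}

# Closed-form propagator for two degenerate states with constant coupling:
# amplitudes rotate by the coupling angle under a global dynamical phase.
rabi_exact <- function(a0, energy, sigma12, t) {
  th <- sigma12 * t
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  exp(-1i * energy * t / hop_units()$hbar_ev_fs) * (rot %*% a0)
}

# Central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

# random rigid motion applied to a geometry
random_rigid_motion <- function(g) {
  A <- matrix(stats::rnorm(9), 3)
  A <- (A - t(A)) / 2
  ee <- eigen(A * 1i, symmetric = TRUE)
  R <- Re(ee$vectors %*% diag(exp(-1i * ee$values)) %*% Conj(t(ee$vectors)))
  sweep(g %*% t(R), 2, stats::rnorm(3), `+`)
}
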