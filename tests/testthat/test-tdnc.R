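test_that("orbital overlap is the identity for identical sets and flags sign flips", {
  set.seed(1)
  inst <- random_cis_pair(3, 3, rotation = 0)
  ov <- orbital_overlap(inst$orbitals_t, inst$orbitals_t)
  expect_lt(max(abs(ov$S - diag(6))), 1e-12)
  flipped <- inst$orbitals_t
  flipped$coefficients[, 2] <- -flipped$coefficients[, 2]
  ov2 <- orbital_overlap(inst$orbitals_t, flipped)
  expect_equal(diag(ov2$S)[2], -1)
  small <- orbital_set(inst$orbitals_t$coefficients[, 1:4], 2)
  expect_error(orbital_overlap(inst$orbitals_t, small), "dimension")
})

test_that("small orthogonal rotations give S = I + eps A to second order", {
  set.seed(3)
  eps <- 1e-4
  for (k in 1:5) {
    n <- 6
    A <- matrix(stats::rnorm(n * n), n); A <- (A - t(A)) / 2
    O0 <- qr.Q(qr(matrix(stats::rnorm(n * n), n)))
    # matrix exponential oracle by scaling and squaring
    E <- diag(n); P <- diag(n)
    for (j in 1:12) { P <- P %*% (eps * A) / j; E <- E + P }
    O1 <- O0 %*% E
    S <- crossprod(O0, O1)
    expect_lt(max(abs(S - diag(n) - eps * A)), 10 * eps^2)
  }
})

test_that("phase matching fixes signs, undoes swaps, and leaves near-identity overlaps alone", {
  set.seed(5)
  inst <- random_cis_pair(3, 3, rotation = 0)
  O <- inst$orbitals_t
  # one negated column
  neg <- O; neg$coefficients[, 4] <- -neg$coefficients[, 4]
  ov <- phase_match(orbital_overlap(O, neg))
  expect_equal(ov$perm, 1:6)
  expect_equal(ov$phases, c(1, 1, 1, -1, 1, 1))
  expect_true(all(diag(ov$S) >= 0))
  # two swapped virtual orbitals
  sw <- O; sw$coefficients[, c(5, 6)] <- sw$coefficients[, c(6, 5)]
  ov2 <- phase_match(orbital_overlap(O, sw))
  expect_equal(ov2$perm, c(1, 2, 3, 4, 6, 5))
  expect_true(all(diag(ov2$S) >= 0))
  # random near-identity rotation: no reordering, no flips
  inst3 <- random_cis_pair(3, 3, rotation = 1e-3)
  ov3 <- phase_match(orbital_overlap(inst3$orbitals_t,
                                     inst3$orbitals_next))
  expect_equal(ov3$perm, 1:6)
  expect_equal(ov3$phases, rep(1, 6))
})

test_that("OD coupling vanishes for frozen inputs and on the diagonal", {
  set.seed(7)
  inst <- random_cis_pair(3, 3, rotation = 0)
  ov <- phase_match(orbital_overlap(inst$orbitals_t, inst$orbitals_t))
  sig <- od_sigma(inst$states_t, inst$states_t, ov, dt = 0.05)
  expect_lt(max(abs(sig)), 1e-12)
  # moving case: diagonal stays zero by antisymmetrization
  inst2 <- random_cis_pair(3, 3, rotation = 1e-2)
  ov2 <- phase_match(orbital_overlap(inst2$orbitals_t,
                                     inst2$orbitals_next))
  sig2 <- od_sigma(inst2$states_t, inst2$states_next, ov2, inst2$dt)
  expect_lt(max(abs(diag(sig2))), 1e-12)
  expect_lt(max(abs(sig2 + t(sig2))), 1e-10)
  # pre-antisymmetrization residual is small but reported
  expect_true(!is.null(attr(sig2, "raw")))
  expect_error(od_sigma(inst2$states_t, inst2$states_next,
                        orbital_overlap(inst2$orbitals_t,
                                        inst2$orbitals_next), inst2$dt),
               "phase-matched")
})

test_that("DD reduces to the Kronecker delta for identical orbital sets", {
  set.seed(9)
  inst <- random_cis_pair(3, 3, rotation = 0)
  sig <- dd_sigma(inst$states_t, inst$states_t, inst$orbitals_t,
                  inst$orbitals_t, dt = 1)
  W <- attr(sig, "overlap_matrix")
  expect_equal(W, diag(2), tolerance = 1e-12)
  expect_lt(max(abs(sig)), 1e-12)
})

test_that("DD matches the hand-checkable one-electron case", {
  # n_occ = 1, n_virt = 1: the wavefunction overlap is the single virtual-
  # virtual orbital overlap <a(t)|b(t+dt)>
  O0 <- diag(2)
  th <- 0.1
  O1 <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  st <- list(cis_state(matrix(1, 1, 1), 1))
  sig <- dd_sigma(st, st, orbital_set(O0, 1), orbital_set(O1, 1), dt = 0.5)
  W <- attr(sig, "overlap_matrix")
  expect_equal(W[1, 1], cos(th), tolerance = 1e-12)
})

test_that("DD equals the independent brute-force determinant expansion", {
  set.seed(13)
  for (k in 1:10) {
    no <- sample(2:4, 1); nv <- sample(2:4, 1)
    inst <- random_cis_pair(no, nv, n_states = 2,
                            rotation = stats::runif(1, 0.01, 0.3),
                            dt = 0.01)
    sig <- dd_sigma(inst$states_t, inst$states_next, inst$orbitals_t,
                    inst$orbitals_next, inst$dt)
    bf <- brute_force_sigma(inst$states_t, inst$states_next,
                            inst$orbitals_t, inst$orbitals_next, inst$dt)
    expect_lt(max(abs(sig - bf)), 1e-12)
  }
})

test_that("OD matches DD on random CIS pairs at small steps", {
  set.seed(17)
  inst <- random_cis_pair(3, 3, rotation = 1e-4, dt = 1e-3)
  ov <- phase_match(orbital_overlap(inst$orbitals_t, inst$orbitals_next))
  s_od <- od_sigma(inst$states_t, inst$states_next, ov, inst$dt)
  s_dd <- dd_sigma(inst$states_t, inst$states_next, inst$orbitals_t,
                   inst$orbitals_next, inst$dt)
  expect_lt(max(abs(s_od - s_dd)), 1e-8)
})

test_that("finite-difference coupling converges linearly in the step", {
  # sigma(dt) - sigma(dt/2) shrinks as O(dt) along a model path
  m <- build_single_crossing()
  v <- 0.01
  sig_at <- function(dt) {
    tt <- c(0, dt)
    snaps <- synthetic_cis_along_path(m, cbind(-0.1 + v * tt),
                                      orbital_dim = 6, seed = 19,
                                      orbital_drift = 0.2)
    ov <- phase_match(orbital_overlap(snaps[[1]]$orbitals,
                                      snaps[[2]]$orbitals))
    od_sigma(snaps[[1]]$states, snaps[[2]]$states, ov, dt)[1, 2]
  }
  d1 <- abs(sig_at(0.4) - sig_at(0.2))
  d2 <- abs(sig_at(0.2) - sig_at(0.1))
  d3 <- abs(sig_at(0.1) - sig_at(0.05))
  expect_lt(d2, d1)
  expect_lt(d3, d2)
})

test_that("OD coupling tracks the analytic mixing-angle derivative", {
  m <- build_single_crossing()
  v <- 0.01; dt <- 0.05
  tt <- seq(-30, 30, by = dt)
  path <- cbind(v * tt)
  snaps <- synthetic_cis_along_path(m, path, orbital_dim = 6, seed = 3,
                                    orbital_drift = 0.5)
  th <- mixing_angle(m, path)
  errs <- vapply(seq_len(length(tt) - 1), function(k) {
    ov <- phase_match(orbital_overlap(snaps[[k]]$orbitals,
                                      snaps[[k + 1]]$orbitals))
    sig <- od_sigma(snaps[[k]]$states, snaps[[k + 1]]$states, ov, dt)
    abs(sig[1, 2] - (th[k + 1] - th[k]) / dt)
  }, 0)
  expect_lt(max(errs), 1e-4)
})

test_that("operation counts scale as N_occ N_virt^2 for OD and faster for DD", {
  tab <- scaling_probe(n_occ_range = c(2, 8, 16),
                       n_virt_range = c(32, 64, 128))
  # doubling n_virt at fixed n_occ multiplies the OD count by ~4
  r_virt <- with(tab, od_ops[n_occ == 8 & n_virt == 128] /
                   od_ops[n_occ == 8 & n_virt == 64])
  expect_gt(r_virt, 3.4); expect_lt(r_virt, 4.6)
  # doubling n_occ at fixed n_virt multiplies the OD count by ~2
  r_occ <- with(tab, od_ops[n_occ == 16 & n_virt == 64] /
                  od_ops[n_occ == 8 & n_virt == 64])
  expect_gt(r_occ, 1.7); expect_lt(r_occ, 2.6)
  # DD dominates OD everywhere on the grid
  expect_true(all(tab$dd_ops > tab$od_ops))
})
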