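harmonic_model <- function(k = 2, mass = 12)
  model_hamiltonian(1, 1, function(q) matrix(0.5 * k * q[1]^2, 1, 1),
                    function(q) list(matrix(k * q[1], 1, 1)),
                    masses = mass, name = "harmonic")

test_that("force-free motion is exactly linear and harmonic motion conserves energy", {
  free <- model_hamiltonian(1, 1, function(q) matrix(1.5, 1, 1),
                            function(q) list(matrix(0, 1, 1)),
                            masses = 12, name = "flat")
  st <- trajectory_state(0.2, 0.013, 1, free)
  st2 <- nuclear_step(st, free, 0.5)
  expect_equal(st2$coords, 0.2 + 0.013 * 0.5, tolerance = 1e-14)
  expect_equal(st2$velocities, 0.013, tolerance = 1e-14)

  m <- harmonic_model()
  st <- trajectory_state(0.3, 0, 1, m)
  e0 <- st$electronic$energies[1] + kinetic_energy(st)
  n <- 1e4
  etot <- numeric(n)
  for (k in seq_len(n)) {
    st <- nuclear_step(st, m, 0.5)
    etot[k] <- st$electronic$energies[1] + kinetic_energy(st)
  }
  # secular drift: linear trend over the full run, not the bounded
  # oscillation of the Verlet shadow energy
  tt <- (1:n) * 0.5
  drift <- abs(unname(stats::coef(stats::lm(etot ~ tt))[2])) * n * 0.5
  expect_lt(drift / e0, 1e-6)
})

test_that("harmonic period matches 2 pi sqrt(m/k) to 0.1 percent", {
  k <- 2; mass <- 12
  m <- harmonic_model(k, mass)
  st <- trajectory_state(0.3, 0, 1, m)
  pos <- numeric(4000)
  for (i in seq_along(pos)) {
    st <- nuclear_step(st, m, 0.5)
    pos[i] <- st$coords
  }
  down <- which(diff(sign(pos)) < 0)
  period <- mean(diff(down)) * 0.5
  expected <- 2 * pi * sqrt(mass * hop_units()$amu_ev / k)
  expect_lt(abs(period - expected) / expected, 1e-3)
})

test_that("amplitudes follow the closed form with zero coupling and Rabi rotation with constant coupling", {
  z <- matrix(0, 2, 2)
  a0 <- c(0.6 + 0i, sqrt(1 - 0.36) * 1i)
  E <- c(1.3, 2.7)
  a <- a0
  for (k in 1:20) a <- electronic_step(a, E, E, z, z, 0.5, 0.025)
  t <- 10
  exact <- a0 * exp(-1i * E * t / hop_units()$hbar_ev_fs)
  expect_lt(max(Mod(a - exact)), 1e-10)

  sig <- matrix(c(0, -0.05, 0.05, 0), 2, 2)
  a <- c(1 + 0i, 0i)
  for (k in 1:40) a <- electronic_step(a, c(1, 1), c(1, 1), sig, sig,
                                       0.5, 0.025)
  expect_lt(max(Mod(a - rabi_exact(c(1, 0), 1, 0.05, 20))), 1e-8)
})

test_that("electronic integration is converged in the substep", {
  sig <- matrix(c(0, -0.04, 0.04, 0), 2, 2)
  sig2 <- matrix(c(0, -0.01, 0.01, 0), 2, 2)
  a0 <- c(sqrt(0.7) + 0i, sqrt(0.3) * 1i)
  E1 <- c(1, 3); E2 <- c(1.2, 2.8)
  a_coarse <- electronic_step(a0, E1, E2, sig, sig2, 0.5, 0.025)
  a_fine <- electronic_step(a0, E1, E2, sig, sig2, 0.5, 0.0125)
  expect_lt(max(Mod(a_coarse - a_fine)), 1e-9)
})

test_that("hop probabilities have the fewest-switches structure", {
  a <- c(0.8 + 0i, 0.6i)
  sig <- matrix(c(0, -0.01, 0.01, 0), 2, 2)
  expect_equal(hop_probability(a, matrix(0, 2, 2), 1, 0.5), c(0, 0))
  expect_equal(hop_probability(c(1 + 0i, 0i), sig, 1, 0.5), c(0, 0))
  # direct evaluation of g(1 -> 2) = max(0, -2 dt Re(conj(a2) s21 a1))/|a1|^2
  g <- hop_probability(a, sig, 1, 0.5)
  hand <- max(0, -2 * 0.5 * Re(Conj(a[2]) * sig[2, 1] * a[1])) / 0.64
  expect_equal(g[2], hand)
  # population flowing 1 -> 2 gives positive probability out of state 1
  a2 <- c(sqrt(0.9) + 0i, sqrt(0.1) + 0i)
  g2 <- hop_probability(a2, sig, 1, 0.5)
  expect_true(g2[2] >= 0)
  expect_warning(hop_probability(c(0i, 1 + 0i), sig, 1, 0.5), "population")
})

test_that("decoherence damps inactive amplitudes by the energy-based lifetime", {
  u <- hop_units()
  alpha <- 0.1 * u$hartree_ev
  a <- sqrt(c(0.5, 0.5)) + 0i
  out <- apply_decoherence(a, c(0, 1), 1, 1, 0.5, alpha)
  tau <- (u$hbar_ev_fs / 1) * (1 + alpha / 1)
  a2_exp <- sqrt(0.5) * exp(-0.5 / tau)
  expect_equal(Mod(out[2]), a2_exp, tolerance = 1e-12)
  expect_equal(sum(Mod(out)^2), 1, tolerance = 1e-12)
  # all population on the active state: unchanged
  pure <- c(1 + 0i, 0i)
  expect_equal(apply_decoherence(pure, c(0, 1), 1, 1, 0.5, alpha), pure)
  # degenerate states are undamped
  deg <- apply_decoherence(a, c(1, 1), 1, 1, 0.5, alpha)
  expect_equal(Mod(deg[2]), sqrt(0.5), tolerance = 1e-12)
  # zero kinetic energy: no damping
  cold <- apply_decoherence(a, c(0, 1), 0, 1, 0.5, alpha)
  expect_equal(cold, a)
})

test_that("hops conserve energy or are frustrated", {
  m <- build_single_crossing()
  st <- trajectory_state(0, 0.02, 2, m)
  # draw above the total probability: nothing happens
  same <- attempt_hop(st, c(0.1, 0), 0.5)
  expect_identical(attr(same, "hop"), "none")
  expect_equal(same$active, 2)
  # accepted downward hop conserves total energy
  hopd <- attempt_hop(st, c(1, 0), 0.1)
  expect_identical(attr(hopd, "hop"), "accepted")
  e_before <- st$electronic$energies[2] + kinetic_energy(st)
  e_after <- hopd$electronic$energies[1] + kinetic_energy(hopd)
  expect_lt(abs(e_before - e_after), 1e-10)
  # upward hop without enough kinetic energy is frustrated
  slow <- trajectory_state(0, 1e-4, 1, m)
  up <- attempt_hop(slow, c(0, 1), 0.1)
  expect_identical(attr(up, "hop"), "frustrated")
  expect_equal(up$active, 1)
  expect_equal(up$velocities, slow$velocities)
})

test_that("termination triggers on the S1/S0 gap and at t_max", {
  m <- build_thymine_model()
  s <- run_settings(gap_stop = 0.15, t_max = 1000)
  near <- trajectory_state(m$anchors$X10_npi$coords, c(0, 0), 2, m)
  chk <- check_termination(near, s)
  expect_false(chk$continue)
  expect_identical(chk$reason, "s1s0_gap")
  expect_equal(chk$crossing_time, 0)
  far <- trajectory_state(c(0.3, 0), c(0, 0), 2, m)
  expect_true(check_termination(far, s)$continue)
  late <- trajectory_state(c(0.3, 0), c(0, 0), 3, m, time = 1000)
  expect_identical(check_termination(late, s)$reason, "t_max")
})

test_that("raising the gap threshold shortens mean crossing times", {
  m <- build_thymine_model()
  ic <- sample_initial_conditions(m, 60, seed = 5)
  ic <- subsample_initial_conditions(ic, 15, seed = 5)
  ct <- sapply(c(0.15, 0.30), function(gap) {
    ens <- run_ensemble(m, ic, run_settings(seed = 7, gap_stop = gap,
                                            t_max = 600))
    mean(vapply(Filter(Negate(is.null), ens$trajectories), function(tr)
      if (tr$termination$reason == "s1s0_gap")
        tr$termination$crossing_time else 600, 0))
  })
  expect_lt(ct[2], ct[1])
})

test_that("ensembles are deterministic, single-state models never hop, and zero coupling keeps occupation exactly 1", {
  m1 <- harmonic_model()
  ics <- list(list(coords = 0.2, velocities = 0),
              list(coords = -0.1, velocities = 0.01))
  s <- run_settings(seed = 3, t_max = 50, gap_stop = NA)
  ens <- run_ensemble(m1, ics, s)
  expect_equal(nrow(ens$hops), 0)
  expect_true(all(vapply(ens$trajectories, function(tr)
    tr$termination$reason, "") == "t_max"))

  # zero diabatic coupling: occupation of the initial state stays 1
  m0 <- model_hamiltonian(2, 1, function(q)
    matrix(c(0.5 * 2 * q[1]^2, 0, 0, 0.5 * 2 * q[1]^2 + 1), 2, 2),
    function(q) list(matrix(c(2 * q[1], 0, 0, 2 * q[1]), 2, 2)),
    masses = 12, name = "uncoupled")
  ens0 <- run_ensemble(m0, list(list(coords = 0.3, velocities = 0)),
                       run_settings(seed = 1, t_max = 100, gap_stop = NA,
                                    initial_state = 2))
  tr <- ens0$trajectories[[1]]
  expect_true(all(tr$log[, "active"] == 2))
  expect_true(all(abs(tr$log[, "pop1"] - 1) < 1e-10))

  m <- build_thymine_model()
  ic <- sample_initial_conditions(m, 10, seed = 2)
  s2 <- run_settings(seed = 9, t_max = 100)
  occ1 <- aggregate_occupations(run_ensemble(m, ic, s2))
  occ2 <- aggregate_occupations(run_ensemble(m, ic, s2))
  expect_identical(occ1$fractions, occ2$fractions)
})

test_that("electronic norm is conserved along full trajectories", {
  m <- build_thymine_model()
  ic <- sample_initial_conditions(m, 5, seed = 8)
  # decoherence off so the raw integrator norm is visible
  ens <- run_ensemble(m, ic, run_settings(seed = 2, t_max = 150,
                                          decoherence_alpha = NA))
  for (tr in Filter(Negate(is.null), ens$trajectories)) {
    pops <- tr$log[, grep("^pop", colnames(tr$log)), drop = FALSE]
    expect_lt(max(abs(rowSums(pops) - 1)), 1e-8)
  }
})

test_that("surface-hopping fractions track the mean quantum populations on a single crossing", {
  m <- build_single_crossing()
  s <- run_settings(seed = 21, t_max = 50, gap_stop = NA,
                    decoherence_alpha = NA, initial_state = 2)
  ics <- replicate(500, list(coords = -0.6, velocities = 0.02),
                   simplify = FALSE)
  ens <- run_ensemble(m, ics, s)
  trajs <- Filter(Negate(is.null), ens$trajectories)
  frac2 <- mean(vapply(trajs, function(tr)
    tr$log[nrow(tr$log), "active"] == 2, TRUE))
  # pop1 column is |a_2|^2 (states are labelled 0-based in the log)
  pop2 <- mean(vapply(trajs, function(tr)
    tr$log[nrow(tr$log), "pop1"], 0))
  expect_lt(abs(frac2 - pop2), 0.05)
})
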