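# Fewest-switches trajectory surface hopping on model potentials:
# velocity-Verlet nuclear propagation, substepped electronic amplitude
# integration (5th-order Butcher Runge-Kutta) on linearly interpolated
# electronic quantities, hopping from overlap-based time-derivative
# couplings, energy-based decoherence, and gap-based termination.

#' Run settings for surface-hopping propagation
#'
#' @param dt_nuclear Classical time step (fs), default 0.5.
#' @param dt_electronic Electronic substep (fs), default 0.025; must divide
#'   `dt_nuclear`.
#' @param decoherence_alpha Decoherence parameter in Hartree (default 0.1);
#'   `NA` disables the correction.
#' @param gap_stop S1/S0 energy-gap termination threshold (eV), default
#'   0.15; `NA` disables the gap stop. While the gap stop is in force,
#'   coupling to the ground state is excluded from amplitude propagation
#'   and hopping: internal conversion to S0 is represented by the stop
#'   criterion alone.
#' @param t_max Maximum propagation time (fs), default 1000.
#' @param seed Master integer seed.
#' @param initial_state Active adiabatic state at t = 0 (1-based; for the
#'   three-state model 3 means S2).
#' @return Object of class `run_settings`.
#' @export
run_settings <- function(dt_nuclear = 0.5, dt_electronic = 0.025,
                         decoherence_alpha = 0.1, gap_stop = 0.15,
                         t_max = 1000, seed = 1, initial_state = NULL) {
  stopifnot(dt_nuclear > 0, dt_electronic > 0, t_max > 0)
  nsub <- dt_nuclear / dt_electronic
  if (abs(nsub - round(nsub)) > 1e-9)
    stop("dt_electronic must divide dt_nuclear")
  structure(list(dt_nuclear = dt_nuclear, dt_electronic = dt_electronic,
                 decoherence_alpha = decoherence_alpha,
                 gap_stop = gap_stop, t_max = t_max, seed = seed,
                 initial_state = initial_state,
                 n_substeps = round(nsub)),
            class = "run_settings")
}

#' Trajectory state
#'
#' Bundles the classical and quantum degrees of freedom of one trajectory.
#'
#' @param coords,velocities Nuclear coordinates (Angstrom) and velocities
#'   (Angstrom/fs).
#' @param active Active adiabatic state (1-based).
#' @param model The [model_hamiltonian()] being propagated.
#' @param time Current time (fs).
#' @param amplitudes Complex electronic amplitudes (defaults to 1 on the
#'   active state).
#' @return Object of class `trajectory_state`.
#' @export
trajectory_state <- function(coords, velocities, active, model, time = 0,
                             amplitudes = NULL) {
  if (is.null(amplitudes)) {
    amplitudes <- rep(0 + 0i, model$n_states)
    amplitudes[active] <- 1 + 0i
  }
  structure(list(time = time, coords = coords, velocities = velocities,
                 amplitudes = amplitudes, active = active,
                 electronic = evaluate_adiabatic(model, coords),
                 masses = model$masses),
            class = "trajectory_state")
}

#' Kinetic energy of a trajectory state (eV)
#' @param state A [trajectory_state()], or a velocity vector if `masses`
#'   is given.
#' @param masses Masses (amu) when `state` is a plain velocity vector.
#' @export
kinetic_energy <- function(state, masses = NULL) {
  if (inherits(state, "trajectory_state"))
    0.5 * sum(state$masses * state$velocities^2) * .amu_ev
  else 0.5 * sum(masses * state^2) * .amu_ev
}

#' One velocity-Verlet step on the active adiabatic surface
#'
#' @param state A [trajectory_state()].
#' @param model The model Hamiltonian.
#' @param dt Time step (fs).
#' @return The advanced `trajectory_state` (time, coords, velocities and
#'   electronic cache updated; amplitudes untouched). The new rotation is
#'   sign-matched to the previous step's for coupling continuity.
#' @export
nuclear_step <- function(state, model, dt) {
  g <- state$electronic$gradients[state$active, ]
  if (!all(is.finite(g)))
    stop("non-finite force at t = ", state$time, " fs; trajectory aborted")
  m_ev <- state$masses * .amu_ev
  acc <- -g / m_ev
  x_new <- state$coords + state$velocities * dt + 0.5 * acc * dt^2
  pt_new <- evaluate_adiabatic(model, x_new)
  # sign-match the adiabatic basis to the previous step
  ov <- crossprod(state$electronic$rotation, pt_new$rotation)
  flips <- ifelse(diag(ov) < 0, -1, 1)
  pt_new$rotation <- sweep(pt_new$rotation, 2, flips, `*`)
  g_new <- pt_new$gradients[state$active, ]
  acc_new <- -g_new / m_ev
  v_new <- state$velocities + 0.5 * (acc + acc_new) * dt
  out <- state
  out$time <- state$time + dt
  out$coords <- x_new
  out$velocities <- v_new
  out$electronic <- pt_new
  out
}

#' Overlap-based time-derivative coupling matrix between two steps
#'
#' `U = R(t)^T R(t+dt)` over the (sign-matched) adiabatic rotations;
#' `sigma = (U - U^T) / (2 dt)`, the finite-difference analog of
#' `R^T dR/dt` assigned to the step midpoint.
#'
#' @param point_t,point_next `electronic_point`s with consistently
#'   sign-matched rotations.
#' @param dt Time step (fs).
#' @return Antisymmetric coupling matrix (1/fs).
#' @export
rotation_sigma <- function(point_t, point_next, dt) {
  U <- crossprod(point_t$rotation, point_next$rotation)
  (U - t(U)) / (2 * dt)
}

# right-hand side of the electronic TDSE in the adiabatic basis:
# da/dt = -(i/hbar) E a - sigma a
.el_rhs <- function(a, E, sig) {
  -(1i / .hbar) * E * a - sig %*% a
}

#' Propagate electronic amplitudes through one nuclear step
#'
#' Integrates the electronic Schroedinger equation in the adiabatic basis
#' with the 6-stage 5th-order Butcher Runge-Kutta scheme, in substeps of
#' `dt_electronic`, with energies and couplings interpolated linearly
#' across the nuclear step. Couplings are finite-difference estimates
#' assigned to step midpoints, so `sig_t` is the previous interval's matrix
#' and `sig_next` the current one; they are interpolated accordingly.
#'
#' @param amplitudes Complex amplitude vector at the step start.
#' @param E_t,E_next Adiabatic energies (eV) at the step endpoints.
#' @param sig_t,sig_next Coupling matrices (1/fs) at the midpoints of the
#'   previous and current nuclear intervals.
#' @param dt_nuclear,dt_electronic Time steps (fs).
#' @return Amplitudes at the step end. Errors out if the norm drifts by
#'   more than 1e-6 within the step.
#' @export
electronic_step <- function(amplitudes, E_t, E_next, sig_t, sig_next,
                            dt_nuclear, dt_electronic) {
  nsub <- round(dt_nuclear / dt_electronic)
  h <- dt_nuclear / nsub
  a <- amplitudes
  # integrate relative to the mean energy (a pure global phase): this
  # removes most of the phase stiffness from the substep integrator and is
  # restored exactly at the end of the step
  Ebar <- mean((E_t + E_next) / 2)
  Efun <- function(tau) E_t + (E_next - E_t) * (tau / dt_nuclear) - Ebar
  # sigma midpoint interpolation: sig_t lives at -dt/2, sig_next at +dt/2
  Sfun <- function(tau) {
    w <- (tau + dt_nuclear / 2) / dt_nuclear
    w <- min(max(w, 0), 1)
    (1 - w) * sig_t + w * sig_next
  }
  rk5 <- function(a, t0, h) {
    k1 <- .el_rhs(a, Efun(t0), Sfun(t0))
    k2 <- .el_rhs(a + h * k1 / 4, Efun(t0 + h / 4), Sfun(t0 + h / 4))
    k3 <- .el_rhs(a + h * (k1 + k2) / 8, Efun(t0 + h / 4), Sfun(t0 + h / 4))
    k4 <- .el_rhs(a - h * k2 / 2 + h * k3, Efun(t0 + h / 2),
                  Sfun(t0 + h / 2))
    k5 <- .el_rhs(a + h * (3 * k1 + 9 * k4) / 16,
                  Efun(t0 + 3 * h / 4), Sfun(t0 + 3 * h / 4))
    k6 <- .el_rhs(a + h * (-3 * k1 + 2 * k2 + 12 * k3 - 12 * k4 + 8 * k5) / 7,
                  Efun(t0 + h), Sfun(t0 + h))
    a + h * (7 * k1 + 32 * k3 + 12 * k4 + 32 * k5 + 7 * k6) / 90
  }
  # the continuous equation conserves the norm exactly (antisymmetric
  # coupling, real energies), so any norm drift is pure truncation error;
  # it is used as the controller for local substep refinement at coupling
  # spikes
  advance <- function(a, t0, h, depth) {
    a1 <- rk5(a, t0, h)
    if (abs(sum(Mod(a1)^2) - sum(Mod(a)^2)) < 1e-12 || depth >= 8)
      return(a1)
    advance(advance(a, t0, h / 2, depth + 1), t0 + h / 2, h / 2, depth + 1)
  }
  for (k in seq_len(nsub))
    a <- advance(a, (k - 1) * h, h, 0)
  a <- a * exp(-1i * Ebar * dt_nuclear / .hbar)
  drift <- abs(sum(Mod(a)^2) - sum(Mod(amplitudes)^2))
  if (drift > 1e-6)
    stop("electronic norm drifted by ", format(drift),
         " in one nuclear step; integration failure")
  a
}

#' Fewest-switches hop probabilities
#'
#' Hammes-Schiffer--Tully probabilities out of the active state `l`:
#' `g(l -> m) = max(0, -2 dt Re(conj(a_m) sigma_ml a_l) / |a_l|^2)`,
#' the positive part of the population flux, consistent with the propagator
#' `da_m/dt = -(i/hbar) E_m a_m - sum_l sigma_ml a_l`. Negative fluxes are
#' clipped to zero; if the probabilities sum beyond 1 they are rescaled.
#'
#' @param amplitudes Complex amplitudes.
#' @param sigma Coupling matrix (1/fs).
#' @param active Active state index.
#' @param dt Nuclear time step (fs).
#' @return Per-state probability vector (zero at the active state).
#' @export
hop_probability <- function(amplitudes, sigma, active, dt) {
  pop <- Mod(amplitudes[active])^2
  if (pop < 1e-12) {
    warning("active-state population below 1e-12; hop probabilities set to 0")
    return(numeric(length(amplitudes)))
  }
  g <- -2 * dt * Re(Conj(amplitudes) * sigma[, active] * amplitudes[active]) /
    pop
  g[active] <- 0
  g <- pmax(g, 0)
  tot <- sum(g)
  if (tot > 1) g <- g / tot
  g
}

#' Energy-based decoherence correction
#'
#' Non-active amplitudes are damped by `exp(-dt/tau_m)` with
#' `tau_m = (hbar / |E_m - E_active|) * (1 + alpha / E_kin)`; the active
#' amplitude is rescaled to restore unit norm. Degenerate states are left
#' undamped (`tau = Inf`), as is everything when the kinetic energy
#' vanishes.
#'
#' @param amplitudes Complex amplitudes.
#' @param energies Adiabatic energies (eV).
#' @param kinetic_energy Nuclear kinetic energy (eV), non-negative.
#' @param active Active state index.
#' @param dt Time step (fs).
#' @param alpha Decoherence parameter in eV (0.1 Hartree = 2.721 eV).
#' @return Corrected amplitudes (unit norm).
#' @export
apply_decoherence <- function(amplitudes, energies, kinetic_energy, active,
                              dt, alpha) {
  stopifnot(kinetic_energy >= 0)
  a <- amplitudes
  if (kinetic_energy == 0) return(a)
  for (m in seq_along(a)) {
    if (m == active) next
    gap <- abs(energies[m] - energies[active])
    if (gap == 0) next
    tau <- (.hbar / gap) * (1 + alpha / kinetic_energy)
    a[m] <- a[m] * exp(-dt / tau)
  }
  rest <- sum(Mod(a[-active])^2)
  pop_act <- Mod(a[active])^2
  if (pop_act > 0)
    a[active] <- a[active] * sqrt(max(0, 1 - rest) / pop_act)
  a
}

#' Attempt a fewest-switches hop
#'
#' Selects a target state by comparing `target_draw` against the cumulative
#' hop probabilities. A selected hop is accepted when the kinetic energy
#' can absorb the potential-energy change; velocities are then rescaled
#' uniformly along the velocity direction to conserve total energy.
#' Otherwise the hop is frustrated: the active state and velocities stay
#' unchanged.
#'
#' @param state A [trajectory_state()].
#' @param probabilities Per-state hop probabilities (from
#'   [hop_probability()]).
#' @param target_draw Uniform random number in (0, 1).
#' @return The (possibly updated) `trajectory_state`, with attributes
#'   `hop` (`"none"`, `"accepted"` or `"frustrated"`) and `target`.
#' @export
attempt_hop <- function(state, probabilities, target_draw) {
  cum <- cumsum(probabilities)
  sel <- which(target_draw <= cum)
  if (!length(sel)) {
    attr(state, "hop") <- "none"
    return(state)
  }
  target <- sel[1]
  ekin <- kinetic_energy(state)
  dE <- state$electronic$energies[state$active] -
    state$electronic$energies[target]
  if (ekin + dE < 0) {
    attr(state, "hop") <- "frustrated"
    attr(state, "target") <- target
    return(state)
  }
  scale <- if (ekin > 0) sqrt((ekin + dE) / ekin) else 1
  state$velocities <- state$velocities * scale
  state$active <- target
  attr(state, "hop") <- "accepted"
  attr(state, "target") <- target
  state
}

#' Check trajectory termination
#'
#' Terminates with reason `"s1s0_gap"` when the trajectory is on S1
#' (state index 2) and the S1/S0 gap has dropped below `gap_stop` -- the
#' current time is reported as the crossing-time estimate -- or with
#' reason `"t_max"` at the time limit.
#'
#' @param state A [trajectory_state()].
#' @param settings A [run_settings()].
#' @return `list(continue = TRUE)` or `list(continue = FALSE, reason =,
#'   crossing_time =)`.
#' @export
check_termination <- function(state, settings) {
  if (!is.na(settings$gap_stop) && state$active == 2 &&
      length(state$electronic$energies) >= 2) {
    gap <- state$electronic$energies[2] - state$electronic$energies[1]
    if (gap < settings$gap_stop)
      return(list(continue = FALSE, reason = "s1s0_gap",
                  crossing_time = state$time))
  }
  if (state$time >= settings$t_max - 1e-9)
    return(list(continue = FALSE, reason = "t_max",
                crossing_time = NA_real_))
  list(continue = TRUE)
}

#' Propagate a single surface-hopping trajectory
#'
#' Runs the full per-step cycle: velocity-Verlet nuclear step, coupling
#' evaluation from the rotation overlap, substepped electronic integration
#' on interpolated quantities, fewest-switches hop attempt, decoherence
#' correction and termination check. Uses the current R random stream for
#' hop draws; seed it before calling for reproducibility.
#'
#' @param model A [model_hamiltonian()].
#' @param coords,velocities Initial conditions.
#' @param settings A [run_settings()].
#' @param active Initial active state (defaults to
#'   `settings$initial_state`, else the highest state).
#' @return Object of class `fssh_trajectory`: `log` (matrix of t, active,
#'   energies, total energy, coords, populations), `hops` (data frame),
#'   `termination` (reason and crossing time), `final` trajectory state.
#' @export
run_trajectory <- function(model, coords, velocities, settings,
                           active = NULL) {
  if (is.null(active))
    active <- if (!is.null(settings$initial_state)) settings$initial_state
              else model$n_states
  alpha_ev <- if (is.na(settings$decoherence_alpha)) NA_real_
              else settings$decoherence_alpha * .hartree_ev
  st <- trajectory_state(coords, velocities, active, model)
  dt <- settings$dt_nuclear
  nmax <- ceiling(settings$t_max / dt)
  ns <- model$n_states
  log <- matrix(NA_real_, nmax + 1, 3 + ns + model$n_coords + ns)
  colnames(log) <- c("t", "active", "e_total",
                     paste0("E", seq_len(ns) - 1),
                     paste0("q", seq_len(model$n_coords)),
                     paste0("pop", seq_len(ns) - 1))
  rec <- function(st, row) {
    log[row, ] <<- c(st$time, st$active,
                     st$electronic$energies[st$active] + kinetic_energy(st),
                     st$electronic$energies, st$coords, Mod(st$amplitudes)^2)
  }
  rec(st, 1)
  hops <- list()
  sigma_prev <- NULL
  term <- list(continue = FALSE, reason = "t_max", crossing_time = NA_real_)
  row <- 1
  repeat {
    chk <- check_termination(st, settings)
    if (!chk$continue) { term <- chk; break }
    st_old <- st
    st <- nuclear_step(st, model, dt)
    sigma_cur <- rotation_sigma(st_old$electronic, st$electronic, dt)
    # when the S1/S0 gap-stop criterion is in force, internal conversion to
    # the ground state is handled by that criterion alone: the ground state
    # is excluded from amplitude transfer and hopping
    if (!is.na(settings$gap_stop)) {
      sigma_cur[1, ] <- 0
      sigma_cur[, 1] <- 0
    }
    if (is.null(sigma_prev)) sigma_prev <- sigma_cur
    st$amplitudes <- electronic_step(st_old$amplitudes,
                                     st_old$electronic$energies,
                                     st$electronic$energies,
                                     sigma_prev, sigma_cur,
                                     dt, settings$dt_electronic)
    probs <- hop_probability(st$amplitudes, sigma_cur, st$active, dt)
    draw <- stats::runif(1)
    from <- st$active
    st <- attempt_hop(st, probs, draw)
    if (attr(st, "hop") %in% c("accepted", "frustrated"))
      hops[[length(hops) + 1]] <-
        data.frame(time = st$time, from = from,
                   to = attr(st, "target"),
                   accepted = attr(st, "hop") == "accepted",
                   draw = draw,
                   coords = I(list(st$coords)))
    if (!is.na(alpha_ev))
      st$amplitudes <- apply_decoherence(st$amplitudes,
                                         st$electronic$energies,
                                         kinetic_energy(st), st$active,
                                         dt, alpha_ev)
    sigma_prev <- sigma_cur
    row <- row + 1
    rec(st, row)
  }
  structure(list(log = log[seq_len(row), , drop = FALSE],
                 hops = if (length(hops)) do.call(rbind, hops)
                        else data.frame(),
                 termination = term, final = st, model = model$name),
            class = "fssh_trajectory")
}

#' @export
print.fssh_trajectory <- function(x, ...) {
  cat(sprintf(
    "<fssh_trajectory on '%s': %d steps, %d hop event(s), ended by %s%s>\n",
    x$model, nrow(x$log) - 1,
    if (nrow(x$hops)) sum(x$hops$accepted) else 0,
    x$termination$reason,
    if (!is.na(x$termination$crossing_time))
      sprintf(" at %.1f fs", x$termination$crossing_time) else ""))
  invisible(x)
}

#' Propagate an ensemble of surface-hopping trajectories
#'
#' Each trajectory gets a derived seed `(seed + 7919 * i) mod (2^31 - 1)`
#' from the master seed, so the ensemble is reproducible independently of
#' evaluation order. Failing trajectories are quarantined (collected with
#' their error message) without aborting the ensemble.
#'
#' @param model A [model_hamiltonian()].
#' @param initial_conditions An `initial_conditions` object (see
#'   [sample_initial_conditions()]) or a list of `list(coords, velocities)`.
#' @param settings A [run_settings()].
#' @return Object of class `fssh_ensemble`: `trajectories`, `hops` (data
#'   frame with trajectory ids), `failures`, `settings`.
#' @export
run_ensemble <- function(model, initial_conditions, settings) {
  ics <- if (inherits(initial_conditions, "initial_conditions")) {
    lapply(seq_len(nrow(initial_conditions$coords)), function(i)
      list(coords = initial_conditions$coords[i, ],
           velocities = initial_conditions$velocities[i, ]))
  } else initial_conditions
  stopifnot(length(ics) >= 1)
  trajs <- vector("list", length(ics))
  failures <- list()
  hops <- list()
  for (i in seq_along(ics)) {
    set.seed((settings$seed + 7919 * i) %% 2147483647)
    res <- tryCatch(
      run_trajectory(model, ics[[i]]$coords, ics[[i]]$velocities, settings),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        list(trajectory = i, message = conditionMessage(res))
      next
    }
    trajs[[i]] <- res
    if (nrow(res$hops)) {
      h <- res$hops
      h$trajectory <- i
      hops[[length(hops) + 1]] <- h
    }
  }
  structure(list(trajectories = trajs,
                 hops = if (length(hops)) do.call(rbind, hops)
                        else data.frame(),
                 failures = failures, settings = settings,
                 model = model$name),
            class = "fssh_ensemble")
}

#' @export
print.fssh_ensemble <- function(x, ...) {
  ok <- sum(!vapply(x$trajectories, is.null, TRUE))
  cat(sprintf(
    "<fssh_ensemble on '%s': %d trajectories (%d failed), %d accepted hops>\n",
    x$model, length(x$trajectories), length(x$failures),
    if (nrow(x$hops)) sum(x$hops$accepted) else 0))
  invisible(x)
}
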