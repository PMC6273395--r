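# Harmonic-oscillator Wigner sampling of initial conditions, the
# nuclear-ensemble absorption spectrum, and excitation-window filtering.

#' Harmonic normal-mode set
#'
#' @param frequencies Mode frequencies (cm^-1); must be positive for
#'   sampled modes.
#' @param masses Reduced mass per mode (amu).
#' @param displacements Matrix (`n_coords x n_modes`) of unit-norm mode
#'   displacement vectors in plain coordinates.
#' @param equilibrium Equilibrium geometry (coordinate vector, Angstrom).
#' @return An object of class `normal_mode_set`.
#' @export
normal_mode_set <- function(frequencies, masses, displacements, equilibrium) {
  displacements <- as.matrix(displacements)
  stopifnot(length(frequencies) == ncol(displacements),
            length(masses) == ncol(displacements),
            length(equilibrium) == nrow(displacements),
            all(masses > 0))
  structure(list(frequencies = frequencies, masses = masses,
                 displacements = displacements, equilibrium = equilibrium),
            class = "normal_mode_set")
}

#' Sample coordinates and momenta from the ground-state Wigner distribution
#'
#' For each harmonic mode the vibrational ground-state Wigner distribution
#' is a product of independent Gaussians with variances
#' `sigma_q^2 = hbar/(2 mu omega)` and `sigma_p^2 = hbar mu omega / 2`
#' (minimum uncertainty, `sigma_q sigma_p = hbar/2`).
#'
#' @param modes A [normal_mode_set()].
#' @param n Number of phase-space points.
#' @param seed Integer seed.
#' @return List with `coords` and `velocities` (`n x n_coords` matrices,
#'   Angstrom and Angstrom/fs) and `mode_q`, `mode_p` (normal-mode
#'   coordinates in Angstrom and momenta in amu Angstrom/fs).
#' @export
wigner_sample <- function(modes, n, seed = 1) {
  stopifnot(inherits(modes, "normal_mode_set"), n >= 1)
  bad <- which(modes$frequencies <= 0)
  if (length(bad))
    stop("non-positive frequency for mode(s) ",
         paste(bad, collapse = ", "), "; cannot Wigner-sample")
  set.seed(seed)
  nm <- length(modes$frequencies)
  omega <- 2 * pi * .c_cm_fs * modes$frequencies    # 1/fs
  mu_ev <- modes$masses * .amu_ev                   # eV fs^2/A^2
  sq <- sqrt(.hbar / (2 * mu_ev * omega))           # Angstrom
  sp_ev <- sqrt(.hbar * mu_ev * omega / 2)          # eV fs / A
  q <- matrix(stats::rnorm(n * nm), n, nm) %*% diag(sq, nm)
  p_ev <- matrix(stats::rnorm(n * nm), n, nm) %*% diag(sp_ev, nm)
  coords <- matrix(rep(modes$equilibrium, each = n), n) +
    q %*% t(modes$displacements)
  vel <- p_ev %*% diag(1 / mu_ev, nm) %*% t(modes$displacements)
  list(coords = coords, velocities = vel,
       mode_q = q, mode_p = p_ev / .amu_ev)
}

#' Build excited-state initial conditions on a model
#'
#' Wigner-samples the ground-state normal modes of `model`, evaluates the
#' vertical excitation energies and oscillator strengths at every sampled
#' geometry and returns one initial-condition record per point.
#'
#' @param model A [model_hamiltonian()] with an `oscillator` function.
#' @param n Ensemble size.
#' @param seed Integer seed.
#' @param modes Optional precomputed [normal_mode_set()]; computed from the
#'   ground surface otherwise.
#' @return Object of class `initial_conditions`: list with `coords`,
#'   `velocities`, `energies` (`n x n_states`, eV), `excitation`
#'   (`n x (n_states-1)`, vertical excitation energies), `fosc`
#'   (oscillator strengths per excited state).
#' @export
sample_initial_conditions <- function(model, n, seed = 1, modes = NULL) {
  if (is.null(modes)) modes <- model_normal_modes(model)
  ws <- wigner_sample(modes, n, seed)
  ns <- model$n_states
  energies <- matrix(NA_real_, n, ns)
  fosc <- matrix(0, n, ns)
  for (i in seq_len(n)) {
    pt <- evaluate_adiabatic(model, ws$coords[i, ], gradients = FALSE)
    energies[i, ] <- pt$energies
    if (!is.null(model$oscillator)) fosc[i, ] <- model$oscillator(pt)
  }
  structure(list(coords = ws$coords, velocities = ws$velocities,
                 energies = energies,
                 excitation = energies[, -1, drop = FALSE] - energies[, 1],
                 fosc = fosc[, -1, drop = FALSE], selected_state = NULL,
                 model = model$name),
            class = "initial_conditions")
}

#' @export
print.initial_conditions <- function(x, ...) {
  cat(sprintf("<initial_conditions: %d points on '%s'%s>\n",
              nrow(x$coords), x$model,
              if (!is.null(x$selected_state))
                sprintf(", selected state S%d", x$selected_state) else ""))
  invisible(x)
}

#' Nuclear-ensemble absorption spectrum
#'
#' The spectrum is the ensemble average of oscillator-strength-weighted
#' normalized Gaussians centered at the vertical excitation energies:
#' `I(E) = (1/n) sum_points sum_states f * g(E - dE; width)`. By default the
#' curve is rescaled to unit band maximum (arbitrary units).
#'
#' @param ensemble An `initial_conditions` object.
#' @param grid Energy grid (eV). Default: spans the transitions +- 5 widths.
#' @param width Gaussian standard deviation (eV), default 0.05.
#' @param normalize Rescale to unit maximum? Default `TRUE`.
#' @return Object of class `spectrum_curve` with `energy`, `intensity`,
#'   `width`, and the located `band_max` (eV).
#' @export
nea_spectrum <- function(ensemble, grid = NULL, width = 0.05,
                         normalize = TRUE) {
  stopifnot(inherits(ensemble, "initial_conditions"))
  dE <- ensemble$excitation
  f <- ensemble$fosc
  if (length(dE) == 0 || nrow(dE) == 0) stop("empty ensemble")
  if (is.null(grid))
    grid <- seq(min(dE) - 5 * width, max(dE) + 5 * width, length.out = 2000)
  intens <- numeric(length(grid))
  n <- nrow(dE)
  for (s in seq_len(ncol(dE)))
    for (i in seq_len(n))
      intens <- intens + f[i, s] *
        stats::dnorm(grid, mean = dE[i, s], sd = width)
  intens <- intens / n
  band_max <- grid[which.max(intens)]
  scale <- if (normalize && max(intens) > 0) max(intens) else 1
  structure(list(energy = grid, intensity = intens / scale, width = width,
                 band_max = band_max, normalized = normalize,
                 mean_total_fosc = mean(rowSums(f))),
            class = "spectrum_curve")
}

#' @export
print.spectrum_curve <- function(x, ...) {
  cat(sprintf("<spectrum_curve: band maximum at %.3f eV, width %.3f eV, %s>\n",
              x$band_max, x$width,
              if (x$normalized) "unit-max normalized" else "absolute"))
  invisible(x)
}

#' Filter initial conditions by an excitation-energy window
#'
#' Keeps points whose vertical excitation energy to `target_state` lies
#' within `center +- half_width` (boundary inclusive).
#'
#' @param ensemble An `initial_conditions` object.
#' @param center Window center (eV).
#' @param half_width Window half width (eV).
#' @param target_state Excited-state index (1 = first excited state).
#' @return The filtered `initial_conditions` (possibly zero rows, with a
#'   warning), with `selected_state` set and the selection count in
#'   attribute `n_selected`.
#' @export
filter_energy_window <- function(ensemble, center, half_width,
                                 target_state = 2) {
  stopifnot(inherits(ensemble, "initial_conditions"))
  dE <- ensemble$excitation[, target_state]
  keep <- abs(dE - center) <= half_width
  if (!any(keep))
    warning(sprintf("no initial conditions inside %.3f +- %.3f eV window",
                    center, half_width))
  out <- ensemble
  out$coords <- ensemble$coords[keep, , drop = FALSE]
  out$velocities <- ensemble$velocities[keep, , drop = FALSE]
  out$energies <- ensemble$energies[keep, , drop = FALSE]
  out$excitation <- ensemble$excitation[keep, , drop = FALSE]
  out$fosc <- ensemble$fosc[keep, , drop = FALSE]
  out$selected_state <- target_state
  attr(out, "n_selected") <- sum(keep)
  out
}

#' Subsample initial conditions
#'
#' Uniform (default) or oscillator-strength-weighted selection of `n`
#' points, seeded; used to cut a filtered ensemble down to a target
#' trajectory count.
#'
#' @param ensemble An `initial_conditions` object.
#' @param n Number of points to keep (all if fewer available).
#' @param seed Integer seed.
#' @param f_weighted Weight selection by the oscillator strength of the
#'   selected state? Default `FALSE`.
#' @export
subsample_initial_conditions <- function(ensemble, n, seed = 1,
                                         f_weighted = FALSE) {
  m <- nrow(ensemble$coords)
  if (m <= n) return(ensemble)
  set.seed(seed)
  w <- NULL
  if (f_weighted) {
    s <- if (is.null(ensemble$selected_state)) 1 else ensemble$selected_state
    w <- ensemble$fosc[, s]
    if (all(w <= 0)) w <- NULL
  }
  idx <- sort(sample.int(m, n, prob = w))
  out <- ensemble
  for (fld in c("coords", "velocities", "energies", "excitation", "fosc"))
    out[[fld]] <- ensemble[[fld]][idx, , drop = FALSE]
  attr(out, "n_selected") <- n
  out
}
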