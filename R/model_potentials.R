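# Analytic multi-state diabatic model Hamiltonians over one or two nuclear
# coordinates. These stand in for ab initio electronic-structure calls: they
# supply adiabatic energies, gradients (Hellmann-Feynman on the diabatic
# matrix) and the diabatic-to-adiabatic rotation at any nuclear configuration.

#' Construct a diabatic model Hamiltonian
#'
#' A model is defined by a function returning the symmetric diabatic matrix
#' (eV) at a coordinate vector (Angstrom), optionally with analytic
#' derivative matrices, plus per-coordinate reduced masses (amu) and
#' per-state diabatic character labels.
#'
#' @param n_states Number of electronic states.
#' @param n_coords Number of nuclear coordinates.
#' @param diabatic Function `coords -> n_states x n_states` symmetric matrix (eV).
#' @param ddiabatic Optional function `coords -> list` of `n_coords` derivative
#'   matrices (eV/Angstrom). When `NULL`, gradients fall back to central
#'   finite differences of the eigenvalues.
#' @param masses Reduced mass per coordinate (amu). Default 12 amu
#'   (carbon-like, giving vibrational periods of a few tens of fs).
#' @param labels Character tags for the diabatic states.
#' @param name Model name.
#' @param anchors Optional named list of anchor configurations, each
#'   `list(coords=, energies=)` with `NA` for unconstrained states.
#' @param oscillator Optional function `electronic_point -> numeric` of
#'   per-state oscillator strengths (ground state entry included, usually 0).
#' @param ring_adapter Optional function `coords -> 6 x 3 matrix` embedding a
#'   model configuration as a six-membered-ring geometry for puckering
#'   analysis.
#' @return An object of class `model_hamiltonian`.
#' @export
model_hamiltonian <- function(n_states, n_coords, diabatic, ddiabatic = NULL,
                              masses = rep(12, n_coords),
                              labels = paste0("state", seq_len(n_states)),
                              name = "custom", anchors = NULL,
                              oscillator = NULL, ring_adapter = NULL) {
  stopifnot(n_states >= 1, n_coords >= 1, is.function(diabatic),
            length(masses) == n_coords, all(masses > 0),
            length(labels) == n_states)
  structure(list(n_states = n_states, n_coords = n_coords,
                 diabatic = diabatic, ddiabatic = ddiabatic,
                 masses = masses, labels = labels, name = name,
                 anchors = anchors, oscillator = oscillator,
                 ring_adapter = ring_adapter),
            class = "model_hamiltonian")
}

#' @export
print.model_hamiltonian <- function(x, ...) {
  cat(sprintf("<model_hamiltonian '%s': %d states [%s], %d coordinate(s)>\n",
              x$name, x$n_states, paste(x$labels, collapse = ", "),
              x$n_coords))
  if (!is.null(x$anchors))
    cat(sprintf("  anchors: %s\n", paste(names(x$anchors), collapse = ", ")))
  invisible(x)
}

#' Adiabatic energies, gradients and rotation at a configuration
#'
#' Diagonalizes the diabatic matrix at `coords`. Energies are sorted
#' ascending; the columns of `rotation` are the corresponding adiabatic
#' states expressed in the diabatic basis, with a deterministic sign
#' convention (largest-magnitude component positive). Gradients are
#' Hellmann-Feynman contractions of the analytic derivative matrices when
#' available, otherwise central finite differences of the eigenvalues.
#'
#' @param model A [model_hamiltonian()].
#' @param coords Coordinate vector of length `model$n_coords` (Angstrom).
#' @param gradients Compute per-state gradients? (Default `TRUE`.)
#' @return An object of class `electronic_point` with fields `energies`
#'   (eV), `gradients` (`n_states x n_coords`, eV/Angstrom), `rotation`,
#'   `coords`.
#' @export
evaluate_adiabatic <- function(model, coords, gradients = TRUE) {
  stopifnot(inherits(model, "model_hamiltonian"))
  if (length(coords) != model$n_coords)
    stop("coords has length ", length(coords), ", model expects ",
         model$n_coords)
  H <- model$diabatic(coords)
  if (!all(is.finite(H)))
    stop("non-finite diabatic matrix entry at coords (",
         paste(signif(coords, 6), collapse = ", "), ")")
  ee <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(ee$values)
  vals <- ee$values[ord]
  vecs <- ee$vectors[, ord, drop = FALSE]
  # deterministic sign: largest |component| of each column made positive
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  grad <- NULL
  if (gradients) {
    grad <- matrix(0, model$n_states, model$n_coords)
    if (!is.null(model$ddiabatic)) {
      dH <- model$ddiabatic(coords)
      for (k in seq_len(model$n_coords))
        grad[, k] <- colSums(vecs * (dH[[k]] %*% vecs))
    } else {
      h <- 1e-5
      for (k in seq_len(model$n_coords)) {
        qp <- coords; qp[k] <- qp[k] + h
        qm <- coords; qm[k] <- qm[k] - h
        ep <- sort(eigen(model$diabatic(qp), symmetric = TRUE,
                         only.values = TRUE)$values)
        em <- sort(eigen(model$diabatic(qm), symmetric = TRUE,
                         only.values = TRUE)$values)
        grad[, k] <- (ep - em) / (2 * h)
      }
    }
  }
  structure(list(energies = vals, gradients = grad, rotation = vecs,
                 coords = coords, diabatic = (H + t(H)) / 2),
            class = "electronic_point")
}

#' @export
print.electronic_point <- function(x, ...) {
  cat("<electronic_point at (", paste(signif(x$coords, 5), collapse = ", "),
      ") eV: ", paste(sprintf("%.4f", x$energies), collapse = ", "), ">\n",
      sep = "")
  invisible(x)
}

#' Diabatic-adiabatic mixing angle of a two-state model
#'
#' For a 2x2 diabatic matrix the rotation diagonalizing it is
#' `R(theta)` with `theta = atan2(2 V12, V22 - V11) / 2`. When `coords` is a
#' matrix (one row per path point) the angle branch is chosen continuously
#' along the path by unwrapping jumps larger than pi/2 (the angle is defined
#' modulo pi).
#'
#' @param model Two-state [model_hamiltonian()].
#' @param coords Coordinate vector, or a matrix with one configuration per row.
#' @return Mixing angle(s) in radians.
#' @export
mixing_angle <- function(model, coords) {
  stopifnot(inherits(model, "model_hamiltonian"))
  if (model$n_states != 2)
    stop("mixing_angle supports two-state models only (model has ",
         model$n_states, " states)")
  one <- function(q) {
    H <- model$diabatic(q)
    0.5 * atan2(2 * H[1, 2], H[2, 2] - H[1, 1])
  }
  if (is.matrix(coords)) {
    th <- apply(coords, 1, one)
    # continuous branch: the angle lives on a circle of period pi
    if (length(th) > 1) {
      d <- diff(th)
      jump <- round(d / pi)
      th <- th - c(0, cumsum(jump)) * pi
    }
    th
  } else {
    one(coords)
  }
}

# ---- built-in models -------------------------------------------------------

# Anchor data for the thymine-like three-state model: printed adiabatic
# energy triples (S0, S1, S2; eV, relative to the ground-state minimum) at
# the six stationary/intersection configurations, with NA where no value is
# printed. Positions: the closed-shell ground diabat is the isotropic
# harmonic 0.5*K*(x^2+y^2), so each anchor sits on the radius fixed by its
# S0 energy; the angles (stretch-like x vs puckering-like y) are model
# design choices reflecting the geometry changes at each point.
.thymine_anchor_energies <- list(
  S0_min   = c(0.00, 4.56, 5.06),
  S1_min   = c(1.33, 3.33, NA),
  S2_min   = c(2.14, 3.50, 4.18),
  X10_npi  = c(3.90, 3.90, NA),
  X10_pipi = c(3.82, 3.82, NA),
  X21      = c(3.37, 4.21, 4.22)
)
.thymine_anchor_angles_deg <- c(S0_min = 0, S1_min = 0, S2_min = 20,
                                X10_npi = 10, X10_pipi = 85, X21 = 60)

.thymine_params <- function() {
  K <- 20                                # ground diabat curvature, eV/A^2
  tgt <- .thymine_anchor_energies
  ang <- .thymine_anchor_angles_deg * pi / 180
  r <- sqrt(vapply(tgt, `[`, 0, 1) / (0.5 * K))
  coords <- rbind(r * cos(ang), r * sin(ang))
  colnames(coords) <- names(tgt)
  # npi* diabat: full quadratic a + b1 x + b2 y + .5 c1 x^2 + .5 c2 y^2,
  # exact linear solve from its five anchor values
  p2pts <- coords[, c("S0_min", "S1_min", "S2_min", "X21", "X10_npi")]
  p2val <- c(4.56, 3.33, 3.50, 4.21, 3.90)
  A2 <- t(apply(p2pts, 2, function(q)
    c(1, q[1], q[2], 0.5 * q[1]^2, 0.5 * q[2]^2)))
  p2 <- solve(A2, p2val)
  # pipi* diabat: positive-definite quadratic with cross term; curvatures
  # c1, c2 fixed, (a, b1, b2, c12) solved exactly from its four anchors
  c1 <- 14; c2 <- 8
  p3pts <- coords[, c("S0_min", "S2_min", "X21", "X10_pipi")]
  p3val <- c(5.06, 4.18, 4.22, 3.82)
  A3 <- t(apply(p3pts, 2, function(q) c(1, q[1], q[2], q[1] * q[2])))
  rhs <- p3val - apply(p3pts, 2, function(q)
    0.5 * c1 * q[1]^2 + 0.5 * c2 * q[2]^2)
  p3 <- solve(A3, rhs)
  list(K = K, p2 = unname(p2), p3 = unname(p3), c1 = c1, c2 = c2,
       c12 = 0.005, c13 = 0.005, c23 = 0.03, coords = coords)
}

#' Three-state thymine-like model over stretch and puckering coordinates
#'
#' A two-coordinate (C4O-stretch-like `x`, ring-puckering-like `y`),
#' three-state diabatic model whose adiabatic energies at six anchor
#' configurations (ground-, first- and second-excited-state minima, the
#' S2/S1 intersection, and the two S1/S0 intersections) reproduce published
#' ADC(2) energies of thymine to better than 0.05 eV. Diabats are quadratic
#' surfaces (closed-shell ground, n-pi*, pi-pi*) with small constant
#' diabatic couplings; parameters are solved exactly from the anchor
#' energies at construction time.
#'
#' @return A [model_hamiltonian()] with an `anchors` table, an oscillator
#'   strength model (bright pi-pi* diabatic character) and a ring-geometry
#'   adapter mapping the puckering coordinate onto a boat-deformed
#'   six-membered ring.
#' @export
build_thymine_model <- function() {
  p <- .thymine_params()
  K <- p$K; p2 <- p$p2; p3 <- p$p3; c1 <- p$c1; c2 <- p$c2
  dia <- function(q) {
    x <- q[1]; y <- q[2]
    v1 <- 0.5 * K * (x^2 + y^2)
    v2 <- p2[1] + p2[2] * x + p2[3] * y + 0.5 * p2[4] * x^2 + 0.5 * p2[5] * y^2
    v3 <- p3[1] + p3[2] * x + p3[3] * y + 0.5 * c1 * x^2 + 0.5 * c2 * y^2 +
      p3[4] * x * y
    m <- diag(c(v1, v2, v3))
    m[1, 2] <- m[2, 1] <- p$c12
    m[1, 3] <- m[3, 1] <- p$c13
    m[2, 3] <- m[3, 2] <- p$c23
    m
  }
  ddia <- function(q) {
    x <- q[1]; y <- q[2]
    dx <- diag(c(K * x, p2[2] + p2[4] * x, p3[2] + c1 * x + p3[4] * y))
    dy <- diag(c(K * y, p2[3] + p2[5] * y, p3[3] + c2 * y + p3[4] * x))
    list(dx, dy)
  }
  anchors <- lapply(names(.thymine_anchor_energies), function(nm)
    list(coords = p$coords[, nm], energies = .thymine_anchor_energies[[nm]]))
  names(anchors) <- names(.thymine_anchor_energies)
  osc <- function(point) {
    # bright state = pipi* diabat (index 3); f proportional to the pipi*
    # weight of each adiabatic state, dark ground state
    f <- 0.2 * point$rotation[3, ]^2
    f[1] <- 0
    f
  }
  ring <- function(q) {
    # synthetic embedding of the puckering coordinate as a 3,6-boat
    # deformation of a regular six-ring; stretch coordinate tilts theta
    Q <- 0.9 * abs(q[2])
    theta <- 90 - 30 * tanh(q[1] - 0.29)
    phi <- if (q[2] >= 0) 120 else 300
    cremer_pople_inverse(Q, theta, phi)
  }
  model_hamiltonian(3, 2, dia, ddia, masses = c(12, 12),
                    labels = c("cs", "npi*", "pipi*"), name = "thymine3s",
                    anchors = anchors, oscillator = osc, ring_adapter = ring)
}

#' Two-state single avoided crossing (one coordinate)
#'
#' Two displaced harmonic diabats with a constant coupling, crossing once.
#' Useful as the minimal testbed for couplings and hopping statistics.
#'
#' @param k Diabat curvature (eV/A^2).
#' @param d Half displacement between the diabat minima (Angstrom).
#' @param e0 Energy offset of the second diabat (eV).
#' @param c Constant diabatic coupling (eV).
#' @param mass Reduced mass (amu).
#' @return A two-state [model_hamiltonian()].
#' @export
build_single_crossing <- function(k = 2, d = 0.5, e0 = 0, c = 0.1, mass = 12) {
  dia <- function(q) {
    x <- q[1]
    matrix(c(0.5 * k * (x + d)^2, c,
             c, 0.5 * k * (x - d)^2 + e0), 2, 2)
  }
  ddia <- function(q) {
    x <- q[1]
    list(matrix(c(k * (x + d), 0, 0, k * (x - d)), 2, 2))
  }
  osc <- function(point) c(0, 0.1 * point$rotation[2, 2]^2)
  model_hamiltonian(2, 1, dia, ddia, masses = mass,
                    labels = c("left", "right"), name = "single_crossing",
                    oscillator = osc)
}

#' Two-state double crossing (one coordinate)
#'
#' A wide harmonic diabat crossed twice by a narrower one offset in energy,
#' giving two symmetric avoided crossings.
#'
#' @inheritParams build_single_crossing
#' @param k2 Curvature of the upper, narrower diabat (eV/A^2); must be less
#'   than `k` for two crossings to exist.
#' @export
build_double_crossing <- function(k = 6, k2 = 1, e0 = 0.75, c = 0.05,
                                  mass = 12) {
  dia <- function(q) {
    x <- q[1]
    matrix(c(0.5 * k * x^2, c, c, 0.5 * k2 * x^2 + e0), 2, 2)
  }
  ddia <- function(q) {
    x <- q[1]
    list(matrix(c(k * x, 0, 0, k2 * x), 2, 2))
  }
  model_hamiltonian(2, 1, dia, ddia, masses = mass,
                    labels = c("lower", "upper"), name = "double_crossing")
}

#' Retrieve a built-in model by name
#'
#' @param name One of `"thymine3s"`, `"single_crossing"`, `"double_crossing"`.
#' @return A [model_hamiltonian()].
#' @export
get_model <- function(name) {
  switch(name,
         thymine3s = build_thymine_model(),
         single_crossing = build_single_crossing(),
         double_crossing = build_double_crossing(),
         stop("unknown model '", name, "'"))
}

#' Load a polynomial diabatic model from a YAML config file
#'
#' The config declares `n_states`, `n_coords`, `masses`, `labels` and a
#' `diabatic` block: a list of matrix entries, each with `i`, `j` and
#' `terms`, where every term is `[coefficient, power_coord1, power_coord2,
#' ...]`. Off-diagonal entries are symmetrized automatically.
#'
#' @param path Path to the YAML file.
#' @return A [model_hamiltonian()].
#' @export
model_from_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("n_states", "n_coords", "diabatic"))
    if (is.null(cfg[[f]])) stop("model config missing field '", f, "'")
  ns <- cfg$n_states; nc <- cfg$n_coords
  entries <- lapply(cfg$diabatic, function(e) {
    terms <- do.call(rbind, lapply(e$terms, as.numeric))
    if (ncol(terms) != nc + 1)
      stop("diabatic term for (", e$i, ",", e$j, ") needs ", nc + 1,
           " numbers per term")
    list(i = e$i, j = e$j, terms = terms)
  })
  dia <- function(q) {
    m <- matrix(0, ns, ns)
    for (e in entries) {
      v <- sum(apply(e$terms, 1, function(tr)
        tr[1] * prod(q^tr[-1])))
      m[e$i, e$j] <- m[e$i, e$j] + v
      if (e$i != e$j) m[e$j, e$i] <- m[e$j, e$i] + v
    }
    m
  }
  model_hamiltonian(ns, nc, dia,
                    masses = if (is.null(cfg$masses)) rep(12, nc)
                             else as.numeric(cfg$masses),
                    labels = if (is.null(cfg$labels))
                               paste0("state", seq_len(ns))
                             else as.character(cfg$labels),
                    name = if (is.null(cfg$name)) "config" else cfg$name)
}

#' Ground-state normal modes of a model
#'
#' Locates the minimum of an adiabatic surface (by quasi-Newton descent from
#' `start`), computes the mass-weighted Hessian by central differences and
#' returns the harmonic normal modes in the format consumed by
#' [wigner_sample()].
#'
#' @param model A [model_hamiltonian()].
#' @param state Adiabatic state index (1 = ground state).
#' @param start Starting coordinates for the minimum search.
#' @return A [normal_mode_set()].
#' @export
model_normal_modes <- function(model, state = 1,
                               start = rep(0, model$n_coords)) {
  energy <- function(q) evaluate_adiabatic(model, q,
                                           gradients = FALSE)$energies[state]
  opt <- stats::optim(start, energy, method = "BFGS",
                      control = list(reltol = 1e-14))
  q0 <- opt$par
  n <- model$n_coords
  h <- 1e-4
  hess <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    qpp <- q0; qpp[i] <- qpp[i] + h; qpp[j] <- qpp[j] + h
    qpm <- q0; qpm[i] <- qpm[i] + h; qpm[j] <- qpm[j] - h
    qmp <- q0; qmp[i] <- qmp[i] - h; qmp[j] <- qmp[j] + h
    qmm <- q0; qmm[i] <- qmm[i] - h; qmm[j] <- qmm[j] - h
    hess[i, j] <- hess[j, i] <-
      (energy(qpp) - energy(qpm) - energy(qmp) + energy(qmm)) / (4 * h^2)
  }
  # mass-weighted eigenproblem: omega^2 = eigvals of M^-1/2 H M^-1/2
  ms_ev <- model$masses * .amu_ev        # eV fs^2 / A^2
  mw <- diag(1 / sqrt(ms_ev), n)
  ee <- eigen(mw %*% hess %*% mw, symmetric = TRUE)
  ord <- order(ee$values)
  om2 <- ee$values[ord]
  if (any(om2 <= 0))
    stop("non-positive curvature at the located minimum of state ", state)
  omega <- sqrt(om2)                               # 1/fs
  disp <- mw %*% ee$vectors[, ord, drop = FALSE]   # plain-coordinate shapes
  disp <- apply(disp, 2, function(d) d / sqrt(sum(d^2)))
  disp <- matrix(disp, n)
  mu_amu <- colSums(disp^2 * model$masses)         # reduced mass per mode
  normal_mode_set(frequencies = omega / (2 * pi * .c_cm_fs),
                  masses = mu_amu, displacements = disp, equilibrium = q0)
}
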