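# Ensemble occupation statistics, sequential kinetic-model fitting,
# binomial confidence half-widths, and interpolated reaction paths.

#' Aggregate state occupations over a trajectory ensemble
#'
#' Fraction of trajectories in each adiabatic state on the common time
#' grid. Trajectories terminated by the S1/S0 gap criterion are counted in
#' the ground-state pool from their crossing time onward, so the fractions
#' sum to one at every time.
#'
#' @param ensemble An `fssh_ensemble` (see [run_ensemble()]).
#' @param t_grid Optional time grid (fs); defaults to the run's nuclear
#'   step grid up to `t_max`.
#' @return Object of class `occupation_series`: `time`, `fractions`
#'   (matrix, one column per state, `S0..`), `n_trajectories`.
#' @export
aggregate_occupations <- function(ensemble, t_grid = NULL) {
  trajs <- Filter(Negate(is.null), ensemble$trajectories)
  stopifnot(length(trajs) > 0)
  dt <- ensemble$settings$dt_nuclear
  if (is.null(t_grid))
    t_grid <- seq(0, ensemble$settings$t_max, by = dt)
  ns <- sum(startsWith(colnames(trajs[[1]]$log), "E"))
  counts <- matrix(0, length(t_grid), ns)
  for (tr in trajs) {
    tt <- tr$log[, "t"]
    act <- tr$log[, "active"]
    idx <- pmin(findInterval(t_grid, tt - dt / 2), length(tt))
    a <- act[pmax(idx, 1)]
    if (tr$termination$reason == "s1s0_gap") {
      after <- t_grid >= tr$termination$crossing_time
      a[after] <- 1
    } else {
      # past the end of a t_max trajectory nothing changes
      a[t_grid > tt[length(tt)] + dt / 2] <- act[length(act)]
    }
    for (s in seq_len(ns)) counts[, s] <- counts[, s] + (a == s)
  }
  frac <- counts / length(trajs)
  structure(list(time = t_grid, fractions = frac,
                 n_trajectories = length(trajs)),
            class = "occupation_series")
}

#' @export
print.occupation_series <- function(x, ...) {
  cat(sprintf("<occupation_series: %d trajectories, %d times (0..%g fs)>\n",
              x$n_trajectories, length(x$time), max(x$time)))
  fin <- x$fractions[nrow(x$fractions), ]
  cat("  final fractions:",
      paste(sprintf("S%d=%.2f", seq_along(fin) - 1, fin), collapse = " "),
      "\n")
  invisible(x)
}

#' Closed-form occupations of the sequential kinetic model
#'
#' The branching sequential model: a fraction `f21` of the initial S2
#' population decays to S1 with time constant `tau21` (the rest is trapped
#' in S2); of the total population, a fraction `f10 <= f21` continues to
#' the ground state with constant `tau10` (the S1 remainder is trapped).
#' With `k1 = 1/tau21`, `k2 = 1/tau10`:
#' `S2(t) = f21 exp(-k1 t) + (1 - f21)`,
#' `S1(t) = f10 k1 (exp(-k1 t) - exp(-k2 t)) / (k2 - k1)
#'          + (f21 - f10)(1 - exp(-k1 t))`,
#' `S0(t) = 1 - S1(t) - S2(t)`.
#'
#' @param t Time grid (fs).
#' @param f21,tau21 Fraction and time constant (fs) of the S2 -> S1 step.
#' @param f10,tau10 Fraction and time constant (fs) of the S1 -> S0 step.
#' @return Matrix with columns `S0`, `S1`, `S2`.
#' @export
occupations_sequential <- function(t, f21, tau21, f10, tau10) {
  k1 <- 1 / tau21; k2 <- 1 / tau10
  s2 <- f21 * exp(-k1 * t) + (1 - f21)
  flow <- if (abs(k2 - k1) < 1e-12)
    f10 * k1 * t * exp(-k1 * t)
  else
    f10 * k1 * (exp(-k1 * t) - exp(-k2 * t)) / (k2 - k1)
  s1 <- flow + (f21 - f10) * (1 - exp(-k1 * t))
  cbind(S0 = 1 - s1 - s2, S1 = s1, S2 = s2)
}

#' Fit the sequential kinetic model to state occupations
#'
#' Least-squares fit of [occupations_sequential()] to the S2, S1 and S0
#' occupation curves, returning the per-process fractions and time
#' constants (the Table-of-time-constants analog for an ensemble run).
#' Parameters are optimized as `(f21, log tau21, g = f10/f21, log tau10)`
#' with box constraints keeping the fractions in [0, 1].
#'
#' @param occ An [aggregate_occupations()] result, or any list with
#'   `time` and a 3-column `fractions` matrix (S0, S1, S2).
#' @param start Optional named starting values
#'   (`f21`, `tau21`, `f10`, `tau10`).
#' @param tau_max Upper bound for the time constants (fs); a fit hitting
#'   it is flagged unbounded and rejected.
#' @return Object of class `kinetic_fit` with fields `coefficients`
#'   (`f21`, `tau21`, `f10`, `tau10`), `residual_norm`, `fitted`,
#'   `data`, `rejected`, `covariance` (Gauss-Newton estimate).
#' @export
fit_sequential_model <- function(occ, start = NULL, tau_max = 1e5) {
  t <- occ$time
  fr <- occ$fractions
  stopifnot(ncol(fr) == 3)
  if (fr[length(t), 3] > fr[1, 3] - 1e-3) {
    res <- structure(list(coefficients = c(f21 = NA, tau21 = NA,
                                           f10 = NA, tau10 = NA),
                          rejected = TRUE,
                          reason = "S2 occupation does not decay"),
                     class = "kinetic_fit")
    warning("non-decaying S2 occupation; kinetic fit rejected")
    return(res)
  }
  colnames(fr) <- c("S0", "S1", "S2")
  obj <- function(p) {
    f21 <- p[1]; tau21 <- exp(p[2]); g <- p[3]; tau10 <- exp(p[4])
    pred <- occupations_sequential(t, f21, tau21, f21 * g, tau10)
    sum((pred - fr[, c("S0", "S1", "S2")])^2)
  }
  starts <- list()
  if (!is.null(start)) {
    starts[[1]] <- c(start[["f21"]], log(start[["tau21"]]),
                     min(start[["f10"]] / start[["f21"]], 1),
                     log(start[["tau10"]]))
  } else {
    # heuristic scale: time at which S2 has lost 63% of its decaying part,
    # bracketed by a deterministic multi-start grid (the least-squares
    # surface has local minima when the decay is far from exponential)
    s2 <- fr[, 3]
    plateau <- min(s2)
    drop1 <- 1 - (1 - plateau) * (1 - exp(-1))
    i1 <- which(s2 <= drop1)[1]
    tau0 <- if (is.na(i1)) max(t) / 3 else max(t[i1], 1)
    f0 <- max(1 - plateau, 0.1)
    for (m1 in c(0.3, 1, 3)) for (m2 in c(1, 3, 10))
      starts[[length(starts) + 1]] <-
        c(f0, log(tau0 * m1), 0.85, log(tau0 * m1 * m2))
  }
  opt <- NULL
  for (p0 in starts) {
    o <- stats::optim(p0, obj, method = "L-BFGS-B",
                      lower = c(0, log(1e-2), 0, log(1e-2)),
                      upper = c(1, log(tau_max), 1, log(tau_max)),
                      control = list(factr = 1e4, maxit = 500))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  cf <- c(f21 = unname(opt$par[1]), tau21 = exp(unname(opt$par[2])),
          f10 = unname(opt$par[1] * opt$par[3]),
          tau10 = exp(unname(opt$par[4])))
  rejected <- cf["tau21"] > 0.99 * tau_max || cf["tau10"] > 0.99 * tau_max
  if (rejected) warning("time constant hit its upper bound; fit rejected")
  pred <- occupations_sequential(t, cf["f21"], cf["tau21"],
                                 cf["f10"], cf["tau10"])
  # Gauss-Newton covariance on the natural parameters
  jac <- matrix(NA_real_, length(t) * 3, 4)
  hstep <- pmax(abs(cf) * 1e-5, 1e-8)
  for (k in 1:4) {
    cp <- cf; cp[k] <- cp[k] + hstep[k]
    cm <- cf; cm[k] <- cm[k] - hstep[k]
    jac[, k] <- (as.vector(occupations_sequential(
      t, cp["f21"], cp["tau21"], cp["f10"], cp["tau10"])) -
        as.vector(occupations_sequential(
          t, cm["f21"], cm["tau21"], cm["f10"], cm["tau10"]))) /
      (2 * hstep[k])
  }
  r <- as.vector(pred) - as.vector(fr[, c("S0", "S1", "S2")])
  s2hat <- sum(r^2) / max(length(r) - 4, 1)
  covm <- tryCatch(s2hat * solve(crossprod(jac)),
                   error = function(e) matrix(NA_real_, 4, 4))
  dimnames(covm) <- list(names(cf), names(cf))
  structure(list(coefficients = cf, residual_norm = sqrt(opt$value),
                 fitted = pred, data = list(time = t, fractions = fr),
                 rejected = rejected, covariance = covm,
                 convergence = opt$convergence),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (isTRUE(x$rejected)) {
    cat("<kinetic_fit: rejected (", x$reason %||% "bound hit", ")>\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat("Sequential kinetic fit:\n")
  cat(sprintf("  S2 -> S1: f = %.3f, tau = %.1f fs\n",
              cf["f21"], cf["tau21"]))
  cat(sprintf("  S1 -> S0: f = %.3f, tau = %.1f fs\n",
              cf["f10"], cf["tau10"]))
  cat(sprintf("  residual norm %.4g\n", x$residual_norm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
summary.kinetic_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$covariance), 0))
  out <- data.frame(estimate = object$coefficients, std_error = se)
  cat("Sequential kinetic model fit\n")
  print(out)
  invisible(out)
}

#' @export
predict.kinetic_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$data$time
  cf <- object$coefficients
  occupations_sequential(t, cf["f21"], cf["tau21"], cf["f10"], cf["tau10"])
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$fractions[, c("S0", "S1", "S2")] - object$fitted
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  t <- x$data$time
  graphics::matplot(t, x$data$fractions, pch = c(1, 2, 3), cex = 0.4,
                    col = c("grey40", "steelblue", "firebrick"),
                    xlab = "time (fs)", ylab = "occupation", ...)
  graphics::matlines(t, x$fitted, lty = 1,
                     col = c("grey40", "steelblue", "firebrick"))
  graphics::legend("right", c("S0", "S1", "S2"), lty = 1,
                   col = c("grey40", "steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Worst-case binomial confidence half-width for ensemble fractions
#'
#' The maximum over p of the normal-approximation half-width
#' `z * sqrt(p (1 - p) / n)`, attained at p = 1/2, in percentage points.
#' This is the maximum statistical uncertainty of any state-population
#' fraction estimated from `n` trajectories at the given confidence level.
#'
#' @param n Number of trajectories.
#' @param level Confidence level in (0, 1), e.g. 0.90.
#' @return Half-width in percent.
#' @export
confidence_halfwidth <- function(n, level) {
  stopifnot(n >= 1)
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("confidence level must be strictly between 0 and 1")
  z <- stats::qnorm((1 + level) / 2)
  100 * z * 0.5 / sqrt(n)
}

#' Simulate a stochastic trajectory ensemble from the sequential model
#'
#' Draws per-trajectory hop and decay times from the branching sequential
#' kinetics (Bernoulli branch + exponential waiting times) and aggregates
#' them on a time grid; used for parameter-recovery studies.
#'
#' @param n Number of trajectories.
#' @param t Time grid (fs).
#' @param f21,tau21,f10,tau10 Model parameters as in
#'   [occupations_sequential()].
#' @param seed Integer seed.
#' @return An `occupation_series`.
#' @export
simulate_sequential_ensemble <- function(n, t, f21, tau21, f10, tau10,
                                         seed = 1) {
  set.seed(seed)
  g <- f10 / f21
  hop21 <- ifelse(stats::runif(n) < f21, stats::rexp(n, 1 / tau21), Inf)
  hop10 <- hop21 + ifelse(stats::runif(n) < g,
                          stats::rexp(n, 1 / tau10), Inf)
  frac <- sapply(t, function(tt)
    c(S0 = mean(hop10 <= tt),
      S1 = mean(hop21 <= tt & hop10 > tt),
      S2 = mean(hop21 > tt)))
  structure(list(time = t, fractions = t(frac), n_trajectories = n),
            class = "occupation_series")
}

#' Mean and standard deviation of a bond distance over an ensemble
#'
#' @param trajs List of coordinate arrays: each trajectory a list with
#'   `time` and `frames` (list of `n_atoms x 3` matrices).
#' @param atom_pair Integer pair of atom indices.
#' @return Data frame `time`, `mean`, `sd` (population standard deviation,
#'   divide-by-n) over the trajectories surviving at each time.
#' @export
bond_distance_series <- function(trajs, atom_pair) {
  stopifnot(length(atom_pair) == 2)
  all_t <- sort(unique(unlist(lapply(trajs, `[[`, "time"))))
  out <- data.frame(time = all_t, mean = NA_real_, sd = NA_real_)
  for (k in seq_along(all_t)) {
    ds <- c()
    for (tr in trajs) {
      i <- match(all_t[k], tr$time)
      if (is.na(i)) next
      fr <- tr$frames[[i]]
      if (max(atom_pair) > nrow(fr))
        stop("atom index out of range for trajectory frame")
      ds <- c(ds, sqrt(sum((fr[atom_pair[1], ] - fr[atom_pair[2], ])^2)))
    }
    if (length(ds)) {
      out$mean[k] <- mean(ds)
      out$sd[k] <- sqrt(mean((ds - mean(ds))^2))
    }
  }
  out
}
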