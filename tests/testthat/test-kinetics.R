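test_that("occupation aggregation counts trajectories exactly", {
  # two synthetic trajectories, one hopping at 10 fs: fractions (1, 0)
  # before, (0.5, 0.5) after
  mk_traj <- function(hop_at) {
    tt <- seq(0, 20, 0.5)
    act <- ifelse(tt < hop_at, 2, 1)
    log <- cbind(t = tt, active = act, e_total = 0, E0 = 0, E1 = 1,
                 q1 = 0, pop0 = 0, pop1 = 1)
    structure(list(log = log, hops = data.frame(),
                   termination = list(reason = "t_max",
                                      crossing_time = NA_real_)),
              class = "fssh_trajectory")
  }
  ens <- structure(list(trajectories = list(mk_traj(Inf), mk_traj(10)),
                        settings = run_settings(t_max = 20)),
                   class = "fssh_ensemble")
  occ <- aggregate_occupations(ens)
  i5 <- which(occ$time == 5)
  i15 <- which(occ$time == 15)
  expect_equal(occ$fractions[i5, ], c(0, 1))
  expect_equal(occ$fractions[i15, ], c(0.5, 0.5))
  expect_true(all(abs(rowSums(occ$fractions) - 1) < 1e-12))
})

test_that("aggregated fractions match a brute-force recount of the raw logs", {
  m <- build_thymine_model()
  ic <- sample_initial_conditions(m, 8, seed = 3)
  ens <- run_ensemble(m, ic, run_settings(seed = 4, t_max = 120))
  occ <- aggregate_occupations(ens)
  trajs <- Filter(Negate(is.null), ens$trajectories)
  for (tq in c(0, 30.5, 60, 119.5)) {
    i <- which(abs(occ$time - tq) < 1e-9)
    counts <- numeric(3)
    for (tr in trajs) {
      gap_terminated <- tr$termination$reason == "s1s0_gap"
      if (gap_terminated && tq >= tr$termination$crossing_time) {
        counts[1] <- counts[1] + 1
      } else {
        k <- which.min(abs(tr$log[, "t"] - tq))
        counts[tr$log[k, "active"]] <- counts[tr$log[k, "active"]] + 1
      }
    }
    expect_equal(occ$fractions[i, ], counts / length(trajs))
  }
})

test_that("the closed-form sequential model conserves population and nests the single exponential", {
  t <- seq(0, 2000, 1)
  occ <- occupations_sequential(t, 0.84, 253, 0.70, 391)
  expect_true(all(abs(rowSums(occ) - 1) < 1e-12))
  expect_true(all(occ >= -1e-12 & occ <= 1 + 1e-12))
  # f21 = 1, f10 = 0 reduces S2 to a plain exponential decay
  occ2 <- occupations_sequential(t, 1, 300, 0, 391)
  expect_equal(occ2[, "S2"], exp(-t / 300), tolerance = 1e-12)
})

test_that("noise-free parameters are recovered to a tenth of a percent", {
  t <- seq(0, 1000, 0.5)
  occ <- list(time = t,
              fractions = occupations_sequential(t, 0.84, 253, 0.70, 391))
  fit <- fit_sequential_model(occ)
  cf <- coef(fit)
  expect_lt(abs(cf["f21"] - 0.84) / 0.84, 1e-3)
  expect_lt(abs(cf["tau21"] - 253) / 253, 1e-3)
  expect_lt(abs(cf["f10"] - 0.70) / 0.70, 1e-3)
  expect_lt(abs(cf["tau10"] - 391) / 391, 1e-3)
  expect_false(fit$rejected)
})

test_that("the kinetic fit is scale consistent and rejects non-decaying input", {
  t <- seq(0, 1000, 0.5)
  occ <- list(time = t,
              fractions = occupations_sequential(t, 0.8, 200, 0.6, 350))
  fit1 <- fit_sequential_model(occ)
  occ2 <- list(time = 3 * t, fractions = occ$fractions)
  fit2 <- fit_sequential_model(occ2)
  expect_equal(coef(fit2)["tau21"], 3 * coef(fit1)["tau21"],
               tolerance = 1e-3)
  expect_equal(coef(fit2)["tau10"], 3 * coef(fit1)["tau10"],
               tolerance = 1e-3)
  flat <- list(time = t, fractions = cbind(S0 = rep(0, length(t)),
                                           S1 = 0, S2 = 1))
  expect_warning(bad <- fit_sequential_model(flat), "non-decaying")
  expect_true(bad$rejected)
})

test_that("stochastic ensembles recover the decay constant within sampling error", {
  t <- seq(0, 1000, 2)
  errs <- vapply(1:20, function(s) {
    so <- simulate_sequential_ensemble(115, t, 0.84, 253, 0.70, 391,
                                       seed = 400 + s)
    f <- suppressWarnings(fit_sequential_model(so))
    abs(coef(f)["tau21"] - 253) / 253
  }, 0)
  expect_lt(stats::median(errs), 0.15)
})

test_that("kinetic_fit behaves like a model object", {
  t <- seq(0, 800, 1)
  occ <- list(time = t,
              fractions = occupations_sequential(t, 0.84, 253, 0.70, 391))
  fit <- fit_sequential_model(occ)
  expect_named(coef(fit), c("f21", "tau21", "f10", "tau10"))
  pr <- predict(fit, t = c(0, 100))
  expect_equal(dim(pr), c(2, 3))
  expect_equal(unname(pr[1, "S2"]), 1)
  expect_lt(max(abs(residuals(fit))), 1e-4)
  expect_output(print(fit), "tau")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("confidence half-width matches the printed worst case and its Monte-Carlo oracle", {
  expect_equal(confidence_halfwidth(115, 0.90), 7.7, tolerance = 0.05)
  expect_equal(round(confidence_halfwidth(115, 0.90)), 8)
  # sqrt(n) law
  expect_equal(confidence_halfwidth(4 * 115, 0.90),
               confidence_halfwidth(115, 0.90) / 2, tolerance = 1e-12)
  # monotone in n and in level
  expect_true(confidence_halfwidth(200, 0.9) < confidence_halfwidth(100, 0.9))
  expect_true(confidence_halfwidth(115, 0.95) > confidence_halfwidth(115, 0.9))
  expect_error(confidence_halfwidth(115, 1.2), "level")
  # Monte-Carlo oracle: worst-case (p = 1/2) binomial CI half-width
  set.seed(31)
  phat <- stats::rbinom(2e5, 115, 0.5) / 115
  mc <- stats::quantile(abs(phat - 0.5), 0.90) * 100
  expect_lt(abs(confidence_halfwidth(115, 0.90) - mc), 0.4)
})

test_that("interpolated paths hit the endpoints and preserve untouched internals", {
  set.seed(17)
  a <- matrix(stats::rnorm(12), 4, 3)
  b <- matrix(stats::rnorm(12), 4, 3)
  p2 <- liic_path(a, b, n_images = 2, coords = "cartesian")
  expect_equal(p2[[1]], a); expect_equal(p2[[2]], b)
  p3 <- liic_path(a, b, n_images = 3, coords = "cartesian")
  expect_equal(p3[[2]], (a + b) / 2)
  # internal mode: pure torsion change leaves all bond lengths fixed
  ga <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.3, 0), c(3.4, 1.5, 0.4))
  ia <- hopdyn:::.chain_internals(ga)
  ib <- ia; ib$torsions <- ia$torsions + 2.5
  gb <- hopdyn:::.chain_rebuild(ib, 4)
  path <- liic_path(ga, gb, n_images = 8, coords = "internal")
  expect_identical(attr(path, "coords"), "internal")
  for (img in path) {
    ints <- hopdyn:::.chain_internals(img)
    expect_equal(ints$bonds, ia$bonds, tolerance = 1e-8)
    expect_equal(ints$angles, ia$angles, tolerance = 1e-8)
  }
  # endpoints reproduce the input shapes (up to rigid motion; image 1 exactly)
  expect_equal(path[[1]], ga, tolerance = 1e-8)
  dlast <- as.matrix(dist(path[[8]])) - as.matrix(dist(gb))
  expect_lt(max(abs(dlast)), 1e-8)
  bad <- matrix(0, 3, 3)
  expect_error(liic_path(a, bad), "atom counts")
})

test_that("bond distance series averages with the population convention", {
  tr1 <- list(time = c(0, 1), frames = list(
    rbind(c(0, 0, 0), c(1, 0, 0)), rbind(c(0, 0, 0), c(1, 0, 0))))
  tr2 <- list(time = c(0, 1), frames = list(
    rbind(c(0, 0, 0), c(1.2, 0, 0)), rbind(c(0, 0, 0), c(1.2, 0, 0))))
  bd <- bond_distance_series(list(tr1, tr2), c(1, 2))
  expect_equal(bd$mean, c(1.1, 1.1))
  expect_equal(bd$sd, c(0.1, 0.1))
  single <- bond_distance_series(list(tr1), c(1, 2))
  expect_equal(single$sd, c(0, 0))
  expect_error(bond_distance_series(list(tr1), c(1, 5)), "atom index")
})
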