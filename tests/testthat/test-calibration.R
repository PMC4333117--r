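# A deterministic stand-in simulator: diffusion responds smoothly to the
# one interaction entry it probes. Used to test the objective and search
# machinery in isolation from the stochastic engine.
mock_simulator <- function(composition, model) {
  x <- model$w_lo["PC", "PC"]
  list(D_lo = exp(-4 * x) * (0.2 + composition[["PC"]]),
       D_ho = 0.01, phase = "Ld")
}

mock_data <- function(x_true = -0.22, alpha = 2) {
  comps <- data.frame(CH = c(0.1, 0.3), PC = c(0.8, 0.4), SM = c(0.1, 0.3))
  rows <- lapply(seq_len(nrow(comps)), function(m) {
    comp <- lipid_composition(comps$CH[m], comps$PC[m], comps$SM[m])
    meas <- mock_simulator(comp, apply_params(energy_model(),
                                              c(w_lo.PC.PC = x_true)))
    data.frame(CH = comp[["CH"]], PC = comp[["PC"]], SM = comp[["SM"]],
               phase = meas$phase, D_lo = alpha * meas$D_lo,
               D_ho = alpha * meas$D_ho)
  })
  do.call(rbind, rows)
}

test_that("the default model satisfies the calibration constraint", {
  expect_true(check_constraints(energy_model())$pass)
  # zeroing the CH-SM ho attraction violates it: 2*0 + 0.70 + 0.80 > 0
  broken <- apply_params(energy_model(), c(w_ho.CH.SM = 0))
  res <- check_constraints(broken)
  expect_false(res$pass)
  expect_match(res$violated, "CH and SM")
  expect_true(check_constraints(broken, constraints = list())$pass)
})

test_that("parameter overrides keep the matrices symmetric", {
  m <- apply_params(energy_model(), c(w_ho.CH.SM = -2, j.PC.lo.SM = 0.7))
  expect_equal(m$w_ho["CH", "SM"], -2)
  expect_equal(m$w_ho["SM", "CH"], -2)
  expect_equal(unname(m$j["PC", "lo", "SM"]), 0.7)
  expect_equal(unname(m$j["SM", "lo", "PC"]), 0.7)
  expect_error(apply_params(energy_model(), c(nonsense.CH = 1)), "unknown")
})

test_that("the objective is invariant where it should be", {
  dat <- mock_data()
  obj <- calibration_objective(energy_model(), dat, mock_simulator)
  # permuting the dataset changes nothing
  obj_perm <- calibration_objective(energy_model(), dat[c(2, 1), ],
                                    mock_simulator)
  expect_equal(obj$epsilon, obj_perm$epsilon)
  # rescaling all measured D is absorbed by alpha; the epsilon landscape
  # scales uniformly, so the minimizing parameter cannot move
  dat10 <- dat
  dat10$D_lo <- dat10$D_lo * 10
  dat10$D_ho <- dat10$D_ho * 10
  xs <- seq(-0.5, 0.1, by = 0.1)
  eps1 <- sapply(xs, function(x) calibration_objective(
    apply_params(energy_model(), c(w_lo.PC.PC = x)), dat, mock_simulator)$epsilon)
  eps10 <- sapply(xs, function(x) calibration_objective(
    apply_params(energy_model(), c(w_lo.PC.PC = x)), dat10, mock_simulator)$epsilon)
  expect_equal(which.min(eps1), which.min(eps10))
  expect_equal(eps10, 100 * eps1, tolerance = 1e-9)
  obj10 <- calibration_objective(energy_model(), dat10, mock_simulator)
  expect_equal(obj10$alpha, 10 * obj$alpha, tolerance = 1e-9)
})

test_that("hypercube refinement recovers analytic minima", {
  quad <- function(par) (par[["x"]] - 0.3)^2
  res <- hypercube_search(quad, c(x = -1), c(x = 1), rounds = 6)
  expect_lt(abs(res$par[["x"]] - 0.3), res$cell[["x"]] + 1e-12)

  two <- function(par) (par[["x"]] - 0.2)^2 + (par[["y"]] + 0.4)^2
  res2 <- hypercube_search(two, c(x = -1, y = -1), c(x = 1, y = 1),
                           rounds = 6)
  expect_lt(abs(res2$par[["x"]] - 0.2), res2$cell[["x"]] + 1e-12)
  expect_lt(abs(res2$par[["y"]] + 0.4), res2$cell[["y"]] + 1e-12)

  # constraints restrict the feasible set
  feas <- function(par) par[["x"]] >= 0.5
  res3 <- hypercube_search(quad, c(x = -1), c(x = 1), rounds = 5,
                           feasible = feas)
  expect_gte(res3$par[["x"]], 0.5)
  expect_lt(res3$par[["x"]], 0.55)

  # flat objective: deterministic lexicographic tie-break
  flat <- function(par) 0
  res4 <- hypercube_search(flat, c(x = -1, y = 2), c(x = 1, y = 3),
                           rounds = 2)
  expect_equal(unname(res4$par), c(-1, 2))

  expect_error(hypercube_search(quad, c(x = -1), c(x = 1),
                                feasible = function(p) FALSE),
               "no feasible point")
})

test_that("fitting the mock data recovers the generating parameter", {
  dat <- mock_data(x_true = -0.22)
  fit <- fit_interaction_matrices(dat, lower = c(w_lo.PC.PC = -0.6),
                                  upper = c(w_lo.PC.PC = 0.2),
                                  simulator = mock_simulator, rounds = 6)
  expect_lt(abs(fit$par[["w_lo.PC.PC"]] + 0.22), fit$cell + 1e-12)
  expect_lt(fit$epsilon, 1e-4)
  expect_equal(fit$alpha, 2, tolerance = 0.05)
})

test_that("ordering fits match simulated phase labels", {
  simr <- calibration_simulator(seed = 31L)
  comps <- data.frame(CH = c(0.00, 0.50, 0.378),
                      PC = c(1.00, 0.04, 0.465),
                      SM = c(0.00, 0.46, 0.157))
  dat <- synthetic_calibration_data(comps, simulator = simr, seed = 17)
  # pure PC sits at the 90% lo boundary, so accept Ld or biphasic there;
  # the CH/SM-rich membrane must be Lo and the physiological one biphasic
  expect_true(dat$phase[1] %in% c("Ld", "biphasic"))
  expect_equal(dat$phase[2], "Lo")
  expect_equal(dat$phase[3], "biphasic")

  fit <- fit_ordering_matrix(dat, lower = c(j.PC.lo.PC = 0.6),
                             upper = c(j.PC.lo.PC = 1.2),
                             simulator = calibration_simulator(seed = 31L),
                             rounds = 2)
  expect_equal(fit$matched, 3)

  # contradictory labels cannot all be matched, and must not crash
  bad <- dat[c(1, 1), ]
  bad$phase <- c("Ld", "Lo")
  fit2 <- fit_ordering_matrix(bad, lower = c(j.PC.lo.PC = 0.6),
                              upper = c(j.PC.lo.PC = 1.2),
                              simulator = calibration_simulator(seed = 31L),
                              rounds = 1)
  expect_lte(fit2$matched, 1)
})
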