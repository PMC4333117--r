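# Calibration: recover energy parameters from (composition, phase,
# diffusion) records via the constrained hypercube-refinement search, with
# the shipped defaults as the reference point. The experimental reference
# data are vesicle (GUV) measurements; a synthetic generator emulates such a
# dataset from the simulator itself for parameter-recovery testing.

#' Simulator for calibration measurements
#'
#' Builds a function `f(composition, model)` that simulates a membrane of
#' the given composition to stationarity, tracks displacements, and returns
#' the per-phase diffusion coefficients and the phase label. Evaluations use
#' a fixed seed (common random numbers) so parameter searches see a smooth
#' objective.
#'
#' @param nrows,ncols Lattice dimensions (calibration runs are deliberately
#'   small).
#' @param control Base [sim_control()].
#' @param z_cycles Tracking horizon (cycles) for the MSD estimate; kept
#'   short because the ordering states fluctuate in equilibrium and a
#'   phase-restricted record is dropped at its first state change.
#' @param max_cycles Equilibration cap.
#' @param min_records Minimum valid records per phase for a D estimate.
#' @param seed Base seed; each composition derives its own fixed stream
#'   from it.
#' @return Function `(composition, model) -> list(D_lo, D_ho, phase)` with
#'   `NA` for phases with too few valid walkers.
#' @export
calibration_simulator <- function(nrows = 20, ncols = 20,
                                  control = sim_control(log_every = 1L),
                                  z_cycles = 4L, max_cycles = 40L,
                                  min_records = 15L, seed = 1L) {
  force(control)
  function(composition, model) {
    ctrl <- control
    # seed derived from the composition: repeated evaluations of the same
    # composition share their random numbers, so parameter searches see a
    # smooth objective
    ctrl$seed <- as.integer((seed +
      round(1e4 * (composition[[1]] * 97 + composition[[2]] * 31 +
                   composition[[3]]))) %% 2147483L)
    ctrl$max_cycles <- as.integer(max_cycles)
    lat <- build_lattice(nrows, ncols, composition, seed = ctrl$seed)
    sim <- suppressWarnings(
      simulate_membrane(lat, model, ctrl, stop = "stationary"))
    tracked <- track_displacements(sim$lattice, z_cycles, model, ctrl)
    d_of <- function(phase) {
      tryCatch(diffusion_coefficient(tracked, phase,
                                     min_records = min_records)$D,
               error = function(e) NA_real_)
    }
    list(D_lo = d_of("lo"), D_ho = d_of("ho"),
         phase = classify_phase(sim$lattice))
  }
}

#' Generate a synthetic calibration dataset
#'
#' Emulates a table of vesicle measurements: for each composition the
#' simulator (at the given, "true" model parameters) provides per-phase
#' diffusion coefficients and a phase label; diffusion values are scaled by
#' a fixed `alpha_true` (the unknown experiment/simulation time-scale
#' factor) and perturbed by multiplicative Gaussian noise.
#'
#' @param compositions Data frame (or list) with columns `CH`, `PC`, `SM`
#'   of mole fractions.
#' @param model The generating [energy_model()].
#' @param simulator A [calibration_simulator()].
#' @param alpha_true Scale applied to simulated D ("experimental units").
#' @param noise_sd Relative (multiplicative) noise standard deviation.
#' @param seed Seed for the noise.
#' @return Data frame with columns `CH`, `PC`, `SM`, `phase`, `D_lo`,
#'   `D_ho` (NA where a phase is absent).
#' @export
synthetic_calibration_data <- function(compositions,
                                       model = energy_model(),
                                       simulator = calibration_simulator(),
                                       alpha_true = 2.5, noise_sd = 0.05,
                                       seed = 1L) {
  compositions <- as.data.frame(compositions)
  set.seed(seed)
  rows <- lapply(seq_len(nrow(compositions)), function(m) {
    comp <- lipid_composition(compositions$CH[m], compositions$PC[m],
                              compositions$SM[m])
    meas <- simulator(comp, model)
    noisy <- function(d) {
      if (!is.finite(d)) return(NA_real_)
      alpha_true * d * (1 + stats::rnorm(1, 0, noise_sd))
    }
    data.frame(CH = comp[["CH"]], PC = comp[["PC"]], SM = comp[["SM"]],
               phase = meas$phase, D_lo = noisy(meas$D_lo),
               D_ho = noisy(meas$D_ho))
  })
  do.call(rbind, rows)
}

#' Apply named parameter overrides to an energy model
#'
#' Parameter names address single entries: `"w_ho.CH.SM"` or
#' `"w_lo.PC.PC"` set (symmetrically) an interaction entry,
#' `"j.PC.lo.PC"` an ordering coupling (mirrored to the species-exchanged
#' entry at the same state, matching the structure of the default matrix).
#'
#' @param model Base [energy_model()].
#' @param params Named numeric vector of overrides.
#' @param symmetrize_j Mirror j overrides to the species-exchanged entry?
#' @return Modified `energy_model`.
#' @export
apply_params <- function(model, params, symmetrize_j = TRUE) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    val <- as.numeric(params[[nm]])
    if (parts[1] %in% c("w_ho", "w_lo")) {
      stopifnot(length(parts) == 3)
      m <- model[[parts[1]]]
      m[parts[2], parts[3]] <- val
      m[parts[3], parts[2]] <- val
      model[[parts[1]]] <- m
    } else if (parts[1] == "j") {
      stopifnot(length(parts) == 4)
      model$j[parts[2], parts[3], parts[4]] <- val
      if (symmetrize_j) model$j[parts[4], parts[3], parts[2]] <- val
    } else stop("unknown parameter: ", nm)
  }
  model
}

#' Check mixing constraints on an energy model
#'
#' Evaluates sign constraints of the form "species X and Y mix (or de-mix)
#' in state sigma" via [mixing_tendency()]. The default constraint set is
#' the single condition used in the original calibration: CH and SM must mix
#' in the ho state.
#'
#' @param model An [energy_model()].
#' @param constraints List of constraints, each
#'   `list(x =, y =, state =, sign =)` with `sign = -1` requiring mixing
#'   (tendency < 0) and `sign = +1` de-mixing (> 0).
#' @return List: `pass` (logical), `violated` (character descriptions).
#' @export
check_constraints <- function(model,
                              constraints = list(list(x = "CH", y = "SM",
                                                      state = "ho",
                                                      sign = -1))) {
  violated <- character(0)
  for (cn in constraints) {
    val <- mixing_tendency(cn$x, cn$y, cn$state, model)
    if (!(val * cn$sign > 0)) {
      want <- if (cn$sign < 0) "mix" else "de-mix"
      violated <- c(violated, sprintf("%s and %s must %s in %s (got %+.3f)",
                                      cn$x, cn$y, want, cn$state, val))
    }
  }
  list(pass = length(violated) == 0, violated = violated)
}

#' Calibration objective epsilon
#'
#' Runs the simulator for every composition of the dataset, pairs the
#' simulated per-phase diffusion coefficients with the measured ones, fits
#' the shared scale factor alpha by least squares and returns the residual
#' `epsilon = sum (D_exp - alpha * D_sim)^2`.
#'
#' @param model Candidate [energy_model()].
#' @param data Calibration data frame (see
#'   [synthetic_calibration_data()]).
#' @param simulator A [calibration_simulator()] (or drop-in function).
#' @return List: `epsilon`, `alpha`, `n` (paired values), `phase_match`
#'   (simulated phase labels equal to the recorded ones, count), `missing`
#'   (measured values the candidate model produced no simulated phase for;
#'   any such value makes `epsilon` infinite).
#' @export
calibration_objective <- function(model, data,
                                  simulator = calibration_simulator()) {
  stopifnot(nrow(data) >= 1)
  D_exp <- c(); D_sim <- c(); match_n <- 0L; missing_n <- 0L
  for (m in seq_len(nrow(data))) {
    comp <- lipid_composition(data$CH[m], data$PC[m], data$SM[m])
    meas <- simulator(comp, model)
    if (identical(meas$phase, data$phase[m])) match_n <- match_n + 1L
    for (ph in c("D_lo", "D_ho")) {
      if (is.finite(data[[ph]][m])) {
        if (is.finite(meas[[ph]])) {
          D_exp <- c(D_exp, data[[ph]][m])
          D_sim <- c(D_sim, meas[[ph]])
        } else {
          # the candidate model fails to reproduce a measured phase at all;
          # an infinite residual keeps objectives comparable across models
          missing_n <- missing_n + 1L
        }
      }
    }
  }
  if (missing_n > 0)
    return(list(epsilon = Inf, alpha = NA_real_,
                n = length(D_sim), phase_match = match_n,
                missing = missing_n))
  if (!length(D_sim)) stop("no overlapping diffusion measurements")
  fit <- alpha_scaling(D_exp, D_sim)
  list(epsilon = fit$epsilon, alpha = fit$alpha, n = fit$n,
       phase_match = match_n, missing = 0L)
}

#' Hypercube-refinement search
#'
#' Minimizes `fn(params)` over a box by evaluating a full grid
#' (`n_grid` points per axis), keeping the best feasible point, shrinking
#' the box around it by `shrink` and repeating -- a discretized downhill
#' search. Infeasible points (per `feasible`) are skipped; ties break by the
#' lexicographically smallest parameter vector.
#'
#' @param fn Objective `function(params)` returning a scalar (smaller is
#'   better).
#' @param lower,upper Named numeric bounds (same names).
#' @param n_grid Grid points per axis and round.
#' @param shrink Box shrink factor per round, in (0, 1).
#' @param rounds Number of refinement rounds.
#' @param feasible Optional `function(params)` returning TRUE/FALSE.
#' @return List: `par` (best parameters), `value`, `cell` (final grid
#'   spacing per axis), `history` (per-round best), `n_eval`.
#' @export
hypercube_search <- function(fn, lower, upper, n_grid = 3, shrink = 0.5,
                             rounds = 4, feasible = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower),
            !is.null(names(lower)), identical(names(lower), names(upper)),
            n_grid >= 2, shrink > 0, shrink < 1, rounds >= 1)
  k <- length(lower)
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  lo <- lower; hi <- upper
  best_par <- NULL; best_val <- Inf
  history <- list(); n_eval <- 0L
  for (round in seq_len(rounds)) {
    axes <- lapply(seq_len(k), function(d) seq(lo[d], hi[d],
                                               length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    colnames(grid) <- names(lower)
    for (row in seq_len(nrow(grid))) {
      par <- grid[row, ]
      if (!is.null(feasible) && !isTRUE(feasible(par))) next
      val <- fn(par)
      n_eval <- n_eval + 1L
      better <- val < best_val ||
        (val == best_val && !is.null(best_par) && lex_less(par, best_par))
      if (better) { best_val <- val; best_par <- par }
    }
    if (is.null(best_par))
      stop("no feasible point in the search hypercube")
    history[[round]] <- list(par = best_par, value = best_val,
                             width = hi - lo)
    w <- (hi - lo) * shrink / 2
    lo <- pmax(lower, best_par - w)
    hi <- pmin(upper, best_par + w)
  }
  cell <- (hi - lo) / (n_grid - 1)
  list(par = best_par, value = best_val, cell = cell, history = history,
       n_eval = n_eval)
}

#' Fit interaction matrices to diffusion data
#'
#' Constrained hypercube-refinement fit of selected interaction-energy
#' entries: minimizes the [calibration_objective()] epsilon subject to
#' [check_constraints()].
#'
#' @param data Calibration data frame.
#' @param lower,upper Named bounds for the free parameters (names as in
#'   [apply_params()], e.g. `"w_lo.PC.PC"`).
#' @param model0 Base model supplying all non-free entries.
#' @param simulator A [calibration_simulator()].
#' @param constraints Constraint list for [check_constraints()].
#' @param ... Passed to [hypercube_search()] (`n_grid`, `shrink`, `rounds`).
#' @return List: `model` (fitted), `par`, `epsilon`, `alpha`, `cell`,
#'   `search` (full search record).
#' @export
fit_interaction_matrices <- function(data, lower, upper,
                                     model0 = energy_model(),
                                     simulator = calibration_simulator(),
                                     constraints = NULL, ...) {
  if (is.null(constraints))
    constraints <- list(list(x = "CH", y = "SM", state = "ho", sign = -1))
  fn <- function(par) {
    m <- apply_params(model0, par)
    calibration_objective(m, data, simulator)$epsilon
  }
  feas <- function(par)
    check_constraints(apply_params(model0, par), constraints)$pass
  res <- hypercube_search(fn, lower, upper, feasible = feas, ...)
  fitted <- apply_params(model0, res$par)
  obj <- calibration_objective(fitted, data, simulator)
  list(model = fitted, par = res$par, epsilon = obj$epsilon,
       alpha = obj$alpha, cell = res$cell, search = res)
}

#' Fit ordering couplings to phase labels
#'
#' Chooses the free ordering-coupling parameters maximizing the number of
#' compositions whose simulated phase label (Lo / Ld / biphasic) matches the
#' recorded one.
#'
#' @inheritParams fit_interaction_matrices
#' @param lower,upper Named bounds for free j entries (e.g. `"j.PC.lo.PC"`).
#' @return List: `model`, `par`, `matched` (matching composition count),
#'   `cell`, `search`.
#' @export
fit_ordering_matrix <- function(data, lower, upper,
                                model0 = energy_model(),
                                simulator = calibration_simulator(), ...) {
  fn <- function(par) {
    m <- apply_params(model0, par)
    matched <- 0L
    for (i in seq_len(nrow(data))) {
      comp <- lipid_composition(data$CH[i], data$PC[i], data$SM[i])
      meas <- simulator(comp, m)
      if (identical(meas$phase, data$phase[i])) matched <- matched + 1L
    }
    -matched
  }
  res <- hypercube_search(fn, lower, upper, ...)
  list(model = apply_params(model0, res$par), par = res$par,
       matched = -res$value, cell = res$cell, search = res)
}
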