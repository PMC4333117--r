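# Two-step stochastic engine: Gillespie kinetic Monte Carlo over neighbor
# swaps alternating with Metropolis relaxation of the ordering states.

#' Simulation control parameters
#'
#' @param n_W Mean number of lattice position changes per lipid in one swap
#'   phase; realized as `ceiling(n_W * N / 2)` executed swaps (each swap
#'   relocates two lipids).
#' @param n_J Ordering-state update proposals per site in one Metropolis
#'   phase (proposal sites drawn independently and uniformly).
#' @param seed Integer RNG seed for the engine stream.
#' @param a_nm Lattice constant (nearest-neighbor lipid spacing) in nm; with
#'   `D_ref` it maps simulation time to physical time.
#' @param D_ref_um2_s Reference lateral diffusion coefficient of the
#'   liquid-disordered phase in um^2/s: physical time is scaled so that the
#'   simulated Ld diffusion coefficient equals `D_ref_um2_s`. The default
#'   2.5 um^2/s is a typical vesicle-measured Ld value for
#'   cholesterol-containing ternary mixtures.
#' @param max_cycles Safety cap on the number of two-step cycles.
#' @param log_every Clock-log granularity in cycles (the final cycle is
#'   always logged; stationarity runs log every cycle).
#' @param swap_events Elementary event set of the swap phase: `"all"`
#'   neighbor pairs, or `"hetero"` (pairs of unlike species only; swapping
#'   two identical lipids leaves the configuration unchanged, so excluding
#'   those events only rescales the event clock).
#' @param stat_tol,stat_window Stationarity detection: the run is stationary
#'   when the lo fraction, the six species-pair contact frequencies and the
#'   windowed diffusion estimate all change by less than `stat_tol`
#'   (relative) between two consecutive windows of `stat_window` cycles.
#' @return List of class `sim_control`.
#' @export
sim_control <- function(n_W = 10L, n_J = 100L, seed = 1L, a_nm = 0.8,
                        D_ref_um2_s = 2.5, max_cycles = 200000L,
                        stat_tol = 0.01, stat_window = 10L,
                        log_every = 10L,
                        swap_events = c("all", "hetero")) {
  swap_events <- match.arg(swap_events)
  stopifnot(n_W >= 1, n_J >= 1, a_nm > 0, D_ref_um2_s > 0, max_cycles >= 0,
            stat_tol > 0, stat_window >= 1, log_every >= 1)
  structure(list(n_W = as.integer(n_W), n_J = as.integer(n_J),
                 seed = as.integer(seed), a_nm = a_nm,
                 D_ref_um2_s = D_ref_um2_s,
                 max_cycles = as.integer(max_cycles),
                 stat_tol = stat_tol, stat_window = as.integer(stat_window),
                 log_every = as.integer(log_every),
                 swap_events = swap_events),
            class = "sim_control")
}

hetero_only <- function(control) identical(control$swap_events, "hetero")

#' Swap rate of an adjacent lipid pair
#'
#' `r(i, k) = exp(beta * (w_i + w_k))` where `w_i` is the interaction energy
#' of site `i` with its six neighbors in the *current* configuration (the
#' rate does not look at the post-swap energies).
#'
#' @param lattice A `lipid_lattice`.
#' @param i,k Adjacent site indices.
#' @param model An [energy_model()].
#' @return Positive rate (simulation time units).
#' @export
switch_rate <- function(lattice, i, k, model = energy_model()) {
  i <- check_site(lattice, i)
  k <- check_site(lattice, k)
  if (!(k %in% site_neighbors(lattice, i)))
    stop("sites ", i, " and ", k, " are not neighbors")
  exp(model$beta * (site_energy(lattice, i, model) +
                    site_energy(lattice, k, model)))
}

#' Total swap rate of the lattice
#'
#' Sum of `r(i, k)` over all unordered neighbor pairs; the Gillespie waiting
#' time is exponential with this rate.
#'
#' @inheritParams switch_rate
#' @return Scalar total rate.
#' @export
total_switch_rate <- function(lattice, model = energy_model()) {
  fl <- flatten_model(model)
  as.numeric(cpp_edge_rates_total(lattice$species, lattice$state,
                                  lattice$nrows, lattice$ncols, fl$pair36,
                                  model$beta))
}

#' Run one Gillespie swap phase
#'
#' Executes `n_swaps` kinetic Monte Carlo events: waiting times are drawn
#' from the exponential distribution of the total rate and swaps are chosen
#' with probability proportional to their rates. Ordering states are frozen
#' during the phase. With `record = TRUE` the executed swaps `(i, k)` and
#' waiting times are returned (meant for small systems).
#'
#' @param lattice A `lipid_lattice`.
#' @param n_swaps Number of swap events to execute.
#' @param model An [energy_model()].
#' @param seed Integer seed.
#' @param record Record per-event details?
#' @return List: `lattice` (updated), `t_sim` (elapsed simulation time),
#'   `displacement` (per-lipid axial displacement, columns `du`, `dv`),
#'   `lipid_at` (site -> lipid id), `r_tot` (total swap rate of the final
#'   configuration, maintained incrementally), and if recorded `steps`
#'   (matrix with columns `i`, `k`, `dt`).
#' @export
interaction_phase <- function(lattice, n_swaps, model = energy_model(),
                              seed = 1L, record = FALSE) {
  fl <- flatten_model(model)
  res <- cpp_interaction_phase(lattice$species, lattice$state, lattice$nrows,
                               lattice$ncols, fl$pair36, model$beta,
                               n_swaps, seed, record)
  out_lat <- new_lattice(lattice$nrows, lattice$ncols, res$species,
                         lattice$state)
  steps <- if (record) {
    colnames(res$steps) <- c("i", "k", "dt")
    res$steps
  } else NULL
  list(lattice = out_lat, t_sim = res$t_sim,
       displacement = cbind(du = res$du, dv = res$dv),
       lipid_at = res$lipid_at, r_tot = res$r_tot, steps = steps)
}

#' Run one Metropolis ordering-relaxation phase
#'
#' Proposes `n_J * N` single-site state flips at uniformly random sites.
#' A flip is accepted with probability 1 if it does not increase the
#' ordering energy J and with probability `exp(-beta * delta J)` otherwise.
#' Species are untouched.
#'
#' @param lattice A `lipid_lattice`.
#' @param n_J Proposals per site.
#' @param model An [energy_model()].
#' @param seed Integer seed.
#' @return List: `lattice` (updated states), `accepted` (accepted flips).
#' @export
metropolis_phase <- function(lattice, n_J = 100L, model = energy_model(),
                             seed = 1L) {
  fl <- flatten_model(model)
  res <- cpp_metropolis(lattice$species, lattice$state, lattice$nrows,
                        lattice$ncols, fl$j18, model$beta,
                        as.numeric(n_J) * n_sites(lattice), seed,
                        spin_product(model))
  list(lattice = new_lattice(lattice$nrows, lattice$ncols, lattice$species,
                             res$spin),
       accepted = res$accepted)
}

#' Map simulation time to physical time
#'
#' The model clock is fixed to physical units by requiring the simulated
#' liquid-disordered diffusion coefficient to equal a reference experimental
#' value: `t_real = t_sim * a^2 * D_sim / D_ref` with the lattice constant
#' `a` converting lattice units to length.
#'
#' @param t_sim Simulation time.
#' @param D_sim Dimensionless Ld diffusion coefficient measured in the
#'   simulation (lattice units^2 per simulation time); must be positive.
#' @param a_nm Lattice constant in nm.
#' @param D_ref_um2_s Reference Ld diffusion coefficient in um^2/s.
#' @return Physical time in seconds.
#' @export
map_time <- function(t_sim, D_sim, a_nm = 0.8, D_ref_um2_s = 2.5) {
  if (any(D_sim <= 0)) stop("D_sim must be positive (no mobility measured)")
  t_sim * (a_nm * 1e-3)^2 * D_sim / D_ref_um2_s
}

#' Simulate membrane self-organization
#'
#' Runs the two-step scheme: the ordering states are initialized (randomly,
#' by default) and relaxed by an initial Metropolis phase for the given
#' random lipid distribution, followed by alternating swap
#' phases (`n_W` position changes per lipid on average) and Metropolis phases
#' (`n_J` update proposals per site), until either the physical life-time
#' `tau_ms` is reached or, with `stop = "stationary"`, the lattice statistics
#' (lo fraction, species-pair contact frequencies, windowed diffusion
#' estimate) stop changing.
#'
#' Physical time advances per cycle by `a^2 * MSD_cycle / (4 * D_ref)`, where
#' `MSD_cycle` is the mean squared displacement accrued during the swap phase
#' by lipids in the liquid-disordered phase at both ends of the phase (all
#' lipids if fewer than 30 qualify).
#'
#' @param lattice A `lipid_lattice` (typically from [build_lattice()]).
#' @param model An [energy_model()].
#' @param control A [sim_control()].
#' @param tau_ms Life-time to simulate, in milliseconds (`tau_ms = 0`
#'   returns the initial relaxed lattice). Ignored for
#'   `stop = "stationary"`.
#' @param stop Stop condition: `"lifetime"` or `"stationary"`.
#' @param init_states Initial ordering states before the first relaxation:
#'   `"random"` (uniform, the default -- required for the cooperative
#'   spin-product ordering energy, whose uniform configurations are
#'   metastable), `"keep"` (use the states in `lattice`, e.g. to continue a
#'   run), or `"lo"` (all liquid-disordered).
#' @return Object of class `membrane_sim`: `lattice` (final), `clock`
#'   (per-cycle data frame: `cycle`, `t_sim`, `t_real`, `dt_sim`, `dmsd`,
#'   `lo_fraction`, `W`, `J`), `cycles`, `t_sim`, `t_real_ms`, `stationary`,
#'   `capped`, `displacement` (per-lipid unwrapped axial displacement),
#'   `lipid_at`, plus the model and control used.
#' @examples
#' lat <- build_lattice(20, 20, lipid_composition(0.378, 0.465, 0.157))
#' sim <- simulate_membrane(lat, tau_ms = 0.01,
#'                          control = sim_control(seed = 7))
#' sim$lattice
#' @export
simulate_membrane <- function(lattice, model = energy_model(),
                              control = sim_control(), tau_ms = 1,
                              stop = c("lifetime", "stationary"),
                              init_states = c("random", "keep", "lo")) {
  stop <- match.arg(stop)
  init_states <- match.arg(init_states)
  n <- n_sites(lattice)
  if (init_states == "random") {
    set.seed(control$seed + 211L)
    lattice$state <- sample(c(-1L, 1L), n, replace = TRUE)
  } else if (init_states == "lo") {
    lattice$state <- rep.int(1L, n)
  }
  if (stop == "lifetime" && (!is.numeric(tau_ms) || tau_ms < 0))
    stop("tau_ms must be non-negative")
  fl <- flatten_model(model)
  tau_s <- if (stop == "lifetime") tau_ms * 1e-3 else -1
  res <- cpp_simulate(lattice$species, lattice$state, lattice$nrows,
                      lattice$ncols, fl$pair36, fl$j18, model$beta,
                      control$n_J, control$n_W, tau_s, control$a_nm,
                      control$D_ref_um2_s, control$seed, control$max_cycles,
                      stop == "stationary", control$stat_tol,
                      control$stat_window, TRUE, spin_product(model),
                      control$log_every, hetero_only(control))
  if (res$capped)
    warning("simulation hit max_cycles = ", control$max_cycles,
            " before the stop condition")
  clock <- as.data.frame(res$log)
  structure(list(lattice = new_lattice(lattice$nrows, lattice$ncols,
                                       res$species, res$spin),
                 clock = clock, cycles = res$cycles, t_sim = res$t_sim,
                 t_real_ms = res$t_real * 1e3, stationary = res$stationary,
                 capped = res$capped,
                 displacement = cbind(du = res$du, dv = res$dv),
                 lipid_at = res$lipid_at,
                 model = model, control = control, tau_ms = tau_ms,
                 stop = stop),
            class = "membrane_sim")
}

#' @export
print.membrane_sim <- function(x, ...) {
  cat(sprintf(
    "membrane_sim: %d cycles, t_sim = %.3g, t_real = %.4g ms%s\n",
    x$cycles, x$t_sim, x$t_real_ms,
    if (x$stationary) " (stationary)" else ""))
  print(x$lattice)
  invisible(x)
}
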