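# Observables: phase-restricted MSD and diffusion, scale-factor fitting,
# phase classification, domain statistics.

#' Track tagged-lipid displacements
#'
#' Continues a simulation from the supplied configuration for `z_cycles`
#' further two-step cycles, with every lipid tagged at the start. Unwrapped
#' displacements are accumulated across the periodic boundaries; a record is
#' invalidated the first time the ordering state of the occupied site differs
#' from the lipid's initial state (checked at every phase boundary), i.e.
#' the lipid crossed a phase border.
#'
#' @param lattice A `lipid_lattice`, normally an equilibrated/stationary
#'   configuration (tagging a non-stationary lattice simply measures the
#'   transient).
#' @param z_cycles Number of cycles to track over.
#' @param model An [energy_model()].
#' @param control A [sim_control()] (provides `n_W`, `n_J`, the seed).
#' @return List of class `displacement_records`: `records` data frame
#'   (per lipid: `species`, `init_state` spin, `du`, `dv`, `disp2`,
#'   `valid`), `t_sim` (elapsed simulation time), `series` (per-cycle MSD of
#'   the still-valid lo/ho cohorts), and the final `lattice`.
#' @export
track_displacements <- function(lattice, z_cycles, model = energy_model(),
                                control = sim_control()) {
  stopifnot(z_cycles >= 0)
  fl <- flatten_model(model)
  res <- cpp_track(lattice$species, lattice$state, lattice$nrows,
                   lattice$ncols, fl$pair36, fl$j18, model$beta,
                   control$n_J, control$n_W, control$seed, z_cycles,
                   spin_product(model), hetero_only(control))
  records <- data.frame(species = lipid_species()[res$lipid_species],
                        init_state = res$init_spin, du = res$du, dv = res$dv,
                        disp2 = res$disp2, valid = res$valid == 1L)
  structure(list(records = records, t_sim = res$t_sim,
                 series = as.data.frame(res$series),
                 lattice = new_lattice(lattice$nrows, lattice$ncols,
                                       res$species, res$spin)),
            class = "displacement_records")
}

#' Phase-restricted diffusion coefficient
#'
#' Estimates `D = <dx^2> / (4 t)` from the valid displacement records whose
#' (constant) ordering state matches `phase`. Time is the Gillespie clock;
#' physical conversion is the job of [map_time()].
#'
#' @param tracked A `displacement_records` object from
#'   [track_displacements()].
#' @param phase `"lo"` or `"ho"` (optionally a species to restrict to).
#' @param species Optional species restriction (`"CH"`, `"PC"`, `"SM"`).
#' @param min_records Minimum number of valid records required.
#' @return List: `D` (lattice units^2 per simulation time), `n` records
#'   used, `se` (standard error of D from the spread of `dx^2`).
#' @export
diffusion_coefficient <- function(tracked, phase = c("lo", "ho"),
                                  species = NULL, min_records = 30L) {
  phase <- match.arg(phase)
  spin <- if (phase == "lo") 1L else -1L
  rec <- tracked$records
  keep <- rec$valid & rec$init_state == spin
  if (!is.null(species)) keep <- keep & rec$species == species
  d2 <- rec$disp2[keep]
  if (length(d2) < min_records)
    stop("only ", length(d2), " valid records in phase ", phase,
         " (need >= ", min_records, ")")
  t <- tracked$t_sim
  list(D = mean(d2) / (4 * t), n = length(d2),
       se = sd(d2) / sqrt(length(d2)) / (4 * t))
}

#' Least-squares scale between measured and simulated diffusion
#'
#' Fits the single scale factor `alpha` minimizing
#' `epsilon = sum_m (D_exp_m - alpha * D_sim_m)^2`, i.e.
#' `alpha = sum(D_exp * D_sim) / sum(D_sim^2)`. One shared alpha converts the
#' simulation time scale to the experimental one across all compositions and
#' both phases.
#'
#' @param D_exp,D_sim Equal-length paired vectors (NA pairs dropped).
#' @return List: `alpha`, `epsilon` (residual at the optimum), `n` pairs.
#' @export
alpha_scaling <- function(D_exp, D_sim) {
  stopifnot(length(D_exp) == length(D_sim))
  keep <- is.finite(D_exp) & is.finite(D_sim)
  D_exp <- D_exp[keep]; D_sim <- D_sim[keep]
  if (!length(D_sim) || all(D_sim == 0))
    stop("need at least one nonzero simulated diffusion coefficient")
  alpha <- sum(D_exp * D_sim) / sum(D_sim^2)
  list(alpha = alpha, epsilon = sum((D_exp - alpha * D_sim)^2),
       n = length(D_sim))
}

#' Classify the phase state of a lattice
#'
#' More than 90% of lipids in the lo state: monophasic liquid-disordered
#' (`"Ld"`); more than 90% in the ho state: monophasic liquid-ordered
#' (`"Lo"`); more than 10% in each: `"biphasic"`.
#'
#' @param lattice A `lipid_lattice`.
#' @return One of `"Lo"`, `"Ld"`, `"biphasic"`.
#' @export
classify_phase <- function(lattice) {
  lo_share <- mean(lattice$state > 0)
  if (lo_share > 0.9) "Ld" else if (lo_share < 0.1) "Lo" else "biphasic"
}

#' Domain statistics of a lattice
#'
#' Connected components of constant ordering state under the periodic
#' 6-neighbor adjacency, with their sizes and compositions, plus the global
#' species-pair contact counts (each undirected lattice edge counted once).
#'
#' @param lattice A `lipid_lattice`.
#' @return List: `domains` data frame (`id`, `state` spin, `size`, `CH`,
#'   `PC`, `SM` counts), `contacts` symmetric 3x3 matrix of species-pair
#'   contact counts.
#' @export
domain_statistics <- function(lattice) {
  lab <- cpp_label_domains(lattice$state, lattice$nrows, lattice$ncols)
  size <- tabulate(lab)
  ids <- seq_along(size)
  state <- lattice$state[match(ids, lab)]
  comp <- matrix(0L, length(ids), 3, dimnames = list(NULL, lipid_species()))
  for (s in 1:3) {
    t <- tabulate(lab[lattice$species == s], nbins = length(ids))
    comp[, s] <- t
  }
  up <- cpp_contact_counts(lattice$species, lattice$nrows, lattice$ncols)
  contacts <- up + t(up) - diag(diag(up))
  dimnames(contacts) <- list(lipid_species(), lipid_species())
  list(domains = data.frame(id = ids, state = state, size = size, comp),
       contacts = contacts)
}
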