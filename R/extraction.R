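# Bile-secretion analysis: bile salts can solubilize hexagonal membrane
# patches that lie entirely inside liquid-disordered (lo-state) regions.
# From the extractable patch placements follow the extractable membrane
# fraction (EMF), the lipid secretion rate LSR(r) = n_patch * n_lipids / tau
# and the predicted bile composition.

#' Extractable hexagonal patch placements
#'
#' Finds every center whose full hexagonal patch of radius `r` lies in
#' lo-state sites ("fully embedded in an Ld nanodomain"). Placements may
#' overlap.
#'
#' @param lattice A `lipid_lattice`.
#' @param r Hexagonal patch radius (graph distance; patch holds
#'   `3 r^2 + 3 r + 1` lipids).
#' @return List of class `patch_placements`: `centers` (site indices of
#'   valid placements), `r`, `n_lipids` (patch size), `covered` (logical per
#'   site: lies under at least one placement), `pooled` (species counts
#'   pooled over all placements, named CH/PC/SM).
#' @export
extractable_patches <- function(lattice, r) {
  if (r < 0 || r != round(r)) stop("r must be a non-negative integer")
  if (2 * r + 1 > min(lattice$nrows, lattice$ncols))
    stop("patch of radius ", r, " does not fit into the lattice")
  off <- hex_offsets(r)
  res <- cpp_patch_scan(lattice$species, lattice$state, lattice$nrows,
                        lattice$ncols, off)
  structure(list(centers = which(res$valid), r = as.integer(r),
                 n_lipids = hex_patch_size(r), covered = res$covered,
                 pooled = setNames(as.numeric(res$pooled), lipid_species()),
                 nrows = lattice$nrows, ncols = lattice$ncols),
            class = "patch_placements")
}

#' Extractable membrane fraction
#'
#' Fraction of the membrane covered by at least one extractable patch of
#' radius `r`.
#'
#' @inheritParams extractable_patches
#' @return Fraction in `[0, 1]`.
#' @export
emf <- function(lattice, r) {
  p <- extractable_patches(lattice, r)
  sum(p$covered) / n_sites(lattice)
}

#' Count disjoint extractable patches
#'
#' Number of patches of radius `r` that can be cut out of the Ld regions
#' simultaneously: valid placements are accepted in randomized order,
#' skipping any that overlap an accepted one (randomized greedy disjoint
#' packing), and the count is averaged over `n_orderings` orders. For
#' `r = 0` this is simply the number of lo sites.
#'
#' @inheritParams extractable_patches
#' @param n_orderings Number of random acceptance orders to average over.
#' @param seed Integer seed for the orderings.
#' @return List: `n_patch` (mean disjoint count), `counts` (per ordering),
#'   `n_placements` (overlapping placement count).
#' @export
count_patches <- function(lattice, r, n_orderings = 8L, seed = 1L) {
  p <- extractable_patches(lattice, r)
  if (length(p$centers) == 0)
    return(list(n_patch = 0, counts = integer(n_orderings), n_placements = 0))
  if (r == 0)
    return(list(n_patch = length(p$centers),
                counts = rep(length(p$centers), n_orderings),
                n_placements = length(p$centers)))
  counts <- cpp_greedy_pack(p$centers - 1L, lattice$nrows, lattice$ncols,
                            hex_offsets(r), n_orderings, seed)
  list(n_patch = mean(counts), counts = counts,
       n_placements = length(p$centers))
}

#' Lipid secretion rate
#'
#' `LSR(r) = n_patch(r) * n_lipids(r) / tau`: the relative lipid flux into
#' the bile carried by patches of radius `r`, for nanodomain life-time
#' `tau`.
#'
#' @inheritParams count_patches
#' @param tau_ms Nanodomain life-time in milliseconds (must be positive).
#' @return Secretion rate (lipids per ms, arbitrary overall scale).
#' @export
lsr <- function(lattice, r, tau_ms, n_orderings = 8L, seed = 1L) {
  if (tau_ms <= 0) stop("tau_ms must be positive")
  np <- count_patches(lattice, r, n_orderings, seed)
  np$n_patch * hex_patch_size(r) / tau_ms
}

#' Bile composition predicted from extractable patches
#'
#' The bile inherits the average lipid composition of all extractable
#' patches (overlapping placements all contribute).
#'
#' @param placements A `patch_placements` object, or a `lipid_lattice`
#'   (with `r` supplied).
#' @param r Patch radius when a lattice is given.
#' @return Named mole-fraction vector (CH, PC, SM), or all-`NA` with a
#'   warning when there is no extractable placement.
#' @export
bile_composition <- function(placements, r = NULL) {
  if (inherits(placements, "lipid_lattice")) {
    stopifnot(!is.null(r))
    placements <- extractable_patches(placements, r)
  }
  tot <- sum(placements$pooled)
  if (tot == 0) {
    warning("no extractable placements; bile composition undefined")
    return(setNames(rep(NA_real_, 3), lipid_species()))
  }
  placements$pooled / tot
}

#' Patch-extraction report for one lattice
#'
#' Per-radius summary of the extraction analysis: placement counts, disjoint
#' patch count, EMF, LSR and bile composition.
#'
#' @param lattice A `lipid_lattice`.
#' @param radii Integer vector of patch radii.
#' @param tau_ms Nanodomain life-time in ms (for the LSR).
#' @param n_orderings,seed Passed to [count_patches()].
#' @return Data frame with one row per radius: `r`, `n_lipids`,
#'   `n_placements`, `n_patch`, `emf`, `lsr`, `CH`, `PC`, `SM`
#'   (bile mole fractions, NA when nothing is extractable).
#' @export
patch_report <- function(lattice, radii, tau_ms, n_orderings = 8L,
                         seed = 1L) {
  rows <- lapply(radii, function(r) {
    p <- extractable_patches(lattice, r)
    cp <- count_patches(lattice, r, n_orderings, seed)
    comp <- if (sum(p$pooled) > 0) p$pooled / sum(p$pooled)
            else setNames(rep(NA_real_, 3), lipid_species())
    data.frame(r = r, n_lipids = hex_patch_size(r),
               n_placements = length(p$centers), n_patch = cp$n_patch,
               emf = sum(p$covered) / n_sites(lattice),
               lsr = cp$n_patch * hex_patch_size(r) / tau_ms,
               CH = comp[["CH"]], PC = comp[["PC"]], SM = comp[["SM"]])
  })
  do.call(rbind, rows)
}

#' Simulate and report bile extraction across seeds
#'
#' Convenience wrapper reproducing the bile-composition analysis: simulates
#' the given membrane composition to life-time `tau_ms` for each seed and
#' reports per-radius means and standard deviations across seeds.
#'
#' @param composition A [lipid_composition()].
#' @param tau_ms Life-time in ms (also used in the LSR).
#' @param radii Patch radii to analyze.
#' @param seeds Integer vector of seeds (one simulation each).
#' @param nrows,ncols Lattice dimensions.
#' @param model An [energy_model()].
#' @param control Base [sim_control()]; its seed is replaced per run.
#' @return List: `table` (per-radius summary: means of `n_patch`, `emf`,
#'   `lsr` and bile fractions `CH`, `PC`, `SM` with `sd_*` across seeds),
#'   `runs` (per-seed patch reports), `sims` (per-seed `membrane_sim`
#'   objects, only if `keep_sims`).
#' @param keep_sims Keep the simulation objects?
#' @export
bile_table <- function(composition, tau_ms = 1, radii = c(0, 3, 7),
                       seeds = 1:10, nrows = 100, ncols = 100,
                       model = energy_model(), control = sim_control(),
                       keep_sims = FALSE) {
  runs <- list()
  sims <- list()
  for (idx in seq_along(seeds)) {
    ctrl <- control
    ctrl$seed <- as.integer(seeds[idx])
    lat <- build_lattice(nrows, ncols, composition, seed = ctrl$seed)
    sim <- simulate_membrane(lat, model, ctrl, tau_ms = tau_ms)
    rep_i <- patch_report(sim$lattice, radii, tau_ms,
                          seed = ctrl$seed)
    rep_i$seed <- seeds[idx]
    runs[[idx]] <- rep_i
    if (keep_sims) sims[[idx]] <- sim
  }
  all <- do.call(rbind, runs)
  agg <- lapply(split(all, all$r), function(d) {
    data.frame(r = d$r[1], n_lipids = d$n_lipids[1],
               n_patch = mean(d$n_patch), sd_n_patch = sd(d$n_patch),
               emf = mean(d$emf), sd_emf = sd(d$emf),
               lsr = mean(d$lsr), sd_lsr = sd(d$lsr),
               CH = mean(d$CH, na.rm = TRUE), sd_CH = sd(d$CH, na.rm = TRUE),
               PC = mean(d$PC, na.rm = TRUE), sd_PC = sd(d$PC, na.rm = TRUE),
               SM = mean(d$SM, na.rm = TRUE), sd_SM = sd(d$SM, na.rm = TRUE))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$r), ]
  rownames(out) <- NULL
  list(table = out, runs = runs, sims = if (keep_sims) sims)
}

#' Composition scan of the extraction analysis
#'
#' Varies the membrane content of one species along a grid while holding the
#' ratio of the other two fixed, simulates each grid point to life-time
#' `tau_ms`, and reports the extraction observables per patch radius,
#' including the extractable cholesterol flux `flux_CH = LSR * CH fraction`.
#'
#' @param axis `"CH"` (vary cholesterol at fixed PC:SM ratio) or `"PC"`
#'   (vary phosphatidylcholine at fixed CH:SM ratio).
#' @param grid_pct Grid of membrane contents for `axis`, in percent.
#' @param ratio Length-2 numeric ratio of the two remaining species, in the
#'   order they appear in CH, PC, SM with `axis` removed (e.g. for
#'   `axis = "CH"`, `c(3, 1)` means PC:SM = 3:1).
#' @param tau_ms Life-time in ms.
#' @param radii Patch radii.
#' @param seeds Seeds (replicate simulations per grid point).
#' @param nrows,ncols Lattice dimensions.
#' @param model,control See [simulate_membrane()].
#' @return Data frame of class `composition_scan`: one row per
#'   (grid value, seed, radius) with extraction observables and the phase
#'   label of the simulated lattice.
#' @export
composition_scan <- function(axis = c("CH", "PC"), grid_pct, ratio,
                             tau_ms = 1, radii = c(0, 7, 14), seeds = 1L,
                             nrows = 100, ncols = 100,
                             model = energy_model(),
                             control = sim_control()) {
  axis <- match.arg(axis)
  stopifnot(length(ratio) == 2, all(ratio >= 0), sum(ratio) > 0)
  ratio <- ratio / sum(ratio)
  rows <- list()
  for (g in grid_pct) {
    x <- g / 100
    if (x < 0 || x > 1) stop("grid values must lie in [0, 100] percent")
    comp <- if (axis == "CH")
      lipid_composition(x, (1 - x) * ratio[1], (1 - x) * ratio[2])
    else
      lipid_composition((1 - x) * ratio[1], x, (1 - x) * ratio[2])
    for (s in seeds) {
      ctrl <- control
      ctrl$seed <- as.integer(s)
      lat <- build_lattice(nrows, ncols, comp, seed = ctrl$seed)
      sim <- simulate_membrane(lat, model, ctrl, tau_ms = tau_ms)
      rep_i <- patch_report(sim$lattice, radii, tau_ms, seed = ctrl$seed)
      rep_i$axis_pct <- g
      rep_i$seed <- s
      rep_i$phase <- classify_phase(sim$lattice)
      rows[[length(rows) + 1]] <- rep_i
    }
  }
  out <- do.call(rbind, rows)
  out$flux_CH <- out$lsr * ifelse(is.na(out$CH), 0, out$CH)
  class(out) <- c("composition_scan", "data.frame")
  out
}

#' Extraction threshold of a composition scan
#'
#' Smallest grid value at which extraction of radius-`r` patches still
#' occurs, i.e. at which the mean disjoint patch count across seeds is at
#' least 1 ("extraction ceases" below it).
#'
#' @param scan A [composition_scan()] result.
#' @param r Patch radius.
#' @return Grid value in percent (NA if extraction never occurs).
#' @export
scan_threshold <- function(scan, r) {
  d <- scan[scan$r == r, ]
  m <- tapply(d$n_patch, d$axis_pct, mean)
  ok <- as.numeric(names(m))[m >= 1]
  if (length(ok)) min(ok) else NA_real_
}

#' Flux optimum of a composition scan
#'
#' Grid value maximizing the mean extractable cholesterol flux
#' (`LSR * CH fraction of extractable patches`) for radius-`r` patches.
#'
#' @inheritParams scan_threshold
#' @return Grid value in percent.
#' @export
scan_flux_peak <- function(scan, r) {
  d <- scan[scan$r == r, ]
  m <- tapply(d$flux_CH, d$axis_pct, mean)
  as.numeric(names(m))[which.max(m)]
}
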