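# Periodic triangular lattice: geometry, occupancy, patch enumeration.
#
# The lattice is a rhombic grid in axial coordinates: row u, column v
# (1-based in R). Site (u, v) sits at Cartesian position
# ((v - 1) + (u - 1)/2, (u - 1) * sqrt(3)/2) in units of the
# nearest-neighbor distance, and its six neighbors are
# (u, v +- 1), (u +- 1, v), (u - 1, v + 1), (u + 1, v - 1),
# wrapped periodically in both directions.

#' Ternary lipid composition
#'
#' Validates a set of mole fractions for the three membrane lipid species.
#'
#' @param CH,PC,SM Mole fractions (each in `[0, 1]`, summing to 1 within
#'   `1e-9`).
#' @return Named numeric vector of class `lipid_composition`.
#' @examples
#' lipid_composition(0.378, 0.465, 0.157)
#' @export
lipid_composition <- function(CH, PC, SM) {
  x <- c(CH = CH, PC = PC, SM = SM)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("mole fractions must lie in [0, 1]")
  if (abs(sum(x) - 1) > 1e-9)
    stop("mole fractions must sum to 1 (got ", format(sum(x), digits = 12), ")")
  structure(x, class = "lipid_composition")
}

# Largest-remainder apportionment of N sites to the mole fractions:
# deterministic and sum-exact. Ties broken by species order.
largest_remainder_counts <- function(composition, n_sites) {
  exact <- as.numeric(composition) * n_sites
  counts <- floor(exact)
  short <- n_sites - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Build a lattice with random lipid placement
#'
#' Creates an `nrows` x `ncols` periodic triangular lattice, assigns species
#' counts by largest-remainder rounding of the composition, places them by a
#' seeded uniform random permutation, and initializes every site in the lo
#' ordering state (the ordering states are meant to be relaxed by
#' [metropolis_phase()] or [simulate_membrane()] before any analysis).
#'
#' @param nrows,ncols Lattice dimensions, both at least 3 so the
#'   6-neighborhood has no self-neighbors.
#' @param composition A [lipid_composition()] (or coercible numeric vector).
#' @param seed Integer seed for the placement permutation.
#' @return Object of class `lipid_lattice`: list with `nrows`, `ncols`,
#'   `species` (integer codes 1 = CH, 2 = PC, 3 = SM per site) and `state`
#'   (spin per site: +1 = lo, -1 = ho). Sites are indexed row-major:
#'   site `i` is row `(i - 1) %/% ncols + 1`, column `(i - 1) %% ncols + 1`.
#' @examples
#' lat <- build_lattice(10, 10, lipid_composition(1/3, 1/3, 1/3), seed = 1)
#' table(lat$species)
#' @export
build_lattice <- function(nrows, ncols, composition, seed = 1L) {
  if (nrows < 3 || ncols < 3)
    stop("nrows and ncols must both be >= 3")
  if (!inherits(composition, "lipid_composition"))
    composition <- lipid_composition(composition[[1]], composition[[2]],
                                     composition[[3]])
  n <- as.integer(nrows * ncols)
  counts <- largest_remainder_counts(composition, n)
  species <- rep.int(1:3, counts)
  set.seed(seed)
  species <- species[sample.int(n)]
  new_lattice(nrows, ncols, species, rep.int(1L, n))
}

new_lattice <- function(nrows, ncols, species, state) {
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 species = as.integer(species), state = as.integer(state)),
            class = "lipid_lattice")
}

n_sites <- function(lattice) lattice$nrows * lattice$ncols

#' @export
print.lipid_lattice <- function(x, ...) {
  n <- n_sites(x)
  cnt <- tabulate(x$species, 3)
  cat(sprintf("lipid_lattice: %d x %d (%d sites)\n", x$nrows, x$ncols, n))
  cat(sprintf("  composition: CH %.1f%%, PC %.1f%%, SM %.1f%%\n",
              100 * cnt[1] / n, 100 * cnt[2] / n, 100 * cnt[3] / n))
  cat(sprintf("  lo fraction: %.3f\n", mean(x$state > 0)))
  invisible(x)
}

check_site <- function(lattice, i) {
  if (any(i < 1 | i > n_sites(lattice)))
    stop("site index out of range")
  as.integer(i)
}

# axial (u, v) of 1-based site indices (also 1-based)
site_axial <- function(lattice, i) {
  cbind(u = (i - 1L) %/% lattice$ncols + 1L,
        v = (i - 1L) %% lattice$ncols + 1L)
}

axial_site <- function(lattice, u, v) {
  u <- (u - 1L) %% lattice$nrows
  v <- (v - 1L) %% lattice$ncols
  unname(u * lattice$ncols + v + 1L)
}

#' Six neighbors of a lattice site
#'
#' @param lattice A `lipid_lattice`.
#' @param i Site index (1-based).
#' @return Integer vector of the 6 distinct neighbor site indices, wrapped
#'   periodically. The relation is symmetric.
#' @export
site_neighbors <- function(lattice, i) {
  i <- check_site(lattice, i)
  uv <- site_axial(lattice, i)
  du <- c(0L, 0L, -1L, 1L, -1L, 1L)
  dv <- c(-1L, 1L, 0L, 0L, 1L, -1L)
  axial_site(lattice, uv[, "u"] + du, uv[, "v"] + dv)
}

# N x 6 neighbor matrix (row i = neighbors of site i)
neighbor_matrix <- function(lattice) {
  i <- seq_len(n_sites(lattice))
  uv <- site_axial(lattice, i)
  du <- c(0L, 0L, -1L, 1L, -1L, 1L)
  dv <- c(-1L, 1L, 0L, 0L, 1L, -1L)
  out <- matrix(0L, n_sites(lattice), 6)
  for (d in 1:6)
    out[, d] <- axial_site(lattice, uv[, "u"] + du[d], uv[, "v"] + dv[d])
  out
}

#' Cartesian position of a lattice site
#'
#' Positions use the fundamental (unwrapped) domain: rows are offset by half
#' a lattice unit and spaced by sqrt(3)/2, so all neighbor distances equal 1.
#'
#' @param lattice A `lipid_lattice`.
#' @param i Site index (may be a vector).
#' @return Numeric matrix with columns `x`, `y` (lattice units).
#' @export
site_position <- function(lattice, i) {
  i <- check_site(lattice, i)
  uv <- site_axial(lattice, i)
  cbind(x = (uv[, "v"] - 1) + (uv[, "u"] - 1) / 2,
        y = (uv[, "u"] - 1) * sqrt(3) / 2)
}

#' Number of lipids in a hexagonal patch
#'
#' A patch of hexagonal graph-distance radius `r` contains the centered
#' hexagonal number `3 r^2 + 3 r + 1` of sites (1, 7, 19, 37, ...).
#'
#' @param r Non-negative integer radius.
#' @return Integer patch size.
#' @export
hex_patch_size <- function(r) {
  stopifnot(all(r >= 0))
  as.integer(3 * r^2 + 3 * r + 1)
}

# axial offsets (du, dv) of all sites within hex distance r of the center
hex_offsets <- function(r) {
  du <- rep(-r:r, each = 2 * r + 1)
  dv <- rep(-r:r, times = 2 * r + 1)
  keep <- pmax(abs(du), abs(dv), abs(du + dv)) <= r
  cbind(du = as.integer(du[keep]), dv = as.integer(dv[keep]))
}

#' Sites of a hexagonal patch
#'
#' All sites within hexagonal graph-distance `r` of `center`, under periodic
#' wrap. The patch diameter `2 r + 1` must not exceed either lattice
#' dimension, so that the patch contains no repeated sites.
#'
#' @param lattice A `lipid_lattice`.
#' @param center Center site index.
#' @param r Non-negative integer radius.
#' @return Integer vector of `3 r^2 + 3 r + 1` distinct site indices.
#' @export
hex_patch <- function(lattice, center, r) {
  center <- check_site(lattice, center)
  if (r < 0 || r != round(r)) stop("r must be a non-negative integer")
  if (2 * r + 1 > min(lattice$nrows, lattice$ncols))
    stop("patch of radius ", r, " does not fit into the lattice")
  off <- hex_offsets(r)
  uv <- site_axial(lattice, center)
  axial_site(lattice, uv[, "u"] + off[, "du"], uv[, "v"] + off[, "dv"])
}

#' Swap the lipids of two adjacent sites
#'
#' Exchanges the species at sites `i` and `k`; the ordering states stay with
#' the lattice sites (they are a property of the site, not of the lipid
#' occupying it).
#'
#' @param lattice A `lipid_lattice`.
#' @param i,k Adjacent site indices.
#' @return The updated lattice.
#' @export
swap_species <- function(lattice, i, k) {
  i <- check_site(lattice, i)
  k <- check_site(lattice, k)
  if (!(k %in% site_neighbors(lattice, i)))
    stop("sites ", i, " and ", k, " are not neighbors")
  tmp <- lattice$species[i]
  lattice$species[i] <- lattice$species[k]
  lattice$species[k] <- tmp
  lattice
}
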