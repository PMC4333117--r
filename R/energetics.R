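# Energy model: pairwise interaction energies (per ordering state), the
# ordering couplings, and the energies W and J they generate.
#
# All energies are in units of k_B*T; beta = 1 by default. W and J are
# written as directed double sums (every unordered neighbor pair counted
# twice), exactly as the model equations define them.

spec_idx <- function(x) {
  if (is.character(x)) match(x, lipid_species()) else as.integer(x)
}

state_idx <- function(s) {
  # 1 = ho, 2 = lo; accepts spins (+1/-1) or labels
  if (is.character(s)) return(match(s, c("ho", "lo")))
  ifelse(s > 0, 2L, 1L)
}

sym_matrix <- function(upper6) {
  m <- matrix(0, 3, 3, dimnames = list(lipid_species(), lipid_species()))
  m[upper.tri(m, diag = TRUE)] <- upper6[c(1, 2, 4, 3, 5, 6)]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Fitted interaction matrices
#'
#' The symmetric 3x3 nearest-neighbor interaction energies (in k_B*T) between
#' lipid species, one matrix per ordering state. The shipped values are the
#' model's calibrated defaults; in the ho state they encode the strong CH-SM
#' affinity and the repulsion of PC from both, in the lo state weak PC
#' de-mixing and CH-SM de-mixing.
#'
#' @return List with symmetric matrices `w_ho` and `w_lo`
#'   (rows/columns CH, PC, SM).
#' @export
default_interaction_matrices <- function() {
  list(
    w_ho = sym_matrix(c(-0.70, +0.55, -1.70, -0.60, +0.45, -0.80)),
    w_lo = sym_matrix(c(-0.55, -0.23, +0.43, -0.22, -0.23, -0.55))
  )
}

#' Fitted ordering-coupling matrix
#'
#' Coupling strengths j (in k_B*T) between the ordering states of neighboring
#' lipids, indexed by the first lipid's species and ordering state and the
#' neighbor's species only: the neighbor's own state does not enter, which
#' leaves energy differences unchanged. For each species the lo/ho pair of
#' rows sets which ordering state it favors (e.g. PC: j_lo = 0.90 > j_ho =
#' 0.50, so PC aligns into the lo phase).
#'
#' @return Numeric array of dimension `c(3, 2, 3)` with dimnames
#'   `(species, state in c("ho","lo"), neighbor species)`.
#' @export
default_ordering_matrix <- function() {
  j <- array(0, dim = c(3, 2, 3),
             dimnames = list(lipid_species(), c("ho", "lo"), lipid_species()))
  j["CH", "lo", ] <- c(0.50, 0.90, 0.50)
  j["CH", "ho", ] <- c(1.00, 0.50, 1.90)
  j["PC", "lo", ] <- c(0.90, 0.90, 0.90)
  j["PC", "ho", ] <- c(0.50, 0.50, 0.50)
  j["SM", "lo", ] <- c(0.50, 0.90, 0.50)
  j["SM", "ho", ] <- c(1.90, 0.50, 0.55)
  j
}

#' Energy model
#'
#' Bundles the interaction matrices, the ordering-coupling matrix and the
#' inverse temperature. Defaults are the calibrated values.
#'
#' The ordering energy can be evaluated in two formulations. The default
#' `"spin_product"` form,
#' `J = -sum_i sum_k j(X_i^sigma_i, X_k) * sigma_i * sigma_k`, is the
#' Ising-like alignment coupling: neighboring lipids gain energy for
#' matching ordering states, with a strength set by the first lipid's
#' species and state and the neighbor's species. It produces clean,
#' cooperative Lo/Ld phases, but requires the ordering states to start from
#' a random configuration (see [simulate_membrane()]): a uniform state is
#' metastable, since with strictly positive couplings any first flip costs
#' more than 12 k_B*T. The alternative `"state_field"` form,
#' `J = -sum_i sum_k j(X_i^sigma_i, X_k)`, drops the alignment factor, so
#' every lipid relaxes independently in the field of its neighbors'
#' species; phases then form without cooperativity and carry an
#' equilibrium sprinkle of minority-state sites.
#'
#' @param w_ho,w_lo Symmetric 3x3 interaction matrices (k_B*T).
#' @param j Ordering-coupling array of dimension `c(3, 2, 3)`, see
#'   [default_ordering_matrix()].
#' @param beta Inverse temperature (1/(k_B*T)); must be positive.
#' @param formulation Ordering-energy formulation, `"spin_product"`
#'   (default) or `"state_field"`.
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(w_ho = NULL, w_lo = NULL, j = NULL, beta = 1,
                         formulation = c("spin_product", "state_field")) {
  formulation <- match.arg(formulation)
  defaults <- default_interaction_matrices()
  if (is.null(w_ho)) w_ho <- defaults$w_ho
  if (is.null(w_lo)) w_lo <- defaults$w_lo
  if (is.null(j)) j <- default_ordering_matrix()
  stopifnot(is.matrix(w_ho), dim(w_ho) == c(3, 3),
            is.matrix(w_lo), dim(w_lo) == c(3, 3),
            length(dim(j)) == 3, dim(j) == c(3, 2, 3))
  if (max(abs(w_ho - t(w_ho))) > 1e-12 || max(abs(w_lo - t(w_lo))) > 1e-12)
    stop("interaction matrices must be symmetric")
  if (!is.numeric(beta) || beta <= 0) stop("beta must be positive")
  structure(list(w_ho = w_ho, w_lo = w_lo, j = j, beta = beta,
                 formulation = formulation),
            class = "energy_model")
}

spin_product <- function(model) identical(model$formulation, "spin_product")

#' @export
print.energy_model <- function(x, ...) {
  cat("energy_model (k_B*T units), beta =", x$beta, "\n\nw_ho:\n")
  print(x$w_ho)
  cat("\nw_lo:\n")
  print(x$w_lo)
  cat("\nj (lo rows / ho rows):\n")
  print(rbind(lo = x$j[, "lo", ], ho = x$j[, "ho", ]))
  invisible(x)
}

# Flat tables in the element order the C++ engine expects.
# pair36: [[a][sa][b][sb]] with a,b species 0..2 and sa,sb 0 = ho, 1 = lo.
# j18:    [[a][sa][b]].
flatten_model <- function(model) {
  pair36 <- numeric(36)
  j18 <- numeric(18)
  for (a in 1:3) for (sa in 1:2) for (b in 1:3) {
    j18[(((a - 1) * 2 + (sa - 1)) * 3 + (b - 1)) + 1] <-
      model$j[a, c("ho", "lo")[sa], b]
    for (sb in 1:2) {
      e <- if (sa == 1 && sb == 1) model$w_ho[a, b]
           else if (sa == 2 && sb == 2) model$w_lo[a, b]
           else (model$w_ho[a, b] + model$w_lo[a, b]) / 2
      pair36[((((a - 1) * 2 + (sa - 1)) * 3 + (b - 1)) * 2 + (sb - 1)) + 1] <- e
    }
  }
  list(pair36 = pair36, j18 = j18, beta = model$beta)
}

#' Pairwise interaction energy of two adjacent lipids
#'
#' Both lipids in the ho state get the `w_ho` entry, both in lo the `w_lo`
#' entry, and a mixed-state pair the arithmetic mean of the two.
#'
#' @param species_a,species_b Species (codes 1:3 or `"CH"`, `"PC"`, `"SM"`).
#' @param state_a,state_b Ordering states (spins +1/-1 or `"lo"`/`"ho"`).
#' @param model An [energy_model()].
#' @return Interaction energy in k_B*T; symmetric in its two arguments.
#' @examples
#' pair_energy("CH", "ho", "SM", "ho")  # -1.70
#' @export
pair_energy <- function(species_a, state_a, species_b, state_b,
                        model = energy_model()) {
  a <- spec_idx(species_a); b <- spec_idx(species_b)
  sa <- state_idx(state_a); sb <- state_idx(state_b)
  n <- max(length(a), length(b), length(sa), length(sb))
  a <- rep_len(a, n); b <- rep_len(b, n)
  sa <- rep_len(sa, n); sb <- rep_len(sb, n)
  e_ho <- model$w_ho[cbind(a, b)]
  e_lo <- model$w_lo[cbind(a, b)]
  ifelse(sa == 1 & sb == 1, e_ho,
         ifelse(sa == 2 & sb == 2, e_lo, (e_ho + e_lo) / 2))
}

#' Interaction energy of one site with its six neighbors
#'
#' `w_i = sum_k w_sigma(X_i, X_k)` over the 6 neighbors `k` of site `i`;
#' this is the quantity entering the swap rates.
#'
#' @param lattice A `lipid_lattice`.
#' @param i Site index (vectorized).
#' @param model An [energy_model()].
#' @return Numeric site interaction energies.
#' @export
site_energy <- function(lattice, i, model = energy_model()) {
  i <- check_site(lattice, i)
  vapply(i, function(ii) {
    nb <- site_neighbors(lattice, ii)
    sum(pair_energy(lattice$species[ii], lattice$state[ii],
                    lattice$species[nb], lattice$state[nb], model))
  }, numeric(1))
}

#' Total interaction energy W
#'
#' Directed double sum `W = sum_i sum_{k in n(i)} w_sigma(X_i, X_k)`; equals
#' the sum of [site_energy()] over all sites (each unordered pair counted
#' twice, as the model defines it).
#'
#' @inheritParams site_energy
#' @return Scalar energy W (k_B*T).
#' @export
total_interaction_energy <- function(lattice, model = energy_model()) {
  fl <- flatten_model(model)
  unname(cpp_total_energies(lattice$species, lattice$state, lattice$nrows,
                            lattice$ncols, fl$pair36, fl$j18,
                            spin_product(model))["W"])
}

#' Ordering energy of one directed neighbor pair
#'
#' The contribution of the directed pair (i, k) to the ordering energy J.
#' The coupling is indexed by the first lipid's species and ordering state
#' and by the neighbor's species only. In the default `"state_field"`
#' formulation the term is `-j(X_i^sigma_i, X_k)` (the neighbor's state does
#' not enter); in the `"spin_product"` formulation it is
#' `-j(X_i^sigma_i, X_k) * sigma_i * sigma_k`.
#'
#' @inheritParams pair_energy
#' @return Energy contribution (k_B*T).
#' @examples
#' ordering_pair_energy("CH", "ho", "SM", "ho")  # -1.90 in either form
#' @export
ordering_pair_energy <- function(species_a, state_a, species_b, state_b,
                                 model = energy_model()) {
  a <- spec_idx(species_a); b <- spec_idx(species_b)
  sa <- state_idx(state_a); sb <- state_idx(state_b)
  n <- max(length(a), length(b), length(sa), length(sb))
  a <- rep_len(a, n); b <- rep_len(b, n)
  sa <- rep_len(sa, n); sb <- rep_len(sb, n)
  jv <- model$j[cbind(a, sa, b)]
  if (spin_product(model)) {
    sig_a <- 2 * sa - 3  # ho (1) -> -1, lo (2) -> +1
    sig_b <- 2 * sb - 3
    -jv * sig_a * sig_b
  } else {
    -jv
  }
}

#' Total ordering energy J
#'
#' `J = -sum_i sum_{k in n(i)} j(X_i^sigma_i, X_k) sigma_i sigma_k`
#' (directed double sum over all sites and their 6 neighbors).
#'
#' @inheritParams site_energy
#' @return Scalar energy J (k_B*T).
#' @export
total_ordering_energy <- function(lattice, model = energy_model()) {
  fl <- flatten_model(model)
  unname(cpp_total_energies(lattice$species, lattice$state, lattice$nrows,
                            lattice$ncols, fl$pair36, fl$j18,
                            spin_product(model))["J"])
}

#' Ordering-energy change of a single state flip
#'
#' Energy difference `delta J` caused by flipping the ordering state of site
#' `i`, computed from the local terms in which the site appears as first or
#' second index (the coupling depends on the first lipid's state, so both
#' directions change).
#'
#' @inheritParams site_energy
#' @param i Single site index.
#' @return Scalar `delta J`.
#' @export
flip_delta <- function(lattice, i, model = energy_model()) {
  i <- check_site(lattice, i)
  stopifnot(length(i) == 1)
  fl <- flatten_model(model)
  cpp_flip_delta(lattice$species, lattice$state, lattice$nrows,
                 lattice$ncols, fl$j18, i - 1L, spin_product(model))
}

#' Mixing tendency of a species pair in a given ordering state
#'
#' Returns `2 w_sigma(X, Y) - w_sigma(X, X) - w_sigma(Y, Y)`: negative values
#' mean the two species mix in that state, positive values mean they de-mix.
#'
#' @param x,y Species (codes or names).
#' @param state Ordering state (`"ho"`/`"lo"` or spin).
#' @param model An [energy_model()].
#' @return Scalar energy; its sign is the qualitative behavior.
#' @examples
#' mixing_tendency("CH", "SM", "ho")  # < 0: CH and SM mix when ordered
#' mixing_tendency("CH", "PC", "ho")  # > 0: PC de-mixes from CH
#' @export
mixing_tendency <- function(x, y, state, model = energy_model()) {
  a <- spec_idx(x); b <- spec_idx(y)
  w <- if (state_idx(state) == 1) model$w_ho else model$w_lo
  2 * w[a, b] - w[a, a] - w[b, b]
}
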