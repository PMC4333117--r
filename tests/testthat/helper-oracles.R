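# Independent brute-force oracles. These deliberately avoid the package's
# energy/geometry code paths (beyond plain lattice accessors) so that
# agreement is a real cross-check and not a tautology.

oracle_state <- function(spin) ifelse(spin > 0, "lo", "ho")

oracle_pair_energy <- function(model, a, sa, b, sb) {
  if (sa == "ho" && sb == "ho") return(model$w_ho[a, b])
  if (sa == "lo" && sb == "lo") return(model$w_lo[a, b])
  (model$w_ho[a, b] + model$w_lo[a, b]) / 2
}

oracle_total_W <- function(lat, model) {
  W <- 0
  for (i in seq_len(lat$nrows * lat$ncols)) {
    for (k in site_neighbors(lat, i)) {
      W <- W + oracle_pair_energy(model, lat$species[i],
                                  oracle_state(lat$state[i]),
                                  lat$species[k],
                                  oracle_state(lat$state[k]))
    }
  }
  W
}

oracle_total_J <- function(lat, model) {
  spin_prod <- identical(model$formulation, "spin_product")
  J <- 0
  for (i in seq_len(lat$nrows * lat$ncols)) {
    for (k in site_neighbors(lat, i)) {
      jv <- model$j[lat$species[i], oracle_state(lat$state[i]),
                    lat$species[k]]
      J <- J - if (spin_prod) jv * lat$state[i] * lat$state[k] else jv
    }
  }
  J
}

# random test lattice: random species placement and random spins
random_lattice <- function(nrows, ncols, seed) {
  lat <- build_lattice(nrows, ncols, lipid_composition(1/3, 1/3, 1/3), seed)
  set.seed(seed + 777L)
  lat$state <- sample(c(-1L, 1L), nrows * ncols, replace = TRUE)
  lat
}

# hexagonal patch via breadth-first graph distance (independent of the
# axial-coordinate distance formula used by hex_patch)
oracle_hex_bfs <- function(lat, center, r) {
  dist <- rep(Inf, lat$nrows * lat$ncols)
  dist[center] <- 0
  frontier <- center
  d <- 0
  while (length(frontier) && d < r) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, site_neighbors, lattice = lat)))
    nxt <- nxt[dist[nxt] > d]
    dist[nxt] <- d
    frontier <- nxt
  }
  which(is.finite(dist))
}

# uniform random neighbor-swap walk with its own displacement bookkeeping
oracle_msd_uniform <- function(nrows, ncols, nswaps, seed) {
  set.seed(seed)
  n <- nrows * ncols
  lip <- seq_len(n)
  du <- dv <- numeric(n)
  offu <- c(0, 0, -1, 1, -1, 1)
  offv <- c(-1, 1, 0, 0, 1, -1)
  for (s in seq_len(nswaps)) {
    i <- sample.int(n, 1)
    d <- sample.int(6, 1)
    uu <- (i - 1) %/% ncols
    vv <- (i - 1) %% ncols
    u2 <- (uu + offu[d]) %% nrows
    v2 <- (vv + offv[d]) %% ncols
    k <- u2 * ncols + v2 + 1
    a <- lip[i]; b <- lip[k]
    du[a] <- du[a] + offu[d]; dv[a] <- dv[a] + offv[d]
    du[b] <- du[b] - offu[d]; dv[b] <- dv[b] - offv[d]
    lip[i] <- b; lip[k] <- a
  }
  mean(du^2 + dv^2 + du * dv)
}

# exhaustive maximum disjoint packing over a list of member-site vectors
oracle_max_packing <- function(members, n_sites) {
  best <- 0L
  n <- length(members)
  rec <- function(idx, used, count) {
    if (count + (n - idx + 1L) <= best) return(invisible())
    if (idx > n) {
      best <<- max(best, count)
      return(invisible())
    }
    m <- members[[idx]]
    if (!any(used[m])) {
      used2 <- used
      used2[m] <- TRUE
      rec(idx + 1L, used2, count + 1L)
    }
    rec(idx + 1L, used, count)
    invisible()
  }
  rec(1L, logical(n_sites), 0L)
  best
}
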