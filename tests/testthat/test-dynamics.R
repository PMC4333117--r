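zero_w <- function() {
  z <- matrix(0, 3, 3, dimnames = list(lipid_species(), lipid_species()))
  z
}

# coupling table that pins every site in the lo state (gap 30 k_B*T)
frozen_lo_j <- function() {
  j <- default_ordering_matrix()
  j[, "lo", ] <- 5
  j[, "ho", ] <- 0
  j
}

test_that("swap rates follow r = exp(beta * (w_i + w_k))", {
  m0 <- energy_model(zero_w(), zero_w())
  lat <- random_lattice(5, 5, 1)
  k <- site_neighbors(lat, 7)[1]
  expect_equal(switch_rate(lat, 7, k, m0), 1)

  lat <- make_fixture("all_ho_10x10_CH")
  expect_equal(switch_rate(lat, 1, 2), exp(-8.4))

  # doubling beta squares every rate
  lat <- random_lattice(6, 6, 2)
  m1 <- energy_model()
  m2 <- energy_model(beta = 2)
  for (i in c(1, 17, 30)) {
    k <- site_neighbors(lat, i)[4]
    expect_equal(switch_rate(lat, i, k, m2),
                 switch_rate(lat, i, k, m1)^2, tolerance = 1e-12)
  }
  expect_error(switch_rate(lat, 1, 20), "not neighbors")
})

test_that("total switch rate sums the unordered neighbor-pair rates", {
  lat <- make_fixture("all_lo_10x10_PC")
  expect_equal(total_switch_rate(lat), 300 * exp(2 * -1.32),
               tolerance = 1e-9)
  # brute force on a mixed lattice
  lat <- random_lattice(5, 5, 3)
  rt <- 0
  for (i in seq_len(25)) for (k in site_neighbors(lat, i))
    if (k > i) rt <- rt + switch_rate(lat, i, k)
  expect_equal(total_switch_rate(lat), rt, tolerance = 1e-9)
})

test_that("waiting times are exponential with the total rate", {
  lat <- make_fixture("all_lo_10x10_PC")  # uniform rates, states frozen
  rtot <- total_switch_rate(lat)
  ph <- interaction_phase(lat, 5000, seed = 42, record = TRUE)
  dt <- ph$steps[, "dt"]
  expect_equal(mean(dt), 1 / rtot, tolerance = 4 / sqrt(5000))
  ks <- stats::ks.test(dt, "pexp", rate = rtot)
  expect_gt(ks$p.value, 0.01)
  expect_equal(ph$t_sim, sum(dt), tolerance = 1e-9)
})

test_that("swap selection frequencies are proportional to the rates", {
  # single species with a frozen half-lo/half-ho state pattern: rates are
  # heterogeneous but constant in time (swaps exchange identical lipids)
  lat <- nanobile:::new_lattice(6, 6, rep(2L, 36),
                                rep(c(1L, -1L), each = 18))
  rates <- c()
  edges <- character(0)
  for (i in seq_len(36)) for (k in site_neighbors(lat, i)) {
    if (k > i) {
      rates <- c(rates, switch_rate(lat, i, k))
      edges <- c(edges, paste(i, k))
    }
  }
  ph <- interaction_phase(lat, 20000, seed = 7, record = TRUE)
  key <- paste(pmin(ph$steps[, "i"], ph$steps[, "k"]),
               pmax(ph$steps[, "i"], ph$steps[, "k"]))
  obs <- table(factor(key, levels = edges))
  expected <- 20000 * rates / sum(rates)
  keep <- expected >= 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / max(sum(expected[!keep]), 1)
  pval <- stats::pchisq(chi, df = sum(keep), lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("a swap phase never changes the species histogram", {
  lat <- random_lattice(8, 8, 5)
  ph <- interaction_phase(lat, 3000, seed = 9)
  expect_equal(tabulate(ph$lattice$species, 3), tabulate(lat$species, 3))
  expect_equal(ph$lattice$state, lat$state)
})

test_that("the swap phase executes ceiling(n_W * N / 2) events", {
  # frozen-lo single-species lattice: constant uniform rates, so the
  # simulation-time increment per cycle is (n_swaps / r_tot) on average
  lat <- make_fixture("all_lo_10x10_PC")
  model <- energy_model(j = frozen_lo_j())
  rtot <- total_switch_rate(lat, model)
  ctrl <- sim_control(n_W = 10, n_J = 5, seed = 3, max_cycles = 20,
                      log_every = 1)
  sim <- suppressWarnings(simulate_membrane(lat, model, ctrl, tau_ms = 1e9,
                                            init_states = "keep"))
  dts <- sim$clock$dt_sim[-1]
  n_swaps <- 500  # ceiling(10 * 100 / 2)
  se <- (n_swaps / rtot) / sqrt(n_swaps * length(dts))
  expect_equal(mean(dts), n_swaps / rtot, tolerance = 5 * se / (n_swaps / rtot))
})

test_that("Metropolis acceptance follows the printed rule", {
  # delta J = 0 everywhere: every proposal is accepted
  m0 <- energy_model(j = default_ordering_matrix() * 0)
  lat <- make_fixture("all_lo_10x10_PC")
  res <- metropolis_phase(lat, n_J = 3, model = m0, seed = 1)
  expect_equal(res$accepted, 300)

  # a flip from the pinned configuration costs exactly delta J = 2:
  # acceptance frequency must match exp(-2)
  j <- default_ordering_matrix()
  j[, , ] <- 1 / 12  # uniform alignment coupling: a flip from the aligned
  m2 <- energy_model(j = j)  # configuration costs 6 * 4 * (1/12) = 2 k_B*T
  fl <- nanobile:::flatten_model(m2)
  lat9 <- nanobile:::new_lattice(3, 3, rep(2L, 9), rep(1L, 9))
  expect_equal(flip_delta(lat9, 5, m2), 2)
  hits <- 0L
  n_trials <- 6000L
  for (s in seq_len(n_trials)) {
    out <- nanobile:::cpp_metropolis(lat9$species, lat9$state, 3, 3,
                                     fl$j18, 1, 1, s, TRUE)
    hits <- hits + (out$accepted > 0)
  }
  p <- exp(-2)
  se <- sqrt(p * (1 - p) / n_trials)
  expect_equal(hits / n_trials, p, tolerance = 4 * se / p)
})

test_that("time mapping is linear and invertible", {
  a2 <- (0.8e-3)^2
  expect_equal(map_time(2, 2.5 / a2), 2)              # identity scaling
  expect_equal(map_time(1, 0.1, D_ref_um2_s = 1.25),  # halving D_ref doubles
               2 * map_time(1, 0.1, D_ref_um2_s = 2.5))
  t_real <- map_time(3.7, 0.42)
  expect_equal(t_real / (a2 * 0.42 / 2.5), 3.7, tolerance = 1e-12)
  expect_error(map_time(1, 0), "positive")
})

test_that("tau = 0 returns the relaxed initial configuration", {
  lat <- build_lattice(20, 20, lipid_composition(0.378, 0.465, 0.157),
                       seed = 2)
  sim <- simulate_membrane(lat, control = sim_control(seed = 2), tau_ms = 0)
  expect_equal(sim$cycles, 0)
  expect_equal(sim$t_real_ms, 0)
  expect_equal(sim$lattice$species, lat$species)  # no swaps yet
  expect_lt(mean(sim$lattice$state > 0), 1)       # states were relaxed
})

test_that("single-species lattices reach stationarity quickly", {
  lat <- nanobile:::new_lattice(16, 16, rep(2L, 256), rep(1L, 256))
  ctrl <- sim_control(seed = 4, max_cycles = 400, stat_window = 15)
  sim <- simulate_membrane(lat, control = ctrl, stop = "stationary")
  expect_true(sim$stationary)
  expect_false(sim$capped)
})

test_that("the physiological mixture self-organizes into two phases", {
  lat <- build_lattice(30, 30, lipid_composition(0.378, 0.465, 0.157),
                       seed = 6)
  sim <- simulate_membrane(lat, control = sim_control(seed = 6),
                           tau_ms = 0.05)
  expect_equal(classify_phase(sim$lattice), "biphasic")
  lo <- sim$lattice$state > 0
  sp <- sim$lattice$species
  # Ld regions are PC-enriched, Lo regions CH/SM-enriched
  expect_gt(mean(sp[lo] == 2), 0.465)
  expect_gt(mean(sp[!lo] %in% c(1, 3)), 0.535)
  # species conserved through the whole run
  expect_equal(tabulate(sp, 3), tabulate(lat$species, 3))
})

test_that("runs are reproducible from the seed", {
  lat <- build_lattice(12, 12, lipid_composition(0.378, 0.465, 0.157),
                       seed = 1)
  s1 <- simulate_membrane(lat, control = sim_control(seed = 11), tau_ms = 0.02)
  s2 <- simulate_membrane(lat, control = sim_control(seed = 11), tau_ms = 0.02)
  s3 <- simulate_membrane(lat, control = sim_control(seed = 12), tau_ms = 0.02)
  expect_identical(s1$lattice, s2$lattice)
  expect_identical(s1$clock, s2$clock)
  expect_false(identical(s1$lattice, s3$lattice))
})
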