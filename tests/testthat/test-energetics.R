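test_that("pair interaction energies match the calibrated tables", {
  expect_equal(pair_energy("CH", "ho", "SM", "ho"), -1.70)
  expect_equal(pair_energy("PC", "lo", "PC", "lo"), -0.22)
  expect_equal(pair_energy("SM", "ho", "SM", "ho"), -0.80)
  expect_equal(pair_energy("CH", "lo", "SM", "lo"), +0.43)
  # mixed ordering states take the mean of the two tables
  expect_equal(pair_energy("CH", "ho", "PC", "lo"), (0.55 - 0.23) / 2)
  expect_equal(pair_energy("CH", "ho", "PC", "lo"), 0.16)

  # symmetry in the two (species, state) arguments, all combinations
  for (a in 1:3) for (b in 1:3) for (sa in c(-1, 1)) for (sb in c(-1, 1))
    expect_equal(pair_energy(a, sa, b, sb), pair_energy(b, sb, a, sa))
})

test_that("site and total interaction energies agree with brute force", {
  lat <- make_fixture("all_ho_10x10_CH")
  expect_equal(site_energy(lat, 37), 6 * -0.70)
  expect_equal(total_interaction_energy(lat), -420)

  lat <- make_fixture("all_lo_10x10_PC")
  expect_equal(site_energy(lat, 1), -1.32)
  expect_equal(total_interaction_energy(lat), -132)

  for (seed in 1:4) {
    lat <- random_lattice(4 + seed %% 2, 5, seed)
    model <- energy_model()
    expect_equal(total_interaction_energy(lat, model),
                 oracle_total_W(lat, model), tolerance = 1e-12)
    expect_equal(sum(site_energy(lat, seq_len(lat$nrows * lat$ncols), model)),
                 oracle_total_W(lat, model), tolerance = 1e-12)
  }
})

test_that("ordering pair terms follow the coupling matrix in both forms", {
  # identical states give the same term in both formulations
  expect_equal(ordering_pair_energy("CH", "ho", "SM", "ho"), -1.90)
  expect_equal(ordering_pair_energy("PC", "lo", "PC", "lo"), -0.90)
  # the spin-product default flips the sign for misaligned pairs
  expect_equal(ordering_pair_energy("PC", "lo", "PC", "ho"), +0.90)
  # the state-field form ignores the neighbor's state
  msf <- energy_model(formulation = "state_field")
  expect_equal(ordering_pair_energy("PC", "lo", "PC", "ho", msf), -0.90)
  expect_equal(ordering_pair_energy("CH", "ho", "SM", "ho", msf), -1.90)
})

test_that("total ordering energy matches exhaustive summation", {
  lat <- make_fixture("all_ho_10x10_CH")
  expect_equal(total_ordering_energy(lat), -600 * 1.00)

  for (seed in 5:8) {
    lat <- random_lattice(4, 4, seed)
    for (form in c("state_field", "spin_product")) {
      model <- energy_model(formulation = form)
      expect_equal(total_ordering_energy(lat, model),
                   oracle_total_J(lat, model), tolerance = 1e-12)
    }
  }
})

test_that("local flip deltas equal global recomputation", {
  for (seed in 1:6) {
    lat <- random_lattice(5, 5, seed)
    for (form in c("state_field", "spin_product")) {
      model <- energy_model(formulation = form)
      for (i in seq_len(25)) {
        d_local <- flip_delta(lat, i, model)
        flipped <- lat
        flipped$state[i] <- -flipped$state[i]
        d_global <- total_ordering_energy(flipped, model) -
          total_ordering_energy(lat, model)
        expect_equal(d_local, d_global, tolerance = 1e-9)
        # involution: flipping back negates the delta
        expect_equal(flip_delta(flipped, i, model), -d_local,
                     tolerance = 1e-9)
      }
    }
  }
  # zero couplings give zero deltas
  j0 <- default_ordering_matrix() * 0
  m0 <- energy_model(j = j0)
  lat <- random_lattice(5, 5, 11)
  expect_equal(flip_delta(lat, 7, m0), 0)
})

test_that("mixing tendencies reproduce the known pairwise behavior", {
  # ho state: CH-SM mix strongly; PC de-mixes from both
  expect_equal(mixing_tendency("CH", "SM", "ho"), -1.90)
  expect_equal(mixing_tendency("CH", "PC", "ho"), +2.40)
  expect_gt(mixing_tendency("PC", "SM", "ho"), 0)
  # lo state: weak PC de-mixing from CH and SM; CH-SM de-mix
  t_chpc <- mixing_tendency("CH", "PC", "lo")
  t_pcsm <- mixing_tendency("PC", "SM", "lo")
  expect_gt(t_chpc, 0); expect_lt(t_chpc, 0.5)
  expect_gt(t_pcsm, 0); expect_lt(t_pcsm, 0.5)
  expect_gt(mixing_tendency("CH", "SM", "lo"), 0)
  # identity pairs are exactly neutral
  for (x in c("CH", "PC", "SM")) for (s in c("ho", "lo"))
    expect_equal(mixing_tendency(x, x, s), 0)
})

test_that("energy model construction validates its inputs", {
  w <- default_interaction_matrices()$w_ho
  w[1, 2] <- 99  # break symmetry
  expect_error(energy_model(w_ho = w), "symmetric")
  expect_error(energy_model(beta = -1), "beta")
  expect_error(energy_model(beta = 0), "beta")
})
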