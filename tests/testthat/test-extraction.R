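test_that("extractable placements on uniform lattices are trivial", {
  lo <- make_fixture("all_lo_10x10_PC")
  ho <- make_fixture("all_ho_10x10_CH")
  expect_length(extractable_patches(lo, 0)$centers, 100)
  for (r in 0:2) {
    expect_length(extractable_patches(ho, r)$centers, 0)
    expect_equal(emf(lo, r), 1)
    expect_equal(emf(ho, r), 0)
  }
  expect_error(extractable_patches(lo, 5), "does not fit")
})

test_that("the radius-2 island fixture is resolved exactly", {
  lat <- make_fixture("hex_r2_island")
  expect_equal(sum(lat$state > 0), 19)
  p2 <- extractable_patches(lat, 2)
  expect_length(p2$centers, 1)
  p1 <- extractable_patches(lat, 1)
  expect_length(p1$centers, 7)
  expect_equal(emf(lat, 2), 19 / 132)
  expect_equal(count_patches(lat, 2, seed = 5)$n_patch, 1)
  expect_equal(unname(bile_composition(p2)), c(0, 1, 0))
})

test_that("disjoint patch counts behave like a packing", {
  lo <- make_fixture("all_lo_10x10_PC")
  expect_equal(count_patches(lo, 0)$n_patch, 100)

  lat <- build_lattice(20, 20, lipid_composition(0.378, 0.465, 0.157),
                       seed = 3)
  sim <- simulate_membrane(lat, control = sim_control(seed = 3),
                           tau_ms = 0.02)
  np <- sapply(0:3, function(r)
    count_patches(sim$lattice, r, seed = 1)$n_patch)
  expect_true(all(diff(np) <= 0))  # non-increasing in the radius
  for (r in 0:3) {
    cp <- count_patches(sim$lattice, r, seed = 2)
    expect_lte(cp$n_patch * hex_patch_size(r), 400)
    expect_gte(emf(sim$lattice, r) * 400 + 1e-9,
               cp$n_patch * hex_patch_size(r))
  }
})

test_that("greedy packing is within one patch of the exhaustive optimum", {
  for (seed in 1:4) {
    set.seed(seed)
    lat <- nanobile:::new_lattice(8, 8, rep(2L, 64),
                                  sample(c(1L, -1L), 64, TRUE,
                                         prob = c(0.75, 0.25)))
    p <- extractable_patches(lat, 1)
    if (length(p$centers) == 0) next
    members <- lapply(p$centers, function(c0) hex_patch(lat, c0, 1))
    opt <- oracle_max_packing(members, 64)
    cp <- count_patches(lat, 1, n_orderings = 16, seed = seed)
    expect_lte(max(cp$counts), opt)
    expect_gte(max(cp$counts), opt - 1)
  }
})

test_that("the secretion rate is n_patch * n_lipids / tau", {
  lo <- make_fixture("all_lo_10x10_PC")
  ho <- make_fixture("all_ho_10x10_CH")
  expect_equal(lsr(lo, 0, tau_ms = 1), 100)
  expect_equal(lsr(lo, 0, tau_ms = 2), 50)
  expect_equal(lsr(ho, 1, tau_ms = 1), 0)
  expect_error(lsr(lo, 0, tau_ms = 0), "positive")
  rep1 <- patch_report(lo, 0:2, tau_ms = 1)
  expect_equal(rep1$lsr, rep1$n_patch * rep1$n_lipids)
  expect_true(all(rep1$emf >= 0 & rep1$emf <= 1))
})

test_that("bile composition pools all overlapping placements", {
  # two isolated lo sites of different species
  lat <- nanobile:::new_lattice(6, 6, rep(3L, 36), rep(-1L, 36))
  lat$species[c(8, 29)] <- c(1L, 2L)
  lat$state[c(8, 29)] <- 1L
  expect_equal(unname(bile_composition(lat, r = 0)), c(0.5, 0.5, 0))
  # nothing extractable: NA with a warning
  ho <- make_fixture("all_ho_10x10_CH")
  expect_warning(bc <- bile_composition(ho, r = 0), "undefined")
  expect_true(all(is.na(bc)))
})

test_that("scan summaries find thresholds and flux peaks", {
  scan <- data.frame(axis_pct = rep(c(10, 20, 30, 40), each = 2),
                     r = 14, seed = rep(1:2, 4),
                     n_patch = c(0, 0, 0.5, 1.2, 2, 2, 3, 3),
                     flux_CH = c(0, 0, 1, 1, 5, 7, 2, 2))
  expect_equal(scan_threshold(scan, 14), 30)  # first grid point with mean >= 1
  expect_equal(scan_flux_peak(scan, 14), 30)
  expect_true(is.na(scan_threshold(scan[scan$axis_pct < 15, ], 14)))
})

test_that("a pure-PC membrane is almost fully extractable", {
  scan <- composition_scan("PC", grid_pct = 100, ratio = c(7, 3),
                           tau_ms = 0.01, radii = c(0, 1), seeds = 1,
                           nrows = 12, ncols = 12,
                           control = sim_control(max_cycles = 500))
  # a pure-PC site prefers lo by 6 * 0.4 k_B*T, i.e. a 91.7% lo share in
  # equilibrium -- right at the 90% classification boundary
  expect_true(unique(scan$phase) %in% c("Ld", "biphasic"))
  expect_gt(scan$emf[scan$r == 0], 0.85)
  expect_equal(scan$CH[scan$r == 0], 0)  # the bile is pure PC
})
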