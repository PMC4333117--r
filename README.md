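# nanobile

Kinetic lattice simulation of lipid nanodomains in the outer leaflet of
the hepatocyte canalicular membrane, and of the biliary lipid secretion
they enable.

## The problem

Bile is formed at the canalicular (apical) membrane of hepatocytes. Its
lipid fraction — mostly phosphatidylcholine with some cholesterol and
traces of sphingomyelin — has to leave the outer membrane leaflet, yet
that leaflet must survive permanent exposure to high concentrations of
bile salts, which are powerful detergents. A long-standing question is
whether lipids are extracted one by one into mixed micelles or as whole
membrane patches carved out of detergent-soluble regions. Because the
process cannot be watched directly, a mechanistic model is needed:
`nanobile` is for membrane biophysicists and modelers who want to
simulate the self-organization of the leaflet into liquid-ordered (Lo)
and liquid-disordered (Ld) nanodomains and quantify which extraction
mechanism reproduces observed bile compositions.

## The model

The leaflet is a periodic triangular lattice; each site holds one lipid
of species X ∈ {CH, PC, SM} and carries an ordering state σ ∈ {ho, lo}
(spins −1/+1). Two energies (in units of k_BT, β = 1) govern the system:

* interaction energy `W = Σ_i Σ_{k∈n(i)} w_σ(X_i, X_k)` with calibrated
  symmetric 3×3 tables `w_ho`, `w_lo` (mixed-state pairs take the mean);
* ordering energy `J = − Σ_i Σ_{k∈n(i)} j(X_i^σ_i, X_k) σ_i σ_k`, an
  Ising-like alignment coupling indexed by the first lipid's species and
  state and the neighbor's species.

Dynamics alternate (i) Gillespie kinetic Monte Carlo over neighbor swaps
with rates `r(i,k) = exp(β(w_i + w_k))` until every lipid has moved
`N_W = 10` times on average, and (ii) Metropolis relaxation of the
ordering states with `N_J = 100` proposals per site, acceptance
`min(1, exp(−βΔJ))`. The Gillespie clock maps to physical time through
the Ld diffusion coefficient (`t_real = t_sim · a² D_sim / D_ref`,
a = 0.8 nm, D_ref = 2.5 µm²/s). Extractable membrane patches are
hexagons of radius r (3r² + 3r + 1 lipids) lying entirely in the lo
phase; from them the package computes the extractable membrane fraction
(EMF), the lipid secretion rate `LSR(r) = n_patch(r)·n_lipids(r)/τ` for
nanodomain life-time τ, and the predicted bile composition (the pooled
composition of all extractable patches). A constrained
hypercube-refinement search re-derives the energy tables from
(composition, phase, diffusion) data; a synthetic-data generator
emulates such measurements for parameter-recovery testing.

See the methods vignette (`vignettes/membrane-nanodomains.Rmd`) for the
full model description, parameter choices and limitations.

## Worked example

Simulate the physiologically normal leaflet composition (CH 37.8%,
PC 46.5%, SM 15.7%) for a nanodomain life-time of 0.5 ms and analyze
what bile salts could extract:

```r
library(nanobile)
lat <- build_lattice(60, 60, lipid_composition(0.378, 0.465, 0.157), seed = 1)
sim <- simulate_membrane(lat, control = sim_control(seed = 1), tau_ms = 0.5)
print(sim)
#> membrane_sim: 585 cycles, t_sim = 2.06e+04, t_real = 0.5006 ms
#> lipid_lattice: 60 x 60 (3600 sites)
#>   composition: CH 37.8%, PC 46.5%, SM 15.7%
#>   lo fraction: 0.507

patch_report(sim$lattice, c(0, 3, 7), tau_ms = 0.5, seed = 1)
#>   r n_lipids n_placements  n_patch   emf     lsr    CH    PC    SM
#> 1 0        1         1826 1826.000 0.507 3652.00 0.104 0.893 0.003
#> 2 3       37          892   24.125 0.499 1785.25 0.099 0.897 0.004
#> 3 7      169          103    4.625 0.381 1563.25 0.100 0.896 0.004
```

The leaflet has separated into a biphasic pattern (half of the sites are
liquid-disordered). The extraction report shows, per patch radius `r`:
how many placements are fully embedded in Ld regions (`n_placements`),
how many disjoint patches can be cut out simultaneously (`n_patch`, the
randomized greedy packing), the membrane fraction covered by any
placement (`emf`), the secretion rate `lsr`, and the predicted bile
composition — strongly PC-enriched (~90% PC vs 46.5% in the membrane)
with a ~10% CH fraction and almost no SM, and nearly independent of the
patch size, as expected for bile.

The same analyses are scriptable from the shell via `exec/nanobile`
(subcommands `simulate`, `scan`, `fixtures`, configured by a YAML file;
see `load_config()`).

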