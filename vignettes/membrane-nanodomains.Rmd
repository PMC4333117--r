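---
title: "Membrane nanodomains and biliary lipid secretion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane nanodomains and biliary lipid secretion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`nanobile` simulates the exoplasmic (outer) leaflet of the canalicular
membrane of hepatocytes as a periodic triangular lattice in which every
site holds exactly one lipid of species cholesterol (CH),
phosphatidylcholine (PC, standing in for the leaflet's
glycerophospholipid pool) or sphingomyelin (SM). Each site additionally
carries a two-valued ordering state: high-ordered (ho, spin $-1$,
stretched acyl chains, low mobility) or low-ordered (lo, spin $+1$,
bulky chains, high mobility). Cooperative alignment of these states
produces the liquid-ordered (Lo) and liquid-disordered (Ld) membrane
phases; the Ld regions are the bile-salt-soluble part of the membrane
from which lipids are secreted into the bile.

Two energies drive the dynamics, both in units of $k_BT$
($\beta = 1$ by default, since the calibrated tables are expressed in
thermal units):

* the **interaction energy**
  $W = \sum_i \sum_{k \in n(i)} w_\sigma(X_i, X_k)$, a directed double
  sum of pairwise species interactions over the six neighbors of every
  site, with separate symmetric $3\times 3$ tables `w_ho` and `w_lo` for
  pairs in the ho and lo state and the arithmetic mean of the two tables
  for mixed-state pairs;
* the **ordering energy**
  $J = -\sum_i \sum_{k \in n(i)} j(X_i^{\sigma_i}, X_k)\,\sigma_i \sigma_k$,
  an Ising-like alignment coupling whose strength depends on the first
  lipid's species and ordering state and on the neighbor's species only
  (the neighbor's own state never enters, so energy differences are
  unaffected by that convention).

The shipped default tables are the calibrated values
(`default_interaction_matrices()`, `default_ordering_matrix()`). Their
signs encode the known pairwise behavior, exposed by
`mixing_tendency(x, y, state)` $= 2w_\sigma(X,Y) - w_\sigma(X,X) -
w_\sigma(Y,Y)$: in the ho state CH and SM mix strongly while PC de-mixes
from both; in the lo state PC de-mixes only weakly and CH and SM de-mix.
The lo/ho pairs of rows of the `j` table set each species' preferred
state per neighbor species: PC always prefers lo (0.90 vs 0.50), CH and
SM prefer ho among CH/SM (up to 1.90) but lo when dissolved among PC —
which is exactly what makes the Ld phase PC-rich with a minor dissolved
CH fraction.

## The two-step dynamics

Lipid motion is restricted to pairwise swaps of lattice neighbors.
Because conformational changes of acyl chains are far faster than
positional exchange, the ordering states are treated as a fast
subsystem: the simulation alternates

1. a **swap phase**: Gillespie kinetic Monte Carlo over all neighbor
   pairs with rates $r(i,k) = \exp(\beta(w_i + w_k))$, where
   $w_i = \sum_{k \in n(i)} w_\sigma(X_i, X_k)$ is the current
   interaction energy of site $i$. Waiting times are exponential with
   the total rate (summed over unordered pairs) and events are chosen
   proportionally to their rates. The phase runs until
   $\lceil N_W N/2 \rceil$ swaps have been executed, i.e. every lipid
   has changed position $N_W$ times on average (one swap relocates two
   lipids). Ordering states are frozen during the phase — they are a
   property of the site, not of the lipid passing through it;
2. a **Metropolis phase**: $N_J N$ single-site state-flip proposals at
   uniformly random sites, each accepted with probability 1 if
   $\Delta J \le 0$ and $\exp(-\beta \Delta J)$ otherwise.

Defaults are $N_J = 100$ and $N_W = 10$; the phase-separation
observables are flat over a wide band around these values, so they are
kept fixed. A run starts from a seeded uniformly random placement of the
species at the requested mole fractions (largest-remainder rounding of
the fractions to site counts: deterministic and sum-exact) and an
initial Metropolis relaxation of the ordering states.

**Initial ordering states.** With the alignment (spin-product) coupling
and strictly positive `j` values, any *uniform* state configuration is
deeply metastable: the first flip out of an aligned background costs
$12$–$19\,k_BT$, so nothing ever nucleates from an all-lo start. The
package therefore initializes the states *randomly* (`init_states =
"random"`); the initial relaxation then crystallizes the spin field onto
the species pattern without any barrier, and the alignment coupling
subsequently suppresses single-site fluctuations, keeping the interior
of each phase clean. An all-lo initialization (`"lo"`) and a
keep-as-given mode (`"keep"`, for continuing runs) are available. A
second formulation of the ordering energy
(`energy_model(formulation = "state_field")`) drops the alignment factor
so that every site relaxes independently in the field of its neighbors'
species; it needs no special initialization but its phases carry an
equilibrium sprinkle of minority-state sites (about 8% even in pure PC),
which makes large uniformly-disordered patches exponentially rare. The
spin-product form is the default because clean phases — and therefore
extractable patches of hundreds of lipids — only exist with genuine
cooperativity.

## Time scale

The Gillespie clock is dimensionless. It is anchored to physical time by
requiring the simulated Ld-phase diffusion coefficient to match a
reference experimental value:
$t_\mathrm{real} = t_\mathrm{sim}\, a^2 D_\mathrm{sim} / D_\mathrm{ref}$,
with lattice constant $a = 0.8$ nm (the nearest-neighbor spacing of
lipids) and $D_\mathrm{ref} = 2.5\ \mu\mathrm{m}^2/\mathrm{s}$, a
typical vesicle-measured Ld diffusion coefficient for
cholesterol-containing ternary mixtures. During a run, each cycle
advances physical time by $a^2 \langle \Delta x^2 \rangle_\mathrm{Ld} /
(4 D_\mathrm{ref})$ where $\langle \Delta x^2 \rangle_\mathrm{Ld}$ is
the mean squared displacement accrued in the swap phase by lipids that
sit on lo sites at both phase ends (all lipids, when fewer than 30
qualify — e.g. in strongly ordered membranes). Displacements are
unwrapped across the periodic boundary and measured in axial
coordinates, where the squared Cartesian distance is
$\Delta u^2 + \Delta v^2 + \Delta u\,\Delta v$. Composition observables
are insensitive to the anchoring constants across the whole
0.1–10 ms band; only the absolute staging of domain growth depends on
them.

Phase-restricted diffusion coefficients for calibration come from
`track_displacements()` + `diffusion_coefficient()`: all lipids are
tagged, and a walker is discarded the first time the ordering state of
its site differs from its initial state (checked at every phase
boundary — the strict reading of "never crossed a phase border").
Because equilibrium states fluctuate, tracking horizons are kept short
(a few cycles) so that enough valid walkers survive.

## Extraction into the bile

Bile salts solubilize hexagonal membrane patches that lie entirely
inside Ld regions. A patch of hexagonal graph-distance radius $r$
contains $3r^2 + 3r + 1$ lipids (1, 7, 19, 37, ... — `hex_patch_size()`),
and a placement is *extractable* when all of its sites are in the lo
state (`extractable_patches()`). From the placements follow

* the extractable membrane fraction `emf()`: the share of sites covered
  by at least one placement;
* the disjoint patch count `count_patches()`: placements accepted in
  randomized order, skipping overlaps (patches are physically removed,
  so they cannot share lipids), averaged over several orders; the
  overlapping placement count is reported alongside;
* the lipid secretion rate `lsr()` $= n_\mathrm{patch}(r)\,
  n_\mathrm{lipids}(r) / \tau$ for nanodomain life-time $\tau$;
* the bile composition `bile_composition()`: the pooled species
  fractions over *all* (overlapping) placements.

`bile_table()` runs the whole pipeline across seeds, and
`composition_scan()` sweeps the membrane content of CH (at fixed PC:SM
ratio) or PC (at fixed CH:SM ratio) across a grid, reporting extraction
thresholds (`scan_threshold()`: smallest grid value whose mean disjoint
patch count reaches 1) and the extractable-cholesterol flux optimum
(`scan_flux_peak()`, flux = LSR × CH fraction of the patches).

## Calibration

The twelve interaction entries were originally fitted to
vesicle-measured diffusion coefficients across ternary compositions by
minimizing $\varepsilon = \sum_m (D^\mathrm{exp}_{m,\sigma} - \alpha
D^\mathrm{sim}_{m,\sigma})^2$ with a single scale factor $\alpha$ shared
by both phases (`alpha_scaling()` uses the closed-form least-squares
optimum $\alpha = \sum D^\mathrm{exp} D^\mathrm{sim} / \sum
(D^\mathrm{sim})^2$; a differently printed expression for $\alpha$ in
the source literature is not self-consistent and is not used), subject
to the single constraint that CH and SM mix in the ho state
(`check_constraints()`). The ordering entries were chosen to match
observed phase labels (Lo / Ld / biphasic, defined by the >90% / >10%
occupancy rules in `classify_phase()`).

The package ships this machinery as a constrained hypercube-refinement
search (`hypercube_search()`): a full grid of 3 points per axis is
evaluated, the best feasible point kept (ties broken by the
lexicographically smallest parameter vector, for determinism), the box
shrunk by 0.5 around it, and the procedure repeated — a discretized
downhill search. `fit_interaction_matrices()` minimizes $\varepsilon$;
`fit_ordering_matrix()` maximizes the number of matched phase labels.
The original measurement table is not public, so
`synthetic_calibration_data()` emulates one: it simulates chosen
compositions at known ("true") parameters, scales the diffusion values
by a fixed $\alpha_\mathrm{true}$ and adds multiplicative Gaussian noise
(5% by default — a typical relative error of fluorescence-based
diffusion measurements). Parameter recovery on such data is the
testable claim: the search must return the generating value within the
final grid cell. Simulator evaluations inside a fit use common random
numbers (fixed seeds per composition) so the search sees a smooth
objective. What this does *not* show is agreement with real vesicle
data, which would require the original measurements.

## Numerical choices and degenerate inputs

* Lattice dimensions must be at least 3 so the 6-neighborhood contains
  no repeated sites; patches must satisfy $2r+1 \le \min(\mathrm{rows},
  \mathrm{cols})$.
* The total Gillespie rate is maintained incrementally (localized
  updates around each executed swap, verified against full
  recomputation to $10^{-9}$) and rebuilt from scratch at every phase
  boundary so floating-point drift cannot accumulate.
* Metropolis acceptance probabilities are looked up from a precomputed
  table when all couplings sit on a 0.05 grid (the default table does);
  arbitrary couplings fall back to `exp()`.
* A swap of two identical lipids changes nothing; the event set can
  optionally be restricted to unlike-species pairs
  (`sim_control(swap_events = "hetero")`), which preserves the
  stationary distribution exactly and only rescales the event clock.
* Stationarity (used when fitting, where no life-time applies) is
  declared when the lo fraction, the six species-pair contact
  frequencies and the windowed diffusion estimate all change by less
  than 1% between two consecutive 10-cycle windows; every run also
  carries a hard cycle cap.
* Membranes whose Ld phase (and hence measured mobility) collapses make
  the diffusion-anchored clock advance extremely slowly; composition
  scans therefore run under a cycle cap, which only binds for such
  near-frozen compositions, whose patch observables are stationary long
  before the cap.
* Domain statistics are connected components of constant ordering state
  on the periodic lattice as-is; a phase that wraps around the torus is
  one component (no unwrapping correction).

## Problem sizes

The default production lattice is $100 \times 100$ (10,000 lipids):
large against the nanodomains of interest (tens to a few thousand
lipids) while keeping a 1-ms life-time simulation at roughly a minute of
CPU. The test-suite and the acceptance script use this size with ten
seeds for the physiological bile-composition measurements; composition
scans run on $36 \times 36$ and $32 \times 32$ lattices with one
replicate per grid point, and the life-time-invariance comparison on
$36 \times 36$, sizes at which the scanned observables are
well-resolved. Calibration fits use $20 \times 20$ lattices with short
tracking horizons.

## Known limitations

* The model's liquid-ordered clusters are kinetically near-frozen under
  the calibrated interaction energies (boundary detachment costs several
  $k_BT$), so domain coarsening beyond a few hundred lipids per Ld
  opening is very slow on the mapped millisecond scale. Consequently the
  secretion-rate profile $\mathrm{LSR}(r)$ at 1 ms, measured with
  disjoint patch counting, decreases from $r = 0$ rather than peaking at
  an interior patch size, and very large extractable patches appear only
  at strongly PC-enriched compositions.
* The predicted bile is strongly PC-enriched relative to the membrane
  (as it should be), but the dissolved CH fraction of the Ld phase, and
  with it the bile CH percentage, sits a few percentage points below the
  published reference values, and the bile SM share below one percent.
* One leaflet only: no bilayer coupling, no flippase traffic, no
  membrane proteins, no explicit bile-salt chemistry (the extraction
  operators represent bile-salt action implicitly), no micelle-to-vesicle
  maturation.
* Phase labels near the 90% occupancy thresholds are intrinsically
  marginal (a pure PC membrane equilibrates to a ~92% lo share).
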