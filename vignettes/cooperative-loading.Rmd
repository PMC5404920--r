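---
title: "Modelling cooperative tropomyosin loading on growing actin filaments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cooperative tropomyosin loading on growing actin filaments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpmcable)
```

Tropomyosin dimers polymerise end-to-end into two continuous "cables"
that occupy the two helical grooves of an actin filament.  Loading of
fission-yeast tropomyosin (Cdc8) onto growing filaments is strongly
cooperative: single molecules bind weakly and transiently, but cables
nucleate, spread, and saturate filaments over a narrow concentration
range.  `tpmcable` implements a family of models that dissect this
behaviour into two microscopic ingredients:

* **end-to-end cooperativity** `w` — a molecule binding next to an
  already-bound neighbour in the same groove binds faster and leaves
  slower, each by a factor `w`;
* **indirect (cross-strand) cooperativity** `c` — the same, by a factor
  `c`, for a molecule binding directly across from a bound molecule in
  the *other* groove, mediated through the filament.

This vignette documents the models, their assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data tests do
and do not demonstrate.

## The two-row lattice model

A filament is a lattice of 2 rows (grooves) by `N` sites; one site is
one tropomyosin footprint, spanning four monomers along one long-pitch
strand — eight monomers of filament, i.e. `site_length_nm()` = 8 × 2.7 =
21.6 nm.  Each site is empty or holds one molecule; there are no partial
footprints, no frame-shifted binding, and no sliding of bound molecules
(molecules move only by unbinding and rebinding).  An empty site binds
at

$$k_\mathrm{on}\, w^{a}\, c^{b},$$

and an occupied site unbinds at $k_\mathrm{off} / (w^{a} c^{b})$, where
$a \in \{0,1,2\}$ counts occupied immediate same-row neighbours (ends
have one neighbour) and $b \in \{0,1\}$ is the occupancy of the opposite
site.  Because each factor accelerates binding *and* decelerates
unbinding, the equilibrium constant of a site gains the factor twice:
the stationary distribution on a fixed lattice is

$$\pi(\mathbf{x}) \propto K^{n}\,(w^2)^{p_\mathrm{row}}\,
  (c^2)^{p_\mathrm{cross}},$$

with $K = k_\mathrm{on}/k_\mathrm{off}$, $n$ the number of bound
molecules, $p_\mathrm{row}$ the same-row adjacent bound pairs and
$p_\mathrm{cross}$ the bound opposite pairs.  This is a two-row Ising
chain in a field; `enumerate_equilibrium()` evaluates it exactly by
summation for $N \le 10$ and `transfer_matrix_coverage()` via a 4×4
column-transfer matrix for any $N$, including the thermodynamic limit
(dominant eigenvalue and its left/right eigenvectors).  The two oracles
agree to 10⁻¹⁰ and the kinetic Monte Carlo time-averages agree with both
within sampling error — this three-way agreement is the package's core
correctness argument for the simulator.

Dynamics are simulated with an exact Gillespie algorithm
(`simulate_lattice()`, compiled core): exponential waiting times from
the total propensity, selection by cumulative sum in fixed order (row 1,
row 2, growth last).  Filament growth is one extra event of rate
`v_grow`; when it fires at time $t$ the site count becomes
$\lfloor t \cdot v_\mathrm{grow}\rfloor$, clamped non-decreasing, and new
barbed-end sites appear empty.  A deterministic-growth mode (site count
updated continuously) is available but not the default.  Site 1 is the
pointed (old) end; growth appends at the barbed end.  Fixed-lattice runs
terminate when completely filled (the model's stopping rule); pass
`stop_when_filled = FALSE` for equilibrium averages.

### Parameters and defaults

| parameter | meaning | default | why |
|---|---|---|---|
| `k_on` | bare per-site association rate (s⁻¹) | — | scanned; proportional to tropomyosin concentration |
| `k_off` | bare dissociation rate (s⁻¹) | — | 116.8 (w-only fit) or 300 (w+c fit) |
| `w` | end-to-end factor | 1 | 40 (w-only) or 125 (w+c) |
| `c` | cross-strand factor | 1 | 1.25 in the w+c parameter set |
| `v_grow` | growth rate (sites/s) | 2.2 | ≈ 47.5 nm/s, typical barbed-end elongation at 1.5 µM Mg-ATP-actin |
| `site_length_nm` | footprint | 21.6 | 8 monomers × 2.7 nm |
| `n0` | initial sites | 1 | a nascent filament |

The effective single-molecule off-rate in a fully coated cable is
$k_\mathrm{off}/(w^2 c)$ — a molecule inside a cable is flanked by two
same-row neighbours and faces a bound opposite molecule.  For the two
fitted parameter sets this gives 0.073 s⁻¹ and 0.0154 s⁻¹, i.e.
residence times of roughly 14 s and 65 s.  The test suite verifies the
identity directly: dwell times extracted from a simulated coated cable
are exponential with exactly this rate.

`v_grow` deserves emphasis: it is **not** fixed by the model fits and it
strongly shapes every kinetic (as opposed to equilibrium) read-out.  We
measured the apparent Hill coefficient of the coverage transition (below)
at roughly 20 for `v_grow = 1.1` sites/s and roughly 11–13 at the default
2.2 sites/s for the `w = 40` parameter set.  Slower growth leaves more
time for the lattice to equilibrate before the read-out length is
reached, sharpening the transition toward its equilibrium limit.  All
`v_grow`-dependent numbers in this package carry that caveat.

## The TIRF observation model

Microscopy sees neither every molecule nor single sites.  Simulated
occupancies are converted to fluorescence in three fixed steps
(label → broaden → sum; the order matters and is regression-tested):

1. **Stochastic labeling** — each molecule carries a dye with
   probability `labeled_fraction` (default 0.2).  By default labels are
   persistent per molecule, which makes kymographs temporally coherent;
   a per-snapshot mode that simply blanks 80% of occupied sites
   independently per frame is also provided, and for any single snapshot
   the two are equivalent in distribution.
2. **Optical broadening** — each visible site lights its row within
   ±4 sites (≈ 100 nm resolution), clipped at the filament ends.
3. **Groove summation** — the two rows are added, giving per-site
   fluorescence 0, 1 or 2.

Saturated filaments do not read 2: with thinning `p` and radius `r` an
interior site stays dark with probability $(1-p)^{2r+1}$, so a full row
reads $1 - (1-p)^{2r+1} \approx 0.866$ at the defaults.  This plateau is
an artifact of the read-out, not a property of binding.
`lattice_coverage_scan()` therefore normalises mean fluorescence by this
factor, and `hill_from_lattice()` fits the Hill curve with a free
amplitude so that residual kinetic unsaturation cannot masquerade as a
change in steepness.  (For user-supplied occupancy data `fit_hill()`
defaults to the literal fixed-amplitude form
$\theta = [L]^n/(K_d + [L]^n)$; note $K_d$ then carries units of
$[L]^n$, so the half-maximal concentration `ec50` $= K_d^{1/n}$ is
reported alongside.)

Kymographs (`render_kymograph()`) use the sentinel −1 for positions
beyond the current barbed end, distinguishing "no filament" from
"filament, dark".  `estimate_boundary_velocity()` tracks the outermost
lit site of the cable region across frames and fits a least-squares
slope over the longest window in which a cable persists (≥ 15 s by
default), separately toward the barbed and pointed ends.  It is a
deliberately simple edge tracker — it assumes one dominant cable region
and will mix edges if several well-separated cables coexist; for
multi-cable kymographs, crop first.

## The apparent cooperativity of loading

`hill_from_lattice()` reproduces the coverage-transition quantification:
for a grid of `k_on` values it grows 24 replicate filaments, snapshots
each at the moment it reaches 6 µm, applies the observation model, and
averages.  The transition is first bracketed by a coarse geometric scan
starting at the equilibrium zipper midpoint $k_\mathrm{off}/(w^2 c)$,
then resolved with 16 log-spaced points.  Mean coverage versus `k_on` is
fitted with the Hill form; `k_on` itself is the abscissa because the
Hill coefficient is invariant to linear rescaling, so no
rate-to-concentration calibration is required.

Two facts about this number are worth keeping in mind.  First, it is a
*kinetic* steepness: the equilibrium transition of a cooperative 1-D
lattice is far sharper (of order $w$), and the finite time available
before the read-out length is reached broadens it.  Hence its strong
dependence on `v_grow` noted above — with the default growth rate the
package obtains Hill coefficients near 13 (`w = 40`, `c = 1`) and near
11 (`w = 125`, `c = 1.25`).  Second, per-replicate coverage at
mid-transition is strongly bimodal (a filament either nucleated a
spreading cable in time or it did not), so the mean over 24 replicates
carries substantial noise; the scan density was chosen to keep the
fitted steepness stable to about ±0.7 across seeds.

## First-binding theory on a growing filament

For the *first* arrival on a filament elongating at constant speed, the
master equation with binding rate proportional to current length
$l(t) = v_\mathrm{grow} t$ gives a Rayleigh law: survival
$P_1(t) = e^{-a t^2/2}$ and binding-time density
$P(\tau) = a\tau e^{-a\tau^2/2}$ with $a = k_\mathrm{on}^{(\mathrm{len})}
v_\mathrm{grow}$ (here $k_\mathrm{on}^{(\mathrm{len})}$ is a rate per
nanometre; 4×10⁻⁶ s⁻¹nm⁻¹ reproduces the measured first-binding times).
Binding position is uniform on the current length, so the age of the
bound site follows the erfc density implemented in `site_age_pdf()`.
The discrete-time twin (`simulate_first_binding()`) mirrors the
published stepping scheme exactly — per-step binding probability
$1 - e^{-a t\,\mathrm{d}t}$ — and matches the analytic laws by
Kolmogorov–Smirnov test once $\mathrm{d}t$ is small.  The default step
is $0.02/\sqrt{a}$: the published scheme leaves $\mathrm{d}t$ open, and
we require the per-step binding probability to stay below 0.1 out to the
99.9% quantile of the binding time, which a 5%-of-mode step does not
quite achieve.  `fit_kon()` inverts the Rayleigh law by maximum
likelihood, $\hat a = 2 n_\mathrm{unc} / \sum \tau^2$, with censored
filaments contributing through the survival term — the published
analysis does not state its censoring convention, so the full
right-censored likelihood was chosen and is documented here.

## Where does the second cable land?

Given a first cable of length $L_1$ at position $x_1$ on a filament of
length $L_a$ (all in 100-nm units, the optical resolution), the chance
that a second cable of length $L_2$ lands overlapping the first is
computed by counting placements: $N_1$ doubles every start position
strictly clear of the first cable (both grooves are free there), and
$N_2$ weights each overlapping placement by $c$ per overlapping unit and
1 per non-overlapping unit, every term clamped to $[0, L_2]$; then
$p_2 = N_2/(N_1+N_2)$.  The counting rules are implemented verbatim,
with two consequences worth knowing:

* placements that merely *touch* the first cable satisfy neither the
  strict clear condition nor the overlap branches and are counted
  nowhere; an `inclusive_ends` variant counts them as clear for
  sensitivity analysis;
* when $L_2 > L_1$ a clamped term can credit more overlap than is
  geometrically available, which breaks mirror symmetry in $x_1$ for
  those geometries.  The test suite checks reflection invariance exactly
  in the regime $L_2 \le L_1$ where the rules are symmetric.

`bootstrap_binned_fractions()` re-performs an observed set of events
5000 times with Bernoulli($p_2$) outcomes and summarises overlap
fractions in the occupancy bins 0–12.5%, 12.5–25% and 25–50% (half-open
at the interior edges; occupancy $L_1/2L_a$ cannot exceed 50%).
`estimate_c()` formalises the visual model comparison as a profile
likelihood over a log-spaced grid of $c$, exploiting that
$N_2(c) = A + cB$ is linear in $c$, with a bootstrap CI and a
likelihood-ratio test against $c = 1$.  The LR p-value relies on the
χ²₁ asymptotics: at 100 events the test over-rejects (~13% at nominal
5%), reaching nominal calibration by ~400 events — with few observed
events, trust the bootstrap CI over the LR p-value.

## Residence times

`kaplan_meier()` wraps the standard product-limit estimator
(right-censoring; deaths before censorings at ties) and
`fit_exponential()` fits $f_0 e^{-x/T_1}$ to the curve — the published
mode — or, alternatively, computes the censored MLE
$T_1 = \sum t_i / n_\mathrm{unc}$, which is better behaved under heavy
censoring.  The two agree within sampling error on synthetic exponential
data.  Filtering of non-moving molecules (surface-adsorbed) is an
input-table concern and is deliberately not applied by the package.

## Synthetic data: what it shows and what it does not

Every input table the pipeline consumes can be generated with known
ground truth (`gen_first_binding()`, `gen_second_binding()`,
`gen_residence()`, `gen_occupancy_curve()`); each generator records its
parameters and seed as metadata that travels with the CSV.  The
generators emulate the *statistical structure the models assume* —
Rayleigh binding times, Bernoulli($p_2$) overlap outcomes, exponential
dwells with right-censoring, Hill-shaped occupancies with truncated
Gaussian noise.  Recovery tests against them demonstrate that the
estimators are correctly implemented and consistent; they cannot
demonstrate that real filaments obey the models.  In particular:
geometry distributions for second-binding events are not constrained by
data (defaults populate all three occupancy bins; configurable);
occupancy noise is additive Gaussian, whereas real intensity
measurements are heteroscedastic; and the observation model includes no
point-spread optics, camera noise, or photobleaching.

## Numerical choices and degenerate inputs

* Event selection uses a compiled binary sum-tree over per-site
  propensities (O(log N) per event); randomness comes from R's RNG, so
  `set.seed()` gives bit-identical trajectories, event logs replay
  exactly, and every stochastic function is reproducible.
* Total propensity 0 (empty lattice, `k_on = v_grow = 0`) is an
  absorbing state and is signalled via the trajectory status rather than
  looping forever; an event cap (default 10⁸) guards runaway runs.
* Hill fitting is parameterised as a logistic in $\log[L]$
  ($\log EC_{50}$ and $n$), which stays conditioned for very steep
  curves where $K_d = EC_{50}^{\,n}$ under- or overflows; the optimiser
  is Levenberg–Marquardt with a logit-log initialiser, and perfect
  (zero-residual) data are handled.  Data that do not span half-maximal
  occupancy are rejected rather than extrapolated.
* Exponential curve fits start from a log-linear regression;
  `transfer_matrix_coverage()` rescales running products to avoid
  overflow at large $K w^2$ and warns if the dominant eigenvalue is
  near-degenerate.
* Problem sizes in the test suite (lattice lengths 2–300 sites, 24
  replicate filaments per scan point, 5000-event KS samples, 100-seed CI
  coverage sweeps) were chosen so the full suite completes in a few
  minutes while keeping every statistical tolerance at 3 standard
  errors or a 1% KS level.

## Known limitations

* No sub-footprint lattice resolution (defects smaller than one
  footprint cannot exist) and no cable sliding — deliberate
  simplifications inherited from the model definition.
* The boundary-velocity tracker handles one cable region per kymograph.
* The apparent Hill coefficient of the simulated coverage transition
  depends on the assumed `v_grow` (see above); comparisons against
  published simulated values inherit that assumption.
* Growing-filament "equilibrium" is ill-defined; the equilibrium oracles
  apply to fixed lattices only.
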