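# tpmcable

Stochastic and analytic models of cooperative tropomyosin loading on
growing actin filaments.

Tropomyosin dimers polymerise end-to-end into two "cables" that run
along the two helical grooves of an actin filament. Loading of
fission-yeast tropomyosin (Cdc8) onto elongating filaments is highly
cooperative — single molecules bind weakly, yet cables nucleate, spread
and saturate filaments over a very narrow concentration range. This
package is for biophysicists who want to dissect that behaviour
quantitatively: it separates **end-to-end cooperativity** (a factor *w*
applied for each bound same-groove neighbour) from **indirect,
cross-strand cooperativity** (a factor *c* applied across the filament),
and provides the estimators needed to quantify single-filament imaging
data.

## What is inside

* **Two-row lattice kinetic Monte Carlo** (`simulate_lattice()`,
  compiled core): sites of 21.6 nm (one tropomyosin footprint, 8 actin
  monomers) in 2 grooves × N columns; an empty site binds at
  `k_on * w^a * c^b` and an occupied one unbinds at `k_off / (w^a c^b)`,
  with `a` the occupied same-row neighbours and `b` the opposite-site
  occupancy; filament growth is a KMC event of rate `v_grow` that sets
  `N = floor(t * v_grow)`. In a fully coated cable the effective
  single-molecule off-rate is `k_off / (w^2 c)`.
* **Exact equilibrium oracles**: configuration enumeration and a 4×4
  transfer matrix for the stationary law
  `pi ∝ K^n (w^2)^p_row (c^2)^p_cross` (`enumerate_equilibrium()`,
  `transfer_matrix_coverage()`), used as ground truth for the simulator.
* **TIRF-like observation model**: 20% stochastic labeling, ±4-site
  (~100 nm) optical broadening, groove summation to fluorescence levels
  {0, 1, 2}; kymographs, coverage read-outs at a target filament length,
  and cable-edge spreading velocities
  (`coverage_at_length()`, `render_kymograph()`,
  `estimate_boundary_velocity()`).
* **First-binding theory on a growing filament**: survival
  `P1(t) = exp(-k_on v_grow t² / 2)`, Rayleigh binding-time density,
  erfc site-age density, a discrete-time Monte Carlo twin, and a
  censoring-aware maximum-likelihood fitter for the per-length
  association rate (`first_binding_pdf()`, `simulate_first_binding()`,
  `fit_kon()`).
* **Second-cable placement counting**: N1/N2/p2 counts for the chance
  that a second cable lands opposite the first, a 5000-replicate
  bootstrap binned by occupancy, and a profile-likelihood estimator of
  the indirect-cooperativity factor (`overlap_probability()`,
  `bootstrap_binned_fractions()`, `estimate_c()`).
* **Residence-time analysis**: Kaplan–Meier with right-censoring and
  single-exponential fitting, `f(x) = f0 exp(-x / T1)`, giving `T1` and
  `k_off` (`kaplan_meier()`, `fit_exponential()`).
* **Quantification**: Hill fits `theta = [L]^n / (K_d + [L]^n)` with a
  well-conditioned log-logistic parameterisation, free-tropomyosin
  correction, severing-rate arithmetic (`fit_hill()`,
  `free_concentration()`, `severing_rate()`).
* **Synthetic data generators** for every table the pipeline consumes,
  with ground truth recorded as metadata (`gen_first_binding()`,
  `gen_second_binding()`, `gen_residence()`, `gen_occupancy_curve()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()`
and `glance()` on fitted objects, `autoplot()` on result types.

## Worked example

Where does a second cable land?  For a 1-µm filament (10 grid units of
100 nm) carrying a 200-nm first cable at position 4, a 200-nm second
cable has 8 placements strictly clear of the first (both grooves free)
and, with a mild cross-strand preference `c = 1.25`, a weighted overlap
count of 7:

```r
library(tpmcable)
g <- tibble::tibble(La = 10, L1 = 2, x1 = 4, L2 = 2)
overlap_probability(g, c = 1.25)
#> # A tibble: 1 × 7
#>      La    L1    x1    L2    N1    N2    p2
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1    10     2     4     2     8     7 0.467
```

so the second cable overlaps the first 47% of the time (6/14 = 43% if
binding is indifferent, `c = 1`).

How cooperative does loading *look* in a coverage titration?  Scan the
lattice model over binding strength, read TIRF-like coverage at 6 µm
over 24 replicate filaments per point, and fit a Hill curve:

```r
set.seed(1)
h <- hill_from_lattice(k_off = 116.8, w = 40, c = 1)
h
#> <lattice_hill> k_off = 116.8, w = 40, c = 1: Hill n = 13.6 (EC50 at k_on = 0.0794 /s)
```

A microscopic `w` of 40 presents as an apparent Hill coefficient near
14: end-to-end contacts alone make loading look far steeper than the
one-site picture. The steepness is kinetic — it also depends on the
actin growth rate (default 2.2 sites/s ≈ 47.5 nm/s); see the vignette.

Residence times with censoring:

```r
d <- gen_residence(T1 = 13.7, censor_time = 60, n = 102, seed = 1)
fit_exponential(d)   # Kaplan-Meier curve + exponential fit
#> <exp_fit (km-curve)> f0 = 1.071, T1 = 13.47 s, k_off = 0.07425 /s
```

recovering the ground-truth dwell scale (13.7 s, the effective
`k_off / w² / c` of the fitted end-to-end parameter set) from 102
partially censored tracks.

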