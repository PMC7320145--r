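---
title: "Methods: enzyme-buffering analysis of NADH channeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-buffering analysis of NADH channeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chankin)
```

This vignette documents the models, the numerical choices and the open
design decisions behind `chankin`.  Units are fixed package-wide: uM for
concentrations, minutes for kinetic time (seconds for sedimentation),
U/mg (umol min^-1 mg^-1) for specific activity.

## 1. The binding equilibrium

The enzyme-buffering assay runs in the tight-binding regime: donor
NADH-binding sites (100-480 uM) vastly exceed NADH (10-40 uM), which in
turn is comparable to or above the donor Kd (0.8-8.2 uM).  Free NADH must
therefore come from the exact single-site mass balance; the free-ligand
approximation is off by orders of magnitude here.  `free_ligand()` solves
the quadratic

$$ L_f = \tfrac12\left(-(S_t - L_t + K_d) +
   \sqrt{(S_t - L_t + K_d)^2 + 4 K_d L_t}\right) $$

in a cancellation-safe form: when the linear coefficient
$b = S_t - L_t + K_d$ is positive (donor excess — the standard assay
regime) the root is computed as $2 K_d L_t / (b + \sqrt{b^2 + 4 K_d L_t})$,
which avoids subtracting nearly equal numbers.  Every returned root is
checked against the equilibrium relation
$[S]_f [L]_f / [SL] = K_d$ (relative residual $10^{-8}$) with a bisection
fallback; the test suite verifies agreement with an independent
root-finding oracle to $10^{-9}$ relative over a $10^{-3}$–$10^{3}$ uM
grid.

Assumptions: one effective Kd per donor, sites independent and identical.
GAPDH's documented negative cooperativity (site affinities spread over
orders of magnitude in some species) is deliberately *not* in the default
model — the assay analysis historically uses one Kd per enzyme and the
fluorescence titrations resolve one effective constant.  A two-class-site
mass balance (`free_ligand_multisite()`) is provided for sensitivity
analyses but is used nowhere by default.

All site concentrations are per NADH-binding site; tetramer conversions
are explicit (`sites_from_tetramer()`), never implicit.

### Kd from fluorescence titrations

`fit_binding_isotherm()` fits $S = S_0 + \Delta S\, f_b(K_d)$ where $f_b$
is the bound-site fraction from the exact quadratic — ligand depletion is
*not* ignored because the titrations run sites at ~1 uM, comparable to the
Kd.  The fit profiles the Kd on a log scale (at fixed Kd the model is
linear in $S_0, \Delta S$, solved exactly), then reports a delta-method
standard error from the full three-parameter Jacobian.  $\Delta S$ is
free, so quenching (signal down) and FRET/anisotropy (signal up) modes are
handled without mode-specific assumptions; flat or non-monotone signals
are rejected with a diagnostic rather than fitted.  Fitting is unweighted
least squares — the four readout modes have different, unknown error
scales, and the per-enzyme summary is in any case the unweighted mean and
SD across modes (`aggregate_kd()`), matching how multi-mode Kd tables are
conventionally averaged.  The two excitation/emission pairs quoted for
protein fluorescence in different sources (295/328 vs 290/335 nm) are
metadata only; they never enter a computation.

## 2. Initial rates from progress curves

NADH oxidation is followed at 340 nm ($\varepsilon$ = 6220 M^-1 cm^-1).
Two regimes:

* **Linear** (starting NADH >= 30 uM): OLS slope over the earliest points.
  The window is defined by consumption, not time: points until 5% of the
  initial NADH is consumed (`window_fraction = 0.05`).  The mean rate over
  a window consuming a fraction $f$ understates the $t = 0$ rate by about
  $f/2$ in this assay (the rate tracks remaining substrate nearly
  linearly below K~M~), so 10% consumption would already bias the rate by
  ~5%; 5% keeps the bias near 2%, within the 3% agreement the test suite
  enforces against the kinetic model's instantaneous rate.
* **Exponential** (starting NADH < 30 uM): $c(t) = A e^{-kt} + c_\infty$,
  $v_0 = A k$, initialised from a log-linear regression and fitted with
  Levenberg–Marquardt.  The functional form is a design choice (none is
  prescribed by the assay description); it is exact for a first-order
  approach to completion and its $v_0$ is offset-invariant.

The 30-40 uM gap between the stated regimes is assigned to the linear
method (a 40 uM starting point loses too few points to curvature to need
the exponential form).  Scattering drift from slowly precipitating donor
enzyme is removed by linear interpolation of a blank trace onto the curve
grid and pointwise subtraction (`subtract_scatter_baseline()`).

## 3. The channeling analysis

For each assay point the free-diffusion prediction is
$V_{cal} = V_{max} [NADH]_f / (K_M + [NADH]_f)$ with $[NADH]_f$ from the
exact equilibrium, and the channeling ratio is the plain quotient
$R = v_{meas} / V_{cal}$ (the ratio description in the source material
fixes it as a quotient; no other form is consistent with "ratio between
measured and calculated activity").  The channeled profile is the excess
$v_{chan} = v_{meas} - V_{cal}$, retained even when negative so that the
no-channeling null is unbiased rather than clipped at zero.

For NADH-titration designs the channeled profile is fitted by
Michaelis–Menten kinetics.  The substrate axis is the donor-NADH complex
concentration ($L_t - L_f$), the species actually feeding the channeled
path; since binding is tight this is numerically close to total NADH, and
the conventional total-NADH axis is available via
`substrate_axis = "total_nadh"`.  Apparent constants from this fit
describe the *competition* between channeled and diffusive paths, not an
elementary binding step — which is why the apparent K~M~ values exceed
the free-NADH K~M~ (a property the test suite asserts on model-generated
data).

Uncertainty on $V_{cal}$ is first-order (delta-method) propagation of the
Kd and Michaelis-constant errors (`calc_vcal_se()`); the source tables
quote plain "+/-" values without a stated method, and the delta method is
the standard first-order choice.

The antibody control (`diffusion_limit_check()`) detects a high-antibody
plateau (last two points within 10%) and compares it with $V_{cal}$: bulky
antibodies block the protein-protein path, so the plateau should fall to
the diffusion prediction (default pass tolerance 15%).

## 4. The transient-complex mass-action model

Species: free acceptor sites L, free donor sites G, free NADH N, binary
complexes GN and LN, ternary complex LGN, product NAD+.  Reactions:

| reaction | constants | meaning |
|---|---|---|
| G + N ⇌ GN | `kon_gn`, `koff_gn` | donor loading |
| L + N ⇌ LN | `kon_ln`, `koff_ln` | diffusive capture |
| L + GN ⇌ LGN | `kon_cx`, `koff_cx` | transient complex |
| LGN → LN + G | `k_transfer` | channeled delivery |
| LN → L + NAD+ | `kcat` | turnover |

Pyruvate (630 uM, saturating and held fixed in every assay) is folded into
`kcat`.  Subunit geometry is not modelled: L and G are independent site
pools.  The channeled delivery is one lumped first-order step; internally
the LN pool and the product are tagged by delivering path (the tag is
dropped if LN releases its NADH back to solution), which makes
`flux_partition()` exact — product is attributed to the capture event that
led to turnover — without altering the total kinetics.

**Calibration** (`calibrate_rate_constants()`).  The acceptor branch is
made to reproduce a macroscopic Vmax/K~M~ pair under Briggs–Haldane
kinetics: `kcat = Vmax * Mr_site` (140 U/mg × 35 kDa = 4900 min^-1 per
site) and `kon_ln = (koff_ln + kcat) / Km`.  A 100 uM^-1 min^-1
association rate cannot realise K~M~ = 4.4 uM with that kcat
(`kon * Km < kcat`), so the NADH capture rate defaults to
2000 uM^-1 min^-1 (~3×10^7 M^-1 s^-1, a typical nucleotide-binding rate),
giving `koff_ln` = 3900 min^-1.  Protein–protein steps default to
100 uM^-1 min^-1 (~1.7×10^6 M^-1 s^-1, sub-diffusion-limited), and
`koff_cx` defaults to 20000 min^-1 — a ~3 ms complex lifetime, the
"transient" premise of the whole mechanism.

**Transfer coupling.**  Channeled delivery is NADH release *within* the
complex followed by capture at the adjacent site, i.e. the same
bond-breaking event as release to solution; the default therefore couples
`k_transfer = transfer_enhancement × koff_gn`.  An instructive exact
cancellation follows: in the tight-binding regime
$[NADH]_f \approx K_d L_t / (S_t - L_t)$ is proportional to `koff_gn`
(at fixed `kon_gn`), and so is the coupled transfer rate — so an
*uncompensated* off-rate increase accelerates the channeled and the
diffusive paths by the same factor, and the channeled flux fraction is
invariant to first order.  The off-rate dependence is resolved by the
*Kd-compensated* sweep (`offrate_sweep(..., compensate_kd = TRUE)`), which
raises `koff_gn` at fixed Kd and shows the channeled fraction and the
measured/calculated ratio rising monotonically — the off-rate-overlap
mechanism: delivery succeeds when NADH release overlaps the complex
lifetime, $p = k_{transfer}/(k_{transfer} + k_{off,cx})$, and fails when
the complex is too short-lived ($k_{off,cx} \to \infty$ drives the
channeled fraction to zero).

**Donor presets** (`donor_rate_constants()`).  Two anchor donors drive the
synthetic studies: "tight" (Kd 0.8 uM, `transfer_enhancement` 30,
`kon_cx` 100) and "weak" (Kd 8.2 uM, `transfer_enhancement` 50,
`kon_cx` 500).  Because of the cancellation above, a tenfold off-rate
difference alone cannot produce the large channeling contrast the
buffering assay resolves between weak- and tight-binding donors; the
measured rate excesses imply roughly an order of magnitude more
per-complex delivery for the weak donor than its off-rate ratio provides.
The weak preset therefore carries a stronger acceptor interface (faster
complex association and larger within-complex release enhancement) as a
structural property of that donor.  With these presets the generated
ratio ranges are ~1.2–1.9 (tight, 100–240 uM sites) and ~2.2–3.9 (weak,
240–480 uM sites), and the weak donor channels more at any shared
condition — the contrast the tests assert.  These are generator
conditions, chosen once; they are not fitted quantities.

**Steady rate** (`steady_rate()`).  Mirrors the assay protocol: donor and
NADH are pre-equilibrated (closed-form, exact for the G+N subsystem),
acceptor is added last, and the network integrated.  The initial steady
rate is read as the instantaneous turnover flux `kcat*[LN]` just after the
acceptor-loading transient (probe at `max(0.004, 6/(koff_ln+kcat))` min).
A finite-window slope was rejected: substrate depletion over any usable
window biases it by 1–3%, visible against the no-channeling null.  A
drift diagnostic warns when the rate is still changing >10% beyond the
probe time.

**Integration.**  `deSolve::lsoda` (stiff-capable), `rtol` 1e-8, `atol`
1e-12 uM.  Pool conservation (L, G, N) is asserted along every test
trajectory at 1e-8 relative; binding-only equilibria are checked against
the closed-form two-pool mass balance at 1e-6.

## 5. Sedimentation velocity

`simulate_lamm()` solves the Lamm equation
$\partial_t c = \frac{1}{r}\partial_r ( r D \partial_r c - s\omega^2 r^2 c )$
by a conservative finite-volume discretisation on a uniform radial grid
(central differences, zero-flux ends) integrated in time by a banded
stiff solver — a Claverie-type numerical solution in the
method-of-lines idiom.  The discrete invariant $\sum_i c_i r_i \Delta r$
(sector geometry) is conserved to machine precision by construction
(`lamm_mass()`); grid refinement changes mid-cell profiles by <0.5% at the
default resolutions, and the early-time solution matches the Faxén
approximation (radially diluted plateau $c_0 e^{-2 s\omega^2 t}$ with an
error-function boundary at $r_m e^{s\omega^2 t}$) within 1% at mid-cell.
A cell-Peclet diagnostic (`s\omega^2 r \Delta r / D > 2`) rejects grids
too coarse for the chosen species rather than producing an oscillating
front.

Defaults: meniscus 5.9 cm, bottom 7.2 cm (standard 12-mm double-sector
cell), 300-500 radial points (the instrument's 30 um radial increment
gives 433), scans every 240 s.  The quoted centrifugal field
"40,000 × g" is a relative force, not a rotor speed; the package defaults
to 25,000 rpm (mid-cell RCF ≈ 45,000 g; a 7.5 S species traverses ~60% of
the cell in 7 h, matching the experiment's scale) and exports
`rcf_to_rpm()` so the conversion is always explicit.  The diffusion
coefficient defaults to the Svedberg relation
$D = sRT/(M_r(1-\bar v \rho))$.

`fit_single_species()` is nonlinear least squares over (s, Mr, loading)
with the solver as forward model; loading enters linearly and is solved by
projection, leaving a 2-D Nelder–Mead search in log(s), log(Mr).  The fit
excludes 0.05 cm at the meniscus and 0.15 cm at the bottom: optical
artefacts live at the meniscus, and the steep back-of-cell accumulation
layer is discretisation-dominated while carrying no boundary information.
`detectability_report()` then simulates the same loading with a fraction
self-associated into a 2× mass dimer (s scaled by $2^{2/3}$, the
constant-shape scaling) and asks whether that profile deviates from the
single-species fit by more than the fit's own residual noise floor; a
clean single-species fit therefore bounds the interaction Kd from below
through the in-cell arithmetic `kd_from_association()` (fraction $f$ of a
$c$/$c$ mixture complexed: $K_d = (c - fc)^2 / (fc)$).

## 6. What the generators emulate — and what they do not

All generators draw multiplicative Gaussian noise (relative SD
`noise_sd`, default 0.02, the scale of routine assay reproducibility) and
are byte-reproducible under a fixed seed.  They emulate: the four
fluorescence titration designs (log-spaced ligand grids around the Kd,
signal direction per mode), the buffering-assay grids (donor titration at
fixed 40 uM NADH — 100-240 uM sites tight, 240-480 uM weak; NADH
titration 10-40 uM at fixed donor), 340-nm progress curves with optional
linear scattering drift, antibody competition (single-site antibody
occupancy; channeled path scaled by $1-\theta$, free path by
$1-\alpha\theta$ with $\alpha = 0.1$ for mild steric inhibition), and
noisy radial scans at the instrument's increment and cadence.

They do **not** emulate: negative cooperativity or NAD+ competition,
inner-filter effects in fluorescence, product inhibition, instrument
artefacts (lamp flicker, radial calibration error), or pyruvate-dependent
changes in the acceptor's Michaelis constants.  Passing tests therefore
demonstrate that the *analysis* inverts data generated under its own
assumptions at realistic noise — not that those assumptions exhaust real
assay behaviour.

## 7. Problem sizes and known limitations

The test suite runs the null-control study at 200 seeded replicates of a
6-point grid (sharing the deterministic model rates across replicates —
exactly the generator's statistical model, computed once), single
sedimentation fits at 150-cell forward grids with 6 scans, and off-rate
sweeps over 3-point grids; these sizes resolve every asserted property
comfortably while keeping the suite fast.

Limitations worth restating: one effective Kd per donor (no cooperativity);
the channeled step is lumped (release-then-capture is not resolved, so
`transfer_enhancement` absorbs interface geometry); acceptor turnover is
capped at the free-NADH `kcat`, so measured rates exceeding the free-NADH
Vmax — which the buffering assay can produce, since Michaelis constants
depend on the fixed pyruvate level — are outside the model; the AUC
module fits exactly one species (no c(s) distributions, no
time-invariant-noise decomposition); and the pipeline deliberately stops
at initial rates rather than globally fitting progress curves to the
kinetic scheme.
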