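# chankin

Enzyme-buffering analysis of NADH substrate channeling between
dehydrogenases.

## The problem

In cytosol-mimicking conditions almost every NADH molecule is bound to
glyceraldehyde-3-phosphate dehydrogenase (GAPDH), the most abundant
NAD(H)-binding enzyme.  Whether lactate dehydrogenase (LDH) can still draw
NADH directly from the GAPDH–NADH complex — substrate channeling through a
transient LDH-(GAPDH-NADH) encounter complex — is tested with the
*enzyme-buffering assay*: measure LDH activity in a large excess of GAPDH,
predict what free-NADH diffusion alone could deliver, and ask whether the
measured rate exceeds the prediction.

`chankin` implements that analysis end to end for kineticists working with
donor/acceptor dehydrogenase pairs:

* **Binding equilibrium** — the exact single-site tight-binding mass
  balance.  With total site concentration *S<sub>t</sub>*, total ligand
  *L<sub>t</sub>* and dissociation constant *K<sub>d</sub>*,

  *L<sub>f</sub>* = ½ ( −(*S<sub>t</sub>* − *L<sub>t</sub>* + *K<sub>d</sub>*) +
  √( (*S<sub>t</sub>* − *L<sub>t</sub>* + *K<sub>d</sub>*)² +
  4 *K<sub>d</sub> L<sub>t</sub>* ) ),

  evaluated in a cancellation-safe form (`free_ligand()`), plus
  *K<sub>d</sub>* estimation from fluorescence titrations in four detection
  modes (`fit_binding_isotherm()`).
* **Free-diffusion prediction and channeling ratio** —
  *V*<sub>cal</sub> = *V*<sub>max</sub> [NADH]<sub>f</sub> /
  (*K*<sub>M</sub> + [NADH]<sub>f</sub>), the ratio
  *R* = *v*<sub>measured</sub> / *V*<sub>cal</sub> (R ≈ 1: diffusion only;
  R > 1: channeling), channeled-profile subtraction and apparent
  Michaelis–Menten constants for the GAPDH–NADH complex as substrate
  (`channeled_profile()`), and the antibody-competition diffusion-limit
  control (`diffusion_limit_check()`).
* **Initial-rate extraction** from 340-nm progress curves, linear or
  exponential regime, with scattering-baseline subtraction
  (`initial_rate()`, `subtract_scatter_baseline()`).
* **Mass-action model** of the parallel channeled and diffusive paths
  through a transient LDH-(GAPDH-NADH) complex, with flux partitioning and
  off-rate sweeps (`build_scheme()`, `simulate_scheme()`, `steady_rate()`,
  `flux_partition()`, `offrate_sweep()`).
* **Sedimentation-velocity toolkit** — a conservative finite-volume Lamm
  equation solver (Claverie-type), single-species fits, and the
  self-association detectability bound
  (`simulate_lamm()`, `fit_single_species()`, `kd_from_association()`).
* **Seeded synthetic-data generators** for every input family, so the whole
  pipeline is testable without instrument data (`gen_titration()`,
  `gen_buffering_dataset()`, `gen_progress_curves()`,
  `gen_antibody_series()`, `gen_scans()`).

Units throughout: concentrations in uM, time in minutes (seconds for AUC),
specific activity in U/mg (1 U = 1 umol/min).

## Worked example

```r
library(chankin)

## how much NADH does a tight donor sequester?
free_ligand(240, 40, 0.8)        # 0.159 uM free of 40 uM total
100 * bound_fraction(240, 40, 0.8)  # 99.6 % bound

## free-diffusion prediction for the acceptor
mm <- michaelis_params(vmax = 140, km = 4.4)
calc_vcal(40, 240, 0.8, mm)      # 4.89 U/mg

## a synthetic NADH titration in the buffered regime, analysed
k  <- donor_rate_constants("tight")
ds <- gen_buffering_dataset(k, "titrate_nadh_fixed_gapdh",
                            nadh_uM = c(10, 16, 22, 28, 34, 40),
                            gapdh_sites_uM = 200, noise_sd = 0.02, seed = 1)
channeled_profile(ds)
#> Enzyme-buffering channeling analysis (titrate_nadh_fixed_gapdh)
#>   ratios 1.67 - 2.12 over 6 points
#>   apparent constants for the donor-NADH complex as substrate:
#>     Michaelis-Menten: Vmax = 9.767 +/- 1.9 U/mg, Km = 51.57 +/- 16 uM

## AUC sensitivity: what Kd would 10% association at 6 uM each imply?
kd_from_association(6, 6, 0.10)  # 48.6 uM
```

The measured/calculated ratios above 1 and an apparent K<sub>M</sub> far
above the free-NADH K<sub>M</sub> (4.4 uM) are the channeling signature:
the acceptor is being fed by the donor–NADH complex, whose delivery
competes with the diffusive path.

`run_full_analysis()` orchestrates the same steps from CSV inputs and a
configuration list (or YAML file) and writes per-stage CSV tables plus a
JSON manifest; `validate_inputs()` checks the file schemas first.

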