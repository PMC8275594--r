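---
title: "Methods: SWIR photon transport in lactate-bearing finger tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SWIR photon transport in lactate-bearing finger tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(swirlmc)
```

This vignette records the model, the estimators, and the judgment calls
behind `swirlmc`, in the spirit of a lab notebook for maintainers: what is
assumed, why each default has the value it has, and what the test suite
does and does not demonstrate.

## The tissue model

The region of interest is a finger phalanx, idealized as a 13 mm × 13 mm
laterally finite slab of seven plane-parallel layers. From the surface
down: stratum corneum (0.02 mm, 5% water), epidermis (0.25 mm, 20% water,
2% melanin), papillary dermis (0.1 mm, 4% blood, 50% water), upper blood
net dermis (0.08 mm, 30% blood, 60% water), reticular dermis (0.2 mm, 4%
blood, 70% water), deep blood net dermis (0.3 mm, 10% blood, 70% water),
and hypodermal fat filling the slab to 13 mm. The dermal sublayer
thicknesses and fractions are the standard multilayer-skin values; the
stratum corneum and epidermis thicknesses are chosen so the papillary
dermis spans 0.27–0.37 mm, anchoring the depth scale used by the noise
criterion below. The hypodermis gets 5% blood and 70% water, the usual
subcutaneous values in this family of models. Every entry is overridable
via `finger_layer_spec()` or the YAML model config
(`inst/extdata/finger_model.yaml`).

Per-layer absorption is a chromophore volume-fraction mixture
(`layer_absorption()`): blood, water and (in the epidermis) melanin terms,
with the remaining volume charged at the absorber-free scaffold baseline
$\mu_{at}(\lambda) = 7.84\times10^{8}\,\lambda^{-3.255}$ mm$^{-1}$
($\lambda$ in nm). Two notes on that baseline. First, the melanin term is
an extension of the published two-absorber mixture: the property table
supplies a melanin coefficient, so it must enter exactly one layer, and it
is budgeted inside the residual so fractions never exceed unity. Second,
the baseline constant is taken at face value in mm$^{-1}$, consistent with
every other tabulated coefficient; at 1310 nm it contributes
$\approx 0.056$ mm$^{-1}$, a few percent of a typical dermal
$\mu_a$. Both the constant and exponent are arguments in case a per-cm
convention is ever preferred.

Blood absorption (`blood_absorption()`) mixes lactate and lipid only:
$\mu_{ab} = V_{lact}\,\mu_{a,lact} + V_{lip}\,\mu_{a,lip}$. Water inside
blood is not double-counted here because the layer water fractions already
include plasma water. The lactate coefficient is calibrated on a
100 mmol/L in-vitro solution, so $V_{lact} = C_{lact}/100\,$mmol/L
(`lactate_volume_fraction()`, reference concentration configurable). The
blood lipid fraction defaults to $V_{lip} = 0.01$; the source material
requires the term but gives no value, and at the tabulated lipid
coefficients its contribution to $\mu_{ab}$ is comparable to the lactate
term at physiological concentrations.

Scattering uses the tabulated skin or fat column as the layer's $\mu_s$,
with a single anisotropy $g = 0.9$ and refractive index $n = 1.4$ for all
layers and wavelengths. Internal interfaces are index-matched; only the
air–tissue surface reflects and refracts. These are stated modelling
choices of the study design, not fitted quantities.

## The transport engine

`run_simulation()` drives a compiled weighted-photon (implicit-capture)
kernel:

* **Launch.** Positions from a circular Gaussian whose 1/e² intensity
  radius is the source radius (0.1 mm), truncated at two radii; normal
  incidence; initial weight $1 - R_{spec}$ with
  $R_{spec} = ((n-1)/(n+1))^2 \approx 0.0278$. A flat-top profile is
  available behind `beam_profile = "flat"`.
* **Propagation.** Dimensionless optical path $\tau = -\ln \xi$; sampled
  steps are clipped at layer interfaces and resumed with the remaining
  $\tau$, so layer-dependent $\mu_t$ is handled without approximation.
* **Interaction.** Deposit $w\,\mu_a/\mu_t$, then redirect by the
  Henyey–Greenstein inverse CDF with uniform azimuth.
* **Surface.** Beyond the critical angle $\arcsin(1/1.4) \approx 45.6°$,
  total internal reflection; otherwise transmission with probability
  $1 - R(\theta)$ (unpolarized Fresnel average). Transmitted packets leave
  with their full current weight.
* **Termination.** Packets exiting the lateral faces or the bottom are
  pooled as escaped; Russian roulette triggers below weight $10^{-4}$ with
  survival probability 0.1 (standard multilayer-MC practice; survivors are
  boosted by 1/0.1, keeping every estimator unbiased). A safety cap of
  $10^5$ events per packet exists; a warning fires if more than 0.1% of
  packets ever reach it (none do in the shipped configurations).

With roulette disabled the weight ledger closes identically:
launched = detected + absorbed + escaped, to better than $10^{-9}$
relative (the engine accumulates in extended precision). With roulette
enabled the same identity holds in expectation — note the boosted
survivors already flow into the budgets, so the kill ledger
(`roulette_lost_weight`) is diagnostic, not a term of the balance.

The engine carries its own xoshiro256++ generator seeded from the
configuration, so results are bit-identical for a given seed and chunk
count, independent of R's RNG state. Work can be split into chunks with
splitmix-derived per-chunk seeds (`n_chunks`), which is the reproducible
unit for any future parallelism; the shipped code runs chunks sequentially.

**Detection.** The geometry places a detector of radius 0.2 mm at
separation $d \in \{0.7, 1.0, 1.5\}$ mm. Two scorings are provided.
`detector_shape = "ring"` (default) accepts every surface exit whose
radial distance from the beam axis is within the detector radius of $d$ —
the azimuthally integrated scoring natural to a cylindrically symmetric
problem. `"disk"` accepts only exits inside the physical disk at
$(d, 0)$. The two see the same mean intensity at radius $d$ and differ by
the collection area (ring ≈ $4d/r$ times the disk). The ring default was
fixed after an energy-conservation analysis of the study's reported power
table: read as true disk powers (% of incident through 0.126 mm²), the
reported values integrate to more than the total incident power over the
sampled annuli, which is unphysical; read as azimuthally integrated
powers they are consistent, and the simulated ring powers land on their
scale (the disk scoring sits 14–46× below across the grid). The
acceptance suite therefore compares ring powers against the reported
table.

## Estimators

* **Relative power** — detected weight as a percentage of the *incident*
  (pre-specular) weight, so "% of input power" means the power a source
  actually emits. Equivalently the mean detected intensity times the
  collection area over the input power; both forms are computed and
  asserted equal.
* **Absorbance** — $-\log_{10}$(detected/incident); zero detected weight
  returns `Inf` with a diagnostic rather than an error.
* **Mean penetration depth $D_M$** — mean of each detected photon's
  maximum $z$. The default weights each detected packet by its exit
  weight: a packet of weight $w$ stands for $w$ analog photons, so the
  weighted mean is what an analog (unweighted) simulation — such as the
  $10^9$–$10^{10}$-photon runs this package's conditions emulate at
  $10^5$–$10^6$ weighted packets — would report as its per-photon mean.
  The unweighted per-packet mean is available (`weighted = FALSE`); it
  runs 0.3–0.5 mm deeper because implicit capture keeps long, deep,
  low-weight paths alive that analog transport would have absorbed.
* **Concentration response** — `concentration_sweep()` defaults to exact
  perturbation reweighting: one simulation at the reference
  concentration, then each detected packet mapped to any other
  concentration by $\exp(-\sum_l \Delta\mu_{a,l} L_l)$ using its recorded
  per-layer pathlengths $L_l$. Because scattering is
  lactate-independent, this is the exact likelihood ratio, every path is
  shared across concentrations, and the $\sim 10^{-4}$ a.u. per mmol/L
  absorbance slopes carry no sampling noise beyond the single shared
  run. Plain common-seed reruns (`method = "rerun"`) are kept for checks
  that need independent realizations — at feasible photon counts their
  slope estimates are noise-dominated, which is why the perturbation
  estimator is the default.

## Sensor-design scoring

`score_design()` formalizes three criteria per grid cell: `noise_ok`
($D_M$ beyond the bloodless-layer bottom, default 0.27 mm — the signal
must come from vascularized tissue), sensitivity (absolute OLS slope of
absorbance versus concentration, closed-form normal equations), and
`power_ok` (relative power ≥ 0.1% by default; the study accepts ≈1% and
rejects ≈0.005%). `select_optimal()` filters on the two boolean criteria
and maximizes sensitivity, tie-breaking to larger wavelength then smaller
separation. This is one concrete formalization of what was a qualitative
multi-criteria judgment; with the shipped table the sensitivities of the
lactate-peak cells agree to within ~15% (they scale as
$\mu_{a,lact}(\lambda)$ times the detected blood pathlength), so the
formalized optimum can land on a neighboring lactate-peak cell (2299 nm,
where the tabulated lactate coefficient is largest) rather than the
1684 nm choice reached qualitatively in the source study. The acceptance
suite records this divergence rather than hiding it.

## Validation fixtures and what the tests show

Degenerate media with independent oracles exercise the engine end to end:

* **Beer–Lambert slab** — $\mu_s = 0$, matched boundaries; bottom-escape
  fraction must equal $e^{-\mu_a L}$ (closed form) within 3 MC standard
  errors.
* **Semi-infinite albedo-0.9 isotropic medium** — total diffuse
  reflectance against a frozen value (0.41507) computed by an unweighted,
  pure-R, brute-force sampler written and run before the engine existed,
  and agreeing to five decimals with the H-function closed form
  $1 - H(1)\sqrt{1-a}$. Engine and oracle must agree within combined
  3 SE. The paired forward-peaked case ($g=0.9$) must reflect less.
* **Azimuthal symmetry** — a centered beam on laterally homogeneous
  layers must give uniform exit azimuths (χ² over 12 sectors, α = 0.01);
  a deliberately decentered beam is the negative control.
* **Moment and distribution checks** — HG mean cosine = $g$,
  Kolmogorov–Smirnov uniformity of the isotropic limit, exponential
  free-path mean, Fresnel closed forms, roulette unbiasedness, bit-exact
  seed determinism.

Perturbed property tables (`perturb_property_table()`, unit-mean
log-normal factors at a given coefficient of variation) support
robustness experiments on the design selection.

What passing these tests shows: the transport physics, estimators and
bookkeeping are correct for plane-layered media under the stated optical
constants. What they do not show: fidelity of the anatomy (homogeneous
slabs, no vessels, nail, bone or curvature), of the property table
(coefficients carry experimental uncertainty), or of any in-vivo
prediction.

## Problem sizes and numerical choices

The shipped analyses use $10^5$–$10^6$ weighted packets per grid cell
(the acceptance runs use $10^6$ for the reported-power cells and
$3\times10^5$ elsewhere), chosen so each relative power carries a ~1–3%
relative standard error — small against the ±50% reproduction band used
for the reported table. Event maps default to 0.02 mm voxels over a
bounded region around the source–detector span, accumulated along
detected-photon paths only (the classic source-to-detector banana); an
all-photon mode exists. Boundary conventions: layer intervals half-open
[top, bottom); detector boundary inclusive; positions exactly on a layer
interface are nudged to the receiving layer.

## Known limitations

* The reported power table is reproduced at the ring scoring to within
  roughly a factor of two per cell, but not its exact orderings: at
  1310 nm (weakest absorption, shallowest radial decay) the simulated
  ring power is nearly flat in $d$, so the "power strictly decreasing
  with separation" pattern fails there while holding at the strongly
  absorbed wavelengths.
* Simulated $D_M$ exceeds the study's printed depth bounds by 12–19%
  everywhere except the water-peak wavelength. The printed bounds are
  internally inconsistent with the printed sublayer thicknesses (the
  depths they assign to named sublayers imply a substantially thicker
  epidermis than any consistent stack), so part of this gap is
  attributable to the under-specified anatomy; the package keeps the
  documented defaults rather than fitting thicknesses to the bounds.
* The design selector reproduces the feasibility structure of the grid
  (water-peak and far-separation low-power cells excluded) but, as noted
  above, can prefer 2299 nm over 1684 nm within the ~15% sensitivity
  spread of the lactate-peak cells.
* No polarization, fluence/time-resolved outputs, internal-interface
  refraction, or GPU path; hemoglobin is deliberately absent from the
  absorber set, matching the source model.
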