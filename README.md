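# swirlmc

Monte Carlo simulation of short-wave-infrared (SWIR, 1300–2500 nm) light
transport through lactate-bearing vascular finger tissue, for the design of a
non-invasive optical blood-lactate sensor.

Blood lactate above ~2 mmol/L flags hypoperfusion in critical care, but no
continuous non-invasive monitor exists. Lactate has absorption features in
the SWIR band that are detectable underneath the dominant water absorption.
Whether a reflectance probe on a finger can see them depends on how SWIR
photons move through skin: how deep they sample, how much power returns at a
given source–detector separation *d*, and how strongly the returned signal
responds to blood-lactate concentration. `swirlmc` answers those questions
in silico for a 10-wavelength × 3-separation design grid.

## Model

The finger is a laterally finite slab (13 mm × 13 mm) of seven plane layers:
stratum corneum and epidermis (bloodless), four dermal sublayers with
different blood/water content, and hypodermal fat. Each layer's absorption
coefficient is a chromophore volume-fraction mixture

μ<sub>aT</sub> = V<sub>b</sub>·μ<sub>ab</sub> + V<sub>w</sub>·μ<sub>aw</sub> +
V<sub>mel</sub>·μ<sub>amel</sub> +
[1 − (V<sub>b</sub>+V<sub>w</sub>+V<sub>mel</sub>)]·μ<sub>at</sub>,
  with blood absorption
μ<sub>ab</sub> = V<sub>lact</sub>·μ<sub>alact</sub> + V<sub>lip</sub>·μ<sub>alip</sub>
  and scaffold baseline μ<sub>at</sub>(λ) = 7.84×10⁸ · λ<sup>−3.255</sup> mm⁻¹.

The lactate volume fraction is C<sub>lact</sub>/100 mmol/L (the coefficient is
calibrated on a 100 mmol/L solution). Wavelength-indexed coefficients for
water, lactate, lipid and melanin absorption and skin/fat scattering ship
with the package at the ten characterizing wavelengths.

Photon packets are propagated by weighted (implicit-capture) Monte Carlo:
exponential free paths clipped at layer interfaces, Henyey–Greenstein
scattering (g = 0.9), unpolarized Fresnel reflection/refraction at the
air–tissue surface (n = 1.4 / 1.0), Russian roulette for low weights, and a
compiled single-stream RNG for bit-reproducible results. Outputs per run:
detected/absorbed/escaped weight budgets, per-detected-photon exit records
and per-layer pathlengths, and a 3-D interaction-event map. Analyses built
on top: mean penetration depth D<sub>M</sub> (weight-averaged maximum depth
of detected photons), relative detected power (% of incident),
absorbance −log₁₀(detected/incident), absorbance-versus-concentration
curves by exact perturbation reweighting, and a three-criteria design
optimizer (sampling depth beyond the bloodless layers, sensitivity to
lactate, minimum power).

## Worked example

```r
library(swirlmc)
tab   <- swir_property_table()
model <- build_finger_model(tab, wavelength = 1684, c_lactate = 2)
geom  <- sensor_geometry(separation = 1.0)          # ring detector, r = 0.2 mm
res   <- run_simulation(model, geom, transport_config(n_photons = 2e5, seed = 1))
relative_power(res); mean_penetration_depth(res); absorbance(res)
```

prints

```
Simulation: 200000 packets, 7838 detected
  detected 0.0108 / absorbed 0.8969 / escaped 0.06456 of incident weight
relative power: 1.080% +/- 0.015%
mean penetration depth: 1.24 mm
absorbance: 1.97 a.u.
```

So at 1684 nm and d = 1 mm roughly 1% of the incident power returns to the
detector ring, and the detected light has sampled a mean maximum depth of
1.24 mm — through the deep blood net dermis, i.e. the signal carries blood
information. Sweeping lactate over the physiological range with shared
photon paths resolves the tiny concentration response exactly:

```r
rows <- concentration_sweep(tab, 1684, 1.0, 1:6,
                            config = transport_config(n_photons = 2e5, seed = 1))
sensitivity_slope(rows$c_lactate, rows$absorbance)
```

```
 c_lactate relative_power_pct absorbance
         1              1.065      1.973
         6              1.061      1.974
sensitivity: 3.45e-04 a.u. per mmol/L (r2 = 1.000)
```

An absorbance change of ~3×10⁻⁴ a.u. per mmol/L: detectable in principle,
but demanding — the quantitative case for a high-sensitivity detection
chain. `grid_sweep()`, `score_design()` and `select_optimal()` run the same
analysis over the full design grid; `inst/cli/swirlmc.R` exposes
`sweep`/`score`/`select` from the shell.

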