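# lvsa — coupled left-ventricle / systemic-artery pulse-wave simulator

`lvsa` is a desk-scale simulator of ventricular–arterial coupling for
cardiovascular modellers. It joins two classical components:

* **A 1D systemic arterial network.** The 24 large arteries are tapered
  elastic tubes carrying cross-sectional-area-averaged flow,

  ```
  A_t + Q_x = 0
  Q_t + (Q²/A)_x + (A/ρ) P_x = −(2πνR/δ*) (Q/A)
  P  = P0 + (4/3)(Eh/r0)(1 − √(A0/A)),   Eh/r0 = k1 e^{k2 r0} + k3
  ```

  advanced with a two-step Lax–Wendroff scheme and mass-exact ghost-cell
  boundary closures. Every terminal artery ends in an asymmetric
  **structured tree** of small vessels (daughter radii `α r`, `β r` from the
  radius exponent ξ and asymmetry γ, termination at 100 µm) whose root
  impedance spectrum — Womersley oscillatory flow per vessel, combined
  leaf-to-root as transmission lines — closes the outflow through a periodic
  impulse-response convolution.

* **A reduced contracting left ventricle.** A thick-walled incompressible
  spherical shell with Holzapfel–Ogden passive myocardium and a normalised
  active-tension twitch scaled by contractility `T0` with length-dependent
  activation; cavity pressure is the thick-shell equilibrium integral
  `P = ∫ 2(σ_θθ − σ_rr)/r dr`.

During systole the two models exchange pressure and flow at the aortic root
(no transvalvular drop): the arterial model supplies the afterload, the
ventricle supplies the inflow. The package reproduces baseline
haemodynamics, four pathological scenarios — arterial stiffening (k3 × 2),
vascular-bed rarefaction (ξ: 2.76 → 2.4), myocardial stiffening (a-type
constants × 2), increased contractility (T0 × 1.33) — and
ventricular–arterial coupling indices (E_A, E_S, ESPVR, pressure–volume
loops).

## Worked example

Count the structured-tree vessels of the default network and the effect of
rarefaction:

```r
library(lvsa)
net <- default_network()
n76 <- count_network_vessels(net, tree_params(xi = 2.76))
n24 <- count_network_vessels(net, tree_params(xi = 2.4))
c(n76, n24, reduction_pct = 100 * (1 - n24 / n76))
#> [1] 610224.00 163832.00     73.15
```

Calibrate the ventricle to the measured stroke volume (72.6 mL), ejection
time (220 ms) and the end-diastolic volume implied by an ejection fraction
of 51%, then run the coupled baseline to periodicity (a few minutes):

```r
cfg <- default_config()
cal <- calibrate_baseline(list(EDV = 72.6 / 0.51, SV = 72.6, t_ej = 0.220),
                          config = cfg)
run <- simulate_case(cal$config)
run
#> Scenario run 'baseline': converged = TRUE (metric 0.00582)
#> Cardiac cycle: EDV 142.4, ESV 69.8, SV 72.5 mL, t_ej 219 ms, peak P_LV 132.8 mmHg

glance(run)[, c("SV_mL", "EF", "Ppeak_LV_mmHg", "Qpeak_ao_mL_s", "SW_cJ", "t_ej_ms")]
#> # A tibble: 1 × 6
#>   SV_mL    EF Ppeak_LV_mmHg Qpeak_ao_mL_s SW_cJ t_ej_ms
#>   <dbl> <dbl>         <dbl>         <dbl> <dbl>   <dbl>
#> 1  72.5 0.509          133.          582.  109.    219.
```

`SV_mL` and `EF` report the ejected volume per beat and its fraction of the
end-diastolic volume; `Ppeak_LV_mmHg` the peak cavity pressure;
`Qpeak_ao_mL_s` the peak aortic flow produced by the coupled exchange;
`SW_cJ` the pressure–volume loop area. Per-probe waveform indices (peak and
trough pressures, peak times, backflow) come from
`waveform_indices(run$sa)`; `autoplot(run)` draws the pressure–volume loop
and `plot_waveforms(run, c("ascending_aorta", "r_subclavian_brachial"))`
the pressure waveforms.

Scenario comparison and elastances:

```r
run1 <- simulate_case(apply_case(cal$config, "case1"))   # stiffer arteries
run2 <- simulate_case(apply_case(cal$config, "case2"))   # rarefaction
el <- elastances(list(baseline = run, case1 = run1, case2 = run2))
el$ES_mmHg_mL           # slope of the ESPVR through the three end-systolic points
#> [1] 1.702763
el$EA_over_ES["baseline"]
#>  baseline
#> 0.8915735
```

Command-line wrappers over the same functions live in `exec/`
(`lvsa-simulate`, `lvsa-tree-count`, `lvsa-indices`).

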