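# rfivm

Simulation and quantification tools for radiofrequency (RF) hyperthermia
experiments observed by intravital microscopy (IVM).

Mild tumor hyperthermia (39–41 °C), induced here by a 13.56 MHz
electric field, transiently opens the tumor perfusion barrier so that
circulating macromolecular tracers (fluorescent albumin, FITC-dextran)
extravasate into the tumor interstitium; at 44 °C and above the vessels
coagulate and shut down.  `rfivm` is aimed at researchers analyzing such
recordings or prototyping the analysis before acquiring data.  It
provides three connected pieces:

1. **RF heating physics.**  The dielectric heating rate of a lossy
   tissue,

   HR = dT/dt = ω ε₀ ε″ |E|² / (2 ρ c_p),

   electric-field reconstruction from voltage-probe grids
   (E = −dV/dx), a lumped thermal model with Newtonian cooling, and the
   on/off set-point controller that modulates tumor temperature between
   45/43/41 °C cut-offs with a 29–31 °C resume band.

2. **A seeded synthetic-scene generator.**  Three-channel time-lapse
   stacks (tumor fluorophore, dextran-highlighted vessels, albumin
   tracer) with full ground truth: vessel networks, two-compartment
   temperature-dependent extravasation kinetics, photon/read noise and
   optional respiration jitter.

3. **The mask-based quantification pipeline.**  Exact Otsu global
   thresholding, dilate/erode mask cleanup, tumor ∖ vessel mask algebra,
   rigid jitter correction, and the perfusion statistics PAF (positive
   area fraction), RTDI (relative tumor dye intensity vs. a baseline
   window) and RAIF (end/start window intensity ratio).

## Worked example

```r
library(rfivm)

rep_t <- run_pipeline(run_config(seed = 1, preset = "treated"))
rep_c <- run_pipeline(run_config(seed = 1, preset = "control"))
print(rep_t)
#> Perfusion report (treated preset, seed 1)
#>   endpoint PAF (thr 20): 0.1905
#>   RAIF: 1.785
#>   final RTDI: 1.784 over 26711 extravascular px
print(rep_c)
#> Perfusion report (control preset, seed 1)
#>   endpoint PAF (thr 20): 0.0463
#>   RAIF: 1.044
#>   final RTDI: 1.047 over 26552 extravascular px
compare_reports(rep_t, rep_c)$paf_ratio
#> [1] 4.121334
```

The treated run holds the tumor in the 39–41 °C band for a 4.5-minute
exposure: about 19 % of the endpoint frame is tracer-positive versus
about 4.6 % in the 37 °C control (vessels only), a roughly five-fold
PAF enhancement, and the albumin signal in the extravascular tumor
region roughly doubles over the session (RAIF ≈ 1.8).  The control
RTDI stays at 1 within noise — no tracer crosses the intact barrier.

The physics layer works the same way:

```r
run <- setpoint_controller(controller_config(), complex_permittivity(80, 70),
                           material_thermal(1000, 4186),
                           field_at_max_power = 6700, cooling_coeff = 0.00704)
run$episodes
#>  setpoint   t_on  t_off t_peak peak_temp
#>        45    0.0  250.7  250.7  45.00180
#>        43  635.3  807.2  807.2  43.00258
#>        41 1171.5 1296.4 1296.4  41.00323
```

Three heating episodes, peaks at the set-points, ~250 s to heat from
30 to 45 °C and ~375 s to cool back — matching the modulation protocol
the defaults encode.

A thin CLI over the same functions lives at `inst/cli/rfivm.R`
(`generate`, `simulate-field`, `simulate-heating`, `quantify`,
`report`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the package's end-to-end computation from scratch: both preset
pipelines at 256 × 256 (reporting the treated:control PAF ratio and the
treated RAIF) and the three-set-point controller simulation, then
writes the results JSON to `--out`.  All randomness derives from
`--seed`.

## Vignette

`vignettes/rfivm-methods.Rmd` documents the models, the preset
parameter choices and their rationale, numerical tolerances, and known
limitations.
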