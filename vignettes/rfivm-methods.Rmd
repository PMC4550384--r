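---
title: "Models and methods behind rfivm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rfivm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfivm)
```

# Scope

`rfivm` packages the computational side of a radiofrequency (RF)
hyperthermia intravital-microscopy (IVM) experiment: how a 13.56 MHz
electric field heats lossy tumor tissue, how an on/off power controller
modulates tumor temperature between set-points, and how fluorescent
tracer extravasation through the heat-permeabilized tumor vasculature is
quantified from multichannel time-lapse recordings.  Because no real
image data accompany the experiment, the package also ships a seeded
synthetic-scene generator with full ground truth, so that every
quantification step can be validated against known answers.

# Dielectric heating

A material in a time-varying field stores energy through the real part
of its complex permittivity $\varepsilon^*(\omega) =
\varepsilon'(\omega) - i\,\varepsilon''(\omega)$ and dissipates it as
heat through the loss factor $\varepsilon''$.  The heating rate
implemented by `heating_rate()` is

$$\mathrm{HR} \;=\; \frac{dT}{dt} \;=\;
  \frac{\omega\,\varepsilon_0\,\varepsilon''\,|E|^2}{2\rho c_p},$$

with $\varepsilon_0 = 8.854\times10^{-12}$ F/m, field intensity $E$ in
V/m, density $\rho$ and specific heat $c_p$.  The relation is sometimes
quoted without the angular frequency $\omega = 2\pi f$; that form is
dimensionally short one factor of 1/s.  Both readings are available
behind the `include_omega` flag; the default is `TRUE` (the
dimensionally consistent form), and the bare form is retained for
fidelity, with both pinned by regression tests at
$\varepsilon'' = 70$, $E = 15$ kV/m, water-like $\rho c_p$.

Electric fields are reconstructed from voltage-probe grids by
`efield_from_voltage()` as $E = -dV/dx$, with central differences at
interior nodes and one-sided differences at grid edges (the edge
handling is documented and tested; an affine potential yields an
exactly constant field).

# Lumped thermal model and set-point control

The experiment reports tumor temperature against applied power, but no
cooling law.  `simulate_temperature()` therefore adopts the simplest
physically sensible closure, a single thermal compartment with
Newtonian cooling toward ambient:

$$\frac{dT}{dt} = \mathrm{HR}\cdot\frac{P(t)}{P_{\max}}
  - c\,(T - T_{\mathrm{amb}}),$$

integrated by explicit Euler at a fixed step (`dt`, default 0.1 s); a
tenfold-finer-step reference in the tests bounds the integration error
below 0.05 °C on step schedules.  Ambient defaults to 30 °C, the
air-conditioned operating-room temperature the tissue relaxed to
between exposures.

`setpoint_controller()` closes the loop the way the experiment did:
heat at `on_power` (default 90 W of a 200 W amplifier) until the
reference probe reaches the active set-point, cut power until the
temperature re-enters the 29–31 °C resume band, then advance to the
next set-point.  The defaults `c(45, 43, 41)` °C reproduce the
three-episode modulation protocol.  Two free parameters — the field at
the probe under full power and the cooling constant — were calibrated
once against the reported timings (30 → 45 °C in ~250 s at 90 W,
~375 s to cool back): 6 700 V/m and 0.00704 s⁻¹.  They are ordinary
arguments, not hidden constants, and the calibration is asserted in the
test suite.

# The synthetic scene generator

The generator states a world with the features the quantification
pipeline assumes, nothing more:

* **Geometry.** An elliptical tumor (about 40 % of the frame) on a dark
  background; vessels drawn as random walks entering at the tumor
  boundary, with per-step angular noise (`tortuosity`) and a 2 px
  radius, rasterized to cover a target fraction (default 10 %) of the
  tumor area.  When an area fraction is requested, vessels are added
  one at a time with lengths capped by the remaining target so the
  realized coverage lands within a few percent of the request.
* **Kinetics.** Two compartments.  Intravascular concentration decays
  as $dC/dt = -(\mathrm{cl} + k(T))\,C$; the wall flux $k(T)\,C$ is
  deposited on the pixels bordering perfused vessels and then spreads
  by isotropic diffusion with zero-flux frame boundaries.  Within each
  frame interval $k$ is frozen at its start-of-interval value and the
  exchange is integrated exactly (matrix-free exponential), so tracer
  mass is conserved to machine precision — the mass-balance test
  tolerance of $10^{-6}$ is loose by design.
* **Temperature coupling.** $k(T)$ is piecewise: baseline $k_0$ below
  39 °C, $\alpha k_0$ across the 39–41 °C mild-hyperthermia band (a
  deliberate jump at the 39 °C edge), a linear decline above 41 °C, and
  zero at/above the 44 °C shutdown temperature where vessels coagulate.
  The shape is qualitative in the source material, so all break-points
  and factors are exposed on `tracer_kinetics()`.
* **Acquisition.** Per-pixel noise with variance
  `photon_scale * I + read_sigma^2`, drawn as a single Gaussian
  (distributionally identical to photon-plus-read draws); optional
  respiration jitter as a rigid sinusoidal translation rounded to whole
  pixels.  No point-spread function, no 3-D sectioning, no red-blood-cell
  flow — a green test therefore establishes the mask algebra and
  statistics, not robustness to optics the generator does not emulate.

## Preset parameter choices

`default_scenarios()` pins one treated and one control world:

| parameter | value | rationale |
|---|---|---|
| `c_vasc0` | 200 | vessel signal well above the background of 10 |
| `clearance_rate` | $10^{-4}$ s⁻¹ | plasma half-life of order hours |
| `permeability_base` | $2\times10^{-5}$ s⁻¹ | near-impermeable barrier: <4 % leak over a 30 min control session |
| `enhancement_factor` | 100 | mild hyperthermia opens the barrier; ~40 % of the tracer extravasates over the 4.5 min exposure |
| `diffusion_coeff` | 0.5 px²/s | 66 kDa albumin in interstitium at ~1.24 µm/px; larger values let tracer leak out of the tumor region fast enough to contradict the observed monotone rise of tumor dye intensity |
| treated trace | 37 → 40.5 °C ramp (90 s), hold to 360 s, exponential relax | enters and stays in the 39–41 °C band for the 4.5 min exposure |
| control trace | 37 °C for 30 min | no RF |

The treated:control contrast these parameters produce — roughly a
five-fold endpoint positive-area-fraction ratio and a doubling of the
albumin signal over the imaging session — is asserted by the acceptance
tests by running the full pipeline, not by reading generator state.
Presets default to 256 × 256 frames (half the 512 × 512 acquisition
frame) purely for memory; pass `frame_shape = c(512, 512)` for full
size.

# Quantification pipeline

The pipeline mirrors the mask-based algorithm used on the real
recordings:

1. **Tumor mask** — global threshold of the constitutive tumor channel,
   then dilate followed by erode (disc, radius 2 px by default) to fill
   holes and smooth edges.  The threshold method is Otsu by default,
   computed exactly over the empirical intensity distribution (every
   distinct value is a candidate split; ties take the lowest), with a
   fixed-value override.  Thresholds are computed on the baseline frame
   and reused across the time-lapse so temporal comparisons are not
   confounded by adaptive thresholds.
2. **Vessel mask** — the same procedure on the high-intensity tracer
   signal of the baseline frame, where tracer is purely intravascular.
3. **Extravascular mask** — tumor AND NOT vessels; exact set algebra.
4. **Statistics** — `paf()` (fraction of pixels above a background
   threshold; whole-frame by default, matching the verbatim definition,
   with a region-restricted variant), `rtdi_series()` (region mean per
   frame normalized to a baseline window), and `raif()` (end-window to
   start-window mean ratio, windows defaulting to the first/last 10 %
   of frames, with replicate mean ± SD aggregation).  Pixels at a
   stated saturation level can be excluded from all means.
5. **Jitter correction** — per-frame integer translation maximizing the
   FFT cross-correlation against a reference frame on the (temporally
   constant) tumor channel, applied to all channels; featureless frames
   degrade to an identity transform with a warning.

## Numerical and edge-case choices

* Diffusion substeps respect the 2-D explicit stability bound
  ($D\,\tau \le 0.2$ per substep).
* The degenerate constant image under Otsu warns and returns the
  constant rather than erroring, so batch pipelines survive empty
  channels.
* The controller's peak overshoot is bounded by one integration step of
  heating; tests assert exactly that bound.
* Mask coordinates are row/column pixel indices; masks are plain
  logical matrices and all mask algebra is exact.
* Image stacks are stored as a plain-text container (one-line JSON
  header plus CSV rows) rather than TIFF: the installed R stack has no
  TIFF codec, and the text form keeps fixtures diffable.
  Integer-valued intensities round-trip exactly.
* The two simulation-facing choices most worth revisiting against real
  data are the permeability jump at 39 °C and the uniform deposition of
  extravasated tracer along vessel boundaries.

# Known limitations

* The thermal model is zero-dimensional; it cannot represent the
  probe-to-probe heating differences caused by field fall-off from the
  transmitting head, which are represented only through per-probe field
  values.
* Jitter correction is integer-pixel and rigid; the sub-pixel residual
  of real respiratory motion is not modeled (the generator injects
  integer shifts, so recovery tests are exact rather than
  approximate).
* The control world's near-zero permeability makes treated:control
  ratios sensitive to the control denominator at small frame sizes;
  recovery of the generator ground truth to within 10 % holds at the
  256 × 256 acceptance frame size, and degrades (10–20 %) at 128 × 128
  where boundary rings around vessels are proportionally larger.
* At the preset 5 s frame interval, a sub-5 s jitter period aliases;
  jitter-recovery checks run at sub-second frame intervals.
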