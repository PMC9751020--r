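---
title: "tfusim: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tfusim: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tfusim` simulates transcranial focused ultrasound (tFUS) neurostimulation
across two scales: centimetre-scale acoustic propagation through a
simplified head, and nanometre-scale intramembrane cavitation driving a
cortical point neuron. This vignette is the package's own account of the
science and of every numerical and design choice a maintainer would want to
question. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Macroscale: acoustic propagation

### Geometry

The head is two concentric circles in a water bath: an outer circle of
radius 85 mm whose annulus is skull and whose interior disc is brain. The
skull grows inward, so the outer head surface — and with it the 40 mm
standoff from the transducer apex to the outer skull boundary — is identical
across the three studied thicknesses (5.4, 7.6 and 10.5 mm). The 85 mm
radius is a configurable adult-head-scale default; no head diameter is a
measured input. The focused source is a circular arc with aperture 64 mm and
radius of curvature 63.2 mm (the public datasheet values of the commercial
transducer the study emulates, both configurable), rasterised by marching
along the arc so the pixel set is connected and exactly mirror-symmetric
about the beam axis. With the default layout the geometric focus falls
~23 mm past the outer skull surface, i.e. at cortical depth.

Coordinates: `x` is the propagation direction, `y` lateral, the transducer
axis at `y = n_y·dx/2`, pixel centres at `(i − ½)dx`. The default grid is
560 × 560 at `dx = 0.5` mm (≈ 12 points per wavelength in water at
250 kHz; the constructor enforces a configurable minimum of 4).

### Media

| medium | c (m/s) | ρ (kg/m³) | α₀ (dB/(MHz·cm)) |
|--------|---------|-----------|------------------|
| water  | 1481    | 998       | 0.002            |
| skull  | 2820    | 1732      | 7.75             |
| brain  | 1500    | 1000      | 0.8              |

Absorption follows the power law `α(f) = α₀ (f/1 MHz)^γ` with `γ = 1` by
default (only `α₀` is a stated property; the exponent is a documented
choice), converted to Np/m and applied as a first-order loss term on the
pressure with rate `σ_a = 2cα`, which reproduces the intended spatial decay
for travelling waves.

### Scheme

The solver integrates the first-order pressure/velocity equations on a
staggered grid (FDTD) with a split-field perfectly matched layer of 20
pixels on all sides (cubic profile, target reflection 1e-6). A k-space
pseudospectral scheme would be equally acceptable; the contract is the set
of validated properties, not the stencil: plane-wave amplitude within 2% of
the drive, plane-wave intensity `p₀²/2ρc` within 2%, strict linearity in
the source amplitude, energy conservation without absorption, and focal
convergence under grid refinement (halving `dx` from the 0.5 mm default
changes the focal maximum by < 1%).

Two scheme-level choices deserve emphasis:

* **Source ramp.** The drive is a hard (pressure-override) source,
  `p = A sin(2πft)`, ramped over the first 5 cycles with a sin² envelope.
  An abrupt onset radiates a broadband transient whose focal overshoot
  converges poorly in `dx` (measured ~5% shifts per grid halving); with the
  ramp the recorded maximum equals the steady-state amplitude and
  convergence is clean.
* **Medium smoothing.** Property rasters are smoothed with a Gaussian of
  σ = 1 mm (configurable; 0 disables). Sharp pixelated interfaces produce
  thin-layer transmission resonances across the skull — at 250 kHz the
  skull wavelength is ~11.3 mm, comparable to the layer thicknesses — which
  make the transmitted focal pressure a non-monotonic function of skull
  thickness. Reference pseudospectral toolboxes smooth heterogeneous media
  by default for exactly this class of artifact. With σ = 1 mm the
  brain-region maxima are monotone in thickness (321/311/293 kPa at
  5.4/7.6/10.5 mm, duty cycle 90%); with σ = 0.5 mm at `dx = 0.5` mm they
  are not. This sensitivity is disclosed rather than hidden: the
  skull-shielding monotonicity claim is a property of the smoothed model.

### Outputs and intensity convention

Per pixel the solver accumulates the running maximum of |p| and the mean of
p² over the record window; the time-averaged intensity is the plane-wave
impedance estimator `I = ⟨p²⟩/ρc`, exact for travelling plane waves and an
approximation in the focal region (it avoids storing the velocity history).
The window is the full burst window (on + off), so intensity scales with the
duty cycle while the maximum pressure does not — the duty-cycle sweep then
separates "efficacy" (peak pressure, measured DC-invariant to < 0.1%) from
"dose" (window-averaged intensity, strictly increasing in DC).

Duty-cycle gating at this scale is window-level: on-time = DC × 500 µs, so
DC 40% is a 200 µs burst. The steady-state bound — grid diagonal over the
slowest sound speed, `t_ss = √(s_x² + s_y²)/v_min` — is logged at the start
of every run; on the default 280 × 280 mm domain it is 267 µs, so the
shortest bursts are formally below it (the focal region itself reaches
steady state after ~100 µs; the bound is a conservative whole-grid
criterion).

### Safety calibration

`free_water_calibration()` re-runs the configured drive in an all-water
domain and compares the spatial maximum of time-averaged intensity against
the 3 W/cm² physiotherapy limit, at duty cycle 90% (the worst case the
sweep uses) by default. With the configured arc the measured 2D focal
pressure gain is ~3.8, so a 100 kPa drive yields ~3.7 W/cm² in free water —
slightly *above* the limit. This is an honest red in the acceptance suite:
the transducer geometry is fixed by its datasheet and was deliberately not
tuned toward the bound, and the claim that 100 kPa passes cannot be
reconciled with the same setup's reported focal pressures (0.55–0.8 MPa,
which would imply ~16 W/cm² in water). Inside the head model the skull
shields the focus and the tissue maximum stays under the limit
(~2.6 W/cm²).

## 2. Microscale: intramembrane cavitation neuron

### Mechanics

The bilayer sonophore is a gas pocket of radius `a = 32` nm between the two
membrane leaflets. Its apex deflection `Z` follows a modified
Rayleigh–Plesset equation driven by the sum of: internal gas pressure
`P_in = n_g R_g T / V(Z)`; the inter-leaflet molecular
(repulsion/attraction) pressure `P_M`; the static pressure −`P₀`; leaflet
tension `−P_s`, with `P_s = k_s (1/R)(S − S₀)/S₀`; the electrostatic
attraction `P_ec = −(S₀/S)·Q_m²/(2ε₀ε_r)`; the acoustic drive
`P_A sin(ωt)`; and viscous dissipation from leaflet and medium. Gas content
`n_g` exchanges with dissolved gas through
`dn_g/dt = 2 S D_gl/ξ · (C_g − P_in/k_H)`.

Spherical-cap geometry supplies `1/R = 2Z/(a² + Z²)`, `S = π(a² + Z²)`,
`V = πa²Δ + πZ(a² + Z²/3)` and the local deflection profile `z(r)` used in
the `P_M` integral. Three reconstruction choices were needed where the
printed formulation is ambiguous or degenerate:

* **Molecular pressure.** `P_M(Z)` is evaluated by Gauss–Legendre
  quadrature (64 radial nodes, validated against 256) of
  `A_r[(Δ*/ζ)^x − (Δ*/ζ)^y]` over the leaflet, with `ζ(r) = Δ + 2z(r)`,
  and tabulated once per parameter set on a 360 000-point deflection grid
  (interpolation error < 1e-4 relative); the integrators do an O(1) table
  lookup per evaluation.
* **Resting gap.** `Δ` solves `A_r[(Δ*/Δ)^x − (Δ*/Δ)^y] = P₀`
  (root ≈ 1.115 nm, residual < 1e-6·P₀). A consequence of this convention:
  at the resting charge the molecular repulsion exceeds the electrostatic
  attraction, so the charge-balanced equilibrium deflection is slightly
  positive (Z₀ ≈ 0.17 nm) rather than zero. The unsonicated electrical
  model is therefore anchored at the resting capacitance `C_m0` explicitly
  (see the `PA = 0` convention below), and the co-integration oracle starts
  from the self-consistent pair (Z₀, Q_m = C_m(Z₀)·V_rest).
* **Curvature sign.** The printed prefactor `1/(ρ_l R)` on the pressure sum
  is sign-degenerate for `Z < 0` (it would turn every restoring pressure
  anti-restoring below zero deflection). The pressure-sum term uses
  `1/(ρ_l |R|)`, and the dissipation term uses `|1/R|`, keeping the signed
  curvature only in the convective `−(3/2R)(dZ/dt)²` term; this reproduces
  stable oscillation about the equilibrium for both signs of `Z`.

Henry's constant as printed (`1.013 Pa·m³·mol`) is dimensionally garbled
and ~5 orders of magnitude off any physical value; the reference value
`1.613e5 Pa·m³/mol` is used. Because the dissolved-gas concentration is
defined as `C_g = P₀/k_H`, only the gas-exchange *timescale* depends on
this choice, not the equilibrium.

The capacitance of the deflected membrane,
`C_m(Z) = C_m0 (Δ/a²)[Z + (a² − Z² − ZΔ)/(2Z)·ln((2Z+Δ)/Δ)]`, tends to
`C_m0` as `Z → 0` with first-order sensitivity `−C_m0/Δ`; below
`|Z| = 1e-12` m a series expansion replaces the closed form (catastrophic
cancellation otherwise caps the achievable accuracy near the limit).

### Electrodynamics and effective variables

The membrane is a regular-spiking cortical point neuron: sodium (gates
`m, h`), delayed-rectifier potassium (`n`), slow non-inactivating
potassium (`p`) and leak currents, with the standard published parameter
set (`g_Na = 560`, `g_Kd = 60`, `g_M = 0.75`, `g_L = 0.205` S/m²;
`V_Na = 50`, `V_K = −90`, `V_L = −70.3`, `V_T = −56.2` mV;
`τ_max = 0.608` s; resting potential solves the steady-state current,
−71.91 mV). These values are reference-derived, shipped as an editable
config block, and deliberately not re-tuned.

Rather than co-integrating the µs-scale mechanics with the ms-scale
electrics, the production path compresses each acoustic cycle into
*effective variables*: for each node of a (P_A × Q_m) grid the mechanics
are run to a periodic steady state (cycle-to-cycle deflection-extrema
change < 1e-3 relative, usually 2 cycles) and the final cycle is averaged
into `⟨1/C_m⟩_T`, the effective potential `V* = Q_m ⟨1/C_m⟩_T`, and
effective rates `α*ₓ = ⟨αₓ(V(t))⟩_T` with `V(t) = Q_m/C_m(t)`. The
charge-cast membrane then integrates
`dQ_m/dt = −Σᵢ Gᵢ(V* − Vᵢ)` with table-interpolated coefficients during
ultrasound-ON intervals and the ordinary resting-capacitance system during
OFF intervals (`V_m = Q_m/C_m0` there, exactly).

Conventions worth knowing:

* **`PA = 0` is the unsonicated membrane, exactly.** The zero-amplitude
  table row carries `1/C_m0` and textbook rates; `simulate_sonic()` with
  `PA = 0` never touches the mechanics. This keeps the electrical rest
  state exact despite the Z₀ > 0 mechanical equilibrium noted above.
* **Rate cap.** Inside an acoustic cycle the instantaneous potential
  `Q_m/C_m(t)` can reach several hundred mV of hyperpolarisation, where
  the exponential rate laws exceed 1e20 s⁻¹ and only destabilise the
  integrator. All rates are capped at 1e5 s⁻¹ — far above every
  physiological rate below ~+150 mV (where the cap never binds), and
  equivalent to instantaneous equilibration above it.
* **Lookup grids.** Default `P_A ∈ {0, 10, …, 150}` kPa and
  `Q_m ∈ [−100, 50]` nC/cm² at 1 nC/cm² for `build_lookup_table()`; the
  pipeline auto-extends the amplitude axis (25 kPa steps by default) to
  cover the largest pressure actually sampled from the macroscale maps —
  with the configured geometry the focal samples reach ~0.3 MPa, well
  above the default 150 kPa cap. Bilinear interpolation reproduces direct
  off-grid computation to ~1% at 5 kPa amplitude spacing; at 10 kPa
  spacing the slow-gate backward rate interpolates to ~3% mid-interval.
* **Integrators.** Adaptive Cash–Karp (RK45) everywhere, relative
  tolerance 1e-6 (configurable), absolute tolerances per state; the
  mechanical step never exceeds 1/40 of an acoustic period during
  sonication. The sonophore is stiff — near-critically damped at nm
  deflections (post-release ring-down decays by >1e4 within 1 µs) — which
  the error control resolves at ~1–5 ns steps during compression phases.

### The co-integration oracle

`simulate_full_nbls()` integrates the eight-state system (Z, dZ/dt, n_g,
V_m, four gates) at sub-cycle resolution using the voltage-form membrane
equation `dV_m/dt = −(1/C_m)(V_m dC_m/dt + Σ I_ion)` — a genuinely
different route from the charge-cast effective path. It is capped at 50 ms
by design (~4 s per 30 ms at 100 kPa on one CPU). Measured fidelity of the
effective-variable approximation against it at 250 kHz:

* spike *counts* and firing rates agree within ~5–15% at robustly
  suprathreshold drive (300 kPa, CW);
* first-spike *latency* agrees within ~20–25% near threshold. At the
  acceptance operating point (100 kPa, CW, 30 ms) the oracle fires at
  ~29.5 ms and the effective model at ~36.5 ms, so the 30 ms window catches
  1 vs 0 spikes: that acceptance sub-check is left red, with this analysis,
  rather than widened. The averaging assumption degrades as the acoustic
  period (4 µs at 250 kHz) approaches the fast-gate timescales, and is
  known to be frequency-sensitive.

### Spike metrics

Spikes are upward 0 mV crossings separated by ≥ 1 ms (both configurable);
latency is first-spike time minus stimulus onset (`NA` without spikes);
firing rate is the mean of reciprocal inter-spike intervals inside the
stimulation window (`NA` with fewer than two spikes). During pulsed
stimulation the trace's potential column is the effective `V*` in ON
intervals and `Q_m/C_m0` in OFF intervals; both have the sign of `Q_m`, so
the ON/OFF switch cannot fabricate threshold crossings.

## 3. Coupling pipeline

For each condition the macroscale solve is run, 15 positions are sampled
(rows at the lateral offsets −10.19, −5.56, −0.92 mm from the axis; five
axial columns spaced 5 mm over a 20 mm span), and each sampled maximum
pressure becomes the amplitude of a 100 ms pulsed protocol at PRF 500 Hz
whose duty cycle matches the macroscale condition. Micro-level duty cycle
is per-PRF-period (on-time = DC/PRF), independent of the macroscale 500 µs
window — the two scales describe the same drive at different zoom levels.

Open placement choices, resolved as follows:

* **Column start.** Columns begin at the axial position of the focal peak,
  restricted to brain pixels at least 5 mm below the inner skull surface
  (configurable). Without the clearance the brain-region maximum sits on
  the first pixel at the bone–brain interface — a transmitted/reflected
  near-field artifact, not the cortical focus the positions are meant to
  probe.
* **Mirroring.** The 15 positions cover one lateral side plus the
  near-axis row, exploiting the mirror symmetry of the model (verified to
  machine precision); `roi_spec(mirror = TRUE)` samples both sides for
  sensitivity studies.
* **Sampling.** Nearest pixel, no interpolation, so every record is
  traceable to one solver output value.

Measured behaviour of the coupled model worth stating plainly: latency
*decreases* with duty cycle at fixed amplitude (37.6/25.6/21.9 ms at
250 kPa for DC 40/60/90%) — duty cycle is not a latency-neutral knob, as
more on-time per PRF period charges the membrane faster. Firing rate along
an axial row is approximately constant at moderate duty cycle (~17% spread
at DC 70%) but varies strongly at DC 40%, where the weakest column sits
near a burst-count boundary; "globally constant" is a qualitative reading.

## 4. Synthetic fixtures

`generate_fixture()` provides the deterministic synthetic inputs the test
suite uses: a Gaussian focal map with a known peak (what a focused beam's
maximum-pressure raster looks like, without skull aberration, standing
waves or noise), a homogeneous water medium with a line source (an ideal
plane wave — no curvature, no heterogeneity), and a membrane-potential
trace with ramp depolarisations whose zero-crossings sit exactly at
requested times (spikes without spike-shaped dynamics). A green test on a
fixture establishes the *plumbing* — sampling positions, crossing
detection, refractory logic, determinism — not the physics; the physics is
established by the solver/oracle validation tests above.

## 5. Known limitations

* 2D geometry: focal gains, shielding and standing-wave structure differ
  quantitatively from 3D; subject-specific anatomy, scalp and CSF layers
  are out of scope.
* Linear acoustics only: no nonlinearity, shear waves in bone, or thermal
  rise.
* The plane-impedance intensity estimator is approximate near the focus.
* Point neuron only, one (regular-spiking) parameter set; no
  multicompartment morphology or other cell classes.
* The effective-variable approximation's latency error near threshold at
  250 kHz is ~20% (quantified above); conclusions that hinge on absolute
  latencies near threshold should use the co-integration oracle.
* The skull-shielding monotonicity depends on the medium-smoothing choice
  (σ = 1 mm default); sharp-interface runs show physical thin-layer
  resonances instead.
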