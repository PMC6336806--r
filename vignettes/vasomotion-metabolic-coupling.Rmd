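---
title: "Methods: joint wavelet analysis of vasomotion and skin metabolic oscillations"
author: "vasomet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint wavelet analysis of vasomotion and skin metabolic oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Skin microvascular perfusion is not steady: vessel tone oscillates
("vasomotion") at characteristic frequencies attributable to cardiac and
respiratory activity and to myogenic, neurogenic and endothelial control of
the vessel wall. In parallel, the cellular energy metabolism of the tissue
oscillates: the autofluorescence of the NAD(P)H and FAD⁺ coenzymes tracks
the turnover between their reduced and oxidised forms. `vasomet` implements
a complete analysis chain for experiments that record both modalities
simultaneously — a laser-Doppler flowmetry (LDF) perfusion trace and a
once-per-minute series of UV-excited emission spectra — over a baseline
period followed by a vasoactive stimulus (iontophoretic phenylephrine, PE),
and asks how the slow metabolic oscillators relate to the endothelial
vasomotion oscillators that share their frequency range.

## From spectra to metabolic biomarkers

Each emission spectrum carries three peaks: elastin (450 nm), NAD(P)H
(490 nm) and FAD⁺ (550 nm). The amplitude of each fluorophore is taken as
the **maximum raw intensity inside a ±10 nm window** around the nominal
centre — no curve fitting, no baseline subtraction. This is deliberately
the simplest reproducible estimator; the window half-width is a
configuration knob (`window_nm`). Two ratios are formed per spectrum:

* redox-ratio index: `RR = NAD(P)H / FAD⁺` — a proxy for the mitochondrial
  redox state;
* normalised NAD(P)H: `NAD(P)H / elastin` — the elastin peak is used as an
  internal reference that cancels blood-volume artefacts scaling the whole
  spectrum.

Both are ratios, hence invariant to any overall intensity scaling — a
property the test suite enforces.

The 20 discrete biomarker values are interpolated to a uniform 1 Hz signal
by a piecewise cubic spline before wavelet analysis. The boundary
condition is **not-a-knot** by default (the first two and last two cubic
pieces coincide), which behaves better than a natural spline at the ends
of a 20-point record; `boundary = "natural"` is available. The
interpolant passes through every knot exactly and is never extrapolated.
1 Hz is far above the ≤ 9 × 10⁻³ Hz bands of interest, cheap, and does not
pretend sub-minute information exists; it is a config knob
(`recon_fs_hz`).

## Oxygen saturation

Reflectance observations at two (or more) wavelengths are unmixed by the
Beer–Lambert law, `mu_a(λ) = Σ_i eps_i(λ) · C_i`, solved in least squares
for relative oxy- and deoxyhaemoglobin concentrations; the saturation is
`SO₂ = 100 · [oxyHb] / [oxyHb + deoxyHb]`. Negative solutions are clipped
to zero and flagged; a collinear extinction pair is rejected as
ill-conditioned. The shipped default extinction table holds nominal
adult-haemoglobin molar extinction values at 530 and 630 nm (the green/red
laser pair of the targeted probe class); any user table can be supplied as
a CSV. Only concentration *ratios* matter for SO₂, so the units of the
table cancel.

## Morlet continuous wavelet transform

All signals are analysed with the continuous wavelet transform

W(s, t) = s^(−1/2) ∫ ψ((u − t)/s) g(u) du,

with the analytic Morlet wavelet ψ(u) = π^(−1/4) · exp(i 2π f₀ u) ·
exp(−u²/2) and cyclic central frequency f₀ = 1, so a scale `s` maps to the
frequency `f = f₀/s`. Two conventions deserve a note:

* The integral is implemented literally as written above, without a
  complex conjugate on ψ. For real signals this conjugates the
  coefficients relative to the common analytic-signal convention:
  magnitudes, energies and phase-coherence moduli are identical, only the
  sign of the phase flips. The FFT implementation is validated against
  direct numerical quadrature of the same integral to < 10⁻³ relative
  error (machine precision in practice, at interior points).
* With f₀ = 1 the equivalent angular centre frequency is 2π ≈ 6.28, large
  enough that the admissibility correction term is negligible; it is
  omitted, as is standard.

Frequencies live on a logarithmic grid with 16 voices per octave
(`voices_per_octave`), from 1.5 × 10⁻³ Hz (covering the slowest metabolic
band) up to `min(fs/4, 6)` Hz for LDF and 0.05 Hz for the metabolic
signals. The f ≤ fs/4 cap keeps the wavelet's spectral support clear of
the Nyquist frequency, where time-sampled and band-limited versions of ψ
diverge. The record mean is removed before the transform (a DC offset
would otherwise leak a spurious low-frequency ridge); the transform is
computed **once over the full 20-minute record** and windows enter only at
the averaging stage, which minimises edge artefacts at the
baseline/stimulus boundary. Signals are zero-padded to the next power of
two at least twice the record length, making circular wrap-around
negligible inside the cone of influence.

### Cone of influence

A coefficient at frequency `f` and time `t` is *inside* the cone of
influence when `t` is at least `√2 · s` away from both record edges
(`s = f₀/f`; `√2` is the Morlet amplitude e-folding time, configurable via
`coi_efold`). Outside the cone, the wavelet overlaps the record boundary
and coefficients are unreliable. For a 1200 s record the closed form says
frequencies below `√2/600 ≈ 2.36 × 10⁻³` Hz retain no interior points at
all.

### Time-averaged spectra and band metrics

Per analysis window, the mean wavelet power `|W|²` and amplitude `|W|`
are computed per frequency over admissible times (inside the cone, by
default). Named physiological bands are summarised by:

* `E_i` — trapezoidal integral of mean power over the band's grid
  frequencies (area under the curve in linear frequency; a plain sum is
  available via `energy = "sum"`),
* `e_i = E_i / (E_tot · n_i)` — relative energy density, with `E_tot` the
  integral over the whole analysed grid and `n_i` the number of grid
  frequencies in the band,
* `A_i` — maximum mean amplitude in the band, and
  `a_i = A_i / (A_tot · n_i)`,
* `f` — the grid frequency of the band's amplitude peak.

Because `n_i` counts log-grid frequencies, `e_i` and `a_i` depend on the
grid density; every metrics row therefore records its `voices_per_octave`
and metrics are only compared across identical grids. Relative metrics are
invariant to positive rescaling of the input signal.

The band catalogues are: for mouse LDF — cardiac 1.35–5 Hz, respiratory
0.15–1.35 Hz, myogenic 0.05–0.15 Hz, neurogenic 0.02–0.05 Hz, endothelial
NO-dependent 0.009–0.02 Hz, endothelial NO-independent (EDHF)
0.005–0.009 Hz; for the metabolic biomarkers — MO-1 5–9 × 10⁻³ Hz, MO-2
2.5–5 × 10⁻³ Hz, MO-3 1.5–2.5 × 10⁻³ Hz. Band intervals are half-open
`[lo, hi)` so shared edges are never double-counted.

### Band reliability

A band is flagged unreliable when any of its grid frequencies keeps less
than half of the averaging span inside the cone of influence
(`min_coverage = 0.5`). The naive alternative — flagging only bands that
overlap the *fully* excluded region — fails to capture bands that retain a
sliver of admissible time: on a 20-minute record the lower edge of MO-2
keeps only ~6 % of the span, which no one should average over. Under the
coverage rule a 20-minute record yields MO-1 reliable and MO-2/MO-3
unreliable, matching the accepted practice of interpreting only the
fastest metabolic oscillator on recordings of this length.

## Wavelet phase coherence

For two signals transformed on identical grids, the phase difference
Δφ(f, t) = arg W_a − arg W_b is collected over admissible times (inside
both cones, within the window) and summarised by the resultant length

Cφ(f) = sqrt(⟨cos Δφ⟩² + ⟨sin Δφ⟩²) ∈ [0, 1],

which is 1 when the phase relation is rigid and near 0 when the phases are
unrelated. Band summaries are arithmetic means of Cφ over the band's grid
frequencies. The package computes the MO-1/EDHF coherence per analysis
window on a shared low-frequency grid: the LDF record is decimated
(anti-aliased, `signal::decimate`) to the metabolic reconstruction rate so
both scalograms share time and frequency grids.

Two caveats are inherited from the measurement geometry. First, at
7 × 10⁻³ Hz a 10-minute window contains fewer than three admissible
oscillation cycles, so Cφ has few effective degrees of freedom and its
*absolute* level is biased upward — independent signal pairs show band
coherences well above zero. Second, no surrogate-data significance test
is included; the package supports comparing coherences between conditions
and groups, not asserting that any single coherence exceeds chance. A
surrogate hook is a natural future extension.

## The synthetic study generator

Since recordings of this kind are not publicly deposited, validation runs
on a generator that emulates the study design with known ground truth:

* **LDF**: 20 min at 20 Hz; a perfusion DC level plus six band-resident
  oscillators plus 1/f noise. Each oscillator is a *phase-diffused*
  sinusoid: its phase performs a Wiener walk around uniform rotation
  (jitter `0.4π√f` rad/√s, i.e. about ±20 % frequency spread at the
  wavelet's own resolution time), which spreads its energy over a band the
  way physiological oscillators do. Default amplitudes put the slow
  endothelial components at a band signal-to-noise ratio near 2 under the
  default noise level (sd 2.8 perfusion units, spectral exponent β = 1).
* **Stimulus reactivity**: at 600 s every oscillator amplitude (and the DC
  level) switches by a per-group factor through a smooth 10 s cosine ramp
  (no artificial broadband edge). Defaults inject *opposite endothelial
  reactivity*: the EDHF oscillator's amplitude halves in the "WT" group
  and doubles in the "KO" group, while the DC level drops a few percent in
  both (mild vasoconstriction).
* **Spectra**: 20 per recording, one per minute; three Gaussian peaks
  (450/490/550 nm, σ = 15 nm) on a 400–650 nm grid. The NAD(P)H and FAD⁺
  amplitudes are modulated in anti-phase (redox turnover) at the MO-1
  frequency with 15 % depth. The two groups carry different metabolic
  baselines (redox ratio 2.2 vs 2.0, normalised NAD(P)H 1.7 vs 1.9 — the
  knockout-like group sits closer to the oxidised state), so the
  between-group biomarker comparison has a real injected effect to find.
  "Amplitude" means the window-maximum of the
  noiseless composite spectrum — what the extractor measures — achieved
  through a 3 × 3 peak-overlap solve plus a few fixed-point steps; without
  this, peak overlap alone biases the elastin window maximum by several
  percent and truth would not be expressed in the measured space.
* **Coupling**: the metabolic phase is the argument of the phasor mixture
  `ρ·exp(iφ_EDHF) + (1−ρ)·exp(iφ_indep)`. ρ = 1 copies the vascular EDHF
  phase exactly; ρ = 0 leaves the oscillators independent; the default
  ρ = 0.8 produces intermediate band coherences.
* **Replicates**: each subject is recorded twice (`n_replicates = 2`) and
  replicate metrics are averaged before statistics, mirroring the
  duplicate-experiment protocol of the emulated study design. Group sizes
  default to 5 and 6.

Everything is deterministic given the configuration seed; each subject,
replicate and sub-stream derives its own seed, and the per-subject truth
record suffices to reconstruct every injected component.

What the generator does **not** emulate: realistic cardiac/respiratory
waveform shapes (only band placement), amplitude co-modulation between
oscillators, motion artefacts, probe drift, melanin/scattering effects on
the optical channels, or any biophysical model of NADH kinetics and
haemodynamics. Tests passing on this generator demonstrate that the
analysis chain recovers known band-limited structure, reactivity signs and
phase coupling under realistic noise — not that it is robust to every
artefact of real recordings.

## Statistics

The statistical layer mirrors a small two-group baseline/stimulus design:
Shapiro–Wilk normality screen (failures are flagged, not excluded — the
pipeline stays parametric), two-sided paired t-tests within group
(baseline vs. PE), two-sided pooled-variance Student t-tests between
groups (Welch behind `var_equal = FALSE`), Pearson correlations with the
relevance rule *p ≤ 0.05 and |r| > 0.5*, pooled over windows (each subject
contributes a baseline and a stimulus row). Sidedness is two-sided
throughout. No multiple-testing correction is applied, matching the
emulated design's reporting style; the report prints the number of tests
performed so users can apply their own.

With n = 5/6 subjects and fewer than three admissible slow-oscillator
cycles per window, the paired t-test on band energy is underpowered for
moderate effects: across repeated synthetic studies the *direction* of an
injected halving/doubling of EDHF amplitude is recovered essentially
always, while p < 0.05 in both groups simultaneously is much rarer. The
acceptance script reports both rates.

## Numerical choices, in one place

* Wavelet grid: 16 voices/octave; f ∈ [1.5 × 10⁻³, min(fs/4, 6)] Hz (LDF)
  or [1.5 × 10⁻³, 0.05] Hz (metabolic).
* "Energy" is `|W|²`, "amplitude" is `|W|`; both are always computed.
* FFT zero-padding to the next power of two ≥ 2 × record length.
* COI e-folding factor √2; band reliability needs ≥ 50 % COI coverage at
  every band frequency.
* Spline boundary: not-a-knot (natural optional); no extrapolation.
* SO₂: least squares, negatives clipped and flagged; reciprocal condition
  number < 10⁻¹⁰ is rejected.
* Ties in band peak location resolve to the lower frequency
  (`which.max`); degenerate paired tests (zero-variance differences)
  report t = 0, p = 1 and a flag.
* Decimation by composite factors is staged (≤ 8 per stage, Chebyshev IIR).

## Problem sizes used in the tests

The validation suite exercises the chain at the study's native geometry —
20-minute records, 20 Hz LDF (24 000 samples), 20 spectra — for
single-subject checks, and at a reduced setting (decimated LDF,
`ldf_fast = TRUE`, which drops the cardiac and respiratory bands from the
catalogue) for the repeated-study Monte-Carlo batteries (20 seed pairs for
coherence properties; 25 studies for reactivity-sign recovery). The
`ldf_fast` path is part of the public configuration surface, not a test
shortcut: all slow-band metrics are computed identically on it.

## Known limitations

* Absolute coherence levels at millihertz frequencies are biased upward;
  only contrasts between conditions are interpretable without surrogate
  testing.
* `e_i`/`a_i` depend on the frequency-grid density through `n_i`; they are
  comparable only across equal grids (the grid is recorded with every
  metrics row).
* The spectral "amplitude" estimator is a raw window maximum: it is biased
  upward under intensity noise (max of noisy points) and has no background
  subtraction. For the ratio biomarkers the bias largely cancels.
* Reflectance preprocessing from raw counts to absorption coefficients is
  instrument-specific and out of scope; the SO₂ module accepts `mu_a`
  directly.
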