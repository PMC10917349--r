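---
title: "Neurodynamics of musical groove: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neurodynamics of musical groove: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Some music makes people want to move; the strength of that urge (the
*groove* experience) depends systematically on how rhythmically predictable
the music is. Empirically, groove ratings follow an inverted U over the
degree of syncopation: rhythms that are fully beat-aligned or extremely
syncopated are rated low, moderately syncopated rhythms highest. This
package implements, as reusable and tested components, the computational
chain needed to study that phenomenon end to end:

* a symbolic representation of beat-gridded rhythms and the
  Longuet-Higgins--Lee (LHL) syncopation index;
* a three-layer gradient-frequency network of canonical Hopf oscillators
  that transforms a rhythm into beat-rate (2 Hz) responses of an auditory,
  a motor-planning (meter) and a groove layer;
* the acoustic (cochlear envelope / modulation spectrum), behavioural
  (tapping, quadratic rating fits) and MEG-style analyses (Morlet spectra,
  1/f rectification, spatial spectral-gradient fits, cross-validated ridge
  decoding with Fisher-z coding precision and Storey FDR, phase-amplitude
  coupling);
* a synthetic multichannel data generator with machine-readable ground
  truth, so every analysis has a planted-recovery test.

# Rhythms and the syncopation index

A `beat_grid` places a strictly periodic beat (2 Hz by default) on a
subdivided metrical grid; position `i` occurs at
`i / (beat_rate * subdivisions_per_beat)` seconds. `metric_weights()`
assigns LHL weights by recursive subdivision: the measure downbeat has
weight 0 and every subdivision level subtracts 1, e.g.
`0 -3 -2 -3 -1 -3 -2 -3` for a 4/4 measure with two subdivisions per beat.
The measure length must factor into 2s and 3s (duple/triple splits, larger
factors first); other meters are rejected explicitly.

A syncopation event is a note onset on a weak position followed, before the
next onset, by silence on a stronger position; its value is the weight
difference, and the index is the sum over events. When several rests
qualify, the maximum-weight rest is used. A rhythm whose onsets all fall on
beats scores 0.

`syncopation_family()` builds graded variants of a beat-aligned bass line
by *anticipation*: moving a note one subdivision earlier, which creates
precisely the defining event (weak-position note before the vacated
strong-position rest). Each candidate anticipation contributes an integer
increment; a seeded subset search combines them to hit each requested index
exactly, and every result is verified with `syncopation()` itself. We chose
anticipation over unconstrained onset shuffling because it preserves note
counts, mirrors how syncopated bass lines are actually composed, and keeps
the acoustic beat content monotonically related to the index (an arbitrary
equal-index pattern need not have comparable 2-Hz energy). An anticipated
downbeat crosses the barline, so per-measure counts may differ by one
between variants.

## Stimulus rendering

`stimulus_from_pattern()` renders onsets as 25-ms unit rectangular pulses
(shape and width configurable), adds the constant beat-aligned drum click
track that every melody shares, tiles the result to 16 s, scales it by the
drive amplitude, and takes the analytic (Hilbert) signal, giving the
complex-valued input the oscillator model consumes. The drum track matters:
a bass line whose notes are *all* anticipated is simply a quarter-period
phase shift of the beat, so its 2-Hz Fourier magnitude returns to the
beat-aligned value; against the fixed drum the anticipated notes interfere
destructively instead, and 2-Hz acoustic energy falls monotonically with
the syncopation index, as it should.

The drive amplitude is not reported in the source material; the default
0.25 keeps the most strongly driven auditory-layer oscillators near
amplitude 0.4, well inside the unit disk, while remaining strong enough to
trigger the meter layer for beat-supporting rhythms.

# The oscillator network

Each layer is a bank of 321 canonical Hopf oscillators with natural
frequencies log-spaced from 0.375 to 12 Hz. The state of oscillator `i`
follows

    dz/dt = z * (a + b|z|^2 + d|z|^4 / (1 - |z|^2)) + x,

with `a = alpha + i*omega`, `b = beta1 + i*delta1`, `d = beta2 + i*delta2`.
The radial part has equilibria where
`alpha + beta1 r^2 + beta2 r^4/(1-r^2) = 0`; `radial_equilibria()` solves
this directly and serves as the closed-form oracle for the integrator.

* Layer 1 (auditory): `alpha = 1e-4, beta1 = 0, beta2 = -3` -- just above a
  supercritical Hopf bifurcation. Spontaneous amplitude is
  `(alpha/3)^(1/4) ~ 0.076`; driven on resonance by a force `F` the
  amplitude is `~ (F/3)^(1/5)`, a strongly compressive resonator.
* Layers 2 (motor planning / meter) and 3 (groove):
  `alpha = -0.8, beta1 = 4, beta2 = -3` -- the double-limit-cycle (bistable)
  regime with a stable rest state, a stable limit cycle at
  `r = sqrt(0.4) ~ 0.632`, and an unstable cycle at `r = sqrt(2/7) ~ 0.535`
  between them. A sustained resonant drive of roughly 0.14 or more pushes an
  oscillator from rest across the unstable cycle ("the jump"); the high
  state is then self-sustaining.

Each oscillator's flow is multiplied by its natural frequency
(`freq_scaling = TRUE`), the standard gradient-frequency convention that
makes transients scale with the oscillator's own period; a flag disables
it. Equilibrium amplitudes are unaffected either way.

## Connection topology and plasticity

Layer 1 hears the stimulus; layer 2 receives plastic connections from layer
1; layer 3 receives fixed 1:1 excitatory input from layer 2 (`w = 0.8`) and
fixed 1:1 inhibitory input from layer 1 (`w = -0.7`), i.e. it responds to
the difference between the meter dynamics and the stimulus-driven dynamics.
Fixed connections are diagonal (same-frequency partner in the other layer),
the minimal reading of a 1:1 topology on a shared grid.

The layer-1 to layer-2 mask connects each frequency to its 1/4, 1/3, 1/2,
unison, 2nd, 3rd and 4th harmonics (pairs within one grid step of those
ratios). Because these are *between-layer* connections, the unison pair is
included: it is the "first harmonic" and the main resonant route. Coupling
terms use mode-locking exponents, `c * z_j^k * Conj(z_i)^(m-1)` with
`k f_j = m f_i`, so every harmonic connection transmits at the target's own
frequency. This is what lets the meter layer infer a 2-Hz pulse from 1-Hz
and 4-Hz rhythm content -- with plain 1:1 terms everywhere, harmonic input
arrives off-resonance, the meter layer can only echo the auditory layer,
and the groove layer's inverted U never forms. A `one_to_one` option
retains the simpler reading.

Connections evolve by the Hebbian rule

    tau * dc/dt = c * (lambda + mu1|c|^2 + mu2|c|^4/(1-|c|^2))
                  + kappa * z_target^m * Conj(z_source)^k,

with `lambda = -1, mu1 = 4, mu2 = -2.2, kappa = 0.2`. This rule is itself
bistable: without coactivation a connection decays unless its magnitude
exceeds the unstable root ~0.606 of its radial equation. Two consequences
fix the remaining free constants:

* *Initial magnitude* (`conn_init = 0.3`). Very weak initialization (e.g.
  0.05) decays to the small root `~kappa*|z2||z1|` within about a second --
  before the compressive auditory layer has entrained (~3-4 s) -- so the
  meter layer can never jump, contradicting the intended bistable
  triggering. Initializing *above* the sustaining threshold (>= 0.61) makes
  the scaffold permanent and over-excites the network (every oscillator
  jumps for every rhythm; no stimulus selectivity). The working regime is a
  sub-threshold scaffold strong enough to transmit while it lasts.
* *Time scale* (`tau = 8` s, half the melody). The scaffold fades over the
  trial unless reinforced by coactivation, creating a selectivity window:
  beat-supporting rhythms entrain layer 1 quickly enough to trigger the
  meter layer before the scaffold fades; heavily syncopated rhythms do not.
  The qualitative behaviour (monotone layer-1 decline, selective layer-2
  engagement, interior layer-3 maximum) is stable over `conn_init` in
  roughly [0.28, 0.33] and `tau` in [8, 10]; the defaults sit at the centre
  of that region.

Initial connection *phases* are zero (coherent transmission); initial
oscillator states are random (seeded) -- layer 1 uniform in a 0.01-radius
disk, layers 2-3 at rest up to 1e-4 noise -- which is the stated source of
run-to-run variability. A `conn_phase = "random"` option exists; random
phases make the multifrequency resonant sum a per-run phase lottery.

## Integration and readout

A fixed-step RK4 integrator (compiled; `dt = 1/480` s default) advances all
963 oscillator and ~5000 connection ODEs; states must stay inside the unit
disk (the `|z|^4/(1-|z|^2)` term diverges at 1) and escapes abort with a
time stamp. Halving `dt` changes 2-Hz amplitudes by well under 0.5% (tested
with a smooth drive so pulse-sampling differences don't masquerade as
integrator error).

The readout discards the first 2 s (evoked transient), Fourier-transforms
each layer's mean field over 2-16 s, and reads the amplitude at the bin
nearest 2 Hz (the 14-s window makes 2 Hz bin-exact). `run_protocol()`
repeats this per melody over 29 seeded runs, mirroring a 29-subject
estimate, and tabulates melody x run x layer amplitudes.

# Acoustic characterization

`cochlear_envelope()` implements a 32-channel gammatone filterbank
(4th-order magnitude response, centre frequencies ERB-spaced from 80 Hz to
min(8 kHz, 0.45 fs)), takes per-band analytic-signal magnitudes and sums
them; `modulation_spectrum()` decimates the envelope to 100 Hz, removes the
mean and reports Fourier amplitudes on the 1-9 Hz grid plus the 2-Hz
amplitude in dB (re 1 a.u.). The filterbank family and band edges of the
original front end are not reported, so acoustic results are matched
qualitatively: for click-rendered melodies the 2-Hz modulation amplitude
decreases monotonically with the syncopation index.

# Time-frequency analysis and the spectral gradient

`morlet_tfr()` uses a unit-energy Morlet wavelet with central frequency 1
and a 3-s FWHM temporal envelope at 1 Hz, scaled by `1/f`
(`sd = FWHM / (2*sqrt(2*log(2)))`); coefficients within one FWHM of a
signal edge are flagged and excluded from time averages. For stationary
windows, `morlet_power_avg()` computes the identical time-averaged power
through Parseval's identity (one FFT per signal and a matrix product),
which is what makes the 29-subject decoding study tractable; the identity
is asserted against the explicit time-resolved route in the tests.

`rectify_1f()` z-scores power across locations per frequency, removing any
spectral profile shared by all locations -- the 1/f background -- exactly.
`dominant_frequency()` takes the band-limited (1-45 Hz) argmax with ties to
the lower frequency, and `fit_spatial_gradient()` fits a 5th-order
polynomial of dominant frequency against each spatial coordinate
independently (coordinates standardized internally for conditioning,
coefficients reported back in mm), with adjusted r-squared per dimension.

Cross-location z-scoring has a structural property worth knowing: at a
frequency where *no* location carries narrowband power, the z-values are
standardized noise, so isolated spectral features can only dominate if each
frequency's "owner" population is a small fraction of all locations. The
synthetic generator therefore plants the dominant-frequency gradient
log-linearly along its coordinate (equal vertex population per
log-frequency band, the natural spacing for neural rhythms); at the study's
grid size (1673 vertices, ~19 levels along y) each frequency is owned by
~5% of vertices and recovery is near-perfect, while heavily down-scaled
grids (few distinct coordinate levels) are intrinsically harder.

# Decoding

`ridge_weights()` solves `(Z'Z + alpha I)^-1 Z'x` with `alpha = 2`;
`crossval_decode()` uses 10 interleaved folds (row i to fold `i mod 10`,
144 trials giving the 129-130/14-15 train/test split), estimates
standardization statistics on the training partition only and applies them
to the held-out rows -- the choice that makes the procedure leakage-free,
which the tests verify directly. `coding_precision()` is the Fisher-z
transformed Pearson correlation between out-of-fold predictions and truth,
capped at |r| = 0.999999 so noiseless synthetic data stay finite.
`searchlight_decode()` repeats this per vertex over the vertex plus its 50
nearest neighbours (optionally band-limited); `roi_decode()` decodes per
frequency within 20-vertex ROIs grown around successive map maxima.
Group-level inference is a per-unit t-test across subjects with Storey FDR
(`storey_fdr()`: pi0 from the 0.05-0.95 lambda grid with a cubic smoothing
spline, q-values by the step-up construction).

In the synthetic study, both regressors are partially co-coded (the
syncopation-groove link makes them correlated), so each regressor's
spectrum can show precision at the other's bands; the signed precision
contrast is what separates them, exactly as in the original analyses.

# Phase-amplitude coupling

`pac_rho()` implements `rho = |sum(a * exp(i phi))| / sqrt(N * sum(a^2))`,
which lies in [0, 1] by Cauchy-Schwarz; equality requires constant
amplitude at constant phase (a single amplitude spike gives `1/sqrt(N)`,
not 1). `pac_comodulogram()` pools wavelet phase (at 1.4 or 2 Hz) and
amplitude (3-45 Hz) over the 0.5-16 s window of all trials, dropping
edge-flagged samples; off-grid frequencies snap to the nearest bin with a
warning. `cluster_vs_wholebrain()` compares mean rho inside a vertex
cluster against the whole grid per amplitude frequency, with a paired
t-test and Storey FDR across amplitude frequencies when per-subject maps
are supplied.

Two estimator properties surface in synthetic data and are worth noting
when reading comodulograms: amplitude modulation creates spectral sidebands
that can promote the bin *adjacent* to the carrier (the sideband falls
closer to that bin's wavelet passband centre), and rho has a positive null
level that depends on the amplitude series' autocorrelation. The generator
therefore gives every vertex a beta oscillation with slowly fluctuating
amplitude -- only inside the PAC cluster is the fluctuation locked to the
local delta phase -- plus ubiquitous beat-locked 2-Hz activity, so the
cluster-versus-rest comparison isolates locking rather than amplitude
structure.

# The synthetic study generator

`synth_config()` fixes the emulated study conditions: 29 subjects, 36
melodies (12 per condition, indices 0-15, low condition all 0) x 4 blocks =
144 trials, 1673 sources on a 10-mm lattice inside an ellipsoid (MNI-like
axes), mixed to 248 sensors by distance-decaying weights, 1/f background
spectra (exponent 1) with lognormal trial noise (sd 0.4) smoothed across
frequency with the kernel implied by the Morlet bandwidth (`sd ~ f/8`), a
4-to-30-Hz dominant-frequency gradient along the posterior-anterior axis, a
syncopation-linked 2-Hz effect in two lateral "auditory" patches, a
rating-linked 1.4-Hz and 20-30-Hz effect in a "dorsal" patch, and
delta-phase to beta-amplitude coupling in a "sensorimotor" patch. Effect
sizes are in units of the log-power noise sd per sd of the standardized
regressor (default 0.5). Ratings follow a quadratic link peaking at index 7
with ordinal noise, clipped to the 1-7 scale; taps are jittered 2-Hz
metronome sequences.

Two generation routes exist. The spectral route draws time-averaged power
directly (fast; used for the full-scale decoding and gradient studies); the
time route synthesizes per-trial source time series and wavelet-decomposes
them into a full power+phase cube (used for PAC and for validating the
spectral route's assumptions). Every dataset carries its ground truth
(vertex sets, bands, coefficients) so analyses are tested as recoveries.

What the generator does *not* emulate: anatomical geometry and realistic
forward fields, artifacts (blinks, cardiac), inter-regional dynamics,
non-stationarity within trials, and 1/f exponent heterogeneity. Passing
recovery tests therefore demonstrate the correctness and sensitivity of the
analysis chain under the stated statistical structure, not performance on
real recordings.

# Problem sizes in the test suite

The package's own validation runs at these scales: the oscillator
inverted-U study uses an 8-level anticipation family (indices 0-14), 5 runs
per level, 321 oscillators per layer at `dt = 1/480`; the decoding study
runs all 29 subjects at full sensor count on a 40-bin frequency grid; the
gradient recovery runs one full-scale dataset (1673 vertices, 100 bins)
plus 100 down-scaled planted-versus-control replicates (300 vertices, 36
trials, 40 bins); the PAC study uses 6 simulated subjects with individual
coupling strengths on a 120-vertex grid. Closed-form oracles (radial
equilibria, ridge normal equations, PAC moments, Fourier pairs) anchor the
numerical components.

# Known limitations

* The Hebbian time scale, drive amplitude, initial connection magnitude and
  phase convention are not reported in the source material; the defaults
  are fixed by the dynamical analysis above and exposed in the
  constructor. Conclusions that depend on transient timing should sweep
  `conn_init`, `tau` and `stim_amplitude`.
* The LHL weight tree assumes binary/ternary meters; additive or irregular
  meters are out of scope.
* `pac_rho` carries no surrogate normalization; comparisons should be
  between conditions or regions, not against an absolute zero.
* MIDI input is not implemented; rhythms enter via JSON/CSV or
  programmatic construction.
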