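# groovedyn

Tools for studying the musical *groove* experience — the pleasurable urge
to move to music — as a problem in auditory–motor neural dynamics. The
package is aimed at computational neuroscientists and music-cognition
researchers who want a tested, fully synthetic-data-backed implementation
of the modelling and analysis chain linking rhythmic syncopation, neural
oscillator dynamics, and MEG-style multivariate analyses.

## What it implements

**Rhythm and syncopation.** Beat-gridded rhythm patterns with
Longuet-Higgins–Lee metric weights (downbeat 0, −1 per subdivision level)
and the LHL syncopation index: every note onset on a weak position followed
by silence on a stronger position contributes the weight difference
`w_rest − w_note`, summed over events. A generator builds families of
variants with prescribed indices by note anticipation.

**A three-layer gradient-frequency Hopf network.** Each layer holds 321
canonical Hopf oscillators (log-spaced 0.375–12 Hz) obeying

```
dz/dt = z (α + iω + β₁|z|² + β₂|z|⁴ / (1 − |z|²)) + x .
```

Layer 1 (auditory, α = 10⁻⁴, β₁ = 0, β₂ = −3) sits near a Hopf bifurcation
and entrains to the stimulus pulse train; layers 2 and 3 (motor planning
and groove, α = −0.8, β₁ = 4, β₂ = −3) are bistable (double limit cycle;
stable rest and a stable cycle at r = √0.4). Layer 1 → 2 connections are
Hebbian-plastic multifrequency couplings at harmonic ratios (mode-locking
exponents k:m with k·f_source = m·f_target); layer 3 receives fixed 1:1
excitation from layer 2 (w = 0.8) and inhibition from layer 1 (w = −0.7),
responding to the meter−stimulus difference. A compiled RK4 integrator
yields per-layer mean fields, read out as the Fourier amplitude at 2 Hz
over seconds 2–16.

**Analyses.** Gammatone cochlear envelopes and 1–9 Hz modulation spectra;
instantaneous tap frequency `F(t) = 1/(m_t − m_{t−1})` and
quadratic/linear fits with adjusted/Pearson r²; Morlet time–frequency
decomposition (Fc = 1, 3-s FWHM at 1 Hz); 1/f rectification by
cross-location z-scoring; dominant-frequency maps and 5th-order spatial
polynomial gradient fits; cross-validated ridge decoding (α = 2, 10
interleaved folds, leakage-free standardization) with Fisher-z coding
precision, searchlight (50 neighbours) and 20-vertex ROI variants, paired
precision contrasts, and Storey FDR; the phase–amplitude coupling
statistic `ρ = |Σ a·e^{iφ}| / √(N·Σ a²)` with comodulograms and
cluster-versus-whole-brain comparisons.

**Synthetic MEG-style studies.** A seeded generator produces source- and
channel-level datasets with the structure those analyses assume — 29
subjects × 144 trials, 1673 sources on a 10-mm ellipsoidal lattice mixed to
248 sensors, 1/f backgrounds, a planted 4→30-Hz spectral gradient,
condition-locked narrowband effects at 2 Hz / 1.4 Hz / 20–30 Hz, and
planted delta→beta coupling — always alongside machine-readable ground
truth, so every analysis stage is tested as a recovery.

## Worked example

```r
library(groovedyn)

# a beat-aligned bass line on a 2-Hz beat, and variants at indices 0, 6, 12
base <- rhythm_pattern(beat_grid(beat_rate = 2, subdivisions_per_beat = 2,
                                 beats_per_measure = 4, n_measures = 4),
                       seq(0, 31, by = 4))
fam <- syncopation_family(base, levels = c(0, 6, 12), seed = 1)
fam[[2]]
#> <rhythm_pattern> 8 onsets on 32 positions
#>  |x..x....|
#>  |x...x...|
#>  |x..x....|
#>  |x..x....|
syncopation(fam[[2]])
#> <syncopation_score> total = 6 (3 events)

model <- hopf_network()
model
#> <hopf_network> 3 layers x 321 oscillators, 0.375-12 Hz (log-spaced)
#>   layer 1 (auditory): alpha=0.0001 beta1=0 beta2=-3
#>   layer 2 (motor planning): alpha=-0.8 beta1=4 beta2=-3; 3643 learned connections from layer 1 (|c0|=0.3)
#>   layer 3 (groove): fixed 1:1 couplings w23=0.8 (excitatory), w13=-0.7 (inhibitory)

tab <- run_protocol(model, fam, n_runs = 3, base_seed = 1)
agg <- aggregate(amplitude_2hz ~ melody + layer, tab, mean)
agg$syncopation <- attr(tab, "syncopation")[agg$melody]
agg[order(agg$layer, agg$melody), c("layer", "syncopation", "amplitude_2hz")]
#>  layer syncopation amplitude_2hz
#>      1           0      0.005516
#>      1           6      0.004347
#>      1          12      0.003559
#>      2           0      0.003321
#>      2           6      0.003678
#>      2          12      0.000416
#>      3           0      0.005162
#>      3           6      0.005264
#>      3          12      0.000653
```

The table shows the model's signature behaviour: the auditory layer's 2-Hz
amplitude falls monotonically as syncopation rises (the rhythm carries less
beat energy), while the groove layer peaks at the *intermediate* degree of
syncopation and collapses at the extreme one — the inverted-U relation
between syncopation and the urge to move. Across a denser 8-level family
with 5 runs each (see `tests/testthat/test-acceptance.R`), the layer-1
amplitude is monotone with Spearman ρ ≤ −0.95 and the layer-3 quadratic has
negative curvature with an interior vertex near index 4.

A small example melody ships in
`inst/extdata/example_melody.json` (readable with `read_rhythm_json()`).

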