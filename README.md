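# rhythmskills

Is there one "rhythm IQ", or are there several dissociable rhythm skills?
`rhythmskills` implements a complete analysis pipeline for a four-test
drumming battery designed to answer that question: two *beat-tapping* tests
(synchronizing to a metronome; adapting to a step change in metronome
tempo) and two *memory/sequencing* tests (drumming along to a repeating
rhythmic sequence; reproducing a sequence from memory during a silent
pause). If rhythm is a single competence, all four scores should correlate;
if beat tapping and rhythm memory are distinct aptitudes, the scores should
form two clusters with strong within-cluster and negligible cross-cluster
correlations, and a two-factor solution should capture the battery.

The package is aimed at auditory-motor researchers who want to run, score,
or simulate this kind of battery: it covers stimulus-schedule construction,
onset extraction from continuous two-channel recordings, the four scoring
procedures, a generative tapping model for synthetic cohorts, and the
cohort-level statistics.

## What is implemented

**Schedules** (`battery_plan()`): 6 metronome trials (40 beats each at
IOIs of 667/500/333 ms), 55 tempo-adaptation trials (6–10 conga pulses at a
500-ms IOI, then five more at a post IOI in {450, …, 550} ms; 50 trials are
shifted), 4 drum-along trials (a 3.2-s, nine-onset sequence with IOI
multiset {200×5, 400×2, 600, 800} ms, repeated 10×) and 30 sequence-memory
trials (sequence ×3, then a silent cycle for reproduction). Strongly
metrical sequences carry onsets on all four 800-ms beats of the cycle;
weakly metrical ones syncopate.

**Onset extraction** (`mark_onsets()`): a sample is an onset iff its
absolute amplitude exceeds a threshold and no sample within a preceding
refractory window exceeded it — the standard threshold-plus-refractory rule
for drum-trigger channels, with adaptive per-channel default thresholds and
a brute-force-verified implementation. A minimal WAV reader/writer and
impulse-train renderer close the loop for audio files.

**Scoring** (`score_participant()` and per-test functions):

- *metronome variability* = SD(produced inter-tap intervals over the last
  20 beats) / stimulus IOI, averaged over the six trials;
- *tempo-adaptation error* = mean |target IOI − produced IOI| over the last
  two produced intervals of each shifted trial, averaged over 50 trials (ms);
- *drum-along* and *sequence-memory accuracy*: stimulus and drumming are
  binarized on a 200-ms hit/rest grid (a tap counts for a slot if it falls
  in [−100, +100) ms around the slot onset) and scored as percent
  positional agreement — e.g. stimulus `[0 1 1 0]` vs drumming `[1 1 1 0]`
  scores 75%.

**Cohort simulator** (`simulate_cohort()`): participants are two
independent latent abilities (beat, memory) plus a verbal component. Taps
follow a linear phase-correction model with Wing–Kristofferson two-source
noise and causal period correction: with asynchrony `A_k = tap_k − stim_k`,

```
tap_{k+1} = tap_k + P_{k+1} − α·A_k + T_k + (M_{k+1} − M_k)
```

so the asynchrony is AR(1) with stationary variance `σ_T²/(1−(1−α)²)`.
Sequence drumming reproduces each grid hit with a recall-fidelity
probability plus Gaussian jitter and occasional false taps.

**Statistics** (`analyze_cohort()`): 3-SD outlier and off-tempo (> 5 ms
mean tempo deviation) exclusions; Jarque–Bera normality checks; log
transform of variability and rationalized-arcsine (rau) transform of the
drum-along proportion; Pearson correlation matrix; two-factor generalized
least squares factor analysis (discrepancy `½·tr[(I − S⁻¹Σ)²]`) with
varimax rotation; and hierarchical regressions relating rhythm memory to
verbal memory (ΔR² with partial F tests).

## Worked example

Simulate the default 65-participant cohort (independent latents), score
it, and run the dissociation analysis:

```r
library(rhythmskills)
scores <- simulate_scores(65, seed = 1)
analyze_cohort(scores)
```

```
Rhythm-skill dissociation analysis (n = 65 )

Pearson correlations (r, lower triangle | p, upper triangle):
                      metronome_variability adaptation_error_ms drumalong_pct memory_pct
metronome_variability                 1.000               0.000         0.496      0.362
adaptation_error_ms                   0.556               1.000         0.117      0.032
drumalong_pct                        -0.086              -0.196         1.000      0.000
memory_pct                           -0.115              -0.266         0.724      1.000

GLS factor loadings (varimax; |loading| > 0.3 marked *):
                      Factor1 Factor2
metronome_variability -0.035   0.668*
adaptation_error_ms   -0.169   0.823*
drumalong_pct          0.721* -0.091 
memory_pct             0.989* -0.120 
Variance explained: 66.9%

Hierarchical regressions:
  memory_pct ~ verbal: R2 = 0.26; + drumalong: dR2 = 0.31 (p = 6.7e-09)
  digits_reversed ~ rhythm memory: R2 = 0.21; + awm: dR2 = 0.29 (p = 1.7e-07)
```

Read: the two beat measures correlate (r = 0.56) and the two memory
measures correlate (r = 0.72), while all four cross-cluster correlations
are near zero — and the varimax-rotated two-factor solution assigns the
beat measures to one factor and the memory measures to the other, with all
cross-loadings below 0.3. That is the two-cluster dissociation pattern the
battery is designed to detect; setting `sim_config(latent_cor = 0.9)`
instead produces a one-factor-dominant solution, the signature of a single
rhythmic competence.

The same pipeline runs from disk artifacts (`cmd_simulate()`,
`cmd_extract()`, `cmd_score()`, `cmd_analyze()`), or from a shell:

```sh
Rscript inst/cli/rhythm-battery.R all --seed 7 --out-dir runs/demo
```

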