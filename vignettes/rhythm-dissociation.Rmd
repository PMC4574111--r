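---
title: "Scoring a rhythm battery and testing the beat-tapping / rhythm-memory dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring a rhythm battery and testing the beat-tapping / rhythm-memory dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmskills)
```

This vignette is the package's methods account: the battery and its
scoring rules, the generative model behind the cohort simulator, the
statistical pipeline, and the numerical and design choices that were
genuinely open — with what each choice does and does not let you conclude.

## The battery

Four tests, one timeline. Every trial is a planned sequence of stimulus
onsets (ms); the same schedule objects drive scoring, simulation, WAV
rendering and the splitting of continuous recordings.

* **Metronome** — six trials of 40 isochronous snare onsets, two each at
  inter-onset intervals (IOIs) of 667, 500 and 333 ms, always in that
  order. Only the last 20 beats are analyzed, giving the participant time
  to lock in.
* **Tempo adaptation** — 55 trials: 6–10 conga pulses at a 500-ms IOI,
  then five more at a post IOI drawn from 450–550 ms in 10-ms steps. Five
  trials per post IOI, so 50 trials are true shifts and five are catch
  trials (generated, but excluded from scoring).
* **Drum-along** — four trials; each repeats a 3.2-s, nine-onset sequence
  ten times. All sequences use the same IOI multiset {200×5, 400×2, 600,
  800} ms and differ only in order.
* **Sequence memory** — thirty trials; the sequence plays three times and
  the participant reproduces it during a silent fourth cycle.

**Sequence bank.** The protocol's source set of rhythmic patterns is
specified only by the IOI multiset and a strong/weak metricality contrast,
so the package enumerates all 1512 orderings of the multiset and
classifies each by how many of the cycle's four 800-ms beat positions
(grid slots 0, 4, 8, 12) carry an onset: *strong* = all four (264
candidates), *weak* = at most two (666 candidates), i.e. more rests in
metrically strong positions. The first *k* of each class in lexicographic
IOI order are used, which makes the bank deterministic and reproducible
without any data file. The drum-along test takes the first two of each
class; the memory test takes the next fifteen.

**Open scheduling choices.** The number of base-tempo repetitions in an
adaptation trial is stated only as a range (6–10); the package draws it
uniformly (maximum-entropy reading), seeded. Trial order is shuffled under
the same seed. Each trial starts after a configurable lead-in
(default 1000 ms) — recordings need a buffer — with 2 s between trials.

## Scoring rules

**Metronome variability** is the sample SD (n−1 denominator; standard for
behavioural inter-response variability) of the produced inter-tap
intervals over the last 20 beats, divided by the stimulus IOI, averaged
over the six trials. Dividing by the IOI makes trials at different tempi
commensurable. The protocol does not define a tap–beat correspondence, so
the package matches taps to beats by nearest-neighbour within half an IOI
(globally, closest pair first); unmatched or extra taps are dropped, and
intervals are taken only between taps matched to consecutive beats. At
least three matched taps are required, else the trial is marked missing.

**Tempo-adaptation error** is the mean of |target IOI − produced interval|
over the last two inter-tap intervals the participant produced in each
shifted trial — operationalized as the final two intervals among taps up
to one post-IOI past the last scheduled onset — averaged over the 50
shifted trials.

**Grid scores.** Stimulus and drumming are binarized on a 200-ms grid: a
slot is a drum hit iff at least one tap falls within 100 ms of the slot
onset. The window is half-open, `[−100, +100)`, so adjacent windows tile
time exactly and a tap at precisely +100 ms belongs to the next slot. The
score is the percentage of slots whose bits agree — stimulus `[0 1 1 0]`
vs drumming `[1 1 1 0]` gives 75% — which penalizes missed hits and
spurious taps symmetrically through the mismatch count, with no separate
penalty term. The drum-along test scores repetitions 2–10 (repetition 1
is a listening pass) and averages the four trials; the memory test scores
the 16 slot times of the virtual fourth repetition and averages all 30
trials, rests included.

**Missing data.** Per-trial failures (too few taps, lost trials) become
missing markers; participant scores are means over available trials with
a completeness count, rather than NA-poisoning the whole battery.

## Onset extraction

Continuous two-channel recordings (stimulus playback, drum trigger) are
converted to onset lists by the threshold-plus-refractory rule: a sample
is marked iff its absolute amplitude strictly exceeds a threshold and no
sample in the preceding refractory window (open interval) exceeded it.
Absolute value matters because drum-trigger transients are bipolar. The
onset time is the first threshold crossing at sample precision (no
sub-sample interpolation); the logged amplitude is the peak within the
refractory window. In the lab this thresholding is tuned per participant
by eye; as a reproducible default the package uses 5× the channel's
median absolute amplitude (falling back to half the channel peak for
nearly-silent synthetic channels) and a 50-ms refractory period — shorter
than any stimulus IOI in the battery, longer than a single hit's ringing —
both overridable per trial. Trials whose extracted stimulus-onset count
disagrees with the schedule are flagged for manual review rather than
silently scored.

## The cohort simulator

No participant-level data are distributed with this battery design, so
the dissociation analysis is validated as a *parameter-recovery
experiment*: a synthetic cohort whose generative truth contains two
independent abilities must yield the two-cluster pattern, and a cohort
generated with strongly correlated abilities must not.

**Latent structure.** Each participant draws independent standard-normal
`beat_ability` and `memory_ability` (optionally correlated via
`latent_cor`). Each *test* gets an effective ability = loading × shared
latent + independent test-specific remainder, with loadings 0.75 (beat
tests) and 0.85 (memory tests). Without the test-specific component the
within-cluster score correlations would approach the measurement ceiling
(~0.95), which no behavioural battery shows; with these loadings they
land near 0.55 and 0.72. Verbal memory scores load 0.4 on the memory
latent plus 0.6 on a verbal-specific factor shared by the two verbal
tests only, so rhythm memory and verbal memory overlap but dissociate.

**Tapping model.** Taps follow a first-order linear phase-correction
model with Wing–Kristofferson two-source noise and a causal first-order
period correction. With asynchrony $A_k = t_k - s_k$:

$$t_{k+1} = t_k + P_{k+1} - \alpha A_k + T_k + (M_{k+1} - M_k)$$

where $\alpha \in (0,2)$ is the phase-correction gain (optimum 1,
stationarity for $|1-\alpha|<1$), $T_k \sim N(0,\sigma_T^2)$ is central
timekeeper noise, $M_k \sim N(0,\sigma_M^2)$ is motor implementation
noise, and the internal period $P$ relaxes toward each *already heard*
stimulus gap with gain $\gamma$. Causality matters: a tempo shift cannot
inform the tap that coincides with its first shifted onset, so the shift
is first absorbed as an asynchrony and then corrected. Two closed forms
anchor the implementation and are verified in the tests: with zero noise
the asynchrony decays geometrically, $A_n = A_0 (1-\alpha)^n$, and with
timekeeper noise only it is an AR(1) with stationary variance
$\sigma_T^2 / (1 - (1-\alpha)^2)$.

**Sequence model.** For each grid slot of the scored span, a stimulus hit
is reproduced with probability `recall_fidelity` at the slot time plus
Gaussian jitter (SD ~30 ms at average ability, small against the 100-ms
window); rest slots spawn false taps at a low rate. Memory-mode emission
is confined to the silent fourth cycle. The expected score has the closed
form $100\,(f h + (1-q)(n-h))/n$ for $h$ hits among $n$ slots, which the
tests verify by Monte Carlo.

**Latent-to-parameter maps** are logistic/exponential squashings, so every
ability value yields valid parameters: $\sigma_T = 12.5\,e^{-0.35 z}$ ms,
$\sigma_M = 6\,e^{-0.2 z}$ ms, $\alpha \in (0.5, 0.95)$ increasing in
ability, $\gamma \in (0, 0.22)$, mean asynchrony −25 ms (the usual
negative anticipation), fidelities `plogis(1.3 + 0.9z)` (drum-along) and
`plogis(0.5 + 0.9z)` (memory, the harder task). These constants were
calibrated once so the cohort marginals are plausible for young
non-musician adults — median normalized variability ≈ 0.044, drum-along
scores mostly 60–95% — and then frozen.

**What the simulator does not emulate.** Missed or doubled taps in the
beat tests; metricality-dependent memory difficulty (strong and weak
sequences are equally hard, whereas real participants find syncopated
patterns harder); learning across repetitions; session-level drift or
fatigue; hardware latency. Simulated tempo-adaptation errors (median
≈ 16 ms, range ≈ 10–28) run somewhat below what published example
subjects suggest (low 20s to high 30s): once phase correction is
effective, steady-state interval noise dominates the last-two-interval
error, and the model has no extra post-shift disruption mechanism. A
passing recovery experiment therefore shows that *the pipeline detects
the structure its inputs contain* — it does not certify that real cohorts
have that structure, nor that real score distributions match these
marginals.

**Determinism.** All randomness flows from one master seed; each
participant gets a derived sub-seed (`(seed·1000003 + i·7919) mod
2^31−19`), so any individual is reproducible in isolation and a cohort
prefix is stable as the cohort grows.

## Statistical pipeline

1. **Exclusions** (applied once, not recursively): participants more than
   3 SD from the mean on any rhythm measure, and participants whose mean
   produced metronome tempo deviates from the stimulus IOI by more than
   5 ms (a participant drumming at their own tempo is not measuring
   synchronization). Both thresholds are the battery's operational
   readings of informally stated rules.
2. **Normality and transforms.** Jarque–Bera,
   $JB = \tfrac{n}{6}(S^2 + \tfrac{(K-3)^2}{4})$ against $\chi^2_2$,
   implemented from the moment definition (no installed package provides
   it) and cross-checked against an external oracle value. Variability is
   log-transformed and the drum-along proportion rau-transformed; the
   rationalized arcsine unit is used in its proportion form
   $R = \tfrac{146}{\pi} \cdot 2\arcsin\sqrt{p} - 23$ (−23 at 0, 50 at
   0.5, 123 at 1). The transform step refuses to run twice.
3. **Correlations.** Pearson r with two-sided p from
   $t = r\sqrt{(n-2)/(1-r^2)}$, complete cases, no multiple-comparison
   correction (two planned within-cluster tests and four null predictions).
4. **Factor analysis.** Generalized least squares: minimize
   $F(\Lambda,\Psi) = \tfrac12\,\mathrm{tr}[(I - S^{-1}\Sigma)^2]$,
   $\Sigma = \Lambda\Lambda' + \Psi$. For fixed uniquenesses the optimal
   loadings are the top-m eigenpairs of $S^{-1/2}(S-\Psi)S^{-1/2}$, so
   only $\Psi$ is optimized (L-BFGS-B from 1 − squared multiple
   correlations, floor 0.005; a solution on the floor is flagged as a
   Heywood case). Loadings are varimax-rotated (tight convergence,
   `eps = 1e-10`), columns ordered by explained variance, signs set so
   each factor's largest loading is positive. The factor count is fixed
   at two — the hypothesis under test — with the correlation-matrix
   eigenvalues reported as a scree diagnostic rather than used for
   selection. Note that with four measures a two-factor model is not
   identified in the degrees-of-freedom sense (df = −1); the varimax
   pattern is still well-defined and is what the analysis interprets,
   which is why the package's exact-recovery tests use six measures and
   the four-measure case is checked at the pattern level. Whether to
   factor raw or transformed scores is not fixed by the protocol; the
   default is transformed, switchable.
5. **Hierarchical regressions** (when verbal scores are present): rhythm
   memory on the two verbal tests, then adding drum-along; and backwards
   digit span on the two rhythm-memory tests, then adding auditory
   working memory. ΔR² is tested with the partial F test,
   $F = (\Delta R^2/q)\,/\,((1-R^2_{full})/(n-k_{full}-1))$.

## Numerical choices and degenerate inputs

Strict `>` at the amplitude threshold; half-open grid windows (no double
counting, ties go late); sample-precision onset times; empty signals give
empty onset lists while non-finite samples are data errors; constant
vectors are moment errors for Jarque–Bera; zero-variance columns are
correlation errors; collinear predictor blocks are rank errors; cohorts
under ten participants analyze but carry an `underpowered` flag, and the
Jarque–Bera step is skipped below n = 8 where its moments are
meaningless.

## Problem sizes

The bundled experiments are sized for a desk machine: the recovery
experiment uses the design cohort size (n = 65) plus one large-cohort
check (n = 1000, full battery, ~30 s), the stationary-variance check uses
10⁵ taps, and the onset-marking oracle equivalence uses 200 random short
signals. All are fixed-seed.

## Known limitations

Binary grid scoring discards within-window timing of sequence taps; the
battery averages strong and weak metricality rather than modelling them;
the GLS fit assumes an interpretable two-factor structure rather than
selecting the factor count from data; and the simulator's score marginals
are calibrated to sparse published anchors, not to a deposited cohort, so
absolute score levels should not be compared against it — only structural
patterns.
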