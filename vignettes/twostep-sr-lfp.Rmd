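---
title: "Model-based valuation and hippocampal LFP analysis in a two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based valuation and hippocampal LFP analysis in a two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(twostepSR)
```

## The scientific problem

In the two-step probabilistic decision task, an animal first chooses between
two options (`S1+`, `S1-`); the choice leads probabilistically to one of two
second-step states (`S2+`, `S2-`), each with its own reward probability. With
the canonical contingencies — 80/20 transitions and 80/20 rewards — the
expected reward of the high-value option is `0.8*0.8 + 0.2*0.2 = 0.68` and
the value of the high-reward state is `0.8`. Because the long-run value of a
choice is only computable by combining the transition structure with the
reward structure, above-chance preference for `S1+` is evidence of
model-based valuation rather than cached stimulus-response values.

`twostepSR` implements, in one tested pipeline:

1. a successor-representation (SR) learner of the task, with softmax choice;
2. static and windowed maximum a posteriori (MAP) estimation of its
   discount/forgetting parameter `gamma` and inverse temperature `beta` from
   choice sequences;
3. a synthetic 16-channel LFP generator with known ground truth, emulating
   the statistical structure that hippocampal recordings in this task are
   reported to carry;
4. the matching neural analysis chain: preprocessing, Morlet time-frequency
   power, representational similarity of the two temporal context states,
   power-value regression, and choice decoding.

No real recordings ship with the package; every neural claim a test makes is
a planted-effect recovery on synthetic data.

## The behavioural model

The SR learner maintains a transition matrix `T` (discounted expected visit
frequencies of each second-step state from each option) and a reward vector
`R` (discounted expected immediate reward per state). With the task's
one-step horizon, option values are `Q_S1 = T %*% R` and state values
`Q_S2 = R`. Choices follow a softmax with inverse temperature `beta`
(`beta = 0` is random responding; large `beta` is greedy).

The definitions of `T` and `R` are expectations; they do not by themselves
prescribe a trial-by-trial estimator. The package uses the simplest
estimator consistent with a "discount or forgetting" parameter: an
exponentially-weighted delta rule with fixed step sizes
`alpha_T = alpha_R = 0.1` (configurable), whose update target is scaled by
`gamma` — the chosen option's row of `T` moves toward `gamma` at the
observed state and toward 0 at the unobserved one, and `R` moves toward
`gamma * I(reward)` at the visited state. At `gamma = 1` in a stationary
environment these estimates converge to the true contingencies, so the
asymptotic values reproduce 0.68 and 0.8 exactly. The unchosen option's row
is left untouched (no counterfactual decay) — the minimal assumption.
`gamma` scales both update targets, so option values carry `gamma` through
both `T` and `R`; all asymptotic checks use `gamma = 1`, where the
distinction from a single-`gamma` parameterisation vanishes.

Initialisation is uninformative and consistently scaled: `T` rows and `R`
start at `0.5 * gamma`.

```{r}
st <- sr_state(T = matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE),
               R = c(0.8, 0.2), gamma = 1)
st$q_s1   # 0.68, 0.32
st$q_s2   # 0.80, 0.20
```

## Fitting

`fit_map()` maximises the posterior of `(gamma, beta)` given a choice
sequence, replaying the learner deterministically over the observed
transitions and rewards. Priors are weakly informative:
`beta ~ Gamma(shape = 1.2, scale = 5)` (shape/scale parameterisation, prior
mean 6 — chosen to be flat over the `beta` range that fitted learning
courses span) and `gamma ~ Beta(1.1, 1.1)`. Optimisation is bounded
L-BFGS-B (`gamma` in `[1e-6, 1-1e-6]`, `beta` in `[1e-6, 50]`) with five
jittered restarts and an objective tolerance driven down to ~1e-8 of
machine scale; the likelihood replay itself is compiled code, so a
3,000-trial dynamic fit takes seconds.

`fit_dynamic()` splits the learning course into `n_windows` contiguous,
disjoint blocks (default 12 — five sessions per window over a 60-session
course; the window count is a free design choice, exposed in
`fit_config()`) and fits each block independently. The agent state at a
window's start is produced by replaying all earlier trials under the
candidate `gamma` being evaluated, which avoids discontinuities at window
edges at the cost of making each window's objective depend on the full
prefix — the replay is cheap, so this is the default rather than an option.
`alpha_T`/`alpha_R` are not fitted; only `(gamma, beta)` are.

`compare_dynamic_static()` simulates closed-loop agents from both fitted
parameterisations (50 rounds by default) and overlays session-wise `S1+`
choice-rate trajectories: nonstationary behaviour is tracked by the
windowed fit and not by the static one.

Parameter recovery, measured in the test suite at 1,000 trials over 20
seeds, is within ±0.1 of a generating `gamma = 0.9` and within 30% of a
generating `beta = 5` (medians); windowed fits of a schedule rising from
`(0.2, 1)` to `(0.95, 8)` recover the trajectories with median Spearman
correlation above 0.8.

## The synthetic LFP generator

`generate_recording()` builds a continuous 16-channel, 2000 Hz recording
whose event-locked structure mirrors a behavioural trial table:

* **1/f background** per channel (band-limited at 250 Hz, emulating the
  acquisition low-pass), plus a broadband **common-mode** component shared
  across channels and **50 Hz line noise** with random phase per channel;
* **high-band bursts** (20 and 45 Hz carriers under a 1 s Hann envelope)
  in the second before each peck, with amplitude `a0 + a1 * Q` — `Q` being
  the model-based value of the chosen option (step 1) or observed state
  (step 2). Carrier phases and channel loadings are drawn independently per
  window: a phase-coherent burst would be a pure common mode and would
  (correctly) be removed by the common average reference, and a fixed
  spatial loading would plant a permanently shared high-band pattern that
  the cross-state similarity analysis is explicitly supposed *not* to find;
* a **6 Hz component** in the two temporal-context windows around the
  step-1 peck (`[-1, 0]` and `[0, 1]` s) whose spatial amplitude pattern
  across the 16 channels is redrawn per window — except on
  common-transition trials after the learning boundary, where the S2-window
  pattern repeats the S1-window pattern. This is the planted "relational"
  effect that representational similarity is meant to find. It is anchored
  to the context windows rather than to the pecks because it models the
  state representation, not motor preparation. Phases are again
  per-channel random; only the amplitude pattern is shared;
* **20 ms biphasic peck artifacts** at every peck.

The learning boundary defaults to the first trial of the first session whose
`S1+` choice rate exceeds 90%, mirroring the late-stage criterion used in
the stage contrasts. All amplitudes are in the generator config
(`synth_config()`), in microvolts: background SD 20, common mode SD 15,
line 15, burst coupling `a0 = 2`, `a1 = 12`, low-band amplitude 25,
artifacts 200. The low-band amplitude is deliberately the largest planted
effect: a spatial pattern must survive single-epoch spectral-power
estimation noise to be recoverable per trial, and 100 ms epochs at 6 Hz
carry little averaging. These sizes were chosen once so that each
downstream detection passes with margin at a few hundred trials, and are
exposed for power analyses.

What the generator does **not** emulate: biophysical volume conduction,
electrode drift, spikes, non-stationary line noise, behaviourally
correlated motion artifacts. Passing tests therefore show that the analysis
chain recovers the effects it targets from realistic noise — not that real
pigeon hippocampus behaves this way.

Step-1 reaction times are uniform on [0.5, 2.0] s, so every synthetic trial
clears the 0.5 s reaction-time exclusion unless deliberately flagged.
Step-2 reaction times are uniform on [1.2, 1.6] s, which places the step-2
peck — and the value-coupled burst preceding it — after the fixed `[0, 1]` s
similarity span. The separation is deliberate: the value-regression and
decoding stages read the burst in per-trial pre-peck windows, while the
similarity stage must not be handed a high-band amplitude signal inside its
span. The two temporal context states are still both represented there,
by the 6 Hz component. If the step-2 burst is instead pushed into the
similarity span (shorter step-2 reaction times), its amplitude — which is
larger on common transitions because `Q(S2+) > Q(S2-)` — leaks into the
cosine maps as a global offset and produces a high-band common-vs-uncommon
cluster; the default geometry keeps that confound out of the map.

Recordings are held in memory as an `lfp_recording` (channels x samples
matrix, sampling rate, event table) and serialised with
`write_recording()` / `read_recording()` to a flat binary-plus-JSON
directory layout with a bit-exact round trip.

## Preprocessing

`median_downsample()` reduces 2000 Hz to 1000 Hz by block medians (robust
to impulsive artifacts; at factor 2 the block median equals the block
mean). `adaptive_car()` removes correlated noise: within contiguous 1 s
blocks, each channel's weight is its correlation with the plain common
average (clipped at zero, renormalised to mean 1) and `weight * average`
is subtracted. Blocks rather than a per-sample sliding window: the common
mode the stage removes is block-stationary, and per-sample weights would
cost an order of magnitude more for no measurable gain; `adaptive = FALSE`
falls back to the standard CAR. `lms_notch_50hz()` is a two-weight LMS
canceller with a sine/cosine reference pair at 50 Hz — narrow-band by
construction (about 1.6 Hz equivalent bandwidth at the default step
`mu = 0.005`), converging within ~0.2 s, and leaving 45/55 Hz intact.

`qc_filter()` drops trials with step-1 reaction times strictly below
0.5 s (exactly 0.5 s is retained) and trials carrying a motion-artifact
flag, logging every exclusion. `epoch_lfp()` extracts windows relative to
the **step-1 peck** (the alignment event for everything downstream):
baseline `[-2.5, -2.0]`, choice `[-1, 0]`, S2 `[0, 1]` seconds, as
half-open sample spans; trials whose windows leave the recording are
excluded with a logged reason.

## Time-frequency analysis

`morlet_power()` computes Morlet wavelet power on 50 logarithmically spaced
frequencies over 1-100 Hz, with a fixed width of 7 cycles at every
frequency — the standard trade-off, stable down to 1 Hz given reflection
padding to the wavelet support (epochs shorter than the support are flagged).
To avoid edge effects at window seams, the transform runs on a single
concatenated `[-2.5, +1.5]` s epoch per trial and the analysis windows are
sliced from it. Power envelopes are smooth, so the stored time axis is
decimated (10 ms steps in the pipeline) to bound memory.

Samples within ±50 ms of any peck are masked (`mask_peck_artifacts()`) and
excluded from every downstream average — never zero-filled.
`baseline_normalize()` divides each trial's power by that trial's mean
baseline power over **all electrodes** and baseline samples, per frequency:
one divisor per trial and frequency, which removes per-trial global drifts
(the stated motivation for trial-wise baselines) and makes the result
invariant to rescaling the whole recording. `band_average()` reduces the
normalised power to the six canonical bands (delta 1-4, theta 4-8, alpha
8-12, beta 12-30, low gamma 30-60, high gamma 60-100 Hz) and to the low
(1-12 Hz) and high (12-100 Hz) aggregate groups, over either a fixed
window or per-trial pre-peck windows.

## Representational similarity

`build_epochs()` tiles 100 ms epochs every 20 ms (80% overlap) across the
`[-1, 1]` s span around the step-1 peck — 46 epochs wholly inside each 1 s
window; epochs straddling the peck are dropped. Epoch-mean power is
z-scored per frequency and per trial across that trial's whole epoch
population, **pooled over electrodes** — one mean and SD per (frequency,
trial). The pooling matters: z-scoring each electrode separately would
normalise every channel's epoch time course to the same shape and erase
exactly the spatial power patterns the similarity analysis is built to
detect. A zero-variance guard maps SD below 1e-12 to z = 0. The z-values
are then averaged into the six bands, giving a
`K = 16 electrodes x 6 bands` feature vector per epoch (or the 3-band low/
high subsets for band-restricted similarity).

`cosine_map()` gives the S1-epoch x S2-epoch matrix of cosine similarities
per trial; masked feature dimensions are dropped pairwise and zero-norm
vectors yield missing cells. `cluster_contrast()` compares two trial
groups: cell-wise pooled two-sample t statistics, two-sided cell threshold
p < 0.05, 4-connected clusters formed separately for positive and negative
signs and scored by mass (sum of |t|), and a permutation null (default
1000 relabellings) for the maximum cluster mass, giving family-wise
corrected cluster p-values. The correction procedure itself is a design
choice — only the corrected-significance convention is fixed — and the
permutation approach is the field standard for exactly this map geometry.
Its false-positive rate is checked by simulation in the test suite (at most
7% empirical at nominal 5% over 200 null repetitions). Stage selection
(`select_stage_trials()`) defines early = first 100 valid trials from
sessions below 65% `S1+` choice rate and late = last 100 from sessions
above 90%, disjoint by construction.

The peck-artifact handling on maps follows the same ±50 ms masking rule as
the spectral stage (epochs built from masked power inherit the missingness);
wider exclusion bands can be passed to `cluster_contrast()` via `exclude`.

## Linking power to valuation

`session_value_regression()` fits `y = b0 + b1 * x` per condition and band
group, with `y` the session-mean normalised power in the 0.5 s before the
relevant peck and `x` the session-mean model-derived value from the
windowed fit (`replay_values()`), reporting R², the ANOVA F(1, n-2) and its
p-value. No multiple-testing correction is applied across the condition x
band table (none is conventional for this layout, and the table is
descriptive). `decode_choice()` classifies the step-1 choice from
electrode x band features with a linear maximum-margin classifier
(regularisation constant 1), using repeated stratified 70/30 splits —
10 rounds, continued until every trial has been tested at least once —
with feature standardisation fit on each training split only. The repeated
70/30 scheme honours both halves of the stated protocol (a 70/30 split
*and* repetition until all data are used); per-round accuracies are
averaged. Inside `run_pipeline()`, decoding is restricted to the second
half of the learning course — the planted amplitudes separate the options
only once their values have been learned — and classes are balanced by
subsampling the majority choice, so chance level is 0.5 and accuracy is
not inflated by the extreme late-stage choice imbalance of a converged
learner. `stat_tests()` gates every two-sample comparison through a
Lilliefors normality test at 5% (t test when normal, Wilcoxon otherwise;
below n = 5 the gate cannot run and the rank branch is taken).

## The end-to-end pipeline and its four signatures

`run_pipeline()` chains everything and writes per-stage artifacts plus a
manifest of md5 hashes; a run is bit-reproducible from (config, root seed),
with per-stage streams derived from the root seed. The summary marks four
qualitative signatures, each of which is a planted effect:

1. high-band normalised power increases from the early to the late learning
   stage for the `S1+` and `S2+` conditions;
2. high-band `S2+` power regresses significantly and positively on the
   fitted state value;
3. high-band choice decoding exceeds low-band decoding by at least 0.1;
4. the low-band common-vs-uncommon late-stage similarity contrast has a
   significant cluster, and the high-band contrast has none.

```{r}
cfg <- run_config(seed = 11)
summary <- run_pipeline(cfg, "run-out")
summary$signatures
```

## Problem sizes and numerical choices

The package's own test suite exercises the pipeline at sizes chosen to make
each statistical check well-powered while keeping the whole suite
desk-scale: behavioural checks at the study layout (60 sessions x 50
trials, simulated in full); parameter recovery at 1,000 trials x 20 seeds;
dynamic-fit tracking at 3,000 trials x 20 seeds; the null calibration of
the cluster test at 200 repetitions of 20-vs-20 maps; and the end-to-end
signature run at 24 sessions x 25 trials (600 trials) of synthetic LFP
with a learning schedule rising from `(gamma, beta) = (0.3, 0.3)` to
`(0.98, 10)`. The converged tail of that schedule uses `beta = 10` so that
short 25-trial sessions reliably clear the strict >90% late-stage
criterion; at the study's 50-trial sessions the criterion is forgiving and
`beta = 8` suffices.

Numerical conventions, in one place: sample windows are half-open
`[start, end)`; times are seconds relative to the step-1 peck; softmax and
log-likelihoods use max-subtraction; degenerate comparisons (identical
paired samples) report a null t result rather than erroring; masked values
propagate as missing and are excluded from means; cosine similarity needs
at least 4 commonly observed feature dimensions per cell; cluster p-values
use the `(1 + #{null >= obs}) / (n_perm + 1)` convention.

## Known limitations

* The generator's effects are additive narrow-band bursts; real LFP
  value-coding is unlikely to be linear in amplitude or confined to two
  carriers. Effect sizes are settings, not findings.
* The dynamic fit assumes piecewise-constant parameters on a fixed grid of
  windows; a smoothly drifting generator is recovered only up to that
  resolution.
* The similarity analysis detects shared spatial *amplitude* patterns;
  phase-coded structure would need coherence measures, which are out of
  scope.
* Statistical utilities report the tests named above; no hierarchical
  (across-subject) modelling is provided.
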