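---
title: "Methods: respiration-derived fMRI confounds, tracking accuracy, and power simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiration-derived fMRI confounds, tracking accuracy, and power simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respitrack)
```

# The problem

Attending to the breath changes the breath. In interoceptive-attention fMRI
paradigms, participants either watch a pulsing circle (exteroception) or
attend to their own respiratory cycle (interoception), passively or while
reporting each inhalation/exhalation with button presses; a fifth condition
paces breathing to the circle. Because breathing rate and depth modulate
arterial CO~2~ and hence the BOLD signal globally, any task that shifts
respiration can masquerade as neural activation. Analyses of such tasks
therefore need, for every scanner run:

1. **per-volume nuisance regressors** — breathing frequency and respiratory
   volume per time (RVT) sampled on the volume grid;
2. **per-trial covariates** — trial-averaged frequency and RVT for
   group-level models;
3. **a behavioral manipulation check** — how accurately each button-press
   stream tracked its target (breath or circle), in milliseconds;
4. **condition-level inference** — mixed-effects comparisons of frequency,
   RVT and tracking error across the five conditions.

This package implements that pipeline, a synthetic-session generator with
exact ground truth to validate it, and the simulation-based power analysis
used to size such studies.

# Respiration signal processing

## Preprocessing

Belt traces (arbitrary units, 500 Hz) are smoothed with a 1 s zero-phase
low-pass window and mean-corrected (`smooth_and_center()`), then z-scored
per run (`zscore()`). The smoother is a moving average run forward and then
backward, so its net phase response is zero and breath peak times are not
displaced; the 1 s width passes the physiological band (0.05–1 Hz)
essentially intact while suppressing cardiac and pump ripple. At the run
edges the signal is continued by antisymmetric reflection (slope-preserving)
before filtering: plain truncation or symmetric reflection visibly flattens
the first and last breath, which costs correlation with the true signal and
displaces edge extrema. Z-scoring is per run, not per trial, so that RVT
values are comparable across a run's trials.

## Peaks, troughs, and RVT

`detect_extrema()` finds local maxima and minima under two constraints: a
*vertical* prominence rule — adjacent peak–trough pairs must differ by at
least 0.5 SD (z-units), which rejects ripples riding on a breath — and a
*temporal* rule — consecutive same-type extrema must be at least 2 s apart.
After pruning, strict peak/trough alternation is enforced (keeping the most
extreme member of any same-type run); alternation is not guaranteed by
independent peak and trough detection but is required for a well-defined
envelope. A second preset (no prominence threshold, 1 s minimum separation)
is used for behavior scoring, where individual breaths shorter than 1 s are
not expected.

`compute_rvt()` linearly interpolates peak values at peak times (upper
envelope) and trough values at trough times (lower envelope); RVT is the
per-sample difference upper − lower, held at the nearest envelope value
before the first and after the last extremum. For a unit sinusoid the
z-scored amplitude is √2 and interior RVT is 2√2 ≈ 2.83, the anchor used in
the recovery tests.

## Frequency estimation

`estimate_frequency_trial()` returns the argmax of the zero-padded FFT
periodogram within 0.05–1 Hz; zero-padding guarantees a spectral grid of at
most 0.005 Hz regardless of segment length. The band floor prevents DC or
slow-drift captures; out-of-band winners are clipped with a warning. A
low-confidence flag is raised when the power within one natural resolution
width (1/T Hz) of the peak is less than half of the in-band power, which is
the typical signature of a noise-dominated segment.

`estimate_frequency_sliding()` applies the same estimator in a 10 s window
centred on each fMRI volume onset (TR 2 s by default), yielding one value
per volume. **Edge handling:** near the run boundaries the window slides
inward so it always covers a full 10 s of recorded data, rather than being
truncated. A window truncated to one or two breathing cycles has a
phase-dependent spectral argmax that can be off by several hundredths of a
hertz — worse than any value it would be replacing — whereas the inward
shift uses only real data and keeps every per-volume estimate within
±0.01 Hz on stationary test signals. No value is imputed.

# Stimulus and behavior waveforms

Three periodic series share a 500 Hz grid. The **keypress waveform** codes
button 1 (inhalation / expansion onset) as −1 and button 2 (exhalation /
contraction onset) as +1 and interpolates linearly between anchors; beyond
the first and last anchor the waveform is clamped to avoid manufacturing
inflections where no behavior exists. The **circle waveform** rises linearly
from −1 to +1 over half the participant's respiratory period, holds for
0.2 × the half-period, falls back at the same rate, and holds again — a full
cycle of 1.2 × the period. It starts at −1 so that a perfect tracker's first
button-1 press coincides with the trial onset; since tracking accuracy is
computed after phase correction, the choice of start phase is immaterial to
the scores. A `pauses = FALSE` switch drops the holds (cycle = period
exactly) for analyses that need a hold-free pacing stimulus; the package
takes no position on which variant a given display implementation used.

# Tracking accuracy

`phase_align()` finds the integer-sample lag (±500 samples = ±1 s) that
maximizes the Pearson correlation between the overlapping parts of stimulus
and keypress waveforms, re-normalized at every candidate lag; ties break
toward the smallest |lag|. A positive lag means the keypresses trail the
stimulus, as expected from sensorimotor transduction delays.

One numerical choice matters here: the correlation uses only samples inside
the keypress waveform's *anchored span* (first to last press). The clamped
constant extrapolation outside that span contains no behavior, and feeding
it into the correlation biases the recovered lag by +14 to +48 ms depending
on how many fractional stimulus cycles fall in the trial; restricted to the
span, injected lags on noiseless fixtures are recovered exactly, and the
cohort-mean tracking error calibrates to the folded-normal value σ√(2/π)
implied by Gaussian keypress jitter σ.

`tracking_error()` then measures, for each stimulus inflection (detected
extrema for the breath target, the analytic expansion/contraction schedule
for the circle), the time to the nearest keypress of either button, and
reports the trial mean in milliseconds. Inflections with no nearby keypress
still contribute their distance to the nearest available press — there is no
cap — and trials with no presses at all are flagged unscorable rather than
dropped. `score_session()` books one row per active trial per applicable
target: breath for Active Interoception, circle for Active Exteroception,
and *both* for Active Matching, where keypresses must align with the circle
and the breath simultaneously.

Note that with the holds included, the circle waveform is a trapezoid while
the keypress waveform is a triangle; their best-correlation alignment then
carries a shape-induced offset of roughly 0.05 cycle that inflates absolute
circle-tracking error. This is a structural property of the waveform-NCC
method (plausibly present in any dataset analysed this way), which is why
the calibration tests use the hold-free configuration where the two shapes
match.

# The synthetic world

`generate_respiration()` models the belt signal as a(t)·sin φ(t) + white
noise. The phase integrates a piecewise-constant instantaneous frequency
that random-walks from breath to breath (SD 0.005 Hz per breath) around a
base rate of 0.21 Hz — the adult resting average — plus per-condition
offsets: −0.022 Hz for active interoception, −0.013 Hz for passive
interoception, ≈0 for the circle conditions. The envelope amplitude
random-walks similarly (SD 0.02 a.u.) with condition offsets ordered
exteroception < passive interoception < matching < active interoception,
mirroring the depth ordering such tasks produce, and is interpolated across
breath midpoints: a hard per-breath amplitude step would shift the smoothed
signal's extrema away from the phase extrema, which no real chest wall does.
An optional coupling scales amplitude by (base/f)^γ to emulate the negative
within-participant rate–depth trade-off (off by default at the signal level;
the block-level simulator couples residuals directly with correlation −0.45).

`generate_session()` lays out 4 blocks per condition of 30 s each (both
configurable; the block count follows the factorial bookkeeping of a
22-participant × 2-session × 5-condition design with 880 condition-block
rows, and 30 s is a typical fMRI block length), separated by 5 s fixation
gaps so that lagged keypresses cannot spill across block boundaries. The
circle period is set from a 60 s calibration recording, emulating the
practice of matching the stimulus to the participant's belt-measured resting
frequency. The behavioral agent presses with a constant 240 ms transduction
lag, Gaussian jitter (default SD 60 ms), and a 5% miss rate; in Active
Interoception it anchors to the true breath inflections, in the circle
conditions to the analytic schedule. During Active Matching the generator
both locks the breathing period to the circle cycle and forces a breath
trough at each block onset — participants synchronizing inhalation to the
expansion do exactly this — because a frequency lock alone leaves an
arbitrary breath–circle phase offset that can exceed the ±1 s alignment
search range.

What the generator does *not* emulate: cardiac or CO~2~ physiology, BOLD
signal, apnea/sigh events, non-sinusoidal flow shapes, display latency, or
learning effects across blocks. A green recovery test therefore establishes
that the estimators invert the stated generative model at realistic noise
levels — not that they are robust to every artifact a scanner belt can
produce.

The block-level companion `simulate_condition_summary()` draws per-block
outcomes directly (condition mean + participant intercept + residual) for
statistical validation at cohort scale, where simulating 500 Hz physiology
for hundreds of replicate cohorts would be pointless. Its default condition
means (frequency 0.188–0.212 Hz; RVT 2.43–3.42 z-units) and noise scales
(residual SDs 0.048 Hz and 0.54 z-units; participant SDs 0.05 Hz and 0.25)
were fixed once from the magnitudes such designs report — they yield
pairwise-contrast standard errors near 0.005 Hz and 0.057 z-units on the
880-row design — and are not tuned per test.

# Mixed-effects inference

`fit_condition_model()` fits outcome ~ condition + group × time +
(1 | participant) by REML with lme4, treating the trial group (intervention
vs control) and timepoint as nuisance factors. `emm_and_tukey()` computes
estimated marginal means — model predictions averaged over the nuisance
grid — and all 10 pairwise condition contrasts, with familywise adjustment
via the studentized-range distribution (`ptukey` at √2·|t|). Each contrast
estimate is exactly the difference of its two EMMs.

Degrees of freedom use the containment approximation
(N_obs − rank(X) − (N_participants − 1)), which equals the classical
within-subject ANOVA df on balanced designs (851 on the 880-row default).
Satterthwaite machinery is deliberately not reimplemented: at dfs in the
hundreds the difference is far below the resolution of any quantity this
model reports, and the validation criteria (CI coverage of injected effects,
type-I error of the condition test) hold under the containment choice.

`within_participant_correlation()` centers both outcomes on participant
means and correlates the pooled residuals — the rate–depth trade-off
statistic. The pooled estimator reports df = N_obs − 2; a `method = "rm"`
variant reports the repeated-measures df = N_obs − N_participants − 1
instead. Both are provided because the two conventions disagree in the
literature; the pooled form is the default. Confidence intervals use the
Fisher z transform.

# Power simulation

The sizing question: how many participants are needed so that up to 10
planned fMRI contrasts are *all* powered, with familywise power ≥ 0.90?

* `per_test_power(0.90, 10)` = 0.90^(1/10) = **0.9895** per test.
* `derive_alpha(4.53, 10)`: the conventional peak-voxel Z threshold 4.53 has
  one-tailed normal tail probability **2.95 × 10⁻⁶**, Bonferroni-corrected
  to **2.95 × 10⁻⁷** for 10 comparisons.
* `simulate_power()`: per-participant contrast values are drawn from
  Normal(5.87, 0.20 + 0.22) — the reference effect and both variance
  components perturb an individual's observed contrast — and tested against
  zero with a one-tailed one-sample t-test at the corrected alpha; power is
  the rejection fraction over ≥ 20,000 draws per candidate N.

The one-tailed convention is forced by the numbers themselves (the upper
normal tail at 4.53 reproduces 2.95 × 10⁻⁶; the two-tailed value would be
twice that). Because the original simulation's exact test statistic lives
only in an external script, every Monte-Carlo estimate is cross-checked
against the noncentral-t closed form
power = P(T_{N−1,ncp} > t_{1−α,N−1}), ncp = 5.87 / √(0.42/N),
which places the power threshold at N = 9 analytically: power(8) ≈ 0.971 is
below the 0.9895 requirement and power(9) ≈ 0.9996 is above it. One caveat
of the extreme alpha: at N = 2 the t-test has df = 1 and a critical value
near 10⁶, so power is negligible there *regardless of effect size* —
claims that huge effects are powered "at any N" fail below N ≈ 5.

# Known limitations

* The respiration model is sinusoidal; flow-shape asymmetries (longer
  exhalation than inhalation) are not represented, so extrema detection is
  easier here than on real belts.
* RVT follows the peak–trough envelope-difference definition; it is not
  divided by breath period, and alternative RVT conventions will differ by
  a rate-dependent factor.
* The containment df is exact only for balanced designs; heavily unbalanced
  data would warrant proper Satterthwaite df.
* The NCC alignment search is ±1 s; behavior lagging by more than a second
  (or anti-phase tracking) aliases to the wrong lag, and such trials should
  be screened by their low maximal correlation.
* Imaging-side confounds (motion, DVARS, FD) are accepted as pass-through
  columns only; nothing imaging-derived is computed here.
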