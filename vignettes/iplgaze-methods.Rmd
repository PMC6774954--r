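---
title: "Methods: gaze screening, looking metrics and inference for infant preferential looking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze screening, looking metrics and inference for infant preferential looking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The paradigm and what the package computes

In an infant preferential-looking (IPL) word-comprehension experiment, two
pictures appear side by side while a recorded voice names one object
("Look at the apple!"). If the infant knows the word, naming should pull gaze
toward the named picture. `iplgaze` implements the analysis chain from the raw
eye-tracker export to the inferential battery, and a synthetic cohort
generator so the chain can be validated end to end with known ground truth.

The design it models: two blocks (a *context* and a *frequency* condition),
each with 8 *matching* trials (the heard word names a displayed object) and 8
*related* trials (the heard word is contextually or frequency-related to a
displayed object but names neither), plus 4 single-object *control* trials —
36 trials per infant. Two counterbalancing lists mirror all object sides;
within each trial type every object appears once left and once right. Infants
are 184–274 days old. Each trial plays ~2 s of carrier before the target word
and ends 3.5 s after word onset (~5.5 s total).

# Gaze accounting

**Geometry.** The display is 1920 × 1080 px; looking is scored inside an
invisible 800 × 680 px rectangle around each object. Placement is not part of
the stimulus description, so the rectangles default to the centers of the two
half-screens, (480, 540) and (1440, 540), mirror-symmetric and separated by a
160 px midline gap; both are configurable. Rectangles are half-open,
`[x0, x1) × [y0, y1)`, pixels with origin top-left.

**Windows.** Relative to trial start: pre-naming `[0, onset)`; post-naming
`[onset + 367, onset + 3500]` (3133 ms, closed on the right as conventionally
printed); cluster-analysis window `[onset − 2000, end]`, tiled in 50 ms bins
anchored at word onset. The 367 ms lag is the earliest latency at which
language-driven eye movements are usually credited.

**Durations, not sample counts.** Each sample carries the interval to the next
sample (the last one the trial's median step), clipped to the window. This
makes every downstream quantity invariant to the sampling rate in the dense
limit (a property test compares 30 vs 120 Hz), which matters because the
generator runs below hardware rates. Whether the original analyses counted
samples or interpolated durations is generally unreported in this literature;
duration weighting is the choice here. Invalid samples contribute nothing —
in particular a trial with no valid samples has zero looking everywhere, not
50%.

# Screening

Trial-level rules, applied in a fixed order so each exclusion carries exactly
one primary reason: experimenter-flagged trials; trials with no valid on-AOI
looking in the pre-naming window (the strictest reading of "no looking
recorded"; a looser any-valid-sample rule is a config switch); trials with
under 0.5 s of summed target + distractor looking post-naming (summed, not
continuous dwell — the criterion is about *either image*); familiarity rules
from the parental questionnaire: a never-used **matching** word removes the
whole picture-pair (matching *and* related trials), a never-used **related**
word removes only the pair's two related trials.

Participants must contribute at least 6 of the 32 experimental trials. The 6
count is authoritative even though it is sometimes glossed as "20%"
(6/32 = 18.75%). A control-trial engagement check (minimum mean target
fixation) is available but off by default, since the generator's control gaze
is strongly target-locked by construction.

The control summary reports mean target fixation over the whole control
trial, the same as a proportion of trial duration, and each infant's
post-naming target proportion with a Wilcoxon test against a configurable
null. The null defaults to 0 — an engagement test against 0 is nearly
trivially significant whenever infants look at all, which is surfaced in the
documentation rather than silently replaced; 0.5 is the natural alternative.

# Dependent variables

**Pair difference score.** With `P = t_target/(t_target + t_distractor)` in
the post-naming window, the score for pair (A, B) is
`P₁ + P₂ − 1 ∈ [−1, 1]`, equal to the difference in the proportion of looks
at A between the trial naming A and the trial naming B, and symmetric in the
pair. Neither-looks are excluded from the denominator, matching the printed
formula. A pair contributes only when both of its trials survive screening.
If a word were presented more than once, presentations are pooled at the
looking-time level before the proportion is taken; with the standard design
each word is named exactly once per trial type, so this is a degenerate
average. Scores average over pairs for by-subject analyses and over subjects
for by-item analyses.

**Baseline-corrected looking**: `(P_t − P_d)_post − (P_t − P_d)_pre` per
trial, in [−2, 2], missing when either window has no AOI looking.

**Binned series.** Target proportion per 50 ms bin over the cluster window,
on an onset-aligned grid. Bins with no AOI looking are *missing*, not zero —
zero would read as distractor preference. Trial-level bins are averaged
within participant × condition × trial type, then arcsine-square-root
transformed (`asin(√p)`; 0.5 ↦ π/4).

# Cluster-based permutation test

Per bin, a one-sample t across participants against transformed chance
(π/4), or a paired t for matching vs related. Bins with |t| > 2 join into
clusters of contiguous, same-sign bins (a missing bin breaks contiguity —
the conservative choice); cluster mass is Σt. The null is built by flipping
whole participants with probability ½ (equivalently reflecting a
participant's series about chance, or swapping their condition labels) and
recording the **maximum |mass|** per permutation — the standard max-statistic
reading of "probability of observing a cluster of the same size", giving
family-wise control. p = (1 + #{null ≥ |mass|})/(1 + B), never exactly zero.
Flips act at the participant-mean level and masses are compared in absolute
value; both choices are exposed in the code because the originals of such
procedures often leave them unstated. For ≤ ~12 participants the full 2ⁿ
sign-flip enumeration is available (`exhaustive = TRUE`) and is tested against
an independent brute-force oracle at n = 4.

# Inferential battery

**Wilcoxon signed-rank** against chance, one-tailed *greater* by default (the
directional comprehension hypothesis; two-sided by flag). Exact p for n ≤ 25
without ties, else normal approximation with continuity correction; zero
differences are dropped (the standard convention — the original reports are
silent on zeros). Reported alongside: the sample mean with a t-based 95% CI
(mirroring symmetric printed intervals; bootstrap would also be defensible),
Cohen's d = |mean − μ₀|/SD, and a JZS Bayes factor.

**JZS Bayes factor.** Cauchy(0, √2⁄2) prior on the standardized effect,
computed from the one-sample t statistic by numerical integration over the
normal-mixture parameter g. Pairing a BF with a V statistic is a hybrid —
the BF is computed on the same values via the t-based route, which is what
reports of "V with BF₁₀" imply in practice; the tests validate the integral
against direct quadrature of the noncentral-t likelihood over the prior. For
correlations the JZS regression form with one predictor is used.

**Mixed-effects age model.** `log(score + 2) ~ trial_type * condition +
age_c + (1|infant) + (1|pair)`; the offset 2 keeps the log argument ≥ 1 for
scores in [−1, 1]; age is mean-centred in days. F tests use Satterthwaite
denominator df (fractional df in the reports imply exactly such an
approximation). The trial-type × age interaction and per-trial-type slopes
(subset refits) are available for the developmental question. Singular fits
are flagged, not hidden. In large Monte-Carlo loops the age-slope CI is the
Wald interval from the lme4 fit, for speed; the Satterthwaite path is the
default elsewhere.

**Median split** at 230 days (an infant aged exactly 230 joins the older
group), rerunning the by-subject Wilcoxon per age group × trial type (pooled
and per condition). **Frequency-imbalance correlation**: Pearson r between
per-pair mean matching scores and the pair's absolute child-directed-speech
frequency difference, one-sided, with the JZS correlation BF.
**Comprehension split**: condition × CDI-understood mixed model on
log-transformed baseline-corrected looking with per-cell two-sided Wilcoxon
tests; a degenerate comprehension factor is dropped with a warning.

**Design-stage numbers.** One-sample t power via the noncentral t
(ncp = d√n): d = 0.41 at n = 50 gives 0.811 two-sided at α = .05, the 0.80
design target. The packaged 32-word stimulus table (8 pairs, both
conditions, child-directed-speech frequencies) has a minimum within-pair
referent frequency ratio of 107/15 ≈ 7.13 in the frequency condition — the
≥ 7:1 design floor.

# The synthetic cohort generator

Gaze is modelled as alternating dwell bouts with exponential durations (mean
500 ms, a realistic infant fixation scale), not a full oculomotor model: the
pipeline consumes only AOI dwell, so richer kinematics would add nothing
testable. Each bout is off-AOI with probability 0.2; otherwise it is on the
target with probability 0.5 before the naming shift point (onset + 367 ms)
and 0.5 + δ after it, so the expected post-naming looking proportion is
0.5 + δ and a pair score has expectation 2δ. A per-infant constant side bias
is available (default 0) to exercise counterbalancing.

Defaults are the study conditions: ages uniform on 184–274 days; two lists;
sampling at 60 Hz — a desk-scale stand-in for 300 Hz hardware, legitimate
because all accounting is duration-weighted (Monte-Carlo replicate cohorts in
the tests run at 30 Hz for the same reason); trial dropout 0.15, per-sample
loss 0.10, fussiness hazard 0.01/s, ~1% experimenter flags — jointly
reproducing the ~25–30% experimental-trial loss such studies report.
Familiarity ratings are 0–5 with a 3% "never used" rate; CDI "understands"
flags are rare (15%) as expected at this age. Control trials use a higher
off-AOI share (0.63) and 0.9 target occupancy, chosen so the mean control
fixation lands at the reported engagement level (~1.4 s, ~25% of a 5.5 s
trial, post-naming target proportion ~0.9).

The default effect specification mirrors the developmental pattern the
paradigm is used to study: matching-trial δ = 0.028 at 229 days with a slope
of 0.0012/day (so ≈ 0 near 6–7 months and ≈ 0.05 — a score of ~0.11 — near
8–9 months), related trials at chance. `zero_effect_spec()` gives null
cohorts. A truth sidecar stores every injected quantity; analysis stages
consume only the three data files, and an interface test runs the pipeline
with the sidecar removed to prove it.

# Validation design and what it shows

The acceptance-style tests check: the two desk-scale design numbers; the
control arithmetic (1.36 s of 5.5 s ↦ 25% at whole-percent rounding); exact
equivalence of the Wilcoxon p with full 2ⁿ enumeration and of the
cluster-permutation null with exhaustive 2⁴ enumeration; type-I calibration —
over 500 null cohorts of 20 infants (250 permutations each), the vs-chance
Wilcoxon and the cluster family-wise rejection rates stay within ±2 binomial
SE of 5%; and recovery — a standardized matching effect of d ≈ 0.44 at
n = 23 (the older-age-group configuration) is detected by the one-tailed
Wilcoxon at a rate bracketing its analytic power (≈ 0.65; band 40–75%), and
an injected age slope is covered by the mixed model's 95% CI in ≥ 90% of 200
replicates. The d ≈ 0.44 condition is constructed at run time by measuring
the generator's null by-subject score SD (≈ 0.19 at n = 23 under default
missingness) and setting δ = 0.44 · SD/2.

Passing these shows the chain is internally correct and calibrated under the
generator's assumptions. It does **not** show robustness to features of real
infant data the generator omits: smooth pursuit and saccade dynamics,
calibration drift, binocular disagreement, autocorrelated fussiness,
non-exponential dwell, or item-specific salience. Those belong to the data,
not the analysis contract.

# Numerical and degenerate-input choices

Proportions with zero AOI time are missing, never 0 or 0.5. Wilcoxon with all
values at the null returns p = 1 with a degenerate flag instead of erroring.
The BF integral uses `integrate` on (0, ∞) with rel.tol 1e−9; a perfect
correlation returns BF = ∞ explicitly. Cluster p values use the add-one rule.
The permutation seed, the cohort seed and the pipeline seed are all explicit,
and identical configuration + seed reproduces byte-identical files (tested).
Problem sizes in the Monte-Carlo tests (20–23 infants, 30 Hz, 250
permutations, 200–500 replicates) are the package's chosen desk-scale
conditions; all are configurable upward.

# Known limitations

Binocular merging is out of scope (one gaze point per timestamp); no
fixation-event detection (dwell is used directly); no growth-curve modelling
of the time course; the trial sheet's word-onset anchoring for shared-onset
pairs (disambiguation-point timing) is metadata responsibility, not
computed from audio.
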