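---
title: "Methods: selectivity, encoding, and population analyses for odor-guided go/no-go electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selectivity, encoding, and population analyses for odor-guided go/no-go electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`odorgng` implements a complete analysis chain for event-aligned spike data
recorded during an odor-guided go/no-go task: a go-cue odor instructs
movement to a water port (with a 300 ms nose-poke wait before reward), a
no-go cue instructs withholding, and odorless catch trials occur once in
ten. This vignette is the package's account of its models, conventions, and
the choices made where the design was genuinely open. Every empirical claim
below is computed by the test suite or the analysis drivers; nothing is
asserted that the code does not check.

## Data model

A session is a trial table plus per-neuron spike-time vectors on one clock
in seconds. Event times are `odor_on` (valve opening = odor-port entry),
`odor_off` (`odor_on` + 0.5 s), `port_exit`, and, when the animal performs
the go behavior, `water_port_entry` and `water_valve_open`
(`water_port_entry` + 0.3 s, go-correct trials only). Absent events are
`NA`, never sentinel times: a go-error trial simply has no water events, and
any operation that needs them filters first. Behavioral accuracy is the
fraction of correct go/no-go trials; catch trials are unrewarded regardless
of choice and excluded.

All behavioral epochs are defined once, in `task_epoch()`, and every stage
obtains window bounds from there — this is the single point at which
millisecond conventions become seconds, which prevents unit drift:

* `baseline_iti`: 200–0 ms before the end of the inter-trial interval
  (= odor-port entry). This is the reference epoch of all vs-baseline
  contrasts.
* `pre_odor_baseline`: 1200–1000 ms before odor-port entry; the reference
  window for the population-distance threshold.
* `nose_poking` / `late_nose_poking`: odor-port entry to exit; the late
  phase starts at valve closure (0.5 s).
* `waiting`: water-port entry to valve opening (0.3 s).
* `drinking`: valve opening to +1000 ms. The task gives no behavioral event
  for the end of drinking, so the analysis bound doubles as the epoch end.

Alignment windows are half-open `[start, end)` so a spike on a shared
boundary is counted exactly once. Every analyzed condition requires at
least five trials; failure produces a typed refusal object that downstream
stages treat as "neuron excluded", not an error.

## Synthetic sessions and what they do (and do not) emulate

The generator is first-class, tested code: it defines the conditions under
which every downstream property is demonstrated. Trial timing follows the
task (500 ms odor, 3 s inter-trial interval, 2 s response window, 300 ms
pre-reward wait, catch every 10th trial). Nose-poke durations are drawn
from a log-normal matched to the reported task statistics — median 927 ms (IQR
745–1123) for go trials, 758 ms (660–910) for no-go — truncated below at
the odor duration, since the animal must hold through odor presentation.
The log-normal was chosen for positive support and the right skew typical
of reaction times; its two parameters are pinned exactly by the median and
IQR. Outcomes are Bernoulli at the configured accuracy (default 0.85;
trained animals hold above 80%). Travel time from odor port to water port
is gamma-distributed with mean 0.4 s (a conventional value; the task only
bounds it by the 2 s response window).

Four archetypes cover the response taxonomy the analyses target, with
piecewise-linear rate profiles (linear knots make thinning ceilings exact
and expected counts analytic):

* `go_cue_late` — baseline except a plateau from 500 ms after odor onset to
  the odor-port exit, on go trials only.
* `waiting_phasic` — a partial go-cue plateau in the late nose-poking phase
  plus a transient bump after water-port entry that decays before the valve
  opens (these neurons prefer the go cue *and* signal reward anticipation).
* `drinking_ramp` — a ramp beginning 0.2 s before valve opening, sustained
  0.4 s into drinking, with firing suppressed below baseline during the
  rest of the trial. The suppression releases just before the ramp so the
  rate is already above baseline at the ramp onset.
* `untuned` — constant baseline; the null model for every calibration test.

Baseline rates default to 3–5 Hz and peaks to 20–25 Hz. These are
conventions in the range typical of cortical recordings, not reproductions
of any dataset (baseline rates are rarely reported for this preparation);
they are configurable parameters, and no test depends on their exact
values beyond signal-to-noise adequacy.

Spikes are an inhomogeneous Poisson process sampled by thinning against an
exact ceiling. What the generator does **not** emulate: non-Poisson
variability (bursting, refractoriness), rate drift within a session (except
where a test constructs it deliberately), correlated noise across neurons,
and sorting artifacts. Consequently, passing recovery tests demonstrates
that the *estimators* are correct and calibrated under the stated
conditions — not that real recordings satisfy those conditions.

## Rates

Peri-event time histograms use 20 ms bins; display and regression responses
are smoothed with a Gaussian kernel. A "60 ms wide
Gaussian filter" is ambiguous between SD and full width; we take SD = 60 ms
(the common usage in this literature) with an FWHM interpretation available
by flag — no classification depends on smoothing, which is confined to
display and the encoding-model response. At window edges the kernel is
truncated and renormalized per source bin, so the total spike count in the
window is conserved exactly and rates show no artificial dips near epoch
boundaries. Sliding windows are 100 ms wide with a 20 ms step; timestamps
are window centers, so the "0 ms" bin is the window centered on the
alignment event. On the nose-poking analysis window this yields bin centers
0–1800 ms: 91 bins, the population-matrix convention.

## auROC selectivity and the permutation test

The central statistic compares two per-trial spike-count samples with the
area under the ROC curve — the probability that a randomly chosen preferred
value exceeds a randomly chosen reference value, with half credit for ties
(a rescaled Mann–Whitney U) — reported as auROC = 2 (ROCarea − 0.5) in
[−1, 1]. Significance is a label permutation test preserving group sizes,
run one-sided in each direction at α = 0.01, with 1000 permutations (500
for response-dynamics summaries). P-values use the add-one correction,
p = (1 + #{permuted ≥ observed}) / (1 + N): a valid test at finite N with
p = 0 impossible; at N = 1000 the correction is negligible relative to
α = 0.01.

**Baseline reference construction.** The vs-baseline contrast compares each
100 ms bin's per-trial counts against counts from the 200 ms pre-trial
baseline. Rescaling the 200 ms count by one half would match exposure in
expectation, but it changes the count support (half-integers vs integers),
and a rank statistic is sensitive to support: under a stationary Poisson
null this mis-calibrates the test severely in one direction (we measured a
14% false-positive rate at α = 0.01 for inhibition). The package instead
tiles the baseline epoch into sub-windows of the sliding-bin width — the
200 ms baseline yields two 100 ms integer counts per trial — which is
exposure-matched *and* exchangeable with the bin counts under the null.
With this construction the measured per-bin false-positive rate is ≈ 0.009
in both directions (the small residual conservatism comes from ties and the
add-one correction). Note that bins of one series share their baseline
sample, so false positives cluster by neuron; any standard error attached
to an aggregate false-positive rate must treat the series, not the bin, as
the sampling unit.

A neuron is **go-cue selective** if its go-correct vs-baseline series has
at least five consecutive significant bins (100 ms of coverage) in the
excitation direction during the nose-poking window; no-go analogously, with
dual qualification resolved by the longer run and ties by peak auROC (dual
qualification has not been observed in practice). For the nose-poking
analyses, a trial stops contributing to bins past its own odor-port exit,
so late bins aggregate only trials still engaged in the epoch; a bin with
fewer than five remaining trials is undefined.

**Response-shape measures** summarize a significant excitatory response:
the time of center of mass (auROC-weighted mean of significant bin times;
a "weighted average of significant time points" is
ambiguous about the weights, so auROC weighting is the default and the
unweighted mean is available by flag), the qualifying run (the maximal
block of ≥ 5 consecutive significant bins containing the bin nearest the
center of mass), its duration (run length × step + (width − step), i.e.
the temporal span the run's windows cover), and the onset (the run's first
bin center). Reward-epoch selectivity aligns go-correct trials to the
water-port entry, analyzes entry to 1000 ms after valve opening, and labels
a neuron waiting- or drinking-selective by the epoch containing its center
of mass. Because a single significant bin suffices for a center of mass,
occasional chance labels on truly untuned neurons are an inherent property
of this criterion (about half of null neurons show ≥ 1 significant bin
among 66); the recovery guarantees quantified by the tests therefore
concern neurons whose ground truth is a reward archetype.

## Encoding model

The model regresses each neuron's smoothed 20 ms firing rate, over the
period from odor onset to 500 ms after the odor-port exit, on lagged binary
event indicators in six groups: odor presentation (lags 0–500 ms after
onset; 25 columns per condition), late nose-poking (lags from valve
closure; 22 columns for go and 13 for no-go, matching the condition medians
of the closure-to-exit interval), and pre-exit (−300 to 0 ms; 15 columns
per condition) — 115 columns plus an intercept. The late lag counts are
fixed at 22/13 rather than re-derived per dataset; the
generator's poke-duration medians make these consistent by construction.
Early-exit trials are included with lag support truncated at the exit.
Columns are z-scored over all rows ("normalized across trials" is read as
per-column normalization over the concatenated bins); folds for
cross-validation partition *trials*, never bins.

Fitting is ordinary least squares (identity-link Gaussian — the model
regresses smoothed rates, not counts, so no Poisson variant is offered),
with a tiny-ridge fallback only on exact rank deficiency. Explained
variance is R² = 1 − SSE/SST pooled over held-out bins of 5-fold trial-wise
cross-validation — a definition that, unlike squared correlation, can go
negative, which is exactly what lets "negative relative contributions"
arise. The relative contribution of variable *i* is

$$\left(1 - R^2_{p,i} / R^2_f\right) \Big/ \sum_{j=1}^{6} \left(1 - R^2_{p,j} / R^2_f\right),$$

with negative terms set to zero before normalization, and the partial model
formed by zeroing the excluded group's fitted coefficients (no refitting;
refitting and a lasso variant — λ chosen to minimize 5-fold CV MSE — are
available and agree on the dominant variable in the recovery tests).
Contribution significance compares each variable's performance drop against
1000 controls formed by zeroing ⌈10% × 115⌉ = 12 predictor columns drawn
uniformly from all columns ("10% of predictors" could also be read as 10%
within the excluded group; the global reading corresponds to one group's
worth of columns, and the two readings are
one flag apart in the code). Labels are positive/negative outside the
control mean ± 2 SD. A model with non-positive cross-validated R² refuses
contributions rather than reporting noise — on mixed simulated populations
this correctly excludes untuned and off-window neurons.

## Population dynamics

Per-neuron go and no-go vs-baseline auROC series on the 91-bin grid are
stacked into a (2 × 91) × N matrix (go block first). For this matrix the
per-trial exit truncation is disabled so every neuron contributes all 91
bins — with truncation the late bins of short-poking sessions would be
undefined and the matrix could not be assembled; neurons with refusals are
dropped, never imputed. PCA is fit on the column-centered nose-poking
matrix by SVD, with the sign convention that each component's
largest-magnitude loading is positive (determinism across platforms). Three
components are retained by default; the distance is
computed in the retained subspace, with an all-components option by flag.
The separation statistic is the per-bin Euclidean distance between the go
and no-go trajectories; the threshold is the mean + 2 SD of the same
pipeline run on the pre-odor baseline window (1200–1000 ms before entry),
*projected into the nose-poking subspace* so threshold and distances live
in the same coordinates. A zero baseline SD is an error, not a silent
threshold.

## Decoding

Pseudo-populations concatenate neurons across sessions, matched only by
trial type and within-type chronological order: pseudo-trial *k* of a type
joins each neuron's *k*-th correct trial of that type from the start of its
session, 40 trials per type. Features are sliding-window spike counts
(100 ms / 20 ms). The decoder is a linear-kernel SVM with the conventional
cost C = 1 (a conventional default), 10-fold stratified
cross-validation with fold assignment drawn before any feature computation;
accuracy is the mean over folds, chance is 50% for the two balanced
classes. The time course reports the first window at which accuracy reaches
the session-averaged behavioral accuracy; the population-size sweep
averages 20 random neuron subsets per size at a fixed window. Error bands
are SD over folds for the time course and SD over subsets for the size
sweep.

## Stability

Go-cue response stability correlates each go-correct trial's
nose-poking-epoch rate (minus the neuron's whole-session mean inter-trial
rate — a constant that cannot change the correlation, retained for axis
comparability) with the trial's position in the session. Significance is a
two-tailed 1% criterion against 1000 trial-shuffled correlations (outside
the 0.5th/99.5th percentiles). The duration–rate analysis is a Pearson
correlation (Spearman by flag) between the late-phase epoch rate and the
per-trial odor-sampling duration, pooled across trials within a neuron,
with the standard t-based p-value; the population summary aggregates
per-neuron results.

## Numerical and reproducibility choices

* Half-open windows everywhere; boundary spikes counted once.
* The per-bin permutation sets of one auROC series are drawn once and
  shared across the series' bins (the permutation is over trial labels,
  which the bins share); this is a common-random-numbers choice that does
  not affect marginal validity.
* Neuron-level analyses seed their RNG with a 31-bit stream derived from
  (base seed, neuron index), so results are independent of processing
  order; all derived seeds stay below 2³¹.
* Ties in rank statistics receive half credit; equal-length dual
  selectivity runs resolve by peak auROC.
* Degenerate inputs refuse or error loudly: empty samples, zero-duration
  epochs, constant matrices, zero baseline SD, single-class decoding.

Problem sizes in the tests and acceptance checks are chosen to make each
property's sampling error small relative to its tolerance on a single CPU:
sessions of 120–240 trials, recovery populations of 50–100 neurons,
permutation calibration over several hundred null series (tens of
thousands of bins), and 20 seeded repetitions for decoding-at-chance. The
false-positive-rate experiment uses many independent neurons because of the
per-series clustering described above.

## Known limitations

* Poisson spiking only; calibration under over-dispersed or history-
  dependent spiking is not demonstrated (the permutation test itself is
  distribution-free, but the generator cannot show it).
* The reward-selectivity criterion admits single-bin responders by
  construction; interpretation of its labels on weakly modulated neurons
  should lean on the response measures, not the label alone.
* The encoding model's binary lag basis cannot represent amplitude
  modulation within a condition (no spline or raised-cosine bases, no
  history filters, no interactions).
* No across-session unit tracking (recordings advance daily), no
  false-discovery-rate correction across bins (the selectivity criterion
  controls multiplicity through the consecutive-bin rule instead), and no
  shuffle-corrected or cross-validated auROC variants.
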