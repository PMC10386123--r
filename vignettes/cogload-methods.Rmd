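---
title: "Methods: from wearable signals to cognitive-load classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wearable signals to cognitive-load classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A wrist-worn device records photoplethysmography (PPG), skin conductance
(GSR, microsiemens), 3-axis acceleration and skin temperature at 51.2 Hz
while a participant alternates between high-cognitive-load tasks
(working-memory and interference tasks) and a low-load condition (a
casual game), with questionnaires and an eating break around the load
block. `cogload` implements the full analysis chain: clock
synchronisation, filtering, beat detection, electrodermal decomposition,
artefact-gated windowing, a 125-feature catalogue, hybrid feature
selection, nested leave-one-subject-out classification, questionnaire
and food statistics, and per-subject aggregation with item clustering.
Because the kind of dataset this targets is typically restricted-access,
the package ships a synthetic session generator with ground truth, so
every stage is testable end to end.

## Synchronisation

The task software's label clock is authoritative. At the start of a
recording the participant shakes the instrumented hand three times; the
bandpassed (0.5–6 Hz, order 4) accelerometer magnitude shows three
dominant peaks. `detect_sync_taps()` finds peaks above
`max(2 m/s^2, 5 x median magnitude)` in the first 60 s and aligns label
time zero to the *last* tap (the software starts after the shake;
`sync_align = "first"` is available since the convention is not
universal). The sensor clock is shifted, never resampled. Intervals are
half-open `[start, end)` in seconds from label start.

## Filtering

Butterworth bandpass filters are designed from the analog prototype via
the bilinear transform with prewarping, and applied forward–backward
(zero phase), so beat timing is not biased. The order parameter (4)
describes the one-pass filter; effective attenuation in dB doubles.
The design was validated against an independent reference
implementation's coefficients, frozen into the test suite. Bands:
0.5–8 Hz for PPG, 0.5–6 Hz for the accelerometer axes.

## Beat detection and the 10 % gate

Candidate beats are local maxima with minimum separation `60 / hr_max`
(`hr_max = 180` beats/min) and height above half the signal's standard
deviation. Peak positions are refined by parabolic interpolation: at
51.2 Hz a one-sample quantisation error alone shifts heart rate by more
than 1 beat/min. Candidates then pass a sequential gate: a candidate is
a beat only if its distance to the last accepted beat is within 10 % of
the reference interval. The reference is seeded with the median of the
first five candidate intervals (the rule is undefined for the first
pair) and updated only on acceptance. Two consequences are deliberate:

* an ectopic extra peak is rejected and does not perturb the reference;
* a *missed* candidate would otherwise deadlock the gate (the distance
  to the last accepted beat grows without bound), so a distance above
  1.5x the reference re-anchors the train; no inter-beat interval is
  emitted for the gap. The heart-rate series therefore contains only
  gate-approved intervals.

## Electrodermal decomposition

Skin conductance is modelled as

    y = tonic + (kernel * driver) + residual,

where the tonic component is a cubic B-spline (knots every 10 s) plus a
linear drift, the driver (sudomotor nerve activity, SMNA) is sparse and
nonnegative, and the kernel is bi-exponential,
`h(t) = exp(-t/2.0) - exp(-t/0.7)` (rise 0.7 s, decay 2.0 s), unit peak.
The fit minimises

    1/2 ||residual||^2 + alpha ||driver||_1 + gamma ||spline coefs||^2,
    driver >= 0,

with `alpha = 8e-4`, `gamma = 1e-2`. Because the driver is nonnegative
the l1 term is linear and the problem is a convex quadratic program. It
is solved at 12.8 Hz (decimation by block means keeps the program
tractable; electrodermal dynamics are far slower than 6 Hz): spline and
drift coefficients are eliminated in closed form, an accelerated
projected-gradient (FISTA) pass localises the support, and an
active-set polish solves the reduced Karush–Kuhn–Tucker system exactly
(add/drop rounds until the optimality residual clears). Components are
re-assembled at the original rate from the spline coefficients and the
driver impulses, so `tonic + phasic + residual == input` holds exactly
by construction and the phasic component is nonnegative. Tests compare
the solver against an independent dense quadratic-program solution
(Goldfarb–Idnani) on 30 s problems; agreement is ~1e-8, far inside the
1e-4 gate.

The synthetic generator uses the *same* kernel constants, which makes
recovery tests self-consistent: that is a deliberate choice — the tests
establish that the decomposition inverts the stated forward model, not
that the kernel is physiologically correct for any given person.

## Windows and artefact gates

Labelled high/low-load slices are cut into 120 s windows with 30 s
stride (75 % overlap), always inside a single slice (label purity). A
slice of `L` seconds yields `floor((L - 120) / 30) + 1` windows. Three
independent gates discard a window (all channels together, since hand
motion corrupts every sensor on the device):

* mean bandpassed accelerometer magnitude > 0.5 m/s^2;
* fewer than 3 distinct integer-rounded heart rates (`artefact_min_unique_hr`);
  a rate series with no variability indicates a sensor artefact, and
  "unique rates" is only meaningful after integer quantisation;
* mean heart rate below 35 beats/min (resting rates run roughly 40–109;
  far lower values mean missed beats). Whether this gate should use the
  mean, the minimum or the beat count is genuinely open; the mean is the
  default and the threshold is configurable.

## The 125-feature catalogue

The catalogue reproduces the documented group sizes exactly: 46 pulse
time-domain descriptors (statistics of the filtered waveform and its
first/second differences plus peak statistics), 4 pulse frequency-domain
features (low-frequency, high-frequency and total band power of the
beat-interval tachogram and their ratio), 11 heart-rate features (mean,
dispersion, successive-difference and percentile statistics, count),
2 temperature features, 43 conductance time-domain features
(amplitude/derivative statistics and trough-to-peak response
descriptors) and 19 decomposition features (component statistics,
maximum Welch power per component, driver count and areas, tonic
slope). The itemised list is a documented reconstruction — the source
material names groups and totals, not all 125 items — and
`feature_catalogue()` asserts the cardinalities so drift is impossible.
Degenerate windows are handled by convention, documented per statistic
(e.g. skewness of a constant signal is 0; the LF/HF ratio of a
powerless tachogram is 0); any non-finite feature drops the window with
a logged reason. The sudomotor count is the number of driver excursions
above 0.01 a.u. separated by at least 1 s; "maximum power" is the
maximum of the component's Welch periodogram.

## Feature selection and nested evaluation

Selection is hybrid: a one-way ANOVA F filter keeps the top 40
features, then recursive feature elimination with cross-validation
(random-forest importance, step 1, macro-F1 scoring, folds grouped by
subject when possible) scores every cardinality from 40 down to 1; the
best cardinality's path prefix is the selected set.

Classification is nested leave-one-subject-out: the outer loop holds
out each subject; the inner loop scores every hyperparameter grid point
by leave-one-subject-out over the remaining subjects; the winner (first
listed on ties, grid rows in documented order) is refit on all
non-held-out rows and evaluated on the held-out subject. The scaler
(z-score by default, min–max available; the normalisation method is an
open choice) is always fit on training rows only. Two modes exist
because the honest default and the faithful reproduction differ:
`leakage_safe` (default) re-runs selection inside each outer fold;
`reproduction` uses one selection computed on all data, mirroring an
analysis order in which selection precedes model training. Row
provenance is asserted on every outer fold: test rows never reach a fit.

Model families: linear support vector machine (dual coordinate descent;
the tuned grid retains a gamma axis for fidelity with common tuning
setups although gamma is inert for a linear kernel), random forest
(Gini splits, bootstrap, mean-decrease-in-impurity importance; the
"auto" and "sqrt" feature-subsampling options coincide for
classification and are documented as aliases), and Gaussian naive Bayes
(variance smoothing swept logarithmically from 1 to 1e-9 with exponent
step 0.099 — a linear step of that size cannot reach 1e-9, so the
sweep is read as logarithmic). No classifier package of this kind is
assumed in the environment; the implementations live in `src/` and are
exercised against separable and label-permuted controls.

Metrics treat high load as the positive class; precision, recall and F1
are computed per class and macro-averaged (unweighted two-class mean),
accuracy is the correct fraction; all as percentages. An undefined 0/0
per-class ratio contributes 0 with a warning. Cohort summaries are
unweighted means over subjects.

## Questionnaire and food statistics

The 20-item affect schedule scores positive and negative affect as sums
of ten 1–5 items (10–50 each). The six-subscale workload index defaults
to the unweighted (raw) variant — the mean of the six 0–100 subscales —
with the weighted variant (`sum(w_i s_i) / 15`) behind an argument,
since which variant produced a given published table is often unstated.

Comparisons run through a normality-routed tree: Shapiro–Wilk per
condition; two paired conditions take a paired t-test when all pass
(p > 0.05) and a Wilcoxon signed-rank test otherwise; three repeated
conditions take the Friedman test. The routing decision is recorded in
every result. Wilcoxon conventions: two-sided, zero differences
dropped; exact p via the signed-rank distribution (no ties, n <= 25) or
complete sign-flip enumeration (ties, n <= 14 — 2^n patterns); beyond
that a tie-corrected normal approximation without continuity
correction. Identical paired samples short-circuit to statistic 0,
p = 1.

The post-hoc after a significant Friedman test is an interpretation:
the default is uncorrected pairwise Wilcoxon signed-rank tests; a
studentized-range (Nemenyi) alternative is switchable
(`posthoc_method`). Neither convention is canonical and they disagree
in the third decimal on typical 12-subject data; results label the
method used.

Food consumption is weighed before and after eating; energy and sugar
come from a static density table shipped with the package (synthetic
stand-in values typical of packaged-food labels; user-overridable; no
network lookups). Per item, the high/low-load session means, the routed
paired test and the direction of change — the ratio of high-load to
low-load mean, rounded to one decimal — are reported. The analysis
subgroup defaults to the subjects whose negative affect peaked right
after load (strictly above both the before-load and after-eating
scores).

## Aggregation and clustering

Per-subject labels binarise classification accuracy at strictly above
80 % and the affect flag as above. Food amounts are min–max normalized
per item-session column across all subjects and both sessions jointly
(one scale for both sessions keeps them comparable); calories are
excluded because water's zero calories would distort the scale.
Items are clustered agglomeratively (Ward linkage on Euclidean
distances by default, k = 3; both configurable) over their
subjects-by-sessions profiles; outputs include the assignment, the
dendrogram in Newick text and a leaf-ordered matrix for heat-map
rendering.

## The synthetic world

`session_spec()` defaults state the world the tests assume: 51.2 Hz;
heart rate 70 beats/min baseline, +15 during high-load tasks (only
high-load tasks elevate arousal — the casual game stays at baseline);
skin-conductance responses at 2/min baseline vs 8/min under load with
lognormal amplitudes around 0.3 uS; tonic drift 0.02 uS/min; three
hand-shake taps just before label zero; motion bursts (4–6/hour,
10–20 s) that corrupt *all* channels so artefact rejection is
observably beneficial — bursts are long enough that a covered 2-minute
window exceeds the 0.5 m/s^2 mean-magnitude gate, which short spikes
cannot. The pulse waveform is two Gaussians per beat (systolic peak and
dicrotic bump), which gives the peak detector realistic morphology
without a haemodynamic model. No published effect sizes exist for the
heart-rate and response-rate deltas between conditions; the defaults
are free parameters chosen once at plausible magnitudes, not estimates
of any real cohort. Consequently a green end-to-end test establishes
that the pipeline recovers the structure this generator plants — not
that real recordings separate this cleanly, and not that the feature
catalogue matches any particular device's firmware.

The default full-length session plan runs ~70 min; `duration_scale`
shrinks it for desk-scale runs (note that below ~0.27 the load segments
fall under one 120 s window and produce no classification rows — tests
use compact custom plans instead).

## Numerical choices and limitations

* Decimation for the decomposition is by block means; impulse positions
  are mapped back to the original grid, so reconstruction is exact but
  driver timing is quantised to ~78 ms.
* FISTA runs to a relative-objective tolerance of 1e-10 with an
  active-set polish; `solver_status` carries the optimality residual.
* The exact post-hoc convention, the heart-rate gate statistic, the
  normalisation method and the first/last-tap alignment are genuinely
  open choices; each is configurable and defaults are documented above.
* The random forest and support vector machine are compact
  reimplementations adequate for a few hundred windows and tens of
  features; they are not drop-in replacements for large-scale learners.
* Statistical tests are run uncorrected for multiplicity, matching the
  analysis style this package reproduces.
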