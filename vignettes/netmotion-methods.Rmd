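---
title: "Monitoring bed net use with net-mounted accelerometers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring bed net use with net-mounted accelerometers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmotion)
```

## The measurement problem

Long-lasting insecticidal nets (LLINs) only protect against malaria while
they are unfurled and occupied. The standard adherence measure —
self-reported use the previous night — is coarse and subject to recall and
social-desirability bias. A small triaxial accelerometer clipped to the net
roof records, cheaply and continuously, the mechanical signature of net
handling: unfurling the net (`net_down`), entering, lying still
(`sleep`, pooled with the no-activity state of an undisturbed net, which is
indistinguishable from it), exiting, and folding the net up (`net_up`).
`netmotion` implements the full classification chain from raw recordings to
behaviour-level performance reports, together with a simulator that stands
in for field recordings, which are not publicly distributable.

## The classification model

Each annotated motion tag yields one **observation**: the 20 s of signal
starting at the tag, split into two contiguous 10-s **epochs**. At the
default 10 Hz sampling an epoch holds 100 triaxial samples, reduced to:

* per-axis means $\bar{x}, \bar{y}, \bar{z}$ (in g),
* per-axis sample standard deviations (n − 1 denominator),
* the displacement-magnitude sum
  $D = \sum_{i} \lVert (\Delta x_i, \Delta y_i, \Delta z_i) \rVert_2$,
  a discrete path length of the acceleration vector.

The default feature scheme, `paper10`, keeps per epoch the three means, the
vertical-axis SD, and $D$ — 10 features per observation. The enumeration of
all per-axis statistics totals 14; because the two readings of the source
protocol conflict, the fuller set is available as `full14`
(`feature_names("full14")`), with `paper10` a subsequence of it. Two other
conventions are deliberately configurable rather than hard-coded, since the
protocol does not pin them down: the displacement norm (Euclidean by
default; a per-axis L1 sum via `disp = "per_axis"`) and the window anchor
(the observation starts exactly at the tag start; device-bin snapping is
not modelled). The inter-epoch boundary step belongs to neither epoch's
$D$, a convention the test suite asserts explicitly.

Observations are classified by a random forest (the `randomForest` package)
with 1000 trees and `mtry = 4` ≈ √10 candidate features per split, after an
80/20 train/validation split with the floor convention (2506 observations
split 2004/502). The split is plain uniform sampling by default — matching
the plain "80/20" description — with a stratified-by-label option; `mtry`
stays 4 under `full14` unless overridden, preserving the published
configuration while exposing the knob. Per-class scores are vote fractions
(they sum to 1 per row); the predicted label is the argmax with ties broken
by fixed class order, so predictions are reproducible. Feature importance
defaults to mean decrease in Gini impurity ("gini"), with permutation
importance ("accuracy") as an option, since the importance type behind the
published ranking is unstated.

Three nested label schemes are supported: `five` (all behaviours), `four`
(enter/exit merged), and `three` (net_down, enter and exit merged into
`net_down_active`, as all three occur only while the net is unfurled). The
three-way mapping factors through the four-way one, and collapsing truths
and predictions can never lose correct classifications — both are tested
properties.

## Evaluation and DeLong inference

`evaluate_model()` reports the confusion matrix, overall accuracy
(trace/total), and one-vs-rest sensitivity, specificity and AUC per class.
A class absent from the validation truth gets an `NA` metric with a
warning, never a silent 0.

The AUC is the Mann–Whitney statistic: the mean over all
(positive, negative) pairs of $\psi = 1, \tfrac12, 0$ as the positive's
score is above, tied with, or below the negative's. Its variance is
DeLong's estimator from the structural components
$V^{10}_i = \tfrac1n \sum_j \psi(X_i, Y_j)$ and
$V^{01}_j = \tfrac1m \sum_i \psi(X_i, Y_j)$:
$\widehat{\mathrm{var}} = S_{10}/m + S_{01}/n$, their sample variances over
the $m$ positives and $n$ negatives. The 95% CI is Wald on the AUC scale,
truncated to [0, 1] (the CI construction behind the published intervals is
unstated; Wald is the convention of the DeLong toolchain). Two comparison
tests are provided:

* `delong_test_independent()` for curves from disjoint samples —
  $z = (\hat A_1 - \hat A_2)/\sqrt{v_1 + v_2}$. This is the default for the
  adults-vs-children contrast, whose two models are fit on disjoint
  subjects.
* `delong_test_paired()` for two score sets on the same rows, which
  subtracts twice the covariance of the paired structural components.

Degenerate inputs are handled explicitly: zero pooled variance with equal
AUCs gives $p = 1$; with unequal AUCs the test is flagged and $p = 0$. ROC
curves are emitted as point tables over all distinct thresholds, so their
trapezoidal area equals the Mann–Whitney AUC to numerical precision
(tested at 1e−9); the suite also checks the estimator against brute-force
pair enumeration and against the independent `pROC` implementation.

## What the simulator emulates — and what it does not

No published signal model exists for net-mounted accelerometers, so the
waveforms are designed, not fitted. The design constraints are the
qualitative findings the classifier chain should reproduce:

* **Gravity and noise.** Accelerations are in g; gravity is a static 1 g
  offset on the vertical (y) axis; sensor noise is white Gaussian
  (`noise_sd` = 0.02 g) on all axes. No orientation drift is modelled.
* **Vertical-axis signal.** `net_down` is a biphasic vertical pulse
  (downward lobe, smaller recoil lobe, damped 3 Hz settling); `net_up` is
  its sign mirror. The unequal lobes give the epoch mean on y a signed
  shift, so y-derived features carry the class signal and top the
  importance ranking.
* **Enter/exit confusability.** Entering is a band-limited oscillation
  burst on y and x under a fast-rise/slow-decay envelope; exiting uses the
  exact time-reversed envelope. Order-insensitive 10-s summaries are blind
  to time reversal, so the two classes collide by construction — the
  dominant error mode of the five-class model. They are kept *partially*
  separable by a small signed lateral drift (±0.004 g on x, entering vs
  exiting) whose epoch-mean effect is a deliberate ~1.6 standard errors of
  the noise-driven epoch mean for adults: enter/exit sensitivities land
  near 0.7–0.8 rather than 0.5 or 1.0. Carrier phases are randomized per
  instance so no deterministic shape constant separates the classes.
* **Children are harder.** Child motions are amplitude-scaled by 0.5
  (`child_scale`), halving the drift relative to the fixed noise floor —
  adult subgroup models beat child models on enter/exit AUC, as observed.
  Children perform only enter/sleep/exit.
* **Protocol.** `simulate_study()` mirrors the field protocol: default 27
  subjects (one third children), each motion repeated 14 times with 60-s
  quiescent breaks, sleep lasting 60 s, instance-level log-normal amplitude
  jitter (sd 0.15). All randomness flows from one seed; identical
  (plan, config, seed) runs are bit-identical.

What passing tests on this synthetic world *cannot* show: robustness to
wind, animals, multiple occupants, orientation changes, device clock drift,
or the true amplitude spectra of field signals — none of which are
modelled. The simulator demonstrates that the chain recovers structure that
is present; it cannot certify field performance.

The default design yields ~1600 observations (sleep prevalence ~23%, lower
than in the field data, where quiescent no-activity stretches inflate the
sleeping class); at this size a full three-scheme-plus-subgroups analysis
runs in seconds, and the ten-seed recovery battery in the test suite in
about a minute — problem sizes chosen to make the stochastic checks cheap
to replicate.

## Numerical choices and degenerate inputs

* Train size uses `floor(0.8 N)`, matching the published 2004/502 split of
  2506.
* Sample SD uses the n − 1 denominator (unstated in the source; standard
  practice).
* AUC ties count ½; the DeLong variance of a single-positive (or
  single-negative) curve treats the undefined component variance as 0.
* `read_recording()` infers the sample rate from the median inter-sample
  interval (snapped to the microsecond grid to absorb timestamp rounding)
  and rejects non-monotone timestamps, malformed rows and gaps beyond 10%
  of the interval, reporting line numbers.
* Intervals are half-open `[start, end)`; timestamps are ISO-8601 with
  fractional seconds, UTC.
* Tags overlapping within a subject, unknown labels, and child entries
  assigned net-handling motions are rejected (the latter downgradeable to
  a warning).

## A worked run

```{r run, eval = FALSE}
res3 <- run_experiment(experiment_config(class_scheme = "three", seed = 7))
res3$report$accuracy
head(res3$importance, 3)

adults <- run_experiment(experiment_config(analysis = "adults_only", seed = 7))
children <- run_experiment(experiment_config(analysis = "children_only", seed = 7))
delong_test_independent(adults$report$rocs$enter, children$report$rocs$enter)
```

At seed 7 the three-category model classifies the simulated validation set
perfectly, y-derived features occupy the top importance ranks, and the
adult enter-AUC (0.93) exceeds the child one (0.77) — the same qualitative
surface the chain is designed to recover. Exact numbers for any seed are
reproduced by `Rscript scripts/acceptance.R --seed <s> --out <path>`.

## Known limitations

* The simulator's parameters are calibration knobs, not field facts; its
  absolute accuracies exceed those achievable on real recordings.
* Continuous-stream event detection (finding motions without tags) is out
  of scope; the pipeline consumes annotated intervals.
* The proprietary binary device format is not read; recordings enter as
  delimited text.
* Vote fractions are a forest-specific score; AUCs under another
  classifier's scores would differ.
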