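---
title: "Coherence networks for motor-recovery prognosis: models and methods"
author: "strokecoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence networks for motor-recovery prognosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecoh)
library(dplyr)
```

## What the package models

After a stroke, the functional coupling between sensorimotor regions of the
two hemispheres reorganizes, and the state of that coupling before a
rehabilitation intervention carries information about how much a patient
will benefit from it.  `strokecoh` implements one complete analysis chain
built on that idea:

1. **Coherence networks.**  Resting-state EEG over a 16-channel sensorimotor
   montage is reduced to magnitude-squared coherence between all 28 pairs of
   eight electrodes (C3/C4 over primary motor, FC3/FC4 premotor, CP3/CP4
   somatosensory, Cz over the supplementary motor area, plus FCz), averaged
   within four frequency bands (delta 1–4, theta 4–8, alpha 8–14, beta
   14–30 Hz) and summarized as five networks: interhemispheric (9 pairs) and
   the ipsi-/contralesional local and SMA-coupling triplets.
2. **Clinical outcomes.**  Upper-limb impairment is scored with the
   Fugl-Meyer Assessment for Upper Extremity (FMA-UE, 0–66) before training,
   after training and at six months.  Patients whose gain at either
   follow-up reaches the minimal clinically important difference (MCID,
   4 points) are labeled *good* recoverers.
3. **Biomarker screening.**  Band × network coherences are compared between
   good and poor recoverers with exact permutation t-tests (Hedges' g as
   effect size, Benjamini–Hochberg FDR across the 20-cell family), and band
   × pair coherences are screened against the intervention gain with
   Spearman correlations validated by a 5000-shuffle permutation null.
4. **Prognosis.**  The coherences passing both screens enter a PLS1
   regression of the gain; components are added until 90% of the response
   variance is explained, predictors with VIP ≥ 1.0 are kept as biomarkers,
   and predictive performance is estimated by leave-one-out cross-validation
   (correlation between predicted and observed gains, RMSE).

A packaged 22-participant clinical table (two arms: a neural-guided
action-observation robot-hand intervention, n = 12, and a text-instructed
control, n = 10) exercises the clinical half exactly; a synthetic-data
module exercises everything else.

## Coherence estimation

Magnitude-squared coherence between channels $x$ and $y$ is

$$C_{xy}(f) = \frac{|S_{xy}(f)|^2}{S_{xx}(f)\,S_{yy}(f)} \in [0, 1],$$

estimated from Welch-averaged cross- and auto-spectra.  The Welch
parameters are exposed in `pipeline_config()` with these defaults:

* **2 s segments** (0.5 Hz resolution — four bins inside delta, and about
  179 segments in a 3-minute recording at 50% overlap);
* **hann taper, 50% overlap, linear detrend** per segment;
* **half-open band edges** `[lo, hi)` so the shared edges 4, 8 and 14 Hz are
  counted once.

Coherence from a single segment is identically 1, so fewer than two
segments is an error rather than a silent degenerate estimate.  Bins where
either channel has no power get `NA`: the ratio is undefined there.

Preprocessing mirrors the acquisition path: an order-4 Butterworth 2–60 Hz
band-pass plus a 48–52 Hz notch, both applied forward–backward so that no
phase distortion enters the cross-spectra.  The 2 Hz high-pass overlaps the
delta band; because an identical linear filter on both channels cancels in
the coherence ratio, delta coherence remains estimable, but it rests on
attenuated power below 2 Hz.  The band-pass can be disabled
(`bandpass = NULL`) and the package points this conflict out once per
session.

### Lesion canonicalization

Left-lesion recordings are flipped across the midline (C3↔C4, FC3↔FC4,
CP3↔CP4; Cz, FCz fixed) so that the ipsilesional hemisphere always occupies
the C4-side labels.  The flip is an involution and only relabels — the
multiset of coherence values is untouched.  The montage literature is not
fully consistent about which side the "ipsilesional local" triplet refers
to, so the convention is a config switch (`ipsi_side`); the default matches
the frame in which the packaged screening results are expressed
(contralesional = C3-side).  FCz pairs are computed and reported but belong
to no network.

## Clinical statistics conventions

The within-group tests are deliberately pinned to the conventions of
mainstream clinical statistics software, because that is what published
FMA-UE analyses use:

* **Friedman test** with within-subject mean ranks and the tie correction
  $C = 1 - \sum(t^3 - t)/(nk(k^2-1))$ dividing the textbook statistic.  FMA
  scores are small integers, ties are everywhere, and the uncorrected
  statistic (what `stats::friedman.test` computes) differs noticeably.
* **Wilcoxon signed-rank** with zero differences dropped, mean ranks on
  ties, the tie-corrected normal variance, no continuity correction, and
  $Z = (\min(W^+, W^-) - \mu)/\sigma$ reported negative.  Bonferroni over
  the three pairwise contrasts.
* **MCID rule** read as gain ≥ 4 (`rule = "gte"`); the strict reading
  (`"gt"`) is available and labels the packaged cohort identically, so the
  choice is documented rather than consequential there.
* **Tukey fences** for screening aberrant post-to-6-month changes use Tukey
  hinges (`stats::fivenum`); the excluded participants' raw values are not
  part of the packaged table, so no convention can be validated against
  them and the quartile method is configurable.
* **LOCF imputation** replaces a missing 6-month score with the
  post-training score and flags the record.

One bookkeeping note on the packaged table: the published intensity summary
for the intervention arm (1436.83 ± 159.94 repetitions) is not reproducible
from the twelve printed per-participant intensities (their mean is
1453.67).  The fixture stores the printed raw values and leaves the
discrepancy alone.

## Permutation inference

Group differences use the **exact** two-sample permutation t-test: all
$\binom{n_a+n_b}{n_a}$ assignments are enumerated (792 for 7 vs 5) and the
two-sided p-value is the fraction of assignments with $|t|$ at least the
observed.  Because the observed split is one of the enumerated assignments,
$p \ge 1/\binom{n}{n_a}$ and no add-one correction is needed; the result is
bit-reproducible with no RNG.  A permutation with zero pooled variance gets
$|t| = \infty$ when the group means differ and 0 otherwise.  The pooled
Student statistic is used; permutation inference is valid for any
statistic, and the pooled t is the conventional default.

The correlation screen is Monte-Carlo: the gain vector is shuffled
`n_perm = 5000` times under an explicit seed and
$p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\})/(n_{perm} + 1)$, the
add-one form that cannot return zero.  Each pair's screen advances the seed
deterministically, and the seed is echoed in the output.

FDR is Benjamini–Hochberg across the band × network family (20 cells) per
arm; whether the published analysis corrected across bands, networks or
both jointly is not stated, so the family is the reported comparison set
and the raw permutation p drives the `discriminative` flag by default
(`use_fdr = TRUE` switches).

## PLS1, VIP and cross-validation

The prognosis model is single-response PLS (NIPALS) on autoscaled
predictors and a centered response.  Autoscaling is the convention VIP is
defined on, and it makes the pipeline invariant to rescaling any predictor.
For each component: $w_a \propto X^\top y$, $t_a = X w_a$,
$p_a = X^\top t_a / t_a^\top t_a$, $b_a = y^\top t_a / t_a^\top t_a$, then
deflation of both $X$ and $y$.  Scores are mutually orthogonal; at full
rank the fit equals ordinary least squares.  If the residual covariance
vanishes early (the response lies along a principal direction of the scaled
predictors), the fit truncates there.

* **Component count**: smallest $A$ with cumulative explained response
  variance $\sum_{a \le A} b_a^2 t_a^\top t_a / \mathrm{SS}_y \ge 0.90$,
  capped at the predictor rank (returned with a warning if the threshold is
  unreachable).
* **VIP**: $\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a
  (w_{aj}/\|w_a\|)^2 / \sum_a \mathrm{SSY}_a}$, satisfying
  $\sum_j \mathrm{VIP}_j^2 = p$ exactly; predictors with VIP ≥ 1.0 are the
  biomarker set (an empty set falls back to all predictors, with a
  warning).
* **LOOCV**: $n$ refits on $n-1$ subjects, autoscaling recomputed inside
  every fold; a fold whose rank drops below $A$ uses its rank.

`pls_prognosis(cv = "paper")` reproduces the published protocol: biomarkers
are selected once on the full sample and held fixed inside the folds.  That
estimate is optimistic, because selection has seen the held-out subject.
The package therefore also ships `cv = "nested"`, which repeats component
choice and VIP selection inside every training fold; on null data the
nested estimate centers near zero (slightly below, as out-of-fold
correlations do) while the paper protocol is positively biased — the test
suite asserts both behaviors by simulation.  The component count inside
folds is held at the full-sample choice, since fold-wise re-selection is
not part of the published protocol; this too is configurable.

## The synthetic-data module

No public EEG accompanies the clinical table, so the generators reproduce
the *statistical structure* the analysis consumes, with closed-form ground
truth:

* **Band-limited noise** is white Gaussian noise masked in the frequency
  domain and standardized — all of its power is in-band by construction.
* **Controlled coherence** uses a shared-source mixing model: for a
  requested pair and band, $x = \sqrt{\gamma} s + \sqrt{1-\gamma} n_x$ and
  $y = \sqrt{\gamma} s + \sqrt{1-\gamma} n_y$ with independent unit-variance
  band-limited $s, n_x, n_y$, giving band coherence exactly $\gamma^2$.
  The generator is therefore its own oracle.  One subtlety: a finite-window
  spectral estimate integrates roughly ±1 Hz around each bin, so a measured
  boundary bin sees both sides of a band edge.  Shared components are
  synthesized 1 Hz past the band edges (every measured bin carries the
  shared structure) and private components 1 Hz inside (independent power
  never reaches a neighbouring band's bins); without this margin the
  band-mean coherence of a strongly coupled pair is biased low by several
  hundredths.  Real rhythms are not brick-wall confined to analysis bands
  either, so the margin is also the more physiological choice.  Within one
  band a channel may join only one shared pair — overlapping shares would
  break the closed form, and such specs are rejected.
* **Cohorts** draw coherence-like features uniform on $[0,1]$ and realize
  gains from $\Delta = \beta_0 + \sum_k \beta_k f_k + \varepsilon$.  The
  defaults — 12 subjects, 20 features of which 3 are informative with
  $\beta = (12, -10, 8)$, $\beta_0 = 2$, noise SD 25% of the signal SD —
  put gains in a clinically plausible range around the MCID and mirror the
  predictor-to-sample ratio of the modeled study.  Gains are rounded
  half-away-from-zero (FMA is integer-valued) and clipped to keep scores in
  0–66; the pre-rounding gains, coefficients and noise draws are returned
  as ground truth.
* **A full two-arm study** (`generate_study`) ties the two halves together:
  the six lateral electrodes share one delta source with subject-specific
  fraction $\gamma$, so every interhemispheric delta pair has true
  coherence $\gamma^2$, and the intervention-arm gain follows
  $\Delta = 7.5 - 10\gamma^2 + \varepsilon$ (higher pre-training
  interhemispheric coupling, smaller gain — the direction of the
  association the pipeline is built to detect, with the MCID falling
  mid-range so both recovery classes are populated).  The control arm's
  gain is noise around the MCID, independent of coherence.

What the generators deliberately do **not** emulate: lesioned spectra,
artifacts, volume conduction, non-stationarity, or any realistic stroke EEG
morphology.  Passing tests therefore demonstrate that the estimators and
the inference chain are correct and calibrated under the assumed
statistical structure — not that the biomarkers generalize to real
recordings.

## Numerical choices and degenerate inputs

* Exact-test tie handling: an assignment counts as "at least as extreme"
  under a $10^{-12}$ relative tolerance, so the observed split always
  counts itself.
* Spearman on constant input, Hedges' g with zero pooled SD, signed-rank
  with all-zero differences, coherence with fewer than two segments, bands
  with no frequency bins: all explicit errors, not NaNs.
* Zero-variance predictor columns are rejected by name before PLS.
* Recovery classes with fewer than two members degrade the group
  comparison to `NA` rows with a warning instead of aborting a pipeline
  run.
* All Monte-Carlo procedures take explicit seeds and echo them; exact
  enumeration needs none.

## Problem sizes in the test suite

The suite checks the clinical statistics on the packaged 22-row table
(exact, sub-second); the $\gamma^2$ oracle on 3-minute synthetic recordings
at 256 Hz; permutation-test calibration on 1000 null replicates of the 7
vs 5 design; parameter recovery on 100 replicate cohorts of 12 subjects ×
20 predictors; and the null-calibration of the correlation screen on 500
replicates of 1000 shuffles.  These sizes keep every Monte-Carlo tolerance
meaningful while the whole suite runs in a few minutes.

## Limitations

* The sensor-space networks carry no source-level claim; with eight
  electrodes, volume conduction alone induces coherence structure that the
  pipeline does not model or remove.
* The paper-protocol LOOCV estimate is optimistic by construction; use the
  nested mode for an honest generalization estimate.
* The exact permutation test is limited to designs whose enumeration fits
  the guard (about $10^6$ assignments); larger designs need a Monte-Carlo
  variant, which this package intentionally does not provide for group
  comparisons.
* EDF input is not supported; recordings enter as channel × sample CSV
  matrices with a YAML sidecar.
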