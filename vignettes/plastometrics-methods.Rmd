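---
title: "Methods: neuroplasticity metrics for neurofeedback-guided rehabilitation"
author: "plastometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuroplasticity metrics for neurofeedback-guided rehabilitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastometrics)
```

## What the package computes

`plastometrics` quantifies training-induced neuroplasticity in
robot-assisted stroke rehabilitation from three data streams:

1. **Clinical outcomes.** Fugl-Meyer Assessment upper-extremity (FMA-UE,
   0–66) scores at baseline, immediately post-intervention and six-month
   follow-up, analysed with tie-corrected rank statistics and a responder
   analysis against the minimal clinically important difference (MCID).
2. **EEG.** The mu-rhythm suppression score that drove the closed-loop
   robot-hand trigger, and the "discriminant rate" (DR) — the accuracy of
   a linear discriminant separating motor-imagery from rest epochs using
   four band powers over one hemisphere's electrodes.
3. **Resting-state fMRI.** The temporal variability of dynamic functional
   connectivity of region-level BOLD time series, aggregated into six
   functional subnetworks.

A seeded generator accompanies each stream so that every pipeline stage is
testable without recordings.

## Clinical rank statistics

The longitudinal test is Friedman's test with within-row mid-ranks and the
tie-correction divisor

$$\chi^2 = \frac{\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)}
                {1 - \sum (t^3 - t) / (n(k^3-k))},$$

the convention used by SPSS, with the tie sum running over within-row tie
groups. Incomplete rows are removed first (complete-case analysis), so the
three-time-point test in a group with two missing follow-ups uses the
complete subjects only.

The post-hoc contrast is the Wilcoxon signed-rank test in the
zero-exclusion convention: zero differences are dropped before ranking,
mid-ranks are applied to the absolute differences, and the statistic is

$$Z = \frac{S - m(m+1)/4}
           {\sqrt{m(m+1)(2m+1)/24 - \sum(t^3-t)/48}},$$

where $S$ sums the ranks of *negative* differences ($d = y - x$), so
improvement gives a negative $Z$. No continuity correction is applied.
Pairs are dropped pairwise (a subject missing the follow-up still
contributes to the pre/post contrast). Our tests document the accuracy of
the normal approximation against the exact $2^m$ enumeration of sign
assignments: the worst-case gap at untied ranks is 0.099 at $m = 6$,
falling to 0.050 at $m = 10$, so the suite bounds the discrepancy by
$0.7/m$.

The baseline between-group comparison is a Mann–Whitney U test with
pooled mid-ranks and tie-corrected variance (again without continuity
correction). The two-way question — does the score depend on time, group,
or their interaction — uses the Scheirer–Ray–Hare extension: a two-way
ANOVA decomposition on the pooled ranks, with each effect's
$H = SS_{\mathrm{effect}} / MS_{\mathrm{total}}$ referred to a
chi-square distribution. The package computes the decomposition through a
standard sequential ANOVA fit, which also defines the behaviour for
unbalanced cells (here: missing six-month scores); since the original
analysis tooling for the unbalanced case is unspecified, the suite asserts
only non-significance of all three effects on the bundled cohort, not
exact p-values.

Responder analysis counts a subject as exceeding the MCID when the score
change is **at least** the threshold (change $\ge 4$; the count 7/13
validates $\ge$ rather than $>$), with subjects missing the later endpoint
excluded from the denominator. Percentages round half away from zero to
one decimal, matching the printed 53.8 / 54.5 / 36.4.

## Mu suppression and the trigger

Raw EEG (16 channels over the central motor areas, 256 Hz) is band-passed
2–60 Hz and notch-filtered 48–52 Hz. Both filters are 4th-order
Butterworth run forward and backward (`signal::filtfilt`), so the package
applies zero-phase versions of the acquisition filters; only corner
frequencies were specified, the order is our choice and documented here.

Band power uses a single Hanning-tapered FFT over the whole 6 s segment
(bin spacing 1/6 Hz), not Welch averaging. The power is integrated over
the bins whose centre frequency lies inside the band, boundaries
inclusive. We define the estimate as the *integrated* in-band power (sum
of one-sided PSD bins times the bin width): this makes white-noise band
power proportional to bandwidth and leaves every power *ratio* — including
the suppression score — identical to the per-bin-mean convention.

The suppression score for one trial is

$$MSS = -\frac{P_{task} - P_{rest}}{P_{rest}} \times 100,$$

computed on the mu band (8–13 Hz; an 8–12 Hz variant can be passed as a
`band` override) of the ipsilesional online electrode — C3 for left
lesions, C4 for right. $P_{rest}$ defaults to the rest segment immediately
preceding the trial, of the same duration as the task window; a running
rest baseline was also plausible from the protocol description, so the
`channel`/`band` arguments and per-trial structure keep both usable, with
per-trial rest as the default. The robot hand triggers when $MSS > 20$
(strictly), i.e. when task mu power fell below 80% of rest. The sham arm
replaces the decision by a Bernoulli draw at 0.8, independent of the EEG.

## The discriminant rate

Features are the powers in alpha (8–13), low-beta (12.5–16), beta
(16.5–20) and high-beta (20.5–28 Hz), each averaged over one hemisphere's
seven electrodes (odd indices left, even right, midline excluded). Each
trial contributes one imagery and one rest vector.

The classifier is a two-class Fisher discriminant written in the package:
pooled within-class covariance, $w = \Sigma^{-1}(\mu_1 - \mu_0)$, boundary
midway between projected class means shifted by the log-prior ratio
(priors default to equal, matching balanced epochs). When the pooled
covariance condition number exceeds $10^8$ a ridge term $10^{-6} \times$
mean diagonal variance is added — only then, so the estimator is the plain
pooled-covariance LDA on well-conditioned data. `MASS::lda` serves as an
independent cross-check of the discriminant direction in the tests, never
as the implementation.

Evaluation follows the session protocol: the early stage uses training
sessions 1–4, the late stage the last four; two sessions train and the
other two test. A single 2+2 split is noisy, so `discriminantRateStudy`
averages over 10 seeded splits by default; `nSplits = 1` reproduces the
single-split protocol. Whether the original feature vectors were
trial-level or session-averaged is ambiguous ("features of all trials in
each session were averaged"); trial-level is the default because a
classifier fitted on two vectors per class is degenerate, and
`sessionAverage = TRUE` provides the literal reading. No numeric DR values
are asserted anywhere: the published ones exist only as figure bars.

## Temporal variability of dynamic connectivity

A region × time BOLD matrix is cut into consecutive non-overlapping
windows of length $L$ starting at the first volume, discarding the
trailing remainder (the windowing origin is exposed as `offset`); each
window yields a Pearson adjacency matrix. The variability of region $k$
is

$$V_k = 1 - \overline{\mathrm{corr}\!\left(W_{i,k}, W_{j,k}\right)},
\qquad i \ne j,$$

with the profile $W_{i,k}$ being row $k$ with the self-entry removed
(keeping the unit diagonal would shrink all profile correlations toward
each other), and the mean running over unordered window pairs — equivalent
to the stated $i \ne j$ mean by symmetry. $V_k \in [0, 2]$, with 0 for
perfectly preserved profiles. Zero-variance profiles and constant regions
within a window produce correlations of 0 with a warning rather than NaN.

$V_k$ is computed for window lengths 10, 12, …, 30 time points (20–60 s at
TR = 2 s) and averaged with equal weights. `windowLengthConsistency`
reports the correlation of the per-region $V$ vector between lengths; on
real recordings this was reported above 0.97, which motivates the
averaging but is not asserted for synthetic data (the suite requires
$r > 0.9$ between adjacent lengths on the state-switching generator).

For group analysis, left-lesion subjects are flipped onto a common
lesion-right orientation by exchanging paired `L_`/`R_` labels
(`flipToLesionRight`, an involution). Subnetwork aggregation takes
unweighted means over six functional subnetworks (sensory-motor,
attention, auditory, visual, default-mode, subcortical). The exact
84-region membership of the original analysis is not public, so
`defaultSubnetworkMap()` ships a synthetic AAL-flavoured stand-in — 42
left/right pairs with the right shape and granularity, clearly documented
as non-canonical; any real mapping can be supplied as JSON.

The pre/post contrast runs a per-region paired t-test across matched
subjects and flags regions at uncorrected $p < 0.01$ — deliberately
uncorrected, as in the source analysis; `adjust = "BH"` enables
Benjamini–Hochberg when a corrected analysis is wanted. The original
voxel-versus-region granularity is ambiguous; the package operates at
region level, which is where its inputs live.

## The synthetic generators

`simulateEEG` superimposes a ~10 Hz mu oscillation (random phase per trial
and channel) on 1/f background noise. ERD is parameterised on the *power*
ratio: task amplitude is `sqrt(erdRatio)` times rest amplitude on the
affected channels, so the expected suppression score is analytic,
$(1 - \mathrm{erdRatio}) \times 100$, and an `erdRatio` of 0.8 should
yield MSS ≈ 20. Defaults — 256 Hz, 6 s segments, mu amplitude five times
the noise SD — keep the in-band noise bias on MSS below one point. The
generator has no artifacts, no volume conduction and no non-stationary
background, so passing tests demonstrate correctness of the computation,
not robustness to real-world EEG contamination.

`simulateBOLD` draws a latent connectivity-state sequence with geometric
dwell times (default mean 30 volumes, the simplest mechanism that yields
controllable profile variability) and generates each volume from a
two-factor model: stable regions keep the same factor and loading sign in
every state, flexible regions receive a state-specific factor and sign, so
their inter-region correlation pattern genuinely changes across states and
their ground-truth variability is higher. Defaults are 84 regions × 230
volumes at TR 2 s. Hemodynamic convolution and measurement drift are not
modelled.

`simulateClinical` draws baselines from N(24, 8²), rounded and clipped to
0–66, and adds per-group change draws (defaults: guided mean +4, sham
mean +1, SD 4 — effect sizes on the order of the MCID). With all change
means at zero it serves as the null generator; the suite checks that the
tie-corrected Friedman and Wilcoxon tests then reject at 0.05 with
empirical rate 0.05 ± 0.02 over 2,000 seeds, i.e. that integer rounding
and the resulting ties do not break the calibration at these sample
sizes.

## Problem sizes and numerical choices

The test suite runs every generator at the study's native scale (100
trials for the suppression-score recovery; 84 × 230 BOLD with 20 seeds for
the flexibility ranking; 50 subjects' worth of 8-session EEG for the
hemispheric DR contrast; 2,000 seeds for the null calibration) and
completes in a few minutes on one CPU. Exact comparisons (the brute-force
variability oracle, filter/Parseval checks, rank-test closed forms) use
small instances where exhaustive evaluation is feasible — 6 regions × 4
windows, $m \le 10$ sign enumerations.

Numerical conventions worth knowing: band boundaries are inclusive at bin
centres; filters error on segments shorter than the warm-up length rather
than silently extrapolating; `fitLDA` errors on single-class input;
`sessionSplit` errors below eight sessions; degenerate rank-test inputs
(all rows constant, all differences zero) raise explicit errors instead of
returning NaN.

## Known limitations

- The subnetwork map is a documented stand-in, not the original
  supplementary table; subnetwork-level numbers on real data will differ
  from the original analysis unless the real map is supplied.
- EEG input is a delimited matrix plus JSON sidecar; EDF files must be
  converted upstream.
- The Scheirer–Ray–Hare behaviour under unbalanced designs follows the
  sequential-ANOVA definition given above; other software may partition
  sums of squares differently, so cross-tool comparisons should fix the
  convention first.
- Repeated-measures ANOVA/MANOVA of the original report are out of scope;
  the package stops at the statistics that are reproducible from its
  inputs.
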