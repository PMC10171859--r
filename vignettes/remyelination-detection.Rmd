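---
title: "Detecting remyelination from serial PDw MRI: models, rules, and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting remyelination from serial PDw MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remyetrack)
```

## The problem

In experimental autoimmune encephalomyelitis (EAE) of the common marmoset —
an induced primate model of multiple sclerosis — focal white-matter lesions
form, demyelinate, and in many cases spontaneously remyelinate over a few
weeks. On proton density-weighted (PDw) MRI normalized to gray matter,
normal-appearing white matter (NAWM) sits in a 0.65–0.75 intensity band;
demyelinated lesions are hyperintense, and remyelination shows as a return
toward isointensity. Because the animals can be scanned weekly and the brains
examined histologically at the end, this system makes it possible to ask
whether conventional serial MRI alone can predict a lesion's myelination
fate. This package implements that analysis end to end: lesion segmentation,
longitudinal linking, trajectory-based three-class categorization, histology
quantification, and the concordance statistics — plus a synthetic-data
generator with known ground truth so that every stage can be validated at
desk scale without any imaging download.

## The classification model

Each lesion track is summarized per scan by its volume (µL) and its mean
GM-normalized PDw intensity. From at least two pre-lesion baseline scans we
estimate the baseline mean $\mu_b$ and SD $\sigma_b$; a timepoint is
**hyperintense** when its mean intensity exceeds
$\mu_b + \max(0.05,\, 2\sigma_b)$, and **isointense** otherwise. The rater
criteria are then applied in order at the terminal scan:

1. hyperintense and gadolinium-enhancing → *early active*;
2. hyperintense, not enhancing → *chronic, at least partially demyelinated*;
3. previously hyperintense, now isointense, not enhancing → *remyelinated*.

Enhancement takes precedence: a terminal-enhancing hyperintense lesion is
early active even if already shrinking, which mirrors how enhancement
separates class 1 from class 2 in the original rater definitions. The
$\max(0.05, 2\sigma_b)$ margin is our operationalization of a criterion the
raters applied qualitatively; both constants are exposed in
`classification_rule_config()`. The 0.05 floor keeps the rule meaningful on
noiseless data (where $\sigma_b = 0$) and roughly matches the half-width of
the NAWM band.

Two derived analyses accompany the classifier. `predict_by_peak_size()`
encodes the empirical size rule — lesions above 0.5 µL at peak do not return
to isointensity — with an inclusive boundary (exactly 0.5 µL still counts as
repair-capable, since the published statement is about lesions *larger than*
0.5 µL). `estimate_remyelination_window()` reads the repair interval off the
trajectory: demyelination starts at the first hyperintense scan,
remyelination at the intensity peak, and the window closes at the first scan
that is isointense and stays isointense; the expected range is 4–9 weeks.

## Segmentation and tracking

The original study segmented lesions with a convolutional network trained on
manually labeled marmoset scans; that model cannot be rebuilt without its
training data, and the claims under test here concern the post-segmentation
logic. We therefore use a transparent segmenter: threshold the GM-normalized
PDw volume at 0.80 inside the white-matter mask (midway between the NAWM
ceiling of 0.75 and the lesion peak range 0.85–1.00), take 26-connected
components, and drop anything smaller than 4 voxels — the same minimum-size
filter the original pipeline applied. Note that at the 0.15 × 0.15 × 1 mm
acquisition resolution one voxel is 0.0225 µL, so the 4-voxel floor is
0.09 µL.

Lesions are linked across consecutive scans when they overlap by at least 4
voxels in 3D; a component overlapping several predecessors goes to the one
with maximal overlap (ties to the smaller label), with the discarded
candidates logged as merge/split events. For scans before first detection,
statistics are taken in a fixed ROI equal to the track's maximum segmented
extent (the published analysis drew this ROI manually; a deterministic rule
replaces the manual step), and the same ROI is propagated after a lesion
disappears, so every track covers every study timepoint. Gadolinium
enhancement is assessed per scan on the post-minus-pre T1 subtraction image:
a lesion is enhancing when its mean subtraction signal exceeds the
non-lesional white-matter mean by more than 3 SD.

## The synthetic generator

`simulate_study()` emulates the study conditions: weekly multicontrast scans
(PDw, T1w pre/post contrast, MT on/off) of a 64 × 64 × 24 grid at
0.15 × 0.15 × 1 mm, with GM/WM reference masks, over 30 timepoints by
default. Lesions are axis-aligned ellipsoids with mild per-axis jitter —
real lesions are irregular, but shape is irrelevant to the trajectory logic
under test. Class proportions default to 30/25/45% (the cohort totals
observed on MRI). Trajectories follow the published phenomenology:

* intensity starts at 0.82 on the onset scan (just above the segmentation
  threshold, so a lesion is detectable from the scan on which it appears,
  matching how "onset" is defined radiologically), rises linearly to a peak
  in 0.85–1.00 over the demyelination phase (4–7 weeks) while the volume
  grows to its peak;
* remyelinating lesions then decay back to baseline as
  $\mu_b + (I_{peak} - \mu_b)(1-u)^{1/4}$ with $u$ the phase fraction over
  the remyelination duration (4–9 weeks), reaching baseline exactly at the
  end of the window. The concave shape keeps the signal detectably elevated
  through the repair period and stabilizes it at baseline at the window's
  end; a straight-line decay would re-enter the isointensity band up to two
  weeks early, making the nominal duration unrecoverable from weekly scans.
  Phase durations are drawn on the scan grid (whole weeks at the default
  weekly interval) for the same reason: weekly sampling cannot resolve
  sub-interval phase lengths;
* remyelinating lesions are constrained to peak volumes ≤ 0.5 µL, the other
  classes may exceed it (peaks are log-uniform in 0.1–3.0 µL; the lower
  bound sits just above the 4-voxel detection floor so that every simulated
  lesion is in principle detectable);
* 82% of new lesions enhance at first detection, occasionally persisting one
  further scan; early-active lesions always enhance at the terminal scan and
  the other two classes never do, reproducing the reported terminal-scan
  behavior;
* the raw PDw scale varies per scan (uniform 150–250 per week) so that
  gray-matter normalization is a real processing step, and Gaussian noise
  (SD 0.01 normalized units by default) is added to every contrast.

Terminal histology truths are drawn per class. Percent-unstained moments
follow the published group statistics (PLP 58 ± 25 / 38 ± 25 / 4.5 ± 1.1 %
for early/chronic/remyelinated, NAWM 2.6 ± 0.3; LFB 63 ± 26 / 43 ± 26 /
15 ± 25, NAWM 3.0 ± 0.4). Oligodendrocyte and OPC counts were published only
as plots, so the generator's count distributions were chosen once to
reproduce the qualitative ordering: mature oligodendrocytes (ASPA+/Olig2+)
average 4 / 3 / 12 per ROI across the three lesion classes and 18 in NAWM
(SD 2–3); OPC (ASPA−/Olig2+) start from class baselines of 10 / 2 / 4 (NAWM
3) and decline with lesion age at 0.12 cells/week (SD 1.5), which yields the
reported negative age–OPC correlation. Iba1 positive-pixel densities are
0.45 / 0.15 / 0.08 (NAWM 0.05), making inflammation a clean separator for
the early-active class.

`render_histology()` inverts the histology quantification: it paints exactly
the right number of null pixels into the PLP/LFB channels (unstained tissue
is encoded as exact zeros, matching the null-pixel thresholding readout) and
places disc-shaped, non-touching cell marks into the ASPA/Olig2 channels so
that connected-component counting is exact. Cells sit on a jittered grid
with guaranteed separation; requesting more cells than the grid can hold is
an error rather than a silent overlap.

### What the generator does *not* emulate

No registration misalignment, bias fields, motion, partial-volume effects,
irregular lesion shapes, confluent or spinal-cord lesions, or realistic
anatomy. Passing the recovery tests therefore shows that the
post-segmentation logic — linking, trajectory classification, window
estimation, quantification, statistics — is correct under the stated signal
model; it does not show that the thresholds would transfer unchanged to real
scanner data, where segmentation quality would dominate.

## Histology quantification and categorization

Demyelinated area is the percentage of exactly-null pixels in the ROI.
The published ROI is described as "1500 µm²", which taken literally is a
~38.7 µm square — too small to "include even the biggest lesion" as the same
text requires. We read it as a 1500 µm-side square by default and expose the
literal-area reading as a switch in `roi_from_center()`. Cells are connected
components of Olig2-positive pixels; a cell at least 50% covered by
ASPA-positive pixels counts as a mature oligodendrocyte, otherwise as an
OPC (the published workflow thresholded in FIJI without stating its overlap
logic; 50% is our rule, exposed as a parameter). Histological categories:
remyelinated iff PLP unstained ≤ 6% (the published cutoff) *and* mature
oligodendrocytes ≥ 6 (above the chronic-class mean); otherwise early active
iff the Iba1 density ≥ 0.3 (prominent infiltration), else chronic. A lesion
remyelinated on PLP but > 20% unstained on LFB is classified by PLP and
flagged discordant — preserving, rather than resolving, the ambiguity of the
one published lesion with exactly that pattern.

## Concordance statistics

For radiological–pathological comparison the three classes collapse to
demyelinated vs remyelinated, with remyelination as the positive class:
sensitivity $tp/(tp+fn)$, specificity $tn/(tn+fp)$. On the published 2×2
table (19/3/0/9) sensitivity is 100% while the table-derived specificity is
19/22 ≈ 86.4%; the stated 90% matches the overall accuracy 28/31 ≈ 90.3%,
so `concordance_summary()` prints both and flags the discrepancy instead of
silently adopting either number. Cohen's kappa uses the standard
$(p_o - p_e)/(1 - p_e)$ form (cross-checked in the tests against an
independent implementation). The corticosteroid analysis uses the
point-biserial correlation with the t-transform p-value; because both
variables are binary, the exact permutation distribution is hypergeometric,
and `point_biserial_exact_p()` computes that exact two-sided tail as an
oracle. The t-test defaults to Welch's unequal-variance form (the published
methods say only "two-sample t-test"; a pooled-variance flag is provided),
ANOVA is the classic one-way fixed-effects test, and no multiple-testing
correction is applied, matching the original analysis.

## Numerical choices and degenerate inputs

* Connected components use 26-connectivity (the original text is silent);
  6/18 are available. Labels are deterministic: descending size, then
  lexicographic centroid.
* Normalization requires a nonempty GM mask with positive mean and is
  idempotent to 1e-9; segmentation warns if its input's GM mean is off 1 by
  more than 0.05.
* MTR guards division by |M0| ≤ eps (default 1e-8) with NA.
* Tracks need ≥ 2 baseline scans (the generator always reserves them); a
  track that is never hyperintense is rejected as "not a lesion track"
  rather than silently categorized.
* A lesion whose entire life is ROI-propagated (never segmented) is an error
  for the size rule.
* Enhancement detection with a single-voxel background falls back to a
  mean-only comparison (SD undefined).

## Problem sizes used in the checks

The validation suite runs entirely on synthetic data sized for a desk run:
recovery cohorts of 25 subjects × 8 lesions (200 lesions) at noise SD 0.01
and 0 for classification accuracy; 3 × 8 noiseless remyelinating lesions for
window recovery; 100 random truths for the histology round trip; 250–1000
random small instances per brute-force oracle; and 1000 null simulations for
test calibration. These sizes give tight Monte-Carlo error on every rate
reported while keeping a full run in the low minutes on one core.

## Known limitations

The segmenter is intentionally simple and would not replace a trained model
on real data. The trajectory model is piecewise-deterministic with additive
Gaussian noise; real lesions show partial, edge-dominant remyelination and
intensity fluctuations that weekly means smooth over. MTR volumes are
generated and computed but not used for categorization: the published
MTR-arm criteria were rater-based and not specified reproducibly, so that
arm's sensitivity/specificity (82%/79%) is out of scope. The interrater
agreement figures (94%, kappa 0.89) depend on unpublished per-lesion rater
tables; kappa is therefore exercised on simulated raters only.
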