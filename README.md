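# remyetrack

Detecting and characterizing **remyelination** of focal white-matter lesions
from serial proton density-weighted (PDw) brain MRI, modeled on longitudinal
7 T imaging of experimental autoimmune encephalomyelitis (EAE) in the common
marmoset — a primate model of multiple sclerosis in which lesions
demyelinate and often spontaneously remyelinate within weeks.

## Who this is for

Researchers analyzing serial small-animal (or, with adaptation, human) MRI
of focal demyelinating lesions who want a transparent, fully testable
implementation of trajectory-based lesion-fate classification and its
validation against histology.

## What it computes

On PDw volumes normalized so mean gray-matter signal = 1, normal-appearing
white matter (NAWM) lies at 0.65–0.75 and demyelinated lesions are
hyperintense. The package:

* **segments** lesions by thresholding (default 0.80) inside the WM mask,
  26-connected components, dropping components < 4 voxels (0.09 µL at
  0.15 × 0.15 × 1 mm);
* **tracks** lesions across weekly scans (linked when 3D overlap ≥ 4
  voxels), propagating a fixed max-extent ROI before lesion onset and after
  disappearance so every track covers every timepoint;
* **classifies** each track against its pre-lesion baseline (mean µ_b, SD
  σ_b; hyperintense ⇔ intensity > µ_b + max(0.05, 2σ_b)) into
  *early active* (terminal hyperintensity + gadolinium enhancement),
  *chronic demyelinated* (terminal hyperintensity, no enhancement), or
  *remyelinated* (return to isointensity, no enhancement); estimates the
  remyelination window from the intensity peak to the isointense plateau;
  and applies the 0.5 µL peak-size rule;
* **quantifies histology**: percent unstained (null-pixel) area on PLP/LFB,
  ASPA+/Olig2+ oligodendrocyte vs ASPA−/Olig2+ OPC counts, Iba1 density,
  and a rule-based histological category;
* **measures concordance**: 2×2 confusion matrix (positive class =
  remyelination), sensitivity tp/(tp+fn) and specificity tn/(tn+fp),
  Cohen's kappa, point-biserial correlation (with an exact
  hypergeometric-permutation oracle), Pearson correlation, Welch t-test and
  one-way ANOVA;
* **simulates** complete studies — multicontrast weekly volumes (PDw,
  T1w±gadolinium, MT on/off), masks, lesion trajectories, and terminal
  stain images — with known ground truth, so the whole chain is testable
  without any imaging download.

MTR maps, (M0 − MSAT)/M0, and T1 subtraction images are computed voxelwise.

## Worked example

```r
library(remyetrack)

# published worked example: lesion-level MRI vs histology concordance
rc <- reported_concordance(published_specificity_pct = 90)
print(reported_lesion_tables()$confusion)
#>               MRI
#> histology      demyelinated remyelinated
#>   demyelinated           19            3
#>   remyelinated            0            9
rc$concordance$sensitivity_pct   # 100
rc$concordance$specificity_pct   # 86.36364  (19/22; published value is 90)
rc$concordance$note
#> "table-derived specificity 86.4% differs from the published 90.0%; overall accuracy is 90.3%"

# synthetic end-to-end round trip
study <- simulate_study(simulation_config(seed = 3, n_lesions = 6))
res <- analyze_study(study$timeline)
res$labels[, c("track_id", "category", "peak_volume_ul",
               "remyelination_duration_weeks")]
#>   track_id             category peak_volume_ul remyelination_duration_weeks
#> 1        1         remyelinated         0.2925                            9
#> 2        2 chronic_demyelinated         0.5175                           NA
#> 3        3         remyelinated         0.2025                            8
#> 4        4         remyelinated         0.3825                            8
#> 5        5         early_active         0.1125                           NA
#> 6        6         early_active         0.7875                           NA
```

Every lesion's MRI category matches the generator's ground truth, the
remyelinated lesions all peak below 0.5 µL, and their estimated repair
windows sit in the expected 4–9 week range.

The numbered scripts under `analysis/` run the full study as a narrative:
`01_reported_tables.R` (published worked examples), `02_simulate_cohort.R`
(synthetic cohort + classification accuracy), `03_trajectory_recovery.R`
(remyelination-window recovery and the size rule), `04_histology_roundtrip.R`
(stain rendering/quantification round trip), `05_statistical_checks.R`
(test calibration). Each writes its tables under `results/`.

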