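# cyclogait

Dynamic centre-of-pressure (COP) cyclogram diagnostics for dual-insole gait
recordings, aimed at screening for balance-impairing conditions such as
diabetic peripheral neuropathy (DPN).

Pressure-sensitive insoles record, for each foot, the vertical force and the
COP position over repeated steps. Combining both feet with force weighting,

    x_C = (F_R x_R + F_L x_L) / (F_R + F_L)   (same for y_C),

gives the *cyclogram* (butterfly diagram): the combined COP follows one
foot's gait line during single support and jumps diagonally to the other
foot during double support; the diagonals cross near the midline. The
package detects gait events from the force traces, extracts ten marker
points per stride — gait-line endpoints E (rearmost) and A (frontmost) per
foot, single-support endpoints D (contralateral toe-off) and B
(contralateral heel strike), and the two transfer crossings C — and derives
15 parameters per dataset: the gait line AE, the single-support line BD,
marker positions, the distances AB, BC, CD, DE, the ratios Ra = BC/AB and
Rp = CD/DE, and a scatter-based **Balance Index**

    BI = sum over zones A..E of (sigma_x sigma_y)_left + (sigma_x sigma_y)_right,

optionally rescaled so its optimal diagnostic threshold sits at BI = 100.

Cohort-level classifier evaluation follows the rank-statistics identities:
with S = U/(n1 n2) from the Mann–Whitney U (smaller orientation), the effect
size is r = 1 − 2S and the AUC is 1 − S = (1 + r)/2. Parameters with large
effects (r > 0.37) get an ROC sweep, the optimal threshold at the maximum of
√(TPR·TNR), and confusion percentages.

Because raw insole recordings of this kind are rarely public, the package
includes a synthetic gait generator (`generate_study()`) that produces
two-cohort 50 Hz recordings with planted marker geometry and scatter and
full ground truth, which the test suite uses for end-to-end recovery checks.

## Worked example

Simulate the default 126-dataset study (56 impaired over 14 participants,
70 healthy over 15), run the full pipeline on the generated recordings and
compare the cohorts:

```r
library(cyclogait)
study  <- generate_study(study_spec(), seed = 1, mode = "recording")
params <- study_parameters(study)
cmp <- compare_cohorts(params[params$cohort == "diabetic", ],
                       params[params$cohort == "healthy", ])
cmp
```

```
<cohort_comparison> 56 positive vs 70 negative datasets; BI scale 181470
   parameter median_pos median_neg    U     S       p     r     effect   auc
1         AE      0.802      0.839    0 0.000 6.6e-22 1.000      large 1.000
...
9         AB      0.127      0.027 3920 0.000 6.6e-22 1.000      large 1.000
10        BC      0.194      0.286    0 0.000 6.6e-22 1.000      large 1.000
13        Ra      1.541     10.492    0 0.000 6.6e-22 1.000      large 1.000
15        BI    179.099     53.979 3917 0.001 7.6e-22 0.998      large 0.999
   orientation threshold tp_pct fn_pct tn_pct fp_pct     se     sp
9         high     0.078 100.00   0.00 100.00   0.00 100.00 100.00
13         low     4.396 100.00   0.00 100.00   0.00 100.00 100.00
15        high   100.000  98.21   1.79 100.00   0.00  98.21 100.00
```

Reading the table: the impaired cohort's cyclogram collapses — its AB
(forefoot distance) median is 0.127 insole lengths versus 0.027 for the
healthy cohort, and Ra drops from ~10.5 to ~1.5 — so AB and Ra separate the
planted cohorts completely (AUC = 1 at this scatter level). The Balance
Index medians (179 vs 54, in calibrated units where the optimal threshold
is exactly 100) show the impaired cohort's larger marker scatter.
Parameters whose effect size is not large (here lat C) get no threshold or
confusion columns. Medians recover the planted template geometry (healthy
AB = 0.027, BC = 0.288; impaired AB = 0.126, BC = 0.193) to within a few
percent.

File-based runs use the same machinery: `run_simulate()`, `run_extract()`
and `run_compare()` work on directories of CSV recordings with a
`manifest.csv`, writing `parameters.csv` and `report.json`/`report.csv`; a
thin command-line wrapper is in `inst/scripts/cyclogait`.

## Package layout

| file | contents |
| --- | --- |
| `R/io.R` | recordings, sensor-frame conversion, normalization, CSV/JSON/YAML |
| `R/gait_events.R` | stance detection, cycle assembly, step validation |
| `R/cyclogram.R` | combined COP, marker extraction, transfer intersections |
| `R/parameters.R` | cluster statistics, Balance Index, geometry parameters |
| `R/cohort_stats.R` | Mann–Whitney/effect size/AUC, ROC, thresholds, correlations |
| `R/synthetic.R` | cohort templates, recording and study generators |
| `R/pipeline.R` | simulate → extract → compare orchestration |

The methods vignette (`vignettes/cop-cyclogram-diagnostics.Rmd`) documents
the models, parameter choices and limitations in detail.
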