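# diamus — diaphragm motion from ultrasound cine loops

`diamus` quantifies cranio-caudal hemidiaphragm movement from B-mode
ultrasound cine loops. It is written for respiratory/POCUS researchers who
want to evaluate the **Area method** — a whole-dome motion measure — against
the two established single-point measurements, on data with known ground
truth.

With the transducer fixed, the borders of the ultrasound window do not move
during a breath, so a traced diaphragm contour can be closed with the image
borders and the enclosed supradiaphragmatic ("intra-thoracic") area computed
by the shoelace formula. The Area method measures

&nbsp;&nbsp;&nbsp;&nbsp;ΔA = A(maximal diaphragm contraction) − A(minimal diaphragm contraction),

where maximal contraction (end-inspiration) is the frame with the largest
enclosed area. The comparators are **M-mode excursion** (range of the bright
interface depth along a fixed scan line, with sub-pixel peak refinement and
temporal tracking) and **B-mode apex displacement** (range of the dome top's
depth). For a pure piston motion the three coincide: ΔA / window width =
excursion = displacement.

The package contains five building blocks:

* **measurement** — `dia_contour`, `area_above_contour`,
  `extrapolate_contour` (continues partially visible traces to the borders),
  `select_extreme_frames`, `delta_area`, `m_mode_excursion`,
  `b_mode_apex_displacement`.
* **phantom** — a circular-arc dome with analytic ground truth
  (`dome_model`, `true_delta_area`, `true_volume`), rendered as speckled
  B-mode-like cine loops (`render_cine`), plus a cohort simulator
  (`simulate_cohort`) with tracing noise, rater noise and an
  accessory-muscle volume term.
* **detection** — `detect_contours`, a semi-automatic column-wise
  bright-interface tracer standing in for manual tracing.
* **stats** — `spearman_ci` (Fisher-z CI, exact permutation p at small n),
  `split_by_mean` (low/high volume strata), `icc_oneway` (ICC(1,1)),
  `clopper_pearson` (exact binomial CI), `study_report`.
* **io / CLI** — TIFF/PNG cine stacks with mandatory YAML calibration
  sidecars, contour JSON in cm, study-table CSV, and a command-line
  interface (`inst/cli/diamus.R`) with `simulate`, `measure`, `stats` and
  `rater-study` subcommands.

## Worked example

Render one phantom breath (4 cm excursion), detect the diaphragm, and
measure it with all three methods:

```r
library(diamus)
model    <- dome_model(amplitude = 4)   # circular-arc dome, 4 cm excursion
out      <- render_cine(model, breath_cycle(11), render_config(seed = 42))
contours <- detect_contours(out$clip)

delta_area(out$clip, contours)
#> <area_result> delta A = 47.8 cm^2 (max 90.2 @ frame 6, min 42.4 @ frame 1)
m_mode_excursion(out$clip, out$truth$mmode_line)
#> <excursion_result> M-mode excursion = 40 mm over 11 frames
b_mode_apex_displacement(out$clip, contours)
#> <apex_result> B-mode apex displacement = 40 mm over 11 frames
```

The analytic truth for this clip is ΔA = 48 cm² (12 cm window × 4 cm rigid
translation), measured as 47.8 cm² from the rendered pixels (0.4% off);
end-inspiration is correctly found at mid-breath (frame 6 of the
raised-cosine cycle), and both single-point methods recover the 40 mm
excursion exactly at report granularity.

Simulate a 20-subject × 4-breath validation cohort (tracing noise 0.15 cm,
two raters, accessory muscles engaging above 80% effort) and run the study
battery:

```r
sim <- simulate_cohort(cohort_spec(n_subjects = 20, n_breaths = 4,
                                   accessory_gain = 1.5, sigma_rater = 0.15,
                                   seed = 1))
study_report(sim$table, ratings = sim$ratings,
             proportions = data.frame(label = c("left mid-clavicular",
                                                "left mid-axillary"),
                                      k = c(2, 10), n = c(10, 10)))
#> == Correlation with expired volume (Spearman) ==
#>   area   r_s = 1.00 (95% CI 1.00-1.00), p = 1.88e-92, n = 80
#>   ...
#> == Mean-split subgroup correlations ==
#>   area   low  volume (cut 0.38 l): r_s = 0.99 (95% CI 0.99-1.00), p = 4.23e-41, n = 44
#>   area   high volume (cut 0.38 l): r_s = 0.99 (95% CI 0.97-0.99), p = 4.32e-28, n = 36
#>   ...
#> == Inter-rater agreement, one-way ICC(1,1) ==
#>   area   ICC = 1.00, p = 1.22e-94 (80 targets, 2 raters)
#>   ...
#> == Feasibility (exact binomial CIs) ==
#>   left mid-clavicular          2/10 =  20% (95% CI 0.03-0.56)
#>   left mid-axillary            10/10 = 100% (95% CI 0.69-1.00)
```

Measurements track the exhaled-volume analog almost perfectly, the
high-volume stratum correlates systematically worse than the low-volume one
once accessory muscles contribute volume the diaphragm cannot see (the gap
widens with `accessory_gain`), and the exact binomial CIs for the
feasibility counts are reproduced, e.g. 2/10 → 20% (0.03–0.56).

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/diamus.R simulate --seed 7 --out runs/sim --clips 2
Rscript inst/cli/diamus.R measure  --input runs/sim/demo_01.tif \
        --contours runs/sim/demo_01_contours.json --method all --out runs/res.csv
Rscript inst/cli/diamus.R stats    --table runs/sim/study_table.csv --out runs/report
```

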