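# proxigap

Interproximal contact morphometry and food-impaction risk analysis for
molar pairs.

Food impaction — food wedging into the space between adjacent teeth under
chewing pressure — occurs even at clinically *tight* proximal contacts
(admitting less than a 60 µm feeler gauge), and which contacts impact is
largely a question of local geometry. `proxigap` is for dental researchers
working with segmented 3D surface scans of first/second molar pairs. It
measures five morphometric features of the interproximal region and runs the
statistical workflow that links them to impaction status:

* **adjacent line length** *L* (mm) — span of the contact boundary in
  occlusal projection;
* **adjacent surface area** *A* (mm²) — area of the contact facet on the
  vertical partition plane;
* **tongue, buccal and occlusal abduction-gap angles** *θ<sub>t</sub>,
  θ<sub>b</sub>, θ<sub>o</sub>* (°) — three-point opening angles of the
  lingual, buccal and occlusal embrasures.

The analysis chain mirrors the clinical study design: normality description
(Shapiro–Wilk, Lilliefors-corrected KS), Welch *t*-tests between impaction
and non-impaction groups, Spearman correlations, correlation-matrix PCA with
Kaiser retention (eigenvalue > 1) and iterative communality screening
(items below 0.4 dropped), binary logistic regression with Wald χ², odds
ratios and 95% CIs, and a fixed published risk scorer

```
logit(p) = 0.889 L + 3.396 A − 0.071 θ_b − 0.089 θ_o − 19.797
```

Because clinical scans cannot be redistributed, the package ships a
synthetic generator: superellipse-prism molar pairs meeting at a flat
contact facet with chamfered embrasures, so every feature has an analytic
ground truth, plus a cohort table simulator parameterised by the published
per-group means and SDs.

## Worked example

```r
library(proxigap)

# a synthetic molar pair at the reference contact morphology, 0.02 mm jitter
pair <- generate_tooth_pair(tooth_pair_spec(seed = 3))
pair$truth
#>   adjacent_line_length_mm adjacent_surface_area_mm2 tongue_angle_deg
#> 1                    3.52                      6.21            52.24
#>   buccal_angle_deg occlusal_angle_deg
#> 1            54.15              89.26

score_features(measure_all(pair$cloud))
#>   adjacent_line_length_mm adjacent_surface_area_mm2 tongue_angle_deg
#> 1                3.525369                  6.280773         52.72938
#>   buccal_angle_deg occlusal_angle_deg risk_probability
#> 1         54.97328           90.73484     0.0006670722
```

The measured features recover the ground truth to about 1% despite the
jitter, and the published model scores this reference morphology at a risk
of 6.7 × 10⁻⁴ — it is the low-risk contact geometry.

```r
cohort <- generate_cohort(published_groups(250), seed = 1)
run_full_analysis(cohort)
#> <impaction_report> n = 250 impaction / 250 nonimpaction
#>
#> Group comparison (welch t-test):
#>                    feature       t        p significant
#>    adjacent_line_length_mm  -9.949 2.83e-21        TRUE
#>  adjacent_surface_area_mm2 -13.047 1.58e-33        TRUE
#>           tongue_angle_deg   4.117 4.49e-05        TRUE
#>           buccal_angle_deg   2.850 4.56e-03        TRUE
#>         occlusal_angle_deg  16.758 1.89e-46        TRUE
#>
#> PCA screening retained: adjacent_line_length_mm,
#>   adjacent_surface_area_mm2, occlusal_angle_deg
#>
#> Logistic fit on retained items:
#> <logistic_model> converged in 6 IRLS iterations
#>                       term estimate     se wald_chi2 p      OR ...
#>    adjacent_line_length_mm   0.7678 0.1363   31.7301 0  2.1551
#>  adjacent_surface_area_mm2   2.6083 0.3367   60.0133 0 13.5758
#>         occlusal_angle_deg  -0.0692 0.0076   82.2605 0  0.9331
```

Length, area and the occlusal angle separate the groups at p < 0.001; the
tongue and buccal angles, whose group contrast is small, only reach
significance at this full sample size (at 50 per group they mostly do not —
the test suite checks both regimes). PCA on independently drawn features
retains fewer items than on real, correlated data; a correlation matrix can
be passed to `generate_cohort()` to emulate that structure.

An end-to-end run (simulate pairs per group → measure → analyse → score,
with a file manifest) is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, n_per_group = 20,
                                    out_dir = "run"))
```

A thin command-line wrapper with `simulate-teeth`, `simulate-cohort`,
`measure`, `analyze`, `score`, `run` and `validate` subcommands is installed
at `inst/cli/proxigap.R`.

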