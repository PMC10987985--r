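# craniospring

Finite-element simulation of spring-assisted cranioplasty (SAC) outcomes in
sagittal craniosynostosis, at desk scale.

Sagittal craniosynostosis fuses the sagittal suture of the newborn skull,
producing a long, narrow head (scaphocephaly). SAC treats it by cutting two
parasagittal osteotomies and inserting compressed metallic springs that
expand over the following weeks, widening the head. The outcome is tracked
with the cranial index

&nbsp;&nbsp;&nbsp;&nbsp;CI = BPD / OFD,&nbsp;&nbsp;&nbsp;ΔCI(t) = 100·(CI(t) − CI(0)) percentage points,

where BPD (biparietal diameter) is the maximal skull width and OFD
(occipitofrontal diameter) the maximal length. The package is aimed at
computational biomechanics researchers and surgical planners who want to
ask: *which surgical choices — osteotomy distance (LAT), spring positions
(A, B) and spring stiffnesses (K_ANT, K_POST) — drive the reshaping, and
when?*

It provides, as composable tidyverse-style functions:

* a **parametric synthetic scaphocephalic calvarium** with labelled
  frontal/suture/parietal/occipital regions, parasagittal osteotomy cracks
  and spring notch sets (`skull_params()`, `generate_skull()`,
  `apply_osteotomies()`);
* a **quasi-static viscoelastic FE solver** with the Prony shear
  relaxation law G(t)/G0 = α∞ + Σ αᵢ·exp(−t/τᵢ) and linear spring
  distractor conditions F = K·(OP∞ − opening) (`material_model()`,
  `spring_model()`, `solve_expansion()`);
* **craniometric outcomes** (`measure_bpd_ofd()`, `compute_ci()`,
  `cranial_measurements()`, `normalize_surgical()`);
* an **optimal space-filling design of experiments** over the five
  surgical parameters with quadratic response surfaces, signed local
  sensitivities S_i = 100·[f(upᵢ) − f(lowᵢ)]/f(mid) and spring-position
  optimum maps (`build_design()`, `run_design()`,
  `fit_response_surface()`, `local_sensitivity()`, `optimum_map()`);
* **synthetic clinical cohorts** emulating the X-ray (n = 42) and 3D-scan
  (n = 20) retrospective groups, with trend fitting and sign-level
  comparison against the simulated design space (`cohort_spec()`,
  `synthesize_cohort()`, `fit_trend()`, `compare_trends()`).

Results come back as tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Simulate the population-mean configuration — LAT = 18.3 mm, anterior
spring 47.9 mm and posterior spring 74.1 mm behind the coronal suture,
two mid-stiffness S12 springs (K = 0.39 N/mm, free length 57.3 mm):

```r
library(craniospring)

sk <- generate_skull(skull_params())
measure_bpd_ofd(sk)
#>   bpd_mm   ofd_mm
#> 108.1668 152.6000

cut <- apply_osteotomies(sk, osteotomy_spec(lat_mm = 18.3,
                                            a_mm = 47.9, b_mm = 26.2))
res <- solve_expansion(cut, material_model(),
                       list(anterior = spring_model("S12"),
                            posterior = spring_model("S12")))
cranial_measurements(res)
#> # A tibble: 3 × 5
#>   time_s bpd_mm ofd_mm    ci delta_ci_points
#>    <dbl>  <dbl>  <dbl> <dbl>           <dbl>
#> 1      1   110.   153. 0.724            1.53
#> 2  86400   114.   153. 0.744            3.54
#> 3 432000   114.   153. 0.747            3.85

tidy(res)
#> # A tibble: 6 × 4
#>   time_s spring    opening_mm force_N
#>    <dbl> <chr>          <dbl>   <dbl>
#> 1      1 anterior        32.9   9.52
#> 2      1 posterior       33.4   9.31
#> 3  86400 anterior        50.9   2.49
#> 4  86400 posterior       51.6   2.21
#> 5 432000 anterior        55.4   0.743
#> 6 432000 posterior       55.7   0.635
```

Reading the numbers: the springs jump from their 18.3 mm insertion opening
to ~33 mm on the table (immediate post-operative, t = 1 s), then relax the
skull open to ~97% of their free length by day 5 while their force decays
from ~9.5 N to under 1 N. The cranial index gains 1.5 points on the table
and 3.9 points by follow-up — inside the clinically reported bands
(day 1: 3.4 ± 2.5; follow-up: 4.4 ± 2.5 points).

The parametric study chains the same pieces:

```r
design <- build_design(parameter_ranges(), n_points = 79, seed = 1)
study  <- run_design(design)
rs     <- fit_response_surface(study)
local_sensitivity(rs)              # signed sensitivity per parameter/time
autoplot(local_sensitivity(rs))    # the sensitivity bar chart
autoplot(optimum_map(rs, "dci_followup"))  # ΔCI over the (A%, B%) plane
```

On this synthetic skull the study reproduces the published pattern:
spring stiffness dominates the on-table reshaping (sensitivities ≈ +38%
each, versus single digits for the positions), then fades to single digits
by follow-up, while osteotomy distance stays adverse throughout (≈ −9% to
−19%) and the spring positions turn beneficial (+6% and +18% at
follow-up); the optimal spring-position combination migrates distally
between post-op and follow-up.

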