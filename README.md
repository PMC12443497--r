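# stickyhab

Two-stage habitat suitability modelling for phytophilic (sticky-egg)
spawning fish — carp, crucian carp and their guild — in reservoir
tributaries whose water levels are drawn down during the spawning season.

Conventional habitat models score *spawning* habitat from hydraulic
preferences alone. For adhesive eggs laid on littoral vegetation that is
not enough: the eggs sit fixed at their deposition depth for the ~5 days
from spawning to free-swimming, and any water-level recession below them is
lethal. `stickyhab` therefore scores the two reproductive stages
separately:

- **Spawning HSI** per mesh cell *i* from trapezoidal suitability curves
  for velocity, depth and temperature:
  `HSI_i = (SI_V · SI_H · SI_T)^(1/3)`
- **Hatching HSI** adds a water-level-fluctuation suitability index:
  `HSI_i = (SI_V · SI_H · SI_T · SI_L)^(1/4)`
  (a plain-product mode is also available; see the methods vignette)
- **SI_L(d) = 1 − F(d)**, the fraction of eggs *not* stranded by a
  cumulative 5-day drop *d*, where *F* is the cumulative egg-deposition
  depth distribution from a binned field survey (163 observations, 0–0.8 m,
  shipped as `egg_depth_reference()`). The realized drop on spawning day
  *t* is `D(t) = max(0, L(t) − min(L(t+1), …, L(t+5)))`.
- **WUA = Σ A_i · HSI_i**, the weighted usable area (m²), plus
  five-class suitability area tables, per stage and date.
- Inverting the curve gives regulation advice: the fastest constant decline
  whose 5-day total stays below the zero-suitability drop
  (`max_sustainable_daily_decline()`).

Synthetic generators for stage regimes (pre-/post-impoundment), 2-D
hydraulic fields, egg-depth samples and larvae-density series make the full
pipeline runnable and testable with no external data, and validation
diagnostics (lagged Pearson correlation, Monte-Carlo egg-cohort survival)
check the model against simulated observations.

## Worked example

```r
library(stickyhab)

curve <- make_drawdown_curve(egg_depth_reference())
evaluate_curve(curve, c(0, 0.2, 0.5, 0.8))
#> [1] 1.0000000 0.9938650 0.4539877 0.0000000
max_sustainable_daily_decline(curve, window_days = 5)
#> [1] 0.16
```

A zero drop strands nothing (SI_L = 1); a 0.2 m drop affects only the
single shallowest clutch of the 163 (SI_L ≈ 0.994); a 0.5 m drop strands
89 of 163 clutches (SI_L ≈ 0.454); at 0.8 m — the deepest deposition —
suitability reaches 0. Spreading that 0.8 m over the 5-day window gives the
0.16 m/day regulation threshold.

Running the drawdown regime against a synthetic post-impoundment May:

```r
stage <- gen_stage_series(regime_spec("post_dam"), "2019-05-01", "2019-05-20", seed = 1)
sl <- si_l_series(stage, curve)
head(sl, 3)
#> # A tibble: 3 × 3
#>   date       drop_5d_m  si_l
#>   <date>         <dbl> <dbl>
#> 1 2019-05-01      1.55     0
#> 2 2019-05-02      1.56     0
#> 3 2019-05-03      1.54     0

field <- gen_hydro_field(field_spec(n_cells = 1000), "2019-05-01", seed = 1)
sm <- habitat_summary(field, sl[1:3, ], mode = "product")
sm[, c("date", "wua_spawn_m2", "wua_hatch_m2", "wua_reduction_pct")]
#> # A tibble: 3 × 4
#>   date       wua_spawn_m2 wua_hatch_m2 wua_reduction_pct
#>   <date>            <dbl>        <dbl>             <dbl>
#> 1 2019-05-01        1032.            0               100
#> 2 2019-05-02        1032.            0               100
#> 3 2019-05-03        1032.            0               100
```

A mean decline of 0.32 m/day makes every 5-day drop exceed 0.8 m, so
hatching habitat vanishes even though ~1000 m² of this small demo mesh
remains hydraulically suitable for spawning — the "high spawning potential,
low hatching realization" mismatch the two-stage model exists to expose.
Under the stable pre-impoundment regime the same pipeline leaves hatching
WUA at or near spawning WUA.

The validation diagnostic on synthetic monitoring data:

```r
pre <- si_l_series(gen_stage_series(regime_spec("pre_dam"),
                                    "2019-04-01", "2019-05-31", seed = 1), curve)
den <- gen_larvae_density(pre, seed = 1)   # lagged signal + lognormal noise
lagged_pearson(pre, den, lag_days = 5)
#> $r 0.642   $n 56   $p 9.7e-08
```

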