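# enzlim

Vector analysis of extracellular enzyme stoichiometry for microbial
metabolic limitation in lake sediments.

## The problem

Sediment microbes secrete extracellular enzymes to liberate the resources
that limit their metabolism. The activities of the five commonly assayed
hydrolases group by the element they acquire:

* **C acquisition** — β-1,4-glucosidase (BG) + cellobiohydrolase (CBH)
* **N acquisition** — β-N-acetyl-glucosaminidase (NAG) + leucine
  aminopeptidase (LAP)
* **P acquisition** — phosphatase (AP)

Relative investments are summarised by two proportions,

```
x = C / (C + P)        y = C / (C + N)
```

and the point (x, y) is read as a vector:

```
VL = sqrt(x^2 + y^2)              (vector length: relative C limitation)
VA = degrees(arctan(y / x))       (vector angle: N vs P limitation)
```

`VA > 45°` indicates phosphorus limitation, `VA < 45°` nitrogen
limitation; departures of the pooled C:N:P activity ratio from the global
~1:1:1 reference tell the same story at cohort level. `enzlim` implements
this analysis end-to-end for a two-region lake-sediment survey — regional
ANOVA, the vector statistics, Shannon/Bray–Curtis community diversity,
permutation Mantel tests, and driver screening by Pearson correlation,
forward-stepwise OLS and permutation importance — plus a calibrated
synthetic cohort generator so the whole pipeline is testable without field
data. Functions take data frames and return tibbles, so stages chain with
the pipe.

## Worked example

```r
library(enzlim)

cfg     <- cohort_config(seed = 1)        # 10 SXK + 20 LXK sites
samples <- simulate_cohort(cfg)
vec     <- limitation_table(samples)
head(tibble::as_tibble(vec), 4)
#> # A tibble: 4 × 7
#>   sample_id region     x     y length angle_deg class
#>   <chr>     <chr>  <dbl> <dbl>  <dbl>     <dbl> <fct>
#> 1 SXK_001   SXK    0.624 0.580  0.852      42.9 N_LIMITED
#> 2 SXK_002   SXK    0.799 0.780  1.12       44.3 N_LIMITED
#> 3 SXK_003   SXK    0.671 0.435  0.799      33.0 N_LIMITED
#> 4 SXK_004   SXK    0.448 0.418  0.613      43.1 N_LIMITED

limitation_summary(vec)
#> # A tibble: 1 × 7
#>       n n_defined p_limited_fraction mean_length mean_angle slope_va_on_vl
#>   <int>     <int>              <dbl>       <dbl>      <dbl>          <dbl>
#> 1    30        30              0.733       0.588       59.7          -38.3
```

73% of the sites sit above the 45° diagonal (phosphorus-limited), the
mean angle of ~60° confirms P limitation dominates, and the negative
slope of angle on length shows nutrient limitation easing where carbon
limitation intensifies. `autoplot(vec)` draws the investment plane with
the 1:1 diagonal.

The cohort-level stoichiometry and driver screen follow the same
data-frame-in, tibble-out pattern:

```r
stoich_summary(samples)                      # pooled C:N:P, C normalised to 1
comms <- simulate_communities(samples, cfg)  # bacterial + fungal OTU tables
run_pipeline(samples, bacteria = comms$bacteria, fungi = comms$fungi,
             outdir = "results/run1", seed = 1)
```

`run_pipeline()` writes one delimited file per stage (vector results,
diversity, Bray–Curtis matrices, correlations, Mantel tests, stepwise
selection, permutation importances) plus a `manifest.json` with the seed
and per-file checksums; re-running with the same seed reproduces the
numeric payloads exactly. A thin command-line front end with `simulate`,
`run`, `vectors`, `diversity` and `mantel` subcommands is installed under
`inst/cli/enzlim`.

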