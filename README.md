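# matesite

Analysis of long-term monitoring data from an elasmobranch courtship and
mating ground.  The package is written for movement ecologists and
reproductive demographers working with passive acoustic telemetry and
multi-method mark–resight records: it turns raw detection streams into
visits and arrival–departure bouts, builds multi-year return histories,
classifies biennial/triennial reproductive cycles, projects lifetime
reproductive output, and supplies the statistical machinery (rank tests, a
two-sample Anderson–Darling test, separation-robust Bayesian-regularized
GLMMs) to compare the sexes.  A synthetic-data generator with full ground
truth makes every stage testable without field data.

## Methods at the core

**Segmentation.**  For one shark's sorted detection times
$t_1 < t_2 < \dots$, a *visit* is a maximal run with
$t_{i+1} - t_i < g_v$ for all internal pairs ($g_v$ = 60 min), and a
*presence string* is a maximal run under $g_s$ = 30 d.  A string's first
detection is an arrival event and its last a departure event; strings
bounded by the stream edge are censored on that side, and strings starting
between tagging and the following April 30 are excluded from phenology as
tagging-biased.  The mating season is June 1 – July 31, inclusive.

**Return cycles.**  A shark is present in a season if any method (capture,
PIT scan, visual, acoustic) identifies it inside the window.  Return
intervals are whole-year differences of consecutive seasons present;
intervals ≥ 4 y (possible missed seasons) and female 1-y intervals
(identification noise during gestation) are excluded from the cycle
sequence, and a *switch* is an adjacent 2↔3 change in the retained
sequence.  The pooled triennial share is
$n_3 / (n_2 + n_3)$ over retained female intervals.

**PRLO.**  With first event at age $a_0$, last possible age $a_1$ and
litter size $L$, a schedule of intervals $d_1, d_2, \dots$ produces events
at $a_0, a_0 + d_1, a_0 + d_1 + d_2, \dots \le a_1$ and total output
$N \cdot L$.  Defaults ($a_0 = 20$, $a_1 = 54$, $L = 34$) give 612 pups
biennially versus 544 under the observed 2/3-yr mixture, an 11.1 %
reduction.

**GLMMs.**  `fit_glmm()` maximizes the Laplace-approximated posterior of a
binomial/Poisson/Gaussian mixed model with independent
$\mathcal{N}(0, \sigma_\beta^2)$ priors on fixed effects (default
$\sigma_\beta = 2.5$ on the link scale) — finite estimates even under
complete separation — and normal random intercepts per grouping factor.
Wald chi-square factor tests and single-step multivariate-normal
(Tukey-style) pairwise comparisons operate on the fit.

## Worked example

```r
library(matesite)

ds <- simulate_dataset(sim_config(n_females = 20, n_males = 15, years = 12,
                                  start_year = 2000), seed = 7)
det_one <- ds$detections[ds$detections$shark_id == "F001", ]

head(segment_visits(det_one)[, c("start", "end", "n_detections", "duration_h")], 3)
#>                 start                 end n_detections duration_h
#> 1 2003-06-20 11:17:05 2003-06-20 14:50:30           22  3.5569444
#> 2 2003-06-20 16:00:21 2003-06-21 17:25:37          163 25.4211111
#> 3 2003-06-22 02:45:02 2003-06-22 03:16:03            4  0.5169444

head(extract_presence_strings(det_one)[, c("arrival", "departure", "n_detections")], 3)
#>               arrival           departure n_detections
#> 1 2003-06-20 11:17:05 2003-06-27 08:23:36          551
#> 2 2005-06-30 04:46:43 2005-07-04 21:43:09           99
#> 3 2008-06-12 23:51:50 2008-06-27 04:07:03          298

pres <- build_presence(ds$sightings, ds$detections, ds$registry)
f1 <- pres$histories[pres$histories$shark_id == "F001", ]
f1$intervals[[1]]
#> [1] 2 3 2
classify_cycles(f1$intervals[[1]])
#>   n_one_year n_two_year n_three_year n_long n_switches switched_once switched_multiple
#> 1          0          2            1      0          2          TRUE              TRUE
```

Shark F001 mated in 2003, 2005, 2008 and 2010: two biennial intervals
around one triennial, i.e. she switched cycle length twice.  The lifetime
cost of such mixing:

```r
ref <- prlo_total(prlo_params(interval = 2), "strict biennial")
alt <- prlo_total(prlo_params(schedule = c(2,2,2,3, 2,2,2,3, 2,2,2,3, 2,2,3)),
                  "observed mixture")
rbind(ref, alt)
#>   n_events total_pups   schedule_label
#> 1       18        612  strict biennial
#> 2       16        544 observed mixture
prlo_reduction(ref, alt)
#> [1] 11.1
```

A female on the mixed schedule completes 16 rather than 18 litters over the
same reproductive span — an 11.1 % reduction in potential lifetime output.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full study-scale analysis on synthetic data, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # 137 sharks x 30 y dataset + ground truth
Rscript analysis/02_segment.R        # visits and presence strings
Rscript analysis/03_season_metrics.R # residency metrics, diel and monthly profiles
Rscript analysis/04_returns.R        # return histories, cycles, cohort report
Rscript analysis/05_prlo.R           # lifetime-output projections
Rscript analysis/06_stats.R          # rank tests, AD test, GLMMs, comparisons
Rscript analysis/07_report.R         # integrated pipeline + markdown report
```

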