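# stepscape

Individual-based step-selection movement simulation and habitat-use
prediction over raster landscapes.

`stepscape` is written for movement ecologists and conservation planners
who have fitted integrated step-selection functions (iSSFs) to telemetry
data and want to project where animals — the motivating system is grizzly
bears recolonizing or being reintroduced into an empty recovery area —
will concentrate use on a landscape they do not yet occupy. The package
takes per-individual selection coefficients and movement-kernel
parameters as *inputs* (it does not fit iSSFs) and provides the full
downstream pipeline: conductance surfaces, trajectory simulation,
quantile-class habitat maps, map validation, and habitat/ownership
summaries. A synthetic-data module generates landscapes, populations and
validation points with the statistical structure the analysis assumes, so
everything is testable without external data.

## The model

Each individual carries an exponential selection function over seven
habitat covariates (NDVI, terrain ruggedness, distance to and density of
forest edge, density of riparian areas, density of buildings, distance to
secure habitat),

    w(x) = exp(x'β),

with β the individual's coefficient vector (terms dropped from that
individual's final model are exactly 0). Its **conductance surface** is
w evaluated at every 300-m cell, winsorized at the 0.025/0.975 quantiles
and min–max rescaled to [0, 1].

Movement is a correlated random walk filtered by conductance: from the
current location and heading, 11 candidate steps are drawn from the
individual's gamma step-length and von Mises turn-angle distributions,
and the next location is sampled with probability proportional to the
conductance at each candidate's endpoint (zero off the mapped area). An
iteration runs 20,000 steps; a scenario runs 100 iterations per female
model and 242 per male model (so 46 females and 19 males give 4,600 and
4,598 iterations), starting either from prior-connectivity-filtered
start nodes (natural recolonization) or from random points inside a
release zone (reintroduction).

Accumulated step endpoints are binned within the study area into 10
equal-area quantile classes of relative predicted use (1 = lowest, 10 =
highest), overall and per consecutive quarter of the step sequence
("sequence maps" showing how use shifts over time). Maps are validated
against point locations via the Spearman rank correlation between class
and per-class location counts, the mean class at locations, and the
percentage of locations in the top class and top half of classes.

## Worked example

```r
library(stepscape)

L   <- synth_landscape(synth_landscape_spec(nrows = 100, ncols = 100, seed = 1))
pop <- synth_bear_models(synth_population_spec(n_females = 5, n_males = 5, seed = 2))
cfg <- scenario_config("reintroduction", n_steps = 1000,
                       iterations_per_female = 20, iterations_per_male = 20,
                       base_seed = 3)
res <- run_scenario(cfg, pop, L)
comb <- combine_step_rasters(list(res$per_sex$F$total, res$per_sex$M$total),
                             L$masks$study_area)
comb$counts
#> <step_count_raster> window=combined: 200000 steps over 9803 occupied cells
comb$classes
#> <class_map> 10 classes over 4900 cells; cells per class: 633 482 486 467 532 388 450 503 486 473

pts <- synth_validation_points(comb$classes, 500, gamma = 3, seed = 4)
validation_summary(comb$classes, pts)
#> <validation_summary> n = 500 (0 excluded)
#>   rho = 0.988, mean class = 8.42, top class 32.2%, top half 93.0%
```

All 200,000 deposited steps are conserved: 10 bears × 20 iterations ×
1,000 steps, with stalled steps depositing in place. Class areas are near-equal but not
exactly 10% each because many short-run cells tie at zero counts and ties
bin to the lower class. The validation points were drawn with preference
∝ class³, so the summary recovers a strongly predictive map: rho = 0.988
and mean class 8.42. Selection leaves a covariate signature — with the
default positive NDVI coefficient, mean NDVI rises from 0.31 in class 1
to 0.75 in class 10:

```r
tab <- class_covariate_means(L, comb$classes)
subset(tab, covariate == "ndvi" & class %in% c(1, 5, 10))
#>    class covariate      mean
#> 1      1      ndvi 0.3140212
#> 29     5      ndvi 0.3811223
#> 64    10      ndvi 0.7519442
```

## Command-line wrapper

A thin Rscript wrapper exposes the pipeline from a shell:

```sh
inst/scripts/stepscape synth    --out bundle --seed 1        # input bundle
inst/scripts/stepscape simulate --config bundle/config.yaml \
                                --scenario recolonization --out sim
inst/scripts/stepscape map      --counts sim/counts_*_total.asc \
                                --mask bundle/landscape/mask_study_area.asc --out maps
inst/scripts/stepscape validate --classes maps/classes_combined.asc \
                                --points pts.csv --out val.json
inst/scripts/stepscape summarize --landscape bundle/landscape \
                                 --classes maps/classes_combined.asc \
                                 --counts maps/counts_combined.asc --out tables
```

See `vignettes/stepscape-methods.Rmd` for the modelling assumptions,
parameter choices and known limitations.
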