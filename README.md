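# mashboard

Fuse per-county marginal datasets into a privacy-preserving synthetic
population and interrogate the fused pool through coordinated
(crossfilter-style) filters, a URL query grammar, cohort-based anchoring
for location-free data, and filtered CSV export.

## Who this is for

Public county statistics ship as *marginals*: one file has gender counts
per county, another income per capita, a third unemployment. They share a
geography key (5-digit FIPS) but no individual records, so they cannot be
cross-filtered directly — and the raw sources may be too sensitive to
republish anyway. mashboard is for analysts and tool builders who want one
queryable archive over such sources: it simulates a scaled population from
the marginals and gives every downstream consumer (engine, API, export)
the same record set.

## The model

A county with population $P$ contributes
$\mathrm{round}_{1/2\uparrow}(P/d)$ samples of weight $d$ (default
$d = 1000$: a 1/1,000-scale population). For a qualitative variable with
county category counts $c_{gk}$, each sample in county $g$ independently
draws label $k$ with probability $c_{gk} / \sum_j c_{gj}$ (simple random
sampling). A quantitative variable is set to the county mean exactly — no
simulated deviation — falling back to the state mean when the county value
is missing. Every sample thus carries only aggregates, so the pool exposes
nothing below the resolution of $d$ persons.

Filtering follows the crossfilter convention: one predicate per dimension
(closed intervals on quantitative dimensions, label sets on qualitative
ones), conjunction across dimensions, and per-dimension aggregation that
excludes the dimension's own filter. The query grammar
(`var[min]=…&var=label&reqVar=…`) is the machine-facing twin of the same
engine, guaranteed to return identical record sets. Location-free datasets
join the system by binning records into equal-width cohorts on a shared
anchor column, the cohort index playing the role of the county code.

See `vignettes/mashboard-methods.Rmd` for the full account of the model,
its conventions and its limitations.

## Worked example

One county, 8,000 residents, 3,000 male and 5,000 female:

```r
library(mashboard)

we   <- worked_example_fixture()
pool <- build_pool(we, "pop", scale_denominator = 1000, seed = 7)
pool <- integrate_qualitative(pool, "gender", we)
pool
#> <sample_pool> 8 samples x 1000 persons, 1 geo units, seed 7
#>   integrated: gender
#> # A tibble: 8 × 4
#>   sample_id geo_id weight gender
#>       <int> <chr>   <dbl> <chr>
#> 1         1 26161    1000 male
#> 2         2 26161    1000 female
#> ...
```

The 8,000-person county became 8 samples of weight 1,000; each drew its
gender from the county distribution (3/8 male), so this particular seed
produced 5 male and 3 female samples — across many seeds the average is 3
male, 5 female. Filtering and aggregating:

```r
cf <- crossfilter(pool)
group_aggregate(cf, "gender")
#> # A tibble: 2 × 2
#>   group  value
#> 1 male       5
#> 2 female     3

cf <- set_filter(cf, "gender", flt_categories("male"))
current_selection(cf)
#> [1] 1 4 5 7 8

cat(export_csv(pool, cf$state, "gender"))
#> gender,weight
#> male,1000
#> ...   (one row per selected sample)
```

The same selection through the query API:

```r
run_query(pool, "gender=male&reqVar=gender")
```

A command-line front end over these functions ships at
`inst/cli/mashboard.R` (subcommands `ingest`, `summarize`, `fuse`,
`integrate`, `query`, `export`, `cohort`, `fixtures`).

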