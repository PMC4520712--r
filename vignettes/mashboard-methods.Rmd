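---
title: "Fusing county marginals into a queryable synthetic population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing county marginals into a queryable synthetic population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mashboard)
```

## The problem

Public county-level statistics come as *marginals*: one file says how many
men and women live in each county, another gives the county's income per
capita, a third its unemployment rate. Each file is internally consistent
but none can be cross-filtered against the others — there is no record that
says "a person in Washtenaw County with this income and this education
level". mashboard fuses such files into a single **synthetic population**: a
pool of weighted samples, each standing for a fixed number of persons in
one county, onto which every variable is projected. The pool can then be
filtered and aggregated across all sources at once, through a shared filter
engine, a URL query grammar, or CSV export.

Because every sample only ever carries county or state **aggregates**, the
pool contains no individual-level record. The smallest unit any query can
resolve is one sample, i.e. `scale_denominator` persons (1,000 by default),
which is what makes the fused archive safe to publish even when a source
touches sensitive subjects.

## The fusion model

**Pool construction.** A county with population $P$ contributes
$\mathrm{round}_{1/2\uparrow}(P / d)$ samples of weight $d$, where $d$ is
the scale denominator (default $d = 1000$, a 1/1,000-scale population). The
rounding rule is round-half-up: for populations whose remainder mod $d$ is
uniform, the expected total weight equals the true population, and a county
needs at least $d/2$ residents to appear at all. The population variable is
mandatory — it is the base dataset without which nothing else can be
scaled. Total weight per county differs from the true population by at most
$d/2$.

**Qualitative variables** (gender, race, education level, ...) arrive as
per-county category counts $c_{gk}$. Each sample in county $g$ draws its
label independently by simple random sampling with
$\Pr(k) = c_{gk} / \sum_j c_{gj}$. The worked single-county example —
8,000 residents, 3,000 male and 5,000 female — fuses to 8 samples of which
on average 3 draw male and 5 female. A county whose counts are all zero has
no distribution and is an integration error rather than a silent guess.

**Quantitative variables** (income per capita, unemployment rate, ...)
arrive as county means and are assigned *exactly*: every sample in the
county carries the county mean, with no simulated deviation, so the
within-county variance of a quantitative variable is zero by construction.
Where the county mean is missing, the state mean is used; where both are
missing, integration fails naming the county. The same fallback logic
applies to qualitative counts: explicit state-level counts if present,
otherwise the within-state sum of the available county counts.

**Independence.** Each variable is integrated separately. Two qualitative
variables are dependent only through shared geography — there is no joint
distribution within a county. This is deliberate: the inputs are marginals,
and inventing cross-variable structure (e.g. by iterative proportional
fitting) would manufacture associations the sources do not support. The
associations the pool *does* expose are exactly the between-county ones.

**Seeding.** A pool carries one base seed. Each integration draws from a
sub-stream derived deterministically from `(seed, variable name)` via a
polynomial string hash, so integrating `gender` then `race` produces
bit-identical columns to integrating `race` then `gender`, and adding a
variable on demand later gives the same pool as integrating it eagerly.
Replicate experiments pass an explicit per-replicate seed instead.

**Derived variables** combine two integrated quantitative variables by
per-sample addition, subtraction or multiplication, mirroring the
dashboard-style "customize" operation.

## Ingest and quality control

Marginal CSVs are read against a declared schema (`marginal_schema()`): one
geo-id column, quantitative columns holding county means, and qualitative
variables spread over one column per category. Validation applies a
**closed** repair list — anything else is a drop, never an interactive fix:

* auto-fix: surrounding whitespace; thousands separators (`8,000`); short
  geo ids, completed with the file's declared 2-digit state prefix when one
  is given (`161` → `26161`) and zero-padded otherwise (`1001` → `01001`);
* drop (whole CSV row): non-numeric or over-long geo ids, values that do
  not parse as numbers, negative category counts.

Every input row ends in exactly one of three states — clean, auto-fixed, or
dropped — and the QC report's error rate is
`(fixed + dropped) / input rows`. Validation is idempotent: a second pass
reports zero errors and returns the identical table. FIPS codes are always
5-character zero-padded strings (leading-zero states make integer codes a
bug factory); rows whose county part is `000` are state-level records by
the standard census convention and are routed to the fallback store rather
than the county records.

Validated tables serialize to a key-value JSON dialect (`meta` block +
`records` keyed by FIPS + `state_fallbacks`), chosen so that
write-then-read is exact. Variable names must be globally unique across the
datasets combined into one summary file; a collision is an ingest error.

## Filtering semantics

The engine follows the coordinated-views (crossfilter) convention:

* at most one predicate per dimension; setting a new one replaces the old
  (brush semantics), and all active predicates combine as a conjunction;
* a category predicate is a disjunction within its own dimension;
* intervals are closed on both ends — a GUI range of \$40,000–\$60,000
  includes both endpoints;
* missing values never satisfy any predicate;
* `group_aggregate()` applies every filter **except** the grouped
  dimension's own, so a brushed chart keeps showing its full axis while
  every other view restricts. Group counts over a dimension therefore sum
  to the selection size under the *other* filters — a partition identity
  the tests assert.

Correctness is defined by a naive full scan; the engine caches one boolean
mask per dimension and recomputes only the mask of the dimension whose
predicate changed, so repeated re-filtering does not rescan the other
dimensions. The number of simultaneous dimensions is capped at 30 and a
single view may combine at most 6 variables — both dashboard-style
configuration values enforced by the engine, not semantic limits.

Quantitative grouping uses equal-width half-open bins $[e_i, e_{i+1})$ with
the top bin closed. Edges are computed as $lo + i\,(hi - lo)/n$ — by
division, never by repeated addition — so the last edge is exactly the top
of the range and no cumulative floating-point drift can push a boundary
value into the wrong bin.

## The query grammar

The machine API accepts URL query strings with three pair forms:
`var[min]=v` / `var[max]=v` set inclusive bounds on a quantitative
variable (repeated bounds merge to the tightest), repeated `var=label`
pairs union into a category set, and each `reqVar=name` appends one
requested output variable (at least one is required). Names are validated
against the summary metadata; `+` and percent-escapes decode as form
encoding. Executing a parsed query translates its filters into the
engine's predicates, so the API path and the GUI-style engine path return
identical record sets — a property the suite checks on hundreds of random
queries. CSV export applies the current filter state, emits only the
displayed variables plus the sample weight, and equals the API result for
the equivalent query.

## Free-anchored mode: cohorts instead of counties

User-supplied study data (the package's running example: neuroimaging
exports sharing a `cerebellum_Volume` column) usually has no geography.
Column kinds are inferred from the entries alone — a column is quantitative
iff every non-missing entry parses as a finite number; the missing tokens
recognised are the empty string, `NA`, `n/a` and `NaN`, case-insensitively.
Records are binned on the shared anchor into `n_cohorts` equal-width
cohorts over a user-chosen `[lo, hi]` (the running demonstration uses 300
cohorts over [0, 300,000], width 1,000), with the same half-open/closed-top
edge convention as histogram bins; `v = lo` lands in cohort 0 and `v = hi`
in cohort `n - 1`. Out-of-range or missing anchors are dropped with a count
— the same philosophy as ingest QC, and it keeps cohort indices dense.

Merging stacks the cohort-assigned records into one pool, prefixing each
column with its dataset label (the anchor and the cohort index stay
shared), with the cohort index playing the role the county FIPS plays in
the location-anchored mode. Stacking, rather than a per-cohort join, was a
deliberate choice: a join would square the record count when a dataset
meets a relabelled copy of itself and could not keep a single unprefixed
anchor column. Under stacking each record carries `NA` for the other
datasets' variables, and since missing values fail every predicate, a
conjunction across two datasets' own variables selects nothing — cross-
dataset comparison goes through the shared cohort and anchor dimensions,
which is exactly how the cohort mode is meant to be used.

## The fixture generators

`make_county_fixture()` emulates the *shape* of national county marginal
files: a population variable, per-county category counts obtained by
scaling flat-Dirichlet proportions to the population (each category kept at
count ≥ 1 so every county has a distribution), and quantitative means drawn
uniformly from declared ranges. `make_anchored_fixture()` emulates study
exports with a shared anchor column. Both are byte-deterministic given a
seed. `make_dirty_fixture()` renders a clean table to CSV and injects the
exact defect classes the validator handles, at declared per-row rates with
disjoint fix/drop rows, so the expected QC report is known in advance —
that ground-truth test is what stands in for the error statistics of the
real national files, which depend on data this package does not ship.

What the fixtures deliberately do **not** emulate: realistic marginal
distributions (real county data is heavy-tailed and spatially correlated),
missing-data patterns of real survey files, and national scale
(hundreds of counties rather than ~3,000). Passing tests therefore
demonstrate correctness of the mechanics — transcription, accounting,
sampling, filtering, parsing — not statistical fidelity to any real
archive.

## Problem sizes and tolerances used by the test suite

* Worked-example experiments: 10,000 replicate integrations of the
  8-sample county; the Monte-Carlo mean male/female counts are asserted
  within 4 standard errors ($\sqrt{8 \cdot 3/8 \cdot 5/8}/\sqrt{10^4}
  \approx 0.0137$) of 3 and 5.
* Engine-vs-oracle equivalence: 1,000 randomized pools of up to ~500
  samples with up to 6 dimensions and random predicates, compared exactly
  (integer sample ids, exact group counts).
* API-vs-engine equivalence: 500 random parsed queries on one fixture pool,
  compared for bit-identical record sets.
* Marginal recovery: 1,000 replicate integrations of a random 3-category
  marginal, pooled frequencies within 4 analytic standard errors.

These sizes keep the whole suite in the low minutes on one CPU while
leaving the stochastic assertions with comfortable power; they are choices
of this package, and all of them are ordinary constants in the tests.

## Known limitations

* No joint structure within a county beyond shared geography (by design).
* Quantitative variables have zero within-county variance, so pool-level
  variance statistics understate true population variance; the pool is built
  for filtering and comparison, not for variance estimation.
* ZIP-code anchoring is not implemented; geography is FIPS-only.
* The cohort merge exposes cross-dataset conjunctions as empty rather than
  attempting statistical matching within cohorts.
* The QC repair list is closed; defects outside it are dropped, and there
  is no interactive repair channel.
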