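---
title: "Assessing seafood contaminants with a statistical range of acceptance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing seafood contaminants with a statistical range of acceptance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msfd9)
library(dplyr)
```

## The assessment problem

Descriptor 9 of the Marine Strategy Framework Directive (2008/56/EC)
requires that contaminants in fish and other seafood for human
consumption do not exceed the maximum levels laid down by food
legislation (Reg. 1881/2006 and its updates for metals, PAHs, dioxins
and dioxin-like PCBs; national standards for mussel-farm waters). The
data available for such an assessment come mostly from public-health
monitoring: concentrations of Hg, Cd, Pb, benzo(a)pyrene and related
PAHs, and dioxins measured in edible tissues of fish, bivalve molluscs,
crustaceans and cephalopods at georeferenced sampling stations.

Judging a whole marine subregion from these data raises two
methodological problems that this package addresses:

1. **A single exceeding sample should not condemn a subregion.** The
   "one out, all out" rule would read any single exceedance as bad
   status for the entire subregion, which is precautionary but loses
   all gradation. Instead, compliance is judged *statistically*,
   through a lognormal acceptance range, and *spatially*, by
   integrating station results onto a regular grid with an explicit
   majority rule.
2. **Health monitoring is not designed for environmental assessment.**
   Samples cover all commercial sizes and seasons, so dispersion is
   large and not attributable to environmental state alone. The
   acceptance model therefore fixes dispersion by convention rather
   than estimating it from heterogeneous data.

## The statistical range of acceptance

Concentrations $Y$ of a contaminant within one regulatory category are
modelled as lognormal, $Y \sim \mathrm{LN}(\mu, \sigma)$. The model is
anchored at the data: $\mu = \log(\mathrm{GM})$, where $\mathrm{GM}$ is
the geometric mean of the collected concentrations, and the dispersion
is fixed at 20 % — the conventional relative variability adopted for
environmental data. The regulatory level $\mathrm{TL}$ is interpreted
as the 90th percentile of this theoretical distribution, and the data
set complies when its **empirical** 90th percentile does not exceed
$\mathrm{TL}$:

$$\hat{q}_{0.90}(\text{data}) \le \mathrm{TL}.$$

A tie passes: the criterion is "must not exceed". The lognormality
assumption is screened with a Shapiro–Wilk test on $\log Y$; a failed
screen is reported (`normality_ok = FALSE`) but never silently changes
the decision, because substituting another distribution behind the
analyst's back would be worse than an explicit warning.

### The two readings of "σ equal to 20 %"

"σ equal to 20 % of µ" is ambiguous when µ lives on the log scale, and
the choice matters:

* **`cv20`** (the default): the *natural-scale* standard deviation is
  20 % of the median, giving the unit-free log-scale value
  $\sigma = \sqrt{\log(1 + 0.2^2)} \approx 0.19804$. Under this reading
  the theoretical 90th percentile is
  $\mathrm{GM} \cdot \exp(z_{0.90}\,\sigma) \approx 1.289\,\mathrm{GM}$,
  independent of the measurement unit.
* **`literal_log`**: $\sigma = 0.2\,|\mu|$ taken literally on the log
  scale. This depends on the unit the concentration happens to be
  expressed in (the same data in mg/kg and µg/kg give different σ) and
  degenerates to $\sigma = 0$ when $\mathrm{GM} = 1$; the package
  raises an error in that case. It is retained behind a flag purely so
  that either reading can be audited.

`cv20` is the default because it is the only unit-invariant reading,
and because scale equivariance — `assess(k·values, k·TL)` must equal
`assess(values, TL)` — is a property the whole pipeline is tested for.

### The quantile estimator

The empirical 90th percentile depends on the order-statistic estimator
near a decision boundary. The default is linear interpolation of the
empirical distribution function (R's type 7); all of R's types 1–9 are
selectable through `quantile_type`. For data simulated so that the true
90th percentile sits exactly at $\mathrm{TL}$, the default estimator
passes in about 56 % of replicates at $n = 200$ — close to the 50 %
that an exactly median-unbiased estimator would give, the residual
asymmetry coming from the right-skew of the lognormal.

## The regulatory catalog

`msfd_catalog()` ships the 17 regulatory categories used in the
assessment: five cadmium, two mercury and four lead categories (mg/kg
wet weight), dioxins and the sum of dioxins and dioxin-like PCBs (pg/g
w.w.), and benzo(a)pyrene plus the sum of four PAHs (µg/kg w.w.). Each
entry carries its category code (analyte plus regulation paragraph,
e.g. `"Hg 3.3.1"`), foodstuff class, limit, unit, and legislation
reference. Measurement records must arrive with a `category_code`
column: mapping species and tissue to a regulatory category is a
food-legislation judgement this package deliberately does not automate.

## Quality control and censored values

`qc_filter()` applies four record-level predicates, each separately
switchable and fully accounted for in a conservation-checked report
(`n_input = n_kept + Σ removals`): coordinates inside the assessment
bounding box; unit agreement with the category; informativeness of
below-LOQ records (a record censored at a quantification limit *above*
the regulatory level can never inform the decision and is removed); and
the sampling-year window, defaulting to 2006–2012, the period of the
MSFD initial assessment.

Censored (below-LOQ) records enter the statistics by substitution;
`loq/2` is the default, with `loq`, `0` and `drop` as explicit
alternatives. Substitution at half the quantification limit is the
common monitoring convention; keeping every alternative one flag away
keeps the choice auditable, since nothing in the data can identify it.

## Spatial integration

The reference grid (fishnet) is built in ETRS89 geographic coordinates
with square angular cells, default side 0.45°, which is roughly 50 km
meridionally at Mediterranean latitudes. The grid is defined by its
lower-left origin, cell size, and row/column counts; the origin
defaults to the data or subregion bounding-box corner and can be
overridden to reproduce an externally defined net. Working in angular
measure keeps the construction reproducible from three numbers, at the
cost of cells that shrink zonally with latitude; a metric equal-area
grid is out of scope.

Cells are half-open, `[low, high)`, with the net's outer top and right
boundary closed, so every point belongs to exactly one cell. A cell
belongs to the subregion when its rectangle *intersects* the subregion
polygon — boundary touches count, and containment is not required,
since coastal monitoring data routinely sit in cells the boundary cuts.

Integration proceeds datum → station → cell → years with the same rule
at every level:

* code 1 (green) for a result not exceeding the threshold, code 2
  (red) otherwise;
* the integrated code is the one with the highest frequency;
* an exact tie integrates to code 2, by the precautionary principle.

Applying the identical rule at every level is a deliberate
simplification: the cell-level rule is the one stated for the
assessment, and using it uniformly makes the pipeline auditable and
the monotonicity property (flipping any constituent vote from green to
red can never turn the aggregate green) provable at all levels at once.
In whole-period mode (the default) a station sampled in several years
casts one vote; in single-year mode each station-year is a separate
vote, which is the variant used for year-by-year trend maps.

## Summary statistics

For each category, `summarize_assessment()` reports spatial coverage
(assessed cells as a share of the subregion's total cells) and the
percentages of data, stations and cells within and outside the limits,
plus all underlying counts. Percentages are rounded half away from zero
to one decimal — `spatial_coverage(42, 51)` prints `82.4` — and counts
are never rounded. Categories without data are reported as `-` and
excluded from denominators. Station denominators count unique stations
under the default mode and station-years under single-year mode.

## The synthetic-data generator

No measurement data from the original Italian assessment were ever
deposited, so the package carries a generator that emulates the
structure the method assumes, making every stage testable offline:

* **Stations** are placed uniformly inside a subregion polygon by
  rejection sampling (three stylised polygon fixtures are packaged: an
  elongated basin, a peninsular coast, and a basin with an island
  hole). An optional coastal-bias mode pulls stations toward the
  boundary, imitating the concentration of sampling effort in coastal
  fishing zones; the default stays uniform because a known sampling
  density makes test expectations exact.
* **Concentrations** are lognormal with median `gm` and natural-scale
  CV `cv` (default 0.2, matching the acceptance model). A target
  exceedance fraction `f` can be requested instead of `gm`; the
  generator solves `gm = TL · exp(−z₁₋f σ)` in closed form.
* **The default scenario** uses 30 stations, 2 records per station,
  category and year over 2006–2012, and four categories spanning the
  three contaminant classes with small exceedance targets (5 % for
  `Hg 3.3.1`, 2 % elsewhere) — a mostly compliant pattern of the kind
  the initial assessment reported.
* A ground-truth sidecar records `gm`, `cv`, `TL` and the expected
  exceedance per category, the supervision signal for
  parameter-recovery tests.

What the generator does **not** emulate: species- and size-dependent
bioaccumulation, seasonality, spatial autocorrelation of contamination,
and analytical error structure. Tests passing on synthetic data
therefore validate the *machinery* (coding, integration, statistics,
bookkeeping), not the field realism of any particular monitoring
programme.

## Worked example

```{r example}
scn <- scenario(polygon = "basin", n_stations = 30, seed = 1)
m <- gen_dataset(scn)
nrow(m)

a <- run_assessment(m, polygon = subregion_polygon("basin"),
                    subregion = "SYN")
format_summary_table(a$summary, drop_empty = TRUE)

a$acceptance |>
  select(category_code, n, gm, empirical_p90, tl, pass, normality_ok)
```

```{r map, fig.width = 6, fig.height = 5}
hg <- filter(a$cells, category_code == "Hg 3.3.1")
plot_cell_map(hg, a$grid, title = "Hg 3.3.1 - cell assessment")
```

## Numerical choices and degenerate inputs

* Geometric means require strictly positive values; zeros must be
  resolved by LOQ substitution first, and violations name the
  offending index.
* The Shapiro–Wilk test is limited to 5000 observations; larger
  samples are subsampled with a fixed internal seed so the reported
  p-value is reproducible and the caller's random stream is untouched.
* Acceptance fits require `n ≥ 3`; categories below that are skipped
  with a warning rather than fitted meaninglessly.
* Grid dimensions use a ceiling rule with a square-root-of-machine-eps
  guard so a bounding box that is an exact multiple of the cell size
  does not gain a spurious row.
* Rounding of percentages is half away from zero, to match how
  regulatory summary tables are conventionally printed; all tie-breaks
  in the integration rule resolve red.

## Problem sizes used in validation

The package's validation suite exercises: exhaustive integration
checks over all 8190 code sequences up to length 12 plus 10⁵
randomized larger cases; calibration of the acceptance test with 1000
replicates at n = 200; closed-form vs Monte-Carlo percentile agreement
with 10⁶ draws for 20 random parameter pairs; parameter recovery on a
generated dataset of ~10⁴ records; byte-level determinism of two
seeded pipeline runs; and the within/outside complement identity over
100 random scenarios. These sizes give Monte-Carlo standard errors
comfortably below the tolerances being checked.

## Known limitations

* The acceptance range fixes dispersion at 20 % by convention; data
  with genuinely larger dispersion will fail the normality screen or
  exceed the range more often than the model predicts.
* Angular cells are not equal-area; comparisons of spatial coverage
  across widely separated latitudes inherit that distortion.
* The species/tissue → category mapping must be supplied by the user.
* One subregion per run; multi-subregion assessments are repeated
  invocations.
* No covariate adjustment (species, season, size): the method judges
  the pooled category, as the regulatory framing requires.
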