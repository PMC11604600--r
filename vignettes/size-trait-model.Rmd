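---
title: "The calcareous nannoplankton size-trait model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The calcareous nannoplankton size-trait model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coccotraits)
```

## The problem

Calcareous nannoplankton (coccolithophores and their allies) build a calcite
cover of interlocking plates (coccoliths). Their fossil record preserves the
plates in vast numbers but almost never the cells, so two quantities central
to plankton biogeochemistry — the organic carbon of the cell (POC) and the
inorganic carbon of its calcite cover (PIC) — must be reconstructed from
coccolith morphometrics. `coccotraits` implements that reconstruction: from
coccosphere geometry and loose-coccolith size data to per-morphogroup
distributions of cell size, POC, PIC and PIC:POC, and from assemblage counts
to community size structure, size-class carbon partitioning and community
PIC:POC through time.

## The model

### Placolith cell size

Intact fossil coccospheres record, for one cell, the coccolith length
$C_L$ (µm), the number of coccoliths $C_N$, and the internal (cell)
diameter $\Theta$ (µm). Treating the cell as a sphere, the surface area
available per coccolith is $\pi\Theta^2/C_N$, and across a morphogroup the
relationship

$$\log_{10}(C_L) = \alpha\,\log_{10}\!\left(\frac{\pi\Theta^2}{C_N}\right) + \beta$$

holds tightly. `fit_loglog_regression()` estimates $(\alpha, \beta)$ by
unweighted OLS on the log-transformed values (no errors-in-variables
correction: the scatter is treated as residual variation in $C_L$, the
response). `cell_diameter_placolith()` inverts the fit:

$$\Theta = 2\sqrt{\frac{C_N \cdot 10^{(\log_{10} C_L - \beta)/\alpha}}{4\pi}}.$$

With $\alpha > 0$, $\Theta$ increases in both $C_L$ and $C_N$: a cell
covered by more, or larger, coccoliths must be bigger.

### Non-placolith cell size

*Discoaster*, *Sphenolithus* and *Zygrhablithus* coccospheres disarticulate
too readily to be preserved intact, so their cell size uses a coverage-factor
budget instead (`cell_diameter_nonplacolith()`): the summed area of $C_N$
elliptical liths of length $C_{LP}$ and aspect ratio $AR$, scaled by a
coverage factor $C_O$, equals the cell surface area:

$$\Theta = \frac{C_{LP}}{2}\sqrt{\frac{C_O \cdot C_N}{AR}}.$$

$C_O < 1$ models overlapping liths (0.8 imposes exactly a 20% cut in
modeled surface area), $C_O > 1$ gaps between abutting liths. Because these
groups also lack observed $C_N$, their $C_N$ distribution is simulated
(`simulate_cn_distribution()`) as rounded Gaussian draws rejected outside a
published range (mean 20, range 10–31 for *Discoaster*; 42.5, 27–60 for
*Sphenolithus*; 22, 9–37 for *Zygrhablithus*). Rejection rather than
clipping is used so no probability mass piles up on the bounds. The
standard deviation is not published; the default $(\max-\min)/6$ puts the
range at $\pm 3\sigma$, which reproduces ranges of that width, and is
overridable in the registry.

### Cellular carbon

POC comes from the prymnesiophyte biovolume relationship
$\mathrm{POC} = 0.228\,V^{0.899}$ (pg C, $V$ in µm³ of the spherical cell) —
sub-linear, so carbon density falls with size. PIC uses the calcite
shape-factor approach: one coccolith carries
$d^3 \cdot K_s \cdot 2.7 \cdot 0.12$ pg C, where $d$ is the characteristic
lith dimension, $K_s$ a morphogroup-specific shape factor, 2.7 the density
of calcite (pg µm⁻³) and 0.12 the carbon mass fraction of CaCO₃ (kept as
the fixed published constant, never recomputed from atomic weights).
Cellular PIC is the per-lith value times $C_N$. Both POC and PIC are pg of
elemental carbon, so PIC:POC as a mass ratio equals the molar ratio.

The dimension $d$ is routed per morphogroup (`pic_dim_scale` in the
registry): placoliths feed the distal shield length directly; *Discoaster*
feeds ray length, half its circumscribing-circle diameter, while the full
diameter feeds the size model; *Z. bijugatus* feeds lith height, obtained
from base length via a mean height:base ratio, while base length feeds the
size model.

### Likelihood weighting

No individual loose coccolith tells us its cell's $C_N$. The model treats
the sample-specific $C_L$ histogram (n ≈ 50 measurements, binned at 0.5 µm —
the optical resolution of the measurements is 0.26 µm, so finer bins would
be spurious) and the morphogroup $C_N$ histogram as independent marginals,
weights every $(C_L, C_N)$ combination by the product of their frequencies
(`build_weight_grid()`), evaluates $\Theta$, POC, PIC and PIC:POC at each
node, and accumulates node weights into bins along each trait axis
(`morphogroup_trait_distribution()`). Independence is an assumption: only
the two marginal distributions are observed, and no joint distribution is
available to do better.

Means are computed on the unbinned node values; in particular the mean
PIC:POC is the weighted mean of per-node ratios, which is *not*
mean PIC / mean POC when the distribution is skewed — both are reported.

### Community aggregation

Assemblage counts (≥ 300 coccoliths per sample) give coccolith proportions
with Wald 95% confidence intervals ($p \pm 1.96\sqrt{p(1-p)/N}$, clamped to
[0, 1]; Wilson selectable). Proportions are renormalized over the ten
modeled morphogroups, smoothed down-record with a centered five-point moving
average (window truncated symmetrically at the ends, so linear trends pass
unbiased), and converted to *cell* proportions by dividing by each
morphogroup's mean $C_N$ — a taxon shedding more liths per cell is
over-represented in coccolith counts. The abundance-weighted morphogroup
distributions are then stacked (`stack_community()`) into the community
size distribution for a fixed accounting standing stock of 100 cells;
community PIC:POC (total PIC / total POC) is independent of that stock.
Size-class partitioning (default edges 2, 5, 8, 11, 15, 20 µm) tracks cells
outside the span in explicit overflow classes so percentages always close
to 100.

## Numerical conventions

* **Bins** are half-open $[\ell, u)$; a value $x$ falls in bin
  $\lfloor x/w\rfloor$ with center $(\lfloor x/w\rfloor + 0.5)w$. Default
  widths — cell size 1 µm (centers on half-integers), POC and PIC 30 pg C
  (centers 15 + 30k), PIC:POC 0.1 (centers 0.05 + 0.1k) — follow the
  lattices on which published percentile bands for these traits are
  printed; all are overridable.
* **Percentiles** are read off the binned cumulative weight; a percentile
  lands in the first bin whose cumulative weight reaches the target.
* **Ages** are piecewise-linear in depth between user-supplied tie points
  (constant sedimentation per interval), with no extrapolation: the record
  is bounded by its datums.
* **Mean community size** is computed on the bin centers of the stacked
  distribution; the binning error is bounded by half a bin width.
* Every renormalization asserts closure to 1 within 1e-9.

## The synthetic study

The generator (`gen_ground_truth_bundle()`) creates every input with known
truth. The `"U1553-like"` preset uses the published model constants
($\alpha$, $\beta$, $K_s$, $C_O$, $C_N$ settings) as the generating truth
for ten morphogroups, 18 samples, 375 coccospheres per placolith group,
50 lith lengths per morphogroup per sample and 300-count assemblages —
the study dimensions of the original record.

* Coccolith lengths are lognormal (right-skewed, positive support; the
  empirical family is not published). Coccosphere cell diameters are
  lognormal, coccolith counts truncated-rounded Gaussian, and coccolith
  length follows the forward allometry with multiplicative $10^\varepsilon$
  scatter, $\varepsilon \sim N(0, 0.05)$ log₁₀ units — strong but noisy
  allometric clouds (fit R² ≈ 0.8 at n = 375). The scatter is placed on
  $C_L$, the regression's response, so the OLS assumptions hold and
  noise-free data reproduce $(\alpha, \beta)$ exactly; placing it on
  $\Theta$ would be an errors-in-variables design that attenuates the
  fitted slope and contradicts exact recovery.
* Nonplacolith size medians and ratios (e.g. *Z. bijugatus* base ≈ 8.5 µm
  with height:base ≈ 0.7, *Sphenolithus* AR = 1) were back-solved once from
  the published mean cell size and mean cellular PIC of those groups so the
  preset is internally consistent; they are package defaults, not measured
  values, and are overridable.
* Abundance paths are smooth (a logistic rise of the small, heavily
  calcified *Cyclicargolithus*-like group; an exponential decline plus a
  size-median drift of the large *R. umbilicus*-like group; a transient
  *Clausicoccus*-like acme) and sampled multinomially at 300 counts.
* Ground truth community values are computed analytically from the
  generating distributions (lognormal quantile integration × exact
  truncated-normal $C_N$ probabilities × true parameters), never through
  the pipeline under test.

What passing the closure test shows — and what it does not: the pipeline
recovers the generator's community PIC:POC to well under 5% and mean
community size to well under half a size bin under lognormal sizes,
Gaussian counts, independent $C_L$–$C_N$, and multinomial counting noise.
Real assemblages add what the generator omits: dissolution and breakage
bias, taxonomy error, non-lognormal and possibly $C_N$-correlated size
distributions, and preservation-dependent coccosphere sampling. Closure on
synthetic data validates the arithmetic and the estimators, not those
field assumptions.

## Design choices on open points

* The source record describes its smoothing both as a five-point moving
  average and as a spline; the named statistic (five-point centered moving
  average) is implemented.
* Smoothed proportions are renormalized across taxa before cell conversion
  (whether the original workflow did is unstated); every renormalization
  is part of the documented contract above.
* Pooled vs per-reconstruction means: summary tables report the pooled
  mean (all samples' measurements in one distribution) and the range of
  per-reconstruction means separately, as the two are distinct statistics.
* Age tie points are user input; no published tie-point table is bundled.
* Rare morphogroups (*Discoaster*, *Sphenolithus*, *Z. bijugatus*) pool
  lith-size measurements across samples into one dataset, as their
  sporadic occurrences leave per-sample samples too small.

## Problem sizes

The bundled workflow and tests run the full study at its native scale —
2,625 coccospheres, 9,000 lith measurements, 18 reconstructions — in a few
seconds; grids up to 10⁴ $(C_L, C_N)$ nodes are checked bit-for-bit against
exhaustive enumeration, and recovery simulations use 200 replicates.

## Worked example

```{r example}
bundle <- gen_ground_truth_bundle("U1553-like", seed = 1)
res <- run_trait_pipeline(bundle$coccospheres, bundle$lith_sizes,
                          bundle$assemblages, bundle$registry,
                          bundle$age_model, seed = 1)
head(res$summary)
res$fits[["Chiasmolithus"]]
```

## Known limitations

* Per-species (sub-morphogroup) allometries, ellipsoidal cell geometries
  and coccolith-thickness modeling beyond $K_s$ are out of scope.
* Regression-parameter uncertainty is quantified (CIs) but not propagated
  into the trait distributions.
* The community accounting assumes a fixed standing stock; absolute
  productivity, carbonate chemistry and preservation state are not modeled.
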