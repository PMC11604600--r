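# coccotraits

Size and biogeochemical trait reconstruction for fossil calcareous
nannoplankton.

Coccolithophores leave behind their calcite plates (coccoliths) in enormous
numbers, but almost never their cells. This package reconstructs what the
fossils cannot show directly — cell size, cellular organic carbon (POC),
cellular inorganic carbon (PIC) and the calcification ratio PIC:POC — from
what they can: coccolith lengths, counts of coccoliths per cell measured on
rare intact coccospheres, and assemblage counts. It then aggregates those
cellular traits into community-level size structure, size-class carbon
partitioning and community PIC:POC through geological time. It is aimed at
quantitative paleobiologists and paleoceanographers working with
nannofossil morphometrics.

## The model in brief

For placolith-bearing morphogroups, intact coccospheres constrain a
log-log allometry between coccolith length C_L and cell surface area per
coccolith (cell of diameter Θ treated as a sphere):

    log10(C_L) = α · log10(π Θ² / C_N) + β

fitted by OLS and inverted to predict Θ for any (C_L, C_N) combination:

    Θ = 2 · sqrt( C_N · 10^((log10(C_L) − β)/α) / (4π) )

Morphogroups whose coccospheres never survive intact (*Discoaster*,
*Sphenolithus*, *Zygrhablithus*) use a coverage-factor budget instead,
Θ = (C_LP/2)·sqrt(C_O·C_N/AR), with simulated Gaussian C_N distributions.
Carbon follows POC = 0.228·V^0.899 (pg C, V the spherical cell volume in
µm³) and, per coccolith, PIC = d³·Ks·2.7·0.12 (pg C) with morphogroup
shape factors Ks. Every (C_L, C_N) combination is weighted by the product
of the sample-specific C_L frequency and the morphogroup C_N frequency,
giving binned distributions of each trait; abundance-weighted stacking
across morphogroups (after converting coccolith counts to cell proportions
via mean C_N) yields the community reconstruction per sample.

A synthetic-data module generates every input with recorded ground truth
(the `"U1553-like"` preset uses the published model constants as the
generating truth), so the whole pipeline is testable without the original
microscopy datasets. See the methods vignette
(`vignettes/size-trait-model.Rmd`) for assumptions, parameter defaults and
numerical conventions.

## Worked example

```r
library(coccotraits)

bundle <- gen_ground_truth_bundle("U1553-like", seed = 1)
res <- run_trait_pipeline(bundle$coccospheres, bundle$lith_sizes,
                          bundle$assemblages, bundle$registry,
                          bundle$age_model, seed = 1)
res$fits[["Chiasmolithus"]]
#> Placolith allometry (Chiasmolithus): alpha = 0.4876 [0.4621, 0.5131],
#>   beta = 0.1302 [0.0797, 0.1807] (n = 375, R2 = 0.791)
head(res$summary, 3)
#>   sample_id    depth      age mean_community_size total_poc total_pic community_pic_poc
#> 1       S01 200.0000 34.28889            11.87444  12434.00  14572.25          1.171968
#> 2       S02 188.8235 33.82941            11.66063  11942.41  13821.26          1.157325
#> 3       S03 177.6471 33.36993            11.82666  12408.12  14385.59          1.159368
```

The fitted slope/intercept recover the generating allometry within their
confidence intervals; each summary row is one reconstructed time slice:
mean community cell size (µm), total POC and PIC (pg C per 100-cell
standing stock) and community PIC:POC (mol:mol), here trending from 1.17
to 1.36 as the small, heavily calcified morphogroups take over the
community up-record.

The numbered scripts under `analysis/` run the same workflow as a
narrative: `01_simulate.R` writes the synthetic study to
`results/synthetic_inputs/`, `02_fit_allometry.R` fits the allometries,
`03_morphogroup_traits.R` tabulates per-morphogroup trait distributions,
`04_community_timeseries.R` reconstructs the community time series and
size-class partitions, and `05_scenarios.R` evaluates standing-stock
scenarios. Each writes its tables under `results/`.

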