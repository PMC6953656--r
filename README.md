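# betascape

Beta diversity — the change in species composition between sites — is the
spatial axis of biodiversity, and for hyper-diverse, under-surveyed groups
such as insects it can only be mapped at scale by combining opportunistic
occurrence records (GBIF-style species/latitude/longitude tables) with
geographically complete environmental layers. `betascape` implements that
analysis chain as a tested R package:

1. **Site formation** — occurrence coordinates are grouped into geographic
   sample sites with the Markov Cluster algorithm (expansion–inflation
   iteration on a Gaussian-kernel coordinate graph), records in
   0.1°-cells straddling region-class boundaries are removed, and the
   site × species count matrix is filtered to a fixed point (species at
   ≥ *m* sites, sites with ≥ *n* records).
2. **Dissimilarity** — pairwise Horn–Morisita dissimilarity
   *d* = 1 − 2Σxᵢyᵢ / ((Σxᵢ²/X² + Σyᵢ²/Y²)·X·Y), robust to unequal sampling
   effort, plus geographic distance and within/between-class Mantel
   contrasts.
3. **MRM** — multiple regression on distance matrices: OLS on unfolded
   lower triangles with response-permutation inference, reported as a
   nested model-comparison table (geographic; + climate; + vegetation;
   + both).
4. **GDM** — generalized dissimilarity modeling written from scratch:
   monotone I-spline transforms of each predictor (knots at the 0/50/100
   percentiles), negative-exponential link μ = 1 − exp(−η), richness-weighted
   binomial-form deviance minimized under β ≥ 0 by IRLS with a non-negative
   least-squares inner solve; per-predictor importance (spline plateau
   height) and permutation significance.
5. **Mapping** — fitted splines transform environmental rasters to
   biological space; a PCA of the transformed stack drives an RGB map in
   which color difference approximates predicted compositional
   dissimilarity.

Because the real inputs (global occurrence snapshots, WorldClim/MODIS
rasters) are enormous and external, the package ships a first-class
**synthetic-world generator**: smooth environmental surfaces, niche-structured
species with spatial range limits, uneven two-patch sampling effort, and a
ground-truth dissimilarity oracle, so the entire chain is validated offline
against known truth.

## Worked example

```r
library(betascape)
cfg <- run_config(out_dir = "demo_run", seed = 42)  # packaged 24x24 scenario
run_pipeline(cfg)                                    # ~20 s on one CPU

read.csv("demo_run/mrm_table.csv")
#>                                               model r_squared     p
#> 1                        dissimilarity ~ geographic 0.5169337 0.005
#> 2              dissimilarity ~ geographic + climate 0.5621778 0.005
#> 3           dissimilarity ~ geographic + vegetation 0.5530036 0.005
#> 4 dissimilarity ~ geographic + climate + vegetation 0.5888832 0.005

read_gdm_model("demo_run/gdm_model.json")
#> GDM: 7 predictors x 3 splines, 72.43% of null deviance explained (8 IRLS iterations)
#> importance (I-spline plateau heights):
#>            lat      herb_like            lon      temp_like treecover_like
#>         1.5348         0.8946         0.8613         0.6878         0.4675
#>    precip_like      elev_like
#>         0.2136         0.0000
```

Reading the output: the MRM table shows how much variance in compositional
dissimilarity each nested predictor set explains (here geography dominates,
and climate and vegetation each add signal — the permutation p of 0.005 is
the smallest attainable with 199 permutations). The GDM explains 72% of the
null deviance; each predictor's importance is the maximum height of its
fitted monotone spline, i.e. the partial ecological distance a full sweep of
that gradient contributes. `demo_run/` also contains the per-site
environmental table, both distance matrices, the class-contrast statistics,
per-predictor significance flags, and the PCA-RGB beta-diversity map
(`beta_map_{r,g,b}.asc` + PNG preview).

The same pipeline is scriptable from a shell via
`Rscript inst/cli/betascape.R --stage all --out demo_run --seed 42`
(stages: simulate, sites, extract, dissim, mrm, gdm, map).

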