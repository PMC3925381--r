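# eccniche

Environmental filtering of local ecomorph community assembly, as a tested,
reusable R pipeline.

Island adaptive radiations (the model system is Greater Antillean *Anolis*
lizards) repeatedly evolve the same six ecomorphs — twig, grass-bush, trunk,
trunk-crown, trunk-ground, crown-giant — yet local communities are rarely
complete. `eccniche` asks whether broad-scale environmental filters, and a
functional trait (body mass) behind them, explain where the community is
complete:

- **ENMs**: a maximum-entropy presence-background niche model per ecomorph
  per island. The Gibbs distribution `q(x) = exp(λ·f(x))/Z` over background
  cells (linear + quadratic features, standardized on the background) is fit
  by maximizing the L1-penalized presence log-likelihood
  `mean(λ·f)_presence − log Z − Σ β_j|λ_j|`, `β_j = β₀ s_j/√m`. Replicate
  ensembles use seeded 75/25 train/test splits with rank (Mann–Whitney)
  AUC; the logistic output `p = e^H q/(1 + e^H q)` scores "typical" sites
  (`q = e^−H`) exactly 0.5.
- **ECC**: ecomorph community completeness, the cellwise sum of min-max
  rescaled suitability maps, in `[0, 6]` with the full complement and unit
  weights.
- **Overlap**: Schoener's `D = 1 − ½ Σ|p_a − p_b|` between surfaces
  normalized over shared cells, for every island pair, cross-fitted on an
  archipelago-wide extent.
- **Correlations**: ECC vs elevation at raster level (Pearson R, OLS line)
  and on decorrelated k-means subsamples of bioclimatic principal components
  (Spearman r with a seeded permutation p).
- **Model selection**: per-island AICc competition of candidate regressions
  (global, elevation-only, all-BioPCs, elevation-dependent and -independent
  BioPC sets), Akaike weights, full-set model averaging with unconditional
  SEs and relative variable importance.
- **Traits**: each ecomorph's elevational constraint (Spearman correlation of
  suitability with elevation) correlated against the fixed body-mass ranking
  twig < grass-bush < trunk < trunk-crown < trunk-ground < crown-giant.
- **Synthetic landscapes**: a generator of island environments and ecomorph
  occurrences with known ground truth (mountain / flat-climate / mixed
  scenarios), so the whole chain is testable without any external data.

See `vignettes/ecc-methods.Rmd` for the model, assumptions, parameter
defaults and limitations.

## Worked example

```r
library(eccniche)

# three synthetic islands: two mountainous, one flat-climate with a reduced
# four-ecomorph complement
arch <- make_archipelago(seed = 42, n_islands = 3, scenario = "mixed",
                         shape = c(48, 64), n_occ = 120)
cfg  <- run_config(seed = 42, n_replicates = 5, n_background = 800,
                   n_permutations = 5000)
res  <- run_pipeline(arch$stacks, arch$occurrences, cfg)

round(res$summary$mean_test_auc, 3)
#> [1] 0.862
res$overlap$ECC
#> <overlap_matrix> level ECC
#>          island_1 island_2 island_3
#> island_1    1.000    0.791    0.244
#> island_2    0.791    1.000    0.213
#> island_3    0.244    0.213    1.000
round(res$summary$spearman_r, 3)
#> island_1 island_2 island_3
#>    0.510    0.731   -0.726
res$traits$r; res$traits$p
#> [1] -0.6474695
#> [1] 0.00699860
```

Reading the output: held-out AUC ≈ 0.86 says the ensembles discriminate
presences from background well. The overlap matrix shows the two mountain
islands' cross-fitted ECC niches are similar (D = 0.79) while the
flat-climate island is dissimilar to both (D ≈ 0.2) — community completeness
occupies a different environmental space there. The reduced-dataset Spearman
correlations show ECC tracking elevation on the mountain islands but not on
the flat-climate one. The trait correlation (r = −0.65, p = 0.007 over 16
ecomorph-island combinations) recovers the generator's construction: smaller
ecomorphs are more strongly confined to high elevations.

Per-ecomorph elevational constraints on one mountain island, decreasing with
body mass:

```
     ecomorph mass_rank          r
         twig         1  0.9095872
   grass-bush         2  0.8786826
        trunk         3  0.7597700
  trunk-crown         4  0.6193186
 trunk-ground         5  0.4690675
  crown-giant         6 -0.3325777
```

## Command line

A thin wrapper over the same functions lives in `inst/cli/eccniche.R`:

```sh
Rscript inst/cli/eccniche.R simulate --seed 1 --out data/
Rscript inst/cli/eccniche.R fit-enm --data data/ --out enm/ --seed 1 --replicates 5 --background 800
Rscript inst/cli/eccniche.R ecc --data enm/ --out ecc/
Rscript inst/cli/eccniche.R overlap --data ecc/ --out out/
Rscript inst/cli/eccniche.R pipeline --seed 7 --out out/   # everything at once
```

Rasters are ESRI ASCII grids, occurrences are `ecomorph,island,x,y` CSVs in
map coordinates, configs are YAML (`run_config()` keys), summaries are JSON.
All stages are bit-reproducible under `--seed`.

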