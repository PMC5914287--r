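# dasypop

Dasymetric downscaling of decadal administrative-unit census counts to a
1-km population grid, with historical urban extents reconstructed from an
urban area–population scaling law.

## Who this is for

Spatial demographers, epidemiologists needing historical population
denominators, and anyone studying long-run human–environment interaction
who has census counts on coarse units (counties) and wants defensible
per-pixel population surfaces across decades — including decades for
which no land-cover or remote-sensing covariates exist.

## What it computes

Five nested allocation models of increasing complexity spread each
census zone's population `P_Z` over its pixels:

    P_k = w0_k * w1_k^s * w2_k^d / Σ_Z (w0 * w1^s * w2^d) * P_Z

* **M1** uniform within counties;
* **M2** separates urban areas (with censused populations) from the
  rural remainder `P_R = P_T − Σ P_U`;
* **M3** adds the binary inhabitability mask `w0` (water ≥ 1 km²,
  protected land, elevation > 3500 m, low-population tracts);
* **M4** adds topographic suitability `w1 = exp(m_μ z)` from regional
  regressions of log county density on mean elevation;
* **M5** adds socioeconomic desirability `w2`: inverse-power distance
  decay `r^−λ` inside urban areas with `λ_δ = 2 − 2 β_δ`, and a gravity
  model of market potential over in-range urban areas for rural pixels.

Historical urban extents come from the power law `A_U = α_δ P_U^β_δ`
(fitted per division on the baseline decade) by concentrically shrinking
each baseline footprint toward its center. Exponents `s` and `d` are
calibrated by grid search against tract-level mean absolute relative
error (MARE); model effectiveness is the MARE reduction between
consecutive models. A seeded synthetic-world generator produces complete
fake study regions with known ground truth so the entire pipeline is
testable without any census download.

## Worked example

```r
library(dasypop)

cfg <- pipeline_config(
  out_dir = "run1",
  world = world_config(n_rows = 100, n_cols = 100,
                       counties_per_division = 8,
                       decades = seq(1950, 2000, 10), seed = 1),
  models = c("M1", "M3", "M5"), d = 0.6, log_level = "quiet")
manifest <- run_pipeline(cfg)
manifest$validation$table
#>   model        mare n_units
#> 1    M1 1.768712546      64
#> 2    M3 0.041123461      64
#> 3    M5 0.002457506      64
```

The pipeline simulated a 100×100-km two-division world (seed 1), fitted
the division scaling laws, backcast urban extents for 1950–2000, built
the three weight surfaces, allocated all three requested models for each
decade, and scored them against the world's 64 census tracts at the
baseline decade. The MARE column shows the accuracy ladder: uniform
county allocation is off by ~177% per tract on average, separating
urban/rural and masking non-inhabitable land cuts that to ~4%, and the
full suitability weighting reaches ~0.2% on this generative world. The
fitted scaling table is written alongside:

```r
read.csv("run1/scaling.csv")
#>   division       alpha      beta    lambda n        r2
#> 1        1 0.002173442 0.9472292 0.1055415 6 0.9856414
#> 2        2 0.001538445 0.8887430 0.2225140 7 0.9866896
```

consistent with the generating exponents (0.95 and 0.86) given the
lognormal scatter and the small number of urban areas. Per-decade
population grids land in `run1/pop_<model>_<decade>.asc`, and
`run1/manifest.json` records parameters and md5 hashes of every output;
rerunning the same configuration reproduces the hashes bit for bit.

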