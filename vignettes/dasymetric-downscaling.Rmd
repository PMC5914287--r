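---
title: "Dasymetric downscaling of decadal census populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dasymetric downscaling of decadal census populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dasypop)
```

## The problem

Census counts are reported on administrative units — counties, in the
setting this package targets — which masks all spatial heterogeneity
inside each unit and imposes artificial jumps at unit boundaries.
Dasymetric mapping redistributes each unit's count onto a fine regular
grid (here 1-km pixels) using ancillary covariates. The historical twist
is that the covariates a modern mapper would reach for (land cover,
night lights, roads) do not exist for the 18th–20th centuries, so the
package relies on covariates that can be reconstructed or assumed stable
over time: urban extents backcast from a scaling law, elevation, water
and protected-area masks, and a gravity model of access to urban
markets.

## The allocation model

Within an allocation zone $Z$ — an (urban area ∩ county) intersection or
a county's rural remainder — each pixel $k$ receives

$$P_k \;=\; \frac{w_{0k}\, w_{1k}^{s}\, w_{2k}^{d}}
  {\sum_{j \in Z} w_{0j}\, w_{1j}^{s}\, w_{2j}^{d}} \; P_Z ,$$

so zone totals are conserved by construction. Five nested models use
progressively more information:

* **M1** — one zone per county, all weights flat (uniform density).
* **M2** — urban/rural zones; urban areas get their censused
  populations, the county remainder $P_R = P_T - \sum_\varphi
  P_{U,\varphi}$ is spread uniformly over rural land.
* **M3** — M2 with the binary inhabitability mask $w_0$.
* **M4** — M3 weighted by topographic suitability $w_1^s$.
* **M5** — M4 weighted by socioeconomic desirability $w_2^d$.

Fractional persons are retained throughout: rounding would break exact
conservation, and the products are floating-point grids anyway. When a
zone's weights are identically zero (for instance a fully
non-inhabitable zone carrying population), the population is spread
uniformly over the zone rather than dropped — census totals are treated
as inviolable, and the event is flagged in the result's diagnostics.

### Urban scaling and the density gradient

Urban footprint areas follow a power law in population,
$A_U = \alpha_\delta P_U^{\beta_\delta}$, fitted per census division
$\delta$ by OLS of $\log_{10} A$ on $\log_{10} P$ at the baseline
decade (the regression direction matches the prediction direction:
areas are predicted from populations when backcasting). The fit is
performed in $\log_{10}$; any base gives the same $\beta$. The
intra-urban density gradient is tied to the same exponent through
$\lambda_\delta = 2 - 2\beta_\delta$, so $\beta = 0.95$ gives
$\lambda = 0.10$ and $\beta = 0.86$ gives $\lambda = 0.28$. Scaling
parameters are held constant over decades; there is no reliable
historical evidence for a drift in $\beta$, and the package deliberately
does not model one.

### Extent reconstruction

Two assumptions make historical extents recoverable from a single
observed baseline: urbanization is monotonic, and urban areas grow
outward from a center. An earlier extent is then the distance-ranked
innermost prefix of the baseline footprint with
$n_t = \mathrm{clamp}(\mathrm{round}(A_t/\text{cell area}), 1,
|\text{footprint}|)$ pixels. Ties in the distance sort are broken by
(distance, angle from east, row, column), a total order that makes
extents bit-reproducible across platforms. The center is the footprint
centroid snapped to the nearest footprint pixel (ties to the smallest
row, then column); census-designated city centers would be an
alternative, but centroids require no extra data and are recorded in the
output. Rounding uses half-up rather than the IEEE half-to-even of base
`round()`, again for platform stability. A predicted area that exceeds
the baseline footprint is clamped to the full footprint with a warning —
backprojection should shrink, never grow. While an urban area exists its
extent never drops below one pixel.

### Influence coefficients

* $w_0$ (inhabitability) is binary: zero on protected land, on water
  patches of at least 1 km², above 3 500 m elevation, and in census
  tracts below a per-division population cutoff; one elsewhere. The mask
  is built once from the calibration decade's tract table and held
  fixed over time.
* $w_1 = e^{m_\mu z_k}$ from the regional regression
  $\ln PD_i = m_\mu z_i + b_\mu$ of log county density (over inhabitable
  area only) on county mean elevation. A region whose slope is not
  significant at $p < 0.05$ is flagged unweighted and gets a flat
  $w_1 \equiv 1$ — the treatment applied to regions with no credible
  elevation–density relationship. Sub-region elevation bands are
  supported for regions where one relation does not span the whole
  elevation range.
* $w_2$ differs between urban and rural pixels. Urban:
  $w_2 = \max(r, r_{\min})^{-\lambda_\delta}$ with distance $r$ from the
  urban center. Rural: the gravity model of market potential
  $w_2 = \sum_\varphi P_\varphi r^{-2} \big/ \sum_\varphi r^{-2}$ over
  urban areas within the decade's travel range $D_t$ — a
  population-weighted mean, hence bounded by the smallest and largest
  in-range urban population.

Numerical guards: $r_{\min}$ is half a cell size, preventing the
singularity at the pixel containing the center. Rural pixels with no
urban area in range get the *neutral* weight 1 rather than 0 — zeroing
them would empty remote counties and contradict conservation. The
travel range grows exponentially with time, implemented as log-linear
interpolation between anchors, 30 km in 1790 to 100 km in 2000 by
default. The 1790 anchor is read as 30 km — a plausible daily travel
range on foot or horseback; both anchors and their decades are
configurable. Weight layers can be max-normalized per division for
storage; allocation is invariant to any positive rescaling within a
zone, so normalization is cosmetic (and tested to be).

### Calibration and validation

Accuracy is scored with the mean absolute relative error over reference
units finer than the input counties (tracts primarily, county
subdivisions as a coarser check):
$\mathrm{MARE} = \frac{1}{N_c}\sum_c |M_c - O_c|/O_c$. Units smaller
than 1 km² are excluded (the grid cannot resolve them); units with zero
observed population are excluded with a warning rather than treated as
infinite errors, since the statistic divides by $O_c$.

The exponents are calibrated sequentially by grid search — $s$ under M4
with no socioeconomic term, then $d$ under M5 with $s$ fixed — matching
the nested construction of the models; ties go to the smaller value.
The default $s$ grid spans 0.2–3 in steps of 0.2. For $d$ two presets
ship: the same coarse span, and an extended preset continuing down to
0.02, because some divisions' optima sit below 0.2. The low-population
tract cutoff is selected the same way over
{1000, 1500, 2000, 2500, 3000} persons.

## The synthetic world

`generate_world()` builds a planar study region in which every
assumption above holds *by construction*, so pipeline testing is a
well-posed parameter-recovery exercise rather than a fit to unknown
truth:

* counties tile the grid as rectangular blocks inside division strips;
  tracts and subdivisions slice counties further;
* county log densities follow $\ln PD = m_\mu z + b_\mu + \varepsilon$
  with the elevation surface drawn first (county base level, a smooth
  within-county tilt, and pixel roughness);
* urban areas are single-county discs sized from
  $\alpha P^\beta \times 10^{\mathcal N(0,\sigma)}$, with the noise
  multiplier fixed per urban area across decades;
* populations grow exponentially at a common per-decade factor, and an
  urban area leaves the registry in decades where its population falls
  below the 2 500-person census threshold;
* per-pixel truth is drawn from the full M5 generative form with known
  $(s, d)$, using the same weight-surface constructions the pipeline
  uses.

Default conditions: $\beta = 0.95$ in every division except the last
("Pacific-like") at 0.86; 80% of county population urban (the 2010
urban share of the US population is 80.7%); growth factor 1.23 per
decade (the long-run US average across 1790–2010); decades 1790–2010;
topographic slope $-0.001\,\mathrm{m}^{-1}$ with ln-density noise 0.3;
scaling scatter 0.05 in $\log_{10}$ area; 5% water and 5% protected
area. The within-county elevation tilt (±150 m) is what makes the
topographic exponent identifiable at tract level — without systematic
between-tract elevation differences, tract sums would carry no
information about $s$.

What the generator does **not** emulate: multi-county agglomerations,
non-concentric growth (corridors along rivers or roads), migration
between counties, boundary changes over time, and spatially
autocorrelated density noise. Passing tests therefore demonstrate
algorithmic correctness and estimator consistency under the model's own
assumptions, not accuracy on real censuses.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "run1",
  world = world_config(n_rows = 100, n_cols = 100,
                       counties_per_division = 8,
                       decades = seq(1950, 2000, 10), seed = 1),
  models = c("M1", "M3", "M5"), d = 0.6, log_level = "quiet")
manifest <- run_pipeline(cfg)
manifest$validation$table
```

The manifest records parameters and md5 hashes of every written grid;
rerunning with the same configuration reproduces the hashes exactly.
All randomness flows from the single seed in the world configuration.

## Problem sizes and numerical choices

The test suite and the acceptance script run on worlds between 40×40
and 160×100 cells with 4–11 decades — large enough that every county
hosts hundreds of pixels and estimator sampling error is small, small
enough that a complete run takes seconds to a couple of minutes on one
CPU. The calibration-recovery experiment uses 20 counties per division:
the regional topographic slope enters the weight surface
exponentially, so recovering the exponent $s$ on a 0.2-spaced grid
requires the slope estimate itself to be within a few percent, which
needs a few dozen counties per regression. Conservation is asserted at
a relative tolerance of $10^{-6}$ (measured errors are at machine
precision); model-nesting identities (M4 at $s=0$ equals M3, M5 at
$d=0$ equals M4) are asserted bit-exactly.

## Known limitations

* Counts below the census urban threshold make small historical towns
  invisible: their attraction is folded into rural market potential.
* The inhabitability mask is static; drained wetlands or newly
  protected land are not tracked, so early-decade inhabitable area is
  likely overestimated.
* Backprojection inherits any error in the baseline footprints and in
  the stationarity of $\beta$.
* Real label rasters must be pre-projected to an equal-area grid; the
  package does no reprojection and treats all distances as planar
  Euclidean between pixel centers.
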