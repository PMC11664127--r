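---
title: "The BPT health index: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The BPT health index: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcehealth)
```

# The model

`bcehealth` scores the health of blue carbon ecotones (mangrove, salt
marsh, seagrass) per 1°×1° coastal pixel as

$$\mathrm{EHI}_i = B_i \times [1 - (P_i \times T_i)]$$

with all three components in $[0,1]$.  Benefits and pressures aggregate
additively (cumulative effects); pressure and transformation risk enter
multiplicatively with the benefit, so high pressure on a climatically
transformable system can cascade the score toward zero, while either
$P = 0$ or $T = 0$ leaves $\mathrm{EHI} = B$.

**Benefit** is the arithmetic mean of the available min–max-normalized
fitness indicators — area and fragment area (habitat structure, ha), age
(yr) and canopy height (m) (species characteristics), aboveground biomass
and soil organic carbon (Mg/ha, ecosystem services) — for mangroves, and
normalized area alone for salt marsh and seagrass, whose other indicators
are unavailable at global scale.  A mangrove record needs at least
`min_present = 3` of the six indicators; otherwise it is no-data.

**Pressure** is the mean of four compound scores: climate (ocean
acidification + sea-surface temperature + sea-level rise), land (organic
chemical + direct human + nutrient pollution), marine (artisanal and four
commercial fishing classes + demersal destructive + light + shipping) and
species (proportion of threatened species).  Salt marsh excludes the
species compound.  At least `min_compounds = 2` compounds must be
available, else no-data.

**Transformation risk** comes from niche geometry: the more two ecotones'
climatic niches overlap, the higher the chance one habitat shifts into the
other.  Niches are five-dimensional kernel-density hypervolumes over PAR
(mol m⁻² d⁻¹), tidal amplitude (m), SST (°C), air temperature (°C) and
precipitation (mm/yr); overlap is the Sørensen index
$2 V_\mathrm{shared} / (V_A + V_B)$.  Overlaps are computed per continent
(one uniform T per ecotone × continent), falling back to the worldwide
matrix when a continent has too few complete records.

# Normalization choices

The aggregation requires commensurable inputs, and two points were
genuinely open:

* *Normalization method.*  Only "normalized" is specified upstream; we use
  min–max over the non-missing pixels of the same ecotone, the minimal
  reading that keeps every component — and hence EHI — in $[0,1]$.
  Optional quantile winsorization (`clip_quantiles`) tames raster
  outliers; it is off by default.  Degenerate vectors (min = max) map to
  0.5 with a warning.
* *Compound pressures.*  The compounds are described as "sums" of raster
  layers with heterogeneous units, so by default each sub-layer is min–max
  normalized before summing and each compound sum is re-normalized to
  $[0,1]$ before entering the pressure mean; summing raw layers first is
  available via `normalize_sublayers = FALSE`.  Without some such
  normalization the multiplicative index could not span the observed ~0–1
  range.

Per-variable normalization statistics (min/max per ecotone) are written to
the `provenance.json` sidecar so a scored table can be reproduced exactly.

# The hypervolume estimator

The niche of an ecotone with observations $x_1,\dots,x_n$ (log10 scale) is
the super-level set $\{x : f(x) \ge c\}$ of the equal-weight Gaussian
mixture $f$ with diagonal bandwidths from Silverman's normal-reference
rule, $h_j = \sigma_j (4/(d+2))^{1/(d+4)} n^{-1/(d+4)}$.  The threshold
$c$ is the $(1-q)$ quantile of the mixture density evaluated at a Monte
Carlo cloud drawn from $f$ itself, so the set retains probability mass
$q$ (default 0.95).  Its volume is the importance-sampling estimate
$\hat V = m^{-1} \sum_s \mathbf{1}\{f(x_s) \ge c\} / f(x_s)$, and the
shared volume of two hypervolumes averages the two directional estimates
(each cloud tested against the other's mixture and threshold), making the
Sørensen index symmetric by construction.  The MC budget defaults to
$\max(10^4, \lceil 10^4/n \rceil n)$ samples; all randomness flows through
an explicit seed, and identical seeds give identical volumes and overlaps
to full precision.

All five climate dimensions are log10-transformed.  Axes that can be
non-positive on natural scales (air temperature in °C) are first shifted
so the minimum maps to +1; shifts are computed once over the whole table
and recorded in provenance, so per-continent hypervolumes share one
transform and their overlaps are comparable.

Two numerical facts matter when reading overlap values.  First, KDE
level-set estimation converges slowly in five dimensions: two
*independent* samples of the same distribution give Sørensen ≈ 0.6–0.7 at
n = 600, so "identical niches" only produce overlap ≈ 1 when the ecotones
share the same climate field (as co-occurring pixels do).  Second, volumes
are products of five axis units and are only meaningful relative to other
volumes under the same transform.

# Transformation-risk collapse

An ecotone on a continent has up to two pairwise overlaps; the mapping to
a scalar T is unspecified upstream.  The default is `max` — the
conservative worst-case transformation pressure — with `mean` and
`sum_capped` (sum clipped at 1) available.  The fallback order
continent → worldwide → no-data is recorded per record in `t_source`.

# Classification

EHI classes use exact Fisher–Jenks natural breaks (`k = 3`): the dynamic
program minimizes the total within-class sum of squared deviations over
all contiguous partitions of the sorted values and provably equals
exhaustive search (a property test checks every random vector up to
n = 25).  Breaks are the class maxima; a value exactly at a break belongs
to the lower class.  Breaks are recomputed per dataset — published
breakpoints are properties of their data, not constants of the method —
and class proportions are reported over all records, with no-data as its
own share, so rows sum to 100%.

# Sensitivity analysis

First-order Sobol indices $S_i = \mathbb{V}[\mathbb{E}(\mathrm{EHI}|X_i)] /
\mathbb{V}(\mathrm{EHI})$ use the paired-matrix design with the
Saltelli-2010 product estimator on centered outputs (centering removes a
finite-sample offset bias; the estimator is then invariant to affine
rescaling of the output).  Standard errors are a nonparametric bootstrap
over base rows (default 100 replicates) and `q05 = s1 − 1.645·se` is the
normal-approximation 0.05 quantile.  Inputs for the pipeline GSA are the
ecotone's normalized fitness indicators, its pressure compounds and T,
resampled *independently* from their empirical marginals — rank
correlations among inputs are deliberately ignored, which is the standard
independence assumption of the variance decomposition and is flagged in
the output metadata.  The oracle suite checks the additive closed form
$S = (1,4,9)/14$ and the Ishigami benchmark against their analytic values.

# Trend regressions and the mixed model

The latitudinal gradient is estimated on 1° bands of $|$latitude$|$: band
means of EHI are regressed on the within-band mean $|$latitude$|$ (exact
for a noiseless linear gradient, unlike nominal band centers), weighting
each band by its record count.  The weighting matters: band means are
heteroscedastic (counts vary between bands, e.g. where only one
hemisphere contributes), and unweighted OLS undercovers the slope CI
(≈91/100 against a nominal 95%); count weighting is the efficient
estimator for binned means and restores nominal coverage.  Record-level
covariate trends (EHI–SOC, EHI–diversity style) are plain OLS with
closed-form slope, $R^2$ and two-sided t-test p-values (no multiple-testing
correction), verified against `lm()` to 12 decimals.

The bioclimatic baseline EHIc is a random-intercept model
$\mathrm{EHIc} = X\beta + b + \epsilon$ with one intercept per continent.
With a single grouping factor the REML criterion profiles down to a 1-D
search over $\log\lambda$, $\lambda = \sigma_b^2/\sigma_e^2$, using the
closed-form blockwise inverse $V_g^{-1} = I - \lambda/(1+\lambda n_g)\,J$;
the search is bounded with tolerance $10^{-8}$ and an explicit
$\sigma_b = 0$ boundary check.  Group intercepts are empirical-Bayes BLUPs
and shrink toward zero as $\sigma_b/\sigma_e \to 0$.  Tests verify the fit
against `lme4::lmer` and, on balanced one-way designs, against the ANOVA
closed form ($\hat\sigma_e^2 = \mathrm{MSW}$,
$\hat\sigma_b^2 = (\mathrm{MSB}-\mathrm{MSW})/n$).  The grouping is a
random intercept per continent; an overlap-valued random slope is a
plausible alternative reading of the design and is intentionally out of
scope.

# The synthetic world

The generator emulates the *structure* of the (undeposited) compiled
global table, not its values:

* Ecotone latitude bands: mangrove 38.5°S–29.5°N; salt marsh 46.5°S–3.5°S
  ∪ 17.5°N–71.5°N (hemisphere sampled with probability proportional to
  band width, keeping density uniform over the union); seagrass
  43.5°S–69.5°N.  Pixel centers snap to the integer+0.5 grid.
* Climate covariates follow linear trends in $|$latitude$|$ plus Gaussian
  noise, on field-realistic scales (SST 28 °C at the equator − 0.3 °C per
  degree, PAR 45 − 0.35 mol m⁻² d⁻¹ per degree, precipitation 2200 − 18
  mm/yr per degree, air temperature 28 − 0.45 °C per degree — crossing
  0 °C poleward, which exercises the log-shift machinery — tidal amplitude
  1.2 + 0.015 m per degree).  Fitness indicators decline poleward
  similarly and are truncated at 0; pressure components are truncated
  normals; the species fraction is Beta(2, 8).  These defaults were chosen
  once as a realistic stated world and are not tuned to test outcomes.
* Missingness defaults to the reported whole-pixel no-data fractions —
  16% (mangrove), 15% (salt marsh), 29% (seagrass) — flagging exactly
  `round(f·n)` records (round half up); a per-field mode exists for
  sparser, indicator-level gaps.
* Continents come from a configurable longitude-sector lookup (with a
  latitude split for the Americas and Europe/Africa), not coastlines, and
  pixels are not spatially autocorrelated.  A `shared_pixels` layout draws
  one set of locations and assigns each ecotone the pixels inside its
  band, since it is unspecified whether the original grid counts pixels
  per ecotone or shares them.

What a green test therefore establishes: the estimators recover known
structure (gradients, mixture weights, variance decompositions, band
memberships) from data with the assumed shape.  What it does not
establish: anything about real coastlines, real spatial dependence, or
the published global numbers, which require the original compiled data.

# Degenerate inputs and tie rules

* min = max in normalization → all 0.5 with a warning; all-missing →
  error.
* Fewer than `min_present` indicators / `min_compounds` compounds, or no
  overlap data at any level → no-data, which propagates through EHI and is
  counted as its own class share.
* Jenks ties → the smallest feasible break index (lower break value);
  classification at a break → lower class.
* A continent × ecotone group under `min_points = 20` complete climate
  rows is reported missing (NA), never zero overlap.
* Single-group mixed model → OLS with a warning; collinear fixed effects →
  error naming the columns.

# Known limitations

Sørensen overlaps of independent finite samples are downward-biased in
5-D (see above); Sobol inputs are resampled independently, so indices on
strongly rank-correlated real data would need a correlated-input method;
the "global coastal wetland EHI" (per-pixel sum over co-occurring
ecotones, range 0–3) is available from the scored table but deliberately
unnormalized; total-order Sobol indices and spatial autocorrelation are
out of scope.
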