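# bcehealth

Composite health scoring for blue carbon ecotones — mangroves, salt marshes
and seagrass meadows — on a 1°×1° coastal pixel grid.

These three ecosystems store disproportionate amounts of carbon at the
land–ocean interface, and conservation triage needs a single, comparable
health score per site.  `bcehealth` implements a
**Benefit–Pressure–Transformation risk (BPT)** model: for pixel *i* of an
ecotone,

```
EHI_i = B_i × [1 − (P_i × T_i)]
```

* **B** (Benefit) — mean of min–max-normalized ecotone-fitness indicators:
  area, fragment area, age, canopy height, aboveground biomass (AGB) and
  soil organic carbon (SOC) for mangroves; normalized area alone for salt
  marsh and seagrass (data limitations).
* **P** (Pressure) — mean of four normalized compound pressures: climate
  (ocean acidification + SST + sea-level rise), land (organic chemical +
  direct human + nutrient pollution), marine (fishing classes + light +
  shipping) and species (proportion of IUCN-threatened species); the
  species compound is excluded for salt marsh.
* **T** (Transformation risk) — the risk that one ecotone shifts into
  another, scored from the Sørensen overlap `2·V_shared / (V_A + V_B)` of
  five-dimensional climatic hypervolumes (PAR, tidal amplitude, SST, air
  temperature, precipitation; Gaussian KDE with Silverman bandwidths on
  log10-transformed axes), computed per continent and collapsed per
  ecotone (default: max over its pairs).

EHI is classified High / Medium / Low with exact Fisher–Jenks natural
breaks, and downstream analyses cover first-order Sobol sensitivity
indices (with bootstrap SEs and normal 0.05 quantiles), binned latitudinal
trend regressions, record-level covariate trends (e.g. EHI vs SOC) and a
profile-REML random-intercept model of the bioclimatic EHI baseline per
continent.

The compiled global dataset behind the original analysis is not publicly
deposited, so the package ships a first-class **synthetic world
generator** reproducing the structure that analysis assumes — ecotone
latitude bands (mangrove 38.5°S–29.5°N, salt marsh 46.5°S–3.5°S and
17.5°N–71.5°N, seagrass 43.5°S–69.5°N), latitudinal climate and fitness
gradients, compound pressure fields and per-ecotone no-data fractions
(16% / 15% / 29%) — so the whole pipeline is testable offline.

## Worked example

```r
library(bcehealth)
cfg <- run_config(world = world_config(n_pixels_per_ecotone = 500, seed = 7),
                  seed = 7)
res <- run_pipeline(cfg)

print(res$overlaps_worldwide)
#> Sorensen overlap matrices (worldwide, q = 0.95)
#>  worldwide:
#>            mangrove salt_marsh seagrass
#> mangrove      1.000      0.136    0.173
#> salt_marsh    0.136      1.000    0.747
#> seagrass      0.173      0.747    1.000

print(res$class_summary)
#>      ecotone  high medium   low no_data   n
#> 1   mangrove 0.286  0.334 0.220    0.16 500
#> 2 salt_marsh 0.246  0.396 0.208    0.15 500
#> 3   seagrass 0.226  0.324 0.160    0.29 500

print(res$trends$latitude_mangrove)
#> Trend ehi ~ abs_latitude: slope = -0.006547, R2 = 0.851, p = 1.81e-16, n = 38
```

Reading the output: in this synthetic world the tropical mangrove niche is
climatically distinct (overlaps 0.14–0.17) while the temperate salt marsh
and seagrass niches overlap strongly (0.75), so their transformation risk
T is high; class proportions per ecotone sum to 1 including the injected
no-data shares (0.16/0.15/0.29); and because the generator gives fitness
indicators a poleward decline, the binned latitudinal regression recovers
a negative EHI gradient (≈ −0.0065 per degree of |latitude|).

Per-ecotone Sobol indices (`res$sobol$mangrove`) decompose EHI variance
over the normalized indicators, the four pressure compounds and T; in the
default world T dominates (S1 ≈ 0.45) because it varies by continent
while pressures are latitude-independent noise.

## Command line

```sh
Rscript -e 'bcehealth::bce_cli()' run-all --out results --seed 7
Rscript -e 'bcehealth::bce_cli()' simulate --out world --n 1000 --seed 3
```

Subcommands: `simulate`, `score`, `hypervolume`, `ehi`, `classify`, `gsa`,
`trends`, `run-all`; flags `--config` (YAML), `--input` (pixel CSV),
`--seed`, `--out`, `--n`, `--verbose`.  `run-all` writes `ehi_table.csv`,
two overlap tables, `class_summary.csv`, `sobol.csv`, `trends.csv` and a
`provenance.json` sidecar (normalization statistics, hypervolume shifts,
seeds, config hash); reruns with the same seed are byte-identical.

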