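# pigloop

Non-contact live-weight estimation from dorsal segmentation masks, and
what it buys a pig farm: precision feeding plans and a smaller
cradle-to-farm-gate carbon footprint. `pigloop` implements the full
downstream loop of a camera-based precision-farming system — everything
after the neural segmenter has produced a binary mask of the pig's back:

1. **Morphometrics** — five features from each mask: relative projection
   area `RA = Pw / Pt`, contour perimeter `CP` (closed polygonal arc
   length of the outer boundary), body length and width `BL, BW` (sides
   of the minimum-area rotated rectangle, by rotating calipers over the
   convex hull), and eccentricity `E = sqrt(1 - (b/a)^2)` of the
   least-squares ellipse fit to the contour.
2. **Weight model** — a random-forest regressor on the feature vector
   `X = [RA, CP, BL, BW, E]`, trained under an animal-level 80/20 split
   (whole pigs on one side, never records) with pig-level 5-fold
   cross-validated grid search over forest size, depth and node size,
   selected by CV mean absolute error.
3. **Feeding optimizer** — growth-stage ration tables (weaning through
   late fattening) plus dynamic rules: in the 30–80 kg rapid-growth band
   corn rises to 68% and soybean meal to 19%; pigs gaining under
   0.6 kg/day get 20% soybean meal plus 2% fishmeal. Rations always
   re-balance to 100%.
4. **Carbon LCA** — five linear components (feed production, transport,
   enteric fermentation, energy, manure management) under AR5 GWPs
   (CO2 = 1, CH4 = 28, N2O = 298), normalised per kg live weight:
   `CF = (CF_forage + CF_transport + CF_enteric + CF_energy +
   CF_manure) / W_live`. Enteric methane scales with body weight,
   `EF(W) = 1.00 kg CH4/head/yr × W / 105`; manure N2O uses per-system
   direct factors plus volatilisation/leaching indirect terms, with
   N2O-N converted by 44/28.
5. **Synthetic data** — superellipse silhouette rendering with analytic
   ground truth, longitudinal growth cohorts with allometrically linked
   features, and farm activity ledgers, so the whole loop is testable
   without proprietary farm data.

## Worked example

```r
library(pigloop)

# a synthetic dorsal mask with known geometry: semi-axes 200 x 100 px
mask <- render_mask(silhouette_spec(200, 100))$mask
round(extract_features(mask), 4)
#>       RA       CP       BL       BW        E
#>   0.1533 968.0623 400.7451 200.8726   0.8670
```

`RA` matches the analytic `pi*200*100/640^2 = 0.1534`; `CP` is within
0.1% of the Ramanujan perimeter 968.84; `BL`/`BW` recover the 400 x 200
extent within a pixel; `E` is within 0.001 of `sqrt(1 - 0.25) = 0.8660`.

```r
co    <- generate_cohort(cohort_spec(n_pigs = 63, noise_sd_weight = 3, seed = 1))
parts <- split_by_pig(co, 0.2, seed = 1)        # 50 train / 13 test pigs
model <- fit_weight_model(parts$train,
                          search_grid(c(100, 200), c(10, 0), c(2, 5), seed = 1))
evaluate_weights(predict(model, parts$test), parts$test$true_weight)[c("MAE", "R2")]
#> $MAE            $R2
#> [1] 1.685       [1] 0.9939
round(feature_importances(model), 3)
#>    RA    CP    BL    BW     E
#> 0.403 0.280 0.150 0.164 0.002
#> (impurity importance, normalised)
```

The held-out error sits well under the 3 kg observation noise and `RA`
— the generator's dominant feature — ranks first in importance.

```r
total_footprint(cf_forage = 4.15, cf_enteric = 2.65, cf_manure = 1.50,
                live_weight = 1)$cf_per_kg
#> [1] 8.3
```

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end and write
their tables to `results/`:

| script | what it does |
| --- | --- |
| `01_simulate.R` | 63-pig cohort, mask gallery with ground truth, activity ledger |
| `02_features.R` | batch feature extraction, agreement with analytic truth |
| `03_weight_model.R` | animal-level split, CV grid search, held-out evaluation |
| `04_feeding.R` | per-pig stage classification, ADG, adjusted rations, labor bookkeeping |
| `05_footprint.R` | baseline footprint and a what-if scenario with the trial's reported feed/manure reductions |

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

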