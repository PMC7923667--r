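# fbdgcarbon

Carbon-footprint modelling of national food-based dietary guidelines (FBDG).

National dietary guidelines tell people how much of each food *group* to eat
(protein foods, dairy, grains, fruit, vegetables, oils/fats) but never which
foods within a group, so the greenhouse-gas footprint of "eating by the
guideline" can only be computed by pairing the recommendation with a
consumption pattern — the shares of beef vs. beans vs. poultry a population
actually eats, derivable from food-balance-sheet supply data. `fbdgcarbon`
implements that model end to end for nutrition and food-system researchers
who want to compare the climate implications of dietary guidance across
countries.

## The model

For a food group *g* with recommended daily amount REC<sub>g</sub>, the
group's emissions are a consumption-weighted average over the commodities
*c* in the group:

```
GHGE_g = Σ_c  REC_g × Proportion_c × CF_c × GHGE_c
```

* **Proportion<sub>c</sub>** — commodity *c*'s share of the group's total
  cooked-edible per-capita supply ("apparent consumption"), computed after
  converting balance-sheet quantities through carcass→boneless,
  shell-removal, and raw↔cooked conversion chains.
* **CF<sub>c</sub>** — a composite factor turning the recommendation's unit
  (g, oz, ml, cups, pieces) into kilograms of *raw edible* commodity. Volume
  units use calorie equivalence (a cup of black beans has 662 kcal, 100 g
  has 341 kcal, so one cup ≡ 194 g); dairy volumes use a milk density of
  1.0305 g/ml; cooked recommendations are adjusted back to the raw basis of
  the emission factors.
* **GHGE<sub>c</sub>** — mean cradle-to-farm-gate emissions per kilogram of
  raw edible food (kg CO₂-eq/kg), from a life-cycle-assessment-derived
  intensity table.

Group values are summed to a diet total; a quantified sugar allowance is
added as its own single-commodity group; and unspecified "discretionary
calories" are allocated pro rata, scaling the total by
`diet_kcal / (diet_kcal − discretionary_kcal)`. Guidelines stated at other
energy levels are first scaled linearly to a common 2000-kcal basis.

Because the pattern term mixes "what the guideline asks" with "what the
country eats", the package also provides a **controlled comparison**:
re-evaluating every guideline under one fixed reference pattern
(conventionally the US), so remaining differences reflect the
recommendations alone.

## Worked example

The packaged worked example carries the US fruit recommendation (2 cups/day)
with its ten balance-sheet fruit commodities:

```r
library(fbdgcarbon)
ex <- us_fruit_example()
res <- group_footprint(ex$rec_amount, ex$pattern, ex$conversions,
                       ex$impacts, unit = "cup")
res$contributions[, c("commodity", "proportion", "cf", "intensity", "ghge")]
```

```
                                      commodity proportion    cf intensity  ghge
1                           Apples and products      0.178 0.110     0.228 0.009
2                                       Bananas      0.113 0.150     0.374 0.013
3                                 Citrus, other      0.002 0.185     0.438 0.000
4                                         Dates      0.001 0.075     2.024 0.000
5                      Grapefruits and products      0.017 0.210     1.210 0.009
6                           Grapes and products      0.085 0.120     0.478 0.010
7                   Lemons, limes, and products      0.091 0.210     0.517 0.020
8  Oranges, tangerines, mandarins, and products      0.231 0.185     0.347 0.030
9                       Pineapples and products      0.061 0.165     0.914 0.018
10                                Fruits, other      0.222 0.196     0.652 0.057
```

Each row is 2 cups × proportion × (kg/cup) × (kg CO₂-eq/kg); the rows sum to
`res$ghge` = **0.165 kg CO₂-eq/day** for the fruit recommendation. Applying
the discretionary-calorie rule to the published US per-group values
(sum 3.31, 270 discretionary kcal of 2000) reproduces the published diet
total:

```r
apply_discretionary(3.31, 270, 2000)
#> 3.83 (2 dp)
```

## Batch runs and synthetic data

A "study bundle" is a directory of plain-text inputs — guideline YAML
configs, supply/dairy CSVs, conversion factors, emission intensities, and a
composition table. `gen_study_bundle()` writes a fully synthetic one (shares
drawn Dirichlet on the cooked-edible simplex, lognormal intensities,
deterministic under a seed), and the reporting layer runs it:

```r
rc <- gen_study_bundle(synthetic_config(n_countries = 3, seed = 42), "bundle/")
run_controlled(rc)[, c("country", "protein_foods", "dairy", "total",
                       "ratio_to_reference")]
```

```
       country protein_foods dairy total ratio_to_reference
1 Synthetia-01          0.30  0.08  1.73               1.00
2 Synthetia-02          0.18  0.35  2.63               0.66
3 Synthetia-03          0.28  0.28  3.57               0.48
```

`run_baseline()` evaluates each country under its own pattern;
`run_controlled()` re-evaluates all countries under the reference country's
pattern and adds the ratio column (reference total ÷ row total). Both write
rounded CSV reports plus a full-precision per-commodity breakdown. A thin
CLI wrapper with `baseline` / `controlled` / `synth` / `validate`
subcommands ships in `inst/cli/fbdgcarbon.R`.

The nine packaged guideline configs (Germany, India, the Netherlands, Oman,
Thailand, the US, the US vegetarian pattern, Uruguay, and EAT-Lancet) are in
`inst/extdata/guidelines/`; `example_guidelines()` loads them.

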