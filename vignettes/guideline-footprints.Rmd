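---
title: "Modelling the carbon footprint of dietary guidelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the carbon footprint of dietary guidelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbdgcarbon)
```

## The problem and the model

National food-based dietary guidelines (FBDG) quantify food *groups* —
"135 g/day of protein foods" — never individual foods, yet the greenhouse-gas
cost of a kilogram of beef is two orders of magnitude above a kilogram of
beans. Attributing emissions to a guideline therefore requires a bridge from
groups to foods. This package uses the apparent-consumption bridge: within
each group, foods are weighted by their share of the country's per-capita
food supply (balance-sheet accounting: production + imports ± stocks −
exports − non-food uses), a standard proxy for national consumption when
intake surveys are unavailable.

The group footprint is a weighted average scaled by the recommendation,

$$\mathrm{GHGE}_g \;=\; \sum_{c}
  \mathrm{REC}_g \times \mathrm{Proportion}_c \times CF_c \times
  \mathrm{GHGE}_c ,$$

with $\mathrm{REC}_g$ the daily recommended amount of group $g$ (in the
guideline's own unit), $\mathrm{Proportion}_c$ commodity $c$'s share of the
group's cooked-edible supply, $CF_c$ the unit-to-raw-kg conversion, and
$\mathrm{GHGE}_c$ the cradle-to-farm-gate emission intensity (kg CO~2~-eq per
kg of raw edible food). Group values sum to the diet total; a quantified
sugar allowance enters as a one-commodity group; discretionary calories —
energy the guideline allows without naming foods — scale the total by
$E/(E - E_{\mathrm{disc}})$, i.e. they are assumed to be eaten with the same
composition as the specified diet. The model's central assumptions, then,
are (i) supply shares approximate intake shares, (ii) one global intensity
per commodity (production-practice differences between countries are not
resolved by current LCA coverage), and (iii) compositional neutrality of
discretionary calories.

## Units and conversion chains

Internally everything is kilograms and kilocalories. Supply-side conversion
to the cooked-edible basis is driven by each record's *processing state*:

| state          | chain                                   | typical factor direction |
|----------------|-----------------------------------------|--------------------------|
| `carcass`      | carcass→boneless, then raw→cooked       | both ≤ 1 (bone-out, cooking loss) |
| `raw_in_shell` | shell removal                           | ≤ 1 |
| `raw_edible`   | raw→cooked                              | ≤ 1 for meat/fish |
| `dry_raw`      | dry→cooked                              | ≥ 1 (water uptake) |
| `as_is`        | none                                    | — |

Factors ship as data (`{commodity, step, factor, direction}`) and are
validated against their declared direction rather than a guessed one; the
"average of dry and wet cooking methods" behind a raw↔cooked factor is an
unweighted arithmetic mean, taken upstream when the factor file is built
(`aggregate_conversion()` provides the mean for aggregate commodities). The
paperwork side of $CF_c$ handles the recommendation units: ounces at
28.3495 g/oz; millilitres through a density of 1.0305 g/ml (milk's printed
density, used for all dairy unless overridden — only milk's value is
commonly published); cups through calorie equivalence
($100 \times \mathrm{kcal_{cup}} / \mathrm{kcal_{100g}}$ grams per cup); one
"piece" of fruit equated to one cup. A `serving` unit is rejected outright:
serving sizes are country-specific, so configs must resolve them to g/ml/cup
before analysis. Full precision is kept everywhere internally; rounding
(2 decimals in country tables, 3 in the worked example) is display-only, and
ratio columns are computed from full-precision totals before rounding.

## Tunable parameters

* `target_kcal` (default **2000 kcal/day**) — the common energy basis;
  scaling is linear (degree-1 homogeneous), so any basis works, but 2000 is
  the convention the packaged guidelines are transcribed at.
* `density` (default **1.0305 g/ml**) — dairy volume-to-mass.
* Share-sum tolerance in `consumption_pattern()` (default **1e-9**) —
  computed patterns are exact simplex points; the packaged worked example
  loosens it to 5e-3 because its published proportions were rounded to three
  decimals at source (they sum to 1.001) and are deliberately fed through
  un-renormalized.
* `synthetic_config()`: 7 countries × 10 commodities per non-dairy group +
  4 dairy products (a vocabulary of the size a real balance-sheet extract
  yields), Dirichlet `share_concentration = 1` (uniform on the simplex — no
  prior structure), lognormal intensities with `log_mean = 0`, `log_sd = 1`
  (median 1 kg CO~2~-eq/kg, right tail into ruminant territory).

## Design choices where the procedure was genuinely open

* **Exclusion-then-renormalization.** Commodities without an emission
  intensity are dropped *before* shares are computed, and the remaining
  shares renormalized to 1; the dropped fraction is kept as
  `excluded_share` and surfaced as an audit message. Renormalizing keeps the
  weighted average well defined; the logged share preserves auditability of
  what was dropped (in the real data those commodities were trivial,
  < 10 kcal/capita/day).
* **Conversion before division.** Proportions are defined on the
  cooked-edible mass basis — conversion chains first, shares second — so a
  group mixing dry legumes with fresh produce is weighted by what is eaten,
  not by what is shipped.
* **Sugar before discretionary.** The sugar add-on joins the base total
  before discretionary scaling. The ordering is numerically immaterial at
  display precision (sugar terms are a few hundredths of a kg CO~2~-eq/day)
  but must be fixed for byte-identical reports.
* **State-keyed chains.** Conversion chains attach to processing states, not
  to individual records; an explicit `conversion_chain` column can override.
  Source descriptions of the chains are per commodity class, which the state
  captures exactly.
* **Subgroups by commodity.** Guidelines that pin sub-quantities inside a
  group (plant-protein splits) carry them as commodity-keyed amounts that
  replace the pattern weighting for that group; amounts must re-sum to the
  group amount within 1%. A full commodity-class taxonomy would add a
  second controlled vocabulary with no gain at this granularity.
* **Combined fruit+vegetables.** For guidelines with a single combined
  group, the pattern is computed by pooling the two groups' supply records
  and sharing over the pool — equivalent to a supply-weighted merge of the
  component patterns.
* **Countries are data.** Guideline configs are YAML files, one per
  country; the engine hard-codes no country. Output ordering follows input
  order.

## What the synthetic generator does and does not emulate

`gen_study_bundle()` emits every input the pipeline reads — supply, dairy
supply, conversion factors, intensities, composition, guidelines — with the
schemas and physical constraints of real data (direction-valid factors,
simplex shares, positive skewed intensities) and full determinism under a
seed. Shares are drawn Dirichlet on the *cooked-edible* simplex and
back-converted through the chains, so the forward pipeline recovers them
exactly; that makes share recovery a sharp test. It does **not** emulate
real country profiles: no correlation between a country's wealth and its
meat share, no commodity-level correlation between intensity and
consumption, no year-to-year structure. Green tests on synthetic bundles
therefore demonstrate the *mechanics* — conversion, exclusion,
renormalization, weighting, scaling, report plumbing — not the empirical
footprints of any real guideline. The empirical anchors are the packaged
worked example (a single-group calculation with every input printed at
source) and the published per-group cells used for arithmetic-identity
regression tests; the full cross-country tables are not recomputable here
because the underlying supply and intensity databases are not
redistributable, which is also why the regression tolerances are those of
rounded cells (±0.005 per cell, looser where an un-printed sugar term enters)
rather than machine precision.

## Numerical notes and degenerate inputs

Share computation refuses groups with zero includable mass
(`fbdg_empty_group_error`) rather than returning NaN; restriction to a
disjoint commodity set fails the same way, naming country and group. Missing
table entries raise `fbdg_missing_reference_error` naming the commodity and
step — a lookup never silently yields zero, because a zero intensity is a
claim, not an absence. A recommendation of 0 yields exactly 0 everywhere.
Discretionary energy equal to or above the diet energy is rejected (the
allocation would divide by ≤ 0). Scaling, resolution, and the footprint sum
are all linear, which the property tests exploit: homogeneity of guideline
scaling, scale invariance of patterns, convex-combination bounds on the
per-unit group intensity (the weighted average cannot leave the range of
$CF_c \cdot \mathrm{GHGE}_c$), idempotent restriction, and equality with
brute-force loop oracles at 1e-9 on 100 random instances each. Test problem
sizes (2–10 commodities per group, 2–7 synthetic countries, 200 Dirichlet
draws for the concentration check) keep the full suite under a minute while
leaving every code path exercised.

## Limitations

Apparent consumption is supply, not intake: waste at retail and household
level inflates it, and it carries no age- or sex-specific structure. One
global intensity per commodity ignores country production differences;
boundaries are cradle-to-farm-gate, so processing, transport, retail, and
cooking energy are outside the accounting, and non-climate impacts (land,
water, eutrophication) are out of scope. The calorie-equivalence cup
conversion assumes the composition table's food matches the commodity's
consumed form. These are properties of the modelling tradition the package
implements, stated here so results are read with the right error bars.
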