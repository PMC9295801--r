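---
title: "Accounting for marine nutrient flows: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accounting for marine nutrient flows: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriflows)
```

## The problem

Marine fisheries catch nutrients, not just tonnage: the same landed mass can
carry very different amounts of calcium, iron, zinc, selenium, omega-3 fatty
acids, vitamin A and protein depending on species composition. Two
distribution processes move those nutrients between nations before anyone
eats them: foreign fishing (fleets catching in other nations' exclusive
economic zones, EEZs, or on the high seas) and international trade.
`nutriflows` converts catch and trade records into nutrient masses and
recommended-nutrient-intake (RNI) equivalents, computes who gains and who
loses from each process, traces flows between categories of nutrient
insecurity, and scores each nation's vulnerability to future changes in
these supplies.

The package operates on five plain tables: long-format catch records
(`year, fishing_nation, source_zone, taxon_id, tonnes`, where `source_zone`
is an EEZ nation or the reserved high-seas token `HS`), bilateral trade
records (`year, exporter, importer, taxon_id, tonnes`), a taxon table with
per-100 g nutrient concentrations at mixed taxonomic resolution, a
flag-of-convenience (FOC) registry, and a national indicator table. A
seeded synthetic-world generator produces self-consistent instances of all
five, so every stage can be exercised and tested offline.

## Assigning nutrient concentrations

Species-rank taxa carry their own concentrations (per 100 g of raw
portion). Genus- and family-rank taxa with missing values are imputed as
unweighted arithmetic means over the species-rank members of the same genus
or family — the averaging is deliberately unweighted, since a weighted
choice would smuggle catch composition into a purely taxonomic estimate.

Taxa reported below family resolution (e.g. "marine finfishes") are
resolved by a four-tier ladder implemented in `resolve_coarse()`:

1. the taxon's own (or taxonomy-imputed) values, if complete;
2. the catch-tonnage-weighted mean concentration over resolvable taxa
   reported from the **same zone** (or by the same trading nation, for
   trade records);
3. the tonnage-weighted mean over resolvable taxa **globally**;
4. the unweighted mean over all species-rank rows.

The ladder is a package default that preserves local-composition logic
(what a coarse "finfishes" record most plausibly contains is whatever else
is being caught there); it is not a literal published rule, and the tier
actually used for every record is recorded in the concentration audit
table so analyses can be screened for heavy reliance on the lower tiers.

## Accounting conventions

* `mass = tonnes × 10⁴ × conc`: a tonne is 10⁴ hundred-gram portions, so
  masses inherit the concentration's native unit (g, mg or mcg).
* RNI-equivalents divide an annual mass by `rni_per_day × 365`. A 365-day
  year is used throughout; fractional persons are kept.
* Per-capita yields are `(annual_mass / 365) / population / rni_per_day ×
  100`, i.e. percent of RNI per capita per day.
* No edible-portion conversion is applied: conversion factors are missing
  or inconsistent for most taxa, so masses are whole-biomass figures and
  should be read as potential, not consumed, supply.
* RNI values are inputs (`rni.csv`), not constants. The synthetic world
  ships defaults at the magnitude of published WHO/FAO recommendations for
  reproductive-age females (protein 46 g/d, calcium 1000 mg/d, iron
  29.4 mg/d, zinc 4.9 mg/d, selenium 26 mcg/d, omega-3 1.1 g/d, vitamin A
  500 mcg/d); any real analysis should supply its own table.

### Flag-of-convenience adjustment

A nation's foreign-fishing catch (foreign EEZs plus high seas) is split
into a retained share `1 − p` and a pool share `p`, where `p` averages the
2013 and 2018 registry columns. The pool is booked under the pseudo-nation
`FOC` and never reassigned: beneficial ownership is unobservable from the
registry. Two asymmetries are deliberate:

* the adjustment applies only to foreign-fishing records — domestic catch
  stays with the flag nation;
* the losses other nations suffer (`LossFF`) are computed from
  **unadjusted** records, because the extraction from a nation's EEZ is
  physical and does not depend on who really owns the vessel.

Consequently the sum of EEZ-only foreign-fishing balances over nations is
exactly zero with the adjustment off, and exactly minus the EEZ share of
the FOC pool with it on — both identities are asserted in the tests.

## Balances and classification

Per nation and nutrient, in RNI-equivalents:

* foreign-fishing balance `FFB = FF − LossFF`, where `FF` optionally
  includes the high-seas catch (`include_high_seas`);
* trade balance `TB = IMP − EXP`.

The across-nutrient summary is an unweighted arithmetic mean of the seven
per-nutrient balances. Quadrant classification uses the signs of the two
mean balances; an exact zero classifies as a gain (a documented,
overridable tie rule — zeros are overwhelmingly "no such channel" cases,
which we read as "not losing").

## Flows between intake categories

Flow matrices are produced for calcium, iron, zinc and vitamin A — the
four nutrients with both concentration estimates and national
inadequate-intake prevalence data. Prevalence bins are right-closed:
`V.Lo` ≤ 5 < `Lo` ≤ 10 < `Med` ≤ 25 < `Hi` ≤ 50 < `V.Hi`, with `ND` for
nations lacking data; boundary prevalences of exactly 5, 10, 25 and 50
land in the lower-labelled category. Foreign-fishing flows route from the
source EEZ's category (or `HS`) to the fleet nation's category (or `FOC`
for pool flows); trade flows route exporter to importer. The
fish-dependence filter is strict (`> 10%` of animal protein from fish) and
drops a flow unless **every** real-nation endpoint qualifies.

Per-category yield summaries are unweighted medians over nations — not
population-weighted — and include only nations actually participating in
the role (positive mass); empty categories are reported as missing rather
than zero. The `log10(x + 1)` transform is provided for display only and
is never stored.

## The vulnerability index

The index composes `V = E + S − AC` with min-max normalization across
nations at every stage:

* **Exposure.** `E_FF` is the mean of normalized foreign-fishing
  volatility (`CvFF`, the sample coefficient of variation of annual
  foreign-fishing tonnage over the full year range, FOC-retained share)
  and reversed, normalized location diversity (`DivFF`, Shannon diversity
  of focal-year nutrient-mass shares over source zones, averaged across
  the seven nutrients). `E_IMP` is the analogue for imports. Each
  component is weighted by the nation's supply share (`w_ff`, `w_imp`)
  before the components are averaged and renormalized.
* **Sensitivity.** Mean of normalized fish-dependence (share of animal
  protein from fish) and the normalized mean prevalence of inadequate
  intake across 14 micronutrients (`S_PIMII`), renormalized.
* **Adaptive capacity.** Socioeconomic status (mean of normalized GDP per
  capita and political stability), normalized health expenditure, and
  reversed net-food-importer status (importer → 0), averaged and
  renormalized.
* **Climate extension.** A third exposure component
  `E_CC = mean(1 − norm(CpDC), 1 − norm(DivDC)) × w_dc` enters the
  exposure mean (now over three weighted terms), where `CpDC` is the
  projected relative change in domestic catch production 2010–2050 (an
  input, not re-derived here) and `DivDC` the nutrient-weighted species
  diversity of domestic catch. Larger projected declines and narrower
  domestic portfolios mean higher exposure.

Design choices made where the composition was genuinely open, all
config-visible in the code:

* Supply-share weights use domestic + foreign-fished + imported
  RNI-equivalents; **exports are excluded** from the denominator, since a
  drop in exports retains nutrients rather than removing them.
* Diversity reversal happens after across-nutrient averaging and
  normalization (`1 − norm(mean H)`), not per nutrient.
* `CV` uses the sample (n−1) standard deviation; zero-mean series return
  `CV = 0`, so an absent channel contributes no exposure, consistent with
  its zero weight.
* Health expenditure is treated as a single variable wherever it appears.
* Net-importer status is binary; a continuous food-trade balance passed in
  its place is thresholded at zero.
* Missing drivers never impute across nations: parent metrics average the
  available normalized children and the nation is flagged incomplete.
* Both the raw score (`V_raw ∈ [−1, 2]`) and the min-max renormalized
  score are emitted; renormalization makes the conventional 0.5 reference
  line meaningful on a unit scale.

Monotonicity is a designed property: raising a nation's intake inadequacy
or its foreign-fishing volatility (at fixed weights) can never lower its
raw score, and the test suite perturbs randomly to confirm it.

## The synthetic world

The generator emulates the statistical shape of global catch/trade
reconstructions rather than any particular dataset:

* heavy-tailed tonnage: log-normal base tonnage across nation-taxon cells,
  with a sparsity knob zeroing most cells;
* a 40-year history (default 1976–2015, focal year 2015) carried by
  per-nation, per-channel geometric random walks, so each nation's
  volatility is controllable;
* roughly 10% of global catch on the high seas, fished by a subset of
  nations;
* mixed taxonomic reporting (default 70% species-rank records, the rest
  genus/family/coarse) to exercise the whole interpolation ladder;
* exact trade closure by construction — each record is simultaneously an
  export and an import;
* an FOC registry with a few heavily flagged nations, and a default 10% of
  nations lacking intake data (the `ND` category);
* indicators generated around a latent wealth axis so that the pruning
  correlations (intake inadequacy vs energy adequacy, GDP vs inequality)
  have realistic signs.

What it does **not** emulate: prices, processing and re-export chains,
illegal/unreported catch, discards, aquaculture, within-country
distribution, or correlations between fleet behaviour and taxon identity.
Passing tests therefore demonstrate the correctness of the accounting and
index arithmetic under realistic data shapes — they do not validate any
empirical claim about real fisheries.

`generate_indicator_extremes()` rewrites two nations to the corners of the
framework (one attaining every exposure/sensitivity maximum and every
adaptive-capacity minimum, one the reverse); after the full pipeline the
two recover vulnerability exactly 1 and 0, which pins the entire
normalization chain end to end.

## Numerical conventions and problem sizes

Conservation and oracle-equivalence checks use a relative tolerance of
1e-9. All CSV output renders floats at 10 significant digits, making
reruns of identical configurations byte-identical (asserted via MD5 in the
manifest). Degenerate cases are conventions, not errors: constant vectors
normalize to 0 with a warning, all-zero mass vectors have Shannon
diversity 0, zero-supply nations get zero weights.

The test suite runs its oracle comparisons on 10-nation, 30-taxon worlds
(where a record-by-record loop oracle is affordable) and its end-to-end
run on a 150-nation, 400-taxon, 40-year world — roughly the scale of the
real global system — which completes in well under a minute on one core.

```{r example}
w <- generate_world(world_config(n_nations = 8, n_taxa = 30, seed = 3))
led <- build_ledger(w, foc_mode = "on")
head(balance_table(led)[balance_table(led)$nutrient == "mean", ], 3)
```

## Known limitations

Reported landings only; no edible-portion conversion; the FOC adjustment
is proportional (no taxon- or tonnage-specific vessel information); the
coarse-taxon ladder is a reconstruction; median yields ignore population
weights; and the vulnerability index inherits the usual caveats of
equal-weight composite indicators — components are substitutable by
construction, and normalization makes every score relative to the set of
nations analysed.
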