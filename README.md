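# nutriflows

Nutrient-flow accounting and vulnerability analysis for marine fisheries.

## What problem this package addresses

Fish are one of the most bioavailable sources of the micronutrients whose
inadequate intake drives hidden hunger. But nutrients caught at sea are not
eaten where they are caught: foreign fleets fish other nations' exclusive
economic zones (EEZs) and the high seas, and international trade moves
landed fish again. `nutriflows` is for food-systems and fisheries analysts
who want to account for where fishery-derived nutrients actually go:

* it converts long-format catch and trade records into masses of seven
  nutrients (protein, calcium, iron, zinc, selenium, long-chain omega-3,
  vitamin A) using per-100 g concentrations imputed up the taxonomy, with
  a four-tier interpolation ladder for coarsely reported taxa;
* it expresses masses as **RNI-equivalents** — the number of
  reproductive-age females whose recommended nutrient intake (RNI) a mass
  could theoretically cover — and computes per nation and nutrient the
  foreign-fishing balance and trade balance

  ```
  FFB_in = FF_in − LossFF_in        TB_in = IMP_in − EXP_in
  ```

  with toggles for including the high seas and for removing
  flag-of-convenience (FOC) catch into an unattributed pool;
* it aggregates flows of calcium, iron, zinc and vitamin A between
  categories of inadequate-intake prevalence (V.Lo … V.Hi, ND, plus the
  HS and FOC pseudo-sources) and summarises per-capita yields (% of RNI
  per capita per day) by category;
* it scores national vulnerability of nutrient supply with the composite
  index

  ```
  Vulnerability = Exposure + Sensitivity − Adaptive capacity
  ```

  built from supply volatility and diversity (coefficients of variation,
  Shannon indices), dietary dependence and intake inadequacy, and
  socioeconomic adaptive-capacity proxies — with an optional climate
  extension driven by projected changes in domestic catch production.

Because the real global catch/trade databases are large external
downloads, the package ships a seeded synthetic-world generator that
emulates their schemas and closure properties (every export is someone's
import; heavy-tailed tonnage; mixed taxonomic resolution), so the whole
pipeline is testable and demonstrable offline. See the vignette
(`vignettes/nutrient-flows.Rmd`) for the full methods account.

## Worked example

```r
library(nutriflows)

w   <- generate_world(world_config(n_nations = 10, n_taxa = 40, seed = 2024))
led <- build_ledger(w, foc_mode = "on")     # FOC catch moved to the pool

bt <- balance_table(led)                    # per nutrient + "mean" rows
m  <- bt[bt$nutrient == "mean", ]
head(cbind(m[c("nation", "ffb", "tb")], classify_nation(m$ffb, m$tb)), 5)
#>   nation        ffb        tb     quadrant      net
#> 1   N001 -166207.75 -80149.19    loss_both negative
#> 2   N002  241898.47 -86235.09 gain_ff_only positive
#> 3   N003   15265.48 -36882.44 gain_ff_only negative
#> 4   N004  170547.16  69482.96    gain_both positive
#> 5   N005   30739.89  88386.52    gain_both positive
```

`ffb` and `tb` are RNI-equivalents averaged across the seven nutrients:
N002's fleet gains the yearly requirement of ~242,000 women from fishing
abroad but loses ~86,000 through net exports, so it gains overall
(`net = positive`) purely through foreign fishing.

```r
fm <- aggregate_flows(led, w$indicators, "calcium", "foreign_fishing")
head(export_sankey_table(fm), 3)
#>   source_category sink_category        mass
#> 1 V.Lo            V.Lo           1622329668
#> 2 Lo              V.Lo           6088967260
#> 3 V.Hi            V.Lo            557006584
```

Each row is an annual calcium mass (mg) moved by foreign fishing from
source-EEZ nations in one inadequate-intake category to fleet nations in
another — here, mostly into nations with very low inadequacy.

```r
vt <- vulnerability_table(w, led)
head(vt[c("nation", "exposure", "sensitivity", "adaptive_capacity",
          "vulnerability", "vulnerability_climate")], 5)
#>   nation exposure sensitivity adaptive_capacity vulnerability
#> 1   N001    0.425       0.835             0.771         0.422
#> 2   N002    0.590       0.943             1             0.449
#> 3   N003    0.535       0.852             0             1
#> 4   N004    0.769       0.377             0.832         0.308
#> 5   N005    0.335       0                 0.500         0
```

All components are min-max normalized across the analysed nations; N003
combines high exposure and sensitivity with the lowest adaptive capacity
and tops the vulnerability ranking.

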