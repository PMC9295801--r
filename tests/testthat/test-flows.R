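test_that("prevalence bins are right-closed with ND for missing data", {
  expect_equal(as.character(categorize_prevalence(c(5, 10, 25, 50))),
               c("V.Lo", "Lo", "Med", "Hi"))
  expect_equal(as.character(categorize_prevalence(c(0, 5.01, 30, 51, NA))),
               c("V.Lo", "Lo", "Hi", "V.Hi", "ND"))
  expect_error(categorize_prevalence(101), "\\[0, 100\\]")
  expect_error(categorize_prevalence(-1), "\\[0, 100\\]")
})

test_that("every nation lands in exactly one category per nutrient", {
  w <- generate_world(world_config(n_nations = 25, n_taxa = 20,
                                   nd_frac = 0.2, seed = 3))
  cats <- nutriflows:::intake_categories(w$indicators, "iron")
  expect_equal(nrow(cats), 25)
  expect_false(any(is.na(cats$category)))
  prev <- w$indicators$intake_iron
  expect_equal(as.character(cats$category[is.na(prev)]),
               rep("ND", sum(is.na(prev))))
})

test_that("a single flow lands in the right cell", {
  w <- micro_world()
  led <- build_ledger(w, "off")
  fm <- aggregate_flows(led, w$indicators, "calcium", "trade")
  tbl <- export_sankey_table(fm)
  # A (V.Hi, prev 60) exports to B (V.Lo, prev 4); C (Med, 20) exports to A
  expect_setequal(paste(tbl$source_category, tbl$sink_category),
                  c("V.Hi V.Lo", "Med V.Hi"))
  expect_equal(sum(fm), sum(tbl$mass))
})

test_that("flow matrices conserve channel mass and match the oracle", {
  w <- generate_world(world_config(n_nations = 10, n_taxa = 30,
                                   foc_heavy_nations = 3, nd_frac = 0.1,
                                   seed = 15))
  for (mode in c("off", "on")) {
    led <- build_ledger(w, mode)
    for (nu in c("iron", "vitamin_a")) {
      for (ch in c("foreign_fishing", "trade")) {
        for (filt in list(NULL, 10)) {
          fm <- aggregate_flows(led, w$indicators, nu, ch, filt)
          om <- oracle_flow_matrix(w, nu, ch, foc_mode = mode,
                                   filter = filt)
          expect_rel_equal(as.numeric(fm), as.numeric(om))
        }
        # unfiltered totals equal the ledger channel totals
        fm <- aggregate_flows(led, w$indicators, nu, ch)
        pairs <- if (ch == "foreign_fishing") led$ff_pairs else
          led$trade_pairs
        expect_rel_equal(sum(fm), sum(pairs[[paste0("mass_", nu)]]))
      }
    }
  }
  led <- build_ledger(w, "on")
  expect_error(aggregate_flows(led, w$indicators, "protein",
                               "foreign_fishing"), "flow matrices")
})

test_that("per-category yields are medians over participating nations", {
  w <- micro_world()
  led <- build_ledger(w, "off")
  y <- yield_by_category(led, w$indicators, "iron", "source")
  # A's and B's EEZs are fished by foreigners; C's EEZ is untouched
  expect_equal(y$n_nations[y$category == "V.Hi"], 1)
  a_mass <- sum(led$ff_pairs$mass_iron[led$ff_pairs$source_zone == "A"])
  rni <- w$rni$rni_per_day[w$rni$nutrient == "iron"]
  expect_rel_equal(y$median_yield[y$category == "V.Hi"],
                   per_capita_yield(a_mass, 1e6, rni))
  expect_true(is.na(y$median_yield[y$category == "Med"]))

  # median robustness on a constructed three-nation category
  w2 <- generate_world(world_config(n_nations = 12, n_taxa = 25, seed = 77))
  led2 <- build_ledger(w2, "off")
  y2 <- yield_by_category(led2, w2$indicators, "zinc", "importer")
  per_nation <- stats::aggregate(
    led2$trade_pairs$mass_zinc,
    list(nation = led2$trade_pairs$importer), sum)
  cats <- nutriflows:::intake_categories(w2$indicators, "zinc")
  rni_z <- w2$rni$rni_per_day[w2$rni$nutrient == "zinc"]
  pops <- w2$indicators$population[match(per_nation$nation,
                                         w2$indicators$nation)]
  yields <- per_capita_yield(per_nation$x, pops, rni_z)
  ccat <- as.character(cats$category[match(per_nation$nation, cats$nation)])
  for (lv in unique(ccat)) {
    expect_rel_equal(y2$median_yield[y2$category == lv],
                     stats::median(yields[ccat == lv]))
  }
})

test_that("sink yields exclude high-seas catch only in the EEZ-only role", {
  w <- micro_world()
  led <- build_ledger(w, "off")
  y_all <- yield_by_category(led, w$indicators, "iron", "sink")
  y_eez <- yield_by_category(led, w$indicators, "iron", "sink_eez_only")
  # B fishes only the high seas, so it disappears from the EEZ-only role
  expect_equal(y_all$n_nations[y_all$category == "V.Lo"], 1)
  expect_equal(y_eez$n_nations[y_eez$category == "V.Lo"], 0)
})

test_that("the display transform has the documented fixed points", {
  expect_equal(log_transform(c(0, 9, 99)), c(0, 1, 2))
  expect_error(log_transform(-1), ">= 0")
})

test_that("sankey tables round-trip losslessly", {
  w <- generate_world(world_config(n_nations = 8, n_taxa = 20, seed = 9))
  led <- build_ledger(w, "on")
  fm <- aggregate_flows(led, w$indicators, "calcium", "foreign_fishing")
  tbl <- export_sankey_table(fm, drop_zero = FALSE)
  back <- tapply(tbl$mass, list(factor(tbl$source_category, category_levels()),
                                factor(tbl$sink_category, category_levels())),
                 sum)
  expect_equal(unname(back), unname(unclass(fm)), ignore_attr = TRUE)
  expect_equal(sum(export_sankey_table(fm)$mass), sum(fm))
})
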