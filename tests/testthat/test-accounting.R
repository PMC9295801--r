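test_that("unit arithmetic: nutrient mass, RNI-equivalents, yields", {
  expect_equal(nutrient_mass(2, 50), 1e6)
  expect_equal(nutrient_mass(0, 50), 0)
  expect_equal(nutrient_mass(1, 18.8), 188000)
  expect_error(nutrient_mass(-1, 5), ">= 0")
  expect_error(nutrient_mass(1, -5), ">= 0")

  expect_equal(rni_equivalents(1e6, 10), 1e6 / 3650)
  expect_equal(rni_equivalents(0, 10), 0)
  expect_equal(rni_equivalents(10 * 365, 10), 1)
  expect_error(rni_equivalents(1, 0), "> 0")

  expect_equal(per_capita_yield(3.65e6, 1000, 10), 100)
  expect_equal(per_capita_yield(0, 1000, 10), 0)
  expect_equal(per_capita_yield(7.3e5, 200, 5), 200)
  expect_error(per_capita_yield(1, 0, 10), "population")
})

test_that("FOC split averages registry years and conserves tonnage", {
  foc <- tibble::tibble(nation = c("A", "B"),
                        prop_foc_2013 = c(0.2, 0),
                        prop_foc_2018 = c(0.4, 0))
  rec <- tibble::tibble(fishing_nation = c("A", "B"),
                        tonnes = c(100, 50))
  sp <- apply_foc(rec, foc)
  # effective p for A is mean(0.2, 0.4) = 0.3
  expect_equal(sp$retained$tonnes, c(70, 50))
  expect_equal(sp$pool$tonnes, 30)
  expect_equal(sp$pool$fishing_nation, "A")

  # p = 0 leaves records unchanged with an empty pool
  sp0 <- apply_foc(rec[2, ], foc)
  expect_equal(sp0$retained, rec[2, ])
  expect_equal(nrow(sp0$pool), 0)

  expect_warning(apply_foc(tibble::tibble(fishing_nation = "Z",
                                          tonnes = 1), foc),
                 "treated as p = 0")
  bad <- tibble::tibble(nation = "A", prop_foc_2013 = 1.4,
                        prop_foc_2018 = 0)
  expect_error(apply_foc(rec, bad), "\\[0, 1\\]")
})

test_that("FOC split conserves mass per nation and taxon under random draws", {
  w <- generate_world(world_config(n_nations = 12, n_taxa = 30,
                                   foc_heavy_nations = 4, seed = 6))
  fc <- w$catch[w$catch$year == 2015, ]
  sp <- apply_foc(fc, w$foc)
  orig <- tapply(fc$tonnes, list(fc$fishing_nation, fc$taxon_id), sum)
  ret <- tapply(sp$retained$tonnes,
                list(sp$retained$fishing_nation, sp$retained$taxon_id), sum)
  pool <- tapply(sp$pool$tonnes,
                 list(sp$pool$fishing_nation, sp$pool$taxon_id), sum)
  pool_full <- orig * 0
  pool_full[rownames(pool), colnames(pool)] <-
    ifelse(is.na(pool), 0, pool)
  expect_equal(ret + pool_full, orig, tolerance = 1e-9)
})

test_that("ledger matches the record-by-record oracle on a hand-built world", {
  w <- micro_world()
  for (mode in c("off", "on")) {
    led <- build_ledger(w, mode)
    oled <- oracle_rni(oracle_ledger(w, mode), w$rni)
    for (i in seq_len(nrow(oled))) {
      got <- led$table[led$table$nation == oled$nation[i] &
                         led$table$nutrient == oled$nutrient[i] &
                         led$table$channel == oled$channel[i], ]
      expect_equal(nrow(got), 1)
      expect_rel_equal(got$mass, oled$mass[i])
      expect_rel_equal(got$rni_equiv, oled$rni_equiv[i])
    }
    # all ledger mass not covered by the oracle must be zero
    key <- paste(led$table$nation, led$table$nutrient, led$table$channel)
    okey <- paste(oled$nation, oled$nutrient, oled$channel)
    expect_true(all(led$table$mass[!key %in% okey] == 0))
  }
})

test_that("ledger channels partition the catch and close the trade", {
  w <- generate_world(world_config(n_nations = 9, n_taxa = 30,
                                   foc_heavy_nations = 3, seed = 10))
  led <- build_ledger(w, "on")
  t <- led$table
  # caught mass: domestic + foreign + high seas + pool = total valued catch
  caught <- sum(t$mass[t$channel %in% c("domestic", "foreign_fished",
                                        "high_seas_share", "foc_pool")])
  total <- sum(as.matrix(
    led$audit_catch[paste0("mass_", nutrient_names())]))
  expect_equal(caught, total, tolerance = 1e-9 * total)
  # global imports equal global exports per nutrient
  imp <- tapply(t$mass[t$channel == "imported"],
                t$nutrient[t$channel == "imported"], sum)
  exp_ <- tapply(t$mass[t$channel == "exported"],
                 t$nutrient[t$channel == "exported"], sum)
  expect_equal(imp, exp_, tolerance = 1e-9)
  # a nation fishing only its own EEZ has zero foreign-fished mass
  dom_only <- setdiff(w$nations,
                      unique(w$catch$fishing_nation[
                        w$catch$source_zone != w$catch$fishing_nation]))
  if (length(dom_only) > 0) {
    ff <- t$mass[t$channel %in% c("foreign_fished", "high_seas_share") &
                   t$nation %in% dom_only]
    expect_true(all(ff == 0))
  }
  expect_error(build_ledger(w, focal_year = 1900), "focal year")
})

test_that("records naming unknown nations are rejected with the offenders", {
  w <- micro_world()
  w$catch$fishing_nation[1] <- "ATLANTIS"
  expect_error(build_ledger(w), "ATLANTIS")
})
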