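# Brute-force, record-iterating oracles: deliberately written as plain
# loops over individual records, independent of the vectorized pipeline
# code paths, so they can serve as a ground truth on small worlds.

NUTR <- c("protein", "calcium", "iron", "zinc", "selenium", "omega3",
          "vitamin_a")

# -- concentration ladder ----------------------------------------------------

# taxonomy-only resolution for one taxon; NULL when unresolvable
oracle_taxo_conc <- function(tid, taxa) {
  row <- taxa[taxa$taxon_id == tid, ]
  v <- sapply(NUTR, function(n) row[[paste0("conc_", n)]])
  if (!any(is.na(v))) return(v)
  sp <- taxa[taxa$rank == "species", ]
  members <- if (row$rank == "genus") sp[sp$genus == row$genus, ]
    else if (row$rank == "family") sp[sp$family == row$family, ]
    else sp[0, ]
  if (nrow(members) == 0) return(NULL)
  for (n in NUTR) {
    cn <- paste0("conc_", n)
    if (is.na(v[n])) v[n] <- mean(members[[cn]])
  }
  if (any(is.na(v))) NULL else v
}

# full ladder for one record; returns list(conc, tier)
oracle_record_conc <- function(tid, zone, records, taxa) {
  v <- oracle_taxo_conc(tid, taxa)
  if (!is.null(v)) return(list(conc = v, tier = 1L))
  wmean_over <- function(recs) {
    num <- stats::setNames(rep(0, length(NUTR)), NUTR)
    den <- 0
    for (i in seq_len(nrow(recs))) {
      ci <- oracle_taxo_conc(recs$taxon_id[i], taxa)
      if (is.null(ci)) next
      num <- num + ci * recs$tonnes[i]
      den <- den + recs$tonnes[i]
    }
    if (den == 0) NULL else num / den
  }
  v <- wmean_over(records[records$zone == zone, , drop = FALSE])
  if (!is.null(v)) return(list(conc = v, tier = 2L))
  v <- wmean_over(records)
  if (!is.null(v)) return(list(conc = v, tier = 3L))
  sp <- taxa[taxa$rank == "species", ]
  v <- sapply(NUTR, function(n) mean(sp[[paste0("conc_", n)]]))
  list(conc = v, tier = 4L)
}

# -- ledger ------------------------------------------------------------------

# per-nation, per-nutrient channel masses by iterating raw records
oracle_ledger <- function(world, foc_mode = "off", focal_year = NULL) {
  if (is.null(focal_year)) focal_year <- world$config$focal_year
  catch <- world$catch[world$catch$year == focal_year, ]
  trade <- world$trade[world$trade$year == focal_year, ]
  p <- (world$foc$prop_foc_2013 + world$foc$prop_foc_2018) / 2
  names(p) <- world$foc$nation

  catch_ctx <- data.frame(taxon_id = catch$taxon_id,
                          zone = catch$source_zone, tonnes = catch$tonnes)
  trade_ctx <- data.frame(taxon_id = trade$taxon_id,
                          zone = trade$exporter, tonnes = trade$tonnes)

  acc <- list()
  add <- function(nation, channel, mass_vec) {
    key <- paste(nation, channel)
    if (is.null(acc[[key]])) acc[[key]] <<- mass_vec else
      acc[[key]] <<- acc[[key]] + mass_vec
  }
  for (i in seq_len(nrow(catch))) {
    nat <- catch$fishing_nation[i]
    zone <- catch$source_zone[i]
    conc <- oracle_record_conc(catch$taxon_id[i], zone, catch_ctx,
                               world$taxa)$conc
    mass <- catch$tonnes[i] * 1e4 * conc
    if (zone == nat) {
      add(nat, "domestic", mass)
    } else {
      pi <- if (foc_mode == "on") {
        pv <- p[nat]
        if (is.na(pv)) 0 else pv
      } else 0
      keep <- mass * (1 - pi)
      pool <- mass * pi
      if (zone == "HS") add(nat, "high_seas_share", keep)
      else add(nat, "foreign_fished", keep)
      if (pi > 0) add("FOC", "foc_pool", pool)
      if (zone != "HS") add(zone, "lost_to_foreign", mass)
    }
  }
  for (i in seq_len(nrow(trade))) {
    conc <- oracle_record_conc(trade$taxon_id[i], trade$exporter[i],
                               trade_ctx, world$taxa)$conc
    mass <- trade$tonnes[i] * 1e4 * conc
    add(trade$importer[i], "imported", mass)
    add(trade$exporter[i], "exported", mass)
  }
  out <- do.call(rbind, lapply(names(acc), function(key) {
    parts <- strsplit(key, " ")[[1]]
    data.frame(nation = parts[1], channel = parts[2], nutrient = NUTR,
               mass = unname(acc[[key]]))
  }))
  rownames(out) <- NULL
  out
}

# RNI-equivalents of an oracle ledger
oracle_rni <- function(oled, rni) {
  r <- rni$rni_per_day[match(oled$nutrient, rni$nutrient)]
  oled$rni_equiv <- oled$mass / (r * 365)
  oled
}

oracle_channel <- function(oled, nation, nutrient, channel) {
  m <- oled$rni_equiv[oled$nation == nation & oled$nutrient == nutrient &
                        oled$channel == channel]
  if (length(m) == 0) 0 else sum(m)
}

oracle_ffb <- function(oled, nation, nutrient, include_hs = TRUE) {
  ff <- oracle_channel(oled, nation, nutrient, "foreign_fished") +
    if (include_hs) oracle_channel(oled, nation, nutrient,
                                   "high_seas_share") else 0
  ff - oracle_channel(oled, nation, nutrient, "lost_to_foreign")
}

oracle_tb <- function(oled, nation, nutrient) {
  oracle_channel(oled, nation, nutrient, "imported") -
    oracle_channel(oled, nation, nutrient, "exported")
}

# -- flow matrix -------------------------------------------------------------

oracle_categorize <- function(p) {
  if (is.na(p)) "ND" else if (p <= 5) "V.Lo" else if (p <= 10) "Lo" else
    if (p <= 25) "Med" else if (p <= 50) "Hi" else "V.Hi"
}

oracle_flow_matrix <- function(world, nutrient, channel,
                               foc_mode = "on", filter = NULL,
                               focal_year = NULL) {
  if (is.null(focal_year)) focal_year <- world$config$focal_year
  lev <- c("V.Lo", "Lo", "Med", "Hi", "V.Hi", "ND", "FOC", "HS")
  m <- matrix(0, 8, 8, dimnames = list(lev, lev))
  ind <- world$indicators
  cat_of <- function(nat) {
    if (nat == "HS") return("HS")
    if (nat == "FOC") return("FOC")
    oracle_categorize(ind[[paste0("intake_", nutrient)]][ind$nation == nat])
  }
  share_of <- function(nat) ind$fish_protein_share[ind$nation == nat]
  pass <- function(nat) {
    if (nat %in% c("HS", "FOC")) return(TRUE)
    if (is.null(filter)) return(TRUE)
    s <- share_of(nat)
    !is.na(s) && s > filter
  }
  p <- (world$foc$prop_foc_2013 + world$foc$prop_foc_2018) / 2
  names(p) <- world$foc$nation

  if (channel == "foreign_fishing") {
    catch <- world$catch[world$catch$year == focal_year, ]
    ctx <- data.frame(taxon_id = catch$taxon_id, zone = catch$source_zone,
                      tonnes = catch$tonnes)
    for (i in seq_len(nrow(catch))) {
      nat <- catch$fishing_nation[i]
      zone <- catch$source_zone[i]
      if (zone == nat) next
      conc <- oracle_record_conc(catch$taxon_id[i], zone, ctx,
                                 world$taxa)$conc
      mass <- catch$tonnes[i] * 1e4 * conc[[nutrient]]
      pi <- if (foc_mode == "on" && !is.na(p[nat])) p[nat] else 0
      src <- cat_of(zone)
      if (pass(zone) && pass(nat) && mass * (1 - pi) > 0)
        m[src, cat_of(nat)] <- m[src, cat_of(nat)] + mass * (1 - pi)
      if (pass(zone) && mass * pi > 0)
        m[src, "FOC"] <- m[src, "FOC"] + mass * pi
    }
  } else {
    trade <- world$trade[world$trade$year == focal_year, ]
    ctx <- data.frame(taxon_id = trade$taxon_id, zone = trade$exporter,
                      tonnes = trade$tonnes)
    for (i in seq_len(nrow(trade))) {
      conc <- oracle_record_conc(trade$taxon_id[i], trade$exporter[i],
                                 ctx, world$taxa)$conc
      mass <- trade$tonnes[i] * 1e4 * conc[[nutrient]]
      if (pass(trade$exporter[i]) && pass(trade$importer[i]))
        m[cat_of(trade$exporter[i]), cat_of(trade$importer[i])] <-
          m[cat_of(trade$exporter[i]), cat_of(trade$importer[i])] + mass
    }
  }
  m
}

# -- vulnerability sub-variables --------------------------------------------

oracle_shannon <- function(x) {
  x <- x[x > 0]
  if (length(x) == 0) return(0)
  pr <- x / sum(x)
  -sum(pr * log(pr))
}

oracle_cv <- function(x) {
  if (mean(x) == 0) 0 else stats::sd(x) / mean(x)
}

oracle_minmax <- function(x, reverse = FALSE) {
  r <- range(x, na.rm = TRUE)
  out <- if (r[1] == r[2]) ifelse(is.na(x), NA, 0) else
    (x - r[1]) / (r[2] - r[1])
  if (reverse) 1 - out else out
}

# CvFF/CvIMP/DivFF/DivIMP/DivDC/weights by iterating records per nation
oracle_subvars <- function(world, foc_mode = "on") {
  oled <- oracle_rni(oracle_ledger(world, foc_mode), world$rni)
  years <- seq(world$config$year_range[1], world$config$year_range[2])
  focal <- world$config$focal_year
  p <- (world$foc$prop_foc_2013 + world$foc$prop_foc_2018) / 2
  names(p) <- world$foc$nation
  catch <- world$catch
  trade <- world$trade
  fc <- catch[catch$year == focal, ]
  ft <- trade[trade$year == focal, ]
  catch_ctx <- data.frame(taxon_id = fc$taxon_id, zone = fc$source_zone,
                          tonnes = fc$tonnes)
  trade_ctx <- data.frame(taxon_id = ft$taxon_id, zone = ft$exporter,
                          tonnes = ft$tonnes)

  do.call(rbind, lapply(world$nations, function(nat) {
    pn <- if (is.na(p[nat])) 0 else p[nat]
    ff <- catch[catch$fishing_nation == nat &
                  catch$source_zone != nat, ]
    s_ff <- sapply(years, function(y)
      sum(ff$tonnes[ff$year == y]) * (1 - pn))
    imp <- trade[trade$importer == nat, ]
    s_imp <- sapply(years, function(y) sum(imp$tonnes[imp$year == y]))

    ffy <- ff[ff$year == focal, ]
    div_ff <- mean(sapply(NUTR, function(nu) {
      mz <- sapply(unique(ffy$source_zone), function(z) {
        rows <- ffy[ffy$source_zone == z, ]
        sum(sapply(seq_len(nrow(rows)), function(i)
          rows$tonnes[i] * 1e4 *
            oracle_record_conc(rows$taxon_id[i], z, catch_ctx,
                               world$taxa)$conc[[nu]]))
      })
      if (length(mz) == 0) 0 else oracle_shannon(mz * (1 - pn))
    }))

    impy <- imp[imp$year == focal, ]
    div_imp <- mean(sapply(NUTR, function(nu) {
      me <- sapply(unique(impy$exporter), function(e) {
        rows <- impy[impy$exporter == e, ]
        sum(sapply(seq_len(nrow(rows)), function(i)
          rows$tonnes[i] * 1e4 *
            oracle_record_conc(rows$taxon_id[i], e, trade_ctx,
                               world$taxa)$conc[[nu]]))
      })
      if (length(me) == 0) 0 else oracle_shannon(me)
    }))

    dom <- fc[fc$fishing_nation == nat & fc$source_zone == nat, ]
    div_dc <- mean(sapply(NUTR, function(nu) {
      mt <- sapply(unique(dom$taxon_id), function(tid) {
        rows <- dom[dom$taxon_id == tid, ]
        sum(sapply(seq_len(nrow(rows)), function(i)
          rows$tonnes[i] * 1e4 *
            oracle_record_conc(tid, nat, catch_ctx,
                               world$taxa)$conc[[nu]]))
      })
      if (length(mt) == 0) 0 else oracle_shannon(mt)
    }))

    dc_r <- mean(sapply(NUTR, function(nu)
      oracle_channel(oled, nat, nu, "domestic")))
    ff_r <- mean(sapply(NUTR, function(nu)
      oracle_channel(oled, nat, nu, "foreign_fished") +
        oracle_channel(oled, nat, nu, "high_seas_share")))
    imp_r <- mean(sapply(NUTR, function(nu)
      oracle_channel(oled, nat, nu, "imported")))
    tot <- dc_r + ff_r + imp_r
    data.frame(nation = nat,
               cv_ff = oracle_cv(s_ff), cv_imp = oracle_cv(s_imp),
               div_ff = div_ff, div_imp = div_imp, div_dc = div_dc,
               w_ff = if (tot > 0) ff_r / tot else 0,
               w_imp = if (tot > 0) imp_r / tot else 0,
               w_dc = if (tot > 0) dc_r / tot else 0)
  }))
}

# -- fixtures ----------------------------------------------------------------

# a tiny hand-built 3-nation world with one taxon per resolution tier
micro_world <- function() {
  taxa <- tibble::tibble(
    taxon_id = c("SP1", "SP2", "GEN1", "CRS1"),
    rank = c("species", "species", "genus", "coarse"),
    species = c("Gen001 a", "Gen001 b", "", ""),
    genus = c("Gen001", "Gen001", "Gen001", ""),
    family = c("Fam01", "Fam01", "Fam01", ""),
    conc_protein = c(18, 20, NA, NA),
    conc_calcium = c(10, 20, NA, NA),
    conc_iron = c(1, 3, NA, NA),
    conc_zinc = c(1, 2, NA, NA),
    conc_selenium = c(30, 50, NA, NA),
    conc_omega3 = c(0.4, 0.8, NA, NA),
    conc_vitamin_a = c(20, 60, NA, NA))
  years <- c(2014L, 2015L)
  catch <- tibble::tibble(
    year = rep(years, each = 5),
    fishing_nation = rep(c("A", "A", "B", "C", "C"), 2),
    source_zone = rep(c("A", "B", "HS", "A", "A"), 2),
    taxon_id = rep(c("SP1", "SP2", "SP1", "CRS1", "GEN1"), 2),
    tonnes = c(100, 50, 30, 20, 10, 120, 40, 35, 25, 15))
  trade <- tibble::tibble(
    year = rep(years, each = 2),
    exporter = rep(c("A", "C"), 2),
    importer = rep(c("B", "A"), 2),
    taxon_id = rep(c("SP1", "SP2"), 2),
    tonnes = c(10, 5, 12, 6))
  foc <- tibble::tibble(nation = c("A", "B", "C"),
                        prop_foc_2013 = c(0, 0.4, 0),
                        prop_foc_2018 = c(0, 0.6, 0))
  ind <- tibble::tibble(
    nation = c("A", "B", "C"),
    population = c(1e6, 2e6, 5e5),
    fish_protein_share = c(30, 8, 15),
    gdp_pc = c(2000, 30000, 8000),
    stability = c(-0.5, 1.2, 0.1),
    health_exp = c(4, 10, 6),
    net_food_importer = c(1L, 0L, 1L),
    production_change = c(-0.3, 0.1, -0.1),
    hdi = c(0.5, 0.9, 0.7),
    inequality_coef = c(30, 8, 18),
    energy_adequacy = c(105, 125, 115))
  prev <- matrix(rep(c(60, 4, 20), 14), nrow = 3)
  colnames(prev) <- paste0("intake_",
                           c("calcium", "copper", "iron", "folate",
                             "magnesium", "niacin", "phosphorus",
                             "riboflavin", "thiamin", "vitamin_a",
                             "vitamin_b12", "vitamin_b6", "vitamin_c",
                             "zinc"))
  ind <- dplyr::bind_cols(ind, tibble::as_tibble(prev))
  structure(list(nations = c("A", "B", "C"), taxa = taxa, catch = catch,
                 trade = trade, foc = foc, indicators = ind,
                 rni = nutriflows::default_rni(),
                 config = nutriflows::world_config(
                   n_nations = 3, n_taxa = 4,
                   year_range = c(2014L, 2015L), focal_year = 2015L)),
            class = "nf_world")
}

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  scale <- pmax(abs(expected), 1)
  testthat::expect_true(all(abs(actual - expected) <= tol * scale))
}
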