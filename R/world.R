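#' Configuration for a synthetic fisheries world
#'
#' Builds and validates the configuration object consumed by
#' [generate_world()]. The defaults describe the study conditions the
#' pipeline is exercised under: a 40-year catch/trade history (1976-2015)
#' with 2015 as the focal accounting year, a heavy-tailed tonnage
#' distribution across nation-taxon cells, roughly 10% of global catch taken
#' on the high seas, a configurable mix of taxonomic reporting resolutions,
#' and a small set of nations whose fleets are dominated by
#' flag-of-convenience (FOC) registrations.
#'
#' @param n_nations Number of nations (>= 3).
#' @param n_taxa Number of distinct reported taxa.
#' @param year_range Inclusive pair of calendar years covered by the catch
#'   and trade series.
#' @param focal_year Year used for the nutrient accounting; must lie within
#'   `year_range`.
#' @param frac_species_level Proportion of catch records reported at species
#'   rank; the remainder is split across genus, family and coarse ranks.
#' @param foc_heavy_nations Number of nations given a high FOC proportion
#'   (0.5-0.9); all others get small proportions.
#' @param nd_frac Proportion of nations with no inadequate-intake data
#'   (the "ND" category).
#' @param high_seas_share Share of global catch tonnage taken on the high
#'   seas.
#' @param hs_fishing_frac Fraction of nations whose fleets fish the high
#'   seas.
#' @param mean_foreign_partners Mean number of foreign EEZs fished per
#'   nation (Poisson).
#' @param domestic_sparsity Probability that a nation-taxon domestic catch
#'   cell is zero (dropped), producing a sparse, skewed catch matrix.
#' @param tonnage_meanlog,tonnage_sdlog Log-normal parameters of base cell
#'   tonnage.
#' @param trade_partners Mean number of import partners per exporter.
#' @param trade_taxa Number of taxa traded per exporter-importer pair.
#' @param walk_sd_range Range of the per-nation annual log-step standard
#'   deviation of the geometric random walks that carry cell tonnages
#'   through time (controls each nation's catch/import variability).
#' @param seed Integer seed; identical seeds give bit-identical worlds.
#'
#' @return A validated list of class `nf_config`.
#' @export
#' @examples
#' cfg <- world_config(n_nations = 5, n_taxa = 20, seed = 42)
world_config <- function(n_nations = 20,
                         n_taxa = 60,
                         year_range = c(1976L, 2015L),
                         focal_year = 2015L,
                         frac_species_level = 0.7,
                         foc_heavy_nations = 2,
                         nd_frac = 0.1,
                         high_seas_share = 0.1,
                         hs_fishing_frac = 0.3,
                         mean_foreign_partners = 2,
                         domestic_sparsity = 0.75,
                         tonnage_meanlog = log(500),
                         tonnage_sdlog = 1.5,
                         trade_partners = 3,
                         trade_taxa = 4,
                         walk_sd_range = c(0.05, 0.3),
                         seed = 1L) {
  if (!is.numeric(n_nations) || length(n_nations) != 1 || n_nations < 3)
    stop_config("n_nations", "must be a single number >= 3")
  if (!is.numeric(n_taxa) || length(n_taxa) != 1 || n_taxa < 4)
    stop_config("n_taxa", "must be a single number >= 4")
  if (length(year_range) != 2 || diff(year_range) < 1)
    stop_config("year_range", "must span at least 2 years")
  if (focal_year < year_range[1] || focal_year > year_range[2])
    stop_config("focal_year", "must lie within year_range")
  if (frac_species_level < 0 || frac_species_level > 1)
    stop_config("frac_species_level", "must be in [0, 1]")
  if (foc_heavy_nations < 0 || foc_heavy_nations > n_nations)
    stop_config("foc_heavy_nations", "must be between 0 and n_nations")
  if (nd_frac < 0 || nd_frac >= 1)
    stop_config("nd_frac", "must be in [0, 1)")
  if (high_seas_share < 0 || high_seas_share >= 1)
    stop_config("high_seas_share", "must be in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop_config("seed", "must be a single integer")
  structure(
    list(n_nations = as.integer(n_nations), n_taxa = as.integer(n_taxa),
         year_range = as.integer(year_range),
         focal_year = as.integer(focal_year),
         frac_species_level = frac_species_level,
         foc_heavy_nations = as.integer(foc_heavy_nations),
         nd_frac = nd_frac, high_seas_share = high_seas_share,
         hs_fishing_frac = hs_fishing_frac,
         mean_foreign_partners = mean_foreign_partners,
         domestic_sparsity = domestic_sparsity,
         tonnage_meanlog = tonnage_meanlog, tonnage_sdlog = tonnage_sdlog,
         trade_partners = trade_partners, trade_taxa = trade_taxa,
         walk_sd_range = walk_sd_range, seed = as.integer(seed)),
    class = "nf_config")
}

# log-normal concentration parameters per nutrient, per 100 g raw portion;
# magnitudes follow published finfish composition ranges
conc_params <- function() {
  list(protein   = c(log(19),  0.08),
       calcium   = c(log(60),  0.9),
       iron      = c(log(1.2), 0.7),
       zinc      = c(log(1.0), 0.5),
       selenium  = c(log(40),  0.5),
       omega3    = c(log(0.5), 0.8),
       vitamin_a = c(log(30),  1.0))
}

draw_concentrations <- function(k) {
  p <- conc_params()
  out <- lapply(nutrient_names(), function(n)
    stats::rlnorm(k, p[[n]][1], p[[n]][2]))
  names(out) <- conc_cols()
  tibble::as_tibble(out)
}

#' Default recommended nutrient intakes (synthetic world)
#'
#' Daily recommended nutrient intakes (RNI) for reproductive-age females
#' used by the synthetic world. These are package defaults at the magnitude
#' of published WHO/FAO recommendations; in any real analysis the RNI table
#' is an input, not a constant.
#'
#' @return Tibble with columns `nutrient`, `rni_per_day`, `unit`.
#' @export
default_rni <- function() {
  tibble::tibble(
    nutrient = nutrient_names(),
    rni_per_day = c(46, 1000, 29.4, 4.9, 26, 1.1, 500),
    unit = unname(nutrient_units()))
}

build_taxa <- function(cfg) {
  n <- cfg$n_taxa
  n_sp <- max(1L, round(cfg$frac_species_level * n))
  n_rest <- n - n_sp
  n_gen_rank <- floor(0.5 * n_rest)
  n_fam_rank <- floor(0.3 * n_rest)
  n_coarse <- n_rest - n_gen_rank - n_fam_rank

  n_fam <- max(3L, ceiling(n_sp / 8))
  n_gen <- max(n_fam, ceiling(n_sp / 3))
  fams <- sprintf("Fam%02d", seq_len(n_fam))
  gen_fam <- sample(fams, n_gen, replace = TRUE)
  gens <- sprintf("Gen%03d", seq_len(n_gen))

  sp_gen <- sample(seq_len(n_gen), n_sp, replace = TRUE)
  species <- tibble::tibble(
    taxon_id = sprintf("T%04d", seq_len(n_sp)),
    rank = "species",
    species = sprintf("%s sp%03d", gens[sp_gen], seq_len(n_sp)),
    genus = gens[sp_gen],
    family = gen_fam[sp_gen])
  species <- dplyr::bind_cols(species, draw_concentrations(n_sp))

  next_id <- n_sp
  mk_ids <- function(k) sprintf("T%04d", next_id + seq_len(k))
  na_conc <- function(k) {
    out <- tibble::as_tibble(stats::setNames(
      rep(list(rep(NA_real_, k)), 7), conc_cols()))
    out
  }

  genus_rank <- tibble::tibble(
    taxon_id = mk_ids(n_gen_rank), rank = rep("genus", n_gen_rank),
    species = rep("", n_gen_rank),
    genus = if (n_gen_rank) sample(gens, n_gen_rank, replace = TRUE) else character(),
    family = "")
  genus_rank$family <- gen_fam[match(genus_rank$genus, gens)]
  genus_rank <- dplyr::bind_cols(genus_rank, na_conc(n_gen_rank))
  next_id <- next_id + n_gen_rank

  family_rank <- tibble::tibble(
    taxon_id = mk_ids(n_fam_rank), rank = rep("family", n_fam_rank),
    species = rep("", n_fam_rank), genus = rep("", n_fam_rank),
    family = if (n_fam_rank) sample(fams, n_fam_rank, replace = TRUE) else character())
  family_rank <- dplyr::bind_cols(family_rank, na_conc(n_fam_rank))
  next_id <- next_id + n_fam_rank

  coarse <- tibble::tibble(
    taxon_id = mk_ids(n_coarse), rank = rep("coarse", n_coarse),
    species = rep("", n_coarse), genus = rep("", n_coarse),
    family = rep("", n_coarse))
  cc <- na_conc(n_coarse)
  if (n_coarse > 0) {
    # roughly half the coarse groups carry their own concentration estimate
    has_own <- seq_len(n_coarse) %% 2 == 1
    own <- draw_concentrations(sum(has_own))
    cc[has_own, ] <- own
  }
  coarse <- dplyr::bind_cols(coarse, cc)

  dplyr::bind_rows(species, genus_rank, family_rank, coarse)
}

# geometric random walk through the year range, one multiplier per year
year_walk <- function(n_years, sd) {
  exp(c(0, cumsum(stats::rnorm(n_years - 1, 0, sd))))
}

#' Generate a synthetic fisheries world
#'
#' Produces a self-consistent world: nations plus the reserved high-seas
#' zone `HS`, a taxon table with mixed reporting resolution, a multi-decade
#' catch series (domestic EEZ catch, foreign-EEZ catch and high-seas catch,
#' each carried through time by per-nation geometric random walks), a closed
#' bilateral trade series (every export record is simultaneously some
#' nation's import, so trade closes exactly by construction), a
#' flag-of-convenience registry, a national indicator table and an RNI
#' table. Generation is fully seeded: the same configuration yields a
#' bit-identical world.
#'
#' @param config An `nf_config` from [world_config()].
#' @return An object of class `nf_world`: a list with elements `nations`,
#'   `taxa`, `catch`, `trade`, `foc`, `indicators`, `rni`, `config`.
#' @export
#' @examples
#' w <- generate_world(world_config(n_nations = 6, n_taxa = 20, seed = 7))
#' nrow(w$indicators)
generate_world <- function(config) {
  if (!inherits(config, "nf_config"))
    stop("config must be created with world_config()", call. = FALSE)
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  nations <- sprintf("N%03d", seq_len(cfg$n_nations))
  years <- seq(cfg$year_range[1], cfg$year_range[2])
  taxa <- build_taxa(cfg)
  taxon_ids <- taxa$taxon_id

  # --- base (time-invariant) catch structure -------------------------------
  dom <- tidyr::expand_grid(fishing_nation = nations, taxon_id = taxon_ids)
  dom <- dom[stats::runif(nrow(dom)) > cfg$domestic_sparsity, ]
  # guarantee every nation a domestic portfolio
  missing <- setdiff(nations, unique(dom$fishing_nation))
  if (length(missing) > 0) {
    dom <- dplyr::bind_rows(dom, tidyr::expand_grid(
      fishing_nation = missing,
      taxon_id = sample(taxon_ids, min(3, length(taxon_ids)))))
  }
  dom$source_zone <- dom$fishing_nation
  dom$channel <- "domestic"
  dom$base <- stats::rlnorm(nrow(dom), cfg$tonnage_meanlog, cfg$tonnage_sdlog)

  frn <- lapply(nations, function(nat) {
    k <- min(stats::rpois(1, cfg$mean_foreign_partners), cfg$n_nations - 1)
    if (k == 0) return(NULL)
    partners <- sample(setdiff(nations, nat), k)
    tidyr::expand_grid(fishing_nation = nat, source_zone = partners,
                       taxon_id = sample(taxon_ids, min(3, length(taxon_ids))))
  })
  frn <- dplyr::bind_rows(frn)
  if (nrow(frn) > 0) {
    frn$channel <- "foreign"
    frn$base <- stats::rlnorm(nrow(frn), cfg$tonnage_meanlog - 0.7,
                              cfg$tonnage_sdlog)
  }

  n_hs <- max(1L, ceiling(cfg$hs_fishing_frac * cfg$n_nations))
  hs_nations <- sample(nations, n_hs)
  hs <- tidyr::expand_grid(
    fishing_nation = hs_nations,
    taxon_id = sample(taxon_ids, min(5, length(taxon_ids))))
  hs$source_zone <- HS_TOKEN
  hs$channel <- "hs"
  hs$base <- stats::rlnorm(nrow(hs), cfg$tonnage_meanlog - 0.7,
                           cfg$tonnage_sdlog)
  # scale high-seas catch to the configured share of the global total
  tot_eez <- sum(dom$base) + sum(frn$base)
  if (sum(hs$base) > 0 && cfg$high_seas_share > 0) {
    hs$base <- hs$base * cfg$high_seas_share * tot_eez /
      ((1 - cfg$high_seas_share) * sum(hs$base))
  }

  base_catch <- dplyr::bind_rows(dom, frn, hs)

  # --- carry through time with per-(nation, channel) geometric walks -------
  walk_key <- unique(base_catch[c("fishing_nation", "channel")])
  walk_key$sd <- stats::runif(nrow(walk_key), cfg$walk_sd_range[1],
                              cfg$walk_sd_range[2])
  walks <- do.call(rbind, lapply(seq_len(nrow(walk_key)), function(i) {
    data.frame(fishing_nation = walk_key$fishing_nation[i],
               channel = walk_key$channel[i], year = years,
               mult = year_walk(length(years), walk_key$sd[i]))
  }))
  catch <- dplyr::inner_join(base_catch, walks,
                             by = c("fishing_nation", "channel"),
                             relationship = "many-to-many")
  catch$tonnes <- catch$base * catch$mult
  catch <- tibble::as_tibble(
    catch[order(catch$year, catch$fishing_nation, catch$source_zone,
                catch$taxon_id),
          c("year", "fishing_nation", "source_zone", "taxon_id", "tonnes")])

  # --- trade ---------------------------------------------------------------
  tr <- lapply(nations, function(nat) {
    k <- min(1 + stats::rpois(1, max(cfg$trade_partners - 1, 0)),
             cfg$n_nations - 1)
    partners <- sample(setdiff(nations, nat), k)
    tidyr::expand_grid(exporter = nat, importer = partners,
                       taxon_id = sample(taxon_ids,
                                         min(cfg$trade_taxa, length(taxon_ids))))
  })
  tr <- dplyr::bind_rows(tr)
  # guarantee every nation imports something (each nation has an import
  # channel, so exposure weights are well defined everywhere)
  never_imp <- setdiff(nations, unique(tr$importer))
  if (length(never_imp) > 0) {
    extra <- tibble::tibble(
      importer = never_imp,
      exporter = vapply(never_imp, function(nat)
        sample(setdiff(nations, nat), 1), character(1)),
      taxon_id = sample(taxon_ids, length(never_imp), replace = TRUE))
    tr <- dplyr::bind_rows(tr, extra[c("exporter", "importer", "taxon_id")])
  }
  tr$base <- stats::rlnorm(nrow(tr), cfg$tonnage_meanlog - 1.2,
                           cfg$tonnage_sdlog)
  imp_key <- data.frame(importer = nations,
                        sd = stats::runif(cfg$n_nations, cfg$walk_sd_range[1],
                                          cfg$walk_sd_range[2]))
  imp_walks <- do.call(rbind, lapply(seq_len(nrow(imp_key)), function(i) {
    data.frame(importer = imp_key$importer[i], year = years,
               mult = year_walk(length(years), imp_key$sd[i]))
  }))
  trade <- dplyr::inner_join(tr, imp_walks, by = "importer",
                             relationship = "many-to-many")
  trade$tonnes <- trade$base * trade$mult
  trade <- tibble::as_tibble(
    trade[order(trade$year, trade$exporter, trade$importer, trade$taxon_id),
          c("year", "exporter", "importer", "taxon_id", "tonnes")])

  # --- flag-of-convenience registry ---------------------------------------
  foc <- tibble::tibble(nation = nations,
                        prop_foc_2013 = stats::rbeta(cfg$n_nations, 1, 25),
                        prop_foc_2018 = stats::rbeta(cfg$n_nations, 1, 25))
  if (cfg$foc_heavy_nations > 0) {
    heavy <- sample(nations, cfg$foc_heavy_nations)
    idx <- match(heavy, foc$nation)
    foc$prop_foc_2013[idx] <- stats::runif(length(idx), 0.5, 0.9)
    foc$prop_foc_2018[idx] <- stats::runif(length(idx), 0.5, 0.9)
  }

  # --- indicators ----------------------------------------------------------
  w <- stats::rnorm(cfg$n_nations)  # latent wealth axis
  ind <- tibble::tibble(
    nation = nations,
    population = stats::rlnorm(cfg$n_nations, log(5e6), 1.2),
    fish_protein_share = 100 * stats::rbeta(cfg$n_nations, 2, 6),
    gdp_pc = exp(7.5 + 1.5 * w + stats::rnorm(cfg$n_nations, 0, 0.4)),
    stability = w + stats::rnorm(cfg$n_nations, 0, 0.5),
    health_exp = stats::runif(cfg$n_nations, 2, 12),
    net_food_importer = stats::rbinom(cfg$n_nations, 1, 0.5),
    production_change = stats::runif(cfg$n_nations, -0.5, 0.3),
    hdi = stats::plogis(0.8 * w + stats::rnorm(cfg$n_nations, 0.5, 0.3)),
    inequality_coef = 100 * stats::plogis(-0.9 * w +
                                            stats::rnorm(cfg$n_nations, -0.8, 0.4)),
    energy_adequacy = 100 + 25 * stats::plogis(2 * w) +
      stats::rnorm(cfg$n_nations, 0, 3))
  prev <- vapply(intake_nutrients(), function(nm)
    100 * stats::plogis(stats::qlogis(0.15) - 1.1 * w +
                          stats::rnorm(cfg$n_nations, 0, 0.9)),
    numeric(cfg$n_nations))
  colnames(prev) <- intake_cols()
  ind <- dplyr::bind_cols(ind, tibble::as_tibble(prev))
  n_nd <- round(cfg$nd_frac * cfg$n_nations)
  if (n_nd > 0) {
    nd <- sample(nations, n_nd)
    ind[ind$nation %in% nd, intake_cols()] <- NA_real_
  }

  structure(list(nations = nations, taxa = taxa, catch = catch,
                 trade = trade, foc = foc, indicators = ind,
                 rni = default_rni(), config = cfg),
            class = "nf_world")
}

#' @export
print.nf_world <- function(x, ...) {
  cat(sprintf(paste0("<nf_world> %d nations, %d taxa, years %d-%d ",
                     "(focal %d)\n  catch: %d records, trade: %d records\n"),
              length(x$nations), nrow(x$taxa), x$config$year_range[1],
              x$config$year_range[2], x$config$focal_year,
              nrow(x$catch), nrow(x$trade)))
  invisible(x)
}

#' Push two nations of a world to the vulnerability extremes
#'
#' Rewrites one nation ("worst") so that it attains the maximum of every
#' exposure and sensitivity driver and the minimum of every
#' adaptive-capacity driver, and a second nation ("best") the reverse. The
#' worst nation keeps no domestic catch (its supply is entirely foreign
#' fishing from a single EEZ plus imports from a single partner, both with
#' maximally spiky time series); the best nation becomes purely domestic
#' with an even portfolio across all species-rank taxa. After the full
#' pipeline the worst nation's renormalized vulnerability is exactly 1 and
#' the best nation's exactly 0, which makes the fixture a sharp end-to-end
#' boundary check.
#'
#' @param world An `nf_world`.
#' @param worst,best Nation identifiers; default the first two nations.
#' @return The modified `nf_world`, with an `extremes` attribute naming the
#'   two nations.
#' @export
generate_indicator_extremes <- function(world,
                                        worst = world$nations[1],
                                        best = world$nations[2]) {
  stopifnot(inherits(world, "nf_world"))
  if (length(world$nations) < 2)
    stop("at least 2 nations are required", call. = FALSE)
  if (worst == best) stop("worst and best must differ", call. = FALSE)
  nations <- world$nations
  years <- seq(world$config$year_range[1], world$config$year_range[2])
  partner <- setdiff(nations, c(worst, best))
  partner <- if (length(partner) > 0) partner[length(partner)] else best

  # single-spike series: near-maximal coefficient of variation while
  # keeping all tonnages strictly positive
  spike <- rep(1e-6, length(years))
  spike[length(spike)] <- 1e6
  sp_taxa <- world$taxa$taxon_id[world$taxa$rank == "species"]
  focal <- world$config$focal_year

  catch <- world$catch
  catch <- catch[catch$fishing_nation != worst, ]
  worst_ff <- tibble::tibble(
    year = years, fishing_nation = worst, source_zone = partner,
    taxon_id = sp_taxa[1], tonnes = spike)
  # keep a solid focal-year foreign catch so supply weights are well defined
  worst_ff$tonnes[worst_ff$year == focal] <- 5000

  catch <- catch[!(catch$fishing_nation == best &
                     catch$source_zone != best), ]
  catch <- catch[!(catch$fishing_nation == best), ]
  best_dom <- tidyr::expand_grid(year = years, fishing_nation = best,
                                 taxon_id = sp_taxa)
  best_dom$source_zone <- best
  best_dom$tonnes <- 100
  catch <- dplyr::bind_rows(
    catch, worst_ff,
    best_dom[c("year", "fishing_nation", "source_zone", "taxon_id", "tonnes")])

  trade <- world$trade
  trade <- trade[trade$importer != worst & trade$importer != best, ]
  worst_imp <- tibble::tibble(
    year = years, exporter = partner, importer = worst,
    taxon_id = sp_taxa[min(2, length(sp_taxa))], tonnes = spike)
  worst_imp$tonnes[worst_imp$year == focal] <- 2000
  trade <- dplyr::bind_rows(trade, worst_imp)

  ind <- world$indicators
  others <- ind$nation != worst & ind$nation != best
  iw <- ind$nation == worst
  ib <- ind$nation == best
  ind[iw, intake_cols()] <- 100
  ind[ib, intake_cols()] <- 0
  ind$fish_protein_share[iw] <- 100
  ind$fish_protein_share[ib] <- 0
  ind$gdp_pc[iw] <- 0.5 * min(ind$gdp_pc[others])
  ind$gdp_pc[ib] <- 2 * max(ind$gdp_pc[others])
  ind$stability[iw] <- min(ind$stability[others]) - 1
  ind$stability[ib] <- max(ind$stability[others]) + 1
  ind$health_exp[iw] <- 0.5
  ind$health_exp[ib] <- max(ind$health_exp[others]) + 5
  ind$net_food_importer[iw] <- 1L
  ind$net_food_importer[ib] <- 0L
  ind$production_change[iw] <- min(ind$production_change[others]) - 0.1
  ind$production_change[ib] <- max(ind$production_change[others]) + 0.1

  foc <- world$foc
  foc$prop_foc_2013[foc$nation %in% c(worst, best)] <- 0
  foc$prop_foc_2018[foc$nation %in% c(worst, best)] <- 0

  out <- world
  out$catch <- tibble::as_tibble(
    catch[order(catch$year, catch$fishing_nation, catch$source_zone,
                catch$taxon_id), ])
  out$trade <- tibble::as_tibble(
    trade[order(trade$year, trade$exporter, trade$importer,
                trade$taxon_id), ])
  out$indicators <- ind
  out$foc <- foc
  attr(out, "extremes") <- list(worst = worst, best = best)
  out
}
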