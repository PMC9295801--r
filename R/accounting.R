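# Converting tonnage to nutrient mass, RNI-equivalents and per-capita
# yields, and building the per-nation channel ledger.

#' Nutrient mass from tonnage and concentration
#'
#' `mass = tonnes * 1e4 * conc`: a tonne contains 10^4 hundred-gram
#' portions, so the mass comes out in the concentration's native unit
#' (g, mg or mcg depending on the nutrient).
#'
#' @param tonnes Tonnage (>= 0), vectorized.
#' @param conc Concentration per 100 g (>= 0), vectorized.
#' @return Nutrient mass in the concentration's unit.
#' @export
#' @examples
#' nutrient_mass(2, 50)   # 2 t at 50 mg/100 g -> 1e6 mg
nutrient_mass <- function(tonnes, conc) {
  if (any(tonnes < 0, na.rm = TRUE)) stop("tonnes must be >= 0", call. = FALSE)
  if (any(conc < 0, na.rm = TRUE)) stop("conc must be >= 0", call. = FALSE)
  tonnes * 1e4 * conc
}

#' RNI-equivalents of an annual nutrient mass
#'
#' Number of reproductive-age females whose recommended nutrient intake a
#' yearly nutrient mass could theoretically cover, under a 365-day year:
#' `persons = annual_mass / (rni_per_day * 365)`. Fractional persons are
#' permitted.
#'
#' @param annual_mass Nutrient mass per year (>= 0), in the RNI's unit.
#' @param rni_per_day Daily recommended intake (> 0).
#' @return Persons (possibly fractional), vectorized.
#' @export
#' @examples
#' rni_equivalents(1e6, 10)  # 273.97 persons
rni_equivalents <- function(annual_mass, rni_per_day) {
  if (any(annual_mass < 0, na.rm = TRUE))
    stop("annual_mass must be >= 0", call. = FALSE)
  if (any(rni_per_day <= 0, na.rm = TRUE))
    stop("rni_per_day must be > 0", call. = FALSE)
  annual_mass / (rni_per_day * 365)
}

#' Per-capita nutrient yield as a percentage of RNI per day
#'
#' `yield = (annual_mass / 365) / population / rni_per_day * 100`.
#'
#' @param annual_mass Nutrient mass per year.
#' @param population Persons (> 0).
#' @param rni_per_day Daily recommended intake (> 0).
#' @return Percent of RNI per capita per day, vectorized.
#' @export
#' @examples
#' per_capita_yield(3.65e6, 1000, 10)  # 100%
per_capita_yield <- function(annual_mass, population, rni_per_day) {
  if (any(population <= 0, na.rm = TRUE))
    stop("population must be > 0", call. = FALSE)
  if (any(rni_per_day <= 0, na.rm = TRUE))
    stop("rni_per_day must be > 0", call. = FALSE)
  (annual_mass / 365) / population / rni_per_day * 100
}

# effective FOC proportion per nation: mean of the 2013 and 2018 columns
foc_proportion <- function(foc) {
  if (any(foc$prop_foc_2013 < 0 | foc$prop_foc_2013 > 1 |
            foc$prop_foc_2018 < 0 | foc$prop_foc_2018 > 1, na.rm = TRUE))
    stop("FOC proportions must be in [0, 1]", call. = FALSE)
  p <- (foc$prop_foc_2013 + foc$prop_foc_2018) / 2
  stats::setNames(p, foc$nation)
}

#' Split catch records into retained and flag-of-convenience shares
#'
#' Each nation's tonnage is split into a retained share `(1 - p)` that
#' stays attributed to the flag nation and a share `p` moved to an
#' unattributed FOC pool, where `p` is the nation's proportion of vessels
#' under flags of convenience averaged across the 2013 and 2018 registry
#' columns. Total tonnage is conserved exactly. The pool is never
#' reassigned to beneficial-owner nations; downstream it is reported under
#' the pseudo-nation `"FOC"`.
#'
#' @param catch Catch (or any) records with `fishing_nation` and `tonnes`.
#' @param foc Registry tibble with `nation`, `prop_foc_2013`,
#'   `prop_foc_2018`.
#' @return List with elements `retained` and `pool`, both record tibbles in
#'   the input schema (zero-tonnage rows dropped from `pool`).
#' @export
#' @examples
#' foc <- tibble::tibble(nation = "A", prop_foc_2013 = 0.2,
#'                       prop_foc_2018 = 0.4)
#' rec <- tibble::tibble(fishing_nation = "A", tonnes = 100)
#' apply_foc(rec, foc)  # 70 t retained, 30 t pool
apply_foc <- function(catch, foc) {
  p <- foc_proportion(foc)
  miss <- setdiff(unique(catch$fishing_nation), names(p))
  if (length(miss) > 0) {
    warning("nations missing from the FOC table treated as p = 0: ",
            paste(miss, collapse = ", "), call. = FALSE)
    p <- c(p, stats::setNames(rep(0, length(miss)), miss))
  }
  pr <- unname(p[catch$fishing_nation])
  retained <- catch
  retained$tonnes <- catch$tonnes * (1 - pr)
  pool <- catch
  pool$tonnes <- catch$tonnes * pr
  pool <- pool[pool$tonnes > 0, , drop = FALSE]
  list(retained = retained, pool = pool)
}

mass_cols <- function() paste0("mass_", nutrient_names())

# add mass_<nutrient> columns to records carrying tonnes + conc columns
add_mass_cols <- function(records) {
  for (n in nutrient_names())
    records[[paste0("mass_", n)]] <-
      nutrient_mass(records$tonnes, records[[paste0("conc_", n)]])
  records
}

sum_mass_by <- function(records, keys) {
  dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(keys))),
    dplyr::across(dplyr::all_of(mass_cols()), sum), .groups = "drop")
}

mass_wide_to_long <- function(df, keys) {
  long <- tidyr::pivot_longer(df[c(keys, mass_cols())],
                              dplyr::all_of(mass_cols()),
                              names_to = "nutrient", values_to = "mass")
  long$nutrient <- sub("^mass_", "", long$nutrient)
  long
}

#' Build the per-nation nutrient ledger for the focal year
#'
#' Values every focal-year catch and trade record in nutrient mass and
#' partitions it into mutually exclusive channels per nation and nutrient:
#' `domestic` (own fleet in own EEZ), `foreign_fished` (own fleet in other
#' nations' EEZs), `high_seas_share` (own fleet on the high seas),
#' `lost_to_foreign` (other fleets in own EEZ, always unadjusted: the
#' extraction happens regardless of who owns the vessel), `imported` and
#' `exported` (trade records), plus a `foc_pool` channel booked under the
#' pseudo-nation `"FOC"` when the flag-of-convenience adjustment is on.
#' With the adjustment on, the FOC share of each nation's foreign-fishing
#' and high-seas catch moves to the pool; tonnage is conserved exactly.
#'
#' @param world An `nf_world` (or any list with the same elements).
#' @param foc_mode `"off"` or `"on"`.
#' @param focal_year Accounting year; defaults to the world's configured
#'   focal year.
#' @return An object of class `nf_ledger`: list with `table` (nation,
#'   nutrient, channel, mass, rni_equiv), `ff_pairs` (source_zone x fleet
#'   nutrient-mass flows, fleet `"FOC"` for pool flows), `trade_pairs`
#'   (exporter x importer flows), `audit` (valued records with
#'   interpolation tiers), `rni`, `foc_mode`, `focal_year`, `nations`.
#' @export
build_ledger <- function(world, foc_mode = c("off", "on"),
                         focal_year = NULL) {
  foc_mode <- match.arg(foc_mode)
  focal_year <- focal_year %||% world$config$focal_year
  nations <- world$nations

  bad <- setdiff(unique(world$catch$fishing_nation), nations)
  bad <- c(bad, setdiff(unique(world$catch$source_zone), c(nations, HS_TOKEN)),
           setdiff(unique(c(world$trade$exporter, world$trade$importer)),
                   nations))
  if (length(bad) > 0)
    stop("records reference unknown nations: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (any(world$catch$tonnes < 0) || any(world$trade$tonnes < 0))
    stop("tonnages must be >= 0", call. = FALSE)

  catch <- world$catch[world$catch$year == focal_year, , drop = FALSE]
  trade <- world$trade[world$trade$year == focal_year, , drop = FALSE]
  if (nrow(catch) == 0)
    stop("no catch records for focal year ", focal_year, call. = FALSE)

  catch <- assign_record_concentrations(catch, world$taxa, "source_zone")
  trade <- assign_record_concentrations(trade, world$taxa, "exporter")
  catch <- add_mass_cols(catch)
  trade <- add_mass_cols(trade)

  is_foreign <- catch$source_zone != catch$fishing_nation  # incl. high seas
  fleet_catch <- catch
  fleet_catch$fleet <- fleet_catch$fishing_nation
  pool <- NULL
  if (foc_mode == "on") {
    split <- apply_foc(catch[is_foreign, , drop = FALSE], world$foc)
    pool <- split$pool
    if (nrow(pool) > 0) {
      pool <- add_mass_cols(pool)
      pool$fleet <- FOC_TOKEN
    } else pool <- NULL
    retained <- add_mass_cols(split$retained)
    retained$fleet <- retained$fishing_nation
    fleet_catch <- dplyr::bind_rows(
      transform(catch[!is_foreign, , drop = FALSE],
                fleet = fishing_nation),
      retained, pool)
  }

  # channel aggregation ------------------------------------------------
  dom <- fleet_catch[fleet_catch$fleet != FOC_TOKEN &
                       fleet_catch$source_zone == fleet_catch$fleet, ]
  ff <- fleet_catch[fleet_catch$fleet != FOC_TOKEN &
                      fleet_catch$source_zone != fleet_catch$fleet &
                      fleet_catch$source_zone != HS_TOKEN, ]
  hs <- fleet_catch[fleet_catch$fleet != FOC_TOKEN &
                      fleet_catch$source_zone == HS_TOKEN, ]
  pool_rows <- fleet_catch[fleet_catch$fleet == FOC_TOKEN, ]
  loss <- catch[catch$source_zone != catch$fishing_nation &
                  catch$source_zone != HS_TOKEN, ]  # unadjusted

  chan <- function(df, key, channel) {
    if (nrow(df) == 0) return(NULL)
    agg <- sum_mass_by(df, key)
    names(agg)[1] <- "nation"
    long <- mass_wide_to_long(agg, "nation")
    long$channel <- channel
    long
  }
  tab <- dplyr::bind_rows(
    chan(dom, "fleet", "domestic"),
    chan(ff, "fleet", "foreign_fished"),
    chan(hs, "fleet", "high_seas_share"),
    chan(loss, "source_zone", "lost_to_foreign"),
    chan(trade, "importer", "imported"),
    chan(trade, "exporter", "exported"),
    chan(pool_rows, "fleet", "foc_pool"))

  # complete the nation x nutrient x channel grid with zeros
  channels <- c("domestic", "foreign_fished", "high_seas_share",
                "lost_to_foreign", "imported", "exported")
  grid <- tidyr::expand_grid(nation = nations, nutrient = nutrient_names(),
                             channel = channels)
  if (foc_mode == "on")
    grid <- dplyr::bind_rows(grid, tidyr::expand_grid(
      nation = FOC_TOKEN, nutrient = nutrient_names(),
      channel = "foc_pool"))
  tab <- dplyr::left_join(grid, tab,
                          by = c("nation", "nutrient", "channel"))
  tab$mass[is.na(tab$mass)] <- 0

  rni <- stats::setNames(world$rni$rni_per_day, world$rni$nutrient)
  tab$rni_equiv <- rni_equivalents(tab$mass, unname(rni[tab$nutrient]))

  ff_flows <- fleet_catch[fleet_catch$source_zone != fleet_catch$fishing_nation, ]
  ff_pairs <- if (nrow(ff_flows) > 0)
    sum_mass_by(ff_flows, c("source_zone", "fleet")) else NULL
  trade_pairs <- if (nrow(trade) > 0)
    sum_mass_by(trade, c("exporter", "importer")) else NULL

  structure(list(table = tibble::as_tibble(tab), ff_pairs = ff_pairs,
                 trade_pairs = trade_pairs,
                 audit_catch = catch, audit_trade = trade,
                 rni = world$rni, foc_mode = foc_mode,
                 focal_year = focal_year, nations = nations),
            class = "nf_ledger")
}

#' @export
print.nf_ledger <- function(x, ...) {
  cat(sprintf("<nf_ledger> %d nations, focal year %d, foc %s\n",
              length(x$nations), x$focal_year, x$foc_mode))
  invisible(x)
}

# channel masses in RNI-equivalents, wide per nation for one nutrient
ledger_channel <- function(ledger, channel, value = c("rni_equiv", "mass")) {
  value <- match.arg(value)
  t <- ledger$table[ledger$table$channel == channel, ]
  stats::setNames(t[[value]], paste(t$nation, t$nutrient))
}
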