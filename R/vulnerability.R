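# Composite vulnerability of national fishery-derived nutrient supply:
#   Vulnerability = Exposure + Sensitivity - Adaptive capacity
# with every constituent min-max normalized across nations at each stage,
# and an optional climate-exposure extension driven by projected change in
# domestic catch production and the diversity of the domestic catch.

#' Coefficient of variation of an annual series
#'
#' Sample standard deviation divided by the mean. Series with zero mean
#' (in particular all-zero series: the nation has no such supply channel)
#' return 0 by convention, so an absent channel contributes no exposure.
#'
#' @param series Numeric vector of at least 2 annual values.
#' @return Dimensionless CV.
#' @export
#' @examples
#' coefficient_of_variation(c(0, 20))  # 1.41421
coefficient_of_variation <- function(series) {
  if (length(series) < 2)
    stop("series must contain at least 2 years", call. = FALSE)
  m <- mean(series)
  if (m == 0) return(0)
  stats::sd(series) / m
}

#' Shannon diversity of a mass vector
#'
#' Shannon-Weaver index `H = -sum(p * log(p))` in nats over the positive
#' shares of the vector (computed with `vegan::diversity`). An all-zero
#' vector returns 0 with a warning.
#'
#' @param masses Nonnegative vector of masses over locations, partners or
#'   species.
#' @return H in nats.
#' @export
#' @examples
#' shannon_diversity(rep(1, 4))  # log(4)
shannon_diversity <- function(masses) {
  if (any(masses < 0, na.rm = TRUE))
    stop("masses must be >= 0", call. = FALSE)
  masses <- masses[!is.na(masses)]
  if (length(masses) == 0 || sum(masses) == 0) {
    warning("all-zero mass vector; Shannon diversity set to 0",
            call. = FALSE)
    return(0)
  }
  as.numeric(vegan::diversity(masses, index = "shannon"))
}

#' Min-max normalization across nations
#'
#' `(x - min) / (max - min)` over the non-missing values; the reversed
#' variant is one minus that (used where high raw values mean low
#' exposure/sensitivity or low adaptive capacity). Missing values stay
#' missing; a constant vector maps to all zeros with a warning.
#'
#' @param values Numeric vector (one entry per nation).
#' @param reverse Reverse the scale?
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' minmax_normalize(c(2, 4, 6))
minmax_normalize <- function(values, reverse = FALSE) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values are missing", call. = FALSE)
  rng <- range(values[ok])
  out <- rep(NA_real_, length(values))
  if (rng[1] == rng[2]) {
    warning("constant vector; min-max normalization returns 0",
            call. = FALSE)
    out[ok] <- 0
  } else {
    out[ok] <- (values[ok] - rng[1]) / (rng[2] - rng[1])
  }
  if (reverse) out <- 1 - out
  out
}

#' Supply-share weights of the exposure components
#'
#' Shares of each nation's fishery-derived nutrient supply contributed by
#' foreign fishing (`w_ff`), imports (`w_imp`) and domestic catch
#' (`w_dc`), computed on the across-seven-nutrient mean of
#' RNI-equivalents. The supply denominator is domestic + foreign-fished
#' (incl. high seas) + imported; exports are excluded because a decline in
#' exports would increase retention of nutrients rather than reduce
#' supply. Nations with zero total supply get all-zero weights.
#'
#' @param ledger An `nf_ledger`; the vulnerability analyses expect the
#'   FOC-adjusted ledger (`foc_mode = "on"`).
#' @return Tibble with `nation`, `w_ff`, `w_imp`, `w_dc`; weights sum to 1
#'   where supply is positive.
#' @export
supply_weights <- function(ledger) {
  t <- ledger$table[ledger$table$nation != FOC_TOKEN, ]
  wide <- tidyr::pivot_wider(t[c("nation", "nutrient", "channel", "rni_equiv")],
                             names_from = "channel",
                             values_from = "rni_equiv", values_fill = 0)
  agg <- dplyr::summarise(
    dplyr::group_by(wide, .data$nation),
    dc = mean(.data$domestic),
    ff = mean(.data$foreign_fished + .data$high_seas_share),
    imp = mean(.data$imported), .groups = "drop")
  tot <- agg$dc + agg$ff + agg$imp
  tibble::tibble(nation = agg$nation,
                 w_ff = ifelse(tot > 0, agg$ff / tot, 0),
                 w_imp = ifelse(tot > 0, agg$imp / tot, 0),
                 w_dc = ifelse(tot > 0, agg$dc / tot, 0))
}

# annual tonnage series per nation for one channel, all years filled with 0
channel_series_cv <- function(flows, nations, years) {
  vapply(nations, function(nat) {
    s <- flows$tonnes[flows$nation == nat][match(years,
                                                 flows$year[flows$nation == nat])]
    s[is.na(s)] <- 0
    coefficient_of_variation(s)
  }, numeric(1))
}

# mean-over-nutrients Shannon diversity from a pair table
pair_diversity <- function(pairs, by_col, over_col, nations) {
  vapply(nations, function(nat) {
    sub <- pairs[pairs[[by_col]] == nat, , drop = FALSE]
    if (nrow(sub) == 0) return(0)
    h <- vapply(mass_cols(), function(mc) {
      m <- tapply(sub[[mc]], sub[[over_col]], sum)
      if (sum(m) == 0) 0 else as.numeric(vegan::diversity(m, "shannon"))
    }, numeric(1))
    mean(h)
  }, numeric(1))
}

#' Raw vulnerability sub-variables per nation
#'
#' Assembles every driver of the vulnerability index from a world and its
#' FOC-adjusted ledger: catch/import volatility (`cv_ff`, `cv_imp`:
#' coefficient of variation of annual foreign-fishing / import tonnage
#' over the world's full year range, FOC-retained share for catches),
#' portfolio diversity (`div_ff`, `div_imp`, `div_dc`: Shannon diversity
#' of focal-year nutrient-mass shares over source locations, import
#' partners and domestic-catch taxa, averaged across the seven nutrients),
#' supply-share weights, and the indicator drivers of sensitivity
#' (`s_fd`, `s_pimii` = mean prevalence over the available intake columns)
#' and adaptive capacity (`ac_gdp`, `ac_s`, `ac_he`, `ac_imp` binary net
#' food importer; a continuous food-trade balance is thresholded at 0),
#' plus the projected relative change in domestic catch production
#' (`cpdc`).
#'
#' @param world An `nf_world`.
#' @param ledger Optional prebuilt `nf_ledger`; defaults to
#'   `build_ledger(world, "on")`.
#' @return Tibble of raw (unnormalized) sub-variables, one row per nation.
#' @export
vulnerability_subvariables <- function(world, ledger = NULL) {
  if (is.null(ledger)) ledger <- build_ledger(world, "on")
  nations <- world$nations
  years <- seq(world$config$year_range[1], world$config$year_range[2])

  p <- foc_proportion(world$foc)
  pr <- unname(p[world$catch$fishing_nation])
  pr[is.na(pr)] <- 0
  ffc <- world$catch[world$catch$source_zone != world$catch$fishing_nation, ]
  ffc_p <- pr[world$catch$source_zone != world$catch$fishing_nation]
  ff_t <- stats::aggregate(
    ffc$tonnes * (1 - ffc_p),
    list(nation = ffc$fishing_nation, year = ffc$year), sum)
  names(ff_t)[3] <- "tonnes"
  cv_ff <- channel_series_cv(ff_t, nations, years)

  imp_t <- stats::aggregate(world$trade$tonnes,
                            list(nation = world$trade$importer,
                                 year = world$trade$year), sum)
  names(imp_t)[3] <- "tonnes"
  cv_imp <- channel_series_cv(imp_t, nations, years)

  ffp <- ledger$ff_pairs
  own_ff <- if (!is.null(ffp)) ffp[ffp$fleet != FOC_TOKEN, ] else
    tibble::tibble(source_zone = character(), fleet = character())
  div_ff <- pair_diversity(own_ff, "fleet", "source_zone", nations)
  trp <- ledger$trade_pairs %||%
    tibble::tibble(exporter = character(), importer = character())
  div_imp <- pair_diversity(trp, "importer", "exporter", nations)

  dom <- ledger$audit_catch
  dom <- dom[dom$source_zone == dom$fishing_nation, ]
  div_dc <- pair_diversity(dom, "fishing_nation", "taxon_id", nations)

  w <- supply_weights(ledger)
  ind <- world$indicators[match(nations, world$indicators$nation), ]
  prev <- as.matrix(ind[intake_cols()])
  s_pimii <- rowMeans(prev, na.rm = TRUE)
  s_pimii[is.nan(s_pimii)] <- NA_real_

  ac_imp <- ind$net_food_importer
  if (any(!ac_imp %in% c(0, 1), na.rm = TRUE))
    ac_imp <- as.integer(ac_imp > 0)  # continuous balance: threshold at 0

  tibble::tibble(nation = nations,
                 cv_ff = unname(cv_ff), div_ff = unname(div_ff),
                 cv_imp = unname(cv_imp), div_imp = unname(div_imp),
                 div_dc = unname(div_dc),
                 w_ff = w$w_ff[match(nations, w$nation)],
                 w_imp = w$w_imp[match(nations, w$nation)],
                 w_dc = w$w_dc[match(nations, w$nation)],
                 s_fd = ind$fish_protein_share, s_pimii = s_pimii,
                 ac_gdp = ind$gdp_pc, ac_s = ind$stability,
                 ac_he = ind$health_exp, ac_imp = as.numeric(ac_imp),
                 cpdc = ind$production_change,
                 population = ind$population)
}

# mean over the non-missing entries of each row of a matrix
row_mean_avail <- function(...) {
  m <- cbind(...)
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Exposure, sensitivity, adaptive capacity and vulnerability scores
#'
#' Composes the normalized vulnerability index from the raw sub-variables:
#'
#' * `E_FF = mean(norm(CvFF), 1 - norm(DivFF))`, likewise `E_IMP`;
#'   diversity enters reversed after across-nutrient averaging and
#'   normalization.
#' * Exposure is the renormalized mean of the supply-weighted components:
#'   `E = norm(mean(w_ff * E_FF, w_imp * E_IMP))`; with `climate = TRUE`
#'   the mean also includes `w_dc * E_CC_core` where
#'   `E_CC_core = mean(1 - norm(CpDC), 1 - norm(DivDC))` (a larger
#'   projected decline and a less diverse domestic catch mean greater
#'   exposure).
#' * `S = norm(mean(norm(S_FD), norm(S_PIMII)))`.
#' * `AC = norm(mean(AC_SE, norm(AC_HE), 1 - importer))` with
#'   `AC_SE = mean(norm(GDP), norm(stability))`; net-importer status is
#'   reversed (importing reduces adaptive capacity).
#' * `V_raw = E + S - AC` in `[-1, 2]`; with `renormalize` the reported
#'   vulnerability is min-max rescaled to `[0, 1]` across nations.
#'
#' Parent metrics are means over their available (non-missing) children;
#' nations with any missing driver are flagged via `complete`.
#'
#' @param subvars Output of [vulnerability_subvariables()] (possibly
#'   perturbed).
#' @param climate Include the climate-exposure component?
#' @param renormalize Min-max rescale the final score across nations?
#' @return Tibble with the raw sub-variables, normalized components
#'   (`e_ff`, `e_imp`, `e_cc`, `exposure`, `sensitivity`,
#'   `adaptive_capacity`), `v_raw`, `vulnerability` and `complete`.
#' @export
vulnerability_scores <- function(subvars, climate = FALSE,
                                 renormalize = TRUE) {
  s <- subvars
  e_ff <- row_mean_avail(minmax_normalize(s$cv_ff),
                         minmax_normalize(s$div_ff, reverse = TRUE))
  e_imp <- row_mean_avail(minmax_normalize(s$cv_imp),
                          minmax_normalize(s$div_imp, reverse = TRUE))
  comp <- cbind(s$w_ff * e_ff, s$w_imp * e_imp)
  e_cc <- rep(NA_real_, nrow(s))
  if (climate) {
    e_cc_core <- row_mean_avail(minmax_normalize(s$cpdc, reverse = TRUE),
                                minmax_normalize(s$div_dc, reverse = TRUE))
    e_cc <- s$w_dc * e_cc_core
    comp <- cbind(comp, e_cc)
  }
  exposure <- minmax_normalize(rowMeans(comp))

  sens_children <- cbind(minmax_normalize(s$s_fd),
                         minmax_normalize(s$s_pimii))
  sensitivity <- minmax_normalize(row_mean_avail(sens_children))

  ac_se <- row_mean_avail(minmax_normalize(s$ac_gdp),
                          minmax_normalize(s$ac_s))
  ac <- minmax_normalize(row_mean_avail(ac_se, minmax_normalize(s$ac_he),
                                        1 - s$ac_imp))

  v_raw <- exposure + sensitivity - ac
  vulnerability <- if (renormalize) minmax_normalize(v_raw) else v_raw
  tibble::tibble(
    nation = s$nation, cv_ff = s$cv_ff, div_ff = s$div_ff,
    cv_imp = s$cv_imp, div_imp = s$div_imp, div_dc = s$div_dc,
    w_ff = s$w_ff, w_imp = s$w_imp, w_dc = s$w_dc,
    e_ff = e_ff, e_imp = e_imp, e_cc = e_cc,
    exposure = exposure, sensitivity = sensitivity,
    adaptive_capacity = ac, v_raw = v_raw,
    vulnerability = vulnerability,
    complete = stats::complete.cases(
      s[c("cv_ff", "div_ff", "cv_imp", "div_imp", "s_fd", "s_pimii",
          "ac_gdp", "ac_s", "ac_he", "ac_imp", "cpdc")]))
}

#' Full vulnerability table, with and without climate exposure
#'
#' Convenience wrapper: builds the FOC-adjusted ledger (unless given),
#' assembles the sub-variables and returns the distribution-only scores
#' joined with the climate-augmented ones (`v_raw_climate`,
#' `vulnerability_climate`, `e_climate`).
#'
#' @param world An `nf_world`.
#' @param ledger Optional prebuilt `nf_ledger`.
#' @param renormalize Min-max rescale the final scores?
#' @return Tibble, one row per nation.
#' @export
vulnerability_table <- function(world, ledger = NULL, renormalize = TRUE) {
  sub <- vulnerability_subvariables(world, ledger)
  base <- vulnerability_scores(sub, climate = FALSE,
                               renormalize = renormalize)
  clim <- vulnerability_scores(sub, climate = TRUE,
                               renormalize = renormalize)
  base$e_cc <- NULL
  base$e_climate <- clim$e_cc
  base$exposure_climate <- clim$exposure
  base$v_raw_climate <- clim$v_raw
  base$vulnerability_climate <- clim$vulnerability
  base
}

#' Spearman correlations between balances and socioeconomic indicators
#'
#' Rank correlation of each nutrient's foreign-fishing and trade balance
#' against national socioeconomic metrics, with pairwise-complete
#' deletion. Pairs with fewer than 3 complete observations are reported as
#' missing with a warning.
#'
#' @param balances A [balance_table()] result.
#' @param indicators Indicator table.
#' @param metrics Indicator columns to correlate against; defaults to GDP
#'   per capita, human development index and the coefficient of human
#'   inequality.
#' @return Tibble with `balance` (`ffb`/`tb`), `nutrient`, `indicator`,
#'   `rho`, `n`.
#' @export
balance_correlations <- function(balances, indicators,
                                 metrics = c("gdp_pc", "hdi",
                                             "inequality_coef")) {
  metrics <- intersect(metrics, names(indicators))
  if (length(metrics) == 0)
    stop("none of the requested indicator columns are present",
         call. = FALSE)
  nutrients <- setdiff(unique(balances$nutrient), "mean")
  out <- tidyr::expand_grid(balance = c("ffb", "tb"), nutrient = nutrients,
                            indicator = metrics)
  res <- lapply(seq_len(nrow(out)), function(i) {
    b <- balances[balances$nutrient == out$nutrient[i], ]
    x <- b[[out$balance[i]]]
    y <- indicators[[out$indicator[i]]][match(b$nation, indicators$nation)]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      warning(sprintf("fewer than 3 complete pairs for %s/%s vs %s",
                      out$balance[i], out$nutrient[i], out$indicator[i]),
              call. = FALSE)
      return(c(NA_real_, sum(ok)))
    }
    c(stats::cor(x[ok], y[ok], method = "spearman"), sum(ok))
  })
  out$rho <- vapply(res, `[`, numeric(1), 1)
  out$n <- as.integer(vapply(res, `[`, numeric(1), 2))
  out
}

#' Correlation screen among candidate indicator drivers
#'
#' Reports the Spearman correlations used to prune redundant drivers from
#' the framework: mean inadequate-intake prevalence (S_PIMII) against
#' dietary energy adequacy, and GDP per capita against the coefficient of
#' human inequality.
#'
#' @param indicators Indicator table with the intake columns plus
#'   `energy_adequacy`, `gdp_pc` and `inequality_coef`.
#' @return Tibble with `pair`, `rho`, `n`.
#' @export
indicator_screen <- function(indicators) {
  prev <- as.matrix(indicators[intake_cols()])
  s_pimii <- rowMeans(prev, na.rm = TRUE)
  s_pimii[is.nan(s_pimii)] <- NA_real_
  sp <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(c(NA_real_, sum(ok)))
    c(stats::cor(x[ok], y[ok], method = "spearman"), sum(ok))
  }
  a <- sp(s_pimii, indicators$energy_adequacy)
  b <- sp(indicators$gdp_pc, indicators$inequality_coef)
  tibble::tibble(pair = c("s_pimii_vs_energy_adequacy",
                          "gdp_pc_vs_inequality_coef"),
                 rho = c(a[1], b[1]), n = as.integer(c(a[2], b[2])))
}
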