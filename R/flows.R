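# Nutrient flows between categories of inadequate-intake prevalence, and
# per-category yield summaries.

#' Category labels for prevalence of inadequate intake
#'
#' @return Character vector of the category labels, in order: `V.Lo`, `Lo`,
#'   `Med`, `Hi`, `V.Hi`, `ND` (no data), plus the reserved pseudo-source
#'   labels `FOC` and `HS`.
#' @export
category_levels <- function() {
  c("V.Lo", "Lo", "Med", "Hi", "V.Hi", "ND", FOC_TOKEN, HS_TOKEN)
}

#' Categorize prevalence of inadequate intake
#'
#' Right-closed bins: `V.Lo` p <= 5; `Lo` 5 < p <= 10; `Med` 10 < p <= 25;
#' `Hi` 25 < p <= 50; `V.Hi` p > 50; missing prevalence maps to `ND`.
#'
#' @param p Prevalence in percent (0-100) or `NA`; vectorized.
#' @return Factor with levels [category_levels()].
#' @export
#' @examples
#' categorize_prevalence(c(5, 10, 25, 50, 51, NA))
categorize_prevalence <- function(p) {
  if (any(p < 0 | p > 100, na.rm = TRUE))
    stop("prevalence must be in [0, 100]", call. = FALSE)
  lab <- ifelse(is.na(p), "ND",
         ifelse(p <= 5, "V.Lo",
         ifelse(p <= 10, "Lo",
         ifelse(p <= 25, "Med",
         ifelse(p <= 50, "Hi", "V.Hi")))))
  factor(lab, levels = category_levels())
}

# per-nation category for one nutrient's intake prevalence
intake_categories <- function(indicators, nutrient) {
  col <- paste0("intake_", nutrient)
  if (!col %in% names(indicators))
    stop("no intake-prevalence column for nutrient: ", nutrient,
         call. = FALSE)
  tibble::tibble(nation = indicators$nation,
                 category = categorize_prevalence(indicators[[col]]))
}

#' Aggregate nutrient flows between inadequate-intake categories
#'
#' Routes every focal-year flow of one nutrient into a source-category by
#' sink-category matrix. For the foreign-fishing channel a flow runs from
#' the source EEZ nation's category (or `HS` for high-seas catch) to the
#' fleet nation's category (or `FOC` for flows into the
#' flag-of-convenience pool, present when the ledger was built with the
#' adjustment on). For the trade channel a flow runs from the exporter's
#' to the importer's category. With the fish-dependence filter on, only
#' flows whose real-nation endpoints all have strictly more than
#' `fish_dependence_filter` percent of animal protein from fish are kept
#' (the `HS`/`FOC` pseudo-endpoints always pass).
#'
#' @param ledger An `nf_ledger`.
#' @param indicators Indicator table with `nation`, `fish_protein_share`
#'   and the `intake_*` columns.
#' @param nutrient One of [flow_nutrients()].
#' @param channel `"foreign_fishing"` or `"trade"`.
#' @param fish_dependence_filter `NULL` (off) or a percent threshold
#'   (strict `>`).
#' @return An `nf_flow_matrix`: a square numeric matrix over
#'   [category_levels()] (nutrient mass per year), with attributes
#'   `nutrient`, `channel`, `filter`.
#' @export
aggregate_flows <- function(ledger, indicators, nutrient,
                            channel = c("foreign_fishing", "trade"),
                            fish_dependence_filter = NULL) {
  channel <- match.arg(channel)
  if (!nutrient %in% flow_nutrients())
    stop("flow matrices are produced for ",
         paste(flow_nutrients(), collapse = ", "), " only", call. = FALSE)
  cats <- intake_categories(indicators, nutrient)
  lev <- category_levels()
  mcol <- paste0("mass_", nutrient)

  pairs <- if (channel == "foreign_fishing") ledger$ff_pairs else
    ledger$trade_pairs
  m <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  if (!is.null(pairs) && nrow(pairs) > 0) {
    if (channel == "foreign_fishing") {
      src_nat <- pairs$source_zone
      snk_nat <- pairs$fleet
    } else {
      src_nat <- pairs$exporter
      snk_nat <- pairs$importer
    }
    nation_cat <- function(nat) {
      out <- as.character(cats$category[match(nat, cats$nation)])
      out[nat == HS_TOKEN] <- HS_TOKEN
      out[nat == FOC_TOKEN] <- FOC_TOKEN
      out
    }
    keep <- rep(TRUE, nrow(pairs))
    if (!is.null(fish_dependence_filter)) {
      share <- stats::setNames(indicators$fish_protein_share,
                               indicators$nation)
      passes <- function(nat) nat %in% c(HS_TOKEN, FOC_TOKEN) |
        (!is.na(share[nat]) & share[nat] > fish_dependence_filter)
      keep <- passes(src_nat) & passes(snk_nat)
    }
    src <- nation_cat(src_nat)[keep]
    snk <- nation_cat(snk_nat)[keep]
    mass <- pairs[[mcol]][keep]
    if (length(mass) > 0) {
      agg <- tapply(mass, list(factor(src, lev), factor(snk, lev)), sum)
      agg[is.na(agg)] <- 0
      m <- m + agg
    }
  }
  structure(m, class = c("nf_flow_matrix", class(m)), nutrient = nutrient,
            channel = channel,
            filter = fish_dependence_filter %||% NA_real_)
}

#' Median per-capita yield within each intake category
#'
#' For one nutrient, computes each nation's per-capita yield (percent of
#' RNI per capita per day) for the chosen role and returns the unweighted
#' median within each intake category. Roles: `source` — mass extracted
#' from the nation's EEZ by foreign fleets; `sink` — mass caught by the
#' nation's own foreign fleet including the high seas; `sink_eez_only` —
#' the same excluding high-seas catch; `exporter` / `importer` — traded
#' mass. Only nations participating in the role (positive mass) enter the
#' medians; empty categories are reported as missing, not zero.
#'
#' @param ledger An `nf_ledger`.
#' @param indicators Indicator table (needs `population` and intake
#'   columns).
#' @param nutrient One of [flow_nutrients()].
#' @param role One of `source`, `sink`, `sink_eez_only`, `exporter`,
#'   `importer`.
#' @return Tibble with `category`, `median_yield` (percent of RNI per
#'   capita per day; `NA` when the category is empty) and `n_nations`.
#' @export
yield_by_category <- function(ledger, indicators, nutrient,
                              role = c("source", "sink", "sink_eez_only",
                                       "exporter", "importer")) {
  role <- match.arg(role)
  mcol <- paste0("mass_", nutrient)
  ffp <- ledger$ff_pairs
  trp <- ledger$trade_pairs
  per_nation <- switch(role,
    source = if (!is.null(ffp))
      stats::aggregate(ffp[[mcol]],
                       list(nation = ffp$source_zone), sum),
    sink = if (!is.null(ffp)) {
      k <- ffp[ffp$fleet != FOC_TOKEN, ]
      stats::aggregate(k[[mcol]], list(nation = k$fleet), sum)
    },
    sink_eez_only = if (!is.null(ffp)) {
      k <- ffp[ffp$fleet != FOC_TOKEN & ffp$source_zone != HS_TOKEN, ]
      if (nrow(k) > 0)
        stats::aggregate(k[[mcol]], list(nation = k$fleet), sum)
    },
    exporter = if (!is.null(trp))
      stats::aggregate(trp[[mcol]], list(nation = trp$exporter), sum),
    importer = if (!is.null(trp))
      stats::aggregate(trp[[mcol]], list(nation = trp$importer), sum))
  cats <- intake_categories(indicators, nutrient)
  lev <- setdiff(category_levels(), c(FOC_TOKEN, HS_TOKEN))
  out <- tibble::tibble(category = factor(lev, category_levels()),
                        median_yield = NA_real_, n_nations = 0L)
  if (is.null(per_nation) || nrow(per_nation) == 0) return(out)
  names(per_nation)[2] <- "mass"
  per_nation <- per_nation[per_nation$nation != HS_TOKEN &
                             per_nation$mass > 0, ]
  if (nrow(per_nation) == 0) return(out)
  rni <- ledger$rni$rni_per_day[match(nutrient, ledger$rni$nutrient)]
  pop <- indicators$population[match(per_nation$nation, indicators$nation)]
  per_nation$yield <- per_capita_yield(per_nation$mass, pop, rni)
  per_nation$category <- cats$category[match(per_nation$nation, cats$nation)]
  med <- stats::aggregate(per_nation$yield,
                          list(category = as.character(per_nation$category)),
                          stats::median)
  idx <- match(as.character(out$category), med$category)
  out$median_yield <- med$x[idx]
  cnt <- table(as.character(per_nation$category))
  out$n_nations <- as.integer(ifelse(is.na(idx), 0,
                                     cnt[as.character(out$category)]))
  out$n_nations[is.na(out$n_nations)] <- 0L
  out
}

#' Presentation transform for yields
#'
#' `log10(y + 1)`; used only for display, never stored in ledgers.
#'
#' @param y Yield (>= 0), vectorized.
#' @return Transformed value.
#' @export
#' @examples
#' log_transform(c(0, 9, 99))
log_transform <- function(y) {
  if (any(y < 0, na.rm = TRUE)) stop("yield must be >= 0", call. = FALSE)
  log10(y + 1)
}

#' Tidy source/sink/mass table from a flow matrix
#'
#' @param flow_matrix An `nf_flow_matrix` from [aggregate_flows()].
#' @param drop_zero Drop zero cells? Default `TRUE`.
#' @return Tibble with `source_category`, `sink_category`, `mass`; the mass
#'   column sums to the matrix total.
#' @export
export_sankey_table <- function(flow_matrix, drop_zero = TRUE) {
  df <- as.data.frame(as.table(unclass(flow_matrix)),
                      stringsAsFactors = FALSE)
  names(df) <- c("source_category", "sink_category", "mass")
  if (drop_zero) df <- df[df$mass != 0, , drop = FALSE]
  tibble::as_tibble(df)
}
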