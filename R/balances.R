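# Foreign-fishing and trade balances per nation and nutrient, in
# RNI-equivalents, plus the quadrant classification used to summarise who
# gains and who loses.

#' Foreign-fishing balance (FFB)
#'
#' `FFB = FF - LossFF`: RNI-equivalents a nation's fleet catches in other
#' nations' EEZs (plus the high seas when `include_high_seas`) minus the
#' RNI-equivalents other fleets extract from the nation's own EEZ. Positive
#' values mean the nation gains more from fishing abroad than foreign
#' fleets take from its waters.
#'
#' @param ledger An `nf_ledger`.
#' @param nation Nation identifier.
#' @param nutrient Nutrient identifier.
#' @param include_high_seas Include high-seas catch in FF? Default `TRUE`.
#' @return RNI persons (scalar).
#' @export
foreign_fishing_balance <- function(ledger, nation, nutrient,
                                    include_high_seas = TRUE) {
  bt <- balance_table(ledger, include_high_seas = include_high_seas)
  row <- bt[bt$nation == nation & bt$nutrient == nutrient, ]
  if (nrow(row) == 0)
    stop("unknown nation or nutrient: ", nation, " / ", nutrient,
         call. = FALSE)
  row$ffb
}

#' Trade balance (TB)
#'
#' `TB = IMP - EXP` in RNI-equivalents; positive values mean the nation is
#' a net importer of the nutrient.
#'
#' @inheritParams foreign_fishing_balance
#' @return RNI persons (scalar).
#' @export
trade_balance <- function(ledger, nation, nutrient) {
  bt <- balance_table(ledger)
  row <- bt[bt$nation == nation & bt$nutrient == nutrient, ]
  if (nrow(row) == 0)
    stop("unknown nation or nutrient: ", nation, " / ", nutrient,
         call. = FALSE)
  row$tb
}

#' Per-nation balance table
#'
#' Computes FFB and TB for every nation and nutrient, plus `"mean"` rows
#' holding the unweighted arithmetic mean across the seven nutrients (the
#' across-nutrient averaging used for the gain/loss classification).
#'
#' @param ledger An `nf_ledger` (its `foc_mode` determines whether FFB is
#'   FOC-adjusted).
#' @param include_high_seas Include high-seas catch in FF? Default `TRUE`.
#' @return Tibble with `nation`, `nutrient` (or `"mean"`), `ffb`, `tb`,
#'   `include_high_seas`, `foc_adjusted`.
#' @export
balance_table <- function(ledger, include_high_seas = TRUE) {
  stopifnot(inherits(ledger, "nf_ledger"))
  t <- ledger$table[ledger$table$nation != FOC_TOKEN, ]
  wide <- tidyr::pivot_wider(t[c("nation", "nutrient", "channel", "rni_equiv")],
                             names_from = "channel",
                             values_from = "rni_equiv", values_fill = 0)
  ff <- wide$foreign_fished +
    if (include_high_seas) wide$high_seas_share else 0
  out <- tibble::tibble(nation = wide$nation, nutrient = wide$nutrient,
                        ffb = ff - wide$lost_to_foreign,
                        tb = wide$imported - wide$exported)
  means <- dplyr::summarise(dplyr::group_by(out, .data$nation),
                            ffb = mean(.data$ffb), tb = mean(.data$tb),
                            .groups = "drop")
  means$nutrient <- "mean"
  out <- dplyr::bind_rows(out, means[c("nation", "nutrient", "ffb", "tb")])
  out$include_high_seas <- include_high_seas
  out$foc_adjusted <- ledger$foc_mode == "on"
  dplyr::arrange(out, .data$nation, .data$nutrient)
}

#' Classify nations by the signs of their mean balances
#'
#' Quadrant from the signs of the across-nutrient mean foreign-fishing and
#' trade balances, and the net sign of their sum. Exact zeros classify as
#' gains (documented tie rule, overridable via `zero_as_gain`).
#'
#' @param ffb_mean,tb_mean Mean balances (vectorized).
#' @param zero_as_gain Treat a balance of exactly zero as a gain?
#' @return Tibble with `quadrant` in `gain_both`, `gain_ff_only`,
#'   `gain_trade_only`, `loss_both`, and `net` in `positive`, `negative`.
#' @export
#' @examples
#' classify_nation(c(3, -3), c(2, 2))
classify_nation <- function(ffb_mean, tb_mean, zero_as_gain = TRUE) {
  gain <- function(x) if (zero_as_gain) x >= 0 else x > 0
  gf <- gain(ffb_mean)
  gt <- gain(tb_mean)
  quadrant <- dplyr::case_when(gf & gt ~ "gain_both",
                               gf & !gt ~ "gain_ff_only",
                               !gf & gt ~ "gain_trade_only",
                               TRUE ~ "loss_both")
  net <- ifelse(gain(ffb_mean + tb_mean), "positive", "negative")
  tibble::tibble(quadrant = quadrant, net = net)
}
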