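# Assigning per-100 g nutrient concentrations to reported taxa.
#
# Species-rank rows carry their own modelled concentrations. Genus- and
# family-rank rows with missing values are imputed as unweighted arithmetic
# means over the species-rank members of the same genus/family. Taxa
# reported below family resolution ("coarse", e.g. "marine finfishes") are
# resolved through a four-tier ladder: own values if present, then a
# catch-composition-weighted local mean, then a composition-weighted global
# mean, then the unweighted global species mean.

# Resolve every taxon that can be resolved from the taxonomy alone.
# Returns taxon_id, method in {direct, genus_mean, family_mean, unresolved},
# and the seven concentration columns (NA when unresolved).
resolve_taxa <- function(taxa) {
  cc <- conc_cols()
  sp <- taxa[taxa$rank == "species", ]
  if (any(!stats::complete.cases(sp[cc])))
    stop("species-rank rows must carry all seven concentrations",
         call. = FALSE)

  genus_means <- dplyr::summarise(
    dplyr::group_by(sp, .data$genus),
    dplyr::across(dplyr::all_of(cc), mean), .groups = "drop")
  family_means <- dplyr::summarise(
    dplyr::group_by(sp, .data$family),
    dplyr::across(dplyr::all_of(cc), mean), .groups = "drop")

  out <- taxa[c("taxon_id", "rank", "genus", "family", cc)]
  own_complete <- stats::complete.cases(out[cc])
  method <- ifelse(own_complete, "direct", "unresolved")

  need <- which(!own_complete & out$rank == "genus")
  if (length(need) > 0) {
    gm <- genus_means[match(out$genus[need], genus_means$genus), cc]
    for (j in cc) {
      fill <- is.na(out[[j]][need]) & !is.na(gm[[j]])
      out[[j]][need[fill]] <- gm[[j]][fill]
    }
    done <- need[stats::complete.cases(out[need, cc])]
    method[done] <- "genus_mean"
  }
  need <- which(method == "unresolved" & out$rank == "family")
  if (length(need) > 0) {
    fm <- family_means[match(out$family[need], family_means$family), cc]
    for (j in cc) {
      fill <- is.na(out[[j]][need]) & !is.na(fm[[j]])
      out[[j]][need[fill]] <- fm[[j]][fill]
    }
    done <- need[stats::complete.cases(out[need, cc])]
    method[done] <- "family_mean"
  }
  method[method == "unresolved" & stats::complete.cases(out[cc])] <- "direct"
  out$method <- method
  # unresolved rows keep NA concentrations for the record-level ladder
  out[method == "unresolved", cc] <- NA_real_
  tibble::as_tibble(out[c("taxon_id", "method", cc)])
}

#' Assign nutrient concentrations to a taxon from the taxonomy
#'
#' Species-rank taxa return their own values; genus- and family-rank taxa
#' with missing values return the unweighted arithmetic mean over the
#' species-rank members of the same genus (or family). Taxa that cannot be
#' resolved this way (coarse groups, or genera/families without species
#' members) raise an error directing to [resolve_coarse()].
#'
#' @param taxon_id Taxon identifier present in `taxa`.
#' @param taxa A taxon table (see [generate_world()] for the schema).
#' @return Named numeric vector of the seven concentrations per 100 g.
#' @export
#' @examples
#' w <- generate_world(world_config(n_nations = 4, n_taxa = 12, seed = 1))
#' assign_concentration(w$taxa$taxon_id[1], w$taxa)
assign_concentration <- function(taxon_id, taxa) {
  if (!taxon_id %in% taxa$taxon_id)
    stop("unknown taxon: ", taxon_id, call. = FALSE)
  res <- resolve_taxa(taxa)
  row <- res[res$taxon_id == taxon_id, ]
  if (row$method == "unresolved")
    stop(sprintf(paste0("taxon %s cannot be resolved from the taxonomy; ",
                        "use resolve_coarse() with catch context"), taxon_id),
         call. = FALSE)
  v <- as.numeric(row[1, conc_cols()])
  names(v) <- nutrient_names()
  v
}

#' Resolve a coarsely reported taxon through the four-tier ladder
#'
#' For taxa reported below family resolution the concentration is taken
#' from the first available tier: (1) the taxon's own (or taxonomy-imputed)
#' values; (2) the catch-tonnage-weighted mean concentration over
#' resolvable taxa reported from the same zone (or by the same trading
#' nation, for trade records); (3) the tonnage-weighted mean over
#' resolvable taxa globally; (4) the unweighted mean over all species-rank
#' rows. The tier definitions are a package default reconstruction of
#' local-composition interpolation, not a literal published rule; the
#' ladder is exposed so it can be swapped.
#'
#' @param taxon_id Taxon identifier.
#' @param context_zone Source zone (EEZ nation or `"HS"`) of the record
#'   being valued; for trade records pass the trading nation and a `catch`
#'   frame of that nation's trade records.
#' @param catch Records with columns `taxon_id`, `tonnes` and `source_zone`
#'   supplying the local composition (usually the focal-year catch).
#' @param taxa Taxon table.
#' @return Named numeric vector of the seven concentrations, with an
#'   attribute `tier` in 1-4 recording the tier used.
#' @export
resolve_coarse <- function(taxon_id, context_zone, catch, taxa) {
  if (nrow(taxa) == 0) stop("empty taxon table", call. = FALSE)
  if (!taxon_id %in% taxa$taxon_id)
    stop("unknown taxon: ", taxon_id, call. = FALSE)
  cc <- conc_cols()
  res <- resolve_taxa(taxa)
  row <- res[res$taxon_id == taxon_id, ]
  if (row$method != "unresolved") {
    v <- as.numeric(row[1, cc])
    names(v) <- nutrient_names()
    attr(v, "tier") <- 1L
    return(v)
  }
  resolved <- res[res$method != "unresolved", c("taxon_id", cc)]
  wmean <- function(recs) {
    recs <- dplyr::inner_join(recs[c("taxon_id", "tonnes")], resolved,
                              by = "taxon_id")
    if (nrow(recs) == 0 || sum(recs$tonnes) <= 0) return(NULL)
    vapply(cc, function(j)
      sum(recs[[j]] * recs$tonnes) / sum(recs$tonnes), numeric(1))
  }
  v <- wmean(catch[catch$source_zone == context_zone, , drop = FALSE])
  tier <- 2L
  if (is.null(v)) {
    v <- wmean(catch)
    tier <- 3L
  }
  if (is.null(v)) {
    sp <- taxa[taxa$rank == "species", ]
    if (nrow(sp) == 0)
      stop("no species-rank rows available for the global fallback",
           call. = FALSE)
    v <- vapply(cc, function(j) mean(sp[[j]]), numeric(1))
    tier <- 4L
  }
  names(v) <- nutrient_names()
  attr(v, "tier") <- tier
  v
}

# Vectorized record-level assignment: adds the seven concentration columns
# and a source_tier column to a frame of records. `zone_col` names the
# column giving the local-composition context (source_zone for catch,
# exporter for trade).
assign_record_concentrations <- function(records, taxa, zone_col = "source_zone") {
  cc <- conc_cols()
  res <- resolve_taxa(taxa)
  unknown <- setdiff(unique(records$taxon_id), taxa$taxon_id)
  if (length(unknown) > 0)
    stop("records reference unknown taxa: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  out <- dplyr::left_join(records, res, by = "taxon_id")
  out$source_tier <- ifelse(out$method == "unresolved", NA_integer_, 1L)
  out$method <- NULL

  todo <- is.na(out$source_tier)
  if (any(todo)) {
    resolved_recs <- out[!todo, c(zone_col, "taxon_id", "tonnes", cc)]
    # tier 2: composition-weighted mean within the same zone
    zm <- dplyr::summarise(
      dplyr::group_by(resolved_recs,
                      dplyr::across(dplyr::all_of(zone_col))),
      dplyr::across(dplyr::all_of(cc),
                    ~ sum(.x * tonnes) / sum(tonnes)), .groups = "drop")
    idx <- match(out[[zone_col]][todo], zm[[zone_col]])
    hit <- !is.na(idx)
    for (j in cc) out[[j]][which(todo)[hit]] <- zm[[j]][idx[hit]]
    out$source_tier[which(todo)[hit]] <- 2L
    todo <- is.na(out$source_tier)
  }
  if (any(todo)) {
    resolved_recs <- out[out$source_tier == 1L & !is.na(out$source_tier),
                         c("tonnes", cc)]
    if (nrow(resolved_recs) > 0 && sum(resolved_recs$tonnes) > 0) {
      gm <- vapply(cc, function(j)
        sum(resolved_recs[[j]] * resolved_recs$tonnes) /
          sum(resolved_recs$tonnes), numeric(1))
      for (j in cc) out[[j]][todo] <- gm[[j]]
      out$source_tier[todo] <- 3L
      todo <- is.na(out$source_tier)
    }
  }
  if (any(todo)) {
    sp <- taxa[taxa$rank == "species", ]
    if (nrow(sp) == 0)
      stop("no species-rank rows available for the global fallback",
           call. = FALSE)
    for (j in cc) out[[j]][todo] <- mean(sp[[j]])
    out$source_tier[todo] <- 4L
  }
  out
}

#' Audit table of assigned concentrations
#'
#' Long-format audit of the concentrations actually used for a set of
#' records: one row per (taxon, zone context, nutrient) with the value and
#' the tier of the interpolation ladder it came from (tier 1 covers direct
#' and taxonomy-imputed values).
#'
#' @param records Output of the internal record-level assignment, i.e. any
#'   frame carrying `taxon_id`, the concentration columns and
#'   `source_tier` (as produced inside [build_ledger()], whose result
#'   stores them as the `audit_catch` and `audit_trade` elements).
#' @return Tibble with columns `taxon_id`, `nutrient`, `value`,
#'   `source_tier`.
#' @export
concentration_audit <- function(records) {
  keep <- unique(records[c("taxon_id", "source_tier", conc_cols())])
  long <- tidyr::pivot_longer(keep, dplyr::all_of(conc_cols()),
                              names_to = "nutrient", values_to = "value")
  long$nutrient <- sub("^conc_", "", long$nutrient)
  dplyr::arrange(long[c("taxon_id", "nutrient", "value", "source_tier")],
                 .data$taxon_id, .data$nutrient)
}
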