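# Canonical CSV schemas shared by the pipeline. All floats are written at
# 10 significant digits so that reruns of an identical configuration produce
# byte-identical outputs.

nf_schemas <- function() {
  list(catch = c("year", "fishing_nation", "source_zone", "taxon_id", "tonnes"),
       trade = c("year", "exporter", "importer", "taxon_id", "tonnes"),
       taxa = c("taxon_id", "rank", "species", "genus", "family", conc_cols()),
       foc = c("nation", "prop_foc_2013", "prop_foc_2018"),
       indicators = c("nation", "population", "fish_protein_share", "gdp_pc",
                      "stability", "health_exp", "net_food_importer",
                      "production_change", intake_cols()),
       rni = c("nutrient", "rni_per_day"))
}

#' Write a data frame as CSV with deterministic float formatting
#'
#' Numeric columns are rendered at 10 significant digits, so identical
#' inputs give byte-identical files across runs and platforms.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nf_write_csv <- function(df, path) {
  out <- as.data.frame(df)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.10g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a pipeline CSV and validate its schema
#'
#' @param path File path.
#' @param schema One of `"catch"`, `"trade"`, `"taxa"`, `"foc"`,
#'   `"indicators"`, `"rni"`, or `NULL` to skip validation.
#' @return A tibble.
#' @export
nf_read_csv <- function(path, schema = NULL) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          na.strings = ""))
  if (!is.null(schema)) {
    want <- nf_schemas()[[schema]]
    if (is.null(want)) stop("unknown schema: ", schema, call. = FALSE)
    miss <- setdiff(want, names(df))
    if (length(miss) > 0)
      stop(sprintf("file '%s' does not match the '%s' schema; missing: %s",
                   path, schema, paste(miss, collapse = ", ")), call. = FALSE)
  }
  # character columns read as logical NA when entirely empty
  for (ch in intersect(c("species", "genus", "family"), names(df)))
    df[[ch]] <- ifelse(is.na(df[[ch]]), "", as.character(df[[ch]]))
  df
}

#' Write a synthetic world to a directory of CSVs
#'
#' Emits `catch.csv`, `trade.csv`, `taxa.csv`, `foc.csv`, `indicators.csv`,
#' `rni.csv` and `config.yaml`, the canonical schemas consumed by every
#' other stage of the pipeline.
#'
#' @param world An `nf_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "nf_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nf_write_csv(world$catch, file.path(dir, "catch.csv"))
  nf_write_csv(world$trade, file.path(dir, "trade.csv"))
  nf_write_csv(world$taxa, file.path(dir, "taxa.csv"))
  nf_write_csv(world$foc, file.path(dir, "foc.csv"))
  nf_write_csv(world$indicators, file.path(dir, "indicators.csv"))
  nf_write_csv(world$rni, file.path(dir, "rni.csv"))
  yaml::write_yaml(unclass(world$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a world back from a directory of CSVs
#'
#' @param dir Directory produced by [write_world()] (or hand-built files in
#'   the same schemas).
#' @return An `nf_world`.
#' @export
read_world <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    do.call(world_config, raw)
  } else NULL
  catch <- nf_read_csv(file.path(dir, "catch.csv"), "catch")
  trade <- nf_read_csv(file.path(dir, "trade.csv"), "trade")
  ind <- nf_read_csv(file.path(dir, "indicators.csv"), "indicators")
  nations <- sort(unique(c(ind$nation, catch$fishing_nation,
                           trade$exporter, trade$importer)))
  nations <- setdiff(nations, HS_TOKEN)
  structure(list(nations = nations,
                 taxa = nf_read_csv(file.path(dir, "taxa.csv"), "taxa"),
                 catch = catch, trade = trade,
                 foc = nf_read_csv(file.path(dir, "foc.csv"), "foc"),
                 indicators = ind,
                 rni = nf_read_csv(file.path(dir, "rni.csv"), "rni"),
                 config = cfg),
            class = "nf_world")
}
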