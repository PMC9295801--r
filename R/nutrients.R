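#' Nutrients tracked by the package
#'
#' The seven nutrients for which fish are an important, bioavailable source
#' and which the pipeline accounts for: protein (g), calcium (mg), iron (mg),
#' zinc (mg), selenium (mcg), long-chain omega-3 fatty acids (g) and
#' vitamin A (mcg). Concentrations are always expressed per 100 g of raw
#' portion; nutrient masses inherit the concentration's native unit.
#'
#' @return Character vector of nutrient identifiers.
#' @export
#' @examples
#' nutrient_names()
nutrient_names <- function() {
  c("protein", "calcium", "iron", "zinc", "selenium", "omega3", "vitamin_a")
}

#' Units of the tracked nutrients
#'
#' @return Named character vector mapping nutrient identifier to the unit of
#'   its per-100 g concentration (and hence of its accounted mass).
#' @export
nutrient_units <- function() {
  c(protein = "g", calcium = "mg", iron = "mg", zinc = "mg",
    selenium = "mcg", omega3 = "g", vitamin_a = "mcg")
}

#' Micronutrients with national inadequate-intake prevalence data
#'
#' The 14 micronutrients whose prevalence of inadequate intake enters the
#' sensitivity index, and of which four (calcium, iron, zinc, vitamin A)
#' also drive the intake-category flow analysis.
#'
#' @return Character vector of 14 micronutrient identifiers.
#' @export
intake_nutrients <- function() {
  c("calcium", "copper", "iron", "folate", "magnesium", "niacin",
    "phosphorus", "riboflavin", "thiamin", "vitamin_a", "vitamin_b12",
    "vitamin_b6", "vitamin_c", "zinc")
}

#' Nutrients with both concentration estimates and intake-prevalence data
#'
#' Intersection of [nutrient_names()] and [intake_nutrients()]; the flow
#' matrices between intake categories are produced for these four only.
#'
#' @return Character vector: calcium, iron, zinc, vitamin_a.
#' @export
flow_nutrients <- function() {
  c("calcium", "iron", "zinc", "vitamin_a")
}

# column names used throughout
conc_cols <- function() paste0("conc_", nutrient_names())
intake_cols <- function() paste0("intake_", intake_nutrients())

# reserved zone token for the high seas and pseudo-nation for the
# flag-of-convenience pool
HS_TOKEN <- "HS"
FOC_TOKEN <- "FOC"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
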