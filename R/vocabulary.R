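#' The 14 basic food-sharing practices
#'
#' Returns the fixed vocabulary of basic sharing practices. A society's sharing
#' sequence is decomposed into these stand-alone distribution behaviours; only
#' presence/absence is retained by the rest of the pipeline, never the order of
#' appearance within the sequence. The row order of this table is the canonical
#' column order used by [encode_practices()] and every serialized matrix.
#'
#' @return A data.frame with columns `code` (two-letter symbol) and `label`.
#' @export
#' @examples
#' sharing_practices()
sharing_practices <- function() {
  data.frame(
    code = c("MM", "TT", "CC", "WD", "OD", "RM", "KS",
             "GS", "NS", "PR", "SD", "DS", "RA", "NN"),
    label = c(
      "Mutualism",
      "Tolerated Theft",
      "Communal Consumption",
      "Women as Distributors",
      "Other Distributors",
      "Ranked Mutualism",
      "Kin Selection",
      "Group Selection",
      "Network Selection",
      "Prestige",
      "Status Distribution",
      "Demand Sharing",
      "Reciprocal Altruism",
      "Necessity"
    ),
    stringsAsFactors = FALSE
  )
}

#' @rdname sharing_practices
#' @export
practice_codes <- function() sharing_practices()$code

#' The 21 socio-ecological variables
#'
#' The fixed roster of environmental and economic variables used throughout the
#' pipeline: climatic means/variances, Colwell's constancy and contingency
#' components of predictability for temperature, precipitation and net primary
#' production (NPP), topography, population size, and the relative percentage
#' of dependence on the five subsistence strategies. Constancy/contingency and
#' percentage variables are consumed as inputs; they are never derived here.
#'
#' @return A data.frame with columns `variable` (canonical snake_case name used
#'   in covariate tables and pairwise-difference columns), `label`, `unit` and
#'   `category` (`"environmental"` or `"economic"`).
#' @export
#' @examples
#' variable_roster()$variable
variable_roster <- function() {
  data.frame(
    variable = c(
      "temp_mean", "temp_variance", "temp_constancy", "temp_contingency",
      "precip_mean", "precip_variance", "precip_constancy", "precip_contingency",
      "dist_coast", "elevation", "slope",
      "npp_mean", "npp_variance", "npp_constancy", "npp_contingency",
      "population",
      "pct_hunting", "pct_gathering", "pct_husbandry", "pct_fishing",
      "pct_agriculture"
    ),
    label = c(
      "Annual mean temperature", "Annual temperature variance",
      "Temperature constancy", "Temperature contingency",
      "Annual mean precipitation", "Annual precipitation variance",
      "Precipitation constancy", "Precipitation contingency",
      "Distance to the coast", "Elevation", "Slope",
      "Monthly mean net primary production",
      "Annual net primary production variance",
      "Net primary production constancy", "Net primary production contingency",
      "Population size",
      "Dependence on hunting", "Dependence on gathering",
      "Dependence on animal husbandry", "Dependence on fishing",
      "Dependence on agriculture"
    ),
    unit = c(
      "degC", "degC^2", "index", "index",
      "mm", "mm^2", "index", "index",
      "km", "masl", "degrees",
      "gC/m^2/month", "(gC/m^2)^2", "index", "index",
      "persons",
      "%", "%", "%", "%", "%"
    ),
    category = c(rep("environmental", 11), rep("economic", 10)),
    stringsAsFactors = FALSE
  )
}

#' @rdname variable_roster
#' @export
roster_names <- function() variable_roster()$variable
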