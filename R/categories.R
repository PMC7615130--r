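#' Default household-variable category map
#'
#' Defines, for each census variable group, the recode from raw census
#' categories to analysis categories and the reference category whose
#' proportion is omitted from the predictor matrix (it is 1 minus the sum
#' of the others). The default follows UN-Habitat style improved/unimproved
#' aggregations: improved drinking water (indoor piped; sachet/bottled) vs
#' outdoor or public taps; flush vs public toilets; owner or rent-free
#' tenure vs renting/perching/squatting; durable vs less-durable walls;
#' metal-sheet roofs; finished floors; clean (gas/electric) vs solid
#' cooking fuel; rubbish collected vs dumped; and dwelling type. Every
#' entry is overridable: pass a modified copy to [aggregate_census()] or
#' [build_matrix()].
#'
#' @return named list; each element has `reference` (single analysis
#'   category) and `categories` (named character vector, raw -> analysis).
#' @export
default_category_map <- function() {
  list(
    water_source = list(
      reference = "outdoor_or_public_tap",
      categories = c(public_tap = "outdoor_or_public_tap",
                     outdoor_tap = "outdoor_or_public_tap",
                     well_or_other = "outdoor_or_public_tap",
                     indoor_piped = "indoor_piped",
                     sachet = "sachet_bottled",
                     bottled = "sachet_bottled")),
    toilet = list(
      reference = "public_toilet",
      categories = c(public_toilet = "public_toilet",
                     flush = "flush_toilet",
                     pit_latrine = "pit_latrine",
                     kvip = "pit_latrine")),
    tenure = list(
      reference = "rent_perch_squat",
      categories = c(renting = "rent_perch_squat",
                     perching = "rent_perch_squat",
                     squatting = "rent_perch_squat",
                     owner = "owned",
                     rent_free = "rent_free")),
    wall = list(
      reference = "durable_wall",
      categories = c(cement_block = "durable_wall",
                     brick = "durable_wall",
                     mud = "less_durable_wall",
                     wood = "less_durable_wall",
                     metal_sheet_wall = "less_durable_wall")),
    roof = list(
      reference = "other_roof",
      categories = c(concrete_roof = "other_roof",
                     tile = "other_roof",
                     thatch = "other_roof",
                     metal_sheet = "metal_sheet_roof")),
    floor = list(
      reference = "finished_floor",
      categories = c(cement_floor = "finished_floor",
                     tile_floor = "finished_floor",
                     earth_floor = "unfinished_floor",
                     wood_floor = "unfinished_floor")),
    fuel = list(
      reference = "solid_fuel",
      categories = c(wood_fuel = "solid_fuel",
                     charcoal = "solid_fuel",
                     gas = "clean_fuel",
                     electricity = "clean_fuel")),
    rubbish = list(
      reference = "collected",
      categories = c(collected = "collected",
                     public_dump = "public_dump",
                     burned = "other_disposal",
                     buried = "other_disposal",
                     dumped_elsewhere = "other_disposal")),
    dwelling = list(
      reference = "separate_house",
      categories = c(separate_house = "separate_house",
                     semi_detached = "separate_house",
                     compound_house = "compound_house",
                     kiosk = "improvised_dwelling",
                     container = "improvised_dwelling",
                     tent = "improvised_dwelling"))
  )
}

# analysis categories per group, reference first
analysis_categories <- function(cmap) {
  lapply(cmap, function(gr) {
    cats <- unique(unname(gr$categories))
    c(gr$reference, setdiff(cats, gr$reference))
  })
}

# the non-reference analysis category names, in stable group order
nonreference_categories <- function(cmap) {
  unlist(lapply(analysis_categories(cmap), function(x) x[-1]),
         use.names = FALSE)
}

validate_category_map <- function(cmap) {
  for (g in names(cmap)) {
    gr <- cmap[[g]]
    if (length(gr$reference) != 1)
      stop("category map: group '", g, "' must have exactly one reference")
    if (!(gr$reference %in% gr$categories))
      stop("category map: reference '", gr$reference,
           "' of group '", g, "' is not an analysis category")
  }
  invisible(cmap)
}

#' Names of the default 18 EA-level predictors
#'
#' Fourteen household-category proportions (one per non-reference analysis
#' category of [default_category_map()]) plus four continuous terms:
#' `crowding` (mean persons per bedroom), `pop_density` (persons/km^2),
#' `ndvi_mean` (unitless) and `elev_diff` (metres relative to the 5-km
#' surroundings).
#'
#' @return character vector of length 18
#' @export
default_predictors <- function() {
  c(nonreference_categories(default_category_map()),
    "crowding", "pop_density", "ndvi_mean", "elev_diff")
}
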