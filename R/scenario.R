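#' ScenarioConfig: full description of a synthetic study scenario
#'
#' A scenario fixes the grid, the county tessellation, the injected
#' vegetation dynamics (per-unit trends, interannual noise, an optional
#' step change), the driver-factor designs (each with a target Geodetector
#' q) and the land-use transition design. Together with its integer seed a
#' scenario fully determines every generated input: the same configuration
#' always yields bit-identical data.
#'
#' @slot gridRows,gridCols grid dimensions.
#' @slot cellArea cell area in km^2.
#' @slot years integer calendar years, strictly increasing.
#' @slot nUnits number of evaluation units (counties).
#' @slot seed integer master seed; generator sub-streams are derived from
#'   it with fixed offsets.
#' @slot baseNdvi,baseSD mean and between-pixel s.d. of the NDVI baseline.
#' @slot baseNpp,nppGain NPP baseline (gC m^-2 yr^-1) and the NPP change
#'   per unit NDVI change used to couple the two variables.
#' @slot trendMean per-unit mean NDVI slope (1/yr); length 1, length
#'   \code{nUnits}, or \code{NA} to draw unit slopes from
#'   \code{N(trendDrawMean, trendDrawSD)}.
#' @slot trendDrawMean,trendDrawSD distribution of unit mean slopes when
#'   \code{trendMean} is \code{NA}.
#' @slot trendSD pixel-level slope dispersion around the unit mean (1/yr).
#' @slot noiseSD interannual NDVI noise s.d. per pixel-year.
#' @slot breakYear calendar year of an abrupt step change (\code{NA} for
#'   none); \code{breakMagnitude} its size in NDVI units.
#' @slot factorSpecs data.frame with columns name, category, designedQ,
#'   nGroups describing the driver factors to design.
#' @slot luProportions named fractions of cropland/forest/grassland/unused
#'   in the first land-use epoch.
#' @slot transitionSpec data.frame with columns from, to, fraction: the
#'   per-unit fraction of cells converted between the two epochs. An
#'   optional unit_id column restricts a row to one unit (\code{NA} =
#'   every unit), allowing spatially varying engineering intensity.
#'
#' @aliases ScenarioConfig
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(gridRows = "integer", gridCols = "integer",
                 cellArea = "numeric", years = "integer",
                 nUnits = "integer", seed = "integer",
                 baseNdvi = "numeric", baseSD = "numeric",
                 baseNpp = "numeric", nppGain = "numeric",
                 trendMean = "numeric", trendDrawMean = "numeric",
                 trendDrawSD = "numeric", trendSD = "numeric",
                 noiseSD = "numeric", breakYear = "integer",
                 breakMagnitude = "numeric", factorSpecs = "data.frame",
                 luProportions = "numeric", transitionSpec = "data.frame"))

setValidity("ScenarioConfig", function(object) {
  if (object@gridRows < 1L || object@gridCols < 1L)
    return("grid dimensions must be positive")
  if (any(diff(object@years) <= 0))
    return("'years' must be strictly increasing")
  if (object@nUnits < 1L)
    return("'nUnits' must be at least 1")
  if (object@nUnits > object@gridRows * object@gridCols)
    return("more units than grid cells")
  if (!length(object@trendMean) %in% c(1L, object@nUnits))
    return("'trendMean' must have length 1 or nUnits")
  if (!is.na(object@breakYear) && !object@breakYear %in% object@years)
    return("'breakYear' must be one of 'years'")
  fs <- object@factorSpecs
  if (nrow(fs)) {
    if (!all(c("name", "category", "designedQ", "nGroups") %in% names(fs)))
      return("factorSpecs needs columns name, category, designedQ, nGroups")
    if (any(fs$designedQ < 0 | fs$designedQ >= 1))
      return("designedQ must lie in [0, 1)")
    if (any(fs$nGroups < 2))
      return("factor nGroups must be >= 2")
  }
  if (abs(sum(object@luProportions) - 1) > 1e-9)
    return("luProportions must sum to 1")
  ts <- object@transitionSpec
  if (nrow(ts)) {
    if (!all(c("from", "to", "fraction") %in% names(ts)))
      return("transitionSpec needs columns from, to, fraction")
    if (any(ts$fraction < 0))
      return("transition fractions must be non-negative")
    hasUnit <- "unit_id" %in% names(ts)
    glob <- if (hasUnit) ts[is.na(ts$unit_id), , drop = FALSE] else ts
    scopes <- list(glob)
    if (hasUnit)
      for (u in unique(ts$unit_id[!is.na(ts$unit_id)]))
        scopes[[length(scopes) + 1L]] <-
          rbind(glob, ts[!is.na(ts$unit_id) & ts$unit_id == u, ,
                         drop = FALSE])
    for (sc in scopes) {
      if (!nrow(sc)) next
      if (sum(sc$fraction) > 1 + 1e-9)
        return("transition fractions must sum to at most 1 per unit")
      bySource <- tapply(sc$fraction, sc$from, sum)
      avail <- object@luProportions[names(bySource)]
      if (any(is.na(avail)) || any(bySource > avail + 1e-9))
        return("transition fractions exceed the source-class share")
    }
  }
  TRUE
})

#' Land-use class codes
#'
#' Integer codes used in generated land-use epoch rasters: 1 = cropland,
#' 2 = forest, 3 = grassland, 4 = unused land.
#' @export
landuseClasses <- c(cropland = 1L, forest = 2L, grassland = 3L,
                    unused = 4L)

#' Default driver-factor design
#'
#' Fourteen driver factors spanning the five categories commonly used in
#' restoration attribution (climate, soil, geography, socioeconomic,
#' ecological engineering), each with a designed Geodetector q and its
#' conventional natural-breaks group count (climate / geography /
#' socioeconomic factors 7 groups; engineering factors 6; soil clay 7,
#' soil moisture 6, soil organic carbon 5). The designed q values follow
#' the importance ranking typical of semi-arid sandstorm-source
#' restoration zones, with annual precipitation dominant.
#'
#' @return data.frame with columns name, category, designedQ, nGroups.
#' @export
defaultFactorSpecs <- function() {
  data.frame(
    name = c("annual_precipitation", "annual_temperature",
             "soil_clay", "soil_moisture", "soil_organic_carbon",
             "altitude", "slope",
             "gdp", "population_density",
             "farmland_to_grassland", "unused_to_grassland",
             "maintain_forest", "maintain_grassland",
             "afforestation_intensity"),
    category = c("climate", "climate",
                 "soil", "soil", "soil",
                 "geography", "geography",
                 "socioeconomic", "socioeconomic",
                 rep("engineering", 5L)),
    designedQ = c(0.75, 0.42,
                  0.04, 0.03, 0.05,
                  0.20, 0.27,
                  0.61, 0.56,
                  0.57, 0.26, 0.19, 0.22, 0.57),
    nGroups = c(7L, 7L, 7L, 6L, 5L, 7L, 7L, 7L, 7L,
                6L, 6L, 6L, 6L, 6L),
    stringsAsFactors = FALSE)
}

#' Construct a synthetic-scenario configuration
#'
#' Defaults describe a Beijing-Tianjin sandstorm-source-like study: an
#' 81-county region observed 2000-2020 at a cell area of 150 km^2
#' (total area ~0.44 M km^2), generally greening vegetation (unit mean
#' NDVI slopes drawn from N(0.0035, 0.0025) per year) with moderate
#' interannual noise and an abrupt gain in 2011, and the
#' \code{\link{defaultFactorSpecs}} driver design.
#'
#' @param gridRows,gridCols grid dimensions.
#' @param cellArea cell area, km^2.
#' @param years calendar years.
#' @param nUnits number of counties.
#' @param seed integer master seed.
#' @param baseNdvi,baseSD NDVI baseline mean and between-pixel s.d.
#' @param baseNpp,nppGain NPP baseline and NPP-per-NDVI coupling.
#' @param trendMean per-unit mean slope(s), or \code{NA} to draw them.
#' @param trendDrawMean,trendDrawSD distribution of drawn unit slopes.
#' @param trendSD pixel slope dispersion within a unit.
#' @param noiseSD interannual noise s.d.
#' @param breakYear,breakMagnitude step-change year (or \code{NA}) and
#'   size in NDVI units.
#' @param factorSpecs driver-factor design table.
#' @param luProportions first-epoch land-use composition.
#' @param transitionSpec land-use transition design.
#' @return a validated \linkS4class{ScenarioConfig}.
#' @examples
#' cfg <- scenarioConfig(gridRows = 12, gridCols = 12, nUnits = 9,
#'                       years = 2000:2010, seed = 1)
#' @export
scenarioConfig <- function(gridRows = 54, gridCols = 54, cellArea = 150,
                           years = 2000:2020, nUnits = 81, seed = 1,
                           baseNdvi = 0.25, baseSD = 0.05,
                           baseNpp = 250, nppGain = 1000,
                           trendMean = NA_real_,
                           trendDrawMean = 0.0035, trendDrawSD = 0.0025,
                           trendSD = 0.001, noiseSD = 0.02,
                           breakYear = 2011, breakMagnitude = 0.03,
                           factorSpecs = defaultFactorSpecs(),
                           luProportions = c(cropland = 0.30,
                                             forest = 0.15,
                                             grassland = 0.40,
                                             unused = 0.15),
                           transitionSpec = data.frame(
                             from = c("cropland", "unused"),
                             to = c("grassland", "grassland"),
                             fraction = c(1 / 4, 1 / 9))) {
  if (missing(breakYear) && !is.na(breakYear) &&
      !breakYear %in% years)
    breakYear <- NA_integer_   # default break outside custom year range
  cfg <- tryCatch(new("ScenarioConfig",
    gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
    cellArea = as.numeric(cellArea), years = as.integer(years),
    nUnits = as.integer(nUnits), seed = as.integer(seed),
    baseNdvi = as.numeric(baseNdvi), baseSD = as.numeric(baseSD),
    baseNpp = as.numeric(baseNpp), nppGain = as.numeric(nppGain),
    trendMean = as.numeric(trendMean),
    trendDrawMean = as.numeric(trendDrawMean),
    trendDrawSD = as.numeric(trendDrawSD),
    trendSD = as.numeric(trendSD), noiseSD = as.numeric(noiseSD),
    breakYear = as.integer(breakYear),
    breakMagnitude = as.numeric(breakMagnitude),
    factorSpecs = factorSpecs,
    luProportions = luProportions, transitionSpec = transitionSpec),
    error = function(e) .vrStop(conditionMessage(e),
                                "VegRestore_invalidConfig"))
  cfg
}

# Fixed sub-stream offsets so every generated product draws from its own
# reproducible stream of the master seed.
.seedOffsets <- c(stacks = 1L, landuse = 2L, afforestation = 3L,
                  factors = 10L)

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv()))
    old <- get(".Random.seed", envir = globalenv())
  else old <- NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %d x %d grid (%g km^2 cells), %d units, years %d-%d, seed %d\n",
              object@gridRows, object@gridCols, object@cellArea,
              object@nUnits, min(object@years), max(object@years),
              object@seed))
  cat(sprintf("  trends: %s, pixel dispersion %g, noise sd %g\n",
              if (all(is.na(object@trendMean)))
                sprintf("unit slopes ~ N(%g, %g)", object@trendDrawMean,
                        object@trendDrawSD)
              else sprintf("fixed slope(s) mean %g",
                           mean(object@trendMean)),
              object@trendSD, object@noiseSD))
  if (!is.na(object@breakYear))
    cat(sprintf("  step change: %+g at %d\n", object@breakMagnitude,
                object@breakYear))
  cat(sprintf("  factors: %d designed; land-use transitions: %d\n",
              nrow(object@factorSpecs), nrow(object@transitionSpec)))
})
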