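#' @import methods
NULL

.vrStop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "VegRestore_error", "error", "condition")))
}

#' AnnualStack: a gridded variable observed yearly on a common grid
#'
#' Container for one variable (NDVI, NPP, FVC, VQQI, ...) on a fixed
#' rectangular grid across an ordered set of calendar years. No-data cells
#' are encoded as \code{NA} and must occupy the same positions in every
#' year (a single shared mask).
#'
#' @slot values numeric array \code{rows x cols x n_years}.
#' @slot years integer vector of strictly increasing calendar years.
#' @slot varname single character, the variable name.
#' @slot cellArea single positive numeric, cell area in km^2.
#'
#' @aliases AnnualStack
#' @exportClass AnnualStack
setClass("AnnualStack",
  representation(values = "array", years = "integer",
                 varname = "character", cellArea = "numeric"))

setValidity("AnnualStack", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("'values' must be a rows x cols x years array")
  if (dim(v)[3] != length(object@years))
    return("third array dimension must equal length(years)")
  if (length(object@years) && any(diff(object@years) <= 0))
    return("'years' must be strictly increasing")
  if (length(object@varname) != 1L)
    return("'varname' must be a single string")
  if (length(object@cellArea) != 1L || !is.finite(object@cellArea) ||
      object@cellArea <= 0)
    return("'cellArea' must be a single positive number")
  if (dim(v)[3] > 1L) {
    m0 <- is.na(v[, , 1L, drop = FALSE])[, , 1L]
    for (k in seq_len(dim(v)[3])[-1L])
      if (!identical(unname(is.na(v[, , k])), unname(m0)))
        return("no-data mask must be identical across years")
  }
  TRUE
})

#' Construct an AnnualStack
#'
#' @param values a \code{rows x cols x n_years} array, or a matrix for a
#'   single year. Cells that are \code{NA} in any year are masked (set to
#'   \code{NA}) in all years so the stack carries one shared mask.
#' @param years integer calendar years, strictly increasing.
#' @param varname variable name.
#' @param cellArea cell area in km^2.
#' @return an \linkS4class{AnnualStack}.
#' @examples
#' s <- annualStack(array(runif(4 * 4 * 3), c(4, 4, 3)), 2000:2002, "NDVI")
#' years(s)
#' @export
annualStack <- function(values, years, varname = "index", cellArea = 1) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  years <- as.integer(years)
  mask <- apply(is.na(values), c(1L, 2L), any)
  if (any(mask))
    values[array(mask, dim(values))] <- NA_real_
  new("AnnualStack", values = values, years = years,
      varname = as.character(varname), cellArea = as.numeric(cellArea))
}

#' UnitMap: tessellation of the grid into evaluation units
#'
#' Assigns every valid grid cell to exactly one evaluation unit (a
#' "county"). Units may carry an optional sub-region label.
#'
#' @slot ids integer matrix of unit ids, \code{NA} outside the study area.
#' @slot cellArea single positive numeric, cell area in km^2.
#' @slot subregion named character vector mapping unit id to sub-region
#'   label; may be empty.
#'
#' @aliases UnitMap
#' @exportClass UnitMap
setClass("UnitMap",
  representation(ids = "matrix", cellArea = "numeric",
                 subregion = "character"))

setValidity("UnitMap", function(object) {
  if (!is.numeric(object@ids)) return("'ids' must be an integer matrix")
  if (length(object@cellArea) != 1L || object@cellArea <= 0)
    return("'cellArea' must be a single positive number")
  ids <- object@ids[!is.na(object@ids)]
  if (!length(ids)) return("unit map has no valid cells")
  if (length(object@subregion) &&
      !all(names(object@subregion) %in% as.character(sort(unique(ids)))))
    return("subregion names must be unit ids")
  TRUE
})

#' AnnualSeries: a regional annual mean series with trend and change point
#'
#' @slot years integer calendar years.
#' @slot values numeric regional means, one per year.
#' @slot trendSlope least-squares slope of values on years.
#' @slot trendP two-sided p-value of the slope.
#' @slot changeYear detected change-point year (\code{NA} if none/untested).
#' @slot changeP approximate p-value of the change-point statistic.
#'
#' @aliases AnnualSeries
#' @exportClass AnnualSeries
setClass("AnnualSeries",
  representation(years = "integer", values = "numeric",
                 trendSlope = "numeric", trendP = "numeric",
                 changeYear = "integer", changeP = "numeric"),
  prototype(changeYear = NA_integer_, changeP = NA_real_))

setValidity("AnnualSeries", function(object) {
  if (length(object@values) != length(object@years))
    return("length(values) must equal length(years)")
  if (length(object@years) && any(diff(object@years) <= 0))
    return("'years' must be strictly increasing")
  TRUE
})

#' TrendGrades: per-pixel slope, significance and grade for one period
#'
#' Grades follow the five-level scheme: 1 = extremely significant
#' improvement (slope > 0, p < 0.01), 2 = significant improvement
#' (slope > 0, 0.01 <= p < 0.05), 3 = no significant change (p >= 0.05),
#' 4 = significant degradation (slope < 0, 0.01 <= p < 0.05),
#' 5 = extremely significant degradation (slope < 0, p < 0.01), with
#' weights 2, 1, 0, -1, -2 respectively.
#'
#' @slot period integer vector (start_year, end_year), inclusive.
#' @slot slope numeric matrix of per-pixel slopes (index units / yr).
#' @slot p numeric matrix of per-pixel F-test p-values.
#' @slot grade integer matrix of grades 1..5 (\code{NA} outside mask).
#' @slot weight numeric matrix of grade weights.
#'
#' @aliases TrendGrades
#' @exportClass TrendGrades
setClass("TrendGrades",
  representation(period = "integer", slope = "matrix", p = "matrix",
                 grade = "matrix", weight = "matrix"))

setValidity("TrendGrades", function(object) {
  if (length(object@period) != 2L || object@period[1] > object@period[2])
    return("'period' must be (start_year, end_year) with start <= end")
  d <- dim(object@slope)
  if (!identical(d, dim(object@p)) || !identical(d, dim(object@grade)) ||
      !identical(d, dim(object@weight)))
    return("slope, p, grade and weight must share one grid shape")
  g <- object@grade[!is.na(object@grade)]
  if (length(g) && (any(g < 1L) || any(g > 5L)))
    return("grades must lie in 1..5")
  TRUE
})

#' FactorPartition: a driver factor with its per-unit stratification
#'
#' @slot factorName factor name.
#' @slot category one of climate, soil, geography, socioeconomic,
#'   engineering.
#' @slot values named numeric vector of per-unit factor values
#'   (names = unit ids).
#' @slot stratum named integer vector of stratum labels 1..L.
#' @slot breaks ordered numeric break points between strata (may be empty
#'   when the partition was designed directly rather than cut from values).
#'
#' @aliases FactorPartition
#' @exportClass FactorPartition
setClass("FactorPartition",
  representation(factorName = "character", category = "character",
                 values = "numeric", stratum = "integer",
                 breaks = "numeric"))

.vrCategories <- c("climate", "soil", "geography", "socioeconomic",
                   "engineering", "other")

setValidity("FactorPartition", function(object) {
  if (!object@category %in% .vrCategories)
    return(paste("category must be one of:",
                 paste(.vrCategories, collapse = ", ")))
  if (length(object@values) != length(object@stratum))
    return("values and stratum must have equal length")
  if (!identical(names(object@values), names(object@stratum)))
    return("values and stratum must carry identical unit-id names")
  h <- object@stratum[!is.na(object@stratum)]
  if (length(h)) {
    L <- max(h)
    if (L < 2L) return("a partition needs at least 2 strata")
    if (!setequal(unique(h), seq_len(L)))
      return("stratum labels must be consecutive integers from 1")
  }
  if (length(object@breaks) > 1L && any(diff(object@breaks) <= 0))
    return("breaks must be strictly increasing")
  TRUE
})

#' FactorDetection: Geodetector factor-detector result
#'
#' Holds the q statistic \code{q = 1 - sum(N_h * sigma_h^2) / (N * sigma^2)}
#' of a stratified factor against a per-unit response, its significance,
#' and the per-stratum decomposition.
#'
#' @slot factorName factor name.
#' @slot q determination power, in [0, 1].
#' @slot p p-value from the noncentral-F transformation of q.
#' @slot strata data.frame with columns stratum, n, mean, var (population
#'   variance).
#' @slot N total number of units used.
#' @slot sigma2 total population variance of the response.
#'
#' @aliases FactorDetection
#' @exportClass FactorDetection
setClass("FactorDetection",
  representation(factorName = "character", q = "numeric", p = "numeric",
                 strata = "data.frame", N = "integer", sigma2 = "numeric"))

setValidity("FactorDetection", function(object) {
  if (object@q < -1e-9 || object@q > 1 + 1e-9)
    return("q must lie in [0, 1]")
  if (sum(object@strata$n) != object@N)
    return("stratum counts must sum to N")
  TRUE
})

#' InteractionDetection: Geodetector interaction-detector result
#'
#' @slot factors character vector of the two factor names.
#' @slot qA,qB single-factor q values.
#' @slot qAB q of the cross-classification of the two stratifications.
#' @slot type one of weaken-nonlinear, weaken-single, enhance-bivariate,
#'   enhance-nonlinear, independent.
#'
#' @aliases InteractionDetection
#' @exportClass InteractionDetection
setClass("InteractionDetection",
  representation(factors = "character", qA = "numeric", qB = "numeric",
                 qAB = "numeric", type = "character"))

#' RiskDetection: Geodetector risk-detector result
#'
#' @slot factorName factor name.
#' @slot strata data.frame with columns stratum, n, mean, valueMin,
#'   valueMax, tested (logical: large enough for pairwise t-tests).
#' @slot tMatrix symmetric matrix of Welch t-test p-values between strata
#'   (\code{NA} where a stratum was too small).
#' @slot argmaxStratum stratum attaining the maximal mean response.
#' @slot argmaxRange numeric (min, max) of the factor values in that
#'   stratum.
#'
#' @aliases RiskDetection
#' @exportClass RiskDetection
setClass("RiskDetection",
  representation(factorName = "character", strata = "data.frame",
                 tMatrix = "matrix", argmaxStratum = "integer",
                 argmaxRange = "numeric"))
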