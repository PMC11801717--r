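#' Accessors for VegRestore classes
#'
#' Small accessor generics: \code{years} (calendar years of a stack or
#' series), \code{gridValues} (the raw array / matrix), \code{varName},
#' \code{cellArea}, \code{unitIds}, \code{unitAreas} (km^2, from cell
#' counts), \code{subRegions}, \code{strata} (per-unit stratum labels),
#' \code{qValue} (Geodetector q), \code{pValue}.
#'
#' @param x an object of the documented classes.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("years", function(x) standardGeneric("years"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("varName", function(x) standardGeneric("varName"))
#' @rdname accessors
#' @export
setGeneric("cellArea", function(x) standardGeneric("cellArea"))
#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname accessors
#' @export
setGeneric("unitAreas", function(x) standardGeneric("unitAreas"))
#' @rdname accessors
#' @export
setGeneric("subRegions", function(x) standardGeneric("subRegions"))
#' @rdname accessors
#' @export
setGeneric("strata", function(x) standardGeneric("strata"))
#' @rdname accessors
#' @export
setGeneric("qValue", function(x) standardGeneric("qValue"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
setMethod("years", "AnnualStack", function(x) x@years)
#' @rdname accessors
setMethod("years", "AnnualSeries", function(x) x@years)
#' @rdname accessors
setMethod("gridValues", "AnnualStack", function(x) x@values)
#' @rdname accessors
setMethod("gridValues", "UnitMap", function(x) x@ids)
#' @rdname accessors
setMethod("varName", "AnnualStack", function(x) x@varname)
#' @rdname accessors
setMethod("cellArea", "AnnualStack", function(x) x@cellArea)
#' @rdname accessors
setMethod("cellArea", "UnitMap", function(x) x@cellArea)
#' @rdname accessors
setMethod("unitIds", "UnitMap", function(x)
  sort(unique(x@ids[!is.na(x@ids)])))
#' @rdname accessors
setMethod("unitAreas", "UnitMap", function(x) {
  tab <- table(x@ids[!is.na(x@ids)])
  a <- as.numeric(tab) * x@cellArea
  names(a) <- names(tab)
  a
})
#' @rdname accessors
setMethod("subRegions", "UnitMap", function(x) x@subregion)
#' @rdname accessors
setMethod("strata", "FactorPartition", function(x) x@stratum)
#' @rdname accessors
setMethod("qValue", "FactorDetection", function(x) x@q)
#' @rdname accessors
setMethod("qValue", "InteractionDetection", function(x) x@qAB)
#' @rdname accessors
setMethod("pValue", "FactorDetection", function(x) x@p)

#' Subset an AnnualStack by year
#'
#' @param x an AnnualStack.
#' @param i integer or logical index into \code{years(x)}, or a vector of
#'   calendar years.
#' @param j,...,drop ignored.
#' @return an AnnualStack restricted to the selected years.
#' @export
setMethod("[", "AnnualStack", function(x, i, j, ..., drop = FALSE) {
  if (!missing(j)) .vrStop("stacks are subset by year only",
                           "VegRestore_invalidSubset")
  if (is.numeric(i) && all(i %in% x@years)) i <- match(i, x@years)
  new("AnnualStack", values = x@values[, , i, drop = FALSE],
      years = x@years[i], varname = x@varname, cellArea = x@cellArea)
})

setMethod("show", "AnnualStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("AnnualStack '%s': %d x %d grid, %d year(s) (%s), %d masked cell(s)\n",
              object@varname, d[1], d[2], d[3],
              if (d[3]) paste(range(object@years), collapse = "-") else "",
              sum(is.na(object@values[, , 1]))))
})

setMethod("show", "UnitMap", function(object) {
  cat(sprintf("UnitMap: %d x %d grid, %d unit(s), cell area %g km^2\n",
              nrow(object@ids), ncol(object@ids),
              length(unitIds(object)), object@cellArea))
  if (length(object@subregion))
    cat("  sub-regions:", paste(unique(object@subregion), collapse = ", "),
        "\n")
})

setMethod("show", "AnnualSeries", function(object) {
  cat(sprintf("AnnualSeries %s-%s: mean %.3f, slope %.4f/yr (p = %.3g)\n",
              min(object@years), max(object@years), mean(object@values),
              object@trendSlope, object@trendP))
  if (!is.na(object@changeYear))
    cat(sprintf("  change point: %d (p = %.3g)\n",
                object@changeYear, object@changeP))
})

setMethod("show", "TrendGrades", function(object) {
  cat(sprintf("TrendGrades %d-%d\n", object@period[1], object@period[2]))
  print(table(grade = object@grade[!is.na(object@grade)]))
})

setMethod("show", "FactorPartition", function(object) {
  cat(sprintf("FactorPartition '%s' (%s): %d unit(s), %d strata\n",
              object@factorName, object@category, length(object@values),
              max(object@stratum, na.rm = TRUE)))
})

setMethod("show", "FactorDetection", function(object) {
  cat(sprintf("FactorDetection '%s': q = %.4f, p = %.3g (N = %d, L = %d)\n",
              object@factorName, object@q, object@p, object@N,
              nrow(object@strata)))
})

setMethod("show", "InteractionDetection", function(object) {
  cat(sprintf("Interaction %s ∩ %s: q = %.4f (single: %.4f, %.4f) -> %s\n",
              object@factors[1], object@factors[2], object@qAB,
              object@qA, object@qB, object@type))
})

setMethod("show", "RiskDetection", function(object) {
  cat(sprintf("RiskDetection '%s': max mean response in stratum %d (values %g..%g)\n",
              object@factorName, object@argmaxStratum,
              object@argmaxRange[1], object@argmaxRange[2]))
})
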