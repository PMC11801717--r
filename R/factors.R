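.luCode <- function(x) {
  if (is.character(x)) {
    if (!x %in% names(landuseClasses))
      .vrStop(sprintf("unknown land-use class '%s'", x),
              "VegRestore_invalidConfig")
    landuseClasses[[x]]
  } else as.integer(x)
}

.checkEpochs <- function(lu0, lu1, units) {
  if (!identical(dim(lu0), dim(lu1)) ||
      !identical(dim(lu0), dim(units@ids)))
    .vrStop("epoch rasters and unit map grids differ",
            "VegRestore_alignment")
}

.classIntensity <- function(lu0, lu1, fromCode, toCode, units,
                            denominator) {
  ids <- units@ids
  ok <- !is.na(ids) & !is.na(lu0) & !is.na(lu1)
  uid <- unitIds(units)
  hit <- ok & lu0 == fromCode & lu1 == toCode
  nHit <- table(factor(ids[hit], levels = uid))
  base <- if (denominator == "unit") ok else ok & lu0 == fromCode
  nBase <- table(factor(ids[base], levels = uid))
  out <- 100 * as.numeric(nHit) / as.numeric(nBase)
  out[as.numeric(nBase) == 0] <- NA_real_
  names(out) <- uid
  out
}

#' Land-use transition intensity per unit
#'
#' Percentage of a unit's cells converted from one class to another
#' between two land-use epochs, e.g. cropland returned to grassland.
#' The denominator is the unit's total cell count by default
#' (\code{denominator = "unit"}), making intensities bounded and
#' comparable across units; \code{"prior"} divides by the first-epoch
#' extent of the source class instead.
#'
#' @param lu0,lu1 integer class-code matrices for the two epochs.
#' @param from,to class codes or names (see
#'   \code{\link{landuseClasses}}).
#' @param units a \linkS4class{UnitMap} on the same grid.
#' @param denominator \code{"unit"} (default) or \code{"prior"}.
#' @return named numeric vector of percentages per unit.
#' @export
transitionIntensity <- function(lu0, lu1, from, to, units,
                                denominator = c("unit", "prior")) {
  denominator <- match.arg(denominator)
  .checkEpochs(lu0, lu1, units)
  .classIntensity(lu0, lu1, .luCode(from), .luCode(to), units,
                  denominator)
}

#' Land-use maintenance intensity per unit
#'
#' Percentage of a unit's cells that kept a class (e.g. forest that
#' remained forest) between the two epochs.
#'
#' @param lu0,lu1 integer class-code matrices for the two epochs.
#' @param klass class code or name that must persist.
#' @param units a \linkS4class{UnitMap}.
#' @param denominator \code{"unit"} (default) or \code{"prior"}.
#' @return named numeric vector of percentages per unit.
#' @export
maintenanceIntensity <- function(lu0, lu1, klass, units,
                                 denominator = c("unit", "prior")) {
  denominator <- match.arg(denominator)
  .checkEpochs(lu0, lu1, units)
  code <- .luCode(klass)
  .classIntensity(lu0, lu1, code, code, units, denominator)
}

#' Accumulated afforestation intensity per unit
#'
#' Sums each unit's afforested area over all recorded years and divides
#' by the unit area, on a percentage scale -- the county-area
#' normalization that puts engineering statistics on a per-unit-area
#' basis. Duplicate (unit, year) rows are summed with a warning; rows
#' whose unit id is not in the unit map raise a join error naming the
#' offenders. Units without records get 0.
#'
#' @param table data.frame with columns unit_id, year,
#'   afforested_area_km2.
#' @param units a \linkS4class{UnitMap}.
#' @return named numeric vector of percentages per unit.
#' @export
afforestationIntensity <- function(table, units) {
  need <- c("unit_id", "year", "afforested_area_km2")
  if (!all(need %in% names(table)))
    .vrStop(paste("afforestation table needs columns:",
                  paste(need, collapse = ", ")), "VegRestore_validation")
  if (any(table$afforested_area_km2 < 0))
    .vrStop("afforested areas must be non-negative",
            "VegRestore_validation")
  areas <- unitAreas(units)
  unknown <- setdiff(unique(table$unit_id),
                     as.integer(names(areas)))
  if (length(unknown))
    .vrStop(sprintf("afforestation rows reference unknown unit id(s): %s",
                    paste(unknown, collapse = ", ")), "VegRestore_join")
  if (anyDuplicated(table[, c("unit_id", "year")]))
    warning("duplicate (unit, year) afforestation rows summed")
  acc <- tapply(table$afforested_area_km2, table$unit_id, sum)
  out <- rep(0, length(areas))
  names(out) <- names(areas)
  out[names(acc)] <- as.numeric(acc)
  100 * out / areas
}

#' Zonal aggregation of a raster over units
#'
#' @param raster numeric matrix (or single-year
#'   \linkS4class{AnnualStack}).
#' @param units a \linkS4class{UnitMap} on the same grid.
#' @param statistic \code{"mean"} or \code{"sum"} over a unit's valid
#'   cells. Units without valid cells are excluded with a warning.
#' @return named numeric vector per unit.
#' @export
zonalAggregate <- function(raster, units, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (is(raster, "AnnualStack")) {
    if (length(raster@years) != 1L)
      .vrStop("zonal aggregation takes a single layer",
              "VegRestore_invalidConfig")
    raster <- raster@values[, , 1L]
  }
  if (!identical(dim(raster), dim(units@ids)))
    .vrStop("raster and unit map grids differ", "VegRestore_alignment")
  ok <- !is.na(units@ids) & !is.na(raster)
  empty <- setdiff(unitIds(units), unique(units@ids[ok]))
  if (length(empty))
    warning(sprintf("unit(s) without valid cells excluded: %s",
                    paste(empty, collapse = ", ")))
  fn <- if (statistic == "mean") mean else sum
  res <- tapply(raster[ok], units@ids[ok], fn)
  out <- as.numeric(res)
  names(out) <- names(res)
  out
}

# Exact Fisher optimal 1-D partition: dynamic program over distinct
# sorted values (weighted by multiplicity, so tied values always share a
# class). D[j, k] = min over i of D[i-1, k-1] + W(i, j), where W is the
# within-class weighted sum of squared deviations from the class mean.
.fisherDP <- function(xs, w, L) {
  m <- length(xs)
  cw <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * xs))
  cwx2 <- c(0, cumsum(w * xs^2))
  W <- function(i, j) { # class covering distinct values i..j
    n <- cw[j + 1] - cw[i]
    s <- cwx[j + 1] - cwx[i]
    (cwx2[j + 1] - cwx2[i]) - s^2 / n
  }
  D <- matrix(Inf, m, L)
  B <- matrix(0L, m, L)
  for (j in 1:m) { D[j, 1] <- W(1, j); B[j, 1] <- 1L }
  if (L > 1) for (k in 2:L) for (j in k:m) {
    for (i in k:j) {
      v <- D[i - 1, k - 1] + W(i, j)
      if (v < D[j, k]) { D[j, k] <- v; B[j, k] <- i }
    }
  }
  # recover class starts
  starts <- integer(L)
  j <- m
  for (k in L:1) { starts[k] <- B[j, k]; j <- B[j, k] - 1L }
  list(ssd = D[m, L], starts = starts)
}

#' Natural-breaks (Jenks) discretization of per-unit values
#'
#' Partitions sorted values into L contiguous classes minimizing the
#' total within-class sum of squared deviations, by the exact
#' Fisher dynamic program (a guaranteed optimum, unlike the common
#' iterative heuristic). Tied values always share a class; class labels
#' run 1..L in increasing value order. Breaks are reported as the upper
#' value of each class but the last.
#'
#' @param values named numeric per-unit values.
#' @param L number of classes; the number of distinct values must be at
#'   least L.
#' @param factorName,category metadata stored in the result.
#' @return a \linkS4class{FactorPartition}.
#' @examples
#' strata(jenksBreaks(c(a = 1, b = 2, c = 10, d = 11), 2))
#' @export
jenksBreaks <- function(values, L, factorName = "factor",
                        category = "other") {
  x <- values[!is.na(values)]
  xs <- sort(unique(x))
  if (length(xs) < L)
    .vrStop(sprintf("%d classes requested but only %d distinct values",
                    L, length(xs)), "VegRestore_infeasibleGrouping")
  if (L < 2L)
    .vrStop("need at least 2 classes", "VegRestore_infeasibleGrouping")
  w <- as.numeric(table(factor(x, levels = xs)))
  fit <- .fisherDP(xs, w, L)
  classOfDistinct <- integer(length(xs))
  bounds <- c(fit$starts, length(xs) + 1L)
  for (k in seq_len(L))
    classOfDistinct[bounds[k]:(bounds[k + 1L] - 1L)] <- k
  h <- rep(NA_integer_, length(values))
  h[!is.na(values)] <- classOfDistinct[match(x, xs)]
  names(h) <- names(values)
  brk <- xs[bounds[2:L] - 1L]
  vv <- as.numeric(values)
  names(vv) <- names(values)
  new("FactorPartition", factorName = factorName, category = category,
      values = vv, stratum = h, breaks = as.numeric(brk))
}
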