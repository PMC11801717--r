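#' Largest-remainder apportionment of integer counts
#'
#' Splits \code{n} items into groups proportional to \code{fractions}
#' (which may sum to less than 1; the remainder is unallocated). Integer
#' parts are assigned first, then the remaining items go to the largest
#' fractional remainders, ties resolved by group order.
#'
#' @param n total item count.
#' @param fractions non-negative fractions, sum <= 1 + 1e-9.
#' @return integer counts, one per fraction, summing to
#'   \code{round(sum(fractions) * n)} at most \code{n}.
#' @keywords internal
.largestRemainder <- function(n, fractions) {
  target <- fractions * n
  base <- floor(target + 1e-9)
  left <- round(sum(target)) - sum(base)
  counts <- base
  if (left > 0) {
    rem <- target - base
    give <- order(rem, decreasing = TRUE)[seq_len(left)]
    counts[give] <- counts[give] + 1L
  }
  as.integer(counts)
}

#' Partition the grid into rectangular evaluation units
#'
#' Tiles the grid with \code{nUnits} contiguous rectangular blocks by
#' factoring the unit count into a rows-of-blocks x cols-of-blocks layout
#' that fits the grid, splitting rows and columns into bands of near-equal
#' width. Every cell belongs to exactly one unit; unit areas are cell
#' count times cell area. When four or more units are laid out, each unit
#' is labeled with the sub-region (quadrant) it falls in: NA (north),
#' OS (west), FZ (east), YM (south).
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @return a \linkS4class{UnitMap}.
#' @examples
#' u <- makeUnits(scenarioConfig(gridRows = 4, gridCols = 4, nUnits = 4,
#'                               seed = 1))
#' table(gridValues(u))
#' @export
makeUnits <- function(config) {
  nr <- config@gridRows; nc <- config@gridCols; n <- config@nUnits
  if (n > nr * nc)
    .vrStop("more units than grid cells", "VegRestore_invalidConfig")
  # factor pair (rows of blocks, cols of blocks) closest to square that fits
  divs <- which(n %% seq_len(n) == 0L)
  fit <- divs[divs <= nr & (n %/% divs) <= nc]
  if (!length(fit))
    .vrStop("unit count cannot tile the grid with rectangular blocks",
            "VegRestore_invalidConfig")
  br <- fit[which.min(abs(fit - sqrt(n)))]
  bc <- n %/% br
  rowBand <- rep(seq_len(br), .largestRemainder(nr, rep(1 / br, br)))
  colBand <- rep(seq_len(bc), .largestRemainder(nc, rep(1 / bc, bc)))
  ids <- outer(rowBand, colBand, function(r, cc) (r - 1L) * bc + cc)
  storage.mode(ids) <- "integer"
  sub <- character(0)
  if (n >= 4L) {
    ctrR <- tapply(row(ids), ids, mean) / nr
    ctrC <- tapply(col(ids), ids, mean) / nc
    lab <- ifelse(ctrR <= 0.5 & ctrC <= 0.5, "NA",
           ifelse(ctrR <= 0.5, "OS",
           ifelse(ctrC <= 0.5, "FZ", "YM")))
    sub <- as.character(lab)
    names(sub) <- names(ctrR)
  }
  new("UnitMap", ids = ids, cellArea = config@cellArea, subregion = sub)
}

.unitSlopes <- function(config) {
  n <- config@nUnits
  if (all(is.na(config@trendMean)))
    .withSeed(config@seed, # drawn before any pixel-level stream
              stats::rnorm(n, config@trendDrawMean, config@trendDrawSD))
  else rep_len(config@trendMean, n)
}

#' Simulate coupled annual NDVI and NPP stacks
#'
#' Each pixel follows \code{base + slope * (year - years[1]) +
#' step * 1[year >= breakYear] + N(0, noiseSD)}. Pixel slopes scatter
#' around their unit's mean slope with s.d. \code{trendSD}; pixel
#' baselines scatter around \code{baseNdvi} with s.d. \code{baseSD}. NPP
#' shares the pixel's trend and step scaled by \code{nppGain}
#' (gC m^-2 yr^-1 per NDVI unit) with independent noise. NDVI is clipped
#' to [-1, 1] and NPP floored at 0. Identical configurations give
#' bit-identical stacks.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param units optional precomputed \linkS4class{UnitMap} (defaults to
#'   \code{makeUnits(config)}).
#' @return list with elements \code{ndvi} and \code{npp}
#'   (\linkS4class{AnnualStack}), \code{unitSlopes} (the per-unit mean
#'   NDVI slopes actually used) and \code{units}.
#' @export
simulateStacks <- function(config, units = makeUnits(config)) {
  nr <- config@gridRows; nc <- config@gridCols
  yrs <- config@years; ny <- length(yrs)
  slopes <- .unitSlopes(config)
  ids <- units@ids
  .withSeed(config@seed + .seedOffsets[["stacks"]], {
    pixSlope <- slopes[ids] + stats::rnorm(nr * nc, 0, config@trendSD)
    pixBase <- config@baseNdvi + stats::rnorm(nr * nc, 0, config@baseSD)
    pixBaseNpp <- config@baseNpp +
      config@nppGain * stats::rnorm(nr * nc, 0, config@baseSD)
    t <- yrs - yrs[1]
    step <- if (is.na(config@breakYear)) rep(0, ny)
            else config@breakMagnitude * as.numeric(yrs >= config@breakYear)
    signal <- outer(pixSlope, t) + rep(step, each = nr * nc)
    ndvi <- pixBase + signal +
      stats::rnorm(nr * nc * ny, 0, config@noiseSD)
    npp <- pixBaseNpp + config@nppGain *
      (signal + stats::rnorm(nr * nc * ny, 0, config@noiseSD))
  })
  ndvi <- pmin(pmax(ndvi, -1), 1)
  npp <- pmax(npp, 0)
  dim(ndvi) <- dim(npp) <- c(nr, nc, ny)
  list(ndvi = annualStack(ndvi, yrs, "NDVI", config@cellArea),
       npp = annualStack(npp, yrs, "NPP", config@cellArea),
       unitSlopes = slopes, units = units)
}

#' Simulate two land-use epochs with exact transition bookkeeping
#'
#' Builds a first-epoch raster whose composition per unit follows
#' \code{luProportions} (largest-remainder cell counts, contiguous runs in
#' raster order), then applies the designed transitions: within each unit,
#' for each (from, to, fraction) row, exactly
#' \code{largestRemainder(fraction * n_cells)} cells of the source class
#' are relabeled in the second epoch. Cells not targeted by a transition
#' keep their class, so maintenance intensities follow by subtraction.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param units optional precomputed \linkS4class{UnitMap}.
#' @return list with integer matrices \code{t0} and \code{t1} (class
#'   codes per \code{\link{landuseClasses}}) and a data.frame
#'   \code{realized} (unit_id, from, to, cells, fraction) recording every
#'   realized conversion.
#' @export
simulateLanduse <- function(config, units = makeUnits(config)) {
  ts <- config@transitionSpec
  ids <- units@ids
  t0 <- matrix(NA_integer_, nrow(ids), ncol(ids))
  t1 <- t0
  realized <- list()
  classes <- landuseClasses
  props <- config@luProportions[names(classes)]
  props[is.na(props)] <- 0
  for (u in unitIds(units)) {
    cells <- which(ids == u)           # raster (column-major) order
    ncell <- length(cells)
    counts <- .largestRemainder(ncell, props)
    # leftover cells (fractions summing < 1) padded into the last class
    counts[length(counts)] <- counts[length(counts)] +
      (ncell - sum(counts))
    lab0 <- rep(classes, counts)
    t0[cells] <- lab0
    lab1 <- lab0
    tsU <- ts
    if (nrow(ts) && "unit_id" %in% names(ts))
      tsU <- ts[is.na(ts$unit_id) | ts$unit_id == u, , drop = FALSE]
    if (nrow(tsU)) {
      if (sum(tsU$fraction) > 1 + 1e-9)
        .vrStop(sprintf("unit %d: transition fractions sum to more than 1",
                        u), "VegRestore_invalidConfig")
      nConv <- .largestRemainder(ncell, tsU$fraction)
      for (k in seq_len(nrow(tsU))) {
        fromCode <- classes[[tsU$from[k]]]
        toCode <- classes[[tsU$to[k]]]
        pool <- which(lab0 == fromCode & lab1 == lab0)
        if (length(pool) < nConv[k])
          .vrStop(sprintf(
            "unit %d: %d '%s' cells available but %d conversions designed",
            u, length(pool), tsU$from[k], nConv[k]),
            "VegRestore_invalidConfig")
        take <- pool[seq_len(nConv[k])]
        lab1[take] <- toCode
        realized[[length(realized) + 1L]] <- data.frame(
          unit_id = u, from = tsU$from[k], to = tsU$to[k],
          cells = nConv[k], fraction = nConv[k] / ncell)
      }
    }
    t1[cells] <- lab1
  }
  realized <- if (length(realized)) do.call(rbind, realized)
              else data.frame(unit_id = integer(0), from = character(0),
                              to = character(0), cells = integer(0),
                              fraction = numeric(0))
  list(t0 = t0, t1 = t1, realized = realized)
}

#' Simulate a per-county afforestation record
#'
#' Draws yearly afforested areas per unit, uniform between 0 and
#' \code{maxRate} times the unit area, from the scenario's afforestation
#' sub-stream. Years default to the scenario years from the third onward,
#' mirroring engineering statistics that typically start two years into a
#' program.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param units optional precomputed \linkS4class{UnitMap}.
#' @param maxRate maximal yearly afforested fraction of a unit's area.
#' @return data.frame (unit_id, year, afforested_area_km2).
#' @export
simulateAfforestation <- function(config, units = makeUnits(config),
                                  maxRate = 0.02) {
  yrs <- config@years
  yrs <- yrs[-seq_len(min(2L, length(yrs) - 1L))]
  areas <- unitAreas(units)
  uid <- as.integer(names(areas))
  .withSeed(config@seed + .seedOffsets[["afforestation"]], {
    g <- expand.grid(unit_id = uid, year = yrs)
    g$afforested_area_km2 <- stats::runif(nrow(g), 0, maxRate) *
      areas[as.character(g$unit_id)]
  })
  g[order(g$unit_id, g$year), , drop = FALSE]
}
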