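#' Per-unit area fractions of the five trend grades
#'
#' For each evaluation unit, the fraction of its valid cells in each
#' grade: \code{A_k = cells of grade k / valid cells}. Units without any
#' valid cell are excluded with a warning.
#'
#' @param grades a \linkS4class{TrendGrades}.
#' @param units a \linkS4class{UnitMap} on the same grid.
#' @return data.frame (unit_id, A1..A5, nCells); the A columns sum to 1
#'   per row.
#' @export
gradeFractions <- function(grades, units) {
  if (!identical(dim(grades@grade), dim(units@ids)))
    .vrStop("grade raster and unit map grids differ",
            "VegRestore_alignment")
  ids <- units@ids
  ok <- !is.na(ids) & !is.na(grades@grade)
  empty <- setdiff(unitIds(units), unique(ids[ok]))
  if (length(empty))
    warning(sprintf("unit(s) without valid cells excluded: %s",
                    paste(empty, collapse = ", ")))
  g <- factor(grades@grade[ok], levels = 1:5)
  u <- factor(ids[ok])
  counts <- table(u, g)
  n <- rowSums(counts)
  A <- counts / n
  out <- data.frame(unit_id = as.integer(rownames(counts)),
                    A1 = A[, 1], A2 = A[, 2], A3 = A[, 3],
                    A4 = A[, 4], A5 = A[, 5],
                    nCells = as.integer(n), row.names = NULL)
  out
}

.checkFractions <- function(A) {
  A <- as.matrix(A)
  if (ncol(A) != 5L)
    .vrStop("grade fractions need 5 columns", "VegRestore_validation")
  if (any(A < -1e-9) || any(abs(rowSums(A) - 1) > 1e-9))
    .vrStop("grade fractions must be non-negative and sum to 1 per unit",
            "VegRestore_validation")
  A
}

#' Net change in vegetation restoration
#'
#' Area-fraction-weighted sum of the grade weights within each unit:
#' \code{N_t = sum_k(omega_k * A_k)}, bounded in [-2, 2].
#'
#' @param A matrix or data.frame of grade fractions (columns A1..A5, one
#'   row per unit; a \code{unit_id} column is carried through if
#'   present).
#' @param weights the five grade weights, default \code{c(2, 1, 0, -1,
#'   -2)}.
#' @return named numeric vector of per-unit net change.
#' @export
netChange <- function(A, weights = gradeWeights) {
  if (length(weights) != 5L)
    .vrStop("five grade weights required", "VegRestore_validation")
  uid <- NULL
  if (is.data.frame(A) && "unit_id" %in% names(A)) {
    uid <- A$unit_id
    A <- A[, c("A1", "A2", "A3", "A4", "A5"), drop = FALSE]
  }
  A <- .checkFractions(A)
  nt <- as.numeric(A %*% weights)
  if (!is.null(uid)) names(nt) <- uid
  nt
}

#' Baseline net change
#'
#' The cross-unit arithmetic mean of the first-period net change, used as
#' the reference every later period is measured against. The baseline
#' must be positive: a near-zero mean makes the effectiveness ratio
#' unusable and a negative one would silently invert its meaning, so both
#' are refused.
#'
#' @param nt0 per-unit net change for the baseline period.
#' @return the scalar baseline.
#' @export
baselineNetChange <- function(nt0) {
  if (!length(nt0)) .vrStop("no units", "VegRestore_unusableBaseline")
  n0 <- mean(nt0)
  if (abs(n0) < 1e-6)
    .vrStop("baseline net change is (near) zero: effectiveness undefined",
            "VegRestore_unusableBaseline")
  if (n0 < 0)
    .vrStop("baseline net change is negative: refusing to invert the effectiveness scale",
            "VegRestore_signInversion")
  n0
}

#' Effectiveness score and class
#'
#' \code{E_t = N_t / N0}. A unit with \code{E_t <= 0} is classed
#' degraded (most of its area degraded significantly); \code{0 < E_t <=
#' 1} recovered but below the baseline (not-significant); \code{E_t > 1}
#' significantly recovered.
#'
#' @param nt per-unit net change for a period.
#' @param n0 positive scalar baseline from
#'   \code{\link{baselineNetChange}}.
#' @return data.frame (unit_id if named, Nt, Et, class).
#' @export
effectivenessScore <- function(nt, n0) {
  if (n0 <= 0)
    .vrStop("baseline must be positive", "VegRestore_unusableBaseline")
  et <- nt / n0
  cls <- cut(et, c(-Inf, 0, 1, Inf),
             labels = c("degraded", "not-significant", "significant"))
  out <- data.frame(Nt = as.numeric(nt), Et = as.numeric(et),
                    class = as.character(cls))
  if (!is.null(names(nt))) {
    ids <- suppressWarnings(as.integer(names(nt)))
    out <- cbind(unit_id = if (anyNA(ids)) names(nt) else ids, out)
  }
  out
}

#' Full effectiveness table over several periods
#'
#' Grades each period's trends, aggregates grade area fractions per unit,
#' computes the per-unit net change, fixes the baseline as the cross-unit
#' mean net change of the baseline period, and scores every unit and
#' period.
#'
#' @param stack the VQQI \linkS4class{AnnualStack}.
#' @param units a \linkS4class{UnitMap}.
#' @param periods list of integer (start, end) pairs; the first is also
#'   the default baseline.
#' @param baselinePeriod the (start, end) pair whose mean net change is
#'   the baseline.
#' @param thresholds significance thresholds for grading.
#' @return data.frame (unit_id, period, A1..A5, Nt, Et, class) with the
#'   scalar baseline in \code{attr(, "baseline")} and the per-period
#'   \linkS4class{TrendGrades} in \code{attr(, "grades")}.
#' @export
effectivenessTable <- function(stack, units,
                               periods = list(c(2000, 2010),
                                              c(2000, 2015),
                                              c(2000, 2020)),
                               baselinePeriod = periods[[1]],
                               thresholds = c(0.01, 0.05)) {
  lab <- function(p) sprintf("%d-%d", p[1], p[2])
  gradeList <- lapply(periods, function(p)
    trendGrades(stack, p, thresholds))
  names(gradeList) <- vapply(periods, lab, "")
  fracs <- lapply(gradeList, gradeFractions, units = units)
  ntList <- lapply(fracs, netChange)
  bl <- lab(as.integer(baselinePeriod))
  if (!bl %in% names(ntList))
    .vrStop("baseline period must be one of the analysis periods",
            "VegRestore_invalidConfig")
  n0 <- baselineNetChange(ntList[[bl]])
  rows <- Map(function(fr, nt, plab) {
    sc <- effectivenessScore(nt, n0)
    cbind(fr[, c("unit_id", "A1", "A2", "A3", "A4", "A5")],
          period = plab, sc[, c("Nt", "Et", "class")])
  }, fracs, ntList, names(ntList))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- n0
  attr(out, "grades") <- gradeList
  out
}

#' Area shares of the effectiveness classes
#'
#' Proportion of the total evaluated area (and, when sub-region labels
#' exist, of each sub-region's area) in each effectiveness class, per
#' period. Proportions sum to 1 within each scope and period.
#'
#' @param table an effectiveness table from
#'   \code{\link{effectivenessTable}} (or any data.frame with unit_id,
#'   period, class).
#' @param units a \linkS4class{UnitMap}.
#' @return data.frame (scope, period, class, areaFraction, nUnits).
#' @export
areaSummary <- function(table, units) {
  areas <- unitAreas(units)
  a <- areas[as.character(table$unit_id)]
  if (any(is.na(a)))
    .vrStop("effectiveness table has unit ids missing from the unit map",
            "VegRestore_join")
  scopes <- data.frame(scope = "all", unit_id = as.integer(names(areas)))
  if (length(units@subregion))
    scopes <- rbind(scopes,
                    data.frame(scope = unname(units@subregion),
                               unit_id = as.integer(names(units@subregion))))
  out <- list()
  cls <- c("degraded", "not-significant", "significant")
  for (sc in unique(scopes$scope)) {
    inScope <- scopes$unit_id[scopes$scope == sc]
    sub <- table[table$unit_id %in% inScope, , drop = FALSE]
    for (per in unique(sub$period)) {
      s2 <- sub[sub$period == per, , drop = FALSE]
      tot <- sum(areas[as.character(s2$unit_id)])
      for (cl in cls) {
        sel <- s2$class == cl
        out[[length(out) + 1L]] <- data.frame(
          scope = sc, period = per, class = cl,
          areaFraction = sum(areas[as.character(s2$unit_id[sel])]) / tot,
          nUnits = sum(sel))
      }
    }
  }
  do.call(rbind, out)
}
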