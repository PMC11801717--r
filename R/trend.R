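.periodSlice <- function(stack, period) {
  period <- as.integer(period)
  if (length(period) != 2L || period[1] > period[2])
    .vrStop("period must be (start_year, end_year)",
            "VegRestore_invalidConfig")
  sel <- stack@years >= period[1] & stack@years <= period[2]
  if (!all(period %in% stack@years))
    .vrStop(sprintf("period %d-%d not covered by stack years %d-%d",
                    period[1], period[2], min(stack@years),
                    max(stack@years)), "VegRestore_invalidConfig")
  if (sum(sel) < 3L)
    .vrStop("per-pixel trends need at least 3 years",
            "VegRestore_insufficientYears")
  list(v = stack@values[, , sel, drop = FALSE],
       years = stack@years[sel], period = period)
}

# Per-pixel closed-form least squares of value on year:
# slope = (l * sum(n*y) - sum(n) * sum(y)) / (l * sum(n^2) - sum(n)^2)
.pixelRegression <- function(v, yrs) {
  d <- dim(v)
  l <- length(yrs)
  m <- matrix(v, d[1] * d[2], l)
  sy <- rowSums(m)
  sny <- as.numeric(m %*% yrs)
  sn <- sum(yrs); snn <- sum(yrs^2)
  denom <- l * snn - sn^2
  slope <- (l * sny - sn * sy) / denom
  sst <- rowSums(m^2) - sy^2 / l
  ssr <- slope^2 * denom / l
  sse <- pmax(sst - ssr, 0)
  p <- rep(NA_real_, length(slope))
  valid <- is.finite(slope)
  const <- valid & sst <= 1e-12 * pmax(sy^2 / l, 1e-300)
  perfect <- valid & !const & sse <= 1e-12 * sst
  reg <- valid & !const & !perfect
  p[const] <- 1
  slope[const] <- 0
  p[perfect] <- 0
  if (any(reg)) {
    Fv <- ssr[reg] / (sse[reg] / (l - 2))
    p[reg] <- stats::pf(Fv, 1, l - 2, lower.tail = FALSE)
  }
  list(slope = matrix(slope, d[1], d[2]), p = matrix(p, d[1], d[2]), l = l)
}

#' Per-pixel least-squares trend of an annual stack
#'
#' Ordinary least-squares slope of the variable on calendar year for each
#' pixel over an inclusive period, by the closed-form normal equations.
#'
#' @param stack an \linkS4class{AnnualStack} (typically VQQI).
#' @param period integer (start_year, end_year); both must be stack years
#'   and the period must span at least 3 years.
#' @return numeric matrix of slopes (index units per year; \code{NA}
#'   outside the mask).
#' @export
pixelSlope <- function(stack, period = range(stack@years)) {
  s <- .periodSlice(stack, period)
  .pixelRegression(s$v, s$years)$slope
}

#' Per-pixel F-test significance of the trend slope
#'
#' Tests each pixel's regression with \code{F = MSR / MSE} on (1, l - 2)
#' degrees of freedom. A constant series has no trend signal (p = 1); a
#' perfect nonconstant line has p = 0.
#'
#' @inheritParams pixelSlope
#' @return numeric matrix of p-values.
#' @export
slopeSignificance <- function(stack, period = range(stack@years)) {
  s <- .periodSlice(stack, period)
  .pixelRegression(s$v, s$years)$p
}

#' Grade weights of the five trend classes
#' @export
gradeWeights <- c(2, 1, 0, -1, -2)

#' Classify per-pixel trends into the five weighted grades
#'
#' Grade 1, extremely significant improvement: slope > 0, p < p1.
#' Grade 2, significant improvement: slope > 0, p1 <= p < p2.
#' Grade 3, no significant change: p >= p2 (and any zero slope).
#' Grade 4, significant degradation: slope < 0, p1 <= p < p2.
#' Grade 5, extremely significant degradation: slope < 0, p < p1.
#' Weights are 2, 1, 0, -1, -2 in grade order. A p exactly on a
#' threshold falls in the less significant class.
#'
#' @param slope,p aligned matrices from \code{\link{pixelSlope}} and
#'   \code{\link{slopeSignificance}}.
#' @param thresholds the two significance thresholds (p1, p2), default
#'   (0.01, 0.05).
#' @param period integer (start_year, end_year) recorded with the result.
#' @return a \linkS4class{TrendGrades}.
#' @export
classifyGrades <- function(slope, p, thresholds = c(0.01, 0.05),
                           period = c(NA_integer_, NA_integer_)) {
  if (!identical(dim(slope), dim(p)))
    .vrStop("slope and p grids differ", "VegRestore_alignment")
  if (thresholds[1] >= thresholds[2])
    .vrStop("thresholds must be increasing", "VegRestore_invalidConfig")
  g <- matrix(NA_integer_, nrow(slope), ncol(slope))
  ok <- !is.na(slope) & !is.na(p)
  g[ok] <- 3L
  g[ok & slope > 0 & p < thresholds[1]] <- 1L
  g[ok & slope > 0 & p >= thresholds[1] & p < thresholds[2]] <- 2L
  g[ok & slope < 0 & p >= thresholds[1] & p < thresholds[2]] <- 4L
  g[ok & slope < 0 & p < thresholds[1]] <- 5L
  w <- matrix(NA_real_, nrow(slope), ncol(slope))
  w[ok] <- gradeWeights[g[ok]]
  per <- as.integer(period)
  if (any(is.na(per))) per <- c(0L, 0L)
  new("TrendGrades", period = per, slope = slope, p = p,
      grade = g, weight = w)
}

#' Slope, significance and grading in one step
#'
#' @inheritParams pixelSlope
#' @param thresholds significance thresholds passed to
#'   \code{\link{classifyGrades}}.
#' @return a \linkS4class{TrendGrades}.
#' @export
trendGrades <- function(stack, period = range(stack@years),
                        thresholds = c(0.01, 0.05)) {
  s <- .periodSlice(stack, period)
  r <- .pixelRegression(s$v, s$years)
  classifyGrades(r$slope, r$p, thresholds, period = s$period)
}
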