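#' Fractional vegetation cover by the dimidiate pixel model
#'
#' Linearly unmixes each pixel between a bare-soil and a full-vegetation
#' NDVI endmember: \code{FVC = (NDVI - NDVI_soil) / (NDVI_veg -
#' NDVI_soil)}, clipped to [0, 1]. The endmembers are taken per year as
#' the \code{soilPct} and \code{vegPct} percentiles of that year's valid
#' NDVI values, the usual practice when no field endmembers are
#' available.
#'
#' @param ndvi an \linkS4class{AnnualStack} of NDVI in [-1, 1].
#' @param soilPct,vegPct endmember percentiles, 0 <= soilPct < vegPct
#'   <= 100 (defaults 5 and 95).
#' @return an \linkS4class{AnnualStack} of FVC in [0, 1].
#' @export
fvcFromNdvi <- function(ndvi, soilPct = 5, vegPct = 95) {
  if (soilPct < 0 || vegPct > 100 || soilPct >= vegPct)
    .vrStop("need 0 <= soilPct < vegPct <= 100",
            "VegRestore_invalidConfig")
  v <- ndvi@values
  out <- v
  for (k in seq_along(ndvi@years)) {
    scene <- v[, , k]
    qs <- stats::quantile(scene, c(soilPct, vegPct) / 100, na.rm = TRUE,
                          names = FALSE)
    if (qs[2] <= qs[1])
      .vrStop(sprintf(
        "degenerate NDVI scene in %d: soil and vegetation endmembers coincide",
        ndvi@years[k]), "VegRestore_degenerateScene")
    out[, , k] <- pmin(pmax((scene - qs[1]) / (qs[2] - qs[1]), 0), 1)
  }
  new("AnnualStack", values = out, years = ndvi@years, varname = "FVC",
      cellArea = ndvi@cellArea)
}

#' Maximum-value composite of sub-annual scenes
#'
#' Reduces sub-annual (e.g. 8-day) scenes to one layer per year by the
#' per-pixel maximum, the standard compositing that suppresses clouds and
#' atmospheric dimming.
#'
#' @param values array \code{rows x cols x n_scenes}.
#' @param sceneYears integer year of each scene.
#' @param varname,cellArea passed to the resulting stack.
#' @return an \linkS4class{AnnualStack} with one band per distinct year.
#' @export
maxValueComposite <- function(values, sceneYears, varname = "NDVI",
                              cellArea = 1) {
  yrs <- sort(unique(as.integer(sceneYears)))
  out <- array(NA_real_, c(dim(values)[1:2], length(yrs)))
  for (k in seq_along(yrs)) {
    sel <- which(sceneYears == yrs[k])
    out[, , k] <- apply(values[, , sel, drop = FALSE], c(1, 2),
                        function(z) if (all(is.na(z))) NA_real_
                                    else max(z, na.rm = TRUE))
  }
  annualStack(out, yrs, varname, cellArea)
}

#' Min-max normalization of an annual stack
#'
#' Rescales a variable to [0, 1] with a single affine map per variable:
#' by default the minimum and maximum are taken jointly over all years
#' and pixels, which removes the unit while preserving interannual
#' ordering and relative change. Per-year scaling (each year mapped to
#' [0, 1] on its own) is available but destroys interannual trends, so it
#' is not the default.
#'
#' @param stack an \linkS4class{AnnualStack}.
#' @param scope \code{"global"} (default) or \code{"annual"}.
#' @return an \linkS4class{AnnualStack} named \code{N_<variable>}.
#' @export
normalizeStack <- function(stack, scope = c("global", "annual")) {
  scope <- match.arg(scope)
  v <- stack@values
  if (!any(is.finite(v)))
    .vrStop("stack has no valid values", "VegRestore_degenerateNormalization")
  if (scope == "global") {
    r <- range(v, na.rm = TRUE)
    if (r[2] <= r[1])
      .vrStop("constant stack cannot be normalized",
              "VegRestore_degenerateNormalization")
    v <- (v - r[1]) / (r[2] - r[1])
  } else {
    for (k in seq_along(stack@years)) {
      r <- range(v[, , k], na.rm = TRUE)
      if (r[2] <= r[1])
        .vrStop(sprintf("constant scene in %d cannot be normalized",
                        stack@years[k]),
                "VegRestore_degenerateNormalization")
      v[, , k] <- (v[, , k] - r[1]) / (r[2] - r[1])
    }
  }
  new("AnnualStack", values = v, years = stack@years,
      varname = paste0("N_", stack@varname), cellArea = stack@cellArea)
}

#' Composite vegetation quality-quantity index
#'
#' Combines normalized fractional cover (vegetation structure) and
#' normalized net primary productivity (vegetation function) with equal
#' weights on a percentage scale:
#' \deqn{VQQI = \frac{N_{FVC} + N_{NPP}}{2} \times 100\%}
#' so the index runs from 0 to 100.
#'
#' @param nfvc,nnpp normalized \linkS4class{AnnualStack}s in [0, 1] on
#'   the same grid and years.
#' @return an \linkS4class{AnnualStack} named \code{VQQI}.
#' @export
vqqi <- function(nfvc, nnpp) {
  if (!identical(dim(nfvc@values), dim(nnpp@values)) ||
      !identical(nfvc@years, nnpp@years))
    .vrStop("inputs must share one grid and one set of years",
            "VegRestore_alignment")
  rng <- range(c(nfvc@values, nnpp@values), na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    .vrStop("inputs must be normalized to [0, 1]", "VegRestore_alignment")
  new("AnnualStack", values = (nfvc@values + nnpp@values) / 2 * 100,
      years = nfvc@years, varname = "VQQI", cellArea = nfvc@cellArea)
}

#' Regional annual mean series with its linear trend
#'
#' Averages the stack over the valid (optionally masked) pixels for each
#' year and fits an ordinary least-squares line to the series, attaching
#' the slope and its two-sided t-test p-value. A constant series gets
#' slope 0 and p = 1.
#'
#' @param stack an \linkS4class{AnnualStack}.
#' @param mask optional logical matrix selecting the pixels to average
#'   (e.g. one unit's cells), or a \linkS4class{UnitMap} together with
#'   \code{unit} to select a single unit.
#' @param unit optional unit id when \code{mask} is a UnitMap.
#' @return an \linkS4class{AnnualSeries}.
#' @export
regionalSeries <- function(stack, mask = NULL, unit = NULL) {
  if (is(mask, "UnitMap")) {
    mask <- if (is.null(unit)) !is.na(mask@ids) else
      !is.na(mask@ids) & mask@ids == unit
  }
  v <- stack@values
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(v)[1:2]))
      .vrStop("mask shape must match the grid", "VegRestore_alignment")
    v[array(!mask, dim(v))] <- NA_real_
  }
  if (!any(is.finite(v)))
    .vrStop("no valid pixels selected", "VegRestore_emptySelection")
  vals <- apply(v, 3, mean, na.rm = TRUE)
  yrs <- stack@years
  n <- length(yrs)
  slope <- 0; p <- 1
  if (n >= 3 && stats::sd(vals) > 0) {
    fit <- stats::lm(vals ~ yrs)
    cf <- summary(fit)$coefficients
    slope <- cf[2, 1]
    p <- cf[2, 4]
    if (is.nan(p)) p <- 0   # perfect nonconstant line
  } else if (n >= 2 && stats::sd(vals) > 0) {
    slope <- diff(vals) / diff(yrs)
    p <- NA_real_
  }
  new("AnnualSeries", years = yrs, values = unname(vals),
      trendSlope = slope, trendP = p,
      changeYear = NA_integer_, changeP = NA_real_)
}

#' Pettitt change-point detection for an annual series
#'
#' Rank-based nonparametric test for a single abrupt shift. For every
#' split point t the statistic \eqn{U_t = \sum_{i \le t}\sum_{j > t}
#' \mathrm{sign}(x_j - x_i)} is accumulated; the change point maximizes
#' \eqn{|U_t|} and its significance is approximated by
#' \eqn{p = 2\exp(-6K^2/(n^3 + n^2))} (capped at 1) with
#' \eqn{K = \max_t |U_t|}. The reported change year is the first year of
#' the new regime (the year after the maximizing split). An all-equal
#' series has K = 0 and p = 1 with no change year.
#'
#' @param series an \linkS4class{AnnualSeries}, or a plain numeric vector
#'   with \code{years} supplied.
#' @param years calendar years when \code{series} is a plain vector.
#' @return list with elements \code{year} (calendar year or \code{NA}),
#'   \code{statistic} (K), \code{p}, and \code{U} (the split statistics).
#' @examples
#' changeYear(c(rep(10, 11), rep(14, 10)), years = 2000:2020)$year  # 2011
#' @export
changeYear <- function(series, years = NULL) {
  if (is(series, "AnnualSeries")) {
    x <- series@values; yrs <- series@years
  } else {
    x <- as.numeric(series)
    yrs <- if (is.null(years)) seq_along(x) else as.integer(years)
  }
  n <- length(x)
  if (n < 4) .vrStop("change-point detection needs at least 4 values",
                     "VegRestore_insufficientYears")
  r <- rank(x)
  # U_t via midranks: U_t = t * (n + 1) - 2 * sum(r[1:t]) equals the
  # double sum of sign(x_j - x_i) over i <= t < j, ties contributing 0
  U <- seq_len(n - 1) * (n + 1) - 2 * cumsum(r)[-n]
  K <- max(abs(U))
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  tstar <- which.max(abs(U))
  list(year = if (K == 0) NA_integer_ else yrs[tstar + 1L],
       statistic = K, p = p, U = U)
}

#' Attach a Pettitt change point to a series
#'
#' @param series an \linkS4class{AnnualSeries}.
#' @return the series with \code{changeYear} and \code{changeP} filled.
#' @export
detectChange <- function(series) {
  cp <- changeYear(series)
  series@changeYear <- if (is.na(cp$year)) NA_integer_
                       else as.integer(cp$year)
  series@changeP <- cp$p
  series
}
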