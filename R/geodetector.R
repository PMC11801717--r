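# Core variance decomposition behind the factor detector.
# Returns within-stratum sum of squares via grouped sums, never forming
# per-stratum subsets, so it is cheap on thousands of units.
.qdecomp <- function(y, h) {
  keep <- !is.na(y) & !is.na(h)
  y <- y[keep]; h <- h[keep]
  N <- length(y)
  if (N < 2L)
    .vrStop("need at least 2 units with response and stratum",
            "VegRestore_undefinedTest")
  f <- factor(h)
  dropped <- nlevels(f) - nlevels(droplevels(f))
  f <- droplevels(f)
  L <- nlevels(f)
  n_h <- as.integer(tabulate(f))
  s_h <- as.numeric(rowsum(y, f))
  ss_h <- as.numeric(rowsum(y * y, f))
  ssw_h <- ss_h - s_h^2 / n_h          # within-stratum sum of squares
  ssw_h[ssw_h < 0] <- 0                # guard rounding on constants
  sst <- sum(y * y) - sum(y)^2 / N
  list(N = N, L = L, n_h = n_h, mean_h = s_h / n_h,
       var_h = ssw_h / n_h,            # population variance per stratum
       ssw = sum(ssw_h), sst = sst, sigma2 = sst / N,
       q = if (sst > 0) 1 - sum(ssw_h) / sst else NA_real_)
}

.partitionInputs <- function(y, partition) {
  if (is(partition, "FactorPartition")) {
    h <- partition@stratum
    if (!is.null(names(y)) && !is.null(names(h))) {
      common <- intersect(names(y), names(h))
      if (!length(common))
        .vrStop("no shared unit ids between response and partition",
                "VegRestore_alignment")
      y <- y[common]; h <- h[common]
    } else if (length(y) != length(h)) {
      .vrStop("response and partition lengths differ",
              "VegRestore_alignment")
    }
    list(y = y, h = h, name = partition@factorName)
  } else {
    if (length(y) != length(partition))
      .vrStop("response and stratum vector lengths differ",
              "VegRestore_alignment")
    list(y = y, h = partition, name = "factor")
  }
}

#' Geodetector factor detector: the q statistic
#'
#' Measures how much of the spatial variance of a per-unit response a
#' categorical stratification explains:
#' \deqn{q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2}}
#' with population variances; q = 0 means the strata carry no information
#' about the response, q = 1 that the response is constant within every
#' stratum. Strata that are empty after dropping missing values are
#' removed (with a warning); single-unit strata contribute zero within
#' variance.
#'
#' @param y per-unit response (e.g. an effectiveness score), optionally
#'   named by unit id.
#' @param partition a \linkS4class{FactorPartition}, or a plain vector of
#'   stratum labels aligned with \code{y}.
#' @param significance compute the p-value (see
#'   \code{\link{qSignificance}})? Default \code{TRUE}.
#' @return a \linkS4class{FactorDetection}.
#' @examples
#' y <- c(1, 1, 2, 2, 5, 5, 6, 6)
#' factorQ(y, rep(1:2, each = 4))  # q = 1 - 2/34
#' @export
factorQ <- function(y, partition, significance = TRUE) {
  inp <- .partitionInputs(y, partition)
  f0 <- if (is.factor(inp$h)) inp$h else factor(inp$h)
  used <- !is.na(inp$y) & !is.na(inp$h)
  if (nlevels(droplevels(f0[used])) < nlevels(f0))
    warning("empty strata dropped and remaining strata relabeled")
  d <- .qdecomp(inp$y, inp$h)
  if (d$sst <= 0)
    .vrStop("response is constant: q undefined",
            "VegRestore_constantResponse")
  if (d$L < 2L)
    .vrStop("partition has a single non-empty stratum",
            "VegRestore_constantPartition")
  det <- new("FactorDetection", factorName = inp$name,
             q = min(max(d$q, 0), 1), p = NA_real_,
             strata = data.frame(stratum = seq_len(d$L), n = d$n_h,
                                 mean = d$mean_h, var = d$var_h),
             N = d$N, sigma2 = d$sigma2)
  if (significance) det@p <- qSignificance(det)
  det
}

#' Significance of a q statistic
#'
#' Uses the noncentral-F transformation of q:
#' \code{F = (N - L) / (L - 1) * q / (1 - q)} referred to a noncentral F
#' distribution with (L - 1, N - L) degrees of freedom and noncentrality
#' \deqn{\lambda = \frac{1}{\sigma^2}\left[\sum_h \bar y_h^2 -
#'   \frac{1}{N}\left(\sum_h \sqrt{N_h}\,\bar y_h\right)^2\right].}
#' A perfect stratification (q = 1) returns p = 0.
#'
#' @param detection a \linkS4class{FactorDetection}.
#' @return the p-value.
#' @export
qSignificance <- function(detection) {
  N <- detection@N; L <- nrow(detection@strata)
  if (N <= L)
    .vrStop("need more units than strata for the q test",
            "VegRestore_undefinedTest")
  q <- detection@q
  if (q >= 1 - 1e-12) return(0)
  Fv <- (N - L) / (L - 1) * q / (1 - q)
  m <- detection@strata$mean; n_h <- detection@strata$n
  lambda <- (sum(m^2) - sum(sqrt(n_h) * m)^2 / N) / detection@sigma2
  stats::pf(Fv, L - 1, N - L, ncp = max(lambda, 0), lower.tail = FALSE)
}

#' Select the main driving factors
#'
#' Retains factors whose q ranks in the top 50 percent (rank <=
#' ceiling(n/2), ties sharing the smaller rank) and whose q is significant
#' at the given level, ordered by decreasing q.
#'
#' @param detections a list of \linkS4class{FactorDetection} objects, or a
#'   data.frame with columns \code{factor} (or \code{name}), \code{q} and
#'   \code{p}.
#' @param alpha significance level (default 0.05, i.e. the 95 percent
#'   confidence level).
#' @return data.frame (factor, q, p) of the selected main factors, ordered
#'   by q descending.
#' @export
selectMainFactors <- function(detections, alpha = 0.05) {
  if (is.data.frame(detections)) {
    tab <- detections
    if (!"factor" %in% names(tab) && "name" %in% names(tab))
      names(tab)[names(tab) == "name"] <- "factor"
  } else {
    tab <- data.frame(
      factor = vapply(detections, function(d) d@factorName, ""),
      q = vapply(detections, function(d) d@q, 0),
      p = vapply(detections, function(d) d@p, 0))
  }
  if (!nrow(tab)) .vrStop("no detections supplied",
                          "VegRestore_emptySelection")
  rk <- rank(-tab$q, ties.method = "min")
  keep <- rk <= ceiling(nrow(tab) / 2) & tab$p < alpha
  out <- tab[keep, c("factor", "q", "p"), drop = FALSE]
  out[order(-out$q), , drop = FALSE]
}

#' Geodetector interaction detector
#'
#' Computes q of the cross-classification of two stratifications (stratum
#' = ordered pair of single-factor strata, empty combinations dropped) and
#' classifies the interaction against the single-factor q values:
#' independent (q_AB = q_A + q_B within tolerance), weaken-nonlinear
#' (q_AB < min), weaken-single (min <= q_AB <= max), enhance-bivariate
#' (max < q_AB < q_A + q_B) or enhance-nonlinear (q_AB > q_A + q_B).
#' Because the cross-classification refines both inputs, q_AB can never
#' fall below max(q_A, q_B) beyond rounding; the weaken categories are
#' kept for completeness of the standard typology.
#'
#' @param y per-unit response, optionally named by unit id.
#' @param partA,partB two \linkS4class{FactorPartition}s over the same
#'   units (or plain stratum vectors aligned with \code{y}).
#' @param tol equality tolerance for the independence category.
#' @return an \linkS4class{InteractionDetection}.
#' @export
interactionQ <- function(y, partA, partB, tol = 1e-9) {
  a <- .partitionInputs(y, partA)
  b <- .partitionInputs(y, partB)
  if (!identical(names(a$y), names(b$y)) && length(a$y) != length(b$y))
    .vrStop("partitions cover different units", "VegRestore_alignment")
  if (!is.null(names(a$y))) { b$h <- b$h[names(a$y)] }
  qA <- factorQ(a$y, a$h, significance = FALSE)@q
  qB <- factorQ(a$y, b$h, significance = FALSE)@q
  cross <- interaction(a$h, b$h, drop = TRUE)
  qAB <- factorQ(a$y, as.integer(cross), significance = FALSE)@q
  lo <- min(qA, qB); hi <- max(qA, qB)
  type <-
    if (abs(qAB - (qA + qB)) <= tol) "independent"
    else if (qAB < lo - tol) "weaken-nonlinear"
    else if (qAB <= hi + tol) "weaken-single"
    else if (qAB < qA + qB) "enhance-bivariate"
    else "enhance-nonlinear"
  new("InteractionDetection", factors = c(a$name, b$name),
      qA = qA, qB = qB, qAB = qAB, type = type)
}

#' Geodetector risk detector
#'
#' Reports per-stratum mean response with pairwise Welch two-sample
#' t-tests between strata, and identifies the stratum with the maximal
#' mean together with the factor-value range it covers -- the range of
#' the driver most favorable to the response. Strata with fewer than two
#' units are excluded from testing and flagged.
#'
#' @param y per-unit response, optionally named by unit id.
#' @param partition a \linkS4class{FactorPartition}.
#' @param alpha significance level recorded with the result.
#' @return a \linkS4class{RiskDetection}.
#' @export
riskDetect <- function(y, partition, alpha = 0.05) {
  inp <- .partitionInputs(y, partition)
  keep <- !is.na(inp$y) & !is.na(inp$h)
  yv <- inp$y[keep]; h <- inp$h[keep]
  vals <- if (is(partition, "FactorPartition"))
    partition@values[names(yv)] else rep(NA_real_, length(yv))
  if (is.null(names(yv)) && is(partition, "FactorPartition"))
    vals <- partition@values[keep]
  f <- droplevels(factor(h))
  L <- nlevels(f)
  if (L < 2L) .vrStop("risk detection needs at least 2 strata",
                      "VegRestore_constantPartition")
  n_h <- as.integer(tabulate(f))
  mean_h <- as.numeric(tapply(yv, f, mean))
  vmin <- suppressWarnings(as.numeric(tapply(vals, f, min, na.rm = TRUE)))
  vmax <- suppressWarnings(as.numeric(tapply(vals, f, max, na.rm = TRUE)))
  tested <- n_h >= 2L
  tm <- matrix(NA_real_, L, L,
               dimnames = list(levels(f), levels(f)))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    if (tested[i] && tested[j]) {
      yi <- yv[f == levels(f)[i]]; yj <- yv[f == levels(f)[j]]
      p <- if (stats::var(yi) + stats::var(yj) == 0) {
        if (mean(yi) == mean(yj)) 1 else 0
      } else stats::t.test(yi, yj)$p.value
      tm[i, j] <- tm[j, i] <- p
    }
  }
  amax <- which.max(mean_h)
  new("RiskDetection", factorName = inp$name,
      strata = data.frame(stratum = as.integer(levels(f)), n = n_h,
                          mean = mean_h, valueMin = vmin, valueMax = vmax,
                          tested = tested),
      tMatrix = tm, argmaxStratum = as.integer(levels(f)[amax]),
      argmaxRange = c(vmin[amax], vmax[amax]))
}
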