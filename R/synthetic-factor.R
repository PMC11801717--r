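#' Design a stratified factor with a target Geodetector q
#'
#' Constructs a factor partition whose explanatory power against a given
#' per-unit response equals a designed q. Units are first ranked by the
#' response into L contiguous strata of near-equal size (the maximal-q
#' arrangement for those sizes); stratum purity is then degraded by
#' random swaps of stratum labels between units until the directly
#' computed variance ratio reaches the target within \code{tol}. Swaps
#' are proposed in shrinking batches and only accepted when they move q
#' toward the target, so the walk converges quickly and is fully
#' reproducible from the scenario seed. A target of exactly 0 is realized
#' as a uniform random permutation of the ranked labels.
#'
#' Factor values are emitted alongside the strata: value = stratum label
#' plus a small uniform jitter, so value ranges are informative for risk
#' detection while the stratification itself carries the designed signal.
#'
#' @param config a \linkS4class{ScenarioConfig} (supplies the seed).
#' @param unitEffectiveness named per-unit response the q is designed
#'   against.
#' @param spec one factor design: a list or one-row data.frame with
#'   \code{name}, \code{category}, \code{designedQ}, \code{nGroups}.
#' @param index integer offset so each factor of a scenario draws from
#'   its own sub-stream.
#' @param tol convergence tolerance on |q - designedQ| (default 0.01,
#'   half the contracted 0.02 design accuracy).
#' @param maxit maximal number of accepted/rejected batch proposals.
#' @return a \linkS4class{FactorPartition}.
#' @examples
#' cfg <- scenarioConfig(seed = 7)
#' y <- stats::setNames(rnorm(500), 1:500)
#' p <- simulateFactor(cfg, y, list(name = "annual_precipitation",
#'   category = "climate", designedQ = 0.75, nGroups = 7))
#' qValue(factorQ(y, p))
#' @export
simulateFactor <- function(config, unitEffectiveness, spec, index = 1L,
                           tol = 0.01, maxit = 20000L) {
  q0 <- as.numeric(spec$designedQ)
  L <- as.integer(spec$nGroups)
  if (is.na(q0) || q0 < 0 || q0 >= 1)
    .vrStop("designedQ must lie in [0, 1)", "VegRestore_infeasibleSpec")
  if (L < 2L) .vrStop("need at least 2 groups", "VegRestore_infeasibleSpec")
  y <- unitEffectiveness
  n <- length(y)
  if (n < L)
    .vrStop(sprintf("%d groups but only %d units", L, n),
            "VegRestore_infeasibleSpec")
  if (stats::sd(y) == 0)
    .vrStop("constant response: no q can be designed",
            "VegRestore_infeasibleSpec")
  uid <- if (is.null(names(y))) as.character(seq_len(n)) else names(y)

  sizes <- .largestRemainder(n, rep(1 / L, L))
  sizes[L] <- sizes[L] + (n - sum(sizes))
  ranked <- rep(seq_len(L), sizes)            # stratum by response rank
  h <- integer(n)
  h[order(y)] <- ranked
  qOf <- function(hh) .qdecomp(y, hh)$q
  qMax <- qOf(h)
  if (q0 > qMax + 2 * tol)
    .vrStop(sprintf(
      "designed q %.3f unattainable: ranked partition reaches only %.3f",
      q0, qMax), "VegRestore_infeasibleSpec")

  .withSeed(config@seed + .seedOffsets[["factors"]] + index, {
    if (q0 == 0) {
      h <- sample(h)
    } else {
      qCur <- qMax
      batch <- max(1L, n %/% 20L)
      it <- 0L; fails <- 0L
      while (abs(qCur - q0) > tol && it < maxit && fails < 500L) {
        it <- it + 1L
        pick <- sample.int(n, min(2L * batch, n))
        hNew <- h
        hNew[pick] <- h[sample(pick)]         # shuffle labels among picks
        qNew <- qOf(hNew)
        # accept only moves toward the target that do not overshoot
        # below the tolerance band (purity only ever degrades, so q
        # lost to an overshoot is hard to win back by random swaps)
        if (abs(qNew - q0) < abs(qCur - q0) && qNew >= q0 - tol) {
          h <- hNew; qCur <- qNew; fails <- 0L
        } else if (batch > 1L) {
          batch <- batch %/% 2L
        } else {
          fails <- fails + 1L
        }
      }
      if (abs(qCur - q0) > 2 * tol)
        .vrStop(sprintf(
          "could not reach designed q %.3f (stalled at %.3f)", q0, qCur),
          "VegRestore_infeasibleSpec")
    }
    jitter <- stats::runif(n, -0.3, 0.3)
  })
  vals <- h + jitter
  names(vals) <- uid
  hh <- as.integer(h); names(hh) <- uid
  new("FactorPartition",
      factorName = as.character(spec$name),
      category = as.character(spec$category),
      values = vals, stratum = hh, breaks = numeric(0))
}
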