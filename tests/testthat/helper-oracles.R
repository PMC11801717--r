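# Independent brute-force oracles used across the suite. These stay
# deliberately naive (double loops, exhaustive enumeration) so they share
# no code path with the implementation they check.

# variance-decomposition q: loop over strata with textbook formulas
qOracle <- function(y, h) {
  N <- length(y)
  sigma2 <- mean((y - mean(y))^2)
  num <- 0
  for (s in unique(h)) {
    v <- y[h == s]
    num <- num + length(v) * mean((v - mean(v))^2)
  }
  1 - num / (N * sigma2)
}

# Pettitt split statistics by the literal double sign sum
pettittOracle <- function(x) {
  n <- length(x)
  U <- numeric(n - 1)
  for (t in 1:(n - 1)) {
    s <- 0
    for (i in 1:t) for (j in (t + 1):n) s <- s + sign(x[j] - x[i])
    U[t] <- s
  }
  U
}

# minimal within-class SSD over every contiguous partition of sorted x
jenksOracle <- function(x, L) {
  xs <- sort(x)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, L - 1)
  for (cc in seq_len(ncol(splits))) {
    b <- c(0, splits[, cc], n)
    tot <- 0
    for (k in 1:L) tot <- tot + ssd(xs[(b[k] + 1):(b[k + 1])])
    best <- min(best, tot)
  }
  best
}

# hand-rolled least squares via the normal equations
slopeOracle <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

noFactors <- data.frame(name = character(0), category = character(0),
                        designedQ = numeric(0), nGroups = integer(0))
noTransitions <- data.frame(from = character(0), to = character(0),
                            fraction = numeric(0))

# a small noiseless scenario used by several module tests
quietConfig <- function(...) {
  defaults <- list(gridRows = 6, gridCols = 6, nUnits = 4,
                   years = 2000:2010, seed = 11,
                   baseSD = 0, trendSD = 0, noiseSD = 0,
                   trendMean = 0.005, breakYear = NA, breakMagnitude = 0,
                   factorSpecs = noFactors,
                   transitionSpec = noTransitions)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(scenarioConfig, defaults)
}
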