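mkGrades <- function(gradeMat, period = c(2000L, 2010L)) {
  w <- matrix(gradeWeights[gradeMat], nrow(gradeMat), ncol(gradeMat))
  new("TrendGrades", period = period,
      slope = matrix(0, nrow(gradeMat), ncol(gradeMat)),
      p = matrix(1, nrow(gradeMat), ncol(gradeMat)),
      grade = gradeMat, weight = w)
}

mkUnits <- function(ids, cellArea = 1, subregion = character(0)) {
  new("UnitMap", ids = ids, cellArea = cellArea, subregion = subregion)
}

test_that("grade fractions count cells per unit and sum to one", {
  ids <- matrix(rep(1:2, each = 10), 2)
  g <- matrix(3L, 2, 10); g[, 1:5] <- 1L       # unit 1 all grade 1
  g[2, 6:10] <- 3L; g[1, 6:8] <- 1L            # unit 2: 3 of grade 1
  fr <- gradeFractions(mkGrades(g), mkUnits(ids))
  expect_equal(fr$A1[fr$unit_id == 1], 1)
  expect_equal(fr$A1[fr$unit_id == 2], 0.3)
  expect_equal(fr$A3[fr$unit_id == 2], 0.7)
  expect_equal(rowSums(fr[, c("A1", "A2", "A3", "A4", "A5")]),
               rep(1, 2))

  set.seed(12)
  gr <- matrix(sample(1:5, 60, TRUE), 6)
  fr2 <- gradeFractions(mkGrades(gr), mkUnits(matrix(rep(1:3, 20), 6)))
  expect_equal(rowSums(fr2[, paste0("A", 1:5)]), rep(1, 3),
               tolerance = 1e-12)
})

test_that("units without valid cells are excluded with a warning", {
  ids <- matrix(rep(1:2, each = 4), 2)
  g <- matrix(1L, 2, 4); g[ids == 2] <- NA
  expect_warning(fr <- gradeFractions(mkGrades(g), mkUnits(ids)), "2")
  expect_equal(fr$unit_id, 1L)
})

test_that("net change is the weighted area sum, bounded in [-2, 2]", {
  expect_equal(netChange(matrix(c(1, 0, 0, 0, 0), 1)), 2)
  expect_equal(netChange(matrix(c(0, 0, 0, 0, 1), 1)), -2)
  expect_equal(netChange(matrix(c(0.5, 0.2, 0.3, 0, 0), 1)), 1.2)
  set.seed(2)
  for (r in 1:20) {
    A <- matrix(stats::rexp(5), 1); A <- A / sum(A)
    nt <- netChange(A)
    expect_gte(nt, -2); expect_lte(nt, 2)
    expect_equal(nt, sum(gradeWeights * A))
  }
  expect_error(netChange(matrix(c(0.5, 0.2, 0.2, 0, 0), 1)),
               class = "VegRestore_validation")
})

test_that("moving area to a better grade never decreases net change", {
  set.seed(9)
  for (r in 1:20) {
    A <- stats::rexp(5); A <- A / sum(A)
    k <- sample(which(A > 1e-6), 1)
    better <- which(gradeWeights > gradeWeights[k])
    if (!length(better)) next
    k2 <- sample(c(better, better), 1)
    eps <- A[k] * runif(1)
    A2 <- A; A2[k] <- A2[k] - eps; A2[k2] <- A2[k2] + eps
    expect_gte(netChange(matrix(A2, 1)), netChange(matrix(A, 1)))
  }
})

test_that("the baseline is the cross-unit mean and must be positive", {
  expect_equal(baselineNetChange(c(1, 2)), 1.5)
  expect_equal(baselineNetChange(0.7), 0.7)
  expect_error(baselineNetChange(c(0, 0)),
               class = "VegRestore_unusableBaseline")
  expect_error(baselineNetChange(c(-1, -0.5)),
               class = "VegRestore_signInversion")
})

test_that("effectiveness scores classify on the stated boundaries", {
  sc <- effectivenessScore(c(a = 0.9, b = -0.18, c = 1.8, d = 0), 0.9)
  expect_equal(sc$Et, c(1, -0.2, 2, 0))
  expect_equal(sc$class, c("not-significant", "degraded",
                           "significant", "degraded"))
  expect_error(effectivenessScore(1, 0),
               class = "VegRestore_unusableBaseline")
})

test_that("mean effectiveness over units is exactly 1 in the baseline period", {
  cfg <- scenarioConfig(gridRows = 12, gridCols = 12, nUnits = 9,
                        years = 2000:2020, seed = 23,
                        trendMean = NA, trendDrawMean = 0.004,
                        trendDrawSD = 0.003, noiseSD = 0.01,
                        factorSpecs = noFactors,
                        transitionSpec = noTransitions)
  s <- simulateStacks(cfg)
  vq <- vqqi(normalizeStack(fvcFromNdvi(s$ndvi)),
             normalizeStack(s$npp))
  eff <- effectivenessTable(vq, s$units)
  e0 <- eff$Et[eff$period == "2000-2010"]
  expect_equal(mean(e0), 1, tolerance = 1e-12)
  expect_true(all(eff$Nt >= -2 & eff$Nt <= 2))
  expect_equal(attr(eff, "baseline"),
               mean(eff$Nt[eff$period == "2000-2010"]))
})

test_that("area summary weights classes by unit area", {
  ids <- matrix(c(1L, 2L), 1)
  tab <- data.frame(unit_id = 1:2, period = "2000-2020",
                    class = c("degraded", "significant"))
  s <- areaSummary(tab, mkUnits(ids))
  expect_equal(s$areaFraction[s$class == "degraded"], 0.5)
  expect_equal(s$areaFraction[s$class == "significant"], 0.5)

  ids2 <- matrix(c(1L, 2L, 2L, 2L), 1)   # areas 1:3
  s2 <- areaSummary(tab, mkUnits(ids2))
  expect_equal(s2$areaFraction[s2$class == "degraded"], 0.25)
  expect_equal(s2$areaFraction[s2$class == "significant"], 0.75)
  expect_equal(sum(s2$areaFraction), 1)

  tabAll <- data.frame(unit_id = 1:2, period = "p",
                       class = "significant")
  s3 <- areaSummary(tabAll, mkUnits(ids))
  expect_equal(s3$areaFraction[s3$class == "significant"], 1)

  sub <- c(`1` = "NA", `2` = "YM")
  s4 <- areaSummary(tab, mkUnits(ids, subregion = sub))
  ym <- s4[s4$scope == "YM", ]
  expect_equal(ym$areaFraction[ym$class == "significant"], 1)
})
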