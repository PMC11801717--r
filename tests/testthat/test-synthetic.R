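test_that("makeUnits tiles the grid into exhaustive rectangular blocks", {
  u <- makeUnits(quietConfig(gridRows = 4, gridCols = 4, nUnits = 4))
  expect_setequal(as.integer(gridValues(u)), 1:4)
  expect_true(all(table(gridValues(u)) == 4))
  # each unit is a 2x2 block: row/col extents both of length 2
  for (id in 1:4) {
    cells <- which(gridValues(u) == id, arr.ind = TRUE)
    expect_equal(diff(range(cells[, 1])), 1)
    expect_equal(diff(range(cells[, 2])), 1)
  }

  u1 <- makeUnits(quietConfig(gridRows = 1, gridCols = 1, nUnits = 1,
                              cellArea = 7))
  expect_equal(unname(unitAreas(u1)), 7)

  u36 <- makeUnits(quietConfig(gridRows = 6, gridCols = 6, nUnits = 4,
                               cellArea = 1))
  expect_equal(sum(unitAreas(u36)), 36)
  expect_false(any(is.na(gridValues(u36))))
})

test_that("makeUnits rejects more units than cells", {
  expect_error(makeUnits(quietConfig(gridRows = 2, gridCols = 2,
                                     nUnits = 5)),
               class = "VegRestore_invalidConfig")
})

test_that("noiseless stacks carry the injected slope exactly", {
  cfg <- quietConfig(trendMean = 0.005, years = 2000:2010)
  s <- simulateStacks(cfg)
  sl <- pixelSlope(s$ndvi, c(2000, 2010))
  expect_true(all(abs(sl - 0.005) < 1e-10))
  # NPP shares the trend scaled by the gain
  slN <- pixelSlope(s$npp, c(2000, 2010))
  expect_true(all(abs(slN - 0.005 * 1000) < 1e-7))
})

test_that("a noiseless break steps the annual mean by its magnitude", {
  cfg <- quietConfig(trendMean = 0, breakYear = 2005,
                     breakMagnitude = 0.04, years = 2000:2010)
  s <- simulateStacks(cfg)
  ser <- regionalSeries(s$ndvi)
  v <- ser@values
  expect_equal(diff(v)[ser@years[-1] == 2005], 0.04, tolerance = 1e-12)
  expect_true(all(abs(diff(v)[ser@years[-1] != 2005]) < 1e-12))
})

test_that("identical configurations give bit-identical stacks", {
  cfg <- scenarioConfig(gridRows = 10, gridCols = 10, nUnits = 4,
                        years = 2000:2005, seed = 42,
                        factorSpecs = noFactors,
                        transitionSpec = noTransitions)
  a <- simulateStacks(cfg)
  b <- simulateStacks(cfg)
  expect_identical(gridValues(a$ndvi), gridValues(b$ndvi))
  expect_identical(gridValues(a$npp), gridValues(b$npp))
})

test_that("noisy unit mean slopes match the design within sampling error", {
  cfg <- scenarioConfig(gridRows = 30, gridCols = 30, nUnits = 4,
                        years = 2000:2020, seed = 5,
                        trendMean = c(0.002, 0.004, -0.001, 0),
                        trendSD = 0.0005, noiseSD = 0.01, baseSD = 0.02,
                        breakYear = NA,
                        factorSpecs = noFactors,
                        transitionSpec = noTransitions)
  s <- simulateStacks(cfg)
  sl <- pixelSlope(s$ndvi, c(2000, 2020))
  for (u in 1:4) {
    est <- mean(sl[gridValues(s$units) == u])  # 225 pixels per unit
    se <- stats::sd(sl[gridValues(s$units) == u]) / sqrt(225)
    expect_lt(abs(est - cfg@trendMean[u]), 4 * se + 1e-6)
  }
})

test_that("designed-q factors reproduce their target q", {
  cfg <- quietConfig(seed = 3)
  set.seed(99)
  y <- stats::setNames(rnorm(500), seq_len(500))
  p <- simulateFactor(cfg, y, list(name = "annual_precipitation",
                                   category = "climate",
                                   designedQ = 0.95, nGroups = 7))
  expect_lt(abs(qOracle(y, strata(p)) - 0.95), 0.0201)
  p0 <- simulateFactor(cfg, y, list(name = "null", category = "other",
                                    designedQ = 0, nGroups = 7))
  expect_lt(qOracle(y, strata(p0)), 0.05)
})

test_that("infeasible factor designs are refused", {
  cfg <- quietConfig()
  y <- stats::setNames(rnorm(5), 1:5)
  expect_error(simulateFactor(cfg, y, list(name = "x", category = "other",
                                           designedQ = 0.5, nGroups = 7)),
               class = "VegRestore_infeasibleSpec")
  y2 <- stats::setNames(rnorm(50), 1:50)
  expect_error(simulateFactor(cfg, y2, list(name = "x", category = "other",
                                            designedQ = 1, nGroups = 5)),
               class = "VegRestore_infeasibleSpec")
})

test_that("land-use generation honours the designed transitions", {
  cfg <- quietConfig(gridRows = 10, gridCols = 10, nUnits = 1,
                     luProportions = c(cropland = 0.5, forest = 0.1,
                                       grassland = 0.3, unused = 0.1),
                     transitionSpec = data.frame(from = "cropland",
                                                 to = "grassland",
                                                 fraction = 0.25))
  lu <- simulateLanduse(cfg)
  expect_equal(sum(lu$t0 == landuseClasses["cropland"] &
                   lu$t1 == landuseClasses["grassland"]), 25)
  expect_equal(lu$realized$cells, 25)
  expect_equal(lu$realized$fraction, 0.25)

  # no transitions: epochs identical
  lu0 <- simulateLanduse(quietConfig())
  expect_identical(lu0$t0, lu0$t1)
})

test_that("transitions exceeding the source class are rejected", {
  expect_error(
    quietConfig(luProportions = c(cropland = 0.2, forest = 0.2,
                                  grassland = 0.4, unused = 0.2),
                transitionSpec = data.frame(from = "cropland",
                                            to = "grassland",
                                            fraction = 0.3)),
    class = "VegRestore_invalidConfig")
})

test_that("afforestation records are reproducible and non-negative", {
  cfg <- quietConfig(seed = 8)
  u <- makeUnits(cfg)
  a1 <- simulateAfforestation(cfg, u)
  a2 <- simulateAfforestation(cfg, u)
  expect_identical(a1, a2)
  expect_true(all(a1$afforested_area_km2 >= 0))
  expect_setequal(unique(a1$unit_id), unitIds(u))
})
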