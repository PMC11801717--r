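test_that("transition and maintenance intensities count conversions", {
  ids <- matrix(1L, 10, 10)
  u <- new("UnitMap", ids = ids, cellArea = 2, subregion = character(0))
  lu0 <- matrix(landuseClasses["cropland"], 10, 10)
  lu1 <- lu0
  lu1[1:25] <- landuseClasses["grassland"]
  expect_equal(unname(transitionIntensity(lu0, lu1, "cropland",
                                          "grassland", u)), 25)
  # identical epochs: zero everywhere
  expect_equal(unname(transitionIntensity(lu0, lu0, "cropland",
                                          "grassland", u)), 0)
  # prior-class denominator
  expect_equal(unname(transitionIntensity(lu0, lu1, "cropland",
                                          "grassland", u,
                                          denominator = "prior")), 25)
  # maintenance: persisting forest share; total loss gives zero
  luF <- matrix(landuseClasses["forest"], 10, 10)
  luF[1:40] <- landuseClasses["cropland"]
  expect_equal(unname(maintenanceIntensity(luF, luF, "forest", u)), 60)
  gone <- matrix(landuseClasses["grassland"], 10, 10)
  expect_equal(unname(maintenanceIntensity(luF, gone, "forest", u)), 0)
  expect_error(transitionIntensity(lu0, matrix(1L, 5, 5), "cropland",
                                   "grassland", u),
               class = "VegRestore_alignment")
})

test_that("generated epochs cross-tabulate exactly to the design", {
  cfg <- quietConfig(gridRows = 12, gridCols = 12, nUnits = 4,
                     luProportions = c(cropland = 0.5, forest = 0.125,
                                       grassland = 0.25, unused = 0.125),
                     transitionSpec = data.frame(
                       from = c("cropland", "unused"),
                       to = c("grassland", "grassland"),
                       fraction = c(0.25, 1 / 9)))
  u <- makeUnits(cfg)
  lu <- simulateLanduse(cfg, u)
  got <- transitionIntensity(lu$t0, lu$t1, "cropland", "grassland", u)
  expect_equal(unname(got), rep(25, 4))
  got2 <- transitionIntensity(lu$t0, lu$t1, "unused", "grassland", u)
  expect_equal(unname(got2), rep(100 / 9, 4))
  # independent oracle: per-unit confusion matrix of the two epochs
  for (id in unitIds(u)) {
    sel <- gridValues(u) == id
    ct <- table(lu$t0[sel], lu$t1[sel])
    expect_equal(100 * ct["1", "3"] / sum(sel), unname(got[as.character(id)]))
  }
  # maintenance + conversions partition each source class
  keepCrop <- maintenanceIntensity(lu$t0, lu$t1, "cropland", u)
  expect_equal(unname(keepCrop + got), rep(50, 4))
})

test_that("afforestation intensity accumulates and normalizes by area", {
  ids <- matrix(rep(1:2, each = 50), 10)
  u <- new("UnitMap", ids = ids, cellArea = 2, subregion = character(0))
  tab <- data.frame(unit_id = rep(1L, 19), year = 2002:2020,
                    afforested_area_km2 = 1)
  out <- afforestationIntensity(tab, u)     # unit area 100 km^2
  expect_equal(unname(out), c(19, 0))
  dup <- rbind(tab, tab[1, ])
  expect_warning(out2 <- afforestationIntensity(dup, u), "duplicate")
  expect_equal(unname(out2[1]), 20)
  bad <- data.frame(unit_id = 9L, year = 2002, afforested_area_km2 = 1)
  err <- tryCatch(afforestationIntensity(bad, u), error = identity)
  expect_s3_class(err, "VegRestore_join")
  expect_match(conditionMessage(err), "9")
})

test_that("zonal aggregation reduces units by mean or sum", {
  ids <- matrix(rep(1:2, each = 8), 4)
  u <- new("UnitMap", ids = ids, cellArea = 1, subregion = character(0))
  r <- matrix(3, 4, 4)
  expect_equal(unname(zonalAggregate(r, u)), c(3, 3))
  chk <- matrix(rep(c(0, 1), 8), 4)
  expect_equal(unname(zonalAggregate(chk, u, "mean")), c(0.5, 0.5))
  expect_equal(unname(zonalAggregate(chk, u, "sum")), c(4, 4))
  # area-weighted unit means reproduce the global mean
  set.seed(6)
  rr <- matrix(rnorm(16), 4)
  zm <- zonalAggregate(rr, u)
  expect_equal(sum(zm * 8) / 16, mean(rr))
})

test_that("Jenks partition is the exact within-class SSD optimum", {
  p <- jenksBreaks(c(a = 1, b = 2, c = 10, d = 11), 2)
  expect_equal(unname(strata(p)), c(1L, 1L, 2L, 2L))
  ssdOf <- function(values, part) {
    sum(tapply(values, strata(part), function(v) sum((v - mean(v))^2)))
  }
  expect_equal(ssdOf(c(1, 2, 10, 11), p), jenksOracle(c(1, 2, 10, 11), 2))

  set.seed(14)
  for (r in 1:30) {
    n <- sample(4:12, 1)
    L <- sample(2:min(5, n - 1), 1)
    x <- round(rnorm(n, 50, 20), 1)
    if (length(unique(x)) < L) next
    part <- jenksBreaks(stats::setNames(x, seq_len(n)), L)
    expect_equal(ssdOf(x, part), jenksOracle(x, L), tolerance = 1e-9)
    # labels increase with value
    expect_true(all(diff(strata(part)[order(x)]) >= 0))
  }
})

test_that("Jenks saturates and refuses infeasible groupings", {
  p <- jenksBreaks(stats::setNames(c(3, 1, 7, 5), 1:4), 4)
  expect_equal(length(unique(strata(p))), 4)
  ss <- tapply(c(3, 1, 7, 5), strata(p), function(v) sum((v - mean(v))^2))
  expect_equal(sum(ss), 0)
  expect_error(jenksBreaks(c(5, 5, 5, 6), 3),
               class = "VegRestore_infeasibleGrouping")
  # tied values always share a class
  pt <- jenksBreaks(stats::setNames(c(1, 1, 1, 2, 2, 9), 1:6), 2)
  expect_equal(unname(strata(pt)), c(1L, 1L, 1L, 1L, 1L, 2L))
})
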