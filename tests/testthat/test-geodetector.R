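test_that("q reproduces the hand variance decomposition", {
  y <- c(1, 1, 2, 2, 5, 5, 6, 6)
  h <- rep(1:2, each = 4)
  d <- factorQ(y, h)
  expect_equal(qValue(d), 1 - 2 / 34, tolerance = 1e-12)
  expect_equal(d@sigma2, 34 / 8)
  expect_equal(d@strata$n, c(4L, 4L))

  # zero within-stratum variance, distinct means: perfect determination
  expect_equal(qValue(factorQ(c(1, 1, 5, 5), c(1, 1, 2, 2))), 1)
  # two identically distributed strata: q = 0
  expect_equal(qValue(factorQ(c(1, 2, 1, 2), c(1, 1, 2, 2))), 0)
})

test_that("q errors on degenerate inputs and drops empty strata", {
  expect_error(factorQ(rep(3, 6), rep(1:2, 3)),
               class = "VegRestore_constantResponse")
  expect_error(factorQ(rnorm(6), rep(1, 6)),
               class = "VegRestore_constantPartition")
  y <- c(1, 2, 3, 4); h <- c(1, 1, 3, 3)    # level 2 empty
  expect_warning(d <- factorQ(y, factor(h, levels = 1:3)), "relabel")
  expect_equal(nrow(d@strata), 2)
  # single-unit strata contribute zero within variance
  d1 <- factorQ(c(1, 2, 9), c(1, 1, 2))
  expect_equal(qValue(d1), qOracle(c(1, 2, 9), c(1, 1, 2)),
               tolerance = 1e-12)
})

test_that("q significance holds its level and its limits", {
  # Monte-Carlo type-I error of the noncentral-F transformation
  set.seed(25)
  rej <- 0L
  reps <- 1000L
  for (r in seq_len(reps)) {
    y <- rnorm(500)
    h <- sample(rep(1:7, length.out = 500))
    if (pValue(factorQ(y, h)) < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / reps - 0.05), 0.02)

  expect_equal(pValue(factorQ(c(1, 1, 5, 5), c(1, 1, 2, 2))), 0)
  # monotone: larger q at fixed N, L gives smaller p
  y <- c(1, 2, 3, 10, 11, 12)
  pStrong <- pValue(factorQ(y, c(1, 1, 1, 2, 2, 2)))
  pWeak <- pValue(factorQ(y, c(1, 2, 1, 2, 1, 2)))
  expect_lt(pStrong, pWeak)
})

test_that("main-factor selection keeps the significant top half by q", {
  tab <- data.frame(
    factor = c("annual_precipitation", "gdp", "afforestation_intensity",
               "farmland_to_grassland", "population_density",
               "annual_temperature", "slope", "unused_to_grassland",
               "maintain_grassland", "altitude", "maintain_forest",
               "soil_organic_carbon", "soil_clay", "soil_moisture"),
    q = c(0.75, 0.61, 0.57, 0.57, 0.56, 0.42, 0.27, 0.26, 0.22, 0.20,
          0.19, 0.05, 0.04, 0.03),
    p = 0.001)
  sel <- selectMainFactors(tab)
  expect_equal(nrow(sel), 7)
  expect_setequal(sel$factor,
                  c("annual_precipitation", "gdp",
                    "afforestation_intensity", "farmland_to_grassland",
                    "population_density", "annual_temperature", "slope"))
  expect_equal(sel$factor[1], "annual_precipitation")

  tab$p <- 0.5
  expect_equal(nrow(selectMainFactors(tab)), 0)
  two <- data.frame(factor = c("a", "b"), q = c(0.3, 0.6), p = 0.01)
  expect_equal(selectMainFactors(two)$factor, "b")
})

test_that("interaction q refines and classifies against the singles", {
  set.seed(33)
  y <- rnorm(200)
  mk <- function(h, nm) new("FactorPartition", factorName = nm,
                            category = "other",
                            values = stats::setNames(as.numeric(h),
                                                     seq_along(h)),
                            stratum = stats::setNames(as.integer(h),
                                                      seq_along(h)),
                            breaks = numeric(0))
  names(y) <- seq_along(y)
  hA <- sample(1:4, 200, TRUE)
  iSame <- interactionQ(y, mk(hA, "A"), mk(hA, "A"))
  expect_equal(iSame@qAB, iSame@qA, tolerance = 1e-12)

  # XOR-style joint determination: neither factor alone explains y
  hB <- sample(1:2, 200, TRUE)
  hA2 <- sample(1:2, 200, TRUE)
  yx <- as.numeric(xor(hA2 == 2, hB == 2))
  names(yx) <- seq_along(yx)
  ix <- interactionQ(yx, mk(hA2, "A"), mk(hB, "B"))
  expect_equal(ix@qAB, 1)
  expect_gt(ix@qAB, ix@qA + ix@qB)
  expect_equal(ix@type, "enhance-nonlinear")
  expect_equal(ix@qAB, qOracle(yx, paste(hA2, hB)), tolerance = 1e-12)
})

test_that("risk detection ranks strata and tests their differences", {
  set.seed(41)
  h <- rep(1:4, each = 30)
  y <- rnorm(120, mean = h)          # means rise with the stratum
  part <- new("FactorPartition", factorName = "annual_precipitation",
              category = "climate",
              values = stats::setNames(h + runif(120, -0.2, 0.2),
                                       seq_len(120)),
              stratum = stats::setNames(as.integer(h), seq_len(120)),
              breaks = numeric(0))
  names(y) <- seq_len(120)
  r <- riskDetect(y, part)
  expect_equal(r@argmaxStratum, 4L)
  expect_true(all(diff(r@strata$mean) > 0))
  expect_lt(r@tMatrix["1", "4"], 0.05)
  expect_equal(r@argmaxRange[1], min(part@values[h == 4]))

  # equal-mean strata are rarely declared different
  y0 <- rnorm(200); h0 <- rep(1:2, each = 100)
  part0 <- new("FactorPartition", factorName = "flat", category = "other",
               values = stats::setNames(rnorm(200), seq_len(200)),
               stratum = stats::setNames(as.integer(h0), seq_len(200)),
               breaks = numeric(0))
  names(y0) <- seq_len(200)
  r0 <- riskDetect(y0, part0)
  expect_gt(r0@tMatrix["1", "2"], 0.001)

  # single-unit strata are excluded from testing but kept in the table
  y1 <- c(1, 2, 3, 9); h1 <- c(1, 1, 1, 2)
  p1 <- new("FactorPartition", factorName = "tiny", category = "other",
            values = stats::setNames(as.numeric(h1), 1:4),
            stratum = stats::setNames(as.integer(h1), 1:4),
            breaks = numeric(0))
  r1 <- riskDetect(stats::setNames(y1, 1:4), p1)
  expect_false(r1@strata$tested[2])
  expect_true(is.na(r1@tMatrix["1", "2"]))
  expect_equal(r1@argmaxStratum, 2L)
})

test_that("q is invariant to affine response transforms", {
  set.seed(55)
  for (r in 1:20) {
    y <- rnorm(40)
    h <- sample(1:4, 40, TRUE)
    a <- runif(1, -5, 5); if (abs(a) < 0.1) a <- 1
    b <- runif(1, -10, 10)
    expect_equal(qValue(factorQ(y, h, significance = FALSE)),
                 qValue(factorQ(a * y + b, h, significance = FALSE)),
                 tolerance = 1e-10)
  }
})
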