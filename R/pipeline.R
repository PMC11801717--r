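#' Validate a bundle of pipeline inputs
#'
#' Pure checks, no mutation: grid alignment of stacks, unit map and
#' land-use epochs; coverage of the analysis periods by the stack years;
#' land-use class codes; resolvability of afforestation unit ids. Returns
#' a data.frame of issues, empty when everything is consistent.
#'
#' @param ndvi,npp \linkS4class{AnnualStack}s (either may be NULL).
#' @param units a \linkS4class{UnitMap} or NULL.
#' @param landuse list with matrices \code{t0}, \code{t1}, or NULL.
#' @param afforestation data.frame or NULL.
#' @param periods list of (start, end) pairs to check coverage for.
#' @return data.frame (stage, message); zero rows means valid.
#' @export
validateInputs <- function(ndvi = NULL, npp = NULL, units = NULL,
                           landuse = NULL, afforestation = NULL,
                           periods = list()) {
  issues <- list()
  note <- function(stage, msg)
    issues[[length(issues) + 1L]] <<- data.frame(stage = stage,
                                                 message = msg)
  dims <- list()
  if (!is.null(ndvi)) dims$ndvi <- dim(ndvi@values)[1:2]
  if (!is.null(npp)) dims$npp <- dim(npp@values)[1:2]
  if (!is.null(units)) dims$units <- dim(units@ids)
  if (!is.null(landuse)) {
    dims$landuse_t0 <- dim(landuse$t0)
    dims$landuse_t1 <- dim(landuse$t1)
  }
  if (length(dims) > 1L) {
    ref <- dims[[1]]
    for (nm in names(dims)[-1])
      if (!identical(dims[[nm]], ref))
        note("alignment", sprintf("grid of '%s' (%s) differs from '%s' (%s)",
             nm, paste(dims[[nm]], collapse = "x"),
             names(dims)[1], paste(ref, collapse = "x")))
  }
  if (!is.null(ndvi) && !is.null(npp) &&
      !identical(ndvi@years, npp@years))
    note("alignment", "NDVI and NPP stacks cover different years")
  if (!is.null(ndvi))
    for (p in periods)
      if (!all(p %in% ndvi@years))
        note("coverage", sprintf("period %d-%d not covered by stack years",
                                 p[1], p[2]))
  if (!is.null(landuse)) {
    codes <- unique(c(landuse$t0, landuse$t1))
    bad <- setdiff(codes[!is.na(codes)], unname(landuseClasses))
    if (length(bad))
      note("landuse", sprintf("unknown land-use class code(s): %s",
                              paste(bad, collapse = ", ")))
  }
  if (!is.null(afforestation) && !is.null(units)) {
    unknown <- setdiff(unique(afforestation$unit_id), unitIds(units))
    if (length(unknown))
      note("join", sprintf("afforestation rows with unknown unit id(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  if (!length(issues))
    return(data.frame(stage = character(0), message = character(0)))
  do.call(rbind, issues)
}

#' Simulate every input of a study scenario
#'
#' One call producing the complete, internally consistent input bundle:
#' unit map, NDVI and NPP stacks, two land-use epochs, an afforestation
#' record, and -- once an effectiveness response is available -- designed
#' factor partitions (those are created later by
#' \code{\link{runPipeline}} because their ground-truth q is defined
#' against the computed effectiveness).
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param outDir optional directory; when given, all inputs are written
#'   (ASCII rasters, CSV, YAML).
#' @return list (config, units, ndvi, npp, landuse, afforestation,
#'   unitSlopes).
#' @export
simulateScenario <- function(config, outDir = NULL) {
  units <- makeUnits(config)
  stacks <- simulateStacks(config, units)
  landuse <- simulateLanduse(config, units)
  aff <- simulateAfforestation(config, units)
  bundle <- list(config = config, units = units,
                 ndvi = stacks$ndvi, npp = stacks$npp,
                 landuse = landuse, afforestation = aff,
                 unitSlopes = stacks$unitSlopes)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeScenarioYaml(config, file.path(outDir, "scenario.yaml"))
    writeUnitsAsc(units, file.path(outDir, "units.asc"))
    writeStackAsc(stacks$ndvi, outDir, "ndvi")
    writeStackAsc(stacks$npp, outDir, "npp")
    cs <- sqrt(config@cellArea)
    writeAsc(landuse$t0, file.path(outDir, "landuse_t0.asc"),
             cellsize = cs)
    writeAsc(landuse$t1, file.path(outDir, "landuse_t1.asc"),
             cellsize = cs)
    utils::write.csv(aff, file.path(outDir, "afforestation.csv"),
                     row.names = FALSE)
  }
  bundle
}

.engineeringFactors <- function(bundle, nGroups = 6L) {
  lu <- bundle$landuse; units <- bundle$units
  vals <- list(
    farmland_to_grassland =
      transitionIntensity(lu$t0, lu$t1, "cropland", "grassland", units),
    unused_to_grassland =
      transitionIntensity(lu$t0, lu$t1, "unused", "grassland", units),
    maintain_forest =
      maintenanceIntensity(lu$t0, lu$t1, "forest", units),
    maintain_grassland =
      maintenanceIntensity(lu$t0, lu$t1, "grassland", units),
    afforestation_intensity =
      afforestationIntensity(bundle$afforestation, units))
  out <- list()
  for (nm in names(vals)) {
    L <- min(nGroups, length(unique(vals[[nm]][!is.na(vals[[nm]])])))
    if (L >= 2L)
      out[[nm]] <- jenksBreaks(vals[[nm]], L, factorName = nm,
                               category = "engineering")
  }
  out
}

#' Run the full restoration-effectiveness pipeline on a scenario
#'
#' simulate -> indices -> per-pixel trends -> county effectiveness ->
#' driver factors -> Geodetector attribution. The stages are: (1) FVC
#' from NDVI (dimidiate pixel model), global min-max normalization of
#' FVC and NPP, VQQI; (2) regional annual series with its linear trend
#' and Pettitt change point; (3) per-pixel slope, F-test and grading for
#' each period; (4) grade area fractions, net change, baseline and
#' effectiveness classes per county; (5) designed factor partitions for
#' every configured factor (ground-truth q against the final-period
#' effectiveness) plus engineering intensities derived from the simulated
#' land-use epochs and afforestation record; (6) factor detection, main
#' -factor selection, interactions among main factors, and risk detection
#' for the strongest factor. Reruns of the same configuration are
#' bit-identical.
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param outDir optional output directory; when given, all tables,
#'   reports, rasters and a manifest with content hashes are written.
#' @param periods analysis periods; the first is the baseline.
#' @param normScope normalization scope, \code{"global"} or
#'   \code{"annual"}.
#' @param soilPct,vegPct dimidiate-model endmember percentiles.
#' @param thresholds trend-significance thresholds.
#' @param alpha significance level of the Geodetector tests.
#' @return list with elements config, bundle, vqqiStack, series,
#'   effectiveness, summary, factors (designed + derived partitions),
#'   detections (data.frame), mainFactors, interactions, risk, manifest.
#' @export
runPipeline <- function(config, outDir = NULL,
                        periods = list(c(2000, 2010), c(2000, 2015),
                                       c(2000, 2020)),
                        normScope = c("global", "annual"),
                        soilPct = 5, vegPct = 95,
                        thresholds = c(0.01, 0.05), alpha = 0.05) {
  normScope <- match.arg(normScope)
  periods <- lapply(periods, function(p) {
    p <- as.integer(p)
    c(max(p[1], min(config@years)), min(p[2], max(config@years)))
  })
  bundle <- simulateScenario(config, outDir)
  issues <- validateInputs(bundle$ndvi, bundle$npp, bundle$units,
                           bundle$landuse, bundle$afforestation, periods)
  if (nrow(issues))
    .vrStop(paste0("invalid inputs: ",
                   paste(issues$stage, issues$message, collapse = "; ")),
            "VegRestore_validation")
  fvc <- fvcFromNdvi(bundle$ndvi, soilPct, vegPct)
  vq <- vqqi(normalizeStack(fvc, normScope),
             normalizeStack(bundle$npp, normScope))
  series <- detectChange(regionalSeries(vq))
  eff <- effectivenessTable(vq, bundle$units, periods,
                            thresholds = thresholds)
  summ <- areaSummary(eff, bundle$units)
  lastLab <- sprintf("%d-%d", periods[[length(periods)]][1],
                     periods[[length(periods)]][2])
  final <- eff[eff$period == lastLab, , drop = FALSE]
  y <- final$Et
  names(y) <- final$unit_id

  fs <- config@factorSpecs
  factors <- list()
  if (nrow(fs))
    for (i in seq_len(nrow(fs)))
      factors[[fs$name[i]]] <-
        simulateFactor(config, y, fs[i, , drop = FALSE], index = i)
  derived <- .engineeringFactors(bundle)
  names(derived) <- paste0("derived_", names(derived))

  detections <- lapply(factors, function(p) factorQ(y, p))
  detTab <- data.frame(
    factor = vapply(detections, function(d) d@factorName, ""),
    category = vapply(factors, function(p) p@category, ""),
    designedQ = if (nrow(fs)) fs$designedQ else numeric(0),
    q = vapply(detections, function(d) d@q, 0),
    p = vapply(detections, function(d) d@p, 0),
    row.names = NULL)
  main <- if (nrow(detTab)) selectMainFactors(detTab, alpha)
          else detTab[, c("factor", "q", "p")]
  interactions <- list()
  if (nrow(main) >= 2L) {
    pairs <- utils::combn(main$factor, 2L)
    for (k in seq_len(ncol(pairs)))
      interactions[[paste(pairs[, k], collapse = " x ")]] <-
        interactionQ(y, factors[[pairs[1, k]]], factors[[pairs[2, k]]])
  }
  risk <- if (nrow(main)) riskDetect(y, factors[[main$factor[1]]], alpha)
          else NULL

  result <- list(config = config, bundle = bundle, vqqiStack = vq,
                 series = series, effectiveness = eff, summary = summ,
                 factors = c(factors, derived), detections = detTab,
                 mainFactors = main, interactions = interactions,
                 risk = risk, manifest = NULL)
  if (!is.null(outDir)) result$manifest <- .writeOutputs(result, outDir)
  result
}

.writeOutputs <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeStackAsc(result$vqqiStack, outDir, "vqqi")
  utils::write.csv(data.frame(year = result$series@years,
                              value = result$series@values),
                   file.path(outDir, "vqqi_series.csv"),
                   row.names = FALSE)
  eff <- result$effectiveness
  utils::write.csv(eff, file.path(outDir, "effectiveness.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summary, file.path(outDir, "area_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$detections,
                   file.path(outDir, "factor_detections.csv"),
                   row.names = FALSE)
  ints <- result$interactions
  if (length(ints))
    utils::write.csv(data.frame(
      pair = names(ints),
      qA = vapply(ints, function(i) i@qA, 0),
      qB = vapply(ints, function(i) i@qB, 0),
      qAB = vapply(ints, function(i) i@qAB, 0),
      type = vapply(ints, function(i) i@type, "")),
      file.path(outDir, "interactions.csv"), row.names = FALSE)
  report <- list(
    baseline = attr(eff, "baseline"),
    changeYear = result$series@changeYear,
    changeP = result$series@changeP,
    trendSlope = result$series@trendSlope,
    mainFactors = result$mainFactors$factor)
  if (!is.null(result$risk))
    report$risk <- list(factor = result$risk@factorName,
                        argmaxStratum = result$risk@argmaxStratum,
                        argmaxRange = result$risk@argmaxRange)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package = as.character(utils::packageVersion("VegRestore")),
    seed = result$config@seed,
    configHash = unname(tools::md5sum(file.path(outDir,
                                                "scenario.yaml"))),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(outDir, files))), files)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}
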