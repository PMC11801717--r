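#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text single-band raster with the standard 6-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#' by rows of values, north row first.
#'
#' @param mat numeric matrix (row 1 = northernmost row).
#' @param file output path.
#' @param cellsize cell edge length (map units).
#' @param xll,yll lower-left corner coordinates.
#' @param nodata value written for \code{NA} cells.
#' @return invisibly, the file path.
#' @export
writeAsc <- function(mat, file, cellsize = 1, xll = 0, yll = 0,
                     nodata = -9999) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               sprintf("xllcorner %.10g", xll),
               sprintf("yllcorner %.10g", yll),
               sprintf("cellsize %.10g", cellsize),
               sprintf("NODATA_value %.10g", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(format(m, trim = TRUE, digits = 15,
                            scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Read an ESRI ASCII raster
#'
#' @param file path to a \code{.asc} file.
#' @return list with \code{values} (numeric matrix, \code{NA} for
#'   no-data), \code{cellsize}, \code{xll}, \code{yll}.
#' @export
readAsc <- function(file) {
  hdr <- readLines(file, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1]); val <- as.numeric(kv[, 2])
  names(val) <- key
  m <- as.matrix(utils::read.table(file, skip = 6L))
  dimnames(m) <- NULL
  if (!is.na(val["nodata_value"]))
    m[m == val["nodata_value"]] <- NA_real_
  list(values = m, cellsize = unname(val["cellsize"]),
       xll = unname(val["xllcorner"]), yll = unname(val["yllcorner"]))
}

#' Write an AnnualStack as one ASCII raster per year
#'
#' Files are named \code{<prefix>_<year>.asc} inside \code{dir}.
#'
#' @param stack an \linkS4class{AnnualStack}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the variable name.
#' @return invisibly, the vector of file paths.
#' @export
writeStackAsc <- function(stack, dir, prefix = varName(stack)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cs <- sqrt(stack@cellArea)
  paths <- character(length(stack@years))
  for (k in seq_along(stack@years)) {
    paths[k] <- file.path(dir, sprintf("%s_%d.asc", prefix,
                                       stack@years[k]))
    writeAsc(stack@values[, , k], paths[k], cellsize = cs)
  }
  invisible(paths)
}

#' Read an AnnualStack from per-year ASCII rasters
#'
#' @param files paths of \code{.asc} files, one per year, in year order.
#' @param years integer calendar years matching \code{files}.
#' @param varname variable name for the stack.
#' @return an \linkS4class{AnnualStack}; the cell area is recovered from
#'   the cell size (assumed square, in km).
#' @export
readStackAsc <- function(files, years, varname = "index") {
  if (length(files) != length(years))
    .vrStop("one file per year required", "VegRestore_invalidConfig")
  first <- readAsc(files[1])
  vals <- array(NA_real_, c(dim(first$values), length(files)))
  vals[, , 1] <- first$values
  for (k in seq_along(files)[-1]) {
    r <- readAsc(files[k])
    if (!identical(dim(r$values), dim(first$values)))
      .vrStop("raster grids differ across years", "VegRestore_alignment")
    vals[, , k] <- r$values
  }
  annualStack(vals, years, varname, cellArea = first$cellsize^2)
}

#' Write and read a unit map
#'
#' The tessellation travels as a labeled ASCII raster plus an optional
#' sub-region CSV (\code{unit_id, subregion}) next to it.
#'
#' @param units a \linkS4class{UnitMap}.
#' @param file path of the \code{.asc} file.
#' @return invisibly, the file path.
#' @export
writeUnitsAsc <- function(units, file) {
  writeAsc(units@ids, file, cellsize = sqrt(units@cellArea))
  if (length(units@subregion))
    utils::write.csv(data.frame(unit_id = as.integer(names(units@subregion)),
                                subregion = unname(units@subregion)),
                     sub("\\.asc$", "_subregions.csv", file),
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writeUnitsAsc
#' @param file path of the \code{.asc} file written by
#'   \code{writeUnitsAsc}.
#' @export
readUnitsAsc <- function(file) {
  r <- readAsc(file)
  ids <- r$values
  storage.mode(ids) <- "integer"
  subFile <- sub("\\.asc$", "_subregions.csv", file)
  sub <- character(0)
  if (file.exists(subFile)) {
    tab <- utils::read.csv(subFile, colClasses = c("integer", "character"),
                           na.strings = character(0))
    sub <- tab$subregion
    names(sub) <- as.character(tab$unit_id)
  }
  new("UnitMap", ids = ids, cellArea = r$cellsize^2, subregion = sub)
}

#' Serialize / restore a scenario configuration as YAML
#'
#' @param config a \linkS4class{ScenarioConfig}.
#' @param file output path.
#' @return \code{writeScenarioYaml} invisibly returns the path;
#'   \code{readScenarioYaml} returns the restored
#'   \linkS4class{ScenarioConfig}.
#' @export
writeScenarioYaml <- function(config, file) {
  lst <- list(
    gridRows = config@gridRows, gridCols = config@gridCols,
    cellArea = config@cellArea, years = config@years,
    nUnits = config@nUnits, seed = config@seed,
    baseNdvi = config@baseNdvi, baseSD = config@baseSD,
    baseNpp = config@baseNpp, nppGain = config@nppGain,
    trendMean = config@trendMean,
    trendDrawMean = config@trendDrawMean,
    trendDrawSD = config@trendDrawSD,
    trendSD = config@trendSD, noiseSD = config@noiseSD,
    breakYear = config@breakYear,
    breakMagnitude = config@breakMagnitude,
    factorSpecs = as.list(config@factorSpecs),
    luProportions = as.list(config@luProportions),
    transitionSpec = as.list(config@transitionSpec))
  yaml::write_yaml(lst, file, precision = 15L)
  invisible(file)
}

#' @rdname writeScenarioYaml
#' @export
readScenarioYaml <- function(file) {
  lst <- yaml::read_yaml(file)
  scenarioConfig(
    gridRows = lst$gridRows, gridCols = lst$gridCols,
    cellArea = lst$cellArea, years = unlist(lst$years),
    nUnits = lst$nUnits, seed = lst$seed,
    baseNdvi = lst$baseNdvi, baseSD = lst$baseSD,
    baseNpp = lst$baseNpp, nppGain = lst$nppGain,
    trendMean = if (is.null(lst$trendMean)) NA_real_
                else unlist(lst$trendMean),
    trendDrawMean = lst$trendDrawMean, trendDrawSD = lst$trendDrawSD,
    trendSD = lst$trendSD, noiseSD = lst$noiseSD,
    breakYear = if (is.null(lst$breakYear)) NA_integer_
                else lst$breakYear,
    breakMagnitude = lst$breakMagnitude,
    factorSpecs = as.data.frame(lst$factorSpecs,
                                stringsAsFactors = FALSE),
    luProportions = unlist(lst$luProportions),
    transitionSpec = as.data.frame(lst$transitionSpec,
                                   stringsAsFactors = FALSE))
}
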