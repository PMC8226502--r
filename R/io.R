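# File formats: run tables, chromatograms, model JSON, design-space and
# robustness CSVs, working-point JSON, project configuration.
# Convention: %B (percent) in all user-facing files, organic fraction
# internally; report CSVs round times and resolutions to 2 decimals.

.RUNTABLE_HEADER <- c("run_id", "tG_min", "T_C", "pH", "flow_mL_min",
                      "pctB_start", "pctB_end", "compound_id", "tR_min")

#' Validate a run table
#'
#' Checks the column contract and that each (run, compound) pair appears at
#' most once. Called by [fitModel()] and [readRunTable()].
#'
#' @param runs run-table data.frame
#' @return the run table, invisibly
#' @export
validateRunTable <- function(runs) {
  if (!all(.RUNTABLE_HEADER %in% names(runs)))
    chromqbdError(paste("run table must have columns",
                        paste(.RUNTABLE_HEADER, collapse = ",")),
                  "chromqbd_parse_error")
  key <- paste(runs$run_id, runs$compound_id)
  if (anyDuplicated(key))
    chromqbdError(sprintf("duplicate (run, compound) entry: %s",
                          key[anyDuplicated(key)]),
                  "chromqbd_input_error")
  invisible(runs)
}

#' Read a run table CSV
#'
#' Expects the exact header `run_id,tG_min,T_C,pH,flow_mL_min,pctB_start,
#' pctB_end,compound_id,tR_min` (UTF-8, '.' decimal separator). Blank
#' `tR_min` cells become missing peaks (NA). Malformed headers or
#' non-numeric cells raise a parse error naming the line.
#'
#' @param path CSV file path
#' @return validated run-table data.frame
#' @export
readRunTable <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  if (!identical(names(raw), .RUNTABLE_HEADER))
    chromqbdError(sprintf(
      "line 1: malformed header (expected %s)",
      paste(.RUNTABLE_HEADER, collapse = ",")),
      "chromqbd_parse_error")
  numcols <- setdiff(.RUNTABLE_HEADER, c("run_id", "compound_id"))
  for (col in numcols) {
    v <- raw[[col]]
    blank <- !nzchar(v)
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !blank)
    if (length(bad))
      chromqbdError(sprintf("line %d: non-numeric value '%s' in column %s",
                            bad[1] + 1L, v[bad[1]], col),
                    "chromqbd_parse_error")
    if (col != "tR_min" && any(blank))
      chromqbdError(sprintf("line %d: blank value in column %s",
                            which(blank)[1] + 1L, col),
                    "chromqbd_parse_error")
    raw[[col]] <- num
  }
  validateRunTable(raw)
  raw
}

#' Write a run table CSV
#'
#' Missing peaks (NA retention) are written as blank cells, matching
#' [readRunTable()].
#'
#' @param runs run-table data.frame
#' @param path output path
#' @export
writeRunTable <- function(runs, path) {
  validateRunTable(runs)
  write.csv(runs[.RUNTABLE_HEADER], path, row.names = FALSE, na = "",
            quote = FALSE)
  invisible(path)
}

#' Export a chromatogram peak table
#'
#' CSV with header `compound_id,tR_min,sigma_min,area`. Internally times
#' are rounded to 4 decimals; in report mode to 2 decimals (half-up, the
#' precision of printed retention tables).
#'
#' @param chrom a [Chromatogram-class]
#' @param path output path
#' @param report round times to 2 decimals instead of 4
#' @export
writeChromatogram <- function(chrom, path, report = FALSE) {
  p <- chrom@peaks
  dg <- if (report) 2 else 4
  p$tR_min <- roundHalfUp(p$tR_min, dg)
  p$sigma_min <- roundHalfUp(p$sigma_min, if (report) 4 else 6)
  write.csv(p[c("compound_id", "tR_min", "sigma_min", "area")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a fitted model to JSON
#'
#' Full-precision floats; round-trips through [readFittedModel()].
#'
#' @param model a [FittedModel-class]
#' @param path output path
#' @export
writeFittedModel <- function(model, path) {
  d <- model@design
  obj <- list(
    compounds = model@compounds,
    T_levels = model@TLevels, pH_levels = model@pHLevels,
    log_kw = model@logKw, S = model@S,
    fitted = model@fitted, residual = model@residual,
    design = list(tG_levels = d@tGLevels, T_levels = d@TLevels,
                  pH_levels = d@pHLevels, flow_mL_min = d@flow,
                  pctB_start = 100 * d@phiStart, pctB_end = 100 * d@phiEnd))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path a file written by [writeFittedModel()]
#' @return a [FittedModel-class]
#' @export
readFittedModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$design
  design <- calibrationDesign(d$tG_levels, d$T_levels, d$pH_levels,
                              d$flow_mL_min, d$pctB_start / 100,
                              d$pctB_end / 100)
  dims <- c(length(obj$compounds), length(obj$T_levels),
            length(obj$pH_levels))
  arr <- function(x)
    array(as.numeric(x), dims, dimnames = list(obj$compounds, NULL, NULL))
  new("FittedModel", compounds = obj$compounds, TLevels = obj$T_levels,
      pHLevels = obj$pH_levels, logKw = arr(obj$log_kw),
      S = arr(obj$S), fitted = array(as.logical(obj$fitted), dims,
                                     dimnames = list(obj$compounds, NULL, NULL)),
      residual = arr(obj$residual), design = design)
}

#' Export a design-space map to CSV
#'
#' Long format `tG_min,T_C,pH,Rs_crit,crit_pair`, resolution rounded to 2
#' decimals in report mode and written at full precision otherwise.
#'
#' @param dsmap a [DesignSpaceMap-class]
#' @param path output path
#' @param report round Rs_crit to 2 decimals
#' @export
writeDesignSpaceMap <- function(dsmap, path, report = FALSE) {
  tab <- as.data.frame(dsmap)
  if (report) tab$Rs_crit <- roundHalfUp(tab$Rs_crit, 2)
  write.csv(tab, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a design-space map from CSV
#'
#' Rebuilds the grid from the long table. The returned map carries no
#' model, so it supports [findRobustWorkingPoint()] but not
#' [extractSubspace()].
#'
#' @param path CSV written by [writeDesignSpaceMap()]
#' @param criterion resolution criterion to attach (default 2.0)
#' @return a [DesignSpaceMap-class]
#' @export
readDesignSpaceMap <- function(path, criterion = 2.0) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("tG_min", "T_C", "pH", "Rs_crit", "crit_pair")
  if (!all(need %in% names(tab)))
    chromqbdError("malformed design-space CSV", "chromqbd_parse_error")
  tG <- sort(unique(tab$tG_min)); T_C <- sort(unique(tab$T_C))
  pH <- sort(unique(tab$pH))
  d <- c(length(tG), length(T_C), length(pH))
  if (nrow(tab) != prod(d))
    chromqbdError("design-space CSV is not a complete grid",
                  "chromqbd_parse_error")
  Rs <- array(NA_real_, d); p1 <- array(NA_character_, d)
  p2 <- array(NA_character_, d)
  gi <- match(tab$tG_min, tG); ti <- match(tab$T_C, T_C)
  pi <- match(tab$pH, pH)
  lin <- gi + d[1] * (ti - 1L) + d[1] * d[2] * (pi - 1L)
  Rs[lin] <- tab$Rs_crit
  pair <- strsplit(as.character(tab$crit_pair), "-", fixed = TRUE)
  p1[lin] <- vapply(pair, function(x) if (length(x) == 2L) x[1] else
    NA_character_, character(1))
  p2[lin] <- vapply(pair, function(x) if (length(x) == 2L) x[2] else
    NA_character_, character(1))
  new("DesignSpaceMap", tG = tG, temperature = T_C, pH = pH, Rs = Rs,
      pairFirst = p1, pairSecond = p2, criterion = criterion,
      model = NULL, instrument = NULL, flow = 0.8, phiStart = 0.1,
      phiEnd = 0.8)
}

#' Export a robustness result to CSV
#'
#' One row per combination: index, the six level indices, the six realised
#' factor values, the critical resolution (2 decimals in report mode) and
#' the critical pair. Deterministic: re-running the same study writes the
#' identical file byte for byte.
#'
#' @param result a [RobustnessResult-class]
#' @param path output path
#' @param report round Rs_crit to 2 decimals
#' @export
writeRobustnessResult <- function(result, path, report = FALSE) {
  tab <- result@table
  if (report) tab$Rs_crit <- roundHalfUp(tab$Rs_crit, 2)
  cols <- c("index", paste0("lvl_", .factorOrder), .factorOrder,
            "Rs_crit", "crit_pair")
  write.csv(tab[cols], path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Export a working point to JSON
#'
#' @param wp a [WorkingPoint-class]
#' @param path output path
#' @export
writeWorkingPoint <- function(wp, path) {
  c0 <- wp@conditions
  jsonlite::write_json(list(
    tG_min = c0@tG, T_C = c0@temperature, pH = c0@pH,
    flow_mL_min = c0@flow, pctB_start = 100 * c0@phiStart,
    pctB_end = 100 * c0@phiEnd, Rs_crit = wp@RsCrit,
    crit_pair = paste(wp@pair, collapse = "-"),
    robustness_radius = wp@radius),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

.CONFIG_KEYS <- list(
  instrument = c("dead_volume_mL", "dwell_volume_mL", "plate_number",
                 "max_pressure_bar"),
  calibration = c("tG_levels", "T_levels", "pH_levels", "flow_mL_min",
                  "pctB_start", "pctB_end"),
  robustness = c("tG_min", "T_C", "pH", "flow_mL_min", "pctB_start",
                 "pctB_end"),
  criterion = NULL, precision = NULL)

#' Read and validate a project configuration
#'
#' YAML or JSON (by extension) with blocks `instrument`, `calibration`,
#' `robustness`, and scalars `criterion` and `precision`. All entries are
#' optional and default to the packaged method settings; unknown keys are
#' rejected.
#'
#' @param path config file (.yaml/.yml or .json)
#' @return list with `instrument` ([InstrumentConfig-class]), `design`
#'   ([CalibrationDesign-class]), `levels` ([FactorLevels-class]),
#'   `criterion`, `precision`
#' @export
readProjectConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else chromqbdError("config must be .yaml/.yml or .json",
                     "chromqbd_config_error")
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), names(.CONFIG_KEYS))
  if (length(unknown))
    chromqbdError(sprintf("unknown config key(s): %s",
                          paste(unknown, collapse = ", ")),
                  "chromqbd_config_error")
  for (blk in c("instrument", "calibration", "robustness")) {
    bad <- setdiff(names(cfg[[blk]]), .CONFIG_KEYS[[blk]])
    if (length(bad))
      chromqbdError(sprintf("unknown key(s) in %s block: %s", blk,
                            paste(bad, collapse = ", ")),
                    "chromqbd_config_error")
  }
  g <- function(blk, key, default)
    if (!is.null(cfg[[blk]][[key]])) cfg[[blk]][[key]] else default
  instr <- instrumentConfig(
    dead_volume_mL = g("instrument", "dead_volume_mL", 0.110),
    dwell_volume_mL = g("instrument", "dwell_volume_mL", 0.12),
    plate_number = g("instrument", "plate_number", 4350),
    max_pressure_bar = g("instrument", "max_pressure_bar", 1000))
  design <- calibrationDesign(
    tG_levels = g("calibration", "tG_levels", c(1.5, 4.5)),
    T_levels = g("calibration", "T_levels", c(20, 50)),
    pH_levels = g("calibration", "pH_levels", c(2.8, 4.6, 6.4)),
    flow_mL_min = g("calibration", "flow_mL_min", 0.8),
    phi_start = g("calibration", "pctB_start", 10) / 100,
    phi_end = g("calibration", "pctB_end", 80) / 100)
  levels <- factorLevels(
    tG_min = g("robustness", "tG_min", c(2.7, 3.0, 3.3)),
    T_C = g("robustness", "T_C", c(38, 40, 42)),
    pH = g("robustness", "pH", c(5.8, 6.0, 6.2)),
    flow_mL_min = g("robustness", "flow_mL_min", c(0.72, 0.80, 0.88)),
    pctB_start = g("robustness", "pctB_start", c(9, 10, 11)),
    pctB_end = g("robustness", "pctB_end", c(79, 80, 81)))
  list(instrument = instr, design = design, levels = levels,
       criterion = if (!is.null(cfg$criterion)) cfg$criterion else 2.0,
       precision = if (!is.null(cfg$precision)) cfg$precision else 2L)
}
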