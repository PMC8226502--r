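#' @import methods
#' @importFrom stats integrate rnorm setNames uniroot
#' @importFrom utils read.csv write.csv
NULL

# condition helpers: every user-facing failure carries a subclass so callers
# (and the CLI) can discriminate programmatically
chromqbdError <- function(msg, class) {
  stop(structure(
    class = c(class, "chromqbd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

chromqbdWarning <- function(msg, class) {
  warning(structure(
    class = c(class, "chromqbd_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.allFinite <- function(...) all(vapply(list(...), function(x) all(is.finite(x)), logical(1)))

#' Instrument configuration
#'
#' Holds the system constants of the UHPLC instrument and column: the column
#' hold-up (dead) volume, the gradient delay (dwell) volume between the mixer
#' and the column inlet, and the apparent plate number used for peak-width
#' prediction. Dead time `t0 = deadVolume / flow` and dwell time
#' `tD = dwellVolume / flow` are always derived from the flow rate of the
#' method conditions, never stored.
#'
#' @slot deadVolume column hold-up volume in mL
#' @slot dwellVolume pre-column gradient delay volume in mL
#' @slot plateNumber dimensionless apparent column efficiency N
#' @slot maxPressure informational operating pressure limit in bar
#' @export
setClass("InstrumentConfig",
  slots = c(
    deadVolume  = "numeric",
    dwellVolume = "numeric",
    plateNumber = "numeric",
    maxPressure = "numeric"
  )
)

setValidity("InstrumentConfig", function(object) {
  msg <- character()
  if (length(object@deadVolume) != 1L || !is.finite(object@deadVolume) ||
      object@deadVolume <= 0)
    msg <- c(msg, "deadVolume must be a single positive number (mL)")
  if (length(object@dwellVolume) != 1L || !is.finite(object@dwellVolume) ||
      object@dwellVolume <= 0)
    msg <- c(msg, "dwellVolume must be a single positive number (mL)")
  if (length(object@plateNumber) != 1L || !is.finite(object@plateNumber) ||
      object@plateNumber <= 0)
    msg <- c(msg, "plateNumber must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Create an instrument configuration
#'
#' Defaults describe a sub-2 um 50 x 2.1 mm UHPLC column on a low-dispersion
#' binary system: dead volume 0.110 mL (about 65% of the empty column
#' volume), dwell volume 0.12 mL, and an apparent plate number calibrated so
#' simulated gradient peak widths are on the scale observed for this column
#' format (see the methods vignette).
#'
#' @param dead_volume_mL column hold-up volume (mL)
#' @param dwell_volume_mL gradient delay volume (mL)
#' @param plate_number apparent (gradient-compressed) plate number
#' @param max_pressure_bar informational pressure ceiling (bar)
#' @return an [InstrumentConfig-class] object
#' @examples
#' instr <- instrumentConfig()
#' deadTime(instr, flow_mL_min = 0.8)
#' @export
instrumentConfig <- function(dead_volume_mL = 0.110, dwell_volume_mL = 0.12,
                             plate_number = 4350, max_pressure_bar = 1000) {
  new("InstrumentConfig", deadVolume = dead_volume_mL,
      dwellVolume = dwell_volume_mL, plateNumber = plate_number,
      maxPressure = max_pressure_bar)
}

#' @describeIn instrumentConfig column dead time t0 (min) at a flow rate
#' @param instr an `InstrumentConfig`
#' @param flow_mL_min flow rate (mL/min)
#' @export
deadTime <- function(instr, flow_mL_min) instr@deadVolume / flow_mL_min

#' @describeIn instrumentConfig gradient dwell (delay) time tD (min) at a flow rate
#' @export
dwellTime <- function(instr, flow_mL_min) instr@dwellVolume / flow_mL_min

#' A complete linear gradient program
#'
#' One run condition: gradient time, column temperature, aqueous-phase pH,
#' flow rate and the initial/final organic fraction of the linear ramp.
#' Organic composition is stored as a fraction (0-1); all file I/O uses %B.
#'
#' @slot tG gradient time (min)
#' @slot temperature column temperature (deg C)
#' @slot pH aqueous phase pH
#' @slot flow flow rate (mL/min)
#' @slot phiStart initial organic fraction (0-1)
#' @slot phiEnd final organic fraction (0-1)
#' @export
setClass("MethodConditions",
  slots = c(
    tG          = "numeric",
    temperature = "numeric",
    pH          = "numeric",
    flow        = "numeric",
    phiStart    = "numeric",
    phiEnd      = "numeric"
  )
)

setValidity("MethodConditions", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@tG) || object@tG <= 0) msg <- c(msg, "tG must be > 0")
  if (!one(object@flow) || object@flow <= 0) msg <- c(msg, "flow must be > 0")
  if (!one(object@pH) || object@pH <= 0 || object@pH >= 14)
    msg <- c(msg, "pH must lie in (0, 14)")
  if (!one(object@temperature)) msg <- c(msg, "temperature must be finite")
  if (!one(object@phiStart) || !one(object@phiEnd) ||
      object@phiStart < 0 || object@phiEnd > 1 ||
      object@phiStart >= object@phiEnd)
    msg <- c(msg, "need 0 <= phiStart < phiEnd <= 1")
  if (length(msg)) msg else TRUE
})

#' Create method conditions
#'
#' @param tG_min gradient time (min)
#' @param T_C column temperature (deg C)
#' @param pH aqueous-phase pH
#' @param flow_mL_min flow rate (mL/min)
#' @param phi_start initial organic fraction (0-1)
#' @param phi_end final organic fraction (0-1)
#' @return a [MethodConditions-class] object
#' @examples
#' # the nominal working point: 3 min gradient 10->80 %B, 40 C, pH 6.0
#' methodConditions(3.0, 40, 6.0)
#' @export
methodConditions <- function(tG_min, T_C, pH, flow_mL_min = 0.8,
                             phi_start = 0.10, phi_end = 0.80) {
  new("MethodConditions", tG = tG_min, temperature = T_C, pH = pH,
      flow = flow_mL_min, phiStart = phi_start, phiEnd = phi_end)
}

#' Linear solvent strength parameters of one solute
#'
#' Under the LSS model the base-10 logarithm of the retention factor falls
#' linearly with the organic fraction phi: `log10 k = logKw - S * phi`.
#' `logKw` extrapolates retention to pure aqueous eluent; `S` is the solvent
#' sensitivity (positive for typical reversed-phase solutes).
#'
#' @slot logKw log10 retention factor at phi = 0
#' @slot S slope of log10 k versus organic fraction
#' @export
setClass("SoluteLSS", slots = c(logKw = "numeric", S = "numeric"))

setValidity("SoluteLSS", function(object) {
  msg <- character()
  # -Inf logKw is the documented sentinel for an unretained marker
  if (length(object@logKw) != 1L || is.na(object@logKw) || object@logKw == Inf)
    msg <- c(msg, "logKw must be a single finite number (or -Inf sentinel)")
  if (length(object@S) != 1L || !is.finite(object@S))
    msg <- c(msg, "S must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @rdname SoluteLSS-class
#' @param log_kw log10 retention factor extrapolated to 0% organic
#' @param S slope of log10 k versus organic fraction
#' @export
soluteLSS <- function(log_kw, S) new("SoluteLSS", logKw = log_kw, S = S)

#' A simulated or predicted chromatogram
#'
#' An ordered peak table at one method condition. Peaks are sorted by
#' ascending retention time, ties broken by compound id (lexicographic).
#'
#' @slot conditions the [MethodConditions-class] the peaks belong to
#' @slot peaks data.frame with columns compound_id, tR_min, sigma_min, area
#' @export
setClass("Chromatogram",
  slots = c(conditions = "MethodConditions", peaks = "data.frame"))

setValidity("Chromatogram", function(object) {
  p <- object@peaks
  need <- c("compound_id", "tR_min", "sigma_min", "area")
  if (!all(need %in% names(p)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (nrow(p)) {
    if (any(p$sigma_min <= 0)) return("all sigma_min must be > 0")
    if (any(p$area < 0)) return("areas must be >= 0")
    o <- order(p$tR_min, p$compound_id)
    if (!identical(o, seq_len(nrow(p))))
      return("peaks must be sorted by tR_min, ties by compound_id")
  }
  TRUE
})

# canonical peak ordering used everywhere a Chromatogram is built
orderPeaks <- function(peaks) {
  peaks <- peaks[order(peaks$tR_min, peaks$compound_id), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

newChromatogram <- function(conditions, peaks) {
  new("Chromatogram", conditions = conditions, peaks = orderPeaks(peaks))
}

#' @describeIn Chromatogram-class peak table accessor
#' @param object a `Chromatogram`
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))

#' @rdname Chromatogram-class
#' @export
setMethod("peaks", "Chromatogram", function(object) object@peaks)

#' @describeIn Chromatogram-class method-conditions accessor
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' @rdname Chromatogram-class
#' @export
setMethod("conditions", "Chromatogram", function(object) object@conditions)

#' The 12-run calibration design
#'
#' Two gradient times x two temperatures x three pH levels (2 x 2 x 3 = 12
#' runs), all sharing flow rate and gradient end points. Two tG levels fix
#' the LSS pair (logKw, S) at each (T, pH) corner; two temperatures support
#' a linear model in 1/T; three pH levels support a quadratic model in pH.
#'
#' @slot tGLevels two gradient times (min), strictly increasing
#' @slot TLevels two temperatures (deg C), strictly increasing
#' @slot pHLevels three pH values, strictly increasing
#' @slot flow shared flow rate (mL/min)
#' @slot phiStart shared initial organic fraction
#' @slot phiEnd shared final organic fraction
#' @export
setClass("CalibrationDesign",
  slots = c(
    tGLevels = "numeric", TLevels = "numeric", pHLevels = "numeric",
    flow = "numeric", phiStart = "numeric", phiEnd = "numeric"
  )
)

setValidity("CalibrationDesign", function(object) {
  msg <- character()
  if (length(object@tGLevels) != 2L || any(diff(object@tGLevels) <= 0))
    msg <- c(msg, "tGLevels must be 2 strictly increasing gradient times")
  if (length(object@TLevels) != 2L || any(diff(object@TLevels) <= 0))
    msg <- c(msg, "TLevels must be 2 strictly increasing temperatures")
  if (length(object@pHLevels) != 3L || any(diff(object@pHLevels) <= 0))
    msg <- c(msg, "pHLevels must be 3 strictly increasing pH values")
  if (length(msg)) msg else TRUE
})

#' Create a calibration design
#'
#' Defaults are the steep/flat gradient pair (1.5 and 4.5 min, 10->80 %B at
#' 0.8 mL/min) with temperatures 20 and 50 deg C and pH levels 2.8, 4.6 and
#' 6.4 — the wide scouting design for an ionizable pharmaceutical mixture.
#'
#' @param tG_levels two gradient times (min)
#' @param T_levels two column temperatures (deg C)
#' @param pH_levels three pH values
#' @param flow_mL_min shared flow rate (mL/min)
#' @param phi_start,phi_end shared gradient end points (organic fraction)
#' @return a [CalibrationDesign-class]
#' @export
calibrationDesign <- function(tG_levels = c(1.5, 4.5),
                              T_levels = c(20, 50),
                              pH_levels = c(2.8, 4.6, 6.4),
                              flow_mL_min = 0.8,
                              phi_start = 0.10, phi_end = 0.80) {
  new("CalibrationDesign", tGLevels = tG_levels, TLevels = T_levels,
      pHLevels = pH_levels, flow = flow_mL_min,
      phiStart = phi_start, phiEnd = phi_end)
}

#' Enumerate the runs of a calibration design
#'
#' Runs are ordered by temperature (slowest), then pH, then gradient time
#' (fastest), with ids R01, R02, ... This order is part of the package's
#' deterministic contract for generated run tables.
#'
#' @param design a [CalibrationDesign-class]
#' @return data.frame with run_id, tG_min, T_C, pH, flow_mL_min,
#'   pctB_start, pctB_end (one row per run; 12 for the default design)
#' @export
designRuns <- function(design) {
  grid <- expand.grid(tG_min = design@tGLevels, pH = design@pHLevels,
                      T_C = design@TLevels, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$T_C, grid$pH, grid$tG_min), , drop = FALSE]
  data.frame(
    run_id = sprintf("R%02d", seq_len(nrow(grid))),
    tG_min = grid$tG_min, T_C = grid$T_C, pH = grid$pH,
    flow_mL_min = design@flow,
    pctB_start = 100 * design@phiStart, pctB_end = 100 * design@phiEnd,
    stringsAsFactors = FALSE
  )
}

#' Fitted retention model for a compound set
#'
#' Per-compound LSS parameters at the 2 x 3 (temperature, pH) calibration
#' corners, with fit diagnostics, plus the interpolation rules (linear in
#' 1/T in kelvin, quadratic in pH) that extend them to arbitrary conditions
#' inside the calibrated region.
#'
#' @slot compounds character vector of compound ids
#' @slot TLevels the two calibrated temperatures (deg C)
#' @slot pHLevels the three calibrated pH values
#' @slot logKw array `[compound, T, pH]` of fitted logKw values
#' @slot S array `[compound, T, pH]` of fitted S values
#' @slot fitted logical array `[compound, T, pH]`, FALSE for unfitted corners
#' @slot residual array `[compound, T, pH]` of max |predicted - observed| (min)
#' @slot design the [CalibrationDesign-class] the model was fitted on
#' @export
setClass("FittedModel",
  slots = c(
    compounds = "character", TLevels = "numeric", pHLevels = "numeric",
    logKw = "array", S = "array", fitted = "array", residual = "array",
    design = "CalibrationDesign"
  )
)

setValidity("FittedModel", function(object) {
  d <- c(length(object@compounds), length(object@TLevels),
         length(object@pHLevels))
  for (nm in c("logKw", "S", "fitted", "residual"))
    if (!identical(dim(slot(object, nm)), as.integer(d)))
      return(sprintf("slot %s must have dim [compound, T, pH]", nm))
  TRUE
})

#' @describeIn FittedModel-class ids of the fitted compounds
#' @param object a `FittedModel`
#' @export
setGeneric("compounds", function(object) standardGeneric("compounds"))

#' @rdname FittedModel-class
#' @export
setMethod("compounds", "FittedModel", function(object) object@compounds)

#' A design-space map
#'
#' Critical resolution evaluated on a (tG, T, pH) grid, with the limiting
#' (critical) peak pair at every node and the acceptance criterion. The
#' fitted model, instrument and shared gradient settings are kept so
#' sub-regions can be re-evaluated (not sliced) on demand.
#'
#' @slot tG,temperature,pH sorted axis grids
#' @slot Rs array `[tG, T, pH]` of critical resolutions
#' @slot pairFirst,pairSecond character arrays with the critical pair ids
#' @slot criterion the resolution acceptance threshold (default 2.0)
#' @slot model the `FittedModel` used (or NULL when read back from file)
#' @slot instrument the `InstrumentConfig` used (or NULL)
#' @slot flow,phiStart,phiEnd shared gradient settings
#' @export
setClass("DesignSpaceMap",
  slots = c(
    tG = "numeric", temperature = "numeric", pH = "numeric",
    Rs = "array", pairFirst = "array", pairSecond = "array",
    criterion = "numeric",
    model = "ANY", instrument = "ANY",
    flow = "numeric", phiStart = "numeric", phiEnd = "numeric"
  )
)

setValidity("DesignSpaceMap", function(object) {
  d <- c(length(object@tG), length(object@temperature), length(object@pH))
  if (!identical(dim(object@Rs), as.integer(d)))
    return("Rs array shape must match the axis lengths")
  if (is.unsorted(object@tG, strictly = TRUE) ||
      is.unsorted(object@temperature, strictly = TRUE) ||
      is.unsorted(object@pH, strictly = TRUE))
    return("axes must be strictly increasing")
  TRUE
})

#' @describeIn DesignSpaceMap-class critical-resolution array accessor
#' @param object a `DesignSpaceMap`
#' @export
setGeneric("rsValues", function(object) standardGeneric("rsValues"))

#' @rdname DesignSpaceMap-class
#' @export
setMethod("rsValues", "DesignSpaceMap", function(object) object@Rs)

#' A selected robust working point
#'
#' The grid node of a design-space map that maximises the L-infinity
#' robustness radius: the half-width (on axes normalised to `[0, 1]`) of the
#' largest box around the node inside which every grid node still meets the
#' resolution criterion.
#'
#' @slot conditions the working-point [MethodConditions-class]
#' @slot radius the normalised L-infinity robustness radius
#' @slot RsCrit critical resolution at the point
#' @slot pair the critical peak pair at the point
#' @export
setClass("WorkingPoint",
  slots = c(conditions = "MethodConditions", radius = "numeric",
            RsCrit = "numeric", pair = "character"))

#' Robustness factor levels
#'
#' Three (or two) ordered levels for each of the six method parameters
#' perturbed in the virtual robustness study. Level 0 (the middle level) is
#' the nominal working point. %B levels are given in percent.
#'
#' @slot levels named list with entries tG_min, T_C, pH, flow_mL_min,
#'   pctB_start, pctB_end, each a strictly increasing numeric vector
#' @export
setClass("FactorLevels", slots = c(levels = "list"))

.factorOrder <- c("tG_min", "T_C", "pH", "flow_mL_min", "pctB_start", "pctB_end")

setValidity("FactorLevels", function(object) {
  if (!identical(names(object@levels), .factorOrder))
    return(paste("levels must be named, in order:",
                 paste(.factorOrder, collapse = ", ")))
  for (nm in .factorOrder) {
    v <- object@levels[[nm]]
    if (!is.numeric(v) || length(v) < 2L || length(v) > 3L)
      return(sprintf("factor %s must have 2 or 3 levels", nm))
    if (any(diff(v) <= 0))
      return(sprintf("levels of %s must be strictly increasing", nm))
  }
  TRUE
})

#' Create robustness factor levels
#'
#' Defaults are the +/-1-level deviations of the published robustness
#' protocol around the nominal working point (tG 3.0 min, 40 deg C, pH 6.0,
#' 0.8 mL/min, 10->80 %B): tG +/-0.3 min, T +/-2 deg C, pH +/-0.2, flow
#' +/-10%, and +/-1 %B on both gradient end points.
#'
#' @param tG_min,T_C,pH,flow_mL_min,pctB_start,pctB_end numeric level
#'   vectors (strictly increasing, 2 or 3 values each)
#' @return a [FactorLevels-class]
#' @export
factorLevels <- function(tG_min = c(2.7, 3.0, 3.3),
                         T_C = c(38, 40, 42),
                         pH = c(5.8, 6.0, 6.2),
                         flow_mL_min = c(0.72, 0.80, 0.88),
                         pctB_start = c(9, 10, 11),
                         pctB_end = c(79, 80, 81)) {
  new("FactorLevels", levels = list(
    tG_min = tG_min, T_C = T_C, pH = pH, flow_mL_min = flow_mL_min,
    pctB_start = pctB_start, pctB_end = pctB_end))
}

#' Result of a virtual robustness study
#'
#' One row per factor combination with the realised method conditions, the
#' critical resolution and the critical pair; plus the success rate against
#' the criterion. Rows are stored in enumeration order (rightmost factor
#' varying fastest); [worstRows()] ranks them ascending by resolution with
#' ties broken by enumeration index (stable).
#'
#' @slot table the per-combination data.frame
#' @slot successRate fraction of combinations with Rs_crit >= criterion
#' @slot criterion the resolution criterion
#' @slot levels the [FactorLevels-class] enumerated
#' @export
setClass("RobustnessResult",
  slots = c(table = "data.frame", successRate = "numeric",
            criterion = "numeric", levels = "FactorLevels"))

#' @describeIn RobustnessResult-class success-rate accessor
#' @param object a `RobustnessResult`
#' @export
setGeneric("successRate", function(object) standardGeneric("successRate"))

#' @rdname RobustnessResult-class
#' @export
setMethod("successRate", "RobustnessResult", function(object) object@successRate)
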