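# Fitting per-compound LSS parameters from the two-gradient calibration runs
# and interpolating them across temperature and pH.

.S_BRACKET <- c(0.5, 100)
.LOGKW_BRACKET <- c(-2, 10)
.FIT_TOL <- 1e-10

#' Invert two gradient runs into LSS parameters
#'
#' Recovers `(logKw, S)` of one solute from its retention times in two runs
#' that differ only in gradient time. Solved by nested one-dimensional root
#' finding: for each trial `S` the inner solve finds the `logKw` that
#' reproduces the first run, the outer solve adjusts `S` until the second
#' run is reproduced. Brackets are fixed (`S` in `[0.5, 100]`, `logKw` in
#' `[-2, 10]`, tolerance 1e-10) for reproducibility.
#'
#' @param tR_1,tR_2 measured retention times (min) in the two runs
#' @param cond_1,cond_2 the two [MethodConditions-class], identical except tG
#' @param instr an [InstrumentConfig-class]
#' @param compound_id label used in error messages
#' @return a [SoluteLSS-class]
#' @export
invertTwoGradients <- function(tR_1, tR_2, cond_1, cond_2, instr,
                               compound_id = "solute") {
  same <- isTRUE(all.equal(cond_1@temperature, cond_2@temperature)) &&
    isTRUE(all.equal(cond_1@pH, cond_2@pH)) &&
    isTRUE(all.equal(cond_1@flow, cond_2@flow)) &&
    isTRUE(all.equal(cond_1@phiStart, cond_2@phiStart)) &&
    isTRUE(all.equal(cond_1@phiEnd, cond_2@phiEnd))
  if (!same || cond_1@tG == cond_2@tG)
    chromqbdError("conditions must differ only in gradient time",
                  "chromqbd_input_error")
  t0 <- deadTime(instr, cond_1@flow)
  if (tR_1 <= t0 + 1e-4 || tR_2 <= t0 + 1e-4)
    chromqbdError(sprintf("%s elutes at or before the dead time: unretained",
                          compound_id),
                  "chromqbd_unretained")
  if (abs(tR_1 - tR_2) <= 1e-7)
    chromqbdError(sprintf(
      "%s is gradient-insensitive (identical tR at both gradient times, S ~ 0)",
      compound_id),
      "chromqbd_gradient_insensitive")

  predict1 <- function(logKw, S)
    lssGradientCore(logKw, S, cond_1@tG, cond_1@flow, cond_1@phiStart,
                    cond_1@phiEnd, instr)$tR
  predict2 <- function(logKw, S)
    lssGradientCore(logKw, S, cond_2@tG, cond_2@flow, cond_2@phiStart,
                    cond_2@phiEnd, instr)$tR

  # tR is monotone increasing in logKw at fixed S
  innerLogKw <- function(S) {
    f <- function(lk) predict1(lk, S) - tR_1
    lo <- f(.LOGKW_BRACKET[1]); hi <- f(.LOGKW_BRACKET[2])
    if (is.na(lo) || is.na(hi) || lo * hi > 0) return(NA_real_)
    uniroot(f, .LOGKW_BRACKET, tol = .FIT_TOL)$root
  }
  outer <- function(S) {
    lk <- innerLogKw(S)
    if (is.na(lk)) return(NA_real_)
    predict2(lk, S) - tR_2
  }

  # the inner solve can be infeasible near the bracket ends (logKw bracket
  # exhausted at extreme S), so locate a sign change on a fixed log-spaced
  # scan of the S bracket, then root-find inside it
  Ss <- exp(seq(log(.S_BRACKET[1]), log(.S_BRACKET[2]), length.out = 40L))
  g <- vapply(Ss, outer, numeric(1))
  ok <- which(!is.na(g))
  lo <- NA_integer_
  for (j in seq_len(length(ok) - 1L)) {
    a <- ok[j]; bb <- ok[j + 1L]
    if (bb == a + 1L && g[a] * g[bb] <= 0) { lo <- a; break }
  }
  if (is.na(lo))
    chromqbdError(sprintf(
      "no solution for %s inside the S bracket [%.1f, %.0f]",
      compound_id, .S_BRACKET[1], .S_BRACKET[2]),
      "chromqbd_fit_failure")
  S <- uniroot(outer, c(Ss[lo], Ss[lo + 1L]), f.lower = g[lo],
               f.upper = g[lo + 1L], tol = .FIT_TOL)$root
  soluteLSS(innerLogKw(S), S)
}

.cornerIndex <- function(values, levels, what) {
  i <- which(abs(levels - values) < 1e-9 |
               abs(levels - values) < 1e-6 * pmax(1, abs(levels)))
  if (length(i) != 1L)
    chromqbdError(sprintf("run condition %s = %g is not a design level",
                          what, values),
                  "chromqbd_input_error")
  i
}

#' Fit the calibration model
#'
#' Applies [invertTwoGradients()] per compound at each (T, pH) corner of the
#' design, using the runs at the two gradient times. A corner missing either
#' tG run for a compound (absent row or blank tR, e.g. a degraded solute) is
#' left unfitted and flagged; a compound with no fitted corner at all is
#' dropped with a warning.
#'
#' @param runs a run table data.frame with columns run_id, tG_min, T_C, pH,
#'   flow_mL_min, pctB_start, pctB_end, compound_id, tR_min (NA = missing
#'   peak), e.g. from [generateRunTable()] or [readRunTable()]
#' @param design the [CalibrationDesign-class] the runs realise
#' @param instr an [InstrumentConfig-class]
#' @return a [FittedModel-class]
#' @export
fitModel <- function(runs, design, instr) {
  validateRunTable(runs)
  comps <- sort(unique(runs$compound_id))
  nT <- length(design@TLevels); npH <- length(design@pHLevels)
  dims <- c(length(comps), nT, npH)
  dn <- list(comps, NULL, NULL)
  logKw <- array(NA_real_, dims, dimnames = dn)
  S <- array(NA_real_, dims, dimnames = dn)
  fitted <- array(FALSE, dims, dimnames = dn)
  residual <- array(NA_real_, dims, dimnames = dn)

  condAt <- function(tG, T_C, pH)
    methodConditions(tG, T_C, pH, design@flow, design@phiStart, design@phiEnd)

  for (ci in seq_along(comps)) {
    rows <- runs[runs$compound_id == comps[ci], , drop = FALSE]
    for (ti in seq_len(nT)) for (pi in seq_len(npH)) {
      T_C <- design@TLevels[ti]; pH <- design@pHLevels[pi]
      here <- rows[abs(rows$T_C - T_C) < 1e-9 & abs(rows$pH - pH) < 1e-9, ,
                   drop = FALSE]
      tRs <- vapply(design@tGLevels, function(tg) {
        m <- here[abs(here$tG_min - tg) < 1e-9, , drop = FALSE]
        if (nrow(m) == 1L) m$tR_min else NA_real_
      }, numeric(1))
      if (anyNA(tRs)) next
      sol <- tryCatch(
        invertTwoGradients(tRs[1], tRs[2],
                           condAt(design@tGLevels[1], T_C, pH),
                           condAt(design@tGLevels[2], T_C, pH),
                           instr, compound_id = comps[ci]),
        chromqbd_error = function(e) NULL)
      if (is.null(sol)) next
      logKw[ci, ti, pi] <- sol@logKw
      S[ci, ti, pi] <- sol@S
      fitted[ci, ti, pi] <- TRUE
      pred <- vapply(design@tGLevels, function(tg)
        gradientRetentionTime(sol, condAt(tg, T_C, pH), instr), numeric(1))
      residual[ci, ti, pi] <- max(abs(pred - tRs))
    }
  }

  dropped <- comps[rowSums(fitted, dims = 1) == 0]
  if (length(dropped)) {
    chromqbdWarning(sprintf("dropping compound(s) with no fitted corner: %s",
                            paste(dropped, collapse = ", ")),
                    "chromqbd_compound_dropped")
    keep <- !(comps %in% dropped)
    comps <- comps[keep]
    logKw <- logKw[keep, , , drop = FALSE]
    S <- S[keep, , , drop = FALSE]
    fitted <- fitted[keep, , , drop = FALSE]
    residual <- residual[keep, , , drop = FALSE]
  }

  new("FittedModel", compounds = comps, TLevels = design@TLevels,
      pHLevels = design@pHLevels, logKw = logKw, S = S, fitted = fitted,
      residual = residual, design = design)
}

# range check with the 10%-of-range extrapolation margin
.checkRange <- function(x, levels, what) {
  lo <- min(levels); hi <- max(levels); rng <- hi - lo
  if (x < lo - 0.1 * rng || x > hi + 0.1 * rng)
    chromqbdError(sprintf(
      "%s = %g is outside the calibrated range [%g, %g] (+10%% margin)",
      what, x, lo, hi),
      "chromqbd_range_error")
  if (x < lo || x > hi)
    chromqbdWarning(sprintf("%s = %g extrapolates beyond [%g, %g]",
                            what, x, lo, hi),
                    "chromqbd_extrapolation")
  invisible(x)
}

# 3-point Lagrange weights (quadratic through xs, evaluated at x)
.lagrange3 <- function(x, xs) {
  c(((x - xs[2]) * (x - xs[3])) / ((xs[1] - xs[2]) * (xs[1] - xs[3])),
    ((x - xs[1]) * (x - xs[3])) / ((xs[2] - xs[1]) * (xs[2] - xs[3])),
    ((x - xs[1]) * (x - xs[2])) / ((xs[3] - xs[1]) * (xs[3] - xs[2])))
}

#' Interpolate fitted LSS parameters to arbitrary (T, pH)
#'
#' `logKw` and `S` are interpolated independently by the tensor-product
#' rule: linear in 1/T (kelvin, van't Hoff convention) between the two
#' temperature corners, quadratic (3-point Lagrange) in pH across the three
#' pH corners. The order of application (T then pH or pH then T) commutes.
#' Queries up to 10% of the calibrated range outside it extrapolate with a
#' warning; beyond that an error is raised.
#'
#' @param model a [FittedModel-class]
#' @param compound a fitted compound id
#' @param T_C,pH query temperature (deg C) and pH
#' @return a [SoluteLSS-class]
#' @export
interpolateParams <- function(model, compound, T_C, pH) {
  ci <- match(compound, model@compounds)
  if (is.na(ci))
    chromqbdError(sprintf("compound %s is not in the model", compound),
                  "chromqbd_input_error")
  .checkRange(T_C, model@TLevels, "T_C")
  .checkRange(pH, model@pHLevels, "pH")
  if (!all(model@fitted[ci, , ]))
    chromqbdError(sprintf(
      "compound %s has unfitted calibration corner(s); cannot interpolate",
      compound),
      "chromqbd_interpolation_failure")
  invT <- 1 / (T_C + 273.15)
  invTs <- 1 / (model@TLevels + 273.15)
  wT <- c(1 - (invT - invTs[1]) / (invTs[2] - invTs[1]),
          (invT - invTs[1]) / (invTs[2] - invTs[1]))
  wPH <- .lagrange3(pH, model@pHLevels)
  comb <- function(a) as.numeric(wT %*% a[ci, , ] %*% wPH)
  soluteLSS(comb(model@logKw), comb(model@S))
}

# parameter matrices for all compounds at one (T, pH); used by the map and
# robustness engines to avoid re-interpolating per grid node
interpolateAll <- function(model, T_C, pH) {
  n <- length(model@compounds)
  out <- matrix(NA_real_, n, 2, dimnames = list(model@compounds, c("logKw", "S")))
  for (i in seq_len(n)) {
    if (!all(model@fitted[i, , ])) next
    s <- interpolateParams(model, model@compounds[i], T_C, pH)
    out[i, ] <- c(s@logKw, s@S)
  }
  out
}

#' Predict a chromatogram from a fitted model
#'
#' For every fitted compound: interpolate the LSS parameters to the query
#' temperature and pH, compute the gradient retention time and Gaussian
#' peak width, and assemble the sorted peak table. Compounds with unfitted
#' corners are silently omitted from the peak table (they are flagged on
#' the model).
#'
#' @param model a [FittedModel-class]
#' @param cond a [MethodConditions-class]
#' @param instr an [InstrumentConfig-class]
#' @param amounts optional named numeric of relative amounts (unit areas
#'   when NULL)
#' @return a [Chromatogram-class]
#' @export
predictChromatogram <- function(model, cond, instr, amounts = NULL) {
  par <- interpolateAll(model, cond@temperature, cond@pH)
  keep <- !is.na(par[, "logKw"])
  par <- par[keep, , drop = FALSE]
  core <- lssGradientCore(par[, "logKw"], par[, "S"], cond@tG, cond@flow,
                          cond@phiStart, cond@phiEnd, instr)
  t0 <- core$t0
  sigma <- (t0 / sqrt(instr@plateNumber)) * (1 + core$kElute)
  ids <- rownames(par)
  area <- if (is.null(amounts)) rep(1, length(ids)) else {
    a <- amounts[ids]
    if (anyNA(a))
      chromqbdError("amounts must name every fitted compound",
                    "chromqbd_input_error")
    as.numeric(a)
  }
  newChromatogram(cond, data.frame(
    compound_id = ids, tR_min = core$tR, sigma_min = sigma, area = area,
    stringsAsFactors = FALSE))
}
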