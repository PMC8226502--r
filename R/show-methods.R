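# show() methods for the main containers

setMethod("show", "InstrumentConfig", function(object) {
  cat(sprintf(
    "InstrumentConfig: Vm=%.3f mL, Vd=%.3f mL, N=%g (max %g bar)\n",
    object@deadVolume, object@dwellVolume, object@plateNumber,
    object@maxPressure))
})

setMethod("show", "MethodConditions", function(object) {
  cat(sprintf(
    "MethodConditions: tG=%g min %g->%g %%B, T=%g C, pH=%g, %g mL/min\n",
    object@tG, 100 * object@phiStart, 100 * object@phiEnd,
    object@temperature, object@pH, object@flow))
})

setMethod("show", "SoluteLSS", function(object) {
  cat(sprintf("SoluteLSS: logKw=%.4f, S=%.4f\n", object@logKw, object@S))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram with %d peak(s) at ", nrow(object@peaks)))
  show(object@conditions)
  if (nrow(object@peaks)) {
    p <- object@peaks
    p$tR_min <- round(p$tR_min, 4)
    p$sigma_min <- signif(p$sigma_min, 3)
    print(p, row.names = FALSE)
  }
})

setMethod("show", "CalibrationDesign", function(object) {
  cat(sprintf(
    "CalibrationDesign: %d runs | tG {%s} min x T {%s} C x pH {%s}, %g mL/min, %g->%g %%B\n",
    2 * length(object@TLevels) * length(object@pHLevels),
    paste(object@tGLevels, collapse = ", "),
    paste(object@TLevels, collapse = ", "),
    paste(object@pHLevels, collapse = ", "),
    object@flow, 100 * object@phiStart, 100 * object@phiEnd))
})

setMethod("show", "FittedModel", function(object) {
  nc <- sum(object@fitted)
  cat(sprintf(
    "FittedModel: %d compound(s), %d/%d corners fitted, max residual %.2g min\n",
    length(object@compounds), nc, length(object@fitted),
    suppressWarnings(max(object@residual, na.rm = TRUE))))
  cat("  compounds:", paste(object@compounds, collapse = ", "), "\n")
})

setMethod("show", "DesignSpaceMap", function(object) {
  rs <- object@Rs
  frac <- mean(!is.na(rs) & rs >= object@criterion)
  cat(sprintf(
    "DesignSpaceMap: %d x %d x %d (tG x T x pH), Rs>=%.2f on %.1f%% of nodes\n",
    length(object@tG), length(object@temperature), length(object@pH),
    object@criterion, 100 * frac))
})

setMethod("show", "WorkingPoint", function(object) {
  cat("WorkingPoint: ")
  show(object@conditions)
  cat(sprintf("  Rs_crit=%.3f (%s), robustness radius=%.3f\n",
              object@RsCrit, paste(object@pair, collapse = "-"),
              object@radius))
})

setMethod("show", "RobustnessResult", function(object) {
  cat(sprintf(
    "RobustnessResult: %d combination(s), success rate %.1f%% at Rs>=%.2f\n",
    nrow(object@table), 100 * object@successRate, object@criterion))
  w <- worstRows(object, 1)
  if (nrow(w) && !is.na(w$Rs_crit))
    cat(sprintf("  worst: Rs_crit=%.3f (%s) at combination %d\n",
                w$Rs_crit, w$crit_pair, w$index))
})

setMethod("show", "TrueSolute", function(object) {
  cat(sprintf("TrueSolute %s: logKw=%.3f S=%.2f%s vh=%g K%s\n",
              object@id, object@logKwN, object@SN,
              if (is.na(object@pKa)) "" else
                sprintf(" (ion logKw=%.3f S=%.2f pKa=%.1f)",
                        object@logKwI, object@SI, object@pKa),
              object@vantHoff,
              if (object@degradable)
                sprintf(" degradable at >=%g C & pH>=%g",
                        object@TThreshold, object@pHThreshold) else ""))
})
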