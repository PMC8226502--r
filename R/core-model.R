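# Forward chromatographic physics under linear solvent strength (LSS) theory:
# isocratic retention, gradient elution with dwell delay, Gaussian peak
# widths, pairwise and critical resolution.

.LN10 <- log(10)

#' Isocratic retention factor under the LSS law
#'
#' `k = 10^(logKw - S * phi)`. A `logKw` of `-Inf` is the sentinel for an
#' unretained marker (k = 0).
#'
#' @param solute a [SoluteLSS-class] (or anything with logKw/S slots)
#' @param phi organic fraction, in `[0, 1]` (vectorised)
#' @return retention factor(s) k >= 0
#' @examples
#' isocraticK(soluteLSS(3, 10), 0.1)  # 10^(3 - 1) = 100
#' @export
isocraticK <- function(solute, phi) {
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    chromqbdError("phi must be finite and in [0, 1]",
                  "chromqbd_invalid_parameter")
  10^(solute@logKw - solute@S * phi)
}

# vectorised scalar core shared by model prediction and map evaluation;
# logKw and S may be vectors (one entry per compound), the condition scalars.
# Returns list(tR, kElute) so sigma can reuse the elution-composition k.
lssGradientCore <- function(logKw, S, tG, flow, phiStart, phiEnd, instr) {
  t0 <- instr@deadVolume / flow
  tD <- instr@dwellVolume / flow
  dphi <- phiEnd - phiStart
  k0 <- 10^(logKw - S * phiStart)
  b <- t0 * dphi * S / tG

  n <- length(k0)
  tR <- numeric(n)
  kE <- numeric(n)

  for (i in seq_len(n)) {
    if (!is.finite(k0[i])) {
      if (k0[i] == 0 || logKw[i] == -Inf) { tR[i] <- t0; kE[i] <- 0; next }
      chromqbdError("non-finite retention parameters",
                    "chromqbd_invalid_parameter")
    }
    if (k0[i] == 0) { tR[i] <- t0; kE[i] <- 0; next }
    if (b[i] <= 1e-12) {           # no effective gradient: isocratic limit
      tR[i] <- t0 * (1 + k0[i])
      kE[i] <- k0[i]
      next
    }
    if (tD >= t0 * k0[i]) {        # elutes before the gradient arrives
      tR[i] <- t0 * (1 + k0[i])
      kE[i] <- k0[i]
      next
    }
    A <- .LN10 * k0[i] * b[i] * (1 - tD / (t0 * k0[i]))
    tauG <- (t0 / b[i]) * log10(A + 1)   # migration time inside the gradient
    if (tauG <= tG) {
      tR[i] <- t0 + tD + tauG
      kE[i] <- k0[i] * 10^(-b[i] * tauG / t0)
    } else {
      # gradient ends first: remaining migration is isocratic at phiEnd
      fD <- tD / (t0 * k0[i])
      fG <- (10^(b[i] * tG / t0) - 1) / (k0[i] * b[i] * .LN10)
      kEnd <- 10^(logKw[i] - S[i] * phiEnd)
      tau <- tD + tG + (1 - fD - fG) * t0 * kEnd
      tR[i] <- tau + t0
      kE[i] <- kEnd
    }
  }
  list(tR = pmax(tR, t0), kElute = kE, t0 = t0, tD = tD)
}

#' Gradient elution retention time
#'
#' Closed-form LSS gradient retention with dwell-delay correction. Three
#' regimes are handled and returned as a single retention time: elution
#' during the pre-gradient (dwell) hold, elution inside the linear gradient,
#' and post-gradient isocratic elution at the final composition. With
#' `b = t0 * (phiEnd - phiStart) * S / tG` and `k0` the retention factor at
#' the initial composition, elution inside the gradient follows
#' `tR = t0 + tD + (t0/b) * log10(2.303 * k0 * b * (1 - tD/(t0 k0)) + 1)`.
#' Degenerate inputs fall back to the isocratic limit `t0 * (1 + k0)`
#' (when `S = 0` or `phiEnd = phiStart`) or to `t0` (unretained, `k0 = 0`).
#'
#' @param solute a [SoluteLSS-class]
#' @param cond a [MethodConditions-class]
#' @param instr an [InstrumentConfig-class]
#' @return retention time in minutes (always >= the dead time t0)
#' @examples
#' cond <- methodConditions(3.0, 40, 6.0)
#' gradientRetentionTime(soluteLSS(3, 10), cond, instrumentConfig())
#' @export
gradientRetentionTime <- function(solute, cond, instr) {
  lssGradientCore(solute@logKw, solute@S, cond@tG, cond@flow,
                  cond@phiStart, cond@phiEnd, instr)$tR
}

#' Gaussian peak standard deviation
#'
#' `sigma = (t0 / sqrt(N)) * (1 + k_e)` where `k_e` is the isocratic
#' retention factor at the (dwell-delayed, clamped) inlet composition at the
#' moment the band leaves the column, and N the apparent plate number.
#' Gradient peak compression is absorbed into the apparent N.
#'
#' @inheritParams gradientRetentionTime
#' @param tR_min retention time from [gradientRetentionTime()]
#' @return peak standard deviation in minutes
#' @export
peakSigma <- function(solute, cond, instr, tR_min) {
  t0 <- deadTime(instr, cond@flow)
  tD <- dwellTime(instr, cond@flow)
  tau <- tR_min - t0
  frac <- min(max((tau - tD) / cond@tG, 0), 1)
  phiE <- cond@phiStart + (cond@phiEnd - cond@phiStart) * frac
  kE <- isocraticK(solute, phiE)
  (t0 / sqrt(instr@plateNumber)) * (1 + kE)
}

#' Resolution of a peak pair
#'
#' USP-style width-based resolution `Rs = 2 |tR_b - tR_a| / (4 sigma_a +
#' 4 sigma_b)`, symmetric and non-negative.
#'
#' @param peak_a,peak_b peaks: lists or one-row data.frames carrying
#'   `tR_min` and `sigma_min`
#' @return the resolution Rs
#' @examples
#' resolution(list(tR_min = 1.0, sigma_min = 0.01),
#'            list(tR_min = 1.1, sigma_min = 0.01))  # 2.5
#' @export
resolution <- function(peak_a, peak_b) {
  2 * abs(peak_b$tR_min - peak_a$tR_min) /
    (4 * peak_a$sigma_min + 4 * peak_b$sigma_min)
}

# vectorised adjacent-pair resolutions of a sorted peak table
adjacentResolutions <- function(peaks) {
  n <- nrow(peaks)
  i <- seq_len(n - 1L)
  2 * (peaks$tR_min[i + 1L] - peaks$tR_min[i]) /
    (4 * peaks$sigma_min[i] + 4 * peaks$sigma_min[i + 1L])
}

#' Critical resolution of a chromatogram
#'
#' The minimum resolution over adjacent peak pairs in elution order, with
#' the limiting ("critical") pair. Ties are resolved in favour of the
#' earlier-eluting pair.
#'
#' @param chrom a [Chromatogram-class] with at least two peaks
#' @return list with `Rs_crit` (numeric) and `pair` (character(2), the
#'   compound ids of the critical pair, in elution order)
#' @export
setGeneric("criticalResolution", function(chrom) standardGeneric("criticalResolution"))

#' @rdname criticalResolution
#' @export
setMethod("criticalResolution", "Chromatogram", function(chrom) {
  p <- chrom@peaks
  if (nrow(p) < 2L)
    chromqbdError("critical resolution needs at least 2 peaks",
                  "chromqbd_undefined_result")
  rs <- adjacentResolutions(p)
  i <- which.min(rs)   # which.min returns the first (earliest) minimum
  list(Rs_crit = rs[i], pair = c(p$compound_id[i], p$compound_id[i + 1L]))
})
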