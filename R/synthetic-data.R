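# Synthetic ground truth: a nine-compound apixaban-like process mixture
# with physically-motivated retention laws (two-species acid-base weighted
# LSS, van't Hoff temperature dependence, optional thermal/pH degradation)
# used to generate calibration data for the whole pipeline.

#' Ground-truth solute
#'
#' The "physical truth" behind the fitted models: each solute has a neutral
#' and (optionally) an ionized species, each with its own LSS law at the
#' reference temperature (40 deg C), a van't Hoff slope shifting log10 k
#' linearly in 1/T (kelvin), an optional acid pKa mixing the species, a UV
#' response slope, and an optional degradation flag with temperature/pH
#' thresholds above which the peak is lost completely.
#'
#' @slot id compound id
#' @slot logKwN,SN neutral-species LSS parameters at 40 deg C
#' @slot logKwI,SI ionized-species LSS parameters (NA when no pKa)
#' @slot pKa acid dissociation constant (NA for non-ionizable solutes)
#' @slot vantHoff d(log10 k)/d(1/T_K) in kelvin (shared by both species)
#' @slot response relative UV response slope (area per amount)
#' @slot degradable logical
#' @slot TThreshold,pHThreshold degradation thresholds (peak lost when both
#'   are met or exceeded)
#' @export
setClass("TrueSolute",
  slots = c(id = "character", logKwN = "numeric", SN = "numeric",
            logKwI = "numeric", SI = "numeric", pKa = "numeric",
            vantHoff = "numeric", response = "numeric",
            degradable = "logical", TThreshold = "numeric",
            pHThreshold = "numeric"))

setValidity("TrueSolute", function(object) {
  if (!is.na(object@pKa)) {
    if (object@pKa <= 2 || object@pKa >= 9)
      return("pKa must lie in (2, 9)")
    if (!is.finite(object@logKwI) || object@logKwI >= object@logKwN)
      return("ionized logKw must be finite and below the neutral logKw (acid)")
  }
  TRUE
})

#' @rdname TrueSolute-class
#' @param id compound id
#' @param log_kw_n,S_n neutral-species LSS parameters at 40 deg C
#' @param log_kw_i,S_i ionized-species LSS parameters (default: no ion)
#' @param pKa acid pKa, or NA
#' @param vant_hoff d(log10 k)/d(1/T_K), kelvin
#' @param response relative UV response slope
#' @param degradable logical
#' @param T_threshold_C,pH_threshold degradation thresholds
#' @export
trueSolute <- function(id, log_kw_n, S_n, log_kw_i = NA_real_,
                       S_i = NA_real_, pKa = NA_real_, vant_hoff = 0,
                       response = 1, degradable = FALSE,
                       T_threshold_C = Inf, pH_threshold = Inf) {
  new("TrueSolute", id = id, logKwN = log_kw_n, SN = S_n,
      logKwI = log_kw_i, SI = S_i, pKa = pKa, vantHoff = vant_hoff,
      response = response, degradable = degradable,
      TThreshold = T_threshold_C, pHThreshold = pH_threshold)
}

.T_REF_K <- 40 + 273.15

# per-species log10 k at (phi, T)
.speciesLogK <- function(logKw, S, phi, T_C, vantHoff)
  logKw - S * phi + vantHoff * (1 / (T_C + 273.15) - 1 / .T_REF_K)

#' Effective retention factor of a ground-truth solute
#'
#' Acid-base weighted retention: with `R = 10^(pH - pKa)` the observed
#' retention factor is `k = (k_neutral + k_ion * R) / (1 + R)`, each
#' species' k taken from its own LSS law and shifted in temperature via the
#' van't Hoff slope `log10 k(T) = log10 k(40C) + vantHoff * (1/T_K -
#' 1/313.15)`. Non-ionizable solutes use the neutral species only. This is
#' a sigmoid in pH — deliberately a different model class than the
#' quadratic-in-pH calibration fit.
#'
#' @param solute a [TrueSolute-class]
#' @param phi organic fraction (vectorised)
#' @param T_C temperature (deg C)
#' @param pH aqueous-phase pH
#' @return retention factor(s)
#' @export
effectiveK <- function(solute, phi, T_C, pH) {
  kN <- 10^.speciesLogK(solute@logKwN, solute@SN, phi, T_C, solute@vantHoff)
  if (is.na(solute@pKa)) return(kN)
  kI <- 10^.speciesLogK(solute@logKwI, solute@SI, phi, T_C, solute@vantHoff)
  R <- 10^(pH - solute@pKa)
  (kN + kI * R) / (1 + R)
}

.isDegraded <- function(solute, T_C, pH)
  solute@degradable && T_C >= solute@TThreshold && pH >= solute@pHThreshold

#' Ground-truth gradient retention time
#'
#' Forward-simulates one ground-truth solute through a gradient program by
#' solving the migration integral `int_0^tau dt / (t0 * k(phi_inlet(t))) =
#' 1` with the dwell-delayed, clamped inlet gradient, then `tR = tau + t0`.
#' When the two species share the same S (or the solute is non-ionizable)
#' the effective law is exactly LSS at fixed (T, pH) and the closed form is
#' used; otherwise the integral is solved numerically.
#'
#' @param solute a [TrueSolute-class]
#' @param cond a [MethodConditions-class]
#' @param instr an [InstrumentConfig-class]
#' @return retention time (min)
#' @export
trueRetentionTime <- function(solute, cond, instr) {
  sameS <- is.na(solute@pKa) || isTRUE(all.equal(solute@SN, solute@SI))
  if (sameS) {
    k0phi0 <- effectiveK(solute, 0, cond@temperature, cond@pH)
    S <- solute@SN
    return(gradientRetentionTime(soluteLSS(log10(k0phi0), S), cond, instr))
  }
  t0 <- deadTime(instr, cond@flow)
  tD <- dwellTime(instr, cond@flow)
  phiAt <- function(t) {
    frac <- pmin(pmax((t - tD) / cond@tG, 0), 1)
    cond@phiStart + (cond@phiEnd - cond@phiStart) * frac
  }
  rate <- function(t)
    1 / (t0 * effectiveK(solute, phiAt(t), cond@temperature, cond@pH))
  migrated <- function(tau)
    integrate(rate, 0, tau, rel.tol = 1e-10, abs.tol = 0,
              subdivisions = 500L)$value
  endG <- tD + cond@tG
  if (migrated(endG) < 1) {
    # remainder elutes isocratically at the final composition
    kEnd <- effectiveK(solute, cond@phiEnd, cond@temperature, cond@pH)
    tau <- endG + (1 - migrated(endG)) * t0 * kEnd
    return(tau + t0)
  }
  up <- endG
  tau <- uniroot(function(x) migrated(x) - 1, c(0, up), tol = 1e-10)$root
  tau + t0
}

#' Ground-truth chromatogram of a mixture
#'
#' Simulates the full peak table of a mixture at one condition from the
#' ground truth (not from a fitted model). Degraded solutes are omitted.
#'
#' @param mixture list of [TrueSolute-class]
#' @param cond a [MethodConditions-class]
#' @param instr an [InstrumentConfig-class]
#' @param amounts named amounts (default: unit amount each); areas are
#'   amount x response slope
#' @param noise optional [NoiseSpec-class]: applies retention jitter and
#'   relative area noise
#' @return a [Chromatogram-class]
#' @export
trueChromatogram <- function(mixture, cond, instr, amounts = NULL,
                             noise = NULL) {
  mixture <- Filter(function(s) !.isDegraded(s, cond@temperature, cond@pH),
                    mixture)
  ids <- vapply(mixture, function(s) s@id, character(1))
  tR <- vapply(mixture, trueRetentionTime, numeric(1), cond = cond,
               instr = instr)
  t0 <- deadTime(instr, cond@flow)
  tD <- dwellTime(instr, cond@flow)
  sigma <- vapply(seq_along(mixture), function(i) {
    frac <- min(max((tR[i] - t0 - tD) / cond@tG, 0), 1)
    phiE <- cond@phiStart + (cond@phiEnd - cond@phiStart) * frac
    kE <- effectiveK(mixture[[i]], phiE, cond@temperature, cond@pH)
    (t0 / sqrt(instr@plateNumber)) * (1 + kE)
  }, numeric(1))
  amt <- if (is.null(amounts)) rep(1, length(ids)) else as.numeric(amounts[ids])
  area <- amt * vapply(mixture, function(s) s@response, numeric(1))
  if (!is.null(noise)) {
    draws <- withSeed(noise@seed, {
      list(dtR = rnorm(length(tR), 0, noise@tRJitterSd),
           dA = rnorm(length(area), 0, noise@areaCV))
    })
    tR <- pmax(tR + draws$dtR, t0)
    area <- pmax(area * (1 + draws$dA), 0)
  }
  newChromatogram(cond, data.frame(
    compound_id = ids, tR_min = tR, sigma_min = sigma, area = area,
    stringsAsFactors = FALSE))
}

#' Noise specification for the generator
#'
#' All generator randomness flows from the single mandatory seed; there is
#' no entropy default.
#'
#' @slot tRJitterSd Gaussian sd of retention-time noise (min)
#' @slot areaCV relative sd of area noise
#' @slot seed integer RNG seed
#' @export
setClass("NoiseSpec",
  slots = c(tRJitterSd = "numeric", areaCV = "numeric", seed = "integer"))

setValidity("NoiseSpec", function(object) {
  if (object@tRJitterSd < 0 || object@areaCV < 0)
    return("noise sds must be >= 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("an explicit integer seed is mandatory")
  TRUE
})

#' @rdname NoiseSpec-class
#' @param tR_jitter_sd_min Gaussian sd of retention noise (min)
#' @param area_cv relative area noise
#' @param seed mandatory integer seed
#' @export
noiseSpec <- function(tR_jitter_sd_min = 0, area_cv = 0, seed) {
  if (missing(seed))
    chromqbdError("noiseSpec requires an explicit seed",
                  "chromqbd_input_error")
  new("NoiseSpec", tRJitterSd = tR_jitter_sd_min, areaCV = area_cv,
      seed = as.integer(seed))
}

# run fn with a local, seeded RNG stream; the global stream is untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' The packaged apixaban-like process mixture
#'
#' Nine ground-truth solutes (Stm1, Stm2, Int1-Int6, apixaban) whose frozen
#' constants were authored once (see tools/fixture_tuning.R in the source
#' repository) so that at the nominal working point — 3.0 min gradient
#' 10->80 %B, 40 deg C, pH 6.0, 0.8 mL/min — the simulated elution order is
#' Int6 < Stm1 < Apixaban < Int2 < Int1 < Int5 < Stm2 < Int4 < Int3 with
#' all peaks inside 0.7-2.5 min and a critical resolution of about 2.4 for
#' the closing Int4/Int3 pair. Int6 is an acid whose retention is strongly
#' pH-dependent below pH ~5; Stm2 is flagged degradable at 80 deg C / pH
#' 6.4 and above. UV response slopes follow the published 280 nm correction
#' factors. The constants are fixture data, never fitted at run time.
#'
#' @return list of nine [TrueSolute-class] objects
#' @export
defaultApixabanMixture <- function() {
  list(
    trueSolute("Stm1",     log_kw_n = 2.00182, S_n = 5.5, vant_hoff = 850,
               response = 1.16),
    trueSolute("Stm2",     log_kw_n = 3.37784, S_n = 6.2, vant_hoff = 1150,
               response = 2.38, degradable = TRUE, T_threshold_C = 80,
               pH_threshold = 6.4),
    trueSolute("Int1",     log_kw_n = 2.84319, S_n = 5.8, vant_hoff = 1100,
               response = 1.34),
    trueSolute("Int2",     log_kw_n = 2.69754, S_n = 6.5, vant_hoff = 950,
               response = 1.82),
    trueSolute("Int3",     log_kw_n = 4.04506, S_n = 6.8, vant_hoff = 1205,
               response = 1.27),
    trueSolute("Int4",     log_kw_n = 3.94982, S_n = 6.8, vant_hoff = 1200,
               response = 1.03),
    trueSolute("Int5",     log_kw_n = 3.53796, S_n = 7.0, vant_hoff = 1050,
               response = 1.29),
    trueSolute("Int6",     log_kw_n = 2.06228, S_n = 5.0, log_kw_i = 1.56228,
               S_i = 5.0, pKa = 3.75, vant_hoff = 900, response = 1.19),
    trueSolute("Apixaban", log_kw_n = 2.39074, S_n = 6.0, vant_hoff = 1000,
               response = 1.00)
  )
}

#' Generate a calibration run table from ground truth
#'
#' Forward-simulates every solute of the mixture through every run of the
#' design (via [trueRetentionTime()], i.e. the migration integral on the
#' effective acid-base retention law — not any fitted model), applies
#' seeded Gaussian retention jitter, and omits degradable solutes at
#' conditions at/beyond their thresholds. Deterministic for a fixed seed.
#'
#' @param mixture list of [TrueSolute-class], e.g.
#'   [defaultApixabanMixture()]
#' @param design a [CalibrationDesign-class]
#' @param instr an [InstrumentConfig-class]
#' @param noise a [NoiseSpec-class]
#' @return run-table data.frame (columns run_id, tG_min, T_C, pH,
#'   flow_mL_min, pctB_start, pctB_end, compound_id, tR_min)
#' @export
generateRunTable <- function(mixture, design, instr, noise) {
  stopifnot(is(noise, "NoiseSpec"))
  runs <- designRuns(design)
  rows <- list()
  for (r in seq_len(nrow(runs))) {
    cond <- methodConditions(runs$tG_min[r], runs$T_C[r], runs$pH[r],
                             runs$flow_mL_min[r], runs$pctB_start[r] / 100,
                             runs$pctB_end[r] / 100)
    for (s in mixture) {
      if (.isDegraded(s, cond@temperature, cond@pH)) next
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = runs$run_id[r], tG_min = runs$tG_min[r],
        T_C = runs$T_C[r], pH = runs$pH[r],
        flow_mL_min = runs$flow_mL_min[r],
        pctB_start = runs$pctB_start[r], pctB_end = runs$pctB_end[r],
        compound_id = s@id,
        tR_min = trueRetentionTime(s, cond, instr),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (noise@tRJitterSd > 0) {
    jit <- withSeed(noise@seed, rnorm(nrow(tab), 0, noise@tRJitterSd))
    tab$tR_min <- tab$tR_min + jit
  }
  tab
}
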