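# Design-space mapping: critical resolution on a (tG, T, pH) grid,
# robust working-point selection and sub-space re-evaluation.

#' Map the design space
#'
#' Evaluates the predicted critical resolution (and its critical pair) at
#' every node of a (tG, T, pH) grid via [predictChromatogram()] and
#' [criticalResolution()]. Evaluation is pure: identical inputs give
#' identical maps.
#'
#' @param model a [FittedModel-class]
#' @param tG,T_C,pH numeric axis grids (sorted internally)
#' @param instr an [InstrumentConfig-class]
#' @param flow,phi_start,phi_end shared gradient settings; default to the
#'   calibration design's values
#' @param criterion the resolution acceptance threshold
#' @return a [DesignSpaceMap-class]
#' @export
mapDesignSpace <- function(model, tG, T_C, pH, instr,
                           flow = model@design@flow,
                           phi_start = model@design@phiStart,
                           phi_end = model@design@phiEnd,
                           criterion = 2.0) {
  tG <- sort(unique(tG)); T_C <- sort(unique(T_C)); pH <- sort(unique(pH))
  d <- c(length(tG), length(T_C), length(pH))
  Rs <- array(NA_real_, d)
  p1 <- array(NA_character_, d)
  p2 <- array(NA_character_, d)
  for (ti in seq_along(T_C)) for (pi in seq_along(pH)) {
    for (gi in seq_along(tG)) {
      cond <- methodConditions(tG[gi], T_C[ti], pH[pi], flow,
                               phi_start, phi_end)
      chrom <- predictChromatogram(model, cond, instr)
      if (nrow(chrom@peaks) < 2L) next
      cr <- criticalResolution(chrom)
      Rs[gi, ti, pi] <- cr$Rs_crit
      p1[gi, ti, pi] <- cr$pair[1]
      p2[gi, ti, pi] <- cr$pair[2]
    }
  }
  new("DesignSpaceMap", tG = tG, temperature = T_C, pH = pH, Rs = Rs,
      pairFirst = p1, pairSecond = p2, criterion = criterion,
      model = model, instrument = instr, flow = flow,
      phiStart = phi_start, phiEnd = phi_end)
}

# normalised axis coordinates in [0, 1]; a single-node axis collapses to 0
.normAxis <- function(x) {
  r <- diff(range(x))
  if (r == 0) rep(0, length(x)) else (x - min(x)) / r
}

#' Select the robust working point of a design-space map
#'
#' Among grid nodes meeting the criterion, picks the node with the largest
#' L-infinity robustness radius on axes normalised to `[0, 1]`: the largest
#' box half-width such that the box stays inside the grid and every grid
#' node inside the closed box still meets the criterion. Ties are broken by
#' smaller tG, then smaller temperature, then smaller pH, so the selection
#' is deterministic. Collapsed (single-node) axes are ignored in the
#' geometry.
#'
#' @param dsmap a [DesignSpaceMap-class]
#' @return a [WorkingPoint-class]
#' @export
setGeneric("findRobustWorkingPoint", function(dsmap)
  standardGeneric("findRobustWorkingPoint"))

#' @rdname findRobustWorkingPoint
#' @export
setMethod("findRobustWorkingPoint", "DesignSpaceMap", function(dsmap) {
  d <- dim(dsmap@Rs)
  idx <- expand.grid(gi = seq_len(d[1]), ti = seq_len(d[2]),
                     pi = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE)
  u1 <- .normAxis(dsmap@tG)[idx$gi]
  u2 <- .normAxis(dsmap@temperature)[idx$ti]
  u3 <- .normAxis(dsmap@pH)[idx$pi]
  live <- c(length(dsmap@tG) > 1L, length(dsmap@temperature) > 1L,
            length(dsmap@pH) > 1L)
  rs <- as.numeric(dsmap@Rs)
  pass <- !is.na(rs) & rs >= dsmap@criterion
  if (!any(pass))
    chromqbdError("no grid node meets the resolution criterion",
                  "chromqbd_no_design_space")

  U <- cbind(u1, u2, u3)[, live, drop = FALSE]
  cand <- which(pass)
  radius <- numeric(length(cand))
  for (j in seq_along(cand)) {
    p <- U[cand[j], , drop = TRUE]
    edge <- if (ncol(U)) min(pmin(p, 1 - p)) else 0
    dist <- if (ncol(U))
      apply(abs(sweep(U, 2, p)), 1, max) else rep(0, nrow(idx))
    dFail <- suppressWarnings(min(dist[!pass]))   # Inf when all pass
    if (is.infinite(dFail)) {
      radius[j] <- edge
    } else {
      ok <- dist[dist < dFail - 1e-12]
      radius[j] <- min(edge, if (length(ok)) max(ok) else 0)
    }
  }
  ord <- order(-radius, dsmap@tG[idx$gi[cand]],
               dsmap@temperature[idx$ti[cand]], dsmap@pH[idx$pi[cand]])
  best <- cand[ord[1]]
  cond <- methodConditions(dsmap@tG[idx$gi[best]],
                           dsmap@temperature[idx$ti[best]],
                           dsmap@pH[idx$pi[best]],
                           dsmap@flow, dsmap@phiStart, dsmap@phiEnd)
  new("WorkingPoint", conditions = cond, radius = radius[ord[1]],
      RsCrit = rs[best],
      pair = c(dsmap@pairFirst[best], dsmap@pairSecond[best]))
})

#' Re-evaluate a sub-region of a design-space map
#'
#' Builds a fresh grid over the requested sub-ranges (default: the close-in
#' region around the working point, tG 2.0-4.0 min, T 35-45 deg C, pH
#' 5.8-6.4) and re-evaluates every node with the stored model — nodes are
#' recomputed, not sliced, so any grid density can be requested.
#'
#' @param dsmap a [DesignSpaceMap-class] that still carries its model
#' @param tG_range,T_range,pH_range length-2 ranges, each within the parent
#'   map's axis range
#' @param tG_step,T_step,pH_step grid steps (defaults 0.1 min, 1 deg C,
#'   0.1 pH)
#' @return a new [DesignSpaceMap-class]
#' @export
setGeneric("extractSubspace", function(dsmap, tG_range = c(2, 4),
                                       T_range = c(35, 45),
                                       pH_range = c(5.8, 6.4),
                                       tG_step = 0.1, T_step = 1,
                                       pH_step = 0.1)
  standardGeneric("extractSubspace"))

#' @rdname extractSubspace
#' @export
setMethod("extractSubspace", "DesignSpaceMap", function(dsmap, tG_range,
                                                        T_range, pH_range,
                                                        tG_step, T_step,
                                                        pH_step) {
  if (is.null(dsmap@model))
    chromqbdError("map carries no model; cannot re-evaluate",
                  "chromqbd_input_error")
  chk <- function(r, axis, what) {
    if (length(r) != 2L || r[1] > r[2])
      chromqbdError(sprintf("%s_range must be an increasing length-2 range", what),
                    "chromqbd_input_error")
    if (r[1] < min(axis) - 1e-9 || r[2] > max(axis) + 1e-9)
      chromqbdError(sprintf("%s_range is outside the parent map", what),
                    "chromqbd_input_error")
  }
  chk(tG_range, dsmap@tG, "tG")
  chk(T_range, dsmap@temperature, "T")
  chk(pH_range, dsmap@pH, "pH")
  mapDesignSpace(dsmap@model,
                 tG = seq(tG_range[1], tG_range[2], by = tG_step),
                 T_C = seq(T_range[1], T_range[2], by = T_step),
                 pH = seq(pH_range[1], pH_range[2], by = pH_step),
                 instr = dsmap@instrument, flow = dsmap@flow,
                 phi_start = dsmap@phiStart, phi_end = dsmap@phiEnd,
                 criterion = dsmap@criterion)
})

#' Flatten a design-space map into a long table
#'
#' @param x a [DesignSpaceMap-class]
#' @param ... unused
#' @return data.frame with tG_min, T_C, pH, Rs_crit, crit_pair
#' @export
setMethod("as.data.frame", "DesignSpaceMap", function(x, ...) {
  d <- dim(x@Rs)
  idx <- expand.grid(gi = seq_len(d[1]), ti = seq_len(d[2]),
                     pi = seq_len(d[3]), KEEP.OUT.ATTRS = FALSE)
  data.frame(
    tG_min = x@tG[idx$gi], T_C = x@temperature[idx$ti], pH = x@pH[idx$pi],
    Rs_crit = as.numeric(x@Rs),
    crit_pair = ifelse(is.na(as.vector(x@pairFirst)), NA_character_,
                       paste0(as.vector(x@pairFirst), "-",
                              as.vector(x@pairSecond))),
    stringsAsFactors = FALSE)
})
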