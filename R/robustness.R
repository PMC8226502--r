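# Full-factorial virtual robustness study: enumeration, per-combination
# prediction, worst-case ranking, success rate and main effects.

#' Enumerate a full-factorial level grid
#'
#' Cartesian product of the factor levels in the fixed factor order
#' (tG_min, T_C, pH, flow_mL_min, pctB_start, pctB_end) with the rightmost
#' factor varying fastest; a 1-based combination index is assigned in that
#' order. The enumeration is the package's deterministic scenario-id
#' convention.
#'
#' @param levels a [FactorLevels-class]
#' @return data.frame with `index`, one value column per factor, and one
#'   `lvl_*` integer column per factor (1-based level index)
#' @examples
#' nrow(enumerateFactorial(factorLevels()))  # 3^6 = 729
#' @export
enumerateFactorial <- function(levels) {
  stopifnot(is(levels, "FactorLevels"))
  validObject(levels)
  lv <- levels@levels
  # expand.grid varies the FIRST factor fastest; feed reversed order and
  # restore, so the rightmost spec factor varies fastest
  codes <- expand.grid(rev(lapply(lv, seq_along)), KEEP.OUT.ATTRS = FALSE)
  codes <- codes[, rev(seq_along(lv)), drop = FALSE]
  names(codes) <- paste0("lvl_", names(lv))
  vals <- as.data.frame(Map(function(v, i) v[i], lv,
                            codes[paste0("lvl_", names(lv))]))
  names(vals) <- names(lv)
  out <- cbind(index = seq_len(nrow(vals)), vals, codes)
  rownames(out) <- NULL
  out
}

#' Run the virtual robustness study
#'
#' For every factor combination the full method conditions are assembled
#' (flow rescales the dead and dwell times; the %B end points rescale the
#' gradient limits), a chromatogram is predicted and the critical
#' resolution recorded. A failed prediction is recorded as `NA` and counts
#' as a failure in the success rate rather than aborting the study.
#'
#' @param model a [FittedModel-class]
#' @param levels a [FactorLevels-class] (defaults to [factorLevels()])
#' @param instr an [InstrumentConfig-class]
#' @param criterion the resolution criterion (default 2.0)
#' @return a [RobustnessResult-class]
#' @export
runVirtualRobustness <- function(model, levels = factorLevels(), instr,
                                 criterion = 2.0) {
  tab <- enumerateFactorial(levels)
  n <- nrow(tab)
  Rs <- rep(NA_real_, n)
  pair <- rep(NA_character_, n)

  # the (T, pH) pair determines the interpolated parameters: cache them
  key <- paste(tab$T_C, tab$pH)
  for (k in unique(key)) {
    rows <- which(key == k)
    T_C <- tab$T_C[rows[1]]; pH <- tab$pH[rows[1]]
    par <- tryCatch(interpolateAll(model, T_C, pH), error = function(e) NULL)
    if (is.null(par)) next
    keep <- !is.na(par[, "logKw"])
    par <- par[keep, , drop = FALSE]
    if (nrow(par) < 2L) next
    for (i in rows) {
      res <- tryCatch({
        core <- lssGradientCore(par[, "logKw"], par[, "S"],
                                tab$tG_min[i], tab$flow_mL_min[i],
                                tab$pctB_start[i] / 100,
                                tab$pctB_end[i] / 100, instr)
        sigma <- (core$t0 / sqrt(instr@plateNumber)) * (1 + core$kElute)
        pk <- orderPeaks(data.frame(compound_id = rownames(par),
                                    tR_min = core$tR, sigma_min = sigma,
                                    area = 1, stringsAsFactors = FALSE))
        rsv <- adjacentResolutions(pk)
        j <- which.min(rsv)
        list(rs = rsv[j], pair = paste0(pk$compound_id[j], "-",
                                        pk$compound_id[j + 1L]))
      }, error = function(e) NULL)
      if (!is.null(res)) { Rs[i] <- res$rs; pair[i] <- res$pair }
    }
  }

  tab$Rs_crit <- Rs
  tab$crit_pair <- pair
  ok <- !is.na(Rs) & Rs >= criterion
  new("RobustnessResult", table = tab, successRate = sum(ok) / n,
      criterion = criterion, levels = levels)
}

#' Worst combinations of a robustness study
#'
#' Rows sorted ascending by critical resolution (failed predictions first),
#' ties broken by enumeration index — a stable, deterministic ranking.
#'
#' @param result a [RobustnessResult-class]
#' @param n how many rows to return
#' @return the n worst rows of the result table
#' @export
worstRows <- function(result, n = 6) {
  tab <- result@table
  ord <- order(is.na(tab$Rs_crit), tab$Rs_crit, tab$index,
               decreasing = c(TRUE, FALSE, FALSE), method = "radix")
  head(tab[ord, , drop = FALSE], n)
}

#' Main effects of the robustness factors
#'
#' For a complete factorial, the mean critical resolution at each level of
#' each factor. In a balanced design the mean of a factor's level means
#' equals the grand mean, which is attached as attribute `grand_mean`.
#'
#' @param result a [RobustnessResult-class] over a complete factorial
#' @return data.frame with factor, level (value), level_index and mean_Rs;
#'   attribute `grand_mean`
#' @export
setGeneric("mainEffects", function(result) standardGeneric("mainEffects"))

#' @rdname mainEffects
#' @export
setMethod("mainEffects", "RobustnessResult", function(result) {
  lv <- result@levels@levels
  tab <- result@table
  if (nrow(tab) != prod(vapply(lv, length, integer(1))))
    chromqbdError("main effects require the complete factorial",
                  "chromqbd_input_error")
  rows <- lapply(names(lv), function(nm) {
    vapply(seq_along(lv[[nm]]), function(i)
      mean(tab$Rs_crit[tab[[paste0("lvl_", nm)]] == i]), numeric(1))
  })
  out <- data.frame(
    factor = rep(names(lv), lengths(lv)),
    level = unlist(lv, use.names = FALSE),
    level_index = unlist(lapply(lengths(lv), seq_len), use.names = FALSE),
    mean_Rs = unlist(rows, use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(out, "grand_mean") <- mean(tab$Rs_crit)
  out
})
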