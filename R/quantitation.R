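# UV response correction factors and corrected area-percent purity.

#' Round half up
#'
#' Report rounding convention (2 decimals, half away from zero) used for
#' printed correction factors and retention times; distinct from R's
#' banker's rounding.
#'
#' @param x numeric
#' @param digits decimal places (default 2)
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 guard keeps exact decimal halves (stored just below .5 in
  # binary) rounding up, e.g. 1.005 -> 1.01
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Build a pairwise correction-factor matrix from response slopes
#'
#' Each compound's detector response slope (area per amount at the working
#' wavelength) is measured by individual injection; the pairwise correction
#' factor is the slope ratio `f[i, j] = slope_i / slope_j`, so the diagonal
#' is exactly 1 and the matrix is multiplicatively consistent at full
#' precision by construction. Report output rounds to 2 decimals; full
#' precision is retained internally.
#'
#' @param slopes named positive numeric vector of response slopes
#' @return square matrix with dimnames = compound ids
#' @examples
#' factorMatrixFromResponses(c(A = 2, B = 1))
#' @export
factorMatrixFromResponses <- function(slopes) {
  if (is.null(names(slopes)) || any(!nzchar(names(slopes))))
    chromqbdError("slopes must be a named vector", "chromqbd_input_error")
  if (any(!is.finite(slopes)) || any(slopes <= 0))
    chromqbdError("all response slopes must be finite and > 0",
                  "chromqbd_input_error")
  outer(slopes, slopes, "/")
}

#' Multiplicative consistency check of a factor matrix
#'
#' A correction-factor matrix is internally consistent when chaining
#' factors reproduces direct ones: `f[i,j] * f[j,k] = f[i,k]`. Every
#' ordered triple of distinct compounds whose three entries are all present
#' (not NA) is tested; triples deviating by more than `tol` are returned.
#'
#' @param mat square factor matrix (NA = missing entry)
#' @param tol absolute tolerance (default 0.02, about the rounding noise of
#'   2-decimal printed factors)
#' @return data.frame of violating triples (i, j, k, chained, direct,
#'   discrepancy); zero rows when consistent
#' @export
consistencyCheck <- function(mat, tol = 0.02) {
  ids <- rownames(mat)
  out <- list()
  n <- nrow(mat)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (is.na(mat[i, j]) || is.na(mat[j, k]) || is.na(mat[i, k])) next
    chained <- mat[i, j] * mat[j, k]
    disc <- abs(chained - mat[i, k])
    if (disc > tol)
      out[[length(out) + 1L]] <- data.frame(
        i = ids[i], j = ids[j], k = ids[k],
        chained = chained, direct = mat[i, k], discrepancy = disc,
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(i = character(), j = character(), k = character(),
               chained = numeric(), direct = numeric(),
               discrepancy = numeric(), stringsAsFactors = FALSE)
}

#' Corrected area-percent purity
#'
#' Converts raw peak areas to response-corrected area percent relative to a
#' reference compound: `percent_i = 100 * area_i * f[ref, i] / sum_j area_j
#' * f[ref, j]`. With full-precision factors the result is invariant to the
#' choice of reference and to a common scaling of the areas; the percents
#' sum to 100.
#'
#' @param areas named non-negative numeric vector of raw peak areas (at
#'   least one > 0)
#' @param factors full-precision factor matrix with `f[i, j] = slope_i /
#'   slope_j` covering every compound with a positive area
#' @param ref reference compound id (a rowname of `factors`)
#' @return named numeric vector of percents summing to 100
#' @examples
#' f <- factorMatrixFromResponses(c(A = 1, B = 3))
#' correctedAreaPercent(c(A = 10, B = 10), f, ref = "A")  # 25 / 75
#' @export
correctedAreaPercent <- function(areas, factors, ref) {
  if (any(areas < 0) || all(areas == 0))
    chromqbdError("areas must be >= 0 with at least one > 0",
                  "chromqbd_input_error")
  if (!ref %in% rownames(factors))
    chromqbdError(sprintf("reference %s missing from the factor matrix", ref),
                  "chromqbd_quantitation_error")
  ids <- names(areas)
  if (is.null(ids) || !all(ids %in% colnames(factors)))
    chromqbdError("a peak with area > 0 has no correction factor",
                  "chromqbd_quantitation_error")
  f <- factors[ref, ids]
  if (anyNA(f))
    chromqbdError("a peak with area > 0 has no correction factor",
                  "chromqbd_quantitation_error")
  w <- areas * f
  100 * w / sum(w)
}

# printed upper triangle of the 280 nm correction-factor table for the
# apixaban process mixture (rows relative to columns, f[i,j] = slope_i/slope_j)
.APX_FACTOR_IDS <- c("Stm1", "Int1", "Int2", "Stm2", "Int3", "Int4", "Int5",
                     "Int6", "Apixaban")
.APX_FACTORS_UPPER <- matrix(c(
  1.00, 0.87, 0.64,   NA, 0.92, 1.13, 0.90, 0.98, 1.16,
    NA, 1.00, 0.73,   NA, 1.06, 1.30, 1.03, 1.13, 1.34,
    NA,   NA, 1.00,   NA, 1.44, 1.77, 1.41, 1.54, 1.82,
    NA,   NA,   NA, 1.00, 1.88, 2.32, 1.84, 2.01, 2.38,
    NA,   NA,   NA,   NA, 1.00, 1.23, 0.98, 1.07, 1.27,
    NA,   NA,   NA,   NA,   NA, 1.00, 0.79, 0.87, 1.03,
    NA,   NA,   NA,   NA,   NA,   NA, 1.00, 1.09, 1.29,
    NA,   NA,   NA,   NA,   NA,   NA,   NA, 1.00, 1.19,
    NA,   NA,   NA,   NA,   NA,   NA,   NA,   NA, 1.00),
  nrow = 9, byrow = TRUE,
  dimnames = list(.APX_FACTOR_IDS, .APX_FACTOR_IDS))

#' Published correction factors of the apixaban process mixture
#'
#' The 280 nm pairwise UV correction factors of the nine process compounds
#' (Stm1, Stm2, Int1-Int6, apixaban), as printed: an upper-triangular table
#' with `f[i, j] = slope_i / slope_j` rounded to 2 decimals. The missing
#' lower triangle can be reconstructed by reciprocal symmetry
#' `f[j, i] = 1 / f[i, j]` on load.
#'
#' @param fill reconstruct the lower triangle by reciprocal symmetry
#'   (default TRUE)
#' @return 9 x 9 factor matrix (NA where not printed and `fill = FALSE`)
#' @export
apixabanCorrectionFactors <- function(fill = TRUE) {
  m <- .APX_FACTORS_UPPER
  if (fill) {
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      if (is.na(m[i, j]) && !is.na(m[j, i])) m[i, j] <- 1 / m[j, i]
  }
  m
}
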