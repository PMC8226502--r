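# Forward LSS physics: isocratic law, gradient elution regimes, widths,
# resolution and the critical pair.

test_that("isocratic retention follows the base-10 LSS law", {
  expect_equal(isocraticK(soluteLSS(0, 0), 0.5), 1)
  expect_equal(isocraticK(soluteLSS(2, 4), 0.5), 1)
  expect_equal(isocraticK(soluteLSS(3, 10), 0.1), 100)
  expect_equal(isocraticK(soluteLSS(-Inf, 5), 0.3), 0)
  expect_error(isocraticK(soluteLSS(1, 5), 1.5), class = "chromqbd_invalid_parameter")
  expect_error(isocraticK(soluteLSS(1, 5), NaN), class = "chromqbd_invalid_parameter")
})

test_that("gradient retention handles degenerate and dwell-elution regimes", {
  instr <- defaultInstr()
  cond <- wpCond()
  t0 <- deadTime(instr, cond@flow)

  # zero steepness: exact isocratic limit at the initial composition
  k <- isocraticK(soluteLSS(0.7, 0), cond@phiStart)
  expect_equal(gradientRetentionTime(soluteLSS(0.7, 0), cond, instr),
               t0 * (1 + k))
  # unretained sentinel elutes at the dead time
  expect_equal(gradientRetentionTime(soluteLSS(-Inf, 8), cond, instr), t0)
  # weakly retained solute leaves during the dwell hold: isocratic at k0
  weak <- soluteLSS(log10(0.5) + 6 * cond@phiStart, 6)  # k0 = 0.5
  expect_lt(dwellTime(instr, cond@flow) / (t0 * 0.5), Inf)
  expect_equal(gradientRetentionTime(weak, cond, instr), t0 * 1.5)
  # every result is bounded below by the dead time
  expect_gte(gradientRetentionTime(soluteLSS(-1.9, 2), cond, instr), t0)
})

test_that("closed-form gradient elution matches the migration-integral oracle", {
  instr <- defaultInstr()
  # the spec-level reference case
  cond <- methodConditions(3.0, 40, 6.0, 0.8, 0.10, 0.80)
  sol <- soluteLSS(3.0, 10)
  expect_lt(abs(gradientRetentionTime(sol, cond, instr) -
                oracleTR(3.0, 10, cond, instr)), 1e-4)

  # random in-gradient cases
  cases <- randomLSSCases(80, seed = 421)
  for (i in seq_len(nrow(cases))) {
    cc <- cases[i, ]
    cond <- methodConditions(cc$tG, 40, 6.0, cc$flow, cc$phiStart, cc$phiEnd)
    tR <- gradientRetentionTime(soluteLSS(cc$logKw, cc$S), cond, instr)
    expect_lt(abs(tR - oracleTR(cc$logKw, cc$S, cond, instr)), 1e-4)
  }

  # post-gradient regime: retained well past the short ramp
  cond3 <- methodConditions(0.4, 40, 6.0, 0.8, 0.10, 0.30)
  for (lk in c(2.0, 2.5, 3.0)) {
    tR <- gradientRetentionTime(soluteLSS(lk, 4), cond3, instr)
    expect_gt(tR, deadTime(instr, 0.8) + dwellTime(instr, 0.8) + 0.4)
    expect_lt(abs(tR - oracleTR(lk, 4, cond3, instr)), 1e-4)
  }
})

test_that("retention is monotone in eluent strength and continuous at the isocratic limit", {
  instr <- defaultInstr()
  sol <- soluteLSS(3.2, 8)
  # stronger initial eluent never increases retention
  tRs <- vapply(seq(0.05, 0.35, by = 0.03), function(phi0)
    gradientRetentionTime(sol, methodConditions(3, 40, 6, 0.8, phi0, 0.8),
                          instr), numeric(1))
  expect_true(all(diff(tRs) <= 1e-12))

  # vanishing gradient span converges to the isocratic limit
  t0 <- deadTime(instr, 0.8)
  iso <- t0 * (1 + isocraticK(sol, 0.3))
  near <- gradientRetentionTime(sol, methodConditions(3, 40, 6, 0.8, 0.3,
                                                      0.3 + 1e-4), instr)
  expect_lt(abs(near - iso), 1e-3)

  # doubling flow shortens retention and still matches the oracle
  for (f in c(0.4, 0.8, 1.6)) {
    cond <- methodConditions(3, 40, 6, f, 0.1, 0.8)
    expect_lt(abs(gradientRetentionTime(sol, cond, instr) -
                  oracleTR(3.2, 8, cond, instr)), 1e-4)
  }
  expect_lt(gradientRetentionTime(sol, methodConditions(3, 40, 6, 1.6, 0.1, 0.8), instr),
            gradientRetentionTime(sol, methodConditions(3, 40, 6, 0.8, 0.1, 0.8), instr))
})

test_that("peak widths follow sigma = (t0/sqrt(N)) (1 + k_e)", {
  instr <- instrumentConfig(dead_volume_mL = 0.110, plate_number = 10000)
  cond <- wpCond()   # t0 = 0.1375 min at 0.8 mL/min
  # k constant at 1 regardless of composition -> sigma = (t0/100) * 2
  sol <- soluteLSS(0, 0)
  tR <- gradientRetentionTime(sol, cond, instr)
  expect_equal(peakSigma(sol, cond, instr, tR), 0.00275)
  # unretained: sigma = t0 / sqrt(N)
  solU <- soluteLSS(-Inf, 5)
  expect_equal(peakSigma(solU, cond, instr, deadTime(instr, 0.8)),
               0.1375 / 100)
  # fixture peaks all fall in the plausible UHPLC width range
  ch <- trueChromatogram(defaultApixabanMixture(), cond, defaultInstr())
  expect_true(all(peaks(ch)$sigma_min > 0.002 & peaks(ch)$sigma_min < 0.02))
})

test_that("resolution is the symmetric USP width-based measure", {
  expect_equal(resolution(list(tR_min = 1, sigma_min = 0.01),
                          list(tR_min = 1, sigma_min = 0.02)), 0)
  expect_equal(resolution(list(tR_min = 1.0, sigma_min = 0.01),
                          list(tR_min = 1.1, sigma_min = 0.01)), 2.5)
  withr::with_seed(7, {
    for (i in 1:20) {
      a <- list(tR_min = runif(1, 0, 3), sigma_min = runif(1, 1e-3, 1e-1))
      b <- list(tR_min = runif(1, 0, 3), sigma_min = runif(1, 1e-3, 1e-1))
      expect_identical(resolution(a, b), resolution(b, a))
      expect_gte(resolution(a, b), 0)
    }
  })
})

test_that("critical resolution is the minimum over adjacent pairs with the earliest-pair tie rule", {
  cond <- wpCond()
  mk <- function(tR, sigma = rep(0.01, length(tR)),
                 id = sprintf("C%02d", seq_along(tR)))
    new("Chromatogram", conditions = cond,
        peaks = data.frame(compound_id = id, tR_min = tR, sigma_min = sigma,
                           area = 1, stringsAsFactors = FALSE))

  two <- mk(c(1.0, 1.1))
  cr <- criticalResolution(two)
  expect_equal(cr$Rs_crit, 2.5)
  expect_equal(cr$pair, c("C01", "C02"))

  # equally spaced, equal widths: first adjacent pair wins the tie
  eq <- mk(c(1.0, 1.2, 1.4, 1.6))
  expect_equal(criticalResolution(eq)$pair, c("C01", "C02"))

  # random 9-peak chromatograms agree with a brute-force scan
  withr::with_seed(99, {
    for (rep in 1:15) {
      tR <- sort(runif(9, 0.5, 3))
      sg <- runif(9, 2e-3, 2e-2)
      ch <- mk(tR, sg)
      p <- peaks(ch)
      brute <- vapply(1:8, function(i)
        resolution(p[i, ], p[i + 1, ]), numeric(1))
      cr <- criticalResolution(ch)
      expect_equal(cr$Rs_crit, min(brute))
      expect_equal(cr$pair,
                   c(p$compound_id[which.min(brute)],
                     p$compound_id[which.min(brute) + 1]))
    }
  })

  expect_error(criticalResolution(mk(1.0)), class = "chromqbd_undefined_result")
})

test_that("chromatograms keep a stable peak order with lexicographic tie-break", {
  cond <- wpCond()
  p <- data.frame(compound_id = c("B", "A", "C"), tR_min = c(1.2, 1.2, 0.9),
                  sigma_min = 0.01, area = 1, stringsAsFactors = FALSE)
  ch <- chromqbd:::newChromatogram(cond, p)
  expect_equal(peaks(ch)$compound_id, c("C", "A", "B"))
  expect_true(validObject(ch))
})
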