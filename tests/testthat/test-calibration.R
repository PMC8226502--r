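# Two-run LSS inversion, 12-run model fitting, (T, pH) interpolation and
# chromatogram prediction.

calCondPair <- function(T_C = 40, pH = 6.0, design = calibrationDesign())
  list(methodConditions(design@tGLevels[1], T_C, pH, design@flow,
                        design@phiStart, design@phiEnd),
       methodConditions(design@tGLevels[2], T_C, pH, design@flow,
                        design@phiStart, design@phiEnd))

test_that("two-gradient inversion recovers known LSS parameters", {
  instr <- defaultInstr()
  cp <- calCondPair()
  truth <- soluteLSS(2.8, 12)
  tR1 <- gradientRetentionTime(truth, cp[[1]], instr)
  tR2 <- gradientRetentionTime(truth, cp[[2]], instr)
  fit <- invertTwoGradients(tR1, tR2, cp[[1]], cp[[2]], instr)
  expect_lt(abs(fit@logKw - 2.8), 1e-3)
  expect_lt(abs(fit@S - 12), 1e-2)

  # random sweep with a held-out third gradient time
  withr::with_seed(11, {
    for (i in 1:30) {
      # keep the solute retained past the dwell at both gradient times
      S <- runif(1, 3, 25); lk <- runif(1, 0.1 * S + 0.5, 4.8)
      t1 <- gradientRetentionTime(soluteLSS(lk, S), cp[[1]], instr)
      t2 <- gradientRetentionTime(soluteLSS(lk, S), cp[[2]], instr)
      f <- invertTwoGradients(t1, t2, cp[[1]], cp[[2]], instr)
      held <- methodConditions(3.0, 40, 6.0)
      expect_lt(abs(gradientRetentionTime(f, held, instr) -
                    gradientRetentionTime(soluteLSS(lk, S), held, instr)),
                1e-3)
    }
  })
})

test_that("inversion flags unretained and gradient-insensitive solutes", {
  instr <- defaultInstr()
  cp <- calCondPair()
  t0 <- deadTime(instr, 0.8)
  expect_error(
    invertTwoGradients(t0, t0 * 1.2, cp[[1]], cp[[2]], instr, "X"),
    class = "chromqbd_unretained")
  # identical retention at both gradient times: S ~ 0, flagged
  iso <- t0 * (1 + 2)
  expect_error(
    invertTwoGradients(iso, iso, cp[[1]], cp[[2]], instr, "flat"),
    class = "chromqbd_gradient_insensitive")
  # conditions must differ only in tG
  cWrongT <- methodConditions(4.5, 45, 6.0)
  expect_error(invertTwoGradients(1.0, 1.4, cp[[1]], cWrongT, instr),
               class = "chromqbd_input_error")
})

test_that("noise-free fitting covers all 54 fixture corners to solver precision", {
  model <- fixtureModel()
  expect_equal(length(compounds(model)), 9L)
  expect_true(all(model@fitted))
  expect_equal(sum(model@fitted), 54L)
  expect_lt(max(model@residual), 1e-6)
})

test_that("missing peaks leave corners unfitted and empty compounds are dropped", {
  instr <- defaultInstr()
  design <- calibrationDesign()
  tab <- generateRunTable(defaultApixabanMixture(), design, instr,
                          noiseSpec(seed = 1))
  # remove Stm2 at the (T2, pH3) corner (both tG runs)
  drop <- tab$compound_id == "Stm2" & tab$T_C == design@TLevels[2] &
    tab$pH == design@pHLevels[3]
  expect_equal(sum(drop), 2L)
  m <- fitModel(tab[!drop, ], design, instr)
  expect_false(m@fitted[match("Stm2", compounds(m)), 2, 3])
  expect_equal(sum(m@fitted), 53L)
  # the other corners of Stm2 are still usable
  expect_true(all(m@fitted[match("Stm2", compounds(m)), , -3]))

  # duplicate (run, compound) rejected
  expect_error(fitModel(rbind(tab, tab[1, ]), design, instr),
               class = "chromqbd_input_error")

  # compound missing everywhere is dropped with a warning
  gone <- tab[tab$compound_id != "Int5" | tab$run_id == "R01", ]
  gone$tR_min[gone$compound_id == "Int5"] <- NA
  expect_warning(m2 <- fitModel(gone, design, instr),
                 class = "chromqbd_compound_dropped")
  expect_false("Int5" %in% compounds(m2))
})

test_that("interpolation is exact at corners, degrades to linear for collinear pH values, and commutes", {
  model <- fixtureModel()
  design <- model@design
  # corner identity
  for (ti in 1:2) for (pi in 1:3) {
    s <- interpolateParams(model, "Apixaban", design@TLevels[ti],
                           design@pHLevels[pi])
    ci <- match("Apixaban", compounds(model))
    expect_equal(s@logKw, unname(model@logKw[ci, ti, pi]))
    expect_equal(s@S, unname(model@S[ci, ti, pi]))
  }

  # tensor-product commutation: T-then-pH equals pH-then-T to machine precision
  ci <- match("Int6", compounds(model))
  T_C <- 37.3; pH <- 5.93
  invT <- 1 / (T_C + 273.15); invTs <- 1 / (model@TLevels + 273.15)
  wT <- c(1 - (invT - invTs[1]) / (invTs[2] - invTs[1]),
          (invT - invTs[1]) / (invTs[2] - invTs[1]))
  wP <- chromqbd:::.lagrange3(pH, model@pHLevels)
  M <- model@logKw[ci, , ]
  tFirst <- sum((wT %*% M) * wP)              # collapse T, then pH
  pFirst <- sum(wT * (M %*% wP))              # collapse pH, then T
  expect_equal(tFirst, pFirst, tolerance = 1e-14)
  expect_equal(interpolateParams(model, "Int6", T_C, pH)@logKw, tFirst)

  # collinear values through three pH points reduce to linear interpolation
  syntheticModel <- model
  syntheticModel@logKw[ci, , ] <- rbind(c(1, 2, 3), c(1.5, 2.5, 3.5))
  mid <- (model@pHLevels[1] + model@pHLevels[2]) / 2
  got <- interpolateParams(syntheticModel, "Int6", model@TLevels[1], mid)
  expect_equal(got@logKw, 1.5)
})

test_that("interpolation warns inside the 10% extrapolation margin and errors beyond", {
  model <- fixtureModel()   # T range 20-50, pH range 2.8-6.4
  expect_warning(interpolateParams(model, "Apixaban", 52, 6.0),
                 class = "chromqbd_extrapolation")
  expect_error(suppressWarnings(interpolateParams(model, "Apixaban", 54, 6.0)),
               class = "chromqbd_range_error")
  expect_warning(interpolateParams(model, "Apixaban", 40, 6.7),
                 class = "chromqbd_extrapolation")
  expect_error(suppressWarnings(interpolateParams(model, "Apixaban", 40, 7.2)),
               class = "chromqbd_range_error")
  expect_error(interpolateParams(model, "NotACompound", 40, 6.0),
               class = "chromqbd_input_error")
})

test_that("a quadratic-in-pH, van't-Hoff-linear truth is recovered exactly at interior points", {
  instr <- defaultInstr()
  design <- calibrationDesign()
  # ground truth in exactly the fitted model class
  lkTrue <- function(T_C, pH)
    2.0 + 0.05 * (pH - 4.6) - 0.08 * (pH - 4.6)^2 +
      1000 * (1 / (T_C + 273.15) - 1 / 313.15)
  sTrue <- function(T_C, pH)
    8 + 0.3 * (pH - 4.6) + 0.05 * (pH - 4.6)^2 +
      150 * (1 / (T_C + 273.15) - 1 / 313.15)
  runs <- designRuns(design)
  runs$compound_id <- "Q"
  runs$tR_min <- vapply(seq_len(nrow(runs)), function(i)
    gradientRetentionTime(
      soluteLSS(lkTrue(runs$T_C[i], runs$pH[i]), sTrue(runs$T_C[i], runs$pH[i])),
      methodConditions(runs$tG_min[i], runs$T_C[i], runs$pH[i], design@flow,
                       design@phiStart, design@phiEnd),
      instr), numeric(1))
  m <- fitModel(runs, design, instr)
  withr::with_seed(5, {
    for (i in 1:20) {
      T_C <- runif(1, 20, 50); pH <- runif(1, 2.8, 6.4)
      got <- interpolateParams(m, "Q", T_C, pH)
      expect_lt(abs(got@logKw - lkTrue(T_C, pH)), 1e-6)
      expect_lt(abs(got@S - sTrue(T_C, pH)), 1e-5)
    }
  })
})

test_that("prediction reproduces calibration runs and the published elution order", {
  instr <- defaultInstr()
  model <- fixtureModel()
  design <- model@design
  tab <- generateRunTable(defaultApixabanMixture(), design, instr,
                          noiseSpec(seed = 1))
  # self-consistency at a calibration run's conditions
  r5 <- tab[tab$run_id == "R05", ]
  ch <- predictChromatogram(model,
                            methodConditions(r5$tG_min[1], r5$T_C[1],
                                             r5$pH[1], r5$flow_mL_min[1],
                                             r5$pctB_start[1] / 100,
                                             r5$pctB_end[1] / 100),
                            instr)
  p <- peaks(ch)
  expect_lt(max(abs(p$tR_min - r5$tR_min[match(p$compound_id,
                                               r5$compound_id)])), 1e-6)

  # elution order at the working point
  expect_equal(peaks(predictChromatogram(model, wpCond(), instr))$compound_id,
               c("Int6", "Stm1", "Apixaban", "Int2", "Int1", "Int5", "Stm2",
                 "Int4", "Int3"))
})

test_that("noise-free prediction matches the generator forward simulation within the fitted class", {
  instr <- defaultInstr()
  model <- fixtureModel()
  mix <- defaultApixabanMixture()
  # perturb tG, T, flow and the gradient end points; keep pH at a calibration
  # level so the quadratic-in-pH model class contains the sigmoid truth and
  # the check isolates the prediction plumbing
  perturbed <- list(
    methodConditions(2.7, 39, 6.4, 0.80, 0.10, 0.80),
    methodConditions(3.3, 41, 6.4, 0.80, 0.10, 0.80),
    methodConditions(3.0, 40, 6.4, 0.72, 0.09, 0.80),
    methodConditions(3.0, 40, 6.4, 0.88, 0.10, 0.81),
    methodConditions(2.9, 43, 6.4, 0.84, 0.11, 0.79),
    methodConditions(3.1, 37, 6.4, 0.76, 0.10, 0.80))
  for (cond in perturbed) {
    tru <- trueTRVector(mix, cond, instr)
    p <- peaks(predictChromatogram(model, cond, instr))
    expect_lt(max(abs(p$tR_min - tru[p$compound_id])), 1e-3)
  }
})
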