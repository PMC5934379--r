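test_that("MDRD eGFR matches the closed form and its gender factor", {
  expect_equal(mdrdEGFR(1.0, 50), 175 * 50^(-0.203), tolerance = 1e-12)
  expect_equal(mdrdEGFR(1.0, 50), 79.0947, tolerance = 1e-4)
  expect_equal(mdrdEGFR(1.3, 60, female = TRUE) / mdrdEGFR(1.3, 60), 0.742,
               tolerance = 1e-12)
  expect_equal(mdrdEGFR(1.12, 54, female = TRUE), 50.6954, tolerance = 1e-4)
  expect_equal(mdrdEGFR(1, 40, black = TRUE) / mdrdEGFR(1, 40), 1.212,
               tolerance = 1e-12)
  expect_error(mdrdEGFR(0, 50), "positive")
  expect_error(mdrdEGFR(1, -3), "positive")
})

test_that("encodeDesign applies the reporting conventions", {
  cohort <- data.frame(
    sample_id = c("a", "b", "c"), donor_age = c(40, 50, 60),
    donor_gender = c("m", "f", "m"), last_donor_creatinine = 1,
    cold_ischemia_time = 10, recipient_age = 50,
    recipient_gender = c("f", "f", "m"),
    transplantation_number = c("1st", "2nd", "1st"),
    panel_reactive_antibodies = c("0%", "<20%", NA),
    hla_mismatches = c(0, 3, 6), rejection = c("yes", "no", NA),
    dgf = c(0, 1, 2), egfr_12m = c(50, 40, 30),
    row.names = c("a", "b", "c"))
  enc <- encodeDesign(cohort, "donor_age")
  expect_equal(dim(enc$design), c(3L, 2L))
  expect_equal(unname(enc$design[, "donor_age"]), c(4, 5, 6))

  enc2 <- encodeDesign(cohort, c("donor_gender", "transplantation_number"))
  expect_equal(unname(enc2$design[, "donor_gender"]), c(0, 1, 0))
  expect_equal(unname(enc2$design[, "transplantation_number"]), c(0, 1, 0))

  enc3 <- suppressMessages(
    encodeDesign(cohort, "panel_reactive_antibodies"))
  expect_equal(enc3$dropped, 1L)
  expect_equal(unname(enc3$design[, 2]), c(0, 1))

  mk <- matrix(c(1.5, 2.5, 3.5), 1,
               dimnames = list("EGF", c("a", "b", "c")))
  enc4 <- encodeDesign(cohort, "EGF", markers = mk)
  expect_equal(unname(enc4$design[, "EGF"]), c(1.5, 2.5, 3.5))
  expect_error(encodeDesign(cohort, "NOPE"), "unresolvable")

  # all-male cohort: gender column is constant -> collinear downstream
  cohortM <- cohort; cohortM$donor_gender <- "m"
  encM <- encodeDesign(cohortM, "donor_gender")
  expect_error(fitOLS(encM$design, encM$response), "donor_gender")
})

test_that("fitOLS agrees with lm and handles exact fits", {
  withr::local_seed(31)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(40), x2 = rnorm(40))
  y <- 2 + 0.5 * X[, "x1"] - X[, "x2"] + rnorm(40)
  fit <- fitOLS(X, y)
  ref <- summary(lm(y ~ X[, "x1"] + X[, "x2"]))
  expect_equal(unname(coefTable(fit)[, "estimate"]),
               unname(ref$coefficients[, 1]), tolerance = 1e-10)
  expect_equal(unname(coefTable(fit)[, "p"]),
               unname(ref$coefficients[, 4]), tolerance = 1e-10)
  expect_equal(adjR2(fit), ref$adj.r.squared, tolerance = 1e-10)
  expect_equal(fitPValue(fit),
               unname(pf(ref$fstatistic[1], ref$fstatistic[2],
                         ref$fstatistic[3], lower.tail = FALSE)),
               tolerance = 1e-10)

  # hand-solved 3-point system: y = b0 + b1 x
  Xs <- cbind(`(Intercept)` = 1, x = c(0, 1, 2))
  ys <- c(1, 2, 4)
  fs <- fitOLS(Xs, ys)
  # normal equations by hand: b1 = Sxy/Sxx = 3/2, b0 = ybar - b1 xbar
  expect_equal(unname(coefTable(fs)[, "estimate"]),
               c(7 / 3 - 3 / 2, 3 / 2), tolerance = 1e-12)

  # exact linear response
  ye <- 3 - 2 * X[, "x1"]
  fe <- fitOLS(X, ye)
  expect_equal(fe@r2, 1, tolerance = 1e-10)
  expect_equal(adjR2(fe), 1, tolerance = 1e-10)
  expect_lt(max(abs(fe@residuals)), 1e-10)
})

test_that("coefficient tests hold their type-I error under the null", {
  withr::local_seed(32)
  pv <- replicate(200, {
    x <- rnorm(100)
    y <- rnorm(100)
    fit <- fitOLS(cbind(`(Intercept)` = 1, x = x), y)
    coefTable(fit)["x", "p"]
  })
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.09)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("PRESS formula equals the explicit refit loop", {
  withr::local_seed(33)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    p <- sample(1:6, 1)
    X <- cbind(1, matrix(rnorm(n * p), n))
    colnames(X) <- c("(Intercept)", paste0("x", 1:p))
    y <- rnorm(n)
    got <- pressLOOCV(X, y)
    want <- oracle_loocv(X, y)
    expect_equal(got$loocvRMSE, want$rmse, tolerance = 1e-8)
    expect_equal(got$loocvR2, want$r2, tolerance = 1e-8)
  }

  # intercept-only model against the oracle
  y <- rnorm(15)
  X0 <- matrix(1, 15, 1, dimnames = list(NULL, "(Intercept)"))
  expect_equal(pressLOOCV(X0, y)$loocvRMSE, oracle_loocv(X0, y)$rmse,
               tolerance = 1e-10)

  # perfect deterministic fit: PRESS ~ 0
  x <- rnorm(30)
  Xp <- cbind(`(Intercept)` = 1, x = x)
  expect_lt(pressLOOCV(Xp, 1 + 2 * x)$loocvRMSE, 1e-10)

  # a leverage of exactly 1 is an error
  Xh <- cbind(1, c(1, 0, 0, 0, 0))
  expect_error(pressLOOCV(Xh, rnorm(5)), "leverage")
})

test_that("the fast C++ objective matches the R PRESS path", {
  withr::local_seed(34)
  X <- cbind(1, matrix(rnorm(60 * 4), 60))
  y <- rnorm(60)
  fast <- donorNet:::cpp_ols_press(X, y)
  slow <- pressLOOCV(X, y)
  expect_equal(unname(fast[["loocv_rmse"]]), slow$loocvRMSE,
               tolerance = 1e-10)
  expect_equal(unname(fast[["loocv_r2"]]), slow$loocvR2, tolerance = 1e-10)
  # rank-deficient design is signalled, not crashed
  Xr <- cbind(X, X[, 2])
  expect_true(is.na(donorNet:::cpp_ols_press(Xr, y)[["loocv_rmse"]]))
})

test_that("bestClinicalModel keeps planted predictors in the selection", {
  # only donor age and donor gender carry signal; the selected model
  # should contain both (exact-set recovery is not expected: a null
  # predictor improves PRESS whenever |t| > ~sqrt(2))
  withr::local_seed(35)
  betas <- plantedBetaDefaults()
  betas[c("CD2BP2", "SF3B1", "EGF", "RALBP1", "DDX19B", "dgf")] <- 0
  betas["(Intercept)"] <- 60   # keep the mean outcome near 50
  hits <- replicate(30, {
    cs <- simulateCohort(seed = sample.int(1e6, 1), plantedBetas = betas,
                         egfrNoiseSD = 12)
    sel <- suppressMessages(bestClinicalModel(cs$cohort))
    all(c("donor_age", "donor_gender") %in% predictorNames(sel$fit))
  })
  expect_gte(mean(hits), 0.9)

  cs <- simulateCohort(seed = 36)
  single <- bestClinicalModel(cs$cohort, candidates = "donor_age")
  expect_identical(predictorNames(single$fit), "donor_age")
  expect_equal(nrow(single$ranking), 1)
})

test_that("saSubsetSearch is reproducible and respects size bounds", {
  cs <- simulateCohort(seed = 37)
  cands <- c("donor_age", "donor_gender", "recipient_age",
             cs$truth$causal, "MK001", "MK002", "MK003", "MK004")
  cfg <- saConfig(iterations = 300, restarts = 3, seed = 99)
  f1 <- suppressMessages(saSubsetSearch(cands, cs$cohort,
                                        markers = cs$markers, config = cfg))
  f2 <- suppressMessages(saSubsetSearch(cands, cs$cohort,
                                        markers = cs$markers, config = cfg))
  expect_identical(predictorNames(f1), predictorNames(f2))
  expect_identical(loocvRMSE(f1), loocvRMSE(f2))
  expect_true(length(predictorNames(f1)) %in% 6:8)

  # zero iterations: best of the random restart initial states
  f0 <- suppressMessages(saSubsetSearch(
    cands, cs$cohort, markers = cs$markers,
    config = saConfig(iterations = 0, restarts = 4, seed = 1)))
  expect_s4_class(f0, "ModelFit")
  expect_true(length(predictorNames(f0)) %in% 6:8)

  expect_error(saSubsetSearch(c("donor_age", "donor_gender"), cs$cohort,
                              config = saConfig()), "fewer candidates")
})

test_that("pruning removes null predictors and keeps significant ones", {
  withr::local_seed(38)
  removed <- replicate(200, {
    x1 <- rnorm(60); x2 <- rnorm(60)
    y <- 2 * x1 + rnorm(60)
    fit <- fitOLS(cbind(`(Intercept)` = 1, x1 = x1, x2 = x2), y)
    !("x2" %in% predictorNames(pruneNonsignificant(fit)))
  })
  expect_gt(mean(removed), 0.90)
  expect_lt(mean(removed), 0.99)

  # strongly significant model is a fixed point
  x <- rnorm(60); y <- 3 * x + rnorm(60, sd = 0.3)
  fit <- fitOLS(cbind(`(Intercept)` = 1, x = x), y)
  expect_identical(predictorNames(pruneNonsignificant(fit)), "x")

  # two near-collinear copies of one signal: exactly one survives
  x1 <- rnorm(80); x2 <- x1 + rnorm(80, sd = 0.01)
  y <- x1 + rnorm(80)
  fit2 <- fitOLS(cbind(`(Intercept)` = 1, a = x1, b = x2), y)
  pruned <- pruneNonsignificant(fit2)
  expect_length(predictorNames(pruned), 1)

  # pure noise model collapses to the intercept with a warning
  fit3 <- fitOLS(cbind(`(Intercept)` = 1, z = rnorm(50)), rnorm(50))
  if (coefTable(fit3)["z", "p"] >= 0.05)
    expect_warning(p3 <- pruneNonsignificant(fit3), "intercept-only")
})

test_that("anovaNested matches stats::anova and its limits", {
  withr::local_seed(39)
  x1 <- rnorm(50); x2 <- rnorm(50)
  y <- 1 + x1 + 0.5 * x2 + rnorm(50)
  small <- fitOLS(cbind(`(Intercept)` = 1, x1 = x1), y)
  large <- fitOLS(cbind(`(Intercept)` = 1, x1 = x1, x2 = x2), y)
  got <- anovaNested(small, large)
  ref <- anova(lm(y ~ x1), lm(y ~ x1 + x2))
  expect_equal(got$F, ref$F[2], tolerance = 1e-10)
  expect_equal(got$p, ref$`Pr(>F)`[2], tolerance = 1e-10)

  # an added column orthogonal to the small model's residuals leaves the
  # RSS unchanged: F = 0, p = 1
  e <- small@residuals
  v <- rnorm(50)
  v <- v - sum(v * e) / sum(e * e) * e
  largeO <- fitOLS(cbind(`(Intercept)` = 1, x1 = x1, v = v), y)
  gotO <- anovaNested(small, largeO)
  expect_equal(gotO$F, 0, tolerance = 1e-8)
  expect_equal(gotO$p, 1, tolerance = 1e-8)

  # non-nested models: strict mode refuses, quasi mode warns
  other <- fitOLS(cbind(`(Intercept)` = 1, x2 = x2), y)
  expect_error(anovaNested(other, fitOLS(
    cbind(`(Intercept)` = 1, x1 = x1, v = v), y)), "not nested")
  expect_warning(anovaNested(other, largeO, quasi = TRUE), "quasi-nested")
  expect_error(anovaNested(small, fitOLS(cbind(`(Intercept)` = 1,
                                               x1 = x1[1:40]), y[1:40])),
               "same response")
})

test_that("gender contrast flips sign exactly under recoding", {
  cs <- simulateCohort(seed = 40)
  enc <- encodeDesign(cs$cohort, c("donor_age", "donor_gender"))
  fit <- fitOLS(enc$design, enc$response)
  flipped <- enc$design
  flipped[, "donor_gender"] <- 1 - flipped[, "donor_gender"]
  fit2 <- fitOLS(flipped, enc$response)
  expect_equal(coefTable(fit2)["donor_gender", "estimate"],
               -coefTable(fit)["donor_gender", "estimate"],
               tolerance = 1e-10)
})

test_that("adjusted R2 is below R2 for any non-trivial fit", {
  withr::local_seed(41)
  for (rep in 1:10) {
    X <- cbind(1, matrix(rnorm(30 * 3), 30))
    colnames(X) <- c("(Intercept)", paste0("x", 1:3))
    fit <- fitOLS(X, rnorm(30))
    expect_lt(adjR2(fit), fit@r2)
  }
})

test_that("correlation matrix flags the planted donor-recipient age link", {
  withr::local_seed(42)
  stats <- replicate(50, {
    cs <- simulateCohort(seed = sample.int(1e6, 1))
    cm <- correlationMatrixBonferroni(
      cs$cohort[, c("donor_age", "recipient_age", "last_donor_creatinine",
                    "cold_ischemia_time")])
    c(r = cm$r["donor_age", "recipient_age"],
      sig = cm$significant["donor_age", "recipient_age"])
  })
  expect_gte(mean(abs(stats["r", ] - 0.47) < 0.2), 0.9)
  expect_gte(mean(stats["sig", ]), 0.9)

  cm <- correlationMatrixBonferroni(cbind(a = rnorm(30), b = rep(1, 30)))
  expect_equal(unname(cm$r["a", "a"]), 1)
  expect_true(is.na(cm$r["a", "b"]))
})

test_that("the planted marker inter-correlations stay below the 0.5 gate", {
  cs <- simulateCohort(n = 2000, seed = 43)
  mk <- SummarizedExperiment::assay(cs$markers)[cs$truth$causal, ]
  cm <- correlationMatrixBonferroni(t(mk))
  off <- abs(cm$r[upper.tri(cm$r)])
  expect_lte(max(off), 0.55)   # 0.5 planted plus sampling noise
})

test_that("postop add-on detects the planted dgf effect but not rejection", {
  withr::local_seed(44)
  res <- replicate(50, {
    cs <- simulateCohort(seed = sample.int(1e6, 1))
    fit <- fitModel(cs$cohort, c("donor_age", "donor_gender",
                                 cs$truth$causal), markers = cs$markers)
    po <- postopAddonAnalysis(fit, cs$cohort, markers = cs$markers)
    c(dgfGain = po$dgf$deltaAdjR2 > 0 & po$dgf$anova$p < 0.05,
      rejP = po$rejection$anova$p,
      rejDelta = po$rejection$deltaAdjR2,
      markerFlags = sum(po$markerTests$flag))
  })
  expect_gte(mean(res["dgfGain", ]), 0.9)
  # rejection is simulated independent of outcome
  expect_gt(mean(res["rejP", ]), 0.2)
  expect_lt(abs(mean(res["rejDelta", ])), 0.02)
  # markers are simulated independent of dgf and rejection
  expect_lte(mean(res["markerFlags", ] > 0), 0.1)
})
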