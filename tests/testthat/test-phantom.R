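test_that("vascular input function is causal and matches closed forms", {
  vif <- generateVif("gammaBiexp", injectionTime = 6.4)
  expect_identical(vif(0), 0)
  expect_identical(vif(c(-10, 0, 6.4)), c(0, 0, 0))
  expect_true(all(vif(seq(6.5, 1500, by = 0.5)) >= 0))

  box <- boxcarVif(c0 = 2.5, tStart = 10, tEnd = 70)
  expect_equal(box(40), 2.5)
  expect_equal(box(c(5, 80)), c(0, 0))

  ## biexponential integral against its closed-form antiderivative
  amp <- c(3.0, 1.0); rate <- c(0.02, 0.002)
  bi <- generateVif("biexponential", list(amp = amp, rate = rate),
                    injectionTime = 0)
  TT <- 400
  closed <- sum(amp / rate * (1 - exp(-rate * TT)))
  quad <- forwardTissueConcentration(bi, ki = 60, vp = 0, times = c(0, TT))
  expect_equal(quad[2], closed, tolerance = 1e-5)
})

test_that("invalid VIF shape parameters are rejected", {
  expect_error(generateVif("biexponential", list(amp = c(-1, 1),
                                                 rate = c(0.01, 0.01))),
               "finite and non-negative")
  expect_error(generateVif("gammaBiexp",
                           modifyList(defaultVifParams(), list(tp = NaN))),
               "finite")
})

test_that("Patlak forward model obeys its limiting closed forms", {
  vif <- generateVif("gammaBiexp", injectionTime = 0)
  times <- seq(0, 300, by = 5)
  ## no leakage: pure plasma term
  expect_equal(forwardTissueConcentration(vif, 0, 0.05, times),
               0.05 * vif(times))
  ## vp = 0, constant input: linear ramp Ct = (ki/60) c0 t
  box <- boxcarVif(c0 = 2, tStart = 0, tEnd = 1000)
  tt <- c(0, 60, 120, 600)
  expect_equal(forwardTissueConcentration(box, 3e-4, 0, tt),
               (3e-4 / 60) * 2 * tt, tolerance = 1e-6)
  expect_error(forwardTissueConcentration(vif, 1e-4, 0.02, c(10, 5)),
               "sorted")
  expect_error(forwardTissueConcentration(vif, -1e-4, 0.02, tt))
})

test_that("forward model agrees with fine-step quadrature at study-scale Ki", {
  vif <- generateVif("gammaBiexp", injectionTime = 0)
  times <- seq(10, 1400, by = 50)
  ct <- forwardTissueConcentration(vif, 3e-4, 0.02, times)
  ## independent oracle: very fine trapezoid integral of Cp
  oracle <- vapply(times, function(tmax) {
    g <- seq(0, tmax, by = 0.002)
    (3e-4 / 60) * pracma::trapz(g, vif(g)) + 0.02 * vif(tmax)
  }, numeric(1))
  expect_equal(ct, oracle, tolerance = 1e-3)
})

test_that("forward model is linear in (ki, vp)", {
  vif <- generateVif("gammaBiexp", injectionTime = 5)
  times <- seq(0, 800, by = 7)
  set.seed(42)
  for (i in 1:5) {
    k1 <- runif(1, 0, 1e-3); k2 <- runif(1, 0, 1e-3)
    v1 <- runif(1, 0, 0.1); v2 <- runif(1, 0, 0.1)
    lhs <- forwardTissueConcentration(vif, k1 + k2, 0, times) +
      forwardTissueConcentration(vif, 0, v1 + v2, times)
    rhs <- forwardTissueConcentration(vif, k1, v1, times) +
      forwardTissueConcentration(vif, k2, v2, times)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("SPGR signal has the right baseline and monotonicity", {
  prot <- acquisitionProtocol()
  a <- prot@flipAngle * pi / 180
  e10 <- exp(-prot@tr / 1.2)
  s0 <- 500 * sin(a) * (1 - e10) / (1 - cos(a) * e10)
  expect_equal(spgrSignal(0, 1.2, prot, m0 = 500), s0)
  cc <- seq(0, 5, by = 0.1)
  expect_true(all(diff(spgrSignal(cc, 1.2, prot, m0 = 500)) > 0))
  expect_error(spgrSignal(1, -0.5, prot), "positive")
})

test_that("simulated acquisition honors the protocol and is reproducible", {
  cfg <- smallPhantom(seed = 11L)
  prot <- acquisitionProtocol()
  acq <- simulateAcquisition(cfg, prot)
  expect_s4_class(acq$fast, "DynamicSeries")
  expect_equal(dim(signalData(acq$fast))[4], 29L)
  expect_equal(dim(signalData(acq$slow))[4], 45L)
  merged <- sort(c(acquisitionTimes(acq$fast), acquisitionTimes(acq$slow)))
  expect_true(all(diff(merged) > 0))
  expect_equal(diff(acquisitionTimes(acq$fast))[1], prot@fastDST)
  ## geometry conservation
  expect_identical(dim(acq$truth$kiMap), cfg@gridShape)
  expect_identical(dim(acq$truth$vpMap), cfg@gridShape)
  expect_identical(dim(acq$t1), cfg@gridShape)
  expect_identical(dim(acq$labels), cfg@gridShape)
  ## determinism
  acq2 <- simulateAcquisition(smallPhantom(seed = 11L, noiseSD = 3),
                              prot)
  acq3 <- simulateAcquisition(smallPhantom(seed = 11L, noiseSD = 3),
                              prot)
  expect_identical(signalData(acq2$fast), signalData(acq3$fast))
  expect_identical(signalData(acq2$slow), signalData(acq3$slow))
  expect_identical(acq2$labels, acq3$labels)
})

test_that("a leak-free noiseless phantom has constant tissue signal", {
  cfg <- smallPhantom(
    kiTrue = c(NAWM = 0, WMH = 0, CGM = 0, DGM = 0),
    vpTrue = c(NAWM = 0, WMH = 0, CGM = 0, DGM = 0))
  acq <- simulateAcquisition(cfg, smallProtocol())
  tissue <- which(acq$labels %in% 1:4)
  d <- dim(signalData(acq$fast))
  mat <- matrix(signalData(acq$fast), nrow = prod(d[1:3]))[tissue, ]
  expect_true(all(abs(mat - mat[, 1]) < 1e-12))
})

test_that("a grid too small for the region fractions is rejected", {
  cfg <- phantomConfig(gridShape = c(3L, 3L, 2L))
  expect_error(simulateAcquisition(cfg, smallProtocol()), "too small")
})

test_that("synthetic cohorts respect missingness and effect references", {
  cc <- cohortConfig(nPatients = 40L, missingRate = 0, seed = 3L)
  coh <- generateCohort(cc)
  expect_equal(nrow(coh), 40L)
  expect_false(anyNA(coh))
  ## determinism
  coh2 <- generateCohort(cohortConfig(nPatients = 40L, missingRate = 0,
                                      seed = 3L))
  expect_identical(coh, coh2)
  ## no effects, no noise: latent decline is the covariate term alone (zero)
  cc0 <- cohortConfig(nPatients = 20L, noiseSDCognition = 0,
                      testNoiseSD = 0, missingRate = 0, seed = 5L)
  lat <- attr(generateCohort(cc0), "truth")
  expect_true(all(lat == 0))
  ## unknown (region, measure) reference errors
  eb <- data.frame(region = "CGM", measure = "nope", domain = "executive",
                   beta = 1)
  expect_error(generateCohort(cohortConfig(nPatients = 20L,
                                           effectBeta = eb)),
               "absent from the leakage table")
  ## missingness rate applied per follow-up score
  ccm <- cohortConfig(nPatients = 300L, missingRate = 0.3, seed = 9L)
  cohm <- generateCohort(ccm)
  fu <- as.matrix(cohm[grep("_followup$", names(cohm))])
  expect_gt(mean(is.na(fu)), 0.25)
  expect_lt(mean(is.na(fu)), 0.35)
  expect_false(anyNA(cohm[grep("_baseline$", names(cohm))]))
})
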