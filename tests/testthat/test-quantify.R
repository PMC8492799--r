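makeSignalSeries <- function(concCurve, t10, prot, m0 = 800,
                             nBaseline = 2L, dt = 3.2, tag = "fast") {
  sig <- spgrSignal(c(rep(0, nBaseline), concCurve), t10, prot, m0 = m0)
  n <- length(sig)
  dynamicSeries(array(sig, dim = c(1L, 1L, 1L, n)),
                (seq_len(n) - 0.5) * dt, tag, nBaseline)
}

test_that("constant signal converts to exactly zero concentration", {
  prot <- acquisitionProtocol()
  ser <- makeSignalSeries(rep(0, 10), 1.1, prot)
  conc <- concentrationFromSignal(ser, array(1.1, dim = c(1, 1, 1)), prot)
  expect_equal(as.numeric(concData(conc)), rep(0, 12), tolerance = 1e-12)
  expect_equal(attr(conc, "qc")$nInvalid, 0L)
})

test_that("SPGR inversion round-trips the forward signal model", {
  prot <- acquisitionProtocol()
  cc <- c(0.25, 1.0, 2.5, 5.0)
  ser <- makeSignalSeries(cc, 0.9, prot)
  conc <- concentrationFromSignal(ser, array(0.9, dim = c(1, 1, 1)), prot)
  expect_equal(as.numeric(concData(conc))[3:6], cc, tolerance = 1e-6)
})

test_that("linearized conversion matches the small-enhancement expansion", {
  prot <- acquisitionProtocol()
  t10 <- 1.0
  ## concentrations small enough that relative enhancement stays below 5%
  cc <- seq(0.001, 0.012, by = 0.001)
  re <- spgrSignal(cc, t10, prot) / spgrSignal(0, t10, prot) - 1
  expect_true(all(re <= 0.05))
  ser <- makeSignalSeries(cc, t10, prot)
  lin <- concentrationFromSignal(ser, array(t10, dim = c(1, 1, 1)), prot,
                                 linearized = TRUE)
  est <- as.numeric(concData(lin))[-(1:2)]
  expect_equal(est, cc, tolerance = 0.05)
})

test_that("voxels with unusable baseline are flagged invalid", {
  prot <- acquisitionProtocol()
  dat <- array(0, dim = c(2, 1, 1, 4))
  dat[2, 1, 1, ] <- spgrSignal(c(0, 0, 1, 1), 1.0, prot, m0 = 500)
  ser <- dynamicSeries(dat, c(1, 2, 3, 4), "fast", 2L)
  t1 <- array(c(1.0, 1.0), dim = c(2, 1, 1))
  conc <- concentrationFromSignal(ser, t1, prot)
  expect_true(all(is.na(concData(conc)[1, 1, 1, ])))
  expect_false(anyNA(concData(conc)[2, 1, 1, ]))
  expect_equal(attr(conc, "qc")$nInvalid, 1L)
})

test_that("dual-sequence merge is sorted, complete and overlap-checked", {
  fast <- concFromMatrix(matrix(1:8, 1), times = c(-1, 1, 2, 3, 4, 5, 6, 7),
                         tag = "fast", nBaseline = 1L)
  slow <- concFromMatrix(matrix(9:12, 1), times = c(-5, 10, 20, 30),
                         tag = "slow", nBaseline = 1L)
  m <- mergeDualSequences(fast, slow)
  expect_equal(length(acquisitionTimes(m)), 12L)
  expect_true(all(diff(acquisitionTimes(m)) > 0))
  expect_equal(m@provenance[1], "slow")     # slow baseline comes first
  expect_equal(sum(m@baseline), 2L)
  ## values follow their timestamps through the sort
  expect_equal(as.numeric(concData(m))[acquisitionTimes(m) == 20], 11)

  empty <- concFromMatrix(matrix(numeric(0), 1, 0), numeric(0), "slow", 0L)
  expect_identical(mergeDualSequences(fast, empty), fast)

  overlap <- concFromMatrix(matrix(1:4, 1), times = c(-5, 5.5, 20, 30),
                            tag = "slow", nBaseline = 1L)
  expect_error(mergeDualSequences(fast, overlap), "overlap")
})

test_that("default protocol merges to 29 + 45 volumes", {
  cfg <- smallPhantom()
  prot <- acquisitionProtocol()
  acq <- simulateAcquisition(cfg, prot)
  cf <- concentrationFromSignal(acq$fast, acq$t1, prot)
  cs <- concentrationFromSignal(acq$slow, acq$t1, prot)
  m <- mergeDualSequences(cf, cs)
  expect_equal(length(acquisitionTimes(m)), 29L + 45L)
})

test_that("VIF extraction applies the hematocrit correction and trapezoid", {
  n <- 31
  times <- seq(0, 60, by = 2)
  cb <- matrix(1, nrow = 4, ncol = n)
  ser <- concFromMatrix(cb, times, dims = c(4, 1, 1), nBaseline = 1L)
  mask <- array(TRUE, dim = c(4, 1, 1))
  vif <- extractVif(ser, NULL, mask, hematocrit = 0.45)
  expect_equal(plasmaCurve(vif), rep(1 / 0.55, n))
  vif0 <- extractVif(ser, NULL, mask, hematocrit = 0)
  expect_equal(plasmaCurve(vif0), bloodCurve(vif0))
  ## boxcar of height 1 over 60 s integrates to 60 on a fine grid
  expect_equal(max(plasmaIntegral(vif0)), 60, tolerance = 0.01)
  expect_error(extractVif(ser, NULL, array(FALSE, dim = c(4, 1, 1))),
               "empty")
})

test_that("Patlak OLS reproduces an exact line to machine precision", {
  times <- seq(100, 1000, by = 50)
  cp <- 2 * exp(-0.001 * times)
  integral <- as.numeric(pracma::cumtrapz(times, cp)) + 150
  vif <- new("VascularInputFunction", times = times, cb = cp * 0.55,
             cp = cp, hematocrit = 0.45, integral = integral)
  a <- 0.037; b <- 4.2e-6                    # intercept, slope per second
  y <- a + b * integral / cp                 # exact Patlak line
  conc <- concFromMatrix(matrix(y * cp, 1), times, nBaseline = 0L)
  conc@baseline <- rep(FALSE, length(times))
  km <- patlakFit(conc, vif, array(TRUE, dim = c(1, 1, 1)),
                  fitWindow = c(0, Inf))
  expect_equal(kiArray(km)[1], b * 60, tolerance = 1e-12)
  expect_equal(vpArray(km)[1], a, tolerance = 1e-12)
  expect_equal(r2Array(km)[1], 1, tolerance = 1e-12)
})

test_that("noise-free closed loop recovers Ki, vp and the null case", {
  cfg <- smallPhantom(kiTrue = c(NAWM = 3e-4, WMH = 0, CGM = 2.3e-4,
                                 DGM = 3.1e-4),
                      vpTrue = c(NAWM = 0.02, WMH = 0.02, CGM = 0.03,
                                 DGM = 0.025))
  prot <- acquisitionProtocol()
  acq <- simulateAcquisition(cfg, prot)
  q <- quantifyKi(acq, prot)
  ki <- kiArray(q$kiMap); vp <- vpArray(q$kiMap)
  for (reg in c("NAWM", "CGM", "DGM")) {
    code <- c(NAWM = 1, CGM = 3, DGM = 4)[[reg]]
    est <- mean(ki[acq$labels == code])
    expect_lt(abs(est - cfg@kiTrue[[reg]]) / cfg@kiTrue[[reg]], 0.01)
    expect_lt(abs(mean(vp[acq$labels == code]) - cfg@vpTrue[[reg]]), 1e-3)
  }
  ## ki = 0 region recovers a null slope
  expect_lt(max(abs(ki[acq$labels == 2])), 1e-9)
})

test_that("symmetric concentration noise gives Ki symmetric about zero", {
  ## the premise of the histogram correction, at the Patlak level: zero-mean
  ## symmetric noise on Ct maps to a symmetric fitted-Ki distribution
  set.seed(71)
  times <- seq(100, 1400, by = 50)
  cp <- 2 * exp(-0.002 * times) + 0.3
  integral <- as.numeric(pracma::cumtrapz(times, cp)) + 200
  vif <- new("VascularInputFunction", times = times, cb = cp * 0.55,
             cp = cp, hematocrit = 0.45, integral = integral)
  nvox <- 4000
  ct <- matrix(0.02 * cp, nrow = nvox, ncol = length(times),
               byrow = TRUE) + rnorm(nvox * length(times), 0, 0.01)
  conc <- concFromMatrix(ct, times, nBaseline = 0L,
                         dims = c(nvox, 1L, 1L))
  km <- patlakFit(conc, vif, array(TRUE, dim = c(nvox, 1, 1)),
                  fitWindow = c(0, Inf))
  ki <- as.numeric(kiArray(km))
  expect_lt(abs(sampleSkewness(ki)), 0.1)
  expect_lt(abs(median(ki)), sd(ki) / 10)
  expect_lt(abs(mean(ki)), 3 * sd(ki) / sqrt(nvox))
})

test_that("signal-noise pipeline keeps null Ki near-symmetric", {
  ## through the nonlinear SPGR inversion the symmetry is approximate: a
  ## mild positive skew remains at realistic SNR
  cfg <- phantomConfig(
    gridShape = c(12L, 12L, 8L),
    kiTrue = c(NAWM = 0, WMH = 0, CGM = 0, DGM = 0),
    noiseSD = 1, seed = 21L)
  prot <- smallProtocol()
  acq <- simulateAcquisition(cfg, prot)
  q <- quantifyKi(acq, prot)
  ki <- kiArray(q$kiMap)[acq$labels %in% 1:4]
  expect_gt(length(ki), 500)
  expect_lt(abs(sampleSkewness(ki)), 0.35)
  expect_lt(abs(median(ki)), sd(ki) / 5)
})

test_that("Ki precision degrades monotonically with signal noise", {
  prot <- smallProtocol()
  sds <- vapply(c(0.5, 2, 8), function(ns) {
    cfg <- phantomConfig(gridShape = c(12L, 12L, 8L),
                         kiTrue = c(NAWM = 3e-4, WMH = 3e-4, CGM = 3e-4,
                                    DGM = 3e-4),
                         noiseSD = ns, seed = 31L)
    acq <- simulateAcquisition(cfg, prot)
    q <- quantifyKi(acq, prot)
    sd(kiArray(q$kiMap)[acq$labels %in% 1:4])
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})
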