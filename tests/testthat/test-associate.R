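test_that("a deterministic linear relation yields standardized B of 1", {
  set.seed(51)
  d <- data.frame(x = rnorm(50))
  d$y <- 2 * d$x
  r <- suppressWarnings(fitAssociation(d, "y", "x"))
  expect_equal(r@b, 1, tolerance = 1e-12)
  expect_lt(r@p, 1e-12)
  expect_equal(r@nUsed, 50L)
  expect_equal(r@model, "univariable")
})

test_that("univariable standardized B equals the Pearson correlation", {
  set.seed(52)
  for (i in 1:5) {
    d <- data.frame(x = rnorm(80), e = rnorm(80))
    d$y <- 0.6 * d$x + d$e
    r <- fitAssociation(d, "y", "x")
    expect_equal(r@b, cor(d$x, d$y), tolerance = 1e-10)
  }
})

test_that("adjusted B satisfies the Frisch-Waugh residualization identity", {
  set.seed(53)
  n <- 120
  d <- data.frame(age = rnorm(n, 67, 10), sex = rbinom(n, 1, 0.5),
                  x = rnorm(n))
  d$y <- 0.4 * d$x + 0.02 * d$age - 0.3 * d$sex + rnorm(n)
  r <- fitAssociation(d, "y", "x", covariates = c("age", "sex"))
  zy <- as.numeric(scale(d$y)); zx <- as.numeric(scale(d$x))
  ry <- resid(lm(zy ~ age + sex, data = d))
  rx <- resid(lm(zx ~ age + sex, data = d))
  expect_equal(r@b, unname(coef(lm(ry ~ rx))[2]), tolerance = 1e-8)
  expect_equal(r@model, "adjusted")
})

test_that("the null distribution of p-values is uniform", {
  pvals <- vapply(1:200, function(s) {
    set.seed(1000 + s)
    d <- data.frame(x = rnorm(500), y = rnorm(500))
    fitAssociation(d, "y", "x")@p
  }, numeric(1))
  expect_lt(mean(abs(vapply(1:200, function(s) {
    set.seed(1000 + s)
    d <- data.frame(x = rnorm(500), y = rnorm(500))
    fitAssociation(d, "y", "x")@b
  }, numeric(1))) > 0.1), 0.05)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(y = rnorm(20), x = rep(1, 20))
  expect_error(fitAssociation(d, "y", "x"), "zero variance")
  expect_error(fitAssociation(d, "y", "missing_col"), "lacks columns")
  expect_error(fitAssociation(d[1:3, ], "y", "x",
                              covariates = c("x", "x")), "complete cases")
})

test_that("the association grid enumerates and survives cell failures", {
  set.seed(55)
  n <- 60
  d <- data.frame(age = rnorm(n, 67, 10), sex = rbinom(n, 1, 0.5),
                  education = sample(1:3, n, TRUE),
                  wmhVolume = runif(n, 0, 0.05),
                  brainVolume = runif(n, 0.6, 0.75))
  for (reg in c("NAWM", "WMH", "CGM", "DGM")) {
    d[[paste0("vL_", reg)]] <- rnorm(n, 30, 15)
    d[[paste0("Ki_", reg)]] <- rnorm(n, 3, 1.5)
  }
  for (oc in c("overall", "executive", "speed", "memory"))
    d[[oc]] <- rnorm(n)
  g <- runAssociationGrid(d)
  expect_equal(nrow(g), 64L)
  expect_equal(sum(g$model == "adjusted"), 32L)
  expect_equal(sum(g$model == "univariable"), 32L)
  expect_true(all(g$error == ""))
  expect_true(all(g$ci_low <= g$B & g$B <= g$ci_high))

  ## a broken predictor fails its cells only, run continues
  d2 <- d; d2$Ki_DGM <- 0
  g2 <- runAssociationGrid(d2)
  expect_equal(sum(g2$error != ""), 8L)
  expect_true(all(grepl("zero variance", g2$error[g2$error != ""])))

  expect_equal(nrow(runAssociationGrid(d, outcomes = character())), 0L)

  gb <- adjustGridBH(g)
  expect_true(all(gb$p_bh >= gb$p - 1e-12, na.rm = TRUE))
})

test_that("an injected effect appears only in its own grid family", {
  set.seed(56)
  n <- 300
  d <- data.frame(age = rnorm(n, 67, 10), sex = rbinom(n, 1, 0.5),
                  education = sample(1:3, n, TRUE),
                  wmhVolume = runif(n, 0, 0.05),
                  brainVolume = runif(n, 0.6, 0.75))
  for (reg in c("NAWM", "WMH", "CGM", "DGM")) {
    d[[paste0("vL_", reg)]] <- rnorm(n, 30, 15)
    d[[paste0("Ki_", reg)]] <- rnorm(n, 3, 1.5)
  }
  for (oc in c("overall", "executive", "speed", "memory")) d[[oc]] <- rnorm(n)
  d$executive <- d$executive + 0.08 * d$vL_CGM     # strong injected effect
  g <- runAssociationGrid(d)
  nullSD <- 1 / sqrt(n)                            # null SD of a correlation
  hits <- g[abs(g$B) > 3 * nullSD, ]
  expect_gt(nrow(hits), 0L)
  expect_true(all(hits$region == "CGM" & hits$measure == "vL" &
                  hits$outcome == "executive"))
})

test_that("dropping a patient with a missing domain only shifts that domain", {
  set.seed(57)
  n <- 80
  d <- data.frame(age = rnorm(n, 67, 10), sex = rbinom(n, 1, 0.5),
                  education = sample(1:3, n, TRUE),
                  wmhVolume = runif(n, 0, 0.05),
                  brainVolume = runif(n, 0.6, 0.75),
                  vL_CGM = rnorm(n, 18, 11))
  d$executive <- rnorm(n); d$memory <- rnorm(n)
  d$executive[1] <- NA
  rExec <- fitAssociation(d, "executive", "vL_CGM")
  rMem <- fitAssociation(d, "memory", "vL_CGM")
  expect_equal(rExec@nUsed, n - 1L)
  expect_equal(rMem@nUsed, n)
  rMemFull <- fitAssociation(d[!is.na(d$executive), ], "memory", "vL_CGM")
  expect_false(isTRUE(all.equal(rMemFull@b, rMem@b)))
})
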