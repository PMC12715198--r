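test_that("the marginal covariance nests the simpler models", {
  p <- popTiny()
  n <- nrow(grm(p$A))
  ## only direct environmental noise: V = I
  V <- marginalCovariance(c(sigma2ED = 1), p$A, p$d)
  expect_equal(V, diag(n), ignore_attr = TRUE)
  ## a cage-mate-free design reduces V to the direct-effects covariance
  d0 <- new("StudyDesign", W = cageIncidence(p$d),
            Wm = maternalIncidence(p$d), Z = matrix(0, n, n),
            cageSizeCov = cageSizeCovariate(p$d),
            samples = sampleData(p$d))
  pars <- c(sigma2AD = 0.4, sigmaADS = 0.2, sigma2AS = 0.3, sigma2ED = 0.5,
            sigmaEDS = 0.1, sigma2ES = 0.2, sigma2C = 0.15, sigma2M = 0.1)
  V0 <- marginalCovariance(pars, p$A, d0)
  W <- cageIncidence(p$d)
  Wm <- maternalIncidence(p$d)
  expect_equal(V0, 0.4 * grm(p$A) + 0.5 * diag(n) + 0.15 * W %*% t(W) +
                 0.1 * Wm %*% t(Wm), ignore_attr = TRUE)
  ## model-1 parameter aliases are honoured
  expect_equal(marginalCovariance(c(sigma2A = 0.3, sigma2E = 0.7), p$A, d0),
               0.3 * grm(p$A) + 0.7 * diag(n), ignore_attr = TRUE)
  ## asymmetric Z is rejected
  dBad <- p$d
  dBad@Z[1, 2] <- 1 - dBad@Z[1, 2]
  expect_error(marginalCovariance(pars, p$A, dBad), "symmetric")
})

test_that("the full fit dominates the null fit and flags confounded
           designs", {
  p <- popCalib()
  sims <- simulatePhenotype(p$truth, p$A, p$d, nReplicates = 3L,
                            seed = 301L)
  for (r in 1:3) {
    fb <- fitSGE(sims$y[, r], p$A, p$d, model = "full", nRestarts = 1L)
    nb <- fitSGE(sims$y[, r], p$A, p$d, model = "null", nRestarts = 1L)
    expect_gte(fb@loglik, nb@loglik - 1e-4)
    expect_true(all(fb@params[c("sigma2AD", "sigma2AS", "sigma2ED",
                                "sigma2ES", "sigma2C", "sigma2M")] >= 0))
    expect_true(is.na(fb@rA) || abs(fb@rA) <= 1)
  }
  ## constant cage size: environmental/cage confounding warning
  pm <- popMain()
  yy <- simulatePhenotype(pm$truth, pm$A, pm$d, seed = 302L)$y
  expect_warning(fitSGE(yy, pm$A, pm$d, model = "null", nRestarts = 1L),
                 "confounded")
})

test_that("mixture p-values interpolate the two chi-square tails", {
  expect_equal(mixtureLRTPvalue(qchisq(0.95, 1), 0), 0.05,
               tolerance = 1e-12)
  expect_equal(mixtureLRTPvalue(qchisq(0.95, 2), 1), 0.05,
               tolerance = 1e-12)
  expect_identical(mixtureLRTPvalue(0, 0.3), 1)
  expect_identical(mixtureLRTPvalue(-2, 0.3), 1)   # clamped at zero
  expect_error(mixtureLRTPvalue(1, 1.4), "m must")
  ## monotone non-increasing in the statistic for any mixture weight
  lam <- seq(0, 12, by = 0.05)
  for (m in c(0, 0.4, 1))
    expect_true(all(diff(mixtureLRTPvalue(lam, m)) <= 0))
  ms <- seq(0, 1, by = 0.05)
  pv <- vapply(ms, function(m) mixtureLRTPvalue(3, m), numeric(1))
  expect_true(all(diff(pv) >= 0))  # chi2_2 tail dominates chi2_1 tail
})

test_that("total genetic variance is exact arithmetic on fits too", {
  p <- popCalib()
  y <- simulatePhenotype(p$truth, p$A, p$d, seed = 303L)$y
  fit <- fitSGE(y, p$A, p$d, model = "full", nRestarts = 1L)
  pr <- fit@params
  expect_identical(totalGeneticVariance(fit),
                   unname(pr["sigma2AD"] +
                            2 * (fit@nBar - 1) * pr["sigmaADS"] +
                            (fit@nBar - 1)^2 * pr["sigma2AS"]))
  expect_identical(totalGeneticVariance(fit, nBar = 1),
                   unname(pr["sigma2AD"]))
})

test_that("cage-mate permutation keeps cages but rewires mates", {
  p <- popSmall()
  dp <- permuteCageMates(p$d, seed = 14L)
  expect_identical(cageIncidence(dp), cageIncidence(p$d))
  expect_identical(maternalIncidence(dp), maternalIncidence(p$d))
  Z0 <- cageMates(p$d)
  Zp <- cageMates(dp)
  expect_identical(sort(unname(rowSums(Zp))), sort(unname(rowSums(Z0))))
  expect_identical(Zp, t(Zp))
  expect_true(all(diag(Zp) == 0))
  expect_false(identical(Zp, Z0))
  ## seeded: reproducible
  expect_identical(cageMates(permuteCageMates(p$d, seed = 14L)), Zp)
})

test_that("ignoring absent indirect effects is harmless and sign of the
           bias follows the correlation", {
  ## no indirect effects: both models agree on the direct variance
  truth0 <- SimTruth(nFamilies = 80L, offspringPerFamily = 3L,
                     nSnps = 2000L, cageSize = 3L, varDge = 0.4,
                     varIge = 0, corDgeIge = 0, varCage = 0.2,
                     varMaternal = 0, varEnvDirect = 0.4, seed = 401L)
  g0 <- simulateGenotypes(truth0)
  d0 <- makeDesign(pedigree(g0), cageSize = 3L, seed = 402L)
  A0 <- computeGRM(g0)
  ex0 <- dgeBiasExperiment(truth0, 10L, A0, d0, nRestarts = 1L,
                           seed = 403L)
  expect_lt(abs(ex0$means["fullDge"] - ex0$means["noIgeDge"]), 0.08)

  ## negative direct-indirect correlation flips the bias direction
  truthNeg <- SimTruth(nFamilies = 80L, offspringPerFamily = 3L,
                       nSnps = 2000L, cageSize = 3L, varDge = 0.4,
                       varIge = 0.2, corDgeIge = -0.9, varCage = 0.2,
                       varMaternal = 0, varEnvDirect = 0.2, seed = 404L)
  exNeg <- dgeBiasExperiment(truthNeg, 10L, A0, d0, nRestarts = 1L,
                             seed = 405L)
  expect_gt(exNeg$means["noIgeDge"], exNeg$means["fullDge"])
})
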