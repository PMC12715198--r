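test_that("REML fits recover simulated variance components", {
  ## truth (sigma2A, sigma2C, sigma2M, sigma2E) = (0.3, 0.2, 0.1, 0.4)
  truth <- SimTruth(nFamilies = 200L, offspringPerFamily = 3L,
                    nSnps = 3000L, cageSize = c(2L, 3L, 4L), varDge = 0.3,
                    varIge = 0, corDgeIge = 0, varCage = 0.2,
                    varMaternal = 0.1, varEnvDirect = 0.4, seed = 61L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = c(2L, 3L, 4L), seed = 62L)
  A <- computeGRM(g)
  R <- 20L
  sims <- simulatePhenotype(truth, A, d, nReplicates = R, seed = 63L)
  est <- matrix(NA_real_, R, 4,
                dimnames = list(NULL, c("sigma2A", "sigma2C", "sigma2M",
                                        "sigma2E")))
  for (r in seq_len(R)) {
    f <- fitVarComp(sims$y[, r], A, d, nRestarts = 1L)
    est[r, ] <- f@params[colnames(est)]
  }
  bias <- colMeans(est) - c(0.3, 0.2, 0.1, 0.4)
  expect_true(all(abs(bias) < 0.05))
})

test_that("pure-noise phenotypes give near-zero heritability", {
  p <- popSmall()
  truth0 <- SimTruth(nFamilies = 40L, offspringPerFamily = 3L, varDge = 0,
                     varIge = 0, corDgeIge = 0, varCage = 0,
                     varMaternal = 0, varEnvDirect = 1, seed = 71L)
  sims <- simulatePhenotype(truth0, p$A, p$d, nReplicates = 25L)
  h2 <- vapply(seq_len(25L), function(r)
    heritability(fitVarComp(sims$y[, r], p$A, p$d, nRestarts = 1L)),
    numeric(1))
  expect_lte(mean(h2), 0.05)
})

test_that("the restricted likelihood at the optimum matches an independent
           contrast evaluation and respects nesting", {
  p <- popTiny()
  y <- simulatePhenotype(p$truth, p$A, p$d, seed = 81L)$y
  full <- fitVarComp(y, p$A, p$d)
  V <- marginalCovariance(full@params, p$A, p$d)
  expect_lt(abs(full@loglik - contrastREML(y, full@details$X, V)), 1e-6)
  ## the package criterion itself agrees with the oracle at arbitrary params
  expect_lt(abs(remlLogLik(y, full@details$X, V) -
                  contrastREML(y, full@details$X, V)), 1e-10)
  ## dropping a component can only lower the restricted likelihood
  red <- fitVarComp(y, p$A, p$d, genetic = FALSE)
  noM <- fitVarComp(y, p$A, p$d, maternal = FALSE)
  expect_gte(full@loglik, red@loglik - 1e-4)
  expect_gte(full@loglik, noM@loglik - 1e-4)
  ## estimates are invariant to reordering individuals
  o <- rev(seq_along(y))
  dR <- new("StudyDesign", W = cageIncidence(p$d)[o, ],
            Wm = maternalIncidence(p$d)[o, ],
            Z = cageMates(p$d)[o, o],
            cageSizeCov = cageSizeCovariate(p$d)[o],
            samples = sampleData(p$d)[o, ])
  fR <- fitVarComp(y[o], grm(p$A)[o, o], dR)
  expect_equal(fR@params, full@params, tolerance = 1e-4)
  expect_equal(fR@loglik, full@loglik, tolerance = 1e-6)
})

test_that("the heritability LRT has the right tail and guards nesting", {
  p <- popTiny()
  y <- simulatePhenotype(p$truth, p$A, p$d, seed = 91L)$y
  full <- fitVarComp(y, p$A, p$d)
  red <- fitVarComp(y, p$A, p$d, genetic = FALSE)
  lrt <- heritabilityLRT(full, red)
  expect_identical(lrt@p, pchisq(lrt@statistic, 1, lower.tail = FALSE))
  ## chi-square(1) anchors
  expect_identical(mixtureLRTPvalue(0, 0), 1)
  expect_equal(mixtureLRTPvalue(qchisq(0.95, 1), 0), 0.05,
               tolerance = 1e-12)
  expect_error(heritabilityLRT(red, full), "nested")
})

test_that("null-simulation LRT p-values are uniform or conservative", {
  truth0 <- SimTruth(nFamilies = 60L, offspringPerFamily = 3L,
                     nSnps = 1500L, cageSize = c(2L, 3L), varDge = 0,
                     varIge = 0, corDgeIge = 0, varCage = 0.2,
                     varMaternal = 0.1, varEnvDirect = 0.7, seed = 95L)
  g <- simulateGenotypes(truth0)
  d <- makeDesign(pedigree(g), cageSize = c(2L, 3L), seed = 96L)
  A <- computeGRM(g)
  R <- 100L
  sims <- simulatePhenotype(truth0, A, d, nReplicates = R, seed = 97L)
  pv <- vapply(seq_len(R), function(r) {
    y <- sims$y[, r]
    heritabilityLRT(fitVarComp(y, A, d, nRestarts = 1L),
                    fitVarComp(y, A, d, genetic = FALSE,
                               nRestarts = 1L))@p
  }, numeric(1))
  ## no anti-conservative excess at the usual working levels
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(pv < a), a + 3 * sqrt(a * (1 - a) / R))
})

test_that("Benjamini-Hochberg selection follows the step-up rule", {
  sel <- bhSignificant(c(0.001, 0.02, 0.03, 0.5), q = 0.1)
  expect_identical(unname(which(sel)), 1:3)
  expect_false(any(bhSignificant(rep(1, 6), q = 0.1)))
  expect_true(all(bhSignificant(rep(0, 6), q = 0.1)))
  expect_error(bhSignificant(c(0.5, 1.2)))
})
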