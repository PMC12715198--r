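test_that("with identity covariance the scan equals OLS likelihood-ratio
           regression", {
  gh <- hweGenotypes(150L, 30L, seed = 21L)
  set.seed(22)
  y <- rnorm(150)
  sc <- lmmScan(y, gh, grms = NULL)
  d <- dosages(gh)
  for (j in c(1L, 7L, 30L)) {
    rss1 <- sum(resid(lm(y ~ d[, j]))^2)
    rss0 <- sum(resid(lm(y ~ 1))^2)
    lrt <- 150 * log(rss0 / rss1)
    expect_equal(sc@results$negLog10P[j],
                 -pchisq(lrt, 1, lower.tail = FALSE, log.p = TRUE) / log(10),
                 tolerance = 1e-8)
  }
  ## scan p-values are invariant to affine rescaling of the phenotype
  sc2 <- lmmScan(3 * y + 2, gh, grms = NULL)
  expect_equal(sc2@results$negLog10P, sc@results$negLog10P,
               tolerance = 1e-6)
})

test_that("LOCO scans exclude the tested chromosome from the GRM and stay
           affine invariant", {
  p <- popSmall()
  grms <- locoGRMs(p$g)
  expect_identical(names(grms), as.character(1:20))
  for (ch in c(1L, 20L))
    expect_identical(nVariants(grms[[as.character(ch)]]),
                     sum(variantMap(p$g)$chrom != ch))
  y <- simulatePhenotype(p$truth, p$A, p$d, seed = 21L)$y
  sc <- lmmScan(y, p$g, grms, design = p$d, nRestarts = 1L)
  expect_identical(nrow(sc@results), ncol(dosages(p$g)))
  expect_true(all(is.finite(sc@results$negLog10P) |
                    is.na(sc@results$negLog10P)))
  sc2 <- lmmScan(2 * y - 5, p$g, grms, design = p$d, nRestarts = 1L)
  expect_equal(sc2@results$negLog10P, sc@results$negLog10P,
               tolerance = 1e-4)
  ## constant variants are reported as missing
  gConst <- p$g
  gConst@dosages[, 3] <- 1
  scc <- lmmScan(y, gConst, grms, design = p$d, nRestarts = 1L)
  expect_true(is.na(scc@results$negLog10P[3]))
})

test_that("the permutation threshold grows with the number of variants", {
  gh100 <- hweGenotypes(200L, 100L, seed = 61L)
  gh1000 <- hweGenotypes(200L, 1000L, seed = 61L)
  set.seed(62)
  y <- rnorm(200)
  t100 <- permutationThreshold(y, gh100, locoGRMs(gh100), nPerm = 150L,
                               seed = 63L)
  t1000 <- permutationThreshold(y, gh1000, locoGRMs(gh1000), nPerm = 150L,
                                seed = 63L)
  expect_gt(t1000, t100)
  ## each is near its closed form for independent variants
  expect_lt(abs(t100 - -log10(1 - 0.95^(1 / 100))), 0.35)
  expect_lt(abs(t1000 - -log10(1 - 0.95^(1 / 1000))), 0.35)
  expect_error(permutationThreshold(y, gh100, nPerm = 10L), "nPerm")
  expect_length(attr(t100, "minima"), 150L)
})

test_that("the phenome-wide adjustment counts effective phenotypes via
           eigenvalues", {
  ## identical phenotypes: rank 1
  Y1 <- matrix(rnorm(100), 100, 1)[, rep(1, 8)]
  a <- adjustedThreshold(5.8, Y1)
  expect_identical(a$nEff, 1L)
  expect_identical(a$adjusted, 5.8)
  ## a single phenotype passes through
  expect_identical(adjustedThreshold(4.2, matrix(rnorm(50)))$nEff, 1L)
  ## orthonormal zero-mean columns: exactly equal eigenvalues, so
  ## nEff = ceiling(0.99 p); with p = 402 that is 398 and the adjustment
  ## reproduces the 5.8 -> 8.4 relation
  H <- contr.helmert(403)
  Y <- sweep(H, 2, sqrt(colSums(H^2)), `/`)
  a4 <- adjustedThreshold(5.8, Y)
  expect_identical(a4$nEff, 398L)
  expect_equal(a4$adjusted, 5.8 + log10(398), tolerance = 1e-12)
  expect_lt(abs(a4$adjusted - 8.4), 0.005)
  ## iid equal-variance phenotypes approach ceiling(0.99 p) at large n
  set.seed(5)
  Yiid <- matrix(rnorm(50000 * 20), 50000, 20)
  expect_identical(adjustedThreshold(3, Yiid)$nEff, 20L)
  ## missing rows are dropped with a warning
  Ym <- matrix(rnorm(60), 20, 3)
  Ym[2, 1] <- NA
  expect_warning(adjustedThreshold(3, Ym), "dropped")
})
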