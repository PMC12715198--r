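mkGeno <- function(d, chrom = NULL) {
  if (is.null(chrom)) chrom <- rep(1L, ncol(d))
  map <- data.frame(chrom = chrom,
                    pos = as.integer(ave(seq_along(chrom), chrom,
                                         FUN = seq_along) * 100L),
                    id = paste0("v", seq_len(ncol(d))))
  GenotypeMatrix(dosages = d, map = map)
}

test_that("variant QC applies the missingness and frequency rules", {
  n <- 100
  set.seed(6)
  ok <- rbinom(n, 2, 0.3)
  highMiss <- ok; highMiss[1:11] <- NA          # 11% missing: removed
  lowMiss <- ok; lowMiss[1:10] <- NA            # 10% missing: kept
  atMaf <- c(rep(1, 10), rep(0, 90))            # MAF exactly 0.05: kept
  below <- c(rep(1, 9), rep(0, 91))             # MAF 0.045: removed
  mono <- rep(2, n)                             # monomorphic: removed
  G <- mkGeno(cbind(ok, highMiss, lowMiss, atMaf, below, mono) * 1)
  kept <- variantMap(qcFilter(G))$id
  expect_identical(kept, c("v1", "v3", "v4"))
})

test_that("LD pruning removes correlated variants and keeps independent
           ones", {
  set.seed(12)
  n <- 150
  g1 <- rbinom(n, 2, 0.4) * 1
  ## duplicated column (r2 = 1): exactly one survives
  G <- mkGeno(cbind(g1, g1, rbinom(n, 2, 0.4)))
  pruned <- ldPrune(G, r2Threshold = 0.5)
  expect_identical(ncol(dosages(pruned)), 2L)
  expect_true("v1" %in% variantMap(pruned)$id)
  ## independent variants all survive
  ind <- matrix(rbinom(n * 20, 2, 0.5), n, 20) * 1
  expect_identical(ncol(dosages(ldPrune(mkGeno(ind), r2Threshold = 0.5))),
                   20L)
  ## r2 chain: no retained pair exceeds the threshold
  base <- rbinom(n, 2, 0.5)
  g2 <- base
  flip <- sample(n, 15)
  g2[flip] <- rbinom(15, 2, 0.5)   # g2 highly correlated with base
  g3 <- g2
  flip <- sample(n, 15)
  g3[flip] <- rbinom(15, 2, 0.5)   # g3 close to g2, farther from base
  Gc <- mkGeno(cbind(base, g2, g3) * 1)
  pr <- ldPrune(Gc, r2Threshold = 0.5)
  dd <- dosages(pr)
  if (ncol(dd) > 1) {
    cc <- cor(dd)^2
    expect_true(all(cc[upper.tri(cc)] <= 0.5))
  }
  expect_gte(ncol(dd), 1L)
})

test_that("the GRM matches hand arithmetic and standardization theory", {
  ## 3 individuals x 2 variants, worked by hand
  d <- rbind(c(0, 2), c(1, 1), c(2, 0)) * 1
  G <- mkGeno(d)
  p <- colMeans(d) / 2                      # (0.5, 0.5)
  S <- sweep(d, 2, 2 * p, `-`) / rep(sqrt(2 * p * (1 - p)), each = 3)
  Ahand <- S %*% t(S) / 2
  expect_equal(unname(grm(computeGRM(G))), unname(Ahand), tolerance = 1e-12)
  ## identical dosage rows give A_ii = A_jj = A_ij
  d2 <- rbind(d[1, ], d[1, ], d[3, ])
  A2 <- grm(computeGRM(mkGeno(d2)))
  expect_equal(A2[1, 1], A2[2, 2], tolerance = 1e-12)
  expect_equal(A2[1, 1], A2[1, 2], tolerance = 1e-12)
  ## unrelated HWE individuals: mean diagonal ~ 1 up to the O(1/n)
  ## finite-sample effect of sample-frequency centering
  gh <- hweGenotypes(80L, 10000L, seed = 41L)
  dg <- diag(grm(computeGRM(gh)))
  expect_lt(abs(mean(dg) - 1), 2 / 80 + 3 * sd(dg) / sqrt(length(dg)))
  ## missing dosages are mean-imputed, monomorphic variants dropped
  d3 <- cbind(c(0, 1, 2, NA), c(2, 2, 2, 2)) * 1
  expect_warning(K3 <- computeGRM(mkGeno(d3)), "monomorphic")
  expect_identical(nVariants(K3), 1L)
})

test_that("leave-one-chromosome-out construction excludes exactly that
           chromosome", {
  p <- popSmall()
  map <- variantMap(p$g)
  K5 <- computeGRM(p$g, locoChrom = 5L)
  expect_identical(locoChromosome(K5), 5L)
  expect_identical(nVariants(K5), sum(map$chrom != 5L))
  ## equals the GRM built on the complementary variant set
  sub <- sgemix:::subsetVariants(p$g, map$chrom != 5L)
  expect_equal(grm(K5), grm(computeGRM(sub)), tolerance = 1e-12)
  ## per-chromosome GRMs recombine (variant-count weighted) into the total
  parts <- lapply(sort(unique(map$chrom)), function(ch) {
    Kc <- computeGRM(sgemix:::subsetVariants(p$g, map$chrom == ch))
    grm(Kc) * nVariants(Kc)
  })
  tot <- computeGRM(p$g)
  expect_equal(Reduce(`+`, parts) / nVariants(tot), grm(tot),
               tolerance = 1e-10)
})
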