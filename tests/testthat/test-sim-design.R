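test_that("no-cohousing designs never cage siblings together", {
  truth <- SimTruth(nFamilies = 100L, offspringPerFamily = 2L,
                    nSnps = 100L, seed = 15L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = 2L, cohousing = FALSE, seed = 8L)
  Z <- cageMates(d)
  expect_true(all(rowSums(Z) == 1))
  mum <- sampleData(d)$mother
  idx <- which(Z == 1, arr.ind = TRUE)
  expect_true(all(mum[idx[, 1]] != mum[idx[, 2]]))
})

test_that("incidence and cage-mate matrices satisfy Z = W W^T - diag", {
  ped <- pedigree(popSmall()$g)
  for (cfg in list(list(cs = c(2L, 3L, 4L), co = FALSE),
                   list(cs = 3L, co = FALSE),
                   list(cs = c(2L, 3L), co = TRUE))) {
    d <- makeDesign(ped, cageSize = cfg$cs, cohousing = cfg$co, seed = 21L)
    W <- cageIncidence(d)
    WWt <- W %*% t(W)
    diag(WWt) <- 0
    expect_equal(unname(cageMates(d)), unname(WWt))
    expect_true(all(rowSums(W) == 1))
    expect_identical(unname(cageSizeCovariate(d)),
                     unname(colSums(W)[max.col(W)]))
  }
})

test_that("fixed cage sizes give the matching cage-mate counts", {
  ped <- pedigree(popSmall()$g)
  d3 <- makeDesign(ped, cageSize = 3L, cohousing = FALSE, seed = 1L)
  expect_true(all(rowSums(cageMates(d3)) == 2))
  ## remainder cages are allowed but never smaller than 2
  ped7 <- ped[seq(1, 19, by = 3), ]   # one offspring from 7 families
  d7 <- makeDesign(ped7, cageSize = 3L, cohousing = FALSE, seed = 1L)
  expect_identical(sum(colSums(cageIncidence(d7))), 7)
  expect_true(all(colSums(cageIncidence(d7)) >= 2))
})

test_that("infeasible sibling constraints fail loudly", {
  ped <- data.frame(id = paste0("i", 1:4), family = 1L,
                    mother = "m1", father = "f1")
  expect_error(makeDesign(ped, cageSize = 2L, cohousing = FALSE, seed = 1L),
               "infeasible")
  ## the same pedigree is fine when siblings may be co-housed
  d <- makeDesign(ped, cageSize = 2L, cohousing = TRUE, seed = 1L)
  expect_true(all(rowSums(cageMates(d)) == 1))
})

test_that("co-housing places siblings together preferentially", {
  truth <- SimTruth(nFamilies = 30L, offspringPerFamily = 2L,
                    nSnps = 100L, seed = 19L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = 2L, cohousing = TRUE, seed = 9L)
  Z <- cageMates(d)
  mum <- sampleData(d)$mother
  idx <- which(Z == 1, arr.ind = TRUE)
  ## sib pairs dominate when cage size matches family size
  expect_gt(mean(mum[idx[, 1]] == mum[idx[, 2]]), 0.9)
})

test_that("pooled designs stack cohorts block-diagonally and share
           mothers by ID", {
  truth <- SimTruth(nFamilies = 20L, offspringPerFamily = 3L,
                    nSnps = 100L, seed = 25L)
  ped <- pedigree(simulateGenotypes(truth))
  pedA <- ped[ped$family <= 10, ]
  pedB <- ped[ped$family > 10, ]
  dA <- makeDesign(pedA, cageSize = 2L, cohousing = FALSE, seed = 1L)
  dB <- makeDesign(pedB, cageSize = 3L, cohousing = TRUE, seed = 2L)
  dp <- combineDesigns(dA, dB, cohorts = c("north", "south"))
  n <- nrow(ped)
  expect_identical(dim(cageMates(dp)), c(n, n))
  ## no cage mates across cohorts
  iA <- seq_len(nrow(pedA))
  expect_true(all(cageMates(dp)[iA, -iA] == 0))
  expect_identical(unname(cageMates(dp)[iA, iA]), unname(cageMates(dA)))
  expect_identical(sampleData(dp)$cohort,
                   rep(c("north", "south"), c(nrow(pedA), nrow(pedB))))
  ## each individual still has exactly one cage and one mother
  expect_true(all(rowSums(cageIncidence(dp)) == 1))
  expect_true(all(rowSums(maternalIncidence(dp)) == 1))
  expect_identical(ncol(maternalIncidence(dp)), 20L)
  expect_true(validObject(dp))
})
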