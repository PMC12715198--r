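test_that("depth filter trims both tails of the library-size distribution", {
  mk <- function(depths) {
    cts <- do.call(cbind, lapply(depths, function(dd)
      c(dd - 1, 1, 0)))
    AbundanceTable(cts, taxonomy = rep("k__B;p__P", 3))
  }
  depths <- c(100, 100, 100, 100, 10000)
  tab <- mk(depths)
  kept <- colnames(counts(filterByDepth(tab, k = 2)))
  outlier <- depths > mean(depths) + 2 * sd(depths) |
    depths < mean(depths) - 2 * sd(depths)
  expect_identical(kept, colnames(counts(tab))[!outlier])
  ## all depths equal: everything is retained, even at k = 0
  same <- mk(rep(500, 4))
  expect_identical(ncol(counts(filterByDepth(same, k = 2))), 4L)
  expect_identical(ncol(counts(filterByDepth(same, k = 0))), 4L)
  ## k = 0 keeps only samples exactly at the mean
  tab2 <- mk(c(100, 200, 300))
  expect_identical(kept <- colnames(counts(filterByDepth(tab2, k = 0))),
                   colnames(counts(tab2))[2])
})

test_that("CLR transform matches its closed form and invariances", {
  x <- c(0.5, 0.3, 0.2)
  tab <- AbundanceTable(matrix(c(5000, 3000, 2000), 3, 1),
                        taxonomy = rep(NA_character_, 3))
  gmean <- prod(x)^(1 / 3)
  out <- clrTransform(tab)
  expect_equal(drop(out), log(x / gmean), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(abs(sum(out)), 1e-10)
  ## zeros are replaced on the relative-abundance scale before the log
  tab0 <- AbundanceTable(matrix(c(600, 400, 0), 3, 1),
                         taxonomy = rep(NA_character_, 3))
  v <- c(0.6, 0.4, 0.00001)
  expect_equal(drop(clrTransform(tab0)), log(v) - mean(log(v)),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## scale invariance: multiplying one sample's counts changes nothing
  set.seed(2)
  cts <- matrix(rpois(30, 50) + 1, 5, 6)
  expect_equal(clrTransform(cts), clrTransform(cts %*% diag(c(7, rep(1, 5)))),
               ignore_attr = TRUE)
  ## all-zero sample fails
  expect_error(clrTransform(matrix(c(1, 0, 0, 0), 2, 2)), "all-zero")
})

test_that("taxonomic collapsing conserves counts and is associative", {
  tab <- simulateCounts(15, 24, seed = 8L)
  fam <- collapseTaxonomy(tab, "family")
  expect_identical(unname(colSums(counts(fam))),
                   unname(colSums(counts(tab))))
  ## two members of one family sum
  gtab <- AbundanceTable(matrix(c(3, 7), 2, 1),
                         taxonomy = rep("k__B;p__P;c__C;o__O;f__F1", 2))
  expect_identical(unname(counts(collapseTaxonomy(gtab, "family"))[1, 1]), 10)
  ## genus then family equals family directly
  viaGenus <- collapseTaxonomy(collapseTaxonomy(tab, "genus"), "family")
  direct <- collapseTaxonomy(tab, "family")
  o <- match(rownames(counts(direct)), rownames(counts(viaGenus)))
  expect_identical(unname(counts(viaGenus)[o, ]), unname(counts(direct)))
  ## unknown level and unassigned pooling
  expect_error(collapseTaxonomy(tab, "kingdoms"), "unknown")
  mixed <- AbundanceTable(matrix(1:4, 2, 2),
                          taxonomy = c("k__B;p__P", NA))
  fam2 <- collapseTaxonomy(mixed, "family")
  expect_true("unassigned" %in% rownames(counts(fam2)))
})

test_that("prevalence filtering keeps taxa at or above the boundary", {
  cts <- rbind(t4 = c(rep(1, 4), rep(0, 6)),
               t5 = c(rep(1, 5), rep(0, 5)),
               t10 = rep(1, 10))
  tab <- AbundanceTable(cts, taxonomy = rep(NA_character_, 3))
  kept <- prevalenceFilter(tab, threshold = 0.5)
  expect_false("t4" %in% kept)   # 40% < 50%
  expect_true("t5" %in% kept)    # exactly 50% passes ("at least")
  expect_identical(prevalenceFilter(tab, threshold = 0),
                   rownames(cts))
  ## per-group filtering and empty-group failure
  grp <- rep(c("a", "b"), each = 5)
  byg <- prevalenceFilter(tab, threshold = 0.5, group = grp)
  expect_identical(byg$a, c("t4", "t5", "t10"))
  expect_identical(byg$b, "t10")
  expect_error(prevalenceFilter(tab, group = factor(grp,
                                                    levels = c("a", "b", "c"))),
               "empty")
})

test_that("rank-normalization is seeded, rank-invariant and orthogonal to
           covariates", {
  set.seed(10)
  y <- rnorm(200)
  cov <- data.frame(sex = factor(rep(c("F", "M"), 100)),
                    batch = factor(rep(1:4, each = 50)),
                    librarySize = rlnorm(200, 10, 0.3))
  r <- normalizePhenotype(y, cov, seed = 3L)
  mm <- model.matrix(~ ., cov)
  expect_true(all(abs(crossprod(mm, r)) < 1e-8))
  ## monotone transforms of tie-free data give identical output
  r2 <- normalizePhenotype(exp(2 * y), cov, seed = 3L)
  expect_identical(r, r2)
  ## standard-normal marginals before residualization
  z <- normalizePhenotype(y, seed = 3L)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sd(z) - 1), 0.02)
  ## constant input: a seeded random permutation of normal quantiles
  z1 <- normalizePhenotype(rep(1, 200), seed = 4L)
  z2 <- normalizePhenotype(rep(1, 200), seed = 5L)
  expect_identical(sort(z1), sort(normalizePhenotype(y, seed = 1L)[order(
    normalizePhenotype(y, seed = 1L))]))
  expect_false(identical(z1, z2))
  expect_gt(suppressWarnings(ks.test(z1, "pnorm"))$p.value, 0.01)
  ## missing covariates are dropped and reported
  cov2 <- cov
  cov2$librarySize[5] <- NA
  expect_message(r3 <- normalizePhenotype(y, cov2, seed = 3L), "dropped")
  expect_true(is.na(r3[5]))
  ## rank-deficient covariates trigger a warning, not a failure
  cov3 <- cov
  cov3$dup <- as.numeric(cov3$sex == "M")
  expect_warning(normalizePhenotype(y, cov3, seed = 3L), "rank")
})
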