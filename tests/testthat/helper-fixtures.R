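## Shared fixtures, built once per test run and cached. All synthetic, all
## seeded: no files are read.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

## Main simulation population: 150 nuclear families x 3 sibs (n = 450),
## cages of 3, siblings never co-housed; strong indirect genetic effects
## (direct 0.4, indirect 0.2, correlation 0.9, cage 0.2).
popMain <- function() fixture("popMain", function() {
  truth <- SimTruth(nFamilies = 150L, offspringPerFamily = 3L,
                    nSnps = 4000L, cageSize = 3L, varMaternal = 0,
                    seed = 11L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = 3L, cohousing = FALSE, seed = 3L)
  list(truth = truth, g = g, d = d, A = computeGRM(g))
})

## The direct-vs-indirect recovery experiment on popMain (100 phenotypes,
## both models per phenotype); shared by several acceptance checks.
mainExperiment <- function() fixture("mainExperiment", function() {
  p <- popMain()
  dgeBiasExperiment(p$truth, 100L, p$A, p$d, nRestarts = 1L, seed = 101L)
})

## Null-calibration population: mixed cage sizes 2-4, direct genetic, cage
## and maternal effects but no indirect genetic effects.
popCalib <- function() fixture("popCalib", function() {
  truth <- SimTruth(nFamilies = 100L, offspringPerFamily = 3L,
                    nSnps = 2500L, cageSize = c(2L, 3L, 4L), varDge = 0.4,
                    varIge = 0, corDgeIge = 0, varCage = 0.2,
                    varMaternal = 0.1, varEnvDirect = 0.3, seed = 42L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = c(2L, 3L, 4L), cohousing = FALSE,
                  seed = 5L)
  list(truth = truth, g = g, d = d, A = computeGRM(g))
})

## Small population for module-level tests (n = 120, mixed cages).
popSmall <- function() fixture("popSmall", function() {
  truth <- SimTruth(nFamilies = 40L, offspringPerFamily = 3L,
                    nSnps = 1500L, cageSize = c(2L, 3L, 4L), seed = 7L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = c(2L, 3L, 4L), cohousing = FALSE,
                  seed = 2L)
  list(truth = truth, g = g, d = d, A = computeGRM(g))
})

## Tiny population (n = 20) for Monte-Carlo covariance oracles.
popTiny <- function() fixture("popTiny", function() {
  truth <- SimTruth(nFamilies = 5L, offspringPerFamily = 4L, nSnps = 2000L,
                    cageSize = c(2L, 3L), varMaternal = 0.1,
                    varEnvIndirect = 0.15, corEnv = 0.4, seed = 13L)
  g <- simulateGenotypes(truth)
  d <- makeDesign(pedigree(g), cageSize = c(2L, 3L), cohousing = FALSE,
                  seed = 4L)
  ## tiny sample: some simulated variants are monomorphic by chance
  list(truth = truth, g = g, d = d, A = suppressWarnings(computeGRM(g)))
})

## Unrelated individuals drawn under Hardy-Weinberg (no families): each
## individual is its own family, so any design is sibling-free.
hweGenotypes <- function(nInd, nSnps, maf = c(0.1, 0.5), seed = 1L) {
  set.seed(seed)
  p <- runif(nSnps, maf[1], maf[2])
  d <- matrix(rbinom(nInd * nSnps, 2L, rep(p, each = nInd)), nInd, nSnps)
  storage.mode(d) <- "double"
  rownames(d) <- sprintf("h_%04d", seq_len(nInd))
  chrom <- sort(rep(1:20, length.out = nSnps))
  map <- data.frame(chrom = chrom,
                    pos = unlist(lapply(tabulate(chrom, 20),
                                        function(k) seq_len(k) * 1000L)),
                    id = sprintf("hsnp_%05d", seq_len(nSnps)),
                    stringsAsFactors = FALSE)
  colnames(d) <- map$id
  ped <- data.frame(id = rownames(d), family = seq_len(nInd),
                    mother = sprintf("hm_%04d", seq_len(nInd)),
                    father = sprintf("hf_%04d", seq_len(nInd)),
                    stringsAsFactors = FALSE)
  GenotypeMatrix(dosages = d, map = map, pedigree = ped)
}

## Independent oracle for the restricted likelihood: log-density of the
## error contrasts L'y with L an orthonormal basis of the orthogonal
## complement of col(X), evaluated by plain determinant() and solve().
contrastREML <- function(y, X, V) {
  n <- length(y)
  X <- as.matrix(X)
  L <- qr.Q(qr(X), complete = TRUE)[, (ncol(X) + 1):n, drop = FALSE]
  S <- t(L) %*% V %*% L
  ly <- drop(t(L) %*% y)
  -0.5 * ((n - ncol(X)) * log(2 * pi) +
            as.numeric(determinant(S, logarithm = TRUE)$modulus) +
            sum(ly * solve(S, ly)))
}

## Monte-Carlo standard error of an empirical covariance entry.
mcCovSE <- function(V, R) sqrt((outer(diag(V), diag(V)) + V^2) / R)
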