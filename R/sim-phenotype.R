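#' Simulate phenotypes from the direct + indirect genetic effects model
#'
#' Draws phenotypes from the exact joint covariance of the social genetic
#' effects model
#' \deqn{y = Xb + a_D + Z a_S + e_D + Z e_S + W c + W' m,}
#' where the direct and indirect genetic effects `(a_D, a_S)` are jointly
#' multivariate normal with covariance
#' `rbind(cbind(varDge * A, covA * A), cbind(covA * A, varIge * A))`
#' (`covA = corDgeIge * sqrt(varDge * varIge)`), the environmental pair
#' `(e_D, e_S)` has the analogous structure with identity kernels, cage
#' effects `c` are iid with variance `varCage`, and maternal effects `m` are
#' iid with variance `varMaternal`. Every component is returned alongside
#' `y`, and the components sum to `y` exactly.
#'
#' @param truth a \linkS4class{SimTruth} holding the variance parameters.
#' @param A a \linkS4class{KinshipMatrix} (or plain symmetric PSD matrix).
#' @param design a \linkS4class{StudyDesign} conformable with `A`.
#' @param nReplicates number of independent phenotype draws.
#' @param seed seed for the phenotype stream (default derives from the
#'   truth's master seed).
#' @return A list with `y` (vector, or n x nReplicates matrix) and
#'   `components`, a named list (`fixed`, `dge`, `ige`, `envDirect`,
#'   `envIndirect`, `cage`, `maternal`) of the additive pieces, plus
#'   `social`, the underlying per-individual social effects `aS`, `eS`.
#' @examples
#' truth <- SimTruth(nFamilies = 10L, nSnps = 300L)
#' g <- simulateGenotypes(truth)
#' d <- makeDesign(pedigree(g), cageSize = 3L, seed = 1L)
#' A <- computeGRM(g)
#' sim <- simulatePhenotype(truth, A, d)
#' stopifnot(all.equal(Reduce(`+`, sim$components), sim$y))
#' @export
simulatePhenotype <- function(truth, A, design, nReplicates = 1L,
                              seed = NULL) {
  stopifnot(is(truth, "SimTruth"), is(design, "StudyDesign"))
  validObject(truth)
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  n <- nrow(Amat)
  Z <- cageMates(design)
  W <- cageIncidence(design)
  Wm <- maternalIncidence(design)
  stopifnot(nrow(Z) == n, nrow(W) == n, nrow(Wm) == n)
  if (is.null(seed)) seed <- streamSeed(truth@seed, "phenotype")
  R <- as.integer(nReplicates)

  sqA <- symSqrt(symmetrize(Amat))
  SgA <- pairSqrt(truth@varDge, truth@varIge, truth@corDgeIge)
  SgE <- pairSqrt(truth@varEnvDirect, truth@varEnvIndirect, truth@corEnv)

  withSeed(seed, {
    za <- matrix(rnorm(n * 2 * R), n)
    ag <- sqA %*% za                      # n x 2R, iid N(0, A) columns
    aD <- ag[, seq_len(R), drop = FALSE] * SgA[1, 1] +
          ag[, R + seq_len(R), drop = FALSE] * SgA[1, 2]
    aS <- ag[, seq_len(R), drop = FALSE] * SgA[2, 1] +
          ag[, R + seq_len(R), drop = FALSE] * SgA[2, 2]
    ze <- matrix(rnorm(n * 2 * R), n)
    eD <- ze[, seq_len(R), drop = FALSE] * SgE[1, 1] +
          ze[, R + seq_len(R), drop = FALSE] * SgE[1, 2]
    eS <- ze[, seq_len(R), drop = FALSE] * SgE[2, 1] +
          ze[, R + seq_len(R), drop = FALSE] * SgE[2, 2]
    cc <- matrix(rnorm(ncol(W) * R, sd = sqrt(truth@varCage)), ncol(W))
    mm <- matrix(rnorm(ncol(Wm) * R, sd = sqrt(truth@varMaternal)), ncol(Wm))
  })

  comp <- list(
    fixed = matrix(truth@fixedCageSizeEffect * cageSizeCovariate(design),
                   n, R),
    dge = aD,
    ige = Z %*% aS,
    envDirect = eD,
    envIndirect = Z %*% eS,
    cage = W %*% cc,
    maternal = Wm %*% mm)
  y <- Reduce(`+`, comp)
  if (R == 1L) {
    y <- drop(y)
    comp <- lapply(comp, drop)
    aS <- drop(aS); eS <- drop(eS)
  }
  list(y = y, components = comp, social = list(aS = aS, eS = eS))
}

## 2x2 symmetric square root of [[v1, c],[c, v2]] with c = r sqrt(v1 v2);
## exact for the degenerate |r| = 1 case (columns proportional).
pairSqrt <- function(v1, v2, r) {
  if (abs(r) > 1) stop("correlation outside [-1, 1]")
  S <- matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
  if (abs(r) == 1) {
    ## rank-1: S = u u' with u = (sqrt(v1), sign(r) sqrt(v2))
    u <- c(sqrt(v1), sign(r) * sqrt(v2))
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(matrix(0, 2, 2))
    return(outer(u, u) / nu)
  }
  symSqrt(S)
}

#' Draw phenotypes from a fitted null (no indirect-genetic) model
#'
#' Parametric bootstrap under the null hypothesis of no indirect genetic
#' effects: phenotypes are drawn from the multivariate normal with mean
#' `X beta` and covariance implied by the fitted null model (direct genetic,
#' cage, maternal and environmental terms; indirect *environmental* terms
#' are allowed). Used to calibrate the chi-square mixture for the
#' social-effects likelihood-ratio test.
#'
#' @param fit an \linkS4class{SGEFit} from `fitSGE(..., model = "null")`, or
#'   any fit whose indirect genetic parameters are zero.
#' @param A kinship matrix (object or plain matrix) used in the fit.
#' @param design the \linkS4class{StudyDesign} used in the fit.
#' @param nBoot number of bootstrap phenotypes.
#' @param seed RNG seed.
#' @return n x nBoot matrix of null phenotype draws.
#' @export
parametricBootstrapNull <- function(fit, A, design, nBoot = 200L, seed = 1L) {
  stopifnot(is(fit, "RemlFit"), is(design, "StudyDesign"))
  p <- fit@params
  if (abs(p["sigma2AS"] %||% 0) > 1e-10 || abs(p["sigmaADS"] %||% 0) > 1e-10)
    stop("fit contains indirect genetic terms; refit with model = 'null'")
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  V <- marginalCovariance(p, Amat, design)
  X <- fit@details$X
  mu <- if (!is.null(X) && length(fit@beta)) drop(X %*% fit@beta)
        else rep(0, nrow(Amat))
  sqV <- symSqrt(symmetrize(V))
  withSeed(streamSeed(seed, "bootstrap"), {
    draws <- sqV %*% matrix(rnorm(nrow(Amat) * nBoot), nrow(Amat)) + mu
  })
  draws
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
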