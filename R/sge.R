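#' Marginal phenotypic covariance of the social genetic effects model
#'
#' Assembles the covariance of `y = Xb + a_D + Z a_S + e_D + Z e_S + Wc +
#' W'm` implied by the joint distribution of the random effects:
#' \deqn{V = \sigma^2_{A_D} A + \sigma_{A_{DS}}(AZ + ZA) +
#'   \sigma^2_{A_S} Z A Z + \sigma^2_{E_D} I + 2\sigma_{E_{DS}} Z +
#'   \sigma^2_{E_S} Z Z + \sigma^2_C W W^T + \sigma^2_M W' W'^T.}
#'
#' @param params named numeric vector; recognized names are `sigma2AD`,
#'   `sigmaADS`, `sigma2AS`, `sigma2ED`, `sigmaEDS`, `sigma2ES`, `sigma2C`,
#'   `sigma2M` (aliases `sigma2A` for `sigma2AD` and `sigma2E` for
#'   `sigma2ED` are accepted; missing entries are treated as 0).
#' @param A kinship matrix (object or plain symmetric matrix).
#' @param design \linkS4class{StudyDesign} providing `Z`, `W`, `W'`.
#' @return The n x n symmetric covariance matrix `V`.
#' @export
marginalCovariance <- function(params, A, design) {
  stopifnot(is(design, "StudyDesign"))
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  Z <- cageMates(design)
  if (max(abs(Z - t(Z))) > 0) stop("Z must be symmetric")
  if (any(diag(Z) != 0)) stop("Z must have a zero diagonal")
  W <- cageIncidence(design)
  Wm <- maternalIncidence(design)
  g <- function(nm, alias = NULL) {
    v <- params[nm]
    if (is.na(v) && !is.null(alias)) v <- params[alias]
    if (is.na(v)) 0 else unname(v)
  }
  n <- nrow(Amat)
  AZ <- Amat %*% Z
  V <- g("sigma2AD", "sigma2A") * Amat +
    g("sigmaADS") * (AZ + t(AZ)) +
    g("sigma2AS") * (Z %*% AZ) +
    g("sigma2ED", "sigma2E") * diag(n) +
    2 * g("sigmaEDS") * Z +
    g("sigma2ES") * (Z %*% Z) +
    g("sigma2C") * (W %*% t(W)) +
    g("sigma2M") * (Wm %*% t(Wm))
  symmetrize(V)
}

#' REML fit of the direct + indirect (social) genetic effects model
#'
#' Fits the mixed model in which an individual's phenotype receives a direct
#' genetic effect of its own genotype and indirect genetic effects of its
#' cage mates' genotypes, together with direct/indirect environmental
#' effects, cage effects and maternal effects (see [marginalCovariance()]
#' for the implied covariance). Genetic and environmental direct--indirect
#' covariances are parametrized as correlation times the geometric mean of
#' the variances, which keeps the joint covariance positive semi-definite.
#'
#' `model = "null"` drops the indirect *genetic* terms (`sigma2AS` and
#' `sigmaADS` fixed at 0) while retaining indirect environmental effects;
#' it is the reference model for the social-effects likelihood-ratio test.
#'
#' When every cage has the same size, `Z Z` and `W W^T` are linear
#' combinations of `I` and `Z`, so the environmental and cage parameters
#' are individually confounded (their sum remains identified, as do the
#' genetic parameters); a warning is issued rather than reparametrizing.
#'
#' @param y phenotype vector.
#' @param A kinship (object or matrix).
#' @param design \linkS4class{StudyDesign}.
#' @param model `"full"` or `"null"`.
#' @param cage,maternal,envIndirect include the corresponding terms.
#' @param covariates optional extra fixed-effect columns.
#' @param nRestarts deterministic optimizer restarts.
#' @param warmStart optional \linkS4class{SGEFit} (or phi vector) whose
#'   optimum seeds the first start; used for bootstrap refits.
#' @param computeSE compute a delta-method standard error for the
#'   direct--indirect genetic correlation (extra gradient evaluations).
#' @param maxit,pgtol optimizer iteration cap and projected-gradient
#'   tolerance (see [optim()]'s L-BFGS-B).
#' @return An \linkS4class{SGEFit}.
#' @export
fitSGE <- function(y, A, design, model = c("full", "null"), cage = TRUE,
                   maternal = TRUE, envIndirect = TRUE, covariates = NULL,
                   nRestarts = 3L, warmStart = NULL, computeSE = FALSE,
                   maxit = 400L, pgtol = 1e-6) {
  model <- match.arg(model)
  stopifnot(is(design, "StudyDesign"))
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  n <- length(y)
  Z <- cageMates(design)
  W <- cageIncidence(design)
  Wm <- maternalIncidence(design)
  stopifnot(nrow(Amat) == n, nrow(Z) == n)
  if (any(rowSums(Z) == 0))
    warning(sum(rowSums(Z) == 0), " individual(s) have no cage mates ",
            "(zero Z row); they inform direct terms only")
  csz <- colSums(W)
  if (envIndirect && cage && length(unique(csz)) == 1L)
    warning("constant cage size: indirect environmental and cage ",
            "parameters are mutually confounded (sums remain identified)")

  X <- fixedDesign(design, n, covariates)
  full <- model == "full"

  AZ <- Amat %*% Z
  kernels <- list(sigma2AD = symmetrize(Amat))
  if (full) {
    kernels$sigmaADS <- AZ + t(AZ)
    kernels$sigma2AS <- symmetrize(Z %*% AZ)
  }
  kernels$sigma2ED <- diag(n)
  if (envIndirect) {
    kernels$sigmaEDS <- 2 * Z
    kernels$sigma2ES <- Z %*% Z
  }
  if (cage) kernels$sigma2C <- W %*% t(W)
  if (maternal) kernels$sigma2M <- Wm %*% t(Wm)

  ## phi layout: log variances for every variance kernel, atanh-scale
  ## correlations for the two covariance kernels
  varNames <- setdiff(names(kernels), c("sigmaADS", "sigmaEDS"))
  nv <- length(varNames)
  idxVar <- setNames(seq_len(nv), varNames)
  k <- nv
  idxZ <- c()
  if (full) { k <- k + 1L; idxZ["zA"] <- k }
  if (envIndirect) { k <- k + 1L; idxZ["zE"] <- k }

  thetaMap <- function(phi) {
    v <- setNames(exp(phi[idxVar]), varNames)
    th <- setNames(numeric(length(kernels)), names(kernels))
    th[varNames] <- v
    if (full)
      th["sigmaADS"] <- tanh(phi[idxZ["zA"]]) *
        sqrt(v["sigma2AD"] * v["sigma2AS"])
    if (envIndirect)
      th["sigmaEDS"] <- tanh(phi[idxZ["zE"]]) *
        sqrt(v["sigma2ED"] * v["sigma2ES"])
    unname(th)
  }
  jacobian <- function(phi) {
    th <- setNames(thetaMap(phi), names(kernels))
    J <- matrix(0, length(kernels), k,
                dimnames = list(names(kernels), NULL))
    for (nm in varNames) J[nm, idxVar[nm]] <- th[nm]
    if (full) {
      J["sigmaADS", idxVar["sigma2AD"]] <- th["sigmaADS"] / 2
      J["sigmaADS", idxVar["sigma2AS"]] <- th["sigmaADS"] / 2
      J["sigmaADS", idxZ["zA"]] <- (1 - tanh(phi[idxZ["zA"]])^2) *
        sqrt(th["sigma2AD"] * th["sigma2AS"])
    }
    if (envIndirect) {
      J["sigmaEDS", idxVar["sigma2ED"]] <- th["sigmaEDS"] / 2
      J["sigmaEDS", idxVar["sigma2ES"]] <- th["sigmaEDS"] / 2
      J["sigmaEDS", idxZ["zE"]] <- (1 - tanh(phi[idxZ["zE"]])^2) *
        sqrt(th["sigma2ED"] * th["sigma2ES"])
    }
    unname(J)
  }

  s2y <- var(y)
  phi0 <- c(rep(log(s2y / nv), nv), rep(0, length(idxZ)))
  lower <- c(rep(log(s2y * 1e-8), nv), rep(-atanh(0.99999), length(idxZ)))
  upper <- c(rep(log(s2y * 1e2), nv), rep(atanh(0.99999), length(idxZ)))
  starts <- restartGrid(phi0, nRestarts, lower, upper)
  if (!is.null(warmStart)) {
    w <- if (is(warmStart, "SGEFit")) warmStart@details$phi else warmStart
    if (length(w) == k)
      starts <- rbind(pmin(pmax(w, lower), upper), starts)
  }

  eng <- remlEngine(y, X, kernels, thetaMap, jacobian, starts,
                    lower, upper,
                    natural = function(phi)
                      setNames(thetaMap(phi), names(kernels)),
                    pgtol = pgtol, maxit = maxit)

  params <- eng$params
  allNames <- c("sigma2AD", "sigmaADS", "sigma2AS", "sigma2ED", "sigmaEDS",
                "sigma2ES", "sigma2C", "sigma2M")
  out <- setNames(numeric(length(allNames)), allNames)
  out[names(params)] <- params
  vr <- zeroAtBound(out[c("sigma2AD", "sigma2AS", "sigma2ED", "sigma2ES",
                          "sigma2C", "sigma2M")], s2y)
  out[names(vr)] <- vr
  if (out["sigma2AS"] == 0) out["sigmaADS"] <- 0
  if (out["sigma2ES"] == 0) out["sigmaEDS"] <- 0

  rA <- if (full && out["sigma2AD"] > 0 && out["sigma2AS"] > 0)
    unname(out["sigmaADS"] / sqrt(out["sigma2AD"] * out["sigma2AS"]))
  else NA_real_
  rAse <- NA_real_
  if (computeSE && full && !is.na(rA)) {
    Vphi <- phiCovariance(eng)
    j <- unname(idxZ["zA"])
    if (!is.null(Vphi) && Vphi[j, j] > 0)
      rAse <- (1 - rA^2) * sqrt(Vphi[j, j])
  }
  nBar <- mean(csz)
  s2H <- totalGeneticVariance(out[c("sigma2AD", "sigmaADS", "sigma2AS")],
                              nBar)
  new("SGEFit", beta = eng$beta, params = out, loglik = eng$loglik,
      convergence = eng$convergence, n = as.integer(n),
      details = list(X = eng$X, phi = eng$phi, kernels = names(kernels)),
      rA = rA, rAse = rAse, sigma2H = s2H, nBar = nBar, model = model)
}

#' Chi-square mixture p-value for the social-effects LRT
#'
#' Testing the two indirect-genetic parameters (`sigma2AS` on the boundary,
#' `sigmaADS` constrained by it) gives a likelihood-ratio statistic whose
#' null distribution is a mixture of chi-squares with 1 and 2 df. The
#' p-value is `(1 - m) S1(lambda) + m S2(lambda)` with `S_k` the chi-square
#' upper tail: `m = 0` recovers the 1-df test, `m = 1` the 2-df test.
#'
#' @param lambda LRT statistic(s); negative values are clamped to 0.
#' @param m mixture weight in \[0, 1\].
#' @return p-value(s) in (0, 1].
#' @examples
#' mixtureLRTPvalue(qchisq(0.95, 1), m = 0)  # 0.05
#' @export
mixtureLRTPvalue <- function(lambda, m) {
  if (length(m) != 1 || is.na(m) || m < 0 || m > 1)
    stop("m must be a single value in [0, 1]")
  lambda <- pmax(lambda, 0)
  (1 - m) * pchisq(lambda, 1, lower.tail = FALSE) +
    m * pchisq(lambda, 2, lower.tail = FALSE)
}

#' Social-effects likelihood-ratio test from a pair of fits
#'
#' @param full,null \linkS4class{SGEFit} objects from `fitSGE()` with
#'   `model = "full"` and `model = "null"` on the same data.
#' @param m mixture weight (see [mixtureLRTPvalue()]; typically chosen by
#'   [calibrateMixture()]).
#' @return A \linkS4class{MixtureLRT}.
#' @export
sgeLRT <- function(full, null, m) {
  stopifnot(is(full, "SGEFit"), is(null, "SGEFit"),
            full@model == "full", null@model == "null",
            full@n == null@n)
  lam <- max(0, 2 * (full@loglik - null@loglik))
  new("MixtureLRT", statistic = lam, m = m, p = mixtureLRTPvalue(lam, m))
}

#' Pick the mixture weight that makes null p-values uniform
#'
#' Given LRT statistics computed on null data (no indirect genetic
#' effects), evaluates the mixture p-values over a grid of weights and
#' returns the weight minimizing the Kolmogorov--Smirnov distance to
#' Uniform(0, 1).
#'
#' @param lambda vector of null LRT statistics.
#' @param mGrid candidate mixture weights.
#' @return List with `m` (chosen weight), `ksDistance` (named per-grid-point
#'   distances) and `ksPvalue` (KS test p-value at the chosen weight).
#' @export
selectMixtureParameter <- function(lambda, mGrid = seq(0, 1, by = 0.1)) {
  stopifnot(length(lambda) >= 2, all(lambda >= -1e-8))
  ks <- vapply(mGrid, function(m) {
    p <- mixtureLRTPvalue(lambda, m)
    as.numeric(suppressWarnings(ks.test(p, "punif")$statistic))
  }, numeric(1))
  names(ks) <- format(mGrid)
  m <- mGrid[which.min(ks)]
  pSel <- mixtureLRTPvalue(lambda, m)
  list(m = m, ksDistance = ks,
       ksPvalue = suppressWarnings(ks.test(pSel, "punif")$p.value))
}

#' Calibrate the mixture weight by parametric bootstrap
#'
#' For each null phenotype (typically drawn by [parametricBootstrapNull()]
#' from a fitted no-indirect-genetic-effects model), fits the full and null
#' social-effects models, computes the LRT statistic, and selects the
#' mixture weight whose p-values are closest to uniform (minimum KS
#' distance over `mGrid`).
#'
#' @param nullPhenotypes n x B matrix of null phenotype draws.
#' @param A kinship (object or matrix).
#' @param design \linkS4class{StudyDesign}.
#' @param mGrid candidate mixture weights.
#' @param cage,maternal,envIndirect passed to [fitSGE()].
#' @param warmStart optional \linkS4class{SGEFit} seeding the bootstrap
#'   refits (each refit also warm-starts from the previous one).
#' @param nRestarts optimizer restarts per bootstrap fit (warm starts make
#'   1 sufficient in practice).
#' @param minBoot fewer null phenotypes than this triggers a warning.
#' @param maxit per-fit optimizer iteration cap; ridge directions in the
#'   environmental/cage block can absorb hundreds of near-no-op iterations,
#'   so bootstrap refits may cap this lower without affecting the LRT.
#' @return List with the chosen `m`, the per-draw statistics `lambda`,
#'   per-grid KS distances and the KS p-value at the chosen weight.
#' @export
calibrateMixture <- function(nullPhenotypes, A, design,
                             mGrid = seq(0, 1, by = 0.1), cage = TRUE,
                             maternal = TRUE, envIndirect = TRUE,
                             warmStart = NULL, nRestarts = 1L,
                             minBoot = 100L, maxit = 400L) {
  nullPhenotypes <- as.matrix(nullPhenotypes)
  B <- ncol(nullPhenotypes)
  if (B < minBoot)
    warning("only ", B, " null phenotypes; calibration may be noisy")
  lam <- numeric(B)
  wsFull <- if (is(warmStart, "SGEFit") && warmStart@model == "full")
    warmStart else NULL
  wsNull <- NULL
  for (b in seq_len(B)) {
    yb <- nullPhenotypes[, b]
    fb <- fitSGE(yb, A, design, model = "full", cage = cage,
                 maternal = maternal, envIndirect = envIndirect,
                 nRestarts = nRestarts, warmStart = wsFull, maxit = maxit)
    nb <- fitSGE(yb, A, design, model = "null", cage = cage,
                 maternal = maternal, envIndirect = envIndirect,
                 nRestarts = nRestarts, warmStart = wsNull, maxit = maxit)
    lam[b] <- max(0, 2 * (fb@loglik - nb@loglik))
    wsFull <- fb
    wsNull <- nb
  }
  sel <- selectMixtureParameter(lam, mGrid)
  c(sel, list(lambda = lam))
}

#' Total heritable variance from direct, indirect and covariance terms
#'
#' Combines the direct genetic variance, the direct--indirect genetic
#' covariance and the indirect genetic variance into the total genetic
#' variance of a cage of average size `nBar`:
#' \deqn{\sigma^2_H = \sigma^2_{A_D} + 2(n - 1)\sigma_{A_{DS}} +
#'   (n - 1)^2 \sigma^2_{A_S}.}
#' This captures genetic variance both in acquiring a phenotype and in
#' transmitting effects to cage mates. Exact arithmetic, no tolerance.
#'
#' @param x an \linkS4class{SGEFit}, or a named numeric vector with
#'   `sigma2AD`, `sigmaADS`, `sigma2AS`.
#' @param nBar average cage size (>= 1); defaults to the fit's.
#' @param ... unused.
#' @return `sigma2H` (scalar).
#' @export
setMethod("totalGeneticVariance", "SGEFit", function(x, nBar, ...) {
  if (missing(nBar)) nBar <- x@nBar
  totalGeneticVariance(x@params[c("sigma2AD", "sigmaADS", "sigma2AS")], nBar)
})

#' @rdname totalGeneticVariance-SGEFit-method
#' @export
setMethod("totalGeneticVariance", "numeric", function(x, nBar, ...) {
  if (is.na(nBar) || nBar < 1) stop("nBar must be >= 1")
  g <- function(nm) if (nm %in% names(x)) unname(x[nm]) else 0
  g("sigma2AD") + 2 * (nBar - 1) * g("sigmaADS") +
    (nBar - 1)^2 * g("sigma2AS")
})

#' Permute cage-mate assignments, keeping cage membership fixed
#'
#' Reassigns individuals to pseudo-cages with the same size multiset and
#' rebuilds the cage-mate indicator `Z` from them, while leaving the cage
#' incidence `W` (and hence the cage random effect), the maternal incidence
#' and the cage-size covariate untouched. Under such permutations indirect
#' genetic effects cannot be captured, so permuted estimates of the
#' indirect variance and of the total genetic variance provide an empirical
#' null.
#'
#' @param design \linkS4class{StudyDesign}.
#' @param seed permutation seed.
#' @return A \linkS4class{StudyDesign} with permuted `Z`.
#' @export
permuteCageMates <- function(design, seed = 1L) {
  stopifnot(is(design, "StudyDesign"))
  W <- cageIncidence(design)
  n <- nrow(W)
  sizes <- as.integer(colSums(W))
  withSeed(streamSeed(seed, "cagemate-permutation"), {
    ord <- sample.int(n)
  })
  pseudo <- integer(n)
  pseudo[ord] <- rep(seq_along(sizes), times = sizes)
  Zp <- outer(pseudo, pseudo, `==`) * 1
  diag(Zp) <- 0
  dimnames(Zp) <- list(rownames(W), rownames(W))
  new("StudyDesign", W = W, Wm = maternalIncidence(design), Z = Zp,
      cageSizeCov = cageSizeCovariate(design), samples = sampleData(design))
}

#' Bias in direct-genetic-variance estimates when indirect effects are
#' ignored
#'
#' Simulates phenotypes with direct and indirect genetic effects (and their
#' correlation) on a design where relatives are present in the sample but
#' not co-housed, then analyses each phenotype twice: with the model
#' including indirect genetic effects and with the model omitting them.
#' When indirect effects are present and positively correlated with direct
#' effects, the omitting model systematically underestimates the direct
#' genetic variance.
#'
#' @param truth \linkS4class{SimTruth} (simulation parameters).
#' @param nPhenotypes number of phenotypes to simulate.
#' @param A kinship (object or matrix) for the simulated individuals.
#' @param design \linkS4class{StudyDesign}.
#' @param nRestarts optimizer restarts per fit.
#' @param seed phenotype stream seed.
#' @return List with `table` (one row per phenotype: full-model `sigma2AD`,
#'   `sigma2AS`, `rA` and no-indirect-model `sigma2AD`) and `means`.
#' @export
dgeBiasExperiment <- function(truth, nPhenotypes, A, design, nRestarts = 2L,
                              seed = NULL) {
  stopifnot(is(truth, "SimTruth"))
  sims <- simulatePhenotype(truth, A, design, nReplicates = nPhenotypes,
                            seed = seed)
  maternal <- truth@varMaternal > 0
  envInd <- truth@varEnvIndirect > 0
  tab <- data.frame(phenotype = seq_len(nPhenotypes), fullDge = NA_real_,
                    fullIge = NA_real_, fullRa = NA_real_,
                    noIgeDge = NA_real_)
  wsFull <- NULL
  Y <- if (nPhenotypes == 1L) matrix(sims$y, ncol = 1) else sims$y
  for (i in seq_len(nPhenotypes)) {
    fb <- fitSGE(Y[, i], A, design, model = "full", cage = TRUE,
                 maternal = maternal, envIndirect = envInd,
                 nRestarts = nRestarts, warmStart = wsFull)
    wsFull <- fb
    vc <- fitVarComp(Y[, i], A, design, cage = TRUE, maternal = maternal,
                     nRestarts = nRestarts)
    tab$fullDge[i] <- fb@params["sigma2AD"]
    tab$fullIge[i] <- fb@params["sigma2AS"]
    tab$fullRa[i] <- fb@rA
    tab$noIgeDge[i] <- vc@params["sigma2A"]
  }
  list(table = tab,
       means = c(fullDge = mean(tab$fullDge), fullIge = mean(tab$fullIge),
                 fullRa = mean(tab$fullRa, na.rm = TRUE),
                 noIgeDge = mean(tab$noIgeDge)))
}
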