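#' Mixed-model association scan with leave-one-chromosome-out GRMs
#'
#' For each chromosome, the null variance-component model (genetic + cage +
#' maternal + noise, with the GRM excluding that chromosome) is fitted once
#' by REML; holding the fitted covariance fixed, every variant on the
#' chromosome is then tested by generalized least squares, comparing the
#' fixed-effect models with and without the variant through a 1-df
#' likelihood-ratio statistic `n log(RSS0 / RSS1)` computed on the whitened
#' data. Missing dosages are mean-imputed; variants constant in the
#' analysis sample get a missing p-value.
#'
#' With `grms = NULL` the scan reduces exactly to ordinary-least-squares
#' single-variant regression (identity covariance).
#'
#' @param y phenotype vector.
#' @param G \linkS4class{GenotypeMatrix}.
#' @param grms named list of leave-one-chromosome-out
#'   \linkS4class{KinshipMatrix} objects (names = chromosomes, as from
#'   [locoGRMs()]), or `NULL` for an identity covariance.
#' @param design optional \linkS4class{StudyDesign}; adds cage and maternal
#'   random effects to the null model and the cage-size fixed covariate.
#' @param covariates optional extra fixed-effect columns.
#' @param nRestarts optimizer restarts for each per-chromosome null fit.
#' @return A \linkS4class{GwasScan}.
#' @export
lmmScan <- function(y, G, grms = NULL, design = NULL, covariates = NULL,
                    nRestarts = 2L) {
  stopifnot(is(G, "GenotypeMatrix"))
  n <- length(y)
  map <- variantMap(G)
  d <- meanImpute(dosages(G))
  stopifnot(nrow(d) == n)
  X <- if (is.null(design)) {
    Xb <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
    if (!is.null(covariates)) cbind(Xb, as.matrix(covariates)) else Xb
  } else fixedDesign(design, n, covariates)

  chrs <- sort(unique(map$chrom))
  if (!is.null(grms))
    stopifnot(all(as.character(chrs) %in% names(grms)))
  res <- data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                    beta = NA_real_, negLog10P = NA_real_)
  nullComp <- list()
  for (ch in chrs) {
    idx <- which(map$chrom == ch)
    if (is.null(grms)) {
      V <- NULL
      nullComp[[as.character(ch)]] <- c(sigma2E = var(y))
    } else {
      K <- grms[[as.character(ch)]]
      fit <- nullModelFit(y, X, if (is(K, "KinshipMatrix")) grm(K) else K,
                          design, nRestarts)
      V <- fit$V
      nullComp[[as.character(ch)]] <- fit$params
    }
    sc <- glsVariantTests(y, X, d[, idx, drop = FALSE], V)
    res$beta[idx] <- sc$beta
    res$negLog10P[idx] <- sc$negLog10P
  }
  new("GwasScan", results = res, nullComponents = nullComp,
      threshold = NA_real_, adjustedThreshold = NA_real_, nEff = NA_real_)
}

## REML fit of the per-chromosome null model; returns the covariance at the
## optimum and the component estimates.
nullModelFit <- function(y, X, Amat, design, nRestarts) {
  n <- length(y)
  kernels <- list(sigma2E = diag(n), sigma2A = symmetrize(Amat))
  if (!is.null(design)) {
    W <- cageIncidence(design)
    Wm <- maternalIncidence(design)
    kernels$sigma2C <- W %*% t(W)
    kernels$sigma2M <- Wm %*% t(Wm)
  }
  nk <- length(kernels)
  s2y <- var(y)
  phi0 <- rep(log(s2y / nk), nk)
  lower <- rep(log(s2y * 1e-8), nk)
  upper <- rep(log(s2y * 1e2), nk)
  fit <- remlEngine(y, X, kernels, thetaMap = exp,
                    jacobian = function(phi) diag(exp(phi)),
                    starts = restartGrid(phi0, nRestarts, lower, upper),
                    lower = lower, upper = upper,
                    natural = function(phi) setNames(exp(phi),
                                                     names(kernels)))
  V <- Reduce(`+`, Map(`*`, as.list(fit$params), kernels))
  list(V = V, params = fit$params)
}

## Whitened single-variant GLS tests with the covariance held fixed.
## V = NULL means identity. Returns per-variant beta and -log10 p from the
## 1-df LRT n log(RSS0/RSS1).
glsVariantTests <- function(y, X, Gchr, V = NULL) {
  n <- length(y)
  if (!is.null(V)) {
    Lt <- t(chol(V))
    ys <- forwardsolve(Lt, y)
    Xs <- forwardsolve(Lt, X)
    Gs <- forwardsolve(Lt, Gchr)
  } else {
    ys <- y; Xs <- X; Gs <- Gchr
  }
  Q <- qr(Xs)
  ey <- qr.resid(Q, ys)
  RSS0 <- sum(ey^2)
  Eg <- qr.resid(Q, Gs)
  s2g <- colSums(Eg^2)
  ok <- s2g > 1e-10 * n
  num <- colSums(Eg * ey)
  beta <- ifelse(ok, num / s2g, NA_real_)
  RSS1 <- pmax(RSS0 - ifelse(ok, num^2 / s2g, 0), 1e-300)
  lrt <- ifelse(ok, n * log(RSS0 / RSS1), NA_real_)
  logp <- pchisq(lrt, df = 1, lower.tail = FALSE, log.p = TRUE)
  list(beta = beta, negLog10P = ifelse(ok, -logp / log(10), NA_real_))
}

#' Permutation-derived genome-wide significance threshold
#'
#' Permutes the genotype rows (equivalently, the phenotype indices, which
#' preserves LD across all chromosomes within a permutation) `nPerm` times;
#' for each permutation the per-chromosome null model is re-estimated, a
#' full scan is run, and the smallest p-value recorded. The threshold is
#' the `1 - alpha` quantile of the `-log10` minima (equivalently the
#' `alpha` quantile of the minima on the p scale).
#'
#' When no design (cage/maternal) terms are present, the per-permutation
#' null refits use the spectral decomposition of each leave-one-chromosome-
#' out GRM, making the 1000-permutation default practical; with design
#' terms every permutation refits the full variance-component model per
#' chromosome, which is substantially slower.
#'
#' @param y phenotype vector.
#' @param G \linkS4class{GenotypeMatrix}.
#' @param grms leave-one-chromosome-out GRMs (as in [lmmScan()]); `NULL`
#'   for identity covariance.
#' @param design optional \linkS4class{StudyDesign}.
#' @param covariates optional extra fixed-effect columns.
#' @param nPerm number of permutations (>= 100).
#' @param alpha genome-wide significance level.
#' @param seed permutation seed.
#' @return The `-log10(p)` threshold, with the per-permutation `-log10`
#'   minima attached as attribute `"minima"`.
#' @export
permutationThreshold <- function(y, G, grms = NULL, design = NULL,
                                 covariates = NULL, nPerm = 1000L,
                                 alpha = 0.05, seed = 1L) {
  stopifnot(nPerm >= 100L)
  n <- length(y)
  map <- variantMap(G)
  d <- meanImpute(dosages(G))
  X <- if (is.null(design)) {
    Xb <- matrix(1, n, 1)
    if (!is.null(covariates)) cbind(Xb, as.matrix(covariates)) else Xb
  } else fixedDesign(design, n, covariates)
  perms <- withSeed(streamSeed(seed, "gwas-permutation"), {
    lapply(seq_len(nPerm), function(i) sample.int(n))
  })
  chrs <- sort(unique(map$chrom))

  if (is.null(design) && !is.null(grms)) {
    ## spectral path: per chromosome, diagonalize the LOCO GRM once
    pre <- lapply(chrs, function(ch) {
      K <- grms[[as.character(ch)]]
      A <- if (is(K, "KinshipMatrix")) grm(K) else K
      e <- eigen(symmetrize(A), symmetric = TRUE)
      idx <- which(map$chrom == ch)
      list(U = e$vectors, dvals = pmax(e$values, 0),
           tX = crossprod(e$vectors, X),
           tG = crossprod(e$vectors, d[, idx, drop = FALSE]))
    })
    minLogp <- vapply(perms, function(pm) {
      yp <- y[pm]
      best <- 0
      for (pc in pre) {
        ty <- drop(crossprod(pc$U, yp))
        h <- optimize(function(hh) diagRemlNegLL(hh, ty, pc$tX, pc$dvals),
                      c(0, 0.9999))$minimum
        w <- sqrt(h * pc$dvals + (1 - h))
        sc <- glsVariantTests(ty / w, pc$tX / w, pc$tG / w, V = NULL)
        best <- max(best, sc$negLog10P, na.rm = TRUE)
      }
      best
    }, numeric(1))
  } else {
    minLogp <- vapply(perms, function(pm) {
      sc <- lmmScan(y[pm], G, grms = grms, design = design,
                    covariates = covariates, nRestarts = 1L)
      max(sc@results$negLog10P, na.rm = TRUE)
    }, numeric(1))
  }
  thr <- unname(quantile(minLogp, probs = 1 - alpha, type = 7))
  attr(thr, "minima") <- minLogp
  thr
}

## Negative restricted log-likelihood (up to constants) of the diagonal
## model V = s2 * (h D + (1 - h) I), with s2 profiled out.
diagRemlNegLL <- function(h, ty, tX, dvals) {
  n <- length(ty)
  p <- ncol(tX)
  w <- h * dvals + (1 - h)
  XtWX <- crossprod(tX, tX / w)
  XtWy <- crossprod(tX, ty / w)
  cX <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(cX)) return(1e10)
  beta <- backsolve(cX, forwardsolve(t(cX), XtWy))
  r <- ty - drop(tX %*% beta)
  q <- sum(r^2 / w)
  0.5 * ((n - p) * log(q) + sum(log(w)) + 2 * sum(log(diag(cX))))
}

#' Phenome-wide adjustment of the genome-wide threshold
#'
#' Bonferroni-adjusts a genome-wide `-log10` significance threshold for the
#' effective number of phenotypes tested, estimated as the number of
#' principal components needed to explain 99% of the total variance of the
#' phenotype matrix.
#'
#' @param genomewideLogp genome-wide `-log10(p)` threshold.
#' @param Y samples x phenotypes matrix; rows with missing values are
#'   dropped.
#' @param varExplained fraction of variance the leading eigenvalues must
#'   reach.
#' @return List with `adjusted` (`genomewideLogp + log10(nEff)`) and `nEff`.
#' @export
adjustedThreshold <- function(genomewideLogp, Y, varExplained = 0.99) {
  Y <- as.matrix(Y)
  if (ncol(Y) == 1L)
    return(list(adjusted = genomewideLogp, nEff = 1L))
  cc <- complete.cases(Y)
  if (!all(cc)) {
    warning(sum(!cc), " sample(s) with missing phenotypes dropped")
    Y <- Y[cc, , drop = FALSE]
  }
  lam <- eigen(cov(Y), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  nEff <- which(cumsum(lam) >= varExplained * sum(lam))[1]
  list(adjusted = genomewideLogp + log10(nEff), nEff = as.integer(nEff))
}
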