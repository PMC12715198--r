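#' Bivariate REML: genetic correlation between two traits
#'
#' Estimates the genetic correlation `rG` between two traits measured on
#' disjoint individual sets (the cross-cohort case: the same taxon measured
#' in two cohorts) or on the same individuals, via a two-trait extension of
#' the genetic variance-component model. The genetic covariance is
#' transmitted through the cross-individual block of the joint relatedness
#' matrix and parametrized as `rG * sqrt(sigma2A1 * sigma2A2)`. When the
#' individual sets are disjoint, residual (and any cage or maternal)
#' covariances across traits are structurally zero; when the sets are
#' identical, a residual cross-trait correlation is estimated as well.
#'
#' Significance of `rG` is assessed with a 1-df likelihood-ratio test
#' against the fit constrained at `rG = 0`.
#'
#' @param y1,y2 trait vectors.
#' @param A joint \linkS4class{KinshipMatrix} (or matrix) covering all
#'   individuals: rows `sets1` then `sets2` unless indices are given.
#' @param sets1,sets2 row indices of `A` for the two traits; default stacks
#'   trait 1 first, trait 2 second (disjoint), or both over all rows when
#'   `length(y1) == nrow(A)` (identical sets).
#' @param nRestarts optimizer restarts per fit.
#' @return A \linkS4class{BivariateFit}; `details(x)$lrt` holds the
#'   \linkS4class{MixtureLRT} for `rG = 0`.
#' @export
fitGeneticCorrelation <- function(y1, y2, A, sets1 = NULL, sets2 = NULL,
                                  nRestarts = 3L) {
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  n1 <- length(y1); n2 <- length(y2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 individuals per trait")
  if (is.null(sets1) || is.null(sets2)) {
    if (n1 == nrow(Amat) && n2 == nrow(Amat)) {
      sets1 <- sets2 <- seq_len(nrow(Amat))
    } else {
      stopifnot(n1 + n2 == nrow(Amat))
      sets1 <- seq_len(n1); sets2 <- n1 + seq_len(n2)
    }
  }
  identicalSets <- identical(sets1, sets2)
  y <- c(y1, y2)
  n <- n1 + n2
  i1 <- seq_len(n1); i2 <- n1 + seq_len(n2)

  blk <- function(B11 = NULL, B22 = NULL, B12 = NULL) {
    K <- matrix(0, n, n)
    if (!is.null(B11)) K[i1, i1] <- B11
    if (!is.null(B22)) K[i2, i2] <- B22
    if (!is.null(B12)) { K[i1, i2] <- B12; K[i2, i1] <- t(B12) }
    K
  }
  kernels <- list(
    sigma2A1 = blk(B11 = Amat[sets1, sets1]),
    sigma2A2 = blk(B22 = Amat[sets2, sets2]),
    covA     = blk(B12 = Amat[sets1, sets2]),
    sigma2E1 = blk(B11 = diag(n1)),
    sigma2E2 = blk(B22 = diag(n2)))
  if (identicalSets) kernels$covE <- blk(B12 = diag(n1))
  X <- cbind(mu1 = c(rep(1, n1), rep(0, n2)),
             mu2 = c(rep(0, n1), rep(1, n2)))

  fitOne <- function(freeRg) {
    ## phi: log vA1, log vA2, [z rG], log vE1, log vE2, [z rE]
    idx <- list(vA1 = 1L, vA2 = 2L)
    k <- 2L
    if (freeRg) { k <- k + 1L; idx$zG <- k }
    idx$vE1 <- k + 1L; idx$vE2 <- k + 2L
    k <- k + 2L
    if (identicalSets) { k <- k + 1L; idx$zE <- k }
    thetaMap <- function(phi) {
      vA1 <- exp(phi[idx$vA1]); vA2 <- exp(phi[idx$vA2])
      vE1 <- exp(phi[idx$vE1]); vE2 <- exp(phi[idx$vE2])
      rG <- if (freeRg) tanh(phi[idx$zG]) else 0
      th <- c(vA1, vA2, rG * sqrt(vA1 * vA2), vE1, vE2)
      if (identicalSets) th <- c(th, tanh(phi[idx$zE]) * sqrt(vE1 * vE2))
      th
    }
    jacobian <- function(phi) {
      th <- thetaMap(phi)
      J <- matrix(0, length(kernels), k)
      J[1, idx$vA1] <- th[1]
      J[2, idx$vA2] <- th[2]
      J[3, idx$vA1] <- th[3] / 2
      J[3, idx$vA2] <- th[3] / 2
      if (freeRg)
        J[3, idx$zG] <- (1 - tanh(phi[idx$zG])^2) * sqrt(th[1] * th[2])
      J[4, idx$vE1] <- th[4]
      J[5, idx$vE2] <- th[5]
      if (identicalSets) {
        J[6, idx$vE1] <- th[6] / 2
        J[6, idx$vE2] <- th[6] / 2
        J[6, idx$zE] <- (1 - tanh(phi[idx$zE])^2) * sqrt(th[4] * th[5])
      }
      J
    }
    s2 <- var(y)
    phi0 <- rep(log(s2 / 2), k)
    lower <- rep(log(s2 * 1e-8), k)
    upper <- rep(log(s2 * 1e2), k)
    zb <- atanh(0.99999)
    for (znm in c("zG", "zE")) if (!is.null(idx[[znm]])) {
      phi0[idx[[znm]]] <- 0; lower[idx[[znm]]] <- -zb; upper[idx[[znm]]] <- zb
    }
    eng <- remlEngine(y, X, kernels, thetaMap, jacobian,
                      starts = restartGrid(phi0, nRestarts, lower, upper),
                      lower = lower, upper = upper,
                      natural = function(phi)
                        setNames(thetaMap(phi), names(kernels)))
    eng$idx <- idx
    eng
  }

  full <- fitOne(freeRg = TRUE)
  red <- fitOne(freeRg = FALSE)
  lam <- max(0, 2 * (full$loglik - red$loglik))
  lrt <- new("MixtureLRT", statistic = lam, m = 0,
             p = pchisq(lam, df = 1, lower.tail = FALSE))

  rG <- unname(full$params["covA"] /
                 sqrt(full$params["sigma2A1"] * full$params["sigma2A2"]))
  rGse <- NA_real_
  Vphi <- phiCovariance(full)
  if (!is.null(Vphi)) {
    j <- full$idx$zG
    if (Vphi[j, j] > 0)
      rGse <- (1 - rG^2) * sqrt(Vphi[j, j])
  }
  new("BivariateFit", beta = full$beta, params = full$params,
      loglik = full$loglik, convergence = full$convergence,
      n = as.integer(n),
      details = list(X = full$X, lrt = lrt, reducedLoglik = red$loglik),
      rG = rG, rGse = rGse)
}
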