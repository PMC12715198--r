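## Generic REML machinery for linear mixed models whose covariance is a
## linear combination of fixed symmetric kernels,
##   V(theta) = sum_k theta_k K_k,
## with theta a smooth map of an unconstrained parameter vector phi
## (log variances; correlations through tanh). All model-specific fitters
## (fitVarComp, fitSGE, fitGeneticCorrelation) are built on remlEngine().

#' Restricted log-likelihood of a Gaussian mixed model
#'
#' Evaluates the REML criterion for `y ~ N(X beta, V)` using the
#' error-contrast convention: the returned value equals the log-density of
#' `L' y` for any orthonormal basis `L` of the orthogonal complement of the
#' column space of `X`. Two model fits on the same `y` and `X` are therefore
#' directly comparable.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (full column rank).
#' @param V covariance matrix (positive definite).
#' @return The restricted log-likelihood (scalar).
#' @export
remlLogLik <- function(y, X, V) {
  n <- length(y)
  X <- as.matrix(X)
  p <- ncol(X)
  R <- chol(V)
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cX <- chol(XtViX)
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(ViX, y)))
  Py <- Vi %*% y - ViX %*% beta
  ldV <- 2 * sum(log(diag(R)))
  ldXtViX <- 2 * sum(log(diag(cX)))
  ldXtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + ldV + ldXtViX - as.numeric(ldXtX) +
            sum(y * Py))
}

## Value and gradient (wrt the kernel coefficients theta) of the restricted
## log-likelihood. Kernels must be symmetric. Returns -Inf on a failed
## Cholesky (optimizer treats it as a rejected step).
remlValueGrad <- function(theta, y, X, kernels, ldXtX) {
  n <- length(y)
  p <- ncol(X)
  V <- theta[1] * kernels[[1]]
  for (k in seq_along(kernels)[-1]) V <- V + theta[k] * kernels[[k]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(value = -Inf, grad = rep(0, length(theta))))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cX)) return(list(value = -Inf, grad = rep(0, length(theta))))
  beta <- backsolve(cX, forwardsolve(t(cX), crossprod(ViX, y)))
  Py <- drop(Vi %*% y - ViX %*% beta)
  value <- -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(R))) +
                     2 * sum(log(diag(cX))) - ldXtX + sum(y * Py))
  ## P = Vi - ViX (X'ViX)^-1 X'Vi ; d l / d theta_k = -(tr(P K_k) - Py'K_k Py)/2
  Pm <- Vi - ViX %*% chol2inv(cX) %*% t(ViX)
  grad <- vapply(kernels, function(K)
    -0.5 * (sum(Pm * K) - drop(crossprod(Py, K %*% Py))), numeric(1))
  list(value = value, grad = grad, beta = drop(beta))
}

## Multi-start bounded quasi-Newton REML fit.
##  y, X        response and fixed-effect design
##  kernels     named list of symmetric kernel matrices
##  thetaMap    function(phi) -> coefficients on the kernels (same order)
##  jacobian    function(phi) -> d theta / d phi matrix (#kernels x #phi)
##  starts      matrix of start values, one row per restart
##  lower/upper box bounds on phi
##  natural     function(phi) -> named parameter vector on the natural scale
remlEngine <- function(y, X, kernels, thetaMap, jacobian, starts,
                       lower, upper, natural, pgtol = 1e-6, maxit = 400L) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("fixed-effect design is rank deficient; dropping ",
            ncol(X) - qx$rank, " redundant column(s)")
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  ldXtX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)

  cache <- new.env(parent = emptyenv())
  evalPoint <- function(phi) {
    if (!is.null(cache$phi) && identical(cache$phi, phi)) return(cache$res)
    vg <- remlValueGrad(thetaMap(phi), y, X, kernels, ldXtX)
    res <- list(value = vg$value,
                grad = if (is.finite(vg$value))
                  drop(crossprod(jacobian(phi), vg$grad)) else vg$grad,
                beta = vg$beta)
    cache$phi <- phi
    cache$res <- res
    res
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[s, ], fn = function(phi) -evalPoint(phi)$value,
            gr = function(phi) -evalPoint(phi)$grad,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, pgtol = pgtol)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("REML optimization failed from every start")
  at <- evalPoint(best$par)
  list(phi = best$par, params = natural(best$par), beta = at$beta,
       loglik = at$value, convergence = as.integer(best$convergence),
       X = X, evalPoint = evalPoint)
}

## Fixed deterministic restart offsets (no RNG): the first row is the
## heuristic start itself, later rows perturb it.
restartGrid <- function(phi0, nStarts, lower, upper) {
  offs <- list(0, c(1, -1), c(-1.5, 0.5), c(0.5, -2), c(2, 1))
  starts <- matrix(phi0, nrow = nStarts, ncol = length(phi0), byrow = TRUE)
  for (s in seq_len(nStarts)[-1]) {
    o <- rep_len(offs[[1 + (s - 1) %% length(offs)]], length(phi0))
    starts[s, ] <- pmin(pmax(phi0 + o, lower + 1e-3), upper - 1e-3)
  }
  starts
}

## Numerical observed information at the optimum (finite differences of the
## analytic gradient); returns the phi-scale covariance matrix or NULL.
phiCovariance <- function(engineFit) {
  H <- tryCatch(
    optimHess(engineFit$phi,
              fn = function(phi) -engineFit$evalPoint(phi)$value,
              gr = function(phi) -engineFit$evalPoint(phi)$grad),
    error = function(e) NULL)
  if (is.null(H)) return(NULL)
  tryCatch(solve(H), error = function(e) NULL)
}
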