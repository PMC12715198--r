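#' REML fit of the genetic + cage + maternal variance-component model
#'
#' Fits, by restricted maximum likelihood, the linear mixed model
#' \deqn{y = Xb + a + e + Wc + W'm,}
#' with `a ~ N(0, sigma2A A)` (polygenic direct genetic effects on the
#' SNP-based relatedness `A`), iid cage effects `c`, iid maternal effects
#' `m` and iid noise `e`. The fixed effects are an intercept and the
#' cage-size covariate (dropped automatically when constant), plus any
#' user-supplied covariate columns. Variances are optimized on the log scale
#' with a bounded quasi-Newton search and deterministic restarts, keeping
#' the best optimum.
#'
#' @param y phenotype vector (typically a normalized, covariate-adjusted
#'   residual from [normalizePhenotype()]).
#' @param A \linkS4class{KinshipMatrix} or plain symmetric PSD matrix.
#' @param design \linkS4class{StudyDesign}.
#' @param genetic,cage,maternal include the corresponding random effect.
#' @param covariates optional numeric matrix of extra fixed-effect columns.
#' @param nRestarts number of deterministic optimizer restarts.
#' @return A \linkS4class{VarCompFit} with parameters `sigma2A`, `sigma2C`,
#'   `sigma2M`, `sigma2E` (those included), heritability
#'   `sigma2A / (sigma2A + sigma2C + sigma2M + sigma2E)` and the restricted
#'   log-likelihood.
#' @seealso [heritabilityLRT()], [fitSGE()] for the model with indirect
#'   genetic effects.
#' @export
fitVarComp <- function(y, A, design, genetic = TRUE, cage = TRUE,
                       maternal = TRUE, covariates = NULL, nRestarts = 3L) {
  stopifnot(is(design, "StudyDesign"))
  Amat <- if (is(A, "KinshipMatrix")) grm(A) else as.matrix(A)
  n <- length(y)
  stopifnot(nrow(Amat) == n, nrow(cageIncidence(design)) == n)
  if (genetic && ncol(cageIncidence(design)) < 2 && cage)
    stop("need at least 2 cages")
  X <- fixedDesign(design, n, covariates)

  kernels <- list(sigma2E = diag(n))
  if (genetic) kernels$sigma2A <- symmetrize(Amat)
  if (cage) {
    W <- cageIncidence(design)
    kernels$sigma2C <- W %*% t(W)
  }
  if (maternal) {
    Wm <- maternalIncidence(design)
    kernels$sigma2M <- Wm %*% t(Wm)
  }
  nm <- names(kernels)
  s2y <- var(y)
  nk <- length(kernels)
  phi0 <- rep(log(s2y / nk), nk)
  lower <- rep(log(s2y * 1e-8), nk)
  upper <- rep(log(s2y * 1e2), nk)
  fit <- remlEngine(y, X, kernels,
                    thetaMap = exp, jacobian = function(phi) diag(exp(phi)),
                    starts = restartGrid(phi0, nRestarts, lower, upper),
                    lower = lower, upper = upper,
                    natural = function(phi) setNames(exp(phi), nm))
  params <- zeroAtBound(fit$params, s2y)
  ord <- intersect(c("sigma2A", "sigma2C", "sigma2M", "sigma2E"), nm)
  params <- params[ord]
  h2 <- if (genetic) unname(params["sigma2A"] / sum(params)) else 0
  new("VarCompFit", beta = fit$beta, params = params, loglik = fit$loglik,
      convergence = fit$convergence, n = as.integer(n),
      details = list(X = fit$X, phi = fit$phi), h2 = h2)
}

## intercept + cage-size covariate (when it varies) + extra columns
fixedDesign <- function(design, n, covariates = NULL) {
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  cs <- cageSizeCovariate(design)
  if (sd(cs) > 0) X <- cbind(X, cageSize = cs)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  X
}

## variances optimized on the log scale never reach 0 exactly; snap
## estimates at the box bound to 0 for reporting
zeroAtBound <- function(params, s2y) {
  ifelse(params <= s2y * 1e-7, 0, params)
}

#' Likelihood-ratio test between nested REML fits
#'
#' Compares two REML fits of nested covariance structures on the same data
#' and fixed effects: the statistic is `2 * (logLik(full) - logLik(reduced))`
#' clamped at zero, referred to the upper tail of chi-square with 1 df
#' (the conventional, conservative choice for testing a single variance
#' component on the boundary).
#'
#' @param full,reduced \linkS4class{RemlFit} objects; the reduced model's
#'   parameters must be a strict subset of the full model's.
#' @return A \linkS4class{MixtureLRT} with `m = 0` (pure 1-df chi-square).
#' @export
heritabilityLRT <- function(full, reduced) {
  stopifnot(is(full, "RemlFit"), is(reduced, "RemlFit"))
  if (full@n != reduced@n)
    stop("fits are not on the same data")
  if (!all(names(reduced@params) %in% names(full@params)) ||
      length(reduced@params) >= length(full@params))
    stop("'reduced' must be nested in 'full'")
  lam <- max(0, 2 * (full@loglik - reduced@loglik))
  new("MixtureLRT", statistic = lam, m = 0,
      p = pchisq(lam, df = 1, lower.tail = FALSE))
}

#' Benjamini--Hochberg discoveries at a target FDR
#'
#' @param p vector of p-values in \[0, 1\].
#' @param q target false discovery rate.
#' @return Logical vector marking discoveries; the adjusted p-values are
#'   attached as attribute `"padj"`.
#' @examples
#' bhSignificant(c(0.001, 0.02, 0.03, 0.5), q = 0.1)
#' @export
bhSignificant <- function(p, q = 0.1) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  padj <- p.adjust(p, method = "BH")
  out <- padj <= q
  attr(out, "padj") <- padj
  out
}
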