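#' @import methods
#' @importFrom stats optim optimHess pchisq qchisq rnorm runif rbinom rmultinom
#'   ks.test p.adjust var sd cov qnorm lm.fit complete.cases setNames rlnorm
#'   cor quantile ecdf model.matrix
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Simulation truth
## ---------------------------------------------------------------------------

#' Parameters of a simulated host--microbiome study
#'
#' A `SimTruth` bundles every parameter needed to generate a synthetic study:
#' the pedigree layout (nuclear families of full sibs), the SNP panel, the
#' housing design, and the variance components of the direct + indirect
#' (social) genetic effects model from which phenotypes are drawn.
#'
#' Variance parameters are absolute variances on the phenotype scale; they
#' need not sum to one. The genetic covariance is parametrized as
#' `corDgeIge * sqrt(varDge * varIge)` (and analogously for the environmental
#' terms), which keeps the joint covariance of direct and indirect effects
#' positive semi-definite whenever the correlations lie in \[-1, 1\].
#'
#' Defaults mirror a group-housed rodent study with strong social genetic
#' effects: direct genetic variance 0.4, indirect genetic variance 0.2, their
#' correlation 0.9, cage variance 0.2, direct environmental variance 0.2.
#'
#' @slot nFamilies number of nuclear families (two parents each).
#' @slot offspringPerFamily number of full-sib offspring per family.
#' @slot nSnps number of biallelic SNPs, spread evenly over 20 autosomes.
#' @slot mafRange range of per-SNP allele frequencies in (0, 0.5]; a
#'   zero-width range pins all SNPs to that frequency.
#' @slot cageSize allowed cage sizes; cages are drawn from this set.
#' @slot cohousing if `TRUE` siblings are preferentially co-housed, if
#'   `FALSE` no two siblings ever share a cage.
#' @slot varDge,varIge direct / indirect (social) genetic variances.
#' @slot corDgeIge correlation between direct and indirect genetic effects.
#' @slot varEnvDirect,varEnvIndirect direct / indirect environmental variances.
#' @slot corEnv correlation between direct and indirect environmental effects.
#' @slot varCage shared cage (micro-environmental) variance.
#' @slot varMaternal maternal-effect variance.
#' @slot fixedCageSizeEffect fixed-effect slope on cage size.
#' @slot seed master seed; all generator streams derive from it.
#' @export
setClass("SimTruth",
  representation(
    nFamilies = "integer",
    offspringPerFamily = "integer",
    nSnps = "integer",
    mafRange = "numeric",
    cageSize = "integer",
    cohousing = "logical",
    varDge = "numeric",
    varIge = "numeric",
    corDgeIge = "numeric",
    varEnvDirect = "numeric",
    varEnvIndirect = "numeric",
    corEnv = "numeric",
    varCage = "numeric",
    varMaternal = "numeric",
    fixedCageSizeEffect = "numeric",
    seed = "integer"
  ),
  prototype(
    nFamilies = 150L,
    offspringPerFamily = 3L,
    nSnps = 5000L,
    mafRange = c(0.05, 0.5),
    cageSize = c(2L, 3L, 4L),
    cohousing = FALSE,
    varDge = 0.4,
    varIge = 0.2,
    corDgeIge = 0.9,
    varEnvDirect = 0.2,
    varEnvIndirect = 0,
    corEnv = 0,
    varCage = 0.2,
    varMaternal = 0,
    fixedCageSizeEffect = 0,
    seed = 1L
  )
)

setValidity("SimTruth", function(object) {
  msg <- character()
  vs <- c(object@varDge, object@varIge, object@varEnvDirect,
          object@varEnvIndirect, object@varCage, object@varMaternal)
  if (any(vs < 0)) msg <- c(msg, "variance parameters must be >= 0")
  if (abs(object@corDgeIge) > 1) msg <- c(msg, "|corDgeIge| must be <= 1")
  if (abs(object@corEnv) > 1) msg <- c(msg, "|corEnv| must be <= 1")
  if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
      any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
    msg <- c(msg, "mafRange must be an interval within (0, 0.5]")
  if (object@nFamilies < 2L) msg <- c(msg, "need at least 2 families")
  if (object@offspringPerFamily < 2L)
    msg <- c(msg, "need at least 2 offspring per family")
  if (any(object@cageSize < 2L)) msg <- c(msg, "cage sizes must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a SimTruth
#'
#' @param ... slot values overriding the defaults; see
#'   \linkS4class{SimTruth}.
#' @return A \linkS4class{SimTruth} object.
#' @examples
#' truth <- SimTruth(nFamilies = 20L, nSnps = 500L, seed = 7L)
#' @export
SimTruth <- function(...) {
  args <- list(...)
  for (nm in intersect(names(args),
                       c("nFamilies", "offspringPerFamily", "nSnps",
                         "cageSize", "seed")))
    args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list(Class = "SimTruth"), args))
}

## ---------------------------------------------------------------------------
## Genotypes
## ---------------------------------------------------------------------------

#' Dosage genotypes with a variant map and pedigree
#'
#' Individuals in rows, variants in columns; dosages count copies of the
#' alternate allele (0/1/2, `NA` for missing). The variant map assigns each
#' SNP to one of the 20 autosomes with a position and an identifier. When the
#' genotypes are simulated, the two-generation pedigree (individual, family,
#' mother, father) travels with the object.
#'
#' @slot dosages numeric matrix, individuals x variants, values in
#'   \{0, 1, 2, NA\}.
#' @slot map data.frame with columns `chrom` (1--20), `pos`, `id`.
#' @slot pedigree data.frame with columns `id`, `family`, `mother`, `father`
#'   (zero rows if unknown).
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", map = "data.frame",
                 pedigree = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  d <- object@dosages
  if (ncol(d) != nrow(object@map))
    msg <- c(msg, "map must have one row per variant")
  if (!all(c("chrom", "pos", "id") %in% names(object@map)))
    msg <- c(msg, "map needs columns chrom, pos, id")
  else if (!all(object@map$chrom %in% 1:20))
    msg <- c(msg, "chromosomes must lie in 1..20 (autosomes)")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (nrow(object@pedigree) &&
      !all(c("id", "family", "mother") %in% names(object@pedigree)))
    msg <- c(msg, "pedigree needs columns id, family, mother")
  if (length(msg)) msg else TRUE
})

#' @export
GenotypeMatrix <- function(dosages, map,
                           pedigree = data.frame()) {
  new("GenotypeMatrix", dosages = dosages, map = map, pedigree = pedigree)
}

## ---------------------------------------------------------------------------
## Study design
## ---------------------------------------------------------------------------

#' Housing and family design of a cohort
#'
#' Holds the incidence structures entering the mixed models: the cage
#' incidence matrix `W` (one column per cage, used for the cage random
#' effect), the maternal incidence `Wm` (one column per mother), the
#' symmetric zero-diagonal cage-mate indicator `Z` (used for indirect
#' effects), the per-individual cage-size covariate, and the sample metadata
#' table. `Z` usually equals `W W^T` minus its diagonal, but the two are kept
#' separate so that cage-mate assignments can be permuted while cage
#' membership (and hence the cage random effect) stays fixed.
#'
#' @slot W individuals x cages 0/1 incidence, one cage per individual.
#' @slot Wm individuals x mothers 0/1 incidence.
#' @slot Z individuals x individuals symmetric 0/1 cage-mate indicator with
#'   zero diagonal.
#' @slot cageSizeCov numeric vector, number of animals in each individual's
#'   cage.
#' @slot samples data.frame of per-sample metadata (id, cage, mother, ...).
#' @export
setClass("StudyDesign",
  representation(W = "matrix", Wm = "matrix", Z = "matrix",
                 cageSizeCov = "numeric", samples = "data.frame"))

setValidity("StudyDesign", function(object) {
  msg <- character()
  n <- nrow(object@W)
  if (!all(rowSums(object@W) == 1))
    msg <- c(msg, "each individual must belong to exactly one cage")
  if (nrow(object@Z) != n || ncol(object@Z) != n)
    msg <- c(msg, "Z must be n x n")
  else {
    if (any(diag(object@Z) != 0)) msg <- c(msg, "Z must have a zero diagonal")
    if (!isTRUE(all.equal(object@Z, t(object@Z), tolerance = 0)))
      msg <- c(msg, "Z must be symmetric")
  }
  if (nrow(object@Wm) != n)
    msg <- c(msg, "Wm must have one row per individual")
  if (length(object@cageSizeCov) != n)
    msg <- c(msg, "cageSizeCov must have one entry per individual")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Kinship
## ---------------------------------------------------------------------------

#' SNP-based genetic relatedness matrix
#'
#' Standardized (Yang-style) GRM: `A[i, j]` averages
#' `(g_i - 2p)(g_j - 2p) / (2p(1 - p))` over the included variants. When
#' built leave-one-chromosome-out, `locoChrom` records the excluded
#' chromosome.
#'
#' @slot A symmetric individuals x individuals relatedness matrix.
#' @slot locoChrom excluded chromosome (NA when all autosomes are used).
#' @slot nVariants number of variants averaged into `A`.
#' @export
setClass("KinshipMatrix",
  representation(A = "matrix", locoChrom = "integer", nVariants = "integer"))

setValidity("KinshipMatrix", function(object) {
  msg <- character()
  A <- object@A
  if (nrow(A) != ncol(A)) msg <- c(msg, "A must be square")
  else {
    if (max(abs(A - t(A))) > 1e-12) msg <- c(msg, "A must be symmetric")
    n <- nrow(A)
    if (n <= 400) {  # eigen check is cheap at small n; large GRMs are Gram
      ev <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
      if (ev < -1e-8 * sum(diag(A)) / n)
        msg <- c(msg, "A must be positive semi-definite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @export
KinshipMatrix <- function(A, locoChrom = NA_integer_,
                          nVariants = NA_integer_) {
  new("KinshipMatrix", A = A, locoChrom = as.integer(locoChrom),
      nVariants = as.integer(nVariants))
}

## ---------------------------------------------------------------------------
## Abundance table
## ---------------------------------------------------------------------------

#' Taxon count table with taxonomy
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment}: the `"counts"`
#' assay holds non-negative integer counts with taxa in rows and samples in
#' columns; `rowData()$taxonomy` holds Greengenes-style lineage strings
#' (`k__...;p__...;...`); `colData()` carries per-sample metadata. Sequencing
#' depth is the per-sample column sum.
#'
#' @export
#' @import SummarizedExperiment
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'counts' assay")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
  if (max(abs(cts - round(cts))) > 1e-8) msg <- c(msg, "counts must be integral")
  if (!"taxonomy" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'taxonomy' column")
  if (length(msg)) msg else TRUE
})

#' Build an AbundanceTable from a count matrix
#'
#' @param counts taxa x samples matrix of non-negative integers.
#' @param taxonomy character vector of lineage strings, one per taxon.
#' @param sampleData optional data.frame of per-sample metadata.
#' @return An \linkS4class{AbundanceTable}.
#' @export
AbundanceTable <- function(counts, taxonomy = rep(NA_character_, nrow(counts)),
                           sampleData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("taxon_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(counts))
        else S4Vectors::DataFrame(sampleData, row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy = taxonomy,
                                   row.names = rownames(counts)),
    colData = cd)
  new("AbundanceTable", se)
}

## ---------------------------------------------------------------------------
## Fit objects
## ---------------------------------------------------------------------------

#' Shared REML fit representation
#'
#' Base class for all REML fits: fixed-effect estimates, variance/covariance
#' parameters on their natural scale, the restricted log-likelihood at the
#' optimum and optimizer diagnostics.
#'
#' @slot beta fixed-effect estimates (intercept first).
#' @slot params named variance/covariance parameters (natural scale).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot convergence optimizer convergence code (0 = clean).
#' @slot n number of observations.
#' @slot details list of optimizer diagnostics (restarts, messages).
#' @export
setClass("RemlFit",
  representation(beta = "numeric", params = "numeric", loglik = "numeric",
                 convergence = "integer", n = "integer", details = "list"))

#' Univariate variance-component fit (genetic + cage + maternal + noise)
#'
#' @slot h2 SNP heritability: genetic variance over the sum of all variance
#'   components.
#' @export
setClass("VarCompFit", contains = "RemlFit",
         representation(h2 = "numeric"))

setValidity("VarCompFit", function(object) {
  if (any(object@params < -1e-8)) return("variances must be non-negative")
  if (object@h2 < -1e-8 || object@h2 > 1 + 1e-8) return("h2 must be in [0,1]")
  TRUE
})

#' Bivariate genetic-correlation fit
#'
#' @slot rG genetic correlation between the two traits.
#' @slot rGse standard error of `rG` (delta method).
#' @export
setClass("BivariateFit", contains = "RemlFit",
         representation(rG = "numeric", rGse = "numeric"))

#' Direct + indirect (social) genetic effects fit
#'
#' The eight parameters of the social-genetic-effects model: direct and
#' indirect genetic variances and their covariance, direct and indirect
#' environmental variances and their covariance, cage variance and maternal
#' variance, plus derived quantities (the direct--indirect genetic
#' correlation and the total heritable variance at the average cage size).
#'
#' @slot rA direct--indirect genetic correlation.
#' @slot rAse its standard error (delta method; NA when not estimable).
#' @slot sigma2H total heritable variance at the average cage size.
#' @slot nBar average cage size used for `sigma2H`.
#' @slot model `"full"` or `"null"` (null: no indirect genetic terms).
#' @export
setClass("SGEFit", contains = "RemlFit",
  representation(rA = "numeric", rAse = "numeric", sigma2H = "numeric",
                 nBar = "numeric", model = "character"))

#' Chi-square mixture likelihood-ratio test result
#'
#' @slot statistic LRT statistic (clamped at zero).
#' @slot m mixture weight on the 2-df chi-square component, in \[0, 1\].
#' @slot p p-value under the `(1 - m) chi2_1 + m chi2_2` upper-tail mixture.
#' @export
setClass("MixtureLRT",
  representation(statistic = "numeric", m = "numeric", p = "numeric"))

setValidity("MixtureLRT", function(object) {
  if (object@statistic < 0) return("statistic must be >= 0")
  if (object@m < 0 || object@m > 1) return("m must be in [0,1]")
  if (object@p <= 0 || object@p > 1) return("p must be in (0,1]")
  TRUE
})

#' Mixed-model GWAS scan
#'
#' @slot results data.frame with one row per variant: chrom, pos, id, beta,
#'   negLog10P (NA for variants constant in the analysis sample).
#' @slot nullComponents list of per-chromosome null variance components.
#' @slot threshold genome-wide -log10(p) significance threshold (NA if not
#'   computed).
#' @slot adjustedThreshold threshold after phenome-wide adjustment.
#' @slot nEff effective number of phenotypes used for the adjustment.
#' @export
setClass("GwasScan",
  representation(results = "data.frame", nullComponents = "list",
                 threshold = "numeric", adjustedThreshold = "numeric",
                 nEff = "numeric"))
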