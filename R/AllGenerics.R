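#' @include AllClasses.R
NULL

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @export
setGeneric("variantMap", function(x) standardGeneric("variantMap"))
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @export
setGeneric("cageIncidence", function(x) standardGeneric("cageIncidence"))
#' @export
setGeneric("maternalIncidence", function(x) standardGeneric("maternalIncidence"))
#' @export
setGeneric("cageMates", function(x) standardGeneric("cageMates"))
#' @export
setGeneric("cageSizeCovariate", function(x) standardGeneric("cageSizeCovariate"))
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))
#' @export
setGeneric("grm", function(x) standardGeneric("grm"))
#' @export
setGeneric("locoChromosome", function(x) standardGeneric("locoChromosome"))
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))
#' @export
setGeneric("sampleDepth", function(x) standardGeneric("sampleDepth"))
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
#' @export
setGeneric("geneticCorrelation", function(x) standardGeneric("geneticCorrelation"))
#' @export
setGeneric("totalGeneticVariance",
           function(x, nBar, ...) standardGeneric("totalGeneticVariance"))

## Accessors ------------------------------------------------------------------

#' @describeIn GenotypeMatrix dosage matrix (individuals x variants).
#' @param x object.
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @describeIn GenotypeMatrix variant map (chrom, pos, id).
#' @export
setMethod("variantMap", "GenotypeMatrix", function(x) x@map)

#' @describeIn GenotypeMatrix pedigree table (id, family, mother, father).
#' @export
setMethod("pedigree", "GenotypeMatrix", function(x) x@pedigree)

#' @describeIn GenotypeMatrix per-variant alternate-allele frequency,
#'   computed on the non-missing dosages.
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(x)
  colMeans(x@dosages, na.rm = TRUE) / 2)

#' @describeIn StudyDesign cage incidence matrix W.
#' @param x object.
#' @export
setMethod("cageIncidence", "StudyDesign", function(x) x@W)

#' @describeIn StudyDesign maternal incidence matrix.
#' @export
setMethod("maternalIncidence", "StudyDesign", function(x) x@Wm)

#' @describeIn StudyDesign symmetric zero-diagonal cage-mate indicator Z.
#' @export
setMethod("cageMates", "StudyDesign", function(x) x@Z)

#' @describeIn StudyDesign per-individual cage-size covariate.
#' @export
setMethod("cageSizeCovariate", "StudyDesign", function(x) x@cageSizeCov)

#' @describeIn StudyDesign sample metadata table.
#' @export
setMethod("sampleData", "StudyDesign", function(x) x@samples)

#' @describeIn KinshipMatrix the relatedness matrix itself.
#' @param x object.
#' @export
setMethod("grm", "KinshipMatrix", function(x) x@A)

#' @describeIn KinshipMatrix excluded chromosome (NA when none).
#' @export
setMethod("locoChromosome", "KinshipMatrix", function(x) x@locoChrom)

#' @describeIn KinshipMatrix number of variants averaged into the GRM.
#' @export
setMethod("nVariants", "KinshipMatrix", function(x) x@nVariants)

#' @importFrom BiocGenerics counts
#' @describeIn AbundanceTable the taxa x samples count matrix.
#' @param object object.
#' @export
setMethod("counts", "AbundanceTable", function(object)
  SummarizedExperiment::assay(object, "counts"))

#' @describeIn AbundanceTable per-taxon lineage strings.
#' @param x object.
#' @export
setMethod("taxonomy", "AbundanceTable", function(x)
  SummarizedExperiment::rowData(x)$taxonomy)

#' @describeIn AbundanceTable per-sample sequencing depth (column sums).
#' @export
setMethod("sampleDepth", "AbundanceTable", function(x)
  colSums(SummarizedExperiment::assay(x, "counts")))

#' @describeIn RemlFit named variance/covariance parameters.
#' @param x object.
#' @export
setMethod("varianceComponents", "RemlFit", function(x) x@params)

#' @describeIn RemlFit fixed-effect estimates.
#' @export
setMethod("fixedEffects", "RemlFit", function(x) x@beta)

#' @describeIn RemlFit restricted log-likelihood at the optimum.
#' @param object object.
#' @export
setMethod("logLik", "RemlFit", function(object) {
  ll <- object@loglik
  attr(ll, "df") <- length(object@params) + length(object@beta)
  class(ll) <- "logLik"
  ll
})

#' @describeIn VarCompFit SNP heritability.
#' @export
setMethod("heritability", "VarCompFit", function(x) x@h2)

#' @describeIn BivariateFit genetic correlation with its standard error as
#'   attribute `"se"`.
#' @export
setMethod("geneticCorrelation", "BivariateFit", function(x) {
  r <- x@rG
  attr(r, "se") <- x@rGse
  r
})

#' @describeIn SGEFit direct--indirect genetic correlation with standard
#'   error as attribute `"se"`.
#' @export
setMethod("geneticCorrelation", "SGEFit", function(x) {
  r <- x@rA
  attr(r, "se") <- x@rAse
  r
})

## show methods ---------------------------------------------------------------

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", object@nFamilies, "families x",
      object@offspringPerFamily, "offspring,", object@nSnps, "SNPs\n")
  cat(sprintf("  genetic: varDge=%.3g varIge=%.3g corDgeIge=%.2f\n",
              object@varDge, object@varIge, object@corDgeIge))
  cat(sprintf("  env: varEnvDirect=%.3g varEnvIndirect=%.3g corEnv=%.2f\n",
              object@varEnvDirect, object@varEnvIndirect, object@corEnv))
  cat(sprintf("  cage=%.3g maternal=%.3g cages{%s} cohousing=%s seed=%d\n",
              object@varCage, object@varMaternal,
              paste(object@cageSize, collapse = ","),
              object@cohousing, object@seed))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "variants on",
      length(unique(object@map$chrom)), "chromosomes\n")
  if (nrow(object@pedigree))
    cat("  pedigree:", length(unique(object@pedigree$family)), "families\n")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", nrow(object@W), "individuals in", ncol(object@W),
      "cages (sizes", paste(sort(unique(colSums(object@W))), collapse = "/"),
      ") from", ncol(object@Wm), "mothers\n")
})

setMethod("show", "KinshipMatrix", function(object) {
  cat("KinshipMatrix:", nrow(object@A), "individuals,",
      object@nVariants, "variants")
  if (!is.na(object@locoChrom))
    cat(" (excluding chromosome", object@locoChrom, ")")
  cat("\n")
})

setMethod("show", "VarCompFit", function(object) {
  cat("VarCompFit (REML), n =", object@n, "\n")
  print(round(object@params, 4))
  cat(sprintf("  h2 = %.3f  restricted logLik = %.3f\n",
              object@h2, object@loglik))
})

setMethod("show", "BivariateFit", function(object) {
  cat("BivariateFit (REML), n =", object@n, "\n")
  cat(sprintf("  rG = %.3f (se %.3f)  restricted logLik = %.3f\n",
              object@rG, object@rGse, object@loglik))
})

setMethod("show", "SGEFit", function(object) {
  cat("SGEFit (REML,", object@model, "model), n =", object@n, "\n")
  print(round(object@params, 4))
  cat(sprintf("  rA = %.3f  sigma2H(nBar=%.2f) = %.4f  logLik = %.3f\n",
              object@rA, object@nBar, object@sigma2H, object@loglik))
})

setMethod("show", "MixtureLRT", function(object) {
  cat(sprintf("MixtureLRT: statistic = %.4f, m = %.2f, p = %.4g\n",
              object@statistic, object@m, object@p))
})

setMethod("show", "GwasScan", function(object) {
  cat("GwasScan:", nrow(object@results), "variants;",
      sum(!is.na(object@results$negLog10P)), "tested\n")
  if (!is.na(object@threshold))
    cat(sprintf("  genome-wide threshold %.2f; adjusted %.2f (nEff = %g)\n",
                object@threshold, object@adjustedThreshold, object@nEff))
})
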