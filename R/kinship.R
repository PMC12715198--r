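#' Variant quality-control filter
#'
#' Removes variants with a missing rate above `maxMissing` (strictly
#' greater) or a minor allele frequency below `minMaf` (strictly smaller;
#' a variant at exactly the threshold is kept). Monomorphic variants have
#' MAF 0 and are always removed when `minMaf > 0`.
#'
#' @param G \linkS4class{GenotypeMatrix}.
#' @param maxMissing maximum tolerated per-variant missing rate.
#' @param minMaf minimum tolerated minor allele frequency.
#' @return The \linkS4class{GenotypeMatrix} restricted to passing variants.
#' @export
qcFilter <- function(G, maxMissing = 0.1, minMaf = 0.05) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column
  keep <- miss <= maxMissing & maf >= minMaf
  subsetVariants(G, keep)
}

subsetVariants <- function(G, keep) {
  GenotypeMatrix(dosages = G@dosages[, keep, drop = FALSE],
                 map = G@map[keep, , drop = FALSE],
                 pedigree = G@pedigree)
}

## Per-variant mean imputation of missing dosages.
meanImpute <- function(d) {
  nav <- which(colSums(is.na(d)) > 0)
  for (j in nav) {
    m <- mean(d[, j], na.rm = TRUE)
    d[is.na(d[, j]), j] <- m
  }
  d
}

#' Sliding-window LD pruning
#'
#' Greedy pairwise-r2 pruning within windows of `window` variants advancing
#' by `step`, per chromosome: scanning variants in map order, a variant is
#' dropped as soon as its squared correlation with an earlier retained
#' variant in the window exceeds `r2Threshold`. The retained set therefore
#' contains no pair above the threshold within any window.
#'
#' @param G \linkS4class{GenotypeMatrix} with variants sorted by chromosome
#'   and position.
#' @param window window size in variants.
#' @param step window advance in variants.
#' @param r2Threshold maximum tolerated pairwise r2.
#' @return The pruned \linkS4class{GenotypeMatrix}.
#' @export
ldPrune <- function(G, window = 50L, step = 5L, r2Threshold = 0.5) {
  stopifnot(is(G, "GenotypeMatrix"), window >= 2, step >= 1)
  d <- meanImpute(dosages(G))
  map <- variantMap(G)
  o <- order(map$chrom, map$pos)
  if (any(o != seq_along(o)))
    stop("variants must be sorted by chromosome and position")
  keep <- rep(TRUE, ncol(d))
  sdv <- apply(d, 2, sd)
  for (chr in unique(map$chrom)) {
    idx <- which(map$chrom == chr)
    startPos <- seq(1L, max(1L, length(idx) - 1L), by = step)
    for (s in startPos) {
      win <- idx[s:min(s + window - 1L, length(idx))]
      win <- win[keep[win] & sdv[win] > 0]
      if (length(win) < 2L) next
      cc <- suppressWarnings(cor(d[, win, drop = FALSE]))^2
      for (j in seq_along(win)[-1]) {
        if (!keep[win[j]]) next
        earlier <- win[seq_len(j - 1L)]
        earlier <- earlier[keep[earlier]]
        if (length(earlier) &&
            any(cc[seq_len(j - 1L), j][keep[win[seq_len(j - 1L)]]] >
                  r2Threshold))
          keep[win[j]] <- FALSE
      }
    }
  }
  subsetVariants(G, keep)
}

#' SNP-based genetic relatedness matrix (standardized estimator)
#'
#' Computes the standardized GRM
#' \deqn{A_{ij} = \frac{1}{M}\sum_m \frac{(g_{im} - 2p_m)(g_{jm} - 2p_m)}
#'   {2 p_m (1 - p_m)}}
#' over the included variants, with allele frequencies computed on the
#' analysis sample and missing dosages mean-imputed before
#' standardization. With `locoChrom` set, all variants on that chromosome
#' are excluded (the leave-one-chromosome-out GRM used in mixed-model
#' association scans). Variants that are monomorphic after imputation are
#' excluded with a warning.
#'
#' @param G \linkS4class{GenotypeMatrix} (typically QC'd and pruned).
#' @param locoChrom chromosome to leave out (NA for none).
#' @return A \linkS4class{KinshipMatrix}.
#' @export
computeGRM <- function(G, locoChrom = NA_integer_) {
  stopifnot(is(G, "GenotypeMatrix"))
  keep <- rep(TRUE, ncol(G@dosages))
  if (!is.na(locoChrom)) keep <- G@map$chrom != as.integer(locoChrom)
  d <- meanImpute(G@dosages[, keep, drop = FALSE])
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic variant(s) excluded from the GRM")
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
  }
  M <- ncol(d)
  if (M == 0) stop("no polymorphic variants left for the GRM")
  S <- sweep(d, 2, 2 * p, `-`)
  S <- sweep(S, 2, sqrt(2 * p * (1 - p)), `/`)
  A <- tcrossprod(S) / M
  dimnames(A) <- list(rownames(G@dosages), rownames(G@dosages))
  KinshipMatrix(symmetrize(A), locoChrom = locoChrom, nVariants = M)
}

#' Leave-one-chromosome-out GRMs for every chromosome present
#'
#' @param G \linkS4class{GenotypeMatrix}.
#' @return Named list of \linkS4class{KinshipMatrix} objects, one per
#'   chromosome in the variant map, each excluding that chromosome.
#' @export
locoGRMs <- function(G) {
  chrs <- sort(unique(variantMap(G)$chrom))
  out <- lapply(chrs, function(ch) computeGRM(G, locoChrom = ch))
  names(out) <- as.character(chrs)
  out
}
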