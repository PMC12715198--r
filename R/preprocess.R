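#' Drop samples with outlying sequencing depth
#'
#' Retains samples whose total count lies within `mean +/- k * sd`, with the
#' mean and standard deviation computed over all input samples. Extreme
#' library sizes are problematic for compositional analyses even after
#' transformation, so both tails are trimmed.
#'
#' @param table \linkS4class{AbundanceTable}.
#' @param k multiplier on the standard deviation (default 2).
#' @return The \linkS4class{AbundanceTable} restricted to retained samples.
#' @export
filterByDepth <- function(table, k = 2) {
  stopifnot(is(table, "AbundanceTable"), k >= 0)
  depth <- sampleDepth(table)
  if (length(depth) < 3) stop("need at least 3 samples")
  m <- mean(depth)
  s <- sd(depth)
  keep <- depth >= m - k * s & depth <= m + k * s
  table[, keep]
}

#' Centred log-ratio transform of a count table
#'
#' Per sample: counts are closed to relative abundances, zeros are replaced
#' by a small constant on the relative-abundance scale, and each value is
#' log-transformed relative to the geometric mean of the sample's values:
#' `clr(x)_j = log(x_j / gm(x))`. CLR values are scale-invariant (per-sample
#' multiplicative factors cancel), and rows with no replaced zeros sum to
#' zero exactly.
#'
#' @param table \linkS4class{AbundanceTable}, or a taxa x samples matrix.
#' @param zeroReplacement value substituted for zero relative abundances.
#' @return taxa x samples matrix of CLR values.
#' @export
clrTransform <- function(table, zeroReplacement = 0.00001) {
  cts <- if (is(table, "AbundanceTable")) counts(table) else as.matrix(table)
  tot <- colSums(cts)
  if (any(tot == 0)) stop("all-zero sample(s): ",
                          paste(colnames(cts)[tot == 0], collapse = ", "))
  rel <- sweep(cts, 2, tot, `/`)
  rel[rel == 0] <- zeroReplacement
  lg <- log(rel)
  sweep(lg, 2, colMeans(lg), `-`)
}

#' Collapse taxa at a taxonomic level
#'
#' Sums counts of taxa sharing the same lineage up to the requested level
#' (Greengenes-style `k__;p__;c__;o__;f__;g__;s__` strings). Taxa whose
#' lineage lacks the level, or is missing, are pooled into an explicit
#' `"unassigned"` group. Per-sample totals are preserved.
#'
#' @param table \linkS4class{AbundanceTable}.
#' @param level one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A collapsed \linkS4class{AbundanceTable}.
#' @export
collapseTaxonomy <- function(table, level = "family") {
  stopifnot(is(table, "AbundanceTable"))
  prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
  if (!level %in% names(prefixes))
    stop("unknown taxonomic level: ", level)
  depthLev <- match(level, names(prefixes))
  key <- vapply(taxonomy(table), function(tx) {
    if (is.na(tx)) return("unassigned")
    parts <- trimws(strsplit(tx, ";")[[1]])
    if (length(parts) < depthLev) return("unassigned")
    lev <- parts[depthLev]
    if (!nzchar(sub("^[a-z]__", "", lev))) return("unassigned")
    paste(parts[seq_len(depthLev)], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  cts <- counts(table)
  grp <- factor(key, levels = unique(key))
  agg <- rowsum(cts, grp, reorder = FALSE)
  AbundanceTable(agg, taxonomy = levels(grp),
                 sampleData = as.data.frame(
                   SummarizedExperiment::colData(table)))
}

#' Prevalence filter for microbiome phenotypes
#'
#' Keeps taxa present (nonzero raw count) in at least a `threshold`
#' fraction of the samples of each group -- the boundary is inclusive, so a
#' taxon present in exactly half the samples passes a 0.5 threshold.
#' Presence is judged on raw counts, never on transformed values.
#'
#' @param table \linkS4class{AbundanceTable}.
#' @param threshold minimum within-group prevalence in \[0, 1\].
#' @param group optional per-sample group labels (e.g. cohort); with
#'   groups, a named list of retained taxa per group is returned.
#' @return Character vector of retained taxon names, or a named list of
#'   such vectors when `group` is given.
#' @export
prevalenceFilter <- function(table, threshold = 0.5, group = NULL) {
  stopifnot(is(table, "AbundanceTable"), threshold >= 0, threshold <= 1)
  pres <- counts(table) > 0
  if (is.null(group)) {
    prev <- rowMeans(pres)
    return(rownames(pres)[prev >= threshold])
  }
  stopifnot(length(group) == ncol(pres))
  group <- as.factor(group)
  if (any(table(group) == 0)) stop("empty group")
  out <- lapply(levels(group), function(g) {
    prev <- rowMeans(pres[, group == g, drop = FALSE])
    rownames(pres)[prev >= threshold]
  })
  names(out) <- levels(group)
  out
}

#' Quantile-normalize a phenotype and regress out covariates
#'
#' Rank-based inverse-normal transform with ties broken at random (seeded),
#' followed by ordinary-least-squares residualization on the supplied
#' covariates (factors are one-hot encoded via `model.matrix`; numeric
#' columns, e.g. library size, enter as-is). Samples with missing
#' covariates are dropped with a message; redundant covariate columns are
#' dropped with a warning. The residuals are returned for genetic analysis.
#'
#' @param y numeric phenotype vector (e.g. one taxon's CLR values).
#' @param covariates optional data.frame of covariates (sex, batches,
#'   library size, ...), one row per sample.
#' @param seed seed for the random tie-breaking, recorded in the
#'   provenance attribute.
#' @return Numeric vector of residuals (NA for dropped samples), with a
#'   `"provenance"` attribute recording the transformation chain, seed and
#'   dropped samples.
#' @export
normalizePhenotype <- function(y, covariates = NULL, seed = 1L) {
  n <- length(y)
  keep <- !is.na(y)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == n)
    keep <- keep & complete.cases(covariates)
  }
  dropped <- which(!keep)
  if (length(dropped))
    message(length(dropped), " sample(s) dropped (missing phenotype or ",
            "covariates)")
  yk <- y[keep]
  nk <- length(yk)
  ## ties receive a random permutation of the tied ranks
  rk <- withSeed(streamSeed(seed, "tiebreak"), {
    ord <- order(yk, runif(nk))
    out <- integer(nk)
    out[ord] <- seq_len(nk)
    out
  })
  z <- qnorm((rk - 0.5) / nk)
  res <- z
  if (!is.null(covariates)) {
    mm <- model.matrix(~ ., data = droplevels(
      as.data.frame(covariates)[keep, , drop = FALSE]))
    qx <- qr(mm)
    if (qx$rank < ncol(mm)) {
      warning("covariate matrix rank deficient; dropping ",
              ncol(mm) - qx$rank, " redundant column(s)")
      mm <- mm[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    }
    res <- qr.resid(qr(mm), z)
  }
  out <- rep(NA_real_, n)
  out[keep] <- res
  names(out) <- names(y)
  attr(out, "provenance") <- list(
    chain = c("rank-inverse-normal (random tie-break)",
              if (!is.null(covariates)) "OLS residualization"),
    seed = seed, dropped = dropped)
  out
}
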