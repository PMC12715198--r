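#' Build a housing design from a pedigree
#'
#' Assigns individuals to cages of the requested sizes and emits the
#' incidence structures used by the mixed models. With `cohousing = FALSE`
#' no two siblings ever share a cage (the arrangement used to avoid
#' confounding of genetic and cage effects); with `cohousing = TRUE` cages
#' are filled family by family, so siblings preferentially share cages.
#'
#' Cage sizes are drawn from `cageSize`; a single remainder cage of size
#' >= 2 is allowed when the sizes do not divide the sample evenly.
#'
#' @param pedigree a data.frame with columns `id`, `family`, `mother`
#'   (as produced by [simulateGenotypes()]), or a
#'   \linkS4class{GenotypeMatrix} carrying one.
#' @param cageSize allowed cage sizes (scalar or vector drawn from
#'   uniformly).
#' @param cohousing logical; co-house siblings or forbid it.
#' @param seed seed for the assignment stream.
#' @return A \linkS4class{StudyDesign}.
#' @examples
#' g <- simulateGenotypes(SimTruth(nFamilies = 10L, nSnps = 100L))
#' d <- makeDesign(pedigree(g), cageSize = 3L, cohousing = FALSE, seed = 1L)
#' all(rowSums(cageMates(d)) == 2)
#' @export
makeDesign <- function(pedigree, cageSize = c(2L, 3L, 4L), cohousing = FALSE,
                       seed = 1L) {
  if (is(pedigree, "GenotypeMatrix")) pedigree <- pedigree(pedigree)
  stopifnot(all(c("id", "family", "mother") %in% names(pedigree)))
  n <- nrow(pedigree)
  cageSize <- as.integer(cageSize)
  stopifnot(all(cageSize >= 2L), n >= min(cageSize))
  withSeed(streamSeed(seed, "design"), {
    sizes <- planCageSizes(n, cageSize)
    cage <- if (cohousing) assignCohoused(pedigree, sizes)
            else assignNoCohousing(pedigree, sizes)
  })
  buildDesign(pedigree, cage)
}

## Draw a multiset of cage sizes summing exactly to n, each >= 2.
planCageSizes <- function(n, cageSize) {
  sizes <- integer()
  left <- n
  while (left > 0) {
    ok <- cageSize[cageSize <= left]
    if (!length(ok)) {
      ## remainder smaller than any allowed size: enlarge it to >= 2 by
      ## borrowing from the previous cage, or merge into it
      if (left >= 2L) { sizes <- c(sizes, left); left <- 0L }
      else if (length(sizes)) {
        sizes[length(sizes)] <- sizes[length(sizes)] + left
        left <- 0L
      } else stop("cannot form cages of size >= 2 from ", n, " individuals")
    } else {
      s <- if (length(ok) == 1L) ok else sample(ok, 1L)
      sizes <- c(sizes, s)
      left <- left - s
    }
  }
  sizes
}

## Greedy no-cohousing assignment: place members of the largest families
## first, each into the cage with most free slots among sibling-free cages.
assignNoCohousing <- function(pedigree, sizes, maxTries = 25L) {
  nCages <- length(sizes)
  famSize <- table(pedigree$family)
  if (max(famSize) > nCages)
    stop("infeasible no-cohousing constraint: a family has more siblings (",
         max(famSize), ") than there are cages (", nCages, ")")
  for (try in seq_len(maxTries)) {
    free <- sizes
    cageFam <- vector("list", nCages)
    cage <- integer(nrow(pedigree))
    ord <- order(-as.integer(famSize[as.character(pedigree$family)]),
                 runif(nrow(pedigree)))
    ok <- TRUE
    for (i in ord) {
      cand <- which(free > 0 &
                    !vapply(cageFam, function(f) pedigree$family[i] %in% f,
                            logical(1)))
      if (!length(cand)) { ok <- FALSE; break }
      pick <- cand[which.max(free[cand] + runif(length(cand)) * 0.5)]
      cage[i] <- pick
      free[pick] <- free[pick] - 1L
      cageFam[[pick]] <- c(cageFam[[pick]], pedigree$family[i])
    }
    if (ok) return(cage)
  }
  stop("infeasible no-cohousing constraint: could not place all siblings ",
       "in distinct cages")
}

## Co-housed assignment: shuffle families, concatenate their members, chunk
## into cages; siblings end up together whenever cage boundaries allow.
assignCohoused <- function(pedigree, sizes) {
  fams <- sample(unique(pedigree$family))
  ord <- unlist(lapply(fams, function(f) which(pedigree$family == f)))
  cage <- integer(nrow(pedigree))
  cage[ord] <- rep(seq_along(sizes), times = sizes)
  cage
}

buildDesign <- function(pedigree, cage) {
  n <- nrow(pedigree)
  cageLev <- sort(unique(cage))
  W <- matrix(0, n, length(cageLev),
              dimnames = list(pedigree$id, paste0("cage_", cageLev)))
  W[cbind(seq_len(n), match(cage, cageLev))] <- 1
  mumLev <- unique(pedigree$mother)
  Wm <- matrix(0, n, length(mumLev), dimnames = list(pedigree$id, mumLev))
  Wm[cbind(seq_len(n), match(pedigree$mother, mumLev))] <- 1
  Z <- W %*% t(W)
  diag(Z) <- 0
  csize <- colSums(W)[match(cage, cageLev)]
  samples <- data.frame(
    id = pedigree$id,
    cage = paste0("cage_", cage),
    mother = pedigree$mother,
    cohort = "cohort_1",
    sex = rep_len(c("F", "M"), n),
    batch = paste0("batch_", rep_len(1:3, n)),
    librarySize = NA_real_,
    stringsAsFactors = FALSE)
  new("StudyDesign", W = W, Wm = Wm, Z = Z,
      cageSizeCov = as.numeric(csize), samples = samples)
}

#' Combine cohort designs into one pooled design
#'
#' Stacks several \linkS4class{StudyDesign} objects block-diagonally:
#' cages and cage-mate relations never cross cohorts, mothers are shared
#' when their IDs coincide (litters split across cohorts), and the sample
#' table gains one cohort label per input design. This mirrors pooled
#' multi-cohort analyses in which each cohort keeps its own housing
#' structure.
#'
#' @param ... \linkS4class{StudyDesign} objects, or a single list of them.
#' @param cohorts optional character vector of cohort labels.
#' @return A pooled \linkS4class{StudyDesign}.
#' @export
combineDesigns <- function(..., cohorts = NULL) {
  designs <- list(...)
  if (length(designs) == 1L && is.list(designs[[1]]) &&
      !is(designs[[1]], "StudyDesign"))
    designs <- designs[[1]]
  stopifnot(length(designs) >= 2L,
            all(vapply(designs, is, logical(1), "StudyDesign")))
  if (is.null(cohorts)) cohorts <- paste0("cohort_", seq_along(designs))
  ns <- vapply(designs, function(d) nrow(cageIncidence(d)), integer(1))
  n <- sum(ns)
  off <- cumsum(c(0L, ns[-length(ns)]))
  ## block-diagonal cages and cage mates
  Ws <- lapply(designs, cageIncidence)
  W <- matrix(0, n, sum(vapply(Ws, ncol, integer(1))))
  Z <- matrix(0, n, n)
  colOff <- 0L
  for (i in seq_along(designs)) {
    ri <- off[i] + seq_len(ns[i])
    W[ri, colOff + seq_len(ncol(Ws[[i]]))] <- Ws[[i]]
    Z[ri, ri] <- cageMates(designs[[i]])
    colOff <- colOff + ncol(Ws[[i]])
  }
  colnames(W) <- unlist(lapply(seq_along(Ws), function(i)
    paste0(cohorts[i], ".", colnames(Ws[[i]]))))
  ## mothers merged by ID across cohorts
  moms <- lapply(designs, function(d) colnames(maternalIncidence(d)))
  momLev <- unique(unlist(moms))
  Wm <- matrix(0, n, length(momLev), dimnames = list(NULL, momLev))
  for (i in seq_along(designs)) {
    ri <- off[i] + seq_len(ns[i])
    Wm[ri, match(moms[[i]], momLev)] <- maternalIncidence(designs[[i]])
  }
  samples <- do.call(rbind, lapply(seq_along(designs), function(i) {
    s <- sampleData(designs[[i]])
    s$cohort <- cohorts[i]
    s$cage <- paste0(cohorts[i], ".", s$cage)
    s
  }))
  rownames(W) <- rownames(Z) <- rownames(Wm) <- samples$id
  colnames(Z) <- samples$id
  new("StudyDesign", W = W, Wm = Wm, Z = Z,
      cageSizeCov = unlist(lapply(designs, cageSizeCovariate),
                           use.names = FALSE),
      samples = samples)
}
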