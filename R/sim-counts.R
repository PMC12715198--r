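#' Simulate a sparse, overdispersed taxon count table
#'
#' Generates amplicon-like counts: each taxon has a log-normal baseline
#' relative abundance and an occupancy probability (the chance it is present
#' in a given sample at all, producing structural zeros); per-sample
#' sequencing depth is log-normal around a target; and counts are multinomial
#' draws from the sample's (renormalized) relative-abundance profile.
#' Taxonomy strings carry family and genus levels so taxonomic collapsing can
#' be exercised.
#'
#' @param nSamples,nTaxa table dimensions (`nTaxa >= 2`).
#' @param meanDepth target sequencing depth (log-normal median).
#' @param depthSdLog log-scale SD of the per-sample depth.
#' @param occupancy per-taxon presence probability; default draws
#'   uniformly on (0.2, 1), spanning the common 50%-prevalence boundary.
#' @param baseAbundance per-taxon baseline relative abundance (need not be
#'   normalized; zeros allowed and produce all-zero taxa). Default:
#'   log-normal with SD 2 on the log scale.
#' @param overdispersionSdLog per-sample log-normal noise on relative
#'   abundances (overdispersion beyond multinomial).
#' @param seed RNG seed.
#' @return An \linkS4class{AbundanceTable} (taxa x samples).
#' @examples
#' tab <- simulateCounts(20, 30, seed = 1)
#' all(colSums(counts(tab)) == sampleDepth(tab))
#' @export
simulateCounts <- function(nSamples, nTaxa, meanDepth = 20000,
                           depthSdLog = 0.2, occupancy = NULL,
                           baseAbundance = NULL, overdispersionSdLog = 1,
                           seed = 1L) {
  stopifnot(nTaxa >= 2, nSamples >= 1, meanDepth >= 1)
  withSeed(streamSeed(seed, "counts"), {
    if (is.null(occupancy)) occupancy <- runif(nTaxa, 0.2, 1)
    stopifnot(length(occupancy) == nTaxa, all(occupancy >= 0),
              all(occupancy <= 1))
    if (is.null(baseAbundance)) baseAbundance <- rlnorm(nTaxa, sdlog = 2)
    stopifnot(length(baseAbundance) == nTaxa, all(baseAbundance >= 0))
    depth <- pmax(1, round(rlnorm(nSamples, log(meanDepth), depthSdLog)))
    cts <- matrix(0L, nTaxa, nSamples)
    for (s in seq_len(nSamples)) {
      present <- rbinom(nTaxa, 1L, occupancy)
      rel <- baseAbundance * present *
        rlnorm(nTaxa, sdlog = overdispersionSdLog)
      if (sum(rel) == 0) # degenerate draw: keep the a-priori dominant taxon
        rel[which.max(baseAbundance)] <- 1
      cts[, s] <- rmultinom(1L, depth[s], rel / sum(rel))
    }
  })
  nGenus <- max(2L, ceiling(nTaxa / 3))
  nFam <- max(2L, ceiling(nGenus / 2))
  genus <- rep_len(seq_len(nGenus), nTaxa)
  fam <- rep_len(seq_len(nFam), nGenus)[genus]
  taxonomy <- sprintf(
    "k__Bacteria;p__Bacteroidota;c__Bacteroidia;o__Bacteroidales;f__Family%02d;g__Genus%03d;s__",
    fam, genus)
  AbundanceTable(cts, taxonomy = taxonomy,
                 sampleData = data.frame(librarySize = depth))
}
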