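#' Simulate family-structured genotypes
#'
#' Generates a two-generation pedigree: `nFamilies` unrelated parental pairs
#' whose genotypes are drawn under Hardy--Weinberg equilibrium at per-SNP
#' allele frequencies uniform in `mafRange`, and `offspringPerFamily`
#' full-sib offspring per pair produced by Mendelian transmission (each
#' parent transmits one allele, drawn without interference). Only the
#' offspring -- the phenotyped generation -- are returned. SNPs are assigned
#' evenly to the 20 autosomes.
#'
#' @param truth a \linkS4class{SimTruth}; uses `nFamilies`,
#'   `offspringPerFamily`, `nSnps`, `mafRange` and the master `seed`
#'   (genotypes get their own derived stream).
#' @return A \linkS4class{GenotypeMatrix} for the offspring, carrying the
#'   pedigree (`id`, `family`, `mother`, `father`).
#' @examples
#' g <- simulateGenotypes(SimTruth(nFamilies = 10L, nSnps = 200L))
#' dim(dosages(g))
#' @export
simulateGenotypes <- function(truth) {
  stopifnot(is(truth, "SimTruth"))
  validObject(truth)
  nf <- truth@nFamilies
  m <- truth@nSnps
  k <- truth@offspringPerFamily
  withSeed(streamSeed(truth@seed, "genotypes"), {
    p <- runif(m, truth@mafRange[1], truth@mafRange[2])
    ## parental dosages under HWE
    mum <- matrix(rbinom(nf * m, 2L, rep(p, each = nf)), nf, m)
    dad <- matrix(rbinom(nf * m, 2L, rep(p, each = nf)), nf, m)
    off <- matrix(0L, nf * k, m)
    for (j in seq_len(k)) {
      ## transmitted allele is Bernoulli(dosage / 2): hets segregate 50:50
      tm <- matrix(rbinom(nf * m, 1L, mum / 2), nf, m)
      td <- matrix(rbinom(nf * m, 1L, dad / 2), nf, m)
      off[seq.int(j, nf * k, by = k), ] <- tm + td
    }
  })
  fam <- rep(seq_len(nf), each = k)
  ids <- sprintf("ind_%04d", seq_len(nf * k))
  rownames(off) <- ids
  ped <- data.frame(id = ids, family = fam,
                    mother = sprintf("mum_%04d", fam),
                    father = sprintf("dad_%04d", fam),
                    stringsAsFactors = FALSE)
  chrom <- rep(1:20, length.out = m)
  o <- order(chrom)
  map <- data.frame(chrom = chrom[o],
                    pos = unlist(lapply(tabulate(chrom, 20),
                                        function(nc) seq_len(nc) * 10000L)),
                    id = sprintf("snp_%05d", seq_len(m))[o],
                    stringsAsFactors = FALSE)
  storage.mode(off) <- "double"
  off <- off[, o, drop = FALSE]
  colnames(off) <- map$id
  GenotypeMatrix(dosages = off, map = map, pedigree = ped)
}
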