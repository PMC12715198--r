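## Readers and writers for the plain-text interchange formats: VCF and
## PLINK-style transposed dosage tables for genotypes, square text GRMs
## with an ID sidecar, TSV designs, counts and phenotypes, BIOM input.

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF 4.2 file with a GT field encoding the dosages (0/0, 0/1,
#' 1/1, ./.) on the 20 autosomes.
#'
#' @param G \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(G, path) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  map <- variantMap(G)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(d)))
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", sort(unique(map$chrom)), ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(map$chrom, map$pos, map$id, "A", "G", ".", "PASS", ".",
                "GT", apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses the GT field into alternate-allele dosages (requires the `vcfR`
#' package).
#'
#' @param path VCF file path.
#' @return A \linkS4class{GenotypeMatrix} (empty pedigree).
#' @export
readGenotypesVCF <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(g) {
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0", "0|0")] <- 0
    out[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    out[g %in% c("1/1", "1|1")] <- 2
    out
  }
  d <- do.call(rbind, lapply(seq_len(ncol(gt)), function(i) conv(gt[, i])))
  rownames(d) <- colnames(gt)
  colnames(d) <- rownames(gt)
  map <- data.frame(chrom = as.integer(vcfR::getCHROM(v)),
                    pos = as.integer(vcfR::getPOS(v)),
                    id = vcfR::getID(v), stringsAsFactors = FALSE)
  GenotypeMatrix(dosages = d, map = map)
}

#' Write genotypes as a PLINK-style transposed dosage table
#'
#' Tab-separated text with columns CHR, SNP, CM, POS, COUNTED, ALT followed
#' by one dosage column per individual (the `.traw` layout).
#'
#' @param G \linkS4class{GenotypeMatrix}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGenotypesTraw <- function(G, path) {
  stopifnot(is(G, "GenotypeMatrix"))
  d <- dosages(G)
  map <- variantMap(G)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(d)))
  out <- data.frame(CHR = map$chrom, SNP = map$id, CM = 0, POS = map$pos,
                    COUNTED = "G", ALT = "A", t(d), check.names = FALSE)
  colnames(out)[-(1:6)] <- ids
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypesTraw
#' @export
readGenotypesTraw <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  d <- t(as.matrix(tab[, -(1:6), drop = FALSE]))
  colnames(d) <- tab$SNP
  map <- data.frame(chrom = as.integer(tab$CHR), pos = as.integer(tab$POS),
                    id = as.character(tab$SNP), stringsAsFactors = FALSE)
  GenotypeMatrix(dosages = d, map = map)
}

#' Write / read a GRM as a square text matrix with an ID sidecar
#'
#' `<prefix>.grm` holds the whitespace-delimited square matrix;
#' `<prefix>.grm.id` one individual ID per line.
#'
#' @param K \linkS4class{KinshipMatrix}.
#' @param prefix output path prefix.
#' @return The prefix (write) or a \linkS4class{KinshipMatrix} (read).
#' @export
writeGRM <- function(K, prefix) {
  stopifnot(is(K, "KinshipMatrix"))
  A <- grm(K)
  write.table(A, paste0(prefix, ".grm"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("ind_", seq_len(nrow(A)))
  writeLines(ids, paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' @rdname writeGRM
#' @export
readGRM <- function(prefix) {
  A <- as.matrix(read.table(paste0(prefix, ".grm")))
  ids <- readLines(paste0(prefix, ".grm.id"))
  dimnames(A) <- list(ids, ids)
  KinshipMatrix(symmetrize(A), nVariants = NA_integer_)
}

#' Write a study design's sample table as TSV
#'
#' @param design \linkS4class{StudyDesign}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  stopifnot(is(design, "StudyDesign"))
  write.table(sampleData(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a count table as TSV (taxa in rows, final column taxonomy)
#'
#' @param table \linkS4class{AbundanceTable}.
#' @param path file path.
#' @return `path` (write) or an \linkS4class{AbundanceTable} (read).
#' @export
writeCountsTSV <- function(table, path) {
  stopifnot(is(table, "AbundanceTable"))
  out <- data.frame(taxon = rownames(counts(table)), counts(table),
                    taxonomy = taxonomy(table), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  cts <- as.matrix(tab[, setdiff(colnames(tab), c("taxon", "taxonomy")),
                       drop = FALSE])
  rownames(cts) <- tab$taxon
  AbundanceTable(cts, taxonomy = as.character(tab$taxonomy))
}

#' Read a BIOM count table
#'
#' @param path BIOM file path (requires the `biomformat` package).
#' @return An \linkS4class{AbundanceTable}.
#' @export
readBiomCounts <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("reading BIOM requires the 'biomformat' package")
  b <- biomformat::read_biom(path)
  cts <- as(biomformat::biom_data(b), "matrix")
  om <- biomformat::observation_metadata(b)
  tax <- if (is.null(om)) rep(NA_character_, nrow(cts))
         else apply(as.data.frame(om), 1, paste, collapse = ";")
  AbundanceTable(round(cts), taxonomy = unname(tax))
}

#' Write phenotypes with a provenance sidecar
#'
#' Writes a sample x phenotype TSV; any `"provenance"` attribute (as set by
#' [normalizePhenotype()]) is recorded in `<path>.provenance.txt`.
#'
#' @param phenotypes named numeric vector or sample x phenotype matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePhenotypes <- function(phenotypes, path) {
  prov <- attr(phenotypes, "provenance")
  m <- as.matrix(phenotypes)
  if (is.null(colnames(m))) colnames(m) <- "phenotype"
  out <- data.frame(sample = if (is.null(rownames(m)))
    seq_len(nrow(m)) else rownames(m), m, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(prov))
    writeLines(c(paste("chain:", paste(prov$chain, collapse = " -> ")),
                 paste("seed:", prov$seed),
                 paste("dropped:", paste(prov$dropped, collapse = ","))),
               paste0(path, ".provenance.txt"))
  invisible(path)
}

#' Snapshot simulation parameters as plain text
#'
#' @param truth \linkS4class{SimTruth}.
#' @param path output file path (`key = value` lines).
#' @return `path`, invisibly.
#' @export
writeSimTruth <- function(truth, path) {
  stopifnot(is(truth, "SimTruth"))
  nms <- slotNames(truth)
  vals <- vapply(nms, function(nm)
    paste(format(slot(truth, nm)), collapse = ","), character(1))
  writeLines(paste(nms, "=", vals), path)
  invisible(path)
}
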