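#' Read and write genotype matrices
#'
#' The TSV dialect is: one row per SNP, first columns `chrom` and `pos`,
#' then one column per individual with calls `AA`/`AB`/`BB`/`NA`.  The VCF
#' dialect maps `GT` values `0/0 -> AA`, `0/1 -> AB`, `1/1 -> BB`,
#' `./. -> NA`, with the P1 line as the reference-allele carrier by
#' convention (`p1Allele = "ALT"` flips the homozygote mapping).
#'
#' @param file path to a TSV genotype matrix or a VCF file.
#' @param p1Allele `"REF"` (default) or `"ALT"`: which VCF allele the P1
#'   parent carries.
#' @return a [SnpGenotypes].
#' @export
readGenotypesTSV <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t",
                  colClasses = "character", check.names = FALSE)
  stopifnot(all(c("chrom", "pos") %in% names(d)))
  geno <- as.matrix(d[, setdiff(names(d), c("chrom", "pos")), drop = FALSE])
  geno[geno %in% c("NA", ".", "")] <- NA_character_
  snpGenotypes(geno, chrom = d$chrom, pos = as.integer(d$pos))
}

#' @rdname readGenotypesTSV
#' @param snp a [SnpGenotypes] to write.
#' @export
writeGenotypesTSV <- function(snp, file) {
  g <- genotypeCalls(snp)
  d <- data.frame(chrom = markerChrom(snp), pos = markerPos(snp),
                  g, check.names = FALSE)
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname readGenotypesTSV
#' @export
readGenotypesVCF <- function(file, p1Allele = c("REF", "ALT")) {
  p1Allele <- match.arg(p1Allele)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  map <- c("0/0" = "AA", "0|0" = "AA", "0/1" = "AB", "0|1" = "AB",
           "1/0" = "AB", "1|0" = "AB", "1/1" = "BB", "1|1" = "BB")
  geno <- matrix(unname(map[gt]), nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
  if (p1Allele == "ALT") {
    flip <- c(AA = "BB", AB = "AB", BB = "AA")
    geno[] <- unname(flip[geno])
  }
  snpGenotypes(geno, chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v))
}

#' @rdname readGenotypesTSV
#' @export
writeGenotypesVCF <- function(snp, file) {
  g <- genotypeCalls(snp)
  map <- c(AA = "0/0", AB = "0/1", BB = "1/1")
  gt <- matrix(map[g], nrow(g), ncol(g))
  gt[is.na(gt)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(g)), collapse = "\t"))
  body <- paste(markerChrom(snp), markerPos(snp), rownames(g), "A", "B", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Read or write a phenotype table
#'
#' CSV with one row per individual: an `individual` id column plus one
#' numeric column per trait.
#'
#' @param file CSV path.
#' @export
readPhenotypesCSV <- function(file) {
  d <- read.csv(file, check.names = FALSE)
  stopifnot("individual" %in% names(d))
  d$individual <- as.character(d$individual)
  d
}

#' @rdname readPhenotypesCSV
#' @param pheno phenotype data.frame to write.
#' @export
writePhenotypesCSV <- function(pheno, file) {
  write.csv(pheno, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write bins as BED plus a genotype matrix
#'
#' `<prefix>.bed` holds the bin coordinates (0-based half-open) and
#' `<prefix>_genotypes.tsv` the bin x individual genotype matrix.
#'
#' @param bins a [BinGenotypes].
#' @param prefix output path prefix.
#' @export
writeBins <- function(bins, prefix) {
  rr <- SummarizedExperiment::rowRanges(bins)
  bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                    start = GenomicRanges::start(rr) - 1L,
                    end = GenomicRanges::end(rr), name = names(rr))
  write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(bin = rownames(bins), genotypeCalls(bins),
                         check.names = FALSE),
              paste0(prefix, "_genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Write a genetic map and its summary as TSV
#'
#' @param map a [GeneticMap].
#' @param prefix output path prefix; writes `<prefix>_map.tsv` and
#'   `<prefix>_map_summary.tsv`.
#' @export
writeMap <- function(map, prefix) {
  write.table(mapTable(map), paste0(prefix, "_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(mapSummary(map), paste0(prefix, "_map_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
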