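#' Construct a SnpGenotypes object
#'
#' @param geno character matrix of calls (`"AA"`, `"AB"`, `"BB"`, `NA`; other
#'   tokens tolerated until filtering), rows = SNPs, columns = individuals.
#' @param chrom chromosome identifier per SNP.
#' @param pos 1-based physical position (bp) per SNP; must be strictly
#'   increasing within a chromosome.
#' @param snpId optional SNP identifiers (default `chrom_pos`).
#' @return A [SnpGenotypes] object.
#' @examples
#' g <- matrix(c("AA","AB","BB","AB"), 2, 2,
#'             dimnames = list(NULL, c("ind1","ind2")))
#' snpGenotypes(g, chrom = c("1","1"), pos = c(100L, 200L))
#' @export
snpGenotypes <- function(geno, chrom, pos, snpId = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "character"
  if (is.null(snpId)) snpId <- paste(chrom, pos, sep = "_")
  o <- order(factor(chrom, levels = unique(chrom)), pos)
  geno <- geno[o, , drop = FALSE]
  rr <- GenomicRanges::GRanges(chrom[o], IRanges::IRanges(pos[o], width = 1L))
  names(rr) <- snpId[o]
  rownames(geno) <- snpId[o]
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("ind", seq_len(ncol(geno)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno), rowRanges = rr)
  methods::new("SnpGenotypes", se)
}

newBinGenotypes <- function(geno, chrom, start, end, nSnps, gridStart, gridEnd) {
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  names(rr) <- paste0("mk", seq_along(rr))
  S4Vectors::mcols(rr)$nSnps <- nSnps
  S4Vectors::mcols(rr)$gridStart <- gridStart
  S4Vectors::mcols(rr)$gridEnd <- gridEnd
  rownames(geno) <- names(rr)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(geno = geno), rowRanges = rr)
  methods::new("BinGenotypes", se)
}

#' Genotype call matrix of a marker container
#'
#' @param x a [SnpGenotypes] or [BinGenotypes] object.
#' @return character matrix, rows = markers, columns = individuals.
#' @export
genotypeCalls <- function(x) SummarizedExperiment::assay(x, "geno")

#' Chromosome of each marker
#' @param x a [SnpGenotypes] or [BinGenotypes] object.
#' @export
markerChrom <- function(x)
  as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(x)))

#' Physical position (bp) of each marker (start for bins)
#' @param x a [SnpGenotypes] or [BinGenotypes] object.
#' @export
markerPos <- function(x)
  GenomicRanges::start(SummarizedExperiment::rowRanges(x))

#' Genetic map coordinate table
#' @param x a [GeneticMap].
#' @return data.frame with columns `bin`, `chrom`, `start`, `end`, `cM`, `rf`,
#'   `gap`.
#' @export
mapTable <- function(x) x@map

#' Scan result table
#' @param x a [ScanResult].
#' @export
scanTable <- function(x) x@table

#' Declaration threshold of a scan
#' @param x a [ScanResult].
#' @export
scanThreshold <- function(x) x@threshold

#' Block table of a BlockSet
#' @param x a [BlockSet].
#' @export
blockTable <- function(x) x@blocks

#' Breakpoint midpoints of a BlockSet
#'
#' The inferred recombination breakpoint between two consecutive blocks of one
#' individual is placed at the midpoint between the last SNP of the upstream
#' block and the first SNP of the downstream block.
#'
#' @param x a [BlockSet].
#' @return data.frame with columns `individual`, `chrom`, `pos`.
#' @export
breakpointMidpoints <- function(x) {
  b <- x@blocks
  out <- do.call(rbind, lapply(split(b, list(b$individual, b$chrom), drop = TRUE),
    function(d) {
      if (nrow(d) < 2) return(NULL)
      d <- d[order(d$start), ]
      data.frame(individual = d$individual[-1], chrom = d$chrom[-1],
                 pos = (d$end[-nrow(d)] + d$start[-1]) / 2)
    }))
  if (is.null(out))
    out <- data.frame(individual = character(), chrom = character(),
                      pos = numeric())
  rownames(out) <- NULL
  out
}
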