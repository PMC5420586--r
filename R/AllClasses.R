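#' @import methods
#' @importFrom stats pchisq optimize rnorm runif rpois rbinom var sd cor
#'   lm lm.fit lm.wfit quantile pt complete.cases setNames median dnorm pf
#'   coef approx qr.resid
#' @importFrom utils read.table write.table read.csv write.csv head tail
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment assay assay<- assayNames rowRanges
#' @importFrom S4Vectors metadata metadata<- mcols mcols<-
NULL

GENO_LEVELS <- c("AA", "AB", "BB")

#' SNP genotype container for a biparental F2 population
#'
#' `SnpGenotypes` holds per-SNP categorical calls for every individual of an
#' F2 population, with genomic coordinates in `rowRanges`.  Calls live in the
#' `"geno"` assay as a character matrix with values `"AA"` (P1 homozygote),
#' `"AB"` (heterozygote), `"BB"` (P2 homozygote) or `NA` (missing).  Tokens
#' outside this vocabulary are allowed on input (they model "abnormal base"
#' calls) and are removed by [filterMarkers()].
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [snpGenotypes()] for construction, [filterMarkers()],
#'   [callBlocks()].
#' @export
setClass("SnpGenotypes", contains = "RangedSummarizedExperiment")

#' Recombination-bin genotype container
#'
#' `BinGenotypes` holds complete (no-missing) genotypes at recombination bins:
#' genomic segments within which no recombination breakpoint was observed in
#' the whole population.  `rowRanges` are the bin spans trimmed to the first
#' and last constituent SNP; `rowData` records the number of constituent SNPs
#' and the 100-kb grid interval span each bin derives from.
#'
#' @seealso [buildBins()], [buildMap()], [cimScan()].
#' @export
setClass("BinGenotypes", contains = "RangedSummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    return("assay 'geno' is required")
  g <- SummarizedExperiment::assay(object, "geno")
  if (!is.character(g)) return("assay 'geno' must be a character matrix")
  pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(object))
  ch <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object)))
  bad <- unlist(lapply(split(pos, ch), function(p) any(diff(p) <= 0)))
  if (any(bad))
    return("SNP positions must be strictly increasing within each chromosome")
  TRUE
})

setValidity("BinGenotypes", function(object) {
  g <- SummarizedExperiment::assay(object, "geno")
  if (!is.character(g)) return("assay 'geno' must be a character matrix")
  if (any(is.na(g)) || !all(g %in% GENO_LEVELS))
    return("bin genotypes must be complete and in {AA, AB, BB}")
  TRUE
})

#' Per-individual genotype blocks from the sliding-window caller
#'
#' A `BlockSet` stores, for every individual and chromosome, the ordered runs
#' of identical consensus genotype produced by [callBlocks()], together with
#' the per-SNP consensus calls they were derived from.  Breakpoints between
#' consecutive blocks are placed at the midpoint between the last SNP of one
#' block and the first SNP of the next.
#'
#' @slot blocks data.frame with columns `individual`, `chrom`, `start`, `end`,
#'   `genotype` (bp coordinates of first/last constituent SNP).
#' @slot consensus named list (one element per chromosome) of lists with
#'   elements `pos` (SNP positions) and `geno` (SNP x individual consensus
#'   matrix).
#' @export
setClass("BlockSet", representation(blocks = "data.frame", consensus = "list"))

#' Genetic map of bin markers
#'
#' Cumulative Kosambi centimorgan coordinate per bin, anchored to physical
#' (reference-assembly) order.  Adjacent-bin recombination fractions are kept
#' for auditing.
#'
#' @slot map data.frame with columns `bin`, `chrom`, `start`, `end`, `cM`,
#'   `rf` (recombination fraction to the previous bin on the same chromosome,
#'   `NA` for the first bin) and `gap` (logical flag, rf >= 0.49).
#' @export
setClass("GeneticMap", representation(map = "data.frame"))

#' QTL genome-scan result
#'
#' @slot trait scanned trait name.
#' @slot method `"CIM"` or `"LASSO"`.
#' @slot table for CIM: one row per scan position with `chrom`, `cM`,
#'   `bp`, `lod`, `neglog10p`, `add`, `dom`, `r2`.  For LASSO: one row per
#'   bin and effect type with `chrom`, `bp`, `cM`, `type` ("A"/"D"),
#'   `effect`, `neglog10p`.
#' @slot threshold declaration threshold: permutation LOD threshold for CIM,
#'   `-log10(0.05)` for LASSO.
#' @export
setClass("ScanResult", representation(trait = "character", method = "character",
                                      table = "data.frame", threshold = "numeric"))

#' Ground truth of a simulated F2 population
#'
#' @slot gametes nested list: `gametes[[individual]][[chrom]]` is a list of two
#'   gametes, each with `origin0` (parental origin at the chromosome start,
#'   1 = P1, 2 = P2) and `xo` (sorted crossover positions in bp).
#' @slot genotypes true [SnpGenotypes] (noise-free calls at the simulated SNPs).
#' @slot qtl data.frame of simulated QTL: `trait`, `chrom`, `pos`, `a`, `d`.
#' @slot genome the genome specification used (see [genomeSpec()]).
#' @export
setClass("SimTruth", representation(gametes = "list", genotypes = "ANY",
                                    qtl = "data.frame", genome = "data.frame"))

setMethod("show", "BlockSet", function(object) {
  b <- object@blocks
  cat("BlockSet:", length(unique(b$individual)), "individuals,",
      length(unique(b$chrom)), "chromosomes,", nrow(b), "blocks\n")
})

setMethod("show", "GeneticMap", function(object) {
  m <- object@map
  cat("GeneticMap:", nrow(m), "bins on", length(unique(m$chrom)),
      "chromosomes,", sprintf("%.2f", sum(tapply(m$cM, m$chrom, max))), "cM total\n")
})

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s) for trait '%s': %d rows, threshold %.3g\n",
              object@method, object@trait, nrow(object@table), object@threshold))
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@gametes), "individuals,",
      nrow(object@genome), "chromosomes,", nrow(object@qtl), "QTL\n")
})
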