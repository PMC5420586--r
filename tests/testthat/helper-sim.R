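# Shared simulation scaffolding for the test suite.

smallGenome <- function(nChrom = 2, lengthBp = 2e7, lengthCM = 80,
                        snpsPerMb = 15) {
  genomeSpec(chrom = as.character(seq_len(nChrom)),
             lengthBp = rep_len(lengthBp, nChrom),
             lengthCM = rep_len(lengthCM, nChrom),
             snpsPerMb = snpsPerMb)
}

# The desk-scale recovery study: full 10-chromosome maize-like genome at one
# tenth physical size and one quarter genetic length, three QTL on one trait
# explaining 8, 12 and 18 percent of the phenotypic variance (d = a/2),
# total h2 = 0.38.
recoveryQtl <- function(genome) {
  a <- sqrt(c(0.08, 0.12, 0.18) / 0.5625)
  data.frame(trait = "KW", chrom = c("1", "4", "7"),
             pos = round(genome$lengthBp[c(1, 4, 7)] * c(0.4, 0.55, 0.45)),
             a = a, d = a / 2)
}

recoveryGenome <- function() maizeGenome(scaleBp = 0.1, scaleCM = 0.25,
                                         snpsPerMb = 10)

recoveryConfig <- function(genome, seed) {
  simConfig(nIndividuals = 199, missingRate = 0.1, errorRate = 0.01,
            hetUndercallRate = 0.1, qtl = recoveryQtl(genome), h2 = 0.38,
            seed = seed)
}

# cM coordinate of a physical position on an estimated map, by interpolation
# between bin centres
mapCmAt <- function(map, chrom, pos) {
  mc <- mapTable(map)
  mc <- mc[mc$chrom == chrom, ]
  stats::approx((mc$start + mc$end) / 2, mc$cM, xout = pos, rule = 2,
                ties = "ordered")$y
}

# true genotype matrix at bin midpoints
trueBinGenotypes <- function(truth, bins) {
  rr <- SummarizedExperiment::rowRanges(bins)
  mid <- (GenomicRanges::start(rr) + GenomicRanges::end(rr)) / 2
  ch <- as.character(GenomicRanges::seqnames(rr))
  t(vapply(seq_along(mid), function(i) trueGenotypeAt(truth, ch[i], mid[i]),
           character(ncol(bins))))
}

makeBins <- function(geno, chrom, start, end) {
  # direct BinGenotypes construction for unit tests
  binQTL:::newBinGenotypes(geno, chrom = chrom, start = start, end = end,
                           nSnps = rep(1L, length(chrom)),
                           gridStart = start, gridEnd = end)
}
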