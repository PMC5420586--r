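test_that("window genotype follows the 11-of-15 supermajority rule", {
  expect_equal(windowGenotype(rep("AA", 15)), "AA")
  expect_equal(windowGenotype(rep(c("AA", "BB"), c(11, 4))), "AA")
  expect_equal(windowGenotype(rep(c("BB", "AA"), c(11, 4))), "BB")
  expect_equal(windowGenotype(rep(c("AA", "BB"), c(10, 5))), "AB")
  expect_equal(windowGenotype(rep(c("AA", "BB"), c(8, 7))), "AB")
  # heterozygous calls split their weight between the parents
  expect_equal(windowGenotype(rep(c("AA", "AB"), c(8, 7))), "AA")  # 8+3.5 >= 11
  expect_equal(windowGenotype(rep(c("AA", "AB"), c(7, 8))), "AA")  # 7+4 = 11 exactly
  expect_equal(windowGenotype(rep(c("AA", "AB"), c(6, 9))), "AB")  # 6+4.5 < 11
  expect_equal(windowGenotype(rep("AB", 15)), "AB")
  # proportional threshold with missing data: 12 informative, cut at 8.8
  expect_equal(windowGenotype(rep(c("AA", "BB", NA), c(9, 3, 3))), "AA")
  expect_equal(windowGenotype(rep(c("AA", "BB", NA), c(8, 4, 3))), "AB")
  expect_true(is.na(windowGenotype(rep(NA_character_, 15))))
  # call counting variant ignores heterozygotes
  expect_equal(windowGenotype(rep(c("AA", "AB"), c(8, 7)), hetSplit = FALSE),
               "AB")
})

test_that("block calling recovers a single crossover and absorbs call errors", {
  pos <- seq(5e4, 3e6, by = 5e4)  # 60 SNPs
  n <- length(pos)
  clean <- matrix(rep(c("AA", "AB"), c(30, n - 30)), n, 1,
                  dimnames = list(NULL, "i1"))
  snp <- snpGenotypes(clean, chrom = rep("1", n), pos = pos)
  bs <- callBlocks(snp)
  b <- blockTable(bs)
  expect_equal(nrow(b), 2)
  expect_equal(b$genotype, c("AA", "AB"))
  # inferred breakpoint within one window-span of the true crossover
  mid <- breakpointMidpoints(bs)
  expect_lt(abs(mid$pos - (pos[30] + pos[31]) / 2), 15 * 5e4)

  # 1% genotype errors on a crossover-free chromosome leave one block
  set.seed(41)
  m <- matrix("AA", 200, 150)
  colnames(m) <- sprintf("i%03d", 1:150)
  flip <- which(matrix(runif(length(m)) < 0.01, nrow(m)))
  m[flip] <- sample(c("AB", "BB"), length(flip), replace = TRUE)
  snp2 <- snpGenotypes(m, chrom = rep("1", 200), pos = seq_len(200) * 1e4)
  b2 <- blockTable(callBlocks(snp2))
  expect_equal(nrow(b2), 150)
  expect_true(all(b2$genotype == "AA"))

  # zero-noise zero-crossover chromosome: one block spanning all SNPs
  m3 <- matrix("BB", 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  snp3 <- snpGenotypes(m3, chrom = rep("1", 30), pos = seq_len(30) * 1e5)
  b3 <- blockTable(callBlocks(snp3))
  expect_equal(nrow(b3), 3)
  expect_true(all(b3$start == 1e5 & b3$end == 30e5))
})

test_that("bins split at the 100-kb grid interval containing a breakpoint", {
  pos <- seq(5e4, 2.5e6, by = 5e4)
  n <- length(pos)
  # individual 1 crosses over between 1.20 and 1.25 Mb; the supermajority
  # rule calls the first heterozygous SNP for the old block, so the inferred
  # midpoint lands at 1.275 Mb; individual 2 has no crossover
  g <- cbind(i1 = rep(c("AA", "AB"), c(sum(pos <= 1.20e6), sum(pos > 1.20e6))),
             i2 = rep("AA", n))
  snp <- snpGenotypes(g, chrom = rep("1", n), pos = pos)
  bs <- callBlocks(snp)
  expect_equal(breakpointMidpoints(bs)$pos, 1.275e6)
  bins <- buildBins(bs)
  expect_equal(nrow(bins), 2)
  rd <- SummarizedExperiment::rowRanges(bins)
  expect_equal(S4Vectors::mcols(rd)$gridStart, c(0, 1.2e6))
  # trimmed to constituent SNPs; recombinant individual takes the genotype
  # right of the breakpoint in the opening interval
  expect_equal(genotypeCalls(bins)[, "i1"], c(mk1 = "AA", mk2 = "AB"))
  expect_equal(unname(genotypeCalls(bins)[, "i2"]), c("AA", "AA"))
})

test_that("bin count equals breakpoint-bearing grid intervals plus chromosomes", {
  gen <- smallGenome(nChrom = 2, lengthBp = 1e7, lengthCM = 60, snpsPerMb = 40)
  cfg <- simConfig(nIndividuals = 60, missingRate = 0, errorRate = 0,
                   hetUndercallRate = 0, seed = 55)
  sim <- simulateF2(gen, cfg)
  bs <- callBlocks(sim$genotypes)
  bins <- buildBins(bs)
  # independent brute-force construction from the breakpoint midpoints
  bp <- breakpointMidpoints(bs)
  expected <- 0L
  for (ch in c("1", "2")) {
    p <- bs@consensus[[ch]]$pos
    hot <- unique(floor(bp$pos[bp$chrom == ch] / 1e5))
    segs <- unique(findInterval(p, sort(hot) * 1e5))
    expected <- expected + length(segs)
  }
  expect_equal(nrow(bins), expected)
  # with dense markers every hot interval is populated, so the count is
  # (distinct hot intervals) + (number of chromosomes)
  nHot <- length(unique(paste(bp$chrom, floor(bp$pos / 1e5))))
  expect_equal(nrow(bins), nHot + 2L)
})

test_that("adding individuals only splits bins and noiseless bins are exact", {
  gen <- smallGenome(nChrom = 1, lengthBp = 1e7, lengthCM = 70, snpsPerMb = 40)
  cfg <- simConfig(nIndividuals = 40, missingRate = 0, errorRate = 0,
                   hetUndercallRate = 0, seed = 77)
  sim <- simulateF2(gen, cfg)
  snp <- sim$genotypes
  binsSub <- buildBins(callBlocks(snp[, 1:20]))
  binsAll <- buildBins(callBlocks(snp))
  gsSub <- S4Vectors::mcols(SummarizedExperiment::rowRanges(binsSub))$gridStart
  gsAll <- S4Vectors::mcols(SummarizedExperiment::rowRanges(binsAll))$gridStart
  expect_true(all(gsSub %in% gsAll))
  expect_gte(nrow(binsAll), nrow(binsSub))

  # near-exactness in the noiseless limit: the only disagreements with truth
  # come from the one-SNP boundary shift of the supermajority window rule at
  # each crossover, so agreement is essentially complete
  tru <- genotypeCalls(snp)
  pos <- markerPos(snp)
  rr <- SummarizedExperiment::rowRanges(binsAll)
  agree <- agreeBody <- total <- totalBody <- 0
  for (i in seq_along(rr)) {
    sel <- which(pos >= GenomicRanges::start(rr)[i] &
                 pos <= GenomicRanges::end(rr)[i])
    bg <- genotypeCalls(binsAll)[i, ]
    eq <- tru[sel, , drop = FALSE] == rep(bg, each = length(sel))
    agree <- agree + sum(eq); total <- total + length(eq)
    body <- pos[sel] >= S4Vectors::mcols(rr)$gridStart[i] + 1e5
    agreeBody <- agreeBody + sum(eq[body, ]); totalBody <- totalBody + sum(body) * ncol(eq)
  }
  expect_gt(agreeBody / totalBody, 0.995)
  expect_gt(agree / total, 0.99)
})

test_that("noiseless inferred breakpoints sit within 15 SNPs of a true crossover", {
  gen <- smallGenome(nChrom = 1, lengthBp = 1e7, lengthCM = 100, snpsPerMb = 40)
  cfg <- simConfig(nIndividuals = 100, missingRate = 0, errorRate = 0,
                   hetUndercallRate = 0, seed = 91)
  sim <- simulateF2(gen, cfg)
  bs <- callBlocks(sim$genotypes)
  bp <- breakpointMidpoints(bs)
  pos <- bs@consensus[["1"]]$pos
  hits <- misses <- 0
  for (ind in names(sim$truth@gametes)) {
    xo <- sort(unlist(lapply(sim$truth@gametes[[ind]][["1"]],
                             function(g) g$xo)))
    for (x in bp$pos[bp$individual == ind]) {
      near <- xo[abs(findInterval(xo, pos) - findInterval(x, pos)) <= 15]
      if (length(near)) hits <- hits + 1 else misses <- misses + 1
    }
  }
  expect_gt(hits / (hits + misses), 0.95)
})

test_that("bin summary reports lengths and per-chromosome counts", {
  bins <- makeBins(matrix(c("AA", "AB"), 1, 2,
                          dimnames = list(NULL, c("a", "b"))),
                   chrom = "1", start = 1e5, end = 4e5 - 1)
  s <- binSummary(bins)
  expect_equal(unname(s$length[c("min", "mean", "median", "max")]),
               rep(3e5, 4))
  expect_equal(s$perChrom$nBins, 1L)
})
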