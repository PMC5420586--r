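test_that("flanking-marker genotype probabilities match a Monte-Carlo oracle", {
  # degenerate interval: position on an observed bin
  expect_equal(qtlGenotypeProbs("AA", "BB", 0, 10), c(1, 0, 0))
  expect_equal(qtlGenotypeProbs("AB", "AA", 0, 3), c(0, 1, 0))
  # both flanks missing: Mendelian prior
  expect_equal(qtlGenotypeProbs(NA, NA, 5, 5), c(0.25, 0.5, 0.25))
  # normalization over random inputs
  set.seed(81)
  for (i in 1:200) {
    p <- qtlGenotypeProbs(sample(c("AA", "AB", "BB", NA), 1),
                          sample(c("AA", "AB", "BB", NA), 1),
                          runif(1, 0, 30), runif(1, 0, 30))
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # AA/AA flanks: monotone ordering
  p <- qtlGenotypeProbs("AA", "AA", 8, 8)
  expect_true(p[1] > p[2] && p[2] > p[3])
  # Monte-Carlo oracle: simulate gamete haplotype triples directly
  mcOracle <- function(gl, gr, rL, rR, n = 2e5) {
    hL <- sample(1:2, 2 * n, TRUE)
    hQ <- ifelse(runif(2 * n) < rL, 3 - hL, hL)
    hR <- ifelse(runif(2 * n) < rR, 3 - hQ, hQ)
    dim(hL) <- dim(hQ) <- dim(hR) <- c(n, 2)
    keep <- rowSums(hL) == gl & rowSums(hR) == gr
    tabulate(rowSums(hQ)[keep] - 1, 3) / sum(keep)
  }
  set.seed(82)
  for (cs in list(c(2, 2), c(2, 3), c(3, 4))) {
    dL <- 12; dR <- 7
    mc <- mcOracle(cs[1], cs[2], kosambiInv(dL), kosambiInv(dR))
    p <- qtlGenotypeProbs(c("AA", "AB", "BB")[cs[1] - 1],
                          c("AA", "AB", "BB")[cs[2] - 1], dL, dR)
    expect_lt(max(abs(p - mc)), 0.02)
  }
})

test_that("EM mixture likelihood is monotone and effects are the coefficients", {
  set.seed(83)
  n <- 120
  for (i in 1:10) {
    prior <- matrix(runif(n * 3), n, 3)
    prior <- prior / rowSums(prior)
    y <- rnorm(n) + prior %*% c(1, 0, -1) * 0.8
    fit <- fitQtlMixture(drop(y), cbind(rep(1, n)), prior)
    if (length(fit$trace) > 1)
      expect_gt(min(diff(fit$trace)), -1e-7)
  }
  expect_equal(unname(effectsFromMeans(10, 8, 4)), c(3, 1))
})

test_that("interval-mapping LOD at an observed marker equals single-marker ANOVA", {
  set.seed(84)
  n <- 150
  g <- sample(c("AA", "AB", "BB"), n, TRUE, c(.25, .5, .25))
  geno <- rbind(g, g)  # two identical bins 0 cM apart
  colnames(geno) <- sprintf("i%03d", 1:n)
  bins <- makeBins(geno, chrom = c("1", "1"), start = c(1e5, 2e5),
                   end = c(1.5e5, 2.5e5))
  mp <- buildMap(bins)
  x <- c(AA = 1, AB = 0, BB = -1)[g]; z <- as.numeric(g == "AB")
  y <- 0.4 * x + 0.2 * z + rnorm(n)
  ph <- data.frame(individual = colnames(geno), y = y)
  sc <- cimScan(bins, mp, ph, "y", step = 0)
  ss0 <- sum((y - mean(y))^2)
  ss1 <- sum(lm(y ~ x + z)$residuals^2)
  lodAnova <- n / 2 * log10(ss0 / ss1)
  expect_equal(scanTable(sc)$lod[1], lodAnova, tolerance = 1e-8)
  # effect estimates equal the genotype-class-mean formulas
  mAA <- mean(y[g == "AA"]); mAB <- mean(y[g == "AB"]); mBB <- mean(y[g == "BB"])
  expect_equal(scanTable(sc)$add[1], unname((mAA - mBB) / 2), tolerance = 1e-6)
  expect_equal(scanTable(sc)$dom[1], unname(mAB - (mAA + mBB) / 2),
               tolerance = 1e-6)
})

test_that("a constant trait scans flat and zero cofactors reduce to interval mapping", {
  set.seed(85)
  n <- 60
  geno <- matrix(sample(c("AA", "AB", "BB"), 5 * n, TRUE, c(.25, .5, .25)),
                 5, n, dimnames = list(NULL, sprintf("i%02d", 1:n)))
  bins <- makeBins(geno, chrom = rep("1", 5), start = (1:5) * 1e6,
                   end = (1:5) * 1e6 + 5e5)
  mp <- buildMap(bins)
  ph <- data.frame(individual = colnames(geno), flat = rep(2.5, n),
                   y = rnorm(n))
  expect_true(all(scanTable(cimScan(bins, mp, ph, "flat", step = 0))$lod == 0))
  s1 <- cimScan(bins, mp, ph, "y", cofactors = NULL, step = 0)
  s2 <- cimScan(bins, mp, ph, "y", cofactors = integer(0), step = 0)
  expect_equal(scanTable(s1), scanTable(s2))
})

test_that("stepwise cofactor selection finds a strong QTL bin first and respects the cap", {
  gen <- smallGenome(nChrom = 2, lengthBp = 1e7, lengthCM = 60, snpsPerMb = 15)
  firstNear <- vapply(1:10, function(seed) {
    qtl <- data.frame(trait = "y", chrom = "1", pos = 5e6, a = 0.65, d = 0)
    cfg <- simConfig(nIndividuals = 199, missingRate = 0, errorRate = 0,
                     hetUndercallRate = 0, qtl = qtl, h2 = 0.15, seed = 3000 + seed)
    sim <- simulateF2(gen, cfg)
    bins <- buildBins(callBlocks(sim$genotypes))
    ph <- simulatePhenotypes(sim$truth, cfg)
    sel <- selectCofactors(bins, ph, "y", maxCofactors = 5)
    expect_lte(length(sel), 5)
    rr <- SummarizedExperiment::rowRanges(bins)
    mid <- (GenomicRanges::start(rr) + GenomicRanges::end(rr)) / 2
    near <- which(markerChrom(bins) == "1" & abs(mid - 5e6) < 1.5e6)
    any(sel %in% near)
  }, logical(1))
  expect_gte(mean(firstNear), 0.9)
})

test_that("permutation threshold honours the quantile definition and the seed", {
  set.seed(86)
  n <- 80
  geno <- matrix(sample(c("AA", "AB", "BB"), 10 * n, TRUE, c(.25, .5, .25)),
                 10, n, dimnames = list(NULL, sprintf("i%02d", 1:n)))
  bins <- makeBins(geno, chrom = rep("1", 10), start = (1:10) * 1e6,
                   end = (1:10) * 1e6 + 5e5)
  mp <- buildMap(bins)
  ph <- data.frame(individual = colnames(geno), y = rnorm(n))
  t1 <- permutationThreshold(bins, mp, ph, "y", nPerm = 100, alpha = 0.05,
                             seed = 5)
  t2 <- permutationThreshold(bins, mp, ph, "y", nPerm = 100, alpha = 0.05,
                             seed = 5)
  expect_identical(t1, t2)
  tmin <- permutationThreshold(bins, mp, ph, "y", nPerm = 100, alpha = 1,
                               seed = 5)
  expect_equal(as.numeric(tmin), min(attr(t1, "maxima")))
  expect_equal(as.numeric(t1), sort(attr(t1, "maxima"))[95])
})

test_that("LASSO selection obeys soft-thresholding and KKT optimality", {
  # single standardized predictor: coefficient is soft(b_ols, lambda)
  set.seed(87)
  n <- 400
  x1 <- rnorm(n); x1 <- (x1 - mean(x1)) / sqrt(var(x1) * (n - 1) / n)
  x2 <- rnorm(n); x2 <- (x2 - mean(x2)) / sqrt(var(x2) * (n - 1) / n)
  y <- 2 * x1 + rnorm(n, 0, 0.01)
  fit <- glmnet::glmnet(cbind(x1, x2), y, lambda = 0.5, standardize = FALSE,
                        thresh = 1e-12)
  bOls <- sum(x1 * (y - mean(y))) / n
  expect_equal(as.numeric(coef(fit)[2]), bOls - 0.5, tolerance = 1e-3)
  # above lambda_max everything is zero
  fit0 <- glmnet::glmnet(cbind(x1, x2), y, lambda = 10, standardize = FALSE)
  expect_true(all(as.numeric(coef(fit0))[-1] == 0))

  # full scan: KKT subgradient conditions at the selected penalty
  gen <- smallGenome(nChrom = 2, lengthBp = 8e6, lengthCM = 50, snpsPerMb = 10)
  qtl <- data.frame(trait = "y", chrom = "1", pos = 4e6, a = 0.6, d = 0.3)
  cfg <- simConfig(nIndividuals = 199, missingRate = 0, errorRate = 0,
                   hetUndercallRate = 0, qtl = qtl, h2 = 0.2, seed = 88)
  sim <- simulateF2(gen, cfg)
  bins <- buildBins(callBlocks(sim$genotypes))
  ph <- simulatePhenotypes(sim$truth, cfg)
  sc <- lassoScan(bins, ph, "y", seed = 89)
  cv <- attr(scanTable(sc), "fit")
  y2 <- ph$y[match(colnames(bins), ph$individual)]
  cd <- binQTL:::genoCodes(bins)
  X <- cbind(t(cd$x), t(cd$z))
  colnames(X) <- c(paste0(rownames(bins), "_A"), paste0(rownames(bins), "_D"))
  X <- X[, apply(X, 2, var) > 0]
  n2 <- nrow(X)
  Xs <- scale(X, scale = apply(X, 2, function(v) sqrt(var(v) * (n2 - 1) / n2)))
  beta <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  betaStd <- beta * attr(Xs, "scaled:scale")
  resid <- y2 - mean(y2) - drop(Xs %*% betaStd)
  grad <- crossprod(Xs, resid) / n2
  lam <- cv$lambda.min
  expect_true(all(abs(grad[betaStd == 0]) <= lam + 1e-3))
  expect_true(all(abs(grad[betaStd != 0] - lam * sign(betaStd[betaStd != 0]))
                  < 1e-3))
  # the simulated QTL bin (or a close neighbour) carries a declared signal
  hits <- callQtl(sc, bins, buildMap(bins))
  expect_gt(nrow(hits), 0)
  expect_true(any(hits$chrom == "1" & abs(hits$peakBp - 4e6) < 2e6))
})

test_that("QTL calling merges nearby peaks and brackets them with flanking bins", {
  geno <- matrix("AA", 30, 2, dimnames = list(NULL, c("a", "b")))
  geno[, 2] <- "BB"
  bins <- makeBins(geno, chrom = rep("1", 30), start = (1:30) * 1e6,
                   end = (1:30) * 1e6 + 9e5)
  m <- data.frame(bin = rownames(bins), chrom = "1",
                  start = (1:30) * 1e6, end = (1:30) * 1e6 + 9e5,
                  cM = seq(0, 58, by = 2), rf = NA, gap = FALSE)
  mp <- methods::new("GeneticMap", map = m)
  mkScan <- function(lod) {
    methods::new("ScanResult", trait = "T", method = "CIM",
                 table = data.frame(chrom = "1", cM = m$cM, bp = m$start,
                                    lod = lod, neglog10p = lod, add = 1,
                                    dom = 0, r2 = 5, emMinStep = 0),
                 threshold = 3)
  }
  # nothing above threshold
  expect_equal(nrow(callQtl(mkScan(rep(1, 30)), bins, mp)), 0)
  # two peaks 6 cM apart merge into one QTL; 30 cM apart stay separate
  lod <- rep(0.5, 30); lod[10] <- 5; lod[13] <- 4.5
  h1 <- callQtl(mkScan(lod), bins, mp)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$peakCM, m$cM[10])
  lod2 <- rep(0.5, 30); lod2[5] <- 5; lod2[20] <- 4.5
  h2 <- callQtl(mkScan(lod2), bins, mp)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$qtl, c("qT-1", "qT-2"))
  # support interval flanks bracket the peak
  expect_true(all(h2$intervalStartBp <= h2$peakBp &
                  h2$intervalEndBp >= h2$peakBp))
  # Table-style column layout
  expect_true(all(c("trait", "qtl", "chrom", "flankLeft", "flankRight",
                    "stat", "add", "dom", "r2") %in% names(h2)))
})
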