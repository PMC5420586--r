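## Composite interval mapping and LASSO scans on a bin map.
##
## The mixture likelihood at a tested position treats the unobserved QTL
## genotype as latent with prior probabilities conditional on the flanking
## bin genotypes (two-locus, no-interference F2 transition model); the EM
## fit alternates posterior weighting and weighted least squares.

transProb <- function(a, b, r) ifelse(a == b, 1 - r, r)

flankProbArray <- function(rL, rR) {
  h <- as.matrix(expand.grid(hL = 1:2, hQ = 1:2, hR = 1:2))
  hp <- 0.5 * transProb(h[, 1], h[, 2], rL) * transProb(h[, 2], h[, 3], rR)
  arr <- array(0, c(3, 3, 3))  # [gLeft, gQTL, gRight]
  for (i in 1:8) for (j in 1:8) {
    gl <- h[i, 1] + h[j, 1] - 1L
    gq <- h[i, 2] + h[j, 2] - 1L
    gr <- h[i, 3] + h[j, 3] - 1L
    arr[gl, gq, gr] <- arr[gl, gq, gr] + hp[i] * hp[j]
  }
  arr
}

#' Conditional QTL genotype probabilities from flanking markers
#'
#' Probabilities of the three QTL genotypes at a position between two
#' flanking markers, conditional on the observed flanking genotypes, under
#' the two-locus no-interference F2 transition model.  Map distances are
#' converted to recombination fractions with [kosambiInv()].  A missing flank
#' is marginalized out; with both flanks missing the prior is the Mendelian
#' (1/4, 1/2, 1/4).
#'
#' @param gLeft,gRight flanking genotypes (`AA`/`AB`/`BB` or `NA`).
#' @param dLeft,dRight map distances (cM) to the left and right flank, >= 0.
#' @return numeric vector `c(QQ, Qq, qq)` summing to 1 (QQ = P1 homozygote).
#' @export
qtlGenotypeProbs <- function(gLeft, gRight, dLeft, dRight) {
  stopifnot(dLeft >= 0, dRight >= 0)
  arr <- flankProbArray(kosambiInv(dLeft), kosambiInv(dRight))
  gl <- match(gLeft, GENO_LEVELS)
  gr <- match(gRight, GENO_LEVELS)
  sl <- if (is.na(gl)) 1:3 else gl
  sr <- if (is.na(gr)) 1:3 else gr
  p <- apply(arr[sl, , sr, drop = FALSE], 2, sum)
  p / sum(p)
}

genoCodes <- function(bins) {
  g <- genotypeCalls(bins)
  list(x = (g == "AA") - (g == "BB"), z = (g == "AB") * 1)
}

gaussLogLik <- function(rss, n) -n / 2 * (log(2 * pi * rss / n) + 1)

#' Fit the 3-component QTL mixture regression by EM
#'
#' Fits `y = X0 beta + a x* + d z* + e` where `x* in {+1,0,-1}` and
#' `z* in {0,1}` are coded from the unobserved QTL genotype with prior
#' probabilities `prior` (rows = individuals, columns = QQ/Qq/qq).  The
#' E-step computes posterior genotype weights; the M-step is
#' posterior-weighted least squares; the observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param y numeric response.
#' @param X0 covariate matrix including the intercept column.
#' @param prior n x 3 prior probability matrix.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param maxit maximum EM iterations (default 100).
#' @return list: `coef` (covariate coefficients, then `a`, `d`), `sigma2`,
#'   `logLik`, `trace` (per-iteration log-likelihood), `posterior`,
#'   `converged`, `rss` (posterior-weighted residual sum of squares).
#' @export
fitQtlMixture <- function(y, X0, prior, tol = 1e-8, maxit = 100) {
  n <- length(y)
  xg <- c(1, 0, -1); zg <- c(0, 1, 0)
  Xs <- rbind(X0, X0, X0)
  Xs <- cbind(Xs, a = rep(xg, each = n), d = rep(zg, each = n))
  ys <- rep(y, 3)
  w <- prior
  ll <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    fit <- lm.wfit(Xs, ys, as.vector(w) + 1e-12)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    mu <- matrix(drop(Xs %*% cf), n, 3)
    resid2 <- (y - mu)^2
    sigma2 <- sum(w * resid2) / n
    dens <- prior * exp(-resid2 / (2 * sigma2)) / sqrt(2 * pi * sigma2)
    rs <- rowSums(dens)
    llNew <- sum(log(rs + 1e-300))
    trace <- c(trace, llNew)
    w <- dens / (rs + 1e-300)
    if (is.finite(ll) && abs(llNew - ll) < tol) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  p <- ncol(Xs)
  list(coef = cf, a = unname(cf[p - 1]), d = unname(cf[p]), sigma2 = sigma2,
       logLik = ll, trace = trace, posterior = w,
       converged = length(trace) < maxit, rss = sum(w * resid2))
}

#' Additive and dominance effects from genotype-class means
#'
#' `a = (mean(QQ) - mean(qq))/2` (positive when the P1 allele increases the
#' trait) and `d = mean(Qq) - (mean(QQ) + mean(qq))/2`.
#'
#' @param mQQ,mQq,mqq genotype-class means.
#' @return named vector `c(a = ..., d = ...)`.
#' @examples
#' effectsFromMeans(10, 8, 4)  # a = 3, d = 1
#' @export
effectsFromMeans <- function(mQQ, mQq, mqq)
  c(a = (mQQ - mqq) / 2, d = mQq - (mQQ + mqq) / 2)

matchPhenotype <- function(bins, pheno, trait) {
  stopifnot(trait %in% names(pheno))
  idx <- match(colnames(bins), pheno$individual)
  y <- pheno[[trait]][idx]
  ok <- !is.na(y)
  list(y = y[ok], cols = which(ok))
}

scanGrid <- function(map, step) {
  m <- mapTable(map)
  do.call(rbind, lapply(split(m, factor(m$chrom, unique(m$chrom))),
    function(d) {
      cm <- d$cM
      pos <- if (step > 0)
        sort(unique(c(cm, seq(0, max(cm), by = step)))) else cm
      data.frame(chrom = d$chrom[1], cM = pos)
    }))
}

positionPrior <- function(gchr, cmBins, pos, tol = 1e-8) {
  # gchr: genotype matrix (bins on one chromosome x individuals)
  hit <- which(abs(cmBins - pos) < tol)
  n <- ncol(gchr)
  if (length(hit)) {
    g <- gchr[hit[1], ]
    pr <- matrix(0, n, 3)
    code <- match(g, GENO_LEVELS)
    miss <- is.na(code)
    pr[cbind(which(!miss), code[!miss])] <- 1
    pr[miss, ] <- rep(c(0.25, 0.5, 0.25), each = sum(miss))
    return(pr)
  }
  li <- findInterval(pos, cmBins)
  ri <- li + 1L
  arr <- flankProbArray(kosambiInv(pos - cmBins[li]),
                        kosambiInv(cmBins[ri] - pos))
  gl <- match(gchr[li, ], GENO_LEVELS)
  gr <- match(gchr[ri, ], GENO_LEVELS)
  flat <- matrix(aperm(arr, c(1, 3, 2)), 9, 3)  # row = (gl, gr) pair
  pr <- matrix(NA_real_, n, 3)
  ok <- !is.na(gl) & !is.na(gr)
  pr[ok, ] <- flat[(gr[ok] - 1L) * 3L + gl[ok], , drop = FALSE]
  if (any(!ok)) for (i in which(!ok))
    pr[i, ] <- qtlGenotypeProbs(gchr[li, i], gchr[ri, i],
                                pos - cmBins[li], cmBins[ri] - pos)
  pr / rowSums(pr)
}

activeCofactorCols <- function(cof, m, chrom, pos, window) {
  if (length(cof) == 0) return(integer(0))
  drop <- m$chrom[cof] == chrom & abs(m$cM[cof] - pos) < window
  cof[!drop]
}

#' Composite interval mapping scan
#'
#' Scans the genome on a cM grid (the bin positions plus, when `step > 0`,
#' intermediate positions every `step` cM).  At each position, cofactor bins
#' closer than `window` cM on the same chromosome are excluded, the
#' three-component mixture regression is fitted by EM ([fitQtlMixture()]),
#' and the LOD score is the log10 likelihood ratio against the same model
#' without the QTL term.  `-log10(p)` uses the chi-square df = 2
#' approximation of `2 ln(10) LOD`; the permutation threshold, not this
#' p-value, is the declaration criterion.
#'
#' @param bins a [BinGenotypes].
#' @param map the matching [GeneticMap].
#' @param pheno phenotype data.frame (`individual` + trait columns).
#' @param trait trait column to scan.
#' @param cofactors integer indices of cofactor bins (see
#'   [selectCofactors()]); `NULL` or empty gives plain interval mapping.
#' @param step scan step in cM; `0` scans at the bin markers only.
#' @param window cofactor exclusion window in cM (default 10).
#' @param threshold optional declaration threshold to store in the result.
#' @param tol,maxit EM controls.
#' @return a [ScanResult]; its table has one row per scan position with
#'   `lod`, `neglog10p`, `add`, `dom`, `r2` and an `emMinStep` column giving
#'   the smallest between-iteration log-likelihood change (never materially
#'   negative).
#' @export
cimScan <- function(bins, map, pheno, trait, cofactors = NULL, step = 1,
                    window = 10, threshold = NA_real_, tol = 1e-8,
                    maxit = 100) {
  mp <- matchPhenotype(bins, pheno, trait)
  y <- mp$y
  n <- length(y)
  g <- genotypeCalls(bins)[, mp$cols, drop = FALSE]
  m <- mapTable(map)
  stopifnot(nrow(m) == nrow(g))
  grid <- scanGrid(map, step)
  tss <- sum((y - mean(y))^2)
  constTrait <- tss < 1e-12
  rows <- vector("list", nrow(grid))
  cd <- genoCodes(bins)
  xAll <- cd$x[, mp$cols, drop = FALSE]
  zAll <- cd$z[, mp$cols, drop = FALSE]
  nullCache <- new.env()
  for (k in seq_len(nrow(grid))) {
    ch <- grid$chrom[k]; pos <- grid$cM[k]
    if (constTrait) {
      rows[[k]] <- data.frame(chrom = ch, cM = pos, bp = NA_real_, lod = 0,
                              neglog10p = 0, add = 0, dom = 0, r2 = 0,
                              emMinStep = 0)
      next
    }
    act <- activeCofactorCols(cofactors, m, ch, pos, window)
    X0 <- cbind(`(Intercept)` = rep(1, n))
    if (length(act))
      X0 <- cbind(X0, t(xAll[act, , drop = FALSE]), t(zAll[act, , drop = FALSE]))
    key <- paste0("c", paste(act, collapse = ","))
    if (is.null(nullCache[[key]])) {
      f0 <- lm.fit(X0, y)
      nullCache[[key]] <- list(rss = sum(f0$residuals^2))
    }
    rss0 <- nullCache[[key]]$rss
    ll0 <- gaussLogLik(rss0, n)
    sel <- which(m$chrom == ch)
    prior <- positionPrior(g[sel, , drop = FALSE], m$cM[sel], pos)
    fit <- fitQtlMixture(y, X0, prior, tol = tol, maxit = maxit)
    lod <- max(0, (fit$logLik - ll0) / log(10))
    bp <- approxPhys(m[sel, ], pos)
    rows[[k]] <- data.frame(
      chrom = ch, cM = pos, bp = bp, lod = lod,
      neglog10p = -pchisq(2 * log(10) * lod, df = 2, lower.tail = FALSE,
                          log.p = TRUE) / log(10),
      add = fit$a, dom = fit$d,
      r2 = 100 * max(0, rss0 - fit$rss) / tss,
      emMinStep = if (length(fit$trace) > 1) min(diff(fit$trace)) else 0)
  }
  methods::new("ScanResult", trait = trait, method = "CIM",
               table = do.call(rbind, c(rows, make.row.names = FALSE)),
               threshold = threshold)
}

approxPhys <- function(mchr, pos) {
  # physical coordinate of a cM position by interpolation between bin centres
  mid <- (mchr$start + mchr$end) / 2
  if (nrow(mchr) == 1) return(mid[1])
  stats::approx(mchr$cM, mid, xout = pos, rule = 2, ties = "ordered")$y
}

#' Forward-backward stepwise cofactor selection
#'
#' Selects background marker cofactors for composite interval mapping by
#' stepwise regression on single-bin additive + dominance terms: at each
#' forward step the bin with the smallest partial-F p-value below
#' `alphaEnter` joins the model (each bin contributes its additive and
#' dominance column as a pair, df = 2); backward steps remove any included
#' bin whose partial-F p-value rises above `alphaStay`.  Selection stops at
#' `maxCofactors`.
#'
#' @param bins a [BinGenotypes].
#' @param pheno phenotype data.frame.
#' @param trait trait column.
#' @param maxCofactors cap on the number of cofactor bins (default 5).
#' @param alphaEnter,alphaStay entry/stay significance levels (default 0.05).
#' @return integer vector of selected bin indices (possibly empty, in which
#'   case the scan degenerates to simple interval mapping).
#' @export
selectCofactors <- function(bins, pheno, trait, maxCofactors = 5,
                            alphaEnter = 0.05, alphaStay = 0.05) {
  mp <- matchPhenotype(bins, pheno, trait)
  y <- mp$y
  n <- length(y)
  if (var(y) < 1e-12) stop("trait is constant")
  cd <- genoCodes(bins)
  xAll <- t(cd$x[, mp$cols, drop = FALSE])
  zAll <- t(cd$z[, mp$cols, drop = FALSE])
  M <- ncol(xAll)
  sel <- integer(0)
  partialP <- function(model, cand) {
    # p-value of the df-2 partial F test for adding bin `cand` to `model`
    X <- cbind(1, xAll[, model, drop = FALSE], zAll[, model, drop = FALSE])
    q <- qr(X)
    ry <- qr.resid(q, y)
    rx <- qr.resid(q, xAll[, cand]); rz <- qr.resid(q, zAll[, cand])
    G <- rbind(c(sum(rx * rx), sum(rx * rz)), c(sum(rx * rz), sum(rz * rz)))
    rhs <- c(sum(rx * ry), sum(rz * ry))
    if (abs(det(G)) < 1e-10) return(1)
    drop <- sum(solve(G, rhs) * rhs)
    rssCur <- sum(ry^2)
    dfRes <- n - q$rank - 2
    if (dfRes < 1 || rssCur - drop <= 0) return(1)
    f <- (drop / 2) / ((rssCur - drop) / dfRes)
    pf(f, 2, dfRes, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    if (length(sel) < maxCofactors) {
      cands <- setdiff(seq_len(M), sel)
      ps <- vapply(cands, function(j) partialP(sel, j), numeric(1))
      if (min(ps) < alphaEnter) {
        sel <- c(sel, cands[which.min(ps)])
        changed <- TRUE
      }
    }
    if (length(sel) > 1) {
      ps <- vapply(seq_along(sel), function(i)
        partialP(sel[-i], sel[i]), numeric(1))
      worst <- which.max(ps)
      if (ps[worst] > alphaStay) {
        sel <- sel[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(sel)
}

#' Genome-wide permutation threshold for CIM
#'
#' Permutes trait values across individuals (genotypes fixed, cofactor set
#' frozen), records the genome-wide maximum LOD of each permuted scan, and
#' returns the empirical `1 - alpha` quantile.  Permuted scans use
#' Haley-Knott regression on the expected QTL genotype codes, which at fully
#' observed bin markers coincides exactly with the EM mixture LOD (bins carry
#' complete genotypes), and is vectorized over all permutations.
#'
#' @param bins,map,pheno,trait,cofactors,step,window as in [cimScan()].
#' @param nPerm number of permutations (>= 100; the reference analysis used
#'   1,000).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed RNG seed for the permutations.
#' @return the LOD threshold, with the per-permutation maxima in
#'   `attr(, "maxima")`.
#' @export
permutationThreshold <- function(bins, map, pheno, trait, cofactors = NULL,
                                 nPerm = 1000, alpha = 0.05, seed = NULL,
                                 step = 0, window = 10) {
  stopifnot(nPerm >= 100 || alpha == 1)
  if (!is.null(seed)) set.seed(seed)
  mp <- matchPhenotype(bins, pheno, trait)
  y <- mp$y
  n <- length(y)
  Y <- vapply(seq_len(nPerm), function(i) y[sample.int(n)], numeric(n))
  mx <- scanMaxLod(bins, map, Y, mp$cols, cofactors, step, window)
  k <- max(1L, ceiling((1 - alpha) * nPerm))
  structure(sort(mx)[k], maxima = mx)
}

scanMaxLod <- function(bins, map, Y, cols, cofactors, step, window) {
  # Haley-Knott max-LOD per column of Y; exact at fully observed markers
  g <- genotypeCalls(bins)[, cols, drop = FALSE]
  m <- mapTable(map)
  n <- nrow(Y)
  grid <- scanGrid(map, step)
  cd <- genoCodes(bins)
  xAll <- cd$x[, cols, drop = FALSE]
  zAll <- cd$z[, cols, drop = FALSE]
  cs2 <- colSums(Y^2)
  csY <- colSums(Y)
  mx <- rep(-Inf, ncol(Y))
  q0cache <- new.env()
  for (k in seq_len(nrow(grid))) {
    ch <- grid$chrom[k]; pos <- grid$cM[k]
    act <- activeCofactorCols(cofactors, m, ch, pos, window)
    key <- paste0("c", paste(act, collapse = ","))
    if (is.null(q0cache[[key]])) {
      X0 <- cbind(rep(1, n))
      if (length(act))
        X0 <- cbind(X0, t(xAll[act, , drop = FALSE]),
                    t(zAll[act, , drop = FALSE]))
      Q0 <- qr.Q(qr(X0))
      q0cache[[key]] <- list(X0 = X0, Q0 = Q0,
                             rss0 = cs2 - colSums(crossprod(Q0, Y)^2))
    }
    cc <- q0cache[[key]]
    sel <- which(m$chrom == ch)
    prior <- positionPrior(g[sel, , drop = FALSE], m$cM[sel], pos)
    xbar <- drop(prior %*% c(1, 0, -1))
    zbar <- prior[, 2]
    Q1 <- qr.Q(qr(cbind(cc$X0, xbar, zbar)))
    rss1 <- cs2 - colSums(crossprod(Q1, Y)^2)
    lod <- n / 2 * log10(pmax(cc$rss0, 1e-300) / pmax(rss1, 1e-300))
    mx <- pmax(mx, lod)
  }
  pmax(mx, 0)
}

#' LASSO multi-locus QTL scan
#'
#' Builds the 2M-column design (additive codes `+1/0/-1` and dominance codes
#' `0/1` per bin, standardized internally), fits one joint L1-penalized
#' least-squares model with the penalty chosen by cross-validation at the
#' minimum CV error, then refits the selected columns by ordinary least
#' squares and reports a Wald `-log10(p)` per selected column (unselected
#' columns get p = 1).  Additive and dominance tests are reported as separate
#' tracks; the declaration threshold is `-log10(0.05) = 1.3`.
#'
#' @param bins a [BinGenotypes].
#' @param pheno phenotype data.frame.
#' @param trait trait column.
#' @param map optional [GeneticMap] to attach cM positions.
#' @param folds cross-validation folds (default 10).
#' @param seed RNG seed controlling fold assignment.
#' @return a [ScanResult] with method `"LASSO"`; the fitted `cv.glmnet`
#'   object is kept in `attr(scanTable(.), "fit")` for auditing.
#' @export
lassoScan <- function(bins, pheno, trait, map = NULL, folds = 10,
                      seed = NULL) {
  mp <- matchPhenotype(bins, pheno, trait)
  y <- mp$y
  n <- length(y)
  stopifnot(n >= 20)
  if (!is.null(seed)) set.seed(seed)
  cd <- genoCodes(bins)
  M <- nrow(cd$x)
  X <- cbind(t(cd$x[, mp$cols, drop = FALSE]), t(cd$z[, mp$cols, drop = FALSE]))
  colnames(X) <- c(paste0(rownames(bins), "_A"), paste0(rownames(bins), "_D"))
  keep <- which(apply(X, 2, var) > 0)
  foldid <- sample(rep_len(seq_len(folds), n))
  cv <- glmnet::cv.glmnet(X[, keep, drop = FALSE], y, foldid = foldid,
                          standardize = TRUE)
  beta <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  selNames <- names(beta)[beta != 0]
  pvals <- setNames(rep(1, ncol(X)), colnames(X))
  effects <- setNames(rep(0, ncol(X)), colnames(X))
  if (length(selNames)) {
    Xs <- X[, selNames, drop = FALSE]
    ols <- summary(lm(y ~ Xs))$coefficients
    rn <- sub("^Xs", "", rownames(ols))
    sel <- rn != "(Intercept)"
    pvals[rn[sel]] <- ols[sel, 4]
    effects[rn[sel]] <- ols[sel, 1]
  }
  rr <- SummarizedExperiment::rowRanges(bins)
  mid <- (GenomicRanges::start(rr) + GenomicRanges::end(rr)) / 2
  cm <- if (!is.null(map)) mapTable(map)$cM else rep(NA_real_, M)
  tab <- data.frame(
    bin = rep(rownames(bins), 2),
    chrom = rep(markerChrom(bins), 2),
    bp = rep(mid, 2), cM = rep(cm, 2),
    type = rep(c("A", "D"), each = M),
    effect = unname(effects), neglog10p = unname(-log10(pvals)))
  attr(tab, "fit") <- cv
  methods::new("ScanResult", trait = trait, method = "LASSO", table = tab,
               threshold = -log10(0.05))
}

#' Call QTL from a scan result
#'
#' For CIM scans: positions with LOD at or above the threshold are grouped
#' into peaks, peaks closer than `mergeCM` centimorgans on the same
#' chromosome are merged (the higher peak wins), and each QTL gets a
#' `lodDrop`-LOD support interval reported through its flanking bins and
#' their physical span.  For LASSO scans: every bin column with
#' `-log10(p)` at or above the threshold is a hit with its own bin as the
#' interval.  Names are assigned `q<TRAIT>-<k>` in genome order.
#'
#' @param scan a [ScanResult].
#' @param bins the [BinGenotypes] scanned.
#' @param map the [GeneticMap].
#' @param threshold overrides the threshold stored in `scan`.
#' @param mergeCM peak-merge radius in cM (default 20).
#' @param lodDrop support-interval LOD drop (default 1.5).
#' @return data.frame of QTL hits (possibly empty): `trait`, `qtl`, `chrom`,
#'   `peakCM`, `peakBp`, `flankLeft`, `flankRight`, `intervalStartBp`,
#'   `intervalEndBp`, `lengthMb`, `stat` (LOD or `-log10(p)`), `add`, `dom`,
#'   `r2`, `type`, `method`.
#' @export
callQtl <- function(scan, bins, map, threshold = NULL, mergeCM = 20,
                    lodDrop = 1.5) {
  thr <- if (!is.null(threshold)) threshold else scan@threshold
  stopifnot(is.finite(thr))
  m <- mapTable(map)
  empty <- data.frame(trait = character(), qtl = character(),
                      chrom = character(), peakCM = numeric(),
                      peakBp = numeric(), flankLeft = character(),
                      flankRight = character(), intervalStartBp = numeric(),
                      intervalEndBp = numeric(), lengthMb = numeric(),
                      stat = numeric(), add = numeric(), dom = numeric(),
                      r2 = numeric(), type = character(), method = character())
  hits <- list()
  if (scan@method == "CIM") {
    tab <- scanTable(scan)
    for (ch in unique(tab$chrom)) {
      d <- tab[tab$chrom == ch, ]
      d <- d[order(d$cM), ]
      above <- d$lod >= thr
      if (!any(above)) next
      runs <- rle(above)
      ends <- cumsum(runs$lengths); starts <- c(1L, head(ends, -1L) + 1L)
      peaks <- integer(0)
      for (ri in which(runs$values)) {
        idx <- starts[ri]:ends[ri]
        peaks <- c(peaks, idx[which.max(d$lod[idx])])
      }
      # merge peaks closer than mergeCM, keeping the higher one
      peaks <- peaks[order(d$cM[peaks])]
      repeat {
        if (length(peaks) < 2) break
        gaps <- diff(d$cM[peaks])
        j <- which(gaps < mergeCM)
        if (!length(j)) break
        j <- j[1]
        drop <- if (d$lod[peaks[j]] >= d$lod[peaks[j + 1]]) j + 1 else j
        peaks <- peaks[-drop]
      }
      mc <- m[m$chrom == ch, ]
      for (pk in peaks) {
        lim <- d$lod[pk] - lodDrop
        li <- pk; while (li > 1 && d$lod[li - 1] >= lim) li <- li - 1
        riX <- pk; while (riX < nrow(d) && d$lod[riX + 1] >= lim) riX <- riX + 1
        cmL <- d$cM[li]; cmR <- d$cM[riX]
        fl <- max(1, sum(mc$cM <= cmL + 1e-9))
        fr <- which(mc$cM >= cmR - 1e-9)[1]
        if (is.na(fr)) fr <- nrow(mc)
        hits[[length(hits) + 1L]] <- data.frame(
          trait = scan@trait, qtl = NA_character_, chrom = ch,
          peakCM = d$cM[pk], peakBp = d$bp[pk],
          flankLeft = mc$bin[fl], flankRight = mc$bin[fr],
          intervalStartBp = mc$start[fl], intervalEndBp = mc$end[fr],
          lengthMb = (mc$end[fr] - mc$start[fl]) / 1e6,
          stat = d$lod[pk], add = d$add[pk], dom = d$dom[pk], r2 = d$r2[pk],
          type = "AD", method = "CIM")
      }
    }
  } else {
    tab <- scanTable(scan)
    sel <- which(tab$neglog10p >= thr)
    for (i in sel) {
      bi <- match(tab$bin[i], m$bin)
      hits[[length(hits) + 1L]] <- data.frame(
        trait = scan@trait, qtl = NA_character_, chrom = tab$chrom[i],
        peakCM = tab$cM[i], peakBp = tab$bp[i],
        flankLeft = tab$bin[i], flankRight = tab$bin[i],
        intervalStartBp = m$start[bi], intervalEndBp = m$end[bi],
        lengthMb = (m$end[bi] - m$start[bi]) / 1e6,
        stat = tab$neglog10p[i], add = NA_real_, dom = NA_real_,
        r2 = NA_real_, type = tab$type[i], method = "LASSO")
      hits[[length(hits)]]$add <- if (tab$type[i] == "A") tab$effect[i] else NA
      hits[[length(hits)]]$dom <- if (tab$type[i] == "D") tab$effect[i] else NA
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, c(hits, make.row.names = FALSE))
  chOrder <- unique(m$chrom)
  out <- out[order(match(out$chrom, chOrder), out$peakCM), ]
  out$qtl <- paste0("q", scan@trait, "-", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
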