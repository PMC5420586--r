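#' Consensus genotype of one window of SNP calls
#'
#' Parental allele scores: an `AA` call contributes 1 to the P1 score, `BB`
#' 1 to the P2 score, and a heterozygous `AB` call half to each (the allele
#' ratio reading of window genotyping; `hetSplit = FALSE` switches to call
#' counting where `AB` contributes to neither).  With the nominal 15-SNP
#' window, a score of 11 or more for either parent calls the window
#' homozygous for that parent; anything less is heterozygous.  Windows with
#' missing calls scale the threshold proportionally
#' (`homMin/windowSize` of the non-missing count).
#'
#' @param calls character vector of window calls (`AA`/`AB`/`BB`/`NA`).
#' @param windowSize nominal window size (default 15).
#' @param homMin homozygosity threshold at full window (default 11).
#' @param hetSplit logical; split heterozygous calls between parents.
#' @return `"AA"`, `"AB"`, `"BB"`, or `NA` when the window has no
#'   non-missing call (genotype deferred to block merging).
#' @examples
#' windowGenotype(rep("AA", 15))                      # "AA"
#' windowGenotype(c(rep("AA", 11), rep("BB", 4)))     # "AA"
#' windowGenotype(c(rep("AA", 8), rep("BB", 7)))      # "AB"
#' @export
windowGenotype <- function(calls, windowSize = 15, homMin = 11,
                           hetSplit = TRUE) {
  h <- if (hetSplit) 0.5 else 0
  sA <- sum(calls == "AA", na.rm = TRUE) + h * sum(calls == "AB", na.rm = TRUE)
  sB <- sum(calls == "BB", na.rm = TRUE) + h * sum(calls == "AB", na.rm = TRUE)
  m <- sum(calls %in% GENO_LEVELS)
  if (m == 0) return(NA_character_)
  thr <- (homMin / windowSize) * m - 1e-9
  if (sA >= thr) return("AA")
  if (sB >= thr) return("BB")
  "AB"
}

rollSum <- function(x, w) {
  cs <- rbind(0, apply(x, 2, cumsum))
  cs[(w + 1):nrow(cs), , drop = FALSE] - cs[1:(nrow(cs) - w), , drop = FALSE]
}

fillRuns <- function(v) {
  # fill NA runs from the upstream non-NA value, else downstream
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (length(idx) == 0) return(v)
  f <- findInterval(seq_along(v), idx)
  v[idx[pmax(f, 1L)]]
}

#' Sliding-window consensus genotypes and block segmentation
#'
#' Scans each chromosome of each individual with a window of `windowSize`
#' SNPs and step 1, assigns each SNP the genotype of the window centred on it
#' (chromosome ends reuse the nearest complete window; chromosomes with fewer
#' SNPs than the window are governed by one truncated window), fills windows
#' with no data from their upstream neighbour, and merges runs of identical
#' per-SNP genotypes into blocks.  Adjacent blocks with different genotypes
#' mark a recombination breakpoint, located at the midpoint between the two
#' flanking SNPs.
#'
#' @param snp a filtered [SnpGenotypes].
#' @param windowSize window size in SNPs (default 15).
#' @param homMin homozygosity threshold at full window (default 11).
#' @param hetSplit see [windowGenotype()].
#' @return a [BlockSet].
#' @export
callBlocks <- function(snp, windowSize = 15, homMin = 11, hetSplit = TRUE) {
  g <- genotypeCalls(snp)
  if (nrow(g) == 0) stop("no markers to scan")
  chs <- markerChrom(snp)
  pos <- markerPos(snp)
  inds <- colnames(g)
  h <- if (hetSplit) 0.5 else 0
  consensus <- list()
  blocks <- list()
  for (ch in unique(chs)) {
    sel <- which(chs == ch)
    gc <- g[sel, , drop = FALSE]
    p <- pos[sel]
    n <- nrow(gc)
    w <- min(windowSize, n)
    A <- (gc == "AA") + h * (gc == "AB"); A[is.na(A)] <- 0
    B <- (gc == "BB") + h * (gc == "AB"); B[is.na(B)] <- 0
    M <- matrix(as.numeric(gc %in% GENO_LEVELS), n)
    sA <- rollSum(A, w); sB <- rollSum(B, w); m <- rollSum(M, w)
    thr <- (homMin / windowSize) * m - 1e-9
    call <- matrix("AB", nrow(sA), ncol(sA))
    call[sB >= thr] <- "BB"
    call[sA >= thr] <- "AA"
    call[m == 0] <- NA_character_
    # per-SNP consensus: window centred on the SNP, clamped at the ends
    widx <- pmin(pmax(seq_len(n) - (ceiling(windowSize / 2) - 1L), 1L), nrow(call))
    cons <- call[widx, , drop = FALSE]
    cons <- apply(cons, 2, fillRuns)
    if (!is.matrix(cons)) cons <- matrix(cons, nrow = n)
    dimnames(cons) <- list(rownames(gc), inds)
    consensus[[ch]] <- list(pos = p, geno = cons)
    for (j in seq_along(inds)) {
      r <- rle(cons[, j])
      if (anyNA(r$values)) next  # whole chromosome missing for this individual
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1L) + 1L)
      blocks[[length(blocks) + 1L]] <- data.frame(
        individual = inds[j], chrom = ch,
        start = p[starts], end = p[ends], genotype = r$values)
    }
  }
  methods::new("BlockSet", blocks = do.call(rbind, blocks),
               consensus = consensus)
}

#' Build recombination-bin markers from block sets
#'
#' Partitions each chromosome into a fixed physical grid (100-kb intervals by
#' default, anchored at coordinate 0, half-open).  A grid interval is "hot"
#' when at least one individual's breakpoint midpoint falls in it; each hot
#' interval opens a new bin (the breakpoint interval is assigned to the
#' downstream bin), and maximal runs of recombination-free intervals extend
#' it.  Within a bin every SNP segregates identically in the whole
#' population, so the bin acts as one marker; its per-individual genotype is
#' the consensus genotype of its constituent SNPs (taken right of any
#' breakpoint in the opening interval).  Bin coordinates are trimmed to the
#' first and last constituent SNP, which is why bins can be shorter than one
#' grid interval.
#'
#' @param blockSet a [BlockSet] from [callBlocks()].
#' @param interval grid interval size in bp (default 1e5).
#' @return a [BinGenotypes].
#' @export
buildBins <- function(blockSet, interval = 1e5) {
  bp <- breakpointMidpoints(blockSet)
  rows <- list()
  genoRows <- list()
  for (ch in names(blockSet@consensus)) {
    cons <- blockSet@consensus[[ch]]
    p <- cons$pos
    hot <- sort(unique(floor(bp$pos[bp$chrom == ch] / interval)))
    bounds <- hot * interval
    binIdx <- findInterval(p, bounds) + 1L
    for (b in unique(binIdx)) {
      sel <- which(binIdx == b)
      geno <- cons$geno[sel[length(sel)], ]
      if (anyNA(geno)) next
      # sanity: past the opening (hot) interval the genotype is constant
      gridStart <- if (b == 1L) 0 else bounds[b - 1L]
      chk <- sel[p[sel] >= gridStart + interval]
      if (length(chk) > 1) {
        cc <- cons$geno[chk, , drop = FALSE]
        stopifnot(all(cc == rep(cc[nrow(cc), ], each = nrow(cc))))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = p[sel[1]], end = p[sel[length(sel)]],
        nSnps = length(sel), gridStart = gridStart,
        gridEnd = if (b <= length(bounds)) bounds[b] else
          (floor(p[length(p)] / interval) + 1) * interval)
      genoRows[[length(genoRows) + 1L]] <- geno
    }
  }
  df <- do.call(rbind, rows)
  geno <- do.call(rbind, genoRows)
  newBinGenotypes(geno, chrom = df$chrom, start = df$start, end = df$end,
                  nSnps = df$nSnps, gridStart = df$gridStart,
                  gridEnd = df$gridEnd)
}

#' Summary statistics of a bin map
#'
#' @param bins a [BinGenotypes].
#' @param shortThreshold bin length (bp) under which a bin counts as "short"
#'   in the reported fraction (default 0.6 Mb).
#' @return list with `perChrom` (data.frame: `chrom`, `nBins`) and `length`
#'   (named vector: min/mean/median/max bin length in bp and the fraction of
#'   bins shorter than `shortThreshold`).
#' @export
binSummary <- function(bins, shortThreshold = 6e5) {
  rr <- SummarizedExperiment::rowRanges(bins)
  len <- GenomicRanges::width(rr)
  ch <- as.character(GenomicRanges::seqnames(rr))
  perChrom <- data.frame(chrom = unique(ch),
                         nBins = as.integer(table(factor(ch, unique(ch)))))
  list(perChrom = perChrom,
       length = c(min = min(len), mean = mean(len), median = median(len),
                  max = max(len), fracShort = mean(len < shortThreshold)))
}
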