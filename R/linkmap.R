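#' Kosambi map function and its inverse
#'
#' `kosambi()` converts a recombination fraction `r` in `[0, 0.5)` to map
#' distance `d = 25 ln((1+2r)/(1-2r))` centimorgans; `kosambiInv()` is the
#' exact inverse `r = tanh(d/50)/2`.  The round trip is an identity to
#' numerical precision.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in cM, `>= 0`.
#' @return map distance in cM, or recombination fraction.
#' @examples
#' kosambi(0.25)        # 25*log(3) = 27.465 cM
#' kosambiInv(kosambi(0.1))
#' @export
kosambi <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("r must be in [0, 0.5); unlinked loci have infinite map distance - ",
         "cap r below 0.5 before converting")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi
#' @export
kosambiInv <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  tanh(d / 50) / 2
}

#' Two-locus F2 genotype-pair probabilities
#'
#' Joint probabilities of the nine codominant genotype pairs for two loci in
#' coupling at recombination fraction `r`, F2 generation, no interference.
#' The double-heterozygote cell mixes the two phases:
#' `P(AB,AB) = ((1-r)^2 + r^2)/2`.
#'
#' @param r recombination fraction.
#' @return 3x3 matrix of probabilities (rows locus 1, cols locus 2, order
#'   AA/AB/BB), summing to 1.
#' @export
f2JointProbs <- function(r) {
  s <- (1 - r) / 2; t <- r / 2
  m <- matrix(c(s^2,     2 * s * t,       t^2,
                2 * s * t, 2 * (s^2 + t^2), 2 * s * t,
                t^2,     2 * s * t,       s^2),
              3, 3, byrow = TRUE,
              dimnames = list(GENO_LEVELS, GENO_LEVELS))
  m
}

rfLogLik <- function(r, counts) sum(counts * log(f2JointProbs(r) + 1e-300))

#' Maximum-likelihood recombination fraction between two markers
#'
#' Maximizes the F2 two-locus multinomial likelihood over the nine
#' genotype-pair cells by bounded one-dimensional optimization (the
#' double-heterozygote phase mixture makes the likelihood non-trivial but
#' still unimodal in practice); the estimate is clamped to `[0, 0.5]`.
#'
#' @param g1,g2 character genotype vectors (`AA`/`AB`/`BB`, `NA` allowed)
#'   over the same individuals.
#' @param tol optimization tolerance.
#' @return list with `r` (the estimate), `logLik` at the maximum, `counts`
#'   (3x3 joint table over individuals non-missing at both markers) and `n`.
#'   Fewer than 2 informative individuals yields `r = NA` (gap).
#' @export
estimateRF <- function(g1, g2, tol = 1e-9) {
  ok <- g1 %in% GENO_LEVELS & g2 %in% GENO_LEVELS
  counts <- table(factor(g1[ok], GENO_LEVELS), factor(g2[ok], GENO_LEVELS))
  n <- sum(counts)
  if (n < 2)
    return(list(r = NA_real_, logLik = NA_real_, counts = counts, n = n))
  opt <- optimize(rfLogLik, c(0, 0.5), counts = counts, maximum = TRUE,
                  tol = tol)
  cand <- c(opt$maximum, 0, 0.5)
  ll <- vapply(cand, rfLogLik, numeric(1), counts = counts)
  best <- which.max(ll)
  list(r = min(max(cand[best], 0), 0.5), logLik = ll[best], counts = counts,
       n = n)
}

#' Build a Kosambi genetic map from bin genotypes
#'
#' Marker order is taken from the genome (bins are anchored to the reference
#' assembly and never re-ordered).  The cM position of bin `k` is the
#' cumulative sum of Kosambi distances between adjacent bins; adjacent pairs
#' with `r >= gapR` are flagged as gaps and their `r` is capped at `capR`
#' before conversion rather than split into new linkage groups.
#'
#' @param bins a [BinGenotypes].
#' @param gapR flagging threshold (default 0.49).
#' @param capR cap applied before the Kosambi transform (default 0.495).
#' @return a [GeneticMap].
#' @export
buildMap <- function(bins, gapR = 0.49, capR = 0.495) {
  g <- genotypeCalls(bins)
  ch <- markerChrom(bins)
  rr <- SummarizedExperiment::rowRanges(bins)
  out <- list()
  for (cc in unique(ch)) {
    sel <- which(ch == cc)
    rs <- rep(NA_real_, length(sel))
    if (length(sel) > 1)
      for (k in 2:length(sel))
        rs[k] <- estimateRF(g[sel[k - 1], ], g[sel[k], ])$r
    d <- numeric(length(rs))
    idx <- which(!is.na(rs))
    d[idx] <- kosambi(pmin(rs[idx], capR))
    d[1] <- 0
    out[[cc]] <- data.frame(
      bin = rownames(g)[sel], chrom = cc,
      start = GenomicRanges::start(rr)[sel], end = GenomicRanges::end(rr)[sel],
      cM = cumsum(d), rf = rs, gap = !is.na(rs) & rs >= gapR)
  }
  methods::new("GeneticMap", map = do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Linkage-map summary table
#'
#' Produces the standard per-linkage-group summary of a genetic map: number
#' of bins, map size in cM, average gap (size divided by bins minus one),
#' and max gap, plus a totals row whose overall average gap is the total size
#' divided by the total number of intervals.
#'
#' @param x a [GeneticMap], or a data.frame with columns `chrom`, `nBins`,
#'   `sizeCM` (and optionally `maxGap`) when only published per-chromosome
#'   values are available.
#' @return data.frame with one row per chromosome and a `"Total"` row.
#' @export
mapSummary <- function(x) {
  if (methods::is(x, "GeneticMap")) {
    m <- mapTable(x)
    rows <- do.call(rbind, lapply(split(m, factor(m$chrom, unique(m$chrom))),
      function(d) {
        gaps <- diff(d$cM)
        data.frame(chrom = d$chrom[1], nBins = nrow(d), sizeCM = max(d$cM),
                   maxGap = if (length(gaps)) max(gaps) else 0)
      }))
  } else {
    rows <- x
    if (is.null(rows$maxGap)) rows$maxGap <- NA_real_
  }
  stopifnot(all(c("chrom", "nBins", "sizeCM") %in% names(rows)))
  rows$aveGap <- rows$sizeCM / pmax(rows$nBins - 1, 1)
  tot <- data.frame(chrom = "Total", nBins = sum(rows$nBins),
                    sizeCM = sum(rows$sizeCM),
                    maxGap = suppressWarnings(max(rows$maxGap)),
                    aveGap = sum(rows$sizeCM) / sum(pmax(rows$nBins - 1, 1)))
  out <- rbind(rows[, c("chrom", "nBins", "sizeCM", "aveGap", "maxGap")],
               tot[, c("chrom", "nBins", "sizeCM", "aveGap", "maxGap")])
  rownames(out) <- NULL
  out
}
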