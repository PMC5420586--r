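#' Classify the segregation pattern of a marker from its parental genotypes
#'
#' Biparental mapping nomenclature distinguishes eight segregation patterns
#' (`ab x cd`, `ef x eg`, `hk x hk`, `lm x ll`, `nn x np`, `aa x bb`,
#' `ab x cc`, `cc x ab`).  For an F2 derived from two inbred parents only the
#' `aa x bb` pattern (both parents homozygous for different alleles) is
#' informative and retained downstream.
#'
#' @param p1,p2 parental genotypes as two-allele strings (e.g. `"AA"`, `"AG"`,
#'   `"CT"`); `NA` or malformed genotypes are uninformative.
#' @return character vector of pattern labels; monomorphic or uncallable
#'   markers are `"uninformative"`.
#' @examples
#' classifySegregation("AA", "GG")  # "aa x bb"
#' classifySegregation("AG", "AA")  # "lm x ll"
#' @export
classifySegregation <- function(p1, p2) {
  one <- function(a, b) {
    if (is.na(a) || is.na(b) || nchar(a) != 2L || nchar(b) != 2L)
      return("uninformative")
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    hetA <- a[1] != a[2]; hetB <- b[1] != b[2]
    shared <- length(intersect(a, b))
    if (hetA && hetB) {
      if (setequal(a, b)) return("hk x hk")
      if (shared == 1) return("ef x eg")
      return("ab x cd")
    }
    if (hetA && !hetB) {
      if (b[1] %in% a) return("lm x ll")
      return("ab x cc")
    }
    if (!hetA && hetB) {
      if (a[1] %in% b) return("nn x np")
      return("cc x ab")
    }
    if (a[1] == b[1]) return("uninformative")  # monomorphic
    "aa x bb"
  }
  mapply(one, as.character(p1), as.character(p2), USE.NAMES = FALSE)
}

#' Chi-square test of 1:2:1 F2 segregation
#'
#' Tests observed genotype counts against the Mendelian 1:2:1 expectation on
#' the non-missing total (df = 2; for this df the p-value has the closed form
#' `exp(-chisq/2)`).
#'
#' @param nAA,nAB,nBB genotype counts (vectors allowed).
#' @return data.frame with columns `chisq` and `p`; an all-missing marker
#'   (total 0) yields `NA` for both.
#' @examples
#' chiSquareSegregation(50, 100, 50)   # chisq 0, p 1
#' chiSquareSegregation(30, 100, 70)   # chisq 16, p exp(-8)
#' @export
chiSquareSegregation <- function(nAA, nAB, nBB) {
  tot <- nAA + nAB + nBB
  e1 <- tot / 4; e2 <- tot / 2
  chisq <- ifelse(tot > 0,
                  (nAA - e1)^2 / e1 + (nAB - e2)^2 / e2 + (nBB - e1)^2 / e1,
                  NA_real_)
  data.frame(chisq = chisq, p = pchisq(chisq, df = 2, lower.tail = FALSE))
}

#' Per-marker call statistics
#'
#' @param snp a [SnpGenotypes].
#' @return data.frame with per-SNP counts (`nAA`, `nAB`, `nBB`, `nNA`,
#'   `nAbnormal`), `missingFrac`, `chisq`, `p`.
#' @export
markerStats <- function(snp) {
  g <- genotypeCalls(snp)
  n <- ncol(g)
  nAA <- rowSums(g == "AA", na.rm = TRUE)
  nAB <- rowSums(g == "AB", na.rm = TRUE)
  nBB <- rowSums(g == "BB", na.rm = TRUE)
  nNA <- rowSums(is.na(g))
  nAb <- n - nAA - nAB - nBB - nNA
  cs <- chiSquareSegregation(nAA, nAB, nBB)
  data.frame(snp = rownames(g), chrom = markerChrom(snp), pos = markerPos(snp),
             nAA = nAA, nAB = nAB, nBB = nBB, nNA = nNA, nAbnormal = nAb,
             missingFrac = nNA / n, chisq = cs$chisq, p = cs$p,
             row.names = NULL)
}

#' Filter SNP markers on abnormal calls, missingness and segregation distortion
#'
#' Applies, in priority order, the three marker-level filters used for
#' low-coverage F2 genotype matrices: (1) any call token outside
#' `{AA, AB, BB, NA}` ("abnormal base") removes the marker; (2) markers with
#' more than `maxMissing` missing calls are removed; (3) markers whose 1:2:1
#' chi-square test gives `p < pThreshold` (segregation distortion) are
#' removed.  Each removed marker carries exactly one primary reason code, and
#' the operation is idempotent.
#'
#' @param snp a [SnpGenotypes] (assumed already restricted to `aa x bb`
#'   markers).
#' @param pThreshold distortion p-value cut-off (default 0.001).
#' @param maxMissing maximum tolerated missing fraction (default 0.25; a
#'   marker at exactly 25% missing is retained).
#' @return list with `genotypes` (filtered [SnpGenotypes]) and `stats`
#'   (the [markerStats()] table plus `retained` flag and `reason` code among
#'   `"abnormal"`, `"missing"`, `"distortion"`, or `NA` when retained).
#' @export
filterMarkers <- function(snp, pThreshold = 0.001, maxMissing = 0.25) {
  st <- markerStats(snp)
  reason <- rep(NA_character_, nrow(st))
  reason[is.na(reason) & st$nAbnormal > 0] <- "abnormal"
  reason[is.na(reason) & st$missingFrac > maxMissing] <- "missing"
  distorted <- !is.na(st$p) & st$p < pThreshold
  reason[is.na(reason) & distorted] <- "distortion"
  reason[is.na(reason) & is.na(st$p)] <- "missing"  # all-missing, untestable
  st$retained <- is.na(reason)
  st$reason <- reason
  keep <- which(st$retained)
  if (length(keep) == 0)
    warning("no markers pass the filters; downstream stages will refuse to run")
  list(genotypes = snp[keep, ], stats = st)
}
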