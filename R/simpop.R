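#' Genome specification for F2 simulation
#'
#' Describes the chromosomes of the simulated species: physical length in bp,
#' genetic length in cM, and either a SNP density or an explicit SNP position
#' list per chromosome.
#'
#' @param chrom chromosome names.
#' @param lengthBp physical lengths (bp), all > 0.
#' @param lengthCM genetic lengths (cM), all >= 0.
#' @param snpsPerMb marker density used when positions are sampled.
#' @param snpPositions optional named list of strictly increasing integer
#'   positions per chromosome; overrides `snpsPerMb`.
#' @return data.frame with one row per chromosome and an attribute carrying
#'   explicit positions when given.
#' @seealso [maizeGenome()] for the default maize-like genome.
#' @export
genomeSpec <- function(chrom, lengthBp, lengthCM, snpsPerMb = 10,
                       snpPositions = NULL) {
  stopifnot(length(chrom) == length(lengthBp),
            length(chrom) == length(lengthCM),
            all(lengthBp > 0), all(lengthCM >= 0), snpsPerMb > 0)
  if (!is.null(snpPositions)) {
    stopifnot(all(names(snpPositions) %in% chrom))
    for (ch in names(snpPositions)) {
      p <- snpPositions[[ch]]
      if (any(diff(p) <= 0) || any(p < 1) ||
          any(p > lengthBp[match(ch, chrom)]))
        stop("SNP positions must be strictly increasing and within [1, lengthBp]")
    }
  }
  g <- data.frame(chrom = as.character(chrom), lengthBp = as.numeric(lengthBp),
                  lengthCM = as.numeric(lengthCM),
                  snpsPerMb = as.numeric(snpsPerMb))
  attr(g, "snpPositions") <- snpPositions
  g
}

#' Maize-like default genome
#'
#' Ten chromosomes with physical sizes proportional to the maize reference
#' assembly (AGPv3) and genetic lengths matching a published maize F2 GBS bin
#' map (total about 2,237 cM).  `scaleBp` shrinks the physical genome for
#' desk-scale simulation (default one tenth of maize); `scaleCM` rescales the
#' genetic lengths.
#'
#' @param scaleBp physical scale factor.
#' @param scaleCM genetic scale factor.
#' @param snpsPerMb marker density for SNP sampling.
#' @return A genome specification (see [genomeSpec()]).
#' @export
maizeGenome <- function(scaleBp = 0.1, scaleCM = 1, snpsPerMb = 10) {
  bp <- c(301.35, 237.07, 232.14, 242.03, 217.96,
          169.41, 176.76, 175.38, 157.04, 149.63) * 1e6
  cm <- c(309.26, 382.80, 228.78, 279.34, 189.79,
          153.86, 185.30, 167.92, 200.09, 139.51)
  genomeSpec(chrom = as.character(1:10), lengthBp = round(bp * scaleBp),
             lengthCM = cm * scaleCM, snpsPerMb = snpsPerMb)
}

#' Simulation configuration
#'
#' Collects population size, GBS observation-noise rates, the QTL model and
#' trait heritabilities for [simulateF2()], [gbsObserve()] and
#' [simulatePhenotypes()].
#'
#' The noise model applies, in order: heterozygote undercalling (a true `AB`
#' observed as `AA` or `BB` with equal probability, emulating single-allele
#' sampling at very low coverage), random genotype error (a call replaced by
#' one of the two other categories), and missingness masking.
#'
#' @param nIndividuals F2 population size (default 199).
#' @param missingRate per-call missing probability in `[0,1]`.
#' @param errorRate per-call probability of replacement by a wrong category.
#' @param hetUndercallRate probability a true heterozygote is observed
#'   homozygous.
#' @param qtl data.frame with columns `trait` (index or name), `chrom`, `pos`
#'   (bp), `a` (additive effect), `d` (dominance effect); may be empty.
#' @param h2 per-trait narrow+dominance heritability target in `(0,1)`
#'   (recycled across traits).
#' @param traitNames optional trait names.
#' @param seed RNG seed; a fixed seed makes all simulation outputs identical
#'   on repeat calls.
#' @return validated configuration list of class `"simConfig"`.
#' @export
simConfig <- function(nIndividuals = 199, missingRate = 0.1, errorRate = 0.01,
                      hetUndercallRate = 0.3, qtl = NULL, h2 = 0.5,
                      traitNames = NULL, seed = NULL) {
  rates <- c(missingRate, errorRate, hetUndercallRate)
  stopifnot(nIndividuals >= 1, all(rates >= 0), all(rates <= 1))
  if (is.null(qtl))
    qtl <- data.frame(trait = integer(), chrom = character(),
                      pos = numeric(), a = numeric(), d = numeric())
  qtl$trait <- as.character(qtl$trait)
  qtl$chrom <- as.character(qtl$chrom)
  nTraits <- max(1L, length(unique(qtl$trait)), length(traitNames), length(h2))
  h2 <- rep_len(h2, nTraits)
  if (is.null(traitNames)) {
    traitNames <- unique(qtl$trait)
    if (length(traitNames) == 0) traitNames <- as.character(seq_len(nTraits))
    traitNames <- c(traitNames,
                    setdiff(as.character(seq_len(nTraits)), traitNames))[seq_len(nTraits)]
  }
  perTraitVar <- vapply(traitNames, function(tr) {
    q <- qtl[qtl$trait == tr, , drop = FALSE]
    sum(qtlVariance(q$a, q$d))
  }, numeric(1))
  bad <- perTraitVar > 0 & (h2 <= 0 | h2 >= 1)
  if (any(bad))
    stop("h2 must be in (0,1) for traits with nonzero QTL effects")
  structure(list(nIndividuals = as.integer(nIndividuals),
                 missingRate = missingRate, errorRate = errorRate,
                 hetUndercallRate = hetUndercallRate, qtl = qtl, h2 = h2,
                 traitNames = traitNames, seed = seed),
            class = "simConfig")
}

#' Genetic variance contributed by one QTL at F2 frequencies
#'
#' At Hardy-Weinberg F2 frequencies (1/4, 1/2, 1/4) a locus with additive
#' effect `a` and dominance effect `d` contributes variance `a^2/2 + d^2/4`.
#'
#' @param a additive effect.
#' @param d dominance effect.
#' @export
qtlVariance <- function(a, d) a^2 / 2 + d^2 / 4

#' Simulate one gamete of an F1 meiosis
#'
#' Crossover count is Poisson with mean `lengthCM/100` (no interference,
#' i.e. a Haldane process); crossover positions are uniform on the physical
#' span; parental origin alternates at each crossover starting from a random
#' parent.
#'
#' @param genome genome specification.
#' @param chrom chromosome to simulate.
#' @return list with `origin0` (1 = P1, 2 = P2 at the chromosome start) and
#'   `xo` (sorted crossover positions, bp).  A chromosome of genetic length 0
#'   always yields zero crossovers.
#' @export
simulateGamete <- function(genome, chrom) {
  i <- match(as.character(chrom), genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  k <- rpois(1L, genome$lengthCM[i] / 100)
  list(origin0 = sample.int(2L, 1L),
       xo = sort(runif(k, min = 1, max = genome$lengthBp[i])))
}

gameteOriginAt <- function(gamete, pos) {
  k <- findInterval(pos, gamete$xo)
  ifelse(k %% 2L == 0L, gamete$origin0, 3L - gamete$origin0)
}

sampleSnpPositions <- function(genome) {
  given <- attr(genome, "snpPositions")
  out <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$chrom[i]
    if (!is.null(given) && !is.null(given[[ch]])) return(as.numeric(given[[ch]]))
    n <- max(2L, round(genome$lengthBp[i] / 1e6 * genome$snpsPerMb[i]))
    sort(sample.int(genome$lengthBp[i], n))
  })
  names(out) <- genome$chrom
  out
}

#' Simulate a biparental F2 population
#'
#' Each individual is formed from two independent gametes per chromosome
#' (see [simulateGamete()]); the true genotype at each SNP is the unordered
#' pair of parental origins, so locus-wise genotype frequencies converge to
#' the Mendelian 1:2:1 ratio.
#'
#' @param genome genome specification ([genomeSpec()] / [maizeGenome()]).
#' @param config simulation configuration ([simConfig()]); `config$seed`, when
#'   non-`NULL`, is applied so repeat calls are identical.
#' @return list with `truth` (a [SimTruth]) and `genotypes` (the true,
#'   noise-free [SnpGenotypes]; apply [gbsObserve()] for GBS-like data).
#' @export
simulateF2 <- function(genome, config) {
  stopifnot(inherits(config, "simConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  snpPos <- sampleSnpPositions(genome)
  n <- config$nIndividuals
  inds <- sprintf("ind%03d", seq_len(n))
  gametes <- vector("list", n)
  names(gametes) <- inds
  genoByChrom <- vector("list", nrow(genome))
  for (ci in seq_len(nrow(genome)))
    genoByChrom[[ci]] <- matrix(NA_character_, length(snpPos[[ci]]), n)
  for (ii in seq_len(n)) {
    percr <- vector("list", nrow(genome))
    names(percr) <- genome$chrom
    for (ci in seq_len(nrow(genome))) {
      g1 <- simulateGamete(genome, genome$chrom[ci])
      g2 <- simulateGamete(genome, genome$chrom[ci])
      percr[[ci]] <- list(g1, g2)
      code <- gameteOriginAt(g1, snpPos[[ci]]) + gameteOriginAt(g2, snpPos[[ci]])
      genoByChrom[[ci]][, ii] <- c("AA", "AB", "BB")[code - 1L]
    }
    gametes[[ii]] <- percr
  }
  geno <- do.call(rbind, genoByChrom)
  colnames(geno) <- inds
  snp <- snpGenotypes(geno,
                      chrom = rep(genome$chrom, lengths(snpPos)),
                      pos = unlist(snpPos, use.names = FALSE))
  truth <- methods::new("SimTruth", gametes = gametes, genotypes = snp,
                        qtl = config$qtl, genome = genome)
  list(truth = truth, genotypes = snp)
}

#' True genotype of every individual at an arbitrary position
#'
#' Reads the crossover mosaics of a [SimTruth] directly, so the position need
#' not coincide with a simulated SNP.
#'
#' @param truth a [SimTruth].
#' @param chrom chromosome.
#' @param pos physical position (bp).
#' @return character vector over individuals (`"AA"`, `"AB"`, `"BB"`).
#' @export
trueGenotypeAt <- function(truth, chrom, pos) {
  chrom <- as.character(chrom)
  vapply(truth@gametes, function(percr) {
    gs <- percr[[chrom]]
    code <- gameteOriginAt(gs[[1]], pos) + gameteOriginAt(gs[[2]], pos)
    c("AA", "AB", "BB")[code - 1L]
  }, character(1))
}

#' Apply GBS-like observation noise to true genotypes
#'
#' Applies, in order, heterozygote undercalling, random genotype error and
#' missingness (see [simConfig()]).  With all three rates zero the output
#' equals the input.  The coordinates of perturbed calls are recorded in
#' `metadata()` for auditing.
#'
#' @param snp true [SnpGenotypes].
#' @param config a [simConfig()].
#' @return observed [SnpGenotypes].
#' @export
gbsObserve <- function(snp, config) {
  stopifnot(inherits(config, "simConfig"))
  g <- genotypeCalls(snp)
  het <- which(g == "AB" & matrix(runif(length(g)) < config$hetUndercallRate,
                                  nrow(g)))
  if (length(het))
    g[het] <- sample(c("AA", "BB"), length(het), replace = TRUE)
  err <- which(matrix(runif(length(g)) < config$errorRate, nrow(g)) & !is.na(g))
  if (length(err)) {
    pick <- vapply(g[err], function(v) sample(setdiff(GENO_LEVELS, v), 1L),
                   character(1))
    g[err] <- pick
  }
  mis <- which(matrix(runif(length(g)) < config$missingRate, nrow(g)))
  if (length(mis)) g[mis] <- NA_character_
  out <- snp
  SummarizedExperiment::assay(out, "geno") <- g
  S4Vectors::metadata(out)$perturbed <-
    list(hetUndercall = het, error = err, missing = mis)
  out
}

#' Simulate phenotypes under an additive + dominance QTL model
#'
#' For each trait, `y = mu + sum_k (a_k x_k + d_k z_k) + e` with `x = +1, 0,
#' -1` for the P1 homozygote, heterozygote and P2 homozygote and `z = 1` for
#' the heterozygote.  The residual variance is set from the theoretical
#' genetic variance at F2 frequencies (`sum a^2/2 + d^2/4`, QTL assumed
#' unlinked) so that genetic variance / total variance equals the trait's
#' `h2`.  Traits without QTL are pure standard-normal noise.
#'
#' @param truth a [SimTruth] from [simulateF2()].
#' @param config the [simConfig()] holding the QTL table and `h2`.
#' @param mu grand mean per trait (recycled, default 0).
#' @return data.frame: `individual` plus one column per trait.
#' @export
simulatePhenotypes <- function(truth, config, mu = 0) {
  stopifnot(inherits(config, "simConfig"))
  inds <- names(truth@gametes)
  n <- length(inds)
  traits <- config$traitNames
  mu <- rep_len(mu, length(traits))
  out <- data.frame(individual = inds)
  for (ti in seq_along(traits)) {
    q <- config$qtl[config$qtl$trait == traits[ti], , drop = FALSE]
    gval <- numeric(n)
    vg <- 0
    if (nrow(q)) {
      for (k in seq_len(nrow(q))) {
        gk <- trueGenotypeAt(truth, q$chrom[k], q$pos[k])
        x <- c(AA = 1, AB = 0, BB = -1)[gk]
        z <- as.numeric(gk == "AB")
        gval <- gval + q$a[k] * x + q$d[k] * z
      }
      vg <- sum(qtlVariance(q$a, q$d))
    }
    ve <- if (vg > 0) vg * (1 - config$h2[ti]) / config$h2[ti] else 1
    out[[traits[ti]]] <- mu[ti] + gval + rnorm(n, 0, sqrt(ve))
  }
  out
}
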