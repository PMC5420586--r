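#' Descriptive statistics of phenotype traits
#'
#' One row per trait with the parental values (when given) and the F2
#' population minimum, maximum, mean and sample standard deviation, in the
#' conventional column order `trait, P1, P2, min, max, mean, sd`.
#'
#' @param pheno phenotype data.frame (`individual` + trait columns).
#' @param parents optional data.frame/matrix with one row per parent (P1
#'   first) and one column per trait.
#' @return data.frame of summary rows; an all-missing trait gives an all-`NA`
#'   row with a warning.
#' @export
traitSummary <- function(pheno, parents = NULL) {
  traits <- setdiff(names(pheno), "individual")
  rows <- lapply(traits, function(tr) {
    v <- pheno[[tr]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning("trait ", tr, " has no non-missing values")
      return(data.frame(trait = tr, P1 = NA_real_, P2 = NA_real_,
                        min = NA_real_, max = NA_real_, mean = NA_real_,
                        sd = NA_real_))
    }
    data.frame(trait = tr,
               P1 = if (!is.null(parents)) parents[1, tr] else NA_real_,
               P2 = if (!is.null(parents)) parents[2, tr] else NA_real_,
               min = min(v), max = max(v), mean = mean(v), sd = sd(v))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Pairwise Pearson correlations with significance flags
#'
#' Pearson correlation over pairwise-complete observations with two-sided
#' t-tests at level `alpha` (unadjusted, as is conventional for trait
#' correlation tables).
#'
#' @param pheno phenotype data.frame.
#' @param alpha significance level for the flags (default 0.05).
#' @return list with matrices `r` (coefficients; unit diagonal), `p`
#'   (two-sided p-values) and `sig` (logical flags).  A zero-variance trait
#'   yields `NA` entries.
#' @export
pearsonMatrix <- function(pheno, alpha = 0.05) {
  traits <- setdiff(names(pheno), "individual")
  k <- length(traits)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    x <- pheno[[traits[i]]]; y <- pheno[[traits[j]]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    if (n < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    rr <- cor(x[ok], y[ok])
    tt <- rr * sqrt((n - 2) / max(1 - rr^2, 1e-300))
    r[i, j] <- rr
    p[i, j] <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  stopifnot(isTRUE(all.equal(r, t(r))))
  list(r = r, p = p, sig = p < alpha & row(p) != col(p))
}

#' Genes overlapping a QTL physical interval
#'
#' Closed-interval, strand-agnostic overlap of gene models with a physical
#' interval (a gene starting exactly at the interval end is included), in
#' positional order.  Accepts either a `GRanges` of genes or a GFF3 file
#' path (read with `rtracklayer`, feature type `gene`).
#'
#' @param chrom,start,end QTL physical interval (same assembly as the genes).
#' @param genes a `GRanges` with a gene identifier column (`ID`, `gene_id` or
#'   `Name`), or a GFF3 file path.
#' @param biotype optional biotype filter (matched against a `biotype` or
#'   `gene_biotype` column when present).
#' @return character vector of gene identifiers (empty when nothing
#'   overlaps); warns and returns empty when the contig name is absent from
#'   the annotation.
#' @export
annotateInterval <- function(chrom, start, end, genes, biotype = NULL) {
  if (is.character(genes)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 files requires the rtracklayer package")
    genes <- rtracklayer::import(genes)
    if ("type" %in% names(S4Vectors::mcols(genes)))
      genes <- genes[genes$type == "gene"]
  }
  if (!is.null(biotype)) {
    bcol <- intersect(c("biotype", "gene_biotype"),
                      names(S4Vectors::mcols(genes)))
    if (length(bcol))
      genes <- genes[S4Vectors::mcols(genes)[[bcol[1]]] %in% biotype]
  }
  if (length(genes) == 0) return(character(0))
  if (!as.character(chrom) %in%
      unique(as.character(GenomicRanges::seqnames(genes)))) {
    warning("contig '", chrom, "' not present in the annotation; contigs: ",
            paste(head(unique(as.character(GenomicRanges::seqnames(genes))), 5),
                  collapse = ", "))
    return(character(0))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hit <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
  g <- genes[S4Vectors::subjectHits(hit)]
  g <- g[order(GenomicRanges::start(g))]
  idcol <- intersect(c("ID", "gene_id", "Name"), names(S4Vectors::mcols(g)))
  if (length(idcol)) as.character(S4Vectors::mcols(g)[[idcol[1]]])
  else as.character(seq_along(g))
}

#' Published per-chromosome summary of the maize SG5 x SG7 F2 bin map
#'
#' Per-chromosome bin counts, map sizes and maximum gaps of the published
#' maize SG5 x SG7 F2 GBS bin map (3,305 bins over 10 linkage groups), as
#' shipped in `inst/extdata/`.  Useful with [mapSummary()] to recompute the
#' derived map statistics, and as a format fixture.
#'
#' @return data.frame with columns `chrom`, `nBins`, `sizeCM`, `maxGap`.
#' @export
maizeBinMapSummary <- function() {
  f <- system.file("extdata", "maize_sg5xsg7_map_summary.tsv",
                   package = "binQTL", mustWork = TRUE)
  read.table(f, header = TRUE, sep = "\t", colClasses =
               c("character", "integer", "numeric", "numeric"))
}

#' Study constants of the maize SG5 x SG7 F2 GBS experiment
#'
#' Read-accounting and design constants of the published experiment the
#' package's defaults emulate: number of F2 individuals, total high-quality
#' reads, raw and filtered aa x bb SNP counts.
#'
#' @return named list.
#' @export
maizeStudyConstants <- function() {
  list(nIndividuals = 199L,
       totalReads = 1046524604,
       rawAaBbSnps = 68882L,
       filteredSnps = 29927L)
}
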