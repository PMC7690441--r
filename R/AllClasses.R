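#' @importClassesFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Gene model on a genome sequence
#'
#' An exon/intron/CDS structure for one gene: ordered, non-overlapping exons
#' as 1-based closed intervals in genomic order, a single coding-sequence
#' interval whose exonic (spliced) length is a multiple of three, and a
#' strand. Introns are always derived from the gaps between consecutive
#' exons, never stored. Minus-strand genes keep exons in genomic order;
#' reverse-complementation happens only when coding sequence is extracted.
#'
#' @slot geneID single gene identifier.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \code{IRanges} of exons, sorted, non-overlapping, separated by
#'   at least one intronic base.
#' @slot cds \code{IRanges} of length one: the genomic coding interval. Its
#'   boundaries must fall inside exons.
#' @export
setClass("GeneModel",
  slots = c(
    geneID = "character",
    chrom = "character",
    strand = "character",
    exons = "IRanges",
    cds = "IRanges"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneID) != 1L || is.na(object@geneID) || !nzchar(object@geneID))
    msg <- c(msg, "geneID must be a single non-empty string")
  if (length(object@chrom) != 1L || is.na(object@chrom) || !nzchar(object@chrom))
    msg <- c(msg, "chrom must be a single non-empty string")
  if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) < 1L) {
    msg <- c(msg, "at least one exon is required")
  } else {
    if (any(BiocGenerics::start(ex) < 1L))
      msg <- c(msg, "exon coordinates must be >= 1")
    if (is.unsorted(BiocGenerics::start(ex), strictly = TRUE) && length(ex) > 1L)
      msg <- c(msg, "exons must be sorted by start")
    if (length(ex) > 1L &&
        any(BiocGenerics::start(ex)[-1L] <= BiocGenerics::end(ex)[-length(ex)] + 1L))
      msg <- c(msg, "exons must be non-overlapping and separated by >= 1 intronic base")
  }
  if (length(object@cds) != 1L) {
    msg <- c(msg, "cds must be a single interval")
  } else if (length(ex) >= 1L) {
    cs <- BiocGenerics::start(object@cds)
    ce <- BiocGenerics::end(object@cds)
    inExon <- function(p) any(p >= BiocGenerics::start(ex) & p <= BiocGenerics::end(ex))
    if (!inExon(cs) || !inExon(ce))
      msg <- c(msg, "cds boundaries must fall inside exons")
    splicedLen <- sum(BiocGenerics::width(BiocGenerics::intersect(ex, object@cds)))
    if (splicedLen < 3L || splicedLen %% 3L != 0L)
      msg <- c(msg, "spliced CDS length must be a positive multiple of 3")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a gene model
#'
#' @param geneID gene identifier.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exonStarts,exonEnds 1-based closed exon intervals in genomic order.
#' @param cdsStart,cdsEnd genomic coding interval; defaults to the full exon
#'   span (coding gene model without untranslated regions).
#' @return A validated \linkS4class{GeneModel}.
#' @examples
#' g <- geneModel("g1", "chr1", "+", c(1, 201), c(100, 300))
#' uniqueExonicLength(g)
#' @export
geneModel <- function(geneID, chrom, strand, exonStarts, exonEnds,
                      cdsStart = NULL, cdsEnd = NULL) {
  ex <- IRanges::IRanges(start = as.integer(exonStarts), end = as.integer(exonEnds))
  if (is.null(cdsStart)) cdsStart <- min(BiocGenerics::start(ex))
  if (is.null(cdsEnd)) cdsEnd <- max(BiocGenerics::end(ex))
  new("GeneModel",
    geneID = as.character(geneID), chrom = as.character(chrom),
    strand = as.character(strand), exons = ex,
    cds = IRanges::IRanges(as.integer(cdsStart), as.integer(cdsEnd)))
}

#' @describeIn geneModel gene identifier accessor
#' @param gene a \linkS4class{GeneModel}.
#' @export
geneID <- function(gene) gene@geneID

#' @describeIn geneModel chromosome accessor
#' @export
geneChrom <- function(gene) gene@chrom

#' @describeIn geneModel strand accessor
#' @export
geneStrand <- function(gene) gene@strand

#' @describeIn geneModel exon intervals (\code{IRanges}, genomic order)
#' @export
geneExons <- function(gene) gene@exons

#' @describeIn geneModel genomic coding interval (\code{IRanges} of length 1)
#' @export
cdsRange <- function(gene) gene@cds

#' @describeIn geneModel derived introns: the gaps between consecutive exons
#' @export
geneIntrons <- function(gene) {
  ex <- gene@exons
  n <- length(ex)
  if (n < 2L) return(IRanges::IRanges())
  IRanges::IRanges(BiocGenerics::end(ex)[-n] + 1L, BiocGenerics::start(ex)[-1L] - 1L)
}

#' @describeIn geneModel number of distinct genomic bases covered by at least
#'   one exon of the gene (the length used as the kilobase denominator in
#'   FPKM).
#' @export
uniqueExonicLength <- function(gene) {
  sum(BiocGenerics::width(IRanges::reduce(gene@exons)))
}

#' @describeIn geneModel full genomic span of the gene as an \code{IRanges}
#' @export
geneSpan <- function(gene) {
  IRanges::IRanges(min(BiocGenerics::start(gene@exons)),
                   max(BiocGenerics::end(gene@exons)))
}

setMethod("show", "GeneModel", function(object) {
  cat("GeneModel ", object@geneID, " (", object@chrom, object@strand, ")\n", sep = "")
  cat("  ", length(object@exons), " exon(s), unique exonic length ",
      uniqueExonicLength(object), " bp\n", sep = "")
  cat("  CDS ", BiocGenerics::start(object@cds), "-",
      BiocGenerics::end(object@cds), "\n", sep = "")
})

#' Windowed mutant-specific homozygosity profile
#'
#' Per-window homozygosity scores along the genome, computed by
#' \code{\link{homozygosityProfile}}. The score of a window is the percentage
#' of variant sites in the window that are homozygous-alternate in the mutant
#' pool but not in the wild-type sibling pool. Windows with fewer than
#' \code{minVariants} sites are ineligible for peak search. The peak is the
#' union interval of all eligible windows attaining the maximum score.
#'
#' @slot windows data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{n_variants}, \code{n_specific}, \code{score},
#'   \code{eligible}.
#' @slot windowSize,step window width and slide step (bp).
#' @slot minVariants minimum variant count for a window to enter peak search.
#' @slot peak \code{GRanges} of length one (or empty when undefined).
#' @export
setClass("HomozygosityProfile",
  slots = c(
    windows = "data.frame",
    windowSize = "numeric",
    step = "numeric",
    minVariants = "numeric",
    peak = "GRanges"
  )
)

setValidity("HomozygosityProfile", function(object) {
  w <- object@windows
  need <- c("chrom", "start", "end", "n_variants", "n_specific", "score", "eligible")
  if (!all(need %in% names(w)))
    return(paste("windows must have columns:", paste(need, collapse = ", ")))
  sc <- w$score[!is.na(w$score)]
  if (length(sc) && (any(sc < 0) || any(sc > 100)))
    return("scores must lie in [0, 100]")
  if (length(object@peak) > 1L)
    return("peak must be empty or a single interval")
  TRUE
})

#' @describeIn homozygosityProfile per-window score table
#' @export
windowScores <- function(profile) profile@windows

#' @describeIn homozygosityProfile peak interval (\code{GRanges}; empty when
#'   no eligible window has a positive score)
#' @export
peakInterval <- function(profile) profile@peak

setMethod("show", "HomozygosityProfile", function(object) {
  w <- object@windows
  cat("HomozygosityProfile: ", nrow(w), " windows of ", object@windowSize,
      " bp (step ", object@step, " bp) on ",
      length(unique(w$chrom)), " chromosome(s)\n", sep = "")
  if (length(object@peak)) {
    cat("  peak: ", as.character(GenomicRanges::seqnames(object@peak)), ":",
        BiocGenerics::start(object@peak), "-", BiocGenerics::end(object@peak),
        " (score ", format(max(w$score[w$eligible], na.rm = TRUE), digits = 4),
        ")\n", sep = "")
  } else {
    cat("  peak: undefined\n")
  }
})

#' Consequence of retaining one intron in the mature transcript
#'
#' Result of \code{\link{retentionConsequence}}: whether continuing the
#' coding reading frame into a retained intron hits an in-frame stop codon
#' (a premature termination codon, PTC), and where.
#'
#' @slot geneID gene identifier.
#' @slot intronIndex retained intron (genomic order, 1-based).
#' @slot ptcFound was an in-frame stop codon found inside the retained intron?
#' @slot ptcCodon the stop codon (\code{"TAA"}, \code{"TAG"} or \code{"TGA"})
#'   or \code{NA}.
#' @slot ptcGenomicPos genomic position of the first (transcript-order) base
#'   of the stop codon, or \code{NA}.
#' @slot truncatedLength number of codons translated before the stop.
#' @export
setClass("RetentionConsequence",
  slots = c(
    geneID = "character",
    intronIndex = "integer",
    ptcFound = "logical",
    ptcCodon = "character",
    ptcGenomicPos = "integer",
    truncatedLength = "integer"
  )
)

setValidity("RetentionConsequence", function(object) {
  if (isTRUE(object@ptcFound) && !object@ptcCodon %in% c("TAA", "TAG", "TGA"))
    return("a found PTC must be one of TAA/TAG/TGA")
  TRUE
})

setMethod("show", "RetentionConsequence", function(object) {
  cat("RetentionConsequence: gene ", object@geneID,
      ", intron ", object@intronIndex, "\n", sep = "")
  if (isTRUE(object@ptcFound)) {
    cat("  PTC ", object@ptcCodon, " at genomic position ", object@ptcGenomicPos,
        "; truncated protein length ", object@truncatedLength, " codons\n", sep = "")
  } else {
    cat("  no in-frame stop within the retained intron\n")
  }
})

#' FPKM quantification result
#'
#' Per-gene, per-sample FPKM values together with the quantities entering the
#' formula: raw fragment counts, unique exonic gene lengths, and the
#' per-sample total exonic fragments.
#'
#' @slot counts gene-by-sample integer fragment counts.
#' @slot fpkm gene-by-sample FPKM matrix.
#' @slot geneLengths unique exonic length (bp) per gene.
#' @slot fAllexon total exonic fragments per sample (column sums of counts).
#' @export
setClass("FpkmTable",
  slots = c(
    counts = "matrix",
    fpkm = "matrix",
    geneLengths = "numeric",
    fAllexon = "numeric"
  )
)

setValidity("FpkmTable", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), dim(object@fpkm)))
    msg <- c(msg, "counts and fpkm must have identical dimensions")
  if (any(object@fpkm < 0)) msg <- c(msg, "FPKM values must be non-negative")
  if (any((object@counts == 0) != (object@fpkm == 0)))
    msg <- c(msg, "FPKM must be zero exactly when the count is zero")
  if (length(object@geneLengths) != nrow(object@counts))
    msg <- c(msg, "one gene length per row is required")
  if (length(object@fAllexon) != ncol(object@counts))
    msg <- c(msg, "one exonic-fragment total per sample is required")
  if (length(msg)) msg else TRUE
})

#' @describeIn computeFpkm FPKM matrix accessor
#' @export
fpkmValues <- function(x) x@fpkm

#' @describeIn computeFpkm per-sample total exonic fragments
#' @export
fAllexon <- function(x) x@fAllexon

#' @describeIn computeFpkm unique exonic gene lengths used as denominators
#' @export
fpkmGeneLengths <- function(x) x@geneLengths

setMethod("show", "FpkmTable", function(object) {
  cat("FpkmTable: ", nrow(object@counts), " genes x ", ncol(object@counts),
      " samples\n", sep = "")
  cat("  exonic fragments per sample: ",
      paste(colnames(object@counts), format(object@fAllexon), sep = "=",
            collapse = ", "), "\n", sep = "")
})
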