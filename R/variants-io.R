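#' Read pooled variant calls from a VCF file
#'
#' Reads a two-sample VCF (wild-type sibling pool first, mutant pool second)
#' carrying per-sample allelic depths in the \code{AD} FORMAT field, and
#' returns one row per biallelic single-nucleotide variant in coordinate
#' order. Indel and multi-allelic records are skipped with a message giving
#' the skipped count: only point mutations enter homozygosity mapping.
#'
#' @param path VCF file with exactly two samples and an \code{AD} field.
#' @param wtSample,mutSample column index or sample name of the wild-type
#'   sibling pool and the mutant pool (defaults: first and second sample).
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{wt_ref}, \code{wt_alt}, \code{mut_ref},
#'   \code{mut_alt}. The number of skipped records is attached as attribute
#'   \code{"n_skipped"}.
#' @export
readVariants <- function(path, wtSample = 1L, mutSample = 2L) {
  stopifnot(file.exists(path))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  if (ncol(vcf) < 2L)
    stop("two pool samples are required; found ", ncol(vcf))
  if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("AD (allelic depth) FORMAT field is missing from ", path)
  nTotal <- nrow(vcf)
  keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  nSkipped <- nTotal - sum(keep)
  if (nSkipped > 0L)
    message(nSkipped, " record(s) skipped (indel or multi-allelic)")
  vcf <- vcf[keep, ]
  if (nrow(vcf) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      wt_ref = integer(), wt_alt = integer(),
                      mut_ref = integer(), mut_alt = integer())
    attr(out, "n_skipped") <- nSkipped
    return(out)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  adPair <- function(sample) {
    v <- ad[, sample]
    if (is.list(v)) {
      m <- do.call(rbind, lapply(v, function(x) as.integer(x[1:2])))
    } else {
      m <- matrix(as.integer(v), ncol = 2L)
    }
    if (anyNA(m)) stop("missing AD depth value in ", path)
    m
  }
  wt <- adPair(wtSample)
  mut <- adPair(mutSample)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a[[1L]]), character(1)),
    wt_ref = wt[, 1L], wt_alt = wt[, 2L],
    mut_ref = mut[, 1L], mut_alt = mut[, 2L],
    row.names = NULL
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- nSkipped
  out
}

#' Write pooled variant calls to a VCF file
#'
#' Inverse of \code{\link{readVariants}} for the records that reader retains:
#' chromosome, position, alleles and both pools' allelic depths round-trip
#' exactly.
#'
#' @param variants data.frame as returned by \code{\link{readVariants}}.
#' @param path output VCF path.
#' @param sampleNames names for the two pool columns.
#' @export
writeVariants <- function(variants, path,
                          sampleNames = c("WT_POOL", "MUT_POOL")) {
  need <- c("chrom", "pos", "ref", "alt", "wt_ref", "wt_alt", "mut_ref", "mut_alt")
  stopifnot(all(need %in% names(variants)), length(sampleNames) == 2L)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=screenmap",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleNames), collapse = "\t")
  )
  body <- if (nrow(variants)) {
    paste(variants$chrom, variants$pos, ".", variants$ref, variants$alt,
          ".", ".", ".", "AD",
          paste0(variants$wt_ref, ",", variants$wt_alt),
          paste0(variants$mut_ref, ",", variants$mut_alt),
          sep = "\t")
  } else {
    character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a count matrix to TSV
#'
#' @param counts matrix with feature row names and sample column names.
#' @param path output TSV path.
#' @export
writeCountMatrix <- function(counts, path) {
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' Expects a \code{feature_id} column followed by one integer column per
#' sample; feature ids must be unique and counts non-negative.
#'
#' @param path TSV written by \code{\link{writeCountMatrix}} or equivalent.
#' @return Integer matrix with feature row names.
#' @export
readCountMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  stopifnot("feature_id" %in% names(df))
  if (anyDuplicated(df$feature_id)) stop("feature ids must be unique")
  m <- as.matrix(df[, setdiff(names(df), "feature_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(m < 0)) stop("counts must be non-negative")
  rownames(m) <- df$feature_id
  m
}
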