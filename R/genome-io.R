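#' Read a genome from FASTA
#'
#' Loads a genome as a named \code{DNAStringSet}, uppercased, with sequence
#' names truncated at the first whitespace. Any genome, real or synthetic,
#' fills the reference-genome role of the pipeline.
#'
#' @param path FASTA file.
#' @return Named \code{DNAStringSet}.
#' @export
readGenome <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  toupper(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome named \code{DNAStringSet}.
#' @param path output FASTA file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, filepath = path)
  invisible(path)
}

.checkChromPos <- function(genome, chrom, pos) {
  if (!chrom %in% names(genome))
    stop("chromosome '", chrom, "' not present in genome")
  len <- length(genome[[chrom]])
  if (any(pos < 1L) || any(pos > len))
    stop("position out of range for ", chrom, " (length ", len, ")")
  invisible(len)
}

#' Look up genome bases by 1-based position
#'
#' @param genome named \code{DNAStringSet}.
#' @param chrom chromosome name.
#' @param pos 1-based position(s); out-of-range positions are an error.
#' @return Character vector of single bases, one per position.
#' @export
genomeBase <- function(genome, chrom, pos) {
  .checkChromPos(genome, chrom, pos)
  as.character(Biostrings::extractAt(genome[[chrom]], IRanges::IRanges(pos, pos)))
}

#' Extract a genomic subsequence (1-based closed interval)
#'
#' @inheritParams genomeBase
#' @param start,end 1-based closed interval bounds.
#' @return Single character string.
#' @export
genomeSlice <- function(genome, chrom, start, end) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  .checkChromPos(genome, chrom, c(start, end))
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

# 1-based closed <-> 0-based half-open (BED) interval conversion.
# Single conversion point for all BED exports; converting there and back is
# the identity.
.toBed0 <- function(start1, end1) {
  data.frame(start0 = as.integer(start1) - 1L, end0 = as.integer(end1))
}

.fromBed0 <- function(start0, end0) {
  data.frame(start1 = as.integer(start0) + 1L, end1 = as.integer(end0))
}

#' Export intervals to a BED file
#'
#' Converts 1-based closed intervals to BED's 0-based half-open convention
#' and writes a plain BED file via \code{rtracklayer}.
#'
#' @param gr \code{GRanges} to export.
#' @param path output BED path.
#' @export
exportBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
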