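# Toy genes with explicit exon/intron sequences, plus independent oracles
# used by the property-style tests.

.rc <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.codonsNoStop <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Build a one-gene genome from transcription-order exon/intron sequences.
# For minus-strand genes the genomic sequence is the reverse complement of
# the transcript-order layout, so the extracted coding sequence equals the
# concatenated exonSeqs on either strand.
toyGene <- function(exonSeqs, intronSeqs = character(), strand = "+",
                    chrom = "chrT", pad = 200L, id = "toy") {
  n <- length(exonSeqs)
  stopifnot(length(intronSeqs) == max(n - 1L, 0L))
  pieces <- character(2L * n - 1L)
  pieces[seq(1L, 2L * n - 1L, by = 2L)] <- exonSeqs
  if (n > 1L) pieces[seq(2L, 2L * n - 2L, by = 2L)] <- intronSeqs
  locus <- paste(pieces, collapse = "")
  widths <- nchar(pieces)
  if (strand == "-") {
    locus <- .rc(locus)
    widths <- rev(widths)
  }
  starts <- pad + 1L + c(0L, cumsum(widths))[seq_along(widths)]
  exIdx <- seq(1L, length(widths), by = 2L)
  exStarts <- starts[exIdx]
  exEnds <- exStarts + widths[exIdx] - 1L
  genomeStr <- paste0(strrep("A", pad), locus, strrep("A", pad))
  genome <- Biostrings::DNAStringSet(stats::setNames(genomeStr, chrom))
  list(gene = geneModel(id, chrom, strand, exStarts, exEnds),
       genome = genome, locusStart = pad + 1L)
}

randomToyGene <- function(maxExons = 5L) {
  nEx <- sample(2:maxExons, 1L)
  exonSeqs <- vapply(seq_len(nEx), function(i)
    paste(sample(.codonsNoStop, sample(5:20, 1L), TRUE), collapse = ""),
    character(1))
  intronSeqs <- vapply(seq_len(nEx - 1L), function(i)
    paste0("GT", randDna(sample(20:60, 1L)), "AG"), character(1))
  toyGene(exonSeqs, intronSeqs, strand = sample(c("+", "-"), 1L))
}

# Independent effect-classification oracle: mutate the full genome string,
# re-extract and translate the CDS, and compare proteins.
oracleClassify <- function(chrom, pos, alt, gene, genome) {
  span <- geneSpan(gene)
  if (geneChrom(gene) != chrom ||
      pos < BiocGenerics::start(span) || pos > BiocGenerics::end(span))
    return("intergenic")
  intr <- geneIntrons(gene)
  if (length(intr)) {
    s <- BiocGenerics::start(intr)
    e <- BiocGenerics::end(intr)
    splice <- if (geneStrand(gene) == "+") c(s, s + 1L, e, e - 1L)
      else c(e, e - 1L, s, s + 1L)
    if (pos %in% splice) return("essential_splice")
  }
  ints <- BiocGenerics::intersect(geneExons(gene), cdsRange(gene))
  cdspos <- unlist(Map(seq.int, BiocGenerics::start(ints), BiocGenerics::end(ints)),
                   use.names = FALSE)
  if (!pos %in% cdspos) return("intronic")
  refChars <- strsplit(as.character(genome[[chrom]]), "")[[1]]
  altChars <- refChars
  altChars[pos] <- alt
  extract <- function(chars) {
    cds <- paste(chars[cdspos], collapse = "")
    if (geneStrand(gene) == "-") cds <- .rc(cds)
    cds
  }
  aa <- function(cds) strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds))), "")[[1]]
  a <- aa(extract(refChars))
  b <- aa(extract(altChars))
  if (identical(a, b)) return("synonymous")
  d <- which(a != b)[1L]
  if (b[d] == "*") "nonsense" else "missense"
}

# Naive per-window recount of the homozygosity score.
oracleWindows <- function(calls, windowSize, step, chromLengths) {
  do.call(rbind, lapply(sort(unique(calls$chrom)), function(ch) {
    sub <- calls[calls$chrom == ch, ]
    chromLen <- chromLengths[[ch]]
    starts <- seq(1, max(chromLen - windowSize + 1, 1), by = step)
    if (chromLen > windowSize &&
        starts[length(starts)] < chromLen - windowSize + 1)
      starts <- c(starts, chromLen - windowSize + 1)
    do.call(rbind, lapply(starts, function(s) {
      e <- min(s + windowSize - 1, chromLen)
      inWin <- sub$pos >= s & sub$pos <= e
      data.frame(chrom = ch, start = s, end = e,
                 n_variants = sum(inWin),
                 n_specific = sum(inWin & sub$mutant_specific_hom),
                 score = if (sum(inWin) > 0)
                   100 * sum(inWin & sub$mutant_specific_hom) / sum(inWin)
                 else NA_real_)
    }))
  }))
}

# Independent evaluation of the four junction predicates plus the count
# prefilter; returns the keys of the retained junctions.
oracleJunctionKeys <- function(j, cfg) {
  wtRpm <- j$wt_count * 1e6 / sum(j$wt_count)
  mutRpm <- j$mut_count * 1e6 / sum(j$mut_count)
  c0 <- cfg$pseudocount
  keep <- logical(nrow(j))
  for (i in seq_len(nrow(j))) {
    li <- (log2(wtRpm[i] + c0) + log2(mutRpm[i] + c0)) / 2
    lr <- log2((mutRpm[i] + c0) / (wtRpm[i] + c0))
    fc <- (max(wtRpm[i], mutRpm[i]) + c0) / (min(wtRpm[i], mutRpm[i]) + c0)
    av <- (wtRpm[i] + mutRpm[i]) / 2
    keep[i] <- li > cfg$minLog2AvgIntensity && abs(lr) > cfg$minAbsLog2Ratio &&
      fc > cfg$minFoldChange && av > cfg$minAvgRpm &&
      max(j$wt_count[i], j$mut_count[i]) >= cfg$minCount
  }
  paste(j$chrom, j$donor_end, j$acceptor_start, sep = ":")[keep]
}

junctionKeys <- function(j) paste(j$chrom, j$donor_end, j$acceptor_start, sep = ":")

wilsonOracle <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

writeTestVcf <- function(path, lines) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "WT_POOL", "MUT_POOL"), collapse = "\t")
  )
  writeLines(c(hdr, lines), path)
  path
}
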