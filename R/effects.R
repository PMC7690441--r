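.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.comp <- function(base) chartr("ACGT", "TGCA", base)

.stopCodons <- c("TAA", "TAG", "TGA")

# Essential splice positions of a gene: the first/last two intronic bases of
# each intron, oriented on the coding strand (donor = intron start on the
# transcription side, canonical GT; acceptor = intron end, canonical AG).
.spliceSiteTable <- function(gene) {
  intr <- geneIntrons(gene)
  if (length(intr) == 0L)
    return(data.frame(pos = integer(), site = character(),
                      offset = integer(), intron = integer()))
  s <- BiocGenerics::start(intr)
  e <- BiocGenerics::end(intr)
  idx <- seq_along(intr)
  if (geneStrand(gene) == "+") {
    df <- data.frame(
      pos = c(s, s + 1L, e, e - 1L),
      site = rep(c("donor", "donor", "acceptor", "acceptor"), each = length(intr)),
      offset = rep(c(1L, 2L, 1L, 2L), each = length(intr)),
      intron = rep(idx, 4L))
  } else {
    df <- data.frame(
      pos = c(e, e - 1L, s, s + 1L),
      site = rep(c("donor", "donor", "acceptor", "acceptor"), each = length(intr)),
      offset = rep(c(1L, 2L, 1L, 2L), each = length(intr)),
      intron = rep(idx, 4L))
  }
  # very short introns: a position can be both donor and acceptor side;
  # donor rows come first and win
  df[!duplicated(df$pos), , drop = FALSE]
}

# Transcription-ordered CDS map: genomic position of each coding base and
# the coding-strand CDS sequence. Minus-strand genes are reverse-complemented
# here and only here.
.codingMap <- function(gene, genome) {
  ints <- BiocGenerics::intersect(geneExons(gene), cdsRange(gene))
  pos <- unlist(mapply(seq.int, BiocGenerics::start(ints), BiocGenerics::end(ints),
                       SIMPLIFY = FALSE), use.names = FALSE)
  chunks <- mapply(function(a, b) genomeSlice(genome, geneChrom(gene), a, b),
                   BiocGenerics::start(ints), BiocGenerics::end(ints))
  seqPlus <- paste(chunks, collapse = "")
  if (geneStrand(gene) == "+") {
    list(pos = pos, seq = seqPlus)
  } else {
    list(pos = rev(pos), seq = .revcomp(seqPlus))
  }
}

.emptyEffects <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), gene_id = character(), category = character(),
             detail = character())
}

#' Classify the consequence of a single-nucleotide variant
#'
#' Assigns one of \code{essential_splice}, \code{nonsense}, \code{missense},
#' \code{synonymous}, \code{intronic} or \code{intergenic}, with precedence
#' in that order. Essential splice sites are the first/last two intronic
#' bases of each intron on the coding strand (the canonical GT donor / AG
#' acceptor dinucleotides); coding consequences are computed by splicing the
#' exons, substituting the alternate allele, and translating the affected
#' codon with the standard nuclear code. Intragenic positions outside the
#' CDS and splice sites (including untranslated exonic bases) fall in the
#' \code{intronic} bucket.
#'
#' @param variant list or one-row data.frame with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (single bases).
#' @param genes named list of \linkS4class{GeneModel} objects.
#' @param genome named \code{DNAStringSet} covering the variant position.
#' @return One-row data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene_id} (\code{NA} when intergenic),
#'   \code{category} and \code{detail}.
#' @export
classifyEffect <- function(variant, genes, genome) {
  chrom <- as.character(variant$chrom)
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  gbase <- genomeBase(genome, chrom, pos)
  if (gbase != ref)
    stop("reference mismatch at ", chrom, ":", pos,
         " (variant ref ", ref, ", genome ", gbase, ")")
  res <- function(geneId, category, detail) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               gene_id = geneId, category = category, detail = detail)
  }
  hit <- NULL
  for (g in genes) {
    if (geneChrom(g) != chrom) next
    sp <- geneSpan(g)
    if (pos >= BiocGenerics::start(sp) && pos <= BiocGenerics::end(sp)) {
      hit <- g
      break
    }
  }
  if (is.null(hit)) return(res(NA_character_, "intergenic", ""))
  ss <- .spliceSiteTable(hit)
  m <- match(pos, ss$pos)
  if (!is.na(m)) {
    return(res(geneID(hit), "essential_splice",
               paste0(ss$site[m], "_site_offset=", ss$offset[m],
                      ";intron=", ss$intron[m])))
  }
  map <- .codingMap(hit, genome)
  ci <- match(pos, map$pos)
  if (!is.na(ci)) {
    codonN <- (ci - 1L) %/% 3L + 1L
    within <- (ci - 1L) %% 3L + 1L
    codon <- substr(map$seq, 3L * codonN - 2L, 3L * codonN)
    altOriented <- if (geneStrand(hit) == "+") alt else .comp(alt)
    newCodon <- codon
    substr(newCodon, within, within) <- altOriented
    aaRef <- Biostrings::GENETIC_CODE[[codon]]
    aaAlt <- Biostrings::GENETIC_CODE[[newCodon]]
    category <- if (newCodon %in% .stopCodons) "nonsense"
      else if (aaRef == aaAlt) "synonymous" else "missense"
    return(res(geneID(hit), category,
               paste0("codon=", codonN, ";", codon, ">", newCodon,
                      ";aa=", aaRef, ">", aaAlt)))
  }
  res(geneID(hit), "intronic", "")
}

#' Classify many variants
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} columns.
#' @inheritParams classifyEffect
#' @return data.frame with one classified row per variant.
#' @export
classifyEffects <- function(variants, genes, genome) {
  if (nrow(variants) == 0L) return(.emptyEffects())
  out <- do.call(rbind, lapply(seq_len(nrow(variants)), function(i)
    classifyEffect(variants[i, ], genes, genome)))
  rownames(out) <- NULL
  out
}

#' Screen the mapped peak for nonsense and essential splice candidates
#'
#' Takes the mutant-specific homozygous variants that fall inside the
#' homozygosity peak interval, classifies each, and returns only those whose
#' consequence is \code{nonsense} or \code{essential_splice}, sorted by
#' position — the candidate causal mutations of the screen.
#'
#' @param profile a \linkS4class{HomozygosityProfile} with a defined peak.
#' @param calls data.frame from \code{\link{callZygosity}}.
#' @inheritParams classifyEffect
#' @return data.frame of candidate variant effects (possibly empty).
#' @export
screenCandidates <- function(profile, calls, genes, genome) {
  peak <- peakInterval(profile)
  if (length(peak) == 0L) return(.emptyEffects())
  pchrom <- as.character(GenomicRanges::seqnames(peak))
  sel <- calls[calls$mutant_specific_hom &
                 calls$chrom == pchrom &
                 calls$pos >= BiocGenerics::start(peak) &
                 calls$pos <= BiocGenerics::end(peak), , drop = FALSE]
  eff <- classifyEffects(sel, genes, genome)
  eff <- eff[eff$category %in% c("nonsense", "essential_splice"), , drop = FALSE]
  eff <- eff[order(eff$pos), , drop = FALSE]
  rownames(eff) <- NULL
  eff
}

#' Predict the consequence of retaining one intron
#'
#' Constructs the transcript with the given intron retained, continues the
#' coding reading frame from the upstream exons into the retained intron,
#' and reports the first in-frame stop codon (a premature termination
#' codon). If the frame runs through the whole intron without a stop,
#' \code{ptcFound} is \code{FALSE}.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param intronIndex intron to retain (1-based, genomic order).
#' @param genome named \code{DNAStringSet}.
#' @return A \linkS4class{RetentionConsequence}.
#' @export
retentionConsequence <- function(gene, intronIndex, genome) {
  intr <- geneIntrons(gene)
  intronIndex <- as.integer(intronIndex)
  if (intronIndex < 1L || intronIndex > length(intr))
    stop("intronIndex must be between 1 and ", length(intr))
  ir <- intr[intronIndex]
  map <- .codingMap(gene, genome)
  plus <- geneStrand(gene) == "+"
  if (plus) {
    upKeep <- map$pos < BiocGenerics::start(ir)
    intronPos <- seq.int(BiocGenerics::start(ir), BiocGenerics::end(ir))
    intronSeq <- genomeSlice(genome, geneChrom(gene),
                             BiocGenerics::start(ir), BiocGenerics::end(ir))
  } else {
    upKeep <- map$pos > BiocGenerics::end(ir)
    intronPos <- seq.int(BiocGenerics::end(ir), BiocGenerics::start(ir))
    intronSeq <- .revcomp(genomeSlice(genome, geneChrom(gene),
                                      BiocGenerics::start(ir), BiocGenerics::end(ir)))
  }
  nUp <- sum(upKeep)
  upSeq <- substr(map$seq, 1L, nUp)
  posVec <- c(map$pos[upKeep], intronPos)
  full <- paste0(upSeq, intronSeq)
  firstIntronCodon <- nUp %/% 3L + 1L
  lastFullCodon <- nchar(full) %/% 3L
  found <- FALSE
  ptcCodon <- NA_character_
  ptcPos <- NA_integer_
  truncated <- NA_integer_
  if (lastFullCodon >= firstIntronCodon) {
    for (k in firstIntronCodon:lastFullCodon) {
      codon <- substr(full, 3L * k - 2L, 3L * k)
      if (codon %in% .stopCodons) {
        found <- TRUE
        ptcCodon <- codon
        ptcPos <- as.integer(posVec[3L * k - 2L])
        truncated <- k - 1L
        break
      }
    }
  }
  new("RetentionConsequence", geneID = geneID(gene),
      intronIndex = intronIndex, ptcFound = found, ptcCodon = ptcCodon,
      ptcGenomicPos = ptcPos, truncatedLength = truncated)
}
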