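#' Read gene models from a GFF3 file
#'
#' Builds validated \linkS4class{GeneModel} objects from \code{gene},
#' \code{exon} and \code{CDS} features. Exons may be parented directly by the
#' gene or by an intermediate transcript (\code{mRNA}) feature; one
#' transcript per gene is assumed (the pipeline works at gene resolution).
#' The CDS interval is taken as the span of all CDS features of the gene.
#'
#' @param path GFF3 file.
#' @return Named list of \linkS4class{GeneModel} objects (names are gene ids).
#' @export
readGeneModels <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  firstParent <- function(i) {
    p <- md$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
  }
  parent <- vapply(seq_along(gr), firstParent, character(1))
  geneIdx <- which(type == "gene")
  if (length(geneIdx) == 0L) stop("no gene features in ", path)
  geneIds <- ids[geneIdx]
  if (anyNA(geneIds)) stop("gene features must carry an ID attribute")
  # resolve a feature's owning gene through at most one transcript level
  toGene <- function(p) {
    if (p %in% geneIds) return(p)
    j <- match(p, ids)
    if (is.na(j)) stop("feature parent '", p, "' not found in ", path)
    gp <- parent[j]
    if (is.na(gp) || !gp %in% geneIds)
      stop("cannot resolve parent '", p, "' to a gene")
    gp
  }
  models <- vector("list", length(geneIdx))
  names(models) <- geneIds
  exonIdx <- which(type == "exon")
  cdsIdx <- which(type == "CDS")
  exonGene <- vapply(parent[exonIdx], toGene, character(1))
  cdsGene <- if (length(cdsIdx)) vapply(parent[cdsIdx], toGene, character(1)) else character()
  for (k in seq_along(geneIdx)) {
    gid <- geneIds[k]
    gi <- geneIdx[k]
    ei <- exonIdx[exonGene == gid]
    if (length(ei) == 0L) stop("gene '", gid, "' has no exons")
    es <- BiocGenerics::start(gr)[ei]
    ee <- BiocGenerics::end(gr)[ei]
    o <- order(es)
    ci <- cdsIdx[cdsGene == gid]
    if (length(ci)) {
      cs <- min(BiocGenerics::start(gr)[ci])
      ce <- max(BiocGenerics::end(gr)[ci])
    } else {
      cs <- NULL
      ce <- NULL
    }
    models[[k]] <- geneModel(
      geneID = gid,
      chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(BiocGenerics::strand(gr))[gi],
      exonStarts = es[o], exonEnds = ee[o],
      cdsStart = cs, cdsEnd = ce
    )
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' @param genes list of \linkS4class{GeneModel} objects.
#' @param path output GFF3 path.
#' @export
writeGeneModels <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    ex <- geneExons(g)
    sp <- geneSpan(g)
    gid <- geneID(g)
    lines <- c(lines,
      paste(geneChrom(g), "screenmap", "gene",
            BiocGenerics::start(sp), BiocGenerics::end(sp), ".",
            geneStrand(g), ".", paste0("ID=", gid), sep = "\t"),
      paste(geneChrom(g), "screenmap", "exon",
            BiocGenerics::start(ex), BiocGenerics::end(ex), ".",
            geneStrand(g), ".",
            paste0("ID=", gid, ":exon", seq_along(ex), ";Parent=", gid),
            sep = "\t"))
    cdsParts <- BiocGenerics::intersect(ex, cdsRange(g))
    lines <- c(lines,
      paste(geneChrom(g), "screenmap", "CDS",
            BiocGenerics::start(cdsParts), BiocGenerics::end(cdsParts), ".",
            geneStrand(g), "0",
            paste0("ID=", gid, ":cds", seq_along(cdsParts), ";Parent=", gid),
            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
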