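#' Compute FPKM with exon-union gene lengths
#'
#' Implements the duplication-aware FPKM used for genomes with many
#' paralogous gene copies: fragments are assumed to have been summed per
#' gene id across all of its genomic loci (the input contract of the count
#' table), and the length denominator is the number of unique exonic bases
#' of the gene. Per sample,
#' \deqn{FPKM = F_{gene} \times 1000 \times 1{,}000{,}000 /
#'   (F_{allexon} \times L_{gene})}
#' where \eqn{F_{gene}} is the gene's fragment count, \eqn{F_{allexon}} the
#' total exonic fragments of the sample (the column sum of the gene counts),
#' and \eqn{L_{gene}} the unique exonic length in bases.
#'
#' @param counts gene-by-sample matrix of non-negative integer fragment
#'   counts with gene ids as row names.
#' @param genes named list of \linkS4class{GeneModel} covering every counted
#'   gene.
#' @return An \linkS4class{FpkmTable}.
#' @export
computeFpkm <- function(counts, genes) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  missing <- setdiff(rownames(counts), names(genes))
  if (length(missing))
    stop("no gene model for: ", paste(head(missing, 5), collapse = ", "))
  L <- vapply(rownames(counts), function(g) uniqueExonicLength(genes[[g]]),
              numeric(1))
  if (any(L < 1)) stop("gene with zero unique exonic length")
  fAll <- colSums(counts)
  if (any(fAll == 0))
    stop("empty library: a sample has zero exonic fragments")
  fpkm <- sweep(counts * 1e9 / L, 2L, fAll, `/`)
  new("FpkmTable", counts = counts, fpkm = fpkm, geneLengths = L,
      fAllexon = fAll)
}

#' Pure fold-change differential expression
#'
#' The screen's differential call uses fold change only (single library per
#' condition, no replicates, hence no dispersion estimate and no p-values).
#' A small pseudocount keeps log2 fold changes finite when one side is zero;
#' such records are flagged. A gene counts as expressed when its FPKM
#' exceeds 0.1 in both samples (strict), and as detected when at least one
#' fragment was observed in either sample.
#'
#' @param fpkmTable an \linkS4class{FpkmTable} with a wild-type and a mutant
#'   sample.
#' @param epsilon pseudocount on the FPKM scale (default 1e-6).
#' @param wtSample,mutSample column names or indices (defaults: first and
#'   second column).
#' @param expressedMinFpkm expressed-filter threshold (default 0.1, strict
#'   greater-than in both samples).
#' @return data.frame with columns \code{gene_id}, \code{wt_fpkm},
#'   \code{mut_fpkm}, \code{log2fc}, \code{expressed_both},
#'   \code{detected_any}, \code{zero_side}.
#' @export
foldChanges <- function(fpkmTable, epsilon = 1e-6,
                        wtSample = 1L, mutSample = 2L,
                        expressedMinFpkm = 0.1) {
  stopifnot(is(fpkmTable, "FpkmTable"), epsilon > 0)
  fp <- fpkmValues(fpkmTable)
  cnt <- fpkmTable@counts
  wt <- fp[, wtSample]
  mut <- fp[, mutSample]
  data.frame(
    gene_id = rownames(fp),
    wt_fpkm = unname(wt),
    mut_fpkm = unname(mut),
    log2fc = unname(log2((mut + epsilon) / (wt + epsilon))),
    expressed_both = unname(wt > expressedMinFpkm & mut > expressedMinFpkm),
    detected_any = unname(cnt[, wtSample] >= 1 | cnt[, mutSample] >= 1),
    zero_side = unname(wt == 0 | mut == 0),
    row.names = NULL
  )
}

#' Top up- and downregulated genes
#'
#' Ranks the expressed genes by log2 fold change and returns the top
#' \code{n} up- and downregulated records, with a deterministic gene-id
#' tie-break. When fewer than \code{n} records qualify, all are returned and
#' the shortfall is messaged.
#'
#' @param records data.frame from \code{\link{foldChanges}}; only rows with
#'   \code{expressed_both} are ranked.
#' @param n list length per direction (default 10).
#' @return List with data.frames \code{up} and \code{down}.
#' @export
rankTop <- function(records, n = 10L) {
  qual <- records[records$expressed_both, , drop = FALSE]
  if (nrow(qual) < n)
    message("only ", nrow(qual), " expressed records available for top-", n,
            " ranking")
  up <- qual[order(-qual$log2fc, qual$gene_id), , drop = FALSE]
  down <- qual[order(qual$log2fc, qual$gene_id), , drop = FALSE]
  list(up = utils::head(up, n), down = utils::head(down, n))
}
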