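#' Simulate a catalogue of gene models
#'
#' Lays random multi-exon gene structures (2-8 exons, coding-frame exon
#' lengths, 80-400 bp introns) end to end along synthetic chromosomes. Used
#' as the annotation substrate for count simulation, FPKM and junction
#' analysis; no genome sequence is attached.
#'
#' @param nGenes number of genes.
#' @param nChromosomes chromosomes to spread the genes over.
#' @param seed RNG seed.
#' @return Named list of \linkS4class{GeneModel} objects.
#' @export
simulateGeneModels <- function(nGenes = 2000L, nChromosomes = 25L, seed = 1L) {
  stopifnot(nGenes >= 1L, nChromosomes >= 1L)
  set.seed(seed)
  perChrom <- ceiling(nGenes / nChromosomes)
  genes <- vector("list", nGenes)
  ids <- sprintf("gene%04d", seq_len(nGenes))
  k <- 0L
  for (ch in seq_len(nChromosomes)) {
    cursor <- 1000L
    for (j in seq_len(perChrom)) {
      k <- k + 1L
      if (k > nGenes) break
      nEx <- sample(2:8, 1L)
      exLen <- 3L * sample(30:80, nEx, replace = TRUE)
      inLen <- sample(80:400, max(nEx - 1L, 1L), replace = TRUE)
      starts <- integer(nEx)
      pos <- cursor
      for (e in seq_len(nEx)) {
        starts[e] <- pos
        pos <- pos + exLen[e]
        if (e < nEx) pos <- pos + inLen[e]
      }
      genes[[k]] <- geneModel(ids[k], paste0("chr", ch), sample(c("+", "-"), 1L),
                              exonStarts = starts,
                              exonEnds = starts + exLen - 1L)
      cursor <- pos + sample(500:2000, 1L)
    }
  }
  stats::setNames(genes, ids)
}

#' Configuration for the RNA-seq count simulator
#'
#' Plants class-structured log2 fold changes on a gene catalogue, mirroring
#' the effect-size menu observed in a splicing-mutant screen: strongly
#' upregulated apoptotic genes (~ +4), mildly upregulated spliceosome
#' components (~ +3.7), moderately downregulated genes (~ -2.7), and
#' vision genes collapsing towards zero expression in the mutant (planted
#' log2 fold changes spread over -17 to -7). One causal gene is upregulated
#' (+3.35) and additionally produces intron-retention junction reads in the
#' mutant sample only.
#'
#' @param nGenes number of genes the catalogue must contain.
#' @param classes data.frame with columns \code{class}, \code{log2fc},
#'   \code{n}: the finite planted classes. Genes not assigned to any class
#'   (or to the vision class) are null (log2 fold change 0).
#' @param visionLog2fc per-gene planted log2 fold changes of the
#'   "down to zero" vision class.
#' @param baselineMean expected wild-type fragments per gene (default 100,
#'   uniform across genes so that planted ratios are the only structure).
#' @param dispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \phi \mu^2}); 0 gives deterministic rounded means.
#' @param librarySizes relative depth factors for the two samples.
#' @param causalGene gene id of the causal gene (default: first gene).
#' @param causalLog2fc planted upregulation of the causal gene.
#' @param retentionFraction fraction of the causal gene's mutant junction
#'   coverage that reads through the retained intron (novel junctions).
#' @param retainedIntron index (genomic order) of the retained intron within
#'   the causal gene; default: the middle intron.
#' @param seed RNG seed.
#' @return Validated list of class \code{"expressionSimConfig"}.
#' @export
expressionSimConfig <- function(nGenes = 2000L,
                                classes = data.frame(
                                  class = c("apoptotic_up", "spliceosome_up",
                                            "moderate_down"),
                                  log2fc = c(4.2, 3.7, -2.7),
                                  n = c(10L, 5L, 10L)),
                                visionLog2fc = seq(-17, -7, length.out = 10L),
                                baselineMean = 100,
                                dispersion = 0.05,
                                librarySizes = c(WT = 1, MUT = 1),
                                causalGene = NULL,
                                causalLog2fc = 3.35,
                                retentionFraction = 0.2,
                                retainedIntron = NULL,
                                seed = 1L) {
  stopifnot(
    nGenes >= 1L,
    all(c("class", "log2fc", "n") %in% names(classes)),
    all(classes$n >= 0L),
    baselineMean > 0, dispersion >= 0,
    length(librarySizes) == 2L, all(librarySizes > 0),
    retentionFraction >= 0, retentionFraction <= 1
  )
  if (sum(classes$n) + length(visionLog2fc) + 1L > nGenes)
    stop("planted classes require more genes than nGenes provides")
  cfg <- list(nGenes = as.integer(nGenes), classes = classes,
              visionLog2fc = visionLog2fc, baselineMean = baselineMean,
              dispersion = dispersion, librarySizes = librarySizes,
              causalGene = causalGene, causalLog2fc = causalLog2fc,
              retentionFraction = retentionFraction,
              retainedIntron = retainedIntron, seed = as.integer(seed))
  class(cfg) <- "expressionSimConfig"
  cfg
}

.nbDraw <- function(mu, dispersion) {
  if (dispersion == 0) return(as.integer(round(mu)))
  as.integer(rnbinom(length(mu), size = 1 / dispersion, mu = mu))
}

#' Simulate gene and junction fragment counts with planted effects
#'
#' Gene counts are negative-binomial around class-planted fold changes;
#' junction counts cover every annotated intron junction of every gene at
#' the gene's expression level, plus, for the causal gene, novel
#' exon-intron boundary junctions carrying the configured retention
#' fraction in the mutant sample only (the canonical junction across the
#' retained intron loses the same fraction).
#'
#' @param config an \code{\link{expressionSimConfig}}.
#' @param genes named list of \linkS4class{GeneModel} (at least
#'   \code{config$nGenes} of them; extra genes are ignored).
#' @return List with \code{geneCounts} (gene-by-sample integer matrix),
#'   \code{junctionCounts} (data.frame: \code{chrom}, \code{donor_end},
#'   \code{acceptor_start}, \code{wt_count}, \code{mut_count}) and
#'   \code{truth} (per-gene class and planted log2 fold change, causal gene,
#'   retained intron, novel junction coordinates).
#' @export
simulateCounts <- function(config, genes) {
  stopifnot(inherits(config, "expressionSimConfig"))
  if (length(genes) < config$nGenes)
    stop("gene catalogue has fewer genes than config$nGenes")
  genes <- genes[seq_len(config$nGenes)]
  ids <- vapply(genes, geneID, character(1))
  names(genes) <- ids
  set.seed(config$seed)

  causal <- if (is.null(config$causalGene)) ids[1L] else config$causalGene
  if (!causal %in% ids) stop("causal gene '", causal, "' not in the catalogue")

  lfc <- stats::setNames(rep(0, length(ids)), ids)
  classLab <- stats::setNames(rep("null", length(ids)), ids)
  lfc[causal] <- config$causalLog2fc
  classLab[causal] <- "causal_up"
  assignable <- sample(setdiff(ids, causal))
  cursor <- 0L
  for (i in seq_len(nrow(config$classes))) {
    n <- config$classes$n[i]
    if (n == 0L) next
    sel <- assignable[cursor + seq_len(n)]
    cursor <- cursor + n
    lfc[sel] <- config$classes$log2fc[i]
    classLab[sel] <- config$classes$class[i]
  }
  nv <- length(config$visionLog2fc)
  if (nv > 0L) {
    sel <- assignable[cursor + seq_len(nv)]
    cursor <- cursor + nv
    lfc[sel] <- config$visionLog2fc
    classLab[sel] <- "vision_down"
  }

  muWt <- rep(config$baselineMean, length(ids)) * config$librarySizes[[1L]]
  muMut <- config$baselineMean * 2^lfc * config$librarySizes[[2L]]
  geneCounts <- cbind(.nbDraw(muWt, config$dispersion),
                      .nbDraw(muMut, config$dispersion))
  dimnames(geneCounts) <- list(ids, names(config$librarySizes))

  # junctions: one record per annotated intron, at the gene's coverage
  retIdx <- NULL
  jrows <- vector("list", length(ids))
  novelRows <- NULL
  for (i in seq_along(ids)) {
    g <- genes[[i]]
    intr <- geneIntrons(g)
    if (length(intr) == 0L) next
    ds <- BiocGenerics::start(intr) - 1L   # last base of upstream exon
    as_ <- BiocGenerics::end(intr) + 1L    # first base of downstream exon
    jMuWt <- rep(config$baselineMean * config$librarySizes[[1L]], length(intr))
    jMuMut <- rep(config$baselineMean * 2^lfc[i] * config$librarySizes[[2L]],
                  length(intr))
    if (ids[i] == causal) {
      retIdx <- if (is.null(config$retainedIntron))
        as.integer(ceiling(length(intr) / 2)) else as.integer(config$retainedIntron)
      if (retIdx < 1L || retIdx > length(intr))
        stop("retainedIntron out of range for the causal gene")
      retained <- intr[retIdx]
      jMuMut[retIdx] <- jMuMut[retIdx] * (1 - config$retentionFraction)
      if (config$retentionFraction > 0) {
        novelMu <- config$baselineMean * 2^lfc[i] * config$librarySizes[[2L]] *
          config$retentionFraction
        novelRows <- data.frame(
          chrom = geneChrom(g),
          donor_end = c(BiocGenerics::start(retained) - 1L, BiocGenerics::end(retained)),
          acceptor_start = c(BiocGenerics::start(retained), BiocGenerics::end(retained) + 1L),
          wt_count = 0L,
          mut_count = .nbDraw(rep(novelMu, 2L), config$dispersion)
        )
      }
    }
    jrows[[i]] <- data.frame(
      chrom = geneChrom(g), donor_end = ds, acceptor_start = as_,
      wt_count = .nbDraw(jMuWt, config$dispersion),
      mut_count = .nbDraw(jMuMut, config$dispersion)
    )
  }
  junctionCounts <- do.call(rbind, c(jrows[!vapply(jrows, is.null, logical(1))],
                                     if (config$retentionFraction > 0)
                                       list(novelRows)))
  junctionCounts <- junctionCounts[order(junctionCounts$chrom,
                                         junctionCounts$donor_end,
                                         junctionCounts$acceptor_start), ]
  rownames(junctionCounts) <- NULL

  truth <- list(
    classes = data.frame(gene = ids, class = unname(classLab),
                         log2fc = unname(lfc)),
    causalGene = causal, retainedIntron = retIdx,
    novelJunctions = if (!is.null(novelRows))
      novelRows[, c("chrom", "donor_end", "acceptor_start")] else NULL
  )
  list(geneCounts = geneCounts, junctionCounts = junctionCounts, truth = truth)
}
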