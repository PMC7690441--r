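#' Configuration for the synthetic F2 mapping cross
#'
#' Describes an F2 incross segregating a recessive lethal point mutation
#' (a G-to-A transition at a splice donor site), with strain/ENU background
#' variants riding the mutagenized founder haplotype shared by both
#' heterozygous F1 parents. Defaults emulate the pooled exome design of a
#' zebrafish forward-genetics screen: 20 mutant and 20 wild-type sibling
#' larvae per pool at ~30x pooled depth.
#'
#' @param nChromosomes number of chromosomes.
#' @param chromLengthBp chromosome length in bp (all chromosomes equal).
#' @param backgroundVariantDensity expected background variants per bp
#'   (default 2e-5, one segregating site per 50 kb — an exome-scale SNV list).
#' @param causalChrom,causalPos location of the planted splice-donor lesion.
#' @param nMutantLarvae,nWtLarvae pool sizes (default 20 each).
#' @param recombRate expected crossovers per chromosome per meiosis
#'   (default 1; Poisson count, uniform placement, no interference).
#' @param meanDepthPerPool mean sequencing depth per pool per site (Poisson).
#' @param seed RNG seed; together with the other fields it fully determines
#'   the simulated data.
#' @return A validated list of class \code{"crossConfig"}.
#' @export
crossConfig <- function(nChromosomes = 5L, chromLengthBp = 25e6,
                        backgroundVariantDensity = 2e-5,
                        causalChrom = "chr3", causalPos = 12.5e6,
                        nMutantLarvae = 20L, nWtLarvae = 20L,
                        recombRate = 1, meanDepthPerPool = 30,
                        seed = 1L) {
  cfg <- list(
    nChromosomes = as.integer(nChromosomes),
    chromLengthBp = as.numeric(chromLengthBp),
    backgroundVariantDensity = backgroundVariantDensity,
    causalChrom = causalChrom, causalPos = as.numeric(causalPos),
    nMutantLarvae = as.integer(nMutantLarvae),
    nWtLarvae = as.integer(nWtLarvae),
    recombRate = recombRate, meanDepthPerPool = meanDepthPerPool,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$nChromosomes >= 1L, cfg$chromLengthBp >= 1e4,
    cfg$backgroundVariantDensity > 0,
    cfg$nMutantLarvae >= 1L, cfg$nWtLarvae >= 1L,
    cfg$recombRate >= 0, cfg$meanDepthPerPool > 0
  )
  chroms <- paste0("chr", seq_len(cfg$nChromosomes))
  if (!cfg$causalChrom %in% chroms)
    stop("causalChrom must be one of ", paste(chroms, collapse = ", "))
  if (cfg$causalPos < 1 || cfg$causalPos > cfg$chromLengthBp)
    stop("causalPos must lie within the causal chromosome")
  class(cfg) <- "crossConfig"
  cfg
}

# Causal-gene geometry: 13 exons of 120 bp separated by 300-bp introns, CDS
# spanning all exons (1560 coding bases). The lesion sits on the first base
# of intron 12 (the donor G of the canonical GT), and intron 12 opens
# GT ATAA so that the reading frame running into the retained intron meets
# an in-frame TAA at its second codon.
.causalExonLen <- 120L
.causalIntronLen <- 300L
.causalNExons <- 13L
.causalLesionOffset <- function() {
  # offset of intron-12 start from gene start
  12L * .causalExonLen + 11L * .causalIntronLen
}

.nonStopCodons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.buildCausalLocus <- function(config) {
  geneStart <- as.integer(config$causalPos - .causalLesionOffset())
  nEx <- .causalNExons
  if (geneStart < 1L)
    stop("causalPos too close to the chromosome start for the causal gene model")
  codons <- .nonStopCodons()
  exonSeq <- function() paste(sample(codons, .causalExonLen / 3L, replace = TRUE),
                              collapse = "")
  intronSeq <- function(planted) {
    inner <- if (planted) {
      paste0("ATAA", .randomDna(.causalIntronLen - 8L))
    } else {
      .randomDna(.causalIntronLen - 4L)
    }
    paste0("GT", inner, "AG")
  }
  pieces <- character(2L * nEx - 1L)
  starts <- integer(nEx)
  off <- 0L
  for (i in seq_len(nEx)) {
    starts[i] <- geneStart + off
    pieces[2L * i - 1L] <- exonSeq()
    off <- off + .causalExonLen
    if (i < nEx) {
      pieces[2L * i] <- intronSeq(planted = (i == 12L))
      off <- off + .causalIntronLen
    }
  }
  locus <- paste(pieces, collapse = "")
  gene <- geneModel("sart1_like", config$causalChrom, "+",
                    exonStarts = starts,
                    exonEnds = starts + .causalExonLen - 1L)
  list(gene = gene, locus = locus, geneStart = geneStart,
       geneEnd = geneStart + nchar(locus) - 1L)
}

# One gamete from a heterozygous F1 parent: haplotype 1 is the mutagenized
# founder haplotype (carries every alt allele), haplotype 0 the wild strain.
.simGamete <- function(len, rate) {
  nco <- rpois(1L, rate)
  list(start = sample(0:1, 1L),
       breaks = if (nco > 0L) sort(runif(nco, min = 1, max = len)) else numeric())
}

.hapAt <- function(gamete, pos) {
  (gamete$start + findInterval(pos, gamete$breaks)) %% 2L
}

#' Simulate a pooled-exome F2 mapping cross
#'
#' Generates the full substrate of a bulked-segregant mapping experiment:
#' background variants on the founder haplotype, F2 larvae produced by two
#' independent meioses each (Poisson crossovers, uniform placement,
#' Mendelian transmission), a mutant pool of larvae homozygous for the
#' planted causal allele and a same-size wild-type sibling pool sampled from
#' the rest, and per-site pooled allele depths (Poisson depth, binomial
#' allele counts at the pool allele frequency). Larvae are simulated until
#' the mutant pool is filled; the total simulated is reported in the truth
#' record. Alongside the variant table, the simulator emits the synthetic
#' genome and the causal gene model so that candidate screening can run on
#' the same coordinates: the genome is a periodic ACGT backbone with a
#' realistic gene locus (GT..AG introns, stop-free coding exons, and an
#' in-frame TAA early in the retained intron) around the lesion.
#'
#' @param config a \code{\link{crossConfig}}.
#' @return List with elements \code{variants} (data.frame as returned by
#'   \code{\link{readVariants}}), \code{genes} (named list with the causal
#'   \linkS4class{GeneModel}), \code{genome} (\code{DNAStringSet}) and
#'   \code{truth} (causal site, gene, per-larva gamete haplotype paths on the
#'   causal chromosome, pool allele frequencies, and counts).
#' @export
simulateCross <- function(config) {
  stopifnot(inherits(config, "crossConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$nChromosomes))
  len <- config$chromLengthBp

  # background variant positions (coordinate-sorted, unique, off the lesion)
  positions <- lapply(chroms, function(ch) {
    n <- rpois(1L, config$backgroundVariantDensity * len)
    pos <- sort(unique(sample.int(len, min(n, len))))
    if (ch == config$causalChrom) pos <- setdiff(pos, config$causalPos)
    pos
  })
  names(positions) <- chroms
  ci <- match(config$causalChrom, chroms)
  positions[[ci]] <- sort(c(positions[[ci]], config$causalPos))
  causalIdx <- match(config$causalPos, positions[[ci]])

  # genome: periodic backbone + causal gene locus; refs read from the genome
  locusInfo <- .buildCausalLocus(config)
  genomeChars <- lapply(chroms, function(ch) {
    s <- strrep("ACGT", ceiling(len / 4))
    s <- substr(s, 1L, len)
    if (ch == config$causalChrom)
      substr(s, locusInfo$geneStart, locusInfo$geneEnd) <- locusInfo$locus
    s
  })
  genome <- Biostrings::DNAStringSet(setNames(unlist(genomeChars), chroms))

  refs <- lapply(chroms, function(ch) genomeBase(genome, ch, positions[[ch]]))
  names(refs) <- chroms
  alts <- lapply(refs, function(r)
    vapply(r, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
           character(1), USE.NAMES = FALSE))
  # the planted lesion is the donor G -> A transition
  stopifnot(refs[[ci]][causalIdx] == "G")
  alts[[ci]][causalIdx] <- "A"

  # simulate larvae until the mutant pool is filled
  nMut <- config$nMutantLarvae
  nWt <- config$nWtLarvae
  mutants <- list()
  others <- list()
  nSim <- 0L
  maxSim <- 400L * (nMut + nWt)
  while ((length(mutants) < nMut || length(others) < nWt) && nSim < maxSim) {
    nSim <- nSim + 1L
    gametes <- lapply(chroms, function(ch)
      list(.simGamete(len, config$recombRate), .simGamete(len, config$recombRate)))
    names(gametes) <- chroms
    dosage <- lapply(chroms, function(ch)
      .hapAt(gametes[[ch]][[1L]], positions[[ch]]) +
        .hapAt(gametes[[ch]][[2L]], positions[[ch]]))
    names(dosage) <- chroms
    larva <- list(dosage = dosage, causalGametes = gametes[[config$causalChrom]])
    if (dosage[[config$causalChrom]][causalIdx] == 2L) {
      if (length(mutants) < nMut) mutants[[length(mutants) + 1L]] <- larva
    } else {
      others[[length(others) + 1L]] <- larva
    }
  }
  if (length(mutants) < nMut || length(others) < nWt)
    stop("failed to fill the pools after ", nSim, " simulated larvae")
  message("simulated ", nSim, " F2 larvae to fill a ", nMut, "-larva mutant pool")
  wtPool <- others[sample.int(length(others), nWt)]

  poolFreq <- function(pool, ch) {
    tot <- Reduce(`+`, lapply(pool, function(l) l$dosage[[ch]]))
    tot / (2 * length(pool))
  }
  mutFreq <- lapply(chroms, function(ch) poolFreq(mutants, ch))
  wtFreq <- lapply(chroms, function(ch) poolFreq(wtPool, ch))
  names(mutFreq) <- names(wtFreq) <- chroms

  variants <- do.call(rbind, lapply(chroms, function(ch) {
    ns <- length(positions[[ch]])
    wtDepth <- rpois(ns, config$meanDepthPerPool)
    mutDepth <- rpois(ns, config$meanDepthPerPool)
    wtAlt <- rbinom(ns, wtDepth, wtFreq[[ch]])
    mutAlt <- rbinom(ns, mutDepth, mutFreq[[ch]])
    data.frame(chrom = rep(ch, ns), pos = positions[[ch]],
               ref = refs[[ch]], alt = alts[[ch]],
               wt_ref = wtDepth - wtAlt, wt_alt = wtAlt,
               mut_ref = mutDepth - mutAlt, mut_alt = mutAlt,
               row.names = NULL)
  }))

  truth <- list(
    config = config,
    causalChrom = config$causalChrom, causalPos = config$causalPos,
    refAllele = "G", altAllele = "A",
    gene = locusInfo$gene, retainedIntron = 12L,
    nLarvaeSimulated = nSim,
    causalIndex = causalIdx,
    mutantGametes = lapply(mutants, `[[`, "causalGametes"),
    wtGametes = lapply(wtPool, `[[`, "causalGametes"),
    mutantDosage = lapply(stats::setNames(chroms, chroms), function(ch)
      do.call(rbind, lapply(mutants, function(l) l$dosage[[ch]]))),
    wtDosage = lapply(stats::setNames(chroms, chroms), function(ch)
      do.call(rbind, lapply(wtPool, function(l) l$dosage[[ch]]))),
    mutPoolFreq = mutFreq, wtPoolFreq = wtFreq,
    positions = positions
  )
  list(variants = variants,
       genes = stats::setNames(list(locusInfo$gene), geneID(locusInfo$gene)),
       genome = genome, truth = truth)
}

#' Count recombinant meioses between a marker and the causal site
#'
#' Each mutant-pool larva represents two scorable meioses. A meiosis is
#' recombinant when the transmitted haplotype carries the marker position and
#' the causal position from different parental haplotypes. With the marker at
#' the lesion itself the count is zero by construction — the positional
#' cloning logic of a fully linked marker.
#'
#' @param truth truth record from \code{\link{simulateCross}}.
#' @param markerPos marker position on the causal chromosome.
#' @param causalPos causal position (default: the planted lesion).
#' @return Named integer vector \code{c(n_recombinant, n_meioses)}.
#' @export
countRecombinants <- function(truth, markerPos, causalPos = truth$causalPos) {
  len <- truth$config$chromLengthBp
  if (length(markerPos) != 1L || is.na(markerPos) || markerPos < 1 || markerPos > len)
    stop("marker position is not on the causal chromosome of the truth record")
  rec <- vapply(truth$mutantGametes, function(pair) {
    sum(vapply(pair, function(g)
      .hapAt(g, markerPos) != .hapAt(g, causalPos), logical(1)))
  }, numeric(1))
  c(n_recombinant = as.integer(sum(rec)),
    n_meioses = 2L * length(truth$mutantGametes))
}
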