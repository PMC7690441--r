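#' Call pool zygosity states and mutant-specific homozygosity
#'
#' For each variant site, each pool is called \code{hom_alt} when its
#' alternate-allele fraction is at least \code{homAltMinFrac},
#' \code{hom_ref} when the fraction is at most \code{1 - homAltMinFrac},
#' \code{nocall} when the pool depth is below \code{minDepth}, and
#' \code{het} otherwise. A site is mutant-specific homozygous when the
#' mutant pool is \code{hom_alt} and the wild-type sibling pool is not
#' (a heterozygous sibling pool is compatible with mutant specificity: the
#' siblings of a recessive mutant segregate the allele). A \code{nocall} in
#' either pool always gives \code{FALSE}.
#'
#' @param variants data.frame as returned by \code{\link{readVariants}} or
#'   \code{\link{simulateCross}}.
#' @param homAltMinFrac minimum alternate fraction for a homozygous-alternate
#'   call (default 0.9); must lie in (0.5, 1].
#' @param minDepth minimum pool depth for any call (default 10).
#' @return The input data.frame with added columns \code{wt_state},
#'   \code{mut_state} and \code{mutant_specific_hom}. Threshold settings are
#'   attached as the \code{"thresholds"} attribute and echoed in a message.
#' @export
callZygosity <- function(variants, homAltMinFrac = 0.9, minDepth = 10L) {
  stopifnot(homAltMinFrac > 0.5, homAltMinFrac <= 1, minDepth >= 1L)
  state <- function(refCount, altCount) {
    depth <- refCount + altCount
    frac <- ifelse(depth > 0, altCount / depth, 0)
    out <- rep("het", length(depth))
    out[frac >= homAltMinFrac] <- "hom_alt"
    out[frac <= 1 - homAltMinFrac] <- "hom_ref"
    out[depth < minDepth] <- "nocall"
    out
  }
  variants$wt_state <- state(variants$wt_ref, variants$wt_alt)
  variants$mut_state <- state(variants$mut_ref, variants$mut_alt)
  variants$mutant_specific_hom <- variants$mut_state == "hom_alt" &
    variants$wt_state != "hom_alt" & variants$wt_state != "nocall"
  attr(variants, "thresholds") <- list(homAltMinFrac = homAltMinFrac,
                                       minDepth = minDepth)
  message("zygosity thresholds: hom_alt fraction >= ", homAltMinFrac,
          ", min depth ", minDepth)
  variants
}

.chromWindows <- function(chromLen, windowSize, step) {
  if (chromLen <= windowSize) return(1)
  starts <- seq(1, chromLen - windowSize + 1, by = step)
  last <- chromLen - windowSize + 1
  if (starts[length(starts)] < last) starts <- c(starts, last)
  starts
}

#' Windowed mutant-specific homozygosity score
#'
#' Slides a window (default 1 Mb, step 100 kb) along each chromosome and
#' scores each window as 100 times the fraction of its variant sites that
#' are mutant-specific homozygous. The denominator is the number of variants
#' observed in the window, which makes the score depth- and density-robust
#' and bounded in [0, 100]. Windows with fewer than \code{minVariants} sites
#' are excluded from peak search; the peak is reported as the union interval
#' of all eligible windows attaining the maximum score (undefined when no
#' eligible window scores above zero).
#'
#' @param calls data.frame from \code{\link{callZygosity}}.
#' @param windowSize window width in bp (default 1,000,000).
#' @param step slide step in bp (default 100,000); \code{step = windowSize}
#'   gives tiled windows.
#' @param minVariants minimum variants per window for peak eligibility.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the last variant position per chromosome.
#' @return A \linkS4class{HomozygosityProfile}.
#' @export
homozygosityProfile <- function(calls, windowSize = 1e6, step = 1e5,
                                minVariants = 5L, chromLengths = NULL) {
  stopifnot(windowSize >= 1, step >= 1, step <= windowSize)
  if (nrow(calls) == 0L) {
    return(new("HomozygosityProfile",
      windows = data.frame(chrom = character(), start = numeric(),
                           end = numeric(), n_variants = integer(),
                           n_specific = integer(), score = numeric(),
                           eligible = logical()),
      windowSize = windowSize, step = step, minVariants = minVariants,
      peak = GenomicRanges::GRanges()))
  }
  chroms <- unique(calls$chrom)
  winList <- lapply(chroms, function(ch) {
    sub <- calls[calls$chrom == ch, ]
    pos <- sort(sub$pos)
    specPos <- sort(sub$pos[sub$mutant_specific_hom])
    chromLen <- if (!is.null(chromLengths) && ch %in% names(chromLengths))
      chromLengths[[ch]] else max(pos)
    starts <- .chromWindows(chromLen, windowSize, step)
    ends <- pmin(starts + windowSize - 1, chromLen)
    nIn <- findInterval(ends, pos) - findInterval(starts - 1, pos)
    nSpec <- findInterval(ends, specPos) - findInterval(starts - 1, specPos)
    data.frame(chrom = ch, start = starts, end = ends,
               n_variants = as.integer(nIn), n_specific = as.integer(nSpec),
               score = ifelse(nIn > 0, 100 * nSpec / nIn, NA_real_),
               eligible = nIn >= minVariants)
  })
  windows <- do.call(rbind, winList)
  rownames(windows) <- NULL
  el <- windows[windows$eligible & !is.na(windows$score), , drop = FALSE]
  peak <- GenomicRanges::GRanges()
  if (nrow(el) > 0L && max(el$score) > 0) {
    topScore <- max(el$score)
    top <- el[el$score == topScore, , drop = FALSE]
    # ties across chromosomes: keep the chromosome holding the first maximum
    topChrom <- top$chrom[1L]
    top <- top[top$chrom == topChrom, , drop = FALSE]
    peak <- GenomicRanges::GRanges(topChrom,
      IRanges::IRanges(min(top$start), max(top$end)))
  }
  new("HomozygosityProfile", windows = windows, windowSize = windowSize,
      step = step, minVariants = minVariants, peak = peak)
}

#' Write a per-window score track as TSV
#'
#' @param profile a \linkS4class{HomozygosityProfile}.
#' @param path output TSV path.
#' @export
writeProfileTsv <- function(profile, path) {
  write.table(windowScores(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
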