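#' Thresholds for the differential splice-junction screen
#'
#' The candidate filter is the conjunction of four strict predicates:
#' average log2 intensity above \code{minLog2AvgIntensity}, absolute log2
#' usage ratio above \code{minAbsLog2Ratio}, fold change (larger over
#' smaller RPM, pseudocounted) above \code{minFoldChange}, and mean RPM of
#' the two samples above \code{minAvgRpm}. A minimum raw fragment count in
#' at least one sample stands in for the upstream low-count filtering step.
#'
#' @param minLog2AvgIntensity average intensity threshold (log2 RPM units,
#'   default 2).
#' @param minAbsLog2Ratio absolute log2 ratio threshold (default 2).
#' @param minFoldChange pseudocounted fold-change threshold (default 4).
#' @param minAvgRpm mean-RPM threshold (default 4).
#' @param pseudocount RPM pseudocount for the log2 transforms (default 0.5).
#' @param minCount minimum fragments in at least one sample (default 5).
#' @param intensityMode \code{"mean_log"} (mean of log2(rpm + c), default)
#'   or \code{"log_mean"} (log2 of the pseudocounted mean RPM).
#' @return Validated list of class \code{"junctionFilterConfig"}.
#' @export
junctionFilterConfig <- function(minLog2AvgIntensity = 2,
                                 minAbsLog2Ratio = 2,
                                 minFoldChange = 4,
                                 minAvgRpm = 4,
                                 pseudocount = 0.5,
                                 minCount = 5L,
                                 intensityMode = c("mean_log", "log_mean")) {
  intensityMode <- match.arg(intensityMode)
  cfg <- list(minLog2AvgIntensity = minLog2AvgIntensity,
              minAbsLog2Ratio = minAbsLog2Ratio,
              minFoldChange = minFoldChange, minAvgRpm = minAvgRpm,
              pseudocount = pseudocount, minCount = as.integer(minCount),
              intensityMode = intensityMode)
  stopifnot(cfg$minLog2AvgIntensity > 0, cfg$minAbsLog2Ratio > 0,
            cfg$minFoldChange > 0, cfg$minAvgRpm > 0, cfg$pseudocount > 0,
            cfg$minCount >= 0L)
  class(cfg) <- "junctionFilterConfig"
  cfg
}

#' Normalize junction counts to reads per million
#'
#' Scales each sample's junction fragment counts by its total junction
#' fragments so that the RPM values of a sample sum to one million.
#'
#' @param junctions data.frame with columns \code{chrom}, \code{donor_end}
#'   (1-based last base of the upstream exon), \code{acceptor_start}
#'   (1-based first base of the downstream exon), \code{wt_count},
#'   \code{mut_count}.
#' @return The input with added \code{wt_rpm} and \code{mut_rpm} columns.
#' @export
normalizeRpm <- function(junctions) {
  need <- c("chrom", "donor_end", "acceptor_start", "wt_count", "mut_count")
  stopifnot(all(need %in% names(junctions)))
  if (any(junctions$donor_end >= junctions$acceptor_start))
    stop("donor_end must be smaller than acceptor_start")
  if (any(junctions$wt_count < 0) || any(junctions$mut_count < 0))
    stop("counts must be non-negative")
  wtTot <- sum(junctions$wt_count)
  mutTot <- sum(junctions$mut_count)
  if (wtTot == 0 || mutTot == 0)
    stop("a sample has zero total junction fragments")
  junctions$wt_rpm <- junctions$wt_count * 1e6 / wtTot
  junctions$mut_rpm <- junctions$mut_count * 1e6 / mutTot
  junctions
}

#' Flag junctions as known or novel against the annotation
#'
#' A junction is known exactly when the interval it skips,
#' \code{(donor_end + 1, acceptor_start - 1)}, equals an annotated intron of
#' some gene (both boundaries). Everything else — including junctions
#' running from an exon boundary into an intron interior, the signature of
#' intron retention — is novel.
#'
#' @param junctions data.frame with \code{chrom}, \code{donor_end},
#'   \code{acceptor_start}.
#' @param genes named list of \linkS4class{GeneModel}.
#' @return The input with an added logical \code{known} column.
#' @export
flagNovel <- function(junctions, genes) {
  keys <- unlist(lapply(genes, function(g) {
    intr <- geneIntrons(g)
    if (length(intr) == 0L) return(character())
    paste(geneChrom(g), BiocGenerics::start(intr), BiocGenerics::end(intr),
          sep = ":")
  }), use.names = FALSE)
  jkeys <- paste(junctions$chrom, junctions$donor_end + 1L,
                 junctions$acceptor_start - 1L, sep = ":")
  junctions$known <- jkeys %in% keys
  junctions
}

.junctionStats <- function(junctions, config) {
  c0 <- config$pseudocount
  wt <- junctions$wt_rpm
  mut <- junctions$mut_rpm
  junctions$log2_ratio <- log2((mut + c0) / (wt + c0))
  junctions$log2_avg_intensity <- if (config$intensityMode == "mean_log") {
    (log2(wt + c0) + log2(mut + c0)) / 2
  } else {
    log2((wt + mut) / 2 + c0)
  }
  junctions$fold_change <- (pmax(wt, mut) + c0) / (pmin(wt, mut) + c0)
  junctions$avg_rpm <- (wt + mut) / 2
  junctions
}

#' Select differentially used junction candidates
#'
#' Applies the conjunction of the four screen thresholds (see
#' \code{\link{junctionFilterConfig}}) plus the minimum-count prefilter, and
#' returns the passing junctions sorted by decreasing absolute log2 ratio.
#' The absolute ratio makes the screen symmetric in sample order, so both
#' gained and lost junctions are candidates.
#'
#' @param junctions data.frame with RPM columns from
#'   \code{\link{normalizeRpm}} (and optionally \code{known} from
#'   \code{\link{flagNovel}}).
#' @param config a \code{\link{junctionFilterConfig}}.
#' @return The candidate subset with added columns \code{log2_ratio},
#'   \code{log2_avg_intensity}, \code{fold_change}, \code{avg_rpm}.
#' @export
filterDifferential <- function(junctions, config = junctionFilterConfig()) {
  stopifnot(inherits(config, "junctionFilterConfig"),
            all(c("wt_rpm", "mut_rpm") %in% names(junctions)))
  ann <- .junctionStats(junctions, config)
  pass <- ann$log2_avg_intensity > config$minLog2AvgIntensity &
    abs(ann$log2_ratio) > config$minAbsLog2Ratio &
    ann$fold_change > config$minFoldChange &
    ann$avg_rpm > config$minAvgRpm &
    pmax(ann$wt_count, ann$mut_count) >= config$minCount
  out <- ann[pass, , drop = FALSE]
  out <- out[order(-abs(out$log2_ratio)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
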