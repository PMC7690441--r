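#' Simulate a qPCR Ct replicate table with planted ddCt structure
#'
#' Builds replicate Ct values for a calibrator ("WT") and a test ("MUT")
#' sample whose planted difference-of-differences versus the reference gene
#' equals the requested ddCt per target gene: the reference gene cycles at
#' the same threshold in both samples, each target at a baseline in the
#' calibrator and baseline + ddCt in the test sample, plus Gaussian
#' replicate noise.
#'
#' @param targets data.frame with columns \code{gene} and \code{ddct}
#'   (planted delta-delta-Ct per gene; negative values mean upregulation in
#'   the test sample, fold = 2^-ddCt).
#' @param nReplicates replicates per gene and sample (default 3 rounds).
#' @param noiseSd Gaussian Ct noise standard deviation (cycles); must be
#'   non-negative.
#' @param referenceGene name of the reference gene row to add.
#' @param samples names of the calibrator and test sample, in that order.
#' @param baselineCt calibrator-sample Ct of every target gene.
#' @param referenceCt Ct of the reference gene in both samples.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{ct}.
#' @export
simulateCt <- function(targets, nReplicates = 3L, noiseSd = 0.1,
                       referenceGene = "actb1", samples = c("WT", "MUT"),
                       baselineCt = 26, referenceCt = 20, seed = 1L) {
  stopifnot(all(c("gene", "ddct") %in% names(targets)),
            nReplicates >= 1L, length(samples) == 2L)
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  genes <- c(referenceGene, targets$gene)
  meanCt <- rbind(
    data.frame(gene = referenceGene, sample = samples, mu = referenceCt),
    data.frame(gene = rep(targets$gene, each = 2L),
               sample = rep(samples, nrow(targets)),
               mu = as.vector(rbind(baselineCt, baselineCt + targets$ddct)))
  )
  out <- meanCt[rep(seq_len(nrow(meanCt)), each = nReplicates), ]
  out$replicate <- rep(seq_len(nReplicates), nrow(meanCt))
  out$ct <- out$mu + rnorm(nrow(out), sd = noiseSd)
  out$mu <- NULL
  rownames(out) <- NULL
  out[, c("gene", "sample", "replicate", "ct")]
}
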