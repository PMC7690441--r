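#' Relative quantification by the delta-delta-Ct method
#'
#' For one target gene, computes per sample the mean-Ct difference to the
#' reference gene (dCt), the difference of those differences between the
#' test and calibrator samples (ddCt), the fold change \eqn{2^{-ddCt}}
#' (ideal doubling efficiency), and the reference-zero normalization
#' \code{fold - 1}. The standard error is taken across replicate rounds:
#' each replicate index forms one round in which the full ddCt statistic is
#' recomputed; rounds missing any of the four Ct values are dropped with a
#' warning.
#'
#' @param ct data.frame with columns \code{gene}, \code{sample},
#'   \code{replicate}, \code{ct} (see \code{\link{simulateCt}}).
#' @param gene target gene id.
#' @param calibratorSample,testSample sample names; the calibrator (usually
#'   the wild type) is the baseline the fold change is relative to.
#' @param referenceGene reference (housekeeping) gene id.
#' @return One-row data.frame with columns \code{gene}, \code{ddct},
#'   \code{fold}, \code{normalized}, \code{se}, \code{n_rounds}.
#' @export
ddct <- function(ct, gene, calibratorSample, testSample,
                 referenceGene = "actb1") {
  need <- c("gene", "sample", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  pick <- function(g, s) ct[ct$gene == g & ct$sample == s, , drop = FALSE]
  parts <- list(
    gTest = pick(gene, testSample), gCal = pick(gene, calibratorSample),
    rTest = pick(referenceGene, testSample),
    rCal = pick(referenceGene, calibratorSample)
  )
  if (any(vapply(parts, nrow, integer(1)) == 0L))
    stop("gene '", gene, "' and reference '", referenceGene,
         "' must have Ct values in both samples")
  meanCt <- vapply(parts, function(p) mean(p$ct), numeric(1))
  dd <- (meanCt[["gTest"]] - meanCt[["rTest"]]) -
    (meanCt[["gCal"]] - meanCt[["rCal"]])
  fold <- 2^(-dd)

  reps <- sort(unique(ct$replicate))
  roundDd <- vapply(reps, function(r) {
    v <- vapply(parts, function(p) {
      x <- p$ct[p$replicate == r]
      if (length(x) == 1L) x else NA_real_
    }, numeric(1))
    (v[["gTest"]] - v[["rTest"]]) - (v[["gCal"]] - v[["rCal"]])
  }, numeric(1))
  bad <- is.na(roundDd)
  if (any(bad))
    warning(sum(bad), " replicate round(s) dropped for gene '", gene,
            "' (missing Ct values)")
  roundDd <- roundDd[!bad]
  if (length(roundDd) == 0L)
    stop("no complete replicate round for gene '", gene, "'")
  roundFold <- 2^(-roundDd)
  se <- if (length(roundFold) > 1L) sd(roundFold) / sqrt(length(roundFold)) else NA_real_
  data.frame(gene = gene, ddct = unname(dd), fold = unname(fold),
             normalized = unname(fold - 1), se = se,
             n_rounds = length(roundDd))
}

#' ddCt for every gene of a Ct table
#'
#' @inheritParams ddct
#' @return data.frame with one \code{\link{ddct}} row per gene (including
#'   the reference gene, whose fold is 1 by construction).
#' @export
ddctAll <- function(ct, calibratorSample, testSample,
                    referenceGene = "actb1") {
  genes <- unique(ct$gene)
  out <- do.call(rbind, lapply(genes, function(g)
    ddct(ct, g, calibratorSample, testSample, referenceGene)))
  rownames(out) <- NULL
  out
}

#' Normalize fold changes to a reference gene set to zero
#'
#' Shifts every gene's fold change by the reference gene's fold so that the
#' reference sits at zero: with the conventional reference fold of 1, this
#' is \code{fold - 1}, making positive values upregulation and negative
#' values downregulation.
#'
#' @param folds data.frame with columns \code{gene} and \code{fold}.
#' @param referenceGene gene whose fold anchors zero.
#' @return data.frame with columns \code{gene}, \code{fold},
#'   \code{normalized}.
#' @export
normalizeFolds <- function(folds, referenceGene = "actb1") {
  stopifnot(all(c("gene", "fold") %in% names(folds)))
  i <- match(referenceGene, folds$gene)
  if (is.na(i)) stop("reference gene '", referenceGene, "' missing")
  data.frame(gene = folds$gene, fold = folds$fold,
             normalized = folds$fold - folds$fold[i])
}

#' Phenotype category proportion with a Wilson confidence interval
#'
#' Percentage of larvae in a phenotype category (for example,
#' morphologically mutant among all screened), with a Wilson score 95%
#' confidence interval around the binomial proportion.
#'
#' @param nCategory larvae in the category.
#' @param nTotal total larvae screened; must be positive.
#' @param confLevel confidence level (default 0.95).
#' @return List with \code{percentage} and \code{ci} (two percentages).
#' @export
phenotypeProportion <- function(nCategory, nTotal, confLevel = 0.95) {
  stopifnot(length(nCategory) == 1L, length(nTotal) == 1L)
  if (nTotal <= 0) stop("nTotal must be positive")
  if (nCategory < 0 || nCategory > nTotal)
    stop("nCategory must lie in [0, nTotal]")
  ciFrac <- prop.test(nCategory, nTotal, conf.level = confLevel,
                      correct = FALSE)$conf.int
  list(percentage = 100 * nCategory / nTotal,
       ci = 100 * as.numeric(ciFrac))
}
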