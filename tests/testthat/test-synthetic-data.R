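# Small cross configuration shared by the generator tests.
smallCross <- function(...) {
  crossConfig(nChromosomes = 2L, chromLengthBp = 4e6,
              causalChrom = "chr1", causalPos = 2e6,
              nMutantLarvae = 12L, nWtLarvae = 12L, seed = 5L, ...)
}

test_that("the cross simulator is a pure function of its config", {
  cfg <- smallCross()
  a <- suppressMessages(simulateCross(cfg))
  b <- suppressMessages(simulateCross(cfg))
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$mutPoolFreq, b$truth$mutPoolFreq)
  expect_identical(as.character(a$genome), as.character(b$genome))
})

test_that("without recombination the mutant pool is homozygous founder along the causal chromosome", {
  cfg <- smallCross(recombRate = 0)
  sim <- suppressMessages(simulateCross(cfg))
  expect_true(all(sim$truth$mutPoolFreq$chr1 == 1))
  expect_true(all(sim$truth$mutantDosage$chr1 == 2L))
})

test_that("pool allele frequencies at and away from the causal site match Mendelian expectation", {
  cfg <- crossConfig(nChromosomes = 2L, chromLengthBp = 4e6,
                     causalChrom = "chr1", causalPos = 2e6,
                     nMutantLarvae = 60L, nWtLarvae = 60L, seed = 9L)
  sim <- suppressMessages(simulateCross(cfg))
  tr <- sim$truth
  # mutant pool fixed for the causal allele before sequencing noise
  expect_equal(tr$mutPoolFreq$chr1[tr$causalIndex], 1)
  # wild-type siblings segregate 2 het : 1 hom-ref, expected alt fraction 1/3
  # (binomial sd ~ 0.03 at 60 larvae; 5 sd tolerance)
  expect_lt(abs(tr$wtPoolFreq$chr1[tr$causalIndex] - 1 / 3), 0.15)
  # off the causal chromosome both pools segregate identically in expectation;
  # chromosome-wide linkage blocks make pool means correlated across sites,
  # so the Monte-Carlo sd of the difference is ~0.065 at 60-larva pools
  expect_lt(abs(mean(tr$mutPoolFreq$chr2) - mean(tr$wtPoolFreq$chr2)), 0.25)
})

test_that("the planted lesion is a donor G-to-A on a GT intron with an in-frame TAA", {
  sim <- suppressMessages(simulateCross(smallCross()))
  v <- sim$variants
  causal <- v[v$chrom == "chr1" & v$pos == 2e6, ]
  expect_equal(nrow(causal), 1L)
  expect_equal(causal$ref, "G")
  expect_equal(causal$alt, "A")
  gene <- sim$genes[[1]]
  intr <- geneIntrons(gene)
  expect_equal(BiocGenerics::start(intr)[sim$truth$retainedIntron], 2e6)
  expect_equal(genomeSlice(sim$genome, "chr1", 2e6, 2e6 + 1), "GT")
})

test_that("recombinant counting respects zero-distance and zero-rate limits", {
  sim0 <- suppressMessages(simulateCross(smallCross(recombRate = 0)))
  n <- length(sim0$truth$mutantGametes)
  expect_equal(countRecombinants(sim0$truth, markerPos = 1e5),
               c(n_recombinant = 0L, n_meioses = 2L * n))
  sim <- suppressMessages(simulateCross(smallCross()))
  expect_equal(countRecombinants(sim$truth, markerPos = sim$truth$causalPos),
               c(n_recombinant = 0L, n_meioses = 2L * length(sim$truth$mutantGametes)))
  expect_error(countRecombinants(sim$truth, markerPos = 9e9), "not on the causal chromosome")
})

test_that("observed recombination fraction matches the crossover model", {
  cfg <- crossConfig(nChromosomes = 1L, chromLengthBp = 25e6,
                     causalChrom = "chr1", causalPos = 12.5e6,
                     nMutantLarvae = 500L, nWtLarvae = 20L, seed = 21L)
  sim <- suppressMessages(simulateCross(cfg))
  rc <- countRecombinants(sim$truth, markerPos = 13.5e6)
  expect_equal(rc[["n_meioses"]], 1000L)
  # expected fraction ~ rate * distance / length = 0.04; 3 SE binomial band
  expFrac <- 1e6 / 25e6
  se <- sqrt(expFrac * (1 - expFrac) / 1000)
  expect_lt(abs(rc[["n_recombinant"]] / 1000 - expFrac), 3 * se + 0.005)
})

test_that("count simulation gives exact ratios in the zero-dispersion limit", {
  genes <- simulateGeneModels(nGenes = 50L, nChromosomes = 4L, seed = 3L)
  cfg <- expressionSimConfig(
    nGenes = 50L,
    classes = data.frame(class = "up2", log2fc = 1, n = 5L),
    visionLog2fc = numeric(), dispersion = 0, seed = 7L)
  sim <- simulateCounts(cfg, genes)
  tr <- sim$truth$classes
  up <- tr$gene[tr$class == "up2"]
  expect_equal(unname(sim$geneCounts[up, "MUT"] / sim$geneCounts[up, "WT"]),
               rep(2, 5))
  nulls <- tr$gene[tr$class == "null"]
  expect_true(all(sim$geneCounts[nulls, "MUT"] == sim$geneCounts[nulls, "WT"]))
})

test_that("planted class references must exist and zero retention plants no novel junctions", {
  genes <- simulateGeneModels(nGenes = 30L, nChromosomes = 2L, seed = 3L)
  cfg0 <- expressionSimConfig(nGenes = 30L,
                              classes = data.frame(class = character(),
                                                   log2fc = numeric(), n = integer()),
                              visionLog2fc = numeric(),
                              retentionFraction = 0, seed = 2L)
  sim <- simulateCounts(cfg0, genes)
  expect_null(sim$truth$novelJunctions)
  ann <- flagNovel(sim$junctionCounts, genes)
  expect_true(all(ann$known))
  cfgBad <- expressionSimConfig(nGenes = 30L, causalGene = "no_such_gene",
                                visionLog2fc = numeric(),
                                classes = data.frame(class = character(),
                                                     log2fc = numeric(), n = integer()))
  expect_error(simulateCounts(cfgBad, genes), "not in the catalogue")
})

test_that("count simulation is deterministic under a fixed seed", {
  genes <- simulateGeneModels(nGenes = 40L, nChromosomes = 3L, seed = 1L)
  cfg <- expressionSimConfig(nGenes = 40L, visionLog2fc = seq(-17, -7, length.out = 3),
                             classes = data.frame(class = "up", log2fc = 4, n = 4L),
                             seed = 13L)
  a <- simulateCounts(cfg, genes)
  b <- simulateCounts(cfg, genes)
  expect_identical(a$geneCounts, b$geneCounts)
  expect_identical(a$junctionCounts, b$junctionCounts)
})

test_that("Ct simulation plants the requested ddCt structure", {
  expect_error(simulateCt(data.frame(gene = "g", ddct = 0), noiseSd = -1),
               "non-negative")
  ct <- simulateCt(data.frame(gene = c("flat", "up4"), ddct = c(0, -2)),
                   noiseSd = 0, seed = 1L)
  expect_equal(nrow(ct), 3L * 2L * 3L)  # 3 genes x 2 samples x 3 replicates
  res <- ddctAll(ct, calibratorSample = "WT", testSample = "MUT")
  expect_equal(res$fold[res$gene == "flat"], 1.0)
  expect_equal(res$fold[res$gene == "up4"], 4.0)
  expect_equal(res$normalized[res$gene == "up4"], 3.0)
  # noisy recovery: mean recovered fold over many seeds stays within 15%
  folds <- vapply(1:60, function(s) {
    ctn <- simulateCt(data.frame(gene = "up4", ddct = -2),
                      noiseSd = 0.1, seed = s)
    ddct(ctn, "up4", "WT", "MUT")$fold
  }, numeric(1))
  expect_lt(abs(mean(folds) / 4 - 1), 0.15)
})
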