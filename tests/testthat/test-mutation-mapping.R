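# Hand-built two-exon toy: ATG TAC GGA | GT ATAA CC AG | CCC GGG AAA.
# With a 200-bp pad the locus starts at 201: exon1 201-209, intron 210-219,
# exon2 220-228.
plusToy <- function(intron = "GTATAACCAG") {
  toyGene(c("ATGTACGGA", "CCCGGGAAA"), intron, strand = "+")
}

test_that("pool zygosity calls follow the threshold rules", {
  v <- data.frame(
    chrom = "chr1", pos = c(100L, 200L, 300L),
    ref = "G", alt = "A",
    wt_ref = c(20L, 0L, 10L), wt_alt = c(10L, 30L, 20L),
    mut_ref = c(0L, 0L, 5L), mut_alt = c(30L, 30L, 0L)
  )
  calls <- suppressMessages(callZygosity(v))
  expect_equal(calls$mut_state, c("hom_alt", "hom_alt", "nocall"))
  expect_equal(calls$wt_state, c("het", "hom_alt", "het"))
  expect_equal(calls$mutant_specific_hom, c(TRUE, FALSE, FALSE))
  # nocall in the wild-type pool also blocks mutant specificity
  v2 <- data.frame(chrom = "chr1", pos = 1L, ref = "G", alt = "A",
                   wt_ref = 2L, wt_alt = 2L, mut_ref = 0L, mut_alt = 30L)
  expect_false(suppressMessages(callZygosity(v2))$mutant_specific_hom)
})

test_that("window scores are per-window fractions with peak rules", {
  calls <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                      mutant_specific_hom = c(TRUE, TRUE, FALSE, FALSE))
  prof <- homozygosityProfile(calls, minVariants = 1L)
  w <- windowScores(prof)
  expect_equal(nrow(w), 1L)
  expect_equal(w$score, 50)
  expect_equal(w$n_variants, 4L)
  expect_length(peakInterval(prof), 1L)
  # all-false flags: scores zero, peak undefined
  calls$mutant_specific_hom <- FALSE
  prof0 <- homozygosityProfile(calls, minVariants = 1L)
  expect_true(all(windowScores(prof0)$score == 0))
  expect_length(peakInterval(prof0), 0L)
  # empty call set: empty profile, no peak
  profE <- homozygosityProfile(calls[0, ])
  expect_equal(nrow(windowScores(profE)), 0L)
  expect_length(peakInterval(profE), 0L)
  # low-coverage windows are excluded from peak search
  profMin <- homozygosityProfile(
    data.frame(chrom = "chr1", pos = c(100L, 200L),
               mutant_specific_hom = c(TRUE, TRUE)), minVariants = 5L)
  expect_length(peakInterval(profMin), 0L)
})

test_that("window scores are permutation-invariant and monotone in call flags", {
  set.seed(31)
  calls <- data.frame(chrom = "chr1", pos = sort(sample.int(3e6, 120)),
                      mutant_specific_hom = sample(c(TRUE, FALSE), 120, TRUE))
  lens <- c(chr1 = 3e6)
  ref <- homozygosityProfile(calls, minVariants = 1L, chromLengths = lens)
  shuf <- calls[sample.int(nrow(calls)), ]
  expect_equal(windowScores(homozygosityProfile(shuf, minVariants = 1L,
                                                chromLengths = lens)),
               windowScores(ref))
  # adding a specific call never lowers, a non-specific never raises
  w1 <- windowScores(ref)[1, ]
  addSpec <- rbind(calls, data.frame(chrom = "chr1", pos = w1$start + 10L,
                                     mutant_specific_hom = TRUE))
  addNon <- rbind(calls, data.frame(chrom = "chr1", pos = w1$start + 10L,
                                    mutant_specific_hom = FALSE))
  s1 <- windowScores(homozygosityProfile(addSpec, minVariants = 1L,
                                         chromLengths = lens))[1, "score"]
  s0 <- windowScores(homozygosityProfile(addNon, minVariants = 1L,
                                         chromLengths = lens))[1, "score"]
  expect_gte(s1, w1$score)
  expect_lte(s0, w1$score)
})

test_that("the profile equals a brute-force per-window recount", {
  set.seed(17)
  calls <- data.frame(chrom = "chr1", pos = sort(sample.int(5e6, 200)),
                      mutant_specific_hom = sample(c(TRUE, FALSE), 200, TRUE,
                                                   prob = c(0.3, 0.7)))
  lens <- c(chr1 = 5e6)
  got <- windowScores(homozygosityProfile(calls, windowSize = 1e6, step = 25e4,
                                          minVariants = 1L, chromLengths = lens))
  want <- oracleWindows(calls, 1e6, 25e4, lens)
  expect_equal(got$start, want$start)
  expect_equal(got$n_variants, want$n_variants)
  expect_equal(got$n_specific, want$n_specific)
  expect_equal(got$score, want$score)
})

test_that("effect classification matches hand-evaluated toy cases", {
  toy <- plusToy()
  genes <- list(toy = toy$gene)
  cls <- function(pos, ref, alt)
    classifyEffect(list(chrom = "chrT", pos = pos, ref = ref, alt = alt),
                   genes, toy$genome)
  donor <- cls(210L, "G", "A")
  expect_equal(donor$category, "essential_splice")
  expect_match(donor$detail, "donor_site_offset=1")
  expect_equal(cls(211L, "T", "C")$category, "essential_splice")
  acceptor <- cls(219L, "G", "C")
  expect_equal(acceptor$category, "essential_splice")
  expect_match(acceptor$detail, "acceptor_site_offset=1")
  expect_equal(cls(215L, "A", "G")$category, "intronic")
  nonsense <- cls(206L, "C", "A")          # TAC -> TAA
  expect_equal(nonsense$category, "nonsense")
  expect_match(nonsense$detail, "TAC>TAA")
  expect_equal(cls(209L, "A", "G")$category, "synonymous")  # GGA -> GGG
  expect_equal(cls(201L, "A", "C")$category, "missense")    # ATG -> CTG
  interg <- cls(50L, "A", "C")
  expect_equal(interg$category, "intergenic")
  expect_true(is.na(interg$gene_id))
  expect_error(cls(201L, "C", "A"), "reference mismatch")
})

test_that("classification agrees with the mutate-and-retranslate oracle on random genes", {
  set.seed(97)
  for (rep in 1:30) {
    toy <- randomToyGene()
    genes <- list(toy = toy$gene)
    span <- geneSpan(toy$gene)
    lo <- max(BiocGenerics::start(span) - 20L, 1L)
    hi <- BiocGenerics::end(span) + 20L
    for (pos in sample(lo:hi, 8L)) {
      ref <- genomeBase(toy$genome, "chrT", pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      got <- classifyEffect(list(chrom = "chrT", pos = pos, ref = ref, alt = alt),
                            genes, toy$genome)$category
      want <- oracleClassify("chrT", pos, alt, toy$gene, toy$genome)
      expect_equal(got, want,
                   info = sprintf("strand %s pos %d %s>%s",
                                  geneStrand(toy$gene), pos, ref, alt))
    }
  }
})

test_that("candidate screening keeps only nonsense/essential-splice inside the peak", {
  toy <- plusToy()
  genes <- list(toy = toy$gene)
  # four mutant-specific sites in one window: the donor lesion plus three
  # coding variants (missense/synonymous) that must not survive the screen
  pos <- c(210L, 203L, 209L, 228L)  # donor, ATG>ATA, GGA>GGG, AAA>AAG
  v <- data.frame(chrom = "chrT", pos = pos,
                  ref = vapply(pos, function(p) genomeBase(toy$genome, "chrT", p),
                               character(1)),
                  alt = c("A", "A", "G", "G"),
                  wt_ref = 20L, wt_alt = 10L, mut_ref = 0L, mut_alt = 30L)
  calls <- suppressMessages(callZygosity(v))
  prof <- homozygosityProfile(calls, minVariants = 1L,
                              chromLengths = c(chrT = 1000))
  cand <- screenCandidates(prof, calls, genes, toy$genome)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$pos, 210L)
  expect_equal(cand$category, "essential_splice")
  # an undefined peak yields an empty candidate table
  calls0 <- calls
  calls0$mutant_specific_hom <- FALSE
  prof0 <- homozygosityProfile(calls0, minVariants = 1L,
                               chromLengths = c(chrT = 1000))
  expect_equal(nrow(screenCandidates(prof0, calls0, genes, toy$genome)), 0L)
})

test_that("intron retention consequence finds the first in-frame stop", {
  toy <- plusToy()                       # intron opens GT ATAA: stop at codon 5
  rc <- retentionConsequence(toy$gene, 1L, toy$genome)
  expect_true(rc@ptcFound)
  expect_equal(rc@ptcCodon, "TAA")
  expect_equal(rc@ptcGenomicPos, 213L)
  expect_equal(rc@truncatedLength, 4L)   # 3 exonic codons + GTA
  # an intron without an in-frame stop runs through
  toy2 <- plusToy(intron = "GTACACCCAG")
  rc2 <- retentionConsequence(toy2$gene, 1L, toy2$genome)
  expect_false(rc2@ptcFound)
  expect_error(retentionConsequence(toy$gene, 3L, toy$genome), "between 1 and")
})

test_that("retention consequence is strand-symmetric", {
  plus <- plusToy()
  minus <- toyGene(c("ATGTACGGA", "CCCGGGAAA"), "GTATAACCAG", strand = "-")
  rcP <- retentionConsequence(plus$gene, 1L, plus$genome)
  rcM <- retentionConsequence(minus$gene, 1L, minus$genome)
  expect_equal(rcM@ptcFound, rcP@ptcFound)
  expect_equal(rcM@ptcCodon, rcP@ptcCodon)
  expect_equal(rcM@truncatedLength, rcP@truncatedLength)
  # and the donor lesion classifies identically on the minus strand
  intrM <- geneIntrons(minus$gene)
  donorPos <- BiocGenerics::end(intrM)[1L]   # first intronic base, coding strand
  eff <- classifyEffect(list(chrom = "chrT", pos = donorPos, ref = "C", alt = "T"),
                        list(minus$gene), minus$genome)
  expect_equal(eff$category, "essential_splice")
  expect_match(eff$detail, "donor_site_offset=1")
})
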