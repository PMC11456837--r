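dna <- function(...) Biostrings::DNAStringSet(c(...))

test_that("GC and purine content match hand counts with N-exclusion", {
  expect_equal(gcContent(dna("ATGC")), 0.5)
  expect_equal(gcContent(dna("GGCC")), 1.0)
  expect_equal(gcContent(dna("ATGCATN")), 2 / 6)
  expect_equal(gcContent(dna("AT", "GC")), 0.5)  # pooling
  expect_error(gcContent(dna("NNN")), "no unambiguous bases")

  expect_equal(purineContent(dna("AGAG")), 1.0)
  expect_equal(purineContent(dna("ATGC")), 0.5)
  expect_equal(purineContent(dna("AAAGTC")), 4 / 6)
  expect_error(purineContent(dna("N")), "no unambiguous bases")
})

test_that("codon-position GC pools codons and applies the partial policy", {
  expect_equal(unname(codonPositionGC(dna("GGGGGG"))), c(1, 1, 1))
  expect_equal(unname(codonPositionGC(dna("ATGGCA"))), c(0.5, 0.5, 0.5))
  expect_error(codonPositionGC(Biostrings::DNAStringSet()), "empty CDS")
  x <- dna(g1 = "ATGGCAT")  # 7 bp: trailing partial codon
  expect_warning(res <- codonPositionGC(x), "partial codon")
  expect_equal(unname(res), c(0.5, 0.5, 0.5))
  expect_error(codonPositionGC(x, partial = "strict"), "g1")
  # ambiguity excluded positionally
  expect_equal(unname(codonPositionGC(dna("ATNGCA"))), c(0.5, 0.5, 0))
})

test_that("pooled codon GC equals GC of concatenated CDS on random input", {
  set.seed(101)
  poolGap <- agSum <- numeric(1000)
  for (i in 1:1000) {
    n <- 3 * sample(2:30, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    poolGap[i] <- mean(codonPositionGC(dna(s))) - gcContent(dna(s))
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    agSum[i] <- purineContent(dna(s)) + purineContent(dna(rc))
  }
  expect_lt(max(abs(poolGap)), 1e-12)
  expect_equal(agSum, rep(1, 1000), tolerance = 1e-12)
})

test_that("noncoding fraction merges overlapping features", {
  contig <- strrep("A", 100)
  g <- makeToyGenome(contig, starts = 1, ends = 80, types = "CDS")
  expect_equal(noncodingFraction(g), 0.2)
  g2 <- makeToyGenome(contig, starts = c(1, 41), ends = c(50, 90),
                      types = "CDS")
  expect_equal(noncodingFraction(g2), 0.1)
  g3 <- makeToyGenome(contig, starts = integer(), ends = integer(),
                      types = character())
  expect_equal(noncodingFraction(g3), 1.0)
  # invariant to ordering and duplication
  g4 <- makeToyGenome(contig, starts = c(41, 1, 41), ends = c(90, 50, 90),
                      types = "CDS")
  expect_equal(noncodingFraction(g4), 0.1)
  # RNA genes count as coding by default, not with includeRna = FALSE
  g5 <- makeToyGenome(contig, starts = c(1, 61), ends = c(50, 80),
                      types = c("CDS", "tRNA"))
  expect_equal(noncodingFraction(g5), 0.3)
  expect_equal(noncodingFraction(g5, includeRna = FALSE), 0.5)
})

test_that("amino-acid composition pools residues and excludes X", {
  a <- aaComposition(aaSet("AAAA"))
  expect_equal(unname(a["A"]), 1)
  expect_equal(sum(a), 1)
  a <- aaComposition(aaSet("DE"))
  expect_equal(unname(a[c("D", "E")]), c(0.5, 0.5))
  a <- aaComposition(aaSet(c("AD", "DE")))
  expect_equal(unname(a[c("A", "D", "E")]), c(0.25, 0.5, 0.25))
  expect_equal(sum(aaComposition(aaSet("MKXVI"))), 1)  # X uncounted
  expect_error(aaComposition(Biostrings::AAStringSet()), "empty")
  expect_error(aaComposition(aaSet("XXX")), "no counted residues")
})

test_that("proteome composition is the length-weighted mean of proteins", {
  set.seed(7)
  prots <- vapply(1:20, function(i) randomProtein(sample(5:60, 1)),
                  character(1))
  pooled <- aaComposition(aaSet(prots))
  per <- t(vapply(prots, function(p) aaComposition(aaSet(p)), numeric(20)))
  w <- nchar(prots) / sum(nchar(prots))
  expect_equal(unname(pooled), unname(colSums(per * w)), tolerance = 1e-12)
})

test_that("IVYWREL is the exact sum of its seven components", {
  set.seed(8)
  p <- aaSet(randomProtein(500))
  aa <- aaComposition(p)
  expect_identical(ivywrel(p),
                   unname(sum(aa[c("I", "V", "Y", "W", "R", "E", "L")])))
})

test_that("dipeptide successor frequency respects protein boundaries", {
  expect_equal(dipeptideContextFreq("DG", "D", "G"), 1.0)
  expect_equal(dipeptideContextFreq("DGDA", "D", "G"), 0.5)
  expect_equal(dipeptideContextFreq("ADGD", "D", "G"), 1.0)  # terminal D
  # no counting across boundaries: D ends protein 1, G starts protein 2
  expect_error(dipeptideContextFreq(c("AD", "GA"), "D", "G"),
               "no 'D'-with-successor")
  set.seed(9)
  prots <- replicate(5, randomProtein(80))
  tot <- sum(vapply(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    function(y) dipeptideContextFreq(prots, "A", y),
                    numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("RNA GC pools features and is strand-invariant", {
  g <- makeToyGenome("AAGCGCAA", starts = 3, ends = 6, types = "tRNA")
  expect_equal(rnaGC(g), 1.0)
  g2 <- makeToyGenome("ATGCAA", starts = c(1, 3), ends = c(2, 4),
                      types = c("rRNA", "tRNA"))
  expect_equal(rnaGC(g2), 0.5)
  gPlus <- makeToyGenome("AAGCGTAA", starts = 3, ends = 6, types = "rRNA",
                         strands = "+")
  gMinus <- makeToyGenome("AAGCGTAA", starts = 3, ends = 6, types = "rRNA",
                          strands = "-")
  expect_equal(rnaGC(gPlus), rnaGC(gMinus))
  g3 <- makeToyGenome("ACGT", starts = 1, ends = 4, types = "CDS")
  expect_error(rnaGC(g3), "no rRNA/tRNA")
})

test_that("composition report carries clade means in heat-map order", {
  cfg <- smallConfig(seed = 2, taxaPerClade = 2)
  sim <- generateGenomes(cfg)
  rep1 <- compositionReport(sim$genomes[1])
  expect_equal(nrow(rep1), 2)  # strain + its clade mean
  num <- vapply(rep1, is.numeric, logical(1))
  expect_equal(unlist(rep1[2, num]), unlist(rep1[1, num]), tolerance = 1e-12,
               ignore_attr = TRUE)
  # two identical strains: mean equals either
  twice <- compositionReport(sim$genomes[c(1, 1)])
  expect_equal(unlist(twice[3, num]), unlist(twice[1, num]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # heat-map column order
  ix <- match(c("GC", "D", "E", "R", "K", "L"), names(rep1))
  expect_true(all(diff(ix) == 1))
})
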