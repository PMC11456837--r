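test_that("global alignment reports identity, coverage and symmetric scores", {
  al <- globalAlign("HEAGAWGHEE", "HEAGAWGHEE")
  expect_equal(al$identity, 100)
  expect_equal(al$query_coverage, 100)

  # +1/-1 scoring: AAAA vs AAAT aligns without gaps, identity 3/4
  m <- matrix(-1, 24, 24,
              dimnames = list(Biostrings::AA_ALPHABET[1:24],
                              Biostrings::AA_ALPHABET[1:24]))
  diag(m) <- 1
  al <- globalAlign("AAAA", "AAAT", matrix = m)
  expect_equal(al$identity, 75)
  expect_equal(al$aligned_length, 4)

  a <- "MKVLDEAWGH"
  b <- "MKVDEAWGY"
  expect_equal(globalAlign(a, b)$score, globalAlign(b, a)$score)
  expect_error(globalAlign("", "AAA"), "empty")
})

test_that("Karlin-Altschul E-values follow the closed form", {
  e1 <- karlinAltschulE(100, 100, 100)
  expect_equal(e1, 0.041 * 1e4 * exp(-26.7))
  expect_equal(karlinAltschulE(100, 100, 200), 2 * e1)  # linear in n
  s <- seq(10, 200, by = 10)
  expect_true(all(diff(karlinAltschulE(s, 100, 100)) < 0))  # monotone
  expect_error(karlinAltschulE(10, 0, 100), ">= 1")
})

test_that("identical proteins cluster together; distant ones stay apart", {
  p <- randomProtein(80)
  prots <- list(gA = aaSet(c(x1 = p)), gB = aaSet(c(x2 = p)),
                gC = aaSet(c(x3 = p)))
  cl <- clusterOrthologs(prots, identityCutoff = 95)
  expect_equal(nClusters(cl), 1L)
  expect_equal(sum(copyNumber(cl)), 3)

  set.seed(21)
  q <- mutateProtein(p, 0.25)  # ~75-80% identity
  prots2 <- list(gA = aaSet(c(x1 = p)), gB = aaSet(c(x2 = q)))
  cl2 <- clusterOrthologs(prots2, identityCutoff = 95)
  expect_equal(nClusters(cl2), 2L)
  expect_error(clusterOrthologs(prots2, identityCutoff = 0), "identityCutoff")
})

test_that("single-linkage matches brute-force transitive closure", {
  set.seed(31)
  nSeeds <- 10
  for (rep_ in seq_len(nSeeds)) {
    # two genomes x 10 proteins from mutated families of varying depth
    fams <- replicate(5, randomProtein(sample(40:70, 1)))
    mk <- function() {
      s <- c(vapply(fams, function(f)
        mutateProtein(f, sample(c(0.01, 0.04, 0.3), 1)), character(1)),
        replicate(5, randomProtein(50)))
      names(s) <- sprintf("p%02d", seq_along(s))
      aaSet(s)
    }
    prots <- list(g1 = mk(), g2 = mk())
    got <- clusterOrthologs(prots, identityCutoff = 90, coverageCutoff = 50)
    mem <- clusterMembers(got)
    gotPart <- canonicalPartition(
      split(paste(mem$genome, mem$protein, sep = "|"), mem$cluster))
    expPart <- canonicalPartition(bruteForceClusters(prots, 90, 50))
    expect_identical(gotPart, expPart)
  }
})

test_that("degenerate cutoffs give all-singletons or one component", {
  set.seed(41)
  prots <- list(g1 = aaSet(replicate(4, randomProtein(40))),
                g2 = aaSet(replicate(4, randomProtein(40))))
  all1 <- clusterOrthologs(prots, identityCutoff = 100)
  expect_equal(nClusters(all1), 8L)
  # cutoff ~0 with no coverage requirement links everything alignable
  one <- clusterOrthologs(prots, identityCutoff = 1e-6,
                          coverageCutoff = 0, prefilter = FALSE)
  expect_equal(nClusters(one), 1L)
})

test_that("clade cores require exactly one copy in every member", {
  p <- randomProtein(60)
  q <- randomProtein(60)
  r <- randomProtein(60)
  prots <- list(
    g1 = aaSet(c(a1 = p, b1 = q, c1 = r)),
    g2 = aaSet(c(a2 = p, b2 = q, b2dup = q)),
    g3 = aaSet(c(a3 = p)))
  cl <- clusterOrthologs(prots, identityCutoff = 95)
  core <- cladeCore(cl, c("g1", "g2", "g3"))
  mem <- clusterMembers(cl)
  coreProts <- mem$protein[mem$cluster %in% core]
  expect_setequal(coreProts, c("a1", "a2", "a3"))  # single-copy everywhere
  # q duplicated in g2 -> excluded; r absent from g2/g3 -> excluded
  expect_false(any(c("b1", "c1") %in% coreProts))
  expect_error(cladeCore(cl, character()), "empty clade")
})

test_that("the relaxation rule reproduces the printed thresholds", {
  expect_equal(relaxedEvalueThreshold(1e-8), 1e-10)
  expect_equal(relaxedEvalueThreshold(1e-30), 5e-31)
})

test_that("unique-gene screening honors coverage and the relaxed pass", {
  set.seed(51)
  core <- randomProtein(80)
  other <- randomProtein(80)
  within <- list(
    w1 = aaSet(c(u1 = core, o1 = other)),
    w2 = aaSet(c(u2 = mutateProtein(core, 0.02),
                 o2 = mutateProtein(other, 0.02))))
  focal <- aaSet(c(u1 = core))

  # an identical out-of-clade copy disqualifies uniqueness
  res <- uniqueGenes(focal, within, list(x1 = aaSet(c(h = core))))
  expect_false(res$unique)
  expect_equal(res$best_coverage, 100)

  # a strong hit covering only 40% of the query does not disqualify
  frag <- substr(core, 1, 32)
  res2 <- uniqueGenes(focal, within, list(x1 = aaSet(c(h = frag))))
  expect_true(res2$unique)

  # no out-of-clade genomes: the whole focal core is unique
  res3 <- uniqueGenes(focal, within, list())
  expect_true(all(res3$unique))
  expect_false(res3$no_within_hit)

  # relaxed threshold recorded from the best within-clade hit
  expect_true(res3$relaxed_pass)
  expect_equal(res3$threshold,
               relaxedEvalueThreshold(res3$best_within_evalue))
})

test_that("lowering the relaxation floor can only grow the unique set", {
  set.seed(61)
  genes <- aaSet(stats::setNames(replicate(4, randomProtein(60)),
                                 paste0("u", 1:4)))
  within <- list(w1 = genes,
                 w2 = aaSet(stats::setNames(
                   vapply(as.character(genes), mutateProtein, character(1),
                          p = 0.25), paste0("v", 1:4))))
  others <- list(x1 = aaSet(stats::setNames(
    vapply(as.character(genes), mutateProtein, character(1), p = 0.35),
    paste0("h", 1:4))))
  floors <- c(1e-4, 1e-10, 1e-30)
  sets <- lapply(floors, function(fl)
    with(uniqueGenes(genes, within, others, eStrict = 1e-60, eFloor = fl),
         gene[unique]))
  # smaller floor -> threshold never larger -> unique set never smaller
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("fragment ANI is reflexive, strand-aware and rejects noise", {
  cfg <- smallConfig(seed = 71, taxaPerClade = 1,
                     genomeSizeAt55 = 13000, genomeSizeSlope = -50,
                     genomeSizeNoiseSd = 0)
  sim <- generateGenomes(cfg)
  gA <- sim$genomes[[1]]
  self <- ani(gA, gA, fragmentLen = 1020)
  expect_true(self$qualified)
  expect_gte(self$ani, 99.9)

  rc <- Biostrings::reverseComplement(contigs(gA))
  names(rc) <- "rc1"
  revAni <- ani(contigs(gA), rc, fragmentLen = 1020)
  expect_gte(revAni$ani, 99.9)

  set.seed(72)
  rnd <- function() Biostrings::DNAStringSet(
    stats::setNames(paste(sample(c("A", "C", "G", "T"), 8000,
                                 replace = TRUE), collapse = ""), "r"))
  noise <- ani(rnd(), rnd(), fragmentLen = 1020)
  expect_false(noise$qualified)
  expect_true(is.na(noise$ani))

  expect_error(ani(rnd(), Biostrings::DNAStringSet(c(s = "ACGT")),
                   fragmentLen = 1020), "too short")
})

test_that("ANI is symmetric on diverged genome pairs", {
  set.seed(81)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, 9000, replace = TRUE)
  b <- a
  hit <- which(runif(9000) < 0.02)  # ~98% nucleotide identity
  b[hit] <- sample(bases, length(hit), replace = TRUE)
  gA <- Biostrings::DNAStringSet(c(cA = paste(a, collapse = "")))
  gB <- Biostrings::DNAStringSet(c(cB = paste(b, collapse = "")))
  a12 <- ani(gA, gB, fragmentLen = 1020)
  a21 <- ani(gB, gA, fragmentLen = 1020)
  expect_true(a12$qualified)
  expect_gt(a12$ani, 95)
  expect_lt(abs(a12$ani - a21$ani), 0.1)
})
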