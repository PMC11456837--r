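test_that("supermatrix concatenation pads missing taxa with gaps", {
  b1 <- aaSet(c(A = "MKVLDEAWGH", B = "MKVLDEAWGY", C = "MKVLDEAWGW"))
  b2 <- aaSet(c(A = strrep("K", 20), B = strrep("R", 20)))
  sm <- concatenateAlignments(list(g1 = b1, g2 = b2))
  expect_equal(unique(nchar(as.character(sm))), 30)
  expect_identical(substr(as.character(sm[["C"]]), 11, 30), strrep("-", 20))
  one <- concatenateAlignments(list(g1 = b1))
  expect_identical(as.character(one), as.character(b1))
  bad <- aaSet(c(A = "MK", B = "MKV"))
  expect_error(concatenateAlignments(list(oops = bad)), "oops")
})

test_that("Poisson distances follow -ln(1 - p) over comparable sites", {
  sm <- aaSet(c(A = strrep("A", 10), B = paste0(strrep("A", 9), "C")))
  D <- proteinDistance(sm)
  expect_equal(D["A", "B"], -log(0.9), tolerance = 1e-9)
  expect_equal(D["A", "A"], 0)
  expect_equal(D, t(D))
  same <- aaSet(c(A = "MKVL", B = "MKVL"))
  expect_equal(proteinDistance(same)["A", "B"], 0)
  sat <- aaSet(c(A = "AAAA", B = "CCCC"))
  expect_error(proteinDistance(sat), "saturated")
  # gapped sites are excluded pairwise
  gap <- aaSet(c(A = "MK-L", B = "MKVL"))
  expect_equal(proteinDistance(gap)["A", "B"], 0)
})

test_that("three-taxon NJ solves the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(D)
  # pendant lengths: a = (d12 + d13 - d23)/2 etc.
  pl <- setNames(tr$edge.length[tr$edge[, 2] <= 3],
                 tr$tip.label[tr$edge[tr$edge[, 2] <= 3, 2]])
  expect_equal(pl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(pl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(pl[["C"]], (4 + 5 - 3) / 2)
  Dbad <- D; Dbad[1, 2] <- 1
  expect_error(njTree(Dbad), "symmetric")
})

test_that("NJ recovers additive trees exactly and ignores taxon order", {
  # hand-drawn 4-taxon tree: ((A:1,B:2):1.5,(C:3,D:4))
  tr0 <- ape::read.tree(text = "((A:1,B:2):1.5,(C:3,D:4):0);")
  D <- ape::cophenetic.phylo(tr0)
  tr <- njTree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr0), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  labs <- rownames(D)
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs], D, tolerance = 1e-9)
  # permutation invariance
  perm <- sample(labs)
  tr2 <- njTree(D[perm, perm])
  expect_equal(ape::cophenetic.phylo(tr2)[labs, labs], D, tolerance = 1e-9)
})

test_that("NJ property: random additive 4-8 taxon matrices are inverted", {
  set.seed(90)
  for (i in 1:100) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n)
    tr0$edge.length <- tr0$edge.length + 0.05
    D <- ape::cophenetic.phylo(tr0)
    tr <- njTree(D)
    labs <- rownames(D)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[labs, labs] - D)), 1e-8)
  }
})

test_that("gCF is 100 when every decisive gene tree contains the branch", {
  sp <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  gts <- rep(list(sp), 5)
  res <- geneConcordance(sp, gts)
  expect_true(all(res$gcf == 100))
  expect_true(all(res$ic == 1))
  expect_true(all(res$n_decisive == 5))
})

test_that("gCF and IC match the frequency arithmetic on mixed gene trees", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  alt <- ape::read.tree(text = "((A,C),(B,D));")
  gts <- c(rep(list(sp), 7), rep(list(alt), 3))
  res <- geneConcordance(sp, gts)
  expect_equal(nrow(res), 1)  # single internal branch AB|CD
  expect_equal(res$gcf, 70)
  p1 <- 0.7; p2 <- 0.3
  expect_equal(res$ic, 1 + p1 * log2(p1) + p2 * log2(p2), tolerance = 1e-9)

  # even conflict: IC exactly 0
  res0 <- geneConcordance(sp, c(rep(list(sp), 5), rep(list(alt), 5)))
  expect_equal(res0$ic, 0)
  # normalized frequencies 0.8 / 0.2
  res82 <- geneConcordance(sp, c(rep(list(sp), 8), rep(list(alt), 2)))
  expect_equal(res82$ic, 1 + 0.8 * log2(0.8) + 0.2 * log2(0.2),
               tolerance = 1e-9)
  expect_equal(round(res82$ic, 4), 0.2781)
})

test_that("gene trees missing one side of a branch are not decisive", {
  sp <- ape::read.tree(text = "((A,B),(C,D));")
  partial <- ape::read.tree(text = "(A,(C,D));")  # B missing: |AB side| = 1
  res <- geneConcordance(sp, list(sp, partial))
  expect_equal(res$n_decisive, 1)
  expect_equal(res$gcf, 100)
  # no decisive trees at all -> NA, never 0
  res2 <- geneConcordance(sp, list(partial))
  expect_true(is.na(res2$gcf))
})

test_that("gCF/IC agree with a brute-force bipartition oracle", {
  set.seed(95)
  for (rep_ in 1:10) {
    sp <- ape::rtree(8, tip.label = LETTERS[1:8])
    gts <- lapply(1:10, function(i) ape::rtree(8, tip.label = LETTERS[1:8]))
    got <- geneConcordance(sp, gts)
    want <- bruteConcordance(sp, gts)
    wantKey <- vapply(want, function(w) paste(w$side, collapse = ","), "")
    for (k in seq_len(nrow(got))) {
      sideGot <- sort(strsplit(got$split[k], ",")[[1]])
      comp <- sort(setdiff(LETTERS[1:8], sideGot))
      i <- match(paste(sideGot, collapse = ","), wantKey)
      if (is.na(i)) i <- match(paste(comp, collapse = ","), wantKey)
      expect_false(is.na(i))
      expect_equal(got$gcf[k], want[[i]]$gcf, tolerance = 1e-9)
      expect_equal(got$ic[k], want[[i]]$ic, tolerance = 1e-9)
      expect_equal(got$n_decisive[k], want[[i]]$n)
    }
  }
})

test_that("IC is invariant to gene-tree order and pairwise duplication", {
  set.seed(96)
  sp <- ape::rtree(6, tip.label = LETTERS[1:6])
  gts <- lapply(1:8, function(i) ape::rtree(6, tip.label = LETTERS[1:6]))
  a <- geneConcordance(sp, gts)
  b <- geneConcordance(sp, rev(gts))
  expect_equal(a$ic, b$ic)
  expect_equal(a$gcf, b$gcf)
  dup <- geneConcordance(sp, c(gts, gts))  # scales f1 and f2 equally
  expect_equal(a$ic, dup$ic)
})

test_that("GC3 outlier scan flags the implanted transferred gene", {
  cfg <- smallConfig(seed = 5, taxaPerClade = 1)
  sim <- generateGenomes(cfg)
  g <- sim$genomes[["c3_s1"]]
  sc <- gc3OutlierScan(g)
  hgt <- sc[grepl("_hgt", sc$gene), ]
  expect_true(hgt$outlier)
  expect_equal(which.max(abs(sc$z)), which(grepl("_hgt", sc$gene)))
  # a gene at the genome mean has z near 0
  expect_lt(min(abs(sc$z)), 0.5)
  # degenerate variance and too-few-genes guards
  rep21 <- paste(rep("ATGGCAGCATAA", 30), collapse = "")
  gdeg <- makeToyGenome(strrep("A", 8000),
                        starts = 1 + 360 * (0:20), ends = 360 * (1:21),
                        types = "CDS")
  expect_error(gc3OutlierScan(gdeg), "identical GC3")
  gfew <- makeToyGenome(strrep("A", 8000), starts = 1, ends = 360,
                        types = "CDS")
  expect_error(gc3OutlierScan(gfew), ">= 20 genes")
})

test_that("Nei-Gojobori reproduces pathway-counting oracle values", {
  # identical sequences: no substitutions, undefined ratio
  r0 <- neiGojobori("ATGAAA", "ATGAAA")
  expect_equal(r0$dn, 0)
  expect_equal(r0$ds, 0)
  expect_true(is.na(r0$ratio))

  # single synonymous difference (values frozen from an independent
  # pathway-counting implementation)
  r1 <- neiGojobori("TTTAAAGGG", "TTCAAAGGG")
  expect_equal(r1$S, 5 / 3, tolerance = 1e-9)
  expect_equal(r1$dn, 0)
  expect_equal(r1$ds, 1.207078, tolerance = 1e-5)
  expect_equal(r1$ratio, 0)

  # two-hit codon averaged over both mutational paths
  r2 <- neiGojobori("TTTGGG", "GTAGGG")
  expect_equal(r2$dn, 0.464279, tolerance = 1e-5)
  expect_equal(r2$ds, 0.383119, tolerance = 1e-5)

  # single nonsynonymous difference: ds = 0, ratio undefined
  r3 <- neiGojobori("ATGAAA", "ATGCAA")
  expect_equal(r3$ds, 0)
  expect_gt(r3$dn, 0)
  expect_true(is.na(r3$ratio))

  expect_error(neiGojobori("ATG", "ATGAAA"), "equal length")
  expect_error(neiGojobori("ATGTAAAAA", "ATGTAAAAA"), "internal stop")
})

test_that("fourfold-degenerate third-position changes give dN = 0", {
  set.seed(97)
  ffd <- c("GCT", "GGT", "CCT", "ACT", "GTT", "TCT", "CGT", "CTT")
  a <- sample(ffd, 40, replace = TRUE)
  b <- vapply(a, function(cd)
    paste0(substr(cd, 1, 2), sample(c("A", "C", "G", "T"), 1)), "")
  res <- neiGojobori(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(res$dn, 0)
  expect_true(res$ds >= 0)
})
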