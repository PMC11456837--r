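# hand-built single-contig genome for composition / annotation tests
makeToyGenome <- function(contigSeq, starts, ends, types, strands = "+",
                          ids = NULL, strain = "toy", clade = "I",
                          temp = 55) {
  ctg <- Biostrings::DNAStringSet(contigSeq)
  names(ctg) <- "c1"
  n <- length(starts)
  if (is.null(ids)) ids <- sprintf("f%02d", seq_len(n))
  gr <- GenomicRanges::GRanges(rep("c1", n),
                               IRanges::IRanges(starts, ends),
                               strand = rep(strands, length.out = n))
  GenomeInfoDb::seqlevels(gr) <- names(ctg)
  GenomeInfoDb::seqlengths(gr) <- Biostrings::width(ctg)
  S4Vectors::mcols(gr)$type <- rep(types, length.out = n)
  S4Vectors::mcols(gr)$feature_id <- ids
  S4Vectors::mcols(gr)$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  GenomeRecord(strain, ctg, gr, clade = clade,
               collectionTemperature = temp)
}

aaSet <- function(x) {
  s <- Biostrings::AAStringSet(x)
  if (is.null(names(s))) names(s) <- sprintf("p%02d", seq_along(s))
  s
}

# random protein mutated at a given per-site probability
mutateProtein <- function(s, p) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v <- strsplit(s, "")[[1]]
  hit <- runif(length(v)) < p
  v[hit] <- sample(aas, sum(hit), replace = TRUE)
  paste(v, collapse = "")
}

randomProtein <- function(len) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aas, len, replace = TRUE), collapse = "")
}

# independent oracle: transitive closure of the pairwise linkage predicate
# by boolean matrix powering over exhaustive all-vs-all alignments
bruteForceClusters <- function(proteomes, identityCutoff, coverageCutoff) {
  genome <- rep(names(proteomes),
                vapply(proteomes, length, integer(1)))
  protein <- unlist(lapply(proteomes, names), use.names = FALSE)
  seqs <- unlist(lapply(proteomes, as.character), use.names = FALSE)
  n <- length(seqs)
  A <- diag(TRUE, n)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[js]), seqs[i],
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    pc <- strsplit(as.character(Biostrings::pattern(aln)), "")
    sc <- strsplit(as.character(Biostrings::subject(aln)), "")
    for (kk in seq_along(js)) {
      j <- js[kk]
      cols <- length(pc[[kk]])
      ident <- 100 * Biostrings::nmatch(aln)[kk] / cols
      both <- sum(pc[[kk]] != "-" & sc[[kk]] != "-")
      ok <- ident >= identityCutoff &&
        100 * both / nchar(seqs[j]) >= coverageCutoff &&
        100 * both / nchar(seqs[i]) >= coverageCutoff
      A[i, j] <- A[j, i] <- ok
    }
  }
  # transitive closure
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      comp[A[i, ] > 0] <- cur
    }
  }
  split(paste(genome, protein, sep = "|"), comp)
}

# canonical form of a partition for set comparison
canonicalPartition <- function(groups) {
  out <- lapply(groups, function(g) sort(unname(g)))
  out[order(vapply(out, `[`, "", 1))]
}

# independent gCF/IC oracle built on ape::prop.part bipartitions
bruteConcordance <- function(speciesTree, geneTrees) {
  sp <- speciesTree$tip.label
  splitsOf <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sides <- lapply(pp, function(ix) sort(labs[ix]))
    ntip <- length(labs)
    keep <- vapply(sides, function(s)
      length(s) >= 2 && ntip - length(s) >= 2, logical(1))
    unique(lapply(sides[keep], function(s) {
      comp <- sort(setdiff(labs, s))
      if (paste(s, collapse = ",") < paste(comp, collapse = ","))
        list(a = s, b = comp) else list(a = comp, b = s)
    }))
  }
  key <- function(sl) paste(sl$a, collapse = ",")
  spSplits <- splitsOf(speciesTree)
  res <- lapply(spSplits, function(spl) {
    s1 <- spl$a; s2 <- spl$b
    nDec <- 0L; f1 <- 0L
    conflictTally <- list()
    for (gt in geneTrees) {
      L <- gt$tip.label
      r1 <- sort(intersect(s1, L)); r2 <- sort(intersect(s2, L))
      if (length(r1) < 2 || length(r2) < 2) next
      nDec <- nDec + 1L
      gts <- splitsOf(gt)
      target <- if (paste(r1, collapse = ",") < paste(r2, collapse = ","))
        paste(r1, collapse = ",") else paste(r2, collapse = ",")
      keys <- vapply(gts, key, "")
      if (target %in% keys) {
        f1 <- f1 + 1L
      } else {
        for (g in gts) {
          conf <- length(intersect(g$a, r1)) > 0 &&
            length(intersect(g$a, r2)) > 0 &&
            length(intersect(g$b, r1)) > 0 &&
            length(intersect(g$b, r2)) > 0
          if (conf) {
            kk <- key(g)
            conflictTally[[kk]] <- (conflictTally[[kk]] %||% 0L) + 1L
          }
        }
      }
    }
    f2 <- if (length(conflictTally)) max(unlist(conflictTally)) else 0L
    gcf <- if (nDec > 0) 100 * f1 / nDec else NA_real_
    ic <- if (nDec == 0 || f1 + f2 == 0) NA_real_
      else if (f2 == 0) 1
      else {
        p1 <- f1 / (f1 + f2); p2 <- f2 / (f1 + f2)
        tt <- function(p) if (p == 0) 0 else p * log2(p)
        raw <- 1 + tt(p1) + tt(p2)
        if (f2 > f1) -raw else raw
      }
    list(side = spl$a, gcf = gcf, ic = ic, n = nDec)
  })
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small three-clade synthetic study for pipeline-level tests
smallConfig <- function(seed = 1, taxaPerClade = 3, ...) {
  syntheticConfig(seed = seed, nClades = 3, taxaPerClade = taxaPerClade,
                  cladeTemperatures = c(55, 60, 70),
                  cladeGC = c(0.585, 0.605, 0.606),
                  cladeGC3 = c(0.52, 0.58, 0.58),
                  rnaGCTarget = c(0.59, 0.59, 0.60),
                  hgtRecipientClades = c(2L, 3L), ...)
}
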