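#' Concatenate per-gene protein alignment blocks into a supermatrix
#'
#' Genes are appended in input order; a taxon missing from a block is padded
#' with gap characters across that block's width.
#'
#' @param blocks named list of aligned `AAStringSet`s (equal widths within a
#'   block; names are taxa).
#' @param taxa taxon set and row order; defaults to the union of block taxa
#'   in order of first appearance.
#' @return an `AAStringSet`, one row per taxon, with a `partitions`
#'   attribute giving each gene's column range.
#' @export
concatenateAlignments <- function(blocks, taxa = NULL) {
  stopifnot(length(blocks) >= 1L)
  if (is.null(names(blocks)))
    names(blocks) <- paste0("gene", seq_along(blocks))
  for (g in names(blocks)) {
    w <- unique(nchar(as.character(blocks[[g]])))
    if (length(w) != 1L)
      stop(sprintf("ragged alignment block: %s", g))
  }
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(blocks, names), use.names = FALSE))
  widths <- vapply(blocks, function(b) nchar(as.character(b)[1]), integer(1))
  rows <- vapply(taxa, function(tx) {
    paste(vapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      if (tx %in% names(b)) as.character(b[[tx]])
      else strrep("-", widths[i])
    }, character(1)), collapse = "")
  }, character(1))
  out <- AAStringSet(rows)
  names(out) <- taxa
  ends <- cumsum(widths)
  attr(out, "partitions") <- data.frame(gene = names(blocks),
                                        start = c(1L, head(ends, -1) + 1L),
                                        end = ends)
  out
}

#' Poisson-corrected protein distance matrix
#'
#' `d = -ln(1 - p)` with `p` the mismatch proportion over mutually ungapped
#' sites of each pair.
#'
#' @param aln an `AAStringSet` supermatrix (equal widths).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
proteinDistance <- function(aln) {
  ch <- as.character(aln)
  stopifnot(length(ch) >= 2L, length(unique(nchar(ch))) == 1L)
  m <- do.call(rbind, strsplit(ch, "", fixed = TRUE))
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop(sprintf("no comparable sites between %s and %s",
                                 names(aln)[i], names(aln)[j]))
      p <- mean(m[i, ok] != m[j, ok])
      if (p >= 1) stop(sprintf("saturated pair %s / %s (p >= 1)",
                               names(aln)[i], names(aln)[j]))
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via `ape::nj`); tiny negative branch lengths
#' produced by the algorithm are clamped to zero.
#'
#' @param D symmetric, non-negative distance matrix with >= 3 taxa.
#' @return an unrooted `ape::phylo`.
#' @export
njTree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need >= 3 taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("negative distances")
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# --- bipartition machinery -------------------------------------------------

# list of nontrivial bipartitions of a phylo; each element holds the child
# node id and the tip labels on the child side
.bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= ntip) next
    tips <- tree$tip.label[.descendantTips(tree, child)]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    out[[length(out) + 1L]] <- list(node = child, side = sort(tips))
  }
  # the root of a rooted tree duplicates one split; deduplicate by key
  keys <- vapply(out, function(b) paste(b$side, collapse = "\r"), character(1))
  compKeys <- vapply(out, function(b)
    paste(sort(setdiff(tree$tip.label, b$side)), collapse = "\r"), character(1))
  canon <- pmin(keys, compKeys)
  out[!duplicated(canon)]
}

.descendantTips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, .descendantTips, tree = tree))
}

.canonKey <- function(side, leafset) {
  other <- setdiff(leafset, side)
  a <- paste(sort(side), collapse = "\r")
  b <- paste(sort(other), collapse = "\r")
  if (a < b) a else b
}

# does bipartition (p, leafset-p) conflict with (s1, s2)?
.conflicts <- function(p, s1, s2, leafset) {
  q <- setdiff(leafset, p)
  length(intersect(p, s1)) > 0 && length(intersect(p, s2)) > 0 &&
    length(intersect(q, s1)) > 0 && length(intersect(q, s2)) > 0
}

#' Gene concordance factor and internode certainty per species-tree branch
#'
#' For each internal (nontrivial) branch of the species tree, the gene
#' concordance factor (gCF) is the percentage of decisive gene trees whose
#' bipartition set, restricted to their own taxa, contains the branch's
#' bipartition. A gene tree is decisive for a branch when at least two taxa
#' of each side of the bipartition remain after restriction. Internode
#' certainty (IC) compares the branch's bipartition frequency `f1` with the
#' frequency `f2` of its most frequent conflicting bipartition:
#' `IC = 1 + p1*log2(p1) + p2*log2(p2)` with `p_i = f_i/(f1+f2)`; with no
#' observed conflict IC is 1, and the value is negated when the conflicting
#' bipartition is the more frequent one (so IC ranges over `[-1, 1]`).
#' Branches with no decisive gene tree get `NA` (undefined), never 0.
#'
#' @param speciesTree an `ape::phylo`.
#' @param geneTrees list (or `multiPhylo`) of gene trees; leaf sets must be
#'   subsets of the species tree's.
#' @param multifurcation how a decisive gene tree that neither contains nor
#'   conflicts with the branch (e.g. an unresolved polytomy) is treated:
#'   `"conflict"` keeps it in the gCF denominator, `"abstain"` drops it.
#' @return `data.frame` per branch: child `node` id, a `split` label
#'   (smaller side), `gcf`, `ic`, `n_decisive`, `f1`, `f2`.
#' @export
geneConcordance <- function(speciesTree, geneTrees,
                            multifurcation = c("conflict", "abstain")) {
  multifurcation <- match.arg(multifurcation)
  stopifnot(inherits(speciesTree, "phylo"))
  geneTrees <- unclass(geneTrees)
  sp <- speciesTree$tip.label
  for (gt in geneTrees)
    if (!all(gt$tip.label %in% sp))
      stop("gene tree leaves must be a subset of the species tree leaves")
  gtBips <- lapply(geneTrees, function(gt)
    lapply(.bipartitions(gt), `[[`, "side"))
  gtLeaves <- lapply(geneTrees, `[[`, "tip.label")

  branches <- .bipartitions(speciesTree)
  rows <- lapply(branches, function(b) {
    s1 <- b$side
    s2 <- setdiff(sp, s1)
    nDecisive <- 0L
    f1 <- 0L
    conflictCounts <- new.env(parent = emptyenv())
    nInformative <- 0L
    for (g in seq_along(geneTrees)) {
      L <- gtLeaves[[g]]
      r1 <- intersect(s1, L)
      r2 <- intersect(s2, L)
      if (length(r1) < 2L || length(r2) < 2L) next  # not decisive
      nDecisive <- nDecisive + 1L
      key1 <- .canonKey(r1, L)
      contained <- FALSE
      confl <- character()
      for (p in gtBips[[g]]) {
        if (.canonKey(p, L) == key1) { contained <- TRUE; break }
        if (.conflicts(p, r1, r2, L)) confl <- c(confl, .canonKey(p, L))
      }
      if (contained) {
        f1 <- f1 + 1L
        nInformative <- nInformative + 1L
      } else if (length(confl)) {
        nInformative <- nInformative + 1L
        for (kk in unique(confl)) {
          prev <- if (!is.null(conflictCounts[[kk]])) conflictCounts[[kk]] else 0L
          conflictCounts[[kk]] <- prev + 1L
        }
      }
    }
    denom <- if (multifurcation == "conflict") nDecisive else nInformative
    gcf <- if (denom > 0L) 100 * f1 / denom else NA_real_
    f2 <- if (length(ls(conflictCounts)))
      max(unlist(as.list(conflictCounts))) else 0L
    ic <- if (nDecisive == 0L || (f1 + f2) == 0L) NA_real_
          else if (f2 == 0L) 1
          else {
            p1 <- f1 / (f1 + f2)
            p2 <- f2 / (f1 + f2)
            term <- function(p) if (p == 0) 0 else p * log2(p)
            raw <- 1 + term(p1) + term(p2)
            # signed: negative when the best conflicting split dominates
            if (f2 > f1) -raw else raw
          }
    small <- if (length(s1) <= length(s2)) s1 else s2
    data.frame(node = b$node, split = paste(small, collapse = ","),
               gcf = gcf, ic = ic, n_decisive = nDecisive,
               f1 = f1, f2 = f2, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GC3 outlier scan for horizontally transferred genes
#'
#' Per-gene third-codon-position GC is standardized against the genome's
#' gene population; genes with `|z| >= zThreshold` are flagged as
#' composition outliers (HGT candidates).
#'
#' @param genome a [GenomeRecord-class].
#' @param minLenCodons minimum gene length (codons) to enter the scan.
#' @param zThreshold outlier threshold on `|z|` (default 3).
#' @return `data.frame` per gene: `gene`, `gc3`, `z`, `outlier`.
#' @export
gc3OutlierScan <- function(genome, minLenCodons = 100L, zThreshold = 3) {
  cds <- cdsSequences(genome)
  cds <- cds[width(cds) >= 3L * minLenCodons]
  if (length(cds) < 20L)
    stop(sprintf("need >= 20 genes passing the length filter (have %d)",
                 length(cds)))
  gc3 <- suppressWarnings(geneGC3(cds))
  names(gc3) <- names(cds)
  s <- stats::sd(gc3)
  if (!is.finite(s) || s == 0) stop("degenerate variance: all genes have identical GC3")
  z <- (gc3 - mean(gc3)) / s
  data.frame(gene = names(cds), gc3 = unname(gc3), z = unname(z),
             outlier = abs(unname(z)) >= zThreshold,
             stringsAsFactors = FALSE)
}

# --- Nei-Gojobori (1986) pathway-counting dN/dS ----------------------------

.GENCODE <- NULL

.gencode <- function() {
  if (is.null(.GENCODE)) {
    gc <- Biostrings::GENETIC_CODE
    utils::assignInMyNamespace(".GENCODE", as.list(gc))
  }
  .GENCODE
}

.codonAA <- function(codon) .gencode()[[codon]]

# expected synonymous sites of one codon; substitutions to stop codons count
# as nonsynonymous
.synSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- .codonAA(codon)
  s <- 0
  cs <- strsplit(codon, "", fixed = TRUE)[[1]]
  for (pos in 1:3) {
    for (b in setdiff(bases, cs[pos])) {
      alt <- cs
      alt[pos] <- b
      altc <- paste(alt, collapse = "")
      if (.codonAA(altc) != "*" && .codonAA(altc) == aa) s <- s + 1 / 3
    }
  }
  s
}

# observed synonymous/nonsynonymous differences between two codons, averaged
# over equally weighted minimal mutational paths; paths through stop codons
# are excluded unless every path is blocked
.pathwayDiffs <- function(ca, cb) {
  a <- strsplit(ca, "", fixed = TRUE)[[1]]
  b <- strsplit(cb, "", fixed = TRUE)[[1]]
  diffPos <- which(a != b)
  nd <- length(diffPos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
    `1` = list(diffPos),
    `2` = list(diffPos, rev(diffPos)),
    `3` = {
      pm <- list()
      for (i in 1:3) for (j in 1:3) for (k in 1:3)
        if (length(unique(c(i, j, k))) == 3L)
          pm[[length(pm) + 1L]] <- diffPos[c(i, j, k)]
      pm
    })
  evalPath <- function(order) {
    cur <- a
    sdc <- 0; ndc <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- .codonAA(paste(cur, collapse = ""))
      aa2 <- .codonAA(paste(nxt, collapse = ""))
      if (aa2 == "*") return(NULL)  # blocked path
      if (aa1 == aa2) sdc <- sdc + 1 else ndc <- ndc + 1
      cur <- nxt
    }
    c(sd = sdc, nd = ndc)
  }
  res <- lapply(perms, evalPath)
  ok <- res[!vapply(res, is.null, logical(1))]
  if (!length(ok)) {
    # all paths pass a stop; fall back to counting steps without the block
    ok <- lapply(perms, function(order) {
      cur <- a; sdc <- 0; ndc <- 0
      for (pos in order) {
        nxt <- cur
        nxt[pos] <- b[pos]
        if (.codonAA(paste(cur, collapse = "")) ==
            .codonAA(paste(nxt, collapse = ""))) sdc <- sdc + 1
        else ndc <- ndc + 1
        cur <- nxt
      }
      c(sd = sdc, nd = ndc)
    })
  }
  colMeans(do.call(rbind, ok))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Expected synonymous (S) and nonsynonymous (N) sites are averaged over the
#' two sequences; observed differences are partitioned along minimal
#' mutational paths between codons (multi-hit codons averaged over equally
#' weighted paths, paths through stop codons excluded); proportions are
#' Jukes-Cantor corrected, `d = -(3/4) ln(1 - (4/3) p)`.
#'
#' @param a,b in-frame codon sequences of equal length (character or
#'   `DNAString(Set)`), without internal stop codons. A shared terminal stop
#'   codon is dropped.
#' @return object of class `"SelectionResult"`: `dn`, `ds`, `ratio` (`NA`
#'   when `ds` is 0), plus site and difference counts.
#' @examples
#' neiGojobori("TTTAAAGGG", "TTCAAAGGG")$dn  # 0
#' @export
neiGojobori <- function(a, b) {
  a <- toupper(as.character(a)[1])
  b <- toupper(as.character(b)[1])
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("length must be divisible by 3")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  nc <- length(ca)
  if (nc && .codonAA(ca[nc]) == "*" && .codonAA(cb[nc]) == "*") {
    ca <- ca[-nc]; cb <- cb[-nc]
  }
  if (any(vapply(ca, .codonAA, character(1)) == "*") ||
      any(vapply(cb, .codonAA, character(1)) == "*"))
    stop("internal stop codon")
  S <- mean(c(sum(vapply(ca, .synSites, numeric(1))),
              sum(vapply(cb, .synSites, numeric(1)))))
  N <- 3 * length(ca) - S
  dif <- vapply(seq_along(ca), function(i)
    .pathwayDiffs(ca[i], cb[i]), numeric(2))
  Sd <- sum(dif["sd", ])
  Nd <- sum(dif["nd", ])
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4) stop("saturation: proportion of differences >= 3/4")
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ds <- jc(Sd / S)
  dn <- jc(Nd / N)
  out <- list(dn = dn, ds = ds,
              ratio = if (ds > 0) dn / ds else NA_real_,
              S = S, N = N, Sd = Sd, Nd = Nd)
  class(out) <- "SelectionResult"
  out
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf("Nei-Gojobori: dN = %.4f, dS = %.4f, dN/dS = %s\n",
              x$dn, x$ds,
              if (is.na(x$ratio)) "undefined (dS = 0)"
              else sprintf("%.4f", x$ratio)))
  invisible(x)
}
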