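#' @importFrom Biostrings pairwiseAlignment nmatch pattern subject
NULL

# distinct k-mers of one sequence (character scalar)
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(substring(s, 1:(n - k + 1L), k:n))
}

# number of distinct k-mers shared by s and each element of others
.sharedKmerCounts <- function(s, others, k) {
  ks <- .kmers(s, k)
  vapply(others, function(o) sum(ks %in% .kmers(o, k)), integer(1))
}

.alignStats <- function(aln, qlen, slen, type) {
  p <- as.character(pattern(aln))
  s <- as.character(subject(aln))
  pl <- strsplit(p, "", fixed = TRUE)
  sl <- strsplit(s, "", fixed = TRUE)
  n <- length(pl)
  alen <- nchar(p)
  ident <- 100 * nmatch(aln) / alen
  both <- vapply(seq_len(n),
                 function(i) sum(pl[[i]] != "-" & sl[[i]] != "-"), numeric(1))
  if (type == "global") {
    qcov <- rep(100, n)
    scov <- rep(100, n)
  } else {
    qcov <- 100 * vapply(seq_len(n), function(i) sum(pl[[i]] != "-"),
                         numeric(1)) / qlen
    scov <- 100 * vapply(seq_len(n), function(i) sum(sl[[i]] != "-"),
                         numeric(1)) / slen
  }
  data.frame(score = BiocGenerics::score(aln), identity = ident,
             query_coverage = qcov, subject_coverage = scov,
             aligned_length = alen, residues_aligned = both)
}

#' Optimal pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (default BLOSUM62,
#' gap open 11 / extend 1, the classic BLASTp scoring). `type = "local"`
#' gives the Smith-Waterman alignment used for homology-hit screening,
#' where query coverage is the aligned fraction of the query.
#'
#' @param a,b protein sequences (character or `AAString(Set)` of length 1).
#' @param matrix substitution matrix name (e.g. `"BLOSUM62"`) or an actual
#'   matrix.
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @param type `"global"` or `"local"`.
#' @return list with `score`, `identity` (% identical positions over
#'   alignment columns, gaps included), `query_coverage` (%), and
#'   `aligned_length`.
#' @examples
#' globalAlign("HEAGAWGHEE", "HEAGAWGHEE")$identity  # 100
#' @export
globalAlign <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                        gapExtend = 1, type = c("global", "local")) {
  type <- match.arg(type)
  a <- as.character(a)[1]
  b <- as.character(b)[1]
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- pairwiseAlignment(AAStringSet(a), AAStringSet(b),
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend,
                           type = type)
  st <- .alignStats(aln, nchar(a), nchar(b), type)
  list(score = st$score, identity = st$identity,
       query_coverage = st$query_coverage,
       subject_coverage = st$subject_coverage,
       aligned_length = st$aligned_length)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of alignments
#' of at least this score between a random query of length `m` and a database
#' of total length `n`. Defaults are the standard gapped BLOSUM62 constants.
#'
#' @param score alignment score in substitution-matrix units.
#' @param m query length (residues).
#' @param n database length (residues).
#' @param lambda,K Karlin-Altschul parameters.
#' @return positive E-value.
#' @export
karlinAltschulE <- function(score, m, n, lambda = 0.267, K = 0.041) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  K * m * n * exp(-lambda * score)
}

# align many candidate patterns against one subject in a single call
.batchAlign <- function(patterns, subjectSeq, matrix, gapOpen, gapExtend,
                        type) {
  aln <- pairwiseAlignment(AAStringSet(patterns), AAStringSet(subjectSeq)[[1]],
                           substitutionMatrix = matrix,
                           gapOpening = gapOpen, gapExtension = gapExtend,
                           type = type)
  .alignStats(aln, nchar(patterns), nchar(subjectSeq), type)
}

#' Single-linkage ortholog clustering
#'
#' Proteins from all genomes are joined whenever a global alignment meets the
#' identity cutoff and both sequences are mutually covered; clusters are the
#' connected components (single linkage, matching transitive closure of the
#' pairwise predicate). In a global alignment, mutual coverage is the
#' percentage of alignment columns in which both sequences hold a residue,
#' relative to each sequence's length. A shared k-mer prescreen
#' (`minSharedKmers` distinct `k`-mers) skips obviously unrelated pairs;
#' disable it with `prefilter = FALSE` for exhaustive all-vs-all alignment.
#'
#' @param proteomes named list of `AAStringSet`s, one per genome; protein
#'   names must be unique within a genome.
#' @param identityCutoff percent identity threshold in `(0, 100]`.
#' @param coverageCutoff mutual coverage threshold (%).
#' @param matrix,gapOpen,gapExtend alignment scoring (see [globalAlign()]).
#' @param prefilter use the k-mer prescreen?
#' @param k,minSharedKmers prescreen parameters.
#' @return an [OrthologClusterSet-class] covering every input protein
#'   (singletons included). Cluster ids are deterministic: numbered by the
#'   lexicographically smallest (genome, protein) member.
#' @export
clusterOrthologs <- function(proteomes, identityCutoff = 95,
                             coverageCutoff = 50, matrix = "BLOSUM62",
                             gapOpen = 11, gapExtend = 1,
                             prefilter = TRUE, k = 4L, minSharedKmers = 3L) {
  stopifnot(length(proteomes) >= 2L, !is.null(names(proteomes)))
  if (identityCutoff <= 0 || identityCutoff > 100)
    stop("identityCutoff must lie in (0, 100]")
  genome <- rep(names(proteomes), vapply(proteomes, length, integer(1)))
  protein <- unlist(lapply(proteomes, names), use.names = FALSE)
  seqs <- unlist(lapply(proteomes, as.character), use.names = FALSE)
  np <- length(seqs)
  if (anyDuplicated(paste(genome, protein)))
    stop("duplicate (genome, protein) ids")
  ord <- order(genome, protein)
  genome <- genome[ord]; protein <- protein[ord]; seqs <- seqs[ord]

  parent <- seq_len(np)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  kmerList <- if (prefilter) lapply(seqs, .kmers, k = k) else NULL
  for (i in seq_len(np - 1L)) {
    js <- (i + 1L):np
    if (prefilter) {
      shared <- vapply(js, function(j)
        sum(kmerList[[i]] %in% kmerList[[j]]), integer(1))
      js <- js[shared >= minSharedKmers]
    }
    if (!length(js)) next
    st <- .batchAlign(seqs[js], seqs[i], matrix, gapOpen, gapExtend, "global")
    both <- st$residues_aligned
    covI <- 100 * both / nchar(seqs[i])
    covJ <- 100 * both / nchar(seqs[js])
    hit <- st$identity >= identityCutoff & covI >= coverageCutoff &
      covJ >= coverageCutoff
    for (j in js[hit]) unite(i, j)
  }
  root <- vapply(seq_len(np), findRoot, integer(1))
  cl <- match(root, sort(unique(root)))
  new("OrthologClusterSet",
      membership = data.frame(cluster = cl, genome = genome,
                              protein = protein, stringsAsFactors = FALSE),
      genomes = names(proteomes))
}

#' Clade core clusters
#'
#' Clusters present in exactly one copy in every member of the clade
#' (single-copy orthologs shared by the whole clade).
#'
#' @param clusters an [OrthologClusterSet-class].
#' @param cladeMembers character vector of genome ids forming the clade.
#' @return integer vector of core cluster ids.
#' @export
cladeCore <- function(clusters, cladeMembers) {
  stopifnot(is(clusters, "OrthologClusterSet"))
  if (length(cladeMembers) == 0L) stop("empty clade")
  miss <- setdiff(cladeMembers, clusters@genomes)
  if (length(miss))
    stop(sprintf("clade members not in cluster set: %s",
                 paste(miss, collapse = ", ")))
  cn <- copyNumber(clusters)[, cladeMembers, drop = FALSE]
  which(apply(cn == 1L, 1L, all))
}

#' Relaxed E-value threshold for unique-gene screening
#'
#' When a focal gene has no out-of-clade hit at the strict threshold, the
#' cutoff is relaxed to half the E-value of its most significant
#' within-clade hit, or `eFloor`, whichever is lower.
#'
#' @param bestWithinE best (smallest) within-clade E-value of the gene.
#' @param eFloor ceiling for the relaxed threshold (default `1e-10`).
#' @return relaxed E-value threshold.
#' @examples
#' relaxedEvalueThreshold(1e-8)   # 1e-10
#' relaxedEvalueThreshold(1e-30)  # 5e-31
#' @export
relaxedEvalueThreshold <- function(bestWithinE, eFloor = 1e-10) {
  pmin(bestWithinE / 2, eFloor)
}

#' Clade-unique gene calling with E-value relaxation
#'
#' A focal core gene is called unique to its clade when no out-of-clade hit
#' passes both the query-coverage threshold and the E-value threshold. The
#' first pass uses `eStrict`; genes surviving it are re-screened at the
#' relaxed threshold `min(best within-clade E / 2, eFloor)`
#' (see [relaxedEvalueThreshold()]). Hits are Smith-Waterman local
#' alignments scored with the Karlin-Altschul E-value against the pooled
#' out-of-clade database length.
#'
#' @param focalGenes named `AAStringSet` of clade-core gene representatives.
#' @param withinProteomes named list of `AAStringSet`s for the focal clade's
#'   genomes (used for the within-clade best hit; the representative itself
#'   is never its own hit).
#' @param otherProteomes named list of `AAStringSet`s for all out-of-clade
#'   genomes.
#' @param coverageMin minimum query coverage (%) for a disqualifying hit.
#' @param eStrict strict E-value threshold (first pass).
#' @param eFloor relaxation ceiling.
#' @param matrix,gapOpen,gapExtend,lambda,K scoring parameters.
#' @param prefilter,k,minSharedKmers k-mer prescreen (see
#'   [clusterOrthologs()]).
#' @return `data.frame` per focal gene: best out-of-clade hit and its
#'   E-value/coverage, best within-clade E-value, the threshold applied,
#'   whether the relaxed pass was used, and the `unique` call. Genes with no
#'   within-clade hit are flagged in `no_within_hit`.
#' @export
uniqueGenes <- function(focalGenes, withinProteomes, otherProteomes,
                        coverageMin = 50, eStrict = 1e-50, eFloor = 1e-10,
                        matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                        lambda = 0.267, K = 0.041,
                        prefilter = TRUE, k = 4L, minSharedKmers = 3L) {
  stopifnot(length(focalGenes) >= 1L, !is.null(names(focalGenes)))
  gseq <- as.character(focalGenes)
  withinSeqs <- unlist(lapply(withinProteomes, as.character),
                       use.names = FALSE)
  withinIds <- unlist(lapply(names(withinProteomes), function(g)
    paste0(g, "|", names(withinProteomes[[g]]))), use.names = FALSE)
  otherSeqs <- unlist(lapply(otherProteomes, as.character), use.names = FALSE)
  otherIds <- unlist(lapply(names(otherProteomes), function(g)
    paste0(g, "|", names(otherProteomes[[g]]))), use.names = FALSE)
  dbLenOther <- sum(nchar(otherSeqs))
  dbLenWithin <- sum(nchar(withinSeqs))

  screen <- function(q, targets, ids, dbLen) {
    if (!length(targets))
      return(data.frame(id = character(), evalue = numeric(),
                        coverage = numeric(), identity = numeric()))
    keep <- seq_along(targets)
    if (prefilter) {
      shared <- .sharedKmerCounts(q, targets, k)
      keep <- which(shared >= minSharedKmers)
    }
    if (!length(keep))
      return(data.frame(id = character(), evalue = numeric(),
                        coverage = numeric(), identity = numeric()))
    # batched: candidate subjects as patterns against the focal gene, so the
    # focal gene's coverage is the subject coverage of the call
    st <- .batchAlign(targets[keep], q, matrix, gapOpen, gapExtend, "local")
    data.frame(id = ids[keep],
               evalue = karlinAltschulE(st$score, nchar(q), dbLen,
                                        lambda, K),
               coverage = st$subject_coverage, identity = st$identity)
  }

  rows <- lapply(seq_along(gseq), function(gi) {
    q <- gseq[gi]
    wi <- screen(q, withinSeqs[withinSeqs != q | duplicated(withinSeqs)],
                 withinIds[withinSeqs != q | duplicated(withinSeqs)],
                 dbLenWithin)
    bestWithin <- if (nrow(wi)) min(wi$evalue) else NA_real_
    oo <- screen(q, otherSeqs, otherIds, dbLenOther)
    pass <- oo[oo$coverage >= coverageMin, , drop = FALSE]
    bestE <- if (nrow(pass)) min(pass$evalue) else NA_real_
    bestId <- if (nrow(pass)) pass$id[which.min(pass$evalue)] else
      NA_character_
    bestCov <- if (nrow(pass)) pass$coverage[which.min(pass$evalue)] else
      NA_real_
    uniqueStrict <- is.na(bestE) || bestE > eStrict
    relaxed <- FALSE
    threshold <- eStrict
    uniq <- uniqueStrict
    if (uniqueStrict && !is.na(bestWithin)) {
      relaxed <- TRUE
      threshold <- relaxedEvalueThreshold(bestWithin, eFloor)
      uniq <- is.na(bestE) || bestE > threshold
    }
    data.frame(gene = names(focalGenes)[gi],
               best_hit = bestId, best_evalue = bestE,
               best_coverage = bestCov, best_within_evalue = bestWithin,
               threshold = threshold, relaxed_pass = relaxed,
               no_within_hit = is.na(bestWithin), unique = uniq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# chop contigs into non-overlapping fragments, dropping the remainder
.fragments <- function(contigSet, fragmentLen) {
  out <- character()
  for (s in as.character(contigSet)) {
    nfrag <- nchar(s) %/% fragmentLen
    if (nfrag == 0L) next
    st <- (seq_len(nfrag) - 1L) * fragmentLen + 1L
    out <- c(out, substring(s, st, st + fragmentLen - 1L))
  }
  out
}

#' Fragment-based average nucleotide identity
#'
#' Both genomes are chopped into non-overlapping `fragmentLen`-bp fragments;
#' fragments are matched by best local alignment (both strands searched),
#' and ANI is the mean identity over reciprocal best fragment pairs with
#' identity >= 30% and aligned coverage >= 70% of the fragment. This is the
#' orthologous-fragment scheme of the OrthoANI family of estimators.
#'
#' @param genomeA,genomeB [GenomeRecord-class] objects or `DNAStringSet`s.
#' @param fragmentLen fragment length in bp (default 1020).
#' @param minIdentity,minCoverage qualification thresholds (%).
#' @param k,minSharedKmers k-mer prescreen for candidate fragment pairs.
#' @return list with `ani` (%, `NA` when no fragment pair qualifies),
#'   `fragments_used`, and `qualified` flag.
#' @export
ani <- function(genomeA, genomeB, fragmentLen = 1020L,
                minIdentity = 30, minCoverage = 70,
                k = 15L, minSharedKmers = 2L) {
  getSeqs <- function(g) if (is(g, "GenomeRecord")) contigs(g) else g
  fa <- .fragments(getSeqs(genomeA), fragmentLen)
  fb <- .fragments(getSeqs(genomeB), fragmentLen)
  if (length(fa) < 2L || length(fb) < 2L)
    stop(sprintf("genomes too short: need >= 2 fragments of %d bp each",
                 fragmentLen))
  fbrc <- as.character(reverseComplement(DNAStringSet(fb)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                     baseOnly = TRUE)
  kb <- lapply(fb, .kmers, k = k)
  kbrc <- lapply(fbrc, .kmers, k = k)
  alignPair <- function(x, j) {
    best <- NULL
    for (target in c(fb[j], fbrc[j])) {
      aln <- pairwiseAlignment(DNAStringSet(x), DNAStringSet(target)[[1]],
                               substitutionMatrix = submat,
                               gapOpening = 5, gapExtension = 2,
                               type = "local")
      st <- .alignStats(aln, nchar(x), nchar(target), "local")
      if (is.null(best) || st$score > best$score) best <- st
    }
    best
  }
  na <- length(fa); nb <- length(fb)
  idMat <- matrix(NA_real_, na, nb)
  okMat <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    ki <- .kmers(fa[i], k)
    cand <- which(vapply(seq_len(nb), function(j)
      sum(ki %in% kb[[j]]) >= minSharedKmers ||
      sum(ki %in% kbrc[[j]]) >= minSharedKmers, logical(1)))
    for (j in cand) {
      st <- alignPair(fa[i], j)
      idMat[i, j] <- st$identity
      cov <- 100 * st$residues_aligned / fragmentLen
      okMat[i, j] <- st$identity >= minIdentity && cov >= minCoverage
    }
  }
  idq <- ifelse(okMat, idMat, NA_real_)
  bestB <- apply(idq, 1L, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  bestA <- apply(idq, 2L, function(r)
    if (all(is.na(r))) NA_integer_ else which.max(r))
  recip <- which(!is.na(bestB) &
                 vapply(seq_len(na), function(i)
                   !is.na(bestB[i]) && !is.na(bestA[bestB[i]]) &&
                   bestA[bestB[i]] == i, logical(1)))
  if (!length(recip))
    return(list(ani = NA_real_, fragments_used = 0L, qualified = FALSE))
  vals <- vapply(recip, function(i) idMat[i, bestB[i]], numeric(1))
  list(ani = mean(vals), fragments_used = length(recip), qualified = TRUE)
}
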