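#' @importFrom Biostrings letterFrequency
NULL

# pooled A/C/G/T counts; ambiguity codes (incl. N) are left uncounted
.baseCounts <- function(seqs) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (is(seqs, "DNAString")) seqs <- DNAStringSet(list(seqs))
  colSums(letterFrequency(seqs, c("A", "C", "G", "T")))
}

#' Pooled GC content of DNA sequences
#'
#' (G+C)/(A+C+G+T) pooled over all sequences; N and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param seqs a `DNAStringSet` (or character vector of DNA).
#' @return GC fraction in `[0, 1]`.
#' @examples
#' gcContent(Biostrings::DNAStringSet("ATGC"))  # 0.5
#' @export
gcContent <- function(seqs) {
  ct <- .baseCounts(seqs)
  tot <- sum(ct)
  if (tot == 0) stop("no unambiguous bases")
  unname((ct["G"] + ct["C"]) / tot)
}

#' Pooled purine (A+G) content
#'
#' @inheritParams gcContent
#' @return AG fraction in `[0, 1]`.
#' @export
purineContent <- function(seqs) {
  ct <- .baseCounts(seqs)
  tot <- sum(ct)
  if (tot == 0) stop("no unambiguous bases")
  unname((ct["A"] + ct["G"]) / tot)
}

# enforce the partial-codon policy, returning in-frame character sequences
.inFrameChars <- function(cds, partial = c("trim", "strict")) {
  partial <- match.arg(partial)
  if (is.character(cds)) cds <- DNAStringSet(cds)
  if (length(cds) == 0L) stop("empty CDS list")
  ch <- as.character(cds)
  rem <- nchar(ch) %% 3L
  if (any(rem != 0L)) {
    who <- names(ch)[rem != 0L]
    if (is.null(who)) who <- which(rem != 0L)
    if (partial == "strict")
      stop(sprintf("CDS length not divisible by 3: %s",
                   paste(who, collapse = ", ")))
    warning(sprintf("dropping trailing partial codon of %d CDS", sum(rem != 0L)))
    ch <- substr(ch, 1L, nchar(ch) - rem)
  }
  ch[nchar(ch) > 0L]
}

#' GC content at the three codon positions
#'
#' Pooled over all codons of all CDS (stop codons included). Sequences whose
#' length is not a multiple of 3 have the trailing partial codon dropped with
#' a warning (`partial = "trim"`, the default) or raise an error
#' (`partial = "strict"`). Ambiguous bases are excluded positionally.
#'
#' @param cds a `DNAStringSet` of coding-sense CDS sequences.
#' @param partial partial-codon policy, `"trim"` or `"strict"`.
#' @return named numeric vector `c(gc1, gc2, gc3)`.
#' @export
codonPositionGC <- function(cds, partial = c("trim", "strict")) {
  ch <- .inFrameChars(cds, partial)
  x <- DNAStringSet(ch)
  clean <- sum(colSums(letterFrequency(x, c("A", "C", "G", "T")))) ==
    sum(nchar(ch))
  if (clean) {
    # fast path: in-frame codon counts in C
    cod <- colSums(Biostrings::trinucleotideFrequency(x, step = 3))
    tot <- sum(cod)
    gcp <- function(p) {
      base <- substr(names(cod), p, p)
      sum(cod[base %in% c("G", "C")]) / tot
    }
    out <- c(gc1 = gcp(1), gc2 = gcp(2), gc3 = gcp(3))
  } else {
    # ambiguity codes excluded positionally
    v <- strsplit(paste(ch, collapse = ""), "", fixed = TRUE)[[1]]
    pos <- ((seq_along(v) - 1L) %% 3L) + 1L
    out <- vapply(1:3, function(p) {
      b <- v[pos == p]
      n <- sum(b %in% c("A", "C", "G", "T"))
      if (n == 0) return(NA_real_)
      sum(b %in% c("G", "C")) / n
    }, numeric(1))
    names(out) <- c("gc1", "gc2", "gc3")
  }
  out
}

#' Per-gene third-codon-position GC
#'
#' @inheritParams codonPositionGC
#' @return named numeric vector of per-sequence GC3 fractions.
#' @export
geneGC3 <- function(cds, partial = c("trim", "strict")) {
  ch <- .inFrameChars(cds, partial)
  x <- DNAStringSet(ch)
  cod <- Biostrings::trinucleotideFrequency(x, step = 3)
  third <- substr(colnames(cod), 3, 3)
  gc <- rowSums(cod[, third %in% c("G", "C"), drop = FALSE])
  tot <- rowSums(cod)
  out <- ifelse(tot > 0, gc / tot, NA_real_)
  names(out) <- names(ch)
  out
}

#' Fraction of the assembly not covered by annotated genes
#'
#' One minus the fraction of assembly length covered by the union of
#' annotated gene-bearing intervals (overlaps merged first). By default
#' structural RNA genes count as coding; set `includeRna = FALSE` to count
#' only CDS.
#'
#' @param genome a [GenomeRecord-class].
#' @param includeRna should rRNA/tRNA features count as gene-bearing?
#' @return non-coding fraction in `[0, 1]` (1 when there are no features).
#' @export
noncodingFraction <- function(genome, includeRna = TRUE) {
  types <- if (includeRna) c("CDS", "rRNA", "tRNA") else "CDS"
  ft <- features(genome)
  ft <- ft[ft$type %in% types]
  gsize <- genomeSize(genome)
  if (length(ft) == 0L) return(1)
  covered <- sum(width(GenomicRanges::reduce(ft, ignore.strand = TRUE)))
  1 - covered / gsize
}

#' Pooled GC of structural RNA genes
#'
#' @param genome a [GenomeRecord-class] with at least one rRNA or tRNA
#'   feature.
#' @return GC fraction of the pooled rRNA+tRNA sequences.
#' @export
rnaGC <- function(genome) {
  seqs <- featureSeqs(genome, types = c("rRNA", "tRNA"))
  if (length(seqs) == 0L) stop("no rRNA/tRNA features")
  gcContent(seqs)
}

#' Amino-acid composition of a proteome
#'
#' Pooled residue counts over all proteins divided by total counted residues.
#' `X`, stop symbols and the rare translated residues U/O are excluded from
#' numerator and denominator.
#'
#' @param proteome an `AAStringSet` (or character vector).
#' @return named 20-vector of fractions summing to 1 (alphabetical one-letter
#'   order).
#' @export
aaComposition <- function(proteome) {
  if (is.character(proteome)) proteome <- AAStringSet(proteome)
  if (length(proteome) == 0L) stop("empty proteome")
  ct <- colSums(letterFrequency(proteome, .AA20))
  tot <- sum(ct)
  if (tot == 0) stop("no counted residues")
  ct / tot
}

#' IVYWREL fraction of a proteome
#'
#' Summed frequency of Ile, Val, Tyr, Trp, Arg, Glu and Leu, a proposed
#' predictor of thermotolerance.
#'
#' @inheritParams aaComposition
#' @return fraction in `[0, 1]`.
#' @export
ivywrel <- function(proteome) {
  aa <- aaComposition(proteome)
  unname(sum(aa[c("I", "V", "Y", "W", "R", "E", "L")]))
}

#' Dipeptide successor frequency P(next = y | current = x)
#'
#' Pooled across proteins; an `x` at a protein's final position has no
#' successor and is excluded from the denominator. Counting never crosses
#' protein boundaries.
#'
#' @inheritParams aaComposition
#' @param x,y single one-letter residue codes.
#' @return conditional frequency in `[0, 1]`.
#' @examples
#' dipeptideContextFreq(c("DGDA"), "D", "G")  # 0.5
#' @export
dipeptideContextFreq <- function(proteome, x, y) {
  if (is(proteome, "AAStringSet")) proteome <- as.character(proteome)
  stopifnot(nchar(x) == 1L, nchar(y) == 1L)
  xr <- charToRaw(x)
  yr <- charToRaw(y)
  num <- 0L
  den <- 0L
  for (s in proteome) {
    v <- charToRaw(s)
    n <- length(v)
    if (n < 2L) next
    isx <- v[-n] == xr
    den <- den + sum(isx)
    num <- num + sum(isx & v[-1L] == yr)
  }
  if (den == 0L) stop(sprintf("no '%s'-with-successor occurrences", x))
  num / den
}

# heat-map presentation order for the amino-acid block
.HEATMAP_AA_ORDER <- c("D", "E", "R", "K", "L", "I", "V", "M", "F", "W",
                       "Y", "A", "S", "T", "Q", "N", "H", "C", "P", "G")

#' Full composition profile of one genome
#'
#' @param genome a [GenomeRecord-class].
#' @param includeRna passed to [noncodingFraction()].
#' @return one-row `data.frame` with GC, codon-position GC, AG, non-coding
#'   fraction, RNA GC (NA without RNA features), the 20 amino-acid
#'   percentages (heat-map order), IVYWREL and the Asp-Gly successor
#'   frequency.
#' @export
compositionProfile <- function(genome, includeRna = TRUE) {
  ctg <- contigs(genome)
  cds <- cdsSequences(genome)
  prot <- proteome(genome)
  if (length(prot) == 0L && length(cds)) prot <- translateCds(genome)
  gc123 <- if (length(cds)) suppressWarnings(codonPositionGC(cds))
           else c(gc1 = NA_real_, gc2 = NA_real_, gc3 = NA_real_)
  rgc <- tryCatch(rnaGC(genome), error = function(e) NA_real_)
  aa <- if (length(prot)) aaComposition(prot) else
    stats::setNames(rep(NA_real_, 20L), .AA20)
  dg <- tryCatch(dipeptideContextFreq(prot, "D", "G"),
                 error = function(e) NA_real_)
  out <- data.frame(
    strain = strain(genome),
    clade = clade(genome),
    collection_temperature = collectionTemp(genome),
    genome_size = genomeSize(genome),
    GC = 100 * gcContent(ctg),
    stringsAsFactors = FALSE)
  for (a in .HEATMAP_AA_ORDER) out[[a]] <- 100 * unname(aa[a])
  out$gc1 <- 100 * unname(gc123["gc1"])
  out$gc2 <- 100 * unname(gc123["gc2"])
  out$gc3 <- 100 * unname(gc123["gc3"])
  out$AG <- 100 * purineContent(ctg)
  out$noncoding_frac <- noncodingFraction(genome, includeRna = includeRna)
  out$rna_gc <- 100 * rgc
  out$ivywrel <- if (all(is.finite(aa)))
    100 * unname(sum(aa[c("I", "V", "Y", "W", "R", "E", "L")])) else NA_real_
  out$dg_context <- 100 * dg
  out
}

#' Composition report across strains, with clade means
#'
#' One row per strain plus one `clade_mean:<clade>` row per clade holding
#' the unweighted mean of that clade's strains; the amino-acid block follows
#' the heat-map presentation order (GC, D, E, R, K, L, I, V, M, F, W, Y, A,
#' S, T, Q, N, H, C, P, G).
#'
#' @param genomes list of [GenomeRecord-class] objects.
#' @param includeRna passed to [noncodingFraction()].
#' @return a `data.frame`; clade-mean rows have `strain` set to
#'   `clade_mean:<clade>`.
#' @export
compositionReport <- function(genomes, includeRna = TRUE) {
  stopifnot(length(genomes) >= 1L)
  rows <- do.call(rbind, lapply(genomes, compositionProfile,
                                includeRna = includeRna))
  num <- vapply(rows, is.numeric, logical(1))
  means <- do.call(rbind, lapply(split(rows, rows$clade), function(d) {
    m <- d[1, , drop = FALSE]
    m$strain <- paste0("clade_mean:", d$clade[1])
    m[num] <- lapply(d[num], mean)
    m
  }))
  out <- rbind(rows, means)
  rownames(out) <- NULL
  out
}
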