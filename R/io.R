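#' @importFrom Biostrings DNAStringSet AAStringSet BStringSet readBStringSet
#'   writeXStringSet width reverseComplement translate subseq
#' @importFrom GenomicRanges GRanges strand
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics start end
#' @importFrom utils read.delim write.table
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")
.PROT_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
                    "X", "U", "O", "*")
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.checkAlphabet <- function(chars, allowed, ids) {
  for (i in seq_along(chars)) {
    s <- strsplit(chars[[i]], "", fixed = TRUE)[[1]]
    bad <- which(!(s %in% allowed))
    if (length(bad))
      stop(sprintf("illegal character '%s' at position %d of record '%s'",
                   s[bad[1]], bad[1], ids[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased, the id is the header token before the first
#' whitespace, and every character is validated against the declared
#' alphabet (IUPAC DNA codes, or the 20 amino acids plus X/U/O and a
#' terminal `*`).
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"`, `"protein"`, or `"auto"` (classify from content:
#'   anything outside the IUPAC DNA codes means protein).
#' @return a [Biostrings::DNAStringSet] or [Biostrings::AAStringSet]; an
#'   empty set for an empty file.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some description", "acgt"), f)
#' readFasta(f)
#' @export
readFasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw, ">"))) {
    if (all(!nzchar(trimws(raw))))
      return(if (alphabet == "protein") AAStringSet() else DNAStringSet())
    stop("not a FASTA file (no '>' header)")
  }
  x <- readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA ids: %s", paste(unique(dup), collapse = ", ")))
  chars <- toupper(as.character(x))
  empty <- which(nchar(chars) == 0L)
  if (length(empty))
    stop(sprintf("empty sequence for record '%s'", ids[empty[1]]))
  if (alphabet == "auto") {
    alldna <- all(vapply(chars, function(s)
      all(strsplit(s, "", fixed = TRUE)[[1]] %in% .DNA_ALPHABET), logical(1)))
    alphabet <- if (alldna) "dna" else "protein"
  }
  if (alphabet == "dna") {
    .checkAlphabet(chars, .DNA_ALPHABET, ids)
    out <- DNAStringSet(chars)
  } else {
    .checkAlphabet(chars, .PROT_ALPHABET, ids)
    out <- AAStringSet(chars)
  }
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a `DNAStringSet` or `AAStringSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  writeXStringSet(x, path)
  invisible(path)
}

.resolveFeatureId <- function(gr) {
  mc <- mcols(gr)
  pick <- function(col) {
    if (!is.null(mc[[col]])) as.character(mc[[col]]) else
      rep(NA_character_, length(gr))
  }
  id <- pick("ID")
  lt <- pick("locus_tag")
  pid <- pick("protein_id")
  id <- ifelse(!is.na(id) & nzchar(id), id,
        ifelse(!is.na(lt) & nzchar(lt), lt,
        ifelse(!is.na(pid) & nzchar(pid), pid,
               sprintf("%s:%d-%d", as.character(seqnames(gr)),
                       start(gr), end(gr)))))
  id
}

#' Read GFF3 annotation against a set of contigs
#'
#' Coordinates keep GFF3's 1-based closed convention (the `GRanges`
#' convention); feature types outside CDS/rRNA/tRNA/gene are kept as
#' `"other"`. A stable `feature_id` is resolved as `ID`, then `locus_tag`,
#' then `protein_id`, else synthesized from the location.
#'
#' @param path GFF3 file path.
#' @param contigs named [Biostrings::DNAStringSet] the annotation refers to.
#' @return a `GRanges` with metadata columns `type`, `feature_id`, `phase`.
#' @export
readGff3 <- function(path, contigs) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gff3")
  unknown <- setdiff(unique(as.character(seqnames(gr))), names(contigs))
  if (length(unknown))
    stop(sprintf("features reference unknown contigs: %s",
                 paste(unknown, collapse = ", ")))
  clen <- width(contigs)[match(as.character(seqnames(gr)), names(contigs))]
  over <- which(end(gr) > clen | start(gr) < 1L)
  if (length(over))
    stop(sprintf("feature %d extends beyond contig '%s' (end %d > length %d)",
                 over[1], as.character(seqnames(gr))[over[1]],
                 end(gr)[over[1]], clen[over[1]]))
  type <- as.character(gr$type)
  type[!(type %in% .FEATURE_TYPES)] <- "other"
  phase <- if (!is.null(gr$phase)) as.integer(as.character(gr$phase))
           else rep(NA_integer_, length(gr))
  fid <- .resolveFeatureId(gr)
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  GenomeInfoDb::seqlevels(out) <- names(contigs)
  GenomeInfoDb::seqlengths(out) <- width(contigs)
  mcols(out)$type <- type
  mcols(out)$feature_id <- make.unique(fid, sep = "_dup")
  mcols(out)$phase <- phase
  out
}

#' Write features as GFF3
#'
#' @param gr a `GRanges` with `type`, `feature_id` and optional `phase`
#'   metadata columns (as produced by [readGff3()]).
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
writeGff3 <- function(gr, path, source = "ThermoGx") {
  phase <- if (!is.null(gr$phase)) ifelse(is.na(gr$phase), ".", gr$phase)
           else rep(".", length(gr))
  str <- as.character(strand(gr))
  str[str == "*"] <- "+"
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\tID=%s",
                   as.character(seqnames(gr)), source,
                   as.character(gr$type), start(gr), end(gr),
                   str, phase, as.character(gr$feature_id))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read and write Newick trees
#'
#' `readNewick()` parses a single Newick tree (balanced-parenthesis check
#' first, with the character offset of the first imbalance on failure);
#' `writeNewick()` serialises an `ape::phylo` back to a Newick string.
#'
#' @param path path to a file holding one Newick tree.
#' @return `readNewick`: an `ape::phylo`; `writeNewick`: a Newick string.
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop(sprintf("unbalanced parentheses at character %d", i))
  }
  if (depth != 0L)
    stop(sprintf("unbalanced parentheses: %d unclosed '(' at end of input",
                 depth))
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick tree")
  if (inherits(tr, "multiPhylo")) stop("expected a single tree per file")
  tr
}

#' @rdname readNewick
#' @param tree an `ape::phylo`.
#' @export
writeNewick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Read a strain trait table (TSV)
#'
#' Expected columns: `strain`, `clade`, `collection_temperature` (degrees C),
#' plus arbitrary numeric trait columns.
#'
#' @param path TSV path with a header row.
#' @return a `data.frame` keyed by unique strain ids.
#' @export
readTraitTable <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicated column names in trait table")
  need <- c("strain", "clade", "collection_temperature")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("trait table missing columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$strain))
    stop("duplicate strain ids in trait table")
  tt <- df$collection_temperature
  if (any(!is.finite(tt)) || any(tt <= 0 | tt >= 100))
    stop("collection_temperature must lie in (0, 100) degrees C")
  df
}

#' Read a genome bundle directory
#'
#' Counterpart of [writeGenomeBundle()]: expects `traits.tsv`,
#' `species_tree.nwk` and, per strain, `<strain>.fna`, `<strain>.faa` and
#' `<strain>.gff3`.
#'
#' @param dir bundle directory.
#' @return list with `genomes` (list of [GenomeRecord-class]), `traits` and
#'   `tree`, as produced by [generateGenomes()].
#' @export
readGenomeBundle <- function(dir) {
  tf <- file.path(dir, "traits.tsv")
  if (!file.exists(tf)) stop(sprintf("missing input path: %s", tf))
  traits <- readTraitTable(tf)
  genomes <- list()
  for (i in seq_len(nrow(traits))) {
    s <- traits$strain[i]
    paths <- file.path(dir, paste0(s, c(".fna", ".faa", ".gff3")))
    miss <- paths[!file.exists(paths)]
    if (length(miss)) stop(sprintf("missing input path: %s", miss[1]))
    ctg <- readFasta(paths[1], alphabet = "dna")
    prot <- readFasta(paths[2], alphabet = "protein")
    ft <- readGff3(paths[3], ctg)
    genomes[[s]] <- GenomeRecord(s, ctg, ft, prot, clade = traits$clade[i],
                                 collectionTemperature =
                                   traits$collection_temperature[i])
  }
  nwk <- file.path(dir, "species_tree.nwk")
  tree <- if (file.exists(nwk)) readNewick(nwk) else NULL
  list(genomes = genomes, traits = traits, tree = tree)
}

#' Extract feature sequences from a genome
#'
#' Minus-strand features are reverse-complemented, so CDS sequences read
#' 5'->3' in the coding sense.
#'
#' @param genome a [GenomeRecord-class].
#' @param types feature types to extract.
#' @return a named `DNAStringSet` (names are feature ids).
#' @export
featureSeqs <- function(genome, types = c("CDS", "rRNA", "tRNA")) {
  ft <- features(genome)
  ft <- ft[ft$type %in% types]
  if (length(ft) == 0L) return(DNAStringSet())
  ctg <- contigs(genome)
  sq <- as.character(seqnames(ft))
  out <- DNAStringSet(rep("", length(ft)))
  for (nm in unique(sq)) {
    idx <- which(sq == nm)
    out[idx] <- Biostrings::extractAt(
      ctg[[nm]], IRanges(start(ft)[idx], end(ft)[idx]))
  }
  minus <- as.character(strand(ft)) == "-"
  if (any(minus)) out[minus] <- reverseComplement(out[minus])
  names(out) <- ft$feature_id
  out
}

#' CDS nucleotide sequences of a genome (coding sense)
#'
#' @param genome a [GenomeRecord-class].
#' @return named `DNAStringSet` of CDS sequences.
#' @export
cdsSequences <- function(genome) featureSeqs(genome, types = "CDS")

#' Translate all CDS of a genome
#'
#' Trailing stop codons are stripped; internal fuzzy codons translate to X.
#'
#' @param genome a [GenomeRecord-class].
#' @return named `AAStringSet`.
#' @export
translateCds <- function(genome) {
  cds <- cdsSequences(genome)
  if (length(cds) == 0L) return(AAStringSet())
  keep <- width(cds) - width(cds) %% 3L
  cds <- subseq(cds, 1L, keep)
  aa <- suppressWarnings(translate(cds, if.fuzzy.codon = "solve"))
  aa <- AAStringSet(sub("\\*$", "", as.character(aa)))
  aa
}
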