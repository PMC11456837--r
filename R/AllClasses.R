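#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomeInfoDb seqlengths seqnames
NULL

.FEATURE_TYPES <- c("CDS", "rRNA", "tRNA", "gene", "other")

#' GenomeRecord: one strain's assembly, annotation, proteome and metadata
#'
#' Container bundling everything the pipeline needs for a single strain:
#' contig sequences, annotated features as a `GRanges` (1-based, closed
#' intervals, the GFF3 and Bioconductor convention), the translated proteome,
#' and the strain metadata used by downstream trait models (clade label and
#' the in situ collection temperature of the source sample).
#'
#' @slot strain single strain identifier.
#' @slot contigs a [Biostrings::DNAStringSet] of assembly contigs.
#' @slot features a [GenomicRanges::GRanges] with metadata columns `type`
#'   (CDS/rRNA/tRNA/gene/other), `feature_id` and, for CDS, `phase`.
#' @slot proteome a [Biostrings::AAStringSet]; names are feature ids of the
#'   CDS each protein was translated from.
#' @slot clade clade label (e.g. `"I"` .. `"VI"`).
#' @slot collectionTemperature in situ collection temperature, degrees C.
#'
#' @seealso [GenomeRecord()] for the user constructor, [compositionProfile()]
#' @export
setClass("GenomeRecord",
  representation(
    strain = "character",
    contigs = "ANY",
    features = "ANY",
    proteome = "ANY",
    clade = "character",
    collectionTemperature = "numeric"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@strain) != 1L || !nzchar(object@strain))
    msg <- c(msg, "'strain' must be a single non-empty string")
  if (!is(object@contigs, "DNAStringSet"))
    msg <- c(msg, "'contigs' must be a DNAStringSet")
  else {
    if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
      msg <- c(msg, "contigs must have unique names")
  }
  if (!is(object@features, "GRanges")) {
    msg <- c(msg, "'features' must be a GRanges")
  } else if (is(object@contigs, "DNAStringSet") && length(object@features)) {
    ft <- object@features
    if (is.null(ft$type) || !all(ft$type %in% .FEATURE_TYPES))
      msg <- c(msg, sprintf("feature 'type' must be one of %s",
                            paste(.FEATURE_TYPES, collapse = "/")))
    if (is.null(ft$feature_id) || anyDuplicated(ft$feature_id))
      msg <- c(msg, "features must carry unique 'feature_id' values")
    bad <- !(as.character(seqnames(ft)) %in% names(object@contigs))
    if (any(bad)) {
      msg <- c(msg, sprintf("features reference unknown contigs: %s",
                            paste(unique(as.character(seqnames(ft))[bad]),
                                  collapse = ", ")))
    } else {
      clen <- width(object@contigs)[match(as.character(seqnames(ft)),
                                          names(object@contigs))]
      if (any(BiocGenerics::end(ft) > clen) || any(BiocGenerics::start(ft) < 1L))
        msg <- c(msg, "feature intervals extend beyond their contig")
    }
  }
  if (!is(object@proteome, "AAStringSet"))
    msg <- c(msg, "'proteome' must be an AAStringSet")
  else if (length(object@proteome) &&
           (is.null(names(object@proteome)) ||
            anyDuplicated(names(object@proteome))))
    msg <- c(msg, "proteome sequences must have unique names")
  if (length(object@collectionTemperature) == 1L &&
      is.finite(object@collectionTemperature) &&
      (object@collectionTemperature <= 0 || object@collectionTemperature >= 100))
    msg <- c(msg, "'collectionTemperature' must lie in (0, 100) degrees C")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param strain strain identifier.
#' @param contigs named [Biostrings::DNAStringSet].
#' @param features [GenomicRanges::GRanges] with `type` and `feature_id`
#'   metadata columns (see [readGff3()]); may be empty.
#' @param proteome named [Biostrings::AAStringSet] (may be empty).
#' @param clade clade label.
#' @param collectionTemperature collection temperature in degrees C.
#' @return a [GenomeRecord-class] object.
#' @examples
#' ctg <- Biostrings::DNAStringSet(c(c1 = "ATGAAATAAGGGCCC"))
#' gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(1, 9), strand = "+",
#'                              type = "CDS", feature_id = "g1", phase = 0L)
#' GenomeRecord("s1", ctg, gr, clade = "I", collectionTemperature = 55)
#' @export
GenomeRecord <- function(strain, contigs,
                         features = GenomicRanges::GRanges(),
                         proteome = Biostrings::AAStringSet(),
                         clade = NA_character_,
                         collectionTemperature = NA_real_) {
  if (length(features) && is.null(features$type))
    stop("'features' must carry a 'type' metadata column")
  new("GenomeRecord", strain = as.character(strain), contigs = contigs,
      features = features, proteome = proteome,
      clade = as.character(clade),
      collectionTemperature = as.numeric(collectionTemperature))
}

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf(
    "GenomeRecord '%s' (clade %s, %.1f degC)\n  %d contig(s), %s bp; %d feature(s); %d protein(s)\n",
    object@strain, object@clade, object@collectionTemperature,
    length(object@contigs),
    format(sum(width(object@contigs)), big.mark = ","),
    length(object@features), length(object@proteome)))
})

#' OrthologClusterSet: protein clusters across genomes
#'
#' Result of single-linkage ortholog clustering: a membership table assigning
#' each clustered protein to exactly one cluster, plus the full genome roster
#' (so absence is distinguishable from an unsampled genome).
#'
#' @slot membership `data.frame` with columns `cluster` (integer), `genome`,
#'   `protein`.
#' @slot genomes character vector of all genomes that entered clustering.
#' @seealso [clusterOrthologs()], [copyNumber()], [cladeCore()]
#' @export
setClass("OrthologClusterSet",
  representation(membership = "data.frame", genomes = "character")
)

setValidity("OrthologClusterSet", function(object) {
  m <- object@membership
  msg <- character()
  if (!all(c("cluster", "genome", "protein") %in% names(m)))
    msg <- c(msg, "membership needs columns cluster/genome/protein")
  else {
    if (anyDuplicated(paste(m$genome, m$protein)))
      msg <- c(msg, "a protein may belong to at most one cluster")
    if (!all(m$genome %in% object@genomes))
      msg <- c(msg, "membership references genomes missing from the roster")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrthologClusterSet", function(object) {
  cat(sprintf("OrthologClusterSet: %d cluster(s), %d protein(s), %d genome(s)\n",
              nClusters(object), nrow(object@membership),
              length(object@genomes)))
})

#' @rdname OrthologClusterSet-class
#' @param object an `OrthologClusterSet`.
#' @return `nClusters`: number of clusters.
#' @export
nClusters <- function(object) {
  stopifnot(is(object, "OrthologClusterSet"))
  if (nrow(object@membership) == 0L) 0L else max(object@membership$cluster)
}

#' Per-cluster per-genome copy numbers
#'
#' @param object an [OrthologClusterSet-class].
#' @return integer matrix, clusters x genomes.
#' @export
copyNumber <- function(object) {
  stopifnot(is(object, "OrthologClusterSet"))
  m <- object@membership
  k <- nClusters(object)
  out <- matrix(0L, nrow = k, ncol = length(object@genomes),
                dimnames = list(seq_len(k), object@genomes))
  if (nrow(m)) {
    tab <- table(factor(m$cluster, levels = seq_len(k)),
                 factor(m$genome, levels = object@genomes))
    out[] <- as.integer(tab)
  }
  out
}

#' @rdname OrthologClusterSet-class
#' @return `clusterMembers`: the membership `data.frame`.
#' @export
clusterMembers <- function(object) {
  stopifnot(is(object, "OrthologClusterSet"))
  object@membership
}
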