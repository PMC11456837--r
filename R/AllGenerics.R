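#' Accessors for GenomeRecord
#'
#' `strain()`, `clade()`, `collectionTemp()`, `contigs()`, `features()` and
#' `proteome()` extract the corresponding slot.
#'
#' @param x a [GenomeRecord-class].
#' @return the slot value.
#' @name GenomeRecord-accessors
NULL

#' @rdname GenomeRecord-accessors
#' @export
setGeneric("strain", function(x) standardGeneric("strain"))
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("clade", function(x) standardGeneric("clade"))
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("collectionTemp", function(x) standardGeneric("collectionTemp"))
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname GenomeRecord-accessors
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))

#' @rdname GenomeRecord-accessors
#' @export
setMethod("strain", "GenomeRecord", function(x) x@strain)
#' @rdname GenomeRecord-accessors
#' @export
setMethod("clade", "GenomeRecord", function(x) x@clade)
#' @rdname GenomeRecord-accessors
#' @export
setMethod("collectionTemp", "GenomeRecord", function(x) x@collectionTemperature)
#' @rdname GenomeRecord-accessors
#' @export
setMethod("contigs", "GenomeRecord", function(x) x@contigs)
#' @rdname GenomeRecord-accessors
#' @export
setMethod("features", "GenomeRecord", function(x) x@features)
#' @rdname GenomeRecord-accessors
#' @export
setMethod("proteome", "GenomeRecord", function(x) x@proteome)

#' Genome size in base pairs
#'
#' @param x a [GenomeRecord-class].
#' @return total assembly length (bp).
#' @export
setGeneric("genomeSize", function(x) standardGeneric("genomeSize"))

#' @rdname genomeSize
#' @export
setMethod("genomeSize", "GenomeRecord",
          function(x) sum(Biostrings::width(contigs(x))))
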