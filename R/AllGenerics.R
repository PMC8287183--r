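#' @include AllClasses.R
NULL

#' @rdname GeneModel-accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("geneStrand", function(x) standardGeneric("geneStrand"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GeneModel-accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' Build the splice graph of a gene
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return a \linkS4class{SpliceGraph} whose edges are the union over
#'   transcripts of consecutive-exon junctions, each annotated with its
#'   supporting transcripts. A single-exon gene yields a graph with no edges.
#' @export
setGeneric("buildSpliceGraph", function(gene) standardGeneric("buildSpliceGraph"))

#' @rdname SpliceGraph-accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
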