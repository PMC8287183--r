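#' @import methods
NULL

#' Gene model: exon structures of one gene
#'
#' A \code{GeneModel} holds the annotated structure of a single gene: the set
#' of distinct exons (1-based, closed genomic coordinates) and the transcripts,
#' each an ordered list of exons. All coordinates are genomic; transcript order
#' follows genomic order regardless of strand, and strand-aware logic
#' (donor/acceptor labelling) is applied downstream.
#'
#' @slot geneId single gene identifier.
#' @slot chrom chromosome name.
#' @slot strand \code{"+"} or \code{"-"}; fixed per gene.
#' @slot exons integer matrix with columns \code{start}, \code{end}; one row
#'   per distinct exon, sorted by (start, end).
#' @slot transcripts named list; each element an integer vector of row indices
#'   into \code{exons}, sorted in genomic order.
#'
#' @exportClass GeneModel
setClass("GeneModel",
  slots = c(
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "matrix",
    transcripts = "list"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@geneId) != 1L) msg <- c(msg, "geneId must be length 1")
  if (length(object@chrom) != 1L) msg <- c(msg, "chrom must be length 1")
  if (!identical(length(object@strand), 1L) ||
      !object@strand %in% c("+", "-")) {
    msg <- c(msg, "strand must be '+' or '-'")
  }
  ex <- object@exons
  if (!is.numeric(ex) || ncol(ex) != 2L ||
      !identical(colnames(ex), c("start", "end"))) {
    msg <- c(msg, "exons must be a numeric matrix with columns start, end")
  } else {
    if (any(ex[, "start"] > ex[, "end"])) {
      msg <- c(msg, "exon start must be <= end")
    }
    if (length(object@transcripts) < 1L) {
      msg <- c(msg, "gene must have at least one transcript")
    }
    for (tx in names(object@transcripts)) {
      idx <- object@transcripts[[tx]]
      if (length(idx) < 1L) {
        msg <- c(msg, sprintf("transcript '%s' has no exons", tx))
        next
      }
      if (any(idx < 1L) || any(idx > nrow(ex))) {
        msg <- c(msg, sprintf("transcript '%s' has out-of-range exon index", tx))
        next
      }
      s <- ex[idx, "start"]; e <- ex[idx, "end"]
      if (length(idx) > 1L && any(s[-1L] <= e[-length(e)])) {
        msg <- c(msg, sprintf(
          "transcript '%s' has overlapping or unordered exons", tx))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Splice graph of one gene
#'
#' Nodes are the gene's annotated exons; edges are annotated splice junctions,
#' i.e. introns between consecutive exons of at least one transcript. Junction
#' coordinates follow the intron convention: \code{intron_start} is the first
#' and \code{intron_end} the last intronic base (1-based).
#'
#' @slot geneId,chrom,strand as in \linkS4class{GeneModel}.
#' @slot exons exon matrix copied from the gene model.
#' @slot edges data.frame with columns \code{donor_end} (last base of the
#'   upstream exon), \code{acceptor_start} (first base of the downstream
#'   exon), \code{intron_start}, \code{intron_end}, \code{transcripts}
#'   (comma-separated supporting transcript ids).
#'
#' @exportClass SpliceGraph
setClass("SpliceGraph",
  slots = c(
    geneId = "character",
    chrom = "character",
    strand = "character",
    exons = "matrix",
    edges = "data.frame"
  )
)

setValidity("SpliceGraph", function(object) {
  ed <- object@edges
  need <- c("donor_end", "acceptor_start", "intron_start", "intron_end",
            "transcripts")
  if (!all(need %in% names(ed))) {
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(ed) && any(ed$intron_start > ed$intron_end)) {
    return("intron_start must be <= intron_end")
  }
  TRUE
})

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the pipeline targets: two groups (knockdown vs control) of
#' three biological replicates, one planted event per canonical type, event
#' read depth around 100, binomial inclusion/exclusion sampling with
#' logit-normal replicate noise, and an expression matrix with planted fold
#' changes, an anchor-gene coexpression block and splicing-factor couplings.
#'
#' @slot seed integer seed; mandatory, drives every random draw.
#' @slot eventsPerType planted events per canonical type (10 types).
#' @slot groups character vector of the two group labels.
#' @slot nReplicates replicates per group (>= 2).
#' @slot psi numeric length-2: alternative-form fraction per group applied to
#'   every planted event (per-event overrides via \code{psiByEvent}).
#' @slot psiByEvent optional named list: event gene id -> numeric length-2 psi.
#' @slot depthMean,depthDispersion negative-binomial event depth; dispersion
#'   \code{Inf} means Poisson.
#' @slot replicateSigma logit-scale replicate noise s.d.
#' @slot exactCounts if TRUE, replicate counts are deterministic expectations
#'   (noise-free fixtures).
#' @slot nGenes expression-matrix size (includes planted genes).
#' @slot nDeGenes,deFold planted differentially expressed genes and their fold.
#' @slot anchorGene anchor for the coexpression block.
#' @slot blockSize,blockSigma coexpression block size and noise s.d.
#' @slot sfGenes splicing-factor gene ids planted in the expression matrix.
#' @slot knockdownEfficiency planted qPCR knockdown (0.7 = 70 percent loss).
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    seed = "integer",
    eventsPerType = "integer",
    groups = "character",
    nReplicates = "integer",
    psi = "numeric",
    psiByEvent = "list",
    depthMean = "numeric",
    depthDispersion = "numeric",
    replicateSigma = "numeric",
    exactCounts = "logical",
    nGenes = "integer",
    nDeGenes = "integer",
    deFold = "numeric",
    anchorGene = "character",
    blockSize = "integer",
    blockSigma = "numeric",
    sfGenes = "character",
    knockdownEfficiency = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msg <- c(msg, "seed is mandatory")
  }
  if (length(object@groups) != 2L) msg <- c(msg, "exactly two groups required")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (any(object@psi < 0) || any(object@psi > 1)) {
    msg <- c(msg, "psi must lie in [0, 1]")
  }
  if (object@depthMean <= 0) msg <- c(msg, "depthMean must be positive")
  if (object@replicateSigma < 0) msg <- c(msg, "replicateSigma must be >= 0")
  if (object@knockdownEfficiency < 0 || object@knockdownEfficiency > 1) {
    msg <- c(msg, "knockdownEfficiency must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
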