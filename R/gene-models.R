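#' @include AllGenerics.R
NULL

## ---- accessors -------------------------------------------------------------

#' Accessors for GeneModel and SpliceGraph
#'
#' @param x a \linkS4class{GeneModel} or \linkS4class{SpliceGraph}.
#' @return \code{geneId}, \code{chrom}, \code{geneStrand}: length-1 character;
#'   \code{exons}: integer matrix (start, end); \code{transcripts}: named list
#'   of exon-index vectors; \code{graphEdges}: the edge data.frame.
#' @name GeneModel-accessors
#' @aliases geneId chrom geneStrand exons transcripts graphEdges
NULL

#' @rdname GeneModel-accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)
#' @rdname GeneModel-accessors
setMethod("chrom", "GeneModel", function(x) x@chrom)
#' @rdname GeneModel-accessors
setMethod("geneStrand", "GeneModel", function(x) x@strand)
#' @rdname GeneModel-accessors
setMethod("exons", "GeneModel", function(x) x@exons)
#' @rdname GeneModel-accessors
setMethod("transcripts", "GeneModel", function(x) x@transcripts)

#' @rdname GeneModel-accessors
setMethod("geneId", "SpliceGraph", function(x) x@geneId)
#' @rdname GeneModel-accessors
setMethod("chrom", "SpliceGraph", function(x) x@chrom)
#' @rdname GeneModel-accessors
setMethod("geneStrand", "SpliceGraph", function(x) x@strand)
#' @rdname GeneModel-accessors
setMethod("exons", "SpliceGraph", function(x) x@exons)
#' @rdname GeneModel-accessors
setMethod("graphEdges", "SpliceGraph", function(x) x@edges)

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s (%s:%d-%d %s): %d exon(s), %d transcript(s)\n",
              object@geneId, object@chrom,
              min(object@exons[, "start"]), max(object@exons[, "end"]),
              object@strand, nrow(object@exons), length(object@transcripts)))
})

setMethod("show", "SpliceGraph", function(object) {
  cat(sprintf("SpliceGraph %s (%s, %s): %d exon node(s), %d junction edge(s)\n",
              object@geneId, object@chrom, object@strand,
              nrow(object@exons), nrow(object@edges)))
})

## ---- construction ----------------------------------------------------------

#' Construct a GeneModel from exon coordinates
#'
#' @param geneId,chrom,strand gene identity.
#' @param transcriptExons named list; each element a two-column matrix or
#'   data.frame of exon (start, end) pairs, 1-based closed.
#' @return a validated \linkS4class{GeneModel}; exons are deduplicated across
#'   transcripts and sorted.
#' @export
GeneModel <- function(geneId, chrom, strand, transcriptExons) {
  if (is.null(names(transcriptExons)) || anyNA(names(transcriptExons))) {
    stop("transcriptExons must be a named list (transcript ids)")
  }
  allex <- unique(do.call(rbind, lapply(transcriptExons, function(m) {
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "end")
    m
  })))
  ord <- order(allex[, "start"], allex[, "end"])
  allex <- allex[ord, , drop = FALSE]
  rownames(allex) <- NULL
  key <- paste(allex[, "start"], allex[, "end"])
  txs <- lapply(transcriptExons, function(m) {
    m <- as.matrix(m)[, 1:2, drop = FALSE]
    idx <- match(paste(as.integer(m[, 1]), as.integer(m[, 2])), key)
    sort(idx)
  })
  new("GeneModel", geneId = geneId, chrom = chrom, strand = strand,
      exons = allex, transcripts = txs)
}

## ---- GTF I/O ---------------------------------------------------------------

gtf_attr <- function(attrs, field) {
  m <- regmatches(attrs, regexec(sprintf('%s "([^"]*)"', field), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
}

#' Parse a GTF annotation into gene models
#'
#' Only \code{exon} feature lines are used; each must carry \code{gene_id} and
#' \code{transcript_id} attributes (GTF2.2 syntax). Coordinates are kept
#' 1-based closed. A gene spread over several chromosomes or strands is
#' rejected, and overlapping exons within one transcript are an error.
#'
#' @param path path to a GTF file.
#' @return named list of \linkS4class{GeneModel} objects (one per gene_id).
#' @export
readGtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("no feature lines in GTF '", path, "'; returning empty collection")
    return(list())
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    bad <- lineno[which(nf < 9L)[1L]]
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields", bad))
  }
  feat <- vapply(fields, `[`, "", 3L)
  exon <- feat == "exon"
  if (!any(exon)) {
    warning("GTF '", path, "' contains no exon features")
    return(list())
  }
  fields <- fields[exon]
  lineno <- lineno[exon]
  chromv <- vapply(fields, `[`, "", 1L)
  startv <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
  endv <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
  strandv <- vapply(fields, `[`, "", 7L)
  attrv <- vapply(fields, `[`, "", 9L)
  if (anyNA(startv) || anyNA(endv)) {
    bad <- lineno[which(is.na(startv) | is.na(endv))[1L]]
    stop(sprintf("malformed GTF line %d: non-numeric coordinates", bad))
  }
  gid <- gtf_attr(attrv, "gene_id")
  tid <- gtf_attr(attrv, "transcript_id")
  if (anyNA(gid)) {
    stop(sprintf("GTF line %d: exon lacks gene_id", lineno[which(is.na(gid))[1L]]))
  }
  if (anyNA(tid)) {
    stop(sprintf("GTF line %d: exon lacks transcript_id",
                 lineno[which(is.na(tid))[1L]]))
  }
  df <- data.frame(chrom = chromv, start = startv, end = endv,
                   strand = strandv, gene = gid, tx = tid,
                   stringsAsFactors = FALSE)
  out <- list()
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, , drop = FALSE]
    if (length(unique(sub$chrom)) > 1L || length(unique(sub$strand)) > 1L) {
      stop("gene '", g, "' spans multiple chromosomes or strands")
    }
    txex <- split(sub[, c("start", "end")], sub$tx)
    txex <- lapply(txex, function(d) {
      d <- d[order(d$start, d$end), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)])) {
        stop("overlapping exons within transcript '",
             sub$tx[1L], "' of gene '", g, "'")
      }
      as.matrix(d)
    })
    ## re-check per transcript with correct transcript name in message
    for (tx in names(txex)) {
      d <- txex[[tx]]
      if (nrow(d) > 1L && any(d[-1L, "start"] <= d[-nrow(d), "end"])) {
        stop("overlapping exons within transcript '", tx, "' of gene '", g, "'")
      }
    }
    out[[g]] <- GeneModel(g, sub$chrom[1L], sub$strand[1L], txex)
  }
  out
}

#' Write gene models back to GTF
#'
#' Emits one \code{exon} line per transcript exon, preserving 1-based closed
#' coordinates, so that \code{readGtf(writeGtf(x))} round-trips exon sets and
#' transcript structures.
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genes) {
    ex <- exons(g)
    for (tx in names(transcripts(g))) {
      idx <- transcripts(g)[[tx]]
      for (i in idx) {
        cat(sprintf(
          '%s\tspliceratio\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";\n',
          chrom(g), ex[i, "start"], ex[i, "end"], geneStrand(g), geneId(g), tx),
          file = con)
      }
    }
  }
  invisible(path)
}

## ---- splice graph ----------------------------------------------------------

#' @rdname buildSpliceGraph
setMethod("buildSpliceGraph", "GeneModel", function(gene) {
  ex <- exons(gene)
  edges <- list()
  for (tx in names(transcripts(gene))) {
    idx <- transcripts(gene)[[tx]]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      de <- ex[idx[k], "end"]
      as_ <- ex[idx[k + 1L], "start"]
      key <- paste(de, as_)
      if (is.null(edges[[key]])) {
        edges[[key]] <- list(donor_end = de, acceptor_start = as_,
                             transcripts = tx)
      } else {
        edges[[key]]$transcripts <- paste(edges[[key]]$transcripts, tx,
                                          sep = ",")
      }
    }
  }
  if (length(edges)) {
    ed <- data.frame(
      donor_end = vapply(edges, function(e) e$donor_end, 0L),
      acceptor_start = vapply(edges, function(e) e$acceptor_start, 0L),
      transcripts = vapply(edges, function(e) e$transcripts, ""),
      row.names = NULL, stringsAsFactors = FALSE
    )
    ed$intron_start <- ed$donor_end + 1L
    ed$intron_end <- ed$acceptor_start - 1L
    ed <- ed[order(ed$intron_start, ed$intron_end),
             c("donor_end", "acceptor_start", "intron_start", "intron_end",
               "transcripts")]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(donor_end = integer(), acceptor_start = integer(),
                     intron_start = integer(), intron_end = integer(),
                     transcripts = character(), stringsAsFactors = FALSE)
  }
  new("SpliceGraph", geneId = geneId(gene), chrom = chrom(gene),
      strand = geneStrand(gene), exons = ex, edges = ed)
})

#' Enumerate annotated splice junctions
#'
#' Collects every consecutive-exon junction of every transcript across a gene
#' collection, deduplicated by (chrom, intron_start, intron_end, strand).
#' Intron coordinates are the first and last intronic base (1-based).
#'
#' @param genes list of \linkS4class{GeneModel}.
#' @return data.frame with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand}.
#' @export
annotatedJunctions <- function(genes) {
  rows <- lapply(genes, function(g) {
    ed <- graphEdges(buildSpliceGraph(g))
    if (!nrow(ed)) return(NULL)
    data.frame(chrom = chrom(g), intron_start = ed$intron_start,
               intron_end = ed$intron_end, strand = geneStrand(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(out)
  out <- out[order(out$chrom, out$intron_start, out$intron_end, out$strand), ]
  rownames(out) <- NULL
  out
}
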