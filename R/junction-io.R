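## Splice-junction table and sample-manifest I/O.
##
## The canonical internal representation of a junction is a data.frame row
## (chrom, intron_start, intron_end, strand, unique_reads) with intron
## coordinates on the first/last intronic base, 1-based. Two on-disk dialects
## are read: the 9-column SJ tab emitted by spliced aligners, and BED12-style
## junction beds (block-structured, converted to intron coordinates here).
## Multimapped read counts are always discarded: only uniquely mapped reads
## carry splicing evidence downstream.

#' Read a splice-junction table
#'
#' @param path file path.
#' @param dialect \code{"sj_tab"}: 9 tab-separated columns (chrom, intron
#'   start, intron end, strand code 0/1/2, motif, annotated flag, unique
#'   reads, multimapped reads, overhang). \code{"bed_junc"}: BED12 junction
#'   bed where each record is an exon-pair block; converted so that
#'   intron_start = chromStart + blockSizes[1] + 1 (1-based) and
#'   intron_end = chromStart + blockStarts[2] (last intronic base).
#' @return data.frame with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end}, \code{strand} (\code{"+"}, \code{"-"} or
#'   \code{"unknown"}), \code{unique_reads}.
#' @export
readJunctions <- function(path, dialect = c("sj_tab", "bed_junc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character(),
                      unique_reads = integer(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (dialect == "sj_tab") {
    nf <- lengths(fields)
    if (any(nf != 9L)) {
      stop(sprintf("SJ tab line %d: expected 9 columns, found %d",
                   which(nf != 9L)[1L], nf[which(nf != 9L)[1L]]))
    }
    chromv <- vapply(fields, `[`, "", 1L)
    s <- as.integer(vapply(fields, `[`, "", 2L))
    e <- as.integer(vapply(fields, `[`, "", 3L))
    sc <- as.integer(vapply(fields, `[`, "", 4L))
    uniq <- as.integer(vapply(fields, `[`, "", 7L))
    if (anyNA(uniq) || any(uniq < 0L)) {
      stop(sprintf("SJ tab line %d: negative or non-numeric unique-read count",
                   which(is.na(uniq) | uniq < 0L)[1L]))
    }
    strand <- c("unknown", "+", "-")[sc + 1L]
    if (any(strand == "unknown")) {
      warning(sum(strand == "unknown"),
              " junction(s) with strand code 0 retained as strand 'unknown'")
    }
    out <- data.frame(chrom = chromv, intron_start = s, intron_end = e,
                      strand = strand, unique_reads = uniq,
                      stringsAsFactors = FALSE)
  } else {
    nf <- lengths(fields)
    if (any(nf < 12L)) {
      stop(sprintf("BED junction line %d: expected 12 columns",
                   which(nf < 12L)[1L]))
    }
    chromv <- vapply(fields, `[`, "", 1L)
    cs <- as.integer(vapply(fields, `[`, "", 2L))    # 0-based
    score <- as.integer(vapply(fields, `[`, "", 5L))
    strand <- vapply(fields, `[`, "", 6L)
    bsz <- lapply(strsplit(vapply(fields, `[`, "", 11L), ","), as.integer)
    bst <- lapply(strsplit(vapply(fields, `[`, "", 12L), ","), as.integer)
    if (any(vapply(bsz, length, 0L) < 2L)) {
      stop("BED junction record without two blocks cannot encode an intron")
    }
    if (anyNA(score) || any(score < 0L)) {
      stop("negative junction read count in BED junction file")
    }
    s <- cs + vapply(bsz, `[`, 0L, 1L) + 1L
    e <- cs + vapply(bst, `[`, 0L, 2L)
    strand[!strand %in% c("+", "-")] <- "unknown"
    out <- data.frame(chrom = chromv, intron_start = s, intron_end = e,
                      strand = strand, unique_reads = score,
                      stringsAsFactors = FALSE)
  }
  if (any(out$intron_start > out$intron_end)) {
    stop("junction with intron_start > intron_end")
  }
  rownames(out) <- NULL
  out
}

#' Load the sample manifest
#'
#' The manifest is a TSV with header columns \code{sample_id}, \code{group},
#' \code{junction_path} and optionally \code{total_fragments}. Junction paths
#' are resolved relative to the manifest's directory when not absolute and
#' must exist. Groups with a single sample are accepted here; the group
#' comparison stage enforces its own replicate minimum.
#'
#' @param path manifest file path.
#' @return data.frame (one row per sample) with validated paths.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "group", "junction_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         m$sample_id[duplicated(m$sample_id)][1L])
  }
  base <- dirname(normalizePath(path))
  resolved <- ifelse(
    m$junction_path == "" | is.na(m$junction_path), NA_character_,
    ifelse(grepl("^(/|[A-Za-z]:)", m$junction_path), m$junction_path,
           file.path(base, m$junction_path)))
  missing <- is.na(resolved) | !file.exists(resolved)
  if (any(missing)) {
    stop("junction file missing for sample '", m$sample_id[missing][1L], "'")
  }
  m$junction_path <- resolved
  if (is.null(m$total_fragments)) m$total_fragments <- NA_integer_
  rownames(m) <- NULL
  m
}

#' Flag junctions as known or novel against an annotation
#'
#' A junction is known iff (chrom, intron_start, intron_end) matches an
#' annotated junction; the strand must also match unless the junction strand
#' is \code{"unknown"}, in which case coordinates alone decide.
#'
#' @param junctions junction data.frame (see \code{\link{readJunctions}}).
#' @param annotated annotated-junction data.frame from
#'   \code{\link{annotatedJunctions}}.
#' @return \code{junctions} with an added character column \code{status}
#'   (\code{"known"} or \code{"novel"}).
#' @export
flagKnownNovel <- function(junctions, annotated) {
  if (!nrow(junctions)) {
    junctions$status <- character()
    return(junctions)
  }
  keyStrand <- paste(annotated$chrom, annotated$intron_start,
                     annotated$intron_end, annotated$strand)
  keyCoord <- paste(annotated$chrom, annotated$intron_start,
                    annotated$intron_end)
  jStrand <- paste(junctions$chrom, junctions$intron_start,
                   junctions$intron_end, junctions$strand)
  jCoord <- paste(junctions$chrom, junctions$intron_start,
                  junctions$intron_end)
  known <- ifelse(junctions$strand == "unknown",
                  jCoord %in% keyCoord,
                  jStrand %in% keyStrand)
  junctions$status <- ifelse(known, "known", "novel")
  junctions
}
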