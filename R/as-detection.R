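## Detection and classification of alternative splicing events from observed
## splice junctions against a gene's splice graph.
##
## Operational definitions (the ten canonical types):
##   ES      one junction bridging a donor to an acceptor while an annotated
##           inclusion path through exactly one annotated exon exists.
##   CE      as ES but skipping a chain of >= 2 consecutive annotated exons
##           (the cassette unit).
##   A5SS/A3SS  two junctions sharing exactly one boundary; the differing
##           boundary shifts the 5' (donor) or 3' (acceptor) splice site.
##           Labels are assigned in transcript orientation: on the minus
##           strand the donor is the numerically larger coordinate side.
##   A5SS&ES / A3SS&ES  an alt-site pair whose longer junction additionally
##           spans >= 1 complete annotated exon that the shorter path retains,
##           excluding pure skip decompositions (a skip junction paired with
##           one of its own annotated inclusion junctions is already an ES/CE
##           event, not a combined alt-site event).
##   MXE     exon pair (B1, B2) with junctions flank->B1, B1->flank',
##           flank->B2, B2->flank' present (observed or annotated) and no
##           B1->B2 junction anywhere.
##   5pMXE / 3pMXE  mutually exclusive transcript-initial (alternative first
##           exon) or transcript-terminal (alternative last exon) exons: no
##           annotated junction enters (initial) or leaves (terminal) either
##           exon; the pair shares the single flanking junction target and has
##           no junction between its members.
##   IR      an annotated junction whose intron shows body read evidence;
##           the alternative form is the retained intron itself (no junction),
##           the model form is the spliced junction.
##
## Structural MXE detection runs before pairwise alt-site classification and
## its junction pairs are excluded from the alt-site pass; likewise skip
## decompositions. This keeps the ten definitions disjoint so that a fixture
## with one planted instance per type yields exactly ten events.

jkey <- function(s, e) paste0(s, "-", e)

junctionString <- function(s, e) paste(jkey(s, e), collapse = ";")

#' Split a junction-set string back into coordinates
#'
#' @param x junction string as stored in event tables
#'   (\code{"start-end;start-end"}; \code{""} for none).
#' @return integer matrix with columns \code{intron_start}, \code{intron_end}.
#' @export
parseJunctionString <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("intron_start", "intron_end"))))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.integer))
  colnames(m) <- c("intron_start", "intron_end")
  m
}

## pooled junction context for one gene: observed + annotated introns
.gene_junction_context <- function(graph, junctions) {
  ed <- graphEdges(graph)
  ex <- exons(graph)
  span <- c(min(ex[, "start"]), max(ex[, "end"]))
  obs <- junctions[junctions$chrom == chrom(graph) &
                   junctions$unique_reads > 0 &
                   (junctions$strand == geneStrand(graph) |
                    junctions$strand == "unknown") &
                   junctions$intron_start >= span[1L] &
                   junctions$intron_end <= span[2L], , drop = FALSE]
  akeys <- jkey(ed$intron_start, ed$intron_end)
  okeys <- jkey(obs$intron_start, obs$intron_end)
  all <- unique(rbind(
    data.frame(s = ed$intron_start, e = ed$intron_end),
    data.frame(s = obs$intron_start, e = obs$intron_end)))
  all <- all[order(all$s, all$e), , drop = FALSE]
  list(exons = ex, A = akeys, All = jkey(all$s, all$e), allJ = all,
       strand = geneStrand(graph))
}

## annotated inclusion chain inside skip junction (s, e): first chain of
## annotated exons fully inside [s, e] connected by annotated junctions from
## donor s to acceptor e; deterministic coordinate order
.find_inclusion_chain <- function(ctx, s, e) {
  ex <- ctx$exons
  inside <- which(ex[, "start"] >= s & ex[, "end"] <= e)
  if (!length(inside)) return(NULL)
  inside <- inside[order(ex[inside, "start"], ex[inside, "end"])]
  starts <- inside[jkey(s, ex[inside, "start"] - 1L) %in% ctx$A &
                   ex[inside, "start"] > s]
  dfs <- function(path) {
    b <- path[length(path)]
    if (jkey(ex[b, "end"] + 1L, e) %in% ctx$A) return(path)
    nxt <- inside[ex[inside, "start"] > ex[b, "end"] + 1L &
                  jkey(ex[b, "end"] + 1L, ex[inside, "start"] - 1L) %in% ctx$A]
    for (b2 in nxt) {
      res <- dfs(c(path, b2))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  for (b in starts) {
    res <- dfs(b)
    if (!is.null(res)) return(res)
  }
  NULL
}

## ES/CE events; also returns the skip-decomposition pairs to exclude later
.detect_skips <- function(ctx) {
  events <- list()
  decomp <- character()
  ex <- ctx$exons
  for (i in seq_len(nrow(ctx$allJ))) {
    s <- ctx$allJ$s[i]; e <- ctx$allJ$e[i]
    if (!any(ex[, "end"] == s - 1L) || !any(ex[, "start"] == e + 1L)) next
    chain <- .find_inclusion_chain(ctx, s, e)
    if (is.null(chain)) next
    mS <- c(s, ex[chain, "end"] + 1L)
    mE <- c(ex[chain, "start"] - 1L, e)
    events[[length(events) + 1L]] <- list(
      type = if (length(chain) == 1L) "ES" else "CE",
      alt = c(ex[chain[1L], "start"], ex[chain[length(chain)], "end"]),
      as_j = jkey(s, e), m_j = jkey(mS, mE))
    decomp <- c(decomp, paste(jkey(s, e), jkey(mS, mE)))
  }
  list(events = events, decomp = decomp)
}

## mutually exclusive exon family; returns events + consumed alt-site pairs
.detect_mxe <- function(ctx) {
  ex <- ctx$exons
  allJ <- ctx$allJ
  entersA <- function(b) any(jkey(allJ$s[allJ$e == ex[b, "start"] - 1L],
                                  ex[b, "start"] - 1L) %in% ctx$A)
  leavesA <- function(b) any(jkey(ex[b, "end"] + 1L,
                                  allJ$e[allJ$s == ex[b, "end"] + 1L]) %in% ctx$A)
  entersAll <- function(b) allJ$s[allJ$e == ex[b, "start"] - 1L]
  leavesAll <- function(b) allJ$e[allJ$s == ex[b, "end"] + 1L]
  events <- list()
  consumed <- character()
  n <- nrow(ex)
  if (n < 2L) return(list(events = events, consumed = consumed))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (ex[j, "start"] <= ex[i, "end"]) next   # overlapping versions
      between <- jkey(ex[i, "end"] + 1L, ex[j, "start"] - 1L) %in% ctx$All
      if (between) next
      eIn1 <- entersA(i); eIn2 <- entersA(j)
      lv1 <- leavesA(i); lv2 <- leavesA(j)
      commonA <- intersect(leavesAll(i), leavesAll(j))
      commonD <- intersect(entersAll(i), entersAll(j))
      alt <- c(ex[i, "start"], ex[j, "end"])
      if (!eIn1 && !eIn2 && length(commonA)) {
        a <- min(commonA)
        events[[length(events) + 1L]] <- list(
          type = if (ctx$strand == "+") "5pMXE" else "3pMXE", alt = alt,
          as_j = jkey(ex[j, "end"] + 1L, a), m_j = jkey(ex[i, "end"] + 1L, a))
        consumed <- c(consumed, paste(jkey(ex[i, "end"] + 1L, a),
                                      jkey(ex[j, "end"] + 1L, a)))
      } else if (!lv1 && !lv2 && length(commonD)) {
        d <- min(commonD)
        events[[length(events) + 1L]] <- list(
          type = if (ctx$strand == "+") "3pMXE" else "5pMXE", alt = alt,
          as_j = jkey(d, ex[j, "start"] - 1L), m_j = jkey(d, ex[i, "start"] - 1L))
        consumed <- c(consumed, paste(jkey(d, ex[i, "start"] - 1L),
                                      jkey(d, ex[j, "start"] - 1L)))
      } else if (length(commonD) && length(commonA)) {
        d <- min(commonD); a <- min(commonA)
        events[[length(events) + 1L]] <- list(
          type = "MXE", alt = alt,
          as_j = c(jkey(d, ex[j, "start"] - 1L), jkey(ex[j, "end"] + 1L, a)),
          m_j = c(jkey(d, ex[i, "start"] - 1L), jkey(ex[i, "end"] + 1L, a)))
        consumed <- c(consumed,
                      paste(jkey(d, ex[i, "start"] - 1L),
                            jkey(d, ex[j, "start"] - 1L)),
                      paste(jkey(ex[i, "end"] + 1L, a),
                            jkey(ex[j, "end"] + 1L, a)))
      }
    }
  }
  list(events = events, consumed = consumed)
}

## pairwise alternative splice-site classification
.detect_alt_sites <- function(ctx, excluded) {
  allJ <- ctx$allJ
  ex <- ctx$exons
  events <- list()
  n <- nrow(allJ)
  if (n < 2L) return(events)
  pickForms <- function(k1, k2) {
    ## model form: the annotated junction when exactly one is annotated,
    ## otherwise the shorter intron (the more-inclusive form)
    a1 <- k1 %in% ctx$A; a2 <- k2 %in% ctx$A
    len <- function(k) { m <- parseJunctionString(k); m[1, 2] - m[1, 1] }
    if (a1 != a2) {
      if (a1) list(m = k1, as = k2) else list(m = k2, as = k1)
    } else if (len(k1) <= len(k2)) list(m = k1, as = k2) else list(m = k2, as = k1)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      s1 <- allJ$s[i]; e1 <- allJ$e[i]; s2 <- allJ$s[j]; e2 <- allJ$e[j]
      shareS <- s1 == s2; shareE <- e1 == e2
      if (shareS == shareE) next            # both or neither boundary shared
      k1 <- jkey(s1, e1); k2 <- jkey(s2, e2)
      pairKey <- c(paste(k1, k2), paste(k2, k1))
      if (any(pairKey %in% excluded)) next
      if (shareE) {                          # differing intron starts
        d1 <- min(s1, s2); d2 <- max(s1, s2)
        region <- c(d1, d2 - 1L)
        base <- if (ctx$strand == "+") "A5SS" else "A3SS"
      } else {                               # differing intron ends
        lo <- min(e1, e2); hi <- max(e1, e2)
        region <- c(lo + 1L, hi)
        base <- if (ctx$strand == "+") "A3SS" else "A5SS"
      }
      insideR <- any(ex[, "start"] >= region[1L] & ex[, "end"] <= region[2L])
      type <- if (insideR) paste0(base, "&ES") else base
      forms <- pickForms(k1, k2)
      events[[length(events) + 1L]] <- list(type = type, alt = region,
                                            as_j = forms$as, m_j = forms$m)
    }
  }
  events
}

.event_rows <- function(graph, evlist) {
  if (!length(evlist)) {
    return(data.frame(event_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      type = character(), alt_start = integer(),
                      alt_end = integer(), as_junctions = character(),
                      m_junctions = character(), known = logical(),
                      stringsAsFactors = FALSE))
  }
  akeys <- jkey(graphEdges(graph)$intron_start, graphEdges(graph)$intron_end)
  df <- do.call(rbind, lapply(evlist, function(ev) {
    jall <- c(ev$as_j, ev$m_j)
    data.frame(gene_id = geneId(graph), chrom = chrom(graph),
               strand = geneStrand(graph), type = ev$type,
               alt_start = ev$alt[1L], alt_end = ev$alt[2L],
               as_junctions = paste(ev$as_j, collapse = ";"),
               m_junctions = paste(ev$m_j, collapse = ";"),
               known = all(jall %in% akeys),
               stringsAsFactors = FALSE)
  }))
  df <- unique(df)
  df <- df[order(df$type, df$alt_start, df$alt_end,
                 df$as_junctions, df$m_junctions), , drop = FALSE]
  df$event_id <- sprintf("%s|%s|%s:%d-%d", df$gene_id, df$type, df$chrom,
                         df$alt_start, df$alt_end)
  dup <- ave(seq_len(nrow(df)), df$event_id, FUN = seq_along)
  df$event_id[dup > 1L] <- paste0(df$event_id[dup > 1L], "#", dup[dup > 1L])
  rownames(df) <- NULL
  df[, c("event_id", "gene_id", "chrom", "strand", "type", "alt_start",
         "alt_end", "as_junctions", "m_junctions", "known")]
}

#' Detect alternative splicing events for one gene
#'
#' Classifies observed junctions (pooled across samples) against the gene's
#' splice graph into the ten canonical event types. Junctions are first
#' restricted to the gene: chromosome match, intron within the gene span, and
#' strand equal to the gene strand or \code{"unknown"}. Intron retention is
#' detected only when an intron body-count table is supplied.
#'
#' @param graph a \linkS4class{SpliceGraph}.
#' @param junctions pooled junction data.frame (\code{\link{readJunctions}}
#'   format); only rows with \code{unique_reads > 0} count as observed.
#' @param intronCounts optional intron body-count table: data.frame with
#'   columns \code{chrom}, \code{intron_start}, \code{intron_end} plus one or
#'   more per-sample numeric count columns.
#' @return event data.frame: \code{event_id}, \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{type}, \code{alt_start}, \code{alt_end},
#'   \code{as_junctions}, \code{m_junctions} (\code{"start-end"} lists,
#'   \code{;}-separated), \code{known} (TRUE iff every junction of both forms
#'   is annotated).
#' @export
detectEvents <- function(graph, junctions, intronCounts = NULL) {
  ctx <- .gene_junction_context(graph, junctions)
  skips <- .detect_skips(ctx)
  mxe <- .detect_mxe(ctx)
  alt <- .detect_alt_sites(ctx, excluded = c(skips$decomp, mxe$consumed))
  evlist <- c(skips$events, mxe$events, alt)
  ev <- .event_rows(graph, evlist)
  if (!is.null(intronCounts)) {
    ev <- rbind(ev, detectIntronRetention(graph, intronCounts))
    rownames(ev) <- NULL
  }
  ev
}

#' Detect intron retention events
#'
#' Emits one IR event per annotated junction whose intron has body-read
#' evidence (count > 0 in at least one sample column). The alternative form is
#' the retained intron (quantified from body counts, no junction); the model
#' form is the spliced junction.
#'
#' @param graph a \linkS4class{SpliceGraph}.
#' @param intronCounts intron body-count table (see
#'   \code{\link{detectEvents}}); required.
#' @return event data.frame in the \code{\link{detectEvents}} layout with
#'   \code{as_junctions = ""}.
#' @export
detectIntronRetention <- function(graph, intronCounts) {
  if (is.null(intronCounts)) {
    stop("intron retention requested without body counts; ",
         "supply the intron body-count table (chrom, intron_start, ",
         "intron_end, per-sample counts)")
  }
  ed <- graphEdges(graph)
  evlist <- list()
  if (nrow(ed) && nrow(intronCounts)) {
    cntCols <- setdiff(names(intronCounts),
                       c("chrom", "intron_start", "intron_end"))
    for (i in seq_len(nrow(ed))) {
      hit <- intronCounts$chrom == chrom(graph) &
        intronCounts$intron_start == ed$intron_start[i] &
        intronCounts$intron_end == ed$intron_end[i]
      if (!any(hit)) next
      counts <- unlist(intronCounts[hit, cntCols, drop = FALSE])
      if (any(counts > 0)) {
        evlist[[length(evlist) + 1L]] <- list(
          type = "IR", alt = c(ed$intron_start[i], ed$intron_end[i]),
          as_j = character(),
          m_j = jkey(ed$intron_start[i], ed$intron_end[i]))
      }
    }
  }
  .event_rows(graph, evlist)
}

#' Classify a pair of junctions sharing one boundary
#'
#' Standalone alternative-splice-site classifier: shared acceptor with
#' differing donors is the A5SS family, shared donor with differing acceptors
#' the A3SS family (labels strand-aware), with the \code{&ES} variant when the
#' longer junction spans at least one complete annotated exon retained by the
#' shorter path. Pure skip decompositions (the longer junction has an
#' annotated inclusion path that includes the shorter junction) and pairs
#' sharing both or neither boundary return \code{"none"}.
#'
#' @param j1,j2 single-row junction data.frames or lists with
#'   \code{intron_start}, \code{intron_end}.
#' @param graph the gene's \linkS4class{SpliceGraph}.
#' @return one of \code{"A5SS"}, \code{"A3SS"}, \code{"A5SS&ES"},
#'   \code{"A3SS&ES"}, \code{"none"}.
#' @export
classifyAltSitePair <- function(j1, j2, graph) {
  s1 <- j1$intron_start; e1 <- j1$intron_end
  s2 <- j2$intron_start; e2 <- j2$intron_end
  if ((s1 == s2) == (e1 == e2)) return("none")
  ed <- graphEdges(graph)
  ctx <- list(exons = exons(graph),
              A = jkey(ed$intron_start, ed$intron_end),
              All = unique(c(jkey(ed$intron_start, ed$intron_end),
                             jkey(c(s1, s2), c(e1, e2)))),
              allJ = unique(data.frame(s = c(ed$intron_start, s1, s2),
                                       e = c(ed$intron_end, e1, e2))),
              strand = geneStrand(graph))
  skips <- .detect_skips(ctx)
  res <- .detect_alt_sites(
    list(exons = ctx$exons, A = ctx$A, All = ctx$All,
         allJ = data.frame(s = c(s1, s2), e = c(e1, e2)),
         strand = ctx$strand),
    excluded = skips$decomp)
  if (!length(res)) "none" else res[[1L]]$type
}

#' Detect events across a gene collection
#'
#' Assigns pooled junctions to genes by coordinate containment within each
#' gene span (chromosome and strand compatible) and runs
#' \code{\link{detectEvents}} per gene.
#'
#' @param genes list of \linkS4class{GeneModel} or \linkS4class{SpliceGraph}.
#' @param junctions pooled junction data.frame.
#' @param intronCounts optional intron body-count table.
#' @return combined event data.frame.
#' @export
detectAllEvents <- function(genes, junctions, intronCounts = NULL) {
  out <- lapply(genes, function(g) {
    graph <- if (is(g, "SpliceGraph")) g else buildSpliceGraph(g)
    detectEvents(graph, junctions, intronCounts)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
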