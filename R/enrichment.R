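## Hypergeometric gene-set enrichment and set-overlap testing. Gene sets are
## user-supplied GMT files; p-values are upper-tail hypergeometric
## (P(X >= overlap)) via stats::phyper, corrected across sets with BH.

#' Read a GMT gene-set file
#'
#' Each line is \code{set_id <TAB> description <TAB> gene1 <TAB> gene2 ...}.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set id -> member genes); the
#'   description is kept in a \code{"description"} attribute per set.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d: expected at least 3 tab-separated fields", i))
    }
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d: empty gene set", i))
    attr(genes, "description") <- f[2L]
    out[[f[1L]]] <- genes
  }
  out
}

.hyper_upper <- function(overlap, setSize, querySize, universeSize) {
  ## P(X >= overlap) with X ~ Hypergeom(N = universe, K = set, n = query)
  stats::phyper(overlap - 1L, setSize, universeSize - setSize, querySize,
                lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests a query gene list against each set in a collection over a gene
#' universe. Query genes outside the universe are dropped (a message reports
#' how many); set members are restricted to the universe. The per-set p-value
#' is the upper-tail hypergeometric probability of the observed overlap or
#' more; BH correction runs across all tested sets and a set is flagged
#' enriched when the corrected p falls below \code{alpha}.
#'
#' @param query character vector of gene ids.
#' @param sets named list of gene sets (e.g. from \code{\link{readGmt}}).
#' @param universe character vector defining the gene universe.
#' @param alpha enrichment cutoff on corrected p (default 0.05).
#' @return data.frame: \code{set_id}, \code{overlap_count}, \code{set_size},
#'   \code{query_size}, \code{universe_size}, \code{p}, \code{corrected_p},
#'   \code{enriched}.
#' @export
hypergeomEnrich <- function(query, sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  query <- unique(query)
  dropped <- sum(!query %in% universe)
  if (dropped > 0) {
    message(dropped, " query gene(s) outside the universe dropped")
  }
  query <- intersect(query, universe)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(sets[[id]]), universe)
    if (!length(members)) return(NULL)
    ov <- length(intersect(members, query))
    data.frame(set_id = id, overlap_count = ov, set_size = length(members),
               query_size = length(query), universe_size = length(universe),
               p = .hyper_upper(ov, length(members), length(query),
                                length(universe)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(set_id = character(), overlap_count = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      corrected_p = numeric(), enriched = logical()))
  }
  res$corrected_p <- bhFdr(res$p)
  res$enriched <- res$corrected_p < alpha
  rownames(res) <- NULL
  res
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail hypergeometric test of |A intersect B| drawing |B| genes from a
#' universe containing |A| marked genes; symmetric in A and B.
#'
#' @param setA,setB character vectors of gene ids (subsets of the universe).
#' @param universe gene universe.
#' @return list with \code{overlap_count} and \code{p}.
#' @export
overlapTest <- function(setA, setB, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty gene universe")
  setA <- intersect(unique(setA), universe)
  setB <- intersect(unique(setB), universe)
  if (!length(setA) || !length(setB)) {
    warning("empty gene set in overlap test; p = 1")
    return(list(overlap_count = 0L, p = 1))
  }
  ov <- length(intersect(setA, setB))
  list(overlap_count = ov,
       p = .hyper_upper(ov, length(setA), length(setB), length(universe)))
}
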