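## Coexpression screening and splicing-factor / event correlation networks.
##
## Expression enters correlations as log2(CPM + 1) (variance stabilisation);
## event AS ratios enter raw (already bounded in [0, 1]). The coexpression
## stage keeps positive correlations only; the SF-event stage thresholds |r|.

#' Pearson (or Spearman) correlation with p-value
#'
#' Two-sided p from the t-distribution transform
#' \code{t = r * sqrt((n - 2) / (1 - r^2))}, delegated to
#' \code{stats::cor.test}. Zero variance in either vector makes the
#' correlation undefined: (NA, NA) is returned.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return list with \code{r} and \code{p}.
#' @export
pearsonWithP <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ht$estimate), p = ht$p.value)
}

#' Screen for genes coexpressed with an anchor gene
#'
#' Correlates every gene's log2(CPM + 1) profile with the anchor's across
#' samples and keeps positively correlated genes with \code{r >= rMin} and
#' \code{p < alpha}. The anchor itself is excluded; zero-variance genes are
#' untested.
#'
#' @param se expression container from \code{\link{makeExpressionMatrix}}.
#' @param anchor gene id present in \code{se}.
#' @param rMin correlation threshold (default 0.6).
#' @param alpha p-value threshold (default 0.05).
#' @param method correlation flavour, see \code{\link{pearsonWithP}}.
#' @return data.frame: \code{gene_id}, \code{r}, \code{p}, sorted by
#'   decreasing r.
#' @export
coexpressedGenes <- function(se, anchor, rMin = 0.6, alpha = 0.05,
                             method = "pearson") {
  lc <- log2(cpm(se) + 1)
  if (!anchor %in% rownames(lc)) stop("anchor gene '", anchor, "' not found")
  if (ncol(lc) < 3L) stop("need at least 3 samples")
  av <- lc[anchor, ]
  rows <- lapply(setdiff(rownames(lc), anchor), function(g) {
    if (stats::sd(lc[g, ]) == 0 || stats::sd(av) == 0) return(NULL)
    ct <- pearsonWithP(av, lc[g, ], method = method)
    if (!is.na(ct$r) && ct$r >= rMin && ct$p < alpha) {
      data.frame(gene_id = g, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
    } else NULL
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(gene_id = character(), r = numeric(), p = numeric()))
  }
  res <- res[order(-res$r, res$gene_id), ]
  rownames(res) <- NULL
  res
}

#' Splicing-factor / event correlation network
#'
#' Correlates each splicing factor's log2(CPM + 1) expression with each
#' event's AS ratio across the shared samples and keeps edges with
#' \code{|r| > rMin} and \code{p < alpha}. Samples with an undefined ratio
#' are dropped pairwise; events with fewer than 3 defined ratios (or zero
#' variance) are untested.
#'
#' @param se expression container holding the splicing-factor genes.
#' @param sfGenes character vector of splicing-factor gene ids.
#' @param ratios events x samples numeric matrix of AS ratios (NA allowed).
#' @param rMin correlation threshold on |r| (default 0.7).
#' @param alpha p-value threshold (default 0.01).
#' @param method correlation flavour.
#' @return edge data.frame: \code{sf}, \code{event_id}, \code{r}, \code{p}.
#' @export
sfAseNetwork <- function(se, sfGenes, ratios, rMin = 0.7, alpha = 0.01,
                         method = "pearson") {
  sfGenes <- intersect(sfGenes, rownames(se))
  if (!length(sfGenes)) stop("none of the splicing-factor genes are present")
  shared <- intersect(colnames(se), colnames(ratios))
  if (!length(shared)) stop("no shared samples between expression and ratios")
  lc <- log2(cpm(se)[sfGenes, shared, drop = FALSE] + 1)
  ratios <- ratios[, shared, drop = FALSE]
  rows <- list()
  for (sf in sfGenes) {
    for (ev in rownames(ratios)) {
      ok <- !is.na(ratios[ev, ])
      if (sum(ok) < 3L) next
      x <- lc[sf, ok]; y <- ratios[ev, ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- pearsonWithP(x, y, method = method)
      if (!is.na(ct$r) && abs(ct$r) > rMin && ct$p < alpha) {
        rows[[length(rows) + 1L]] <- data.frame(
          sf = sf, event_id = ev, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(sf = character(), event_id = character(),
                      r = numeric(), p = numeric()))
  }
  rownames(res) <- NULL
  res
}

#' Rank hub splicing factors by connection count
#'
#' Ranks splicing factors by their number of distinct connected events and
#' returns the top k; ties are broken lexicographically by splicing-factor id
#' so the ranking is deterministic.
#'
#' @param edges edge data.frame from \code{\link{sfAseNetwork}}.
#' @param k number of hubs to return (default 10); when larger than the
#'   number of factors, all are returned.
#' @return data.frame: \code{sf}, \code{degree}, \code{rank}.
#' @export
hubFactors <- function(edges, k = 10) {
  if (!nrow(edges)) stop("edge list is empty")
  deg <- tapply(edges$event_id, edges$sf, function(x) length(unique(x)))
  res <- data.frame(sf = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$degree, res$sf), ]
  res <- utils::head(res, k)
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
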