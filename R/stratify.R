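## Expression-based sample stratification: top-k / bottom-k by anchor-gene
## CPM, and parsing of external grouping tables (the shipped gastric-cancer
## cohort fixture uses the four-column layout: tumor type, sample, group
## description, anchor CPM).

#' Stratify samples by anchor-gene expression
#'
#' The k samples with the highest anchor CPM form the \code{high} group, the
#' k lowest the \code{low} group, the rest are \code{excluded} (written out
#' explicitly so downstream stages cannot silently include them). Ties at a
#' group boundary are broken lexicographically by sample id with a warning;
#' all-equal expression is an error because the stratification would be
#' meaningless.
#'
#' @param expr named numeric vector: per-sample anchor-gene CPM.
#' @param k group size (default 25).
#' @return data.frame: \code{sample_id}, \code{group} (\code{high},
#'   \code{low} or \code{excluded}), \code{anchor_cpm}.
#' @export
stratifyByExpression <- function(expr, k = 25) {
  if (k < 1L) stop("k must be >= 1")
  n <- length(expr)
  if (2L * k > n) {
    stop("2k = ", 2L * k, " exceeds the number of samples (", n, ")")
  }
  if (is.null(names(expr)) || anyDuplicated(names(expr))) {
    stop("expr must be named with unique sample ids")
  }
  if (length(unique(expr)) == 1L) {
    stop("all samples have identical anchor expression; ",
         "stratification is meaningless")
  }
  ord <- order(expr, names(expr))          # ascending; id breaks ties
  sorted <- expr[ord]
  lowCut <- sorted[k]; highCut <- sorted[n - k + 1L]
  if (sum(expr == lowCut) > sum(sorted[seq_len(k)] == lowCut) ||
      sum(expr == highCut) > sum(sorted[seq(n - k + 1L, n)] == highCut)) {
    warning("tied anchor expression at a group boundary; ",
            "ties broken by sample id")
  }
  group <- rep("excluded", n)
  group[seq_len(k)] <- "low"
  group[seq(n - k + 1L, n)] <- "high"
  res <- data.frame(sample_id = names(sorted), group = group,
                    anchor_cpm = unname(sorted), stringsAsFactors = FALSE)
  if (min(res$anchor_cpm[res$group == "high"]) <=
      max(res$anchor_cpm[res$group == "low"])) {
    warning("high/low groups are not separated by expression ",
            "(boundary ties present)")
  }
  res <- res[order(res$sample_id), ]
  rownames(res) <- NULL
  res
}

#' Parse an external sample-grouping table
#'
#' Reads a TSV with columns tumor type, sample, group description and anchor
#' CPM (in that order; header names are not interpreted beyond position).
#' Group descriptions containing \code{high}/\code{low} (case-insensitive)
#' map to the \code{high}/\code{low} groups.
#'
#' @param path grouping TSV path.
#' @return data.frame: \code{sample_id}, \code{group}, \code{anchor_cpm},
#'   \code{tumor_type}.
#' @export
readGroupTable <- function(path) {
  if (!file.exists(path)) stop("grouping table not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(tb)) stop("grouping table is empty")
  if (ncol(tb) < 4L) stop("grouping table must have 4 columns")
  sample_id <- as.character(tb[[2L]])
  desc <- as.character(tb[[3L]])
  cpmv <- as.numeric(tb[[4L]])
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id in grouping table: ",
         sample_id[duplicated(sample_id)][1L])
  }
  group <- ifelse(grepl("high", desc, ignore.case = TRUE), "high",
                  ifelse(grepl("low", desc, ignore.case = TRUE), "low", NA))
  if (anyNA(group)) {
    stop("unknown group label: ", desc[which(is.na(group))[1L]])
  }
  data.frame(sample_id = sample_id, group = group, anchor_cpm = cpmv,
             tumor_type = as.character(tb[[1L]]), stringsAsFactors = FALSE)
}
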