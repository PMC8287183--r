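## Expression container, normalisation, stand-in DEG calling and qPCR
## quantification.
##
## The container is a SummarizedExperiment: assay "counts", rowData column
## gene_length (exon-union length in bp, needed for FPKM only) and colData
## column total_fragments (library size). The differential caller is an
## explicit stand-in for a count-model package: CPM normalisation, group-mean
## fold change with pseudocount 1, Welch t-test on log2(CPM + 1), BH FDR.
## It is tuned to recover planted effects in simulation, not to reproduce a
## negative-binomial GLM.

#' Build the expression container
#'
#' @param counts genes x samples matrix of non-negative counts with row and
#'   column names.
#' @param geneLengths optional named numeric vector of per-gene exon-union
#'   lengths (bp); required later for FPKM.
#' @param totalFragments optional named numeric vector of per-sample total
#'   mapped fragments; defaults to column sums of \code{counts}.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment}.
#' @export
makeExpressionMatrix <- function(counts, geneLengths = NULL,
                                 totalFragments = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(totalFragments)) totalFragments <- colSums(counts)
  totalFragments <- totalFragments[colnames(counts)]
  if (anyNA(totalFragments) || any(totalFragments <= 0)) {
    bad <- colnames(counts)[which(is.na(totalFragments) |
                                  totalFragments <= 0)[1L]]
    stop("non-positive total fragment count for sample '", bad, "'")
  }
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(geneLengths)) {
    gl <- geneLengths[rownames(counts)]
    if (any(!is.na(gl) & gl <= 0)) stop("gene lengths must be positive")
    rd$gene_length <- unname(gl)
  } else {
    rd$gene_length <- NA_real_
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = rd,
    colData = S4Vectors::DataFrame(total_fragments = unname(totalFragments),
                                   row.names = colnames(counts)))
}

.counts <- function(se) SummarizedExperiment::assay(se, "counts")
.totals <- function(se) SummarizedExperiment::colData(se)$total_fragments

#' FPKM normalisation
#'
#' \code{fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])}: fragments
#' per kilobase of exon per million mapped fragments.
#'
#' @param se expression container from \code{\link{makeExpressionMatrix}}.
#' @return numeric matrix of FPKM values.
#' @export
fpkm <- function(se) {
  len <- SummarizedExperiment::rowData(se)$gene_length
  if (anyNA(len)) {
    stop("missing gene length for gene '",
         rownames(se)[which(is.na(len))[1L]], "'")
  }
  cts <- .counts(se)
  sweep(cts / len, 2L, .totals(se), "/") * 1e9
}

#' CPM normalisation
#'
#' \code{cpm[g, s] = counts[g, s] * 1e6 / total[s]}.
#'
#' @param se expression container from \code{\link{makeExpressionMatrix}}.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(se) {
  sweep(.counts(se), 2L, .totals(se), "/") * 1e6
}

#' Stand-in differential expression caller
#'
#' Fold change is computed on group-mean CPM with pseudocount 1
#' (\code{log2FC = log2((meanA + 1) / (meanB + 1))}); the p-value is a
#' two-sided Welch t-test on log2(CPM + 1); FDR is Benjamini-Hochberg over
#' all tested genes. Status is \code{up} when the fold change is at least
#' \code{upFc} and the significance criterion holds (\code{fdr < alpha} when
#' \code{useFdr}, else raw \code{p < alpha}); \code{down} symmetric with
#' \code{downFc}. The two threshold presets used in practice are
#' (1.5, 0.67, FDR < 0.05) and (2, 0.5, p < 0.01).
#'
#' @param se expression container.
#' @param manifest data.frame with \code{sample_id}, \code{group}.
#' @param groupA,groupB group labels (fold change is A over B).
#' @param upFc,downFc fold-change thresholds (defaults 1.5 and 1/1.5).
#' @param alpha significance level (default 0.05).
#' @param useFdr apply \code{alpha} to the BH FDR (default TRUE) instead of
#'   the raw p-value.
#' @return data.frame: \code{gene_id}, \code{log2_fold_change},
#'   \code{p_value}, \code{fdr}, \code{status}.
#' @export
callDegs <- function(se, manifest, groupA, groupB,
                     upFc = 1.5, downFc = 1 / 1.5, alpha = 0.05,
                     useFdr = TRUE) {
  sampA <- manifest$sample_id[manifest$group == groupA]
  sampB <- manifest$sample_id[manifest$group == groupB]
  if (length(sampA) < 2L || length(sampB) < 2L) {
    stop("each group needs at least 2 samples")
  }
  if (!all(c(sampA, sampB) %in% colnames(se))) {
    stop("manifest samples missing from the expression matrix")
  }
  cm <- cpm(se)
  la <- log2(cm[, sampA, drop = FALSE] + 1)
  lb <- log2(cm[, sampB, drop = FALSE] + 1)
  fc <- (rowMeans(cm[, sampA, drop = FALSE]) + 1) /
        (rowMeans(cm[, sampB, drop = FALSE]) + 1)
  p <- vapply(seq_len(nrow(cm)), function(i) {
    x <- la[i, ]; y <- lb[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 2e-308)
    }
    stats::t.test(x, y)$p.value
  }, 0)
  fdr <- bhFdr(p)
  sig <- if (useFdr) fdr < alpha else p < alpha
  status <- ifelse(sig & fc >= upFc, "up",
                   ifelse(sig & fc <= downFc, "down", "ns"))
  data.frame(gene_id = rownames(cm), log2_fold_change = log2(fc),
             p_value = p, fdr = fdr, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (monotone, capped at 1), delegated to
#' \code{stats::p.adjust(method = "BH")} after range validation.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return adjusted values, same order as the input.
#' @export
bhFdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Relative qPCR quantification (2^-ddCT)
#'
#' \code{fold = 2^-((CT_target,case - CT_ref,case) -
#' (CT_target,ctrl - CT_ref,ctrl))} using replicate-mean CT values; the
#' reference is a housekeeping gene measured in the same conditions.
#'
#' @param targetCase,refCase,targetCtrl,refCtrl numeric CT replicate vectors,
#'   finite and positive.
#' @return the relative expression fold change (1 = no change).
#' @export
ddctFoldChange <- function(targetCase, refCase, targetCtrl, refCtrl) {
  vals <- list(targetCase = targetCase, refCase = refCase,
               targetCtrl = targetCtrl, refCtrl = refCtrl)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!length(v)) stop("missing CT values for condition '", nm, "'")
    if (!all(is.finite(v)) || any(v <= 0)) {
      stop("CT values for '", nm, "' must be finite and positive")
    }
  }
  ddct <- (mean(targetCase) - mean(refCase)) -
          (mean(targetCtrl) - mean(refCtrl))
  2^(-ddct)
}
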