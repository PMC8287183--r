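## AS-ratio quantification and regulated-event (RASE) calling.

#' AS ratio
#'
#' The inclusion statistic of an event in one sample: alternative-form
#' junction reads divided by alternative plus model-form junction reads.
#' Undefined (NA) when both counts are zero.
#'
#' @param asReads,mReads non-negative read counts (vectorised).
#' @return numeric in [0, 1], or NA where both counts are zero.
#' @export
asRatio <- function(asReads, mReads) {
  if (any(asReads < 0, na.rm = TRUE) || any(mReads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  tot <- asReads + mReads
  ifelse(tot > 0, asReads / tot, NA_real_)
}

.sum_junction_reads <- function(jstring, sampleJunctions, chromName) {
  jm <- parseJunctionString(jstring)
  if (!nrow(jm)) return(0L)
  total <- 0L
  for (i in seq_len(nrow(jm))) {
    hit <- sampleJunctions$chrom == chromName &
      sampleJunctions$intron_start == jm[i, 1L] &
      sampleJunctions$intron_end == jm[i, 2L]
    total <- total + sum(sampleJunctions$unique_reads[hit])
  }
  total
}

#' Quantify events per sample
#'
#' For each event and sample, sums unique reads over the alternative-form and
#' model-form junction sets (a junction absent from the sample's table counts
#' as zero). For IR events the alternative-form count is the sample's intron
#' body count. The ratio is \code{\link{asRatio}} of the two sums.
#'
#' @param events event data.frame from \code{\link{detectEvents}}.
#' @param sampleJunctions named list (sample_id -> junction data.frame).
#' @param intronCounts optional intron body-count table whose per-sample count
#'   columns are named by sample_id; required to quantify IR events.
#' @return long data.frame: \code{event_id}, \code{sample_id},
#'   \code{as_reads}, \code{m_reads}, \code{ratio}.
#' @export
quantifyEvents <- function(events, sampleJunctions, intronCounts = NULL) {
  if (any(events$type == "IR") && is.null(intronCounts)) {
    stop("events include IR but no intron body-count table was supplied")
  }
  rows <- vector("list", nrow(events) * length(sampleJunctions))
  k <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    for (sid in names(sampleJunctions)) {
      sj <- sampleJunctions[[sid]]
      if (ev$type == "IR") {
        hit <- intronCounts$chrom == ev$chrom &
          intronCounts$intron_start == ev$alt_start &
          intronCounts$intron_end == ev$alt_end
        asr <- if (any(hit) && sid %in% names(intronCounts)) {
          sum(intronCounts[hit, sid])
        } else 0L
      } else {
        asr <- .sum_junction_reads(ev$as_junctions, sj, ev$chrom)
      }
      mr <- .sum_junction_reads(ev$m_junctions, sj, ev$chrom)
      k <- k + 1L
      rows[[k]] <- data.frame(event_id = ev$event_id, sample_id = sid,
                              as_reads = asr, m_reads = mr,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out)) {
    out <- data.frame(event_id = character(), sample_id = character(),
                      as_reads = integer(), m_reads = integer())
  }
  out$ratio <- asRatio(out$as_reads, out$m_reads)
  rownames(out) <- NULL
  out
}

#' Two-sided unpaired Student t-test (pooled variance)
#'
#' Thin wrapper around \code{stats::t.test(var.equal = TRUE)} with explicit
#' handling of the degenerate zero-variance case: when both groups are
#' constant and equal the test carries no evidence of a difference and
#' (t = 0, p = 1) is returned with a warning; when both are constant but
#' unequal, t is signed infinite and p is floored at the smallest positive
#' double.
#'
#' @param x,y numeric vectors, each of length >= 2, finite.
#' @return list with elements \code{t} and \code{p}.
#' @export
studentTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero variance in both groups with equal means; p set to 1")
      return(list(t = 0, p = 1))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 2e-308))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Call regulated splicing events between two groups
#'
#' For each event, computes per-group mean AS ratios over samples with
#' defined ratios, the RASE ratio (signed difference of group means,
#' groupA - groupB), and a pooled-variance Student t-test on the per-sample
#' ratios. An event is significant iff |RASE ratio| exceeds
#' \code{raseThreshold}, p < \code{alpha}, and both groups have at least
#' \code{minSamples} defined ratios. Events failing the read-support filter
#' (as + m reads >= \code{minSupport} in every sample of both groups) are
#' excluded up front; their number is reported in a message. A
#' Benjamini-Hochberg adjusted column \code{bh_q} is emitted for reference
#' but does not enter the significance flag.
#'
#' @param quants quantification table from \code{\link{quantifyEvents}}.
#' @param manifest sample manifest data.frame (\code{sample_id}, \code{group}).
#' @param groupA,groupB the two group labels to compare.
#' @param raseThreshold effect-size threshold on |RASE ratio| (default 0.2).
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param minSupport minimum as + m reads per sample (default 10).
#' @param minSamples minimum defined ratios per group (default 2).
#' @return data.frame: \code{event_id}, \code{mean_ratio_A},
#'   \code{mean_ratio_B}, \code{rase_ratio}, \code{t_statistic},
#'   \code{p_value}, \code{bh_q}, \code{tested}, \code{reason},
#'   \code{significant}.
#' @export
callRases <- function(quants, manifest, groupA, groupB,
                      raseThreshold = 0.2, alpha = 0.05,
                      minSupport = 10, minSamples = 2) {
  if (!all(c(groupA, groupB) %in% manifest$group)) {
    stop("unknown group label: ",
         paste(setdiff(c(groupA, groupB), manifest$group), collapse = ", "))
  }
  sampA <- manifest$sample_id[manifest$group == groupA]
  sampB <- manifest$sample_id[manifest$group == groupB]
  q <- quants[quants$sample_id %in% c(sampA, sampB), , drop = FALSE]
  events <- unique(q$event_id)
  support <- vapply(events, function(eid) {
    sub <- q[q$event_id == eid, ]
    all(sub$as_reads + sub$m_reads >= minSupport)
  }, TRUE)
  if (any(!support)) {
    message(sum(!support), " event(s) excluded by the read-support filter ",
            "(as + m < ", minSupport, " in at least one sample)")
  }
  events <- events[support]
  rows <- lapply(events, function(eid) {
    sub <- q[q$event_id == eid, ]
    ra <- sub$ratio[sub$sample_id %in% sampA]
    rb <- sub$ratio[sub$sample_id %in% sampB]
    ra <- ra[!is.na(ra)]; rb <- rb[!is.na(rb)]
    ok <- length(ra) >= max(2L, minSamples) && length(rb) >= max(2L, minSamples)
    if (!ok) {
      return(data.frame(event_id = eid,
                        mean_ratio_A = if (length(ra)) mean(ra) else NA_real_,
                        mean_ratio_B = if (length(rb)) mean(rb) else NA_real_,
                        rase_ratio = NA_real_, t_statistic = NA_real_,
                        p_value = NA_real_, tested = FALSE,
                        reason = "fewer than the minimum defined ratios",
                        stringsAsFactors = FALSE))
    }
    tt <- suppressWarnings(studentTTest(ra, rb))
    data.frame(event_id = eid, mean_ratio_A = mean(ra),
               mean_ratio_B = mean(rb), rase_ratio = mean(ra) - mean(rb),
               t_statistic = tt$t, p_value = tt$p, tested = TRUE, reason = "",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(event_id = character(), mean_ratio_A = numeric(),
                      mean_ratio_B = numeric(), rase_ratio = numeric(),
                      t_statistic = numeric(), p_value = numeric(),
                      tested = logical(), reason = character())
  }
  res$bh_q <- rep(NA_real_, nrow(res))
  res$bh_q[res$tested] <- bhFdr(res$p_value[res$tested])
  res$significant <- res$tested & !is.na(res$rase_ratio) &
    abs(res$rase_ratio) > raseThreshold & res$p_value < alpha
  rownames(res) <- NULL
  res
}
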