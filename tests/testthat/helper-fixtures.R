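## Shared fixtures and independent oracles. The oracles deliberately avoid
## the code paths they check: the BH oracle is a literal step-up loop, the
## hypergeometric oracle a choose() sum, the correlation oracle the textbook
## moment formulas.

write_tmp_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(chrom, start, end, strand, gene, tx) {
  sprintf('%s\tsrc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start, end, strand, gene, tx)
}

## three-exon skipping gene: transcripts F-B-G and F-G
es_gene <- function(strand = "+") {
  GeneModel("gES", "chr1", strand,
            list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
                 t2 = rbind(c(101, 200), c(501, 600))))
}

junc_df <- function(starts, ends, reads, chrom = "chr1", strand = "+") {
  chrom <- rep_len(chrom, length(starts))
  strand <- rep_len(strand, length(starts))
  data.frame(chrom = chrom, intron_start = as.integer(starts),
             intron_end = as.integer(ends), strand = strand,
             unique_reads = as.integer(reads), stringsAsFactors = FALSE)
}

## Benjamini-Hochberg step-up, written out literally
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  for (i in seq(n - 1L, 1L)) {
    if (n < 2L) break
    ranked[i] <- min(ranked[i], ranked[i + 1L])
  }
  out <- pmin(ranked, 1)
  out[order(o)]
}

## P(X >= ov) for X ~ Hypergeom(N, K, n) as an explicit choose() sum
hyper_tail_oracle <- function(ov, K, n, N) {
  i <- seq(ov, min(K, n))
  if (!length(i)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Pearson r and two-sided p from the moment and t-transform formulas
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

## pooled-variance two-sample t-test from the textbook formula
pooled_t_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

## enumerate all maximal exon paths of a gene given a pooled junction set;
## an independent route to skip (ES/CE) and mutually-exclusive (MXE) events
enumerate_paths <- function(graph, junctions) {
  ex <- exons(graph)
  ed <- graphEdges(graph)
  keys <- unique(c(paste(ed$intron_start, ed$intron_end),
                   paste(junctions$intron_start, junctions$intron_end)))
  n <- nrow(ex)
  adj <- lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j) {
      ex[j, "start"] > ex[i, "end"] + 1L &&
        paste(ex[i, "end"] + 1L, ex[j, "start"] - 1L) %in% keys
    }, TRUE))
  })
  hasIn <- vapply(seq_len(n), function(j) any(vapply(seq_len(n), function(i) {
    j %in% adj[[i]]
  }, TRUE)), TRUE)
  paths <- list()
  walk <- function(path) {
    nxt <- adj[[path[length(path)]]]
    if (!length(nxt)) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (j in nxt) walk(c(path, j))
    }
  }
  for (s in which(!hasIn)) walk(s)
  paths
}

## skip and mutually-exclusive event sets from path comparison
path_events_oracle <- function(graph, junctions) {
  ex <- exons(graph)
  paths <- enumerate_paths(graph, junctions)
  out <- list()
  np <- length(paths)
  if (np < 2L) return(out)
  for (a in seq_len(np - 1L)) {
    for (b in seq((a + 1L), np) ) {
      p1 <- paths[[a]]; p2 <- paths[[b]]
      if (length(p1) < length(p2)) { tmp <- p1; p1 <- p2; p2 <- tmp }
      missing <- setdiff(p1, p2)
      added <- setdiff(p2, p1)
      if (!length(added) && length(missing) &&
          all(diff(match(missing, p1)) == 1L)) {
        ## p2 skips a consecutive internal run of p1
        i1 <- match(missing[1L], p1); i2 <- match(missing[length(missing)], p1)
        if (i1 > 1L && i2 < length(p1)) {
          out[[length(out) + 1L]] <- list(
            type = if (length(missing) == 1L) "ES" else "CE",
            alt = c(ex[missing[1L], "start"],
                    ex[missing[length(missing)], "end"]))
        }
      } else if (length(added) == 1L && length(missing) == 1L &&
                 length(p1) == length(p2) &&
                 match(missing, p1) == match(added, p2) &&
                 match(missing, p1) > 1L && match(missing, p1) < length(p1)) {
        pair <- sort(c(missing, added))
        keys <- unique(c(paste(graphEdges(graph)$intron_start,
                               graphEdges(graph)$intron_end),
                         paste(junctions$intron_start,
                               junctions$intron_end)))
        ## mutual exclusivity demands no junction between the pair
        if (!paste(ex[pair[1L], "end"] + 1L,
                   ex[pair[2L], "start"] - 1L) %in% keys) {
          out[[length(out) + 1L]] <- list(
            type = "MXE",
            alt = c(ex[pair[1L], "start"], ex[pair[2L], "end"]))
        }
      }
    }
  }
  unique(out)
}
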