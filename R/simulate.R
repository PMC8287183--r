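## Synthetic-data generator with planted ground truth.
##
## The generator works at the junction-table level (the pipeline's own input
## boundary): for every planted event it draws a total event depth d (negative
## binomial; Poisson in the infinite-dispersion default), perturbs the group
## inclusion level on the logit scale per replicate, draws inclusion reads
## X ~ Binomial(d, psi'), and distributes X over the alternative-form
## junctions and d - X over the model-form junctions. Intron retention gets
## its alternative evidence as intron body counts. Expression matrices carry
## planted fold changes, an anchor-coexpression block and splicing-factor
## couplings; qPCR CT tables encode a planted knockdown efficiency.

#' Create a simulation configuration
#'
#' Defaults describe the emulated study design: knockdown vs control with
#' three biological replicates, one planted event per canonical type with
#' group inclusion levels 0.65 vs 0.35 (a planted AS-ratio change of 0.3),
#' event depth 100 with Poisson-like dispersion, logit-scale replicate noise
#' 0.2, 500-gene expression matrix with 20 four-fold genes, a 20-gene
#' coexpression block around the anchor and five splicing factors, and a 70
#' percent planted knockdown.
#'
#' @param seed integer seed (mandatory).
#' @param eventsPerType,groups,nReplicates,psi,psiByEvent,depthMean,
#'   depthDispersion,replicateSigma,exactCounts,nGenes,nDeGenes,deFold,
#'   anchorGene,blockSize,blockSigma,sfGenes,knockdownEfficiency see
#'   \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(seed,
                             eventsPerType = 1L,
                             groups = c("KD", "CTRL"),
                             nReplicates = 3L,
                             psi = c(0.65, 0.35),
                             psiByEvent = list(),
                             depthMean = 100,
                             depthDispersion = Inf,
                             replicateSigma = 0.2,
                             exactCounts = FALSE,
                             nGenes = 500L,
                             nDeGenes = 20L,
                             deFold = 4,
                             anchorGene = "KRT18",
                             blockSize = 20L,
                             blockSigma = 0.1,
                             sfGenes = c("SRSF1", "SRSF3", "HNRNPK",
                                         "PTBP1", "U2AF2"),
                             knockdownEfficiency = 0.7) {
  new("SimulationConfig", seed = as.integer(seed),
      eventsPerType = as.integer(eventsPerType), groups = groups,
      nReplicates = as.integer(nReplicates), psi = psi,
      psiByEvent = psiByEvent, depthMean = depthMean,
      depthDispersion = depthDispersion, replicateSigma = replicateSigma,
      exactCounts = exactCounts, nGenes = as.integer(nGenes),
      nDeGenes = as.integer(nDeGenes), deFold = deFold,
      anchorGene = anchorGene, blockSize = as.integer(blockSize),
      blockSigma = blockSigma, sfGenes = sfGenes,
      knockdownEfficiency = knockdownEfficiency)
}

#' The ten canonical event type labels
#'
#' @return character vector of the type labels the classifier can assign.
#' @export
eventTypes <- function() {
  c("ES", "CE", "A5SS", "A3SS", "MXE", "5pMXE", "3pMXE",
    "A5SS&ES", "A3SS&ES", "IR")
}

## local-coordinate templates realising each event type; "tx" lists exon
## (start, end) pairs per transcript, "as"/"m" the junction forms the
## classifier is expected to emit, "alt" the alternative region
.event_template <- function(type) {
  switch(type,
    "ES" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
                t2 = rbind(c(101, 200), c(501, 600))),
      as = "201-500", m = "201-300;401-500", alt = c(301, 400)),
    "CE" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600),
                           c(701, 800)),
                t2 = rbind(c(101, 200), c(701, 800))),
      as = "201-700", m = "201-300;401-500;601-700", alt = c(301, 600)),
    "A5SS" = list(
      tx = list(t1 = rbind(c(101, 200), c(401, 500)),
                t2 = rbind(c(101, 260), c(401, 500))),
      as = "201-400", m = "261-400", alt = c(201, 260)),
    "A3SS" = list(
      tx = list(t1 = rbind(c(101, 200), c(401, 500)),
                t2 = rbind(c(101, 200), c(341, 500))),
      as = "201-400", m = "201-340", alt = c(341, 400)),
    "MXE" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400), c(701, 800)),
                t2 = rbind(c(101, 200), c(501, 600), c(701, 800))),
      as = "201-500;601-700", m = "201-300;401-700", alt = c(301, 600)),
    "5pMXE" = list(
      tx = list(t1 = rbind(c(101, 200), c(501, 600)),
                t2 = rbind(c(301, 400), c(501, 600))),
      as = "401-500", m = "201-500", alt = c(101, 400)),
    "3pMXE" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400)),
                t2 = rbind(c(101, 200), c(501, 600))),
      as = "201-500", m = "201-300", alt = c(301, 600)),
    "A5SS&ES" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
                t2 = rbind(c(101, 160), c(501, 600))),
      as = "161-500", m = "401-500", alt = c(161, 400)),
    "A3SS&ES" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
                t2 = rbind(c(101, 200), c(461, 600))),
      as = "201-460", m = "201-300", alt = c(301, 460)),
    "IR" = list(
      tx = list(t1 = rbind(c(101, 200), c(301, 400))),
      as = "", m = "201-300", alt = c(201, 300)),
    stop("unknown event type: ", type))
}

.shift_junctions <- function(x, offset) {
  if (!nzchar(x)) return(x)
  m <- parseJunctionString(x)
  paste(paste0(m[, 1] + offset, "-", m[, 2] + offset), collapse = ";")
}

#' Simulate a gene annotation with one gene per planted event
#'
#' Builds, for each of the ten canonical types, \code{eventsPerType} genes
#' whose transcript structures realise that type (two transcripts differing
#' by one exon for ES, mutually exclusive middle exons for MXE,
#' transcript-initial alternatives for the alternative-first-exon variant,
#' and so on). The output is deterministic given the configuration.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{genes} (named list of \linkS4class{GeneModel})
#'   and \code{truth} (event skeleton data.frame: gene_id, type, chrom,
#'   strand, event_id, as_junctions, m_junctions, alt_start, alt_end,
#'   psi_A, psi_B).
#' @export
simulateAnnotation <- function(config) {
  validObject(config)
  chromName <- "chrS"
  genes <- list()
  rows <- list()
  idx <- 0L
  for (type in eventTypes()) {
    for (i in seq_len(config@eventsPerType)) {
      idx <- idx + 1L
      offset <- (idx - 1L) * 10000L
      tpl <- .event_template(type)
      gid <- sprintf("G_%s_%02d", gsub("&", "", type, fixed = TRUE), i)
      txs <- lapply(tpl$tx, function(m) m + offset)
      genes[[gid]] <- GeneModel(gid, chromName, "+", txs)
      psi <- config@psiByEvent[[gid]]
      if (is.null(psi)) psi <- config@psi
      alt <- tpl$alt + offset
      rows[[idx]] <- data.frame(
        gene_id = gid, type = type, chrom = chromName, strand = "+",
        event_id = sprintf("%s|%s|%s:%d-%d", gid, type, chromName,
                           alt[1L], alt[2L]),
        as_junctions = .shift_junctions(tpl$as, offset),
        m_junctions = .shift_junctions(tpl$m, offset),
        alt_start = alt[1L], alt_end = alt[2L],
        psi_A = psi[1L], psi_B = psi[2L], stringsAsFactors = FALSE)
    }
  }
  list(genes = genes, truth = do.call(rbind, rows))
}

.draw_depth <- function(n, config) {
  if (config@exactCounts) return(rep(round(config@depthMean), n))
  if (is.infinite(config@depthDispersion)) {
    stats::rpois(n, config@depthMean)
  } else {
    stats::rnbinom(n, mu = config@depthMean, size = config@depthDispersion)
  }
}

.split_reads <- function(total, k, exact) {
  if (k == 0L) return(integer())
  if (k == 1L) return(as.integer(total))
  if (exact || total == 0) {
    base <- total %/% k
    out <- rep(base, k)
    out[1L] <- out[1L] + total %% k
    return(as.integer(out))
  }
  as.integer(stats::rmultinom(1L, total, rep(1 / k, k)))
}

#' Simulate per-sample junction tables with planted inclusion levels
#'
#' For every planted event and replicate, draws the event depth, perturbs the
#' group inclusion level with logit-normal replicate noise, draws inclusion
#' reads binomially and distributes them over the event's junction forms
#' (intron body counts for IR). Annotated junctions of a gene that belong to
#' neither form receive the model-form complement so every annotated path has
#' coverage. With \code{exactCounts = TRUE} all draws are replaced by their
#' rounded expectations (noise-free fixture).
#'
#' @param annotation output of \code{\link{simulateAnnotation}}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return list: \code{samples} (named list of junction data.frames in
#'   \code{\link{readJunctions}} layout), \code{intronCounts} (IR body-count
#'   table with one column per sample), \code{manifest} (sample_id, group).
#' @export
simulateJunctions <- function(annotation, config) {
  validObject(config)
  set.seed(config@seed + 1L)
  truth <- annotation$truth
  sampleIds <- as.vector(t(outer(config@groups, seq_len(config@nReplicates),
                                 paste, sep = "_")))
  groupOf <- rep(config@groups, each = config@nReplicates)
  names(groupOf) <- sampleIds
  irTruth <- truth[truth$type == "IR", , drop = FALSE]
  intronCounts <- NULL
  if (nrow(irTruth)) {
    mm <- do.call(rbind, lapply(irTruth$m_junctions, parseJunctionString))
    intronCounts <- data.frame(chrom = irTruth$chrom,
                               intron_start = mm[, 1L],
                               intron_end = mm[, 2L])
    for (sid in sampleIds) intronCounts[[sid]] <- 0L
  }
  samples <- stats::setNames(vector("list", length(sampleIds)), sampleIds)
  for (sid in sampleIds) {
    grp <- groupOf[[sid]]
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      ev <- truth[i, ]
      psi <- if (grp == config@groups[1L]) ev$psi_A else ev$psi_B
      d <- .draw_depth(1L, config)
      if (config@exactCounts || config@replicateSigma == 0) {
        psiRep <- psi
      } else {
        psiRep <- stats::plogis(stats::qlogis(min(max(psi, 1e-9), 1 - 1e-9)) +
                                stats::rnorm(1L, 0, config@replicateSigma))
      }
      x <- if (config@exactCounts) round(d * psiRep) else
        stats::rbinom(1L, d, psiRep)
      asm <- parseJunctionString(ev$as_junctions)
      mm <- parseJunctionString(ev$m_junctions)
      asCounts <- .split_reads(x, nrow(asm), config@exactCounts)
      mCounts <- .split_reads(d - x, nrow(mm), config@exactCounts)
      if (ev$type == "IR") {
        hit <- intronCounts$chrom == ev$chrom &
          intronCounts$intron_start == ev$alt_start &
          intronCounts$intron_end == ev$alt_end
        intronCounts[hit, sid] <- as.integer(x)
      }
      g <- annotation$genes[[ev$gene_id]]
      ed <- graphEdges(buildSpliceGraph(g))
      evKeys <- c(if (nrow(asm)) jkey(asm[, 1L], asm[, 2L]),
                  jkey(mm[, 1L], mm[, 2L]))
      extra <- ed[!jkey(ed$intron_start, ed$intron_end) %in% evKeys, ,
                  drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ev$chrom,
        intron_start = c(asm[, 1L], mm[, 1L], extra$intron_start),
        intron_end = c(asm[, 2L], mm[, 2L], extra$intron_end),
        strand = ev$strand,
        unique_reads = c(asCounts, mCounts,
                         rep(as.integer(d - x), nrow(extra))),
        stringsAsFactors = FALSE)
    }
    sj <- do.call(rbind, rows)
    sj <- sj[order(sj$chrom, sj$intron_start, sj$intron_end), , drop = FALSE]
    rownames(sj) <- NULL
    samples[[sid]] <- sj
  }
  list(samples = samples, intronCounts = intronCounts,
       manifest = data.frame(sample_id = sampleIds, group = unname(groupOf),
                             stringsAsFactors = FALSE))
}

#' Simulate grouped event counts directly (calibration helper)
#'
#' Bypasses gene structures and emits the quantification table for
#' \code{nEvents} synthetic events under the generator's sampling law
#' (depth draw, logit-normal replicate noise, binomial inclusion): useful for
#' null-calibration and power studies at event counts where building one gene
#' per event is unnecessary.
#'
#' @param nEvents number of events.
#' @param psiA,psiB group inclusion levels (scalars or length-nEvents).
#' @param config a \linkS4class{SimulationConfig} (depth, noise, replicate
#'   and group settings are honoured; \code{seed} seeds the draws).
#' @return quantification data.frame as from \code{\link{quantifyEvents}}.
#' @export
simulateEventCounts <- function(nEvents, psiA, psiB, config) {
  validObject(config)
  set.seed(config@seed + 2L)
  psiA <- rep_len(psiA, nEvents)
  psiB <- rep_len(psiB, nEvents)
  sampleIds <- as.vector(t(outer(config@groups, seq_len(config@nReplicates),
                                 paste, sep = "_")))
  groupOf <- rep(config@groups, each = config@nReplicates)
  rows <- lapply(seq_along(sampleIds), function(si) {
    psi <- if (groupOf[si] == config@groups[1L]) psiA else psiB
    d <- .draw_depth(nEvents, config)
    psiRep <- if (config@replicateSigma > 0) {
      stats::plogis(stats::qlogis(pmin(pmax(psi, 1e-9), 1 - 1e-9)) +
                    stats::rnorm(nEvents, 0, config@replicateSigma))
    } else psi
    x <- stats::rbinom(nEvents, d, psiRep)
    data.frame(event_id = sprintf("SIM%05d", seq_len(nEvents)),
               sample_id = sampleIds[si], as_reads = x, m_reads = d - x,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ratio <- asRatio(out$as_reads, out$m_reads)
  rownames(out) <- NULL
  out
}

#' Simulate an expression matrix with planted structure
#'
#' Baseline expression is log-normal across genes. The anchor gene carries a
#' sample-level latent signal; the coexpression block follows that signal
#' plus independent noise; the planted differentially expressed genes are
#' shifted by \code{deFold} in the first group; the anchor is reduced by the
#' knockdown efficiency in the first group. Counts are Poisson draws of the
#' per-sample expectation. A qPCR CT table consistent with the planted
#' knockdown is generated for the anchor against a reference gene.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list: \code{counts} (matrix), \code{geneLengths}, \code{manifest},
#'   \code{ct} (list of CT replicate vectors), \code{truth} (list: de_genes,
#'   block_genes, anchor).
#' @export
simulateExpression <- function(config) {
  validObject(config)
  set.seed(config@seed + 3L)
  sampleIds <- as.vector(t(outer(config@groups, seq_len(config@nReplicates),
                                 paste, sep = "_")))
  groupOf <- rep(config@groups, each = config@nReplicates)
  nCore <- 1L + length(config@sfGenes) + config@blockSize + config@nDeGenes
  if (config@nGenes < nCore) stop("nGenes too small for the planted structure")
  blockGenes <- sprintf("COEX%03d", seq_len(config@blockSize))
  deGenes <- sprintf("DEG%03d", seq_len(config@nDeGenes))
  nullGenes <- sprintf("GENE%04d", seq_len(config@nGenes - nCore))
  genes <- c(config@anchorGene, config@sfGenes, blockGenes, deGenes, nullGenes)
  baseMu <- stats::setNames(exp(stats::rnorm(length(genes), log(100), 1)),
                            genes)
  z <- stats::rnorm(length(sampleIds))          # latent anchor signal
  names(z) <- sampleIds
  mu <- matrix(0, length(genes), length(sampleIds),
               dimnames = list(genes, sampleIds))
  inA <- groupOf == config@groups[1L]
  for (s in seq_along(sampleIds)) {
    lmu <- log(baseMu)
    lmu[config@anchorGene] <- lmu[config@anchorGene] + 0.5 * z[s]
    lmu[blockGenes] <- lmu[blockGenes] + 0.5 * z[s] +
      stats::rnorm(length(blockGenes), 0, config@blockSigma)
    lmu[config@sfGenes] <- lmu[config@sfGenes] + 0.4 * z[s] +
      stats::rnorm(length(config@sfGenes), 0, 0.2)
    if (inA[s]) {
      lmu[config@anchorGene] <- lmu[config@anchorGene] +
        log(1 - config@knockdownEfficiency)
      lmu[deGenes] <- lmu[deGenes] + log(config@deFold)
    }
    mu[, s] <- exp(lmu)
  }
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu),
                   dimnames = dimnames(mu))
  geneLengths <- stats::setNames(
    round(stats::runif(length(genes), 500, 5000)), genes)
  fold <- 1 - config@knockdownEfficiency
  ct <- list(
    targetCase = 22 - log2(fold) + stats::rnorm(3L, 0, 0.05),
    refCase = 20 + stats::rnorm(3L, 0, 0.05),
    targetCtrl = 22 + stats::rnorm(3L, 0, 0.05),
    refCtrl = 20 + stats::rnorm(3L, 0, 0.05))
  list(counts = counts, geneLengths = geneLengths,
       manifest = data.frame(sample_id = sampleIds, group = unname(groupOf),
                             stringsAsFactors = FALSE),
       ct = ct,
       truth = list(de_genes = deGenes, de_fold = config@deFold,
                    block_genes = blockGenes, anchor = config@anchorGene,
                    knockdown = config@knockdownEfficiency))
}

#' Simulate a stratification cohort with coexpression and SF couplings
#'
#' A single-group cohort whose anchor gene varies across samples; the
#' coexpression block and splicing factors follow the anchor's latent signal,
#' and each synthetic event's AS-ratio profile is a logistic function of one
#' splicing factor's (standardised) expression plus noise, recorded in the
#' truth couplings.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nSamples cohort size (default 50).
#' @param nEvents number of coupled events (default 20).
#' @param ratioSigma additive ratio noise s.d. (default 0.05).
#' @return list: \code{counts}, \code{geneLengths}, \code{sampleIds},
#'   \code{ratios} (events x samples), \code{truth} (couplings data.frame).
#' @export
simulateCohort <- function(config, nSamples = 50L, nEvents = 20L,
                           ratioSigma = 0.05) {
  validObject(config)
  set.seed(config@seed + 4L)
  sampleIds <- sprintf("S%03d", seq_len(nSamples))
  blockGenes <- sprintf("COEX%03d", seq_len(config@blockSize))
  nullGenes <- sprintf("GENE%04d", seq_len(100L))
  genes <- c(config@anchorGene, config@sfGenes, blockGenes, nullGenes)
  baseMu <- stats::setNames(exp(stats::rnorm(length(genes), log(100), 1)),
                            genes)
  z <- stats::rnorm(nSamples)
  mu <- matrix(0, length(genes), nSamples,
               dimnames = list(genes, sampleIds))
  for (s in seq_len(nSamples)) {
    lmu <- log(baseMu)
    lmu[config@anchorGene] <- lmu[config@anchorGene] + 0.8 * z[s]
    lmu[blockGenes] <- lmu[blockGenes] + 0.8 * z[s] +
      stats::rnorm(length(blockGenes), 0, config@blockSigma)
    lmu[config@sfGenes] <- lmu[config@sfGenes] + 0.8 * z[s] +
      stats::rnorm(length(config@sfGenes), 0, 0.3)
    mu[, s] <- exp(lmu)
  }
  counts <- matrix(stats::rpois(length(mu), mu), nrow(mu),
                   dimnames = dimnames(mu))
  geneLengths <- stats::setNames(
    round(stats::runif(length(genes), 500, 5000)), genes)
  sfOf <- rep_len(config@sfGenes, nEvents)
  se <- makeExpressionMatrix(counts, geneLengths)
  sfExpr <- log2(cpm(se)[config@sfGenes, , drop = FALSE] + 1)
  ratios <- matrix(NA_real_, nEvents, nSamples,
                   dimnames = list(sprintf("EV%03d", seq_len(nEvents)),
                                   sampleIds))
  for (i in seq_len(nEvents)) {
    sfz <- as.numeric(scale(sfExpr[sfOf[i], ]))
    r <- stats::plogis(1.5 * sfz) + stats::rnorm(nSamples, 0, ratioSigma)
    ratios[i, ] <- pmin(pmax(r, 0), 1)
  }
  list(counts = counts, geneLengths = geneLengths, sampleIds = sampleIds,
       ratios = ratios,
       truth = data.frame(event_id = rownames(ratios), sf = sfOf,
                          stringsAsFactors = FALSE))
}

#' Run the full study simulation
#'
#' Convenience wrapper: annotation + junction tables + expression matrix
#' under one configuration.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{annotation}, \code{junctions},
#'   \code{expression}.
#' @export
simulateStudy <- function(config) {
  ann <- simulateAnnotation(config)
  jx <- simulateJunctions(ann, config)
  ex <- simulateExpression(config)
  list(annotation = ann, junctions = jx, expression = ex)
}

#' Write a simulated study to disk
#'
#' Emits annotation.gtf, one SJ tab per sample, intron_counts.tsv,
#' manifest.tsv, counts.tsv, gene_lengths.tsv and truth.json. Output is
#' byte-identical for identical configurations.
#'
#' @param study output of \code{\link{simulateStudy}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGtf(study$annotation$genes, file.path(dir, "annotation.gtf"))
  jx <- study$junctions
  for (sid in names(jx$samples)) {
    sj <- jx$samples[[sid]]
    code <- c("unknown" = 0L, "+" = 1L, "-" = 2L)[sj$strand]
    tab <- data.frame(sj$chrom, sj$intron_start, sj$intron_end, code,
                      0L, 1L, sj$unique_reads, 0L, 20L)
    utils::write.table(tab, file.path(dir, paste0(sid, ".sj.tab")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (!is.null(jx$intronCounts)) {
    utils::write.table(jx$intronCounts, file.path(dir, "intron_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  man <- jx$manifest
  man$junction_path <- paste0(man$sample_id, ".sj.tab")
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ex <- study$expression
  utils::write.table(data.frame(gene_id = rownames(ex$counts), ex$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(ex$geneLengths),
                                length = unname(ex$geneLengths)),
                     file.path(dir, "gene_lengths.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(events = study$annotation$truth, de = ex$truth),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}
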