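test_that("GTF parsing reconstructs genes, transcripts and exons", {
  path <- write_tmp_gtf(c(
    gtf_exon_line("chr1", 1, 100, "+", "g1", "t1"),
    gtf_exon_line("chr1", 201, 300, "+", "g1", "t1")))
  genes <- readGtf(path)
  expect_length(genes, 1L)
  expect_equal(nrow(exons(genes$g1)), 2L)
  expect_length(transcripts(genes$g1), 1L)

  ## cassette structure: two transcripts sharing flanks, one skipping the middle
  path2 <- write_tmp_gtf(c(
    gtf_exon_line("chr1", 1, 100, "+", "g2", "t1"),
    gtf_exon_line("chr1", 201, 300, "+", "g2", "t1"),
    gtf_exon_line("chr1", 401, 500, "+", "g2", "t1"),
    gtf_exon_line("chr1", 1, 100, "+", "g2", "t2"),
    gtf_exon_line("chr1", 401, 500, "+", "g2", "t2")))
  g2 <- readGtf(path2)$g2
  expect_equal(nrow(exons(g2)), 3L)
  expect_length(transcripts(g2), 2L)
})

test_that("GTF parse errors carry line numbers and transcript names", {
  empty <- write_tmp_gtf(character())
  expect_warning(res <- readGtf(empty), "empty|no feature")
  expect_length(res, 0L)

  bad <- write_tmp_gtf(c(
    gtf_exon_line("chr1", 1, 100, "+", "g1", "t1"),
    "chr1\tonly\tthree"))
  expect_error(readGtf(bad), "line 2")

  noTx <- write_tmp_gtf('chr1\tsrc\texon\t1\t100\t.\t+\t.\tgene_id "g1";')
  expect_error(readGtf(noTx), "transcript_id")

  overlap <- write_tmp_gtf(c(
    gtf_exon_line("chr1", 1, 100, "+", "g1", "tA"),
    gtf_exon_line("chr1", 50, 200, "+", "g1", "tA")))
  expect_error(readGtf(overlap), "tA")

  twoChrom <- write_tmp_gtf(c(
    gtf_exon_line("chr1", 1, 100, "+", "g1", "t1"),
    gtf_exon_line("chr2", 1, 100, "+", "g1", "t2")))
  expect_error(readGtf(twoChrom), "chromosome|strand")
})

test_that("splice graph edges are the union of consecutive-exon junctions", {
  chain <- GeneModel("g", "chr1", "+",
                     list(t1 = rbind(c(1, 100), c(201, 300), c(401, 500))))
  ed <- graphEdges(buildSpliceGraph(chain))
  expect_equal(nrow(ed), 2L)
  expect_equal(ed$intron_start, c(101L, 301L))
  expect_equal(ed$intron_end, c(200L, 400L))

  skip <- GeneModel("g", "chr1", "+",
                    list(t1 = rbind(c(1, 100), c(201, 300), c(401, 500)),
                         t2 = rbind(c(1, 100), c(401, 500))))
  edS <- graphEdges(buildSpliceGraph(skip))
  expect_equal(nrow(edS), 3L)
  expect_true("t1,t2" %in% edS$transcripts == FALSE)  # skip edge is t2 only
  expect_setequal(paste(edS$intron_start, edS$intron_end),
                  c("101 200", "301 400", "101 400"))

  single <- GeneModel("g", "chr1", "+", list(t1 = rbind(c(1, 100))))
  expect_equal(nrow(graphEdges(buildSpliceGraph(single))), 0L)
})

test_that("annotated junction enumeration deduplicates and keeps strand", {
  skip2tx <- GeneModel("g", "chr1", "+",
                       list(t1 = rbind(c(1, 100), c(201, 300), c(401, 500)),
                            t2 = rbind(c(1, 100), c(401, 500))))
  aj <- annotatedJunctions(list(skip2tx))
  expect_equal(nrow(aj), 3L)

  plus <- GeneModel("gp", "chr1", "+",
                    list(t1 = rbind(c(1, 100), c(201, 300))))
  minus <- GeneModel("gm", "chr1", "-",
                     list(t1 = rbind(c(1, 100), c(201, 300))))
  aj2 <- annotatedJunctions(list(plus, minus))
  expect_equal(nrow(aj2), 2L)           # strand distinguishes
  shared <- GeneModel("gp2", "chr1", "+",
                      list(tx = rbind(c(1, 100), c(201, 300))))
  aj3 <- annotatedJunctions(list(plus, shared))
  expect_equal(nrow(aj3), 1L)           # same junction from two genes
})

test_that("GTF round trip preserves structures; edge-count bounds hold", {
  cfg <- simulationConfig(seed = 11)
  ann <- simulateAnnotation(cfg)
  path <- tempfile(fileext = ".gtf")
  writeGtf(ann$genes, path)
  back <- readGtf(path)
  expect_setequal(names(back), names(ann$genes))
  for (g in names(ann$genes)) {
    expect_equal(exons(back[[g]]), exons(ann$genes[[g]]), ignore_attr = FALSE)
    expect_equal(lapply(transcripts(back[[g]]), sort),
                 lapply(transcripts(ann$genes[[g]]), sort)[
                   names(transcripts(back[[g]]))])
  }
  aj <- annotatedJunctions(ann$genes)
  bound <- sum(vapply(ann$genes, function(g) {
    sum(vapply(transcripts(g), length, 0L) - 1L)
  }, 0))
  expect_lte(nrow(aj), bound)
  for (g in ann$genes) {
    expect_equal(nrow(graphEdges(buildSpliceGraph(g))),
                 sum(aj$chrom == chrom(g) &
                       aj$intron_start >= min(exons(g)[, "start"]) &
                       aj$intron_end <= max(exons(g)[, "end"])))
  }
})
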