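test_that("exon skipping is detected with disjoint AS/M junction sets", {
  g <- GeneModel("g", "chr1", "+",
                 list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600))))
  graph <- buildSpliceGraph(g)
  j <- junc_df(c(201, 401, 201), c(300, 500, 500), c(40, 40, 20))
  ev <- detectEvents(graph, j)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "ES")
  expect_equal(ev$as_junctions, "201-500")
  expect_equal(ev$m_junctions, "201-300;401-500")
  expect_equal(c(ev$alt_start, ev$alt_end), c(301L, 400L))
  expect_false(ev$known)                 # skip junction is unannotated
  asj <- parseJunctionString(ev$as_junctions)
  mj <- parseJunctionString(ev$m_junctions)
  expect_length(intersect(paste(asj[, 1], asj[, 2]),
                          paste(mj[, 1], mj[, 2])), 0L)
  ## every referenced junction is present in the pooled input
  all_in <- rbind(asj, mj)
  expect_true(all(paste(all_in[, 1], all_in[, 2]) %in%
                    paste(j$intron_start, j$intron_end)))
})

test_that("the planted fixture yields one event per type (identity confusion)", {
  cfg <- simulationConfig(seed = 5, exactCounts = TRUE)
  ann <- simulateAnnotation(cfg)
  jx <- simulateJunctions(ann, cfg)
  pooled <- unique(do.call(rbind, jx$samples))
  ev <- detectAllEvents(ann$genes, pooled, jx$intronCounts)
  expect_equal(nrow(ev), 10L)
  expect_setequal(ev$type, eventTypes())
  merged <- merge(ev, ann$truth, by = "gene_id")
  expect_equal(merged$type.x, merged$type.y)   # confusion matrix = identity
  expect_equal(sort(ev$event_id), sort(ann$truth$event_id))
  expect_true(all(ev$known))
})

test_that("detection is invariant to junction row order", {
  cfg <- simulationConfig(seed = 6, exactCounts = TRUE)
  ann <- simulateAnnotation(cfg)
  jx <- simulateJunctions(ann, cfg)
  pooled <- unique(do.call(rbind, jx$samples))
  set.seed(42)
  shuffled <- pooled[sample(nrow(pooled)), ]
  ev1 <- detectAllEvents(ann$genes, pooled, jx$intronCounts)
  ev2 <- detectAllEvents(ann$genes, shuffled, jx$intronCounts)
  ord <- function(d) d[order(d$event_id), ]
  expect_equal(ord(ev1), ord(ev2), ignore_attr = TRUE)
})

test_that("alternative splice-site pairs classify strand-aware", {
  g <- GeneModel("g", "chr1", "+",
                 list(t1 = rbind(c(101, 200), c(401, 500)),
                      t2 = rbind(c(101, 260), c(401, 500))))
  graph <- buildSpliceGraph(g)
  j1 <- list(intron_start = 201L, intron_end = 400L)
  j2 <- list(intron_start = 261L, intron_end = 400L)
  expect_equal(classifyAltSitePair(j1, j2, graph), "A5SS")
  expect_equal(classifyAltSitePair(j1, j1, graph), "none")
  j3 <- list(intron_start = 211L, intron_end = 340L)
  expect_equal(classifyAltSitePair(j1, j3, graph), "none")  # neither boundary

  ## same structure on the minus strand: the donor is the high-coordinate side
  gm <- GeneModel("gm", "chr1", "-",
                  list(t1 = rbind(c(101, 200), c(401, 500)),
                       t2 = rbind(c(101, 200), c(341, 500))))
  evm <- detectEvents(buildSpliceGraph(gm),
                      junc_df(c(201, 201), c(400, 340), c(10, 10),
                              strand = "-"))
  expect_equal(evm$type, "A5SS")

  ## shared acceptor with the long junction spanning a whole annotated exon
  gc <- GeneModel("gc", "chr1", "+",
                  list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600)),
                       t2 = rbind(c(101, 160), c(501, 600))))
  jl <- list(intron_start = 161L, intron_end = 500L)
  js <- list(intron_start = 401L, intron_end = 500L)
  expect_equal(classifyAltSitePair(jl, js, buildSpliceGraph(gc)), "A5SS&ES")
})

test_that("skip decompositions are not mislabelled as alt-site events", {
  ## an ES gene: the (skip, inclusion) pairs share a boundary but must not
  ## produce A5SS&ES / A3SS&ES events next to the ES call
  g <- es_gene()
  graph <- buildSpliceGraph(g)
  j <- junc_df(c(201, 401, 201), c(300, 500, 500), c(40, 40, 20))
  ev <- detectEvents(graph, j)
  expect_equal(ev$type, "ES")
  j1 <- list(intron_start = 201L, intron_end = 500L)
  j2 <- list(intron_start = 401L, intron_end = 500L)
  expect_equal(classifyAltSitePair(j1, j2, graph), "none")
})

test_that("path-enumeration oracle agrees on skip and mutually exclusive events", {
  cfg <- simulationConfig(seed = 7, exactCounts = TRUE)
  ann <- simulateAnnotation(cfg)
  jx <- simulateJunctions(ann, cfg)
  pooled <- unique(do.call(rbind, jx$samples))
  for (gid in c("G_ES_01", "G_CE_01", "G_MXE_01")) {
    graph <- buildSpliceGraph(ann$genes[[gid]])
    ev <- detectEvents(graph, pooled)
    ev <- ev[ev$type %in% c("ES", "CE", "MXE"), ]
    oracle <- path_events_oracle(graph, pooled)
    expect_equal(nrow(ev), length(oracle), info = gid)
    for (o in oracle) {
      hit <- ev$type == o$type & ev$alt_start == o$alt[1] &
        ev$alt_end == o$alt[2]
      expect_true(any(hit), info = paste(gid, o$type))
    }
  }
  ## a two-cassette gene exercises the oracle beyond the planted fixtures
  g2 <- GeneModel("g2", "chr1", "+", list(
    t1 = rbind(c(1, 100), c(201, 300), c(401, 500), c(601, 700)),
    t2 = rbind(c(1, 100), c(401, 500), c(601, 700)),
    t3 = rbind(c(1, 100), c(201, 300), c(601, 700))))
  graph2 <- buildSpliceGraph(g2)
  none <- junc_df(integer(), integer(), integer())
  ev2 <- detectEvents(graph2, none)
  ev2 <- ev2[ev2$type %in% c("ES", "CE", "MXE"), ]
  oracle2 <- path_events_oracle(graph2, none)
  expect_equal(nrow(ev2), length(oracle2))
})

test_that("intron retention needs body-count evidence", {
  g <- GeneModel("g", "chr1", "+",
                 list(t1 = rbind(c(101, 200), c(301, 400), c(501, 600))))
  graph <- buildSpliceGraph(g)
  expect_error(detectIntronRetention(graph, NULL), "body-count")
  ic0 <- data.frame(chrom = "chr1", intron_start = c(201L, 401L),
                    intron_end = c(300L, 500L), s1 = c(0L, 0L), s2 = c(0L, 0L))
  expect_equal(nrow(detectIntronRetention(graph, ic0)), 0L)
  ic1 <- ic0; ic1$s2[1] <- 4L
  ir <- detectIntronRetention(graph, ic1)
  expect_equal(nrow(ir), 1L)            # only the covered intron
  expect_equal(ir$type, "IR")
  expect_equal(ir$as_junctions, "")
  expect_equal(c(ir$alt_start, ir$alt_end), c(201L, 300L))
})

test_that("gene with no junctions yields no events", {
  g <- es_gene()
  ev <- detectEvents(buildSpliceGraph(g),
                     junc_df(integer(), integer(), integer()))
  ## annotated junctions alone: the skip path is annotated too, so the ES
  ## event is still discoverable from annotation
  expect_true(all(ev$known))
  single <- GeneModel("s", "chr1", "+", list(t1 = rbind(c(1, 100))))
  expect_equal(nrow(detectEvents(buildSpliceGraph(single),
                                 junc_df(integer(), integer(), integer()))),
               0L)
})
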