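test_that("the AS ratio follows its defining formula", {
  expect_equal(asRatio(30, 70), 0.3)
  expect_equal(asRatio(0, 50), 0)
  expect_true(is.na(asRatio(0, 0)))
  expect_error(asRatio(-1, 5), "non-negative")
  ## vectorised and bounded
  expect_true(all(asRatio(0:10, 10:0)[-6] >= 0 & asRatio(0:10, 10:0)[-6] <= 1,
                  na.rm = TRUE))
})

make_es_event <- function() {
  data.frame(event_id = "E1", gene_id = "g", chrom = "chr1", strand = "+",
             type = "ES", alt_start = 301L, alt_end = 400L,
             as_junctions = "201-500", m_junctions = "201-300;401-500",
             known = TRUE, stringsAsFactors = FALSE)
}

test_that("event quantification sums form junction reads per sample", {
  ev <- make_es_event()
  sj <- list(s1 = junc_df(c(201, 401, 201), c(300, 500, 500), c(40, 40, 20)),
             s2 = junc_df(c(999), c(1500), c(7)))   # all event junctions absent
  q <- quantifyEvents(ev, sj)
  q1 <- q[q$sample_id == "s1", ]
  expect_equal(q1$as_reads, 20)
  expect_equal(q1$m_reads, 80)
  expect_equal(q1$ratio, 0.2)
  q2 <- q[q$sample_id == "s2", ]
  expect_equal(c(q2$as_reads, q2$m_reads), c(0, 0))
  expect_true(is.na(q2$ratio))
})

test_that("IR events quantify from intron body counts", {
  ir <- data.frame(event_id = "I1", gene_id = "g", chrom = "chr1",
                   strand = "+", type = "IR", alt_start = 201L,
                   alt_end = 300L, as_junctions = "", m_junctions = "201-300",
                   known = TRUE, stringsAsFactors = FALSE)
  sj <- list(s1 = junc_df(201, 300, 90))
  ic <- data.frame(chrom = "chr1", intron_start = 201L, intron_end = 300L,
                   s1 = 10L)
  q <- quantifyEvents(ir, sj, ic)
  expect_equal(q$ratio, 0.1)
  expect_error(quantifyEvents(ir, sj), "intron body-count")
})

test_that("the Student t-test matches the pooled-variance formula", {
  x <- c(0.1, 0.2, 0.15); y <- c(0.5, 0.6, 0.55)
  got <- studentTTest(x, y)
  want <- pooled_t_oracle(x, y)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)

  expect_warning(deg <- studentTTest(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)),
                 "zero variance")
  expect_equal(deg$p, 1)
  expect_equal(deg$t, 0)

  sym <- studentTTest(c(0, 1), c(0, 1))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)

  expect_error(studentTTest(0.5, c(0.4, 0.6)), "at least 2")
})

null_manifest <- function(n = 3) {
  data.frame(sample_id = c(paste0("KD_", 1:n), paste0("CTRL_", 1:n)),
             group = rep(c("KD", "CTRL"), each = n),
             stringsAsFactors = FALSE)
}

test_that("RASE calling applies the joint effect-size and p-value rule", {
  man <- null_manifest()
  ## planted change of 0.4 at depth 100, noise-free by construction
  mk <- function(eid, ra, rb) {
    data.frame(event_id = eid, sample_id = man$sample_id,
               as_reads = round(100 * c(ra, rb)),
               m_reads = 100 - round(100 * c(ra, rb)),
               ratio = c(ra, rb), stringsAsFactors = FALSE)
  }
  q <- rbind(mk("big", c(0.69, 0.70, 0.71), c(0.29, 0.30, 0.31)),
             mk("small", c(0.44, 0.45, 0.46), c(0.34, 0.35, 0.36)))
  res <- callRases(q, man, "KD", "CTRL")
  expect_true(res$significant[res$event_id == "big"])
  expect_equal(res$rase_ratio[res$event_id == "big"], 0.4)
  ## a 0.10 change stays below the 0.2 threshold regardless of p
  small <- res[res$event_id == "small", ]
  expect_lt(small$p_value, 0.05)
  expect_false(small$significant)
})

test_that("swapping group labels negates the effect and keeps p", {
  cfg <- simulationConfig(seed = 21)
  q <- simulateEventCounts(50, 0.7, 0.4, cfg)
  man <- null_manifest()
  suppressMessages({
    ab <- callRases(q, man, "KD", "CTRL", minSupport = 0)
    ba <- callRases(q, man, "CTRL", "KD", minSupport = 0)
  })
  expect_equal(ab$rase_ratio, -ba$rase_ratio)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
  expect_true(all(abs(ab$rase_ratio) <= 1, na.rm = TRUE))
  expect_true(all(q$ratio >= 0 & q$ratio <= 1, na.rm = TRUE))
})

test_that("support filtering and group validation behave as specified", {
  man <- null_manifest()
  low <- data.frame(event_id = "weak", sample_id = man$sample_id,
                    as_reads = c(2, 2, 2, 1, 1, 1),
                    m_reads = c(3, 3, 3, 4, 4, 4),
                    ratio = c(0.4, 0.4, 0.4, 0.2, 0.2, 0.2),
                    stringsAsFactors = FALSE)
  expect_message(res <- callRases(low, man, "KD", "CTRL"), "support")
  expect_equal(nrow(res), 0L)
  expect_error(callRases(low, man, "KD", "nope"), "unknown group")
})

test_that("events with too few defined ratios are reported untested", {
  man <- null_manifest()
  q <- data.frame(event_id = "E", sample_id = man$sample_id,
                  as_reads = c(50, 0, 0, 40, 40, 40),
                  m_reads = c(50, 0, 0, 60, 60, 60),
                  stringsAsFactors = FALSE)
  q$ratio <- asRatio(q$as_reads, q$m_reads)
  res <- callRases(q, man, "KD", "CTRL", minSupport = 0)
  expect_false(res$tested)
  expect_false(res$significant)
  expect_match(res$reason, "minimum defined ratios")
})
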