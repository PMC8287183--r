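toy_se <- function() {
  counts <- matrix(c(100, 0, 50, 200), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  makeExpressionMatrix(counts, geneLengths = c(gA = 1000, gB = 2000),
                       totalFragments = c(s1 = 1e6, s2 = 2e6))
}

test_that("FPKM and CPM follow their closed forms", {
  se <- toy_se()
  f <- fpkm(se)
  expect_equal(f["gA", "s1"], 100)        # 100 reads, 1 kb, 1e6 total
  expect_equal(f["gB", "s1"], 0)
  c_ <- cpm(se)
  expect_equal(c_["gA", "s1"], 100)
  expect_equal(c_["gA", "s2"], 25)
  ## homogeneity of degree -1 in library size
  se2 <- makeExpressionMatrix(SummarizedExperiment::assay(se),
                              geneLengths = c(gA = 1000, gB = 2000),
                              totalFragments = c(s1 = 2e6, s2 = 4e6))
  expect_equal(cpm(se2), cpm(se) / 2)
  expect_equal(fpkm(se2), fpkm(se) / 2)
})

test_that("FPKM conservation identity recovers column count sums", {
  set.seed(31)
  counts <- matrix(rpois(300, 40), 30, 10,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%02d", 1:10)))
  lens <- setNames(round(runif(30, 300, 4000)), rownames(counts))
  tot <- setNames(colSums(counts), colnames(counts))
  se <- makeExpressionMatrix(counts, lens, tot)
  f <- fpkm(se)
  recovered <- colSums(f * lens / 1e3) * tot / 1e6
  expect_equal(unname(recovered), unname(colSums(counts)))
})

test_that("missing lengths and degenerate totals are rejected", {
  counts <- matrix(c(1, 2, 0, 0), 2, 2,
                   dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(makeExpressionMatrix(counts), "s2")   # all-zero column
  se <- makeExpressionMatrix(counts, totalFragments = c(s1 = 10, s2 = 10))
  expect_error(fpkm(se), "gA")
})

test_that("the stand-in DEG caller recovers planted fold changes", {
  cfg <- simulationConfig(seed = 32, depthMean = 100)
  ex <- simulateExpression(cfg)
  se <- makeExpressionMatrix(ex$counts, ex$geneLengths)
  res <- callDegs(se, ex$manifest, "KD", "CTRL")
  de <- res[res$gene_id %in% ex$truth$de_genes, ]
  ## three replicates cap the attainable significance; most but not
  ## necessarily all planted genes clear the FDR threshold
  expect_gte(mean(de$status == "up"), 0.8)
  expect_true(all(de$log2_fold_change > 1))
  ## null genes mostly stay unflagged
  null <- res[grepl("^GENE", res$gene_id), ]
  expect_lt(mean(null$status != "ns"), 0.05)
  ## the knocked-down anchor loses expression (the latent coexpression
  ## signal adds replicate noise on top of the planted 70 percent loss)
  expect_lt(res$log2_fold_change[res$gene_id == "KRT18"], -0.5)
})

test_that("group swap inverts fold changes and preserves p-values", {
  cfg <- simulationConfig(seed = 33)
  ex <- simulateExpression(cfg)
  se <- makeExpressionMatrix(ex$counts, ex$geneLengths)
  ab <- callDegs(se, ex$manifest, "KD", "CTRL")
  ba <- callDegs(se, ex$manifest, "CTRL", "KD")
  expect_equal(ab$log2_fold_change, -ba$log2_fold_change)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("threshold relaxation yields nested up-gene sets", {
  cfg <- simulationConfig(seed = 34)
  ex <- simulateExpression(cfg)
  se <- makeExpressionMatrix(ex$counts, ex$geneLengths)
  strict <- callDegs(se, ex$manifest, "KD", "CTRL",
                     upFc = 2, downFc = 0.5, alpha = 0.01, useFdr = FALSE)
  lax <- callDegs(se, ex$manifest, "KD", "CTRL",
                  upFc = 1.5, downFc = 0.67, alpha = 0.05, useFdr = FALSE)
  expect_true(all(strict$gene_id[strict$status == "up"] %in%
                    lax$gene_id[lax$status == "up"]))
})

test_that("constant genes give fold change 1 and status ns", {
  counts <- matrix(50, 2, 6,
                   dimnames = list(c("flat1", "flat2"), paste0("s", 1:6)))
  counts[2, ] <- c(10, 12, 11, 90, 95, 100)   # keeps library sizes unequal
  man <- data.frame(sample_id = paste0("s", 1:6),
                    group = rep(c("A", "B"), each = 3))
  se <- makeExpressionMatrix(counts,
                             totalFragments = setNames(rep(1e5, 6),
                                                       colnames(counts)))
  res <- callDegs(se, man, "A", "B")
  flat <- res[res$gene_id == "flat1", ]
  expect_equal(flat$log2_fold_change, 0)
  expect_equal(flat$status, "ns")
})

test_that("BH adjustment equals the literal step-up rule", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(rep(0.5, 4)), rep(0.5, 4))
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(35)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFdr(p), bh_oracle(p))
  }
})

test_that("2^-ddCT quantification matches its closed form", {
  expect_equal(ddctFoldChange(20, 20, 20, 20), 1)
  expect_equal(ddctFoldChange(23, 20, 22, 20), 0.5)    # ddCT = 1
  expect_equal(ddctFoldChange(20, 20, 22, 20), 4)      # ddCT = -2
  expect_error(ddctFoldChange(numeric(), 20, 22, 20), "targetCase")
  cfg <- simulationConfig(seed = 36)
  ex <- simulateExpression(cfg)
  fold <- do.call(ddctFoldChange, ex$ct)
  expect_equal(fold, 0.3, tolerance = 0.1)     # planted 70 percent knockdown
})
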