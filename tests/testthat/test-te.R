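test_that("median-of-ratios size factors match the formula oracle and DESeq2", {
  set.seed(21)
  counts <- matrix(rnbinom(500 * 8, mu = 200, size = 10), nrow = 500)
  rownames(counts) <- sprintf("g%03d", 1:500)
  sheet <- data.frame(
    sample_id = paste0("s", 1:8),
    strain = rep(c("WT", "ntd-del"), each = 4),
    condition = rep(c("SD", "urea"), times = 4),
    assay = rep(c("RNA", "Ribo"), each = 2, times = 2),
    replicate = 1L
  )
  colnames(counts) <- sheet$sample_id
  rce <- normalizeCounts(RiboCountExperiment(counts, sheet))
  sf <- sizeFactors(rce)
  expect_equal(unname(sf), unname(sizeFactorOracle(counts)), tolerance = 1e-12)
  # independent cross-check against the reference implementation
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-12)
  expect_equal(SummarizedExperiment::assay(rce, "normalized"),
               sweep(counts, 2, sf, "/"), tolerance = 1e-12)
})

test_that("identical columns give unit size factors; cpm scales to 1e6", {
  counts <- matrix(rep(c(10L, 50L, 200L, 1000L), 8), ncol = 8)
  rownames(counts) <- paste0("g", 1:4)
  sheet <- data.frame(sample_id = paste0("s", 1:8), strain = "WT",
                      condition = "SD", assay = "RNA", replicate = 1:8)
  colnames(counts) <- sheet$sample_id
  rce <- RiboCountExperiment(counts, sheet)
  expect_equal(unname(sizeFactors(normalizeCounts(rce))), rep(1, 8))
  cpm <- normalizeCounts(rce, method = "cpm")
  expect_equal(unname(colSums(SummarizedExperiment::assay(cpm, "normalized"))),
               rep(1e6, 8))
})

test_that("scaling one sample moves size factors as the model predicts", {
  set.seed(31)
  counts <- matrix(rnbinom(300 * 8, mu = 150, size = 8) + 1L, nrow = 300)
  rownames(counts) <- paste0("g", 1:300)
  sheet <- data.frame(sample_id = paste0("s", 1:8), strain = "WT",
                      condition = "SD", assay = "RNA", replicate = 1:8)
  colnames(counts) <- sheet$sample_id
  sf1 <- sizeFactors(normalizeCounts(RiboCountExperiment(counts, sheet)))
  doubled <- counts
  doubled[, 3] <- 2L * doubled[, 3]
  sf2 <- sizeFactors(normalizeCounts(RiboCountExperiment(doubled, sheet)))
  # the doubled sample's size factor doubles relative to every other sample
  expect_equal(unname(sf2[3] / sf2[-3]), unname(2 * sf1[3] / sf1[-3]),
               tolerance = 1e-9)
  # under cpm the doubled column's size factor doubles, others are unchanged
  cf1 <- sizeFactors(normalizeCounts(RiboCountExperiment(counts, sheet), "cpm"))
  cf2 <- sizeFactors(normalizeCounts(RiboCountExperiment(doubled, sheet), "cpm"))
  expect_equal(unname(cf2[3]), unname(2 * cf1[3]), tolerance = 1e-12)
  expect_equal(unname(cf2[-3]), unname(cf1[-3]), tolerance = 1e-12)
})

test_that("median-of-ratios refuses an all-zero-overlap matrix", {
  counts <- rbind(c(5L, 0L), c(0L, 7L))
  rownames(counts) <- c("g1", "g2")
  sheet <- data.frame(sample_id = c("s1", "s2"), strain = "WT",
                      condition = "SD", assay = "RNA", replicate = 1:2)
  colnames(counts) <- sheet$sample_id
  rce <- RiboCountExperiment(counts, sheet)
  expect_error(normalizeCounts(rce), "cpm")
})

test_that("TE is the ratio of mean normalized Ribo to RNA with a pseudocount", {
  # 5 test genes, hand-computed: equal columns so size factors are 1
  rna <- c(100, 200, 0, 50, 400)
  ribo <- c(100, 100, 30, 200, 100)
  counts <- cellCounts(list(WT_SD_RNA = rna, WT_SD_Ribo = ribo), nGenes = 5)
  rce <- normalizeCounts(toyExperiment(counts))
  te <- computeTE(rce, "WT", "SD", pseudocount = 0.5)
  idx <- grep("^x", names(te))
  expect_equal(unname(te[idx]), (ribo + 0.5) / (rna + 0.5), tolerance = 1e-9)
  # Ribo = RNA exactly -> TE = 1 everywhere
  same <- cellCounts(list(), nGenes = 3)
  teSame <- computeTE(normalizeCounts(toyExperiment(same)), "WT", "urea")
  expect_equal(unname(teSame), rep(1, length(teSame)))
  # zero RNA mean forces TE = (m + c) / c
  expect_equal(unname(te[idx][3]), (30 + 0.5) / 0.5, tolerance = 1e-9)
})

test_that("contrasts recover planted fold-changes and the TE identity", {
  # plant a 2x TE increase (Ribo doubles, RNA flat) in WT urea vs SD
  counts <- cellCounts(list(WT_SD_Ribo = rep(120, 4),
                            WT_urea_Ribo = rep(240, 4)), nGenes = 4)
  rce <- normalizeCounts(toyExperiment(counts))
  ct <- teContrast(rce, list(strain = "WT", condition = "urea"),
                   list(strain = "WT", condition = "SD"))
  tab <- contrastTable(ct)
  idx <- grepl("^x", tab$gene_id)
  expect_equal(tab$log2FC_te[idx], rep(1, 4), tolerance = 1e-9)
  expect_equal(tab$log2FC_rna[idx], rep(0, 4), tolerance = 1e-9)
  # identical cells -> all zero
  ct0 <- teContrast(rce, list(strain = "ntd-del", condition = "urea"),
                    list(strain = "ntd-del", condition = "SD"))
  expect_equal(max(abs(contrastTable(ct0)$log2FC_te), na.rm = TRUE), 0,
               tolerance = 1e-9)
  # algebraic identity, exact
  m <- tab$measurable
  expect_identical(tab$log2FC_te[m], tab$log2FC_ribo[m] - tab$log2FC_rna[m])
  expect_error(
    teContrast(rce, list(strain = "WT", condition = "caffeine"),
               list(strain = "WT", condition = "SD")),
    "missing samples"
  )
})

test_that("measurability requires minCount summed raw counts in all four cells", {
  counts <- cellCounts(list(WT_SD_RNA = c(9, 10, 100),
                            WT_urea_RNA = c(100, 100, 4)), nGenes = 3)
  rce <- normalizeCounts(toyExperiment(counts), method = "cpm")
  ct <- teContrast(rce, list(strain = "WT", condition = "urea"),
                   list(strain = "WT", condition = "SD"), minCount = 10)
  tab <- contrastTable(ct)
  x <- tab[grepl("^x", tab$gene_id), ]
  expect_identical(x$measurable, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(x$log2FC_te[!x$measurable])))
  expect_setequal(measurableGenes(ct),
                  tab$gene_id[tab$measurable])
})

test_that("fold-change sets honor the inclusive 1.5-fold boundary", {
  # TE ratios exactly 1.5, 1.49, 1/1.5 via Ribo counts, RNA flat
  counts <- cellCounts(list(WT_SD_Ribo = c(100, 100, 150),
                            WT_urea_Ribo = c(150, 149, 100)), nGenes = 3)
  rce <- normalizeCounts(toyExperiment(counts))
  ct <- teContrast(rce, list(strain = "WT", condition = "urea"),
                   list(strain = "WT", condition = "SD"))
  sets <- classifySets(ct, tau = 1.5)
  expect_true("x001" %in% members(sets$te_up))     # exactly 1.5
  expect_false("x002" %in% members(sets$te_up))    # 1.49
  expect_false("x002" %in% members(sets$te_down))
  expect_true("x003" %in% members(sets$te_down))   # exactly 1/1.5
  # up and down sets are disjoint for every assay
  for (a in c("rna", "ribo", "te")) {
    expect_length(intersect(members(sets[[paste0(a, "_up")]]),
                            members(sets[[paste0(a, "_down")]])), 0)
  }
  expect_error(classifySets(ct, tau = 1), "tau > 1")
})

test_that("contrast correlation runs over jointly measurable genes", {
  sim <- simulateExperiment(simulationConfig(nGenes = 400, librarySize = 2e5,
                                             seed = 17))
  norm <- normalizeCounts(sim$experiment)
  a <- teContrast(norm, list(strain = "WT", condition = "urea"),
                  list(strain = "WT", condition = "SD"))
  b <- teContrast(norm, list(strain = "ntd-del", condition = "urea"),
                  list(strain = "ntd-del", condition = "SD"))
  cr <- correlateContrasts(a, b, field = "te")
  expect_true(abs(cr$r) <= 1)
  expect_equal(cr$n, length(intersect(measurableGenes(a), measurableGenes(b))))
  # identical contrasts give r = 1; a negated field gives r = -1
  expect_equal(correlateContrasts(a, a, field = "te")$r, 1, tolerance = 1e-12)
  bNeg <- b
  bNeg@table$log2FC_te <- -a@table$log2FC_te
  bNeg@table$log2FC_ribo <- bNeg@table$log2FC_te + bNeg@table$log2FC_rna
  expect_equal(correlateContrasts(a, bNeg, field = "te")$r, -1, tolerance = 1e-12)
})
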