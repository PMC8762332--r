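# Independent oracles and fixture builders used across the suite.

# Random transcript fixtures with a mix of 5'UTR lengths (including 0 and
# sub-window lengths) and variable CDS coverage.
randomTranscriptSet <- function(n, seed, maxUtr = 80, coveredCds = NULL) {
  set.seed(seed)
  utr <- sample(c(0L, 1L, 5L, 14L, 15L, 29L, 30L, sample.int(maxUtr, n, replace = TRUE)),
                n, replace = TRUE)
  covered <- if (is.null(coveredCds)) {
    sample(c(0L, 14L, 15L, 40L, 90L), n, replace = TRUE)
  } else {
    rep(as.integer(coveredCds), n)
  }
  ids <- sprintf("t%04d", seq_len(n))
  scores <- lapply(seq_len(n), function(i) stats::rnorm(utr[i] + covered[i]))
  TranscriptSet(ids, utr, rep(300L, n), scores)
}

# Brute-force window summation oracle: positions laid out explicitly as
# signed coordinates, window membership checked per position. Window
# extents restated independently from their printed definitions.
bruteWindowSum <- function(scores, utr5Len, window) {
  covered <- length(scores) - utr5Len
  pos <- c(if (utr5Len > 0) seq(-utr5Len, -1L) else integer(),
           if (covered > 0) seq_len(covered) else integer())
  range <- switch(window,
    total5utr = if (utr5Len >= 1) c(-utr5Len, -1) else return(NA_real_),
    first30 = if (utr5Len >= 30) c(-utr5Len, -utr5Len + 29) else return(NA_real_),
    start30 = if (utr5Len >= 15 && covered >= 15) c(-15, 15) else return(NA_real_),
    plus15 = if (covered >= 30) c(1, 30) else return(NA_real_),
    plus30 = if (covered >= 45) c(16, 45) else return(NA_real_),
    plus45 = if (covered >= 60) c(31, 60) else return(NA_real_),
    plus60 = if (covered >= 75) c(46, 75) else return(NA_real_),
    plus75 = if (covered >= 90) c(61, 90) else return(NA_real_)
  )
  sum(scores[pos >= range[1] & pos <= range[2]])
}

allWindowNames <- c("total5utr", "first30", "start30",
                    "plus15", "plus30", "plus45", "plus60", "plus75")

# Closed-form pooled-variance Student t oracle.
studentTOracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * stats::pt(-abs(t), df = na + nb - 2))
}

# Exhaustive hypergeometric enumeration oracle for Fisher's exact test,
# built on lchoose (not dhyper) so it shares no code with the package.
fisherEnumOracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  lo <- max(0L, K + n - N); hi <- min(K, n)
  x <- lo:hi
  probs <- exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n))
  pObs <- probs[x == a]
  list(
    twoSided = min(1, sum(probs[probs <= pObs * (1 + 1e-7)])),
    enrich = min(1, sum(probs[x >= a]))
  )
}

# Median-of-ratios formula oracle, written straight from the definition.
# The median of an even number of ratios averages the two middle values
# geometrically (the log-scale convention of the reference implementation).
sizeFactorOracle <- function(counts) {
  geo <- exp(rowMeans(log(counts)))
  apply(counts, 2, function(col) {
    r <- sort((col / geo)[geo > 0 & col > 0])
    m <- length(r)
    if (m %% 2 == 1) r[(m + 1) / 2] else sqrt(r[m / 2] * r[m / 2 + 1])
  })
}

# Small deterministic count experiment: 2 strains x 2 conditions x 2
# assays x `reps` replicates, filler genes keep size factors at 1.
toyExperiment <- function(testCounts, reps = 1, nFiller = 50, fillerSeed = 11) {
  set.seed(fillerSeed)
  filler <- matrix(rep(sample(50:500, nFiller), times = 8 * reps),
                   nrow = nFiller)
  counts <- rbind(filler, testCounts)
  rownames(counts) <- c(sprintf("f%03d", seq_len(nFiller)),
                        sprintf("x%03d", seq_len(nrow(testCounts))))
  sheet <- expand.grid(
    replicate = seq_len(reps), assay = c("RNA", "Ribo"),
    condition = c("SD", "urea"), strain = c("WT", "ntd-del"),
    stringsAsFactors = FALSE
  )
  sheet$sample_id <- with(sheet, paste(strain, condition, assay, replicate, sep = "_"))
  colnames(counts) <- sheet$sample_id
  RiboCountExperiment(counts, sheet[, c("sample_id", "strain", "condition",
                                        "assay", "replicate")])
}

# Expand a named per-cell count spec into the 8 x reps column layout of
# toyExperiment. `spec` maps "strain_condition_assay" to a vector of
# per-gene counts (recycled across replicates).
cellCounts <- function(spec, nGenes, reps = 1, default = 100) {
  sheet <- expand.grid(
    replicate = seq_len(reps), assay = c("RNA", "Ribo"),
    condition = c("SD", "urea"), strain = c("WT", "ntd-del"),
    stringsAsFactors = FALSE
  )
  mat <- matrix(default, nrow = nGenes, ncol = nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    key <- paste(sheet$strain[j], sheet$condition[j], sheet$assay[j], sep = "_")
    if (key %in% names(spec)) mat[, j] <- spec[[key]]
  }
  mat
}
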