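#' Build a SimulationConfig
#'
#' Defaults emulate a desk-scale factorial ribosome-profiling study in
#' yeast: two strains (WT and an initiation-factor NTD deletion), two
#' conditions (SD medium with or without 3% urea), RNA and Ribo assays,
#' two independent cultures per cell — 16 libraries in the default design.
#' Two gene classes are planted: "membrane-like" genes have longer, more
#' structured 5'UTRs and a WT-specific TE boost under urea;
#' "cytoplasmic-like" genes have shorter, less structured 5'UTRs (and
#' slightly more structured CDS). The mutant strain carries a log2-TE
#' penalty of `betaStructureTE` per standard deviation of the cumulative
#' 5'UTR structure score, coupling translation to 5'UTR structure.
#'
#' @param nGenes number of genes (default 4000).
#' @param replicates biological replicates per cell (default 2).
#' @param librarySize expected reads per library (default 5e6).
#' @param nbDispersion NB dispersion, variance = mu + mu^2 * disp
#'   (default 0.05).
#' @param fracMembraneLike fraction of membrane-like genes (default 0.2).
#' @param utrLenLogmeanByClass named (per class) log-mean of the log-normal
#'   5'UTR length model (defaults log(90) membrane-like, log(60)
#'   cytoplasmic-like).
#' @param utrLenLogsd log-sd of 5'UTR lengths (default 0.6).
#' @param parsMean5utrByClass,parsMeanCdsByClass named per-class means of
#'   the per-nucleotide structure score (defaults 0.3 / -0.2 in the 5'UTR,
#'   0.0 / 0.2 in the CDS).
#' @param parsSd per-nucleotide score SD (default 1).
#' @param cdsLen CDS length in nt (default 300; tracks cover the first 90).
#' @param betaStructureTE mutant log2-TE penalty per SD of cumulative
#'   5'UTR score (default 0.4).
#' @param ureaTeBoostMembraneWT log2-TE boost for membrane-like genes in
#'   WT urea samples (default 1).
#' @param seed RNG seed (default 1).
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 4000,
                             replicates = 2,
                             librarySize = 5e6,
                             nbDispersion = 0.05,
                             fracMembraneLike = 0.2,
                             utrLenLogmeanByClass = c(
                               "membrane-like" = log(90),
                               "cytoplasmic-like" = log(60)
                             ),
                             utrLenLogsd = 0.6,
                             parsMean5utrByClass = c(
                               "membrane-like" = 0.3,
                               "cytoplasmic-like" = -0.2
                             ),
                             parsMeanCdsByClass = c(
                               "membrane-like" = 0.0,
                               "cytoplasmic-like" = 0.2
                             ),
                             parsSd = 1,
                             cdsLen = 300,
                             betaStructureTE = 0.4,
                             ureaTeBoostMembraneWT = 1,
                             seed = 1) {
  methods::new("SimulationConfig",
    nGenes = as.integer(nGenes),
    replicates = as.integer(replicates),
    librarySize = as.numeric(librarySize),
    nbDispersion = as.numeric(nbDispersion),
    fracMembraneLike = as.numeric(fracMembraneLike),
    utrLenLogmeanByClass = utrLenLogmeanByClass,
    utrLenLogsd = as.numeric(utrLenLogsd),
    parsMean5utrByClass = parsMean5utrByClass,
    parsMeanCdsByClass = parsMeanCdsByClass,
    parsSd = as.numeric(parsSd),
    cdsLen = as.integer(cdsLen),
    betaStructureTE = as.numeric(betaStructureTE),
    ureaTeBoostMembraneWT = as.numeric(ureaTeBoostMembraneWT),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %d genes, %d replicates/cell, library size %.3g\n",
           "  NB dispersion %.3g, membrane-like fraction %.2f\n",
           "  beta(structure->TE) = %.3g, WT urea membrane boost = %.3g log2\n",
           "  seed %d\n"),
    object@nGenes, object@replicates, object@librarySize,
    object@nbDispersion, object@fracMembraneLike,
    object@betaStructureTE, object@ureaTeBoostMembraneWT, object@seed
  ))
})

# stream-separated derived seeds, kept inside 32-bit range
.derivedSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 99991 * offset) %% 2147483647)
}

.geneIds <- function(n) {
  paste0("gene", formatC(seq_len(n), width = nchar(n), flag = "0"))
}

# covered CDS nucleotides in the score track
.coveredCds <- function(config) min(90L, config@cdsLen)

#' Generate transcript annotation with structure-score tracks
#'
#' Draws, per gene: a class label (membrane-like with probability
#' `fracMembraneLike`), a 5'UTR length (log-normal by class, rounded,
#' floor 1 nt), a fixed CDS length, and per-nucleotide structure scores
#' (normal, class-specific means for 5'UTR vs CDS positions, common SD).
#' Tracks cover the 5'UTR plus the first 90 CDS nt — every window the
#' downstream analysis uses.
#'
#' @param config a [SimulationConfig-class].
#' @return List with `transcripts` (a [TranscriptSet-class]) and `classes`
#'   (named character vector of class labels).
#' @export
generateAnnotation <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  set.seed(.derivedSeed(config@seed, 1L))
  n <- config@nGenes
  ids <- .geneIds(n)
  nMem <- round(config@fracMembraneLike * n)
  classes <- rep("cytoplasmic-like", n)
  classes[sample.int(n, nMem)] <- "membrane-like"
  names(classes) <- ids

  utrLen <- pmax(1L, as.integer(round(stats::rlnorm(
    n,
    meanlog = config@utrLenLogmeanByClass[classes],
    sdlog = config@utrLenLogsd
  ))))
  covered <- .coveredCds(config)
  scores <- lapply(seq_len(n), function(i) {
    mu <- c(rep(config@parsMean5utrByClass[[classes[i]]], utrLen[i]),
            rep(config@parsMeanCdsByClass[[classes[i]]], covered))
    stats::rnorm(utrLen[i] + covered, mean = mu, sd = config@parsSd)
  })
  list(
    transcripts = TranscriptSet(ids, utrLen, rep(config@cdsLen, n), scores),
    classes = classes
  )
}

# per-gene log2 TE for each strain x condition, from the planted model
.planTE <- function(config, annotation, baseLog2TE) {
  total5utr <- cumulativeScore(annotation$transcripts, "total5utr")
  z <- if (stats::sd(total5utr) > 0) {
    (total5utr - mean(total5utr)) / stats::sd(total5utr)
  } else {
    rep(0, length(total5utr))
  }
  mem <- annotation$classes == "membrane-like"
  log2te <- list(
    WT_SD = baseLog2TE,
    WT_urea = baseLog2TE + config@ureaTeBoostMembraneWT * mem,
    `ntd-del_SD` = baseLog2TE - config@betaStructureTE * z,
    `ntd-del_urea` = baseLog2TE - config@betaStructureTE * z
  )
  list(log2te = log2te, z = z)
}

#' Generate paired Ribo/RNA count matrices with planted TE effects
#'
#' Per gene, a baseline mRNA abundance is drawn log-normally; RNA counts
#' are negative binomial with mean proportional to abundance and library
#' size, and Ribo counts are negative binomial with mean proportional to
#' the RNA mean times the cell's TE. log2 TE is a gene-level baseline,
#' minus `betaStructureTE` times the standardized cumulative 5'UTR
#' structure score in the mutant strain, plus `ureaTeBoostMembraneWT` for
#' membrane-like genes in WT urea samples. Each library's expected counts
#' are rescaled to sum to `librarySize` (sequencing depth is fixed by
#' design; the per-library factor is absorbed by normalization, so planted
#' log2-TE contrasts are preserved).
#'
#' The default design emits 2 strains x 2 conditions x 2 assays x 2
#' replicates = 16 libraries.
#'
#' @param config the [SimulationConfig-class] used for the annotation.
#' @param annotation result of [generateAnnotation()] under `config`.
#' @return List with `experiment` (a [RiboCountExperiment-class]) and
#'   `truth` (data.frame: class, baseline TE per strain x condition, and
#'   true log2-TE responses for the four standard contrasts).
#' @export
generateCounts <- function(config, annotation) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  if (!is.list(annotation) ||
      !methods::is(annotation$transcripts, "TranscriptSet") ||
      length(annotation$transcripts) != config@nGenes) {
    stop("'annotation' does not match 'config': run generateAnnotation(config)")
  }
  set.seed(.derivedSeed(config@seed, 2L))
  n <- config@nGenes
  ids <- geneIds(annotation$transcripts)

  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  rel <- abundance / sum(abundance)
  baseLog2TE <- stats::rnorm(n, 0, 0.25)
  plan <- .planTE(config, annotation, baseLog2TE)

  strains <- c("WT", "ntd-del")
  conditions <- c("SD", "urea")
  reps <- seq_len(config@replicates)
  size <- 1 / config@nbDispersion

  sheet <- expand.grid(
    replicate = reps, assay = c("RNA", "Ribo"),
    condition = conditions, strain = strains,
    stringsAsFactors = FALSE
  )
  sheet$sample_id <- with(sheet, paste(strain, condition, assay, replicate, sep = "_"))
  sheet <- sheet[, c("sample_id", "strain", "condition", "assay", "replicate")]

  counts <- matrix(0L, nrow = n, ncol = nrow(sheet),
                   dimnames = list(ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    cell <- paste(sheet$strain[j], sheet$condition[j], sep = "_")
    mu <- if (sheet$assay[j] == "RNA") {
      rel
    } else {
      rel * 2^plan$log2te[[cell]]
    }
    mu <- mu / sum(mu) * config@librarySize
    counts[, j] <- as.integer(stats::rnbinom(n, mu = mu, size = size))
  }

  truth <- data.frame(
    gene_id = ids,
    class = unname(annotation$classes),
    te_WT_SD = 2^plan$log2te$WT_SD,
    te_WT_urea = 2^plan$log2te$WT_urea,
    te_ntd_SD = 2^plan$log2te$`ntd-del_SD`,
    te_ntd_urea = 2^plan$log2te$`ntd-del_urea`,
    lfc_te_ntd_vs_wt_sd = plan$log2te$`ntd-del_SD` - plan$log2te$WT_SD,
    lfc_te_ntd_vs_wt_urea = plan$log2te$`ntd-del_urea` - plan$log2te$WT_urea,
    lfc_te_urea_vs_sd_wt = plan$log2te$WT_urea - plan$log2te$WT_SD,
    lfc_te_urea_vs_sd_ntd = plan$log2te$`ntd-del_urea` - plan$log2te$`ntd-del_SD`,
    stringsAsFactors = FALSE
  )

  list(
    experiment = RiboCountExperiment(counts, sheet),
    truth = truth
  )
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: annotation + counts + the class term map (a
#' GMT-style list with one term per planted class) under one config.
#'
#' @param config a [SimulationConfig-class].
#' @return List with `transcripts`, `classes`, `experiment`, `truth`,
#'   `termMap`.
#' @examples
#' sim <- simulateExperiment(simulationConfig(nGenes = 200, librarySize = 1e5))
#' sim$experiment
#' @export
simulateExperiment <- function(config) {
  ann <- generateAnnotation(config)
  cnt <- generateCounts(config, ann)
  classes <- ann$classes
  termMap <- split(names(classes), classes)
  list(
    transcripts = ann$transcripts,
    classes = classes,
    experiment = cnt$experiment,
    truth = cnt$truth,
    termMap = termMap
  )
}

#' Write a simulated experiment as a TSV bundle
#'
#' Writes `annotation.tsv`, `counts.tsv`, `samples.tsv`, `truth.tsv`,
#' `classes.tsv` (gene_id, class) and `classes.gmt` into a directory.
#' Identical config + seed produces byte-identical files.
#'
#' @param sim result of [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
writeSimulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    annotation = file.path(dir, "annotation.tsv"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    truth = file.path(dir, "truth.tsv"),
    classes = file.path(dir, "classes.tsv"),
    gmt = file.path(dir, "classes.gmt")
  )
  writeAnnotation(sim$transcripts, paths["annotation"])
  writeCountExperiment(sim$experiment, paths["counts"], paths["samples"])
  .writeTsv(sim$truth, paths["truth"])
  .writeTsv(
    data.frame(gene_id = names(sim$classes), class = unname(sim$classes),
               stringsAsFactors = FALSE),
    paths["classes"]
  )
  writeGmt(sim$termMap, paths["gmt"])
  invisible(paths)
}
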