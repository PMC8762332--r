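#' TranscriptSet: transcript models with per-nucleotide structure scores
#'
#' Holds, for a collection of transcripts, the 5'UTR and CDS lengths and an
#' ordered per-nucleotide structure-score track (e.g. PARS scores; higher =
#' more double-stranded) covering the 5'UTR followed by the first covered CDS
#' nucleotides (5' to 3').
#'
#' @slot geneId character vector of unique gene identifiers.
#' @slot utr5Len integer vector, 5'UTR length in nucleotides (>= 0).
#' @slot cdsLen integer vector, CDS length in nucleotides (>= 0).
#' @slot scores [IRanges::NumericList] of per-nucleotide scores; element
#'   length is \code{utr5Len + min(cdsLen, covered CDS nt)}.
#'
#' @seealso [TranscriptSet()], [windowScoreTable()], [cumulativeScore()]
#' @exportClass TranscriptSet
setClass("TranscriptSet",
  representation(
    geneId = "character",
    utr5Len = "integer",
    cdsLen = "integer",
    scores = "NumericList"
  )
)

setValidity("TranscriptSet", function(object) {
  msg <- character()
  n <- length(object@geneId)
  if (anyDuplicated(object@geneId)) {
    msg <- c(msg, "gene ids must be unique")
  }
  if (length(object@utr5Len) != n || length(object@cdsLen) != n ||
      length(object@scores) != n) {
    msg <- c(msg, "geneId, utr5Len, cdsLen and scores must have equal length")
  } else {
    if (any(object@utr5Len < 0L) || any(object@cdsLen < 0L)) {
      msg <- c(msg, "utr5Len and cdsLen must be non-negative")
    }
    len <- lengths(object@scores)
    # track covers 5'UTR plus at most the CDS
    bad <- len < object@utr5Len | len > object@utr5Len + object@cdsLen
    if (any(bad)) {
      msg <- c(msg, sprintf(
        "score track length must lie in [utr5Len, utr5Len + cdsLen] (%d offending gene(s), first: %s)",
        sum(bad), object@geneId[which(bad)[1L]]
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' RiboCountExperiment: paired Ribo-seq/RNA-seq counts with factorial design
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose `colData` carries the
#' factorial sample sheet (`strain`, `condition`, `assay`, `replicate`) and,
#' after [normalizeCounts()], per-sample `sizeFactor`s. The `"counts"` assay
#' holds non-negative integer counts; normalization adds a `"normalized"`
#' assay.
#'
#' @seealso [RiboCountExperiment()], [normalizeCounts()], [teContrast()]
#' @exportClass RiboCountExperiment
setClass("RiboCountExperiment",
  contains = "SummarizedExperiment"
)

setValidity("RiboCountExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  needed <- c("strain", "condition", "assay", "replicate")
  missing_cols <- setdiff(needed, colnames(cd))
  if (length(missing_cols)) {
    msg <- c(msg, paste0(
      "colData must contain columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "an assay named 'counts' is required")
  } else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
  }
  if ("sizeFactor" %in% colnames(cd)) {
    sf <- cd$sizeFactor
    if (any(!is.finite(sf)) || any(sf <= 0)) {
      msg <- c(msg, "size factors must be positive and finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ContrastResult: per-gene log2 fold-changes for one contrast
#'
#' Per-gene log2 fold-changes of RNA abundance, ribosome footprints, and TE
#' between two strain-by-condition cells, together with the measurability
#' flag. For every measurable gene the identity
#' `log2FC_te = log2FC_ribo - log2FC_rna` holds exactly; non-measurable genes
#' carry `NA` fold-changes.
#'
#' @slot label character scalar naming the contrast
#'   (e.g. `"urea_vs_sd.WT"`).
#' @slot numerator,denominator named character vectors with elements
#'   `strain` and `condition` defining the two cells.
#' @slot table a [S4Vectors::DataFrame] with columns `gene_id`,
#'   `log2FC_rna`, `log2FC_ribo`, `log2FC_te`, `measurable`.
#'
#' @seealso [teContrast()], [classifySets()], [correlateContrasts()]
#' @exportClass ContrastResult
setClass("ContrastResult",
  representation(
    label = "character",
    numerator = "character",
    denominator = "character",
    table = "DataFrame"
  )
)

setValidity("ContrastResult", function(object) {
  msg <- character()
  tab <- object@table
  needed <- c("gene_id", "log2FC_rna", "log2FC_ribo", "log2FC_te", "measurable")
  if (!all(needed %in% colnames(tab))) {
    msg <- c(msg, paste0("table must have columns ", paste(needed, collapse = ", ")))
  } else {
    m <- tab$measurable
    if (any(m)) {
      dev <- abs(tab$log2FC_te[m] - (tab$log2FC_ribo[m] - tab$log2FC_rna[m]))
      if (any(dev > 1e-9)) {
        msg <- c(msg, "log2FC_te must equal log2FC_ribo - log2FC_rna for measurable genes")
      }
    }
    if (any(!m) && any(!is.na(tab$log2FC_te[!m]))) {
      msg <- c(msg, "non-measurable genes must carry NA fold-changes")
    }
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(msg)) msg else TRUE
})

#' GeneSet: a direction-classified fold-change gene set
#'
#' @slot name character scalar.
#' @slot direction `"up"` or `"down"` (or `"none"` for rank-selected sets).
#' @slot assay `"rna"`, `"ribo"` or `"te"` (or `"metric"`).
#' @slot contrast contrast label this set derives from (may be `NA`).
#' @slot genes character vector of member gene ids.
#' @exportClass GeneSet
setClass("GeneSet",
  representation(
    name = "character",
    direction = "character",
    assay = "character",
    contrast = "character",
    genes = "character"
  )
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "member genes must be unique")
  if (!object@direction %in% c("up", "down", "none")) {
    msg <- c(msg, "direction must be 'up', 'down' or 'none'")
  }
  if (length(msg)) msg else TRUE
})

#' OverlapResult: 2x2 overlap contingency with Fisher's exact test
#'
#' @slot nUniverse,nA,nB,nOverlap non-negative integer counts.
#' @slot pctOfA,pctOfB percent of each set shared with the other.
#' @slot oddsRatio sample odds ratio (Haldane 0.5 correction when a cell is 0).
#' @slot pTwoSided two-sided Fisher p (minimum-likelihood summation).
#' @slot pEnrich one-sided (upper-tail, enrichment) p.
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    nUniverse = "integer",
    nA = "integer",
    nB = "integer",
    nOverlap = "integer",
    pctOfA = "numeric",
    pctOfB = "numeric",
    oddsRatio = "numeric",
    pTwoSided = "numeric",
    pEnrich = "numeric"
  )
)

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@nOverlap > min(object@nA, object@nB)) {
    msg <- c(msg, "overlap cannot exceed either set size")
  }
  if (object@nA + object@nB - object@nOverlap > object@nUniverse) {
    msg <- c(msg, "union cannot exceed the universe")
  }
  for (p in c(object@pTwoSided, object@pEnrich)) {
    if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "p values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' GroupComparison: unpaired two-group comparison (Student's t)
#'
#' @slot meanA,meanB group means.
#' @slot nA,nB group sizes after dropping missing values.
#' @slot t t statistic (NA on the degenerate equal-constant path).
#' @slot p two-sided p value.
#' @slot significant logical, `p < alpha`.
#' @slot alpha significance level (default 0.05).
#' @slot degenerate logical; TRUE when both groups are constant and equal.
#' @slot method `"student"` (pooled variance) or `"welch"`.
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(
    meanA = "numeric",
    meanB = "numeric",
    nA = "integer",
    nB = "integer",
    t = "numeric",
    p = "numeric",
    significant = "logical",
    alpha = "numeric",
    degenerate = "logical",
    method = "character"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@p) && (object@p < 0 || object@p > 1)) {
    msg <- c(msg, "p must lie in [0, 1]")
  }
  if (!is.na(object@p) && object@significant != (object@p < object@alpha)) {
    msg <- c(msg, "significance flag must equal p < alpha")
  }
  if (length(msg)) msg else TRUE
})

#' GradientTrace: a sucrose-gradient A254 absorbance trace
#'
#' @slot position strictly increasing gradient positions (arbitrary units).
#' @slot a254 absorbance at 254 nm at each position.
#' @exportClass GradientTrace
setClass("GradientTrace",
  representation(position = "numeric", a254 = "numeric")
)

setValidity("GradientTrace", function(object) {
  msg <- character()
  if (length(object@position) != length(object@a254)) {
    msg <- c(msg, "position and a254 must have equal length")
  }
  if (length(object@position) < 3L) {
    msg <- c(msg, "a trace needs at least 3 points")
  }
  if (length(object@position) >= 2L && any(diff(object@position) <= 0)) {
    msg <- c(msg, "positions must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' PMResult: polysome-to-monosome area quantification
#'
#' @slot monoArea,polyArea baseline-subtracted areas under the curve (>= 0).
#' @slot pmRatio polysome/monosome area ratio.
#' @exportClass PMResult
setClass("PMResult",
  representation(monoArea = "numeric", polyArea = "numeric", pmRatio = "numeric")
)

setValidity("PMResult", function(object) {
  msg <- character()
  if (object@monoArea < 0 || object@polyArea < 0) msg <- c(msg, "areas must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: study-design parameters for the synthetic generator
#'
#' Defines the factorial design (2 strains x 2 conditions x 2 assays x
#' replicates), the transcript-annotation model, and the planted
#' structure-coupled TE effects. Identical config + seed reproduces
#' byte-identical outputs.
#'
#' @slot nGenes number of genes.
#' @slot replicates biological replicates per cell (default 2; the default
#'   design emits 16 libraries).
#' @slot librarySize expected reads per library.
#' @slot nbDispersion negative-binomial dispersion (variance = mu + mu^2 * disp).
#' @slot fracMembraneLike fraction of genes in the membrane-like class.
#' @slot utrLenLogmeanByClass,utrLenLogsd log-normal 5'UTR length model per class.
#' @slot parsMean5utrByClass,parsMeanCdsByClass,parsSd per-nucleotide score model.
#' @slot betaStructureTE log2-TE penalty in the mutant strain per SD of
#'   standardized 5'UTR cumulative score.
#' @slot ureaTeBoostMembraneWT log2-TE boost for membrane-like genes in WT
#'   urea samples.
#' @slot seed integer RNG seed.
#' @seealso [simulationConfig()], [generateAnnotation()], [generateCounts()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    nGenes = "integer",
    replicates = "integer",
    librarySize = "numeric",
    nbDispersion = "numeric",
    fracMembraneLike = "numeric",
    utrLenLogmeanByClass = "numeric",
    utrLenLogsd = "numeric",
    parsMean5utrByClass = "numeric",
    parsMeanCdsByClass = "numeric",
    parsSd = "numeric",
    cdsLen = "integer",
    betaStructureTE = "numeric",
    ureaTeBoostMembraneWT = "numeric",
    seed = "integer"
  )
)

.simClasses <- c("membrane-like", "cytoplasmic-like")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkPos <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x <= 0) {
      sprintf("'%s' must be a single positive finite value", name)
    } else character()
  }
  msg <- c(msg,
    chkPos(object@nGenes, "nGenes"),
    chkPos(object@replicates, "replicates"),
    chkPos(object@librarySize, "librarySize"),
    chkPos(object@nbDispersion, "nbDispersion"),
    chkPos(object@utrLenLogsd, "utrLenLogsd"),
    chkPos(object@parsSd, "parsSd"),
    chkPos(object@cdsLen, "cdsLen")
  )
  if (length(object@fracMembraneLike) != 1L || is.na(object@fracMembraneLike) ||
      object@fracMembraneLike < 0 || object@fracMembraneLike > 1) {
    msg <- c(msg, "'fracMembraneLike' must lie in [0, 1]")
  }
  for (nm in c("utrLenLogmeanByClass", "parsMean5utrByClass", "parsMeanCdsByClass")) {
    v <- slot(object, nm)
    if (!all(.simClasses %in% names(v))) {
      msg <- c(msg, sprintf("'%s' must be named for classes: %s",
                            nm, paste(.simClasses, collapse = ", ")))
    }
  }
  if (object@cdsLen < 90L) {
    msg <- c(msg, "'cdsLen' must be >= 90 nt so that all CDS windows are covered")
  }
  if (length(msg)) msg else TRUE
})
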