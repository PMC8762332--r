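#' Construct a RiboCountExperiment
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames.
#' @param sampleSheet data.frame with one row per column of `counts` and
#'   columns `sample_id`, `strain`, `condition`, `assay` (values `"RNA"` /
#'   `"Ribo"`), `replicate`. Row order must match the count columns (matched
#'   by `sample_id` when column names are present).
#' @return A [RiboCountExperiment-class].
#' @export
RiboCountExperiment <- function(counts, sampleSheet) {
  counts <- as.matrix(counts)
  if (!"sample_id" %in% colnames(sampleSheet)) {
    stop("sample sheet must have a 'sample_id' column")
  }
  if (!is.null(colnames(counts))) {
    idx <- match(colnames(counts), sampleSheet$sample_id)
    if (anyNA(idx)) {
      stop("sample sheet does not cover count columns: ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    }
    sampleSheet <- sampleSheet[idx, , drop = FALSE]
  } else {
    if (nrow(sampleSheet) != ncol(counts)) {
      stop("sample sheet must have one row per count column")
    }
    colnames(counts) <- sampleSheet$sample_id
  }
  cd <- S4Vectors::DataFrame(sampleSheet, row.names = sampleSheet$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd
  )
  methods::new("RiboCountExperiment", se)
}

#' Read counts + sample sheet TSVs into a RiboCountExperiment
#'
#' The counts TSV has `gene_id` as its first column and one column per
#' library; the sample sheet TSV has columns `sample_id`, `strain`,
#' `condition`, `assay`, `replicate`.
#'
#' @param countsPath,samplesPath file paths.
#' @return A [RiboCountExperiment-class].
#' @export
readCountExperiment <- function(countsPath, samplesPath) {
  for (p in c(countsPath, samplesPath)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  tab <- utils::read.delim(countsPath, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(tab)[1L] != "gene_id") {
    stop("counts TSV must have 'gene_id' as its first column")
  }
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab$gene_id
  sheet <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  RiboCountExperiment(counts, sheet)
}

#' @param rce a [RiboCountExperiment-class].
#' @rdname readCountExperiment
#' @export
writeCountExperiment <- function(rce, countsPath, samplesPath) {
  cts <- SummarizedExperiment::assay(rce, "counts")
  df <- data.frame(gene_id = rownames(cts), cts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(df, countsPath)
  cd <- as.data.frame(SummarizedExperiment::colData(rce))
  keep <- intersect(c("sample_id", "strain", "condition", "assay", "replicate"),
                    colnames(cd))
  .writeTsv(cd[, keep, drop = FALSE], samplesPath)
  invisible(c(countsPath, samplesPath))
}

#' Size factors of a normalized RiboCountExperiment
#'
#' @param rce a [RiboCountExperiment-class] after [normalizeCounts()].
#' @return Named numeric vector of per-sample size factors.
#' @export
sizeFactors <- function(rce) {
  cd <- SummarizedExperiment::colData(rce)
  if (!"sizeFactor" %in% colnames(cd)) {
    stop("no size factors: run normalizeCounts() first")
  }
  stats::setNames(cd$sizeFactor, rownames(cd))
}

# median-of-ratios size factors: per-sample median, over genes with a
# nonzero geometric mean, of count / geometric mean (zero counts excluded).
.medianOfRatios <- function(counts) {
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use)) {
    stop("median-of-ratios is undefined: no gene has nonzero counts in every ",
         "sample; use method = 'cpm' instead")
  }
  apply(counts, 2L, function(col) {
    exp(stats::median((log(col) - logGeo)[use & col > 0]))
  })
}

#' Normalize a count experiment
#'
#' `"median-of-ratios"` (default) computes per-sample size factors as the
#' median, over genes with a nonzero geometric mean across samples, of the
#' ratio of the sample's count to that geometric mean; the normalized assay
#' is `counts / sizeFactor`. `"cpm"` scales every column to sum to 1e6
#' (size factor = column sum / 1e6).
#'
#' @param object a [RiboCountExperiment-class]; every sample must have at
#'   least one nonzero gene.
#' @param method `"median-of-ratios"` or `"cpm"`.
#' @param ... unused.
#' @return The input with a `"normalized"` assay and a `sizeFactor` column
#'   in `colData`.
#' @rdname normalizeCounts
#' @export
setMethod("normalizeCounts", "RiboCountExperiment",
  function(object, method = c("median-of-ratios", "cpm"), ...) {
    method <- match.arg(method)
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(colSums(cts) == 0)) {
      stop("every sample must have at least one nonzero gene")
    }
    sf <- switch(method,
      "median-of-ratios" = .medianOfRatios(cts),
      cpm = colSums(cts) / 1e6
    )
    SummarizedExperiment::assay(object, "normalized") <-
      sweep(cts, 2L, sf, "/")
    object$sizeFactor <- unname(sf)
    S4Vectors::metadata(object)$normalization <- method
    methods::validObject(object)
    object
  }
)

setMethod("show", "RiboCountExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat("design: ",
      paste0(length(unique(cd$strain)), " strain(s) x ",
             length(unique(cd$condition)), " condition(s) x ",
             length(unique(cd$assay)), " assay(s)"), "\n")
  if ("sizeFactor" %in% colnames(cd)) {
    cat("normalized (", S4Vectors::metadata(object)$normalization, ")\n", sep = "")
  }
})
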