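#' @importFrom SummarizedExperiment assay assayNames colData
NULL

# columns of `rce` belonging to one assay x strain x condition cell
.cellColumns <- function(rce, assayType, strain, condition) {
  cd <- colData(rce)
  which(cd$assay == assayType & cd$strain == strain & cd$condition == condition)
}

.cellMeans <- function(mat, cols) {
  if (length(cols) == 1L) mat[, cols] else rowMeans(mat[, cols, drop = FALSE])
}

.requireNormalized <- function(rce) {
  if (!"normalized" %in% assayNames(rce)) {
    stop("no normalized assay: run normalizeCounts() first")
  }
}

#' Translation efficiency per gene for one strain x condition cell
#'
#' TE is the ratio of normalized ribosome-footprint signal to normalized
#' mRNA signal: `(mean normalized Ribo + pseudocount) / (mean normalized
#' RNA + pseudocount)`, with means taken across replicates. The pseudocount
#' keeps the ratio finite for genes with zero RNA signal.
#'
#' @param rce a normalized [RiboCountExperiment-class].
#' @param strain,condition the cell to evaluate.
#' @param pseudocount positive value added to both means (default 0.5
#'   normalized counts).
#' @return Named numeric vector of per-gene TE (positive).
#' @export
computeTE <- function(rce, strain, condition, pseudocount = 0.5) {
  .requireNormalized(rce)
  stopifnot(pseudocount > 0)
  norm <- assay(rce, "normalized")
  ribo <- .cellColumns(rce, "Ribo", strain, condition)
  rna <- .cellColumns(rce, "RNA", strain, condition)
  if (!length(ribo) || !length(rna)) {
    stop("both assays must be present for strain=", strain,
         ", condition=", condition)
  }
  te <- (.cellMeans(norm, ribo) + pseudocount) /
        (.cellMeans(norm, rna) + pseudocount)
  stats::setNames(te, rownames(norm))
}

#' Per-gene log2 fold-changes between two strain x condition cells
#'
#' For each gene, computes the log2 ratio of replicate-mean normalized
#' counts between the numerator and denominator cells, separately for the
#' RNA and Ribo assays, and the TE fold-change as their difference
#' (`log2FC_te = log2FC_ribo - log2FC_rna`, exact).
#'
#' A gene is *measurable* when its raw counts, summed across replicates,
#' reach `minCount` in every one of the four assay x cell combinations;
#' only measurable genes receive fold-changes (they have strictly positive
#' means, so no pseudocount is needed and contrast log2FCs are exactly
#' invariant to per-sample rescaling). A pseudocount may still be supplied
#' for exploratory use on unfiltered data.
#'
#' @param rce a normalized [RiboCountExperiment-class].
#' @param numerator,denominator named character vectors (or lists) with
#'   elements `strain` and `condition`.
#' @param label contrast name; default
#'   `"<numStrain>_<numCond>_vs_<denStrain>_<denCond>"`.
#' @param minCount measurability threshold on summed raw counts per cell
#'   (default 10).
#' @param pseudocount added to replicate-mean normalized counts before the
#'   ratio (default 0; see Details).
#' @return A [ContrastResult-class].
#' @export
teContrast <- function(rce, numerator, denominator, label = NULL,
                       minCount = 10, pseudocount = 0) {
  .requireNormalized(rce)
  numerator <- unlist(numerator)[c("strain", "condition")]
  denominator <- unlist(denominator)[c("strain", "condition")]
  if (anyNA(numerator) || anyNA(denominator)) {
    stop("numerator and denominator need 'strain' and 'condition' elements")
  }
  if (is.null(label)) {
    label <- paste0(numerator[["strain"]], "_", numerator[["condition"]],
                    "_vs_", denominator[["strain"]], "_", denominator[["condition"]])
  }
  raw <- assay(rce, "counts")
  norm <- assay(rce, "normalized")

  cells <- list(
    rna_num = .cellColumns(rce, "RNA", numerator[["strain"]], numerator[["condition"]]),
    rna_den = .cellColumns(rce, "RNA", denominator[["strain"]], denominator[["condition"]]),
    ribo_num = .cellColumns(rce, "Ribo", numerator[["strain"]], numerator[["condition"]]),
    ribo_den = .cellColumns(rce, "Ribo", denominator[["strain"]], denominator[["condition"]])
  )
  empty <- names(cells)[lengths(cells) == 0L]
  if (length(empty)) {
    stop("missing samples for contrast cell(s): ", paste(empty, collapse = ", "))
  }

  measurable <- Reduce(`&`, lapply(cells, function(cols) {
    rowSums(raw[, cols, drop = FALSE]) >= minCount
  }))

  lfcRna <- log2(.cellMeans(norm, cells$rna_num) + pseudocount) -
            log2(.cellMeans(norm, cells$rna_den) + pseudocount)
  lfcRibo <- log2(.cellMeans(norm, cells$ribo_num) + pseudocount) -
             log2(.cellMeans(norm, cells$ribo_den) + pseudocount)
  lfcRna[!measurable] <- NA_real_
  lfcRibo[!measurable] <- NA_real_

  methods::new("ContrastResult",
    label = label,
    numerator = numerator,
    denominator = denominator,
    table = S4Vectors::DataFrame(
      gene_id = rownames(raw),
      log2FC_rna = unname(lfcRna),
      log2FC_ribo = unname(lfcRibo),
      log2FC_te = unname(lfcRibo - lfcRna),
      measurable = unname(measurable)
    )
  )
}

#' Accessors for ContrastResult
#'
#' @param x a [ContrastResult-class].
#' @param ... unused.
#' @return `contrastTable`: the per-gene [S4Vectors::DataFrame].
#' @name ContrastResult-accessors
NULL

#' @rdname ContrastResult-accessors
#' @export
setMethod("contrastTable", "ContrastResult", function(x, ...) x@table)

#' @rdname ContrastResult-accessors
#' @param object a [ContrastResult-class].
#' @export
measurableGenes <- function(object) {
  tab <- object@table
  tab$gene_id[tab$measurable]
}

#' @rdname ContrastResult-accessors
#' @export
contrastLabel <- function(object) object@label

setMethod("show", "ContrastResult", function(object) {
  tab <- object@table
  cat("ContrastResult '", object@label, "'\n", sep = "")
  cat(sprintf("  %d genes, %d measurable\n", nrow(tab), sum(tab$measurable)))
  if (any(tab$measurable)) {
    cat(sprintf("  median |log2FC_te| (measurable) = %.3g\n",
                stats::median(abs(tab$log2FC_te[tab$measurable]))))
  }
})

#' Classify fold-change gene sets at a threshold
#'
#' Splits measurable genes into "up" (fold-change >= tau) and "down"
#' (fold-change <= 1/tau) sets for each of the RNA, Ribo and TE
#' fold-changes. Boundaries are inclusive; comparison is done on the log2
#' scale with a 1e-9 relative guard so a ratio that is exactly `tau` lands
#' in the up set despite floating-point round-trip.
#'
#' @param result a [ContrastResult-class].
#' @param tau fold-change threshold (> 1; default 1.5).
#' @param assays which fold-changes to classify.
#' @return Named list of [GeneSet-class] objects
#'   (`"<assay>_up"`, `"<assay>_down"`).
#' @export
classifySets <- function(result, tau = 1.5, assays = c("rna", "ribo", "te")) {
  stopifnot(methods::is(result, "ContrastResult"), tau > 1)
  tab <- result@table
  m <- tab$measurable
  thr <- log2(tau)
  eps <- 1e-9
  out <- list()
  for (a in assays) {
    lfc <- tab[[paste0("log2FC_", a)]]
    up <- m & !is.na(lfc) & lfc >= thr * (1 - eps)
    down <- m & !is.na(lfc) & lfc <= -thr * (1 - eps)
    out[[paste0(a, "_up")]] <- methods::new("GeneSet",
      name = paste0(result@label, ".", a, "_up"),
      direction = "up", assay = a, contrast = result@label,
      genes = tab$gene_id[up]
    )
    out[[paste0(a, "_down")]] <- methods::new("GeneSet",
      name = paste0(result@label, ".", a, "_down"),
      direction = "down", assay = a, contrast = result@label,
      genes = tab$gene_id[down]
    )
  }
  out
}

#' Accessors for GeneSet
#'
#' @param x a [GeneSet-class].
#' @param ... unused.
#' @name GeneSet-accessors
NULL

#' @rdname GeneSet-accessors
#' @export
setMethod("members", "GeneSet", function(x, ...) x@genes)

#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%s/%s): %d genes\n",
              object@name, object@assay, object@direction, length(object@genes)))
})

#' Pearson correlation between two contrasts
#'
#' Correlates one fold-change field across the genes measurable in both
#' contrasts.
#'
#' @param resultA,resultB [ContrastResult-class] objects over the same gene
#'   universe.
#' @param field `"te"`, `"rna"` or `"ribo"`.
#' @return List with `r` (Pearson correlation) and `n` (genes used).
#' @export
correlateContrasts <- function(resultA, resultB, field = c("te", "rna", "ribo")) {
  field <- match.arg(field)
  col <- paste0("log2FC_", field)
  ta <- resultA@table
  tb <- resultB@table
  common <- intersect(ta$gene_id[ta$measurable], tb$gene_id[tb$measurable])
  if (length(common) < 3L) {
    stop("need at least 3 genes measurable in both contrasts")
  }
  va <- ta[[col]][match(common, ta$gene_id)]
  vb <- tb[[col]][match(common, tb$gene_id)]
  list(r = stats::cor(va, vb), n = length(common))
}
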