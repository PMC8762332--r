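#' Construct a TranscriptSet
#'
#' @param geneId character vector of unique gene ids.
#' @param utr5Len,cdsLen non-negative integer lengths (nucleotides).
#' @param scores a list (or [IRanges::NumericList]) of per-nucleotide score
#'   tracks, 5' to 3', covering the 5'UTR then the covered CDS nucleotides.
#'
#' @return A [TranscriptSet-class] object.
#' @examples
#' ts <- TranscriptSet("g1", utr5Len = 3, cdsLen = 90,
#'                     scores = list(c(1, -1, 0.5, rep(0, 90))))
#' utr5Lengths(ts)
#' @export
TranscriptSet <- function(geneId, utr5Len, cdsLen, scores) {
  if (!methods::is(scores, "NumericList")) scores <- IRanges::NumericList(scores)
  names(scores) <- geneId
  methods::new("TranscriptSet",
    geneId = as.character(geneId),
    utr5Len = as.integer(utr5Len),
    cdsLen = as.integer(cdsLen),
    scores = scores
  )
}

#' Accessors for TranscriptSet
#'
#' @param x a [TranscriptSet-class].
#' @param ... unused.
#' @return `geneIds`: character; `utr5Lengths`, `cdsLengths`: named integer;
#'   `scoreTracks`: a named [IRanges::NumericList].
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
setMethod("geneIds", "TranscriptSet", function(x, ...) x@geneId)

#' @rdname TranscriptSet-accessors
#' @export
setMethod("utr5Lengths", "TranscriptSet", function(x, ...) {
  stats::setNames(x@utr5Len, x@geneId)
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("cdsLengths", "TranscriptSet", function(x, ...) {
  stats::setNames(x@cdsLen, x@geneId)
})

#' @rdname TranscriptSet-accessors
#' @export
setMethod("scoreTracks", "TranscriptSet", function(x, ...) x@scores)

#' @export
setMethod("length", "TranscriptSet", function(x) length(x@geneId))

#' Subset a TranscriptSet by index or gene id
#'
#' @param x a [TranscriptSet-class].
#' @param i numeric, logical or character index.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@geneId)
    if (anyNA(idx)) {
      stop("unknown gene id(s): ", paste(i[is.na(idx)], collapse = ", "))
    }
    i <- idx
  }
  methods::initialize(x,
    geneId = x@geneId[i],
    utr5Len = x@utr5Len[i],
    cdsLen = x@cdsLen[i],
    scores = x@scores[i]
  )
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts\n")
  if (length(object)) {
    cat("  5'UTR length: median", stats::median(object@utr5Len),
        "nt [", min(object@utr5Len), "-", max(object@utr5Len), "]\n")
    cat("  covered CDS nt:", max(lengths(object@scores) - object@utr5Len), "(max)\n")
  }
})

#' Read / write transcript annotation with structure-score tracks
#'
#' The TSV has columns `gene_id`, `utr5_len`, `cds_len`, `scores`, the last
#' a semicolon-delimited list of per-nucleotide scores ordered 5' to 3'
#' (5'UTR first, then the covered CDS nucleotides).
#'
#' @param path file path.
#' @return `readAnnotation`: a [TranscriptSet-class].
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("gene_id", "utr5_len", "cds_len", "scores")
  if (!all(needed %in% colnames(tab))) {
    stop("annotation TSV must have columns: ", paste(needed, collapse = ", "))
  }
  scores <- lapply(strsplit(tab$scores, ";", fixed = TRUE), as.numeric)
  TranscriptSet(tab$gene_id, tab$utr5_len, tab$cds_len, scores)
}

#' @param ts a [TranscriptSet-class].
#' @rdname readAnnotation
#' @export
writeAnnotation <- function(ts, path) {
  tracks <- as.list(scoreTracks(ts))
  df <- data.frame(
    gene_id = geneIds(ts),
    utr5_len = unname(utr5Lengths(ts)),
    cds_len = unname(cdsLengths(ts)),
    scores = vapply(
      tracks,
      function(s) paste(formatC(s, digits = 6, format = "g"), collapse = ";"),
      character(1)
    ),
    stringsAsFactors = FALSE
  )
  .writeTsv(df, path)
  invisible(path)
}
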