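#' @rdname TranscriptSet-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("utr5Lengths", function(x, ...) standardGeneric("utr5Lengths"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("cdsLengths", function(x, ...) standardGeneric("cdsLengths"))

#' @rdname TranscriptSet-accessors
#' @export
setGeneric("scoreTracks", function(x, ...) standardGeneric("scoreTracks"))

#' @rdname cumulativeScore
#' @export
setGeneric("cumulativeScore", function(x, window, ...) {
  standardGeneric("cumulativeScore")
})

#' @rdname meanPerNt5utr
#' @export
setGeneric("meanPerNt5utr", function(x, ...) standardGeneric("meanPerNt5utr"))

#' @rdname normalizeCounts
#' @export
setGeneric("normalizeCounts", function(object, method = c("median-of-ratios", "cpm"), ...) {
  standardGeneric("normalizeCounts")
})

#' @rdname ContrastResult-accessors
#' @export
setGeneric("contrastTable", function(x, ...) standardGeneric("contrastTable"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))

#' @rdname pmRatio
#' @export
setGeneric("pmRatio", function(trace, monoInterval, polyInterval, baseline = 0, ...) {
  standardGeneric("pmRatio")
})
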