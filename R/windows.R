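#' Named structure-score windows
#'
#' Transcript coordinates are 1-based and signed: position +1 is the first
#' CDS nucleotide (the A of the AUG), position -1 the last 5'UTR nucleotide;
#' there is no position 0. The named windows are:
#'
#' * `total5utr`: the whole 5'UTR, `[-L, -1]` for a 5'UTR of length L;
#' * `first30`: the first 30 5'UTR nucleotides from the cap,
#'   `[-L, -L + 29]`;
#' * `start30`: 30 nucleotides surrounding the start codon,
#'   `[-15, +15]` (15 UTR + 15 CDS nt);
#' * `plus15`, `plus30`, `plus45`, `plus60`, `plus75`: 30-nt CDS windows
#'   `[+1, +30]`, `[+16, +45]`, `[+31, +60]`, `[+46, +75]`, `[+61, +90]`
#'   (named after the window midpoint).
#'
#' A window that does not fully fit within the available 5'UTR or covered
#' CDS is missing (`NULL` bounds, `NA` scores): truncated sums would not be
#' comparable across genes.
#'
#' @name structure-windows
NULL

.windowNames <- c("total5utr", "first30", "start30",
                  "plus15", "plus30", "plus45", "plus60", "plus75")

#' Window coordinate bounds
#'
#' @param window one of the names in [structure-windows].
#' @param utr5Len 5'UTR length (nt, >= 0).
#' @param coveredCds number of CDS nucleotides covered by the score track.
#' @return Signed 1-based inclusive interval `c(start, end)` (position 0
#'   does not exist and is skipped), or `NULL` if the window does not fully
#'   fit.
#' @examples
#' windowBounds("plus30", utr5Len = 50, coveredCds = 90)  # c(16, 45)
#' windowBounds("first30", utr5Len = 29, coveredCds = 90) # NULL
#' @export
windowBounds <- function(window, utr5Len, coveredCds) {
  stopifnot(utr5Len >= 0, coveredCds >= 0)
  cds <- switch(window,
    plus15 = c(1L, 30L),
    plus30 = c(16L, 45L),
    plus45 = c(31L, 60L),
    plus60 = c(46L, 75L),
    plus75 = c(61L, 90L),
    NULL
  )
  if (!is.null(cds)) {
    if (coveredCds < cds[2L]) return(NULL)
    return(cds)
  }
  switch(window,
    total5utr = if (utr5Len >= 1L) c(-utr5Len, -1L) else NULL,
    first30 = if (utr5Len >= 30L) c(-utr5Len, -utr5Len + 29L) else NULL,
    start30 = if (utr5Len >= 15L && coveredCds >= 15L) c(-15L, 15L) else NULL,
    stop("unknown window name: ", window)
  )
}

# signed transcript position -> index into a score track
.posToIndex <- function(pos, utr5Len) {
  ifelse(pos < 0L, utr5Len + pos + 1L, utr5Len + pos)
}

.windowSum1 <- function(scores, utr5Len, window) {
  bounds <- windowBounds(window, utr5Len, length(scores) - utr5Len)
  if (is.null(bounds)) return(NA_real_)
  pos <- setdiff(seq.int(bounds[1L], bounds[2L]), 0L)
  sum(scores[.posToIndex(pos, utr5Len)])
}

#' Cumulative structure score over a named window
#'
#' Sums the per-nucleotide scores over a window defined in
#' [structure-windows]; returns `NA` for transcripts where the window does
#' not fully fit.
#'
#' @param x a [TranscriptSet-class].
#' @param window window name (see [structure-windows]).
#' @param ... unused.
#' @return Named numeric vector (one value per transcript, `NA` = missing).
#' @examples
#' ts <- TranscriptSet("g1", 30, 90, list(rep(1, 120)))
#' cumulativeScore(ts, "total5utr")  # 30
#' @rdname cumulativeScore
#' @export
setMethod("cumulativeScore", "TranscriptSet", function(x, window, ...) {
  window <- match.arg(window, .windowNames)
  tracks <- as.list(scoreTracks(x))
  out <- vapply(seq_along(tracks), function(i) {
    .windowSum1(tracks[[i]], x@utr5Len[i], window)
  }, numeric(1))
  stats::setNames(out, x@geneId)
})

#' Mean per-nucleotide score over the full 5'UTR
#'
#' `total5utr / utr5Len`; `NA` when the 5'UTR is empty.
#'
#' @param x a [TranscriptSet-class].
#' @param ... unused.
#' @return Named numeric vector.
#' @rdname meanPerNt5utr
#' @export
setMethod("meanPerNt5utr", "TranscriptSet", function(x, ...) {
  tot <- cumulativeScore(x, "total5utr")
  ifelse(x@utr5Len > 0L, tot / x@utr5Len, NA_real_)
})

#' Per-transcript window-score table
#'
#' One row per transcript with the cumulative score for every named window,
#' the mean per-nucleotide 5'UTR score, and the 5'UTR length. Missing
#' windows are `NA`, never zero-filled.
#'
#' @param ts a [TranscriptSet-class].
#' @return A data.frame with columns `gene_id`, `utr5_len`, one per window,
#'   and `mean_5utr_per_nt`.
#' @export
windowScoreTable <- function(ts) {
  stopifnot(methods::is(ts, "TranscriptSet"))
  out <- data.frame(
    gene_id = geneIds(ts),
    utr5_len = unname(utr5Lengths(ts)),
    stringsAsFactors = FALSE
  )
  for (w in .windowNames) out[[w]] <- unname(cumulativeScore(ts, w))
  out$mean_5utr_per_nt <- unname(meanPerNt5utr(ts))
  out
}

#' Per-set window-score summaries
#'
#' For each gene set, reports the mean cumulative score per named window,
#' the mean per-nucleotide 5'UTR score, and the mean 5'UTR length, with the
#' number of genes contributing to each cell (genes whose window is defined).
#'
#' @param ts a [TranscriptSet-class].
#' @param geneSets named list of character vectors (or [GeneSet-class]
#'   objects) referencing genes in `ts`.
#' @return A long data.frame: `set`, `feature`, `mean`, `n`.
#' @export
featureTable <- function(ts, geneSets) {
  stopifnot(methods::is(ts, "TranscriptSet"))
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets)))) {
    stop("'geneSets' must be a named list")
  }
  wt <- windowScoreTable(ts)
  feats <- c(.windowNames, "mean_5utr_per_nt", "utr5_len")
  rows <- lapply(names(geneSets), function(nm) {
    gs <- geneSets[[nm]]
    if (methods::is(gs, "GeneSet")) gs <- members(gs)
    if (length(gs) == 0L) stop("gene set '", nm, "' is empty")
    unknown <- setdiff(gs, wt$gene_id)
    if (length(unknown)) {
      stop("gene set '", nm, "' references unknown genes: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    }
    sub <- wt[wt$gene_id %in% gs, , drop = FALSE]
    data.frame(
      set = nm,
      feature = feats,
      mean = vapply(feats, function(f) mean(sub[[f]], na.rm = TRUE), numeric(1)),
      n = vapply(feats, function(f) sum(!is.na(sub[[f]])), integer(1)),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}
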