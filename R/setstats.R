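#' Fisher's exact test for a 2x2 table (by counts)
#'
#' Two-sided p by minimum-likelihood summation: with margins fixed, all
#' hypergeometric tables whose probability does not exceed that of the
#' observed table (up to a 1 + 1e-7 relative guard, the standard exact-test
#' convention) are summed. The one-sided upper-tail (enrichment) p is
#' `P(X >= observed)`.
#'
#' @param nOverlap,nA,nB,nUniverse counts of the overlap, the two sets and
#'   the universe.
#' @return List with `pTwoSided`, `pEnrich` and `oddsRatio` (sample odds
#'   ratio with Haldane 0.5 correction when any cell is 0).
#' @keywords internal
fisherCounts <- function(nOverlap, nA, nB, nUniverse) {
  a <- nOverlap
  b <- nA - nOverlap
  c <- nB - nOverlap
  d <- nUniverse - nA - nB + nOverlap
  if (min(a, b, c, d) < 0) stop("inconsistent 2x2 counts")
  lo <- max(0L, nA + nB - nUniverse)
  hi <- min(nA, nB)
  support <- lo:hi
  probs <- stats::dhyper(support, nA, nUniverse - nA, nB)
  pObs <- probs[support == a]
  pTwo <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  pEnrich <- min(1, sum(probs[support >= a]))
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  list(
    pTwoSided = pTwo,
    pEnrich = pEnrich,
    oddsRatio = (cells[1] * cells[4]) / (cells[2] * cells[3])
  )
}

#' Overlap between two gene sets with Fisher's exact test
#'
#' Builds the 2x2 contingency table (in both / A only / B only / neither)
#' over a gene universe and tests the statistical significance of the
#' overlap with Fisher's exact test: two-sided by minimum-likelihood
#' summation, plus the one-sided upper-tail (enrichment) p.
#'
#' @param setA,setB character vectors (or [GeneSet-class]) of gene ids,
#'   both subsets of `universe`.
#' @param universe character vector of background gene ids (>= 2).
#' @return An [OverlapResult-class].
#' @examples
#' overlapFisher(letters[1:5], letters[1:5], letters[1:10])
#' @export
overlapFisher <- function(setA, setB, universe) {
  if (methods::is(setA, "GeneSet")) setA <- members(setA)
  if (methods::is(setB, "GeneSet")) setB <- members(setB)
  setA <- unique(setA)
  setB <- unique(setB)
  universe <- unique(universe)
  if (length(universe) < 2L) stop("the universe needs at least 2 genes")
  outside <- c(setdiff(setA, universe), setdiff(setB, universe))
  if (length(outside)) {
    stop("set members outside the universe: ",
         paste(utils::head(unique(outside), 10L), collapse = ", "))
  }
  nA <- length(setA)
  nB <- length(setB)
  nOv <- length(intersect(setA, setB))
  ft <- fisherCounts(nOv, nA, nB, length(universe))
  methods::new("OverlapResult",
    nUniverse = length(universe), nA = nA, nB = nB, nOverlap = nOv,
    pctOfA = if (nA > 0) 100 * nOv / nA else NA_real_,
    pctOfB = if (nB > 0) 100 * nOv / nB else NA_real_,
    oddsRatio = ft$oddsRatio,
    pTwoSided = ft$pTwoSided,
    pEnrich = ft$pEnrich
  )
}

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf(
    paste0("OverlapResult: %d of %d (A) / %d (B) shared, universe %d\n",
           "  %.1f%% of A, %.1f%% of B; OR = %.3g\n",
           "  Fisher p (two-sided) = %.3g, enrichment p = %.3g\n"),
    object@nOverlap, object@nA, object@nB, object@nUniverse,
    object@pctOfA, object@pctOfB, object@oddsRatio,
    object@pTwoSided, object@pEnrich
  ))
})

#' Convert an OverlapResult to a one-row data.frame
#'
#' @param x an [OverlapResult-class].
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @export
as.data.frame.OverlapResult <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    n_universe = x@nUniverse, n_A = x@nA, n_B = x@nB, n_overlap = x@nOverlap,
    pct_of_A = x@pctOfA, pct_of_B = x@pctOfB, odds_ratio = x@oddsRatio,
    p_two_sided = x@pTwoSided, p_enrich = x@pEnrich,
    stringsAsFactors = FALSE
  )
}

#' Read / write GMT gene-set files
#'
#' GMT is tab-separated: term id, description, then member genes.
#'
#' @param path file path.
#' @return `readGmt`: a named list of character vectors, with term
#'   descriptions in the `"description"` attribute.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  terms <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(terms) <- vapply(parts, `[[`, character(1), 1L)
  attr(terms, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), names(terms)
  )
  terms
}

#' @param terms named list of character vectors.
#' @param descriptions optional named character vector of term descriptions.
#' @rdname readGmt
#' @export
writeGmt <- function(terms, path, descriptions = NULL) {
  lines <- vapply(names(terms), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else nm
    paste(c(nm, desc, terms[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric term enrichment with BH correction
#'
#' For each term in a GMT-style map, tests over-representation of the gene
#' set among the term's members with the upper-tail hypergeometric test
#' (classic GO-style enrichment), then adjusts across tested terms with
#' Benjamini-Hochberg. Terms are intersected with the universe before
#' testing; terms left empty by the intersection are dropped.
#'
#' @param geneSet character vector (or [GeneSet-class]), a subset of
#'   `universe`.
#' @param termMap named list of character vectors (see [readGmt()]).
#' @param universe character vector of background genes.
#' @param dropZero drop terms with zero overlap instead of reporting them
#'   with p = 1 (default FALSE).
#' @return data.frame with columns `term`, `term_size`, `overlap`, `p`,
#'   `q`, sorted by `p` (ties by term id).
#' @export
enrichTerms <- function(geneSet, termMap, universe, dropZero = FALSE) {
  if (methods::is(geneSet, "GeneSet")) geneSet <- members(geneSet)
  geneSet <- unique(geneSet)
  universe <- unique(universe)
  if (length(setdiff(geneSet, universe))) {
    stop("gene set members outside the universe: ",
         paste(utils::head(setdiff(geneSet, universe), 10L), collapse = ", "))
  }
  n <- length(geneSet)
  N <- length(universe)
  termsU <- lapply(termMap, intersect, universe)
  termsU <- termsU[lengths(termsU) > 0L]
  if (!length(termsU)) stop("no term intersects the universe")
  K <- lengths(termsU)
  k <- vapply(termsU, function(t) length(intersect(t, geneSet)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term = names(termsU),
    term_size = unname(K),
    overlap = unname(k),
    p = unname(p),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (dropZero) out <- out[out$overlap > 0L, , drop = FALSE]
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$term), , drop = FALSE]
}

#' Select the top or bottom fraction of genes by a metric
#'
#' Takes `floor(fraction * n)` genes ranked by the metric (missing values
#' excluded first); ties are broken by ascending gene id, so the selection
#' is deterministic.
#'
#' @param metric named numeric vector (names are gene ids).
#' @param fraction fraction of non-missing genes to take (0 < fraction < 1;
#'   default 0.30).
#' @param side `"top"` (largest values) or `"bottom"`.
#' @param name optional set name.
#' @return A [GeneSet-class].
#' @export
rankSelect <- function(metric, fraction = 0.30, side = c("top", "bottom"),
                       name = NULL) {
  side <- match.arg(side)
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(names(metric))) stop("'metric' must be named by gene id")
  metric <- metric[!is.na(metric)]
  k <- floor(fraction * length(metric))
  ord <- if (side == "top") {
    order(-metric, names(metric))
  } else {
    order(metric, names(metric))
  }
  sel <- names(metric)[ord][seq_len(k)]
  if (is.null(name)) name <- paste0(side, "_", format(fraction))
  methods::new("GeneSet",
    name = name, direction = "none", assay = "metric",
    contrast = NA_character_, genes = sel
  )
}

#' Overlap between two enrichment term lists
#'
#' Jaccard index over the terms passing a q-value cutoff in each result
#' (both computed on the same term map).
#'
#' @param enrichA,enrichB data.frames from [enrichTerms()].
#' @param qCutoff significance cutoff on the BH q value (terms with
#'   `q <= qCutoff` count; default 0.05).
#' @return List with `jaccard`, `shared` (character vector of shared term
#'   ids), `nA`, `nB`.
#' @export
termListOverlap <- function(enrichA, enrichB, qCutoff = 0.05) {
  sigA <- enrichA$term[enrichA$q <= qCutoff]
  sigB <- enrichB$term[enrichB$q <= qCutoff]
  shared <- intersect(sigA, sigB)
  uni <- union(sigA, sigB)
  list(
    jaccard = if (length(uni)) length(shared) / length(uni) else NA_real_,
    shared = sort(shared),
    nA = length(sigA),
    nB = length(sigB)
  )
}
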