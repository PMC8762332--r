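#' Construct a GradientTrace
#'
#' @param position strictly increasing gradient positions (arbitrary
#'   units, top of the gradient first).
#' @param a254 absorbance at 254 nm at each position.
#' @return A [GradientTrace-class].
#' @export
GradientTrace <- function(position, a254) {
  methods::new("GradientTrace",
    position = as.numeric(position), a254 = as.numeric(a254))
}

#' Read a two-column absorbance trace TSV
#'
#' Expects columns `position` and `a254` (header optional if exactly two
#' numeric columns).
#'
#' @param path file path.
#' @return A [GradientTrace-class].
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("position", "a254") %in% colnames(tab))) {
    if (ncol(tab) == 2L) colnames(tab) <- c("position", "a254")
    else stop("trace TSV must have columns 'position' and 'a254'")
  }
  GradientTrace(tab$position, tab$a254)
}

setMethod("show", "GradientTrace", function(object) {
  cat(sprintf("GradientTrace: %d points, position %.3g-%.3g, max A254 = %.3g\n",
              length(object@position), min(object@position),
              max(object@position), max(object@a254)))
})

# trapezoidal area of (a254 - baseline), clipped at 0, over [lo, hi];
# interval endpoints are added by linear interpolation of the trace.
.peakArea <- function(trace, interval, baseline) {
  lo <- interval[1L]
  hi <- interval[2L]
  pos <- trace@position
  inside <- pos > lo & pos < hi
  x <- c(lo, pos[inside], hi)
  y <- stats::approx(pos, trace@a254, xout = x, rule = 2)$y
  base <- if (length(baseline) == 2L) {
    # per-interval linear baseline between values given at the endpoints
    baseline[1L] + (x - lo) / (hi - lo) * (baseline[2L] - baseline[1L])
  } else {
    rep(baseline, length(x))
  }
  pracma::trapz(x, pmax(y - base, 0))
}

.checkInterval <- function(interval, trace, what) {
  if (length(interval) != 2L || interval[1L] >= interval[2L]) {
    stop("'", what, "' must be an increasing (lo, hi) pair")
  }
  rng <- range(trace@position)
  if (interval[1L] < rng[1L] || interval[2L] > rng[2L]) {
    stop("'", what, "' lies outside the trace range")
  }
}

#' Polysome-to-monosome ratio from an absorbance trace
#'
#' Quantifies the area under the curve for operator-chosen monosome and
#' polysome peaks by trapezoidal integration of the baseline-subtracted
#' A254 signal (negative values clipped at 0), and reports their ratio:
#' the bulk P:M readout of translation initiation activity.
#'
#' @param trace a [GradientTrace-class].
#' @param monoInterval,polyInterval non-overlapping `(lo, hi)` position
#'   intervals within the trace range.
#' @param baseline a constant, or a length-2 numeric giving baseline values
#'   at each interval's endpoints (linear in between), or a list with
#'   elements `mono` and `poly` of either form (default 0).
#' @param ... unused.
#' @return A [PMResult-class].
#' @examples
#' x <- seq(0, 10, by = 0.01)
#' tr <- GradientTrace(x, dnorm(x, 3, 0.3) + 2 * dnorm(x, 7, 0.5))
#' pmRatio(tr, c(2, 4), c(5, 9))
#' @rdname pmRatio
#' @export
setMethod("pmRatio", "GradientTrace",
  function(trace, monoInterval, polyInterval, baseline = 0, ...) {
    .checkInterval(monoInterval, trace, "monoInterval")
    .checkInterval(polyInterval, trace, "polyInterval")
    if (monoInterval[2L] > polyInterval[1L] && polyInterval[2L] > monoInterval[1L]) {
      stop("monosome and polysome intervals must not overlap")
    }
    if (is.list(baseline)) {
      baseMono <- baseline$mono
      basePoly <- baseline$poly
      if (is.null(baseMono) || is.null(basePoly)) {
        stop("list 'baseline' needs elements 'mono' and 'poly'")
      }
    } else {
      baseMono <- basePoly <- baseline
    }
    mono <- .peakArea(trace, monoInterval, baseMono)
    poly <- .peakArea(trace, polyInterval, basePoly)
    if (mono <= 0) stop("monosome area is 0: P:M ratio undefined")
    methods::new("PMResult", monoArea = mono, polyArea = poly,
                 pmRatio = poly / mono)
  }
)

setMethod("show", "PMResult", function(object) {
  cat(sprintf("PMResult: mono area = %.4g, poly area = %.4g, P:M = %.4g\n",
              object@monoArea, object@polyArea, object@pmRatio))
})

#' Percent-of-total signal across gradient fractions
#'
#' Converts per-fraction signal (e.g. western-blot band quantification of a
#' protein across the gradient) into percent of the total.
#'
#' @param signal non-negative numeric vector, one value per fraction.
#' @return Numeric vector of percentages (sums to 100).
#' @examples
#' fractionDistribution(rep(2, 10))  # 10% in each fraction
#' @export
fractionDistribution <- function(signal) {
  if (!length(signal)) stop("at least one fraction is required")
  if (any(is.na(signal)) || any(signal < 0)) {
    stop("signals must be non-negative and non-missing")
  }
  tot <- sum(signal)
  if (tot <= 0) stop("total signal must be > 0")
  100 * signal / tot
}

#' Compare early- vs late-gradient mass between two conditions
#'
#' Pools each replicate's percent-of-total mass at or after `splitIndex`
#' (e.g. the first ribosome-containing fraction, so early = mRNP, late =
#' ribosomal) and compares the two conditions with an unpaired Student's
#' t test via [compareGroups()].
#'
#' @param distA,distB matrices of replicate distributions (replicates x
#'   fractions, rows in percent), or lists of per-replicate percent
#'   vectors; >= 2 replicates per condition.
#' @param splitIndex 1-based index of the first "late" fraction.
#' @param ... passed to [compareGroups()].
#' @return A [GroupComparison-class] on the pooled late mass.
#' @export
partitionCompare <- function(distA, distB, splitIndex, ...) {
  toMat <- function(d) {
    if (is.list(d)) d <- do.call(rbind, d)
    as.matrix(d)
  }
  a <- toMat(distA)
  b <- toMat(distB)
  if (nrow(a) < 2L || nrow(b) < 2L) {
    stop("each condition needs at least 2 replicate distributions")
  }
  if (splitIndex < 1L || splitIndex > ncol(a) || ncol(a) != ncol(b)) {
    stop("'splitIndex' must index a fraction present in both conditions")
  }
  late <- function(m) rowSums(m[, splitIndex:ncol(m), drop = FALSE])
  compareGroups(late(a), late(b), ...)
}
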