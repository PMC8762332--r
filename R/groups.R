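#' Unpaired two-group comparison (Student's t test)
#'
#' Two-sided unpaired t test between two groups of values, pooled-variance
#' (Student) by default, Welch behind a flag. Missing values are dropped
#' first. When both groups are constant and equal the statistic is
#' undefined; the comparison returns `t = NA`, `p = 1` with the degenerate
#' flag set. Constant groups with different means (zero pooled variance but
#' a nonzero difference) are an error.
#'
#' @param a,b numeric vectors (>= 2 non-missing values each).
#' @param alpha significance level for the flag (default 0.05).
#' @param welch use the Welch (unequal-variance) form instead of pooled.
#' @return A [GroupComparison-class].
#' @examples
#' cmp <- compareGroups(rnorm(50), rnorm(50, 1))
#' cmp
#' @export
compareGroups <- function(a, b, alpha = 0.05, welch = FALSE) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values")
  }
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      degenerate <- TRUE
      tstat <- NA_real_
      p <- 1
    } else {
      stop("degenerate variance: both groups constant with different means")
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = !welch)
    tstat <- unname(ht$statistic)
    p <- ht$p.value
  }
  methods::new("GroupComparison",
    meanA = mean(a), meanB = mean(b),
    nA = length(a), nB = length(b),
    t = tstat, p = p,
    significant = p < alpha, alpha = alpha,
    degenerate = degenerate,
    method = if (welch) "welch" else "student"
  )
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison (%s t test, two-sided)\n  mean A = %.4g (n = %d), mean B = %.4g (n = %d)\n",
    object@method, object@meanA, object@nA, object@meanB, object@nB
  ))
  if (object@degenerate) {
    cat("  degenerate: both groups constant and equal; p = 1\n")
  } else {
    cat(sprintf("  t = %.4g, p = %.4g%s\n", object@t, object@p,
                if (object@significant) " *" else ""))
  }
})
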