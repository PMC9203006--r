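#' Exact Wilcoxon signed-rank test
#'
#' Exact p-value of the one-sample signed-rank statistic by full
#' enumeration of the 2^n equiprobable sign assignments of the ranks of
#' |differences| (computed via the generating function of the rank-sum
#' distribution, which enumerates all assignments without materializing
#' them). Ties receive average ranks; zero differences are dropped with a
#' warning. At n = 4 with all differences of one sign the one-sided p-value
#' is 1/16 = 0.0625, the smallest attainable with that sample size.
#'
#' @param d Numeric vector of paired differences.
#' @param alternative `"greater"` (positive location shift), `"less"`, or
#'   `"two.sided"`; two-sided doubles the smaller tail (capped at 1).
#' @return An object of class `tf_wilcoxon`: list with `statistic` (V, the
#'   positive-rank sum), `p.value`, `n` (non-zero differences) and
#'   `alternative`.
#' @export
wilcoxon_exact <- function(d, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- d[is.finite(d)]
  if (!length(d)) stop("no finite differences", call. = FALSE)
  nz <- d != 0
  if (!any(nz)) stop("all differences are zero", call. = FALSE)
  if (any(!nz)) {
    warning(sum(!nz), " zero difference(s) dropped")
    d <- d[nz]
  }
  n <- length(d)
  if (n > 30) {
    stop("exact enumeration limited to n <= 30", call. = FALSE)
  }
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks are integers
  v2 <- sum(r2[d > 0])                        # doubled positive-rank sum
  # generating function of the doubled-rank sum over all sign assignments
  counts <- c(1, numeric(sum(r2)))
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  total <- 2^n
  support <- seq_along(counts) - 1L
  p_ge <- sum(counts[support >= v2]) / total
  p_le <- sum(counts[support <= v2]) / total
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(statistic = c(V = v2 / 2), p.value = p, n = n,
                 alternative = alternative,
                 method = "exact Wilcoxon signed-rank (full enumeration)"),
            class = "tf_wilcoxon")
}

#' @method print tf_wilcoxon
#' @export
print.tf_wilcoxon <- function(x, ...) {
  cat(sprintf("%s\nV = %g, n = %d, p = %.6g (%s)\n",
              x$method, x$statistic, x$n, x$p.value, x$alternative))
  invisible(x)
}
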