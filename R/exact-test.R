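#' @include utils.R
NULL

#' Audic-Claverie exact test for two tag counts
#'
#' Tests whether a gene's tag counts \code{x} and \code{y} in two
#' libraries of (effective) sizes \code{n1} and \code{n2} are consistent
#' with equal underlying expression. Conditional on \code{x}, the count
#' in the second library follows
#' \deqn{p(y\mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},}
#' a negative-binomial distribution in \code{y}. The two-sided P value is
#' twice the smaller of the lower tail \eqn{P(Y \le y)} and the upper
#' tail \eqn{P(Y \ge y)}, capped at 1. Both tails are accumulated
#' directly in log space (the upper tail summed far past the
#' distribution's mean rather than by complementing the lower sum), so
#' no catastrophic cancellation occurs for extreme counts.
#'
#' @param x,y non-negative integer counts (vectors recycle).
#' @param n1,n2 positive (effective) library sizes.
#' @return vector of two-sided P values in (0, 1].
#' @examples
#' exactTestP(5, 50, 1e6, 1e6)
#' exactTestP(10, 10, 1e6, 1e6)  # 1: perfectly symmetric
#' @export
exactTestP <- function(x, y, n1, n2) {
  if (any(x != round(x)) || any(y != round(y)))
    stop("counts must be integers")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  m <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, m); y <- rep_len(y, m)
  n1 <- rep_len(n1, m); n2 <- rep_len(n2, m)
  vapply(seq_len(m), function(i) .acTwoSided(x[i], y[i], n2[i] / n1[i]), 0)
}

# log p(k|x) for the Audic-Claverie conditional distribution, ratio r = N2/N1
.acLogPmf <- function(k, x, r) {
  k * log(r) + lchoose(x + k, k) - (x + k + 1) * log1p(r)
}

.acTwoSided <- function(x, y, r) {
  lower <- exp(logSumExp(.acLogPmf(0:y, x, r)))
  # direct upper-tail sum from y to well past the mean + 20 SD
  mu <- (x + 1) * r
  sdv <- sqrt((x + 1) * r * (1 + r))
  kMax <- ceiling(max(y, mu) + 20 * sdv + 50)
  upper <- exp(logSumExp(.acLogPmf(y:kMax, x, r)))
  min(1, 2 * min(lower, upper))
}

#' Log2 fold change with pseudo-count
#'
#' \eqn{\log_2(((y+c)/N_2)/((x+c)/N_1))} for pseudo-count \code{c}. With
#' \code{pseudo = 0} this is the raw normalised ratio; the DEG caller
#' uses the raw ratio whenever both counts are positive and falls back
#' to \code{pseudo = 1} only when a zero would make the ratio infinite.
#'
#' @inheritParams exactTestP
#' @param pseudo pseudo-count added to both counts.
#' @return vector of log2 fold changes (B relative to A).
#' @export
logFoldChange <- function(x, y, n1, n2, pseudo = 1) {
  log2(((y + pseudo) / n2) / ((x + pseudo) / n1))
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up false discovery rate adjustment (a thin wrapper over
#' \code{stats::p.adjust(method = "BH")}), monotone in P value rank and
#' capped at 1.
#'
#' @param p vector of P values in [0, 1].
#' @return adjusted P values.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
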