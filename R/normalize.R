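#' @include mapping.R
NULL

#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' Computes one scaling factor per library against a reference library.
#' For each library, gene-wise log-ratios
#' \eqn{M = \log_2((x/N)/(x_{ref}/N_{ref}))} and average log-abundances
#' \eqn{A = \frac{1}{2}\log_2((x/N)(x_{ref}/N_{ref}))} are formed over
#' genes expressed in both libraries, doubly trimmed (\code{trimM} of
#' each M tail, \code{trimA} of each A tail), and the factor is
#' \eqn{2^{\bar M_w}} with \eqn{\bar M_w} the mean of the surviving M
#' values weighted by inverse asymptotic binomial variance
#' \eqn{(N-x)/(Nx) + (N_{ref}-x_{ref})/(N_{ref}x_{ref})}. Factors are
#' rescaled to unit geometric mean across libraries, so the effective
#' sizes (library size times factor) preserve overall scale.
#'
#' @param object a \linkS4class{GeneCountMatrix}.
#' @param refLabel reference library label (default: first column).
#' @param trimM fraction of M values trimmed from each tail.
#' @param trimA fraction of A values trimmed from each tail.
#' @return data.frame with columns \code{library}, \code{factor},
#'   \code{librarySize}, \code{effectiveSize}; the factors multiply to 1.
#' @seealso [callDEGs()], which uses the effective sizes.
#' @export
tmmFactors <- function(object, refLabel = colnames(object)[1],
                       trimM = 0.30, trimA = 0.05) {
  cts <- SummarizedExperiment::assay(object, "counts")
  if (!refLabel %in% colnames(cts))
    stop("reference library '", refLabel, "' not in the matrix")
  sizes <- librarySizes(object)
  ref <- cts[, refLabel]
  nRef <- sizes[refLabel]
  f <- vapply(colnames(cts), function(lab) {
    .tmmPair(cts[, lab], ref, sizes[lab], nRef, trimM, trimA, lab, refLabel)
  }, 0)
  f <- f / exp(mean(log(f)))
  data.frame(library = colnames(cts), factor = unname(f),
             librarySize = unname(sizes),
             effectiveSize = unname(sizes * f),
             stringsAsFactors = FALSE)
}

.tmmPair <- function(obs, ref, nObs, nRef, trimM, trimA, lab, refLab) {
  pos <- obs > 0 & ref > 0
  if (!any(pos))
    stop("no gene expressed in both '", lab, "' and '", refLab,
         "': TMM factor undefined")
  o <- obs[pos]; r <- ref[pos]
  M <- log2((o / nObs) / (r / nRef))
  A <- (log2(o / nObs) + log2(r / nRef)) / 2
  w <- (nObs - o) / (nObs * o) + (nRef - r) / (nRef * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) return(1)
  # zero weights can only arise when a count equals its library size
  w <- pmax(w, .Machine$double.eps)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}
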