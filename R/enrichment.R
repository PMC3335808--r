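#' @include exact-test.R
NULL

.checkNnMm <- function(N, n, M, m) {
  if (n > N) stop("invalid table: n > N")
  if (M > N) stop("invalid table: M > N")
  if (m > n) stop("invalid table: m > n")
  if (m > M) stop("invalid table: m > M")
  if (any(c(N, n, M, m) < 0)) stop("invalid table: negative count")
  invisible(TRUE)
}

#' Hypergeometric enrichment P value
#'
#' Upper-tail hypergeometric probability
#' \deqn{P = 1 - \sum_{i=0}^{m-1}
#'   \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}}
#'   = P(X \ge m),}
#' where \eqn{N} is the number of annotated background genes, \eqn{n}
#' the number of DEGs among them, \eqn{M} the background genes carrying
#' the term, and \eqn{m} the DEGs carrying it. Computed by summing the
#' upper tail in log space, so large tables do not overflow.
#'
#' @param N,n,M,m counts as above (scalars or equal-length vectors).
#' @return P value(s); \code{m = 0} gives 1.
#' @examples
#' hypergeomEnrichmentP(20, 5, 5, 3)  # = 1126/15504
#' @export
hypergeomEnrichmentP <- function(N, n, M, m) {
  len <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, len); n <- rep_len(n, len)
  M <- rep_len(M, len); m <- rep_len(m, len)
  vapply(seq_len(len), function(j) {
    .checkNnMm(N[j], n[j], M[j], m[j])
    i <- m[j]:min(n[j], M[j])
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(1, exp(logSumExp(lt)))
  }, 0)
}

#' One-sided Fisher's exact test for pathway enrichment
#'
#' Enrichment-direction Fisher's exact test on the 2x2 table
#' (m, n-m; M-m, N-M-n+m), via \code{stats::fisher.test(alternative =
#' "greater")}. For these tables the one-sided Fisher P coincides with
#' the upper-tail hypergeometric probability of
#' [hypergeomEnrichmentP()].
#'
#' @inheritParams hypergeomEnrichmentP
#' @return P value(s).
#' @export
fisherPathwayP <- function(N, n, M, m) {
  len <- max(length(N), length(n), length(M), length(m))
  N <- rep_len(N, len); n <- rep_len(n, len)
  M <- rep_len(M, len); m <- rep_len(m, len)
  vapply(seq_len(len), function(j) {
    .checkNnMm(N[j], n[j], M[j], m[j])
    tab <- matrix(c(m[j], n[j] - m[j], M[j] - m[j],
                    N[j] - M[j] - n[j] + m[j]), 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, 0)
}

#' GO / pathway enrichment of a DEG set
#'
#' Restricts the analysis to annotated genes: the background universe
#' \eqn{N} is the background genes carrying at least one term of the
#' vocabulary, \eqn{n} the DEGs among them; per term, \eqn{M} and
#' \eqn{m} count the term's genes in background and DEG set. P values
#' come from the hypergeometric upper tail (GO) or the equivalent
#' one-sided Fisher test (pathway); Q values are Benjamini-Hochberg
#' across the terms of the run. Significance follows the domain's rule:
#' raw \eqn{P < 0.05} for GO, \eqn{Q < 0.05} for pathways. The
#' enrichment factor is \eqn{(m/n)/(M/N)}.
#'
#' @param degGenes character vector of DEG ids (subset of background).
#' @param background character vector of all genes considered.
#' @param geneSets named list: term id -> character vector of gene ids;
#'   an optional \code{"description"} attribute per element (or a
#'   \code{descriptions} named character vector) supplies term
#'   descriptions.
#' @param domain "GO" or "pathway".
#' @param descriptions optional named character vector of term
#'   descriptions.
#' @return data.frame with columns \code{term_id}, \code{description},
#'   \code{N}, \code{n}, \code{M}, \code{m}, \code{p}, \code{q},
#'   \code{enrichment_factor}, \code{significant}, in the input term
#'   order.
#' @export
enrich <- function(degGenes, background, geneSets,
                   domain = c("GO", "pathway"), descriptions = NULL) {
  domain <- match.arg(domain)
  if (!length(background)) stop("background is empty")
  degGenes <- unique(degGenes)
  background <- unique(background)
  if (!all(degGenes %in% background))
    stop("degGenes must be a subset of background")
  geneSets <- lapply(geneSets, function(s) intersect(unique(s), background))
  annotated <- unique(unlist(geneSets, use.names = FALSE))
  N <- length(annotated)
  if (N == 0) stop("no background gene carries any annotation")
  deg <- intersect(degGenes, annotated)
  n <- length(deg)
  M <- vapply(geneSets, length, 0L)
  m <- vapply(geneSets, function(s) sum(deg %in% s), 0L)
  pfun <- if (domain == "GO") hypergeomEnrichmentP else fisherPathwayP
  p <- ifelse(M == 0 | n == 0, 1, pfun(N, n, M, m))
  q <- bhFdr(p)
  ef <- ifelse(n > 0 & M > 0, (m / n) / (M / N), NA_real_)
  sig <- if (domain == "GO") p < 0.05 else q < 0.05
  data.frame(term_id = names(geneSets),
             description = if (is.null(descriptions)) names(geneSets)
                           else unname(descriptions[names(geneSets)]),
             N = N, n = n, M = unname(M), m = unname(m),
             p = unname(p), q = unname(q),
             enrichment_factor = unname(ef),
             significant = unname(sig),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top enriched terms by enrichment factor
#'
#' Filters an enrichment table to its significant terms and returns the
#' first \code{k} ordered by decreasing enrichment factor, ties broken
#' by increasing P then term id.
#'
#' @param table result of [enrich()].
#' @param k number of terms to keep (default 15).
#' @return the ranked sub-table (possibly shorter than \code{k}).
#' @export
topTerms <- function(table, k = 15) {
  s <- table[table$significant, , drop = FALSE]
  o <- order(-s$enrichment_factor, s$p, s$term_id)
  utils::head(s[o, , drop = FALSE], k)
}

#' Pathway significance heatmap matrix
#'
#' Builds the \eqn{-\log_{10} P} matrix over the union of pathways
#' significant in at least one comparison (columns stay in the supplied
#' comparison order; a pathway missing from a comparison contributes
#' \eqn{P = 1}, i.e. 0). Rows are ordered by average-linkage
#' hierarchical clustering on Euclidean distance.
#'
#' @param tables named list of [enrich()] results (>= 2 comparisons).
#' @return list with \code{matrix} (rows in dendrogram order),
#'   \code{rowOrder} (pathway ids) and \code{hclust} (the row
#'   clustering, NULL when fewer than 3 rows).
#' @export
pathwayHeatmapMatrix <- function(tables) {
  if (length(tables) < 2L) stop("need at least two comparisons")
  if (is.null(names(tables)))
    names(tables) <- paste0("cmp", seq_along(tables))
  sig <- unique(unlist(lapply(tables, function(t)
    t$term_id[t$significant])))
  if (!length(sig))
    return(list(matrix = matrix(0, 0, length(tables),
                                dimnames = list(NULL, names(tables))),
                rowOrder = character(), hclust = NULL))
  m <- vapply(tables, function(t) {
    p <- t$p[match(sig, t$term_id)]
    p[is.na(p)] <- 1
    -log10(p)
  }, numeric(length(sig)))
  if (length(sig) == 1L) m <- matrix(m, nrow = 1L,
                                     dimnames = list(sig, names(tables)))
  else rownames(m) <- sig
  hc <- NULL
  ord <- seq_len(nrow(m))
  if (nrow(m) >= 3L) {
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "average")
    ord <- hc$order
  }
  list(matrix = m[ord, , drop = FALSE], rowOrder = rownames(m)[ord],
       hclust = hc)
}
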