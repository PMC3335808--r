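#' @include normalize.R exact-test.R
NULL

#' Call differentially expressed genes between library pairs
#'
#' For each ordered library pair, applies the Audic-Claverie exact test
#' per gene using TMM effective library sizes, adjusts P values by
#' Benjamini-Hochberg within the pair, and calls a gene up-regulated
#' when \eqn{\log_2 FC \ge} \code{lfcThreshold}, \eqn{P \le}
#' \code{pThreshold} and \eqn{FDR <} \code{fdrThreshold} (down-regulated
#' symmetrically; otherwise NS). The fold change uses the raw normalised
#' ratio for genes observed in both libraries and a pseudo-count of 1
#' only when a zero count would make the ratio infinite, so the
#' four-fold threshold keeps its exact meaning for co-expressed genes.
#' The per-gene table carries \code{logMean} (average log2 counts per
#' million) for smear-plot export.
#'
#' @param object a \linkS4class{GeneCountMatrix}.
#' @param pairs list of length-2 character vectors (A, B); default the
#'   three consecutive time-course pairs.
#' @param pThreshold P-value threshold (inclusive).
#' @param fdrThreshold FDR threshold (strict).
#' @param lfcThreshold absolute log2 fold-change threshold (inclusive).
#' @param refLabel TMM reference library.
#' @param norm optional precomputed [tmmFactors()] result.
#' @return named list of \linkS4class{DEComparison} objects
#'   ("A_vs_B").
#' @export
callDEGs <- function(object, pairs = consecutivePairs(),
                     pThreshold = 0.01, fdrThreshold = 0.01,
                     lfcThreshold = 2, refLabel = colnames(object)[1],
                     norm = NULL) {
  cts <- SummarizedExperiment::assay(object, "counts")
  for (pr in pairs)
    if (!all(pr %in% colnames(cts)))
      stop("pair ", paste(pr, collapse = ":"), " not in the matrix")
  if (is.null(norm)) norm <- tmmFactors(object, refLabel)
  eff <- stats::setNames(norm$effectiveSize, norm$library)
  out <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    x <- cts[, a]; y <- cts[, b]
    nA <- eff[a]; nB <- eff[b]
    p <- exactTestP(x, y, nA, nB)
    fdr <- bhFdr(p)
    both <- x > 0 & y > 0
    lfc <- ifelse(both, logFoldChange(x, y, nA, nB, pseudo = 0),
                  logFoldChange(x, y, nA, nB, pseudo = 1))
    call <- rep("NS", length(x))
    pass <- p <= pThreshold & fdr < fdrThreshold
    call[pass & lfc >= lfcThreshold] <- "up"
    call[pass & lfc <= -lfcThreshold] <- "down"
    logMean <- log2(((x + 0.5) / nA + (y + 0.5) / nB) / 2 * 1e6)
    res <- data.frame(gene = rownames(cts), x = unname(x), y = unname(y),
                      log2fc = unname(lfc), p = unname(p),
                      fdr = unname(fdr), call = call,
                      logMean = unname(logMean),
                      stringsAsFactors = FALSE)
    new("DEComparison", pair = pr,
        effectiveSizes = stats::setNames(c(nA, nB), pr),
        results = res,
        thresholds = list(p = pThreshold, fdr = fdrThreshold,
                          lfc = lfcThreshold))
  })
  names(out) <- vapply(pairs, function(pr) paste(pr, collapse = "_vs_"), "")
  out
}

#' DEG genes of a comparison
#'
#' @param comparison a \linkS4class{DEComparison}.
#' @param direction "any", "up" or "down".
#' @return character vector of gene ids called DE.
#' @export
degGenes <- function(comparison, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  r <- deResults(comparison)
  keep <- if (direction == "any") r$call != "NS" else r$call == direction
  r$gene[keep]
}

#' Venn summary of DEG sets
#'
#' Counts the genes differentially expressed in exactly one, two, ...
#' of the supplied comparisons, and the distinct total.
#'
#' @param comparisons list of \linkS4class{DEComparison} objects or of
#'   character vectors of DEG ids (typically the three consecutive-pair
#'   comparisons).
#' @return list with \code{perComparison} (named sizes),
#'   \code{exactly} (integer vector; element k = genes DE in exactly k
#'   comparisons) and \code{distinct} (sum of the classes). The classes
#'   sum with multiplicity to the per-comparison total.
#' @export
vennSummary <- function(comparisons) {
  sets <- lapply(comparisons, function(cmp)
    if (is.character(cmp)) unique(cmp) else degGenes(cmp))
  if (length(sets) < 2L) stop("need at least two comparisons")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("cmp", seq_along(sets))
  univ <- unique(unlist(sets))
  times <- rowSums(vapply(sets, function(s) univ %in% s,
                          logical(length(univ))))
  exactly <- vapply(seq_along(sets), function(k) sum(times == k), 0L)
  list(perComparison = lengths(sets),
       exactly = exactly,
       distinct = length(univ))
}

#' Common-reference log2-ratio matrix
#'
#' Re-expresses every library as a log2 ratio to a common reference
#' time point: entry (g, L) is [logFoldChange()] of gene g between the
#' reference and library L under TMM effective sizes. The reference
#' column is identically zero.
#'
#' @inheritParams callDEGs
#' @param pseudo pseudo-count passed to [logFoldChange()].
#' @return numeric matrix, genes x libraries.
#' @export
toCommonReference <- function(object, refLabel = "0h", pseudo = 1,
                              norm = NULL) {
  cts <- SummarizedExperiment::assay(object, "counts")
  if (!refLabel %in% colnames(cts))
    stop("reference library '", refLabel, "' not in the matrix")
  if (is.null(norm)) norm <- tmmFactors(object, refLabel)
  eff <- stats::setNames(norm$effectiveSize, norm$library)
  x <- cts[, refLabel]
  out <- vapply(colnames(cts), function(lab)
    logFoldChange(x, cts[, lab], eff[refLabel], eff[lab], pseudo),
    numeric(nrow(cts)))
  rownames(out) <- rownames(cts)
  out
}

#' Log-scale expression profiles for clustering
#'
#' Returns the genes x libraries matrix clustered by
#' [clusterProfiles()]: by default \eqn{\log_2(\mathrm{CPM} + 1)} on TMM
#' effective sizes (tag count on a log2 scale); alternatively the
#' common-reference log2 ratios of [toCommonReference()].
#'
#' @inheritParams toCommonReference
#' @param genes optional subset of gene ids (e.g. the DEG union).
#' @param method "logCPM" or "commonReference".
#' @return numeric matrix, genes x libraries.
#' @export
expressionProfiles <- function(object, genes = NULL,
                               method = c("logCPM", "commonReference"),
                               refLabel = colnames(object)[1],
                               norm = NULL) {
  method <- match.arg(method)
  if (is.null(norm)) norm <- tmmFactors(object, refLabel)
  m <- if (method == "logCPM") {
    cts <- SummarizedExperiment::assay(object, "counts")
    eff <- stats::setNames(norm$effectiveSize, norm$library)
    log2(sweep(cts, 2, eff[colnames(cts)], "/") * 1e6 + 1)
  } else {
    toCommonReference(object, refLabel = refLabel, norm = norm)
  }
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  m
}
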