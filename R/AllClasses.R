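#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' TagLibrary: one sample's clean tag counts plus filter-stage statistics
#'
#' A \code{TagLibrary} holds the distinct clean tags of one DGE library —
#' 21-nt sequences anchored on the NlaIII site (\code{CATG} + 17 nt) — with
#' their copy numbers, together with the bookkeeping of every cleaning
#' stage (raw reads, adaptor-only removal, ambiguous-base removal,
#' structure filtering, singleton removal).
#'
#' In the clean state every stored tag has length 21, begins with
#' \code{CATG} and has copy number at least 2; the stage counters are
#' non-increasing along the filter chain.
#'
#' @slot label sample label, e.g. \code{"0h"}.
#' @slot counts named integer vector; names are tag sequences, values
#'   copy numbers (all \eqn{\ge 2}).
#' @slot stats named list of stage counters; see [libraryStats()].
#'
#' @seealso [cleanReads()], [libraryStats()], [tagCounts()]
#' @export
setClass("TagLibrary",
  slots = c(label = "character", counts = "integer", stats = "list"))

.statsRequired <- c("raw", "afterAdaptorTrim", "afterQualityDrop",
                    "cleanTotal", "distinctClean")

setValidity("TagLibrary", function(object) {
  msg <- character()
  cnt <- object@counts
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  if (length(cnt)) {
    tg <- names(cnt)
    if (is.null(tg) || anyNA(tg)) msg <- c(msg, "counts must be named by tag")
    else {
      if (any(nchar(tg) != 21L)) msg <- c(msg, "all tags must be 21 nt")
      if (!all(startsWith(tg, "CATG"))) msg <- c(msg, "all tags must start with CATG")
      if (anyDuplicated(tg)) msg <- c(msg, "tags must be unique")
    }
    if (any(cnt < 2L)) msg <- c(msg, "clean libraries contain no singletons (all counts >= 2)")
  }
  st <- object@stats
  if (!all(.statsRequired %in% names(st))) {
    msg <- c(msg, paste("stats must contain:", paste(.statsRequired, collapse = ", ")))
  } else {
    if (!(st$raw >= st$afterAdaptorTrim &&
          st$afterAdaptorTrim >= st$afterQualityDrop &&
          st$afterQualityDrop >= st$cleanTotal))
      msg <- c(msg, "stage counters must satisfy raw >= afterAdaptorTrim >= afterQualityDrop >= cleanTotal")
    if (st$distinctClean > st$cleanTotal && st$cleanTotal > 0)
      msg <- c(msg, "distinctClean must not exceed cleanTotal")
    if (st$cleanTotal != sum(cnt)) msg <- c(msg, "cleanTotal must equal sum(counts)")
    if (st$distinctClean != length(cnt)) msg <- c(msg, "distinctClean must equal length(counts)")
  }
  if (length(msg)) msg else TRUE
})

#' VirtualTagDB: all CATG+17-nt windows of a reference transcript set
#'
#' The virtual tag database enumerates, for every reference gene, every
#' sense-strand occurrence of \code{CATG} with at least 17 nt downstream;
#' each such window yields one 21-nt virtual tag. Tags shared by several
#' genes are kept with the union of their owners and flagged ambiguous at
#' mapping time. The 3'-rank records each tag's position among its gene's
#' tags (rank 1 = 3'-most, the tag the protocol actually captures).
#'
#' @slot entries data.frame with columns \code{tag}, \code{gene_id},
#'   \code{rank} (one row per tag/gene pair).
#' @slot tagIndex named list: tag sequence -> character vector of owning
#'   gene ids.
#' @slot genes character vector of all reference gene ids (including
#'   genes without any taggable site).
#' @slot noTagGenes gene ids with no CATG+17-nt window (undetectable by
#'   the assay).
#'
#' @seealso [buildVirtualTagDB()], [mapTags()]
#' @export
setClass("VirtualTagDB",
  slots = c(entries = "data.frame", tagIndex = "list",
            genes = "character", noTagGenes = "character"))

setValidity("VirtualTagDB", function(object) {
  msg <- character()
  e <- object@entries
  if (!all(c("tag", "gene_id", "rank") %in% names(e)))
    msg <- c(msg, "entries needs columns tag, gene_id, rank")
  else if (nrow(e)) {
    if (any(nchar(e$tag) != 21L) || !all(startsWith(e$tag, "CATG")))
      msg <- c(msg, "entry tags must be CATG + 17 nt")
    if (any(e$rank < 1L)) msg <- c(msg, "ranks start at 1")
    if (!all(e$gene_id %in% object@genes))
      msg <- c(msg, "entry gene ids must appear in genes")
  }
  if (any(lengths(object@tagIndex) < 1L))
    msg <- c(msg, "every indexed tag must own at least one gene")
  if (length(msg)) msg else TRUE
})

#' GeneCountMatrix: genes x libraries tag counts
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding the integer
#' gene-level tag counts after unique-tag mapping. \code{colData} carries
#' a \code{librarySize} column equal to the total mapped tag instances of
#' each library (the column sums), the sizes the exact test conditions on.
#'
#' @seealso [buildGeneCountMatrix()], [tmmFactors()], [callDEGs()]
#' @export
setClass("GeneCountMatrix", contains = "SummarizedExperiment")

setValidity("GeneCountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts))) msg <- c(msg, "counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  if (!"librarySize" %in% names(cd)) msg <- c(msg, "colData needs a librarySize column")
  else if (!isTRUE(all.equal(unname(colSums(cts)), as.numeric(cd$librarySize))))
    msg <- c(msg, "librarySize must equal the column sums of counts")
  if (length(msg)) msg else TRUE
})

#' DEComparison: exact-test results for one library pair
#'
#' Per-gene counts, log2 fold change, Audic-Claverie exact-test P value,
#' Benjamini-Hochberg FDR and the up/down/NS call for one ordered pair of
#' libraries (A -> B), under TMM effective library sizes.
#'
#' @slot pair character of length 2: labels of libraries A and B.
#' @slot effectiveSizes named numeric of length 2: TMM effective sizes.
#' @slot results data.frame with columns \code{gene}, \code{x}, \code{y},
#'   \code{log2fc}, \code{p}, \code{fdr}, \code{call}, \code{logMean}.
#' @slot thresholds list with \code{p}, \code{fdr}, \code{lfc}.
#' @seealso [callDEGs()], [deResults()]
#' @export
setClass("DEComparison",
  slots = c(pair = "character", effectiveSizes = "numeric",
            results = "data.frame", thresholds = "list"))

setValidity("DEComparison", function(object) {
  msg <- character()
  if (length(object@pair) != 2L) msg <- c(msg, "pair must have length 2")
  need <- c("gene", "x", "y", "log2fc", "p", "fdr", "call")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, paste("results needs columns:", paste(need, collapse = ", ")))
  else if (!all(object@results$call %in% c("up", "down", "NS")))
    msg <- c(msg, "call must be up/down/NS")
  if (length(msg)) msg else TRUE
})

#' ClusterModel: K-means partition of time-course expression profiles
#'
#' Result of Lloyd's algorithm on genes x time-points log2 expression
#' profiles: centroids, hard assignments, total within-cluster sum of
#' squares (inertia) and the peak-time pattern letters (A-D peak at the
#' four successive sampling times; remaining monotone clusters lettered
#' E, F, ... by decreasing size).
#'
#' @slot K integer, number of clusters.
#' @slot centroids K x T numeric matrix (T time points).
#' @slot assignments named integer vector, gene -> cluster index in 1..K.
#' @slot inertia total within-cluster sum of squared distances.
#' @slot patternLabels character of length K, one letter per cluster.
#' @seealso [clusterProfiles()], [labelPatterns()]
#' @export
setClass("ClusterModel",
  slots = c(K = "integer", centroids = "matrix", assignments = "integer",
            inertia = "numeric", patternLabels = "character"))

setValidity("ClusterModel", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@K) msg <- c(msg, "centroids must have K rows")
  a <- object@assignments
  if (length(a) && (min(a) < 1L || max(a) > object@K))
    msg <- c(msg, "assignments must lie in 1..K")
  if (is.null(names(a)) && length(a)) msg <- c(msg, "assignments must be named by gene")
  if (object@inertia < 0) msg <- c(msg, "inertia must be non-negative")
  if (length(object@patternLabels) &&
      length(object@patternLabels) != object@K)
    msg <- c(msg, "one pattern label per cluster")
  if (length(msg)) msg else TRUE
})
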