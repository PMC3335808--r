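#' @include AllClasses.R utils.R
NULL

#' Construct a TagLibrary from a clean count vector
#'
#' Builds a \linkS4class{TagLibrary} directly from a named vector of
#' clean tag counts (all tags 21 nt, CATG-anchored, counts >= 2), filling
#' trivially consistent stage statistics unless \code{stats} is given.
#' [cleanReads()] is the usual constructor; this one serves constructed
#' or re-imported libraries.
#'
#' @param counts named integer vector (tag -> copy number).
#' @param label sample label.
#' @param stats optional stage-counter list; defaults to a chain in which
#'   no read was lost.
#' @return a \linkS4class{TagLibrary}.
#' @export
TagLibrary <- function(counts, label = "library", stats = NULL) {
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (is.null(stats)) {
    tot <- sum(counts)
    stats <- list(raw = tot, afterAdaptorTrim = tot, afterQualityDrop = tot,
                  cleanTotal = tot, distinctClean = length(counts),
                  droppedAdaptorOnly = 0L, droppedAmbiguousBase = 0L,
                  droppedStructure = 0L, droppedSingleton = 0L,
                  mappedDistinct = NA_integer_, mappingRate = NA_real_)
  }
  new("TagLibrary", label = label, counts = counts, stats = stats)
}

# earliest 3'-anchored adaptor trim: longest suffix of the read (between
# minOverlap and nchar(adaptor) nt) equal to a prefix of the adaptor.
# Returns candidate tags; reads without an adaptor hit pass unchanged.
.trimAdaptor <- function(reads, adaptor, minOverlap) {
  w <- nchar(reads)
  cand <- reads
  done <- logical(length(reads))
  for (k in seq(nchar(adaptor), minOverlap)) {
    idx <- which(!done & w > k)
    if (!length(idx)) next
    hit <- substr(reads[idx], w[idx] - k + 1L, w[idx]) ==
      substr(adaptor, 1L, k)
    hi <- idx[hit]
    cand[hi] <- substr(reads[hi], 1L, w[hi] - k)
    done[hi] <- TRUE
  }
  cand
}

#' Clean raw reads into a tag library
#'
#' Applies the cleaning filters in order: (1) discard adaptor-only reads
#' (reads beginning with the full adaptor, or empty); (2) trim the
#' 3'-anchored adaptor to obtain the candidate tag; (3) discard
#' candidates containing an ambiguous base 'N' (the sole "low-quality"
#' criterion); (4-5) discard candidates whose length is not 21 nt or
#' that do not begin with \code{CATG} (structure filter — the protocol
#' guarantees CATG anchoring, so violations are read artifacts);
#' (6) count identical tags; (7) drop single-copy tags. Every stage's
#' loss is recorded in the library statistics.
#'
#' Adaptor trimming requires at least \code{minOverlap} nt of 3'-anchored
#' agreement with the adaptor's prefix, so short chance suffix matches
#' inside genuine tags are not trimmed (the same device as cutadapt's
#' minimum overlap); with the default 14-nt adaptor on 35-nt reads the
#' true adaptor always offers the full 14.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector of
#'   uppercase reads over A/C/G/T/N.
#' @param adaptor the 3' adaptor sequence.
#' @param label sample label stored in the library.
#' @param minOverlap minimum 3'-anchored adaptor overlap for trimming.
#' @return a \linkS4class{TagLibrary}; empty input yields an empty
#'   library with all-zero statistics.
#' @seealso [simulateTagLibrary()] for the read structure this inverts.
#' @export
cleanReads <- function(reads, adaptor = defaultAdaptor(),
                       label = "library", minOverlap = 10) {
  if (!is.character(reads)) reads <- as.character(reads)
  n <- length(reads)
  stats <- list(raw = n, afterAdaptorTrim = 0L, afterQualityDrop = 0L,
                cleanTotal = 0L, distinctClean = 0L,
                droppedAdaptorOnly = 0L, droppedAmbiguousBase = 0L,
                droppedStructure = 0L, droppedSingleton = 0L,
                mappedDistinct = NA_integer_, mappingRate = NA_real_)
  if (n == 0L)
    return(new("TagLibrary", label = label, counts = integer(), stats = stats))

  adaptorOnly <- startsWith(reads, adaptor) | nchar(reads) == 0L
  stats$droppedAdaptorOnly <- sum(adaptorOnly)
  reads <- reads[!adaptorOnly]
  stats$afterAdaptorTrim <- length(reads)

  cand <- .trimAdaptor(reads, adaptor, minOverlap)

  hasN <- grepl("N", cand, fixed = TRUE)
  stats$droppedAmbiguousBase <- sum(hasN)
  cand <- cand[!hasN]
  stats$afterQualityDrop <- length(cand)

  ok <- nchar(cand) == 21L & startsWith(cand, "CATG")
  stats$droppedStructure <- sum(!ok)
  cand <- cand[ok]

  tab <- table(cand)
  singles <- tab == 1L
  stats$droppedSingleton <- sum(tab[singles])
  tab <- tab[!singles]
  counts <- stats::setNames(as.integer(tab), names(tab))
  stats$cleanTotal <- sum(counts)
  stats$distinctClean <- length(counts)
  new("TagLibrary", label = label, counts = counts, stats = stats)
}

#' Distribution of distinct clean tags over abundance bins
#'
#' Counts how many distinct clean tags fall into each copy-number bin.
#' The bins must partition \eqn{[2, \infty)}: contiguous, non-overlapping
#' integer ranges starting at 2 with the last extending to infinity.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param bins list of \code{c(lo, hi)} integer ranges (hi of the last
#'   bin \code{Inf}).
#' @return data.frame with columns \code{lo}, \code{hi}, \code{label},
#'   \code{distinct}; the \code{distinct} column sums to the library's
#'   distinct clean tag count.
#' @export
abundanceDistribution <- function(lib,
    bins = list(c(2, 5), c(6, 10), c(11, 20), c(21, 50),
                c(51, 100), c(101, Inf))) {
  lo <- vapply(bins, `[`, 0, 1)
  hi <- vapply(bins, `[`, 0, 2)
  if (is.unsorted(lo, strictly = TRUE) || any(hi < lo))
    stop("bins must be sorted, non-overlapping ranges")
  if (lo[1] != 2 || !is.infinite(hi[length(hi)]) ||
      any(lo[-1] != hi[-length(hi)] + 1))
    stop("bins must partition [2, Inf)")
  cnt <- tagCounts(lib)
  distinct <- vapply(seq_along(bins), function(i)
    sum(cnt >= lo[i] & cnt <= hi[i]), 0L)
  data.frame(lo = lo, hi = hi,
             label = ifelse(is.infinite(hi), paste0(">=", lo),
                            paste0(lo, "-", hi)),
             distinct = distinct)
}

#' Tags private to and shared between libraries
#'
#' For every non-empty subset of the supplied libraries, counts the
#' distinct tags present in exactly those libraries. The counts sum to
#' the size of the union of all distinct tag sets.
#'
#' @param libs named list of at least two \linkS4class{TagLibrary}
#'   objects.
#' @return data.frame with columns \code{subset} (labels joined by
#'   \code{"+"}), \code{nLibraries} and \code{distinct}.
#' @export
libraryOverlap <- function(libs) {
  if (length(libs) < 2L) stop("need at least two libraries")
  labs <- vapply(libs, libraryLabel, "")
  if (anyDuplicated(labs)) labs <- names(libs)
  sets <- lapply(libs, function(l) names(tagCounts(l)))
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(m) paste(labs[m], collapse = "+"))
  k <- length(libs)
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(seq_len(k), sz, function(ix)
      paste(labs[ix], collapse = "+"), simplify = TRUE)))
  tab <- table(factor(key, levels = subsets))
  data.frame(subset = subsets,
             nLibraries = rep(seq_len(k), choose(k, seq_len(k))),
             distinct = as.integer(tab))
}

#' Gene-detection saturation curve
#'
#' Subsamples the library's tag instances without replacement at each
#' depth of an increasing grid (a single seeded permutation, read as
#' prefixes, so the realised curve is non-decreasing) and counts the
#' distinct genes detected with at least one mapped tag. A plateau
#' indicates the library was sequenced deeply enough to see essentially
#' every expressed gene.
#'
#' @param lib a \linkS4class{TagLibrary}.
#' @param geneOfTag named character vector mapping tag sequence to
#'   gene id (unmappable tags absent or NA); see [tagGeneMap()].
#' @param depthGrid increasing depths, each at most the library's clean
#'   tag total.
#' @param seed integer seed for the subsampling permutation.
#' @return data.frame with columns \code{depth} and \code{genes}.
#' @export
saturationCurve <- function(lib, geneOfTag, depthGrid, seed = 1) {
  cnt <- tagCounts(lib)
  total <- sum(cnt)
  if (is.unsorted(depthGrid, strictly = TRUE))
    stop("depthGrid must be strictly increasing")
  bad <- depthGrid[depthGrid > total]
  if (length(bad))
    stop("depth ", bad[1], " exceeds the clean tag total (", total, ")")
  inst <- rep(names(cnt), cnt)
  withSeed(seed, {
    perm <- if (length(inst)) sample.int(length(inst)) else integer()
    g <- unname(geneOfTag[inst[perm]])
    newGene <- !is.na(g) & !duplicated(g)
    cum <- cumsum(newGene)
    genes <- vapply(depthGrid, function(d)
      if (d == 0) 0L else cum[d], 0L)
    data.frame(depth = depthGrid, genes = genes)
  })
}
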