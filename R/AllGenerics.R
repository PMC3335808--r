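#' @include AllClasses.R
NULL

#' Accessors for TagDGE classes
#'
#' Small accessor generics: \code{tagCounts} returns the named count
#' vector of a \linkS4class{TagLibrary}; \code{libraryLabel} its sample
#' label; \code{libraryStats} its filter-stage counters;
#' \code{dbEntries} the tag/gene/rank table of a
#' \linkS4class{VirtualTagDB} and \code{noTagGenes} its undetectable
#' genes; \code{librarySizes} the mapped-tag totals of a
#' \linkS4class{GeneCountMatrix}; \code{deResults} the per-gene table of
#' a \linkS4class{DEComparison} and \code{dePair} its library labels;
#' \code{centroids}, \code{assignments}, \code{inertia} and
#' \code{patternLabels} the components of a \linkS4class{ClusterModel}.
#'
#' @param object an object of the corresponding TagDGE class.
#' @return the slot contents described above.
#' @name accessors
#' @aliases tagCounts libraryLabel libraryStats dbEntries noTagGenes
#'   librarySizes deResults dePair centroids assignments inertia
#'   patternLabels
NULL

#' @rdname accessors
#' @export
setGeneric("tagCounts", function(object) standardGeneric("tagCounts"))
#' @rdname accessors
#' @export
setGeneric("libraryLabel", function(object) standardGeneric("libraryLabel"))
#' @rdname accessors
#' @export
setGeneric("libraryStats", function(object) standardGeneric("libraryStats"))
#' @rdname accessors
#' @export
setGeneric("dbEntries", function(object) standardGeneric("dbEntries"))
#' @rdname accessors
#' @export
setGeneric("noTagGenes", function(object) standardGeneric("noTagGenes"))
#' @rdname accessors
#' @export
setGeneric("librarySizes", function(object) standardGeneric("librarySizes"))
#' @rdname accessors
#' @export
setGeneric("deResults", function(object) standardGeneric("deResults"))
#' @rdname accessors
#' @export
setGeneric("dePair", function(object) standardGeneric("dePair"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))
#' @rdname accessors
#' @export
setGeneric("inertia", function(object) standardGeneric("inertia"))
#' @rdname accessors
#' @export
setGeneric("patternLabels", function(object) standardGeneric("patternLabels"))

#' @rdname accessors
setMethod("tagCounts", "TagLibrary", function(object) object@counts)
#' @rdname accessors
setMethod("libraryLabel", "TagLibrary", function(object) object@label)
#' @rdname accessors
setMethod("libraryStats", "TagLibrary", function(object) object@stats)
#' @rdname accessors
setMethod("dbEntries", "VirtualTagDB", function(object) object@entries)
#' @rdname accessors
setMethod("noTagGenes", "VirtualTagDB", function(object) object@noTagGenes)
#' @rdname accessors
setMethod("librarySizes", "GeneCountMatrix", function(object) {
  s <- SummarizedExperiment::colData(object)$librarySize
  names(s) <- colnames(object)
  s
})
#' @rdname accessors
setMethod("deResults", "DEComparison", function(object) object@results)
#' @rdname accessors
setMethod("dePair", "DEComparison", function(object) object@pair)
#' @rdname accessors
setMethod("centroids", "ClusterModel", function(object) object@centroids)
#' @rdname accessors
setMethod("assignments", "ClusterModel", function(object) object@assignments)
#' @rdname accessors
setMethod("inertia", "ClusterModel", function(object) object@inertia)
#' @rdname accessors
setMethod("patternLabels", "ClusterModel", function(object) object@patternLabels)

setMethod("show", "TagLibrary", function(object) {
  st <- object@stats
  cat("TagLibrary '", object@label, "': ", length(object@counts),
      " distinct clean tags, ", st$cleanTotal, " tag instances\n", sep = "")
  cat("  stages: raw=", st$raw, " afterAdaptorTrim=", st$afterAdaptorTrim,
      " afterQualityDrop=", st$afterQualityDrop,
      " clean=", st$cleanTotal, "\n", sep = "")
  if (!is.null(st$mappedDistinct) && !is.na(st$mappedDistinct))
    cat("  mapped distinct: ", st$mappedDistinct, " (",
        formatC(st$mappingRate, format = "f", digits = 2), "%)\n", sep = "")
})

setMethod("show", "VirtualTagDB", function(object) {
  e <- object@entries
  amb <- sum(lengths(object@tagIndex) > 1L)
  cat("VirtualTagDB: ", length(object@tagIndex), " distinct virtual tags over ",
      length(object@genes), " genes (", amb, " ambiguous, ",
      length(object@noTagGenes), " genes without taggable site)\n", sep = "")
})

setMethod("show", "DEComparison", function(object) {
  r <- object@results
  cat("DEComparison ", object@pair[1], " -> ", object@pair[2], ": ",
      nrow(r), " genes; up=", sum(r$call == "up"),
      " down=", sum(r$call == "down"), " NS=", sum(r$call == "NS"), "\n",
      sep = "")
})

setMethod("show", "ClusterModel", function(object) {
  sz <- tabulate(object@assignments, nbins = object@K)
  cat("ClusterModel: K=", object@K, ", ", length(object@assignments),
      " genes, inertia=", format(object@inertia, digits = 6), "\n", sep = "")
  if (length(object@patternLabels)) {
    o <- order(object@patternLabels)
    cat("  patterns:", paste0(object@patternLabels[o], "(", sz[o], ")",
                              collapse = " "), "\n")
  }
})
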