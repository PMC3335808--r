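#' @include AllClasses.R synthetic.R
NULL

#' Build the virtual CATG+17-nt tag database
#'
#' Enumerates every sense-strand occurrence of \code{CATG} with at least
#' 17 nt downstream in every reference transcript; each window yields one
#' 21-nt virtual tag. Windows shared by several genes are merged into one
#' entry owning the union of genes (ambiguous tags). Each tag's 3'-rank
#' within its gene is recorded (rank 1 = the 3'-most site, the one the
#' NlaIII/oligo-dT protocol captures); rank is reported, not used in
#' counting.
#'
#' @param genes a [Biostrings::DNAStringSet] named by gene id.
#' @return a \linkS4class{VirtualTagDB}; genes with no taggable window
#'   are listed in [noTagGenes()].
#' @export
buildVirtualTagDB <- function(genes) {
  ids <- names(genes)
  seqs <- as.character(genes)
  per <- lapply(seq_along(seqs), function(i) {
    p <- .catgSites(seqs[i])
    if (!length(p)) return(NULL)
    p <- sort(p, decreasing = TRUE)   # rank 1 = 3'-most
    data.frame(tag = substr(rep(seqs[i], length(p)), p, p + 20L),
               gene_id = ids[i], rank = seq_along(p),
               stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, per)
  if (is.null(entries))
    entries <- data.frame(tag = character(), gene_id = character(),
                          rank = integer(), stringsAsFactors = FALSE)
  # a gene may contain the same 21-mer at several sites; one row per
  # tag/gene pair, keeping the most 3' (smallest) rank
  o <- order(entries$tag, entries$gene_id, entries$rank)
  entries <- entries[o, , drop = FALSE]
  dup <- duplicated(entries[c("tag", "gene_id")])
  entries <- entries[!dup, , drop = FALSE]
  rownames(entries) <- NULL
  tagIndex <- lapply(split(entries$gene_id, entries$tag), unique)
  new("VirtualTagDB", entries = entries, tagIndex = tagIndex,
      genes = ids, noTagGenes = setdiff(ids, unique(entries$gene_id)))
}

#' Unambiguous tag-to-gene lookup
#'
#' Returns the tag -> gene map restricted to virtual tags owned by
#' exactly one gene (the tags [mapTags()] can assign at zero mismatches),
#' as used by [saturationCurve()].
#'
#' @param db a \linkS4class{VirtualTagDB}.
#' @return named character vector (tag sequence -> gene id).
#' @export
tagGeneMap <- function(db) {
  ix <- db@tagIndex
  uni <- lengths(ix) == 1L
  stats::setNames(unlist(ix[uni], use.names = FALSE), names(ix)[uni])
}

# all 3 x width single-substitution neighbours of each tag
.neighbours <- function(tags, width = 21L) {
  n <- length(tags)
  if (!n) return(list(tag = character(), neighbour = character()))
  reps <- 3L * width
  tagRep <- rep(tags, each = reps)
  pos <- rep(rep(seq_len(width), each = 3L), times = n)
  cur <- substr(tagRep, pos, pos)
  altPool <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3L,
                    dimnames = list(NULL, .BASES))
  alt <- altPool[cbind(rep(1:3, times = width * n), match(cur, .BASES))]
  nb <- tagRep
  substr(nb, pos, pos) <- alt
  list(tag = tagRep, neighbour = nb)
}

#' Map clean tags to genes with at most one mismatch
#'
#' Assigns each distinct clean tag to a gene using the virtual tag
#' database: exact matches take precedence; a tag with no exact match is
#' compared through its single-substitution neighbours. At the tag's best
#' mismatch level, an entry set spanning more than one gene makes the tag
#' multigene and it is discarded (exact multigene tags are likewise
#' removed and excluded from the mapped-distinct count). Each gene's
#' expression value is the sum of the counts of its uniquely assigned
#' tags.
#'
#' @param lib a clean \linkS4class{TagLibrary}.
#' @param db a \linkS4class{VirtualTagDB}.
#' @param maxMismatch 0 or 1.
#' @return list with \code{geneCounts} (named integer over all reference
#'   genes), \code{assignments} (data.frame tag, count, gene_id,
#'   mismatch), \code{multigene} and \code{unmapped} (character vectors
#'   of discarded distinct tags), \code{mappedDistinct},
#'   the instance partition (\code{assignedInstances},
#'   \code{multigeneInstances}, \code{unmappedInstances}, summing to the
#'   library's clean total) and \code{library}, the input library with
#'   mapping statistics filled in.
#' @export
mapTags <- function(lib, db, maxMismatch = 1) {
  stopifnot(maxMismatch %in% c(0L, 1L))
  cnt <- tagCounts(lib)
  tags <- names(cnt)
  ix <- db@tagIndex
  hitGenes <- ix[tags]                       # NULL where no exact hit
  nExact <- lengths(hitGenes)
  exactUnique <- which(nExact == 1L)
  exactMulti <- which(nExact > 1L)
  noExact <- which(nExact == 0L)

  assigned <- data.frame(tag = tags[exactUnique],
                         count = unname(cnt[exactUnique]),
                         gene_id = unlist(hitGenes[exactUnique],
                                          use.names = FALSE) %||% character(),
                         mismatch = rep(0L, length(exactUnique)),
                         stringsAsFactors = FALSE)
  multigene <- tags[exactMulti]
  unmapped <- character()

  if (length(noExact) && maxMismatch >= 1L) {
    qt <- tags[noExact]
    nb <- .neighbours(qt)
    hit <- match(nb$neighbour, names(ix))
    ok <- !is.na(hit)
    if (any(ok)) {
      genesPerHit <- ix[hit[ok]]
      gl <- split(unlist(genesPerHit, use.names = FALSE),
                  rep(nb$tag[ok], lengths(genesPerHit)))
      gl <- lapply(gl, unique)
    } else gl <- list()
    nG <- lengths(gl)
    uni <- names(gl)[nG == 1L]
    multigene <- c(multigene, names(gl)[nG > 1L])
    unmapped <- setdiff(qt, names(gl))
    if (length(uni))
      assigned <- rbind(assigned, data.frame(
        tag = uni, count = unname(cnt[uni]),
        gene_id = unlist(gl[uni], use.names = FALSE),
        mismatch = 1L, stringsAsFactors = FALSE))
  } else if (length(noExact)) {
    unmapped <- tags[noExact]
  }

  geneCounts <- stats::setNames(integer(length(db@genes)), db@genes)
  if (nrow(assigned)) {
    agg <- tapply(assigned$count, assigned$gene_id, sum)
    geneCounts[names(agg)] <- as.integer(agg)
  }
  st <- lib@stats
  st$mappedDistinct <- nrow(assigned)
  st$mappingRate <- if (length(cnt) > 0)
    mappingRate(nrow(assigned), length(cnt)) else NA_real_
  libOut <- new("TagLibrary", label = lib@label, counts = lib@counts,
                stats = st)
  list(geneCounts = geneCounts,
       assignments = assigned,
       multigene = multigene,
       unmapped = unmapped,
       mappedDistinct = nrow(assigned),
       assignedInstances = sum(assigned$count),
       multigeneInstances = sum(cnt[multigene]),
       unmappedInstances = sum(cnt[unmapped]),
       library = libOut)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Distinct-tag mapping rate
#'
#' The percentage of distinct clean tags uniquely assigned to a gene,
#' rounded to two decimals with halves away from zero.
#'
#' @param mappedDistinct uniquely assigned distinct tags.
#' @param distinctClean distinct clean tags (> 0).
#' @return percentage on the 0-100 scale.
#' @examples
#' mappingRate(113281, 135590)  # 83.55
#' @export
mappingRate <- function(mappedDistinct, distinctClean) {
  if (any(distinctClean == 0))
    stop("mapping rate undefined: distinctClean is 0")
  roundHalfUp(100 * mappedDistinct / distinctClean, 2)
}

#' Assemble the gene count matrix from per-library mapping results
#'
#' @param mapResults named list (library label -> [mapTags()] result).
#' @return a \linkS4class{GeneCountMatrix}; column sums equal the
#'   per-library mapped tag instances stored as \code{librarySize}.
#' @importFrom SummarizedExperiment SummarizedExperiment
#' @export
buildGeneCountMatrix <- function(mapResults) {
  counts <- vapply(mapResults, function(m) m$geneCounts,
                   integer(length(mapResults[[1]]$geneCounts)))
  GeneCountMatrix(counts)
}

#' @rdname GeneCountMatrix-class
#' @param counts integer matrix, genes x libraries.
#' @param librarySizes per-library mapped tag instances; defaults to the
#'   column sums.
#' @export
GeneCountMatrix <- function(counts, librarySizes = colSums(counts)) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(librarySize = unname(librarySizes),
                                   row.names = colnames(counts)))
  new("GeneCountMatrix", se)
}
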