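#' @include utils.R
NULL

# library labels of the four-point reprogramming time course
.LIBS <- c("0h", "24h", "48h", "72h")

#' Time-course library labels and default adaptor
#'
#' \code{timeCourseLabels()} returns the four sampling-time labels used
#' throughout the package (\code{"0h"}, \code{"24h"}, \code{"48h"},
#' \code{"72h"}); \code{consecutivePairs()} the three consecutive library
#' pairs compared for differential expression; \code{defaultAdaptor()}
#' the fixed 14-nt 3' adaptor shared by the read simulator and the
#' cleaner (the protocol's adaptor sequence is configurable; simulator
#' and cleaner must simply agree).
#'
#' @return character vector / list of character pairs / single string.
#' @export
timeCourseLabels <- function() .LIBS

#' @rdname timeCourseLabels
#' @export
consecutivePairs <- function() {
  lapply(seq_len(length(.LIBS) - 1L), function(i) .LIBS[c(i, i + 1L)])
}

#' @rdname timeCourseLabels
#' @export
defaultAdaptor <- function() "TCGTATGCCGTCTT"

# positions (1-based, 5'->3') of CATG occurrences with >= 17 nt downstream
.catgSites <- function(seq) {
  hits <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer())
  hits <- as.integer(hits)
  hits[hits + 20L <= nchar(seq)]
}

#' Generate a synthetic reference transcriptome
#'
#' Draws \code{nGenes} random transcript sequences (uniform A/C/G/T) with
#' lengths uniform in \code{lengthRange}, guarantees every gene at least
#' one taggable NlaIII site (a \code{CATG} with >= 17 nt downstream; one
#' is planted at a random admissible position when none arises by
#' chance), and assigns GO terms and pathway memberships by sampling each
#' term's gene set with a size drawn uniformly from
#' \code{termSizeRange}.
#'
#' @param nGenes number of genes (>= 1).
#' @param lengthRange integer min/max transcript length; minimum 25 so a
#'   CATG + 17-nt tag fits.
#' @param nGoTerms,nPathways number of GO terms / pathways to simulate.
#' @param termSizeRange min/max genes per term (capped at \code{nGenes}).
#' @param seed integer seed; the output is byte-identical for equal seeds.
#' @return a [Biostrings::DNAStringSet] named by gene id, with
#'   \code{mcols()} columns \code{go} and \code{pathway}
#'   (CharacterLists of term ids).
#' @examples
#' ref <- generateReference(20, c(100, 300), seed = 1)
#' S4Vectors::mcols(ref)$go[[1]]
#' @importFrom Biostrings DNAStringSet
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom IRanges CharacterList
#' @export
generateReference <- function(nGenes, lengthRange = c(300, 1200),
                              nGoTerms = 40, nPathways = 20,
                              termSizeRange = c(5, 50), seed = NULL) {
  if (nGenes < 1) stop("nGenes must be >= 1")
  if (lengthRange[1] < 25)
    stop("minimum transcript length is 25 (CATG + 17 nt must fit)")
  withSeed(seed, {
    lens <- if (lengthRange[1] == lengthRange[2]) rep(lengthRange[1], nGenes)
            else sample(lengthRange[1]:lengthRange[2], nGenes, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(.BASES, L, replace = TRUE), collapse = ""), "")
    # plant a taggable CATG where chance produced none
    for (i in seq_along(seqs)) {
      if (!length(.catgSites(seqs[i]))) {
        p <- sample.int(lens[i] - 20L, 1L)
        substr(seqs[i], p, p + 3L) <- "CATG"
      }
    }
    ids <- sprintf("g%0*d", max(4L, nchar(nGenes)), seq_len(nGenes))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- ids
    S4Vectors::mcols(ref)$go <- .sampleAnnotation(ids, nGoTerms, "GO:%07d",
                                                  termSizeRange)
    S4Vectors::mcols(ref)$pathway <- .sampleAnnotation(ids, nPathways,
                                                       "path%04d",
                                                       termSizeRange)
    ref
  })
}

# per-gene CharacterList of term ids, terms sized uniformly in sizeRange
.sampleAnnotation <- function(ids, nTerms, fmt, sizeRange) {
  perGene <- rep(list(character()), length(ids))
  names(perGene) <- ids
  if (nTerms > 0) {
    for (t in seq_len(nTerms)) {
      sz <- min(length(ids), sample(sizeRange[1]:sizeRange[2], 1L))
      members <- sample(ids, sz)
      tid <- sprintf(fmt, t)
      for (g in members) perGene[[g]] <- c(perGene[[g]], tid)
    }
  }
  IRanges::CharacterList(perGene)
}

#' Simulate time-course expression truth
#'
#' Assigns each gene a mean expression level in the four libraries.
#' A fraction \code{deFraction} of genes is differentially expressed with
#' the mean ratio between at least one consecutive pair equal to exactly
#' \code{fold} (or \code{1/fold}); each DE gene follows one of six
#' trajectory shapes — a peak at one of the four sampling times (patterns
#' A-D) or a monotone decrease/increase (E/F) with every consecutive step
#' exactly \code{fold} — and all six shapes are represented whenever at
#' least six genes are DE. Non-DE genes keep \code{baseMean} in all four
#' libraries.
#'
#' @param genes a [Biostrings::DNAStringSet] from [generateReference()]
#'   or a character vector of gene ids.
#' @param deFraction probability a gene is differentially expressed.
#' @param fold effect size (>= 4, matching the pipeline's four-fold
#'   calling threshold \eqn{|log_2 ratio| \ge 2}).
#' @param baseMean baseline mean expression (arbitrary units; only
#'   relative values matter for read sampling).
#' @param seed integer seed.
#' @return data.frame with gene_id, the four per-library means
#'   (\code{mean_0h} .. \code{mean_72h}), the three consecutive-pair DE
#'   labels (\code{up}/\code{down}/\code{none}) and the pattern letter
#'   (A-F, or NA for non-DE genes).
#' @export
simulateExpressionProfiles <- function(genes, deFraction = 0.2, fold = 4,
                                       baseMean = 100, seed = NULL) {
  .checkProb(deFraction, "deFraction")
  if (fold < 4) stop("fold must be >= 4")
  ids <- if (is.character(genes)) genes else names(genes)
  n <- length(ids)
  withSeed(seed, {
    isDE <- stats::runif(n) < deFraction
    nDE <- sum(isDE)
    pats <- character(0)
    if (nDE > 0) {
      pats <- if (nDE >= 6)
        sample(c(LETTERS[1:6], sample(LETTERS[1:6], nDE - 6L, replace = TRUE)))
      else sample(LETTERS[1:6], nDE)
    }
    b <- baseMean; f <- fold
    shapes <- list(
      A = c(f * b, b, b, b),
      B = c(b, f * b, b, b),
      C = c(b, b, f * b, b),
      D = c(b, b, b, f * b),
      E = b * f^c(1.5, 0.5, -0.5, -1.5),
      F = b * f^c(-1.5, -0.5, 0.5, 1.5))
    means <- matrix(baseMean, n, 4,
                    dimnames = list(ids, paste0("mean_", .LIBS)))
    pattern <- rep(NA_character_, n)
    pattern[isDE] <- pats
    for (i in which(isDE)) means[i, ] <- shapes[[pattern[i]]]
    lab <- matrix("none", n, 3)
    for (j in 1:3) {
      r <- means[, j + 1] / means[, j]
      lab[r >= f - 1e-9, j] <- "up"
      lab[r <= 1 / f + 1e-9, j] <- "down"
    }
    out <- data.frame(gene_id = ids, means, stringsAsFactors = FALSE)
    out$de_0h_24h <- lab[, 1]
    out$de_24h_48h <- lab[, 2]
    out$de_48h_72h <- lab[, 3]
    out$pattern <- pattern
    rownames(out) <- NULL
    out
  })
}

#' Simulate one raw tag-read library
#'
#' Emulates the DGEP read structure: each sampled transcript molecule
#' contributes its 3'-most CATG + 17-nt sense tag, padded with the 3'
#' adaptor to 35 nt. Per-gene molecule counts are multinomial on the
#' normalised per-library means of the truth table (fixed total depth,
#' matching the fixed-library-size conditioning of the exact test).
#' Contamination classes: a fraction of reads are pure (cycled) adaptor;
#' a fraction of tag reads carry an ambiguous base 'N' at a random
#' position within the tag; substitution errors hit every base
#' independently at \code{errorRate} (no indels — mapping tolerates
#' substitutions only). Genes without a taggable CATG site contribute no
#' reads and are flagged undetectable in the origin table.
#'
#' @param genes reference [Biostrings::DNAStringSet].
#' @param truth truth table from [simulateExpressionProfiles()].
#' @param library which library to simulate ("0h", "24h", "48h", "72h").
#' @param depth total reads.
#' @param errorRate per-base substitution probability.
#' @param adaptorOnlyFraction fraction of reads that are pure adaptor.
#' @param nReadFraction fraction of tag reads given an 'N'.
#' @param adaptor 3' adaptor sequence (shared with [cleanReads()]).
#' @param readLength read length in nt (tag + adaptor fill).
#' @param seed integer seed; output deterministic given the seed.
#' @return list with \code{reads} (a [Biostrings::DNAStringSet]),
#'   \code{origin} (data.frame gene_id, tag, count, detectable — the
#'   error-free per-gene tag-read counts), \code{label},
#'   \code{nAdaptorOnly} and \code{nNReads}.
#' @export
simulateTagLibrary <- function(genes, truth, library = "0h", depth = 1e5,
                               errorRate = 0, adaptorOnlyFraction = 0,
                               nReadFraction = 0,
                               adaptor = defaultAdaptor(),
                               readLength = 35, seed = NULL) {
  .checkProb(errorRate, "errorRate")
  .checkProb(adaptorOnlyFraction, "adaptorOnlyFraction")
  .checkProb(nReadFraction, "nReadFraction")
  if (depth <= 0) stop("depth must be positive")
  if (!library %in% names(truth) && !library %in% .LIBS)
    stop("unknown library label: ", library)
  ids <- names(genes)
  if (!all(truth$gene_id %in% ids))
    stop("every gene in the truth table must exist in the reference")
  meanCol <- paste0("mean_", library)
  if (!meanCol %in% names(truth)) stop("truth lacks column ", meanCol)

  seqs <- as.character(genes)
  tags <- vapply(seqs, function(s) {
    p <- .catgSites(s)
    if (!length(p)) NA_character_ else substr(s, max(p), max(p) + 20L)
  }, "", USE.NAMES = FALSE)
  names(tags) <- ids
  tagOf <- tags[truth$gene_id]
  detectable <- !is.na(tagOf)
  mu <- truth[[meanCol]]

  withSeed(seed, {
    nAdapt <- stats::rbinom(1L, depth, adaptorOnlyFraction)
    nTag <- depth - nAdapt
    prob <- mu * detectable
    if (sum(prob) <= 0 && nTag > 0)
      stop("no detectable gene with positive expression")
    cnt <- if (nTag > 0) as.integer(stats::rmultinom(1L, nTag, prob))
           else integer(length(prob))
    fill <- cycleSeq(adaptor, readLength - 21L)
    reads <- rep(paste0(tagOf, fill)[cnt > 0], times = cnt[cnt > 0])
    # ambiguous-base contamination, placed inside the tag region
    nN <- stats::rbinom(1L, length(reads), nReadFraction)
    if (nN > 0) {
      hit <- sample.int(length(reads), nN)
      pos <- sample.int(21L, nN, replace = TRUE)
      for (k in seq_len(nN)) substr(reads[hit[k]], pos[k], pos[k]) <- "N"
    }
    if (nAdapt > 0) reads <- c(reads, rep(cycleSeq(adaptor, readLength), nAdapt))
    # per-base substitution errors over the whole read
    if (errorRate > 0 && length(reads)) {
      L <- readLength
      err <- which(stats::runif(length(reads) * L) < errorRate)
      for (e in err) {
        i <- ((e - 1L) %/% L) + 1L
        p <- ((e - 1L) %% L) + 1L
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(.BASES, cur), 1L)
      }
    }
    if (length(reads)) reads <- reads[sample.int(length(reads))]
    rd <- Biostrings::DNAStringSet(reads)
    if (length(rd)) names(rd) <- sprintf("read_%s_%06d", library, seq_along(rd))
    origin <- data.frame(gene_id = truth$gene_id,
                         tag = unname(tagOf),
                         count = cnt,
                         detectable = detectable,
                         stringsAsFactors = FALSE)
    list(reads = rd, origin = origin, label = library,
         nAdaptorOnly = nAdapt, nNReads = nN)
  })
}

#' Simulate a gene count matrix directly from expression truth
#'
#' The multinomial count layer of [simulateTagLibrary()] without the
#' read strings: for each library, per-gene counts are multinomial on
#' the normalised truth means at fixed total depth. Useful for
#' calibration studies of the testing stage where the read, cleaning and
#' mapping layers are exercised separately.
#'
#' @param truth truth table from [simulateExpressionProfiles()].
#' @param depth total tag count per library.
#' @param seed integer seed.
#' @return a \linkS4class{GeneCountMatrix}, genes x the four libraries.
#' @export
simulateCountMatrix <- function(truth, depth = 1e5, seed = NULL) {
  withSeed(seed, {
    cts <- vapply(.LIBS, function(lab)
      as.integer(stats::rmultinom(1L, depth, truth[[paste0("mean_", lab)]])),
      integer(nrow(truth)))
    rownames(cts) <- truth$gene_id
    GeneCountMatrix(cts)
  })
}

#' Simulate the full four-library time course
#'
#' Convenience wrapper calling [simulateTagLibrary()] once per library
#' with per-library seeds derived from \code{seed}.
#'
#' @inheritParams simulateTagLibrary
#' @param seed base seed; library i uses \code{seed + i - 1}.
#' @return named list of [simulateTagLibrary()] results, one per label.
#' @export
simulateTimeCourse <- function(genes, truth, depth = 1e5, errorRate = 0,
                               adaptorOnlyFraction = 0, nReadFraction = 0,
                               adaptor = defaultAdaptor(), seed = 1) {
  sims <- lapply(seq_along(.LIBS), function(i) {
    simulateTagLibrary(genes, truth, library = .LIBS[i], depth = depth,
                       errorRate = errorRate,
                       adaptorOnlyFraction = adaptorOnlyFraction,
                       nReadFraction = nReadFraction, adaptor = adaptor,
                       seed = seed + i - 1L)
  })
  names(sims) <- .LIBS
  sims
}
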