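#' @include AllClasses.R cleaning.R
NULL

#' Read and write pipeline files
#'
#' Plain-text interchange for every stage: FASTA references and FASTQ
#' reads (via Biostrings; FASTQ qualities are a fixed 'I'), clean tag
#' libraries and gene count matrices as TSV, library statistics as a
#' table shaped like a DGEP library-summary table (sample, raw,
#' trim_adaptor, drop_low_quality, clean, distinct, mapped, rate),
#' truth tables as TSV, and gene sets as GMT-style TSV
#' (term, description, then gene ids).
#'
#' @param x object to write (see individual functions).
#' @param path file path.
#' @name tagdge-io
NULL

#' @rdname tagdge-io
#' @export
writeReferenceFasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
readReferenceFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' @rdname tagdge-io
#' @importFrom Biostrings BStringSet writeXStringSet readDNAStringSet
#' @export
writeReadsFastq <- function(x, path) {
  if (is.character(x)) {
    nm <- names(x) %||% sprintf("read_%06d", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
    names(x) <- nm
  }
  qual <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    strrep("I", w), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
readReadsFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname tagdge-io
#' @export
writeTagLibrary <- function(x, path) {
  cnt <- tagCounts(x)
  utils::write.table(data.frame(tag = names(cnt), count = unname(cnt)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge-io
#' @param label sample label for the re-imported library.
#' @export
readTagLibrary <- function(path, label = "library") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  TagLibrary(stats::setNames(df$count, df$tag), label = label)
}

#' @rdname tagdge-io
#' @param libs named list of \linkS4class{TagLibrary} objects.
#' @export
writeLibraryStatsTable <- function(libs, path) {
  rows <- lapply(libs, function(l) {
    st <- libraryStats(l)
    data.frame(sample = libraryLabel(l), raw = st$raw,
               trim_adaptor = st$afterAdaptorTrim,
               drop_low_quality = st$afterQualityDrop,
               clean = st$cleanTotal, distinct = st$distinctClean,
               mapped = st$mappedDistinct, rate = st$mappingRate,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
writeGeneCountMatrix <- function(x, path) {
  cts <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
readGeneCountMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  GeneCountMatrix(m)
}

#' @rdname tagdge-io
#' @export
writeTruthTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
readTruthTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' @rdname tagdge-io
#' @param geneSets named list of gene-id vectors.
#' @param descriptions optional named character vector of term
#'   descriptions (defaults to the term ids).
#' @export
writeGmt <- function(geneSets, path, descriptions = NULL) {
  lines <- vapply(names(geneSets), function(t) {
    d <- if (is.null(descriptions)) t else descriptions[[t]]
    paste(c(t, d, geneSets[[t]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname tagdge-io
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' @rdname tagdge-io
#' @param comparison a \linkS4class{DEComparison}.
#' @export
writeDEComparison <- function(comparison, path) {
  utils::write.table(deResults(comparison), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotation gene sets from a simulated reference
#'
#' Collects the per-gene GO or pathway annotations of a
#' [generateReference()] object into a term -> genes list suitable for
#' [enrich()] and [writeGmt()].
#'
#' @param genes the annotated [Biostrings::DNAStringSet].
#' @param which "go" or "pathway".
#' @return named list of gene-id vectors.
#' @export
annotationSets <- function(genes, which = c("go", "pathway")) {
  which <- match.arg(which)
  ann <- S4Vectors::mcols(genes)[[which]]
  ids <- names(genes)
  long <- data.frame(gene = rep(ids, lengths(ann)),
                     term = unlist(ann, use.names = FALSE),
                     stringsAsFactors = FALSE)
  lapply(split(long$gene, long$term), unique)
}
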