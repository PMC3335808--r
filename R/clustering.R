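#' @include AllClasses.R utils.R
NULL

# k-means++ initial centres: first centre uniform, later centres sampled
# with probability proportional to squared distance to the nearest chosen
# centre. Guarantees distinct rows whenever K distinct profiles exist.
.kmeansppCentres <- function(x, K) {
  n <- nrow(x)
  centres <- matrix(0, K, ncol(x))
  idx <- sample.int(n, 1L)
  centres[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centres[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # fewer distinct profiles than K: fall back to any unused rows
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centres[k, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centres[k, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centres
}

#' K-means clustering of time-course expression profiles
#'
#' Partitions genes into \code{K} clusters by Lloyd's algorithm with
#' Euclidean distance, taking the best (lowest inertia) of \code{nInit}
#' k-means++-seeded restarts. Deterministic given \code{seed}. The input
#' is typically the log2 expression profile matrix of the DEG union
#' across the three consecutive-pair comparisons (see
#' [expressionProfiles()]).
#'
#' @param profiles numeric matrix, genes x time points, finite values,
#'   rownames = gene ids.
#' @param K number of clusters (default 6, the six trajectory
#'   patterns).
#' @param nInit number of seeded restarts.
#' @param maxIter maximum Lloyd iterations per restart.
#' @param seed integer seed.
#' @return a \linkS4class{ClusterModel} with pattern labels assigned by
#'   [labelPatterns()] when the profiles have four columns.
#' @export
clusterProfiles <- function(profiles, K = 6, nInit = 20, maxIter = 100,
                            seed = 1) {
  profiles <- as.matrix(profiles)
  if (!all(is.finite(profiles))) stop("profiles must be finite")
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(profiles))
    stop("K (", K, ") exceeds the number of genes (", nrow(profiles), ")")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("gene", seq_len(nrow(profiles)))
  best <- NULL
  withSeed(seed, {
    for (i in seq_len(nInit)) {
      centres <- .kmeansppCentres(profiles, K)
      fit <- suppressWarnings(tryCatch(
        stats::kmeans(profiles, centers = centres, iter.max = maxIter,
                      algorithm = "Lloyd"),
        error = function(e) NULL))
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  if (is.null(best)) stop("k-means failed on every restart")
  model <- new("ClusterModel", K = as.integer(K),
               centroids = unname(best$centers),
               assignments = stats::setNames(as.integer(best$cluster),
                                             rownames(profiles)),
               inertia = best$tot.withinss,
               patternLabels = character())
  if (ncol(profiles) == 4L) model@patternLabels <- labelPatterns(model)
  model
}

#' Label clusters by time-course pattern
#'
#' Assigns the letters A-D to clusters whose centroid peaks at the
#' first, second, third or fourth time point (a peak, as opposed to a
#' monotone trend: the centroid is not steadily decreasing or
#' increasing). Monotone clusters — and any surplus cluster sharing a
#' peak time with a larger one — receive the remaining letters E, F, ...
#' in order of decreasing size, ties broken by earlier peak time.
#' Monotonicity tolerates flat steps up to \code{monotoneTol} times the
#' centroid's range, so a sharp single peak followed by a flat tail is
#' not mistaken for a monotone trend.
#'
#' @param model a \linkS4class{ClusterModel} fitted on four time points.
#' @param monotoneTol flatness tolerance as a fraction of each
#'   centroid's range.
#' @return character vector of per-cluster letters.
#' @export
labelPatterns <- function(model, monotoneTol = 0.1) {
  cen <- centroids(model)
  if (ncol(cen) != 4L) stop("pattern labels are defined for 4 time points")
  K <- nrow(cen)
  sizes <- tabulate(assignments(model), nbins = K)
  peak <- apply(cen, 1L, which.max)
  monotone <- vapply(seq_len(K), function(k) {
    d <- diff(cen[k, ])
    tol <- monotoneTol * (max(cen[k, ]) - min(cen[k, ]))
    all(d < -tol) || all(d > tol)
  }, TRUE)
  labels <- rep(NA_character_, K)
  for (t in 1:4) {
    cand <- which(!monotone & peak == t)
    if (!length(cand)) next
    winner <- cand[order(-sizes[cand])][1L]
    labels[winner] <- LETTERS[t]
  }
  rest <- which(is.na(labels))
  rest <- rest[order(-sizes[rest], peak[rest])]
  labels[rest] <- LETTERS[4L + seq_along(rest)]
  labels
}

#' Export per-pattern gene lists
#'
#' Writes one TSV per pattern with columns \code{gene_id}, the profile
#' values and \code{cluster}; row counts across files sum to the number
#' of clustered genes. An empty cluster yields an empty file and a
#' warning.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param profiles the matrix the model was fitted on.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written file paths.
#' @export
exportClusterLists <- function(model, profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  labs <- patternLabels(model)
  if (!length(labs)) labs <- as.character(seq_len(model@K))
  asg <- assignments(model)
  files <- stats::setNames(file.path(dir, paste0("pattern_", labs, ".tsv")),
                           labs)
  for (k in seq_len(model@K)) {
    genes <- names(asg)[asg == k]
    if (!length(genes))
      warning("cluster ", labs[k], " is empty")
    df <- data.frame(gene_id = genes,
                     profiles[genes, , drop = FALSE],
                     cluster = rep(labs[k], length(genes)),
                     stringsAsFactors = FALSE, row.names = NULL)
    utils::write.table(df, files[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}

#' Read back exported cluster lists
#'
#' Inverse of [exportClusterLists()]: reconstructs the gene-to-pattern
#' assignment from a directory of per-pattern TSVs.
#'
#' @param dir directory written by [exportClusterLists()].
#' @return named character vector, gene id -> pattern letter.
#' @export
readClusterLists <- function(dir) {
  files <- list.files(dir, pattern = "^pattern_.*\\.tsv$",
                      full.names = TRUE)
  out <- character()
  for (f in files) {
    df <- utils::read.table(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    if (nrow(df))
      out[df$gene_id] <- df$cluster
  }
  out
}
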