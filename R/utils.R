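# internal helpers

.BASES <- c("A", "C", "G", "T")

# run expr under a local RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# round half away from zero (stats::round is half-to-even)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(sum(exp(lx))) without overflow; lx may be length 0 -> -Inf
logSumExp <- function(lx) {
  if (!length(lx)) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# cycle a short sequence to length n (used for adaptor-only reads)
cycleSeq <- function(s, n) {
  paste(rep_len(strsplit(s, "")[[1]], n), collapse = "")
}

.checkProb <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single probability in [0, 1]", call. = FALSE)
  x
}
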