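# small in-code fixtures shared across test files

# a tag with a given 17-nt body
tagOf <- function(body) paste0("CATG", body)

# deterministic 17-nt bodies distinct from one another
tagBody <- function(i) {
  set.seed(5000 + i)
  paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")
}

# a read carrying `tag` plus the default adaptor fill
readOf <- function(tag, adaptor = defaultAdaptor()) paste0(tag, adaptor)

# tiny annotated reference + truth + four simulated libraries
simWorld <- function(nGenes = 60, depth = 5000, deFraction = 0.2,
                     errorRate = 0, adaptorOnlyFraction = 0,
                     nReadFraction = 0, seed = 1) {
  ref <- generateReference(nGenes, c(150, 400), nGoTerms = 10,
                           nPathways = 6, termSizeRange = c(3, 15),
                           seed = seed)
  truth <- simulateExpressionProfiles(ref, deFraction = deFraction,
                                      fold = 4, baseMean = 100,
                                      seed = seed + 1)
  sims <- simulateTimeCourse(ref, truth, depth = depth,
                             errorRate = errorRate,
                             adaptorOnlyFraction = adaptorOnlyFraction,
                             nReadFraction = nReadFraction,
                             seed = seed + 10)
  list(ref = ref, truth = truth, sims = sims)
}
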