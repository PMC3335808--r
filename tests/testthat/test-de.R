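mkGcm <- function(cts) {
  if (is.null(rownames(cts))) rownames(cts) <- sprintf("g%03d", seq_len(nrow(cts)))
  GeneCountMatrix(cts)
}

test_that("TMM factors are 1 for identical or depth-scaled libraries", {
  set.seed(31)
  a <- rnbinom(500, mu = 50, size = 10) + 1L
  cts <- cbind(A = a, B = a)
  expect_equal(tmmFactors(mkGcm(cts), "A")$factor, c(1, 1))
  # pure depth change: every gene doubled, composition unchanged
  cts2 <- cbind(A = a, B = 2L * a)
  expect_equal(tmmFactors(mkGcm(cts2), "A")$factor, c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches a from-definition trimmed weighted mean", {
  set.seed(32)
  cts <- matrix(rnbinom(900, mu = 80, size = 8) + 1L, ncol = 3,
                dimnames = list(NULL, c("A", "B", "C")))
  cts[1:30, 2] <- cts[1:30, 2] * 10L   # spiked composition in B
  gcm <- mkGcm(cts)
  res <- tmmFactors(gcm, "A")

  # independent straightforward re-computation
  oracle <- function(obs, ref) {
    nO <- sum(cts[, obs]); nR <- sum(cts[, ref])
    o <- cts[, obs]; r <- cts[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    M <- log2((o / nO) / (r / nR))
    A <- 0.5 * log2((o / nO) * (r / nR))
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  raw <- c(oracle("A", "A"), oracle("B", "A"), oracle("C", "A"))
  raw[1] <- 1
  expected <- raw / exp(mean(log(raw)))
  expect_equal(res$factor, expected, tolerance = 1e-6)
  # factors multiply to 1 and effective sizes follow
  expect_equal(prod(res$factor), 1, tolerance = 1e-12)
  expect_equal(res$effectiveSize, res$librarySize * res$factor)
})

test_that("TMM agrees with edgeR's weighted TMM on a spiked matrix", {
  skip_if_not_installed("edgeR")
  set.seed(33)
  cts <- matrix(rnbinom(4000, mu = 100, size = 5) + 1L, ncol = 4,
                dimnames = list(NULL, timeCourseLabels()))
  cts[1:80, 2] <- cts[1:80, 2] * 6L
  gcm <- mkGcm(cts)
  mine <- tmmFactors(gcm, "0h")$factor
  ed <- edgeR::calcNormFactors(edgeR::DGEList(counts = cts),
                               method = "TMM", refColumn = 1)
  expect_equal(mine, unname(ed$samples$norm.factors), tolerance = 1e-10)
})

test_that("TMM errors when a pair shares no expressed gene", {
  cts <- cbind(A = c(5L, 0L), B = c(0L, 7L))
  rownames(cts) <- c("g1", "g2")
  expect_error(tmmFactors(GeneCountMatrix(cts), "A"), "no gene expressed")
})

test_that("exact test matches the negative-binomial tail oracle", {
  # the conditional p(k|x) is NB(size = x+1, prob = N1/(N1+N2))
  grid <- expand.grid(x = c(0, 1, 5, 20, 100, 1000),
                      y = c(0, 1, 5, 20, 100, 1000),
                      r = c(0.5, 1, 2.3))
  for (i in seq_len(nrow(grid))) {
    x <- grid$x[i]; y <- grid$y[i]; r <- grid$r[i]
    p <- exactTestP(x, y, 1e6, r * 1e6)
    pr <- 1 / (1 + r)
    lower <- pnbinom(y, size = x + 1, prob = pr)
    upper <- pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
    expect_equal(p, min(1, 2 * min(lower, upper)), tolerance = 1e-10)
  }
})

test_that("exact test is 1 for symmetric observations and near-symmetric on swap", {
  expect_identical(exactTestP(7, 7, 1e5, 1e5), 1)
  expect_identical(exactTestP(0, 0, 2e5, 1e5), 1)
  # swapping (x, N1) and (y, N2) changes p only through tail discreteness
  set.seed(34)
  for (i in 1:20) {
    x <- rpois(1, 40); y <- rpois(1, 60)
    n1 <- 1e6; n2 <- runif(1, 0.5, 2) * 1e6
    p1 <- exactTestP(x, y, n1, n2)
    p2 <- exactTestP(y, x, n2, n1)
    expect_lt(abs(log(p1) - log(p2)), log(2.5))
  }
  expect_error(exactTestP(1.5, 2, 1e5, 1e5), "integer")
})

test_that("log fold change follows the pseudo-count contract", {
  expect_equal(logFoldChange(10, 160, 1e6, 1e6, pseudo = 1), log2(161 / 11))
  expect_equal(logFoldChange(10, 160, 1e6, 1e6, pseudo = 0), 4)
  expect_equal(logFoldChange(5, 5, 1e6, 1e6), 0)
  expect_equal(logFoldChange(3, 90, 1e6, 2e6, 1),
               -logFoldChange(90, 3, 2e6, 1e6, 1))
})

test_that("BH adjustment matches the from-definition step-up oracle", {
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(0.03), 0.03)
  set.seed(35)
  p <- runif(10)
  # from-definition: q_(i) = min over j>=i of p_(j) * n / j
  o <- order(p); n <- 10
  q <- numeric(n)
  for (i in 1:n) q[o[i]] <- min(1, min(p[o][i:n] * n / (i:n)))
  expect_equal(bhFdr(p), q)
})

test_that("DEG calling is NS for absent genes and monotone in thresholds", {
  w <- simWorld(nGenes = 40, depth = 4000, seed = 131)
  gcm <- simulateCountMatrix(w$truth, depth = 4000, seed = 132)
  # plant an absent gene
  cts <- SummarizedExperiment::assay(gcm, "counts")
  cts["g0001", ] <- 0L
  gcm0 <- GeneCountMatrix(cts)
  cmps <- callDEGs(gcm0)
  for (cmp in cmps) {
    r <- deResults(cmp)
    expect_identical(r$call[r$gene == "g0001"], "NS")
  }
  nDeg <- function(cmps) sum(vapply(cmps, function(c) length(degGenes(c)), 0L))
  base <- nDeg(cmps)
  expect_gte(nDeg(callDEGs(gcm0, pThreshold = 0.05)), base)
  expect_gte(nDeg(callDEGs(gcm0, fdrThreshold = 0.05)), base)
  expect_gte(nDeg(callDEGs(gcm0, lfcThreshold = 1)), base)
})

test_that("null libraries produce few calls at the raw 1% level", {
  frac <- numeric(3)
  for (r in 1:3) {
    truth <- simulateExpressionProfiles(sprintf("g%04d", 1:800),
                                        deFraction = 0, seed = 140 + r)
    gcm <- simulateCountMatrix(truth, depth = 800 * 50, seed = 150 + r)
    cmps <- callDEGs(gcm)
    p <- unlist(lapply(cmps, function(c) deResults(c)$p))
    frac[r] <- mean(p <= 0.01)
    expect_identical(sum(vapply(cmps, function(c) length(degGenes(c)), 0L)), 0L)
  }
  se <- sqrt(0.01 * 0.99 / (800 * 3))
  expect_lte(mean(frac), 0.01 + 3 * se)
})

test_that("venn summary reproduces set algebra", {
  # three disjoint sets
  v <- vennSummary(list(a = paste0("x", 1:3), b = paste0("y", 1:4),
                        c = paste0("z", 1:5)))
  expect_identical(v$distinct, 12L)
  expect_identical(v$exactly, c(12L, 0L, 0L))

  # constructed overlaps vs brute force
  set.seed(36)
  univ <- sprintf("g%03d", 1:60)
  sets <- lapply(1:3, function(i) sample(univ, 25))
  v2 <- vennSummary(sets)
  times <- table(factor(unlist(lapply(sets, unique)),
                        levels = unique(unlist(sets))))
  expect_identical(v2$exactly,
                   vapply(1:3, function(k) sum(times == k), 0L))
  expect_identical(v2$distinct, length(unique(unlist(sets))))
  # multiplicity identity
  expect_identical(sum(v2$exactly * 1:3), sum(lengths(lapply(sets, unique))))
})

test_that("common-reference transform telescopes and matches recomputation", {
  set.seed(37)
  cts <- matrix(rnbinom(200, mu = 60, size = 8) + 1L, ncol = 4,
                dimnames = list(sprintf("g%02d", 1:50), timeCourseLabels()))
  gcm <- mkGcm(cts)
  norm <- tmmFactors(gcm, "0h")
  eff <- setNames(norm$effectiveSize, norm$library)
  cr <- toCommonReference(gcm, "0h", pseudo = 0, norm = norm)
  expect_true(all(cr[, "0h"] == 0))
  # telescoping with pseudo = 0
  cmp <- callDEGs(gcm, pairs = list(c("24h", "48h")), norm = norm)[[1]]
  lfc <- deResults(cmp)$log2fc
  expect_equal(unname(cr[, "48h"] - cr[, "24h"]), unname(lfc),
               tolerance = 1e-12)
  # direct recomputation with pseudo = 1
  cr1 <- toCommonReference(gcm, "0h", pseudo = 1, norm = norm)
  direct <- log2(((cts[, "72h"] + 1) / eff["72h"]) /
                   ((cts[, "0h"] + 1) / eff["0h"]))
  expect_equal(unname(cr1[, "72h"]), unname(direct))
})
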