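test_that("hypergeometric upper tail matches exact enumeration", {
  expect_identical(hypergeomEnrichmentP(100, 10, 20, 0), 1)
  # N=20, M=5, n=5, m=3: three tail terms 1050 + 75 + 1 over C(20,5)
  expect_equal(hypergeomEnrichmentP(20, 5, 5, 3), 1126 / 15504,
               tolerance = 1e-12)
  # single-term tail: C(5,4)/C(10,4)
  expect_equal(hypergeomEnrichmentP(10, 4, 5, 4), 5 / 210,
               tolerance = 1e-12)
  expect_error(hypergeomEnrichmentP(10, 11, 5, 3), "n > N")
  expect_error(hypergeomEnrichmentP(10, 4, 5, 5), "m > n")
})

test_that("Fisher and hypergeometric formulations coincide", {
  set.seed(41)
  for (i in 1:100) {
    N <- sample(20:2000, 1)
    n <- sample.int(N, 1)
    M <- sample.int(N, 1)
    rng <- max(0, n + M - N):min(n, M)
    m <- rng[sample.int(length(rng), 1)]
    expect_equal(fisherPathwayP(N, n, M, m),
                 hypergeomEnrichmentP(N, n, M, m), tolerance = 1e-9)
  }
  # most extreme table: single stratum
  expect_equal(fisherPathwayP(30, 6, 6, 6),
               choose(24, 0) * choose(6, 6) / choose(30, 6),
               tolerance = 1e-12)
  # table at its expectation is unremarkable
  expect_gt(fisherPathwayP(1000, 100, 100, 10), 0.05)
})

test_that("p is monotone non-increasing in m", {
  p <- hypergeomEnrichmentP(200, 40, 30, 0:20)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("enrich builds the N/n/M/m contingency counts on annotated genes", {
  bg <- sprintf("g%03d", 1:100)
  deg <- bg[1:10]
  sets <- list(all = bg, hit = deg)
  et <- enrich(deg, bg, sets, domain = "GO")
  expect_identical(et$N, c(100L, 100L))
  expect_identical(et$n, c(10L, 10L))
  expect_identical(et$m[et$term_id == "hit"], 10L)
  expect_equal(et$p[et$term_id == "hit"], 1 / choose(100, 10))
  # saturation: DEG set == background makes every factor 1
  etAll <- enrich(bg, bg, list(a = bg[1:30], b = bg[10:90]), domain = "GO")
  expect_equal(etAll$enrichment_factor, c(1, 1))
  expect_error(enrich(deg, character(), sets), "empty")
  expect_error(enrich(c(deg, "notInBg"), bg, sets), "subset")
})

test_that("GO uses raw p < 0.05 while pathways use q < 0.05", {
  bg <- sprintf("g%03d", 1:200)
  deg <- bg[1:20]
  # one strongly enriched term among many null ones
  set.seed(42)
  sets <- c(list(hit = c(deg[1:15], bg[100:104])),
            lapply(1:30, function(i) sample(bg, 20)))
  names(sets) <- c("hit", sprintf("null%02d", 1:30))
  go <- enrich(deg, bg, sets, domain = "GO")
  pw <- enrich(deg, bg, sets, domain = "pathway")
  expect_equal(go$p, pw$p, tolerance = 1e-9)
  expect_identical(go$significant, go$p < 0.05)
  expect_identical(pw$significant, pw$q < 0.05)
  # q values do not depend on term order
  perm <- sample(length(sets))
  pw2 <- enrich(deg, bg, sets[perm], domain = "pathway")
  expect_equal(pw2$q[match(pw$term_id, pw2$term_id)], pw$q)
})

test_that("a planted enriched term ranks first in nearly all replicates", {
  hits <- 0
  for (r in 1:20) {
    set.seed(500 + r)
    bg <- sprintf("g%04d", 1:600)
    sets <- lapply(1:30, function(t) sample(bg, 30))
    names(sets) <- sprintf("T%02d", 1:30)
    deg <- sample(bg, 40)
    sets[["T01"]] <- unique(c(sample(deg, 20), sample(bg, 10)))
    et <- enrich(deg, bg, sets, domain = "GO")
    hits <- hits + (et$term_id[which.min(et$p)] == "T01")
  }
  expect_gte(hits, 19)
})

test_that("top terms rank by enrichment factor with documented tie-breaks", {
  tab <- data.frame(
    term_id = c("t1", "t2", "t3", "t4", "t5"),
    description = "d", N = 100L, n = 10L, M = 10L,
    m = c(5L, 4L, 4L, 3L, 2L),
    p = c(0.01, 0.004, 0.002, 0.2, 0.3),
    q = 0.1,
    enrichment_factor = c(5, 4, 4, 3, 2),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  top <- topTerms(tab, k = 15)
  expect_identical(nrow(top), 3L)
  expect_identical(top$term_id, c("t1", "t3", "t2"))  # tie: smaller p first
  # from-definition sort oracle on a random table
  set.seed(43)
  tab2 <- data.frame(term_id = sprintf("t%02d", 1:20), description = "d",
                     N = 100L, n = 10L, M = 10L, m = 1L,
                     p = runif(20), q = runif(20),
                     enrichment_factor = sample(seq(0.5, 6, 0.5), 20, TRUE),
                     significant = runif(20) < 0.7,
                     stringsAsFactors = FALSE)
  top2 <- topTerms(tab2, k = 8)
  s <- tab2[tab2$significant, ]
  o <- s[order(-s$enrichment_factor, s$p, s$term_id), ]
  expect_identical(top2$term_id, head(o$term_id, 8))
})

test_that("pathway heatmap matrix is -log10 p with average-linkage row order", {
  mkTab <- function(p, sig) data.frame(
    term_id = sprintf("P%02d", seq_along(p)), description = "d",
    N = 100L, n = 10L, M = 10L, m = 2L, p = p, q = p,
    enrichment_factor = 1, significant = sig, stringsAsFactors = FALSE)
  t1 <- mkTab(c(0.001, 0.5, 0.2), c(TRUE, FALSE, FALSE))
  t2 <- mkTab(c(0.9, 0.01, 0.6), c(FALSE, TRUE, FALSE))
  hm <- pathwayHeatmapMatrix(list(a = t1, b = t2))
  expect_setequal(rownames(hm$matrix), c("P01", "P02"))
  expect_equal(hm$matrix["P01", "a"], -log10(0.001))
  expect_equal(hm$matrix["P02", "a"], -log10(0.5))
  # a pathway absent from a comparison contributes p = 1 -> 0
  t3 <- mkTab(c(0.002), TRUE); t3$term_id <- "P09"
  hm2 <- pathwayHeatmapMatrix(list(a = t1, b = t3))
  expect_equal(hm2$matrix["P09", "a"], 0)
  expect_gt(hm2$matrix["P09", "b"], 0)
  # identical tables: constant rows, deterministic output
  hmId <- pathwayHeatmapMatrix(list(a = t1, b = t1))
  expect_true(all(hmId$matrix[, 1] == hmId$matrix[, 2]))

  # linkage heights equal a naive O(n^3) average-linkage agglomeration
  set.seed(44)
  m <- matrix(runif(15, 0, 4), 5, 3)
  ps <- 10^(-m)
  tabs <- lapply(1:3, function(j) {
    tt <- mkTab(ps[, j], rep(TRUE, 5)); tt })
  names(tabs) <- c("a", "b", "c")
  hm3 <- pathwayHeatmapMatrix(tabs)
  naiveAvgLinkHeights <- function(x) {
    d <- as.matrix(dist(x))
    groups <- as.list(seq_len(nrow(x)))
    heights <- numeric(0)
    while (length(groups) > 1) {
      best <- c(NA, NA); bh <- Inf
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        h <- mean(d[groups[[i]], groups[[j]]])
        if (h < bh) { bh <- h; best <- c(j, i) }
      }
      heights <- c(heights, bh)
      groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
      groups[[best[2]]] <- NULL
    }
    heights
  }
  expect_equal(sort(hm3$hclust$height),
               sort(naiveAvgLinkHeights(-log10(ps))), tolerance = 1e-10)
})
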