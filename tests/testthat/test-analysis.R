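twoSeqMotifTrack <- function() {
  regionTrack(list(
    s1 = regionFrame(c(0, 10), c(5, 15), c("A", "A"), 1, "+"),
    s2 = regionFrame(c(3, 20), c(8, 26), c("A", "B"), 1, "-")),
    c(s1 = 100, s2 = 100))
}

test_that("occurrence counting reports totals and sequence support", {
  res <- countMotifOccurrences(twoSeqMotifTrack())
  expect_equal(res@rows$id, c("A", "B"))
  expect_equal(res@rows$total, c(3L, 1L))
  expect_equal(res@rows$support, c(2L, 1L))
  ## empty track: zero rows
  empty <- countMotifOccurrences(regionTrack(list(), c(a = 10)))
  expect_equal(nrow(empty@rows), 0L)
  ## restriction to a collection
  res1 <- countMotifOccurrences(twoSeqMotifTrack(), collection("sequence", "s1"))
  expect_equal(res1@rows$total, 2L)
  ## invariants: support <= #sequences, total >= support
  expect_true(all(res@rows$support <= 2))
  expect_true(all(res@rows$total >= res@rows$support))
})

test_that("overrepresentation p-values equal exhaustive binomial tails", {
  ## worked example: n=10, p=0.5, k=8 -> 56/1024
  counts <- analysisResultForTest(c(A = 8))
  freq <- numericMap("motif", c(A = 0.5))
  res <- overrepresentation(counts, freq, total_bp = 10)
  expect_equal(res@rows$p_value, 56 / 1024)
  ## exhaustive enumeration for all n <= 30, a grid of k and p
  for (n in c(1, 7, 13, 30)) {
    for (p0 in c(0.01, 0.2, 0.5)) {
      for (k in unique(c(0, 1, floor(n / 2), n))) {
        res <- overrepresentation(analysisResultForTest(c(M = k)),
                                  numericMap("motif", c(M = p0)), total_bp = n)
        enum <- sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0))
        if (k == 0) enum <- 1
        expect_equal(res@rows$p_value, enum, tolerance = 1e-12)
      }
    }
  }
  expect_error(overrepresentation(analysisResultForTest(c(M = 1)),
                                  numericMap("motif", c(M = 1.5)), 10), "not a probability")
})

test_that("Bonferroni correction over 931 motifs gives the printed threshold", {
  expect_equal(bonferroniThreshold(0.05, 931), 5.37e-5, tolerance = 1e-3)
  counts <- analysisResultForTest(stats::setNames(rep(0L, 931), sprintf("M%03d", 1:931)))
  freq <- numericMap("motif", stats::setNames(rep(1e-4, 931), sprintf("M%03d", 1:931)))
  res <- overrepresentation(counts, freq, total_bp = 1000)
  expect_equal(res@provenance$threshold, 0.05 / 931)
  expect_true(all(res@rows$p_value == 1))
  expect_true(all(res@rows$significant == "no"))
})

test_that("group comparison classifies overrepresentation and is antisymmetric", {
  ## many A sites in group 1, none in group 2
  regs <- list(g1 = regionFrame(seq(0, 390, 10), seq(4, 394, 10), "A", 1, "+"),
               g2 = emptyRegions())
  tr <- regionTrack(regs, c(g1 = 400L, g2 = 400L))
  A <- collection("sequence", "g1"); B <- collection("sequence", "g2")
  res <- groupComparison(tr, A, B)
  expect_identical(res@rows$group, "A")
  ## swap: A/B <-> D
  resSwap <- groupComparison(tr, B, A)
  expect_identical(resSwap@rows$group, "D")
  ## identical rates: class C
  regs2 <- list(g1 = regionFrame(0, 5, "A", 1, "+"), g2 = regionFrame(0, 5, "A", 1, "+"))
  tr2 <- regionTrack(regs2, c(g1 = 400L, g2 = 400L))
  expect_identical(groupComparison(tr2, A, B)@rows$group, "C")
  expect_error(groupComparison(tr, A, collection("sequence", "g1")), "disjoint")
})

test_that("positional distribution anchors at the TSS strand-aware", {
  ss <- sequenceSet(c("p", "m"), c("c1", "c2"), c(0, 0), c(100, 100),
                    strand = c("+", "-"), tss_offset = c(80, 20))
  ## midpoints: p: (10+14)/2=12 -> rel 12-80=-68 ; m: mid 50 -> rel 20-50=-30
  tr <- regionTrack(list(p = regionFrame(10, 14, "A", 1, "+"),
                         m = regionFrame(48, 53, "A", 1, "-")), seqLengths(ss))
  res <- positionalDistribution(tr, ss, "tss", bin_size = 10)
  h <- res@rows$histogram[[1]]
  breaks <- res@provenance$breaks
  expect_equal(sum(h), 2L)
  expect_equal(breaks[1], -70)
  ## both sites upstream (negative): -68 in [-70,-60), -30 in [-30,-20)
  expect_equal(h[1], 1L)
  expect_equal(which(h == 1L), c(1L, 5L))
  expect_error(positionalDistribution(tr, sequenceSet(c("p", "m"), c("c1", "c2"),
                                                      c(0, 0), c(100, 100)), "tss"),
               "TSS offset")
})

test_that("kurtosis follows the population-moment definition", {
  ss <- simpleSeqSet(c(a = 200), tss = 100)
  ## midpoints at -1,-1,1,1 relative to TSS: m4 = 1, m2 = 1 -> kurtosis 1
  starts <- c(97, 97, 99, 99)
  tr <- regionTrack(list(a = regionFrame(starts, starts + 4, "A", 1, "+")), c(a = 200))
  res <- positionalDistribution(tr, ss, "tss", bin_size = 2)
  expect_equal(res@rows$kurtosis, 1.0)
  ## fewer than 4 sites: blank
  tr3 <- regionTrack(list(a = regionFrame(c(10, 30, 50), c(14, 34, 54), "A", 1, "+")), c(a = 200))
  expect_true(is.na(positionalDistribution(tr3, ss, "tss")@rows$kurtosis))
  ## all sites at one position: blank with warning
  tr1 <- regionTrack(list(a = regionFrame(rep(10, 4), rep(14, 4), "A", 1, "+")), c(a = 200))
  expect_warning(res1 <- positionalDistribution(tr1, ss, "tss"), "undefined")
  expect_true(is.na(res1@rows$kurtosis))
  ## ~normal midpoints: kurtosis near 3
  set.seed(19)
  mids <- round(rnorm(10000, 0, 30))
  L <- 1000
  starts <- pmin(pmax(mids + 500 - 2, 0), L - 5)
  trN <- regionTrack(list(a = regionFrame(starts, starts + 4, "A", 1, "+")), c(a = L))
  ssN <- simpleSeqSet(c(a = L), tss = 500)
  kurt <- positionalDistribution(trN, ssN, "tss")@rows$kurtosis
  expect_lt(abs(kurt - 3), 0.1)
})

test_that("site-feature averages are position-weighted", {
  feat <- numericTrack(list(a = c(1, 3, 5, 7, 9, 11)))
  tr <- regionTrack(list(a = regionFrame(c(0, 2), c(2, 6), "A", 1, "+")), c(a = 6))
  res <- sitesVsNumeric(tr, feat)
  ## positions 0..1 and 2..5: mean over the flattened values
  expect_equal(res@rows$mean, mean(c(1, 3, 5, 7, 9, 11)))
  ## one short + one long site for different motifs
  tr2 <- regionTrack(list(a = regionFrame(c(0, 0), c(2, 6), c("S", "L"), 1, "+")), c(a = 6))
  res2 <- sitesVsNumeric(tr2, feat)
  expect_equal(res2@rows$mean[res2@rows$id == "S"], 2)
  expect_equal(res2@rows$mean[res2@rows$id == "L"], 6)
})

test_that("rank sum uses midranks, ranks blanks last, and is monotone-invariant", {
  m1 <- numericMap("motif", c(a = 1, b = 1, c = 2))
  m2 <- numericMap("motif", c(a = 5, b = 1, c = 3))
  rs <- rankSum(list(m1, m2), c("ascending", "ascending"))
  ## m1 ranks: a=1.5 b=1.5 c=3 ; m2 ranks: a=3 b=1 c=2
  expect_equal(unname(mapValues(rs, c("a", "b", "c"))), c(4.5, 2.5, 5))
  ## descending flips
  rsd <- rankSum(list(m1, m1), c("descending", "descending"))
  expect_equal(unname(mapValues(rsd, "c")), 2)
  ## blanks (NA in plain vectors) rank last
  v1 <- c(a = 1, b = NA, c = 0.5)
  rs2 <- rankSum(list(v1, v1), c("ascending", "ascending"))
  expect_equal(unname(mapValues(rs2, "b")), 6)
  ## invariant under strictly monotone transforms
  set.seed(3)
  x <- stats::setNames(runif(10), letters[1:10])
  y <- stats::setNames(runif(10), letters[1:10])
  r1 <- rankSum(list(x, y), c("ascending", "descending"))
  r2 <- rankSum(list(exp(3 * x), y), c("ascending", "descending"))
  expect_equal(mapValues(r1, letters[1:10]), mapValues(r2, letters[1:10]))
  expect_error(rankSum(list(x), "ascending"), "at least 2")
  expect_error(rankSum(list(c(q = 1), c(z = 1)), c("ascending", "ascending")), "disjoint")
})

test_that("perfect predictions score 1 on every benchmark statistic", {
  ans <- randomRegionTrack(c(a = 200L, b = 150L), 3, "site")
  st <- benchmarkStats(ans, ans)
  expect_equal(st$Sn, 1); expect_equal(st$Sp, 1); expect_equal(st$PPV, 1)
  expect_equal(st$CC, 1); expect_equal(st$sSn, 1); expect_equal(st$F, 1)
})

test_that("Matthews correlation matches the closed form on fixed counts", {
  ## TP=3, FP=1, FN=2, TN=94 -> CC = 280 / sqrt(182400)
  pred <- regionTrack(list(a = regionFrame(c(0), c(4), "p", 1, "+")), c(a = 100))
  answ <- regionTrack(list(a = regionFrame(c(1), c(6), "t", 1, "+")), c(a = 100))
  st <- benchmarkStats(pred, answ)
  expect_equal(st$TP, 3); expect_equal(st$FP, 1); expect_equal(st$FN, 2); expect_equal(st$TN, 94)
  expect_equal(st$CC, 280 / sqrt(182400))
  expect_equal(st$CC, 0.6556, tolerance = 1e-4)
})

test_that("site-level sensitivity honours the 25% overlap rule", {
  ## prediction [0,10) vs target [8,40): overlap 2 < 0.25*32 -> not counted
  pred <- regionTrack(list(a = regionFrame(0, 10, "p", 1, "+")), c(a = 100))
  answ <- regionTrack(list(a = regionFrame(8, 40, "t", 1, "+")), c(a = 100))
  expect_equal(benchmarkStats(pred, answ)$sSn, 0)
  ## overlap exactly at the threshold counts
  pred2 <- regionTrack(list(a = regionFrame(0, 16, "p", 1, "+")), c(a = 100))
  expect_equal(benchmarkStats(pred2, answ)$sSn, 1)
})

test_that("benchmark statistics equal the brute-force labeler on random pairs", {
  set.seed(333)
  for (rep in 1:10) {
    lens <- c(a = 80L, b = 120L)
    pred <- randomRegionTrack(lens, sample(0:6, 1), "p")
    answ <- randomRegionTrack(lens, sample(1:6, 1), "t")
    expect_equal(benchmarkStats(pred, answ), bruteBenchmark(pred, answ))
  }
  ## degenerate: no predictions at all -> zero-denominator stats are 0
  none <- regionTrack(list(a = emptyRegions(), b = emptyRegions()), c(a = 80L, b = 120L))
  answ <- randomRegionTrack(c(a = 80L, b = 120L), 2, "t")
  st <- benchmarkStats(none, answ)
  expect_equal(st$PPV, 0); expect_equal(st$CC, 0); expect_equal(st$Sn, 0)
})

test_that("collation joins analysis columns on member keys", {
  tr <- twoSeqMotifTrack()
  counts <- countMotifOccurrences(tr)
  freq <- numericMap("motif", c(A = 0.001, B = 0.001))
  over <- overrepresentation(counts, freq, total_bp = 200)
  ss <- sequenceSet(c("s1", "s2"), c("c1", "c2"), c(0, 0), c(100, 100),
                    strand = "+", tss_offset = c(50, 50))
  pos <- positionalDistribution(tr, ss, "tss", bin_size = 20)
  feat <- numericTrack(list(s1 = runif(100), s2 = runif(100)))
  cons <- sitesVsNumeric(tr, feat)
  meta <- collateAnalyses(list(
    list(result = counts, columns = c("total", "support")),
    list(result = over, columns = c("p_value", "significant")),
    list(result = cons, columns = "mean"),
    list(result = pos, columns = c("kurtosis", "histogram"))))
  expect_equal(names(meta@rows), c("id", "total", "support", "p_value",
                                   "significant", "mean", "kurtosis", "histogram"))
  expect_equal(meta@rows$id, c("A", "B"))
  ## single input is the identity on values
  solo <- collateAnalyses(list(list(result = counts, columns = NULL)))
  expect_equal(solo@rows$total, counts@rows$total)
  ## duplicate labels get suffixed with a warning
  expect_warning(dup <- collateAnalyses(list(list(result = counts, columns = "total"),
                                             list(result = counts, columns = "total"))),
                 "renamed")
  expect_true("total.2" %in% names(dup@rows))
})

test_that("collation can sort by a rank-sum specification", {
  counts <- analysisResultForTest(c(A = 10, B = 5, C = 1), column = "p_value")
  meta <- collateAnalyses(list(list(result = counts, columns = "p_value")),
                          sortBy = list(labels = "p_value",
                                        directions = "descending"))
  expect_equal(meta@rows$id, c("A", "B", "C"))
})

test_that("raw rendering round-trips the numeric content", {
  tr <- twoSeqMotifTrack()
  counts <- countMotifOccurrences(tr)
  ss <- sequenceSet(c("s1", "s2"), c("c1", "c2"), c(0, 0), c(100, 100),
                    strand = "+", tss_offset = c(50, 50))
  pos <- positionalDistribution(tr, ss, "tss", bin_size = 20)
  meta <- collateAnalyses(list(list(result = counts, columns = NULL),
                               list(result = pos, columns = c("kurtosis", "histogram"))))
  raw <- renderResult(meta, "raw")
  back <- parseRawResult(raw)
  expect_equal(back@rows$total, meta@rows$total)
  expect_equal(back@rows$kurtosis, meta@rows$kurtosis)
  expect_equal(back@rows$histogram, meta@rows$histogram)
  ## rendering is deterministic
  expect_identical(raw, renderResult(meta, "raw"))
})

test_that("HTML rendering flags class cells and embeds histograms and logos", {
  counts <- analysisResultForTest(c(A = 8))
  over <- overrepresentation(counts, numericMap("motif", c(A = 0.001)), 1000)
  html <- paste(renderResult(over, "html"), collapse = "\n")
  expect_match(html, 'class="yes"')
  lib <- motifSet(list(hardMotif("A", "ACGT")))
  ss <- simpleSeqSet(c(s1 = 100), tss = 50)
  tr <- regionTrack(list(s1 = regionFrame(c(0, 10, 20, 30), c(4, 14, 24, 34), "A", 1, "+")),
                    c(s1 = 100))
  pos <- positionalDistribution(tr, ss, "tss", bin_size = 10)
  html2 <- paste(renderResult(pos, "html", motifs = lib), collapse = "\n")
  expect_match(html2, "<svg")
  expect_match(html2, "font-family=\"monospace\"")   # the logo letters
  ## empty result: header-only document
  empty <- countMotifOccurrences(regionTrack(list(), c(a = 10)))
  lines <- renderResult(empty, "raw")
  expect_length(lines, 2L)
})

test_that("analysis columns convert to maps and collections", {
  counts <- countMotifOccurrences(twoSeqMotifTrack())
  m <- resultColumnAsMap(counts, "total")
  expect_equal(unname(mapValues(m, c("A", "B"))), c(3, 1))
  coll <- resultToCollection(counts, "total", ">=", 2)
  expect_identical(members(coll), "A")
  expect_error(resultColumnAsMap(counts, "nope"), "no column")
})
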