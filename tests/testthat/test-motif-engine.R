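test_that("order-0 background training applies the +1 pseudocount", {
  bg <- suppressWarnings(trainBackground(dnaTrack(c(a = "AACC")), 0))
  q <- baseFrequencies(bg)
  ## counts A=2, C=2, G=0, T=0; +1 each; /8
  expect_equal(unname(q), c(3, 3, 1, 1) / 8)
})

test_that("order-1 conditionals favour the observed transitions", {
  bg <- suppressWarnings(trainBackground(dnaTrack(c(a = "AAAA")), 1))
  tabA <- bg@tables[[2]]["A", ]
  expect_true(which.max(tabA) == 1)          # P(A|A) dominates
  expect_equal(sum(tabA), 1)
  ## all conditional rows are proper distributions
  for (tab in bg@tables) expect_equal(unname(rowSums(tab)), rep(1, nrow(tab)))
})

test_that("background sampling is seed-deterministic and matches the model", {
  txt <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  bg <- trainBackground(dnaTrack(c(a = txt)), 0)
  s1 <- sampleBackground(bg, 500, seed = 99)
  s2 <- sampleBackground(bg, 500, seed = 99)
  expect_identical(s1, s2)
  ## chi-square goodness of fit of 1-mer counts on a 20 kb sample
  big <- sampleBackground(bg, 20000, seed = 100)
  counts <- table(factor(strsplit(big, "")[[1]], levels = c("A", "C", "G", "T")))
  p <- stats::chisq.test(as.numeric(counts), p = unname(baseFrequencies(bg)))$p.value
  expect_gt(p, 0.01)
  ## empirical 2-mer frequencies of an order-1 model stay within 3 SE
  bg1 <- trainBackground(dnaTrack(c(a = txt)), 1)
  big1 <- strsplit(sampleBackground(bg1, 20000, seed = 101), "")[[1]]
  dimers <- paste0(big1[-length(big1)], big1[-1])
  for (ctx in c("A", "C", "G", "T")) {
    n <- sum(big1[-length(big1)] == ctx)
    for (b in c("A", "C", "G", "T")) {
      phat <- sum(dimers == paste0(ctx, b)) / n
      p0 <- bg1@tables[[2]][ctx, b]
      se <- sqrt(p0 * (1 - p0) / n)
      expect_lt(abs(phat - p0), 3.5 * se)
    }
  }
})

test_that("degenerate background model samples a constant string", {
  bg <- uniformBackground(0)
  bg@tables[[1]][1, ] <- c(1 - 3e-9, 1e-9, 1e-9, 1e-9)
  expect_identical(sampleBackground(bg, 5, seed = 1), "AAAAA")
})

test_that("single-base motif scan finds forward and reverse hits", {
  mA <- hardMotif("A1", "A")
  hits <- flattenTrack(scanMotifs(dnaTrack(c(x = "ATA")), motifSet(list(mA)), 1))
  expect_equal(hits$start, c(0, 1, 2))
  expect_equal(hits$strand, c("+", "-", "+"))   # T is A on the reverse strand
  expect_equal(hits$score, rep(1, 3))
})

test_that("threshold zero yields a hit at every window on every strand", {
  set.seed(2)
  d <- randomDnaTrack(1, 30)
  m <- randomMotif("m", 4)
  hits <- flattenTrack(scanMotifs(d, motifSet(list(m)), 0))
  expect_equal(nrow(hits), 2 * (30 - 4 + 1))
})

test_that("scanner agrees exactly with the naive oracle on random inputs", {
  set.seed(1234)
  d <- randomDnaTrack(6, 120)
  motifs <- lapply(1:4, function(i) randomMotif(sprintf("m%d", i), sample(3:8, 1)))
  got <- flattenTrack(scanMotifs(d, motifSet(motifs), 0.8))
  want <- naiveScan(dnaStrings(d), motifs, 0.8)
  rownames(want) <- NULL
  expect_equal(got[c("seq", "start", "end", "type", "strand")],
               want[c("seq", "start", "end", "type", "strand")])
  expect_equal(got$score, want$score, tolerance = 1e-9)
})

test_that("scanning is strand-symmetric", {
  set.seed(55)
  d <- randomDnaTrack(1, 80)
  rc <- dnaTrack(c(s1 = reverseComplement(dnaStrings(d)[["s1"]])))
  m <- randomMotif("m", 5)
  h1 <- flattenTrack(scanMotifs(d, motifSet(list(m)), 0.7))
  h2 <- flattenTrack(scanMotifs(rc, motifSet(list(m)), 0.7))
  ## mirror h2 back onto d's coordinates with strands swapped
  h2$startM <- 80 - h2$end
  h2$strandM <- ifelse(h2$strand == "+", "-", "+")
  h2 <- h2[order(h2$startM, h2$strandM), ]
  h1 <- h1[order(h1$start, h1$strand), ]
  expect_equal(h1$start, h2$startM)
  expect_equal(h1$strand, h2$strandM)
  expect_equal(h1$score, h2$score, tolerance = 1e-12)
})

test_that("relative score is invariant under column scaling of the matrix", {
  set.seed(8)
  chars <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  M <- randomMotif("m", 6)@matrix
  relFor <- function(mat) {
    lom <- log(mat / 0.25)
    bounds <- list(min = sum(apply(lom, 2, min)), max = sum(apply(lom, 2, max)))
    regulab:::windowRelScores(chars, lom, bounds)
  }
  expect_equal(relFor(M), relFor(3.7 * M), tolerance = 1e-12)
})

test_that("N and X bases score as the background expectation", {
  m <- hardMotif("m", "ACG")
  dN <- dnaTrack(c(x = "NNNNN"))
  ## every window scores the neutral point between Smin and Smax
  prof <- trackValues(pwmScoreProfile(dN, m))$x
  expect_true(all(prof[1:3] > 0 & prof[1:3] < 1))
  ## consensus window still scores 1 even with flanking Ns
  d2 <- dnaTrack(c(x = "NACGN"))
  hits <- flattenTrack(scanMotifs(d2, motifSet(list(m)), 1))
  expect_true(any(hits$start == 1 & hits$strand == "+"))
})

test_that("consensus matching handles IUPAC codes and both orientations", {
  d <- dnaTrack(c(x = "ACCAATG"))
  hits <- flattenTrack(matchConsensus(d, "CCAAT"))
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$start, hits$end), c(1, 6))
  expect_identical(hits$strand, "+")
  ## reverse orientation: ATTGG is CCAAT read on the minus strand
  d2 <- dnaTrack(c(x = "GATTGGC"))
  hits2 <- flattenTrack(matchConsensus(d2, "CCAAT"))
  expect_identical(hits2$strand, "-")
  expect_equal(c(hits2$start, hits2$end), c(1, 6))
  ## N matches any base; pattern of width 1 matches everywhere (both strands collapse)
  expect_equal(nrow(flattenTrack(matchConsensus(dnaTrack(c(x = "ACGT")), "N"))), 4L)
  ## degenerate letters
  expect_equal(nrow(flattenTrack(matchConsensus(dnaTrack(c(x = "AGA")), "R", "forward"))), 3L)
  expect_null(flattenTrack(matchConsensus(dnaTrack(c(x = "CCCC")), "AT")))
  expect_error(matchConsensus(d, "AZ"), "invalid IUPAC")
})

test_that("motifs built from aligned sites use the 0.25 pseudocount", {
  m <- motifFromSites(c("AA", "AA"), "m")
  expect_equal(unname(m@matrix["A", 1]), 2.25 / 3)
  single <- motifFromSites("ACGT", "one")
  expect_identical(single@consensus, "ACGT")
  expect_error(motifFromSites(c("AA", "AAA"), "bad"), "equal lengths")
  expect_error(motifFromSites(character(), "none"), "at least one")
})

test_that("score profiles agree with scan hits and handle degenerate motifs", {
  set.seed(99)
  d <- randomDnaTrack(2, 100)
  m <- randomMotif("m", 5)
  prof <- pwmScoreProfile(d, m)
  hits <- flattenTrack(scanMotifs(d, motifSet(list(m)), 0))
  for (nm in seqNames(d)) {
    v <- trackValues(prof)[[nm]]
    h <- hits[hits$seq == nm, ]
    best <- tapply(h$score, h$start, max)
    expect_equal(unname(v[as.integer(names(best)) + 1]), as.numeric(best), tolerance = 1e-12)
    ## trailing w-1 positions are zero
    expect_equal(v[97:100], rep(0, 4))
  }
  uni <- motif("flat", matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_warning(pu <- pwmScoreProfile(d, uni), "zero score range")
  expect_true(all(unlist(trackValues(pu)) == 0))
})
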