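test_that("mask replaces exactly the selected positions", {
  d <- dnaTrack(c(a = "ACGT"))
  where <- regionTrack(list(a = regionFrame(1, 3, "m")), c(a = 4))
  expect_identical(dnaStrings(maskTrack(d, "N", where))[["a"]], "ANNT")
  ## input not mutated
  expect_identical(dnaStrings(d)[["a"]], "ACGT")
})

test_that("repeat masking changes exactly the covered bases", {
  set.seed(7)
  d <- randomDnaTrack(3, 200)
  reps <- randomRegionTrack(seqLengths(d), 4, "repeat")
  masked <- maskTrack(d, "N", reps)
  for (nm in seqNames(d)) {
    cov <- regionsToNumeric(reps, "coverage")
    inRep <- trackValues(cov)[[nm]] > 0
    before <- strsplit(dnaStrings(d)[[nm]], "")[[1]]
    after <- strsplit(dnaStrings(masked)[[nm]], "")[[1]]
    expect_true(all(after[inRep] == "N"))
    expect_identical(after[!inRep], before[!inRep])
    expect_equal(sum(after == "N"), sum(inRep))
  }
})

test_that("background fill is seeded, reproducible and condition-scoped", {
  d <- dnaTrack(c(a = "ACGTACGTACGT"))
  bg <- uniformBackground(1)
  where <- parseCondition("inside(m)")
  env <- list(m = regionTrack(list(a = regionFrame(2, 9, "m")), c(a = 12)))
  expect_error(maskTrack(d, bg, where, tracks = env), "seed")
  m1 <- maskTrack(d, bg, where, tracks = env, seed = 11)
  m2 <- maskTrack(d, bg, where, tracks = env, seed = 11)
  expect_identical(dnaStrings(m1), dnaStrings(m2))
  ## untouched outside the masked run
  expect_identical(substr(dnaStrings(m1)[["a"]], 1, 2), "AC")
  expect_identical(substr(dnaStrings(m1)[["a"]], 10, 12), "CGT")
})

test_that("filterRegions keeps survivors unchanged and respects conditions", {
  set.seed(13)
  cons <- numericTrack(list(a = runif(300), b = runif(300)))
  preds <- randomRegionTrack(c(a = 300L, b = 300L), 10, c("M1", "M2"))
  keepAll <- filterRegions(preds, "true")
  expect_equal(trackRegions(keepAll), trackRegions(preds))
  filtered <- filterRegions(preds, "avg(cons) >= 0.5", tracks = list(cons = cons))
  ## brute-force check
  for (nm in c("a", "b")) {
    df <- trackRegions(preds)[[nm]]
    keep <- vapply(seq_len(nrow(df)), function(i)
      mean(trackValues(cons)[[nm]][(df$start[i] + 1):df$end[i]]) >= 0.5, TRUE)
    expect_equal(trackRegions(filtered)[[nm]], sortRegionsForTest(df[keep, , drop = FALSE]))
  }
})

test_that("filtering predictions by answer overlap keeps exactly the overlapping ones", {
  set.seed(5)
  answer <- randomRegionTrack(c(a = 400L), 5, "site")
  preds <- randomRegionTrack(c(a = 400L), 30, "site")
  cov <- regionsToNumeric(answer, "coverage")
  kept <- filterRegions(preds, "avg(anscov) > 0", tracks = list(anscov = cov))
  df <- trackRegions(preds)$a
  adf <- trackRegions(answer)$a
  overlapping <- vapply(seq_len(nrow(df)), function(i)
    any(adf$start < df$end[i] & adf$end > df$start[i]), TRUE)
  expect_equal(nrow(trackRegions(kept)$a), sum(overlapping))
})

test_that("extend clips at bounds and honours strand awareness", {
  rt <- regionTrack(list(a = regionFrame(10, 20, "x", 1, "-")), c(a = 100))
  e1 <- transformRegions(rt, "extend", up = 5, down = 3)
  expect_equal(c(trackRegions(e1)$a$start, trackRegions(e1)$a$end), c(5, 23))
  ## on the minus strand, up/down swap
  e2 <- transformRegions(rt, "extend", up = 5, down = 3, strand_aware = TRUE)
  expect_equal(c(trackRegions(e2)$a$start, trackRegions(e2)$a$end), c(7, 25))
  ## clipping
  e3 <- transformRegions(rt, "extend", up = 50, down = 200)
  expect_equal(c(trackRegions(e3)$a$start, trackRegions(e3)$a$end), c(0, 100))
})

test_that("merge unions regions within the gap and is idempotent", {
  rt <- regionTrack(list(a = regionFrame(c(0, 3, 12), c(5, 8, 20), c("x", "x", "y"),
                                         c(0.5, 0.9, 0.2), c("+", "+", "-"))), c(a = 50))
  m0 <- transformRegions(rt, "merge", max_gap = 0)
  df <- trackRegions(m0)$a
  expect_equal(nrow(df), 2L)
  expect_equal(c(df$start[1], df$end[1]), c(0, 8))
  expect_equal(df$score[1], 0.9)     # max of members
  expect_identical(df$type[1], "x")  # unanimous type kept
  m4 <- transformRegions(rt, "merge", max_gap = 4)
  df4 <- trackRegions(m4)$a
  expect_equal(nrow(df4), 1L)
  expect_identical(df4$type, "merged")
  expect_identical(df4$strand, ".")
  ## idempotence
  expect_equal(trackRegions(transformRegions(m4, "merge", max_gap = 4)), trackRegions(m4))
})

test_that("arithmetic operations broadcast scalars, tracks and maps", {
  nt <- numericTrack(list(s1 = c(0, 1, 2), s2 = c(2, 4, 6)))
  expect_equal(trackValues(trackArithmetic(nt, "add", 1))$s1, c(1, 2, 3))
  expect_equal(trackValues(trackArithmetic(nt, "range_normalize", c(0, 1)))$s2,
               c(1, 2, 3) / 3)  # joint min 0, max 6
  m <- numericMap("sequence", c(s1 = 2), default = 1)
  expect_equal(trackValues(trackArithmetic(nt, "mul", m))$s1, c(0, 2, 4))
  expect_equal(trackValues(trackArithmetic(nt, "mul", m))$s2, c(2, 4, 6))
  other <- numericTrack(list(s1 = c(1, 1, 2), s2 = c(1, 1, 1)))
  expect_equal(trackValues(trackArithmetic(nt, "div", other))$s1, c(0, 1, 1))
  expect_equal(trackValues(trackArithmetic(nt, "max", 3))$s2, c(3, 4, 6))
  ## domain errors name the sequence and position
  expect_error(trackArithmetic(nt, "log"), "s1.*position 0")
  zero <- numericTrack(list(s1 = c(1, 0, 1), s2 = c(1, 1, 1)))
  expect_error(trackArithmetic(nt, "div", zero), "s1.*position 1")
})

test_that("arithmetic with a where-condition touches only matching positions", {
  nt <- numericTrack(list(s1 = c(1, 2, 3, 4)))
  sel <- regionTrack(list(s1 = regionFrame(1, 3, "w")), c(s1 = 4))
  out <- trackArithmetic(nt, "add", 10, where = "inside(w)", tracks = list(w = sel))
  expect_equal(trackValues(out)$s1, c(1, 12, 13, 4))
})

test_that("sliding windows clip at edges and match brute force", {
  nt <- numericTrack(list(a = c(0, 3, 6)))
  expect_equal(trackValues(slidingWindow(nt, "mean", 3))$a, c(1.5, 3, 4.5))
  expect_equal(trackValues(slidingWindow(nt, "median", 1))$a, c(0, 3, 6))
  expect_error(slidingWindow(nt, "mean", 4), "odd")
  set.seed(31)
  v <- rnorm(100)
  tr <- numericTrack(list(a = v))
  for (stat in c("mean", "median", "min", "max", "sum")) {
    fn <- switch(stat, mean = mean, median = median, min = min, max = max, sum = sum)
    for (size in c(3, 7, 11)) {
      half <- (size - 1) / 2
      expected <- vapply(seq_along(v), function(i)
        fn(v[max(1, i - half):min(length(v), i + half)]), 0)
      expect_equal(trackValues(slidingWindow(tr, stat, size))$a, expected,
                   info = paste(stat, size))
    }
  }
})

test_that("weighted track combination equals the manual sum", {
  t1 <- numericTrack(list(a = c(0, 1)))
  t2 <- numericTrack(list(a = c(1, 0)))
  expect_equal(trackValues(combineTracks(list(t1, t2), c(1, 0)))$a, c(0, 1))
  expect_equal(trackValues(combineTracks(list(t1, t2), c(0.5, 0.5)))$a, c(0.5, 0.5))
  set.seed(3)
  ts <- lapply(1:3, function(i) numericTrack(list(a = rnorm(50))))
  w <- c(0.2, -1, 3)
  manual <- w[1] * trackValues(ts[[1]])$a + w[2] * trackValues(ts[[2]])$a + w[3] * trackValues(ts[[3]])$a
  expect_equal(trackValues(combineTracks(ts, w))$a, manual)
  expect_error(combineTracks(ts, c(1, 2)), "one weight per track")
})

test_that("thresholded runs become regions scored by the run mean", {
  nt <- numericTrack(list(a = c(0, 1, 1, 0)))
  df <- trackRegions(numericToRegions(nt, 1))$a
  expect_equal(c(df$start, df$end), c(1, 3))
  expect_equal(nrow(trackRegions(numericToRegions(nt, 2))$a), 0L)
  ## random track vs brute-force run finder
  set.seed(17)
  v <- round(runif(200), 1)
  tr <- numericTrack(list(a = v))
  got <- trackRegions(numericToRegions(tr, 0.7, min_length = 3))$a
  above <- v >= 0.7
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= 3
  expect_equal(got$start, starts[keep] - 1L)
  expect_equal(got$end, ends[keep])
  for (i in seq_len(nrow(got)))
    expect_equal(got$score[i], mean(v[(got$start[i] + 1):got$end[i]]))
})

test_that("region-to-numeric conversion matches per-position counting", {
  rt <- regionTrack(list(a = regionFrame(c(1, 2), c(3, 4), "x", c(0.5, 2), "+")), c(a = 5))
  expect_equal(trackValues(regionsToNumeric(rt, "coverage"))$a, c(0, 1, 2, 1, 0))
  expect_equal(trackValues(regionsToNumeric(rt, "max_score"))$a, c(0, 0.5, 2, 2, 0))
  set.seed(23)
  rnd <- randomRegionTrack(c(a = 150L), 8)
  cov <- trackValues(regionsToNumeric(rnd, "coverage"))$a
  df <- trackRegions(rnd)$a
  brute <- vapply(1:150, function(p) sum(df$start < p & df$end >= p), 0)
  expect_equal(cov, brute)
})

test_that("sequence statistics exclude ambiguous bases from GC content", {
  d <- dnaTrack(c(x = "GGCC", y = "ANGC", z = strrep("A", 100)))
  gc <- sequenceStatistic(d, "gc_content")
  expect_equal(unname(mapValues(gc, "x")), 1.0)
  expect_equal(unname(mapValues(gc, "y")), 2 / 3)
  expect_equal(unname(mapValues(sequenceStatistic(d, "length"), "z")), 100)
  expect_equal(unname(mapValues(sequenceStatistic(d, "count_base", base = "G"), "y")), 1)
})

test_that("collections derive from numeric maps by thresholding", {
  gc <- numericMap("sequence", c(s1 = 0.3, s2 = 0.5))
  expect_identical(members(collectionFromMap(gc, "<", 0.40)), "s1")
  support <- numericMap("motif", c(m1 = 0.85, m2 = 0.4, m3 = 0.8))
  expect_identical(sort(members(collectionFromMap(support, ">=", 0.80))), c("m1", "m3"))
  expect_length(members(collectionFromMap(gc, ">", 2)), 0L)
})

test_that("operations are pure: repeated application gives identical results", {
  set.seed(41)
  nt <- numericTrack(list(a = rnorm(50)))
  expect_identical(trackValues(slidingWindow(nt, "mean", 5)),
                   trackValues(slidingWindow(nt, "mean", 5)))
  rt <- randomRegionTrack(c(a = 50L), 5)
  expect_identical(trackRegions(transformRegions(rt, "merge", max_gap = 2)),
                   trackRegions(transformRegions(rt, "merge", max_gap = 2)))
})
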