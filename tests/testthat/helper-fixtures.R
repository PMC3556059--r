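## Shared builders for small in-code fixtures.

## Hard (deterministic) motif from a consensus string: 1 for the consensus
## base, 0 elsewhere.
hardMotif <- function(id, consensus) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  m <- matrix(0, 4, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(chars)) m[chars[j], j] <- 1
  motif(id, m)
}

## Soft random column-stochastic motif.
randomMotif <- function(id, width) {
  m <- matrix(stats::runif(4 * width, 0.05, 1), 4, width,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  motif(id, sweep(m, 2, colSums(m), "/"))
}

randomDnaTrack <- function(nseq, len, prefix = "s") {
  seqs <- vapply(seq_len(nseq), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""), "")
  names(seqs) <- paste0(prefix, seq_len(nseq))
  dnaTrack(seqs)
}

simpleSeqSet <- function(lens, chrom = NULL, start = 0, strand = "+", tss = NA_real_) {
  nms <- names(lens)
  sequenceSet(nms, if (is.null(chrom)) nms else chrom,
              start = start, end = start + unname(lens),
              strand = strand, tss_offset = tss)
}

## Independent naive PWM scanner: plain O(L*w) loops, min-max normalized
## log-odds, both strands. Used as the oracle for scanMotifs.
naiveScan <- function(seqs, motifs, threshold, q = rep(0.25, 4)) {
  names(q) <- c("A", "C", "G", "T")
  hits <- list()
  for (nm in names(seqs)) {
    chars <- strsplit(seqs[[nm]], "", fixed = TRUE)[[1]]
    L <- length(chars)
    for (m in motifs) {
      mat <- pmax(m@matrix, 1e-6)
      w <- ncol(mat)
      smin <- sum(apply(log(mat / q), 2, min))
      smax <- sum(apply(log(mat / q), 2, max))
      for (start in 0:(L - w)) {
        win <- chars[(start + 1):(start + w)]
        for (strand in c("+", "-")) {
          ww <- if (strand == "+") win else rev(chartr("ACGT", "TGCA", win))
          S <- 0
          for (j in seq_len(w)) {
            if (ww[j] %in% rownames(mat)) S <- S + log(mat[ww[j], j] / q[[ww[j]]])
          }
          r <- (S - smin) / (smax - smin)
          if (r >= threshold)
            hits[[length(hits) + 1L]] <- data.frame(
              seq = nm, start = start, end = start + w, type = m@id,
              score = r, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  df <- do.call(rbind, hits)
  df[order(df$seq, df$start, df$end, df$type, df$strand), , drop = FALSE]
}

## Flatten a RegionTrack into a comparable data.frame.
flattenTrack <- function(track) {
  regs <- trackRegions(track)
  out <- do.call(rbind, lapply(names(regs), function(nm) {
    df <- regs[[nm]]
    if (nrow(df) == 0L) return(NULL)
    data.frame(seq = nm, start = df$start, end = df$end, type = df$type,
               score = df$score, strand = df$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) return(NULL)
  out <- out[order(out$seq, out$start, out$end, out$type, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Brute-force nucleotide benchmark oracle by explicit per-position labeling.
bruteBenchmark <- function(predicted, answer, fraction = 0.25) {
  TP <- FP <- TN <- FN <- 0
  nSites <- 0; nHit <- 0
  for (nm in names(seqLengths(answer))) {
    L <- seqLengths(answer)[[nm]]
    p <- logical(L); a <- logical(L)
    pdf <- trackRegions(predicted)[[nm]]; adf <- trackRegions(answer)[[nm]]
    if (nrow(pdf)) for (i in seq_len(nrow(pdf))) p[(pdf$start[i] + 1):pdf$end[i]] <- TRUE
    if (nrow(adf)) for (i in seq_len(nrow(adf))) a[(adf$start[i] + 1):adf$end[i]] <- TRUE
    TP <- TP + sum(p & a); FP <- FP + sum(p & !a); TN <- TN + sum(!p & !a); FN <- FN + sum(!p & a)
    if (nrow(adf)) for (i in seq_len(nrow(adf))) {
      nSites <- nSites + 1
      tlen <- adf$end[i] - adf$start[i]
      hit <- FALSE
      if (nrow(pdf)) for (j in seq_len(nrow(pdf))) {
        ov <- min(pdf$end[j], adf$end[i]) - max(pdf$start[j], adf$start[i])
        if (ov > 0 && ov >= fraction * tlen) hit <- TRUE
      }
      if (hit) nHit <- nHit + 1
    }
  }
  safe <- function(num, den) if (den == 0) 0 else num / den
  Sn <- safe(TP, TP + FN); Sp <- safe(TN, TN + FP); PPV <- safe(TP, TP + FP)
  den <- sqrt((TP + FN) * (TN + FP) * (TP + FP) * (TN + FN))
  list(TP = TP, FP = FP, TN = TN, FN = FN, Sn = Sn, Sp = Sp, PPV = PPV,
       Acc = safe(TP + TN, L <- TP + FP + TN + FN), PC = safe(TP, TP + FP + FN),
       ASP = (Sn + PPV) / 2, F = if (Sn + PPV == 0) 0 else 2 * Sn * PPV / (Sn + PPV),
       CC = if (den == 0) 0 else (TP * TN - FN * FP) / den, sSn = safe(nHit, nSites))
}

## Pair-counting AUC oracle with half-credit for ties.
pairCountAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## Minimal counts-style AnalysisResult for exercising downstream analyses.
analysisResultForTest <- function(counts, column = "total") {
  rows <- data.frame(id = names(counts), stringsAsFactors = FALSE)
  rows[[column]] <- unname(counts)
  regulab:::analysisResult("counts", rows, "number")
}

sortRegionsForTest <- function(df) {
  rownames(df) <- NULL
  df
}

## Random region track over given sequence lengths.
randomRegionTrack <- function(lens, nPerSeq, types = "t", maxLen = 12) {
  regs <- lapply(names(lens), function(nm) {
    L <- lens[[nm]]
    n <- nPerSeq
    if (n == 0) return(NULL)
    start <- sample.int(L - maxLen, n, replace = TRUE) - 1L
    len <- sample.int(maxLen - 1L, n, replace = TRUE) + 1L
    regionFrame(start, pmin(start + len, L), sample(types, n, replace = TRUE),
                stats::runif(n), sample(c("+", "-"), n, replace = TRUE))
  })
  names(regs) <- names(lens)
  regionTrack(regs, lens)
}
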