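## Native PWM/consensus scanning and Markov background models.
##
## Score convention: for a window b1..bw, the raw log-odds score is
##   S = sum_i log(M[b_i, i] / Q(b_i))
## with Q the order-0 view of the background model. The relative match score
##   r = (S - S_min) / (S_max - S_min)
## rescales S by the minimal/maximal achievable raw scores of the motif, so
## r is in [0,1] and "80% match" means r >= 0.8. Non-ACGT letters contribute
## 0 to S (the background expectation in log-odds terms).

BASES <- c("A", "C", "G", "T")

allContexts <- function(k) {
  if (k == 0L) return("")
  apply(expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE], 1, paste, collapse = "")
}

## Context row lookup ("" denotes the empty order-0 context, which character
## subscripting cannot address directly).
ctxRow <- function(tab, ctx) if (ctx == "") 1L else match(ctx, rownames(tab))

#' Train a Markov background model on DNA sequences
#'
#' Counts (k+1)-mers on the forward strand only, adds a +1 pseudocount per
#' context cell, and stores lower-order fallback tables (used at sequence
#' starts and after masked letters). Windows containing non-ACGT letters are
#' skipped.
#'
#' @param dna a [DNATrack] (or character vector of sequences).
#' @param order model order k (0..5).
#' @return a [BackgroundModel].
#' @export
trainBackground <- function(dna, order = 0L) {
  seqs <- if (is(dna, "DNATrack")) dna@seqs else as.character(dna)
  if (length(seqs) == 0L || sum(nchar(seqs)) == 0L) stop("empty input: cannot train a background model")
  order <- as.integer(order)
  if (order < 0L || order > 5L) stop("order must be between 0 and 5")
  if (sum(nchar(seqs)) <= 4^(order + 1L))
    warning(sprintf("training data is short for order %d (%d bp <= 4^%d)",
                    order, sum(nchar(seqs)), order + 1L))
  tables <- vector("list", order + 1L)
  for (j in 0:order) {
    ctxs <- allContexts(j)
    counts <- matrix(1, nrow = length(ctxs), ncol = 4, dimnames = list(ctxs, BASES))
    for (s in seqs) {
      chars <- toupper(strsplit(s, "", fixed = TRUE)[[1]])
      L <- length(chars)
      if (L < j + 1L) next
      for (i in (j + 1L):L) {
        win <- chars[(i - j):i]
        if (any(!win %in% BASES)) next
        ctx <- if (j == 0L) "" else paste(win[1:j], collapse = "")
        ri <- ctxRow(counts, ctx)
        counts[ri, win[j + 1L]] <- counts[ri, win[j + 1L]] + 1
      }
    }
    tables[[j + 1L]] <- counts / rowSums(counts)
  }
  new("BackgroundModel", order = order, tables = tables,
      trainedOn = sprintf("%d sequences, %d bp", length(seqs), sum(nchar(seqs))))
}

#' Uniform background model of a given order
#' @param order model order.
#' @return a [BackgroundModel] with all conditionals equal to 1/4.
#' @export
uniformBackground <- function(order = 0L) {
  order <- as.integer(order)
  tables <- lapply(0:order, function(j) {
    ctxs <- allContexts(j)
    matrix(0.25, nrow = length(ctxs), ncol = 4, dimnames = list(ctxs, BASES))
  })
  new("BackgroundModel", order = order, tables = tables, trainedOn = "uniform")
}

#' Order-0 base distribution of a background model
#' @param model a [BackgroundModel].
#' @return named numeric vector over A,C,G,T.
#' @export
baseFrequencies <- function(model) {
  stats::setNames(as.numeric(model@tables[[1]][1L, ]), BASES)
}

## Preceding context of up to `order` characters before position i (1-based).
prevContext <- function(chars, i, order) {
  if (order == 0L || i <= 1L) return("")
  paste(chars[max(1L, i - order):(i - 1L)], collapse = "")
}

## Draw one base given the (possibly shorter or interrupted) preceding context.
sampleBase <- function(model, context) {
  chars <- strsplit(toupper(context), "", fixed = TRUE)[[1]]
  ## longest clean ACGT suffix, at most the model order
  usable <- 0L
  for (i in rev(seq_along(chars))) {
    if (usable >= model@order) break
    if (!chars[i] %in% BASES) break
    usable <- usable + 1L
  }
  j <- usable
  ctx <- if (j == 0L) "" else paste(chars[(length(chars) - j + 1L):length(chars)], collapse = "")
  tab <- model@tables[[j + 1L]]
  sample(BASES, 1L, prob = tab[ctxRow(tab, ctx), ])
}

#' Sample a DNA string from a background model
#'
#' The first k bases are drawn from the lower-order fallback tables;
#' deterministic under a fixed seed.
#'
#' @param model a [BackgroundModel].
#' @param length length in bp (>= 1).
#' @param seed integer seed (required).
#' @return a DNA string.
#' @export
sampleBackground <- function(model, length, seed) {
  if (length < 1) stop("length must be >= 1")
  withSeed(seed, sampleBgString(model, length))
}

## Ambient-RNG sampler backing sampleBackground and the fixture generators.
sampleBgString <- function(model, length) {
  out <- character(length)
  for (i in seq_len(length)) {
    out[i] <- sampleBase(model, prevContext(out, i, model@order))
  }
  paste(out, collapse = "")
}

## Per-motif log-odds scoring machinery -------------------------------------

logOddsMatrix <- function(motif, background) {
  q <- baseFrequencies(background)
  ## floor the probabilities so hard (zero-containing) matrices score finitely
  log(pmax(motif@matrix, 1e-6) / q)
}

scoreBounds <- function(lom) {
  list(min = sum(apply(lom, 2, min)), max = sum(apply(lom, 2, max)))
}

## Relative scores of every window start on one character vector (forward
## orientation of the scanned strand). Non-ACGT letters contribute 0.
windowRelScores <- function(chars, lom, bounds) {
  w <- ncol(lom)
  L <- length(chars)
  n <- L - w + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(chars, BASES)   # NA for N/X
  S <- numeric(n)
  for (j in seq_len(w)) {
    contrib <- lom[, j][idx[j:(j + n - 1L)]]
    contrib[is.na(contrib)] <- 0
    S <- S + contrib
  }
  if (bounds$max == bounds$min) return(rep(NA_real_, n))
  (S - bounds$min) / (bounds$max - bounds$min)
}

#' Scan DNA for matches to a motif collection
#'
#' Every window whose relative match score reaches `threshold` is emitted as
#' a region typed by the motif id, scored by the relative score, on the
#' matching strand. Reverse-strand windows are scored on the reverse
#' complement but reported in forward coordinates. Overlapping hits and hits
#' on both strands at the same position are all kept.
#'
#' @param dna a [DNATrack].
#' @param motifs a [MotifSet] (or a single [Motif]).
#' @param threshold relative score in `[0,1]`; 0.8 is a sensitive setting.
#' @param background a [BackgroundModel]; its order-0 view supplies the
#'   log-odds denominator. Defaults to uniform.
#' @param strands `"both"` or `"forward"`.
#' @return a motif [RegionTrack].
#' @export
scanMotifs <- function(dna, motifs, threshold = 0.8, background = uniformBackground(),
                       strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(is(dna, "DNATrack"))
  if (is(motifs, "Motif")) motifs <- motifSet(list(motifs))
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  prepared <- lapply(motifs@motifs, function(m) {
    lom <- logOddsMatrix(m, background)
    list(motif = m, lom = lom, bounds = scoreBounds(lom), w = ncol(m@matrix))
  })
  out <- lapply(names(dna@seqs), function(nm) {
    chars <- toupper(strsplit(dna@seqs[[nm]], "", fixed = TRUE)[[1]])
    L <- length(chars)
    hits <- list()
    for (pm in prepared) {
      w <- pm$w
      if (w > L) next
      rF <- windowRelScores(chars, pm$lom, pm$bounds)
      sel <- which(!is.na(rF) & rF >= threshold)
      if (length(sel))
        hits[[length(hits) + 1L]] <- regionFrame(sel - 1L, sel - 1L + w, pm$motif@id, rF[sel], "+")
      if (strands == "both") {
        rcChars <- rev(chartr("ACGTNX", "TGCANX", chars))
        rR <- windowRelScores(rcChars, pm$lom, pm$bounds)
        selR <- which(!is.na(rR) & rR >= threshold)
        if (length(selR)) {
          ## window j (1-based) on the reverse complement covers forward
          ## positions [L - j - w + 1, L - j + 1) 0-based half-open
          fwdStart <- L - (selR - 1L) - w
          hits[[length(hits) + 1L]] <- regionFrame(fwdStart, fwdStart + w, pm$motif@id, rR[selR], "-")
        }
      }
    }
    if (length(hits) == 0L) emptyRegions() else do.call(rbind, hits)
  })
  names(out) <- names(dna@seqs)
  regionTrack(out, dna@seqlengths)
}

iupacRegexChar <- function(sym) {
  s <- IUPAC_SETS[[toupper(sym)]]
  if (is.null(s)) stop(sprintf("invalid IUPAC character '%s'", sym))
  if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
}

#' Find exact IUPAC consensus matches
#'
#' Degenerate IUPAC letters match their base set (`N` matches any base,
#' including itself only via A/C/G/T letters in the sequence). All hits score
#' 1. With `strands = "both"` the reverse complement of the pattern is also
#' matched and reported on the minus strand.
#'
#' @param dna a [DNATrack].
#' @param pattern IUPAC string.
#' @param strands `"both"` or `"forward"`.
#' @return a [RegionTrack] of matches typed by the pattern.
#' @export
matchConsensus <- function(dna, pattern, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(is(dna, "DNATrack"))
  pat <- toupper(pattern)
  chars <- strsplit(pat, "", fixed = TRUE)[[1]]
  rx <- paste(vapply(chars, iupacRegexChar, ""), collapse = "")
  pats <- list(list(rx = rx, strand = "+"))
  if (strands == "both") {
    rcPat <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pat)
    rcPat <- paste(rev(strsplit(rcPat, "", fixed = TRUE)[[1]]), collapse = "")
    if (rcPat != pat)
      pats[[2]] <- list(rx = paste(vapply(strsplit(rcPat, "", fixed = TRUE)[[1]],
                                          iupacRegexChar, ""), collapse = ""), strand = "-")
  }
  w <- nchar(pat)
  out <- lapply(names(dna@seqs), function(nm) {
    s <- toupper(dna@seqs[[nm]])
    hits <- list()
    for (p in pats) {
      starts <- integer()
      from <- 1L
      repeat {
        m <- regexpr(p$rx, substring(s, from), perl = TRUE)
        if (m == -1L) break
        st <- from + as.integer(m) - 1L
        starts <- c(starts, st)
        from <- st + 1L   # allow overlapping matches
      }
      if (length(starts))
        hits[[length(hits) + 1L]] <- regionFrame(starts - 1L, starts - 1L + w, pattern, 1, p$strand)
    }
    if (length(hits) == 0L) emptyRegions() else do.call(rbind, hits)
  })
  names(out) <- names(dna@seqs)
  regionTrack(out, dna@seqlengths)
}

#' Build a motif from aligned binding sequences
#'
#' Column counts get a 0.25 pseudocount per cell before normalization.
#'
#' @param aligned character vector of equal-length ACGT strings.
#' @param id motif identifier.
#' @return a [Motif].
#' @export
motifFromSites <- function(aligned, id) {
  if (length(aligned) < 1L) stop("need at least one site")
  if (length(unique(nchar(aligned))) != 1L) stop("aligned sites must have equal lengths")
  if (any(grepl("[^ACGTacgt]", aligned))) stop("sites must contain only A,C,G,T")
  w <- nchar(aligned[1])
  counts <- matrix(0, nrow = 4, ncol = w, dimnames = list(BASES, NULL))
  for (s in toupper(aligned)) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (j in seq_len(w)) counts[chars[j], j] <- counts[chars[j], j] + 1
  }
  counts <- counts + 0.25
  motif(id, sweep(counts, 2, colSums(counts), "/"))
}

#' Per-position best-strand relative motif score profile
#'
#' Position i holds the maximum over strands of the relative score of the
#' window starting at i; the trailing w-1 positions hold 0. A degenerate
#' motif whose achievable score range is empty (all columns uniform) yields
#' an all-zero profile with a warning.
#'
#' @param dna a [DNATrack].
#' @param motif a [Motif].
#' @param background a [BackgroundModel] (order-0 view used).
#' @return a [NumericTrack].
#' @export
pwmScoreProfile <- function(dna, motif, background = uniformBackground()) {
  stopifnot(is(dna, "DNATrack"), is(motif, "Motif"))
  lom <- logOddsMatrix(motif, background)
  bounds <- scoreBounds(lom)
  w <- ncol(lom)
  degenerate <- bounds$max == bounds$min
  if (degenerate)
    warning("motif has zero score range (uniform matrix); profile is all zero")
  out <- lapply(names(dna@seqs), function(nm) {
    chars <- toupper(strsplit(dna@seqs[[nm]], "", fixed = TRUE)[[1]])
    L <- length(chars)
    v <- numeric(L)
    if (degenerate || w > L) return(v)
    rF <- windowRelScores(chars, lom, bounds)
    rcChars <- rev(chartr("ACGTNX", "TGCANX", chars))
    rRrev <- windowRelScores(rcChars, lom, bounds)
    ## map reverse-window scores onto forward start coordinates
    n <- L - w + 1L
    rR <- rRrev[n:1]
    v[seq_len(n)] <- pmax(rF, rR)
    v
  })
  names(out) <- names(dna@seqs)
  numericTrack(out)
}
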