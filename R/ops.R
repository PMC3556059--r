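## General data-processing operations on feature tracks. All operations are
## pure: inputs are never mutated and identical arguments give identical
## results (stochastic fills require an explicit seed).

whereMask <- function(where, tracks, seqname, L) {
  if (is.null(where)) return(rep(TRUE, L))
  if (is(where, "RegionTrack")) return(coverageVector(where, seqname) > 0L)
  evalConditionPositions(asCondition(where)@ast, tracks, seqname, L)
}

#' Mask parts of a DNA track
#'
#' Replaces the bases at positions satisfying `where` either with a fixed
#' letter (classic repeat masking with `N` or `X`) or with random bases
#' sampled from a Markov background model. Background fill walks each masked
#' run left to right, conditioning each draw on the (possibly already
#' masked) preceding context; contexts interrupted by non-ACGT letters fall
#' back to the lower-order tables.
#'
#' @param dna a [DNATrack].
#' @param fill a single letter from the track alphabet, or a
#'   [BackgroundModel].
#' @param where a [Condition], condition text, or a [RegionTrack] (positions
#'   covered by any region are masked).
#' @param tracks track environment for condition evaluation (named list or
#'   repository); defaults to `list(dna = dna)` plus `where` when it is a
#'   track.
#' @param seed integer seed, required for background fill.
#' @return a new [DNATrack].
#' @export
maskTrack <- function(dna, fill, where, tracks = NULL, seed = NULL) {
  stopifnot(is(dna, "DNATrack"))
  isBg <- is(fill, "BackgroundModel")
  if (!isBg) {
    if (!is.character(fill) || nchar(fill) != 1L || !grepl("^[ACGTNXacgtnx]$", fill))
      stop("fill must be a single letter from the track alphabet or a BackgroundModel")
  } else if (is.null(seed)) {
    stop("background fill requires a seed (reproducibility contract)")
  }
  if (is.null(tracks)) tracks <- list(dna = dna)
  doFill <- function() {
    out <- dna@seqs
    for (nm in names(out)) {
      L <- dna@seqlengths[[nm]]
      sel <- whereMask(where, tracks, nm, L)
      if (!any(sel)) next
      chars <- strsplit(out[[nm]], "", fixed = TRUE)[[1]]
      if (!isBg) {
        chars[sel] <- fill
      } else {
        for (i in which(sel)) {
          chars[i] <- sampleBase(fill, prevContext(chars, i, fill@order))
        }
      }
      out[[nm]] <- paste(chars, collapse = "")
    }
    dnaTrack(out)
  }
  if (isBg) withSeed(seed, doFill()) else doFill()
}

#' Remove regions that fail a condition
#'
#' Typical use: drop predicted binding sites whose average conservation is
#' below a threshold (`avg(conservation) >= 0.3`), or sites not overlapping
#' open chromatin.
#'
#' @param track a [RegionTrack].
#' @param where a region-context [Condition] or condition text; regions for
#'   which it is `FALSE` are removed.
#' @param tracks track environment for condition evaluation.
#' @return a new [RegionTrack] with the surviving regions, unchanged.
#' @export
filterRegions <- function(track, where, tracks = NULL) {
  stopifnot(is(track, "RegionTrack"))
  cond <- asCondition(where)
  if (is.null(tracks)) tracks <- list()
  out <- lapply(names(track@regions), function(nm) {
    df <- track@regions[[nm]]
    if (nrow(df) == 0L) return(df)
    keep <- evalConditionRegions(cond@ast, tracks, nm, df)
    df[keep, , drop = FALSE]
  })
  names(out) <- names(track@regions)
  regionTrack(out, track@seqlengths)
}

#' Extend or merge regions
#'
#' `extend` grows every region by `up` bp toward lower coordinates and
#' `down` bp toward higher coordinates (swapped for minus-strand regions when
#' `strand_aware`), clipping at sequence bounds. `merge` unions regions whose
#' nearest-edge gap is at most `max_gap`; the merged score is the maximum of
#' the members, the type is kept only if unanimous (else `"merged"`), and
#' the strand only if unanimous (else `"."`).
#'
#' @param track a [RegionTrack].
#' @param op `"extend"` or `"merge"`.
#' @param up,down extension in bp (extend).
#' @param strand_aware logical (extend).
#' @param max_gap maximum gap to bridge in bp (merge).
#' @return a new [RegionTrack].
#' @export
transformRegions <- function(track, op = c("extend", "merge"), up = 0, down = 0,
                             strand_aware = FALSE, max_gap = 0) {
  op <- match.arg(op)
  stopifnot(is(track, "RegionTrack"))
  if (op == "extend") {
    stopifnot(up >= 0, down >= 0)
    out <- lapply(names(track@regions), function(nm) {
      df <- track@regions[[nm]]
      if (nrow(df) == 0L) return(df)
      L <- track@seqlengths[[nm]]
      minus <- strand_aware & df$strand == "-"
      u <- ifelse(minus, down, up)
      d <- ifelse(minus, up, down)
      df$start <- pmax(0L, as.integer(df$start - u))
      df$end <- pmin(L, as.integer(df$end + d))
      df
    })
  } else {
    stopifnot(max_gap >= 0)
    out <- lapply(names(track@regions), function(nm) {
      df <- sortRegions(track@regions[[nm]])
      if (nrow(df) < 2L) return(df)
      groups <- integer(nrow(df))
      g <- 1L
      groups[1] <- g
      hi <- df$end[1]
      for (i in 2:nrow(df)) {
        if (df$start[i] - hi <= max_gap) {
          groups[i] <- g
        } else {
          g <- g + 1L
          groups[i] <- g
        }
        hi <- max(hi, df$end[i])
      }
      merged <- lapply(split(seq_len(nrow(df)), groups), function(ix) {
        sub <- df[ix, , drop = FALSE]
        regionFrame(min(sub$start), max(sub$end),
                    if (length(unique(sub$type)) == 1L) sub$type[1] else "merged",
                    max(sub$score),
                    if (length(unique(sub$strand)) == 1L) sub$strand[1] else ".")
      })
      do.call(rbind, merged)
    })
  }
  names(out) <- names(track@regions)
  regionTrack(out, track@seqlengths)
}

#' Arithmetic and mathematical transforms of a numeric track
#'
#' @param track a [NumericTrack].
#' @param op one of `add`, `sub`, `mul`, `div`, `min`, `max`, `log`,
#'   `range_normalize`.
#' @param operand a scalar, a [NumericTrack] (positionwise), or a
#'   [NumericMap] (per-sequence scalar). For `range_normalize`, a numeric
#'   `c(lo, hi)` target; the observed min/max over all sequences jointly is
#'   mapped onto it. `log` takes no operand (natural logarithm).
#' @param where optional [Condition]/text: positions failing it are left
#'   unchanged (not supported for `range_normalize`).
#' @param tracks track environment for condition evaluation.
#' @return a new [NumericTrack].
#' @export
trackArithmetic <- function(track, op, operand = NULL, where = NULL, tracks = NULL) {
  stopifnot(is(track, "NumericTrack"))
  op <- match.arg(op, c("add", "sub", "mul", "div", "min", "max", "log", "range_normalize"))
  if (is.null(tracks)) tracks <- list()
  vals <- track@values
  if (op == "range_normalize") {
    if (!is.null(where)) stop("range_normalize does not support 'where'")
    if (is.null(operand) || length(operand) != 2L) stop("range_normalize needs a (lo, hi) target")
    lo <- operand[1]; hi <- operand[2]
    all <- unlist(vals, use.names = FALSE)
    mn <- min(all); mx <- max(all)
    out <- lapply(vals, function(v) {
      if (mx == mn) rep((lo + hi) / 2, length(v))
      else lo + (v - mn) / (mx - mn) * (hi - lo)
    })
    if (mx == mn) warning("constant track: range_normalize maps all values to the interval midpoint")
    names(out) <- names(vals)
    return(numericTrack(out))
  }
  operandFor <- function(nm, L) {
    if (is(operand, "NumericTrack")) return(operand@values[[nm]])
    if (is(operand, "NumericMap")) return(rep(unname(mapValues(operand, nm)), L))
    if (is.numeric(operand) && length(operand) == 1L) return(rep(operand, L))
    if (op == "log" && is.null(operand)) return(NULL)
    stop("operand must be a scalar, NumericTrack or NumericMap")
  }
  out <- lapply(names(vals), function(nm) {
    v <- vals[[nm]]
    L <- length(v)
    sel <- whereMask(where, tracks, nm, L)
    b <- operandFor(nm, L)
    r <- v
    newv <- switch(op,
      add = v + b, sub = v - b, mul = v * b,
      div = {
        if (any(sel & b == 0))
          stop(sprintf("division by zero in sequence '%s' at position %d",
                       nm, which(sel & b == 0)[1] - 1L))
        v / b
      },
      min = pmin(v, b), max = pmax(v, b),
      log = {
        if (any(sel & v <= 0))
          stop(sprintf("log of non-positive value in sequence '%s' at position %d",
                       nm, which(sel & v <= 0)[1] - 1L))
        suppressWarnings(log(v))
      })
    r[sel] <- newv[sel]
    r
  })
  names(out) <- names(vals)
  numericTrack(out)
}

#' Sliding-window summary of a numeric track
#'
#' Centered window of odd size; windows are shrunk (clipped) at sequence
#' edges rather than padded, so the output has the same length as the input.
#'
#' @param track a [NumericTrack].
#' @param stat one of `mean`, `median`, `min`, `max`, `sum`.
#' @param size odd window size in bp.
#' @return a new [NumericTrack].
#' @export
slidingWindow <- function(track, stat = c("mean", "median", "min", "max", "sum"), size) {
  stat <- match.arg(stat)
  stopifnot(is(track, "NumericTrack"))
  if (size < 1 || size %% 2 == 0) stop("window size must be odd and >= 1")
  half <- (size - 1L) / 2L
  fn <- switch(stat, mean = mean, median = stats::median, min = min, max = max, sum = sum)
  out <- lapply(track@values, function(v) {
    L <- length(v)
    if (size == 1L) return(v)
    if (stat %in% c("mean", "sum")) {
      ## cumulative-sum implementation; edge windows shrink
      cs <- c(0, cumsum(v))
      i <- seq_len(L)
      lo <- pmax(1L, i - half); hi <- pmin(L, i + half)
      s <- cs[hi + 1L] - cs[lo]
      if (stat == "sum") s else s / (hi - lo + 1L)
    } else {
      vapply(seq_len(L), function(i) fn(v[max(1L, i - half):min(L, i + half)]), 0)
    }
  })
  names(out) <- names(track@values)
  numericTrack(out)
}

#' Weighted per-position combination of numeric tracks
#'
#' @param tracks list of [NumericTrack]s over the same sequences.
#' @param weights numeric vector, one weight per track.
#' @return a [NumericTrack] holding the per-position weighted sum.
#' @export
combineTracks <- function(tracks, weights) {
  if (length(tracks) != length(weights)) stop("need exactly one weight per track")
  if (length(tracks) == 0L) stop("need at least one track")
  ref <- tracks[[1]]
  for (t in tracks) {
    if (!identical(t@seqlengths, ref@seqlengths))
      stop("all tracks must cover the same sequences with equal lengths")
  }
  out <- lapply(names(ref@values), function(nm) {
    Reduce(`+`, Map(function(t, w) w * t@values[[nm]], tracks, weights))
  })
  names(out) <- names(ref@values)
  numericTrack(out)
}

#' Threshold a numeric track into regions
#'
#' Maximal runs of positions with value `>= threshold` and length at least
#' `min_length` become regions scored by the run mean.
#'
#' @param track a [NumericTrack].
#' @param threshold minimum value.
#' @param min_length minimum run length in bp.
#' @param type type label assigned to the regions.
#' @return a [RegionTrack].
#' @export
numericToRegions <- function(track, threshold, min_length = 1L, type = "region") {
  stopifnot(is(track, "NumericTrack"), min_length >= 1)
  out <- lapply(track@values, function(v) {
    above <- v >= threshold
    if (!any(above)) return(emptyRegions())
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_length
    if (!any(keep)) return(emptyRegions())
    s <- starts[keep]; e <- ends[keep]
    regionFrame(s - 1L, e, type,
                vapply(seq_along(s), function(i) mean(v[s[i]:e[i]]), 0), ".")
  })
  names(out) <- names(track@values)
  regionTrack(out, track@seqlengths)
}

#' Convert region evidence to a per-position numeric signal
#'
#' @param track a [RegionTrack].
#' @param mode `"coverage"` (number of covering regions per position) or
#'   `"max_score"` (maximum score among covering regions, 0 where none).
#' @return a [NumericTrack].
#' @export
regionsToNumeric <- function(track, mode = c("coverage", "max_score")) {
  mode <- match.arg(mode)
  stopifnot(is(track, "RegionTrack"))
  out <- lapply(names(track@regions), function(nm) {
    L <- track@seqlengths[[nm]]
    df <- track@regions[[nm]]
    v <- numeric(L)
    if (nrow(df)) for (i in seq_len(nrow(df))) {
      ix <- (df$start[i] + 1L):df$end[i]
      if (mode == "coverage") v[ix] <- v[ix] + 1 else v[ix] <- pmax(v[ix], df$score[i])
    }
    v
  })
  names(out) <- names(track@regions)
  numericTrack(out)
}

#' Per-sequence summary statistics of a DNA track
#'
#' @param dna a [DNATrack].
#' @param stat `"gc_content"` (G+C fraction of unambiguous bases; N/X are
#'   excluded from numerator and denominator), `"length"`, or
#'   `"count_base"`.
#' @param base base letter for `count_base` (case-insensitive).
#' @return a sequence [NumericMap].
#' @export
sequenceStatistic <- function(dna, stat = c("gc_content", "length", "count_base"), base = "A") {
  stat <- match.arg(stat)
  stopifnot(is(dna, "DNATrack"))
  vals <- vapply(names(dna@seqs), function(nm) {
    chars <- toupper(strsplit(dna@seqs[[nm]], "", fixed = TRUE)[[1]])
    switch(stat,
      gc_content = {
        acgt <- sum(chars %in% c("A", "C", "G", "T"))
        if (acgt == 0L) 0 else sum(chars %in% c("G", "C")) / acgt
      },
      length = length(chars),
      count_base = sum(chars == toupper(base)))
  }, 0)
  numericMap("sequence", vals)
}

#' Build a collection from a numeric map by thresholding
#'
#' E.g. sequences with less than 40% GC-content, or motifs supported by at
#' least 80% of the sequences.
#'
#' @param map a [NumericMap].
#' @param op comparison operator: one of `<`, `<=`, `>`, `>=`, `==`, `!=`.
#' @param value constant to compare against.
#' @return a [Collection] of the members satisfying the predicate.
#' @export
collectionFromMap <- function(map, op, value) {
  stopifnot(is(map, "NumericMap"))
  keep <- applyCmp(map@values, op, value)
  collection(map@memberType, names(map@values)[keep])
}
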