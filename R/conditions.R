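## Condition expressions: Boolean combinations of per-position or per-region
## predicates, evaluated against a track environment. The concrete syntax is
## shared with the protocol language, e.g.
##   avg(conservation) >= 0.3 and not overlaps(repeats)
##   inside(peaks) and conservation > 0.5 and base(dna) in {A,T}
##   score >= 0.8 and distance_to_nearest(partner_sites) <= 10

#' Condition expression over feature tracks
#'
#' @slot ast parsed expression tree (nested lists).
#' @slot text the source text.
#' @export
setClass("Condition", representation(ast = "list", text = "character"))

setMethod("show", "Condition", function(object) {
  cat("Condition:", object@text, "\n")
})

## --------------------------- tokenizer -------------------------------------

condTokenize <- function(text) {
  pats <- c(
    ws = "^\\s+",
    num = "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?",
    str = '^"[^"]*"',
    op = "^(>=|<=|==|!=|>|<|=)",
    punct = "^[(){},]",
    id = "^[A-Za-z_][A-Za-z0-9_]*"
  )
  tokens <- list()
  pos <- 1L
  rest <- text
  while (nchar(rest) > 0L) {
    matched <- FALSE
    for (kind in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[kind]], rest))
      if (length(m) == 1L && nchar(m) > 0L) {
        if (kind != "ws")
          tokens[[length(tokens) + 1L]] <- list(kind = kind, value = m, col = pos)
        pos <- pos + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop(sprintf("condition syntax error at column %d: unexpected '%s'", pos, substring(rest, 1, 1)))
  }
  tokens
}

## --------------------------- parser ----------------------------------------

condParserState <- function(tokens) {
  env <- new.env()
  env$tokens <- tokens
  env$i <- 1L
  env
}

pPeek <- function(st) if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
pNext <- function(st) { tk <- pPeek(st); st$i <- st$i + 1L; tk }
pExpect <- function(st, value) {
  tk <- pNext(st)
  if (is.null(tk) || tk$value != value)
    stop(sprintf("condition syntax error: expected '%s'%s", value,
                 if (is.null(tk)) " at end of input" else sprintf(" at column %d", tk$col)))
  tk
}
pIsId <- function(tk, word = NULL) {
  !is.null(tk) && tk$kind == "id" && (is.null(word) || tolower(tk$value) == word)
}

parseOrExpr <- function(st) {
  left <- parseAndExpr(st)
  args <- list(left)
  while (pIsId(pPeek(st), "or")) {
    pNext(st)
    args[[length(args) + 1L]] <- parseAndExpr(st)
  }
  if (length(args) == 1L) left else list(kind = "or", args = args)
}

parseAndExpr <- function(st) {
  left <- parseNotExpr(st)
  args <- list(left)
  while (pIsId(pPeek(st), "and")) {
    pNext(st)
    args[[length(args) + 1L]] <- parseNotExpr(st)
  }
  if (length(args) == 1L) left else list(kind = "and", args = args)
}

parseNotExpr <- function(st) {
  if (pIsId(pPeek(st), "not")) {
    pNext(st)
    return(list(kind = "not", arg = parseNotExpr(st)))
  }
  parseAtom(st)
}

parseValue <- function(st) {
  tk <- pNext(st)
  if (is.null(tk)) stop("condition syntax error: expected a value at end of input")
  if (tk$kind == "num") return(list(kind = "number", value = as.numeric(tk$value)))
  if (tk$kind == "str") return(list(kind = "string", value = gsub('^"|"$', "", tk$value)))
  if (tk$kind == "id") return(list(kind = "ref", name = tk$value))
  stop(sprintf("condition syntax error: unexpected '%s' at column %d", tk$value, tk$col))
}

parseCmpTail <- function(st, lhs) {
  tk <- pNext(st)
  if (is.null(tk) || tk$kind != "op")
    stop(sprintf("condition syntax error: expected comparison operator%s",
                 if (is.null(tk)) " at end of input" else sprintf(" at column %d", tk$col)))
  op <- if (tk$value == "=") "==" else tk$value
  list(kind = "cmp", lhs = lhs, op = op, rhs = parseValue(st))
}

parseAtom <- function(st) {
  tk <- pPeek(st)
  if (is.null(tk)) stop("condition syntax error: unexpected end of input")
  if (tk$value == "(") {
    pNext(st)
    inner <- parseOrExpr(st)
    pExpect(st, ")")
    return(inner)
  }
  if (tk$kind != "id")
    stop(sprintf("condition syntax error: unexpected '%s' at column %d", tk$value, tk$col))
  word <- tolower(tk$value)
  if (word %in% c("true", "false")) {
    pNext(st)
    return(list(kind = "const", value = word == "true"))
  }
  if (word == "inside") {
    pNext(st); pExpect(st, "(")
    nm <- pNext(st); pExpect(st, ")")
    return(list(kind = "inside", track = nm$value))
  }
  if (word == "overlaps") {
    pNext(st); pExpect(st, "(")
    nm <- pNext(st); pExpect(st, ")")
    return(list(kind = "overlaps", track = nm$value))
  }
  if (word == "base") {
    pNext(st); pExpect(st, "(")
    nm <- pNext(st); pExpect(st, ")")
    intk <- pNext(st)
    if (!pIsId(intk, "in")) stop("condition syntax error: expected 'in' after base(...)")
    pExpect(st, "{")
    letters <- character()
    repeat {
      tk2 <- pNext(st)
      if (is.null(tk2)) stop("condition syntax error: unterminated base set")
      if (tk2$value == "}") break
      if (tk2$value == ",") next
      letters <- c(letters, toupper(tk2$value))
    }
    return(list(kind = "base_in", track = nm$value, letters = letters))
  }
  if (word == "avg") {
    pNext(st); pExpect(st, "(")
    nm <- pNext(st); pExpect(st, ")")
    return(parseCmpTail(st, list(kind = "avg", track = nm$value)))
  }
  if (word == "distance_to_nearest") {
    pNext(st); pExpect(st, "(")
    nm <- pNext(st); pExpect(st, ")")
    return(parseCmpTail(st, list(kind = "distance", track = nm$value)))
  }
  if (word %in% c("length", "score", "type")) {
    pNext(st)
    return(parseCmpTail(st, list(kind = word)))
  }
  ## bare identifier: numeric track value at the position
  pNext(st)
  parseCmpTail(st, list(kind = "track", track = tk$value))
}

#' Parse a condition expression
#'
#' Position predicates: `trackname >= 0.3` (numeric track value at the
#' position, compared to a constant, another numeric track, or a per-sequence
#' NumericMap value), `inside(regiontrack)`, `base(dnatrack) in {A,C}`.
#' Region predicates: `length`/`score`/`type` comparisons,
#' `overlaps(regiontrack)`, `avg(numerictrack) >= c`,
#' `distance_to_nearest(regiontrack) <= d`. Combine with `and`, `or`, `not`
#' and parentheses; literals `true`/`false` are accepted.
#'
#' @param text condition source text.
#' @return a [Condition].
#' @export
parseCondition <- function(text) {
  st <- condParserState(condTokenize(text))
  ast <- parseOrExpr(st)
  if (!is.null(pPeek(st)))
    stop(sprintf("condition syntax error: trailing input at column %d", pPeek(st)$col))
  new("Condition", ast = ast, text = text)
}

## --------------------------- evaluation ------------------------------------

condResolve <- function(trackEnv, name) {
  obj <- if (is.environment(trackEnv) || is(trackEnv, "Repository")) {
    if (repoHas(trackEnv, name)) repoGet(trackEnv, name) else NULL
  } else trackEnv[[name]]
  if (is.null(obj)) stop(sprintf("condition references unknown track '%s'", name))
  obj
}

coverageVector <- function(rtrack, seqname) {
  L <- rtrack@seqlengths[[seqname]]
  cov <- integer(L)
  df <- rtrack@regions[[seqname]]
  if (!is.null(df) && nrow(df)) for (i in seq_len(nrow(df)))
    cov[(df$start[i] + 1L):df$end[i]] <- cov[(df$start[i] + 1L):df$end[i]] + 1L
  cov
}

rhsPositionValues <- function(rhs, trackEnv, seqname, L) {
  if (rhs$kind == "number") return(rep(rhs$value, L))
  if (rhs$kind == "string") stop("cannot compare a numeric value to a string")
  obj <- condResolve(trackEnv, rhs$name)
  if (is(obj, "NumericTrack")) return(obj@values[[seqname]])
  if (is(obj, "NumericMap")) return(rep(unname(mapValues(obj, seqname)), L))
  stop(sprintf("'%s' is not usable as a numeric comparison operand", rhs$name))
}

applyCmp <- function(a, op, b) switch(op,
  ">" = a > b, ">=" = a >= b, "<" = a < b, "<=" = a <= b,
  "==" = a == b, "!=" = a != b,
  stop("unknown comparison operator"))

## Vectorized per-position evaluation over one sequence; returns logical(L).
evalConditionPositions <- function(ast, trackEnv, seqname, L) {
  k <- ast$kind
  if (k == "const") return(rep(ast$value, L))
  if (k == "and") return(Reduce(`&`, lapply(ast$args, evalConditionPositions, trackEnv, seqname, L)))
  if (k == "or") return(Reduce(`|`, lapply(ast$args, evalConditionPositions, trackEnv, seqname, L)))
  if (k == "not") return(!evalConditionPositions(ast$arg, trackEnv, seqname, L))
  if (k == "inside") {
    obj <- condResolve(trackEnv, ast$track)
    if (!is(obj, "RegionTrack")) stop(sprintf("inside() needs a region track, got %s", class(obj)[1]))
    return(coverageVector(obj, seqname) > 0L)
  }
  if (k == "base_in") {
    obj <- condResolve(trackEnv, ast$track)
    if (!is(obj, "DNATrack")) stop(sprintf("base() needs a DNA track, got %s", class(obj)[1]))
    chars <- toupper(strsplit(obj@seqs[[seqname]], "", fixed = TRUE)[[1]])
    return(chars %in% ast$letters)
  }
  if (k == "cmp") {
    lhs <- ast$lhs
    if (lhs$kind != "track")
      stop(sprintf("'%s' is a region predicate and cannot be evaluated at a position", lhs$kind))
    obj <- condResolve(trackEnv, lhs$track)
    if (!is(obj, "NumericTrack"))
      stop(sprintf("'%s' is not a numeric track", lhs$track))
    return(applyCmp(obj@values[[seqname]], ast$op, rhsPositionValues(ast$rhs, trackEnv, seqname, L)))
  }
  stop(sprintf("predicate '%s' cannot be evaluated in position context", k))
}

nearestEdgeGap <- function(start, end, df) {
  if (is.null(df) || nrow(df) == 0L) return(Inf)
  gaps <- pmax(df$start - end, start - df$end)
  max(0, min(gaps))
}

## Per-region evaluation: regions is the candidate data.frame; returns logical(n).
evalConditionRegions <- function(ast, trackEnv, seqname, regions, self = NULL) {
  n <- nrow(regions)
  k <- ast$kind
  if (k == "const") return(rep(ast$value, n))
  if (k == "and") return(Reduce(`&`, lapply(ast$args, evalConditionRegions, trackEnv, seqname, regions, self)))
  if (k == "or") return(Reduce(`|`, lapply(ast$args, evalConditionRegions, trackEnv, seqname, regions, self)))
  if (k == "not") return(!evalConditionRegions(ast$arg, trackEnv, seqname, regions, self))
  if (k == "overlaps") {
    obj <- condResolve(trackEnv, ast$track)
    if (!is(obj, "RegionTrack")) stop("overlaps() needs a region track")
    other <- obj@regions[[seqname]]
    return(vapply(seq_len(n), function(i) {
      !is.null(other) && nrow(other) > 0L &&
        any(other$start < regions$end[i] & other$end > regions$start[i])
    }, TRUE))
  }
  if (k == "cmp") {
    lhs <- ast$lhs
    lhsVals <- switch(lhs$kind,
      length = regions$end - regions$start,
      score = regions$score,
      type = regions$type,
      avg = {
        obj <- condResolve(trackEnv, lhs$track)
        if (!is(obj, "NumericTrack")) stop(sprintf("avg() needs a numeric track, not '%s'", class(obj)[1]))
        v <- obj@values[[seqname]]
        vapply(seq_len(n), function(i) mean(v[(regions$start[i] + 1L):regions$end[i]]), 0)
      },
      distance = {
        obj <- condResolve(trackEnv, lhs$track)
        if (!is(obj, "RegionTrack")) stop("distance_to_nearest() needs a region track")
        other <- obj@regions[[seqname]]
        vapply(seq_len(n), function(i) nearestEdgeGap(regions$start[i], regions$end[i], other), 0)
      },
      track = stop(sprintf("per-position predicate on '%s' cannot be evaluated for a region; use avg(%s)",
                           lhs$track, lhs$track)),
      stop(sprintf("unsupported region predicate '%s'", lhs$kind))
    )
    rhs <- ast$rhs
    if (lhs$kind == "type") {
      if (!ast$op %in% c("==", "!=")) stop("type supports only == and !=")
      rv <- if (rhs$kind == "string") rhs$value else if (rhs$kind == "ref") rhs$name
        else stop("type must be compared to a string")
      return(applyCmp(lhsVals, ast$op, rv))
    }
    rv <- if (rhs$kind == "number") rhs$value
      else if (rhs$kind == "ref") {
        obj <- condResolve(trackEnv, rhs$name)
        if (is(obj, "NumericMap")) unname(mapValues(obj, seqname))
        else stop(sprintf("'%s' is not usable as a region comparison operand", rhs$name))
      } else stop("cannot compare a numeric region property to a string")
    return(applyCmp(lhsVals, ast$op, rv))
  }
  stop(sprintf("predicate '%s' cannot be evaluated in region context", k))
}

#' Evaluate a condition at a single position or region
#'
#' @param cond a [Condition] (or condition source text).
#' @param tracks a named list of data objects, or a repository.
#' @param sequence sequence name.
#' @param position 0-based position (position context), or `NULL`.
#' @param region one-row region data.frame or list with `start`, `end`,
#'   `type`, `score`, `strand` (region context), or `NULL`.
#' @return logical scalar.
#' @export
evalCondition <- function(cond, tracks, sequence, position = NULL, region = NULL) {
  if (is.character(cond)) cond <- parseCondition(cond)
  if (!is.null(position) && !is.null(region)) stop("give either a position or a region, not both")
  if (is.null(position) && is.null(region)) stop("give a position or a region to evaluate at")
  if (!is.null(position)) {
    L <- inferSeqLength(tracks, sequence)
    if (position < 0L || position >= L) stop("position outside sequence")
    mask <- evalConditionPositions(cond@ast, tracks, sequence, L)
    return(mask[[position + 1L]])
  }
  if (is.list(region) && !is.data.frame(region)) {
    region <- regionFrame(region$start, region$end,
                          if (is.null(region$type)) "" else region$type,
                          if (is.null(region$score)) 0 else region$score,
                          if (is.null(region$strand)) "." else region$strand)
  }
  evalConditionRegions(cond@ast, tracks, sequence, region)[[1L]]
}

inferSeqLength <- function(tracks, sequence) {
  objs <- if (is.environment(tracks) || is(tracks, "Repository"))
    lapply(repoNames(tracks), function(nm) repoGet(tracks, nm))
  else tracks
  for (obj in objs) {
    if (is(obj, "FeatureTrack") && sequence %in% names(obj@seqlengths))
      return(obj@seqlengths[[sequence]])
    if (is(obj, "SequenceSet") && sequence %in% obj@info$name)
      return(unname(seqLengths(obj)[sequence]))
  }
  stop(sprintf("cannot determine length of sequence '%s' from the track environment", sequence))
}

asCondition <- function(x) {
  if (is(x, "Condition")) x else if (is.character(x)) parseCondition(x)
  else stop("expected a Condition or condition text")
}
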