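## Cis-regulatory module modelling: constraint-based scanning of motif
## tracks for module occurrences, and interaction-partner filtering.
## All distances are nearest-edge gaps; overlapping sites have gap 0.

#' Construct a ModuleModel
#'
#' @param id module identifier.
#' @param slots list of character vectors: alternative motif ids per slot.
#' @param maxSpan maximum whole-occurrence length in bp.
#' @param ordered must sites appear in slot order along the sequence?
#' @param orientation per-slot strand constraint ("+", "-" or "any");
#'   recycled if length 1.
#' @param gaps data.frame with columns `min`, `max`, one row per adjacent
#'   slot pair (default: unconstrained up to `maxSpan`).
#' @return a [ModuleModel].
#' @export
moduleModel <- function(id, slots, maxSpan = Inf, ordered = TRUE,
                        orientation = "any", gaps = NULL) {
  k <- length(slots)
  if (length(orientation) == 1L) orientation <- rep(orientation, k)
  if (is.null(gaps)) gaps <- data.frame(min = rep(0, k - 1L), max = rep(Inf, k - 1L))
  new("ModuleModel", id = id, slots = lapply(slots, as.character),
      maxSpan = maxSpan, ordered = ordered, orientation = orientation, gaps = gaps)
}

edgeGap <- function(s1, e1, s2, e2) max(0, max(s1 - e2, s2 - e1))

#' Scan a motif track for module occurrences
#'
#' Enumerates selections of one binding site per slot (distinct sites;
#' member sites may overlap each other) and emits every selection
#' satisfying the span, order, orientation and gap constraints as a module
#' region spanning the members, with the member sites as children. Two
#' selections with the same member set are emitted once.
#'
#' @param motif_track a motif [RegionTrack] (region types are motif ids).
#' @param model a [ModuleModel].
#' @param motifs optional [MotifSet]; when given, every motif id referenced
#'   by the model must exist in it.
#' @param score how to combine member scores into the module score:
#'   `"sum"` (default), `"mean"` or `"min"`.
#' @return a module [RegionTrack] (regions typed by the module id).
#' @export
scanModules <- function(motif_track, model, motifs = NULL, score = c("sum", "mean", "min")) {
  score <- match.arg(score)
  stopifnot(is(motif_track, "RegionTrack"), is(model, "ModuleModel"))
  if (!is.null(motifs)) {
    missing <- setdiff(unique(unlist(model@slots)), motifIds(motifs))
    if (length(missing))
      stop(sprintf("module references unknown motif id(s): %s", paste(missing, collapse = ", ")))
  }
  scoreFn <- switch(score, sum = sum, mean = mean, min = min)
  k <- length(model@slots)
  out <- lapply(names(motif_track@regions), function(nm) {
    df <- motif_track@regions[[nm]]
    if (nrow(df) == 0L) return(emptyRegions())
    cand <- lapply(model@slots, function(ids) which(df$type %in% ids))
    if (any(vapply(cand, length, 0L) == 0L)) return(emptyRegions())
    combos <- as.matrix(expand.grid(cand, KEEP.OUT.ATTRS = FALSE))
    ## vectorized constraint screening over all slot assignments
    S <- matrix(df$start[combos], nrow = nrow(combos))
    E <- matrix(df$end[combos], nrow = nrow(combos))
    ok <- rep(TRUE, nrow(combos))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      ok <- ok & combos[, i] != combos[, j]       # one site fills only one slot
    for (i in seq_len(k)) {
      o <- model@orientation[i]
      if (o != "any") ok <- ok & df$strand[combos[, i]] == o
    }
    span <- Reduce(pmax, lapply(seq_len(k), function(i) E[, i])) -
      Reduce(pmin, lapply(seq_len(k), function(i) S[, i]))
    ok <- ok & span <= model@maxSpan
    if (model@ordered) for (i in seq_len(k - 1L))
      ok <- ok & (S[, i] < S[, i + 1L] | (S[, i] == S[, i + 1L] & E[, i] <= E[, i + 1L]))
    for (i in seq_len(k - 1L)) {
      gap <- pmax(0, pmax(S[, i] - E[, i + 1L], S[, i + 1L] - E[, i]))
      ok <- ok & gap >= model@gaps$min[i] & gap <= model@gaps$max[i]
    }
    sel <- which(ok)
    if (length(sel) == 0L) return(emptyRegions())
    ## same member set emitted once
    keys <- vapply(sel, function(r) paste(sort(combos[r, ]), collapse = ","), "")
    sel <- sel[!duplicated(keys)]
    hits <- lapply(sel, function(r) {
      ix <- combos[r, ]
      sites <- df[ix, , drop = FALSE]
      regionFrame(min(sites$start), max(sites$end), model@id, scoreFn(sites$score), ".",
                  children = list(regionFrame(sites$start, sites$end, sites$type,
                                              sites$score, sites$strand)))
    })
    do.call(rbind, hits)
  })
  names(out) <- names(motif_track@regions)
  regionTrack(out, motif_track@seqlengths)
}

#' Filter binding sites lacking a nearby interaction partner
#'
#' A site survives if and only if some other site in the same sequence,
#' whose motif is a declared partner of the site's motif, lies within
#' `max_gap` bp (nearest-edge distance; overlap counts as 0). Survival is
#' evaluated against the input track, so removals do not cascade.
#'
#' @param motif_track a motif [RegionTrack].
#' @param partners either a [MotifSet] (partner annotations are taken from
#'   the motifs) or a named list mapping motif id to a character vector of
#'   partner motif ids.
#' @param max_gap maximum nearest-edge gap in bp (>= 0; may be `Inf`).
#' @return a filtered [RegionTrack].
#' @export
interactionFilter <- function(motif_track, partners, max_gap) {
  stopifnot(is(motif_track, "RegionTrack"), max_gap >= 0)
  rel <- if (is(partners, "MotifSet"))
    lapply(partners@motifs, function(m) m@partners)
  else partners
  out <- lapply(names(motif_track@regions), function(nm) {
    df <- motif_track@regions[[nm]]
    if (nrow(df) == 0L) return(df)
    keep <- vapply(seq_len(nrow(df)), function(i) {
      ps <- rel[[df$type[i]]]
      if (is.null(ps) || length(ps) == 0L) return(FALSE)
      others <- setdiff(which(df$type %in% ps), i)
      if (length(others) == 0L) return(FALSE)
      any(vapply(others, function(j)
        edgeGap(df$start[i], df$end[i], df$start[j], df$end[j]) <= max_gap, TRUE))
    }, TRUE)
    df[keep, , drop = FALSE]
  })
  names(out) <- names(motif_track@regions)
  regionTrack(out, motif_track@seqlengths)
}

## --------------------------- module mini-grammar ---------------------------

#' Parse a declarative module description
#'
#' Grammar (whitespace-separated clauses):
#' `slots=[{M1,M2},{M3}]` (required), `span<=N`, `ordered` or `unordered`,
#' `gap[i,j]=min..max` for adjacent slots i,j (1-based),
#' `orient[i]=+|-|any`.
#'
#' @param text module description.
#' @param id module identifier (default "module").
#' @return a [ModuleModel].
#' @export
moduleFromSpec <- function(text, id = "module") {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  slots <- NULL; maxSpan <- Inf; ordered <- TRUE
  orientation <- NULL; gapSpecs <- list()
  for (tk in toks) {
    if (grepl("^slots=", tk)) {
      body <- sub("^slots=\\[", "", sub("\\]$", "", tk))
      groups <- regmatches(body, gregexpr("\\{[^}]*\\}", body))[[1]]
      if (length(groups) == 0L) stop("module spec: slots must be like slots=[{M1,M2},{M3}]")
      slots <- lapply(groups, function(g) {
        ids <- strsplit(gsub("[{}]", "", g), ",", fixed = TRUE)[[1]]
        ids <- trimws(ids)
        if (any(ids == "")) stop("module spec: empty motif id in slot")
        ids
      })
    } else if (grepl("^span<=", tk)) {
      maxSpan <- as.numeric(sub("^span<=", "", tk))
      if (is.na(maxSpan) || maxSpan <= 0) stop("module spec: invalid span bound")
    } else if (tk == "ordered") {
      ordered <- TRUE
    } else if (tk == "unordered") {
      ordered <- FALSE
    } else if (grepl("^gap\\[", tk)) {
      m <- regmatches(tk, regexec("^gap\\[([0-9]+),([0-9]+)\\]=(-?[0-9]+)\\.\\.(-?[0-9]+|inf)$", tk))[[1]]
      if (length(m) == 0L) stop(sprintf("module spec: cannot parse gap clause '%s'", tk))
      i <- as.integer(m[2]); j <- as.integer(m[3])
      if (j != i + 1L) stop("module spec: gap constraints apply to adjacent slots only")
      lo <- as.numeric(m[4])
      hi <- if (m[5] == "inf") Inf else as.numeric(m[5])
      if (lo < 0 || hi < lo) stop("module spec: gap bounds must satisfy 0 <= min <= max")
      gapSpecs[[length(gapSpecs) + 1L]] <- list(i = i, min = lo, max = hi)
    } else if (grepl("^orient\\[", tk)) {
      m <- regmatches(tk, regexec("^orient\\[([0-9]+)\\]=(\\+|-|any)$", tk))[[1]]
      if (length(m) == 0L) stop(sprintf("module spec: cannot parse orientation clause '%s'", tk))
      orientation <- c(orientation, stats::setNames(m[3], m[2]))
    } else if (tk != "") {
      stop(sprintf("module spec: unknown clause '%s'", tk))
    }
  }
  if (is.null(slots)) stop("module spec: missing slots=[...] clause")
  k <- length(slots)
  if (k < 2L) stop("module spec: a module needs at least 2 slots")
  orient <- rep("any", k)
  if (!is.null(orientation)) {
    ix <- as.integer(names(orientation))
    if (any(ix < 1L | ix > k)) stop("module spec: orientation index out of range")
    orient[ix] <- unname(orientation)
  }
  gaps <- data.frame(min = rep(0, k - 1L), max = rep(Inf, k - 1L))
  for (g in gapSpecs) {
    if (g$i < 1L || g$i > k - 1L) stop("module spec: gap index out of range")
    gaps$min[g$i] <- g$min; gaps$max[g$i] <- g$max
  }
  moduleModel(id, slots, maxSpan = maxSpan, ordered = ordered,
              orientation = orient, gaps = gaps)
}

#' Canonical re-serialization of a ModuleModel
#' @param model a [ModuleModel].
#' @return the spec text (parseable by [moduleFromSpec()]).
#' @export
moduleToSpec <- function(model) {
  k <- length(model@slots)
  parts <- sprintf("slots=[%s]",
                   paste(vapply(model@slots, function(s)
                     sprintf("{%s}", paste(s, collapse = ",")), ""), collapse = ","))
  if (is.finite(model@maxSpan)) parts <- c(parts, sprintf("span<=%d", as.integer(model@maxSpan)))
  parts <- c(parts, if (model@ordered) "ordered" else "unordered")
  for (i in seq_len(k - 1L)) {
    if (model@gaps$min[i] != 0 || is.finite(model@gaps$max[i]))
      parts <- c(parts, sprintf("gap[%d,%d]=%d..%s", i, i + 1L, as.integer(model@gaps$min[i]),
                                if (is.finite(model@gaps$max[i]))
                                  sprintf("%d", as.integer(model@gaps$max[i])) else "inf"))
  }
  for (i in seq_len(k)) {
    if (model@orientation[i] != "any")
      parts <- c(parts, sprintf("orient[%d]=%s", i, model@orientation[i]))
  }
  paste(parts, collapse = " ")
}
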