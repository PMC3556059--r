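## Constructors, accessors and coordinate conventions for the core data model.
## Internal coordinates are 0-based half-open on the genomic forward strand;
## strand awareness is applied at operation level.

#' Construct a SequenceSet
#'
#' @param name,chromosome,start,end vectors describing each sequence; `start`
#'   and `end` are genomic, 0-based half-open.
#' @param strand "+" or "-" per sequence.
#' @param build genome build label (free text).
#' @param tss_offset optional TSS position within each sequence (bp from
#'   sequence start; `NA` if unknown, may lie outside `[0, length)`).
#' @return a [SequenceSet].
#' @export
sequenceSet <- function(name, chromosome, start, end, strand = "+",
                        build = "custom", tss_offset = NA_real_) {
  df <- data.frame(name = as.character(name), build = build,
                   chromosome = as.character(chromosome),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = strand, tss_offset = as.numeric(tss_offset),
                   stringsAsFactors = FALSE)
  new("SequenceSet", info = df)
}

#' Sequence names of an object
#' @param x a SequenceSet or FeatureTrack.
#' @return character vector of sequence names.
#' @export
setGeneric("seqNames", function(x) standardGeneric("seqNames"))

#' @rdname seqNames
#' @export
setMethod("seqNames", "SequenceSet", function(x) x@info$name)

#' @rdname seqNames
#' @export
setMethod("seqNames", "FeatureTrack", function(x) names(x@seqlengths))

#' Sequence lengths (bp) of an object
#' @param x a SequenceSet or FeatureTrack.
#' @return named numeric vector of lengths.
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname seqLengths
#' @export
setMethod("seqLengths", "SequenceSet", function(x)
  stats::setNames(x@info$end - x@info$start, x@info$name))

#' @rdname seqLengths
#' @export
setMethod("seqLengths", "FeatureTrack", function(x) x@seqlengths)

seqInfoRow <- function(seqs, nm) {
  i <- match(nm, seqs@info$name)
  if (is.na(i)) stop(sprintf("unknown sequence '%s'", nm))
  seqs@info[i, , drop = FALSE]
}

#' Construct a DNATrack
#' @param seqs named character vector of DNA strings (forward orientation).
#' @return a [DNATrack].
#' @export
dnaTrack <- function(seqs) {
  new("DNATrack", seqs = seqs,
      seqlengths = stats::setNames(nchar(seqs), names(seqs)))
}

#' Construct a NumericTrack
#' @param values named list of numeric vectors.
#' @return a [NumericTrack].
#' @export
numericTrack <- function(values) {
  new("NumericTrack", values = values,
      seqlengths = stats::setNames(vapply(values, length, 0L), names(values)))
}

#' Per-sequence numeric vectors of a NumericTrack
#' @param x a NumericTrack.
#' @return named list of numeric vectors.
#' @export
trackValues <- function(x) {
  stopifnot(is(x, "NumericTrack"))
  x@values
}

#' Per-sequence DNA strings of a DNATrack
#' @param x a DNATrack.
#' @return named character vector.
#' @export
dnaStrings <- function(x) {
  stopifnot(is(x, "DNATrack"))
  x@seqs
}

## Canonical empty per-sequence region table.
emptyRegions <- function() {
  data.frame(start = integer(), end = integer(), type = character(),
             score = numeric(), strand = character(), stringsAsFactors = FALSE) |>
    (\(df) { df$properties <- list(); df$children <- list(); df })()
}

regionFrame <- function(start, end, type, score = 0, strand = ".",
                        properties = NULL, children = NULL) {
  n <- length(start)
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   type = rep_len(as.character(type), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  df$properties <- if (is.null(properties)) rep(list(list()), n) else properties
  df$children <- if (is.null(children)) rep(list(NULL), n) else children
  df
}

sortRegions <- function(df) {
  if (nrow(df) < 2L) return(df)
  df[order(df$start, df$end, df$type), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Construct a RegionTrack
#'
#' @param regions named list of per-sequence region data.frames (columns
#'   `start`, `end`, `type`, `score`, `strand`, optionally list-columns
#'   `properties` and `children`); missing sequences get empty tables.
#' @param seqlengths named integer vector of sequence lengths, or a
#'   [SequenceSet] to take them from.
#' @return a [RegionTrack] with per-sequence tables sorted by (start, end, type).
#' @export
regionTrack <- function(regions, seqlengths) {
  if (is(seqlengths, "SequenceSet")) seqlengths <- seqLengths(seqlengths)
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  full <- lapply(names(seqlengths), function(nm) {
    df <- regions[[nm]]
    if (is.null(df) || nrow(df) == 0L) return(emptyRegions())
    if (is.null(df$properties)) df$properties <- rep(list(list()), nrow(df))
    if (is.null(df$children)) df$children <- rep(list(NULL), nrow(df))
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    if (is.null(df$score)) df$score <- 0
    if (is.null(df$strand)) df$strand <- "."
    sortRegions(df[c("start", "end", "type", "score", "strand", "properties", "children")])
  })
  names(full) <- names(seqlengths)
  new("RegionTrack", regions = full, seqlengths = seqlengths)
}

#' Per-sequence region tables of a RegionTrack
#' @param x a RegionTrack.
#' @return named list of data.frames.
#' @export
trackRegions <- function(x) {
  stopifnot(is(x, "RegionTrack"))
  x@regions
}

#' Total number of regions in a RegionTrack
#' @param x a RegionTrack.
#' @return integer count over all sequences.
#' @export
regionCount <- function(x) sum(vapply(trackRegions(x), nrow, 0L))

## ---------------------------------------------------------------------------
## Coordinate conventions
## ---------------------------------------------------------------------------

#' Convert internal 0-based half-open coordinates to GFF 1-based inclusive
#' @param start,end internal coordinates.
#' @return list with `start` and `end` in GFF convention.
#' @export
toGFFCoords <- function(start, end) list(start = start + 1L, end = end)

#' Convert GFF 1-based inclusive coordinates to internal 0-based half-open
#' @param start,end GFF coordinates.
#' @return list with internal `start` and `end`.
#' @export
fromGFFCoords <- function(start, end) list(start = start - 1L, end = end)

#' Genomic position x bp upstream of a sequence's TSS
#'
#' Strand-relative: on a plus-strand sequence upstream means smaller genomic
#' coordinates (`tss - x`); on a minus-strand sequence it means larger ones
#' (`tss + x`).
#'
#' @param seqs a [SequenceSet].
#' @param name sequence name (must have a TSS offset).
#' @param x distance upstream in bp.
#' @return genomic position (numeric).
#' @export
upstreamPosition <- function(seqs, name, x) {
  row <- seqInfoRow(seqs, name)
  if (is.na(row$tss_offset)) stop(sprintf("sequence '%s' has no TSS offset", name))
  tssGenomic <- row$start + row$tss_offset
  if (row$strand == "+") tssGenomic - x else tssGenomic + x
}

## ---------------------------------------------------------------------------
## DNA utilities
## ---------------------------------------------------------------------------

#' Reverse complement of a DNA string
#'
#' Handles the full track alphabet including N, X and lowercase.
#' @param x character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
reverseComplement <- function(x) {
  comp <- chartr("ACGTNXacgtnx", "TGCANXtgcanx", x)
  vapply(comp, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
         "", USE.NAMES = FALSE)
}

## IUPAC degeneracy tables used for consensus derivation and matching.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

iupacForSet <- function(bases) {
  bases <- sort(unique(bases))
  for (sym in names(IUPAC_SETS)) {
    s <- IUPAC_SETS[[sym]]
    if (length(s) == length(bases) && all(s == bases)) return(sym)
  }
  "N"
}

#' Derive the IUPAC consensus of a frequency matrix
#'
#' Per column, the consensus symbol is the IUPAC code covering every base
#' whose frequency is at least 0.25; if no base reaches 0.25, the single most
#' frequent base is used. Ties resolve toward the smaller degeneracy class.
#'
#' @param matrix 4 x w column-stochastic matrix with rows A,C,G,T.
#' @return IUPAC consensus string.
#' @export
consensusFromMatrix <- function(matrix) {
  paste(vapply(seq_len(ncol(matrix)), function(j) {
    col <- matrix[, j]
    bases <- rownames(matrix)[col >= 0.25]
    if (length(bases) == 0L) bases <- rownames(matrix)[which.max(col)]
    iupacForSet(bases)
  }, ""), collapse = "")
}

#' Construct a Motif
#'
#' @param id motif identifier.
#' @param matrix 4 x w column-stochastic matrix (rows A,C,G,T). Rows are
#'   named automatically if unnamed.
#' @param consensus optional IUPAC consensus; derived from the matrix when
#'   omitted.
#' @param tfNames,organisms,tissues,partners,alternatives annotation vectors.
#' @return a [Motif].
#' @export
motif <- function(id, matrix, consensus = NULL, tfNames = character(),
                  organisms = character(), tissues = character(),
                  partners = character(), alternatives = character()) {
  if (is.null(rownames(matrix))) rownames(matrix) <- c("A", "C", "G", "T")
  if (is.null(consensus)) consensus <- consensusFromMatrix(matrix)
  new("Motif", id = id, matrix = matrix, consensus = consensus,
      tfNames = tfNames, organisms = organisms, tissues = tissues,
      partners = partners, alternatives = alternatives)
}

#' Construct a MotifSet
#'
#' The partner relation is symmetrized: if A lists B as partner, B gains A.
#' @param motifs list of [Motif] objects.
#' @return a [MotifSet] keyed by motif id.
#' @export
motifSet <- function(motifs = list()) {
  names(motifs) <- vapply(motifs, function(m) m@id, "")
  ids <- names(motifs)
  for (id in ids) {
    for (p in motifs[[id]]@partners) {
      if (p %in% ids && !(id %in% motifs[[p]]@partners))
        motifs[[p]]@partners <- c(motifs[[p]]@partners, id)
    }
  }
  new("MotifSet", motifs = motifs)
}

#' Retrieve one motif from a MotifSet
#' @param x a MotifSet.
#' @param id motif id.
#' @return the [Motif].
#' @export
getMotif <- function(x, id) {
  m <- x@motifs[[id]]
  if (is.null(m)) stop(sprintf("no motif '%s' in set", id))
  m
}

#' Motif ids of a MotifSet
#' @param x a MotifSet.
#' @return character vector.
#' @export
motifIds <- function(x) names(x@motifs)

## ---------------------------------------------------------------------------
## Collections, maps
## ---------------------------------------------------------------------------

#' Construct a Collection
#' @param memberType "sequence", "motif" or "module".
#' @param members character vector of member names.
#' @return a [Collection].
#' @export
collection <- function(memberType, members = character()) {
  new("Collection", memberType = memberType, members = unique(as.character(members)))
}

#' Members of a Collection
#' @param x a Collection.
#' @return character vector.
#' @export
members <- function(x) x@members

#' Construct a NumericMap
#' @param memberType "sequence", "motif" or "module".
#' @param values named numeric vector.
#' @param default value for members not present in `values`.
#' @return a [NumericMap].
#' @export
numericMap <- function(memberType, values = numeric(), default = 0) {
  new("NumericMap", memberType = memberType, values = values, default = default)
}

#' Look up NumericMap values (default-filled)
#' @param map a NumericMap.
#' @param keys member names.
#' @return numeric vector, `map@default` where absent.
#' @export
mapValues <- function(map, keys) {
  v <- map@values[keys]
  v[is.na(names(v)) | !(keys %in% names(map@values))] <- map@default
  stats::setNames(as.numeric(v), keys)
}

#' Elementwise arithmetic on a NumericMap
#'
#' @param map a [NumericMap].
#' @param op one of `add`, `sub`, `mul`, `div`.
#' @param operand a scalar or a second [NumericMap] (matched by member; the
#'   other map's default fills absences).
#' @return a new [NumericMap] over the same members.
#' @export
mapArithmetic <- function(map, op = c("add", "sub", "mul", "div"), operand) {
  op <- match.arg(op)
  stopifnot(is(map, "NumericMap"))
  b <- if (is(operand, "NumericMap")) unname(mapValues(operand, names(map@values)))
    else rep(operand, length(map@values))
  if (op == "div" && any(b == 0)) stop("division by zero in map arithmetic")
  v <- switch(op, add = map@values + b, sub = map@values - b,
              mul = map@values * b, div = map@values / b)
  numericMap(map@memberType, v, default = map@default)
}

#' Construct a Partition
#' @param memberType "sequence", "motif" or "module".
#' @param clusters named character vector member -> cluster label.
#' @return a [Partition].
#' @export
partition <- function(memberType, clusters = character()) {
  new("Partition", memberType = memberType, clusters = clusters)
}

#' Members of one cluster of a Partition
#' @param x a Partition.
#' @param label cluster label.
#' @return character vector of member names.
#' @export
clusterMembers <- function(x, label) names(x@clusters)[x@clusters == label]

#' Construct a TextVariable
#' @param text character vector.
#' @return a [TextVariable].
#' @export
textVariable <- function(text) new("TextVariable", text = text)

## ---------------------------------------------------------------------------
## Repository
## ---------------------------------------------------------------------------

#' Create an in-memory data repository
#'
#' The repository stores every data object of a session under a unique name.
#' It also carries the operation log and, when recording is active, the
#' protocol statements captured by [performStep()].
#'
#' @return a repository (environment-backed handle).
#' @export
newRepository <- function() {
  env <- new.env(parent = emptyenv())
  env$objects <- new.env(parent = emptyenv())
  env$log <- character()
  env$recording <- FALSE
  env$recorded <- character()
  class(env) <- "Repository"
  env
}

validIdentifier <- function(name) {
  grepl("^[A-Za-z_][A-Za-z0-9_]*$", name)
}

#' Store an object in a repository
#'
#' Re-assignment under an existing name replaces the prior object and is
#' noted in the repository log (a type change is logged explicitly).
#'
#' @param repo a repository from [newRepository()].
#' @param name identifier (letters, digits, underscore; no leading digit).
#' @param obj any data object.
#' @return the stored object, invisibly.
#' @export
repoPut <- function(repo, name, obj) {
  if (!validIdentifier(name))
    stop(sprintf("invalid identifier '%s' (letters, digits, underscore; must not start with a digit)", name))
  if (exists(name, envir = repo$objects, inherits = FALSE)) {
    old <- get(name, envir = repo$objects)
    note <- if (!identical(class(old), class(obj)))
      sprintf("replaced '%s' (%s -> %s)", name, class(old)[1], class(obj)[1])
    else sprintf("replaced '%s'", name)
    repo$log <- c(repo$log, note)
    warning(note, call. = FALSE)
  }
  assign(name, obj, envir = repo$objects)
  invisible(obj)
}

#' Retrieve an object from a repository
#' @param repo a repository.
#' @param name object name.
#' @return the stored object.
#' @export
repoGet <- function(repo, name) {
  if (!exists(name, envir = repo$objects, inherits = FALSE))
    stop(sprintf("no object named '%s' in repository", name))
  get(name, envir = repo$objects)
}

#' Does the repository contain a name?
#' @param repo a repository.
#' @param name object name.
#' @return logical.
#' @export
repoHas <- function(repo, name) exists(name, envir = repo$objects, inherits = FALSE)

#' Names of all objects in a repository
#' @param repo a repository.
#' @return character vector.
#' @export
repoNames <- function(repo) sort(ls(repo$objects))

#' Repository operation log
#' @param repo a repository.
#' @return character vector of log lines.
#' @export
repoLog <- function(repo) repo$log

#' Deep-copy a repository
#' @param repo a repository.
#' @return an independent repository with the same contents.
#' @export
repoClone <- function(repo) {
  out <- newRepository()
  for (nm in ls(repo$objects)) assign(nm, get(nm, envir = repo$objects), envir = out$objects)
  out$log <- repo$log
  out
}

## ---------------------------------------------------------------------------
## Seeded evaluation
## ---------------------------------------------------------------------------

#' Evaluate an expression under a fixed RNG seed, restoring RNG state after
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for stochastic operations")
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
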