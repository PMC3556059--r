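#' @import methods
#' @importFrom stats pbinom fisher.test chisq.test runif rnorm rpois setNames
#' @importFrom utils head tail
NULL

## ---------------------------------------------------------------------------
## Sequence sets and feature tracks
## ---------------------------------------------------------------------------

#' Set of genomic sequence regions under analysis
#'
#' A `SequenceSet` holds the genomic anchoring of every sequence in a study:
#' name, genome build, chromosome, genomic start/end (0-based half-open on the
#' forward strand), strand, and an optional transcription start site offset
#' (`tssOffset`, in bp relative to the sequence start; may lie outside the
#' sequence). Sequence objects are pure references; the actual base letters
#' live in [DNATrack] objects.
#'
#' @slot info data.frame with columns `name`, `build`, `chromosome`, `start`,
#'   `end`, `strand`, `tss_offset`.
#' @export
setClass("SequenceSet", representation(info = "data.frame"))

setValidity("SequenceSet", function(object) {
  df <- object@info
  need <- c("name", "build", "chromosome", "start", "end", "strand", "tss_offset")
  if (!all(need %in% names(df))) return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$name)) return("sequence names must be unique")
  if (any(df$end <= df$start)) return("end must be > start for every sequence")
  if (!all(df$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  TRUE
})

#' Common interface for per-sequence feature data
#'
#' Virtual parent of [DNATrack], [NumericTrack] and [RegionTrack]. Every track
#' knows the lengths of the sequences it annotates and answers [seqLengths()]
#' and [seqNames()] consistently with its owning [SequenceSet].
#'
#' @slot seqlengths named integer vector of sequence lengths (bp).
#' @export
setClass("FeatureTrack", representation("VIRTUAL", seqlengths = "integer"))

#' Per-position DNA letters for a sequence set
#'
#' One string per sequence over the alphabet `A,C,G,T,N,X` (lowercase
#' permitted, typically marking repeat-masked bases). Strings are always
#' stored in genomic forward orientation; minus-strand views are computed on
#' demand with [reverseComplement()].
#'
#' @slot seqs named character vector, one element per sequence.
#' @export
setClass("DNATrack", contains = "FeatureTrack", representation(seqs = "character"))

setValidity("DNATrack", function(object) {
  if (!identical(names(object@seqs), names(object@seqlengths)))
    return("sequence names of data and lengths differ")
  if (any(nchar(object@seqs) != object@seqlengths))
    return("DNA string length must equal sequence length")
  bad <- grepl("[^ACGTNXacgtnx]", object@seqs)
  if (any(bad)) return(paste0("invalid DNA characters in: ", paste(names(object@seqs)[bad], collapse = ",")))
  TRUE
})

#' Per-position numeric signal for a sequence set
#'
#' One finite numeric value per position per sequence: conservation scores,
#' DNase accessibility, positional priors, coverage, and so on.
#'
#' @slot values named list of numeric vectors, one per sequence.
#' @export
setClass("NumericTrack", contains = "FeatureTrack", representation(values = "list"))

setValidity("NumericTrack", function(object) {
  if (!identical(names(object@values), names(object@seqlengths)))
    return("sequence names of data and lengths differ")
  len <- vapply(object@values, length, 0L)
  if (any(len != object@seqlengths)) return("value vector length must equal sequence length")
  if (!all(vapply(object@values, function(v) all(is.finite(v)), TRUE)))
    return("numeric tracks must be finite everywhere (no NA/NaN/Inf)")
  TRUE
})

#' Interval annotations (regions) for a sequence set
#'
#' Each sequence carries a list of regions: subsegments with a type label
#' (for motif/module tracks, a motif or module id), a score, a strand, an
#' open property map, and optionally child regions (module occurrences list
#' their member binding sites as children). Regions may overlap; per-sequence
#' tables are kept sorted by (start, end, type).
#'
#' @slot regions named list of data.frames with columns `start`, `end`
#'   (0-based half-open, relative to sequence start), `type`, `score`,
#'   `strand`, and list-columns `properties` and `children`.
#' @export
setClass("RegionTrack", contains = "FeatureTrack", representation(regions = "list"))

setValidity("RegionTrack", function(object) {
  if (!identical(names(object@regions), names(object@seqlengths)))
    return("sequence names of data and lengths differ")
  for (sq in names(object@regions)) {
    df <- object@regions[[sq]]
    if (nrow(df) == 0L) next
    L <- object@seqlengths[[sq]]
    if (any(df$start < 0L) || any(df$end > L) || any(df$start >= df$end))
      return(sprintf("region out of bounds or empty in sequence '%s'", sq))
    if (!all(df$strand %in% c("+", "-", "."))) return("region strand must be +, - or .")
    for (i in seq_len(nrow(df))) {
      ch <- df$children[[i]]
      if (!is.null(ch) && nrow(ch) > 0L &&
          (any(ch$start < df$start[i]) || any(ch$end > df$end[i])))
        return("child regions must lie within their parent region")
    }
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Motifs and modules
## ---------------------------------------------------------------------------

#' Transcription factor binding motif
#'
#' A position weight matrix (4 x w column-stochastic frequency matrix with
#' rows A,C,G,T), its IUPAC consensus, and annotations: bound transcription
#' factors, organisms, tissues, known interaction partners and alternative
#' motif ids.
#'
#' @slot id unique motif identifier.
#' @slot matrix 4 x w numeric matrix; every column sums to 1.
#' @slot consensus IUPAC consensus string of length w.
#' @slot tfNames,organisms,tissues character vectors of annotations.
#' @slot partners,alternatives character vectors of related motif ids.
#' @export
setClass("Motif", representation(
  id = "character", matrix = "matrix", consensus = "character",
  tfNames = "character", organisms = "character", tissues = "character",
  partners = "character", alternatives = "character"
))

setValidity("Motif", function(object) {
  m <- object@matrix
  if (!identical(rownames(m), c("A", "C", "G", "T"))) return("matrix rows must be A,C,G,T")
  if (ncol(m) < 1L) return("motif width must be >= 1")
  if (any(abs(colSums(m) - 1) > 1e-9)) return("matrix columns must sum to 1")
  if (any(m < 0)) return("matrix entries must be non-negative")
  if (nchar(object@consensus) != ncol(m)) return("consensus length must equal motif width")
  TRUE
})

#' Ordered collection of motifs keyed by id
#'
#' @slot motifs named list of [Motif] objects (names equal motif ids).
#' @export
setClass("MotifSet", representation(motifs = "list"))

setValidity("MotifSet", function(object) {
  ids <- vapply(object@motifs, function(m) m@id, "")
  if (length(ids) && !identical(names(object@motifs), unname(ids)))
    return("list names must equal motif ids")
  if (anyDuplicated(ids)) return("motif ids must be unique")
  TRUE
})

#' Cis-regulatory module model
#'
#' An ordered list of slots, each slot a set of alternative motif ids, with
#' constraints on the whole occurrence span, on slot order along the
#' sequence, on per-slot strand orientation, and on the nearest-edge distance
#' between sites of adjacent slots.
#'
#' @slot id module identifier.
#' @slot slots list of character vectors of motif ids.
#' @slot maxSpan maximum whole-occurrence length (bp).
#' @slot ordered logical; must sites appear in slot order along the sequence.
#' @slot orientation character per slot: "+", "-" or "any".
#' @slot gaps data.frame with columns `min`, `max`: nearest-edge gap bounds
#'   between adjacent slots (row i constrains slots i and i+1; overlap = 0).
#' @export
setClass("ModuleModel", representation(
  id = "character", slots = "list", maxSpan = "numeric", ordered = "logical",
  orientation = "character", gaps = "data.frame"
))

setValidity("ModuleModel", function(object) {
  if (length(object@slots) < 2L) return("a module needs at least 2 slots")
  if (length(object@orientation) != length(object@slots))
    return("one orientation constraint per slot required")
  if (!all(object@orientation %in% c("+", "-", "any"))) return("orientation must be +, - or any")
  if (nrow(object@gaps) != length(object@slots) - 1L)
    return("need one gap constraint row per adjacent slot pair")
  if (any(object@gaps$min < 0) || any(object@gaps$max < object@gaps$min))
    return("gap bounds must satisfy 0 <= min <= max")
  TRUE
})

## ---------------------------------------------------------------------------
## Collections, partitions, maps, text
## ---------------------------------------------------------------------------

#' Named subset of sequences, motifs or modules
#' @slot memberType one of "sequence", "motif", "module".
#' @slot members character vector of member names (no duplicates).
#' @export
setClass("Collection", representation(memberType = "character", members = "character"))

setValidity("Collection", function(object) {
  if (!object@memberType %in% c("sequence", "motif", "module")) return("invalid member type")
  if (anyDuplicated(object@members)) return("collection members must be unique")
  TRUE
})

#' Division of data objects into non-overlapping clusters
#'
#' Each member belongs to at most one cluster; unassigned members are
#' permitted.
#' @slot memberType one of "sequence", "motif", "module".
#' @slot clusters named character vector mapping member name to cluster label.
#' @export
setClass("Partition", representation(memberType = "character", clusters = "character"))

setValidity("Partition", function(object) {
  if (anyDuplicated(names(object@clusters))) return("a member may be assigned to only one cluster")
  TRUE
})

#' Per-member numeric annotation (e.g. expression value, expected frequency)
#' @slot memberType one of "sequence", "motif", "module".
#' @slot values named numeric vector.
#' @slot default value returned for members absent from `values`.
#' @export
setClass("NumericMap", representation(memberType = "character", values = "numeric", default = "numeric"))

setValidity("NumericMap", function(object) {
  if (any(!is.finite(object@values))) return("map values must be finite")
  if (length(object@default) != 1L) return("default must be a single value")
  TRUE
})

#' Free-form text payload
#' @slot text character vector of lines (or a single string).
#' @export
setClass("TextVariable", representation(text = "character"))

## ---------------------------------------------------------------------------
## Background models, priors generators, analyses
## ---------------------------------------------------------------------------

#' Order-k Markov background model over DNA
#'
#' Conditional distributions P(base | previous j bases) for every order
#' j = 0..k, pseudocount-smoothed so all probabilities are positive. The
#' lower-order tables serve as fallback for sequence starts and for contexts
#' interrupted by non-ACGT letters.
#'
#' @slot order the model order k (>= 0).
#' @slot tables list of length k+1; element j+1 is a (4^j x 4) matrix of
#'   conditionals, rows named by context string ("" for order 0), columns
#'   A,C,G,T, each row summing to 1.
#' @slot trainedOn free-text provenance note.
#' @export
setClass("BackgroundModel", representation(order = "integer", tables = "list", trainedOn = "character"))

setValidity("BackgroundModel", function(object) {
  if (length(object@tables) != object@order + 1L) return("need one table per order 0..k")
  for (tab in object@tables) {
    if (!identical(colnames(tab), c("A", "C", "G", "T"))) return("table columns must be A,C,G,T")
    if (any(tab <= 0)) return("all conditional probabilities must be > 0")
    if (any(abs(rowSums(tab) - 1) > 1e-9)) return("each conditional distribution must sum to 1")
  }
  TRUE
})

#' Trained per-position classifier producing positional priors
#'
#' Maps windowed feature-track values at a position to the probability that
#' the position lies within a transcription factor binding site. The default
#' classifier is a single-hidden-layer feed-forward network with logistic
#' output; the stored weights are applied with the package's own forward
#' pass, so a generator serialized with [savePriorsGenerator()] and reloaded
#' reproduces its outputs bit-identically.
#'
#' @slot features character vector of input feature track names.
#' @slot windows integer vector of centered window sizes (bp) applied to each
#'   feature.
#' @slot norm data.frame with per-input-column `min` and `max` from training.
#' @slot net list with elements `size` (hidden units) and `wts` (nnet-ordered
#'   weight vector).
#' @slot meta list: seed, sample counts, positive fraction.
#' @export
setClass("PriorsGenerator", representation(
  features = "character", windows = "integer", norm = "data.frame",
  net = "list", meta = "list"
))

#' Typed result table of a statistical analysis
#'
#' Rectangular table keyed by member (motif, sequence or module) with a typed
#' column schema (`number`, `text`, `histogram`, `class`). Numeric columns
#' can be extracted as [NumericMap]s, boolean predicates on them as
#' [Collection]s, and the whole table rendered to HTML or raw text.
#'
#' @slot name analysis name.
#' @slot schema data.frame with columns `label`, `type`.
#' @slot rows data.frame; first column `id` (member key), remaining columns
#'   as in `schema` (histogram columns are list-columns).
#' @slot provenance list recording the producing operation and parameters.
#' @export
setClass("AnalysisResult", representation(
  name = "character", schema = "data.frame", rows = "data.frame", provenance = "list"
))

setValidity("AnalysisResult", function(object) {
  if (names(object@rows)[1] != "id") return("first rows column must be 'id'")
  if (anyDuplicated(object@rows$id)) return("row keys must be unique")
  if (!identical(object@schema$label, names(object@rows)[-1]))
    return("schema labels must match row columns")
  if (!all(object@schema$type %in% c("number", "text", "histogram", "class")))
    return("invalid column type")
  TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SequenceSet", function(object) {
  cat(sprintf("SequenceSet with %d sequences\n", nrow(object@info)))
  print(head(object@info, 5))
  if (nrow(object@info) > 5) cat("  ...\n")
})

setMethod("show", "DNATrack", function(object) {
  cat(sprintf("DNATrack over %d sequences (total %d bp)\n",
              length(object@seqs), sum(object@seqlengths)))
})

setMethod("show", "NumericTrack", function(object) {
  cat(sprintf("NumericTrack over %d sequences (total %d bp)\n",
              length(object@values), sum(object@seqlengths)))
})

setMethod("show", "RegionTrack", function(object) {
  n <- sum(vapply(object@regions, nrow, 0L))
  cat(sprintf("RegionTrack over %d sequences (%d regions)\n", length(object@regions), n))
})

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif %s: width %d, consensus %s\n", object@id, ncol(object@matrix), object@consensus))
})

setMethod("show", "MotifSet", function(object) {
  cat(sprintf("MotifSet with %d motifs: %s\n", length(object@motifs),
              paste(head(names(object@motifs), 8), collapse = ", ")))
})

setMethod("show", "ModuleModel", function(object) {
  cat(sprintf("ModuleModel %s: %d slots, span<=%g, %s\n", object@id, length(object@slots),
              object@maxSpan, if (object@ordered) "ordered" else "unordered"))
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel of order %d (%s)\n", object@order, object@trainedOn))
})

setMethod("show", "Collection", function(object) {
  cat(sprintf("Collection of %d %ss\n", length(object@members), object@memberType))
})

setMethod("show", "NumericMap", function(object) {
  cat(sprintf("NumericMap over %d %ss (default %g)\n",
              length(object@values), object@memberType, object@default))
})

setMethod("show", "PriorsGenerator", function(object) {
  cat(sprintf("PriorsGenerator on features {%s}, windows {%s}, %d hidden units\n",
              paste(object@features, collapse = ","), paste(object@windows, collapse = ","),
              object@net$size))
})

setMethod("show", "AnalysisResult", function(object) {
  cat(sprintf("AnalysisResult '%s': %d rows x %d columns\n",
              object@name, nrow(object@rows), nrow(object@schema)))
})
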