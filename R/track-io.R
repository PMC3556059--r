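## Reading and writing the standard text formats the workbench touches:
## FASTA, GFF3, BED(6), WIG/bedGraph, JASPAR/TRANSFAC/MEME motif files and
## MEME-style PSP priors. Genomic records (GFF/BED/WIG) are mapped onto the
## sequence set by exact chromosome label match plus coordinate overlap;
## internal coordinates are 0-based half-open relative to sequence start.

fmtNum <- function(x, digits = 17) {
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) sprintf("%d", as.integer(v))
    else sprintf(paste0("%.", digits, "g"), v)
  }, "")
}

gffEscape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

gffUnescape <- function(x) {
  x <- gsub("%3B", ";", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

propToText <- function(v) {
  if (is.numeric(v)) fmtNum(v) else as.character(v)
}

propFromText <- function(s) {
  if (grepl("^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$", s)) as.numeric(s) else s
}

## ---------------------------------------------------------------------------
## Reading feature tracks
## ---------------------------------------------------------------------------

#' Read a feature track from a standard text format
#'
#' `fasta` yields a [DNATrack] (headers matched to sequence names), `gff`
#' and `bed` a [RegionTrack], `wig` (fixed step) and `bedgraph` a
#' [NumericTrack]. GFF coordinates are 1-based inclusive, BED and bedGraph
#' 0-based half-open; all are genomic and mapped onto `sequences` by exact
#' chromosome label and coordinate overlap. Records overlapping no sequence
#' are dropped (count reported via `message()`); partially overlapping
#' regions are clipped.
#'
#' @param path input file.
#' @param format one of `"fasta"`, `"gff"`, `"bed"`, `"wig"`, `"bedgraph"`.
#' @param sequences the [SequenceSet] the track annotates.
#' @return a [FeatureTrack].
#' @export
readTrack <- function(path, format = c("fasta", "gff", "bed", "wig", "bedgraph"), sequences) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
    fasta = readFastaTrack(path, sequences),
    gff = readGffTrack(path, sequences),
    bed = readBedTrack(path, sequences),
    wig = readWigTrack(path, sequences),
    bedgraph = readBedGraphTrack(path, sequences))
}

readFastaTrack <- function(path, sequences) {
  ss <- Biostrings::readBStringSet(path)
  nms <- sub("\\s.*$", "", names(ss))
  want <- seqNames(sequences)
  lens <- seqLengths(sequences)
  out <- character(0)
  for (nm in want) {
    i <- match(nm, nms)
    if (is.na(i)) stop(sprintf("FASTA is missing sequence '%s'", nm))
    s <- as.character(ss[[i]])
    if (nchar(s) != lens[[nm]])
      stop(sprintf("FASTA length mismatch for '%s': %d vs expected %d", nm, nchar(s), lens[[nm]]))
    out[[nm]] <- s
  }
  dnaTrack(out)
}

## Map one genomic interval (0-based half-open) onto the sequence set; returns
## data.frame(seq, relStart, relEnd) of clipped per-sequence projections.
mapInterval <- function(chrom, gstart, gend, sequences) {
  info <- sequences@info
  hit <- info$chromosome == chrom & info$start < gend & info$end > gstart
  if (!any(hit)) return(NULL)
  sub <- info[hit, , drop = FALSE]
  data.frame(seq = sub$name,
             relStart = pmax(gstart, sub$start) - sub$start,
             relEnd = pmin(gend, sub$end) - sub$start,
             stringsAsFactors = FALSE)
}

parseGffAttributes <- function(text) {
  out <- list()
  if (is.na(text) || text == "." || text == "") return(out)
  for (kv in strsplit(text, ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq == -1L) next
    out[[gffUnescape(substring(kv, 1, eq - 1))]] <- gffUnescape(substring(kv, eq + 1))
  }
  out
}

readGffTrack <- function(path, sequences) {
  lines <- readLines(path)
  recs <- list()
  dropped <- 0L
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop(sprintf("malformed GFF record at line %d", li))
    g1 <- suppressWarnings(as.integer(f[4])); g2 <- suppressWarnings(as.integer(f[5]))
    if (is.na(g1) || is.na(g2)) stop(sprintf("malformed GFF coordinates at line %d", li))
    ic <- fromGFFCoords(g1, g2)
    attrs <- parseGffAttributes(f[9])
    m <- mapInterval(f[1], ic$start, ic$end, sequences)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    score <- if (f[6] == ".") 0 else as.numeric(f[6])
    strand <- if (f[7] %in% c("+", "-")) f[7] else "."
    type <- if (!is.null(attrs$Name)) attrs$Name else f[3]
    props <- attrs[setdiff(names(attrs), c("ID", "Name", "Parent"))]
    props <- if (length(props) == 0L) list() else lapply(props, propFromText)
    for (k in seq_len(nrow(m))) {
      recs[[length(recs) + 1L]] <- list(seq = m$seq[k], start = m$relStart[k], end = m$relEnd[k],
                                        type = type, score = score, strand = strand,
                                        props = props, id = attrs$ID, parent = attrs$Parent)
    }
  }
  if (dropped > 0L) message(sprintf("%d GFF record(s) overlapped no sequence and were dropped", dropped))
  assembleRegionTrack(recs, sequences)
}

## Builds the RegionTrack, attaching Parent-linked records as children.
assembleRegionTrack <- function(recs, sequences) {
  lens <- seqLengths(sequences)
  perSeq <- lapply(seqNames(sequences), function(nm) {
    mine <- Filter(function(r) r$seq == nm, recs)
    tops <- Filter(function(r) is.null(r$parent), mine)
    kids <- Filter(function(r) !is.null(r$parent), mine)
    if (length(tops) == 0L) return(emptyRegions())
    df <- regionFrame(
      vapply(tops, `[[`, 0, "start"), vapply(tops, `[[`, 0, "end"),
      vapply(tops, `[[`, "", "type"), vapply(tops, `[[`, 0, "score"),
      vapply(tops, `[[`, "", "strand"),
      properties = lapply(tops, `[[`, "props"))
    ids <- lapply(tops, `[[`, "id")
    if (length(kids)) {
      for (i in seq_along(tops)) {
        if (is.null(ids[[i]])) next
        ch <- Filter(function(r) r$parent == ids[[i]], kids)
        if (length(ch))
          df$children[[i]] <- regionFrame(
            vapply(ch, `[[`, 0, "start"), vapply(ch, `[[`, 0, "end"),
            vapply(ch, `[[`, "", "type"), vapply(ch, `[[`, 0, "score"),
            vapply(ch, `[[`, "", "strand"),
            properties = lapply(ch, `[[`, "props"))
      }
    }
    df
  })
  names(perSeq) <- seqNames(sequences)
  regionTrack(perSeq, lens)
}

readBedTrack <- function(path, sequences) {
  lines <- readLines(path)
  recs <- list()
  dropped <- 0L
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop(sprintf("malformed BED record at line %d", li))
    g1 <- suppressWarnings(as.integer(f[2])); g2 <- suppressWarnings(as.integer(f[3]))
    if (is.na(g1) || is.na(g2)) stop(sprintf("malformed BED coordinates at line %d", li))
    m <- mapInterval(f[1], g1, g2, sequences)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    type <- if (length(f) >= 4L) f[4] else "region"
    score <- if (length(f) >= 5L && f[5] != ".") as.numeric(f[5]) else 0
    strand <- if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else "."
    for (k in seq_len(nrow(m)))
      recs[[length(recs) + 1L]] <- list(seq = m$seq[k], start = m$relStart[k], end = m$relEnd[k],
                                        type = type, score = score, strand = strand,
                                        props = list(), id = NULL, parent = NULL)
  }
  if (dropped > 0L) message(sprintf("%d BED record(s) overlapped no sequence and were dropped", dropped))
  assembleRegionTrack(recs, sequences)
}

fillNumeric <- function(sequences) {
  lens <- seqLengths(sequences)
  vals <- lapply(lens, numeric)
  names(vals) <- names(lens)
  vals
}

readWigTrack <- function(path, sequences) {
  lines <- readLines(path)
  vals <- fillNumeric(sequences)
  chrom <- NULL; gpos <- NA_integer_; step <- 1L
  dropped <- 0L
  for (li in seq_along(lines)) {
    line <- trimws(lines[[li]])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    if (startsWith(line, "fixedStep")) {
      kv <- parseKeyVals(line)
      chrom <- kv[["chrom"]]
      gpos <- as.integer(kv[["start"]]) - 1L   # WIG fixedStep is 1-based
      step <- if (!is.null(kv[["step"]])) as.integer(kv[["step"]]) else 1L
      next
    }
    if (startsWith(line, "variableStep")) stop(sprintf("variableStep WIG not supported (line %d)", li))
    if (is.null(chrom)) stop(sprintf("WIG data before any fixedStep header at line %d", li))
    v <- suppressWarnings(as.numeric(line))
    if (is.na(v)) stop(sprintf("malformed WIG value at line %d", li))
    m <- mapInterval(chrom, gpos, gpos + 1L, sequences)
    if (is.null(m)) dropped <- dropped + 1L
    else for (k in seq_len(nrow(m))) vals[[m$seq[k]]][m$relStart[k] + 1L] <- v
    gpos <- gpos + step
  }
  if (dropped > 0L) message(sprintf("%d WIG value(s) fell outside all sequences and were dropped", dropped))
  numericTrack(vals)
}

readBedGraphTrack <- function(path, sequences) {
  lines <- readLines(path)
  vals <- fillNumeric(sequences)
  dropped <- 0L
  for (li in seq_along(lines)) {
    line <- trimws(lines[[li]])
    if (line == "" || startsWith(line, "#") || startsWith(line, "track")) next
    f <- strsplit(line, "[ \t]+")[[1]]
    if (length(f) < 4L) stop(sprintf("malformed bedGraph record at line %d", li))
    g1 <- suppressWarnings(as.integer(f[2])); g2 <- suppressWarnings(as.integer(f[3]))
    v <- suppressWarnings(as.numeric(f[4]))
    if (is.na(g1) || is.na(g2) || is.na(v)) stop(sprintf("malformed bedGraph record at line %d", li))
    m <- mapInterval(f[1], g1, g2, sequences)
    if (is.null(m)) { dropped <- dropped + 1L; next }
    for (k in seq_len(nrow(m)))
      vals[[m$seq[k]]][(m$relStart[k] + 1L):m$relEnd[k]] <- v
  }
  if (dropped > 0L) message(sprintf("%d bedGraph record(s) overlapped no sequence and were dropped", dropped))
  numericTrack(vals)
}

parseKeyVals <- function(line) {
  parts <- strsplit(line, "[ \t]+")[[1]][-1]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) out[[kv[1]]] <- kv[2]
  }
  out
}

## ---------------------------------------------------------------------------
## Writing feature tracks
## ---------------------------------------------------------------------------

#' Write a feature track to a standard text format
#'
#' Writers are deterministic (identical input gives byte-identical output)
#' and compose with [readTrack()] to reproduce the track exactly: GFF region
#' property maps are serialized as attributes (dialect: `ID`, `Name` = region
#' type, `Parent` for children, one attribute per property), and numeric
#' values are written with enough digits to round-trip.
#'
#' @param track a [FeatureTrack].
#' @param path output file.
#' @param format `"fasta"` (DNA), `"gff"`/`"bed"` (region), `"wig"`
#'   (numeric, fixed step 1).
#' @param sequences the owning [SequenceSet] (provides chromosome and genomic
#'   offset for genomic formats).
#' @return the path, invisibly.
#' @export
writeTrack <- function(track, path, format = c("fasta", "gff", "bed", "wig"), sequences) {
  format <- match.arg(format)
  ok <- switch(format,
    fasta = is(track, "DNATrack"),
    gff = , bed = is(track, "RegionTrack"),
    wig = is(track, "NumericTrack"))
  if (!ok) stop(sprintf("format '%s' is incompatible with a %s", format, class(track)[1]))
  lines <- switch(format,
    fasta = unlist(lapply(names(track@seqs), function(nm)
      c(paste0(">", nm), gsub("(.{60})", "\\1\n", track@seqs[[nm]]) |>
          strsplit("\n") |> unlist()))),
    gff = writeGffLines(track, sequences),
    bed = writeBedLines(track, sequences),
    wig = writeWigLines(track, sequences))
  writeLines(lines, path)
  invisible(path)
}

regionAttrText <- function(id, type, props, parent = NULL) {
  parts <- c(paste0("ID=", gffEscape(id)),
             if (!is.null(parent)) paste0("Parent=", gffEscape(parent)),
             paste0("Name=", gffEscape(type)))
  if (length(props)) {
    for (k in sort(names(props)))
      parts <- c(parts, paste0(gffEscape(k), "=", gffEscape(propToText(props[[k]]))))
  }
  paste(parts, collapse = ";")
}

writeGffLines <- function(track, sequences) {
  info <- sequences@info
  out <- "##gff-version 3"
  for (nm in names(track@regions)) {
    df <- track@regions[[nm]]
    if (nrow(df) == 0L) next
    row <- seqInfoRow(sequences, nm)
    for (i in seq_len(nrow(df))) {
      id <- sprintf("%s_r%d", nm, i)
      g <- toGFFCoords(row$start + df$start[i], row$start + df$end[i])
      out <- c(out, paste(row$chromosome, "regulab", "region", g$start, g$end,
                          fmtNum(df$score[i]), df$strand[i], ".",
                          regionAttrText(id, df$type[i], df$properties[[i]]), sep = "\t"))
      ch <- df$children[[i]]
      if (!is.null(ch) && nrow(ch)) for (j in seq_len(nrow(ch))) {
        gj <- toGFFCoords(row$start + ch$start[j], row$start + ch$end[j])
        out <- c(out, paste(row$chromosome, "regulab", "region", gj$start, gj$end,
                            fmtNum(ch$score[j]), ch$strand[j], ".",
                            regionAttrText(sprintf("%s_c%d", id, j), ch$type[j],
                                           ch$properties[[j]], parent = id), sep = "\t"))
      }
    }
  }
  out
}

writeBedLines <- function(track, sequences) {
  out <- character()
  for (nm in names(track@regions)) {
    df <- track@regions[[nm]]
    if (nrow(df) == 0L) next
    row <- seqInfoRow(sequences, nm)
    for (i in seq_len(nrow(df))) {
      out <- c(out, paste(row$chromosome, row$start + df$start[i], row$start + df$end[i],
                          df$type[i], fmtNum(df$score[i]),
                          if (df$strand[i] == ".") "." else df$strand[i], sep = "\t"))
    }
  }
  out
}

writeWigLines <- function(track, sequences) {
  out <- character()
  for (nm in names(track@values)) {
    row <- seqInfoRow(sequences, nm)
    out <- c(out,
             sprintf("fixedStep chrom=%s start=%d step=1", row$chromosome, row$start + 1L),
             fmtNum(track@values[[nm]], digits = 9))
  }
  out
}

## ---------------------------------------------------------------------------
## Motif libraries
## ---------------------------------------------------------------------------

normalizeCountMatrix <- function(counts, pseudo) {
  if (any(colSums(counts) == 0)) stop("motif matrix has a column summing to 0")
  counts <- counts + pseudo
  sweep(counts, 2, colSums(counts), "/")
}

#' Read a motif library
#'
#' Supports JASPAR PFM, TRANSFAC matrix blocks and the MEME minimal motif
#' format. Count matrices (JASPAR, TRANSFAC) get a 0.25 pseudocount per cell
#' before column normalization; probability matrices (MEME) get 0.01 per
#' cell and are renormalized.
#'
#' @param path input file.
#' @param format one of `"jaspar"`, `"transfac"`, `"meme"`.
#' @return a [MotifSet].
#' @export
readMotifs <- function(path, format = c("jaspar", "transfac", "meme")) {
  format <- match.arg(format)
  lines <- readLines(path)
  switch(format,
    jaspar = readJaspar(lines),
    transfac = readTransfac(lines),
    meme = readMeme(lines))
}

readJaspar <- function(lines) {
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (!startsWith(line, ">")) { i <- i + 1L; next }
    id <- strsplit(sub("^>", "", line), "[ \t]+")[[1]][1]
    rows <- list()
    i <- i + 1L
    while (i <= length(lines) && length(rows) < 4L) {
      rl <- trimws(lines[[i]])
      if (rl == "") { i <- i + 1L; next }
      base <- sub("^([ACGTacgt]).*$", "\\1", rl)
      nums <- regmatches(rl, gregexpr("-?[0-9]+(\\.[0-9]+)?", rl))[[1]]
      if (grepl("^[ACGT]", toupper(rl))) rows[[toupper(base)]] <- as.numeric(nums)
      else rows[[length(rows) + 1L]] <- as.numeric(nums)
      i <- i + 1L
    }
    if (length(rows) != 4L) stop(sprintf("JASPAR motif '%s' does not have 4 matrix rows", id))
    if (is.null(names(rows)) || !all(c("A", "C", "G", "T") %in% names(rows)))
      names(rows) <- BASES
    counts <- rbind(A = rows[["A"]], C = rows[["C"]], G = rows[["G"]], T = rows[["T"]])
    motifs[[length(motifs) + 1L]] <- motif(id, normalizeCountMatrix(counts, 0.25))
  }
  if (length(motifs) == 0L) stop("no JASPAR motifs found (unknown format marker?)")
  motifSet(motifs)
}

readTransfac <- function(lines) {
  motifs <- list()
  id <- NULL; rows <- list()
  flush <- function() {
    if (is.null(id)) return()
    if (length(rows) == 0L) stop(sprintf("TRANSFAC motif '%s' has no matrix rows", id))
    counts <- t(do.call(rbind, rows))
    rownames(counts) <- BASES
    motifs[[length(motifs) + 1L]] <<- motif(id, normalizeCountMatrix(counts, 0.25))
    id <<- NULL; rows <<- list()
  }
  for (line in lines) {
    line <- trimws(line)
    if (startsWith(line, "ID") || startsWith(line, "AC")) {
      if (is.null(id)) id <- strsplit(line, "[ \t]+")[[1]][2]
    } else if (grepl("^[0-9]+[ \t]", line)) {
      nums <- strsplit(line, "[ \t]+")[[1]]
      rows[[length(rows) + 1L]] <- as.numeric(nums[2:5])
    } else if (line == "//") {
      flush()
    }
  }
  flush()
  if (length(motifs) == 0L) stop("no TRANSFAC motifs found (unknown format marker?)")
  motifSet(motifs)
}

readMeme <- function(lines) {
  if (!any(grepl("^MEME version", lines))) stop("not a MEME minimal format file (missing version line)")
  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[[i]])
    if (startsWith(line, "MOTIF")) {
      id <- strsplit(line, "[ \t]+")[[1]][2]
      ## find the letter-probability header
      j <- i + 1L
      while (j <= length(lines) && !grepl("^letter-probability matrix", trimws(lines[[j]]))) j <- j + 1L
      if (j > length(lines)) stop(sprintf("MEME motif '%s' has no probability matrix", id))
      kv <- regmatches(lines[[j]], gregexpr("w= *[0-9]+", lines[[j]]))[[1]]
      w <- as.integer(sub("w= *", "", kv[1]))
      rows <- matrix(0, nrow = w, ncol = 4)
      for (r in seq_len(w)) {
        nums <- as.numeric(strsplit(trimws(lines[[j + r]]), "[ \t]+")[[1]])
        if (length(nums) != 4L) stop(sprintf("malformed MEME matrix row %d for motif '%s'", r, id))
        rows[r, ] <- nums
      }
      probs <- t(rows)
      rownames(probs) <- BASES
      motifs[[length(motifs) + 1L]] <- motif(id, normalizeCountMatrix(probs, 0.01))
      i <- j + w + 1L
    } else i <- i + 1L
  }
  if (length(motifs) == 0L) stop("no MEME motifs found")
  motifSet(motifs)
}

## ---------------------------------------------------------------------------
## Sequence set construction
## ---------------------------------------------------------------------------

#' Create a sequence set from chromosomal coordinates
#'
#' @param specs data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`, `build` (0-based half-open genomic coordinates).
#' @return a [SequenceSet].
#' @export
sequencesFromCoordinates <- function(specs) {
  if (anyDuplicated(specs$name)) stop("duplicate sequence names")
  if (any(specs$end <= specs$start)) stop("end must be > start for every sequence")
  sequenceSet(specs$name, specs$chrom, specs$start, specs$end,
              strand = specs$strand, build = specs$build)
}

#' Read a gene annotation table
#'
#' Tab-separated with header: columns `gene`, `chrom`, `strand`, `tss`,
#' `tes` (genomic positions).
#'
#' @param path input file.
#' @return a data.frame.
#' @export
readGeneAnnotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df))) stop("annotation needs columns gene, chrom, strand, tss, tes")
  if (anyDuplicated(df$gene)) stop("gene ids must be unique")
  if (any(df$tss < 0 | df$tes < 0)) stop("positions must be non-negative")
  df
}

#' Create a sequence set around gene anchors
#'
#' For a plus-strand gene the window is `[anchor - upstream, anchor +
#' downstream)`; mirrored for minus-strand genes. `tss_offset` is set so
#' that strand-aware positional analyses can anchor at the TSS. Windows
#' extending below position 0 are clipped with a warning; gene ids missing
#' from the annotation are reported but not fatal.
#'
#' @param genes character vector of gene ids.
#' @param annotation a gene annotation data.frame ([readGeneAnnotation()]).
#' @param anchor `"TSS"` or `"TES"`.
#' @param upstream,downstream extents in bp (their sum must be positive).
#' @param build genome build label.
#' @return a [SequenceSet] (one sequence per found gene, named by gene id).
#' @export
sequencesFromGenes <- function(genes, annotation, anchor = c("TSS", "TES"),
                               upstream, downstream, build = "custom") {
  anchor <- match.arg(anchor)
  if (upstream + downstream <= 0) stop("empty window: upstream + downstream must be positive")
  found <- genes %in% annotation$gene
  if (any(!found))
    message(sprintf("%d gene id(s) not in annotation: %s", sum(!found),
                    paste(utils::head(genes[!found], 5), collapse = ", ")))
  genes <- genes[found]
  if (length(genes) == 0L) stop("none of the requested genes are in the annotation")
  rows <- annotation[match(genes, annotation$gene), ]
  a <- if (anchor == "TSS") rows$tss else rows$tes
  plus <- rows$strand == "+"
  start <- ifelse(plus, a - upstream, a - downstream)
  end <- ifelse(plus, a + downstream, a + upstream)
  if (any(start < 0)) {
    warning(sprintf("%d window(s) clipped at position 0", sum(start < 0)))
    start <- pmax(start, 0)
  }
  tssOff <- rows$tss - start
  sequenceSet(rows$gene, rows$chrom, start, end, strand = rows$strand,
              build = build, tss_offset = tssOff)
}

## ---------------------------------------------------------------------------
## Positional priors export (MEME PSP dialect)
## ---------------------------------------------------------------------------

#' Export a priors track in MEME PSP format
#'
#' FASTA-like records, one line of space-separated per-position values per
#' sequence, written with 6 significant digits. All values must be >= 0.
#'
#' @param priors a [NumericTrack] of non-negative values.
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportPriors <- function(priors, path) {
  stopifnot(is(priors, "NumericTrack"))
  if (any(vapply(priors@values, function(v) any(v < 0), TRUE)))
    stop("priors must be non-negative for PSP export")
  lines <- unlist(lapply(names(priors@values), function(nm)
    c(paste0(">", nm), paste(sprintf("%.6g", priors@values[[nm]]), collapse = " "))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PSP priors file written by [exportPriors()]
#' @param path input file.
#' @return a [NumericTrack].
#' @export
readPriors <- function(path) {
  lines <- readLines(path)
  vals <- list()
  nm <- NULL
  for (line in lines) {
    if (startsWith(line, ">")) {
      nm <- sub("\\s.*$", "", sub("^>", "", line))
      vals[[nm]] <- numeric(0)
    } else if (!is.null(nm) && trimws(line) != "") {
      vals[[nm]] <- c(vals[[nm]], as.numeric(strsplit(trimws(line), "[ \t]+")[[1]]))
    }
  }
  numericTrack(vals)
}
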