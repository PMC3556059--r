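## Statistical analyses over motif tracks: occurrence counting, binomial
## overrepresentation with Bonferroni correction, group comparison,
## positional distributions with kurtosis, site-feature averages, rank-sum
## combination, nucleotide/site-level benchmark metrics, meta-analysis
## collation and HTML/raw-text rendering.

analysisResult <- function(name, rows, types, provenance = list()) {
  schema <- data.frame(label = names(rows)[-1], type = types, stringsAsFactors = FALSE)
  new("AnalysisResult", name = name, schema = schema, rows = rows, provenance = provenance)
}

#' Extract a numeric column of an analysis as a NumericMap
#' @param result an [AnalysisResult].
#' @param label column label (must be of type "number").
#' @param memberType member type of the resulting map.
#' @param default default for absent members.
#' @return a [NumericMap] (rows with blank values are omitted).
#' @export
resultColumnAsMap <- function(result, label, memberType = "motif", default = 0) {
  ix <- match(label, result@schema$label)
  if (is.na(ix)) stop(sprintf("no column '%s'", label))
  if (result@schema$type[ix] != "number") stop(sprintf("column '%s' is not numeric", label))
  v <- result@rows[[label]]
  keep <- !is.na(v)
  numericMap(memberType, stats::setNames(v[keep], result@rows$id[keep]), default = default)
}

#' Extract members satisfying a predicate on an analysis column
#' @param result an [AnalysisResult].
#' @param label numeric column label.
#' @param op comparison operator.
#' @param value constant.
#' @param memberType member type of the collection.
#' @return a [Collection].
#' @export
resultToCollection <- function(result, label, op, value, memberType = "motif") {
  v <- result@rows[[label]]
  if (is.null(v)) stop(sprintf("no column '%s'", label))
  keep <- !is.na(v) & applyCmp(v, op, value)
  collection(memberType, result@rows$id[keep])
}

#' Count motif occurrences in a sequence set
#'
#' Per motif: `total` (number of sites) and `support` (number of sequences
#' with at least one site).
#'
#' @param motif_track a motif [RegionTrack].
#' @param sequences optional sequence [Collection] (default: all sequences
#'   of the track).
#' @return an [AnalysisResult] keyed by motif id.
#' @export
countMotifOccurrences <- function(motif_track, sequences = NULL) {
  stopifnot(is(motif_track, "RegionTrack"))
  seqnames <- if (is.null(sequences)) names(motif_track@regions)
    else if (is(sequences, "Collection")) members(sequences) else as.character(sequences)
  tabs <- motif_track@regions[seqnames]
  ids <- sort(unique(unlist(lapply(tabs, function(df) df$type))))
  total <- integer(length(ids)); support <- integer(length(ids))
  names(total) <- names(support) <- ids
  for (df in tabs) {
    if (nrow(df) == 0L) next
    tt <- table(df$type)
    total[names(tt)] <- total[names(tt)] + as.integer(tt)
    support[names(tt)] <- support[names(tt)] + 1L
  }
  rows <- data.frame(id = ids, total = as.integer(total), support = as.integer(support),
                     stringsAsFactors = FALSE)
  analysisResult("count motif occurrences", rows, c("number", "number"),
                 list(operation = "countMotifOccurrences", sequences = seqnames))
}

#' Binomial overrepresentation of motif counts
#'
#' For each motif with observed count k, the p-value is the exact binomial
#' upper tail P(X >= k) with X ~ Binomial(n = total_bp, p = expected
#' per-bp frequency). Expected frequencies are typically derived by counting
#' occurrences in background-sampled control sequences and dividing by the
#' control length. Significance is flagged at `alpha / m` under Bonferroni
#' correction (m = number of motifs tested).
#'
#' @param counts an [AnalysisResult] from [countMotifOccurrences()].
#' @param expected_freq a motif [NumericMap] of expected sites per bp.
#' @param total_bp total scanned length in bp (the binomial n).
#' @param alpha nominal significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return an [AnalysisResult] with columns total, expected, p_value,
#'   significant; the corrected threshold is in `provenance$threshold`.
#' @export
overrepresentation <- function(counts, expected_freq, total_bp, alpha = 0.05,
                               correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is(counts, "AnalysisResult"), total_bp > 0)
  ids <- counts@rows$id
  k <- counts@rows$total
  p0 <- unname(mapValues(expected_freq, ids))
  if (any(p0 < 0)) stop("expected frequencies must be >= 0")
  if (any(p0 > 1)) stop("expected frequency above 1 site per bp is not a probability")
  pv <- ifelse(k == 0, 1, stats::pbinom(k - 1, size = total_bp, prob = p0, lower.tail = FALSE))
  m <- length(ids)
  threshold <- if (correction == "bonferroni") alpha / m else alpha
  rows <- data.frame(id = ids, total = k, expected = p0 * total_bp, p_value = pv,
                     significant = ifelse(pv <= threshold, "yes", "no"),
                     stringsAsFactors = FALSE)
  analysisResult("overrepresentation", rows, c("number", "number", "number", "class"),
                 list(operation = "overrepresentation", alpha = alpha, m = m,
                      correction = correction, threshold = threshold, total_bp = total_bp))
}

#' Bonferroni-corrected significance threshold
#' @param alpha nominal level.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha, m) alpha / m

#' Compare motif site counts between two sequence groups
#'
#' Per motif, the 2x2 table (sites vs remaining bp in each group) is tested
#' two-sided with Fisher's exact test. Class labels: `A` = overrepresented
#' in group A at the Bonferroni-corrected level, `B` = in group A at the
#' nominal level only, `C` = not significant, `D` = overrepresented in
#' group B at the nominal level or better.
#'
#' @param motif_track a motif [RegionTrack].
#' @param groupA,groupB disjoint, non-empty sequence [Collection]s.
#' @param alpha nominal significance level.
#' @return an [AnalysisResult] with site counts, rates, p-values and class.
#' @export
groupComparison <- function(motif_track, groupA, groupB, alpha = 0.05) {
  a <- members(groupA); b <- members(groupB)
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  bpA <- sum(motif_track@seqlengths[a]); bpB <- sum(motif_track@seqlengths[b])
  ids <- sort(unique(unlist(lapply(motif_track@regions[c(a, b)], function(df) df$type))))
  m <- length(ids)
  countIn <- function(seqs, id) sum(vapply(motif_track@regions[seqs],
                                           function(df) sum(df$type == id), 0L))
  rows <- do.call(rbind, lapply(ids, function(id) {
    kA <- countIn(a, id); kB <- countIn(b, id)
    p <- stats::fisher.test(matrix(c(kA, bpA - kA, kB, bpB - kB), nrow = 2))$p.value
    rateA <- kA / bpA; rateB <- kB / bpB
    cls <- if (p <= alpha / m && rateA > rateB) "A"
      else if (p <= alpha && rateA > rateB) "B"
      else if (p <= alpha && rateB > rateA) "D"
      else "C"
    data.frame(id = id, sites_A = kA, sites_B = kB, p_value = p, group = cls,
               stringsAsFactors = FALSE)
  }))
  analysisResult("group comparison", rows,
                 c("number", "number", "number", "class"),
                 list(operation = "groupComparison", alpha = alpha, m = m,
                      bpA = bpA, bpB = bpB))
}

#' Positional distribution of binding sites with kurtosis
#'
#' Site midpoints (`floor((start+end)/2)`) are expressed relative to the
#' anchor, strand-aware so that upstream positions are negative. Kurtosis is
#' the Pearson measure m4/m2^2 on population moments (normal = 3), a simple
#' measure of positional clustering; motifs with fewer than 4 sites, or
#' with all sites at one position, get a blank.
#'
#' @param motif_track a motif [RegionTrack].
#' @param sequences the [SequenceSet] (supplies strand and TSS offsets).
#' @param anchor `"tss"` (requires `tss_offset` on all sequences) or
#'   `"sequence_end"`.
#' @param bin_size histogram bin width in bp.
#' @param excess if `TRUE` report excess kurtosis (m4/m2^2 - 3).
#' @return an [AnalysisResult] with site count, kurtosis and histogram;
#'   `provenance$breaks` holds the common bin breaks.
#' @export
positionalDistribution <- function(motif_track, sequences, anchor = c("tss", "sequence_end"),
                                   bin_size = 10, excess = FALSE) {
  anchor <- match.arg(anchor)
  stopifnot(is(motif_track, "RegionTrack"))
  info <- sequences@info
  if (anchor == "tss" && any(is.na(info$tss_offset[info$name %in% names(motif_track@regions)])))
    stop("anchor 'tss' requires a TSS offset on every sequence")
  rels <- list()
  for (nm in names(motif_track@regions)) {
    df <- motif_track@regions[[nm]]
    if (nrow(df) == 0L) next
    row <- seqInfoRow(sequences, nm)
    mid <- floor((df$start + df$end) / 2)
    rel <- if (anchor == "tss") {
      if (row$strand == "+") mid - row$tss_offset else row$tss_offset - mid
    } else {
      L <- row$end - row$start
      if (row$strand == "+") mid - L else -mid
    }
    for (i in seq_along(rel))
      rels[[df$type[i]]] <- c(rels[[df$type[i]]], rel[i])
  }
  ids <- sort(names(rels))
  allRel <- unlist(rels)
  lo <- floor(min(allRel) / bin_size) * bin_size
  hi <- ceiling((max(allRel) + 1) / bin_size) * bin_size
  breaks <- seq(lo, hi, by = bin_size)
  anyDegenerate <- FALSE
  rows <- do.call(rbind, lapply(ids, function(id) {
    x <- rels[[id]]
    kurt <- NA_real_
    if (length(x) >= 4L) {
      m2 <- mean((x - mean(x))^2)
      if (m2 == 0) anyDegenerate <<- TRUE
      else {
        kurt <- mean((x - mean(x))^4) / m2^2
        if (excess) kurt <- kurt - 3
      }
    }
    data.frame(id = id, sites = length(x), kurtosis = kurt, stringsAsFactors = FALSE)
  }))
  ## left-closed bins, consistent with half-open coordinates
  rows$histogram <- lapply(ids, function(id)
    as.integer(graphics::hist(rels[[id]], breaks = breaks, plot = FALSE, right = FALSE)$counts))
  if (anyDegenerate)
    warning("kurtosis undefined for motif(s) with all sites at one position")
  analysisResult("positional distribution", rows, c("number", "number", "histogram"),
                 list(operation = "positionalDistribution", anchor = anchor,
                      bin_size = bin_size, breaks = breaks))
}

#' Average a numeric feature over each motif's binding sites
#'
#' Position-weighted: the mean is taken over all covered positions of all
#' sites of the motif, so longer sites weigh more. Motifs occur in the
#' output even when another analysis knows them but they have no sites here
#' only if present in the track.
#'
#' @param motif_track a motif [RegionTrack].
#' @param feature a [NumericTrack] (e.g. conservation).
#' @param stat summary statistic; only `"mean"` is defined.
#' @return an [AnalysisResult] with the per-motif average.
#' @export
sitesVsNumeric <- function(motif_track, feature, stat = "mean") {
  stopifnot(is(motif_track, "RegionTrack"), is(feature, "NumericTrack"), stat == "mean")
  vals <- list()
  for (nm in names(motif_track@regions)) {
    df <- motif_track@regions[[nm]]
    if (nrow(df) == 0L) next
    fv <- feature@values[[nm]]
    for (i in seq_len(nrow(df)))
      vals[[df$type[i]]] <- c(vals[[df$type[i]]], fv[(df$start[i] + 1L):df$end[i]])
  }
  ids <- sort(names(vals))
  rows <- data.frame(id = ids,
                     mean = vapply(ids, function(id) mean(vals[[id]]), 0),
                     positions = vapply(ids, function(id) length(vals[[id]]), 0L),
                     stringsAsFactors = FALSE)
  analysisResult("sites vs numeric feature", rows, c("number", "number"),
                 list(operation = "sitesVsNumeric", stat = stat))
}

rankWithBlanksLast <- function(v, direction) {
  n <- length(v)
  key <- if (direction == "ascending") v else -v
  r <- rank(key, ties.method = "average", na.last = "keep")
  nn <- sum(!is.na(v))
  r[is.na(v)] <- (nn + 1 + n) / 2   # blanks share the trailing midrank
  r
}

#' Combine numeric maps by rank sum
#'
#' Members are ranked 1..n within each map in the stated direction
#' (midranks for ties; blanks rank last) and the ranks are summed; lower is
#' better. The classic promoter-analysis combination ranks p-values
#' ascending and conservation and kurtosis descending.
#'
#' @param maps list of [NumericMap]s (or named numeric vectors; `NA` =
#'   blank), all over the same member set.
#' @param directions character vector, `"ascending"` or `"descending"` per
#'   map.
#' @return a [NumericMap] of rank sums.
#' @export
rankSum <- function(maps, directions) {
  if (length(maps) < 2L) stop("rank sum needs at least 2 maps")
  if (length(maps) != length(directions)) stop("need one direction per map")
  directions <- vapply(directions, function(d) match.arg(d, c("ascending", "descending")), "")
  vecs <- lapply(maps, function(m) if (is(m, "NumericMap")) m@values else m)
  common <- Reduce(union, lapply(vecs, names))
  if (length(Reduce(intersect, lapply(vecs, names))) == 0L)
    stop("maps have disjoint member sets")
  total <- numeric(length(common))
  names(total) <- common
  for (i in seq_along(vecs)) {
    v <- vecs[[i]][common]
    names(v) <- common
    total <- total + rankWithBlanksLast(unname(v), directions[i])
  }
  memberType <- if (is(maps[[1]], "NumericMap")) maps[[1]]@memberType else "motif"
  numericMap(memberType, stats::setNames(total, common), default = length(vecs) * length(common))
}

#' Nucleotide- and site-level benchmark statistics
#'
#' A position is predicted-positive if covered by any predicted region and
#' truly positive if covered by any answer region; the confusion counts give
#' sensitivity Sn, specificity Sp, positive predictive value PPV, accuracy
#' Acc, performance coefficient PC, average site performance ASP, F-measure
#' and the Matthews correlation coefficient CC. Site-level sensitivity sSn
#' is the fraction of answer sites overlapped by a prediction covering at
#' least `site_overlap_fraction` of the site's length. Zero-denominator
#' statistics (and CC) are defined as 0.
#'
#' @param predicted,answer [RegionTrack]s over the same sequences.
#' @param site_overlap_fraction minimum overlap fraction for sSn
#'   (default 0.25).
#' @return named list with TP, FP, TN, FN, Sn, Sp, PPV, Acc, PC, ASP, F,
#'   CC and sSn.
#' @export
benchmarkStats <- function(predicted, answer, site_overlap_fraction = 0.25) {
  stopifnot(is(predicted, "RegionTrack"), is(answer, "RegionTrack"))
  if (!identical(sort(names(predicted@regions)), sort(names(answer@regions))))
    stop("predicted and answer tracks must cover the same sequences")
  TP <- FP <- TN <- FN <- 0
  nSites <- 0L; nHit <- 0L
  for (nm in names(answer@regions)) {
    p <- coverageVector(predicted, nm) > 0L
    a <- coverageVector(answer, nm) > 0L
    TP <- TP + sum(p & a); FP <- FP + sum(p & !a)
    TN <- TN + sum(!p & !a); FN <- FN + sum(!p & a)
    adf <- answer@regions[[nm]]
    pdf <- predicted@regions[[nm]]
    if (nrow(adf)) {
      nSites <- nSites + nrow(adf)
      for (i in seq_len(nrow(adf))) {
        need <- site_overlap_fraction * (adf$end[i] - adf$start[i])
        if (nrow(pdf) && any(pmin(pdf$end, adf$end[i]) - pmax(pdf$start, adf$start[i]) >= need &
                             pmin(pdf$end, adf$end[i]) - pmax(pdf$start, adf$start[i]) > 0))
          nHit <- nHit + 1L
      }
    }
  }
  safe <- function(num, den) if (den == 0) 0 else num / den
  Sn <- safe(TP, TP + FN); Sp <- safe(TN, TN + FP); PPV <- safe(TP, TP + FP)
  ccDen <- sqrt((TP + FN) * (TN + FP) * (TP + FP) * (TN + FN))
  CC <- if (ccDen == 0) 0 else (TP * TN - FN * FP) / ccDen
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       Sn = Sn, Sp = Sp, PPV = PPV,
       Acc = safe(TP + TN, TP + FP + TN + FN),
       PC = safe(TP, TP + FP + FN),
       ASP = (Sn + PPV) / 2,
       F = if (Sn + PPV == 0) 0 else 2 * Sn * PPV / (Sn + PPV),
       CC = CC,
       sSn = safe(nHit, nSites))
}

#' Collate analyses into a meta-analysis table
#'
#' Column-joins selected columns from several analyses on their member keys
#' (union of keys; missing cells blank) and optionally sorts by a rank-sum
#' specification. Duplicate column labels get a numeric suffix with a
#' warning.
#'
#' @param analyses list of entries `list(result = AnalysisResult, columns =
#'   character)` (`columns = NULL` takes all).
#' @param sortBy optional `list(labels = character, directions = character)`
#'   naming numeric columns of the collated table to combine with
#'   [rankSum()]; rows are sorted by increasing rank sum.
#' @param name name of the collated analysis.
#' @return an [AnalysisResult].
#' @export
collateAnalyses <- function(analyses, sortBy = NULL, name = "meta-analysis") {
  ids <- sort(unique(unlist(lapply(analyses, function(a) a$result@rows$id))))
  rows <- data.frame(id = ids, stringsAsFactors = FALSE)
  types <- character()
  for (a in analyses) {
    res <- a$result
    cols <- if (is.null(a$columns)) res@schema$label else a$columns
    for (cl in cols) {
      ix <- match(cl, res@schema$label)
      if (is.na(ix)) stop(sprintf("analysis '%s' has no column '%s'", res@name, cl))
      label <- cl
      if (label %in% names(rows)) {
        k <- 2L
        while (sprintf("%s.%d", cl, k) %in% names(rows)) k <- k + 1L
        label <- sprintf("%s.%d", cl, k)
        warning(sprintf("duplicate column label '%s' renamed to '%s'", cl, label))
      }
      type <- res@schema$type[ix]
      src <- res@rows[[cl]]
      pos <- match(ids, res@rows$id)
      if (type == "histogram") {
        rows[[label]] <- lapply(pos, function(p) if (is.na(p)) NULL else src[[p]])
      } else {
        v <- src[pos]
        if (type %in% c("text", "class")) v[is.na(pos)] <- NA_character_
        rows[[label]] <- v
      }
      types <- c(types, type)
    }
  }
  res <- analysisResult(name, rows, types, list(operation = "collate"))
  if (!is.null(sortBy)) {
    maps <- lapply(sortBy$labels, function(l)
      stats::setNames(res@rows[[l]], res@rows$id))
    combined <- if (length(maps) == 1L)
      rankWithBlanksLast(unname(maps[[1]]), sortBy$directions[1])
    else unname(mapValues(rankSum(maps, sortBy$directions), res@rows$id))
    ord <- order(combined, res@rows$id)
    res@rows <- res@rows[ord, , drop = FALSE]
    rownames(res@rows) <- NULL
  }
  res
}

## --------------------------- rendering -------------------------------------

histogramSvg <- function(counts, width = 120, height = 30) {
  if (length(counts) == 0L || max(counts) == 0) counts <- c(counts, 0)
  n <- length(counts)
  bw <- width / n
  mx <- max(counts, 1)
  bars <- vapply(seq_len(n), function(i) {
    h <- counts[i] / mx * height
    sprintf('<rect x="%.2f" y="%.2f" width="%.2f" height="%.2f" fill="steelblue"/>',
            (i - 1) * bw, height - h, bw * 0.9, h)
  }, "")
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">%s</svg>',
          width, height, paste(bars, collapse = ""))
}

motifLogoSvg <- function(m, colHeight = 30, colWidth = 12) {
  mat <- m@matrix
  w <- ncol(mat)
  cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
  parts <- character()
  for (j in seq_len(w)) {
    ic <- 2 + sum(ifelse(mat[, j] > 0, mat[, j] * log2(mat[, j]), 0))
    y <- colHeight
    ord <- order(mat[, j])
    for (b in rownames(mat)[ord]) {
      h <- mat[b, j] * ic / 2 * colHeight
      if (h < 0.5) next
      y <- y - h
      parts <- c(parts, sprintf(
        '<text x="%.1f" y="%.1f" font-family="monospace" font-size="%.1f" fill="%s">%s</text>',
        (j - 1) * colWidth, y + h, h * 1.3, cols[[b]], b))
    }
  }
  sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">%s</svg>',
          w * colWidth, colHeight, paste(parts, collapse = ""))
}

#' Render an analysis result as HTML or raw text
#'
#' HTML output is a self-contained document: histogram columns become inline
#' SVG bar charts, motif rows get an inline SVG sequence logo when a
#' [MotifSet] is supplied, and class-typed cells carry a `class` attribute
#' (so significant rows can be styled). Raw output is UTF-8 TSV with a
#' `#types` comment line; histograms are comma-joined bin counts. Both are
#' byte-deterministic for fixed input.
#'
#' @param result an [AnalysisResult].
#' @param format `"html"` or `"raw"`.
#' @param motifs optional [MotifSet] for logo rendering.
#' @return character vector of document lines.
#' @export
renderResult <- function(result, format = c("html", "raw"), motifs = NULL) {
  format <- match.arg(format)
  rows <- result@rows
  schema <- result@schema
  if (format == "raw") {
    header <- paste(c("id", schema$label), collapse = "\t")
    typeLine <- paste0("#types\t", paste(schema$type, collapse = "\t"))
    body <- vapply(seq_len(nrow(rows)), function(i) {
      cells <- vapply(seq_len(nrow(schema)), function(j) {
        v <- rows[[schema$label[j]]][if (schema$type[j] == "histogram") i else i]
        if (schema$type[j] == "histogram") {
          h <- rows[[schema$label[j]]][[i]]
          if (is.null(h)) "" else paste(h, collapse = ",")
        } else if (is.na(v)) "" else if (is.numeric(v)) fmtNum(v) else as.character(v)
      }, "")
      paste(c(rows$id[i], cells), collapse = "\t")
    }, "")
    return(c(header, typeLine, body))
  }
  ## html
  head <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            sprintf("<title>%s</title>", result@name),
            "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font-family:sans-serif;font-size:12px}td.yes,td.A,td.B{background:#fdd}td.D{background:#dfd}td.C{background:#ffd}</style>",
            "</head><body>", sprintf("<h1>%s</h1>", result@name), "<table>",
            paste0("<tr><th>id</th>",
                   if (!is.null(motifs)) "<th>logo</th>" else "",
                   paste(sprintf("<th>%s</th>", schema$label), collapse = ""), "</tr>"))
  body <- vapply(seq_len(nrow(rows)), function(i) {
    cells <- vapply(seq_len(nrow(schema)), function(j) {
      type <- schema$type[j]
      if (type == "histogram") {
        h <- rows[[schema$label[j]]][[i]]
        sprintf("<td>%s</td>", if (is.null(h)) "" else histogramSvg(h))
      } else {
        v <- rows[[schema$label[j]]][i]
        txt <- if (is.na(v)) "" else if (is.numeric(v)) fmtNum(v, 6) else as.character(v)
        if (type == "class" && !is.na(v)) sprintf('<td class="%s">%s</td>', v, txt)
        else sprintf("<td>%s</td>", txt)
      }
    }, "")
    logo <- if (!is.null(motifs) && rows$id[i] %in% motifIds(motifs))
      sprintf("<td>%s</td>", motifLogoSvg(getMotif(motifs, rows$id[i]))) else
      if (!is.null(motifs)) "<td></td>" else ""
    paste0("<tr><td>", rows$id[i], "</td>", logo, paste(cells, collapse = ""), "</tr>")
  }, "")
  c(head, body, "</table></body></html>")
}

#' Re-parse raw-text analysis output
#' @param lines character vector produced by `renderResult(format="raw")`.
#' @param name analysis name for the reconstructed object.
#' @return an [AnalysisResult].
#' @export
parseRawResult <- function(lines, name = "parsed") {
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  types <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  labels <- header[-1]
  body <- lines[-(1:2)]
  cells <- lapply(body, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  cells <- lapply(cells, function(x) c(x, rep("", length(header) - length(x))))
  rows <- data.frame(id = vapply(cells, `[`, "", 1), stringsAsFactors = FALSE)
  for (j in seq_along(labels)) {
    raw <- vapply(cells, `[`, "", j + 1L)
    rows[[labels[j]]] <- switch(types[j],
      number = ifelse(raw == "", NA_real_, suppressWarnings(as.numeric(raw))),
      histogram = lapply(raw, function(s) if (s == "") NULL else as.integer(strsplit(s, ",", fixed = TRUE)[[1]])),
      ifelse(raw == "", NA_character_, raw))
  }
  analysisResult(name, rows, types, list(operation = "parseRawResult"))
}
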