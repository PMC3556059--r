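## Synthetic planted-motif datasets with answer keys and emulated feature
## tracks, so every pipeline stage is testable without external data.
## Background sequence comes from a Markov model, binding sites are sampled
## from the motif's PWM and implanted without overlap, and each synthetic
## feature mixes smoothed answer coverage with independent noise at an
## informativeness rho.

#' Specification for a planted-motif dataset
#'
#' @param n_sequences number of sequences.
#' @param length sequence length in bp.
#' @param motif the [Motif] to implant.
#' @param background a [BackgroundModel] (default uniform order 0).
#' @param sites_per_seq fixed count, or `list(poisson = lambda)`.
#' @param position_law `list(kind = "uniform")` or `list(kind = "gaussian",
#'   center = -100, sd = 30)` (center in bp relative to the TSS, which sits
#'   at the sequence end; negative = upstream).
#' @param strand_prob probability that an implant goes on the plus strand.
#' @param features named numeric vector of informativeness values rho in
#'   [0,1], one synthetic feature track per entry (rho = 1: the feature is
#'   smoothed answer coverage; rho = 0: pure noise).
#' @param seed integer seed (mandatory).
#' @return a `PlantSpec` list.
#' @export
plantSpec <- function(n_sequences = 10, length = 500, motif,
                      background = uniformBackground(),
                      sites_per_seq = 2, position_law = list(kind = "uniform"),
                      strand_prob = 0.5, features = c(conservation = 0.8),
                      seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (ncol(motif@matrix) >= length) stop("motif width must be smaller than the sequence length")
  if (strand_prob < 0 || strand_prob > 1) stop("strand_prob must be in [0,1]")
  if (any(features < 0 | features > 1)) stop("feature informativeness must be in [0,1]")
  structure(list(n_sequences = n_sequences, length = length, motif = motif,
                 background = background, sites_per_seq = sites_per_seq,
                 position_law = position_law, strand_prob = strand_prob,
                 features = features, seed = as.integer(seed)),
            class = "PlantSpec")
}

sampleSiteString <- function(m) {
  paste(vapply(seq_len(ncol(m@matrix)), function(j)
    sample(BASES, 1L, prob = m@matrix[, j]), ""), collapse = "")
}

drawSiteCount <- function(spec) {
  s <- spec$sites_per_seq
  if (is.list(s)) stats::rpois(1L, s$poisson) else as.integer(s)
}

drawPosition <- function(law, L, w, tss) {
  if (law$kind == "uniform") sample.int(L - w + 1L, 1L) - 1L
  else if (law$kind == "gaussian") {
    p <- round(tss + law$center + stats::rnorm(1L, 0, law$sd))
    min(max(p, 0), L - w)
  } else stop(sprintf("unknown position law '%s'", law$kind))
}

placeSites <- function(spec, nSites, L, w, tss) {
  placed <- list()
  tries <- 0L
  maxTries <- 200L * max(nSites, 1L)
  while (length(placed) < nSites) {
    tries <- tries + 1L
    if (tries > maxTries)
      stop(sprintf("cannot place %d non-overlapping sites in %d bp after %d tries",
                   nSites, L, maxTries))
    p <- drawPosition(spec$position_law, L, w, tss)
    ok <- all(vapply(placed, function(q) p + w <= q || q + w <= p, TRUE))
    if (ok) placed[[length(placed) + 1L]] <- p
  }
  sort(unlist(placed))
}

implantInto <- function(chars, site, at) {
  s <- strsplit(site, "", fixed = TRUE)[[1]]
  chars[(at + 1L):(at + length(s))] <- s
  chars
}

## Feature emulation: rho * (11 bp smoothed answer coverage) + (1 - rho) *
## standard Gaussian noise, min-max normalized to [0,1]. Gaussian noise keeps
## per-position signal and noise overlapping at every rho < 1, which is what
## real epigenetic evidence looks like; a bounded noise term would make even
## moderately informative features separate the classes almost perfectly.
buildFeatureTracks <- function(spec, answer, lens) {
  covTrack <- regionsToNumeric(answer, "coverage")
  smooth <- slidingWindow(trackArithmetic(covTrack, "min", 1), "mean", 11L)
  out <- list()
  for (f in names(spec$features)) {
    rho <- spec$features[[f]]
    vals <- lapply(names(lens), function(nm)
      rho * smooth@values[[nm]] + (1 - rho) * stats::rnorm(lens[[nm]]))
    names(vals) <- names(lens)
    out[[f]] <- normalizePriors(numericTrack(vals))
  }
  out
}

#' Generate a planted-motif dataset
#'
#' Samples background sequence, implants motif sites without overlap at
#' positions from the position law, and returns the sequences, the DNA
#' track, the exact answer key (a motif [RegionTrack] with implant
#' coordinates, strands and motif id), one emulated feature track per
#' configured feature, and an implant-free control DNA track from the same
#' background. Fully determined by the spec's seed.
#'
#' @param spec a [plantSpec()].
#' @return list with `sequences`, `dna`, `answer`, `features` (named list
#'   of [NumericTrack]s), `control`, `motif`, `spec`.
#' @export
generatePlantedDataset <- function(spec) {
  stopifnot(inherits(spec, "PlantSpec"))
  w <- ncol(spec$motif@matrix)
  L <- spec$length
  withSeed(spec$seed, {
    nms <- sprintf("s%d", seq_len(spec$n_sequences))
    dna <- character(); ctrl <- character(); regions <- list()
    for (nm in nms) {
      chars <- strsplit(sampleBgString(spec$background, L), "", fixed = TRUE)[[1]]
      ctrl[[nm]] <- sampleBgString(spec$background, L)
      nSites <- drawSiteCount(spec)
      if (nSites > 0L) {
        at <- placeSites(spec, nSites, L, w, tss = L)
        strands <- ifelse(stats::runif(nSites) < spec$strand_prob, "+", "-")
        for (i in seq_along(at)) {
          site <- sampleSiteString(spec$motif)
          if (strands[i] == "-") site <- reverseComplement(site)
          chars <- implantInto(chars, site, at[i])
        }
        regions[[nm]] <- regionFrame(at, at + w, spec$motif@id, 1, strands)
      } else {
        regions[[nm]] <- emptyRegions()
      }
      dna[[nm]] <- paste(chars, collapse = "")
    }
    sequences <- sequenceSet(nms, chromosome = nms, start = 0, end = L,
                             strand = "+", build = "synthetic", tss_offset = L)
    answer <- regionTrack(regions, seqLengths(sequences))
    list(sequences = sequences, dna = dnaTrack(dna), answer = answer,
         features = buildFeatureTracks(spec, answer, seqLengths(sequences)),
         control = dnaTrack(ctrl), motif = spec$motif, spec = spec)
  })
}

#' Generate a planted module (motif pair) dataset
#'
#' Implants ordered pairs of sites for two motifs with the gap between them
#' drawn from the gap law. The returned `answer` is the motif-level site
#' track; `module_answer` holds module-level regions with the pair as
#' children.
#'
#' @param spec a [plantSpec()] for the first motif; `sites_per_seq` is the
#'   number of pairs per sequence.
#' @param motif2 the second [Motif] of the pair.
#' @param gap_law `list(kind = "fixed", gap = g)` or `list(kind =
#'   "uniform", min = a, max = b)` (nearest-edge gap in bp).
#' @return list as in [generatePlantedDataset()] plus `module_answer` and
#'   `motif2`.
#' @export
generateModuleDataset <- function(spec, motif2, gap_law = list(kind = "fixed", gap = 5)) {
  stopifnot(inherits(spec, "PlantSpec"))
  w1 <- ncol(spec$motif@matrix); w2 <- ncol(motif2@matrix)
  L <- spec$length
  maxGap <- if (gap_law$kind == "fixed") gap_law$gap else gap_law$max
  if (w1 + w2 + maxGap >= L) stop("combined pair span must be smaller than the sequence length")
  withSeed(spec$seed, {
    nms <- sprintf("s%d", seq_len(spec$n_sequences))
    dna <- character(); ctrl <- character()
    siteRegions <- list(); moduleRegions <- list()
    for (nm in nms) {
      chars <- strsplit(sampleBgString(spec$background, L), "", fixed = TRUE)[[1]]
      ctrl[[nm]] <- sampleBgString(spec$background, L)
      nPairs <- drawSiteCount(spec)
      placedSpans <- list()
      sdf <- emptyRegions(); mdf <- emptyRegions()
      for (k in seq_len(nPairs)) {
        gap <- if (gap_law$kind == "fixed") gap_law$gap
          else sample(gap_law$min:gap_law$max, 1L)
        span <- w1 + gap + w2
        ok <- FALSE
        for (try in 1:200) {
          at <- sample.int(L - span + 1L, 1L) - 1L
          if (all(vapply(placedSpans, function(q) at + span <= q[1] || q[2] <= at, TRUE))) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("cannot place module pair without overlap")
        placedSpans[[length(placedSpans) + 1L]] <- c(at, at + span)
        s1 <- sampleSiteString(spec$motif)
        s2 <- sampleSiteString(motif2)
        strand1 <- if (stats::runif(1) < spec$strand_prob) "+" else "-"
        strand2 <- if (stats::runif(1) < spec$strand_prob) "+" else "-"
        chars <- implantInto(chars, if (strand1 == "-") reverseComplement(s1) else s1, at)
        chars <- implantInto(chars, if (strand2 == "-") reverseComplement(s2) else s2, at + w1 + gap)
        pair <- regionFrame(c(at, at + w1 + gap), c(at + w1, at + span),
                            c(spec$motif@id, motif2@id), 1, c(strand1, strand2))
        sdf <- rbind(sdf, pair)
        mdf <- rbind(mdf, regionFrame(at, at + span, "module", 2, ".",
                                      children = list(pair)))
      }
      siteRegions[[nm]] <- sdf
      moduleRegions[[nm]] <- mdf
      dna[[nm]] <- paste(chars, collapse = "")
    }
    sequences <- sequenceSet(nms, chromosome = nms, start = 0, end = L,
                             strand = "+", build = "synthetic", tss_offset = L)
    answer <- regionTrack(siteRegions, seqLengths(sequences))
    list(sequences = sequences, dna = dnaTrack(dna), answer = answer,
         module_answer = regionTrack(moduleRegions, seqLengths(sequences)),
         features = buildFeatureTracks(spec, answer, seqLengths(sequences)),
         control = dnaTrack(ctrl), motif = spec$motif, motif2 = motif2, spec = spec)
  })
}

#' Write a planted dataset bundle to files
#'
#' FASTA (DNA and control), GFF (answer key, plus module answer when
#' present), one WIG per feature track, and an XML echo of the generating
#' parameters — all loadable with [readTrack()].
#'
#' @param bundle output of [generatePlantedDataset()] or
#'   [generateModuleDataset()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writePlantedDataset <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTrack(bundle$dna, file.path(dir, "sequences.fasta"), "fasta", bundle$sequences)
  writeTrack(bundle$control, file.path(dir, "control.fasta"), "fasta", bundle$sequences)
  writeTrack(bundle$answer, file.path(dir, "answer.gff"), "gff", bundle$sequences)
  if (!is.null(bundle$module_answer))
    writeTrack(bundle$module_answer, file.path(dir, "module_answer.gff"), "gff", bundle$sequences)
  for (f in names(bundle$features))
    writeTrack(bundle$features[[f]], file.path(dir, sprintf("%s.wig", f)), "wig", bundle$sequences)
  spec <- bundle$spec
  doc <- xml2::xml_new_root("planted_dataset")
  xml2::xml_set_attrs(doc, c(n_sequences = spec$n_sequences, length = spec$length,
                             motif = spec$motif@id, seed = spec$seed,
                             strand_prob = spec$strand_prob))
  xml2::write_xml(doc, file.path(dir, "spec.xml"))
  invisible(dir)
}
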