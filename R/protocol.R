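## Protocol scripts: a linear, recordable workflow language.
## Statement grammar:  target = opname arg1=value arg2=value [where <cond>]
## Values are numbers, quoted strings, bare names (resolved against the
## repository at execution time) or comma-joined lists of these. '#' starts
## a comment. There is no control flow; every statement stores its result
## under the target name. One master seed deterministically derives a
## per-statement seed from the statement index and target name, so scripts
## replay bit-identically.

#' Parsed protocol script
#'
#' @slot statements list of statements: `target`, `op`, `args` (named list
#'   of raw value strings), `where` (condition text or NULL), `line`.
#' @slot source the original source lines.
#' @export
setClass("ProtocolScript", representation(statements = "list", source = "character"))

setMethod("show", "ProtocolScript", function(object) {
  cat(sprintf("ProtocolScript with %d statements\n", length(object@statements)))
})

protoTokenizeArgs <- function(text, line) {
  ## split "k=v k2='v 2' ... [where ...]" respecting quotes
  args <- list()
  where <- NULL
  rest <- trimws(text)
  while (nchar(rest) > 0L) {
    if (grepl("^where(\\s|$)", rest)) {
      where <- trimws(sub("^where", "", rest))
      if (where == "") stop(sprintf("protocol line %d: empty where clause", line))
      break
    }
    m <- regexec('^([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^ \t]+)', rest)[[1]]
    if (m[1] == -1L)
      stop(sprintf("protocol line %d: expected key=value, found '%s'",
                   line, strsplit(rest, "[ \t]")[[1]][1]))
    key <- substring(rest, m[2], m[2] + attr(m, "match.length")[2] - 1L)
    val <- substring(rest, m[3], m[3] + attr(m, "match.length")[3] - 1L)
    args[[key]] <- val
    rest <- trimws(substring(rest, attr(m, "match.length")[1] + 1L))
  }
  list(args = args, where = where)
}

#' Parse a protocol script
#'
#' @param text protocol source (single string or vector of lines).
#' @return a [ProtocolScript]; syntax errors report the line.
#' @export
parseProtocol <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) strsplit(text, "\n")[[1]] else text
  statements <- list()
  for (li in seq_along(lines)) {
    line <- lines[[li]]
    stripped <- trimws(sub("#.*$", "", line))
    if (stripped == "") next
    m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*(.*)$", stripped)[[1]]
    if (m[1] == -1L) {
      eq <- regexpr("=", stripped, fixed = TRUE)
      stop(sprintf("protocol syntax error at line %d%s: expected 'target = opname args...'",
                   li, if (eq == -1L) " (missing '=')" else sprintf(", column %d", eq)))
    }
    target <- substring(stripped, m[2], m[2] + attr(m, "match.length")[2] - 1L)
    op <- substring(stripped, m[3], m[3] + attr(m, "match.length")[3] - 1L)
    tail <- substring(stripped, m[4], m[4] + attr(m, "match.length")[4] - 1L)
    aw <- protoTokenizeArgs(tail, li)
    statements[[length(statements) + 1L]] <-
      list(target = target, op = op, args = aw$args, where = aw$where, line = li)
  }
  new("ProtocolScript", statements = statements, source = lines)
}

#' Serialize a protocol script canonically
#' @param script a [ProtocolScript].
#' @return character vector of statement lines.
#' @export
serializeProtocol <- function(script) {
  vapply(script@statements, function(st) {
    parts <- c(st$target, "=", st$op,
               vapply(names(st$args), function(k) paste0(k, "=", st$args[[k]]), ""))
    if (!is.null(st$where)) parts <- c(parts, "where", st$where)
    paste(parts, collapse = " ")
  }, "")
}

## Per-statement seed derivation: stable integer hash of (master, index, target).
statementSeed <- function(master, index, target) {
  h <- as.double(master) %% 2147483647
  h <- (h * 31 + index * 1000003) %% 2147483647
  for (c in utf8ToInt(target)) h <- (h * 131 + c) %% 2147483647
  as.integer(h)
}

## Raw protocol value -> R value (resolving repository names).
resolveValue <- function(raw, repo) {
  if (grepl("^\".*\"$", raw)) return(gsub('^"|"$', "", raw))
  if (grepl(",", raw, fixed = TRUE)) {
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    vals <- lapply(parts, resolveValue, repo)
    if (all(vapply(vals, is.numeric, TRUE))) return(unlist(vals))
    return(vals)
  }
  if (grepl("^-?[0-9.]+([eE][+-]?[0-9]+)?$", raw)) return(as.numeric(raw))
  if (raw %in% c("true", "TRUE")) return(TRUE)
  if (raw %in% c("false", "FALSE")) return(FALSE)
  if (raw == "inf" || raw == "Inf") return(Inf)
  if (repoHas(repo, raw)) return(repoGet(repo, raw))
  raw   # bare word literal (e.g. stat=mean)
}

## R value -> canonical protocol text. Character values naming repository
## objects serialize as bare references, other strings are quoted.
unparseValue <- function(v, repo) {
  one <- function(x) {
    if (is.character(x)) {
      if (validIdentifier(x) && repoHas(repo, x)) x else paste0('"', x, '"')
    } else if (is.logical(x)) {
      if (x) "true" else "false"
    } else if (is.numeric(x)) {
      if (is.infinite(x)) "inf" else fmtNum(x)
    } else stop("cannot serialize a non-literal argument; pass repository object names")
  }
  if (is.list(v)) paste(vapply(v, one, ""), collapse = ",")
  else if (length(v) > 1L) paste(vapply(v, one, ""), collapse = ",")
  else one(v)
}

## --------------------------- operation registry ----------------------------

argOr <- function(args, name, default) if (is.null(args[[name]])) default else args[[name]]

protocolRegistry <- function() {
  reg <- list()
  reg$put <- function(repo, a, seed) a$value
  reg$mask <- function(repo, a, seed)
    maskTrack(a$dna, if (is(a$fill, "BackgroundModel")) a$fill else as.character(a$fill),
              where = if (!is.null(a$where_track)) a$where_track else a$.where,
              tracks = repo, seed = seed)
  reg$filter_regions <- function(repo, a, seed)
    filterRegions(a$track, a$.where, tracks = repo)
  reg$transform_regions <- function(repo, a, seed)
    transformRegions(a$track, op = a$op, up = argOr(a, "up", 0), down = argOr(a, "down", 0),
                     strand_aware = argOr(a, "strand_aware", FALSE),
                     max_gap = argOr(a, "max_gap", 0))
  reg$arithmetic <- function(repo, a, seed)
    trackArithmetic(a$track, op = a$op, operand = a$operand, where = a$.where, tracks = repo)
  reg$sliding_window <- function(repo, a, seed)
    slidingWindow(a$track, stat = a$stat, size = a$size)
  reg$combine_tracks <- function(repo, a, seed)
    combineTracks(if (is.list(a$tracks)) a$tracks else list(a$tracks), a$weights)
  reg$numeric_to_regions <- function(repo, a, seed)
    numericToRegions(a$track, threshold = a$threshold,
                     min_length = argOr(a, "min_length", 1), type = argOr(a, "type", "region"))
  reg$regions_to_numeric <- function(repo, a, seed)
    regionsToNumeric(a$track, mode = argOr(a, "mode", "coverage"))
  reg$sequence_statistic <- function(repo, a, seed)
    sequenceStatistic(a$dna, stat = a$stat, base = argOr(a, "base", "A"))
  reg$collection_from_map <- function(repo, a, seed)
    collectionFromMap(a$map, op = a$op, value = a$value)
  reg$map_arithmetic <- function(repo, a, seed)
    mapArithmetic(a$map, op = a$op, operand = a$operand)
  reg$train_background <- function(repo, a, seed)
    trainBackground(a$dna, order = argOr(a, "order", 0))
  reg$sample_background <- function(repo, a, seed) {
    if (!is.null(a$like)) {
      lens <- a$like@seqlengths
      out <- character()
      for (i in seq_along(lens))
        out[[names(lens)[i]]] <- sampleBackground(a$model, lens[[i]], seed = seed + i)
      dnaTrack(out)
    } else {
      count <- argOr(a, "count", 1)
      out <- character()
      for (i in seq_len(count))
        out[[sprintf("control_%d", i)]] <- sampleBackground(a$model, a$length, seed = seed + i)
      dnaTrack(out)
    }
  }
  reg$scan_motifs <- function(repo, a, seed)
    scanMotifs(a$dna, a$motifs, threshold = argOr(a, "threshold", 0.8),
               background = if (is.null(a$background)) uniformBackground() else a$background,
               strands = argOr(a, "strands", "both"))
  reg$match_consensus <- function(repo, a, seed)
    matchConsensus(a$dna, a$pattern, strands = argOr(a, "strands", "both"))
  reg$pwm_score_profile <- function(repo, a, seed)
    pwmScoreProfile(a$dna, if (is(a$motif, "Motif")) a$motif else getMotif(a$motifs, a$motif),
                    background = if (is.null(a$background)) uniformBackground() else a$background)
  reg$motif_from_sites <- function(repo, a, seed) {
    sites <- if (is.list(a$sites)) unlist(a$sites) else a$sites
    motifFromSites(sites, id = a$id)
  }
  reg$normalize_priors <- function(repo, a, seed) normalizePriors(a$track)
  reg$discriminative_prior <- function(repo, a, seed)
    discriminativePrior(a$priors, a$control_mean)
  reg$train_priors_generator <- function(repo, a, seed) {
    fnames <- if (is.list(a$features)) unlist(a$features) else a$features
    feats <- stats::setNames(lapply(fnames, repoGet, repo = repo), fnames)
    trainPriorsGenerator(feats, a$target, trainingSequences = a$sequences,
                         windows = argOr(a, "windows", c(1L, 11L, 101L)),
                         negativeRatio = argOr(a, "ratio", 1),
                         hidden = argOr(a, "hidden", 8L),
                         maxit = argOr(a, "maxit", 500L), seed = seed)
  }
  reg$apply_priors_generator <- function(repo, a, seed) {
    fnames <- if (is.list(a$features)) unlist(a$features) else a$features
    feats <- stats::setNames(lapply(fnames, repoGet, repo = repo), fnames)
    applyPriorsGenerator(a$generator, feats)
  }
  reg$evaluate_priors <- function(repo, a, seed) evaluatePriors(a$priors, a$answer)
  reg$module_from_spec <- function(repo, a, seed) moduleFromSpec(a$spec, id = a$.target)
  reg$scan_modules <- function(repo, a, seed)
    scanModules(a$motif_track, a$model, motifs = a$motifs,
                score = argOr(a, "score", "sum"))
  reg$interaction_filter <- function(repo, a, seed)
    interactionFilter(a$motif_track, a$partners, max_gap = a$max_gap)
  reg$count_motif_occurrences <- function(repo, a, seed)
    countMotifOccurrences(a$motif_track, sequences = a$sequences)
  reg$overrepresentation <- function(repo, a, seed)
    overrepresentation(a$counts, a$expected_freq, total_bp = a$total_bp,
                       alpha = argOr(a, "alpha", 0.05),
                       correction = argOr(a, "correction", "bonferroni"))
  reg$group_comparison <- function(repo, a, seed)
    groupComparison(a$motif_track, a$groupA, a$groupB, alpha = argOr(a, "alpha", 0.05))
  reg$positional_distribution <- function(repo, a, seed)
    positionalDistribution(a$motif_track, a$sequences, anchor = argOr(a, "anchor", "tss"),
                           bin_size = argOr(a, "bin_size", 10))
  reg$sites_vs_numeric <- function(repo, a, seed)
    sitesVsNumeric(a$motif_track, a$feature)
  reg$result_column <- function(repo, a, seed)
    resultColumnAsMap(a$result, a$column, memberType = argOr(a, "member_type", "motif"))
  reg$rank_sum <- function(repo, a, seed) {
    maps <- if (is.list(a$maps)) a$maps else list(a$maps)
    dirs <- if (is.list(a$directions)) unlist(a$directions) else a$directions
    rankSum(maps, dirs)
  }
  reg$collate <- function(repo, a, seed) {
    results <- if (is.list(a$analyses)) a$analyses else list(a$analyses)
    entries <- lapply(results, function(r) list(result = r, columns = NULL))
    sortBy <- if (!is.null(a$sort_labels))
      list(labels = if (is.list(a$sort_labels)) unlist(a$sort_labels) else a$sort_labels,
           directions = if (is.list(a$sort_directions)) unlist(a$sort_directions) else a$sort_directions)
    collateAnalyses(entries, sortBy = sortBy, name = a$.target)
  }
  reg$benchmark_stats <- function(repo, a, seed)
    benchmarkStats(a$predicted, a$answer,
                   site_overlap_fraction = argOr(a, "fraction", 0.25))
  reg
}

.registryEnv <- new.env(parent = emptyenv())

getRegistry <- function() {
  if (is.null(.registryEnv$reg)) .registryEnv$reg <- protocolRegistry()
  .registryEnv$reg
}

executeStatement <- function(repo, st, seed) {
  reg <- getRegistry()
  fn <- reg[[st$op]]
  if (is.null(fn)) stop(sprintf("unknown operation '%s'", st$op))
  args <- lapply(st$args, resolveValue, repo = repo)
  ## an explicit seed=... argument (as recorded from interactive sessions)
  ## overrides the derived per-statement seed, so replays reproduce sessions
  if (!is.null(args$seed)) {
    seed <- as.integer(args$seed)
    args$seed <- NULL
  }
  args$.where <- st$where
  args$.target <- st$target
  fn(repo, args, seed)
}

#' Execute a protocol script
#'
#' Statements run in order on a copy of the repository; each result is
#' stored under its target name. A single master seed deterministically
#' derives per-statement seeds (hash of statement index and target name),
#' so the same script and seed reproduce every output bit-identically,
#' including background-sampled sequences. Any error aborts the whole run
#' with the failing line identified; the input repository is left untouched.
#'
#' @param script a [ProtocolScript] or protocol source text.
#' @param repo the input repository (not mutated).
#' @param seed integer master seed.
#' @param log optional file to append a run log to.
#' @return the resulting repository.
#' @export
executeProtocol <- function(script, repo, seed = 1L, log = NULL) {
  if (!is(script, "ProtocolScript")) script <- parseProtocol(script)
  work <- repoClone(repo)
  logLines <- character()
  for (i in seq_along(script@statements)) {
    st <- script@statements[[i]]
    sSeed <- statementSeed(seed, i, st$target)
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(executeStatement(work, st, sSeed),
      error = function(e) stop(sprintf("protocol aborted at line %d (%s = %s ...): %s",
                                       st$line, st$target, st$op, conditionMessage(e)),
                               call. = FALSE))
    suppressWarnings(repoPut(work, st$target, value))
    logLines <- c(logLines, sprintf("line %d: %s = %s [%s] (%.3fs, seed %d)",
                                    st$line, st$target, st$op,
                                    paste(names(st$args), unlist(st$args), sep = "=", collapse = " "),
                                    proc.time()[["elapsed"]] - t0, sSeed))
  }
  work$log <- c(work$log, logLines)
  if (!is.null(log)) writeLines(logLines, log)
  work
}

#' Start or stop protocol recording on a repository
#'
#' Between start and stop, every operation performed through
#' [performStep()] is appended as a canonical protocol statement. `stop`
#' returns the recorded script text.
#'
#' @param repo a repository.
#' @param switch `"start"` or `"stop"`.
#' @return for `"stop"`, the protocol text (character vector); otherwise
#'   invisible `NULL`.
#' @export
recordProtocol <- function(repo, switch = c("start", "stop")) {
  switch <- match.arg(switch)
  if (switch == "start") {
    repo$recording <- TRUE
    repo$recorded <- character()
    return(invisible(NULL))
  }
  if (!repo$recording) stop("recording was never started")
  repo$recording <- FALSE
  repo$recorded
}

#' Perform one operation against the repository (recordable)
#'
#' Executes the named operation with the given arguments (argument values
#' are literals or names of repository objects), stores the result under
#' `target`, and — when recording is active — appends the canonical
#' protocol statement. This is the programmatic twin of one protocol line.
#'
#' @param repo a repository.
#' @param target name to store the result under.
#' @param op operation name (protocol vocabulary, e.g. `"scan_motifs"`).
#' @param ... named arguments; character values naming repository objects
#'   are passed as references.
#' @param where optional condition text.
#' @param seed integer seed for stochastic operations.
#' @return the result, invisibly.
#' @export
performStep <- function(repo, target, op, ..., where = NULL, seed = NULL) {
  rawArgs <- list(...)
  if (!is.null(seed)) rawArgs$seed <- as.integer(seed)
  argTexts <- lapply(rawArgs, unparseValue, repo = repo)
  st <- list(target = target, op = op, args = argTexts, where = where, line = NA_integer_)
  value <- executeStatement(repo, st, if (is.null(seed)) 0L else as.integer(seed))
  suppressWarnings(repoPut(repo, target, value))
  if (isTRUE(repo$recording))
    repo$recorded <- c(repo$recorded, serializeProtocol(
      new("ProtocolScript", statements = list(st), source = character())))
  invisible(value)
}

## --------------------------- external tool adapter -------------------------

#' Load and validate an external-tool configuration
#'
#' The XML document declares the command template (with `{placeholder}`
#' substitution), typed input and output file slots, and a parameter
#' schema. Every placeholder must be bound by a declared slot or parameter,
#' and slot formats must be ones the track readers/writers understand.
#'
#' @param path XML file (or a string of XML).
#' @return a tool config (list with `name`, `command`, `inputs`, `outputs`,
#'   `params`).
#' @export
loadToolConfig <- function(path) {
  doc <- xml2::read_xml(path)
  name <- xml2::xml_attr(doc, "name")
  command <- xml2::xml_text(xml2::xml_find_first(doc, "./command"))
  getSlots <- function(xp) {
    nodes <- xml2::xml_find_all(doc, xp)
    lapply(nodes, function(n) list(name = xml2::xml_attr(n, "name"),
                                   type = xml2::xml_attr(n, "type"),
                                   format = xml2::xml_attr(n, "format")))
  }
  inputs <- getSlots("./input")
  outputs <- getSlots("./output")
  params <- lapply(xml2::xml_find_all(doc, "./param"), function(n)
    list(name = xml2::xml_attr(n, "name"), type = xml2::xml_attr(n, "type"),
         default = xml2::xml_attr(n, "default")))
  placeholders <- unique(gsub("[{}]", "", regmatches(command, gregexpr("\\{[^}]+\\}", command))[[1]]))
  declared <- c(vapply(inputs, `[[`, "", "name"), vapply(outputs, `[[`, "", "name"),
                vapply(params, `[[`, "", "name"))
  unbound <- setdiff(placeholders, declared)
  if (length(unbound))
    stop(sprintf("tool config '%s': unbound placeholder(s): %s", name,
                 paste(unbound, collapse = ", ")))
  okFormats <- c("fasta", "gff", "bed", "wig", "bedgraph", "psp")
  for (s in c(inputs, outputs)) {
    if (!s$format %in% okFormats)
      stop(sprintf("tool config '%s': unsupported slot format '%s'", name, s$format))
  }
  list(name = name, command = command, inputs = inputs, outputs = outputs, params = params)
}

#' Run an external program through the generic adapter
#'
#' Serializes the inputs to their declared formats in `workdir`, substitutes
#' file paths and parameter values into the command template, executes it,
#' and parses the declared outputs back into data objects. The executable
#' must resolve before any file is written; a nonzero exit (or unparseable
#' output) raises an error carrying the captured diagnostics.
#'
#' @param config a tool config from [loadToolConfig()].
#' @param inputs named list of data objects matching the declared input
#'   slots.
#' @param params named list of parameter values (declared defaults fill the
#'   gaps).
#' @param workdir working directory for the exchange files.
#' @param sequences the [SequenceSet] used to serialize and parse tracks.
#' @return named list of parsed output objects.
#' @export
runExternalTool <- function(config, inputs, params = list(), workdir, sequences) {
  exe <- strsplit(trimws(config$command), "[ \t]")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe))
    stop(sprintf("external tool executable '%s' not found", exe))
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  subst <- list()
  for (s in config$inputs) {
    obj <- inputs[[s$name]]
    if (is.null(obj)) stop(sprintf("missing input '%s'", s$name))
    path <- file.path(workdir, sprintf("%s.%s", s$name, s$format))
    if (s$format == "psp") exportPriors(obj, path)
    else writeTrack(obj, path, format = s$format, sequences = sequences)
    subst[[s$name]] <- path
  }
  outPaths <- list()
  for (s in config$outputs) {
    path <- file.path(workdir, sprintf("%s.%s", s$name, s$format))
    subst[[s$name]] <- path
    outPaths[[s$name]] <- s
  }
  for (p in config$params) {
    v <- params[[p$name]]
    if (is.null(v)) v <- p$default
    if (is.null(v) || is.na(v)) stop(sprintf("missing parameter '%s'", p$name))
    subst[[p$name]] <- as.character(v)
  }
  cmd <- config$command
  for (k in names(subst)) cmd <- gsub(sprintf("{%s}", k), subst[[k]], cmd, fixed = TRUE)
  parts <- strsplit(trimws(cmd), "[ \t]+")[[1]]
  out <- suppressWarnings(system2(parts[1], parts[-1], stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop(sprintf("external tool '%s' exited with status %d; output:\n%s",
                 config$name, status, paste(out, collapse = "\n")))
  results <- list()
  for (nm in names(outPaths)) {
    s <- outPaths[[nm]]
    path <- subst[[nm]]
    if (!file.exists(path))
      stop(sprintf("external tool '%s' did not produce declared output '%s'; output:\n%s",
                   config$name, nm, paste(out, collapse = "\n")))
    results[[nm]] <- tryCatch({
      if (s$format == "psp") readPriors(path)
      else readTrack(path, format = s$format, sequences = sequences)
    }, error = function(e)
      stop(sprintf("external tool '%s': cannot parse output '%s': %s; tool output:\n%s",
                   config$name, nm, conditionMessage(e), paste(out, collapse = "\n")),
           call. = FALSE))
  }
  results
}
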