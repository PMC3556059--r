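## Positional priors: normalization, discriminative conversion, trainable
## Priors Generators (per-position classifiers over windowed feature values)
## and priors merit evaluation via ROC/AUC.

#' Rescale a numeric track into a priors track
#'
#' Min-max rescales to [0,1] over all sequences jointly. A constant track
#' maps to 0.5 everywhere, with a warning.
#'
#' @param track a [NumericTrack].
#' @return a [NumericTrack] with values in [0,1].
#' @export
normalizePriors <- function(track) {
  stopifnot(is(track, "NumericTrack"))
  all <- unlist(track@values, use.names = FALSE)
  mn <- min(all); mx <- max(all)
  if (mx == mn) {
    warning("constant track: priors set to 0.5 everywhere")
    out <- lapply(track@values, function(v) rep(0.5, length(v)))
  } else {
    out <- lapply(track@values, function(v) (v - mn) / (mx - mn))
  }
  names(out) <- names(track@values)
  numericTrack(out)
}

#' Convert a priors track into a discriminative prior
#'
#' Applies the odds correction d = p(1-q) / (p(1-q) + q(1-p)) against the
#' control expectation q, so that positions at the control level map to 0.5,
#' 0 and 1 are fixed points, and the transform is order-preserving.
#'
#' @param priors a [NumericTrack] with values in [0,1].
#' @param control_mean the control expectation q in (0,1): a constant, or a
#'   [NumericTrack] over control sequences whose grand mean is used.
#' @return a [NumericTrack] with values in [0,1].
#' @export
discriminativePrior <- function(priors, control_mean) {
  stopifnot(is(priors, "NumericTrack"))
  q <- if (is(control_mean, "NumericTrack")) mean(unlist(control_mean@values)) else control_mean
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("control mean must lie strictly inside (0,1)")
  rng <- range(unlist(priors@values))
  if (rng[1] < 0 || rng[2] > 1) stop("priors values must lie in [0,1]")
  out <- lapply(priors@values, function(p) p * (1 - q) / (p * (1 - q) + q * (1 - p)))
  names(out) <- names(priors@values)
  numericTrack(out)
}

## Feature design matrix: one row per position, one column per
## (feature, window) pair, built from centered-window means.
priorsDesignMatrix <- function(features, windows, seqnames) {
  cols <- list()
  for (f in names(features)) {
    for (w in windows) {
      sm <- if (w == 1L) features[[f]] else slidingWindow(features[[f]], "mean", w)
      cols[[sprintf("%s.w%d", f, w)]] <- unlist(sm@values[seqnames], use.names = FALSE)
    }
  }
  do.call(cbind, cols)
}

positionLabels <- function(answer, seqnames) {
  unlist(lapply(seqnames, function(nm) coverageVector(answer, nm) > 0L), use.names = FALSE)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

## Forward pass over nnet-ordered weights (single hidden layer, logistic out).
netForward <- function(net, x) {
  nIn <- net$n_in; H <- net$size
  wts <- net$wts
  hidden <- matrix(0, nrow = nrow(x), ncol = H)
  for (h in seq_len(H)) {
    off <- (h - 1L) * (nIn + 1L)
    hidden[, h] <- sigmoid(wts[off + 1L] + x %*% wts[(off + 2L):(off + nIn + 1L)])
  }
  off <- H * (nIn + 1L)
  as.numeric(sigmoid(wts[off + 1L] + hidden %*% wts[(off + 2L):(off + H + 1L)]))
}

#' Train a Priors Generator
#'
#' Builds a per-position training set from the feature tracks (feature
#' vector = centered-window means of every feature at every configured
#' window size, min-max normalized with parameters kept from training),
#' labels positions by membership in the answer-site track, subsamples
#' negatives to the configured positive:negative ratio, and fits the
#' classifier to output a binding-site probability. The wizard flow (select
#' target, select inputs, build training set, train, save) is this one call
#' plus [savePriorsGenerator()].
#'
#' @param features named list of [NumericTrack]s.
#' @param target a [RegionTrack] of answer binding sites.
#' @param trainingSequences optional [Collection] or character vector
#'   restricting the training sequences (default: all).
#' @param windows centered window sizes in bp (default `c(1, 11, 101)`:
#'   point, local and broad context).
#' @param negativeRatio negatives sampled per positive (default 1).
#' @param hidden hidden units of the feed-forward classifier (default 8).
#' @param maxit training epochs cap (default 500; convergence tolerance 1e-4).
#' @param decay L2 weight decay of the network (default 1e-3; a little
#'   regularization keeps isolated fits from collapsing into poor optima).
#' @param seed integer seed (required; governs subsampling and weight init).
#' @return a [PriorsGenerator].
#' @export
trainPriorsGenerator <- function(features, target, trainingSequences = NULL,
                                 windows = c(1L, 11L, 101L), negativeRatio = 1,
                                 hidden = 8L, maxit = 500L, decay = 1e-3, seed = NULL) {
  if (is.null(seed)) stop("training requires a seed")
  if (length(features) == 0L || is.null(names(features))) stop("features must be a named list")
  seqnames <- if (is.null(trainingSequences)) names(features[[1]]@values)
    else if (is(trainingSequences, "Collection")) members(trainingSequences)
    else as.character(trainingSequences)
  X <- priorsDesignMatrix(features, as.integer(windows), seqnames)
  y <- positionLabels(target, seqnames)
  if (!any(y)) stop("no positive positions: the target track is empty on the training sequences")
  norm <- data.frame(min = apply(X, 2, min), max = apply(X, 2, max))
  Xn <- normalizeColumns(X, norm)
  pos <- which(y); neg <- which(!y)
  withSeed(seed, {
    nNeg <- min(length(neg), ceiling(length(pos) * negativeRatio))
    negSel <- sample(neg, nNeg)
    sel <- c(pos, negSel)
    fit <- nnet::nnet(Xn[sel, , drop = FALSE], as.numeric(y[sel]), size = hidden,
                      entropy = TRUE, maxit = maxit, abstol = 1e-4, decay = decay,
                      trace = FALSE)
    new("PriorsGenerator",
        features = names(features), windows = as.integer(windows), norm = norm,
        net = list(size = as.integer(hidden), n_in = ncol(Xn), wts = as.numeric(fit$wts)),
        meta = list(seed = as.integer(seed), n_pos = length(pos), n_neg = nNeg,
                    positive_fraction = length(pos) / (length(pos) + nNeg)))
  })
}

normalizeColumns <- function(X, norm) {
  for (j in seq_len(ncol(X))) {
    mn <- norm$min[j]; mx <- norm$max[j]
    X[, j] <- if (mx == mn) rep(0.5, nrow(X)) else pmin(1, pmax(0, (X[, j] - mn) / (mx - mn)))
  }
  X
}

#' Apply a Priors Generator to feature tracks
#'
#' @param pg a [PriorsGenerator].
#' @param features named list of [NumericTrack]s; must include every feature
#'   the generator was trained on.
#' @return a [NumericTrack] of per-position probabilities in [0,1].
#' @export
applyPriorsGenerator <- function(pg, features) {
  missing <- setdiff(pg@features, names(features))
  if (length(missing))
    stop(sprintf("missing input feature(s): %s", paste(missing, collapse = ", ")))
  seqnames <- names(features[[pg@features[1]]]@values)
  X <- priorsDesignMatrix(features[pg@features], pg@windows, seqnames)
  Xn <- normalizeColumns(X, pg@norm)
  p <- netForward(pg@net, Xn)
  lens <- features[[pg@features[1]]]@seqlengths
  out <- list()
  off <- 0L
  for (nm in seqnames) {
    out[[nm]] <- p[(off + 1L):(off + lens[[nm]])]
    off <- off + lens[[nm]]
  }
  numericTrack(out)
}

#' Serialize a Priors Generator to a self-contained JSON file
#'
#' The file holds the feature list, window sizes, normalization parameters,
#' classifier weights and training metadata; [loadPriorsGenerator()]
#' restores a generator producing bit-identical outputs.
#'
#' @param pg a [PriorsGenerator].
#' @param path output file.
#' @return the path, invisibly.
#' @export
savePriorsGenerator <- function(pg, path) {
  ## doubles stored as C99 hex-float strings so reload is bit-exact
  obj <- list(features = pg@features, windows = pg@windows,
              norm_min = sprintf("%a", pg@norm$min), norm_max = sprintf("%a", pg@norm$max),
              net_size = pg@net$size, net_n_in = pg@net$n_in,
              net_wts = sprintf("%a", pg@net$wts),
              meta = pg@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a Priors Generator saved with [savePriorsGenerator()]
#' @param path input file.
#' @return a [PriorsGenerator].
#' @export
loadPriorsGenerator <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PriorsGenerator",
      features = obj$features, windows = as.integer(obj$windows),
      norm = data.frame(min = as.numeric(obj$norm_min), max = as.numeric(obj$norm_max)),
      net = list(size = as.integer(obj$net_size), n_in = as.integer(obj$net_n_in),
                 wts = as.numeric(obj$net_wts)),
      meta = as.list(obj$meta))
}

#' Evaluate how well a track separates binding-site positions
#'
#' Labels every position (inside any answer region = positive) and computes
#' the ROC curve and the area under it. The AUC uses the rank (Mann-Whitney)
#' formula with midrank tie correction, so a constant track scores exactly
#' 0.5.
#'
#' @param priors a [NumericTrack] (priors or any per-position score).
#' @param answer a non-empty [RegionTrack] of true sites.
#' @return list with `auc` and `roc_points` (data.frame of threshold, fpr,
#'   tpr at every distinct score).
#' @export
evaluatePriors <- function(priors, answer) {
  stopifnot(is(priors, "NumericTrack"), is(answer, "RegionTrack"))
  seqnames <- names(priors@values)
  scores <- unlist(priors@values, use.names = FALSE)
  labels <- positionLabels(answer, seqnames)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("evaluation needs both positive and negative positions")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  ## ROC points at every distinct threshold (descending)
  ord <- order(scores, decreasing = TRUE)
  sSorted <- scores[ord]; lSorted <- labels[ord]
  cumTP <- cumsum(lSorted); cumFP <- cumsum(!lSorted)
  lastOfValue <- !duplicated(sSorted, fromLast = TRUE)
  roc <- data.frame(threshold = sSorted[lastOfValue],
                    fpr = cumFP[lastOfValue] / nNeg,
                    tpr = cumTP[lastOfValue] / nPos)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  rownames(roc) <- NULL
  list(auc = auc, roc_points = roc)
}
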