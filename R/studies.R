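## Desk-scale evaluation studies bundled with the package: replicated
## leave-one-dataset-out training of Priors Generators, module-candidate
## filtering versus matched random filtering, and a complete promoter
## overrepresentation protocol. They mirror the classic workbench use cases
## on synthetic planted data so the whole pipeline can be exercised and
## benchmarked end to end without external data.

studyMotif <- function(id, seed, width = 8, sharpness = 1) {
  withSeed(seed, {
    m <- matrix(stats::runif(4 * width, 0.02, 1), 4, width,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m <- m^sharpness
    motif(id, sweep(m, 2, colSums(m), "/"))
  })
}

## Concatenate several planted datasets into one feature set + answer track
## with dataset-prefixed sequence names.
mergePlantedDatasets <- function(dsets, idx) {
  featureNames <- names(dsets[[1]]$features)
  feats <- stats::setNames(rep(list(list()), length(featureNames)), featureNames)
  ans <- list(); lens <- integer()
  for (k in idx) {
    d <- dsets[[k]]
    for (nm in seqNames(d$dna)) {
      new <- sprintf("d%d_%s", k, nm)
      for (f in featureNames) feats[[f]][[new]] <- d$features[[f]]@values[[nm]]
      ans[[new]] <- d$answer@regions[[nm]]
      lens[[new]] <- d$dna@seqlengths[[nm]]
    }
  }
  list(features = lapply(feats, numericTrack), answer = regionTrack(ans, lens))
}

#' Replicated leave-one-dataset-out Priors Generator study
#'
#' Generates `nDatasets` planted-motif datasets, each carrying two
#' informative synthetic features (informativeness 0.8 and 0.5) and one pure
#' noise feature. Each replicate trains a Priors Generator on all datasets
#' but one and evaluates on the held-out one, comparing the generator's
#' AUC with the best single input feature's AUC on the same held-out data.
#'
#' @param seed master seed; dataset seeds and per-replicate training seeds
#'   derive from it.
#' @param nReplicates number of independently seeded generators (default 20).
#' @param nDatasets number of planted datasets (default 6).
#' @param nSequences,length dataset dimensions (default 8 sequences of 300 bp).
#' @return data.frame with one row per replicate: held-out dataset index,
#'   generator AUC, best single-feature AUC, and whether the generator won.
#' @export
priorsRecoveryStudy <- function(seed, nReplicates = 20, nDatasets = 6,
                                nSequences = 8, length = 300) {
  tf <- studyMotif("TF", seed * 17 + 3, width = 8, sharpness = 6)
  dsets <- lapply(seq_len(nDatasets), function(i) generatePlantedDataset(plantSpec(
    n_sequences = nSequences, length = length, motif = tf, sites_per_seq = 2,
    features = c(informative = 0.8, weak = 0.5, noise = 0),
    seed = (seed * 1000 + i) %% 2147483647)))
  rows <- lapply(seq_len(nReplicates), function(r) {
    held <- ((r - 1) %% nDatasets) + 1
    train <- mergePlantedDatasets(dsets, setdiff(seq_len(nDatasets), held))
    test <- mergePlantedDatasets(dsets, held)
    pg <- trainPriorsGenerator(train$features, train$answer,
                               windows = c(1L, 11L), hidden = 8L, maxit = 300L,
                               seed = (seed * 100 + r) %% 2147483647)
    priors <- applyPriorsGenerator(pg, test$features)
    aucGen <- evaluatePriors(priors, test$answer)$auc
    aucSingle <- max(vapply(test$features, function(f)
      evaluatePriors(f, test$answer)$auc, 0))
    data.frame(replicate = r, held_out = held, auc_generator = aucGen,
               auc_best_feature = aucSingle, win = aucGen > aucSingle)
  })
  do.call(rbind, rows)
}

removeRandomRegions <- function(track, nRemove, seed) {
  withSeed(seed, {
    total <- regionCount(track)
    drop <- sample(total, min(nRemove, total))
    keep <- list(); offset <- 0L
    for (nm in names(track@regions)) {
      df <- track@regions[[nm]]
      keep[[nm]] <- df[!(seq_len(nrow(df)) + offset) %in% drop, , drop = FALSE]
      offset <- offset + nrow(df)
    }
    regionTrack(keep, track@seqlengths)
  })
}

#' Module-candidate filtering study
#'
#' For each seeded run, plants motif-pair modules (gap 3-8 bp), produces a
#' sensitive candidate site set by scanning both motifs at relative score
#' 0.8, and scans for modules under a permissive model (gap up to 30 bp).
#' The nucleotide-level Matthews correlation of the module predictions
#' against the planted module answer is compared across candidate sets:
#' unfiltered, filtered by site-average feature value (>= 0.5), filtered by
#' interaction partners within `interactionGap` bp, and a random filter
#' matched to the interaction filter's removal count.
#'
#' @param seed master seed.
#' @param nRuns number of seeded runs (default 10).
#' @param interactionGap partner distance for the interaction filter
#'   (default 10 bp; 20 is the relaxed regime).
#' @return data.frame with per-run CC values for each candidate set.
#' @export
moduleFilteringStudy <- function(seed, nRuns = 10, interactionGap = 10) {
  rows <- lapply(seq_len(nRuns), function(run) {
    s <- (seed * 100 + run) %% 2147483647
    mA <- studyMotif("A", s + 7, width = 8, sharpness = 8)
    mB <- studyMotif("B", s + 13, width = 8, sharpness = 8)
    spec <- plantSpec(n_sequences = 8, length = 400, motif = mA, sites_per_seq = 1,
                      strand_prob = 1, features = c(cons = 0.9), seed = s)
    b <- generateModuleDataset(spec, mB, gap_law = list(kind = "uniform", min = 3, max = 8))
    sites <- scanMotifs(b$dna, motifSet(list(mA, mB)), threshold = 0.8)
    model <- moduleModel("mod", list("A", "B"), ordered = TRUE,
                         gaps = data.frame(min = 0, max = 30), maxSpan = 60)
    ccOf <- function(cand) benchmarkStats(scanModules(cand, model), b$module_answer)$CC
    byFeature <- filterRegions(sites, "avg(cons) >= 0.5",
                               tracks = list(cons = b$features$cons))
    byPartner <- interactionFilter(sites, list(A = "B", B = "A"), interactionGap)
    nRemoved <- regionCount(sites) - regionCount(byPartner)
    random <- removeRandomRegions(sites, nRemoved, seed = s + 999)
    data.frame(run = run, candidates = regionCount(sites),
               cc_baseline = ccOf(sites), cc_feature_filter = ccOf(byFeature),
               cc_interaction_filter = ccOf(byPartner), cc_random_filter = ccOf(random))
  })
  do.call(rbind, rows)
}

#' Build a demo promoter-analysis repository and protocol
#'
#' Assembles a planted-motif promoter dataset (TSS at the sequence end), a
#' five-motif library containing the planted motif, and a conservation-like
#' feature track, together with a complete protocol script: train a
#' background model, sample control sequences, scan target and control,
#' derive expected per-bp motif frequencies from the control counts, test
#' overrepresentation with Bonferroni correction, analyse positional
#' distribution (kurtosis) and site conservation, combine the three
#' criteria by rank sum, and collate everything into one report.
#'
#' @param seed seed for the synthetic inputs.
#' @param nSequences,length dataset dimensions.
#' @return list with `repo` (the prepared repository) and `protocol`
#'   (character vector of protocol lines).
#' @export
promoterStudyDemo <- function(seed, nSequences = 10, length = 400) {
  ## consensus-dominant motifs: one preferred base per column at 0.85
  peakyMotif <- function(id, s, width = 8) {
    withSeed(s, {
      m <- matrix(0.05, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
      picks <- sample(4, width, replace = TRUE)
      for (j in seq_len(width)) m[picks[j], j] <- 0.85
      motif(id, m)
    })
  }
  planted <- peakyMotif("TF_planted", seed + 29)
  decoys <- lapply(1:4, function(i) peakyMotif(sprintf("TF_decoy%d", i), seed + 31 * i))
  b <- generatePlantedDataset(plantSpec(
    n_sequences = nSequences, length = length, motif = planted, sites_per_seq = 2,
    position_law = list(kind = "gaussian", center = -80, sd = 25),
    features = c(cons = 0.9), seed = seed))
  repo <- newRepository()
  repoPut(repo, "seqs", b$sequences)
  repoPut(repo, "dna", b$dna)
  repoPut(repo, "cons", b$features$cons)
  repoPut(repo, "lib", motifSet(c(list(planted), decoys)))
  totalBp <- sum(seqLengths(b$dna))
  protocol <- c(
    "# promoter overrepresentation analysis",
    "bg = train_background dna=dna order=2",
    "ctrl = sample_background model=bg like=dna",
    "sites = scan_motifs dna=dna motifs=lib threshold=0.8 background=bg",
    "ctrl_sites = scan_motifs dna=ctrl motifs=lib threshold=0.8 background=bg",
    "counts = count_motif_occurrences motif_track=sites",
    "ctrl_counts = count_motif_occurrences motif_track=ctrl_sites",
    "ctrl_totals = result_column result=ctrl_counts column=total",
    sprintf("exp_freq = map_arithmetic map=ctrl_totals op=div operand=%d", totalBp),
    sprintf("over = overrepresentation counts=counts expected_freq=exp_freq total_bp=%d alpha=0.05 correction=bonferroni", totalBp),
    "pos = positional_distribution motif_track=sites sequences=seqs anchor=tss bin_size=50",
    "cons_by_motif = sites_vs_numeric motif_track=sites feature=cons",
    "p_map = result_column result=over column=p_value",
    "cons_map = result_column result=cons_by_motif column=mean",
    "kurt_map = result_column result=pos column=kurtosis",
    "ranks = rank_sum maps=p_map,cons_map,kurt_map directions=ascending,descending,descending",
    "report = collate analyses=counts,over,cons_by_motif,pos sort_labels=p_value,mean,kurtosis sort_directions=ascending,descending,descending")
  list(repo = repo, protocol = protocol, planted = b, total_bp = totalBp)
}
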