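# regulab

A scriptable R workbench for regulatory sequence analysis: predicting
transcription factor binding sites and cis-regulatory modules in promoter
regions, and — crucially — integrating the additional evidence (phylogenetic
conservation, DNase accessibility, ChIP peaks, repeats, expression-derived
groupings) that separates functional sites from the sea of spurious motif
matches. It is aimed at computational biologists who want the feature-track
algebra, scanning machinery, positional-priors construction and statistical
reporting of a motif-discovery workbench as a programmable library with a
reproducible batch mode.

## What is inside

* **Feature-track data model** — genomic `SequenceSet`s annotated with DNA,
  numeric and region tracks (0-based half-open coordinates, strand-aware
  operations, open region property maps, module occurrences with child
  sites), plus motifs, module models, collections, partitions, numeric maps
  and a named object repository.
* **Condition-driven operations** — mask (letters or seeded background
  fill), filter/extend/merge regions, track arithmetic, sliding windows,
  weighted track combination, thresholded runs, coverage conversion, all
  accepting Boolean conditions such as
  `avg(conservation) >= 0.3 and not overlaps(repeats)`.
* **Native scanning** — PWM scanning on both strands against order-k Markov
  background models with the min-max normalized log-odds *relative match
  score* (r in [0, 1]; an "80% match" threshold is `r >= 0.8`):

      S = sum_i log( M[b_i, i] / Q(b_i) ),    r = (S - S_min) / (S_max - S_min)

  plus IUPAC consensus matching, motif construction from aligned sites, and
  per-position best-strand score profiles.
* **Positional priors** — min-max priors tracks, the discriminative odds
  correction `d = p(1-q) / (p(1-q) + q(1-p))`, and trainable **Priors
  Generators**: per-position classifiers (single-hidden-layer network over
  windowed feature means) mapping evidence tracks to binding-site
  probabilities, with bit-exact serialization and ROC/AUC merit evaluation.
* **Module scanning** — slot-based module models (alternative motifs per
  slot, span/order/orientation constraints, nearest-edge gap bounds), plus
  interaction-partner filtering of candidate sites.
* **Statistics & benchmarks** — occurrence counts, exact binomial
  overrepresentation with Bonferroni correction, Fisher group comparison,
  positional distributions with kurtosis, site-conservation averages,
  rank-sum combination, meta-analysis collation, HTML/TSV reports, and
  nucleotide/site-level benchmark metrics (Sn, Sp, PPV, Acc, PC, ASP, F,
  Matthews CC, sSn at a 25% site-overlap rule).
* **Protocol scripts** — a linear, recordable workflow language with seeded
  replay determinism, a batch CLI (`inst/cli/regulab.R`), and a generic
  XML-configured adapter for external motif-discovery programs.
* **Synthetic fixtures** — planted-motif and planted-module dataset
  generators with exact answer keys and tunable-informativeness feature
  tracks, so every stage is testable without external data.

## Worked example

Plant a motif into synthetic promoters with a conservation-like feature,
scan sensitively, and rescue precision with a conservation filter:

```r
library(regulab)

tf <- motif("TF1", local({                      # consensus ACTGAAGC
  m <- matrix(0.04, 4, 8, dimnames = list(c("A","C","G","T"), NULL))
  picks <- c(1,2,4,3,1,1,3,2)
  for (j in 1:8) m[picks[j], j] <- 0.88
  m
}))

b <- generatePlantedDataset(plantSpec(
  n_sequences = 12, length = 500, motif = tf, sites_per_seq = 2,
  position_law = list(kind = "gaussian", center = -100, sd = 30),
  features = c(conservation = 0.9), seed = 42))

hits <- scanMotifs(b$dna, motifSet(list(tf)), threshold = 0.8)
kept <- filterRegions(hits, "avg(conservation) >= 0.5",
                      tracks = list(conservation = b$features$conservation))

regionCount(hits); regionCount(kept)
benchmarkStats(hits, b$answer)$CC; benchmarkStats(kept, b$answer)$CC
```

This prints 20 candidate sites, 16 after filtering, and:

```
unfiltered: Sn=0.667 PPV=0.800 CC=0.722 sSn=0.667
filtered:   Sn=0.667 PPV=1.000 CC=0.812 sSn=0.667
```

The filter removed exactly the four false positives (PPV 0.80 → 1.00,
Matthews CC 0.72 → 0.81) without losing a single true site — the core
workbench idea: sequence matches plus independent evidence beat sequence
matches alone. The same workflow as a protocol script:

```
sites = scan_motifs dna=dna motifs=lib threshold=0.8
kept  = filter_regions track=sites where avg(conservation) >= 0.5
```

runs in batch via
`Rscript inst/cli/regulab.R run my.protocol --data-dir data/ --out out/ --seed 7`.

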