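---
title: "regulab: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regulab: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulab)
```

# The data model

regulab analyses *regulatory sequence regions*: genomic segments (typically
promoters) annotated with evidence tracks. A `SequenceSet` anchors each
sequence on a genome build (chromosome, 0-based half-open genomic
coordinates, strand, optional TSS offset). Feature tracks carry the
evidence: `DNATrack` (one base letter per position, always stored in genomic
forward orientation), `NumericTrack` (one finite value per position —
conservation, DNase signal, priors), and `RegionTrack` (interval
annotations — repeats, CpG islands, ChIP peaks, predicted binding sites).
Region tracks whose region types are motif or module identifiers are motif
and module tracks. Regions may overlap, carry a score, a strand, an open
property map, and child regions (module occurrences list their member sites
as children).

All internal coordinates are 0-based half-open on the forward strand;
strand-awareness is applied inside individual operations. The GFF reader and
writer translate to and from 1-based inclusive coordinates; BED and bedGraph
are 0-based half-open, as the formats prescribe. Chromosome matching between
genomic records and sequences is exact string equality — aliasing
(`chr1` vs `1`) is deliberately left to the caller so that file mapping
stays deterministic.

A session's objects live in a *repository* keyed by unique identifiers.
Every operation is pure: inputs are never mutated, and stochastic
operations demand an explicit seed.

# Motif scanning

A motif is a 4 x w column-stochastic position frequency matrix. Count
matrices read from JASPAR or TRANSFAC files get a pseudocount of 0.25 per
cell before normalization; probability matrices (MEME minimal format) get
0.01 and are renormalized. The IUPAC consensus of a matrix takes, per
column, the degeneracy code covering every base with frequency at least
0.25 (ties resolve toward the smaller degeneracy class; if no base reaches
0.25 the single most frequent base is used).

A window $b_1..b_w$ scores
$$S = \sum_{i=1}^{w} \log \frac{M[b_i, i]}{Q(b_i)},$$
where $Q$ is the order-0 view of the background model. The *relative match
score* rescales $S$ by the motif's achievable range,
$$r = \frac{S - S_\min}{S_\max - S_\min},$$
so that $r \in [0,1]$ and the consensus-best window scores exactly 1. A
threshold of 0.8 ("80% match") is the conventional sensitive setting. This
min-max normalized log-odds convention was chosen over raw-probability
normalization because it is the one under which an 80% threshold behaves as
a sensitive scan; the background enters only through $Q$, so $r$ is
invariant under rescaling matrix columns. Probabilities are floored at
1e-6 inside the scorer so hard (zero-containing) matrices still score
finitely. Non-ACGT letters (N, X) contribute 0 to $S$ — the background
expectation in log-odds terms — which treats masked or unknown bases
neutrally rather than penalizing or rewarding them.

Both strands are scanned by scoring the reverse complement and reporting
hits in forward coordinates; overlapping hits and double-strand hits are
all kept. `pwmScoreProfile()` exposes the per-position best-strand relative
score as a numeric track so conditions and priors can consume it; a motif
whose achievable score range is empty (all columns uniform) yields an
all-zero profile with a warning rather than an error, because such motifs
legitimately arise from degenerate inputs.

# Background models

`trainBackground()` fits an order-k Markov chain (k at most 5) on the
forward strand only, with a +1 pseudocount per context cell and lower-order
fallback tables for sequence starts. Windows containing non-ACGT letters
are skipped during training. Sampling (`sampleBackground()`) draws the
first k bases from the fallback tables and is fully determined by its
seed. The same fallback logic serves the masking operation: when a
background model fills masked positions, each draw conditions on the
(possibly already masked) preceding context, trimmed at the first non-ACGT
letter.

# Conditions and track operations

Operations accept *conditions*: Boolean expressions over per-position
predicates (numeric-track comparisons against constants, other tracks or
per-sequence map values; `inside(regionTrack)`; `base(dna) in {A,C}`) or
per-region predicates (`length`, `score`, `type`, `overlaps(track)`,
`avg(track)` over the region's half-open span,
`distance_to_nearest(track)`). `distance_to_nearest` measures nearest-edge
gaps and reports 0 for overlapping regions — matching the semantics of the
interaction filter. Mixing position and region predicates in one context is
a type error, caught at evaluation.

Sliding windows are centered, odd-sized, and *clipped* (shrunk) at sequence
edges rather than padded, so no values are invented. Region merging unions
regions whose nearest-edge gap is at most `max_gap`; merged regions keep a
unanimous type or become `"merged"`, keep a unanimous strand or become
`"."`, and score the maximum of their members — no information is
fabricated. Range normalization maps the observed min/max over *all*
sequences jointly, so cross-sequence comparability survives the transform.

# Positional priors and Priors Generators

Any non-negative numeric track can be rescaled into a priors track
(min-max over all sequences jointly; a constant track maps to 0.5 with a
warning). The discriminative conversion against a control expectation
$\bar q \in (0,1)$ is the odds correction
$$d = \frac{p\,(1-\bar q)}{p\,(1-\bar q) + \bar q\,(1-p)},$$
the identity on $\{0, 1\}$, fixed at 0.5 when $p = \bar q$, and strictly
order-preserving. $\bar q$ may be a constant or the grand mean of a priors
track over control sequences.

A *Priors Generator* is a per-position classifier. Its feature vector at a
position is the centered-window mean of every input feature at every
configured window size — defaults 1, 11 and 101 bp for point, local and
broad context; window sizes are configurable because the right context
width depends on the feature's correlation length. Features are min-max
normalized with parameters frozen from training. Labels are positive inside
any answer-site region; negatives are subsampled to a 1:1 ratio (binding
site positions are rare, and balance keeps the logistic output usable as a
probability without recalibration). The default classifier is a
single-hidden-layer feed-forward network (8 units, logistic output,
entropy loss, at most 500 epochs, convergence tolerance 1e-4, L2 weight
decay 1e-3 — the small decay keeps occasional fits from collapsing into
poor optima). Training is fitted with `nnet`; application always runs the
package's own forward pass over the stored weights, so a generator
serialized to JSON (doubles as C99 hex-float strings) reloads to
bit-identical outputs.

Priors merit is measured by `evaluatePriors()`: every position is labeled
by answer-site membership and the AUC is computed by the rank
(Mann-Whitney) formula with midrank tie correction, so constant priors
score exactly 0.5.

# Module models

A module model is an ordered list of slots, each a set of alternative motif
ids, with a bound on the whole-occurrence span, optional slot order along
the sequence, per-slot orientation constraints, and nearest-edge gap bounds
between adjacent slots (edge-to-edge was chosen over center-to-center so
that overlap means distance 0, consistent with the interaction filter).
`scanModules()` enumerates one-site-per-slot selections (distinct sites;
overlaps between member sites allowed), screens the constraints
vectorized, and emits each qualifying member set once, as a region spanning
its members with the sites as children. The module score is the sum of
member relative scores by default (mean and min are available).

The interaction filter keeps a site exactly when some other site whose
motif is a declared partner lies within the gap; survival is judged against
the input track so removals cannot cascade. Partner relations are stored
symmetrically when motifs are assembled into a `MotifSet`.

# Statistics

*Overrepresentation*: for a motif observed k times, the p-value is the
exact binomial upper tail $P(X \ge k)$ with $X \sim \mathrm{Bin}(n, p)$,
where n is the total scanned length in bp and p the expected sites per bp
(typically: control-sequence counts divided by control length). Base pairs
were chosen as the exposure because the alternative — window counts —
depends on motif width and double-strand counting conventions, while
per-bp frequencies compose across motifs of different widths.
Significance is flagged at alpha/m under Bonferroni correction (m = motifs
tested).

*Group comparison*: per motif, a 2x2 table of sites versus remaining bp in
each group, tested two-sided by Fisher's exact test. Classes: `A` =
overrepresented in group A at the corrected level, `B` = at the nominal
level only, `C` = not significant, `D` = overrepresented in group B at the
nominal level or better. The boundary between `A`/`B` (corrected vs
nominal) is this package's definition; swapping the groups maps
`A`/`B` to `D` and back.

*Positional distribution*: site midpoints (`floor((start+end)/2)`) are
taken relative to the TSS (or sequence end), strand-aware so upstream is
negative. Clustering is summarized by Pearson kurtosis $m_4 / m_2^2$ on
population moments (normal = 3; an `excess` switch subtracts 3). Motifs
with fewer than 4 sites, or all sites at one position, get a blank.
Histogram bins are left-closed, consistent with half-open coordinates.

*Site conservation*: the feature average over all covered positions of all
sites — position-weighted, so longer sites weigh more; a site-weighted
variant would overweight short spurious hits.

*Rank sum*: members are ranked per map in the stated direction with
midranks for ties; blanks share the trailing midrank so missing values
cannot promote a motif. The combined promoter ranking sorts p-values
ascending and conservation and kurtosis descending.

*Benchmark metrics*: nucleotide-level confusion counts from per-position
coverage give Sn, Sp, PPV, Acc, PC, ASP, F and the Matthews correlation
coefficient; zero-denominator statistics (and CC) are defined as 0 so
batch benchmarking survives perfect-absence cases. Site-level sensitivity
counts an answer site as found when some prediction overlaps at least 25%
of the site's length (the fraction is a parameter).

# Protocol scripts

Workflows are linear scripts, one statement per line:
`target = opname arg=value ... [where <condition>]`. There is no control
flow — a protocol is a reproducible record, not a program. Execution runs
on a copy of the repository (errors abort the whole run, leaving the input
untouched; silent partial runs would corrupt downstream analyses). One
master seed derives a per-statement seed by hashing the statement index and
target name, so inserting a statement does not reshuffle unrelated
randomness; operations recorded interactively with an explicit seed keep
that seed as an argument, so replays reproduce the session bit-exactly.
`performStep()` is the recordable programmatic twin of one protocol line.

External programs attach through XML tool configs declaring a command
template with `{placeholder}` substitution, typed input/output file slots,
and a parameter schema. All placeholders must be bound and all slot formats
must be ones the track readers/writers understand; inputs and outputs cross
the boundary only as files in the declared formats.

# The synthetic planted-motif generator

`generatePlantedDataset()` emulates a benchmark dataset with a known answer
key: background sequence from a Markov model, binding sites sampled from
the motif's PWM and implanted without overlap (overlap-free implants keep
nucleotide-level metrics unambiguous) at positions drawn from a uniform or
TSS-anchored Gaussian law, strands drawn with a configurable plus-strand
probability. The TSS sits at the sequence end, the promoter convention.
Companion feature tracks emulate epigenetic evidence with an
informativeness parameter $\rho$: feature = $\rho$ x (11 bp smoothed
answer coverage) + $(1-\rho)$ x standard Gaussian noise, min-max
normalized. Gaussian noise is the deliberate choice here: with a bounded
noise term, any $\rho$ above roughly 0.5 separates site from background
positions almost perfectly, which no real epigenetic signal does; unbounded
noise keeps the classes overlapping at every $\rho < 1$, so single-feature
AUCs land in the realistic 0.6–0.97 range. The smoothing window (11 bp)
mimics broad signals around point answers. `generateModuleDataset()`
implants motif pairs with gaps drawn from a fixed or uniform gap law and
records module-level answers with the pair as children.

What passing tests on these fixtures do *not* show: real conservation has
phylogeny-driven autocorrelation, real ChIP signal has fragment-length
smearing, and real binding sites deviate from their PWMs in structured
ways. The fixtures validate the machinery, not biological performance.

# Bundled studies and problem sizes

Three study harnesses exercise the full pipeline at desk scale:

* `priorsRecoveryStudy()` — 6 planted datasets (8 sequences x 300 bp, 2
  sites each) carrying features with $\rho$ = 0.8, 0.5 and 0 (noise); 20
  replicates, each training a generator (windows 1 and 11 bp, 8 hidden
  units, 300 epochs) on 5 datasets and comparing its held-out AUC with the
  best single feature's. One held-out fold per replicate keeps 20
  independently seeded generators, which is the replication design of
  interest. The combined generator beats the best single feature in
  essentially every replicate because windowed averaging suppresses the
  independent per-position noise that caps each raw feature's AUC.
* `moduleFilteringStudy()` — planted motif pairs (gap 3–8 bp) scanned
  sensitively (relative score 0.8) produce noisy candidates; modules are
  scanned under a permissive model (gap up to 30 bp, span up to 60 bp).
  Filtering candidates by site-average feature value (>= 0.5) or by
  interaction partners within 10 bp raises the nucleotide-level CC of the
  module predictions; a random filter matched to the interaction filter's
  removal count does not. The permissive model versus tight filter split is
  essential: a filter at the model's own gap bound cannot remove anything
  the model would not already reject.
* `promoterStudyDemo()` — a complete promoter analysis as one protocol:
  background training (order 2), control-sequence sampling, sensitive
  scanning of target and control, per-bp expected frequencies from control
  counts, exact binomial overrepresentation with Bonferroni correction,
  positional distribution with kurtosis, site conservation, and a rank-sum
  combination collated into one report.

These sizes were chosen so each study completes in seconds to a couple of
minutes on a single core while leaving every effect it tests clearly
resolved.

# Known limitations

De novo motif and module discovery are reachable only through the external
tool adapter — the workbench scans with known models natively. Genome-scale
lazy tracks, remote data retrieval and binary formats (2bit, bigWig) are
out of scope. The protocol language has no conditionals or loops by design.
Generators do not transfer across renamed features. Partition objects allow
unassigned members.
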