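---
title: "Mapping hotspots of de novo telomere addition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping hotspots of de novo telomere addition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtascan)
```

## The problem

When a double-strand break occurs in a chromosome, telomerase occasionally
acts on the resected 3' overhang and caps the break with a new telomere.
This *de novo* telomere addition (dnTA) truncates the chromosome but can
rescue a cell from an otherwise lethal lesion. In budding yeast, dnTA is not
uniform along the genome: certain TG-rich sequences — Sites of
Repair-associated Telomere Addition (SiRTAs) — act as hotspots, stimulating
telomerase through recruitment of the single-stranded-DNA binding protein
Cdc13. `sirtascan` implements the computational side of mapping these
hotspots: a telomere-likeness scanner, the statistical null models used to
interpret a genome-wide map, a permutation test for overlap with genomic
annotations, and a quantifier for pooled telomere-addition sequencing
(PT-seq) read sets.

## The window score

Yeast telomeric DNA is an irregular repeat, a single T followed by one to
three Gs (TG~1–3~). The scanner scores similarity to this pattern while
tolerating divergence from it. Within a window (default 75 nt, stride 1 nt),
a greedy left-to-right pass collects *candidate tracts*:

* a tract opens at each G that begins a run of at least 4 consecutive G/T
  characters;
* the tract is truncated, inclusively, at the first T of a TT pair or at the
  third G of a run of four or more Gs — neither TT nor GGGG occurs in the
  telomeric repeat;
* scanning resumes immediately after the truncation point, so one G/T run
  can contribute several tracts;
* fragments shorter than 4 nt after truncation, and fragments without any T
  (all-G), are discarded.

The window score is the summed tract length, minus an optional penalty of
1.5 points per occurrence of the pentanucleotide GGTGG (also absent from
telomeric repeats; occurrences may overlap), minus an optional penalty per T
immediately flanking a tract. Scores are not floored at zero. The window
size of 75 nt reflects the spatial scale over which multiple Cdc13 binding
sites cooperate; the GGTGG penalty of 1.5 and the threshold of 20 points
were calibrated against sequences assayed for dnTA activity, where a score
of 20 separates active from inactive sequences with few errors. Defaults in
`scoring_params()` apply no penalties (matching the scanner's published
defaults); `scan_genome()` defaults to the genome-analysis configuration
(penalty 1.5, threshold 20).

```{r}
score_window(strrep("TG", 31), scoring_params(ggtgg_penalty = 1.5))
```

A perfect TG-dinucleotide 62-mer scores 61 — one point per base after the
leading T — the score of the strongest non-subtelomeric site in the yeast
genome.

Windows meeting or exceeding the threshold are merged when they overlap or
abut; a merged region spans from the start of its most upstream window to
the end of its most downstream window and carries the maximum window score.
Raising the threshold never widens a region, but it can *split* one: a
sub-threshold bridging window between two strong windows drops out and
leaves two regions where there was one. Region counts are therefore not
monotone in the threshold, and the tests assert the true property
(containment and shrinking footprint) instead.

## Genome scans, orientation and naming

`scan_genome()` scans both strands of every chromosome: the plus strand
directly, the minus strand as the reverse complement with window
coordinates mapped back to forward coordinates. Terminal perfect telomeric
repeats are excluded via per-chromosome analysis bounds in the
`genome_layout()`; subtelomeric X/Y' intervals can additionally be excised.
Excision adjusts the scan bounds rather than filtering hits afterwards, so
no window ever straddles an excised boundary.

Each region is annotated with:

* **arm** — L or R by the region midpoint relative to the centromere
  midpoint (a deterministic rule; regions spanning the centromere are a
  theoretical edge case);
* **orientation** — TG when the region's TG-rich strand matches the strand
  carrying the 3' TG overhang at the nearest telomere (minus strand on left
  arms, plus strand on right arms), otherwise CA. dnTA at a TG-oriented
  region stabilises the centric fragment;
* **name** — `{chromosome number}{arm}{kb}({strand})`, e.g. `6R210(+)`,
  where kb is the forward-strand start coordinate rounded half-up to the
  nearest kilobase. The start coordinate (rather than the midpoint) is used
  because it matches how region coordinates are tabulated; round-half-up
  makes the kb figure deterministic at `.5` boundaries.
* **genic context** — `classify_genic()` marks a region genic on any 1 bp
  overlap with a gene; among genic regions, the gene with the largest
  overlap (ties: leftmost gene start) decides whether the TG-rich strand is
  the transcription template or the coding strand.

All coordinates in data frames and BED files are 0-based half-open;
`read_genome_layout()` accepts 1-based inclusive files behind an explicit
flag. Conversion to the 1-based `GRanges` convention happens only inside
the overlap machinery.

## Null models

**Composition-preserving shuffles.** `shuffle_genome()` permutes the
nucleotides of each (adjusted) chromosome, preserving length and
mononucleotide composition exactly. Scanning a handful of shuffled genomes
and comparing score spectra (`score_spectrum()`, scores binned by
`floor(score)`) asks whether telomere-like sequences are more abundant than
base composition alone predicts. Five replicate shuffles, with sub-seeds
derived from one master seed, are the default in the CLI — enough to
estimate the null mean and spread of counts at this genome size, where the
per-replicate totals differ by only a few percent. Higher-order
(dinucleotide-preserving) shuffles are deliberately out of scope.

**Random repair placement.** `gcr_event_model()` asks how many of `n`
repair events would fall in a fixed test window if repair were uniform over
the recoverable region. The defaults encode the assay geometry: 30 gross
chromosomal rearrangement (GCR) events scored per experiment, a 300 bp test
insert, and 21,922 bp between the induced break and the first essential
gene — the window is ~1.4% of the region. Each Monte-Carlo trial literally
drops points uniformly and counts hits; the exact binomial tail is computed
alongside as an analytic cross-check, and the Monte-Carlo path is the
reported one (the published tail probabilities were themselves simulated).
With two or more of 30 events expected in the window in only ~6% of random
trials, an observed *average* above 2/30 ≈ 6.6% is unlikely under random
repair — hence `classify_active()`'s strict `> 6.6`% rule.

```{r}
m <- gcr_event_model(iterations = 20000, seed = 1)
m$tail[m$tail$k %in% 2:3, ]
```

**Strand distribution.** Whether hotspot regions cluster on one strand is
tested by `strand_switch_null()`: strand labels are permuted uniformly
within each chromosome (preserving the per-chromosome strand counts), the
statistic — strand switches between consecutive regions, or singlet runs —
is summed across chromosomes within each iteration, and the observed value
is compared with the resulting distribution. Summing per-iteration rather
than pooling avoids edge effects at chromosome ends. The raw empirical
fraction r/n is reported as the p-value, with the (r+1)/(n+1) corrected
value alongside; the closed form E[switches] = Σ 2·n₊·n₋/(n₊+n₋) serves as
a test oracle but is not the primary computational path.

## Overlap enrichment

`permutation_enrichment()` compares the observed number of query regions
with a qualifying annotation overlap against `n_perm` (default 1000)
length- and strand-matched random re-placements of the annotations; the
queries stay fixed. Qualification uses a 50% coverage rule whose side
depends on the annotation type: focal features (protein binding sites,
G4 motifs) must themselves be at least half covered, while for broad
regions (essential/nonessential spans) at least half of the *query* must be
covered. Placement is genome-wide — a chromosome is chosen with probability
proportional to the placement space it offers — with a per-chromosome mode
behind a flag for sensitivity analysis; placements never overlap each other
or the excluded intervals (rejection sampling with an attempt cap).
One-sided empirical p-values are reported in the direction of the observed
effect, with a Bonferroni multiplier for multi-set runs. Because the
permutation counts are small integers, the raw-fraction p-value is
conservative under ties; the test suite asserts type-I error control at the
nominal level rather than exact uniformity.

## PT-seq quantification

PT-seq pools 30 GCR clones, sequences the pool, and counts reads that carry
evidence of telomere addition at a 300 bp target locus, normalised to read
depth at a 300 bp control locus inside an essential gene:

1. **Assignment** (`assign_reads()`): a read belongs to a locus if it shares
   a contiguous exact match of ≥ 30 nt with either strand of it; a read
   matching both loci goes with the longer match. Alignment is pluggable —
   `ptseq_reads_from_bam()` accepts SAM/BAM from an external local aligner
   and feeds the same downstream logic.
2. **Event detection** (`detect_telomere_addition()`): the read is oriented
   to the TG-rich strand, its longest exact match to the target is located,
   and an event is called when a telomere seed motif (`GGGTGTGG`, or
   `CCACACCC` on the other strand) lies beyond the matching segment. The
   junction — the last aligned base, i.e. the 3'-most position at which
   telomerase may have initiated — is reported in target coordinates. The
   requirement that the seed fall *outside* the matching segment is the
   default because target sequences are themselves TG-rich and may contain
   the seed; the simpler "read contains the motif" rule is available behind
   a flag for exact reproduction of the published tabulation.
3. **Summary** (`summarize_ptseq()`): telomere reads as a percent of control
   reads (scale-invariant under uniform duplication), plus a junction
   profile giving the fraction of telomere reads at each junction.
4. **Calibration** (`apply_standard_curve()`): linear standard curves
   relating the normalized percentage to the percent of clones with dnTA
   were established against clone-by-clone PCR mapping at two chromosomal
   locations (slopes 3.961 and 3.8022, statistically indistinguishable);
   the curve direction is taken as x = sequencing percentage, y = clone
   percentage, and outputs are clamped to [0, 100].

Reads, not fragments, are the counting unit, and no deduplication is
performed, matching the read-level description of the assay.

## Synthetic data: what it does and does not emulate

The package validates itself on synthetic inputs with machine-readable
truth:

* `simulate_planted_genome()` plants tracts of known score into a
  background that is either **G-free on both strands** (A/T only) or
  composition-matched. The A/T background guarantees zero false positives —
  note that an A/C/T background would *not*: a plus-strand C is a
  minus-strand G, and two-strand scans of such backgrounds produce abundant
  chance tracts. Each plant is insulated by one run-breaking base on each
  side so that background Ts cannot extend the planted run and inflate its
  score past the recorded truth value.
* `simulate_ptseq_reads()` builds event reads as a target prefix ending at
  a chosen junction plus a simulated tail — a canonical 12-mer head
  (guaranteeing a detectable seed) extended with irregular T-G~1–3~
  repeats — and control reads as exact substrings of the control locus. The
  generator refuses junctions whose following target base is a G, because
  the read's exact match would then extend past the intended junction and
  the truth table would be wrong. The "degenerate tail" miss-behaviour
  control draws a G-free tail rather than merely omitting the head, since
  irregular TG repeats can still contain the 8-mer seed by chance.

What passing these tests shows: the scanner, caller and statistics are
internally correct, exactly recover planted signal, and agree with
independent oracles. What they do not show: behaviour on real genomes with
repeats, soft-masked regions and sequencing errors — the simulators model
neither sequencing error (beyond an optional uniform-substitution hook) nor
the repetitive structure of real subtelomeres, and genome-scale counts are
sensitive to the exact reference and trim coordinates used.

## Numerical and design choices

* Tokenizer edge cases are resolved as: minimum length and the all-G filter
  apply **after** truncation; scanning resumes immediately after a
  truncation stop, so tracts separated by TT/GGGG within one run each
  count; GGTGG penalties are counted window-wide with overlaps allowed;
  non-ACGT characters break runs and never match GGTGG; lowercase is
  uppercased. These choices make background scores conservative while
  preserving the scores of genuinely telomere-like sequences, which contain
  TT interruptions yet remain active.
* Sequences shorter than one window are scored whole rather than rejected,
  so score mode degrades gracefully on short FASTA records.
* The flanking-T penalty has no published magnitude; it defaults to 0 and
  is configurable.
* Integer score reporting (score spectra) rounds down.
* Monte-Carlo sizes in the tests (10–20 thousand iterations; 100 thousand
  in the acceptance script) put 3 standard errors well inside the
  tolerances being asserted while keeping the default run fast.
* Empty inputs are errors where a statistic would be undefined (zero
  control reads, zero queries) and empty results otherwise.

## Known limitations

* The scanner is a pattern score, not a binding model: sequences that bind
  Cdc13 through dispersed GxGT motifs can be active yet score low (a known
  false-negative mode), and incorporating GxGT matching was tested in the
  source study and rejected for inflating false positives. No
  probabilistic/HMM generalisation is attempted here.
* Genome-scale reproduction of published hotspot counts requires the exact
  reference build and the published trim/subtelomere coordinates; those are
  external inputs, and counts are sensitive to the tokenizer conventions
  above.
* `shuffle_annotations()` uses rejection sampling; extremely dense
  annotation sets relative to the allowed space will hit the attempt cap
  and error rather than silently bias placements.
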