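---
title: "splitsv: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{splitsv: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Structural variants (SVs) — deletions, insertions, tandem duplications,
inversions, translocations and transpositions larger than ~50 bp — are hard
to call from short reads because a single read rarely spans a whole
rearrangement junction. Long reads (ONT, PacBio) span junctions easily, but
their high per-base error rate and, in many study designs, low depth of
coverage (4–12X) defeat approaches that rely on consensus or deep pileups.
splitsv implements a split-read caller built for exactly this regime: every
informative read is treated as independent evidence for one or more *novel
adjacencies* — pairs of reference coordinates that are adjacent in the
sample genome but not in the reference — and a small neural network turns
per-adjacency alignment quality into a confidence score, so that useful
calls survive even at 2–4 supporting reads.

# The pipeline

## Alignment profiles

The caller consumes alignments, not reads. Three dialects are parsed into a
single normalised segment table (`parse_alignments()`): BLAST tabular
("outfmt 6"), PAF and SAM. All coordinates become 0-based half-open, and
read coordinates are always expressed in the original read orientation;
they are converted to 1-based only when VCF is written. This single
convention is deliberate: dialect conversions are where off-by-one errors
breed.

The method was designed around a BLAST-like aligner run with near-zero gap
tolerance (`-reward 2 -penalty -3 -gapopen 0 -gapextend 4
-max_target_seqs 3 -outfmt 6`); with those scores the aligner fragments an
alignment at every SV junction, so deleted, inserted, duplicated or
transposed segments appear as separate local alignments. Modern long-read
mappers (minimap2) instead thread mid-size indels *through* an alignment as
CIGAR operations, which would hide those junctions from a split-read
detector. The PAF/SAM parsers therefore split alignment records at
insertion/deletion CIGAR operations of at least `split_gap` (default 50 bp,
the minimum SV size), recovering BLAST-like segments from any aligner. This
is a normalisation choice of this package, and it matters: in our
experiments a transposed segment threaded as one long insertion op is
unrecoverable as a transposition, because the inserted sequence never gets
its own alignment to its source locus.

Two score surrogates are used where a dialect lacks a field. PAF/SAM carry
no bitscore or E-value: the `AS` tag (fallback: matched bases, MAPQ) stands
in for the bitscore, and `2^-bitscore` for the E-value. Since E-values only
enter the classifier through `-log10`, the surrogate is a monotone rescaled
bitscore — adequate for ranking, not a statistical E-value. BLAST tabular
reports gap *openings*, not gap bases, so the tabular `gap_frac` is
`gapopen/length`.

## Overlap resolution

Within a read, overlapping alignments are resolved by bitscore
(`resolve_overlaps()`): a segment contained in a higher-scoring one is
dropped; a partial overlap is trimmed from the lower-scoring segment, whose
reference interval shrinks proportionally (tabular dialects carry no
per-base alignment, so exact CIGAR-based trimming is not generally
available; proportional mapping errs by at most the local indel density).
Ties are broken by smaller reference start, then chromosome name, making
the operation deterministic; it is also idempotent, which the test suite
asserts on randomised profiles.

## Novel-adjacency detection

For each pair of consecutive segments on a read, two *junction coordinates*
are computed: `j1`, the reference coordinate of the first segment at its
read-right end, and `j2`, the second segment's coordinate at its read-left
end (for a minus-strand segment these are its `ref_start`/`ref_end`
swapped). This makes the rules strand-symmetric:

* different chromosomes → translocation (BND);
* strand flip → inversion; `j1` and `j2` are the two inversion boundaries;
* same chromosome and strand: reference gap ≥ 50 bp with read gap < 50 bp →
  deletion; read gap ≥ 50 bp with |reference gap| < 50 bp → insertion;
  reference gap ≤ −50 bp (backward jump, read order preserved) → tandem
  duplication;
* a junction qualifying on both axes is classified by the larger gap (tie →
  deletion);
* flank–middle–flank triples whose outer flanks are concordant and whose
  middle maps elsewhere (another chromosome or ≥ 10 kb away) → transposition
  (BND), with the middle's locus kept as the partner coordinate. This is a
  reconstruction of the published decision cascade at main-text resolution;
  the original tool's exact conditional statements are not public in
  machine-readable form.

Adjacencies of one class whose primary breakends lie within `merge_distance`
(default 400 bp, deliberately equal to the benchmark's error distance) are
clustered by single-linkage chaining; the representative breakend is the
member median; calls with fewer than `min_support` (default 1: the score,
not a hard support cutoff, arbitrates low-support junctions; 2 is the
recommended clinical setting) distinct
reads are dropped.

## Breakend depth and the outlier threshold U

At each call's primary breakend, B counts distinct supporting reads and O
counts distinct other reads spanning the position. The ratio `B/(B+O)` is
~1 for homozygous and ~0.5 for heterozygous variants; the package labels
HOM at ratio ≥ 0.8 and HET in [0.35, 0.8) — the anchors 1.0 and 0.5 are
the method's, the band edges are this package's choice.

Artifactual breakends in repetitive sequence attract implausibly many
supporting reads. The genome-wide depth distribution is estimated by
sampling `n` = 10,000 uniformly random positions (reproducible under a
fixed seed; positions inside an exclusion BED are resampled) and the
threshold

$$U = 4\,k\,\frac{1}{n}\sum_{i=1}^n |x_i - m(X)| + m(X),\qquad k = 1.4826$$

is applied: calls with `B > U` (strictly) are removed. The dispersion term
is the *mean* absolute deviation around the median, scaled by the usual
1.4826 — the mean is used instead of the median of deviations to avoid
jumps from discontinuous integer medians. `n` is unspecified in the
original description; 10,000 gives a stable median and MAD at negligible
cost. The even-length median is the mean of the central order statistics.

## Confidence scoring

Each adjacency yields 23 features: five aligned/unaligned percentages
around the junction (upstream-aligned %, downstream-aligned %, junction gap
%, total aligned %, largest unaligned fragment %), flanking E-values
(−log10), relative bitscores (bitscore per aligned base), identities,
mismatch fractions and gap fractions for both flanks, junction complexity
(co-located adjacencies within 400 bp), alignments per read, adjacencies
per read, distinct chromosomes hit, fraction of alignments shorter than 5%
of the read, B, B/(B+O), and the indel size for DEL/INS. The five
"percentages flanking the adjacency" and the "relative bitscore" are
reconstructions — the original feature list names the groups but not the
exact quantities. Features are min-max scaled into [0,1] with bounds
computed from the training pool, frozen in the model file, and clipped at
inference.

The classifier is a 23-12-5-1 feed-forward network (ReLU hidden layers,
sigmoid output, inverted dropout 0.4/0.3 after the hidden layers during
training only), implemented directly over base matrix algebra with
gradient-checked backpropagation — no deep-learning framework, so a model
is a small JSON file of plain numbers and training is bit-reproducible from
a seed. Training uses binary cross-entropy and plain SGD for 63 epochs,
each drawing 12,000 true and 12,000 false examples (with replacement when
the pool is smaller) in minibatches of 400. The learning rate is fixed at
0.1: the framework-default 0.01 of the original description assumes that
framework's update conventions, and under plain SGD it underfits within the
same step budget.

The network's inference value P becomes the Phred-like score

$$S = -10 \log_{10}\bigl(1 - \tanh(0.4B)\,P\bigr),$$

so that few supporting reads (B = 1–3) shrink P nonlinearly; S is capped at
100 when the logarithm's argument underflows. Calls with S below the
threshold (default 1.0) are excluded from the filtered callset; both total
and filtered callsets are written.

Per-call P is the mean over the call's member adjacencies. Training
examples are labelled class-agnostically: an adjacency inside the 400-bp
window of any truth breakend is a true novel adjacency even if its class
was read differently — the junction exists. (Class-aware labelling is
available; it injects contradictory labels at transposition and duplication
sites, where the same junction is read as INS by some reads, and measurably
degrades the fit.)

# The simulator

The generator is the package's study-condition definition, not a tuning
surface. Defaults follow the full-scale recipe: per dataset, one genome
with 20,000 deletions, 1,000 balanced inversions, 1,000 single tandem
duplications and 10,000 transpositions, plus a second genome with 10,000
novel (viral-like) insertions — 42,000 SVs in total — with all counts
scaled proportionally for desk-scale references (`sv_profile(scale=)`).
SV sizes are log-normal (median ≈ 400 bp, sdlog 1.2) bounded to
[50 bp, 100 kb], a stated approximation of the DGV-derived size
distribution, which is not published in tabulated form. Transpositions are
copy-paste: a distant reference segment (≥ 50 kb away or another
chromosome) is inserted at the target site, so the inserted sequence exists
elsewhere in the reference — the defining property of the class. Novel
insertions draw from a user-supplied donor FASTA or, by default, random
sequence, so nothing needs downloading. Each junction's 20-bp window is
mutated (25% per-base SNP; 50% chance of one indel of ≤ 5 bp) to emulate
junction microheterogeneity. Optional repeat bias multiplies the acceptance
odds of breakends inside user-supplied intervals; without a BED, placement
is uniform with non-overlapping footprints.

Reads are sampled uniformly at the requested fold-coverage with log-normal
lengths (median 8 kb, sdlog 0.4) and independent per-base substitution /
insertion / deletion rates of 0.05 / 0.025 / 0.035 — a parametric stand-in
for a learned ONT error profile. Heterozygous datasets draw half the reads
from the unmutated reference. The default recipe contains no chimeric
reads, matching the reference simulation protocol; a chimera rate (two
unrelated fragments joined end to end) is available as the *artifact
injection* device that supplies false novel adjacencies when building
classifier training sets — on a repeat-free random reference such chimeric
junctions are the only systematic false class, and at single-read support
they are intentionally indistinguishable from real junctions, which is why
the score, not the classifier alone, arbitrates them. The mixed-zygosity
trio for training nests one SV plan at 100%/83%/50% (C ⊂ B ⊂ A) and mixes
reads 1:1:2, so SVs are homozygous (50%), heterozygous (33%) or
low-confidence (17%) by construction.

What the simulator does *not* emulate: real repeat structure (the reference
is random sequence, so repeat-driven artifact breakends are rare compared
with a human genome), learned error profiles with homopolymer bias, GC
bias, and base-quality information. Passing the simulation benchmark
therefore demonstrates the machinery — detection, depth modelling, scoring,
evaluation — under the stated conditions, not performance on human data.

# The benchmark

Evaluation is breakend-based: each truth SV is segregated into its
breakends (two for DEL/INV/DUP, one for INS/BND), each breakend becomes a
window of ± 400 bp (inclusive at exactly 400), and a predicted breakend
falling inside a window is a hit; class-aware mode additionally requires
the classes to match. Precision = TP/(TP+FP), recall = TP/(TP+FN),
F1 = 2PR/(P+R). By default multiple predictions inside one window count as
a single TP and the extras count as neither TP nor FP (they locate a real
event); `dedup = FALSE` switches to counting every matched prediction in
precision. Whether the original evaluation deduplicated is not stated, so
both modes exist. Recall can be stratified by repeat family from a BED with
a family name column.

# Problem sizes

All empirical checks run on synthetic references sized to finish on a
single CPU while leaving enough truth breakends (hundreds) for stable
rates: the acceptance script uses a 16-Mb reference (≈ 215 SVs, ≈ 390
breakend windows per dataset) at 4X and 8X; the test suite's end-to-end
blocks use 10–12 Mb. The genome-wide SV density always matches the
full-scale recipe (≈ 13.5 SVs/Mb), so per-breakend statistics are
comparable; only their sampling variance grows, which is covered by the
stated tolerances. The shipped classifier is trained by
`scripts/train_model.R` on a 16-Mb mixed-zygosity trio sequenced at 4X
with 2% chimeric reads injected. The aligned reads are split into four
~1X sub-datasets before calling — at 1X every junction has near-singleton
support, so the network cannot lean on read counts and must learn
alignment quality — and those examples are pooled with the full-depth run,
whose heterozygous and low-confidence SVs supply the intermediate
support/ratio regimes seen at inference (≈ 1000 labelled adjacencies in
total). The fit is verified on an independently simulated held-out dataset
(ROC-AUC ≥ 0.99 at these conditions).

# Degenerate inputs and numerical choices

Empty alignment files parse to empty profiles; reads with one segment are
normal reads; an empty callset writes a header-only, standards-valid VCF.
Bitscore ties in overlap resolution, equal read/reference gaps at a
junction, and even-length medians all have documented deterministic
tie-breaks (see above). E-values are floored at 1e−300 before the log
transform. The score cap (100) keeps VCF QUAL finite. Depth sampling,
simulation and training each take explicit seeds; every randomised result
in the package is reproducible from those seeds alone.

# Known limitations

* Tandem duplications shorter than the typical inter-error alignment
  fragment and inversions under ~100 bp are hard to recover from noisy
  split alignments; their class-aware F1 trails the point-mutation-free
  classes.
* Proportional reference trimming can misplace a trimmed segment's
  breakend by the local indel imbalance; exact trimming would need CIGARs
  in every dialect.
* The transposition rule requires the inserted copy to be alignable as its
  own segment; with aligners that bury the copy inside a long insertion
  operation (without CIGAR splitting) such events degrade to insertions.
* Genotype likelihoods, local assembly and consensus polishing are out of
  scope; zygosity is a ratio heuristic, not a genotype model.
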