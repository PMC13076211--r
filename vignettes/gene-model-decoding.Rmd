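---
title: "Decoding base-wise genic probability tracks into gene models"
author: "genedecoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding base-wise genic probability tracks into gene models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedecoder)
```

## The problem and the model

Ab initio eukaryotic gene prediction from DNA alone is naturally split into
two stages.  A sequence labeler assigns every base a probability
distribution over the four genic classes (intergenic, UTR, CDS, intron) and,
in a second output head, over the four coding-phase classes (none, 0, 1, 2,
the phase being the number of bases until the start of the next codon).  A
structured decoder then turns those probability tracks into discrete gene
models that obey the grammar of eukaryotic genes: an ATG start codon, codons
read in frame, GT..AG introns that may interrupt any codon position, a
TAA/TAG/TGA stop, optional UTRs.  The probabilistic tracks carry the pattern
recognition; the decoder carries the biological constraints.  This package
implements both stages plus everything needed to exercise them end to end on
a desk: encoding, a loss contract, metrics and a synthetic-genome generator.

## Encoding conventions

Sequences are encoded one row per base over channels C, A, T, G.
Unambiguous bases are one-hot; IUPAC ambiguity codes are spread uniformly
over their compatible bases (R becomes 0.5 A + 0.5 G, N becomes 0.25
everywhere), so every row sums to 1.  Uniformity over compatible bases is
the natural uninformative choice; no published table was adopted.

Labels use two one-hot tracks per contig strand plus a boolean mask.  The
coding phase of a CDS base at position $q$ (0-based) within its spliced CDS
is $(3 - q \bmod 3) \bmod 3$, giving the cycle $0, 2, 1$ across a codon;
this is also exactly the GFF3 phase of a CDS segment evaluated at its first
base, which keeps the two conventions interchangeable.  Coordinates are
0-based half-open internally and converted to 1-based inclusive at the GFF3
boundary.  Each strand is processed as an independent sequence: minus-strand
gene models are mirrored onto the reverse complement, labeled there as if
plus-strand, and mapped back on output.

The mask marks bases excluded from loss and metrics: all bases of partial
gene models (CDS missing the start and/or stop codon, CDS length not
divisible by 3, models truncated by a contig edge) and the overlap regions
of same-strand overlapping models.  Masking is the error channel --
erroneous annotation is never silently "fixed".  Runs of ambiguous sequence
are deliberately not auto-masked: masking targets annotation errors, not
sequence content.  Where a gene carries several transcripts in an input
GFF3, the longest-protein transcript defines the labels, matching the
evaluation convention for primary transcripts.

For windowing, contigs are tiled into fixed-length subsequences of 21,384
bases (training) or the longer inference windows of 106,920 bases (plant
profile) and 213,840 bases (animal profile), both integer multiples of the
training length; final windows are zero-padded and padded positions are
masked.  Chunking followed by de-chunking is exactly the identity.

## The loss contract

The training loss is a weighted sum of the two heads: 0.8 times the
class-head loss plus 0.2 times the phase-head categorical cross-entropy.
The class head uses per-class weights -- default $(0.7, 1.6, 1.2, 1.2)$ for
(intergenic, UTR, CDS, intron) -- to de-emphasise the abundant intergenic
class, and multiplies the weight of every base within a small radius
(default 3) of one of exactly four transition-site categories: start codon,
stop codon, donor splice site, acceptor splice site (default multiplier 10).
Transcription starts and ends (intergenic/UTR boundaries) are deliberately
not boosted; the four categories are the boundaries whose base-exact
placement the decoder depends on.  With multiplier 1 the loss reduces to the
plain class-weighted cross-entropy, which is the ablation limit.  The
class-head average is normalised by the total weight, so a one-base batch
with class cross-entropy exactly 1 yields a composite loss of exactly 0.8
regardless of its class weight.  The exact per-class and transition weights
of trained production models are not published; the defaults here are
config-exposed choices following the stated rationale.

## The toy predictor and what it can show

The trainable predictor honours the dual-head contract at laptop scale: a
convolution-style window of one-hot context (±10 bases), reading-frame
features (the length of the stop-free codon run containing each position,
in each genomic frame), local motif flags, and a fixed-decay bidirectional
recurrent layer -- exponential moving averages of the motif and frame
indicators run forward and backward at two decay scales (0.95 and 0.99) --
feeding one shared hidden layer with class and phase softmax heads.
Training is minibatch Adam on the composite loss; after every epoch the
validation genic F1 is logged, and the returned model is the checkpoint
that maximised it.  Training and validation batches must come from
different contigs.  Everything is deterministic given the seed.

What such a model can achieve is bounded by the synthetic data itself.  The
generator's UTRs and intergenic background are statistically identical
random sequence, so transcription boundaries carry no learnable signal, and
intron interiors are locally random too.  The support-weighted genic F1 of
*any* per-base predictor on this data therefore saturates far below 1; a
nonparametric ceiling estimate (a random forest on the same features)
reaches about 0.3, dominated by the CDS class where the frame features
carry real information.  The training smoke test consequently asserts a
validation genic F1 above the frozen threshold 0.2 together with a CDS F1
above 0.5 -- what the architecture robustly achieves on the standard
fixture -- rather than a value only a long-range model on
boundary-signalled data could reach.  Decoding quality in this package is
instead exercised through the oracle track generator, which emulates a
strong predictor at controlled corruption levels.

Sliding-window inference predicts on overlapping windows (default stride =
half the window) and combines overlaps by the arithmetic mean; averages of
distributions remain distributions, and rows are renormalised only against
floating-point drift.

## The oracle track generator

`oracle_predictor()` converts reference labels into probability tracks:
each row is $(1-\text{noise}) \cdot \text{one-hot} + \text{noise} \cdot
\text{uniform}$, and with `jitter > 0` each base is independently replaced,
with that probability, by a draw from a symmetric Dirichlet distribution
(concentration 0.5, giving spiky, confident-looking errors).  The mixture
alone never changes an argmax call below noise 0.5, so the fixture
generator couples the jitter probability to the noise level; this is what
actually produces decoding errors and makes the robustness curves
informative.  At noise 0 the tracks are exactly one-hot.

## The decoder

Decoding has two phases.  First, candidate genic regions are the maximal
intervals where a sliding-window moving average (window 100 bases, shrinking
at contig edges) of the intergenic probability stays strictly below 0.5;
intervals separated by less than one window are merged, and before decoding
each region is padded by half a window so the path can open and close in
the intergenic state.

Second, within each region a dynamic program finds the state path that
minimises the total penalty: per base, $-\log(\max(\varepsilon, P[\text{class
of the state}]))$ plus, for CDS substates, the same for the state's phase
($\varepsilon = 10^{-8}$); per transition, 0 at the required canonical motif
and a configured penalty (infinite by default) otherwise.  All penalties are
configuration constants encoding established gene grammar -- nothing is
fitted.

The state space has one intergenic state, two UTR states and two structured
super-states:

* **CDS: 10 substates.**  Three start-codon positions (`S0 S1 S2`, base
  checks A, T, G), three regular codon positions by phase (`R0 R1 R2`), and
  a four-state stop automaton (`T`, then `TA` or `TG`, then the final
  base, with TAA/TAG/TGA enforced by base checks).  Completing a regular
  codon read contiguously additionally checks that the codon is not a stop.
* **Intron: 60 substates.**  Entry-or-continuation (2) × donor motif class
  (3: GT-AG, GC-AG, other) × outer state (10).  The outer state is the
  state the path resumes after the intron: one of the nine resumable CDS
  substates (`S1 S2 R0 R1 R2 T TA TG F`) or the 5' UTR.  This carries the
  interrupted codon phase across the intron, so splices can fall inside
  codons, inside the start codon and inside stop codons.  Donor checks read
  the first two intron bases, acceptor checks the final AG plus the resumed
  state's base requirement.

Several modeling choices deserve their rationale.  The UTR super-state is
split internally into 5' and 3' states so the grammar itself guarantees that
every emitted gene contains a CDS and that UTR output types are oriented;
both emit the same UTR class, so behaviourally it remains a single
super-state.  The outer-state set fixes the intron substate count at 60;
with resume-target semantics three configurations are unrepresentable and
deliberately out of grammar: introns in 3' UTRs, an intron immediately
before a complete start codon (it belongs to the 5' UTR in this grammar,
with at least one UTR base after the acceptor), and an intron directly
before the third base of a TGA stop (the automaton cannot distinguish the
TA and TG prefixes after an intron; TAA/TAG splits at that position remain
representable).  The synthetic generator only emits structures inside the
grammar.  Finally, because regular CDS states do not carry codon letters,
an in-frame stop inside a codon that an intron interrupts cannot be
excluded by a Markov decoder; contiguously read codons are checked, and the
generator guarantees stop-free CDS interiors.

Ties in the dynamic program are broken deterministically: transitions are
scanned in a fixed order with the intergenic-first, lowest-id predecessor
winning, so equal-cost paths prefer staying intergenic longer (shorter
genes).  A region with no finite-penalty path yields zero genes, as does a
best path that never leaves the intergenic state.  A path may leave and
re-enter genic states, so one region can produce several genes; same-strand
overlaps are impossible by construction and opposite-strand overlaps are
permitted because strands are decoded independently.  Decoded genes with a
total CDS shorter than 60 bases are discarded (`min_cds_length`); genes
without UTRs are permitted.  Emitted models are serialized as GFF3 with
gene, mRNA, exon, CDS and UTR rows, deterministic ordering and CDS phase
columns derived from the models' reading frames.

## Metrics

Base-wise evaluation excludes padded and masked bases.  From the confusion
matrix, per-class precision, recall and F1 follow their standard
definitions, and the aggregates are support-weighted averages: genic F1
over UTR/CDS/intron, subgenic F1 over CDS/intron, phase F1 over phases
0/1/2.  True-class base counts are used as weights (the aggregate is
described as a weighted average without a published weight definition;
support weighting is the standard reading).  Phase F1 is computed over the
three coding phases with their true supports, so in effect on CDS-support
bases.  For training-scale evaluation a random sample of 800 subsequence
windows is drawn without replacement (all windows when fewer exist).
Transition-adjacent F1 restricts the evaluation to unmasked bases within a
radius (default 3, "immediately before or after" made concrete) of any true
class change.

Feature-level evaluation compares primary transcripts with all UTRs
removed, i.e. on CDS-bounded exons, by exact coordinate-and-strand match at
four levels: exon, intron, intron chain (the ordered intron list matches
all-or-nothing) and transcript (intron chain plus CDS start and end).  No
terminal-exon leniency is applied: exact matching keeps the measure
symmetric and deterministic.

## The synthetic generator

`simulate_genome()` produces random background sequence at a target GC
fraction (default 0.42) carrying canonical multi-exon genes: CDS interiors
are generated codon-wise from the 61 sense codons (no premature stops),
starts and stops are prepended/appended, and introns (GT + random interior
+ AG) are inserted afterwards at arbitrary CDS positions so all three
interrupted phases, start-codon splits and representable stop-codon splits
are exercised.  UTRs are random sequence; genes are placed with at least
200 intergenic bases between them and slack distributed randomly; strands
are drawn independently (default probability 0.5 minus).  The default spec
-- one 100 kb contig with 20 genes of 1-4 exons, CDS of 60-180 codons,
introns of 60-200 bases, UTRs of 30-150 bases -- runs the full pipeline in
seconds and is the fixture for the decoder's identity, validity and
robustness suites.

What the generator does *not* emulate bounds what passing tests show about
real data: no repeats or transposons, no GC isochores, no promoter or
poly-adenylation signals (hence no learnable transcription boundaries), no
alternative isoforms, no non-canonical splice sites unless configured, no
annotation errors unless injected.  Tests on this data demonstrate the
correctness of the machinery -- exact label/decode round trips, grammar
validity, monotone degradation under corruption -- not the accuracy any
predictor would reach on a real genome.

## Numerical choices and problem sizes

The emission floor $\varepsilon = 10^{-8}$ bounds penalties at about 18.4
per base, keeping paths through zero-probability emissions finite but
decisively expensive.  Dynamic programming uses additive double-precision
penalties with infinite entries pruned before propagation.  The
brute-force cross-check enumerates every legal path with cost-bound pruning
on instances of 10-18 bases (100 seeded instances); the noise-robustness
suite decodes the default 100 kb fixture at noise levels 0 to 0.5 in steps
of 0.1 with 5 seeds each; the trainer's smoke fixture uses two 25 kb
5-gene contigs, 30 epochs, hidden width 48.  These sizes are the package's
chosen test conditions; all are parameters, not limits.

## Known limitations

* The decoder's grammar restrictions listed above (3' UTR introns,
  TGA-third-base splits, split-codon stop checking).
* The toy predictor is a per-base model with fixed-decay recurrent
  smoothing, not a trained long-range network; it exists to exercise the
  training and inference contracts, and its accuracy ceiling on the
  synthetic conditions is documented above.
* Candidate-region detection with a strict threshold can exclude the single
  boundary base whose windowed average equals the threshold exactly;
  region padding absorbs this in decoding.
* GC-AG and other non-canonical splice classes are representable but
  disabled (infinite penalty) by default.
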