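---
title: "Discovering RNA duplexes from proximity-ligation CLIP reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering RNA duplexes from proximity-ligation CLIP reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiclipr)
library(dplyr)
```

## The problem

hiCLIP and related proximity-ligation CLIP protocols capture RNA duplexes
bound by a double-strand RNA-binding protein (the motivating case is STAU1):
the two strands of a bound duplex are ligated — either across a linker
adapter or directly to each other — so that a single sequencing read carries
both *arms* of the duplex. A third class of reads arises from short-range
stem-loops whose loop escapes RNase digestion; these map contiguously and
look like ordinary single-site CLIP reads, but their downstream structure
can be inferred computationally.

`hiclipr` implements the computational core of this analysis:

1. **Read preparation** — UMI extraction, detection of the full-length or
   3'-truncated linker, splitting of linker reads into arms with at least
   12 nt flanking the linker on both sides.
2. **Hybrid calling** — for reads without a linker, a seed-and-extend
   partial aligner plus a filter cascade selects at most one two-arm
   solution per read.
3. **Directional UMI deduplication** keyed on the transcript and start
   coordinate of *both* arms.
4. **Duplex clustering** — overlapping hybrids are collapsed into duplexes
   by graph connected components.
5. **Structure and energetics** — intermolecular minimum-free-energy
   structures, dinucleotide-preserving shuffled controls, windowed per-base
   pairing probabilities.
6. **Derived stem-loops** — short-range duplexes inferred downstream of
   crosslink peaks from pairing-probability profiles.
7. **Metabolism integration** — k-medoid clustering of synthesis,
   processing and degradation rates, compaction scores, 3' UTR thirds.
8. **Synthetic data** — a generator that plants duplexes with known
   coordinates and structures, so every step above is testable end to end
   without any external download.

All coordinates are 0-based half-open; transcripts are treated as
plus-strand transcriptome sequences throughout (hybrid arms never map to the
reverse strand), matching the transcriptomic reference design of the assay.

## Hybrid calling

Reads are first screened for the linker adapter by exact substring search,
trying the full linker, then the linker missing its last nucleotide, then
missing its last two; the longest matching variant wins. The linker sequence
is library-specific and therefore a required argument — there is no default
in the detection functions (the simulator documents an arbitrary 19-mer).
Linker reads are split into arms; each arm is aligned independently, and a
hybrid is reported only when both arms have a unique best placement.

Reads without a linker enter the direct proximity-ligation path:

* **Partial alignment.** The built-in aligner indexes the reference with
  11-mers sampled every 5 positions and extends every exact seed to its
  maximal exact segment, keeping segments of at least 15 matches. An
  e-value is attached with the Karlin–Altschul formula
  $e = K m n e^{-\lambda S}$ using the ungapped $+1/{-2}$ nucleotide
  constants ($\lambda = 1.33$, $K = 0.621$), where $S$ is the number of
  matches. We deliberately extend to the first mismatch rather than across
  mismatches: it makes the aligner's output *provably identical* to an
  exhaustive scan over all read substrings (any exact run of 15 nt or more
  must contain an indexed seed), which in turn lets the whole calling
  cascade be validated against brute-force enumeration. Mismatch- and
  gap-tolerant alignments can be supplied instead as PSL or BLAST-8 tables
  from an external aligner.
* **Filter cascade.** Alignments with e-value above 0.001 are removed;
  reads retaining more than 100 alignments are dropped; only the
  best-scoring alignment per read span is kept (ties retained). A read in
  which a single alignment leaves at most 15 nt unaligned is called a
  non-hybrid — non-hybrid explanations always take precedence over hybrid
  ones. Remaining alignments are cross-joined into ordered arm pairs;
  pairs overlapping by more than 4 nt or separated by more than 4 nt in the
  read are removed, as are intra-transcript pairs whose reference intervals
  overlap and solutions whose first arm starts more than 5 nt into the read
  (the crosslink is taken to sit at the read 5' end; this read-relative
  reading is configurable via `max_start_offset`).
* **Multimap resolution.** A read with several surviving solutions is
  resolved against the pool of unique solutions: candidates whose two arms
  both overlap a pooled solution are kept, the greatest total aligned
  length wins, and unresolved ties stay ambiguous.

PCR duplicates are collapsed per mapping key (proximal transcript/start,
distal transcript/start) with the directional UMI network: UMIs at Hamming
distance 1 are merged when the higher count $A$ satisfies
$c_A \ge 2 c_B - 1$.

## Duplex clustering

Two deduplicated hybrids overlap validly when both arm pairs overlap with a
fraction of at least 0.5, the fraction being overlap length over the union
span of the two arms. Valid overlaps are edges of an undirected graph whose
connected components are duplexes; duplex arm ends are per-arm medians of
the member coordinates (even counts resolve to the lower middle value so
coordinates stay integral) and the component size is the support. Transitive
chains whose end members fall below the pairwise threshold are inherent to
connected-component clustering and accepted; `max_component_span` can warn
about runaway chains. Atlases from different sources (linker, direct,
derived) are merged by pooling and re-clustering with the same rule, with
sources unioned per merged duplex.

## Energy models and their scope

Structure prediction is deliberately pluggable, with two built-in models:

* **`simple`** — additive pair energies (G:C $-3$, A:U $-2$, G:U $-1$
  kcal/mol), $+1$ kcal/mol per unpaired loop nucleotide between helices,
  no initiation term. This model exists to be *exhaustively enumerable*:
  the test-suite verifies the dynamic program against brute-force
  enumeration of all legal pairings.
* **`nearest_neighbour`** (default) — stacking energies from a Turner-style
  table (values approximate published stacks to within a few tenths of a
  kcal/mol and satisfy the strand-exchange symmetry
  $st[p][q] = st[\mathrm{flip}(q)][\mathrm{flip}(p)]$), logarithmic bulge
  and internal-loop penalties with an asymmetry term, and a duplex
  initiation penalty of $+4.1$ kcal/mol. Temperature is fixed at 37 °C and
  dangling ends are not modelled.

Both models allow Watson–Crick and G:U pairs and forbid lonely pairs (every
helix has at least two stacked pairs). Exact reproduction of a full Turner
2004 parameterisation is out of scope: every comparative statement the
package supports (true versus shuffled-control energies, ranking of duplex
classes) is rank-based and robust to the parameter choice.

Shuffled controls preserve dinucleotide content exactly via an
Altschul–Erikson Euler-path shuffle; the arborescence toward the terminal
nucleotide is drawn with Wilson's loop-erased random walk, which makes the
shuffle uniform over valid sequences. The control energy is the mean
minimum free energy over 100 shuffle iterations of both arms.

The windowed pairing-probability profile slides 100-nt windows one
nucleotide at a time and computes, per window, a McCaskill-style partition
function over the same structural ensemble (hairpin loops of at least 3 nt,
no lonely pairs) with simple-model pair weights plus a $+4.1$ kcal/mol
helix-nucleation penalty charged once per maximal helix. Without the
nucleation term the pair-only model saturates random sequence with pairing
(mean per-base paired probability about 0.66); with it, random-sequence
backgrounds (mean about 0.6, strongly position-correlated) behave like the
reference implementation of local folding on the same sequences. Per-base
values are averaged over all windows covering the base; this per-window
mean is a documented approximation to the reference tool's window
averaging.

## Derived stem-loops

For each crosslink peak (restricted to the 3' UTR of one representative
transcript per gene — a user table, else the longest annotated 3' UTR), the
profile over −100..+100 nt around the peak start is computed, together with
a dinucleotide-shuffled control profile. Profiles are clustered by k-means
on the +10..+75 nt region; k is chosen from 2..8 by the maximum mean
silhouette width, and clusters are labelled by decreasing mean region
probability. A cluster metaprofile showing the paired–unpaired–paired
("M"-shaped) signature — two local maxima at least 0.05 above the region
mean separated by a local minimum at least 0.05 below it, after smoothing
with a width-5 moving average — marks structure-bearing clusters. The
amplitude margin and the smoothing width are package choices: without a
margin any noisy flat profile (including shuffled controls) would register
as M-shaped.

Arm regions are delineated per cluster from the local minima of the
smoothed metaprofile over +1..+100: the proximal region runs from the rise
start to the first minimum after the first maximum, the distal region to
the next minimum; a minimum on a boundary belongs to the proximal region.
Per peak, the two region sequences are folded against each other, unpaired
flanks are trimmed to the outermost pair, and the loop length is the gap
between the trimmed arms.

The minimum-stem filter retains duplexes whose *longest contiguous helix*
reaches 8 bp (`stem_rule = "contiguous"`, the default). The total-pair
variant (`stem_rule = "total"`) is provided but is a poor proxy for a
bindable stem: reference-grade duplex prediction reaches 8 *total* pairs on
more than half of random region pairs of the relevant sizes, because
scattered short helices accumulate pairs without forming a stem, whereas
the biophysical motivation for the 8-bp threshold is the stem length a
double-strand RNA-binding domain must engage.

Two limitations of per-cluster delineation are worth knowing. First, the
arm regions are fixed per cluster, so when a cluster mixes stem geometries
the region boundary necessarily clips the longest stems of some members; in
planted-hairpin simulations with stems of 8–15 bp and loops of 4–10 nt this
caps exact-loop recovery at roughly 85–90%. Second, peaks whose true
structure sits mostly outside the +10..+75 clustering window (stems
starting within a few nucleotides of the peak) cannot produce a two-bump
signature inside the window; the synthetic generator therefore plants
hairpins 8–16 nt downstream of the peak start, matching the offsets of the
observed structure clusters.

## Metabolism integration

Genes are expression-matched by keeping those whose copy number exceeds the
5th percentile (linear interpolation between order statistics) of
duplex-bearing genes. Synthesis, processing and degradation rates are
log10-transformed, scaled and centred, and clustered by partitioning around
medoids with k = 3; the average silhouette width over k = 2..8 is reported
alongside. Clusters are relabelled A/B/C by decreasing mean degradation so
the labels are stable across seeds and input orderings. The compaction
score of a duplex is its intron-corrected span divided by the
intron-corrected length of the representative 3' UTR (the longest 3' UTR
overlapping the duplex); 3' UTRs are split into three equal thirds
(remainder to the last third) to count how many thirds a duplex spans. Both
raw and corrected spans are available, since published per-gene span
summaries do not state which was used.

The span mixture model is a univariate Gaussian mixture fitted by EM with
k-means++-style seeding, a $10^{-6}$ log-likelihood tolerance, a
$10^{-3}$ standard-deviation floor, and components reported by decreasing
mean. The log-likelihood is asserted non-decreasing at every iteration.
Spans are fitted on the raw (not log) scale by default.

## What the synthetic data does and does not emulate

The generator builds a transcriptome of 50 random transcripts of 1–3 kb
(15-mer reuse rejection-sampled away so alignment is unambiguous), plants
500 duplexes whose distal arm is the reverse complement of the facing part
of the proximal arm, with intra-transcript spans drawn from a 50/50 mixture
of N(250, 50) and N(20, 8) — mirroring the bimodal long/short character of
3' UTR duplex spans — arms of 25–40 nt, and a 10% inter-transcript
fraction. Reads of the three classes are emitted with 75–100 nt of
informative sequence, a 6-nt UMI, 20% PCR duplication with occasional
1-mismatch UMI errors, and full or 1–2-nt-truncated linkers in configurable
proportions. Contiguous stem-loop reads are emitted only for duplexes whose
span is at most 10 nt, reflecting that short loops escape RNase digestion.

Planted hairpins for the derivation workflow are written so that the
planted stem is the unique local minimum-free-energy duplex: loop ends are
rejection-sampled to be non-complementary and the base just downstream of
the hairpin is set non-complementary to the base just upstream, so "exact
loop length" is well-defined ground truth.

Reads are error-free by default (an error model would be orthogonal to the
exact-substring linker detection and alignment scoring being tested), the
background sequence is i.i.d. random rather than transcriptome-like, and
expression is not modelled beyond copy-number draws. Passing tests
therefore demonstrate the correctness of the algorithms under their stated
assumptions — unambiguous references, error-free reads — not performance on
real libraries, where mismatch-tolerant external alignments and
experimental peak callers feed the same interfaces.

## Numerical and degenerate-input choices

* Median duplex ends with even member counts use the lower middle value.
* `filter_alignments` keeps ties for the best score per read span so the
  multimap resolver can act; ties surviving to the end are ambiguous.
* The e-value threshold is inclusive (`e <= 0.001` kept), as are the
  unaligned-length (15), gap (4) and start-offset (5) boundaries.
* EM on identical values collapses to one component at the sigma floor;
  k-medoid clustering of identical records warns and returns one cluster.
* Sequences are stored uppercase with U normalised to T internally; N never
  pairs and never seeds an alignment.
* The problem sizes used by the validation suite (2,000-read recovery runs,
  1,000-read oracle-equivalence runs over a 5-kb reference, 200-peak
  derivation runs) were chosen so planted-truth recovery rates have small
  binomial error while each suite section completes in minutes on one core.
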