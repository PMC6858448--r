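---
title: "CRISPRome analysis: models, parameters and design choices"
author: "crisprome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRISPRome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A CRISPR array is a genomic locus of near-identical direct repeats
separated by unique spacers acquired from viruses and other mobile
genetic elements. Amplifying spacers with repeat-specific primers and
deep-sequencing the amplicons yields the *CRISPRome* of a community: the
totality of its spacers, observed as reads of one to three
repeat-spacer units. From that raw material this package reconstructs:

* the spacer inventory (extraction, clustering, diversity),
* the order of spacers in arrays (a directed graph of
  neighbouring-spacer pairs),
* virus-borne *mini-CRISPR arrays* of only 1-2 spacers, distinguished
  statistically from truncated fragments of long arrays,
* protospacer targets, PAM consensus, and whether targeting coincides
  with divergence between closely related viral genomes,
* viral contigs tiled from overlapping spacers.

Every stage is exercised on synthetic communities with planted ground
truth, because raw environmental CRISPRome data is not required for the
package's tests.

# Spacer extraction

Repeats vary between genomes, so repeat and primer motifs are given as
IUPAC-degenerate strings and matched by a Hamming scan
(`scan_motif()`): a window matches when at most `max_mismatch` bases
fall outside the degeneracy sets. Matching is substitution-only; the
stated mismatch allowance (a 2-5 range) is interpreted as Hamming
distance, with defaults of 3 for repeats and 2 for primers, both
exposed as parameters. Overlapping hits are resolved greedily left to
right, preferring lower mismatch counts on ties - a deterministic rule
chosen because the original procedure does not specify one.

Spacers are the maximal substrings strictly between consecutive kept
motif hits (with at least one repeat flank). Two filters follow, at
their published values:

* length: spacers shorter than 25 nt or longer than 60 nt are removed;
* quality: every base must have Phred quality strictly greater
  than 20. The strict reading (`> 20`, i.e. Q21+) follows the verbatim
  phrasing; the floor is configurable.

If the reverse complement of a read carries more repeat hits than the
forward orientation, the read is flipped before extraction, so spacer
order always follows repeat orientation. Consecutive surviving spacers
form the neighbouring-pair observations that drive array
reconstruction; a three-spacer read contributes two pairs.

# Clustering and diversity

Spacers are clustered at 85% identity under an alignment with zero
penalty for terminal gaps (`semi_global_identity()`). Identity is
matches over aligned columns, counting internal gaps as mismatches and
excluding terminal gaps - with one guard: the denominator is floored at
the shorter sequence's length. Without the floor, two unrelated spacers
sharing a chance 5-base terminal overlap would align over just those 5
columns and score identity 1.0; flooring makes an unaligned overhang of
the shorter sequence count as non-matching, which restores the intended
meaning of "85% identity" for spacer-length sequences. The alignment
itself is a standard free-end-gap dynamic program (unit match/mismatch/
gap scores) implemented in C++; ties in the traceback are resolved
deterministically (diagonal, then vertical, then horizontal; endpoint at
the bottom-right-most maximal cell).

Clustering is greedy centroid assignment: unique sequences in
descending abundance (ties lexicographic), each joining the first
earlier centroid at >= 0.85 identity or founding a new cluster. This
mirrors common centroid-clustering practice; the input order rule makes
it deterministic. Cluster abundance is the summed member read count per
sample.

Diversity summaries are single formulas, kept deliberately transparent:
Good's coverage `C = 1 - N/S` with `N` the clusters seen once or twice
and `S` the cluster count (both computed on clusters; whether the
original computed `N` on sequences or clusters is ambiguous, so the
rare-count ceiling is a parameter); Shannon entropy in nats; Chao1
`S + F1^2/(2 F2)`, switching to the bias-corrected
`S + F1(F1-1)/(2(F2+1))` when doubletons are absent to avoid division
by zero. The loss-of-spacers confidence half-width is
`z(0.975) * sqrt(lost (1-lost) / N)`.

Cross-repeat-type intersection (primer specificity) asks, for each
ordered pair of repeat types, what fraction of type-i spacers have a
counterpart among type-j spacers within 2 mismatches, allowing end gaps
and insertions: the shorter sequence is aligned globally within the
longer (free ends on the longer only), and mismatches plus internal
gaps must total at most 2.

# Array reconstruction and the 5% chimera rule

All neighbouring-spacer pairs of a sample form a directed graph: nodes
are spacer clusters, edge weights are pair multiplicities. PCR can
join spacers from different arrays into chimeric pairs (template
switching), which appear as low-weight edges. For each edge (u, v) the
filter compares its weight with 5% of u's total outgoing weight and 5%
of v's total incoming weight, both computed once from the unfiltered
graph (a single pass, one test per edge).

The rule has two readings and the package implements both. Under the
conjunctive reading ("both"), an edge is removed only when it is below
the threshold against *both* sums; under the disjunctive reading
("either"), below either sum suffices. The default is "either", for a
structural reason: a chimeric edge whose head has no other incoming
evidence - the leader-proximal spacer of an array, or a mini-array
spacer - constitutes 100% of its own incoming sum, so the conjunctive
rule can never remove it, and precisely those spacers are frequent
chimera targets. The concern that motivates the conjunctive reading
(protecting the sole edge of a rare array) is unfounded under the
disjunctive rule too: a sole edge is ~100% of both of its endpoint sums
and is always retained. The conjunctive variant remains available via
`mode = "both"` for the case it does handle better - a true low-weight
edge into a hub spacer shared by arrays of very different abundance.

How much coverage does the 5% rule need? A chimeric edge of weight 1 is
removed when its tail's outgoing sum exceeds 20, i.e. when the true
junction it displaced was sequenced at least ~21 times; a weight-2
chimera (the same template switch sampled twice) needs ~41. The default
synthetic community is therefore dimensioned to give every true
junction ~45x expected coverage, which puts Poisson fluctuations below
these thresholds with large margin. This analysis fixed the default
depth before any test was run and is the reason the planted-truth check
demands *all* chimeric edges removed with zero true-edge losses.

Cycles (possible only through noise) are broken at the minimum-weight
edge of each detected cycle, with a lexicographic tie-break. Array
paths are then all maximal source-to-sink paths of the DAG; branches
yield one path per branch, and isolated nodes single-spacer paths. Node
eccentricity - the spacer count of the longest path through a node - is
computed by dynamic programming over the DAG and checked in the tests
against exhaustive path enumeration.

When several samples are available, components whose mean
log10(count+1) abundance profiles correlate at Pearson r >= 0.9 are
grouped by single linkage, reflecting that one genome usually carries
several arrays with the same repeat.

# Mini-CRISPR array statistics

Mini-arrays carry 1 or 2 spacers by definition, so every reconstructed
path of length <= 2 in a component of eccentricity <= 2 is a candidate;
the test asks whether it is a complete mini-array or a truncated
fragment of a long array.

For a single spacer sequenced `N` times, let `p` be the per-sample
probability that a spacer observation lies in a read with two or more
spacers (estimated directly from the sample as the multi-read fraction
of observations). If the spacer actually had a neighbour, never seeing
a pair across `N` observations has probability `P = (1-p)^N`. For a
pair sequenced `N` times, each spacer appears first with probability
0.5, so observing one spacer only ever first and the other only ever
second across the remaining `N-1` pairs has probability `0.5^(N-1)` per
side, giving `P = 1 - (1 - 0.5^(N-1))^2` that the two-spacer array is
complete. The implementation evaluates the algebraically identical
`x(2-x)` with `x = 0.5^(N-1)`, which stays exact where the literal
form underflows (N above ~55).

Calling uses two gates, reported separately: `P < alpha` (default
0.01) and a fixed abundance threshold of `n = 100` (one spacer) or
`n = 20` (two spacers). The fixed thresholds are deliberately more
conservative than the formula minima (`min_abundance_threshold()`
gives N = 7 at p = 0.5 and N = 9 respectively); both the principled and
the conservative gate are kept because the published analysis chose the
conservative ones.

# Protospacer analysis

Spacer-to-genome matching is seed-and-extend: exact 8-mer seeds on both
strands anchor ungapped full-length comparisons, and hits need >= 85%
identity over the full spacer length. Identity is ungapped because at
spacer lengths (25-60 nt) a full-length identity gate makes gapped
extension an unnecessary complication; the e-value gate of a
general-purpose search is replaced by this identity threshold, which is
what actually defined protospacers in the analysis this package
reimplements. A hit with `m` mismatches retains an exact 8-mer only
when `(m+1)*8 <= length`; the per-spacer `seed_guaranteed` flag makes
this theoretical miss condition visible, and the tests compare the
matcher against a sliding-window oracle in the regime where seeds
survive. Overlapping same-strand hits of one spacer are merged (>= 50%
overlap, best identity kept) to avoid double counting. PAM profiles are
built from 10 nt flanks oriented to the protospacer strand, on both
sides - no side is assumed - with majority consensus above 0.5
frequency and `N` elsewhere.

For the targeting/divergence question, a two-genome alignment is
classified per column (identical, no gap), and a protospacer span
counts as "conserved" only if every column in it is identical; a 50 bp
windowed identity track is emitted for reporting. Per-column
classification is the default because a windowed definition would make
"fully conserved" depend on an arbitrary window phase. The test then
simulates 10,000 spacers at uniform random alignment positions with
lengths resampled from the observed spans, classifies them, and
compares the observed conserved/variable split with the simulated
proportions by a df = 1 chi-square goodness of fit (expected counts
scaled to the observed total). A 2x2 contingency chi-square of the raw
observed vs simulated counts is reported alongside: for the
published-style counts (22, 42 observed vs 5674, 4326 simulated) the
goodness of fit gives a statistic of ~13.0 and P ~ 3e-4, which does not
match the printed P = 0.006 of the source analysis - the exact variant
used there is not stated, so both framings are exposed and the
goodness-of-fit result is primary. Genome coverage by protospacers is
an interval union divided by genome length.

# Spacer tiling assembly

Spacers sampled densely from one viral genome overlap each other, so an
all-vs-all match graph (edge when the best ungapped extension from a
shared 8-mer reaches identity > 0.7 over the overlap, either strand)
decomposes into components that tile contiguous genome stretches.
Identity is computed over the overlap, not the full spacer length,
because partial overlap is exactly the signal when spacers tile a
genome; overlaps shorter than the 8-mer seed are not considered. Each
component is laid out greedily from its highest-degree spacer by
descending edge identity, orientations propagated along the overlaps;
edges whose implied offset disagrees with the layout by more than 2 nt
are dropped (logged) and the component re-decomposed - this replaces
the manual alignment curation of the original procedure with a
deterministic, reviewable rule. The consensus is the per-column
majority base with lexicographic tie-break.

# The synthetic community

`generate_community()` and `generate_amplicon_reads()` define the study
conditions the tests run under:

* 20 host strains, one long array each of 10-30 spacers (35-45 nt),
  under a single repeat consensus by default; strain abundances from a
  3-component log-normal mixture (medians 300/500/800, sdlog 0.1),
  giving the multimodal abundance structure seen in community
  CRISPRome data.
* 5 viral genomes carrying a 120 nt leader followed by a mini-array of
  1-2 spacers; viral abundance log-normal around 1200, higher than the
  hosts because mini-array-carrying viruses dominate the samples they
  occur in.
* Reads of 1-3 repeat-spacer units (probabilities 0.3/0.4/0.3), merged
  single amplicons of 250 nt, primer-flanked, sampled from replicons
  proportionally to abundance x array length so that per-spacer
  coverage is proportional to abundance alone; depth 3 reads per
  abundance unit (~50,000 reads), dimensioned so every true junction is
  covered ~45x (see the 5% rule analysis above) and every mini-array
  spacer >= 200x.
* Substitution errors at 0.5% per base, applied after read assembly so
  that the same seed with a different rate yields the same templates;
  Phred qualities from a truncated normal (mean 35, sd 3, floor 2).
* Chimeras: each junction switches template with probability 1% to a
  different array (chosen abundance-proportionally, entered at a
  uniform position), continuing along the foreign array - the
  template-switch model of PCR chimera formation. The truth tables
  record every extractable unit and every junction with its chimeric
  flag.

What the generator does *not* emulate - and what passing tests
therefore do not demonstrate about real data: PCR efficiency and
primer bias, indel sequencing errors, unmerged read pairs and merge
artifacts, repeat variants beyond a per-strain IUPAC realisation,
within-community homology between spacers, and contamination. The
repeat consensuses shipped as defaults are synthetic stand-ins for the
principal repeat families, constructed for the generator rather than
taken from any database.

The diverged genome pair generator plants a conserved/variable block
mosaic (40% variable blocks of 500 nt) with per-column substitution
rates chosen to hit a target identity (0.92 by default, realised
within +-0.01 on 20 kb), and places protospacers with a configurable
odds ratio favouring variable-overlapping spans. The power check in
the acceptance tests uses an odds ratio of 3 with 64 protospacers - a
moderate enrichment comparable to the ~2.5 marginal odds ratio implied
by the 22/42 vs 5674/4326 split - where the analytic noncentral
chi-square power at alpha = 0.01 is ~0.97.

# Numerical and degenerate-input choices

* All coordinates are 0-based, half-open.
* Alignments, layouts and consensus calls resolve every tie
  deterministically (documented above), so identical seeds reproduce
  identical artifacts byte for byte; the pipeline manifest records MD5
  hashes to make this checkable.
* `two_spacer_pvalue()` uses the cancellation-free form `x(2-x)`.
* Chao1 switches to its bias-corrected form when `F2 = 0`.
* Empty inputs are errors where a statistic is undefined (empty count
  vectors, zero spacer-bearing reads, degenerate single-class
  conservation tracks) and empty results where emptiness is meaningful
  (motif longer than the read, genome shorter than the spacer).
* Problem sizes in the test suite: the planted-truth check runs the
  full ~50,000-read community once; oracle equivalences use 5 kb
  genomes, 200 random DAGs of <= 12 nodes, and ~80 spacers all-vs-all;
  the calibration check uses 500 null replicates of the coincidence
  test at its full 10,000-spacer simulation size. These sizes keep the
  whole suite in a few minutes while leaving each check statistically
  meaningful.

# Known limitations

* Motif matching is substitution-only; an indel inside a repeat shifts
  the frame and usually costs that read's spacers.
* The chimera filter reasons about weights only; a systematically
  recurrent template switch (weight comparable to true junctions)
  would survive it.
* Greedy centroid clustering depends on the abundance ordering in the
  usual way: it is deterministic, but not an optimal partition.
* The protospacer matcher can miss hits whose mismatch pattern breaks
  every exact 8-mer; the miss condition is reported but not worked
  around (no reduced word size fallback).
* `correlate_components()` needs at least two samples; with the
  default single-sample simulation it is exercised only in unit tests.
* The toy global alignment setting for diverged pairs is
  substitution-only; genomes with real indels must be aligned
  externally and supplied as an alignment.
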