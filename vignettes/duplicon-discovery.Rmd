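---
title: "Duplicon discovery from alignment matrices: model and methods"
author: "dupmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Duplicon discovery from alignment matrices: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupmosaic)
```

# The problem

Segmental duplications (SDs) and copy number variants (CNVs) are mosaics of
smaller duplicated subunits, duplicons, that were juxtaposed by recurrent
duplication from seeding blocks.  Because the same duplicon recurs in many
SDs, conventional multiple alignment of whole duplication blocks cannot
delineate the subunits.  `dupmosaic` instead works from the *coverage
pattern*: when all SDs are aligned against one CNV, a true duplicon shows
up as a column block covered by many SD rows at once, while spurious
alignments scatter short, thin runs.

# The alignment matrix

For CNV *k* of length $n_k$, `build_matrix()` constructs the binary
$m \times n_k$ matrix $A_k = (a_{ij})$ with $a_{ij} = 1$ when SD $i$ aligns
over position $j$.  Conventions:

* Rows are indexed by distinct SD; all HSPs of one SD are OR-ed together and
  overlapping or book-ended spans are merged into maximal 1-runs
  (`IRanges::reduce`).
* Coordinates are 0-based half-open internally; BLAST tabular input is
  1-based inclusive and converted on read (reversed subject coordinates are
  normalised with strand `-`); BED output is 0-based half-open.  These are
  the standard conventions of each format and round-trip bit-exactly.
* Strand is recorded but ignored by the matrix: coverage is
  orientation-free.
* Tabular alignments carry no per-base detail, so by default the whole HSP
  span is marked.  When a 13th match-mask column is present
  (`"a-b,c-d"` matched subject segments), strict mode marks only matched
  bases, excluding gaps and mismatches.

The matrix is stored as per-row run lists, never densely; `column_stats()`
derives the observation sequence $o_j$ (1s per column) and the
adjacent-column pattern counts $f_{1,1}, f_{0,1}, f_{1,0}$ by difference
arrays in $O(\text{runs} + n_k)$.

# The hidden Markov model

States are $S = (D_1, D_2, N)$: two interchangeable duplicon states —
needed so that two *adjacent* duplicons are decoded as distinct segments
rather than one — and a non-duplicon state.

**Initial distribution.** Probability $1/2$ on $D_1$ and $1/2$ on $N$.
Because $D_1$ and $D_2$ are exchangeable, giving the prior to one duplicon
state only loses no generality; $D_2$ is reachable by switching, and its
zero prior is a true $-\infty$ in log space.

**Transitions** are *non-homogeneous*: the matrix used between columns $j$
and $j+1$ is built from that pair's pattern counts.  With
$\omega = f_{1,1}/(f_{1,1}+f_{0,1}+f_{1,0})$ and
$\gamma = f_{0,1}/(f_{0,1}+f_{1,0})$, a duplicon state stays with
probability $p\omega$, switches to the other duplicon state with
$(1-p\omega)\gamma$, and exits to $N$ with $(1-p\omega)(1-\gamma)$, where
$p = 1 - 1/L$ is the self-transition base probability of a geometric
length prior with mean $L$.  The three transitions out of $N$ are $1/3$
each.  Degenerate denominators resolve conservatively: no coverage
evidence gives $\omega = 0$, no switching evidence gives $\gamma = 0$, so
absent evidence never invents a duplicon.

**Emissions.** A column with $k$ of $m$ rows set emits
$P_d = \sum_{i=0}^{k} \binom{m}{i} P_o^i (1-P_o)^{m-i}$ (the binomial CDF,
computed by `stats::pbinom`, stable for $m$ up to $10^5$) in a duplicon
state and $1 - P_d$ in $N$.  $P_o$ is the probability that a random SD
carries a given duplicon (mean duplicon copy number over the number of
library SDs).

**Decoding.** `viterbi()` runs in log space with a probability floor
(default $10^{-300}$) applied before logs — zero-probability transitions
stay structurally impossible in effect but never produce NaN — and breaks
exact ties deterministically, preferring $N$ over $D_1$ over $D_2$
(conservative calls).  A zero-row matrix decodes to the all-$N$ path.
Maximal runs of at least `min_len = 100` duplicon states become candidate
duplicons.

# The permutation test

The copy number of a candidate is its mean column coverage.  The null
model asks: could a segment of this copy number arise if each SD's
alignment mass were placed at random?  `permute_matrix()` relocates the
1-runs of every row independently: run lengths are preserved exactly, run
order is shuffled, and the gaps are drawn uniformly over all arrangements
that keep runs separated — interior gaps of at least one zero (so the run
multiset is conserved and runs stay maximal; this is always feasible since
the original row satisfied it) with free end gaps.  For a single run this
reduces to a uniform draw over all valid start positions.  Each of
$B = 100$ artificial matrices is re-decoded by the same HMM and its
maximum candidate copy number recorded; one null is shared by all the
matrix's candidates.  The P value is the fraction of artificial maxima
*strictly* exceeding the observed copy number (ties do not count against
the candidate), so it takes values in $\{0, 1/B, \dots, 1\}$ and a
significant call at $\alpha = 0.01$ with $B = 100$ means no artificial
maximum reached it.  Surviving calls on the same CNV with reciprocal
overlap of at least 95% are collapsed, keeping the lowest P value; an
optional sequence mode instead collapses calls matching at ≥ 95% identity
over ≥ 100 bp.

# Downstream mosaic analyses

* **Profiles** (`build_profiles`): a duplication segment with ten or more
  distinct duplicons (at ≥ 95% identity, ≥ 100 bp) gets a presence/absence
  bit vector.  Distance is the Hamming fraction — the simplest metric on
  binary vectors; segments sharing no duplicon are flagged as having no
  related evolutionary history.
* **Trees** (`nj_tree`): standard neighbor joining (`ape::nj`), leaves
  sorted lexicographically first so results are deterministic.  NJ is
  exact on additive distances, which the test suite exploits.
* **Core duplicons** (`core_duplicons`): a duplicon present in strictly
  more than 67% of a clade's leaf segments.  Clades are taken as every
  internal node with ≥ 3 leaves — a stated convention, since no canonical
  clade delimitation exists for profile trees.
* **Flanking pairs** (`flanking_pairs`): two copies of one duplicon lying
  wholly within the first and last 25% of a CNV.  With sequences
  available, "one duplicon" means pairwise identity > 90% and length
  ratio > 0.90; in coordinate-only mode, equality of duplicon id stands in
  for the identity test (the ratio is then implied).
* **Weighted density** (`weighted_density`): each duplicon weighs its
  frequency among training CNVs; a region's density is the summed weight
  of occurrences with ≥ 50% of their bases inside, per base.  The ≥ 50%
  membership rule avoids double counting across a partition of the genome
  except at exact ties.  Non-CNV regions are the complement of merged CNVs
  within chromosome bounds; CNV versus non-CNV densities are compared by
  Welch's two-tailed unequal-variance t test.

# Synthetic data and what it does (not) show

`generate_matrix()` plants duplicon column-blocks carried by a
Bernoulli(carrier fraction) subset of rows and adds background noise:
per row a Poisson(`noise_rate`, default 2) number of runs with geometric
lengths (mean 20 bases) at uniform positions — mimicking short spurious
alignments, for which no canonical generative model exists.
`generate_segment_set()` emulates duplication groups descended from common
seeding blocks (within-group duplicon sharing, zero cross-group sharing,
one designated core present in 80% of the group).  `generate_flanked_cnv()`
plants flanking pairs in the terminal 25% windows.  All generators are
bit-reproducible given a seed.

These fixtures reproduce the *coverage statistics* the decoder exploits,
not real sequence evolution: no nucleotide-level divergence, no
length-correlated identity decay, no assembly collapse of near-identical
copies, and block boundaries are exact rather than frayed by alignment
trimming.  Passing tests therefore demonstrate the statistical machinery
(decoding, calibration of the permutation null, profile clustering), not
performance on a particular genome build.

## Choosing $P_o$

$P_o$ is the one parameter without a universal default, because it is a
property of the duplicon library (mean copy number / library size); 0.05
is the package default for real libraries.  For the planted-block
simulations the suite uses $P_o = 0.2$, from the design rule that
$m P_o$ — the emission model's break-even coverage — must sit between the
expected background column coverage (about 4 of 50 rows under the default
noise model) and the planted duplicon coverage (about 40 of 50 rows): at
$m P_o = 10$ the cumulative-binomial emission cleanly separates noise
columns from duplicon columns.  Mis-setting $P_o$ below the background
coverage makes the duplicon states absorb noise; far above the carrier
coverage, true blocks are missed.

# Problem sizes in the test suite

Structure-recovery simulations use $m = 50$ SD rows, $n = 500$ columns, a
150-column planted block at carrier fraction 0.8, $B = 100$ permutations
and 50 seeds for each of the planted and pure-noise conditions; exhaustive
Viterbi cross-checks enumerate all $3^n$ paths for $n \le 8$, $m \le 5$;
NJ exactness uses 100 random additive trees with up to 8 leaves.  These
sizes give stable pass/fail behaviour at desk scale while exercising every
code path.

# Known limitations

* The permutation null relocates runs within their own row only,
  preserving each SD's alignment budget; cross-row relocation would be a
  different (less conservative) null.
* Copy numbers and the permutation test are per-CNV; an SD aligning to
  several CNVs contributes independent rows to each matrix.
* The coordinate-only flanking mode cannot detect pairs whose copies were
  annotated under different duplicon ids.
* Profile distances treat all duplicons equally; weighting by duplicon
  length or copy number is deliberately out of scope.
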