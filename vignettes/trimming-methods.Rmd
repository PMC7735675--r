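---
title: "Retaining informative sites: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retaining informative sites: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimkit)
```

## The trimming model

Alignment trimming is usually framed as outlier removal: score each column
for divergence, entropy or gappyness and excise the worst. That framing has
a documented failure mode — the removed columns often carry phylogenetic
signal, and inference accuracy can drop with the number of sites removed.
`trimkit` frames the problem the other way around: classify each column by
the signal it demonstrably carries and *retain* the informative ones.

Each column is assigned exactly one of three labels from its non-gap
character states (case-folded):

* **parsimony-informative** — at least two states each occur in at least
  two taxa. These are the sites that discriminate between topologies under
  parsimony, and they remain informative under likelihood models.
* **constant** — exactly one state occurs in at least two taxa; singleton
  states are ignored. Constant sites carry no topological signal but inform
  the base/residue frequencies of substitution models.
* **other** — no state reaches two taxa: singleton-only columns, columns
  with one residue in one taxon, and all-gap columns. Such columns are
  exactly the "aberrant sites" flagged by earlier work on alignment
  artifacts; the classification removes them implicitly, with no null model
  needed.

The three labels are mutually exclusive and exhaustive, and every column is
classified independently of every other column, so classification commutes
with any column subset and with taxon reordering.

**Gappyness** is the exact fraction of taxa with a gap/missing symbol at
the column. The five modes combine the two per-site quantities as shown in
the README table. Two points deserve emphasis:

* The gap comparison is **strict** (`keep iff gappyness < g`). A 10-taxon
  column with exactly 9 gaps has gappyness 0.9 and is *removed* at the
  default `g = 0.9`. Because gappyness is a ratio of small integers, the
  boundary behaves exactly; there is no floating-point tolerance at the
  threshold. Consequently `g = 0` removes every column and `g = 1` removes
  only fully gapped ones.
* All five keep rules are pointwise predicates on (classification,
  gappyness), which yields the mode lattice `kpi ⊆ kpic`,
  `kpi-gappy = kpi ∩ gappy`, `kpic-gappy = kpic ∩ gappy`, idempotence of
  every mode, and monotonicity of the kept set in `g`. The test suite
  asserts all of these as properties over generated alignments.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `gappy` | keep rule; `gappy` is the least aggressive and the default |
| `g` | 0.9 | gappyness threshold, dimensionless fraction in [0, 1]. Very high thresholds are recommended in practice; lower values can remove so many sites that inference worsens |
| `gap_chars` | `-?*X` (+`N` for DNA) | symbols counted as missing; case-insensitive, user-overridable |

The gap set deserves a note: no universal convention exists for which
symbols denote missing data. `-` is always a gap; `?` and `*` conventionally
mean unknown/stop; `X` is an unknown residue; `N` an unknown base. We treat
`N` as missing only for nucleotide data (for amino acids `N` is asparagine).
Every other symbol — including IUPAC ambiguity codes such as `R` or `Y` —
counts as its own character state, because expanding ambiguity codes into
state sets would require assumptions the classification definition does not
license. Users who prefer ambiguity codes to be missing can add them to
`gap_chars`. The nucleotide/amino-acid decision itself uses a 0.80
non-gap-fraction rule (`detect_sequence_type()`), tolerant of ambiguity
codes in DNA while rarely misclassifying proteins.

## File formats

Eight formats are read and written: FASTA, Clustal, MAF, XMFA (Mauve's
extended multi-FASTA), strict/sequential/relaxed PHYLIP, and Stockholm. The
contract is exact sequence fidelity: `read(write(a, F))` reproduces taxon
order, labels and the character matrix for every format, and the sniffer
returns `F` for files this package writes. Trimming operates on single
alignments, so multi-block MAF/XMFA files yield their first block plus a
warning. `.` is normalized to `-` on input from Stockholm/MAF, where it is
a gap convention.

The unqualified name "phylip" is taken to mean the strict interleaved
dialect (10-character fixed-width label field). Distinguishing the three
phylip dialects from content alone is genuinely ambiguous in corners, so
the writers commit to recognizable shapes — strict: sequence begins at
column 11 in space-separated groups of ten; relaxed: label padded to at
least eleven columns, continuous sequence; sequential: label on its own
line — and the sniffer tries strict, then sequential, then relaxed.
Content matching no clean signature (including zero-length alignments,
where every dialect degenerates to bare labels) is read as relaxed with a
warning. Strict phylip refuses labels longer than ten characters rather
than silently truncating them, because truncation would break round-trip
fidelity; relaxed phylip exists for long labels.

Empty trimmed alignments are written, with a warning and exit status 0:
aggressive settings can legitimately empty an alignment, and a batch
pipeline over thousands of genes should receive a (empty) file and a
warning, not an abort.

## Evaluation machinery

Benchmarking trimming strategies requires comparing the trees they lead to.
The package implements the standard quantities:

* **Normalized Robinson–Foulds**: the symmetric difference of the two
  trees' non-trivial bipartition sets divided by the total bipartition
  count of both trees — `2(n−3)` for two binary trees, and a graceful
  degradation for multifurcating ones (two identical star trees are at
  distance 0). Bipartition enumeration is implemented here directly
  (postorder accumulation of tip sets, canonicalized against the
  lexicographically smallest leaf) and is cross-checked in the tests
  against an independent enumeration route.
* **Average bipartition support**: the arithmetic mean of numeric
  internal-node labels (e.g. bootstrap percentages); nodes without a
  numeric label are skipped, and a tree with none is an error rather than
  a silent `NaN`.
* **Desirability integration**: to combine an accuracy metric (low is
  best) and a support metric (high is best) on one scale, each is linearly
  rescaled per gene across strategies to [0, 1], anchored so the best
  observed value maps to 1 and the worst to 0, then clamped. The printed
  piecewise forms of this transform in the literature are not always
  internally consistent about the boundary inequalities; clamping
  reproduces the stated anchors exactly within the observed range, which is
  the property that matters, and is the semantics implemented. When a
  metric does not discriminate (all values equal) every strategy receives
  1.0 on it, so a non-discriminating metric cannot reorder strategies.
  The two desirabilities are integrated by arithmetic mean by default — a
  geometric mean is available, but it annihilates a strategy's score
  whenever either metric hits its observed worst, which is rarely the
  intended reading. Strategies are ranked per gene by descending
  integrated score with average ranks on ties (ties are common: many genes
  leave several strategies' trees identical), and ordered overall by mean
  per-gene rank; ordering by mean integrated score is available as an
  option.
* **Branch-length accuracy**: Spearman rank correlation between branch
  lengths of two *topology-matched* trees, pairing internal edges by the
  bipartition they induce and terminal edges by leaf label. Requiring
  identical bipartition sets is deliberate — pairing edges across
  different topologies is not well defined — and mirrors the practice of
  constraining re-estimated trees to the reference topology before
  comparing lengths. Identical and perfectly rank-reversed length vectors
  return exactly ±1 (detected on the rank vectors) rather than
  floating-point neighbors of ±1.

Newick parsing and serialization delegate to `ape`, the de facto standard,
with an added balanced-parenthesis check that reports the offset of the
first imbalance.

## The synthetic-data generator

Two generators make every module testable without external data.

**Designed alignments** (`make_designed_alignment()`) build columns that
classify exactly as requested, with gappyness snapped to the nearest
realizable fraction: a parsimony-informative column needs ≥ 4 non-gap
cells, a constant column ≥ 2, and an "other" column can hold at most one
cell per alphabet symbol unless fully gapped (with the 4-letter DNA
alphabet, an "other" column in 10 taxa needs ≥ 6 gaps). The generator's
output is verified against the classifier itself in the tests — that
round trip is the module's acceptance gate.

**Sequence evolution** (`evolve_sequences()`) simulates a root sequence
drawn from the stationary frequencies and evolves it down each branch
under a continuous-time process in which substitutions, insertions and
deletions share one event queue (Gillespie event sampling; substitution
events are thinned against the fastest-leaving state, which keeps
per-event cost constant). Defaults follow common simulated-benchmark
practice: nucleotide stationary frequencies 0.1, 0.2, 0.3, 0.4 for
T, C, A, G; insertion and deletion rates each 5% of the substitution rate
for nucleotides (1% for amino acids, each per process, matching how
simulators parameterize insertions and deletions separately); indel
lengths from a power law with exponent 1.7 truncated at 500; root sequence
length 1,000 by convention (tests use shorter roots; see problem sizes
below). Exchangeabilities default to all-equal — making the default
nucleotide model F81-like — because a specific GTR exchangeability scheme
is dataset-dependent; a full GTR matrix can be supplied. Insertions create
fresh homology columns tracked in a global registry, so the returned
alignment is the true alignment of surviving sites, with `-` where a
lineage deleted or never had the site.

What the simulator deliberately does **not** emulate: among-site rate
heterogeneity (no Gamma rates), codon structure, selection, alignment
error. Designed alignments likewise have no phylogenetic autocorrelation
between columns. Passing tests therefore demonstrate correctness of the
classification, trimming and evaluation machinery under controlled
conditions — they do not demonstrate that any trimming strategy improves
inference on real data, which is an empirical question outside what a unit
test can answer.

## Numerical choices and degenerate inputs

* Gappyness and the threshold comparison are exact small-integer ratios;
  no epsilon is applied at the boundary.
* Desirability with `A == B` returns all 1.0 (degenerate distribution).
* Rank ties take average ranks everywhere, keeping mean-rank summaries
  stable under strategy permutation.
* All-gap columns classify as "other" and have gappyness 1.0; zero-length
  alignments classify to an empty table, trim to themselves, and write
  valid files for all eight formats.
* The log prints gappyness with four decimals; positions are 1-based.
* All generator randomness is seed-controlled and restores the caller's
  RNG state; identical seeds give identical alignments.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path while remaining quick to re-run: exhaustive
classification checks over all 5⁶ length-6 columns; 1,000 designed
alignments for the mode-lattice property; 200 random tree pairs (up to 20
leaves) for the RF oracle; stationarity checked on a 4-taxon tree with
branch lengths of 2 substitutions/site and a 3,000-site root, which puts
the empirical base composition within ±0.02 of the stationary values with
comfortable margin. The full-scale published benchmarks this style of tool
is evaluated on (tens of thousands of gene alignments, trees inferred by
maximum likelihood) require external tree-search software and are outside
the package's scope; only their design arithmetic is reproduced.

## Known limitations

* Trimming removes columns only; taxon (row) filtering and masking-in-place
  are out of scope.
* Classification counts every non-gap symbol as a state; ambiguity codes
  are neither expanded nor (by default) treated as missing.
* `normalized_rf` compares leaf-labeled topologies only; it does not weight
  by branch length or support.
* The simulator is adequate for generating gap-bearing test fixtures with
  known dynamics, not a replacement for a full-featured sequence simulator
  (no rate heterogeneity, no codon or empirical amino-acid matrices beyond
  user-supplied exchangeabilities).
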