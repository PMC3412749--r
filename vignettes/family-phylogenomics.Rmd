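---
title: "Mining and molecular evolution of conserved-motif gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and molecular evolution of conserved-motif gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ugtfam)
```

## The scientific problem

Plant family-1 UDP glycosyltransferases (UGTs) attach sugars from
UDP-activated donors to hormones, secondary metabolites and xenobiotics.
The family is large (tens to hundreds of genes per genome) and is
recognizable by a single diagnostic feature: the PSPG box, a 44-residue
motif near the C terminus that binds the UDP-sugar donor.  A genome-wide
study of such a family typically proceeds in five steps, and `ugtfam`
implements each of them as a reusable, testable stage:

1. **Mining** — scan every predicted protein with the 44-residue
   consensus, keep genes whose best window scores high enough, then
   filter by protein length (375--530 residues) and intron count (at
   most 2), the architecture characteristic of this family.
2. **Phylogeny** — build a neighbour-joining tree from the family
   protein alignment, attach bootstrap supports, and name groups by
   anchoring them to reference sequences of known classification.
3. **Intron evolution** — compute intron positions and phases from the
   gene models, project them onto the family alignment, cluster nearby
   positions into conserved intron classes, and reconstruct gain/loss
   events on the tree by Dollo parsimony.
4. **Homology structure** — find recently duplicated pairs (global
   identity at or above 90%), best-hit orthologs in comparator
   proteomes, and "diverged" genes with no qualifying ortholog anywhere
   at the E < 1e-100 cutoff.
5. **Expression** — count ESTs per gene and tissue by mapping them onto
   the coding sequences, summarize per gene/group/tissue, order
   expression matrices by correlation clustering, and quantify qPCR
   tables by the comparative-CT method.

Real inputs of this kind (a draft genome, public EST libraries, a
microarray series) cannot be redistributed or re-downloaded at desk
scale, so the package carries a first-class synthetic-data generator
whose ground truth exercises every stage end to end.

## Models and procedures

### Motif scan

The scan is an ungapped sliding window: for protein $x$ and motif $m$,
the window score at offset $o$ is $\sum_{i=1}^{44} S(m_i, x_{o+i-1})$
with $S$ a substitution matrix (BLOSUM62 by default, half-bit units).
The best window per protein is reported when it reaches `min_score`,
which defaults to 50% of the motif's self-score.  Classic motif screens
used a BLAST search with a single 44-residue query; a consensus scan is
the faithful desk-scale equivalent, and no screening threshold is ever
reported, so the 50% default is a declared package choice (it tolerates
the simulator's motif drift while rejecting every random window we have
ever generated).  Ties go to the smallest offset.

### Distances, neighbour joining, bootstrap

Pairwise distances exclude, per pair, every column where either row has
a gap.  Two models are exposed: the raw p-distance and the Dayhoff
correction $d = -\ln(1 - p - 0.2\,p^2)$, which saturates when the
argument is non-positive; such pairs fall back to $p$ and are flagged.
Which correction a given desktop phylogenetics suite applied is usually
not recoverable from a methods section, so both are options and neither
is asserted as "what was done"; the default is `p_distance`.

Trees come from the standard Saitou--Nei agglomeration
(`ape::nj`); negative branch-length estimates are clamped to zero and
counted.  Bootstrap supports resample alignment columns with
replacement; replicate $r$ draws its RNG substream from the pair
(seed, $r$), so enlarging `n_reps` never reshuffles earlier replicates.
Support is the percentage of replicate trees containing each internal
bipartition of the full-data tree.

Parsimony is used as a consistency check (a Fitch small-parsimony score
with gaps treated as missing), not as a second tree search: studies of
this kind report concordant groupings between distance and parsimony
trees rather than a separate parsimony topology.

### Group assignment

After midpoint rooting, a leaf receives the label of the smallest clade
that (a) has bootstrap support at or above the threshold (default 85,
the support level used to define groups in this literature), and (b)
contains reference leaves of exactly one group.  Leaves in no such
clade stay `unassigned` — a deliberate behavior: with poorly supported
deep structure the method refuses to guess.

### Intron classes and Dollo events

An intron's phase is its CDS offset modulo 3 (0 between codons, 1 after
the first base, 2 after the second), and its protein position is
`floor(offset / 3) + 1` — one uniform formula for all phases, placing a
phase-0 intron on the residue that follows it.  Projected onto the
family alignment, introns from different genes cluster by single-linkage
with a merge radius of 45 alignment columns.  The field describes
conserved introns as lying "within 40--45 residues" of the class mean;
we take the permissive end as the default because it minimizes false
class splits, ship the radius as a parameter, and include a 40-vs-45
sensitivity test.  A class is called conserved when its members span at
least 2 phylogenetic groups or at least 10 genes; published narratives
imply breadth rather than a numeric cutoff, so both knobs are explicit.

Under Dollo parsimony each class is gained exactly once, at the most
recent common ancestor of the genes that carry it; the loss set is the
collection of maximal subtrees inside the gain clade containing no
carrier — provably the minimal explanation, found in one post-order
pass.  An unconstrained Fitch reconstruction is also available; Dollo
can never need fewer events, and a property test asserts exactly that.
A class whose gain maps to the root is flagged ancestral — reported as
a derived statement, never assumed.

### Homology calls

Duplicates and orthologs rest on optimal global alignment with affine
gaps (Needleman--Wunsch via `Biostrings::pairwiseAlignment`; open 10,
extend 0.5, BLOSUM62).  Identity is matches over aligned non-gap
columns.  The E-value uses the ungapped Karlin--Altschul form
$E = K\,m\,n\,e^{-\lambda S}$ with $\lambda = 0.318$, $K = 0.13$ (the
ungapped BLOSUM62 half-bit constants) and search space
$m \times n$.  This reproduces the *ordering* a BLAST search gives at
desk scale; absolute calibration differs from gapped local BLAST
statistics, which matters only near the diverged-gene cutoff and is
accounted for in the simulator design below.  Duplicate pairs are all
unordered pairs at identity $\ge 0.90$ (the conventional similarity level for
calling recent duplicates in these surveys); diverged genes are queries with no
comparator hit below $E = 10^{-100}$ in any proteome, the cutoff
conventional in such ortholog screens.

### Digital expression and ΔCT

EST mapping seeds exact 11-mers against an index of the coding
sequences, extends each seeded diagonal without gaps over the full
overlap, and assigns the EST to the single best gene by
identity × matched length, requiring identity ≥ 0.95 over ≥ 100 nt (or
the whole EST when shorter).  Published analyses of this kind name BLAST
but no cutoffs; these defaults are declared package choices, set so that
mapping is exact at a realistic 1% EST error rate — and verified to be
so against the simulator's planted counts.  Equal-best ties across
genes are discarded and counted rather than split, because published
EST tallies are integers per gene.  Every run satisfies
mapped + unmapped + ties = input ESTs by construction, and a test
asserts it.

Summary statistics are printed under two explicit rounding conventions:
round-half-up to 2 decimals (default) and truncation, because published
percentage tables mix both (62.04% = 85/137 rounds, while 43.79% =
60/137 truncates).  The convention is a parameter, never a silent
choice.

Expression matrices are ordered by average-linkage clustering of
$1 - r$ (Pearson) distances; count tables are log2(x+1)-transformed
first and flagged.  Zero-variance rows have undefined correlation and
are pushed to the maximum distance of 2, flagged.  The leaf order is
canonicalized (subtree containing the lexicographically smallest gene
first), which makes the heat-map order invariant to input row
permutation up to that convention.  The microarray "expressed" cutoff
defaults to 6.96 on the log2 scale, the threshold used with
RMA-normalized gene-level values in this literature.

The comparative-CT method averages technical replicates within each
biological replicate, takes
$\Delta C_T = \bar{C_T}^{target} - \bar{C_T}^{reference}$ per
biological replicate, reports $2^{-\Delta C_T}$, and summarizes mean ±
standard error over biological replicates (three biological × two
technical replicates being the standard design).  Biological replicates
lacking a reference measurement are dropped with a warning; losing all
of them is an error.

## The synthetic-data generator

`simulate_family()` emulates the study inputs with known truth:

* a birth--death tree (`ape::rphylo`), rescaled to unit depth, with
  monophyletic ground-truth groups cut from it;
* a root protein of 470 residues carrying the 44-residue PSPG consensus
  30 residues from the C terminus;
* substitutions along each branch under a PAM-like kernel
  ($P(a \to b) \propto e^{S_{ab}/2}$ from PAM250 scores), with the
  motif window evolving at 0.15 × the global rate and protected from
  indels — every gene keeps exactly one recognizable motif;
* indels tracked through real-valued column keys, so the implied true
  alignment is exact, not re-estimated;
* an intron history capped at two introns per gene, mirroring the
  family's architecture: one class gained at the root, one on a deep
  stem (the "either intron 3 or intron 4" pattern), each with at most
  one loss placed so the surviving carriers keep the gain branch as
  their MRCA (making the planted history Dollo-identifiable), plus
  younger classes gained only where the per-gene load stays within 2;
* back-translation with uniform synonymous codons, canonical GT..AG
  intron ends, log-uniform intron lengths in [65, 2258] bp (the
  range observed in plant UGT surveys), genes alternating strands on their own
  flanked contigs;
* decoys (30% of emitted genes) split across the three failure modes —
  no motif, out-of-range length (with an intact motif, so the failure
  reason is unambiguous), three or more introns;
* per-tissue expression weights (columns sum to 1) with 30% of genes
  unexpressed, uniform tissue draws, uniformly placed error-bearing EST
  substrings; and qPCR CTs as
  $C_T^{target} = C_T^{ref} - \log_2(\text{abundance}) + \epsilon$,
  $\epsilon \sim N(0, sd_{ct})$ per technical replicate.

Two calibrations deserve their rationale spelled out.  First,
`subst_rate = 0.75` per unit depth: plant UGT family surveys report
roughly 36--98% pairwise similarity *measured on trimmed, unambiguously
aligned regions*; full-length divergence is necessarily deeper, so the
generator's full-protein similarity floor sits near 30% while
well-aligned regions stay near the published range.  Second, comparator
proteomes (`simulate_comparators`) carry ortholog copies at 25%
divergence — 75% identity, typical of orthologs between dicot lineages
separated on the order of 100 My — and the planted diverged subfamily
is the deepest-attaching small clade (the root split; singletons
allowed, as singleton diverged genes are reported in practice).  Both
choices make "diverged" a structural property of the planted system
rather than a numerical accident at the E-value cutoff.

What the generator does **not** emulate: codon-usage bias, heterotachy
or paralog-specific rate shifts, UTR exons, spliced EST alignment
across introns (ESTs sample the spliced CDS), microarray probe-level
noise, or library-size imbalance between tissues.  Passing tests
therefore demonstrate correctness of the *computations* under a
well-specified model of the data, not robustness to every artifact of
real genome drafts.

## Numerical choices

* Coordinates are GFF3-style throughout: 1-based, inclusive; minus-
  strand models are normalized to transcription order at parse time;
  trailing stop codons are removed and flagged.
* Incomplete CDS models (length not divisible by 3) are kept but
  excluded from intron-phase analysis.
* `round_half_up()` and `trunc_digits()` implement the two printing
  conventions; R's own banker's rounding is never used for reported
  statistics.
* NJ Q-matrix ties are resolved by `ape::nj`'s deterministic scan
  order; all property tests use generic (tie-free) matrices.
* Fitch at multifurcations folds children pairwise in postorder, which
  equals Fitch on a zero-length binary resolution.
* Bootstrap replicates that produce a pair with no comparable columns
  assign that pair the maximal p-distance (0.75) instead of failing.
* The ΔCT recovery tolerance in tests is three times the *true*
  sampling SE implied by the known CT noise (the SE estimated from
  three replicates is itself too noisy to be a stable yardstick).

## Problem sizes used by the shipped tests

The reference simulation is 12 genes (plus 5 decoys), 200 bootstrap
replicates, 1200 ESTs, and 6 qPCR genes × 5 tissues × 3 × 2 replicates;
the analysis scripts use 20 genes and 2000 ESTs.  These sizes keep the
whole suite within a few minutes on one core while leaving every
recovery exact; all of them are parameters, and nothing in the
implementation depends on them.

## Known limitations

* The motif model is a single consensus scored with a substitution
  matrix, not a profile; a PSSM would be the natural extension.
* E-values are ungapped Karlin--Altschul numbers applied to global
  alignment scores: correct ordering, approximate absolute scale.
* Group assignment depends on midpoint rooting; a pathological rate
  asymmetry could misroot the tree and change assignments (an outgroup
  can be supplied as a reference instead).
* Dollo inference assumes the true gene tree is supplied; inferring
  events on an estimated tree propagates its errors.
* The EST mapper is ungapped and CDS-level; it will not place reads
  spanning indels or splice boundaries.
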