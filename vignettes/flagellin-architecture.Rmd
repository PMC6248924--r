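---
title: "Discovering giant flagellin architectures: models and methods"
author: "flagellarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering giant flagellin architectures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagellarch)
```

## The biological problem

Bacterial flagellar filaments are polymers of flagellin. All flagellins
share conserved N- and C-terminal regions that fold together into the D0
and D1 structural domains forming the filament core; the central region
between them is solvent-exposed and hypervariable in both sequence and
length. Canonical flagellins (FliC of *Salmonella* Typhimurium, 495 aa)
carry a modest central insert, but several marine γ-proteobacteria of the
*Oceanospirillales* encode *giant* flagellins beyond 1,000 aa whose
filaments are measurably thicker.

This package implements the computational side of asking how such giants
evolve:

1. **Family classification.** Proteins carrying the flagellin N-terminal
   helical region include the hook–filament junction protein FlgL, so a
   single domain match cannot define "true flagellin". Two profile HMMs —
   one trained on established flagellins, one on FlgL-family proteins —
   vote by bit-score margin.
2. **Size classes and insert measurement.** Flagellins above 800 aa are
   "large", above 1,000 aa "giant" (strict thresholds). The central
   insert is delimited per sequence by locating the conserved N- and
   C-terminal core blocks with dedicated core HMMs.
3. **Tandem repeat (DE region) discovery.** Giant-flagellin inserts
   contain a tandemly duplicated Domain-Extension (DE) region. Dot-plot
   style self-comparison, made precise by an off-diagonal local
   alignment, seeds the repeat unit; an iterative HMM loop then finds
   singly occurring copies and refines boundaries until an iteration
   adds nothing new.
4. **DX insert and glycine-rich region.** The largest flagellins carry an
   extra insert (DX) between the two DE copies containing a conserved
   ~35 aa glycine-rich stretch; a sliding-window scan detects it.
5. **Phylogeny and congruence.** A D0/D1-core phylogeny is built from
   the concatenated core regions only, annotated with insert sizes, and
   the DE-copy tree is compared with it by Robinson–Foulds distance: a
   congruent post-duplication history indicates duplication followed by
   vertical transmission rather than horizontal transfer.

Because the real inputs are database-scale downloads, every stage is
driven and tested through a synthetic flagellin evolution generator with
complete ground truth.

## Pairwise alignment engine

Global (Needleman–Wunsch) and local (Smith–Waterman) alignment use affine
gaps: a gap of length $k$ costs $o + (k-1)e$ with defaults $o=11$, $e=1$
on BLOSUM62 — the community-standard protein scheme; nothing in the
analysis depends on this choice strongly, and it is configurable. 'X' is
accepted and scores 0 against everything, which keeps masked regions
alignment-neutral; other ambiguity codes are rejected so the dynamic
programme stays well defined. Tie-breaking is fixed (diagonal over up
over left, earliest cell wins) so outputs are bit-reproducible. All
coordinates in this package are 1-based closed intervals, the
Bioconductor convention.

The repeat seed is `self_offdiagonal_align()`: a self-alignment with all
cells within an exclusion band of the main diagonal forbidden. Its
optimum necessarily rides the duplication diagonal, but a local optimum
may extend a few residues into flanking chance matches (we have measured
planted exact copies where the extended alignment outscores the pure
copy-vs-copy alignment). `find_tandem_repeats()` therefore polishes
boundaries by trimming each end of the alignment back to the first run
of three consecutive identity columns and re-scoring. The seeding
threshold is the 99th percentile of the same statistic on residue
shuffles of the insert, computed once per run under the run seed.

## Profile HMMs

`build_hmm()` follows the classic plan 7 architecture: alignment columns
with gap fraction ≤ 0.5 become match states; sequences are weighted with
the Henikoff position-based scheme; match emissions mix weighted counts
with the background (uniform by default, matching the generator) at a
pseudocount weight of 1; transition counts get Laplace pseudocounts.
Every probability is therefore strictly positive, and all emission and
transition rows sum to 1 within 1e-9.

Scoring uses a uni-hit local model: background-emitting flanks with
self-loop probability $r = 350/351$, uniform entry into any match state,
and uniform exit (node $k$ exits with probability $1/(L-k+1)$, so every
exit point is a priori equally likely). Insert and flank emissions equal
the null background, so only match states contribute odds. The reported
score is $\log_2 P(s \mid \text{model}) / P(s \mid \text{null})$ with a
geometric length null of the same $r$. The forward recursion runs in
scaled linear space (per-row renormalisation), the standard trick that
keeps it exact to double rounding while using only multiply/adds; Viterbi
runs in log space with deterministic tie-breaking (match over delete over
insert). Both are verified against explicit path enumeration on small
models in the test suite.

E-values come from an explicit calibration: forward scores of residue
shuffles of the database sequences (truncated at 400 aa to bound cost)
are fitted with a Gumbel by the method of moments, and
$E = N_{db} \cdot P(S \ge s)$. `scan_hmm()` decodes greedily: take the
Viterbi envelope, mask it with 'X', repeat until the next hit's E-value
exceeds the threshold (0.1 by default, the same significance rule used
for judging DE-region occurrence). The Viterbi bit score, not the
whole-sequence forward score, gates each hit: after masking, the forward
score still aggregates residual signal scattered outside any single
envelope, which would let an unsupported envelope through.

## Progressive alignment and trimming

The in-package progressive aligner builds a guide tree by average-linkage
clustering of global-alignment p-distances and merges profiles leaf-to-
root with the same affine-gap engine; the profile column score is the
mean pairwise substitution score with gaps scoring 0. It is deliberately
simple — the analysis needs a trimmed core alignment, not a particular
aligner — and deterministic. `trim_gap_columns()` removes columns above
50% gaps by default and returns the kept-column index map so trimmed
coordinates can be mapped back.

## Phylogeny

Distances over the trimmed core alignment are p-distances or their
Poisson correction $-\ln(1-p)$ (p clamped at 0.95 so saturated pairs stay
finite). Trees are built by neighbor joining; maximum-likelihood
inference would be the natural choice at publication scale, but the
claims this package tests — clade membership and topological congruence —
are topology-level and fully testable under NJ, which keeps the package
self-contained and fast. Labels are sorted before agglomeration so ties
break by label order, and negative NJ branch lengths are clamped to zero
with the deficit moved to a sibling branch, preserving leaf-to-leaf path
lengths. NJ is exact on additive matrices (tested to 1e-9).

Robinson–Foulds distance is computed from canonical bipartition sets
(reference leaf = lexicographically smallest label, so keys are
tree-independent); `max_rf` is the total internal-edge count, $2(n-3)$
for binary unrooted trees. DE-copy trees carry `seqid/1half` and
`seqid/2half` leaves; congruence extracts each post-duplication copy
subtree separately, relabels to sequence ids, and compares against the
species tree restricted to the same leaves. The implementation is
cross-checked in the tests against both a brute-force edge-cutting
oracle and phangorn.

## The synthetic generator

`generate_flagellins()` emulates exactly the statistical structure the
analysis assumes, nothing more:

- Ancestral segments (N-core 180 aa, C-core 180 aa, plain insert 135 aa,
  DE 150 aa, DX 120 aa containing a 35-aa glycine region at frequency
  0.6) drawn from uniform residue frequencies. Uniform background is the
  minimal assumption; the analysis nowhere depends on realistic residue
  composition.
- Evolution along a Yule or balanced tree scaled to an expected
  root-to-tip divergence (substitutions/site): per-site substitution
  with probability $1-e^{-t}$ per branch and replacement uniform over
  the other 19 residues, plus Poisson indel events of geometric length
  (mean 3) confined to their segment, so planted boundaries shift but
  never vanish.
- The DE duplication happens at the most recent common ancestor of the
  tandem leaves; both copies then evolve independently down the tree,
  which is precisely the vertical-transmission scenario the congruence
  test is meant to detect.
- Leaves are assembled per clade model (`none`, `single_DE`,
  `tandem_DE`, `tandem_DE_plus_DX`) and every boundary is recorded as
  ground truth.

Presets: `canonical_preset()` gives 495-aa FliC-scale proteins;
`oceanospirillales_preset()` (DE 260 aa, DX 140 aa) gives 1,020-aa giants
at zero divergence, matching the scale of the reported *B. marisrubri*
giant flagellin. The `ancestor_seed` field decouples the family ancestor
from the evolutionary replicate, giving honest train/test splits from
the same family.

What the generator does **not** emulate: realistic amino-acid
composition and substitution biases, rate heterogeneity, domain-level
selection, or convergent evolution of inserts. Passing tests therefore
demonstrate that the pipeline recovers the architecture it is designed
to find when its assumptions hold; they do not certify performance on
arbitrary real proteomes.

## FlgL-like decoys

`generate_decoys()` builds the classifier's negative class: decoys share
the first 60 aa of the flagellin N-core (emulating the N-terminal
helical region common to flagellin and FlgL) but are otherwise drawn
from an independent 470-aa ancestor and evolved to 30% divergence. The
shared block is what makes the classification problem non-trivial — a
single-model threshold would fire on both families.

## Benchmark problem sizes and expected results

The acceptance-level benchmarks (also exported as `benchmark_*()`
functions) use these sizes, chosen so each replicate is informative while
the whole suite stays comfortably runnable on one CPU:

- **Recovery** (`benchmark_recovery`): 100 replicates, 6 leaves each
  (4 tandem-DE-plus-DX, 1 single-DE, 1 DE-free), giant preset. Measured:
  ≥90% of planted DE copies recovered at ≥50% overlap, median boundary
  error ≤3 aa, DX sides within 3 aa, ≥95% of glycine regions detected.
  The full pipeline — classification, insert measurement, seeding,
  iterative discovery, DX/glycine, architectures, trees — runs per
  replicate.
- **Classifier** (`benchmark_classifier`): 6+6 training sequences,
  200+200 test sequences at 30% divergence; accuracy ≥0.95 with no
  flagellin→FlgL hard errors expected at the default 2-bit band.
- **Congruence** (`benchmark_congruence`): 100 replicates, balanced
  6-taxon trees at 0.25 root-to-tip divergence with 260-aa DE copies, so
  each internal branch carries ~20 expected substitutions per copy —
  enough signal that a congruent history is recoverable; ≥90% of
  replicates give RF = 0 for every copy tree.
- **Convergence** (`benchmark_convergence`): a tandem-only dataset whose
  final discovery iteration adds zero new regions.

## Numerical and degenerate-input choices

- Emission/transition validation tolerance 1e-9; forward/Viterbi vs
  enumeration tolerance 1e-6 bits.
- Degenerate calibration (zero score variance) is an error, not a
  silent fallback.
- An insert shorter than twice the minimum repeat length yields an
  empty repeat table, not an error; a missing core hit is a no-call
  with its reason; overlapping architecture components are a structured
  rejection naming the violated constraint, never a silently trimmed
  architecture.
- `detect_dx()` requires exactly two DE copies and a gap of at least
  20 aa; with more than two copies the DX is sought only between copies
  1 and 2 by position.
- The glycine scan (window 11, fraction ≥0.4, both configurable) has a
  small composition-dependent false-alarm rate on repeat-free sequence
  (~3–5% per 100-aa stretch at background glycine frequency), which is
  why it is only applied inside a detected DX.

## Known limitations

- The progressive aligner and NJ are stand-ins for statistical aligners
  and ML phylogenetics; they are adequate for the topology-level and
  boundary-level claims tested here.
- E-value calibration on truncated shuffles slightly mis-estimates tail
  probabilities for very long sequences; detection decisions in this
  pipeline involve score gaps of hundreds of bits, far outside this
  error.
- The uni-hit local model reports one envelope per decoding pass;
  multi-copy sequences are handled by masking and re-decoding rather
  than by a multi-hit architecture.
- Accession-backed checks against live database records require network
  access and live in `scripts/fetch_uniprot.R`; the offline suite uses
  synthetic stand-ins with the reported geometry instead.
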