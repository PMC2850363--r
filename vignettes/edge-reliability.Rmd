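---
title: "Edge reliability from near-optimal protein sequence alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge reliability from near-optimal protein sequence alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearaln)
```

## The problem

A pairwise protein sequence alignment is optimal only with respect to a
substitution matrix and gap penalties; the alignment a structural
superposition implies is often a *suboptimal* sequence alignment. For
homologous proteins in the 20-40% identity range this matters: the
optimal sequence alignment typically contains misplaced residue pairs,
and downstream uses (homology modelling, transfer of site annotations)
inherit those errors. `nearaln` treats each aligned residue pair -- an
**edge** (i, j) in the dynamic-programming path graph -- as the unit of
reliability, asks how strongly the near-optimal alignment neighborhood
supports each edge, and uses that evidence to remove suspect edges or
to generate new alignments.

## Alignment model

All alignments are over two full sequences. The score of an alignment is
the sum of its substitution scores over MATCH columns plus
`gap_open + k * gap_extend` for every *interior* maximal run of k gap
columns in one sequence. Terminal gap columns -- everything before the
first MATCH column and after the last -- are free. This is the
semi-global ("end gaps not penalized") convention, with two properties
worth stating explicitly because implementations differ:

* a fully staggered alignment (`AC--` over `--GT`) scores exactly 0, and
  the optimal score is never negative;
* appending an identical residue to both sequences can never decrease
  the optimal score, because the new residues can always ride in the
  free terminal overhangs.

Gap costs follow the SSEARCH/FASTA convention: a gap of length 1 under
the default BLOSUM50 −10/−2 scheme costs −12. Traceback ties are broken
with the fixed priority MATCH > DELETE > INSERT, so every result is
deterministic; pool compositions (below) depend on this tie-break, which
is why pool *sizes* are implementation-specific and never asserted.
Wildcard handling is permissive by design: residues absent from the
matrix but in the tolerated set (X/B/Z/U) score 0 against everything,
anything else is an input error naming the offending character.

## The near-optimal neighborhood

For every cell (i, j), a forward and a backward set of affine-state
matrices are stitched at the MATCH transition to give the **through
score** T(i, j): the best score of any alignment containing edge
(i, j). Edges with `T(i, j) >= fraction * s_opt` form the
percent-of-optimal neighborhood (default fraction 0.75). For each
qualifying edge one alignment through it is built by deterministic
bidirectional traceback; after deduplication this pool

* covers every qualifying edge at least once (the coverage guarantee of
  this sampling strategy), and
* always contains an optimal alignment,

but it is only a sample of the full near-optimal space, which can be
astronomically larger. Percent thresholds are refused when
`s_opt <= 0`, where "75% of optimal" has no meaning; in practice this
excludes only pairs with no positively scoring residue pair at all.

## Per-edge features and their normalization

Three features feed the reliability model:

* **robustness** (raw units: matrix score): `T(e)` minus the best score
  over alignments *avoiding* e. It is positive exactly when e lies in
  every optimal alignment. The avoiding score is computed exactly by a
  row decomposition: an alignment avoids (i, j) by matching residue i
  elsewhere, deleting it in a charged interior run, keeping all its
  matches on one side of row i, or being empty.
* **frequency**: the fraction of pool members containing e; in `[0, 1]`
  by construction.
* **maximum bits-per-position**: the best
  `score * bits_per_unit / columns` over pool members containing e
  (BLOSUM50 is a 1/3-bit matrix, BLOSUM62 1/2-bit). This measures the
  overall quality of the best alignment an edge appears in.

Robustness and max bits-per-position are min-max normalized to
`[0, 1]` per sequence pair, over the pool's edge set; edges outside the
pool are clamped into the range. A constant feature maps to 0.5. Two
choices here were genuinely open and are worth recording: normalization
is per pair (not per corpus), applied identically to both features for
consistency; and edges never seen in the pool have no defined
bits-per-position, so the model layer imputes 0 for them -- they are
exactly the edges the neighborhood gives no support to.

## The logistic model

The shipped default coefficients are

```{r}
default_coefficients()
```

on the scale `logit(p) = a0 + a_f * f + a_r * r + a_m * m` with all
three features normalized. They derive from a fit to 5000 edges sampled
from the local region of 75%-of-optimal pools over three scoring
schemes (BLOSUM50 −10/−2, BLOSUM50 −12/−2, BLOSUM62 −11/−1), an edge
being labelled positive when at least 2 of 4 structure-based reference
alignments contain it. Refitting (`fit_model()`) uses `glm` with the
logit link, deviance tolerance 1e-8 and at most 100 iterations;
separation is flagged rather than silently accepted. Model comparison is
by AIC across predictor subsets (`aic_comparison()`), with the
single-variable p < 0.25 screen (`screen_predictors()`) reported as a
diagnostic only. Train/test splits are always by sequence pair
(`partition_by_pair()`), never by edge, so no pair contributes to both
sides.

## Improving alignments

`trim_alignment()` replaces each MATCH column scoring below a threshold
(default: model probability < 0.5) with a DELETE column followed by an
INSERT column, so residue content is untouched and no new edges appear;
adjacent replacements merge into runs. The 0.5 default is read on the
probability scale -- it corresponds to log-odds 0, the only place a 0.5
cutoff is meaningful. `trim_to_local_region()` gaps out matches beyond
the local (Smith-Waterman) alignment boundaries, which removes the
poorly determined alignment ends. `model_guided_align()` reruns the
semi-global DP with the model probability as the MATCH score and affine
gaps of −10/−2 on that scale; a `score = "logit"` switch uses the
log-odds instead, since the probability-versus-logit reading of the
scoring is ambiguous in the source protocol. Because the DP is free to
choose any path, model-guided alignments can contain correct edges the
optimal sequence alignment misses.

On the probability scale a −10/−2 gap is roughly ten matches' worth, so
model-guided alignments are strongly gap-averse; this is faithful to
the published protocol, and the logit switch is provided for users who
want gap costs commensurate with the score scale.

## Comparing alignments

`shift_score()` implements the Cline score with ε = 0.2: residues
aligned in both alignments contribute `(1 + ε) / (1 + |shift|) − ε`
per alignment they appear in, residues aligned in only one contribute
−ε, and the total is divided by the number of aligned-residue instances
in both alignments. Identical edge sets score exactly 1, disjoint
aligned-residue sets exactly −ε. `edge_confusion()` counts true/false
positives of a candidate against the k-of-n reference rule, and
`pair_summary()` tabulates strictly-better / strictly-worse pairs with
the means and standard deviations of the positive and negative deltas
separately, ties counting in neither column.

## The synthetic benchmark

Real evaluation of edge reliability needs structure-based reference
alignments, which require 3D coordinates and external structure
aligners. The generator in this package stands in for that data: an
ancestor is drawn from Robinson-Robinson background frequencies; two
descendants mutate independently, with the per-site substitution
probability solved (by `uniroot` on the exact site-identity expectation)
so the expected identity over matched sites equals the target; indels
start at rate 0.015 per site per lineage with geometric lengths of mean
2; and the true alignment is recorded from the mutation history. Four
references per pair are produced by displacing each gap run of the true
alignment by up to ±2 columns, emulating the disagreement of independent
structure aligners, and the 2-of-4 labelling rule is applied against
them.

The default tiers target mean identities of 48% / 26.9% / 22.6%,
matching the high/medium/low similarity groups of the CATH-derived
benchmark the model was developed on. The indel rate was chosen once,
under two constraints: a realistic indel-to-substitution ratio (~1:10
at ~48% identity), and the calibration property that the true alignment
scores within 75% of optimal for at least 90% of high-tier pairs --
the regime in which near-optimal neighborhoods overlap structural
alignments at all. The benchmark suites use 20 pairs per tier with
100-residue ancestors, a size at which every pipeline stage
(neighborhood, features, fit, ROC, trims) runs in well under a minute.

What the generator does *not* emulate: secondary-structure-dependent
substitution and gap placement, the block structure of real structural
disagreement (references differ from the truth only by local gap
jitter), and compositional bias. Passing benchmarks therefore show that
the machinery is correct and that the qualitative orderings (full model
above robustness alone in ROC; trimmed above untrimmed in true-positive
fraction) hold under a clean generative model -- not that the published
effect sizes transfer to real structure-based references.

## Numerical choices and degenerate inputs

* All DP is exact in double precision; traceback equality tests use a
  1e-9 tolerance, far below the integer score granularity.
* Empty local alignments (no positive-scoring pair) return score 0 with
  `NA` bounds; trimming to an empty local region is refused.
* `percent_identity()` divides by total columns by default, with a
  matched-columns alternative behind a flag, since published identity
  figures use both conventions.
* Test oracles are independent: exhaustive enumeration of all
  alignments for every core DP quantity (scores, through-scores,
  robustness, coverage) on small instances, an independent
  Smith-Waterman for local scores, and an independent AUC
  implementation for ROC analysis.

## Known limitations

Robustness, through-scores and the pool are quadratic in sequence
length and fast for domain-sized inputs (hundreds of residues), but the
pool can hold thousands of alignments for highly similar pairs. The
model coefficients shipped as defaults were estimated on real
structure-based labels; on synthetic benchmarks they are applied as-is,
and refitting on synthetic labels will generally produce different
coefficients. The CLI is a thin reproducibility layer over the R API --
every subcommand writes a `run_log.txt` from which the run can be
repeated exactly.
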