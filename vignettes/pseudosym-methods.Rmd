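---
title: "Detecting internal C2 pseudosymmetry and weighing remote homology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting internal C2 pseudosymmetry and weighing remote homology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudosym)
```

## The problem

Many membrane channels, the SecY protein-conducting channel among them, are
internally pseudosymmetric: a single polypeptide contains two structurally
similar halves related by a two-fold (C2) rotation about an axis parallel to
the membrane plane. This architecture is the fingerprint of an ancient gene
duplication and fusion of an antiparallel homodimer. Establishing such
pseudosymmetry quantitatively — and then asking whether the ancestral half
resembles another protein family (for SecY, the Oxa1/YidC insertases) —
requires a chain of routine but easily mis-specified computations:

1. splitting the chain into candidate halves and superposing one onto the
   other without using sequence;
2. extracting the *common core* (residue pairs deviating by less than a
   cutoff, conventionally 4 Å) and its refitted RMSD;
3. asking how much *sequence* memory survives, via cross-group percent
   identity against a residue-shuffled null;
4. calibrating structure-search Z-scores into p-values under an
   extreme-value model, and translating those p-values into database-scale
   expectations; and
5. profiling membrane topology (hydropathy, charge, TMH counts) to check
   that the compared objects are architecturally comparable.

This package implements that chain as small composable functions, each
testable against synthetic inputs with planted ground truth.

## Structural alignment and TM-score

`kabsch()` computes the least-squares proper rotation by SVD with the usual
determinant correction, so reflections are never returned. The test suite
checks it against an independent quaternion-eigenvalue implementation of the
same optimisation.

`align_traces()` is a sequence-independent iterative aligner in the TM-align
family, standing in for an external multiple-structure aligner.
Correspondences are seeded two ways: gapless threading of the shorter trace
onto the longer at every offset, and pairings of length-20 fragments. Each
seed alternates (a) Kabsch superposition on the current pair set with (b)
dynamic-programming re-alignment under the similarity `1/(1 + (d/d0)^2)`,
until the TM-score changes by less than `1e-6` or 50 iterations elapse; the
highest-scoring seed wins. Determinism: for fixed input the result is
bit-reproducible (no randomness anywhere in the aligner).

Numerical choices:

* `d0(L) = 1.24 (L − 15)^{1/3} − 1.8` Å, floored at 0.5 Å — the standard
  TM-score normalisation; pairwise alignments normalise by the shorter
  trace's length.
* The DP uses affine gaps (open −0.6, extension free) on the similarity
  scale, with ties broken toward the diagonal so ungapped correspondence is
  preferred. End gaps are free (semi-global): when threading halves of
  unequal length, terminal overhangs should not be penalised.
* The DP inner loop is compiled (C++); everything else is plain R.
* After one refinement pass of every seed only the best eight are iterated
  to convergence. At the trace lengths this package targets (100–500
  residues) an alignment costs tens of milliseconds.

`common_core()` drops pairs deviating by ≥ cutoff, refits the superposition
on the survivors, and repeats until stable. Pairs are only ever dropped,
never re-admitted, which makes core size monotone in the cutoff. The
reported RMSD is refit on the core members (the refit-or-not convention is
not universal among alignment servers; we refit and say so).

## The split scan

Where exactly a duplicated protein should be split is underdetermined —
every position inside the inter-half linker yields the same two-domain
topology. `scan_splits()` therefore scores *every* candidate split in a
window: align the halves, extract the core, and score the split by the core
TM-score normalised by the **longer** half. This normalisation is the load-
bearing choice: normalising by the shorter half rewards truncating one half
(any sub-fragment aligns perfectly into the other half, so the score
plateaus at 1 for all early splits), whereas normalising by the longer half
peaks at the balanced split — the linker midpoint — and degrades on either
side as coverage is lost. Consistently, the synthetic dimer generator
reports the linker midpoint as its ground-truth split.

The symmetry verdict uses a core TM-score threshold of 0.30 by default:
well below the ~0.5 same-fold convention, deliberately permissive because
duplication-derived halves are typically highly diverged; it is a parameter,
not a constant. Random-coil controls score ~0.2 and are judged asymmetric.

`c2_axis()` recovers the rotation angle from `acos((tr(R) − 1)/2)` and the
axis from the eigenvector at eigenvalue 1, fixing the sign so that
(axis, angle) reconstructs `R` to 1e−9. For a near-180° rotation the axis
direction is inherently sign-ambiguous; comparisons with a planted axis are
made up to sign. With a membrane frame the tilt of the axis out of the
membrane plane is reported (a duplication-derived channel should have it
near 0°).

`helix_tilts()` measures per-helix tilts as the first principal direction of
the segment's Cα coordinates, oriented N→C so angles are signed-comparable,
and reports the angle between corresponding N- and C-half helices after
mapping through the half-to-half superposition — large values flag
symmetry-breaking distortions of individual helices. Helix segment ranges
are user-supplied; secondary-structure assignment is out of scope.

`count_connectivities()` computes `n_in! × n_out! × n_prepend`, the number
of distinct TMH connectivities compatible with a pseudosymmetric
architecture (orderings of the helices entering from the cytoplasmic side,
orderings of the others, and the choice of helix to which a peripheral H0
is prepended); `enumerate_connectivities()` generates the orderings
explicitly and is tested to agree everywhere.

## Sequence statistics

Percent identity is defined as identical residues over co-occupied (both
non-gap) columns, ×100, with `X` never counting as a match; this is the
closest common reading of the all-against-all matrices reported by
alignment servers. Two modes are supported, because published figures do
not always say which was used: `from_msa` scores the given alignment's
columns directly; `pairwise_realign` re-aligns each pair globally
(BLOSUM62, affine gaps 10/0.5) before applying the same column rule.

The shuffled null (`shuffled_identity_null()`) permutes each sequence's
residues uniformly — composition is preserved exactly, a property-tested
invariant — and recomputes the cross-group identities. In `from_msa` mode
the null converges to the composition coincidence rate `q0 = Σ f_i g_i`; in
`pairwise_realign` mode the aligner is allowed to hunt for spurious
register, which inflates the null above `q0` — exactly the effect that makes
a shuffled null preferable to a composition formula when the observed
identities come from re-alignment. `excess_identity()` converts the
observed-minus-null difference into residues per fixed length (rounded
half-down), the "how many amino acids of memory survive" number.

Column conservation is `1 − H/log 20` from the Shannon entropy of non-gap
residues — an explicitly labelled entropy stand-in, not a phylogenetic
rate model; columns over 50% gaps are flagged low-confidence. Logo
information content is `log2(20) − H` bits with heights `frequency × IC`.
Consensus sequences take the modal non-gap residue, breaking ties
lexicographically (flagged).

## Extreme-value calibration of search scores

Structure-search Z-scores are converted to p-values under a Gumbel model:

$$p = 1 - \exp\!\big(-\exp\big(-(\tfrac{\pi}{\sqrt 6} Z - \gamma)\big)\big)$$

with γ the Euler–Mascheroni constant. The inner negation makes this the
upper tail — strictly decreasing in Z — and reproduces the conventional
worked values (Z = 4.2 → p ≈ 0.0081; Z = 5.6 → p ≈ 0.0014); the same
expression typeset without the negation would *increase* with Z, which is
clearly a sign slip rather than an alternative model. Note the location
convention this formula implies: the distribution whose tail it computes
has scale √6/π (unit variance) but location +γ√6/π, i.e. mean 2γ√6/π ≈
0.90, not zero. The sampling counterpart `make_gumbel_scores()` draws from
exactly that distribution, so Monte-Carlo exceedance frequencies match
`z_to_p()` — the property the calibration is for — at the cost of a
nonzero sample mean, which is documented rather than hidden.

Database-scale interpretation is linear arithmetic made explicit:
`expected_false_hits(p, N) = pN` chance hits in a database of N comparable
entries; `candidate_threshold(p) = 1/p` is the ancestral-repertoire size at
which one chance hit of that strength is expected. `combine_pvalues()`
implements Fisher's method (Stouffer behind a flag) for combining a
structure-search p-value with p-values for independent non-structural
coincidences; which combination rule to use was an open choice, and
Fisher's is the default because the components are bounded away from the
degenerate p = 1 case in this application.

## Topology profiling

Hydropathy profiles are centred moving averages of the Kyte–Doolittle scale
over an odd window (default 9 residues), with no partial windows — matching
how such profiles are plotted. Charge tracks mark K/R and D/E only;
histidine, being mostly neutral at membrane pH, is excluded. The
transmembrane-segment caller is an explicitly heuristic threshold rule
(runs of window-averaged hydropathy ≥ 1.6 spanning ≥ 15 positions): a
stand-in for HMM topology predictors, adequate for simulation and for the
length-vs-TMH-count histogram, and never claimed to reproduce any
predictor's output. The 2-D histogram bins lengths half-open in 25-residue
increments with contour levels every 3 proteins per bin.

## Synthetic data: what it does and does not emulate

`make_c2_dimer()` builds idealised α-helical bundles (100°/residue, 1.5 Å
rise, 2.3 Å radius), duplicates one half by an exact 180° rotation about a
planted membrane-parallel axis, joins the halves with a linker, and adds
isotropic per-coordinate Gaussian noise. It emulates the geometry that the
superposition/scan machinery assumes; it does **not** emulate correlated
domain motions, loop flexibility, sequence-structure covariation, or real
helix packing, so passing recovery tests demonstrates correctness of the
detection machinery, not performance on distorted real structures.

`make_msa_pair()` plants a target *realised* cross-group identity: because
unrelated residues coincide at the composition rate `q0 = Σ f_i²`, the
site-copy probability is back-solved (also accounting for within-group
divergence, default 95% identity to the group ancestor) so that the
expected cross-group pairwise identity equals the requested value — the
parameter a recovery test should recover. Defaults (200 columns, 12.5%
cross identity, membrane-protein-like composition) match the diverged-half
regime the identity statistics are designed for. No gaps are planted, so
alignment-inflation effects must be studied with the re-alignment mode, not
the generator.

`make_imp_set()` samples log-normal lengths (median 350 aa) with
length-coupled Poisson TMH counts floored at 1 — a caricature of a
bacterial multi-pass membrane proteome adequate for histogram plumbing, not
a proteome model.

All generators are pure functions of parameters plus seed, restore the
caller's RNG state, and return their ground truth alongside the data.

## Problem sizes used by the test suite

The suite exercises: dimers of 3 helices × 23 residues per half (the scan
window spans the linker ±8); 50-seed recovery batteries at 0.3 Å noise plus
a five-level noise ladder (0–2 Å, 16 paired seeds per level); 10⁶-sample
Monte-Carlo checks of the Gumbel tail; 1000-instance Kabsch-vs-quaternion
comparisons; and 50-seed identity-recovery batteries on 4 + 4 row × 200
column alignments. These sizes give comfortable statistical resolution for
the tolerances asserted while keeping the whole suite in a few minutes.

Two checks consume real data that ships with neither the package nor its
tests (the 6FTI/6ITC coordinate files and the published N-/C-half
alignment); `scripts/fetch_reference_data.R` downloads/stages them, and the
corresponding tests fail with an instructive message when the files are
absent rather than silently skipping.

## Known limitations

* The aligner is pairwise only; no multiple-structure alignment, no
  flexible/hinge alignment, no distance-matrix (Dali-style) comparison.
* Conservation scoring is entropy-only; no tree, no rate model.
* The TM-segment caller is a threshold heuristic; topology (in/out
  orientation) is not predicted.
* Membrane frames are user-specified; no membrane-positioning optimisation
  is performed — structures are assumed pre-oriented with the membrane
  normal along z.
* Higher-order internal symmetry (C3+, translational repeats) is not
  searched.
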