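# pseudosym

Quantitative tools for establishing **internal C2 pseudosymmetry** in
membrane-protein structures and for the statistics used to argue **remote
homology** between protein families — the analysis chain by which one shows
that a channel such as SecY consists of two anciently duplicated halves, and
weighs whether the ancestral half is related to another family (e.g. the
Oxa1/YidC insertases).

For structural bioinformaticians and molecular evolution researchers who
need these steps as small, tested, composable R functions rather than a
chain of web servers.

## What it computes

**Structure.** Cα traces from PDB/mmCIF (`read_structure()`, via bio3d);
Kabsch superposition (`kabsch()`); a sequence-independent iterative TM-score
aligner (`align_traces()`, the DP core in C++) with common-core extraction
(`common_core()`, pairs deviating < 4 Å, refit RMSD). A split-point scan
(`scan_splits()`) tries every candidate division of a chain into N- and
C-halves, aligns the halves, and reports the split maximising the core
TM-score, the C2 axis and rotation angle (`c2_axis()`), and per-helix
symmetry-breaking tilts (`helix_tilts()`). The TM-score is

    TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2),  d0 = 1.24 (L-15)^(1/3) - 1.8

**Sequence.** Cross-group percent identity over co-occupied columns, with
optional per-pair global re-alignment (`pairwise_identity()`); a
residue-shuffled permutation null (`shuffled_identity_null()`); excess
identity in residues per fixed length (`excess_identity()`); entropy-based
column conservation, consensus sequences, and sequence-logo information
content.

**Significance.** Extreme-value calibration of structure-search Z-scores,

    p = 1 - exp(-exp(-(pi/sqrt(6) * Z - gamma)))

(`z_to_p()`), with database-scale interpretation: expected chance hits
`p * N` (`expected_false_hits()`), the implied homology-candidate threshold
`1/p` (`candidate_threshold()`), and Fisher/Stouffer combination of
independent evidence (`combine_pvalues()`). Fold-connectivity combinatorics
`n_in! * n_out! * n_prepend` (`count_connectivities()`), cross-checked by
explicit enumeration.

**Topology.** Kyte–Doolittle hydropathy profiles (9-residue window), charge
tracks, a heuristic TM-segment caller, and the length-vs-TMH-count 2-D
histogram (25-aa bins, 3-proteins-per-bin contours).

**Synthetic data.** Seeded generators with planted ground truth for every
stage: C2-symmetric helical bundles with Gaussian noise (`make_c2_dimer()`),
two-group MSAs with a planted cross-identity (`make_msa_pair()`), calibrated
Gumbel score samples (`make_gumbel_scores()`), and proteome-like
length/TMH records (`make_imp_set()`).

`run_pipeline()` wires the stages together from a config list and writes a
deterministic JSON report plus TSV tables.

## Worked example

```r
library(pseudosym)

# a synthetic duplicated channel: two 3-helix halves, 0.3 A noise
d <- make_c2_dimer(noise_sd = 0.3, seed = 7)
rep <- scan_splits(d$trace, c(64, 84), frame = membrane_frame(30))
rep
#> <symreport> verdict symmetric (core TM 0.884 vs threshold 0.30)
#>   best split 74: core 69 pairs, RMSD 0.72 A, rotation 179.7 deg
rep$axis
#> <axisreport> angle 179.72 deg (C2 deviation 0.28), axis (-0.001, -1.000, 0.000),
#>   tilt out of membrane plane 0.00 deg
```

The scan found the duplication boundary (the generator's ground truth is
split 74), a 69-residue common core at 0.72 Å — consistent with the 0.3 Å
planted noise — and a 179.7° rotation about an axis lying in the membrane
plane: the C2 fingerprint.

```r
# how much sequence memory would survive at this divergence?
m   <- make_msa_pair(n_rows_per_group = 6, length = 200,
                     cross_identity = 0.125, seed = 7)
obs  <- pairwise_identity(m, "A", "B")
obs
#> <identity_summary> 13.6 +/- 0.9 % (s.d.) over 36 pairs [from_msa]
null <- shuffled_identity_null(m, "A", "B", n_reps = 10, seed = 7)
null
#> <null_summary> 6.4 +/- 1.7 % (s.d.), 10 shuffle rep(s), seed 7 [from_msa]
as.integer(excess_identity(obs, null, 200))
#> [1] 14
```

Observed cross-half identity barely exceeds the shuffled null — here 14
excess residues per 200: the regime where structure, not sequence, must
carry the homology argument. The significance side:

```r
signif(z_to_p(c(4.2, 5.6)), 2)         # Gumbel tail of search Z-scores
#> [1] 0.0081 0.0014
expected_false_hits(0.02, 1e4)         # chance hits in a 10^4-entry proteome
#> [1] 200
candidate_threshold(0.0014, present = TRUE)
#> [1] 700
count_connectivities(3, 2, 3)          # connectivities of a 3-in/2-out fold
#> [1] 36
```

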