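---
title: "Methods: rank-based detection of backbone atom-type flexibility patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based detection of backbone atom-type flexibility patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexrank)
```

# The question and the statistical model

Within one residue, are some backbone heavy atom types systematically
more mobile than others? `flexrank` answers this with a within-block rank
design that deliberately discards the absolute scale of the flexibility
measure. The measure `u` may be a coordinate variance across superposed
models of an NMR ensemble or MD snapshot stack, or a crystallographic
B-factor — all in Å², but on incomparable absolute scales across
structures and methods. Ranking the k = 4 types {N, Cα, C′, O} within
each residue (1 = least variable; mid-ranks on ties) removes residue- and
structure-level scale entirely: the ranks, the test, and the F-score
category are invariant under any affine map `u → a·u + b` (a > 0) applied
residue-wide, which is what lets one code path serve NMR, MD and crystal
inputs.

The per-structure test is Friedman's: blocks are the n residues that
possess all k types, treatments the atom types. We use the tie-corrected
chi-square form

S = [ 12/(n·k·(k+1)) · Σⱼ Rⱼ² − 3n(k+1) ] / [ 1 − Σ(t³−t)/(n·k·(k²−1)) ],

with Rⱼ the rank sum of type j and t running over tie-group sizes within
blocks, referred to χ² with k−1 degrees of freedom. Its assumptions are
mild — exchangeability of the within-residue values under the null and
independence between blocks — but note that residues of one protein are
not strictly independent; the type-I simulations below probe how much
that matters under a realistic generator (it stays nominal).

Post hoc, each pair of atom types is compared on mean ranks, declared
significantly different when |R̄ₐ − R̄ᵦ| > 3·SE with SE = √(k(k+1)/(6n)).
The "three standard deviations" rule is stated by its users without a
formula; we interpret the base quantity as the standard error of a
difference of two mean ranks under the Friedman null, which is the
single largest reproduction risk when comparing significance counts
against published bar charts, and we record the formula in every report's
provenance block. No multiple-testing correction is applied across
structures when counting significant pairs: counts are raw per-structure
outcomes, matching how such bar charts are conventionally drawn.

The per-residue F-score, F = (u(O) − u(N))² / (u(C′) − u(N))², measures
how anomalous the carbonyl oxygen is relative to the amide-nitrogen
baseline, with C′ − N setting the within-residue scale. Categories: green
whenever u(O) < u(N) (overriding F); otherwise red for F > 10, blue for
F < 0.1, white between. Degenerate denominators are encoded in the
category rather than raised as errors: F = ∞ (red) when only the
numerator is positive, `undefined` when both vanish.

# Superposition

Coordinate variances are meaningful only after the models are superposed;
the package implements three schemes, exposed via `flex_rank(...,
superpose = )` because the pattern of interest should not be an artifact
of any one of them:

* `lsq` — iterative least squares: each model is fit to the current mean
  structure by a Kabsch (SVD) rotation, the mean is recomputed, and the
  two steps alternate until the mean moves by less than `tol`. Default
  fit set: all heavy atoms.
* `weighted` — a simplified variance-weighted analog of
  maximum-likelihood ensemble superposition: per-atom weights
  `wᵢ = 1/(vᵢ + ε)` with `vᵢ` the current per-atom variance, iterated to
  convergence. It is *not* the full published maximum-likelihood
  treatment (no covariance model across atoms); it captures the essential
  behaviour that ill-defined atoms should not steer the fit.
* `core` — least squares restricted to a core atom set grown greedily
  from the matrix of interatomic-distance standard deviations (seed: the
  lowest-SD pair; grow by smallest max-SD to the current core; stop at
  `core_cutoff`). Distance SDs are superposition-independent, so the core
  is invariant under per-model rigid transforms and model order. This is
  a simplified analog of dendrogram-based core identification, and its
  default cutoff (0.5 Å) is a reasonable convergence scale for
  well-defined NMR ensembles, not a statement about any published
  tool's parameterisation.

Numerical choices: convergence tolerance `tol = 1e-6` Å and
`max_iter = 100` (well below the 1e-3 Å precision of PDB coordinates;
non-convergence warns and returns the flagged state); reflections in the
Kabsch step are corrected by flipping the smallest singular vector;
near-collinear fit sets (second singular value ≈ 0) raise a degeneracy
error rather than returning an arbitrary rotation; the weight
regulariser `ε = 1e-6` Å² keeps perfectly converged atoms from acquiring
infinite weight. The variance divisor is M−1 (sample variance); ranks
are unaffected by the M vs. M−1 choice, only absolute variances and
F-scores depend on it.

# Reading structures

The PDB reader is deliberately conservative and record-level, because
the analysis contract depends on details generic readers hide:

* atoms are intersected across MODEL blocks (an atom absent from any
  model cannot contribute a variance), kept in first-model order;
* alternate locations resolve to the highest-occupancy conformer, ties
  to the first in file order;
* author residue numbering and insertion codes are preserved — no
  renumbering;
* hydrogens are dropped except the amide proton `H`, retained so the
  extended atom set {N, CA, C, O, CB, H} can be analysed; proline, which
  has no amide H, simply drops out of extended-set blocks;
* `HETATM` records are ignored except selenomethionine (`MSE`), which
  `map_modified_residues()` relabels to MET (SE → SD) so
  selenomethionine-phased crystal structures align with their NMR
  counterparts;
* OXT is not O: terminal carboxylate oxygens never enter the backbone4
  set. For multi-chain crystal structures `read_bfactors()` keeps all
  chains by default and exposes a `chain` argument.

# The synthetic generator

Three generators provide data with known structure. All are seeded and
bit-reproducible, and (by default) give every simulated model a random
rigid transform so that no test can accidentally bypass superposition.

`build_backbone_template()` constructs an ideal-geometry chain (N–CA
1.458 Å, CA–C 1.525 Å, C–O 1.231 Å, C–N 1.329 Å, N–H 1.01 Å, standard
angles, planar trans peptide ω = 180°) in extended (φ/ψ = −139°/135°) or
α-helical (−57°/−47°) conformation; the helix preset places O(i)···N(i+4)
near 3.1 Å, i.e. genuine helical hydrogen-bond geometry. Any
self-consistent ideal-geometry set would do, since all tests are
internal comparisons.

`simulate_additive_ensemble()` adds i.i.d. Gaussian displacement per
atom with per-type σ (per axis, Å). With equal σ across types it is the
exchangeable null for the Friedman test; with unequal σ it produces
known rank patterns. Defaults (σ = 0.1 Å, 20 models) are an NMR-like
coordinate spread and ensemble size.

`simulate_rocking_ensemble()` implements the peptide-plane rocking
model: for each plane i, the atoms {CA(i), C′(i), O(i), N(i+1), H(i+1)}
rotate by θ ~ N(0, σ_rock) about an axis through N(i+1) along the N→C′
bond tilted by `tilt_deg` toward CA(i). Geometry then dictates the
variance ordering var(O) > var(CA) > var(C′) > var(N): in the
small-angle limit each atom's variance is (distance from axis)² ·
Var(θ), and the lever arms at the default 15° tilt are ≈ 1.5 Å (O),
0.8 Å (CA), 0.34 Å (C′), 0 (N). The defaults σ_rock = 10°, tilt = 15°
give an unambiguous interior-residue pattern at 20 models; the
small-angle closed form is verified in tests at σ_rock = 3° within 20%,
a band chosen to cover both linearisation error and Monte-Carlo noise.
A 0.05 Å isotropic jitter floor emulates the residual coordinate noise
real ensembles always carry (and keeps degenerate zero-variance atoms
out of the generic case); set `jitter = 0` for exact geometric checks.
The rocking amplitude is illustrative — the motional model's published
description is qualitative — so tests assert ordering and significance
patterns, never absolute variances from real data.

`simulate_null_bfactors()` draws B ~ N(mean_b, sd_b) truncated at zero
and quantised to 0.01 Å² as in PDB files; the quantisation produces the
ties that exercise the mid-rank and tie-correction paths, and sd_b = 0
produces the fully tied degenerate table (statistic 0, p = 1, flagged).

What the generators do *not* emulate: correlated motions between
residues, anisotropy, secondary-structure-dependent restraint density,
side chains beyond CB, and solvent. Passing tests therefore demonstrate
the statistical machinery is correct under its stated model, not that
any particular protein behaves this way.

# Verification design and problem sizes

Every stage has an independent oracle: Kabsch fits are checked against a
brute-force rotation search (Euler-angle grid plus Nelder-Mead
refinement, agreement to 1e-6 Å RMSD); the Friedman statistic against
direct formula evaluation and `stats::friedman.test` on tie-free tables
(R's implementation applies no tie correction, so tied cases are checked
against the formula and the degenerate contract instead); the chi-square
p-value against full permutation enumeration of the (k!)ⁿ null at
n ≤ 4, k = 3 — where the approximation's own worst-case error, measured
by that same enumeration, is ≈ 0.23 and concentrated at small statistic
values; the PDB reader against `bio3d`; simulated variances against
their closed forms.

The simulation studies use 200 null replicates (100 residues, 20
models) for the type-I check — nominal 0.05, asserted within the 99%
binomial interval [0.014, 0.10] — and 100 rocking replicates (50
residues, 20 models) for pattern recovery, sizes at which the checks are
statistically sharp while the full suite runs in well under a minute.
The cohort-level count (in how many ensembles is C′ significantly below
O?) is demonstrated on 20 simulated NMR-sized ensembles.

# Known limitations

* The weighted and core schemes are simplified analogs, suitable for
  testing robustness of rank patterns to the superposition method, not
  drop-in replacements for the published maximum-likelihood or
  dendrogram-based tools.
* The 3-SE post-hoc rule is one defensible reading of a verbally stated
  criterion; counts of significant pairs are sensitive to the choice of
  SE basis at small n.
* Chi-square p-values are approximate below ~10 blocks; the package
  reports them regardless (flagging degeneracy), since the post-hoc rule
  rather than the omnibus p drives the cross-structure counts.
* mmCIF, anisotropic B-factors (ANISOU) and raw MD trajectory formats
  are out of scope; convert trajectories to multi-model PDB first.
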