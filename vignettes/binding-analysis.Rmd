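---
title: "Models and methods behind stacbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stacbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stacbind)
```

stacbind analyses four complementary lines of evidence for direct
small-molecule binding to a protein domain: conformational-ensemble
clustering and contact statistics, NMR chemical-shift-perturbation (CSP)
mapping, one-site isothermal titration calorimetry (ITC), and ratiometric
FRET group comparison. This vignette documents the underlying models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic-data generators can demonstrate.

## Rigid superposition and selective RMSD

All structural comparisons rest on the Kabsch solution of the orthogonal
Procrustes problem: given paired point sets, the rotation maximising
tr(*R H*) with *H* the cross-covariance of the centred sets is
*R* = *V U*ᵀ from the SVD *H* = *U S V*ᵀ. Two choices deserve note:

* **Reflections are forbidden.** The determinant correction (flipping the
  sign of the smallest singular direction when det(*V U*ᵀ) < 0) restricts
  the solution to proper rotations. Molecular frames are chiral; an
  improper "superposition" would align a molecule onto its mirror image.
* **Uniform weights.** Every selected atom counts equally; no mass or
  B-factor weighting is applied.

`rmsd_selective()` separates *alignment* from *measurement*: the transform
is computed on one atom selection (default: protein Cα), applied to the
whole frame, and the RMSD is evaluated over another (default: Cα plus
ligand heavy atoms). With a rigidly held protein this makes ligand
displacement directly visible: a ligand shift of *d* Å over *m* of *n*
measured atoms gives exactly *d*·√(*m*/*n*).

Atom roles are carried per atom (`protein-calpha`, `protein-heavy`,
`ligand-heavy`, `hydrogen`). Hydrogens are identified from the element
column when present, falling back to H/1H/2H/3H atom-name prefixes —
name-based detection alone misclassifies atoms like Hg-containing het
groups, so the element field wins whenever the file provides it.

Degenerate inputs are rejected rather than patched: fewer than three
points, mismatched point counts, and all-coincident sets raise errors.
Collinear sets are accepted (the in-line rotation component is arbitrary
but the RMSD is well defined).

## Ensemble clustering by iterative average structures

`cluster_ensemble()` partitions frames into metastable states:

1. The tentative reference is the first remaining frame (at the very
   start, the first snapshot of the first run).
2. All remaining frames within the membership cutoff (default **2.0 Å**,
   inclusive) of the reference are collected.
3. The members are superposed onto the reference and averaged atom-wise;
   the average becomes the new reference.
4. Steps 2–3 repeat until the selective RMSD between the cycle's average
   and its reference falls below the convergence threshold (default
   **0.01 Å**). The converged member set is removed as a new cluster, and
   the whole procedure repeats on the remainder until no frames are left.

Design decisions taken where the procedure is genuinely open:

* **Reference after a cluster is removed** — the earliest remaining frame.
  This is the simplest deterministic reading of "take a structure from the
  trajectories", and makes results reproducible given frame order.
* **Membership during refinement** is recomputed against the current
  average over *remaining* frames only; frames already assigned to earlier
  clusters never rejoin. The alternative (recomputing over all frames)
  could break the partition property that every frame belongs to exactly
  one cluster.
* **Convergence comparison** — each cycle's average is compared to the
  reference it was computed against (the tentative reference in cycle 1,
  the previous average thereafter). A cluster of identical frames
  therefore converges in a single refinement cycle.
* **Distance selections** — the 2.0 Å metric aligns on Cα and measures
  over Cα ∪ ligand heavy atoms, the same convention as the RMSD traces;
  both selections are exposed as parameters rather than hard-coded.
* A safety cap (`max_iter`, default 100) finalises a non-converging
  cluster at its last iterate with a warning; with a finite cutoff and
  averaging this is a guard, not an expected path.
* Concatenated runs are clustered jointly; run boundaries are metadata.

Limiting behaviour follows from the construction and is enforced by tests:
an infinite cutoff yields one cluster, a vanishing cutoff on all-distinct
frames yields all singletons, and permuting frames within a well-separated
mode changes discovery order but not the partition.

## Contact statistics

Per-residue contact probability is the fraction of frames in which the
minimum heavy-atom distance between the residue and the ligand is within
the cutoff (default **4.0 Å**, inclusive); hydrogens are excluded on both
sides. The bound fraction uses the any-protein-atom criterion, so it
dominates every per-residue probability by set containment. Categories
follow the reporting convention low < 20 %, moderate 20–50 %, high > 50 %;
both category boundaries place the exact value in the moderate bin (high
is strictly "> 50 %"), and the same inclusive choice is applied at 20 %.
Probabilities are fractions internally and percentages in written reports.

## CSP mapping

The combined amide perturbation is
δΔ = √(δΔ²(HN) + 0.25·δΔ²(¹⁵N)), with shift differences taken
free-minus-bound (the formula is even, so the sign convention only affects
the reported components). The 0.25 weighting compensates the roughly
five-fold wider dispersion of the ¹⁵N dimension. Categories: none
[0, 0.04) ppm, moderate [0.04, 0.08] ppm, large > 0.08 ppm — both printed
boundaries fall in the moderate bin, mirroring how the ranges
"0.04–0.08" and "> 0.08" partition the line. Prolines (no backbone NH),
unassigned residues, and residues missing from either list are carried as
`unobservable` and never enter the δΔ computation. Side-chain NH₂ pairs
are outside the backbone table's scope. `annotate_structure()` writes
categories as numeric codes (−1/0/1/2) into the PDB B-factor column,
constant within each residue, for molecular-viewer colouring.

## One-site ITC

### Cell bookkeeping

An overflow cell of volume *V₀* keeps constant volume: injecting *dV*
displaces an equal volume of well-mixed content. stacbind uses the
continuous-perfusion limit, under which each species concentration relaxes
toward the syringe composition as
*c′* = *c*ᵢₙ + (*c* − *c*ᵢₙ)·e^(−dV/V₀) (with *c*ᵢₙ = 0 for the
macromolecule and *X₀* for the titrant). This is exactly the limit of
step-by-step mole/volume bookkeeping with infinitesimal injection
increments — the test suite verifies it against such a micro-step oracle —
and agrees with the common ΔV/2V₀ correction to first order in dV/V₀
(≈ 1 % here).

### Isotherm and heats

At each composition the bound complex concentration solves the single-site
mass-action quadratic; the numerically safe root
[C] = 2·N·M·X / (a + √(a² − 4·N·M·X)), a = N·M + X + K_D,
avoids catastrophic cancellation at low saturation. The heat of injection
*i* is ΔH times the change in moles of complex, with a trapezoid term
crediting complex formed in, then displaced from, the cell:
q_i = ΔH·[V₀·(C_i − C_{i−1}) + dV_i·(C_i + C_{i−1})/2] (µcal with
concentrations in µM, volumes in µL, ΔH in kcal/mol). In the tight-binding
limit this reduces to ΔH × moles injected per pre-equivalence injection;
total heat approaches N·(moles of macromolecule)·ΔH at saturation.

### Fitting

`fit_one_site()` minimises squared residuals of *normalised* heats
(kcal per mol of injectant) against this forward model by
Levenberg–Marquardt, parameterising the affinity as log K_D to keep the
optimiser on the positive axis (standard errors are mapped back by the
delta method; the curvature matrix provides the covariance). Defaults and
their rationale:

* **First injection excluded.** The customary small pre-injection (0.4 µL
  here) suffers syringe diffusion in real experiments and is conventionally
  discarded; `include_first = TRUE` restores it.
* **Offset term.** A constant per-injection offset absorbs residual
  dilution heat that background subtraction missed.
* **Low-c handling.** The Wiseman parameter c = N·M₀/K_D governs
  identifiability; below c ≈ 1 the stoichiometry is barely constrained, so
  the fit warns and `fix_n = TRUE` fixes N (default 1). A 10 µM cell with
  K_D ≈ 55 µM (c ≈ 0.18) is exactly this regime.
* **Starting values** derive from the data (ΔH from total heat at assumed
  saturation, K_D at M₀ i.e. c = 1, offset 0) and can be overridden.
* **Units** are µcal internally and kcal/mol-of-injectant for fitting and
  reports.
* Out-of-order thermograms are refused outright — the forward model is
  sequential, so a permuted injection column cannot be fit meaningfully.

`fold_change()` is the reference-over-condition K_D ratio; reports print
it to one decimal, e.g. 55.0/6.67 → 8.2 and 55.0/38.8 → 1.4.

### Noise model

Simulated thermograms add i.i.d. Gaussian noise to the integrated heats;
a seed is mandatory whenever noise is requested, so simulations are
reproducible by construction. Recovery experiments in the test suite use
noise at 2 % of the largest noise-free heat, 100 replicates per planted
value, and check the median fitted K_D within 15 % (c ≥ 1) or 25 %
(low c, N fixed) of the planted value.

## FRET group statistics

The FRET ratio is acceptor over donor emission intensity (600 nm/515 nm
under donor excitation), invariant to overall gain. Group comparison is a
classical fixed-effects one-way ANOVA followed by Tukey HSD: the pairwise
statistic q = |m_i − m_j| / √(MSE/2·(1/n_i + 1/n_j)) is referred to the
studentized range distribution (R's `ptukey`), which for unbalanced groups
is the Tukey–Kramer harmonic correction. For two groups this reduces
exactly to the pooled two-sample t-test via q = √2·|t|, one of the
identities the tests pin down; a single-step max-q permutation oracle
(10⁵ permutations) provides an independent check of the three-group
adjusted p-values within Monte-Carlo error.

The compact letter display uses the insert-and-absorb procedure: start
with one letter shared by all groups; for each significantly different
pair, split every letter column containing both, then absorb columns that
became subsets of others. Letters are ordered by group means (ties broken
by label order), so output is deterministic, and the defining relation —
groups share a letter **iff** their adjusted p ≥ α — holds exactly by
construction and is asserted in the tests.

## Synthetic data: what it does and does not emulate

Every generator returns its ground truth alongside the data, and all
recovery tests consume these (data, truth) pairs. Regeneration with the
same seed is bit-identical.

* **Ensembles** (`make_ensemble`): frames dwell in a small number of
  ligand poses and jump by a first-order Markov process whose stationary
  distribution equals the mode weights (each step redraws the mode with
  probability `switch_prob`, emulating the dwell structure of metastable
  states), plus isotropic Gaussian positional noise (default 0.2 Å per
  coordinate, i.e. ≈ 0.35 Å frame RMSD about a pose). The default
  scaffold is a 49-residue helical Cα trace numbered 183–231 with a rigid
  20-heavy-atom two-ring ligand — the size of an NTD–flavonoid system —
  and the default poses separate the ligand centres by ≈ 15 Å so that the
  combined-selection inter-mode RMSD comfortably exceeds the 2 Å cluster
  cutoff. Truth contact fractions are recomputed from the generated
  coordinates by an independent straight-loop implementation.
* **Peak lists** (`make_peaklists`): free shifts uniform in realistic
  amide ranges (¹H 7.2–9.8 ppm, ¹⁵N 105–130 ppm), bound = free − planted
  differences + optional noise, prolines/unassigned positions emitted as
  unobservable in both lists.
* **ITC** (`make_itc`): binding heats from the forward model plus a small
  constant per-injection dilution heat; the blank carries the dilution
  heat alone, so noise-free background subtraction recovers the binding
  heats exactly. The planted enthalpy defaults to −10 kcal/mol, a typical
  exothermic peptide–protein binding enthalpy (the assay only constrains
  ΔH jointly with the data; no printed value exists for this system).
* **FRET** (`make_fret`): Gaussian replicate ratios per condition
  (default n = 3), emitted with consistent donor/acceptor intensities.

What passing tests on these data *do not* show: force-field realism (the
scaffold has no side chains, no solvent, no physical dynamics), peak
overlap or exchange broadening in spectra, baseline drift or injection
artefacts in thermograms, or non-Gaussian replicate structure. The tests
demonstrate that the *analysis* is correct on data with the assumed
statistical structure, not that real instruments produce such data.

## Problem sizes and runtime choices

The test suite clusters ensembles of a few hundred frames (69 atoms each),
fits 100-replicate ITC recovery experiments per planted K_D, compares
Kabsch superpositions against rotation grids of 10⁵–10⁶ quasi-uniform
random rotations (evaluated through the trace identity
rmsd²(R) = (Σ|p|² + Σ|q|² − 2⟨R, H⟩)/n, so a grid scan is a single
matrix product), and runs a 10⁵-permutation oracle for the Tukey check.
These sizes were chosen so the full suite runs in a few minutes on one
core while keeping every statistical bound comfortably powered.

## Known limitations

* Clustering is the iterative average-structure method only; no k-means,
  gromos, or Markov-state variants, and no kinetic analysis.
* Atom matching requires identical topology across frames; there is no
  sequence-based matching between different constructs.
* ITC covers the one-site model only — no multi-site or competitive
  schemes, and no ΔG/ΔS decomposition beyond the fitted parameters.
* CSP analysis does not do peak picking or assignment, and does not fit
  K_D from titration series.
* File formats: PDB (multi-model), Sparky-style peak lists, CSV, and flat
  key-value protocol configs; mmCIF and compressed trajectory formats
  (XTC/DCD) are future extensions.
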