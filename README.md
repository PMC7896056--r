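# stacbind

Analysis toolkit for characterising how a small-molecule activator binds a
protein domain, built around the four assays typically combined in such a
study: molecular-dynamics ensemble analysis, NMR chemical-shift-perturbation
(CSP) mapping, isothermal titration calorimetry (ITC), and ratiometric FRET.
The motivating system is a sirtuin-activating compound (STAC) binding the
SIRT1 N-terminal domain (NTD, residues 183–231) and enhancing the enzyme's
affinity for its native acetyl-p53 substrate peptide, but every stage is
generic: a conformational ensemble, a pair of peak lists, a thermogram, or a
replicate table from any comparable system will do.

Because raw instrument data for such studies are rarely deposited, the
package ships seeded synthetic-data generators that emulate each assay *with
known ground truth* — every analysis stage can be exercised and validated
end to end without any download.

## What it computes

**Ensemble clustering into binding modes.** Frames of a trajectory are
partitioned by the iterative average-structure method: a tentative reference
(the first remaining frame) collects all frames within a 2.0 Å cutoff of it,
the average of the superposed members becomes the new reference, and the
cycle repeats until successive averages differ by < 0.01 Å; the converged
member set is removed as a cluster and the procedure repeats until no frames
remain. The distance is a selective RMSD: a Kabsch superposition
(proper rotations only) on the protein Cα trace, measured over Cα plus
ligand heavy atoms, so clusters separate ligand *binding modes* rather than
protein breathing.

**Contact statistics.** Per-residue contact probability = fraction of frames
in which any heavy atom of the residue is within 4 Å of any ligand heavy
atom, binned as low (< 20 %), moderate (20–50 %) or high (> 50 %); the bound
fraction is the fraction of frames with *any* protein–ligand heavy-atom
contact.

**CSP mapping.** From free/bound ¹H–¹⁵N peak lists,
δΔ = √(δΔ²(HN) + 0.25·δΔ²(¹⁵N)) per residue, classified as
none (0.00–0.04 ppm), moderate (0.04–0.08 ppm) or large (> 0.08 ppm), with
prolines and unassigned residues carried as unobservable, and categories
writable onto a PDB B-factor column for structure colouring.

**One-site ITC.** Simulation and nonlinear least-squares fitting of the
"one set of sites" isotherm: at each injection the bound-complex
concentration solves the mass-action quadratic
[C] = ((N·M + X + K_D) − √((N·M + X + K_D)² − 4·N·M·X))/2
at the current cell composition (displaced-volume bookkeeping for the
overflow cell), heats are enthalpy changes of the complex, and the fit
returns N, K_D, ΔH and a baseline offset with curvature standard errors and
the Wiseman c-value (N·M₀/K_D; below c ≈ 1 fix N). K_D fold changes
quantify affinity enhancement by an activator.

**FRET group comparison.** Acceptor/donor intensity ratios compared across
conditions by one-way ANOVA with Tukey HSD adjusted p-values (studentized
range; Tukey–Kramer for unbalanced groups) and a compact letter display:
groups sharing a letter are not significantly different at α.

## Worked example

```r
library(stacbind)

# --- a two-mode synthetic ensemble, clustered and contact-profiled
gen <- make_ensemble(ensemble_spec(n_frames = 200, weights = c(0.7, 0.3),
                                   switch_prob = 0.2, noise_sd = 0.2,
                                   seed = 42))
cluster_ensemble(gen$ensemble, cutoff = 2.0, convergence = 0.01)
#> Ensemble clustering: 2 cluster(s) over 200 frames (cutoff 2 A)
#>   cluster 1: 58 frames (29.0%), 2 refinement cycle(s)
#>   cluster 2: 142 frames (71.0%), 2 refinement cycle(s)
```

The two planted binding modes are recovered exactly (58 frames dwell in the
minor, quasi-dissociated pose; 142 in the bound pose), and the contact
profile of the same ensemble gives a bound fraction of 0.710 with the
pocket residues in the high (> 50 %) category.

```r
# --- ITC: simulate a titration at the activator-bound affinity, re-fit it
pr <- itc_protocol()  # 200 uL cell, 10 uM protein, 500 uM titrant,
                      # 20 injections: 0.4 uL then 19 x 2.0 uL
tg <- simulate_titration(pr, N = 1, kd = 6.67, dH = -10,
                         noise_sd = 0.03, seed = 42)
fit_one_site(tg, fix_n = TRUE)
#> One-site ITC fit
#>   K_D   = 6.26 uM (se 0.27), N fixed
#>   N     = 1 (fixed)
#>   dH    = -9.76 kcal/mol (se 0.17)
#>   c     = 1.60
fold_change(55.0, 6.67)   # reference vs activator-bound K_D
#> [1] 8.245877            # prints as 8.2-fold
```

```r
# --- CSP: planted perturbations recovered and classified
pk <- make_peaklists(peaklist_spec(
  perturbed = list(`200` = c(0.10, 0.05), `206` = c(0.06, 0.30),
                   `216` = c(0.05, 0.04)),
  noise_sd = 0.002, seed = 42))
subset(csp_table(pk$free, pk$bound), category %in% c("moderate", "large"))
#>    resno resid       d_hn        d_n     ddelta category
#> 18   200     T 0.09932830 0.05076467 0.10252012    large
#> 24   206     E 0.05875296 0.30294087 0.16246601    large
#> 34   216     S 0.04982312 0.04098575 0.05387301 moderate

# --- FRET: compact letters separate the activator + substrate condition
d <- make_fret(c(apo = 1.02, kpmf8 = 1.01, kpmf8_acp53 = 0.83),
               sd = 0.04, n = 3, seed = 42)
fret_compare(d)
#> One-way ANOVA: F(2, 6) = 19.26, p = 0.002447
#> Tukey HSD at alpha = 0.05 (same letter: not significantly different)
#>        group n      mean         sd letters
#>          apo 3 1.0355918 0.03872415       a
#>        kpmf8 3 1.0224134 0.01513370       a
#>  kpmf8_acp53 3 0.8758038 0.04412674       b
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/stacbind` (subcommands `cluster`, `contacts`, `csp`,
`itc-sim`, `itc-fit`, `itc-fold`, `fret-compare`, `simulate`).

## Methods documentation

See `vignettes/binding-analysis.Rmd` for the models, their assumptions,
parameter choices, numerical details, and what the synthetic generators do
and do not emulate.
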