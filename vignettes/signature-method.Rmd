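---
title: "Graph-based signatures for mutation effects on protein–nucleic acid binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-based signatures for mutation effects on protein–nucleic acid binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nabind)
```

## The model

`nabind` predicts the change in binding free energy, ΔΔG in kcal/mol,
caused by a single missense mutation in a protein–nucleic acid complex.
Negative means reduced affinity. The core assumption is that the
mutation's effect is largely determined by (i) the physicochemical
texture of the wild-type residue's structural neighbourhood and (ii) the
chemical nature of the substitution itself. Both are encoded without any
force field:

1. **Environment signature.** Every heavy atom within a radius of the
   mutated residue is assigned pharmacophore classes. Protein atoms may
   carry several classes at once (arginine's NH1 is both positively
   charged and an H-bond donor); nucleic-acid atoms carry one class
   under the default group scheme (phosphate / sugar / base). For each
   unordered class pair and each cutoff of a distance schedule the
   signature stores the cumulative count of atom pairs within that
   cutoff. Cumulative counts make the vector monotone in the cutoff and
   robust to small coordinate noise; they are invariant to atom order
   and to rigid-body motion because only interatomic distances enter.
2. **Mutation encoding.** The substitution is encoded as the difference
   of per-residue pharmacophore compositions, counts(mut) − counts(wt).
   This "change vector" is anti-symmetric by construction, which is what
   lets reverse-mutation records carry consistent information without a
   modelled mutant structure.
3. **Complementary evidence.** Relative solvent accessibility of the
   site, its minimum distance to the nucleic acid, a protein-stability
   term, and the user-declared nucleic-acid type (never inferred from
   the coordinates).

A Gaussian process with an RBF kernel plus white noise regresses ΔΔG on
this vector.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| environment radius | 10 | Å | matches the outer distance shell used in evaluation; beyond ~10 Å class-pair counts are dominated by bulk composition |
| cutoff schedule | 0–10 step 2 | Å | 6 cutoffs × 78 class pairs keeps the vector (~480 features) proportionate to a ~660-record training set; configurable via `cutoff_schedule()` |
| NA typing scheme | `NUC_GROUP` | — | phosphate/sugar/base distinguishes backbone from base contacts; `NUC_BASE` (purine/pyrimidine) retained behind a flag for comparison |
| multi-class mode | on | — | atoms contribute to every class pair they realise; a primary-class-only mode exists behind a flag |
| probe radius / sphere points | 1.4 / 92 | Å / — | standard water probe, classic point count for Shrake–Rupley |
| GP noise variance | 0.01 (floor 1e-3) | — | white-noise term of the kernel; the floor is a hard constraint of the backend |
| trim fraction | 0.10 | — | evaluation-time outlier removal |

## Numerical and convention choices

- **Altloc resolution**: highest summed occupancy per residue wins; ties
  go to the alphabetically first altloc identifier. Hydrogens and waters
  are always dropped; multi-model files are truncated to model 1 with a
  warning; modified residues (HETATM) are kept in the atom table as kind
  "other" but never enter signatures — each exclusion is logged rather
  than silently guessed at.
- **Charge counting**: residue compositions count each charged group
  once, on its central atom (LYS NZ, ARG CZ, ASP CG, GLU CD), so a
  D→K substitution changes the negative count by −1 and the positive
  count by +1. Atom-level class *sets*, used in signatures, still mark
  the terminal N/O atoms of those groups as charged, so charge–phosphate
  contact cells behave chemically.
- **RSA convention**: accessibility is computed on the protein chains
  alone, nucleic acid stripped, so interface residues are not reported
  as artificially buried by their binding partner. The normalisation
  table is the theoretical per-residue maximum ASA (Tien et al. 2013),
  shipped as an editable TSV.
- **Stability term**: the published approach uses a dedicated stability
  predictor whose values are not recoverable; `nabind` therefore makes
  the feature pluggable. `external_value` injects per-record predictions
  from any stability tool (recommended); `baseline_heuristic` is a
  transparent stand-in — hydropathy and volume change scaled by burial,
  anti-symmetric at fixed RSA; `zero` disables the feature.
- **Reverse augmentation**: ΔG is a state function, so the reverse
  record's ΔΔG is the exact negation of the forward one. The source
  sentence omits the sign, but anti-symmetry is forced by thermodynamics
  and by the augmentation's purpose (balancing reducing vs increasing
  examples). Reverse records without a modelled mutant structure are
  featurized on the wild-type structure: the environment block is shared
  with the forward partner while the mutation-encoding features negate —
  exactly the change-vector route.
- **Folds**: forward/reverse partners always share a fold; otherwise a
  model could read half of each test label from its training partner. An
  optional structure-grouped mode (`by_structure = TRUE`) additionally
  keeps all mutations of one complex together.
- **Outlier trimming**: "10% outlier removal" is defined here as removing
  the ⌈0.1·n⌉ records with the largest absolute residual, ties broken by
  record order. No standard definition exists and the choice changes the
  reported trimmed ρ, so it is stated prominently rather than buried.
- **Distance shells** are nested (≤5 Å ⊂ ≤10 Å ⊂ all), matching the
  monotone phrasing of the evaluation they mirror; empty shells are
  reported with n = 0, never raised as errors.
- **GP determinism**: the RBF bandwidth uses the median-pairwise-distance
  heuristic on an evenly strided subsample (never a random one), features
  are standardised with training statistics stored in the model, and the
  target is centred and restored. Training twice on the same data and
  seed gives bit-identical predictions. The backend's noise-variance
  floor (1e-3) means the noiseless limit recovers targets to ~0.05
  kcal/mol rather than interpolating exactly.
- **Manifest enforcement**: the ordered feature names are frozen in the
  trained model; prediction on a matrix with renamed, missing or
  reordered columns is refused with the discrepancy listed. This is the
  contract that keeps featurizer and model from silently disagreeing.

## What the synthetic generators emulate — and what they do not

The package tests itself without any downloads, so every input class has
a generator:

- `generate_complex()` emits idealised complexes: a helix-like protein
  chain facing a straight nucleic-acid "ladder" (with an exactly realised
  interface contact distance), a random two-blob cloud, and a sealed
  cage for burial tests. These exercise parsing, geometry and signature
  code paths with verifiable ground truth. They are *not* realistic
  biomolecules: no base pairing, no backbone continuity, no sterically
  sensible side chains. Passing tests on them demonstrates correctness
  of the computations, not predictive accuracy on real complexes.
- `generate_planted_dataset()` draws feature matrices with latent-factor
  correlation (real signature columns are strongly collinear — cumulative
  counts share the underlying atom density) and targets
  y = Xw + ε with a known w (signal sd ≈ 1.5 kcal/mol, noise 0.3 by
  default). Recovery of w's predictions by the GP validates the learning
  stack; it says nothing about whether real ΔΔG is linear in signatures.
- `generate_structural_dataset()` closes the loop: synthetic complexes,
  the real featurizer, and a target planted on the mutation-encoding
  features (positive-charge change, hydrophobicity change, stability
  term), which are exactly anti-symmetric — so reverse augmentation is
  consistent by construction. The loss-of-charge vs charge-gain sign
  check runs against a complex never seen in training.
- `generate_training_table()` emulates only the *composition* of the
  curated study data (331 mutations, 38 complexes, 258 reducing;
  222 dsDNA / 42 ssDNA / 67 RNA; one complex identifier shared between
  the dsDNA and ssDNA strata, which reconciles the per-type structure
  counts with the overall total). Its rows are synthetic and not
  featurizable; it exercises reading, validation, augmentation and fold
  construction, and a curated table in the same schema drops in
  unchanged.

Problem sizes used by the test-suite and the acceptance script — 500
planted records for held-out recovery, 662 (331 pairs) for
cross-validation, 8 complexes × 12 mutations (192 after augmentation)
for the structural loop — were chosen to mirror the scale of the curated
study while keeping a full run comfortably fast on a single CPU.

## Known limitations

- Predictions on real complexes require real training data; the shipped
  generators validate the machinery, not biological accuracy.
- The exact feature schedule, stability predictor and GP settings of the
  published server are not recoverable from its description, so
  prediction-level agreement with it is out of scope by design.
- Modified nucleotides and non-standard residues are excluded from
  signatures rather than typed heuristically; mutation sites at
  non-standard residues are rejected.
- The stability heuristic is a documented stand-in. When stability
  predictions from a dedicated tool are available, use
  `stability_provider = "external_value"`.
- mmCIF input, automatic ssDNA/dsDNA discrimination and network fetching
  of structures are deliberately unsupported.
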