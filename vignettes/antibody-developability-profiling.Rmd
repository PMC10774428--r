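---
title: "Structure-based antibody developability profiling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based antibody developability profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abtap)
```

# The problem

Biophysical liabilities of therapeutic antibody candidates —
aggregation propensity, viscosity, poly-specificity — track with
surface properties of the variable fragment (Fv): large contiguous
hydrophobic or charged patches near the antigen-binding loops, very
long CDRs, and strongly opposed net charges on the two variable
domains. `abtap` quantifies these as five metrics over an
IMGT-numbered Fv model and flags candidates whose scores fall in the
extreme tails of a reference distribution built from clinical-stage
therapeutics. This vignette is the package's account of the model,
its tunable parameters, the numerical choices, and what the synthetic
test surface does and does not demonstrate.

# The profiling pipeline

For one structure the pipeline is strictly staged, and every stage is
exposed as its own function:

1. **Ingestion** (`readFvPdb`). ATOM records of the two mapped chains
   only; hydrogens, waters and heteroatoms dropped; alternate
   locations resolved to the blank/'A' conformer. The metrics are
   heavy-atom quantities by construction, matching the
   parameterisation of the maximum-SASA references. When the file
   stems from a structure predictor that writes per-residue error
   estimates into the B-factor column, the mean backbone (N, CA, C,
   O) B-factor of each residue is retained as its predicted error.
2. **Solvent accessibility** (`shrakeRupley`). Shrake–Rupley with a
   1.4 Å probe over both chains *together* — exposure must reflect
   burial at the VH/VL interface. Radii: C 1.70, N 1.55, O 1.52,
   S 1.80, default 1.70 Å (configurable; no radii are mandated by the
   protocol itself).
3. **Exposure** (`classifyExposure`). Residue X is exposed when its
   SASA is at least 7.5 % of the theoretical maximum for X, an
   inclusive comparison. The maxima are computed by the same SASA
   routine on extended Ala-X-Ala tripeptides (below).
4. **Regions and vicinity** (`assignRegions`, `buildAnchorSet`,
   `buildCdrVicinity`). CDRs are purely positional (IMGT 27–38,
   56–65, 105–117 on both chains, insertion codes included). Anchors
   are CDR residues plus two flanking residues per side *in chain
   order*; the vicinity adds every exposed residue within 4.5 Å of an
   anchor, in a single pass.
5. **Metrics** (`pshScore`, `ppcScore`, `pncScore`, `sfvcspScore`,
   `totalCdrLength`, orchestrated by `computeTapProfile`). The patch
   kernel sums w_i w_j / d_ij² over unordered pairs of exposed,
   positively weighted vicinity residues with d_ij ≤ 7.5 Å. Every
   contributing pair is returned, so the score equals the sum of its
   components to machine precision — the decomposition is an identity,
   not an approximation.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water-sized solvent probe |
| `n_sphere_points` | 960 | — | SASA quadrature resolution |
| `exposure_fraction` | 0.075 | — | exposed/buried cut, fraction of max SASA |
| `vicinity_cutoff` | 4.5 | Å | anchor-to-residue inclusion distance |
| `pair_cutoff` | 7.5 | Å | maximum pair distance in patch kernel |
| `distance_exponent` | 2 | — | kernel distance power |
| `distance_mode` | min-heavy | — | residue–residue distance definition |
| `hydrophobicity_range` | [1, 2] | — | affine target of the Kyte–Doolittle scale |
| `his_charge` | +0.1 | e | fractional histidine protonation |
| `sfvcsp_scope` | domain | — | residues summed for charge symmetry |

All of these live in `tapConfig()` and are serialised (as a hash)
into every CLI output, so a profile is reproducible from its header.

## Open choices and why they were made this way

The probe radius, exposure fraction, CDR ranges, flank width and the
4.5 Å vicinity cutoff are fixed by the published protocol. Several
elements of the original implementation are not printed anywhere and
had to be decided here; they are deliberately configuration, not
code:

* **Patch kernel.** The functional form w_i·w_j/d² with a 7.5 Å pair
  cutoff and minimum heavy-atom distances is the package's default.
  The published guideline numbers imply a specific historical
  parameterisation that can only be confirmed by calibrating against
  the deposited reference models; until then, absolute PSH/PPC/PNC
  values from this package should be compared against thresholds
  fitted *by this package* on a user's own reference cohort, which is
  how the flagging API is designed to be used anyway.
* **Hydrophobicity normalisation.** The raw Kyte–Doolittle scale
  spans [−4.5, +4.5]; patch weights must be positive for
  contributions to be rankable. The affine map onto [1, 2] preserves
  the scale's order exactly and keeps the dynamic range modest.
* **Histidine charge.** +0.1, reflecting its minority protonation at
  formulation pH; configurable because published charge-symmetry
  thresholds with two decimals suggest fractional charges but do not
  pin down the value.
* **Charge-symmetry scope.** Net charges are summed over all exposed
  residues of each variable domain (not just the vicinity): charge
  asymmetry is a whole-domain colloidal property.
* **Flanks in chain order.** "±2 residues" is counted on the ordered
  residue list, not by IMGT arithmetic — IMGT numbering has gaps, and
  position arithmetic would silently produce one- or zero-residue
  flanks.
* **Non-transitive vicinity.** The 4.5 Å expansion is measured to the
  anchor set only; newly added members do not recruit further
  residues. The phrase "within 4.5 Å of one of these residues" reads
  most naturally as anchored, and a transitive closure would make the
  vicinity percolate across the surface.

# Flagging and cohort statistics

Thresholds are the 0th/5th/95th/100th percentiles of a reference
score collection, computed by sorted linear interpolation (the
`type = 7` convention; conventions differ in the second decimal at
cohort sizes of a few hundred, which is why the choice is documented
and fixed). Amber boundaries are inclusive and red requires strictly
exceeding the observed extremum — consequently a reference cohort
flagged against its own thresholds has exactly zero red flags and
close to 5 % amber per flagged tail, a property the test suite
asserts. Ensemble consensus over repeat runs is the worst flag raised
on any run; repeat-run spread is reported as the population variance
(divisor n), since two or three repeats are a descriptive sample of a
stochastic modelling step, not an estimator of a larger population.
Reported standard deviations in cohort length statistics default to
divisor n − 1 and are configurable.

Confidence filtering summarises per-residue predicted error over the
CDRH3 as an RMS value and retains structures at or below a threshold;
the threshold may be derived as a percentile of the cohort's RMS
values after excluding a user-supplied id list (the natural workflow
when some reference entries have solved structures and should not
inform a model-confidence cut).

# The synthetic test surface

`makePeptide` builds ideal-geometry backbones (N–CA 1.46, CA–C 1.52,
C–N 1.33 Å; φ = −120°, ψ = +120° extended strands by default) with
the full heavy-atom complement of each residue type as placeholder
atoms laid out from the CB direction. `makeMiniFv` assembles two such
chains with designed CDR lengths, valid IMGT numbers (insertion codes
at position 111 for long CDR3 loops), seeded sequences, optional
coordinate jitter and per-residue predicted error. Everything is a
deterministic function of its spec and seed.

These fixtures emulate: valid numbering, chain pairing, realistic
atom densities and distances, exposure gradients, and every contract
of the pipeline. They do **not** emulate folded immunoglobulin
geometry, packed hydrophobic cores, or real CDR loop conformations.
Passing tests therefore demonstrate the correctness of the
*computations* (SASA quadrature, kernel sums, percentiles,
superposition, aggregation logic) on arbitrary geometry — they do not
demonstrate that absolute metric values on real Fv models match the
historical implementation, which is exactly the calibration question
deferred to the reference-model deposit.

Independent oracles are kept strictly separate from the
implementations they check: a rejection-sampling Monte-Carlo SASA
estimator (`mcSasaOracle`), closed forms for isolated and pairwise
overlapping spheres, naive double-loop patch sums, longhand
percentile interpolation, and an externally implemented least-squares
superposition.

# Numerical choices

* SASA quadrature uses a deterministic golden-spiral lattice — no
  RNG, so profiles are bitwise reproducible; 960 points put the
  isolated-sphere error well under 0.5 % and doubling the lattice
  changes fixture totals by < 0.5 %.
* Neighbour pruning uses the exact criterion
  d < r_i + r_j + 2·probe; a distant atom cannot change any SASA
  value, which the tests assert as an invariant.
* Component rankings break contribution ties lexicographically on
  (chain, sequence index) of both pair members, so reports are stable
  across platforms.
* Degenerate inputs are defined, not accidental: an empty vicinity
  yields score 0 with an empty component table; a CDR abutting a
  chain terminus truncates its flanks; residues missing backbone
  atoms are skipped (with a warning) in superposition; an empty CDRH3
  or absent predicted error is an error rather than a silent zero.
* Kabsch superposition uses base SVD with a determinant correction,
  guaranteeing a proper rotation even for degenerate point sets.

# Problem sizes

The shipped tests and the acceptance script run on mini-Fv fixtures
of roughly 50–80 residues, randomized kernel clouds of 3–8 residues
(100 replicates), synthetic reference cohorts of 664 scores, a
100-structure confidence-filter cohort, and a 12-structure profiled
cohort with one jittered repeat run — sizes chosen so the full suite
exercises every code path in a few minutes on a single core while
keeping Monte-Carlo standard errors small. The same functions run
unchanged on full-size cohorts (hundreds of Fvs) via the CLI.

# Known limitations

* Absolute patch-score scales depend on the unpublished historical
  kernel parameterisation (see above); cross-package comparisons of
  raw PSH values are not meaningful without calibration.
* No protonation-state modelling: charges are formal, pH-independent
  assignments; histidine is a single fractional value.
* mmCIF input, antigen or constant-domain chains, and non-IMGT CDR
  definitions (Kabat/Chothia/North) are out of scope; numbering is
  consumed as given, never recomputed.
* Exposure calls very close to the 7.5 % boundary are sensitive to
  the maximum-SASA reference geometry (the extended tripeptide
  choice), which can shift vicinity membership for borderline
  residues.
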