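# abtap

Structure-based developability profiling of antibody Fv models in R.

Therapeutic antibody candidates fail in development for biophysical
reasons — aggregation, high viscosity, poly-specificity — that correlate
with surface properties of the variable fragment (Fv). `abtap`
implements the five-metric structural developability profile used to
screen candidates against the observed property ranges of
clinical-stage therapeutics (CSTs), for computational antibody
engineers working with IMGT-numbered Fv models (e.g. ABodyBuilder2
output, where the B-factor column carries per-residue predicted error).

## The metrics

For an Fv with heavy (H) and light (L) chains, IMGT CDRs are positions
27–38 (CDR1), 56–65 (CDR2) and 105–117 (CDR3) on each chain. Solvent
accessibility is computed by a deterministic Shrake–Rupley
implementation (probe 1.4 Å, golden-spiral lattice); a residue X is
*exposed* when SASA(X) ≥ 7.5 % of its theoretical maximum (central
residue of an extended Ala-X-Ala tripeptide). The *CDR vicinity* is
the CDR residues ± 2 sequence flanks, plus every exposed residue
within 4.5 Å (minimum heavy-atom distance) of those anchors.

* **L_tot** — total residue count of the six CDRs (insertions
  included).
* **PSH** (patches of surface hydrophobicity) — over unordered pairs
  (i, j) of exposed vicinity residues with d_ij ≤ 7.5 Å:

      PSH = Σ_{i<j} H'_i · H'_j / d_ij²

  where H' is the Kyte–Doolittle scale mapped affinely onto [1, 2]
  and d_ij is the minimum heavy-atom distance.
* **PPC / PNC** (patches of surface positive / negative charge) — the
  same kernel with weights |q| restricted to R, K, H (+1, +1, +0.1)
  or D, E (−1).
* **SFvCSP** (structural Fv charge symmetry parameter) —
  (Σ q over exposed VH residues) × (Σ q over exposed VL residues);
  negative values mean opposed net domain charges.

Every patch score is returned with its full pairwise decomposition,
so extreme scores can be traced to the residue pairs (and IMGT
positions) that drive them.

Flagging thresholds are percentiles of a reference cohort: **amber**
in the extreme 5 % tail(s) (0–5th and/or 95–100th percentile,
inclusive), **red** strictly beyond the observed reference extremum.
L_tot and PSH are two-sided, PPC and PNC upper-tail, SFvCSP
lower-tail. The package also provides CDRH3 RMS-predicted-error
confidence filtering, repeat-run ensemble consensus ("flagged on any
run"), cohort comparisons (flag rates by group, CDR-length
statistics, gene-usage enrichment, inter-run agreement), and
framework-aligned per-region backbone RMSD (Kabsch superposition on
framework backbone atoms, region RMSD without re-fitting).

## Worked example

```r
library(abtap)

fv <- makeMiniFv(miniFvSpec(seed = 1))   # synthetic two-chain mini-Fv
fv
#> FvStructure: minifv_s1
#>   chain H: 42 residues; chain L: 34 residues; 639 heavy atoms
#>   light locus: kappa

prof <- computeTapProfile(fv)
prof
#> TapProfile: minifv_s1
#>   L_tot 44  PSH 104.24  PPC 0.10  PNC 0.57  SFvCSP -1.08
#>   components: 248/4/1 (psh/ppc/pnc pairs)

topComponents(tapComponents(prof, "psh"), 3, "non_adjacent")[,
  c("chain_i", "imgt_i", "aa_i", "chain_j", "imgt_j", "aa_j",
    "distance", "contribution")]
#>   chain_i imgt_i aa_i chain_j imgt_j aa_j distance contribution
#> 1       H     32    I       H     34    I 4.174918    0.2294902
#> 2       H     59    C       H     61    I 4.174918    0.2039913
#> 3       H    109    V       L    119    T 3.792268    0.1944913
```

L_tot 44 is the designed CDR total (8+8+10 heavy, 6+3+9 light). The
PSH of 104.24 is the sum of the 248 returned pair contributions; the
top non-adjacent pairs show which exposed vicinity residues dominate
the hydrophobic patches. Fit thresholds on a cohort of profiles with
`fitThresholds()`, flag with `assignFlags()`, and aggregate repeat
runs with `ensembleProfile()`.

A shell interface wrapping the same functions is installed at
`system.file("scripts", "tap.R", package = "abtap")` with commands
`profile`, `thresholds`, `flag`, `decompose`, `confidence`,
`ensemble`, `cohort`, `rmsd` and `fixtures`; every output CSV embeds
the resolved configuration hash.

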