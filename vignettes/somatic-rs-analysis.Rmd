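---
title: "Region-stratified R/S mutation analysis and interface metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-stratified R/S mutation analysis and interface metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticRS)
```

## The model

Somatic mutations in an antibody V gene are classified along three axes
relative to the unmutated germline gene:

* **effect** — replacement (R) if the codon's translation changes, silent
  (S) otherwise, with a stop codon counted as a distinct residue so
  nonsense changes are R;
* **chemistry** — transition (purine↔purine, pyrimidine↔pyrimidine) or
  transversion;
* **location** — Kabat region (FR1, CDR1, FR2, CDR2, FR3), with codons
  beyond FR3 treated as junction and excluded from tallies, because
  junction nucleotides cannot be attributed to the germline gene.

Antigen-driven selection predicts an excess of R mutations in the CDRs.
With several antibodies the evidence is stratified — each antibody
contributes one 2×2 table (CDR/FR × R/S) — and summarised by the
Mantel–Haenszel common odds ratio, the CMH chi-square test of
association (df 1), and the Breslow–Day chi-square test of odds-ratio
homogeneity (df K−1). Stratification protects the pooled estimate from
Simpson's paradox when mutation loads differ between antibodies.

```{r headline}
vh <- ley_vh_mutation_counts()
stratified_report(vh)
```

### Statistical conventions

* **Continuity correction** is off by default in `cmh_test()`: the
  uncorrected statistic on the published counts is 3.919, matching the
  reported 3.92; the corrected one is materially smaller. The flag
  exists for completeness.
* **Breslow–Day** uses the MH common OR as the homogeneity null and no
  Tarone adjustment by default (keeping df = K−1 = 3 on four strata);
  Tarone's correction is available via a flag. The expected cell in each
  stratum is the admissible root of the quadratic consistency equation;
  an out-of-range root raises an error naming the stratum.
* **Zero cells**: the MH estimator uses raw counts (zero terms vanish);
  per-stratum ORs report `Inf`/`0`/`NaN` under the raw policy, or the
  Haldane +0.5 policy on request. Nothing is silently pseudocounted.
* P-values come from the upper tail of the chi-square distribution
  (`chi2_upper_tail()`, a thin wrapper over R's `pchisq`).

### The inherent R/S baseline

An observed CDR R/S ratio is only meaningful against the ratio the
sequence would produce without selection. `inherent_rs_ratio()`
enumerates all nine single-nucleotide substitutions of every selected
codon and counts replacement vs silent outcomes under the standard
genetic code. For long random coding sequences the value sits near 2.9,
the conventional no-selection reference; tryptophan codons (TGG) have no
synonymous single-step neighbour, so single-codon selections can
legitimately return `+Inf` (flagged with a warning).

```{r inherent}
as.numeric(inherent_rs_ratio("TCT"))   # Ser: 6 R / 3 S
g <- generate_germline(1, 98)
round(as.numeric(inherent_rs_ratio(g)), 2)
```

## The synthetic-data generator

Because no sequence accessions accompany the original antibody set, the
package ships a generator that emulates the structure of the data rather
than any particular gene:

* `generate_germline()` draws codons uniformly from the 61 sense codons,
  producing an open reading frame annotated with a Kabat-style region
  map (default: FR1 1–30, CDR1 31–35, FR2 36–49, CDR2 50–66, FR3 67–98).
* `mutate_clone()` mutates each nucleotide independently with
  probability rate/3 per region (so `per_region_rate` is the expected
  number of substitutions per codon), draws the target base with a
  transition:transversion proposal weight of `titv_ratio : 2`, and
  returns the exhaustive, fully labelled list of planted mutations. The
  default rates concentrate mutations in CDR2 with lighter load in the
  flanking frameworks, and the default `titv_ratio = 0.5` makes
  transversions predominate — the mutation landscape reported for the
  anti-LeY heavy chains. Defaults produce a handful of mutations per
  clone, the low mutation load typical of T-independent responses.
* Multi-hit codons are allowed by default (all base substitutions in a
  codon are counted, sharing one codon-level R/S verdict computed from
  the germline codon vs the final clone codon — the stepwise order is
  unknowable from endpoint sequences). Stop-codon-producing mutations
  are allowed and labelled R; a `forbid` policy redraws them.
* `generate_toy_complex()` and `generate_toy_trajectory()` produce atom
  clouds with pinned pairwise distances and Gaussian-displacement
  trajectories whose RMSF has a closed-form expectation
  (σ√3·(n−1)/n per atom for per-coordinate noise σ over n frames).

What the generator does **not** emulate: AID hotspot motifs (WRC/GYW),
insertion/deletion events, clonal lineage structure, and selection
itself. Tests passing on synthetic data therefore validate the
classification and counting machinery, not any biological claim about
real repertoires; sequences are assumed pre-aligned to germline
coordinates, and length mismatches are an error rather than a trigger
for alignment.

## Structure metrics

The interface operators work on plain atom tables read from PDB files
(parsing via bio3d; highest-occupancy altloc kept):

* `vdw_contacts()` — inter-selection heavy-atom pairs within 4 Å
  (boundary inclusive; hydrogens excluded by default).
* `hydrogen_bonds()` — donor/acceptor typing from a residue+atom-name
  dictionary (backbone N/O, side-chain and sugar hydroxyls; unknown N/O
  atoms fall back to element typing). Criterion: D···A ≤ 3.5 Å and,
  when an explicit hydrogen sits within 1.25 Å of the donor,
  D–H···A ≥ 120°; with no hydrogens the result is flagged
  `distance_only`. The geometric thresholds are configurable since no
  single convention is universal.
* `interaction_energy()` — pairwise Coulomb
  (332.0637·q₁q₂/(ε·r) kcal/mol) plus Lennard-Jones
  (ε_ij[(r_min/r)¹² − 2(r_min/r)⁶], Lorentz–Berthelot combination)
  under a hard 14 Å spherical cutoff and dielectric 1 (in vacuo).
  Parameters come from a bundled, editable element-keyed TSV — a
  generic parameter set for exercising the operators, with no claim of
  agreement with any production force field; published interaction-
  energy magnitudes for modeled complexes are accordingly not
  reproduction targets here. Missing parameters are an error listing
  the offending atoms; pairs closer than 0.1 Å are rejected to keep
  energies finite. `per_residue_energy()` partitions the same sum by
  residue and conserves the total to 1e-6 kcal/mol.
* `rmsd()` — least-squares (Kabsch, SVD-based) superposition then RMS
  deviation; `rmsf()` — frames are fitted on a selection (e.g.
  backbone) to an iteratively refined average structure (3 passes,
  which converges for near-rigid fixtures), then per-atom RMS
  displacement about the average.
* `phi_psi()`/`ramachandran_code()` — backbone dihedrals under the
  IUPAC sign convention, coded by quadrant: `a` (φ≤0, −120<ψ≤50), `b`
  (φ≤0 otherwise), `l` (φ>0, −120<ψ≤50), `e` (φ>0 otherwise). The
  boundaries are configurable; the `e` region is this package's
  positive-φ analogue of `b`, chosen because the published coding
  scheme names four codes but fully specifies only three.
  `takeoff_code()` concatenates the codes over a loop-base window and
  flags the `bab` kinked-plus-bulge candidate pattern; it is a
  descriptor, not a full CDR-H3 classification, since the complete
  decision procedure for kinked/extended classes is beyond a quadrant
  code.

## Numerical and design choices

* Translation uses the standard genetic code via Biostrings; the test
  suite cross-checks every codon-pair verdict against seqinr — two
  independent implementations of the same code table.
* MH/CMH results are cross-validated against `stats::mantelhaen.test`
  on randomized tables to 1e-6; Breslow–Day against an independent
  root-finding oracle. The package's own closed-form implementations
  are the ones exported.
* Degenerate inputs are represented, not hidden: strata with empty
  margins contribute zero CMH information (skipped with a warning), a
  degenerate common OR (0 or ∞) skips the Breslow–Day test with a note,
  and single-frame trajectories return zero RMSF with a warning.
* Problem sizes in the tests (98-codon genes, 100-seed recovery sweeps,
  3000-replicate null calibration, 400-frame trajectories, 40–50-atom
  clouds) were chosen so every oracle comparison is exact or
  statistically decisive while the whole suite stays interactive.

## Limitations

* The light-chain analysis of the original antibody set is not
  reproducible from published material (its per-stratum counts were not
  printed) and is therefore not included as a reference dataset.
* Kabat region boundaries are inputs, not computed; the package does
  not implement Kabat/IMGT numbering.
* No germline inference, junction reconstruction, lineage trees, or
  hotspot-motif analysis; no energy minimisation, dynamics, or solvent
  models — coordinates and trajectories are analysed, never generated
  (beyond the synthetic fixtures).
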