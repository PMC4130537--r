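# somaticRS

Codon-aware somatic mutation analysis for antibody variable-region genes,
with the stratified contingency statistics used to ask whether replacement
mutations concentrate in the antigen-binding loops, plus the structural
operators used to characterise antibody–carbohydrate interfaces.

## The scientific problem

Antibodies reactive with the tumour-associated carbohydrate antigen
Lewis Y (LeY) derive from a restricted set of germline V genes
(heavy-chain VH7183.a13.20, light-chain Vκ cr1) and carry only a handful
of somatic mutations. Whether those few mutations show the signature of
antigen-driven selection is a statistical question: a replacement (R)
mutation changes the encoded amino acid, a silent (S) one does not, and
selection is inferred when the odds of an R mutation are higher in the
complementarity-determining regions (CDRs) than in the framework regions
(FRs).

With several antibodies, pooling their counts invites Simpson's paradox,
so each antibody is kept as its own stratum of a 2×2 table
(region × mutation type) and three classical statistics summarise the
stratified evidence:

- the **Mantel–Haenszel common odds ratio**
  `OR_MH = Σᵢ(aᵢdᵢ/nᵢ) / Σᵢ(bᵢcᵢ/nᵢ)` over strata *i* with cells
  *a* = CDR-R, *b* = CDR-S, *c* = FR-R, *d* = FR-S;
- the **Cochran–Mantel–Haenszel (CMH) chi-square**
  `(Σaᵢ − ΣEᵢ)²/ΣVᵢ` with hypergeometric expectation and variance,
  df = 1, testing the significance of the common OR;
- the **Breslow–Day chi-square** of homogeneity (df = K−1), testing
  whether one common OR describes every antibody.

The observed R/S ratios are judged against the *inherent* R/S ratio of
the sequence itself — the ratio expected under mutation without
selection, computed by enumerating all nine single-nucleotide
substitutions of every codon (≈2.9 for a random coding sequence).

The package also implements the structure-analysis operators applied to
antibody–LeY complexes: Van der Waals contacts at a 4 Å cutoff,
intermolecular hydrogen-bond detection, electrostatic + Lennard-Jones
interaction-energy decomposition (14 Å spherical cutoff, dielectric 1,
Coulomb constant 332.0637 kcal·Å/(mol·e²)), per-residue energy
partitions, Kabsch-superposed RMSD, RMSF against the trajectory-average
structure, and Ramachandran φ/ψ quadrant coding of the CDR-H3 take-off
(the kinked-plus-bulge `bab` pattern).

## Worked example

```r
library(somaticRS)

vh <- ley_vh_mutation_counts()   # the four anti-LeY VH strata
stratified_report(vh)
```

```
Per-stratum odds ratios:
 BR55-2      B3    BR96 mu3S193
      2       6     Inf     Inf

MH common OR: 6.260
CMH chi-square: 3.919 (df 1), p = 0.048
Breslow-Day chi-square: 1.083 (df 3), p = 0.781
```

The odds of a replacement mutation are about six-fold higher in the CDRs
than in the frameworks (common OR 6.26), the association is significant
at the 5% level (CMH p = 0.048), and the non-significant Breslow–Day
test (p = 0.78) says a single common OR is adequate across the four
antibodies.

A fully synthetic round trip — simulate clones with planted, labelled
mutations, re-classify them against the germline, and tabulate:

```r
sim <- simulate_clone_set(sim_config(seed = 1, n_clones = 4))
recs <- do.call(rbind, lapply(names(sim$clones), function(id)
  compare_to_germline(sim$germline, sim$clones[[id]], clone_id = id)))
tabulate_mutations(recs, sim$germline$regions)

inherent_rs_ratio(sim$germline)  # enumeration-expected R/S, ~2.9-3.2
```

## The analysis workflow

Numbered drivers under `analysis/` run the pipeline end to end and write
their tables under `results/`:

1. `01_simulate.R` — germline + four clones with planted mutations
   (FASTA, truth TSV, region map, manifest);
2. `02_classify.R` — mutation records and the per-clone region × R/S
   table, checked against the planted truth;
3. `03_stratified_stats.R` — per-stratum ORs, MH common OR, CMH and
   Breslow–Day on both the published VH counts and the simulated set,
   plus the inherent R/S baseline per region;
4. `04_structure_metrics.R` — contacts, hydrogen bonds, energy
   decomposition, RMSF/RMSD and take-off coding on toy fixtures with
   geometry known by construction.

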