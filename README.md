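# vartraj

Two companion pipelines for the computational study of a recessive
disease variant found in a consanguineous family — written for
statistical geneticists triaging exome candidates and for structural
bioinformaticians comparing wild-type and mutant molecular-dynamics
trajectories.

**The genetics arm** takes a multi-sample VCF plus a pedigree and applies
the classic homozygous-candidate triage:

1. a *hard-filter cascade* — per-sample coverage (DP > 5), genotype
   quality (GQ > 10) and allele read fraction (ARF ≥ 0.75 on hom-alt
   calls); site rarity (gnomAD MAF < 0.001, in-house AF < 0.001) and
   quality (FS < 40, MQRankSum ≥ −5, QD > 5, MQ > 50,
   ReadPosRankSum ≥ −5, splice change ≤ 15%), and a consequence-class
   whitelist;
2. an *autosomal-recessive co-segregation test* under full penetrance:
   affected members hom-alt, unaffected members not hom-alt, genotyped
   parents of affected members obligate heterozygotes;
3. intersection with *runs of homozygosity* (ROH) shared by the affected
   members — maximal homozygous genotype runs with ≥ 25 markers over
   ≥ 1 Mb;
4. *ranking* by normalized pathogenicity rank score (0 = benign,
   1 = pathogenic), ties broken by phred-scaled CADD.

**The structural arm** computes comparative trajectory statistics:
Kabsch least-squares superposition and per-frame RMSD; per-residue
Cα RMSF about the two-pass mean structure,
`RMSF_i = sqrt(⟨|r_i − ⟨r_i⟩|²⟩)`; residue–residue *contact occupancy*
(fraction of frames with center-of-mass distance < 5 Å, trailing
analysis window) with wild-type-minus-mutant difference maps in
percentage points (positive = more contact in WT); geometric
hydrogen-bond occupancy (D–A ≤ 3.5 Å, D–H–A ≥ 120°); Cα distance
mean ± sd; and a Shrake–Rupley hydrophobic-surface score (960-point
solvent-accessible surface area, probe 1.4 Å, apolar-atom
decomposition).

Both arms ship with synthetic-data generators that plant known ground
truth — a six-member pedigree VCF with one causal variant inside an ROH
block among labelled decoys, and toy-dimer trajectories with planted
contact / hydrogen-bond events recovered *exactly* — so the whole
pipeline is testable offline.

## Worked example

```r
library(vartraj)

## -- genetics arm: 500 labelled decoys + 1 planted causal variant
sim <- simulate_family_vcf(n_background = 500, seed = 42)
rep <- run_prioritize(sim$vcf, sim$ped)
rep
#> prioritization_report: 561 variants in, 51 past cascade, 16 co-segregating, 1 in shared ROH
#> top candidate: 1:74510000:T:C
rep$candidates[, c("rank", "id", "csq", "rankscore", "cadd")]
#>   rank             id      csq rankscore cadd
#> 1    1 1:74510000:T:C missense      0.79 26.9
```

The 561 input records are the causal variant, 60 common homozygosity
markers and 500 decoys; the cascade removes 510 (each decoy fails the
one stage it was planted to fail, the markers fall at the MAF stage),
co-segregation removes 35 more, and the shared-ROH intersection leaves
exactly the planted causal variant, ranked by its pathogenicity scores.

```r
## -- structural arm: a contact break at the dimer interface
dimer <- make_toy_dimer(20)                       # 40-residue homodimer
pair  <- data.frame(chain_i = "A", resno_i = 5, chain_j = "B", resno_j = 5)
wt  <- simulate_trajectory(dimer, n_frames = 200,
                           planted_contacts = cbind(pair, occupancy = 0.98),
                           seed = 1)
mut <- simulate_trajectory(dimer, n_frames = 200,
                           planted_contacts = cbind(pair, occupancy = 0.01),
                           seed = 2)
cmp <- run_compare_trajectories(wt$trajectories, mut$trajectories, dimer)
cmp
#> trajectory_comparison: 3 WT / 3 MUT replicates, cutoff 5 A, window full
#> largest contact difference: A5-B5 (+97.0 pp)
```

The pair planted at 98% occupancy in the wild type and 1% in the mutant
is recovered as the map's extremum at +97 percentage points — the
positive sign meaning contact lost in the mutant, the direction a real
contact-breaking substitution would show.

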