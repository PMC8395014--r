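---
title: "Methods: recessive variant prioritization and comparative trajectory analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive variant prioritization and comparative trajectory analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vartraj)
```

# Scope

`vartraj` reimplements, as a tested pipeline, the two computational
procedures of a family study of recessive cardiac conduction disease: the
triage of a homozygous candidate variant in a consanguineous pedigree, and
the comparative analysis of wild-type versus mutant protein trajectories
for a serine-to-proline substitution in a kinase-domain homodimer. Both
arms run end to end on synthetic data with planted ground truth, so every
stage is testable without external downloads. This vignette records the
models, the tunable parameters, and the design decisions taken where the
design was genuinely open.

# The genetics arm

## Hard-filter cascade

`apply_filter_cascade()` retains a biallelic record only if every
threshold in `filter_config()` holds. Defaults, in cascade order:

| stage | threshold | level | absent value |
|---|---|---|---|
| depth | DP > 5 reads | per genotyped sample | fails |
| genotype quality | GQ > 10 | per genotyped sample | fails |
| allele read fraction | ARF >= 0.75 | hom-alt calls only | fails |
| gnomAD MAF | < 0.001 | site | passes |
| in-house AF | < 0.001 | site | passes |
| strand bias (FS) | < 40 | site | fails |
| MQRankSum | >= -5 | site | fails |
| quality by depth (QD) | > 5 | site | fails |
| mapping quality (MQ) | > 50 | site | fails |
| ReadPosRankSum | >= -5 | site | fails |
| splice/initiation change | \|x\| <= 15% | site | passes |
| consequence | in {missense, nonsense, splice, frameshift} | site | fails |
| quorum | SNV >= 2, indel >= 1 callers | site | stage skipped |

Three interpretation decisions deserve a note:

* **Absent population frequencies pass.** A variant unseen in any database
  is maximally rare — exactly the situation of a novel causal allele — so
  `NA` MAF/in-house AF passes while absent *quality* metrics fail
  conservatively.
* **"Quality score" is per-sample GQ.** The source criteria list both a
  generic quality score and the site-level QD; we read the former as
  genotype quality, and collapse the twice-listed mapping-quality
  criterion into the single site-level MQ filter. The configuration file
  documents this reading.
* **ARF applies to homozygous-alternate calls only.** The cascade hunts
  homozygous candidates; heterozygous carrier parents sit near 50% ARF by
  construction, and a cascade that checked ARF on their calls would
  discard every true recessive candidate. The threshold therefore
  constrains the calls that assert homozygosity.

Per-stage counts charge each record to the *first* stage it fails, so
input count = survivors + the sum of stage exclusions, and tightening any
single threshold can only shrink the survivor set (a property the test
suite checks explicitly).

## Co-segregation and ROH

`cosegregates_recessive()` encodes autosomal-recessive inheritance with
full penetrance: every affected member homozygous-alternate, every
unaffected member not homozygous-alternate, every genotyped parent of an
affected member an obligate heterozygous carrier. Missing genotypes are
ignored and never veto — ungenotyped relatives carry no information.

`detect_roh()` is a deliberate heuristic replacement for linkage-based
homozygosity mapping: maximal runs of consecutive homozygous calls per
sample, allowing up to `max_het` heterozygous interruptions (default 0),
with at least `min_markers = 25` markers spanning `min_length_bp = 1e6`.
Missing calls break runs. One megabase is the conventional floor below
which runs arise by chance rather than by recent parental relatedness;
25 markers at exome-like density makes a run statistically solid. Regions
are 0-based half-open (BED convention); VCF positions stay 1-based.
Candidates must fall in the *intersection* of the affected members' runs.

`rank_candidates()` orders the final set by the normalized pathogenicity
rank score (0 = benign, 1 = pathogenic) descending, ties broken by
phred-scaled CADD descending, then chromosome and position.

## The family simulator

`simulate_family_vcf()` emits a VCF/PED/BED trio plus a truth record. Its
defaults are the study conditions: the six-member sequenced pedigree (two
consanguineous carrier parents, two affected and two unaffected siblings),
one causal missense variant (rank score 0.79, CADD 26.9, absent from
population databases) inside a 2 Mb homozygosity block on chromosome 1,
and 60 common homozygous markers spanning the block. Marker density is
not dictated by any published value; ~34 kb spacing matches what an exome
pipeline typically yields over a gene-dense region, and the markers are
deliberately common alleles so they fall at the MAF stage and can never
become candidates themselves.

Each background variant is planted to violate *exactly one* stage of the
triage — a cascade threshold, the co-segregation pattern, or ROH
membership — according to an explicit `violation_mix`. That makes the
expected per-stage attrition a bookkeeping fact of the generator (each
label maps to one stage), so end-to-end runs can be checked against
planted truth without re-deriving anything from the implementation under
test. Background variants live on chromosomes 2–22 so they cannot
perturb the planted block. A fixed seed yields byte-identical files.

What the simulator does *not* emulate: linkage disequilibrium, realistic
site-frequency spectra, genotyping error, caller artifacts, or multiple
interacting violations per record. Passing tests therefore demonstrate
the correctness of the *procedure* under its stated semantics, not
robustness to messy real exomes.

# The structural arm

## Contacts and difference maps

A residue pair is "in contact" in a frame when the mass-weighted centers
of mass of the two residues (all atoms present in the model, hydrogens
included) lie strictly within 5 Angstrom — the strict `<` follows the
stated contact definition; an inclusive flag exists because vendor
monitors are not documented on this point. Occupancy is the in-contact
fraction of frames in the analysis window; the window is a trailing
duration (the study convention is the last 200 ns of 1 microsecond runs,
1 frame/ns), converted to frames by rounding down. Difference maps are
`100 * (mean_WT - mean_MUT)` percentage points over replicate means:
positive entries mean more contact in the wild type. Per-replicate maps
remain available for error bars.

## Superposition, RMSD, RMSF

`kabsch_superpose()` computes the closed-form least-squares rigid
transform via SVD of the 3x3 cross-covariance with the determinant
correction, guaranteeing a proper rotation; near-collinear or coincident
selections are rejected rather than silently fit. `rmsf_profile()` uses
the conventional two-pass reference: align frames to the first frame,
average, re-align to the average, and take
`RMSF_i = sqrt(<|r_i - <r_i>|^2>)` over C-alpha atoms, reporting
cross-replicate mean and sample sd.

For isotropic Gaussian noise of sd sigma per coordinate the expected
RMSF is `sigma * sqrt(3)`. Superposing on the same atoms that are
measured absorbs six rigid-body degrees of freedom of noise, shrinking
measured RMSF by roughly `6/(3N)` in mean square — about 2.5% for 40
fitted C-alpha atoms — with the largest shrinkage at the atoms with the
longest lever arms about the centroid. This is why the toy dimer lays
each chain's C-alpha trace on a 270-degree circular arc (exact 3.8
Angstrom chords) rather than a straight rod: a folded chain is compact,
and the arc keeps the fit leverage comparable across residues so the
closed-form recovery holds per residue to within a few percent. The
shrinkage itself is intrinsic to superposition-based RMSF and is shared
by standard MD tooling.

## Hydrogen bonds

The source analysis names the bonds but not the geometry, so
`hbond_criteria()` defaults to the conventional thresholds:
donor-acceptor distance <= 3.5 Angstrom and donor-H-acceptor angle
>= 120 degrees, both configurable. When the donor carries no hydrogen in
the model the check degrades to distance-only with a warning rather than
failing — heavy-atom-only structures are common. The donor-acceptor
length series is reported for every in-window frame regardless of bond
state, as in the study's bond-length traces.

## Distances and replicate statistics

`ca_distance_stats()` reports mean and *population* standard deviation
over in-window frames (a per-frame time series is a complete population
of the window); `aggregate_replicates()` reports the *sample* standard
deviation across replicates (three replicates estimate a distribution).
Single replicates report sd 0 with an explicit n = 1 flag.

## Hydrophobic surface score

`shrake_rupley_sasa()` implements the classic sphere-sampling SASA:
near-uniform golden-spiral points (default 960) on each atom's
solvent-expanded sphere (vdW radius + 1.4 Angstrom probe), a point being
accessible when outside every neighbour's expanded sphere. An isolated
atom recovers the analytic `4*pi*(r + probe)^2` exactly at any point
count; boundary ties (coincident duplicate atoms) bury only on the
earlier-indexed atom so duplicates expose one surface, not two or zero.

`hydrophobic_surface_score()` summarises hydrophobicity two ways. The
*primary* score is the apolar SASA — the summed area of carbon and
sulfur atoms, the standard apolar decomposition. A residue-level score
weighting residue SASA by Kyte-Doolittle hydropathy normalised to [0, 1]
is reported alongside. The apolar-atom score is primary for a concrete
reason: a serine-to-proline substitution replaces a polar side-chain
oxygen with carbon and therefore *increases* apolar surface, matching
the physical claim under study, whereas whole-residue hydropathy scales
place proline below serine (proline's ring is counted amphipathic) and
would move the residue-weighted score the other way. The per-residue
table exposes both so users can choose.

## The trajectory simulator

`simulate_trajectory()` replaces MD production runs. Frames are the
reference coordinates plus i.i.d. Gaussian per-coordinate noise (default
sigma 0.3 Angstrom; no covariance — correlated-noise modes are a
non-goal since the source dynamics are not reproducible anyway). Planted
events are exact by construction, not statistical: for target occupancy
`f`, a deterministic prefix of `round(f * n_frames)` frames pins the
pair's center-of-mass distance at 3.5 Angstrom (inside the cutoff) and
the rest at 6.5 (outside), translating the second residue along the
center-of-mass axis *after* the noise so recovery is exact. The
out-of-contact distance is 6.5 rather than something larger so the
displaced residue stays near its own chain: its neighbours then remain
in contact in both genotypes and a planted contact break is the unique
extremum of the difference map rather than tied with side effects.
Planted hydrogen bonds pin the acceptor at 2.9/6.0 Angstrom from the
donor with the hydrogen on the axis (angle 180 degrees in bonded
frames). Residues across planting specs must be disjoint. Replicates
share the planted prefix and differ in noise; the study design of three
replicates is the default.

# Determinism and problem sizes

All randomness flows from a single integer seed per generator call;
fixed seed means byte-identical output files and reports (no timestamps
are written). The shipped tests and the acceptance script use desk-scale
sizes chosen to exercise every property well inside a coffee break: a
40-residue dimer with 200-frame replicates for occupancy properties,
10^4 frames for the RMSF closed form, 20–50 seeded families for the
filter/ROH oracles, and one 2000-decoy family for the end-to-end triage.

# Known limitations

* The genetics arm consumes annotations (consequence class, rank score,
  CADD, splice change); it never predicts them.
* ROH detection is a genotype-run heuristic, not a linkage model; it has
  no allele-frequency model and no genotyping-error tolerance beyond
  `max_het`.
* The structural statistics assume identical atom ordering between a
  structure and its trajectories, and multi-model PDB / XYZ input only;
  binary trajectory formats are out of scope.
* No force-field physics: the simulator cannot say anything about real
  conformational ensembles, only about the correctness of the
  statistics computed from ensembles.
* Compound-heterozygous inheritance models and CNVs are out of scope.
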