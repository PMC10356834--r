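# gpcrint

Comparative structural analysis of GPCR–G-protein complex interfaces in R.

G-protein-coupled receptors (GPCRs) transduce extracellular signals by
recruiting heterotrimeric G proteins, and the coupling selectivity of a
receptor — whether it activates Gs, Gi/o, Gq/11 or G12/13 — is imprinted in
the residue–residue contacts its intracellular face makes with the Gα
subunit, above all with the C-terminal α5 helix (H5) that inserts into the
receptor's transmembrane bundle. `gpcrint` implements a reusable pipeline
for dissecting this interface across cohorts of experimental or predicted
complex structures, for structural bioinformaticians who want the analysis
steps as composable, tested functions rather than one-off scripts.

## What it computes

* **Interface contacts on consensus numbering.** Two residues are in
  contact when their Cβ atoms (Cα for glycine) lie strictly closer than
  8 Å. Contacts are mapped to GPCRdb generic numbers (e.g. `3.50`) and the
  common Gα numbering (CGN, e.g. `G.H5.25`); receptor loop and terminus
  positions without a residue-level generic number are aggregated to their
  segment (`ICL3`). Redundant structures of the same receptor–G-protein
  pair are pooled, counting each equivalent contact once.
* **Contact enrichment.** For each contact feature and coupling group, a
  2×2 contingency table (coupled/not-coupled × contact/no-contact) and its
  log-odds ratio

  LOR = ln[(CC · NN) / (CN · NC)],

  with a Haldane–Anscombe +0.5 pseudocount when a cell is zero. Features
  with cohort frequency ≥ 10% and |LOR| > 2 in some group are "informative";
  binary complex fingerprints (CF; or per-side RF/GF projections) restricted
  to those features are clustered with Ward linkage on Euclidean distances.
* **Contact networks and cohort comparison.** Contacts projected onto
  secondary-structure elements give conservation-weighted bipartite
  networks (degree, betweenness); per-structure contact graphs are compared
  by the Frobenius norm of adjacency differences, and group separation /
  dispersion are tested by seeded PERMANOVA and PERMDISP.
* **Docking modes.** Complexes are superposed on the receptor consensus
  core (Kabsch least squares); the RMSD over the Gα core after that fit
  measures how differently the G protein docks. The pipeline produces the
  pairwise RMSD matrix, Ward pose clusters, per-group centroid complexes
  and per-position fluctuation profiles ρᵢ = √⟨(xᵢ − x′ᵢ)²⟩ against a
  reference structure.
* **Predicted-model quality filter.** For models from complex-structure
  predictors: best-of-N selection by 0.2·pTM + 0.8·ipTM, an H5-anchor
  topology check (≥1 contact at G.H5.16/19/20/23/24/25), pDockQ ≥ 0.23,
  trimming of residues with pLDDT < 70, and interface buried area
  ΔSASA ≥ 1500 Å² (Shrake–Rupley), with a per-stage audit trail.
* **Synthetic data with ground truth.** Seeded generators produce an
  idealized 7TM/Gα complex template, pose ensembles with planted rigid
  docking modes plus Gaussian noise, contact cohorts with planted
  enrichment probabilities, and model sets whose verdict at every QC stage
  is known by construction — so the whole pipeline is testable hermetically.

## Worked example

```r
library(gpcrint)

# cohort of 40 synthetic complexes: 20 Gs, 20 Gi/o, 15 features enriched in Gs
cohort <- sample_contact_cohort(cohort_spec(seed = 42))
fp <- build_fingerprints(cohort$contact_sets, mode = "CF")
dim(fp)
#> [1] 40 60

enr <- enrichment_table(fp, cohort$groups)
head(enr[order(-abs(enr$lor)), c("feature", "group", "CC", "CN", "NC", "NN",
                                 "lor", "frequency")], 5)
#>          feature group CC CN NC NN       lor frequency
#> 30  3.50|G.H5.25  Gi/o  2 18 19  1 -5.141664     0.525
#> 90  3.50|G.H5.25    Gs 19  1  2 18  5.141664     0.525
#> 42  3.54|G.H5.25  Gi/o  4 16 19  1 -4.330733     0.575
#> 102 3.54|G.H5.25    Gs 19  1  4 16  4.330733     0.575
#> 11  2.39|G.H5.24  Gi/o  4 16 18  2 -3.583519     0.550
```

The top feature is the contact between receptor position 3.50 (the DRY-motif
arginine at the bottom of TM3) and the Gα C-terminal residue G.H5.25: 19 of
20 Gs complexes show it against 2 of 20 Gi/o, an enrichment of e^5.1 ≈ 170
in odds. Filtering to informative features and clustering recovers the
coupling groups exactly, and the contact-graph PERMANOVA confirms the
separation:

```r
kept <- filter_informative(fp, enr)
ncol(kept)
#> [1] 14
cl <- cluster_fingerprints(kept, k = 2)
table(cl, cohort$groups[names(cl)])
#> cl  Gi/o Gs
#>   1    0 20
#>   2   20  0

d <- graph_distance_matrix(cohort$contact_sets)
permanova(d, attr(d, "groups"), n_permutations = 999, seed = 1)
#> PERMANOVA: statistic = 6.018, p = 0.001 (999 permutations)
```

`run_pipeline(run_config(seed = 1), outdir = "out")` runs every stage —
synthesis, contact extraction from coordinates, fingerprints, enrichment,
networks, permutation tests, pose analysis, model QC — writing TSV/JSON
artifacts and a manifest of MD5 content hashes; reruns with the same seed
are bit-identical.

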