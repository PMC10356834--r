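---
title: "Methods behind gpcrint: interface contacts, enrichment, docking modes and model QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gpcrint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrint)
```

# The analysis model

`gpcrint` treats a receptor–Gα complex as a pair of chains whose interface
is summarized as a *set of consensus-labelled contacts*. Everything
downstream — fingerprints, enrichment, networks, graph distances — consumes
that set, so the package is organized as one extraction step and several
statistics over its output.

## Contact definition

Two residues are in contact when their representative atoms lie strictly
closer than the cutoff (default 8 Å). The representative atom is the Cβ,
except for glycine, which has none and is measured at its Cα. This is the
standard side-chain-proximity criterion used in contact-map work: Cβ
positions capture side-chain orientation while staying insensitive to
rotamer noise. Two implementation details matter:

* **Strict inequality.** A pair at exactly 8.00 Å is *not* a contact; the
  boundary is tested explicitly. With experimental coordinates the measure
  of the boundary is zero, so the choice is a convention, but it must be
  fixed for reproducibility.
* **Degraded residues.** A non-glycine residue that lacks a Cβ in the file
  (incomplete side chains are common in cryo-EM models) falls back to its
  Cα with a warning; a residue with neither atom is skipped with a warning.
  Alternate locations resolve to the highest-occupancy conformer, ties to
  altloc "A".

Contact search uses a cell-list spatial index (grid cells of one cutoff
length; only the 27 neighbouring cells are scanned per residue). A dense
O(n·m) search is retained as `method = "brute"` and the two are asserted
equal on random structures — the index is an optimization, never a
definition.

## Consensus numbering and aggregation

Structure residues are mapped to UniProt positions and then to consensus
labels — GPCRdb generic numbers for the receptor, CGN for Gα — via mapping
tables supplied as TSVs. The package deliberately does *not* recompute
generic numbers from structure or alignment: those assignments are curated
upstream, and carrying them as data keeps every analysis hermetic and
testable. Receptor positions in loops or termini that have no residue-level
generic number (written `ICL3(299)`) aggregate to their segment name
(`ICL3`); numbered loop positions such as `ICL2.51` and all Gα labels pass
through. Aggregation is idempotent, and contact sets are stored *after*
aggregation so that fingerprints, networks and frequency tables share one
feature universe.

Contacts from multiple structures of the same receptor–G-protein pair are
pooled by set union: an equivalent residue pair seen five times counts
once. Group-wise *contact frequency* is the fraction of unique complexes in
the group showing the contact (heatmap-style exports typically filter at
frequency > 0.2).

## Enrichment statistics

For a feature (a contact pair, or a single-side position) and a coupling
group, the 2×2 table counts coupled/not-coupled complexes with and without
the contact (cells CC, CN, NC, NN). The default log-odds ratio is the
standard one,

$$\mathrm{LOR} = \ln\frac{CC \cdot NN}{CN \cdot NC},$$

computed as $(\ln CC + \ln NN) - (\ln CN + \ln NC)$ so that swapping the
group with its complement negates the value bit-exactly. A second variant,
`as_printed` $= \ln\left(\frac{CC}{NN}\cdot\frac{NC}{CN}\right)$, is
exposed because that algebraic form circulates in the literature on this
analysis even though it is *not* the odds ratio of the stated contingency
table (it equals $\ln\frac{CC\cdot NC}{NN\cdot CN}$, which is not
antisymmetric under group swap). We default to the standard form and keep
both so results under either convention can be reproduced; the choice is a
one-argument switch.

Zero cells get a Haldane–Anscombe +0.5 added to *all four* cells — the
conventional correction that keeps the estimator finite and roughly
median-unbiased. The informative-feature filter keeps columns with cohort
frequency ≥ 0.10 *and* |LOR| > 2 (natural-log units; an odds factor of
about 7.4) in at least one group. Frequency here is over unique complexes:
redundant structures were already collapsed, so "structures" and
"complexes" coincide by construction in this package.

Fingerprint rows are clustered with Ward linkage on Euclidean distances
(`hclust(method = "ward.D2")`, the Ward criterion on unsquared distances,
matching scipy's `ward` used by seaborn clustermaps). `k` defaults to 2 —
the Gs/Gi-o dichotomy is the primary axis of interest — and is a parameter.

## Networks and cohort-level tests

Contacts projected onto secondary-structure elements give a bipartite
network: node weight is the number of distinct contact pairs the SSE
mediates, edge weight the number of unique complexes with at least one
contact between the two SSEs, edge conservation the mean per-pair contact
frequency. Betweenness is computed on the unweighted graph (igraph,
unnormalized): the network's edge weights are counts, not path costs, so
weighting shortest paths with them would be meaningless.

Per-structure contact graphs over the cohort's union universe are binary
adjacency matrices; the distance between two structures is the Frobenius
norm of the adjacency difference, which for binary matrices is
$\sqrt{\#\text{differing cells}}$ — a true metric. Group separation on the
distance matrix is tested by one-way PERMANOVA (pseudo-F from within- vs
between-group sums of squared distances; label permutations from a seeded
RNG; $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + N)$), and dispersion
homogeneity by PERMDISP (distances to group centroids in
principal-coordinate space via `vegan::betadisper`, one-way F on those
distances, permutation of the distances across groups). The centroid — not
spatial-median — flavour of PERMDISP was chosen as the more common default;
the embedding step is delegated to vegan, the permutation loop is ours for
exact seed control, and the PERMANOVA statistic is cross-checked against
`vegan::adonis2` in the tests. Permutation counts default to 999 (9999 for
publication-grade runs); at desk scale the Monte-Carlo error of a p-value
at 999 permutations (±0.01 near p = 0.05) is far below the effect sizes of
interest. Note one property of this estimator worth knowing: with perfectly
separated groups the attainable minimum is $1/(1+N)$, but any permutation
that happens to redraw the original partition ties $F_{obs}$ and is counted,
so the observed p can sit a notch above the floor; with 12 exchangeable
complexes in two groups of 6 that happens with probability 2/924 per draw.

## Docking modes

Complexes are superposed on the *receptor consensus core* — the labels with
a resolved Cα in every member of the ensemble — by the Kabsch algorithm
(SVD of the cross-covariance; the reflection case is corrected to a proper
rotation, determinant +1). The docking-mode RMSD between two complexes is
then the RMSD over the *Gα core* Cαs under that receptor-frame transform:
identical receptor folds with differently docked G proteins score high,
global rigid motions score zero. Fitting A onto B and B onto A differ
microscopically when the receptor cores are not congruent; the RMSD matrix
removes this deterministically by always fitting with the
lexicographically smaller complex key as target. Fewer than 3 fit points,
or a collinear fit set (rotation about the line undetermined), are errors.

Pose clusters come from Ward clustering of the RMSD matrix *rows* as
feature vectors — the same operation a clustermap performs on such a
matrix — rather than linkage on the condensed distances; both give nearly
identical trees on our ensembles and the row-vector form matches the
fingerprint clustering code path. `k` defaults to 3, configurable. The
group centroid is the member minimizing mean RMSD to the rest
(lexicographic tie-break), and the fluctuation profile is

$$\rho_i = \sqrt{\langle (x_i - x'_i)^2 \rangle},$$

the root mean squared 3-D deviation of Gα core position $i$ across the
ensemble from the reference structure $x'$ — by default a group's centroid,
or any supplied reference. Under isotropic per-coordinate noise of scale σ
about the reference, $\rho_i$ concentrates at $\sigma\sqrt{3}$, which is
the calibration the tests exploit. When the reference is itself a noisy
ensemble member (the centroid case) the expectation inflates toward
$\sigma\sqrt{6}$; calibration checks therefore use the known mean
structure, while pipeline outputs use the centroid as reference because
with real data no noise-free mean exists.

## Predicted-model QC

The composite filter for predicted complexes runs four stages in order,
recording each model's first failure:

1. **H5-anchor topology**: at least one interface contact at a CGN H5
   anchor position (G.H5.16/19/20/23/24/25) — the positions that most
   recurrently anchor experimental interfaces; models docking the G protein
   by any other face are topologically implausible.
2. **pDockQ ≥ 0.23**: the sigmoid
   $L/(1+e^{-k(x-x_0)}) + b$ with $x = \overline{\mathrm{pLDDT}}_{iface}
   \cdot \ln(\#\text{contacts})$ and the published constants
   $(L, k, x_0, b) = (0.724, 0.052, 152.611, 0.018)$ as configurable
   defaults. The interface is defined by the same Cβ < 8 Å rule as the rest
   of the package, for internal consistency.
3. **pLDDT trimming**: residues with pLDDT < 70 (strict) are removed;
   coordinates of retained residues are untouched. A model only fails here
   if nothing (or a whole chain) survives.
4. **ΔSASA ≥ 1500 Å²** on the trimmed model: buried area
   $\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(AB)$ by
   Shrake–Rupley quadrature — a deterministic Fibonacci sphere lattice
   (default 100 points/atom), probe 1.4 Å, element vdW radii. This is a
   purely geometric buried area with no side-chain repacking, so the
   threshold's semantics are approximate relative to energy-function-based
   interface analysis; it cleanly separates docked from grazing interfaces,
   which is its role in the chain. Because the quadrature directions are
   fixed in space, ΔSASA is invariant under rigid motion only to within
   quadrature noise (≲2% at 100 points; halving vs doubling the lattice
   moves values by a similar margin).

Thresholds sit in a single `qc_config()` object; the audit table makes the
effect of stage order inspectable.

# The synthetic generator

The generator supplies *study conditions*, not tuning knobs. Its template
is an idealized complex: seven ideal α-helical arcs (1.5 Å rise, 100° turn,
2.3 Å helix radius) on a 6 Å circle form the 7TM bundle with the
intracellular face at z = 0; the Gα contributes an H5 helix inserted into
the cytoplasmic cavity, an H4 arm lying under the intracellular face, and
HN/S1/S3 segments well away from the interface. Residues carry backbone
pseudo-atoms (N, CA, C, O) and CB/CG/CD side-chain pseudo-atoms (glycines
backbone-only, every 7th residue), giving realistic enough atom density for
surface-area work; a sub-Ångström seeded jitter breaks exact symmetries.
Defaults (70 receptor / 36 Gα core positions) were sized once so that the
docked template buries ≈1700 Å² — comfortably on the "real interface" side
of the 1500 Å² threshold — while a Gα pulled 14 Å away grazes at a few
hundred.

On top of the template:

* **Pose ensembles** apply one rigid transform per group to the Gα block
  and add i.i.d. isotropic Gaussian noise to every atom coordinate. The
  defaults (two groups 12 Å apart, σ = 0.5 Å, 6–10 members/group) make
  within/between RMSDs analytic at σ = 0 and keep clustering
  non-trivial at σ > 0. Isotropic noise is the simplest model under which
  the RMSF expectation is known in closed form (σ√3).
* **Contact cohorts** draw each complex's contacts independently:
  Bernoulli(p_in = 0.8) at the first group's 15 enriched features,
  Bernoulli(p_out = 0.2) elsewhere, over a 60-feature universe of plausible
  GPCRdb×CGN pairs, 20 complexes per group. The expected standard LOR at an
  enriched feature is ln 16 ≈ 2.77. The companion coupling map couples each
  receptor to its own family and to others with a planted promiscuity rate
  (default 0.1).
* **Model sets** construct one model per verdict kind: docked/high-pLDDT
  (passes everything), docked with low-confidence terminal residues
  (trimmed, passes), Gα flipped upside-down and re-docked at the same gap
  (interface via HN/S strands only — anchor fail), docked with uniform
  pLDDT 20 (pDockQ fail), and the grazing Gα (ΔSASA fail, with pLDDT 98 so
  earlier stages pass). Each verdict holds by construction, not by running
  the filter.

What passing on these conditions does *not* show: real complexes have
correlated atomic displacements, partial occupancy, heterogeneous per-chain
resolution and non-ideal secondary structure; real enrichment features are
correlated through physical contact geometry rather than independent
Bernoulli draws; and real predictor confidence correlates with geometry in
ways the planted pLDDT profiles do not emulate. The synthetic results
validate the *statistics and their implementation*, not the biological
effect sizes.

# Numerical and design choices

* Lexicographic tie-breaks everywhere a choice is otherwise arbitrary
  (chain-pair selection, representatives, model ranking, centroid) —
  determinism over elegance.
* Unmapped interface residues count as chimeric evidence and exclude the
  structure: a conservative reading of the exclusion rule, preferring a
  smaller clean cohort.
* The representative structure per pair is chosen by best resolution, then
  largest Gα coverage, then id.
* `run_pipeline()` derives one RNG stream per stage from the master seed,
  so re-running one stage cannot perturb another; all artifacts are
  plain-text tables plus a manifest of MD5 hashes, and a full run is
  bit-reproducible under a fixed seed.
* Problem sizes in the shipped tests (cohorts of 40, ensembles of 12–20,
  999-permutation tests, 50-member RMSF ensembles) were chosen as the
  smallest sizes at which the statistics' expectations are sharp enough to
  assert — e.g. the delta-method SE of an LOR at n = 20+20 is ≈0.65, so
  enriched features sit >3 SE from zero.

# Limitations

* Generic-number assignment is out of scope by design; garbage mapping
  tables produce garbage labels (validation catches duplicates and
  malformed labels, not wrong biology).
* ΔSASA is geometric; models relaxed or repacked by an energy function
  would bury somewhat different areas, so the 1500 Å² threshold should be
  treated as calibrated to this package's SASA, not universally.
* PERMDISP's permutation scheme permutes centroid distances, the common
  approximation; exact distance-matrix re-embedding per permutation is not
  implemented.
* The pDockQ constants are the published sigmoid fit; applying them to
  models from other predictors may need refitting (they are config
  parameters for that reason).
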