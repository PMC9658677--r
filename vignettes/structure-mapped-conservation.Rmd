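---
title: "Structure-mapped conservation analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-mapped conservation analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conserv3d)
```

conserv3d implements a pipeline for locating candidate functional sites in a
protein family: score the evolutionary conservation of every alignment
column, map the most conserved residues onto a 3D structure, group them into
spatial clusters, and interrogate those clusters with motif-coevolution
tables, cavity detection, aromatic electron-transfer networks and
missense-variant overlays. The package was built around the frataxin/CyaY
family — a small iron-binding protein whose eukaryotic and *Rickettsia*
members share a Y143/S158/S161/E189 tetrad absent from other bacterial
homologues — and ships fixtures for that analysis, but every stage is
generic.

## The conservation score

For an alignment column we compare the observed amino-acid distribution with
a background distribution using the Jensen–Shannon divergence (base 2,
mixing weight 1/2):

$$\mathrm{JSD}(P, Q) = H\!\left(\tfrac{P+Q}{2}\right) -
  \tfrac{1}{2}H(P) - \tfrac{1}{2}H(Q),$$

where $H$ is the Shannon entropy in bits. The JSD is bounded by 1 bit, so
the raw score is already in $[0, 1]$: a column indistinguishable from
background scores 0 and an invariant column of a rare residue approaches 1.
The observed distribution is sequence-weighted: records are weighted by the
Henikoff position-based scheme (each column splits one unit of weight evenly
across its distinct residues, and each residue's share evenly across the
sequences carrying it), which damps the over-representation of densely
sampled taxa. Gaps and the ambiguity codes X/B/Z carry no weight.

This score is a deterministic stand-in for phylogenetic rate estimation
(Rate4Site-style Bayesian inference is deliberately out of scope): the
downstream analyses only consume the discretized grades, and the JSD score
is monotone in column homogeneity, invariant under sequence duplication, and
cheap enough to run thousands of times in tests.

Two per-column qualifiers accompany the score:

* **Reliability** — a column with fewer than `min_informative` (default 6)
  standard residues is flagged unreliable; it still receives a grade but is
  never selected for clustering. The threshold is configurable because the
  "insufficient data" criterion of the reference web tools is
  version-dependent.
* **Grade** — reliable scores are ranked and quantile-binned into nine
  equal-count grades, grade 9 being the most conserved. Ties share the
  *higher* grade, so a degenerate profile in which every column has the same
  score is all grade 9. Unreliable columns are graded by where their score
  falls among the reliable ones. A consequence of equal-count binning worth
  knowing: the grade-9 bin holds about $L/9$ columns, so no more than that
  many residues can ever be "maximally conserved" — the planted-signal
  checks below are designed with this in mind.

## From grades to spatial clusters

`select_conserved()` keeps reliable, top-grade positions and drops glycines
and prolines by default: those residues are typically conserved to maintain
folding (turns, helix breaks) rather than function. `spatial_clusters()`
then forms single-linkage connected components of the selected residues,
joining two residues when their side-chain centroids are within 8 Å. The
source analysis grouped residues by visual inspection; a standard
contact-scale cutoff between side-chain centroids is the closest
reproducible rule, and both the cutoff and the distance mode (Cα, side-chain
centroid, closest atom) are exposed in the configuration. Each cluster is
classified by its mean relative solvent accessibility: buried at mean RSA
≤ 0.20, exposed at ≥ 0.35, mixed in between (both boundaries inclusive
toward their class); these are conventional buried/exposed thresholds.

RSA comes from a Shrake–Rupley accessible-surface computation (probe 1.4 Å,
960 golden-spiral test points per atom by default; doubling the point count
moves no residue's RSA by more than 0.02) normalized by the Tien et al.
(2013) theoretical maxima. Van der Waals radii are a fixed element table
(C 1.70, N 1.55, O 1.52, S 1.80 Å, 1.70 otherwise); hydrogens, waters,
heteroatoms and non-first models are ignored, and alternate locations
resolve to the highest occupancy.

## Motif coevolution

A motif is an ordered set of reference positions with consensus letters
(e.g. the cluster-3 tetrad, `frataxin_tetrad()`). `motif_table()` reads each
sequence's letter at each motif column through the reference mapping;
*presence* is exact identity with the consensus. This is deliberately
conservative — the published presence table records the actual letter when
it differs (a rat G at position 158, a microsporidian T at 161), and those
count as absent here; `conservative = TRUE` relaxes matching to exchange
groups (S/T, D/E, K/R, Y/F/W, I/L/V/M, N/Q) for sensitivity analyses. A gap
is recorded as `-` and is always absent. Taxon grouping
(eukaryote/*Rickettsia*/bacteria in the fixtures) is supplied by the user or
the input file, never inferred.

## Cavities

`find_cavities()` voxelizes the bounding box (default 0.7 Å grid), blocks
voxels within vdW + probe radius of any atom, flood-fills the solvent from
the boundary, and reports the 6-connected components of the remaining
interior voxels as cavities, each with volume (voxel count × voxel volume,
in Å³) and lining residues (atoms within vdW + probe + one grid step of a
cavity voxel). On a closed shell fixture with a 4 Å probe-accessible
interior the method recovers the analytic $\tfrac{4}{3}\pi r^3$ volume
within a few percent, and halving the grid spacing changes volumes by well
under 15%. Published cavity sizes for this family are quoted in "Å"; a
volume must be meant, and we read them as Å³.

## Aromatic electron-transfer networks

Tyrosine and tryptophan radicals can relay electrons between redox centers
when the residues are close enough for hopping. `build_transfer_network()`
connects Tyr/Trp ring centroids within 10.5 Å by default: distances the
literature describes as "~10 Å" should form edges, while a strict
"less than 10 Å" reading is available by setting the cutoff to 10.0.
Designated site residues (acidic-ridge positions, D167, His86) are attached
with closest-heavy-atom edges, since no ring is defined for them.
`transfer_path()` returns hop-count-shortest paths, breaking ties by total
distance. Phe/His can be added to the node set but are excluded from the
headline composition statistic, which counts Tyr + Trp over the sequence
and reports a percentage rounded half-up to one decimal. For human frataxin
that statistic refers to the full mature form Fxn81–210 (130 residues,
7 Tyr + 3 Trp = 7.7%); computed over the 129 crystallized residues from G82
the same counts give 7.8%.

## Variant overlay

`read_variants()` ingests delimited exports in the style of a gnomAD
download through a column-mapping dialect, collapsing duplicate
(position, alternate, dataset) rows to the maximum frequency. A residue
"presents variation" when any alternate allele exists at that position in
any configured dataset — matching the pooling of the v2.1.1 and v3.1.1
non-neuro sets in the source analysis. Pathogenicity is an input flag from
a curated list, never predicted. `cluster_overlap()` reports residue-level
counts (residues with ≥ 1 qualifying variant / cluster members); the
packaged pathogenic table also supports mutation-level counts — at L182 two
distinct substitutions map to one residue, which is why mutation-level and
residue-level proportions differ and both are reported rather than
adjudicated.

## The synthetic-data generator

Every stage is testable offline because `simulation_spec()` plants known
signal:

* **Alignments** — sequences are i.i.d. per column (star phylogeny): the
  site's consensus letter with probability θ, otherwise a background draw.
  An optional two-level mode routes non-consensus draws through a
  group-level consensus, exercising the Henikoff weighting. Motif carrier
  groups are forced to the consensus; everyone else is forced away from it.
  Consensus letters at conserved sites exclude G/P so the planted sites
  survive the G/P exclusion.
* **Structures** — a Cα trace as a self-avoiding random walk (3.8 Å steps,
  ≥ 3.5 Å between non-neighbors) with a pseudo side-chain atom 1.5 Å from
  each Cα. Members of a planted cluster are steered to a common spatial
  target (their side chains pointing at it) so that pairwise side-chain
  centroid distances stay within `d_plant`; steps adjacent to relocated
  residues may stretch to 4.2 Å, and distinct cluster targets are kept at
  least 2.5 × `d_plant` apart. This produces enough geometry for the
  distance, clustering and network code without pretending to be a fold.
* **Variant tables** — each unprotected site receives a variant with the
  configured rate, frequencies uniform on (10⁻⁶, 10⁻⁴); protected positions
  never appear.

What passing the planted-recovery tests shows: the scorer ranks planted
sites above background columns, the clustering recovers planted geometry at
the planting distance, the motif table separates carrier from non-carrier
groups, and protected positions stay variant-free — each in ≥ 95% of seeds.
What it does not show: behavior on real phylogenies (correlated sequences,
substitution-matrix exchangeabilities, indel structure) or real protein
geometry (rotamers, packing, secondary structure). Accordingly, published
grade-class counts from Bayesian scorers on database snapshots
(21/48/60-style tallies) are out of reach by design and are not asserted
anywhere; the package's claims about real data are limited to what the
transcribed tables and sequences support.

## Numerical choices and degenerate inputs

* Quantile grades use ties-max ranks, so exactly tied scores share the
  higher grade; an all-equal profile is all grade 9 rather than an error.
* The Kabsch superposition constrains the rotation to determinant +1
  (reflections are never returned) and rejects < 3 points or collinear
  sets, where the optimum is not unique.
* The flood fill uses 6-connectivity; a margin of max-radius + probe + two
  grid steps guarantees the boundary layer is solvent.
* Distances are inclusive at the cutoff throughout (`d ≤ cutoff` forms an
  edge), and cluster/RSA boundaries are inclusive toward their class.
* Percentages are rounded half-up (`floor(10x + 0.5) / 10`), so 7.75 prints
  as 7.8 rather than banker's-rounding to 7.7 — which is precisely why the
  130-residue mature form (7.69 → 7.7) and the 129-residue chain (7.75 →
  7.8) must not be conflated.
* Reference numbering is never hard-coded: `map_to_reference()` takes the
  start number (81 for Fxn81–210, 82 for the 3S4M chain) so both
  conventions coexist.

## Problem sizes used by the tests

The property suites run 100 alignments of 40 × 120 for the planted-grade
check, 200 random instances against a union-find clustering oracle, 100
random rigid transforms for the superposition, a 600-atom shell for the
cavity benchmark, and a 20 × 30 pipeline bundle for determinism — sizes
chosen so the whole battery completes in well under a minute while leaving
the binomial sampling bounds meaningful.

## Known limitations

* The JSD score is not a rate of evolution: it ignores tree topology,
  branch lengths and substitution exchangeabilities. It is a ranking
  device for grades, and it is documented (and tested) only as such.
* The packaged structure fixture carries the true 3S4M chain-A sequence
  and numbering over *simulated* coordinates (its filename says so);
  geometric claims about the real crystal (ring-centroid spacings, the
  bacterial cavity) therefore require the genuine depositions, which the
  test suite requests at `inst/extdata/3s4m.pdb` / `2eff.pdb` and
  otherwise reports as unavailable.
* RSA on simulated pseudo-side-chain structures is qualitative; the
  buried/exposed thresholds were chosen for real all-atom structures.
* Single-linkage clustering chains: one intermediate residue can merge two
  visually distinct clusters, which is why the cutoff is a first-class
  parameter rather than a constant.
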