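---
title: "Methods: multi-state structural mechanism classification of missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-state structural mechanism classification of missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechvar)
```

## The problem and the model

ABC transporters work by cycling through conformations: an inward-facing
apo state, an intermediate ligand-bound state, and an outward-facing
ATP-bound state. A missense variant can break this machine in
mechanistically distinct ways, and a single static structure cannot
distinguish them. `mechvar` therefore scores each variant against three
conformational-state models simultaneously and interprets the *pattern*
of per-state folding free-energy changes (ΔΔG, kcal/mol, positive =
destabilizing) together with residue-level structural context.

The package deliberately consumes ΔΔG values rather than computing them:
stability estimation (FoldX and relatives) and membrane placement are
mature external tools, and their outputs are inputs here. What the
package contributes is everything downstream: context annotation, the
spatial burden scan with its permutation null, the mechanism decision
tree, and the ACMG evidence engine.

## Residue context

Annotations are pure functions of (structure, configuration); repeated
calls are identical. All interval data — domain boundaries, motif
ranges, PTM sites, regulatory intervals, membrane slab, reference ligand
coordinates — are configuration, not code, because none of them are
derivable from coordinates alone. The packaged ABCC6 configuration is
labeled a default assembled from UniProt-style annotation; production
analyses should supply curated intervals.

Numerical choices worth stating:

* **Contacts** use the minimum heavy-atom distance with a strict `<`
  comparison ("within 10 Å" is read as an open ball). Heavy-atom minima,
  rather than Cα–Cα distances, capture the side-chain adjacencies that
  bond-network arguments rely on.
* **Pockets** are the union of motif intervals, conserved-site lists,
  and residues with any heavy atom `< 5` Å from a reference ATP or
  substrate atom in *any* state, so a residue that approaches the
  nucleotide only in the outward-facing state still counts.
* **Relative ASA** is computed by an in-package Shrake–Rupley
  implementation (92 golden-spiral points, 1.4 Å probe, element-typed
  van der Waals radii). The "fully exposed" reference for each residue
  is the same set of atoms recomputed in isolation. This
  self-normalizing reference behaves identically for full-atom models
  and for the reduced synthetic representation; against tabulated
  Gly-X-Gly maxima it is slightly conservative for residues whose
  neighbors in sequence would shade them even when fully extended.
* **Membrane exposure** requires both the side-chain centroid (Cα for
  glycine) inside the configured slab and relative ASA `> 0.50`.
* **Interface residues** are those contacting a residue of a different
  domain, with the linker loops L0/L1 excluded as partners — a contact
  into a flexible linker is not evidence of a stabilizing domain joint.

## The hotspot scan

Burden is a neighborhood sum: each variant contributes its weight
(gnomAD allele count, or 1 per distinct variant) to every residue whose
10 Å neighborhood contains the variant's position. Two weightings are
run because allele counts exist only for the subset of variants observed
in gnomAD; variants lacking counts are skipped with a warning rather
than imputed.

The permutation null reassigns the observed variants' positions
uniformly at random **without replacement** over all modeled residues,
keeping each variant's weight attached. This choice preserves the total
variant count and total allele mass exactly in every draw, which is the
property that makes the burden comparison meaningful; the alternative
(resampling variants independently) preserves the totals only in
expectation. Empirical p-values use a `≥` exceedance comparison
(conservative for discrete weights) and carry no pseudocount — a residue
no null draw can match gets p = 0, matching a plain exceedance-count
definition. Users should read p = 0 as "< 1/n_permutations".

Hotspot calling derives the burden threshold from the p-values: the
smallest observed burden B such that *every* residue at or above B has
p < α (default 10⁻⁴). This reproduces the fixed thresholds a manual
analysis would read off a ranked table, and it degrades to an empty set
(not an error) when nothing is significant. Membership for downstream
PM1 evidence is the union over states and weightings, treating the
spatial regions as one annotation layer.

The synthetic uniform-cohort generator draws background positions
without replacement, mirroring the null. With that pairing the scan is
exchangeable under the no-signal hypothesis, which is what the
calibration test exercises (300-residue bundles, 84 variants, 10,000
permutations, 50 seeds — sizes chosen to match a realistic single-gene
cohort).

## The mechanism decision tree

Six categories, tested in a fixed order of specificity, first match
wins:

1. **ATP binding** — ATP-pocket residue, replacement nonconservative
   (PAM30 < 0) *or* destabilizing (ΔΔG ≥ 1.8 kcal/mol) in ≥ 1 state.
2. **Ligand binding** — the same pattern at a substrate-pocket residue.
3. **Regulation** — nonconservative replacement at a PTM-proximal or
   regulatory residue.
4. **Membrane interactions** — lipid-exposed residue with a
   Kyte–Doolittle drop ≤ −2.0 or a charge change.
5. **Conformational dynamics** — |ΔΔG| ≥ 1.8 kcal/mol in **exactly
   one** state: a state-specific defect that blocks movement between
   conformations.
6. **Functional stability** — significant in **two or more** states, or
   loss of a charged residue (R/K/D/E → uncharged, nonconservative) at
   an inter-domain interface.

Anything else is *uncategorized*; the tree prefers abstention to a
forced call. Pocket-specific rules precede global ones so that a
destabilizing variant inside the ATP pocket reads as an ATP-binding
defect, not a generic stability defect; the relative order of the
remaining rules is a design choice of this package, kept configurable
through `mechanism_rules()`.

The one/multiple-state split in rules 5–6 is the load-bearing decision.
A variant destabilizing a single state leaves the others intact — the
protein folds but cannot cycle — whereas destabilization in several
states is a fold problem. This reading also cleanly separates the
reference clinical cohort shipped under `inst/extdata/`
(`abcc6_cohort_stability.tsv`): state-specific scores like (−0.1, 0, 8)
classify as conformational dynamics, multi-state patterns like
(0.5, 5.1, 2.2) or (−0.5, −1.8, 5.2) as stability, and the two
borderline variants with no |ΔΔG| ≥ 1.8 in any state and no contextual
trigger stay uncategorized.

Threshold conventions: the ±1.8 kcal/mol significance bound is
**inclusive** (the reference cohort contains an exact −1.8 entry, and
near-boundary values are treated as meaningful); `largest_across_states`
breaks exact magnitude ties toward the positive (destabilizing) value;
"nonconservative" is PAM30 < 0, taking PAM30 from Biostrings and the
published 20-value Kyte–Doolittle scale embedded as a constant. A
missing stability profile degrades to the annotation-only rules (1–4)
and stamps the call with a `no-data` note rather than failing silently.

## ACMG evidence and reclassification

Five lines are populated from pipeline outputs:

* **PM1** — residue in a conserved nucleotide-binding motif or in a 3D
  hotspot.
* **PM2** — present in ClinVar but absent from gnomAD, *or* allele
  frequency strictly below 0.33% at a position strictly past residue
  250. The two clauses are OR-ed; the frequency cutoff reflects
  expected carrier frequencies for the diseases, and the positional
  cutoff excludes the early region where population-database coverage
  is poor.
* **PM5** — a *different* pathogenic substitution is known at the same
  residue.
* **PP3** — the mechanism classifier assigned a category.
* **PP4** — the reported phenotype is disease-specific.

The combiner encodes the complete 2015 table — PVS/PS/PM/PP on the
pathogenic side, BA/BS/BP on the benign side, conflicting evidence
collapsing to VUS — even though this pipeline populates only five lines,
so user-supplied extra lines combine correctly. `evidence_gap` searches
additions at moderate or supporting strength in any mix and returns the
minimum count needed to reach Likely Pathogenic; it is exactly zero for
variants already at Likely Pathogenic or stronger. Percent-increase
outputs round to the nearest integer percent.

An evidence-override mode (`read_evidence_table`) replays published
per-variant flags verbatim, separating validation of the combiner from
calibration of the upstream thresholds.

## The synthetic generator

`make_structure` builds two pseudo-domains of three idealized helices
each (Cα plus one pseudo side-chain atom per residue, 1.5 Å rise, 100°
twist, small seeded jitter), with states 2 and 3 translating the second
domain rigidly. It emulates exactly the properties downstream code
consumes — inter-residue distances, a domain interface that opens across
states, and a computable relative ASA — and nothing else. It does not
emulate realistic packing, loops, side-chain rotamers, or sequence
conservation, so passing tests demonstrate algorithmic correctness, not
predictive accuracy on real proteins.

`make_variant_cohort` plants spatial clusters (enriched positions drawn
from a center's 10 Å neighborhood) over a uniform without-replacement
background, with heavy-tailed allele counts (truncated discrete Pareto,
optionally constrained to an exact total). `make_stability_profiles`
plants category-specific ΔΔG patterns with Gaussian noise and sets
PAM30/hydropathy values to fire or avoid each rule;
`synthetic_cohort` wires these together with an emitted annotation
configuration so planted labels are recoverable by the real pipeline.
All generators are byte-deterministic in (parameters, seed).

Test problem sizes — 300-residue bundles for scan calibration (50
seeds) and recovery (20 seeds), 120-residue cohorts for classifier
round-trips (20 seeds) — keep the full suite under a minute while
leaving each check statistically meaningful.

## Known limitations

* ΔΔG quality bounds everything downstream; the package propagates, but
  cannot detect, systematic errors in the upstream stability tool.
* The decision tree is protein-family-specific by design: thresholds
  and precedence were chosen for an ABC transporter and are exposed as
  configuration rather than claimed universal.
* Folding-pathway, trafficking and protein–protein interaction defects
  are out of scope; a variant damaging only those will stay
  uncategorized.
* The derived hotspot threshold assumes the permutation null is
  exchangeable with the observed placement; cohorts with strong
  position-level duplication (many alternate alleles at one residue)
  make the scan anti-conservative at the extreme tail.
* The packaged ABCC6 annotation intervals are approximate defaults, not
  curated truth.
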