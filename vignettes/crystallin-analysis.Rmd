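---
title: "Comparative sequence and structure analysis of lens crystallins with crystkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative sequence and structure analysis of lens crystallins with crystkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystkit)
```

## The scientific setting

The βγ-crystallins are the structural and refractive proteins of the
vertebrate eye lens. They share a two-domain double-Greek-key fold, and the
monomeric γ-crystallins are unusually rich in cysteine and — in fish —
methionine, even though Cys positions are poorly conserved across the
superfamily. Two functional pressures are thought to shape this
composition: sulfur-containing residues are highly polarizable and raise
the protein's refractive index increment, while solvent-exposed cysteines
risk intermolecular disulfide cross-linking and hence light-scattering
aggregation in the aging, progressively oxidizing lens.

crystkit packages the computational side of this comparative analysis as
reusable, tested components:

1. **Composition** — Cys/Met counts and percentages per protein and
   subfamily block (γS, γD-like, fish γM, and basal βγ), plus Lys/Arg and
   Ala/Cys ratios.
2. **Refractivity** — the additive Gladstone–Dale refractive index
   increment, $dn/dc = \sum_i w_i\,(dn/dc)_i$, with $w_i$ the mass fraction
   of residue type $i$.
3. **Alignment and clustering** — global pairwise alignment with affine
   gaps, percent-identity dissimilarity matrices ($100 - \mathrm{PID}$),
   progressive multiple alignment, and agglomerative ward.D2 clustering.
4. **Codon-level phylogenetics** — threading coding sequences through the
   protein alignment, Jukes–Cantor or p-distances with pairwise deletion,
   Neighbor-Joining trees, and bootstrap supports.
5. **Structural exposure** — Shrake–Rupley solvent-accessible surface area
   (SASA) and per-domain combined cysteine SASA classified against a
   buried-control baseline.
6. **Motif classification** — the N-terminal Asp-Cys repeat ("DCDCDC"
   loop) as a rule-based γS-like vs γD-like discriminator.
7. **Synthetic data** — seeded generators for sequence families, coding
   sequences, additive distance matrices, and toy structures, so every
   stage has a ground-truth oracle and runs offline.

## The packaged survey table

The packaged table (`load_table1_fixture()`) lists 42 βγ/γ-crystallins from
representative chordates with mature-chain length and Cys/Met content,
partitioned into four contiguous subfamily blocks (4 basal βγ, 11 γS,
16 γD-like, 11 γM). Initiator methionines are assumed cleaved in the
mature protein and are excluded from the counts, while percentages keep
the full chain length as denominator — the convention that reproduces the
printed values (e.g. human γS: 5 Met / 178 residues = 2.8%). Percentages
are rounded half-to-even at one decimal, which matches every checkable
cell; one printed cell (the Cys percentage of the *Xenopus laevis*
γ-crystallin 3 row) is inconsistent with its own count and length, is
stored as printed, and is flagged by `table1_consistency()`.

```{r}
tab <- load_table1_fixture()
group_means(tab)
```

The γD-like block deliberately contains the shark γS1/γS2 and zebrafish
γS3/γS4 rows: despite their database names, these proteins cluster with
the γD-crystallins by sequence identity and lack the γS signature motif,
so subfamily means are computed over the blocks, not the names.

## Refractivity model

The per-residue $dn/dc$ table ships as a swappable TSV
(`residue_refractivity_table()`), with the standard literature values for
all 20 residues (Arg 0.206 mL/g, Lys 0.181 mL/g; residue masses are the
free amino acid minus one water). `protein_dndc()` applies the additive
model; its known blind spots — hydration differences and aromatic-pair
interactions, which make the additive model underestimate crystallin
refractivity — are out of model scope. A hook (`pair_coef`) adds a
user-chosen increment per aromatic pair within a sequence window, default
off, because no standard coefficient exists for the correction.

```{r}
protein_dndc(strrep("R", 20))$dndc   # homopolymer identity: 0.206
```

## Alignment, dissimilarity, and clustering choices

The paper-scale analysis aligns full protein sets with Clustal Omega;
crystkit re-implements the pairwise and progressive stages explicitly so
they are testable:

* Pairwise: Needleman–Wunsch with affine gaps (Gotoh), default BLOSUM62,
  gap open 10, gap extend 0.5 (Clustal-like; the originating analysis does
  not publish its parameters). Traceback tie-breaks are fixed
  (diagonal > up > left), so alignments are deterministic.
* Percent identity: identities over mutually ungapped columns (the exact
  Clustal convention is unpublished; two alternatives are selectable).
* Progressive MSA: profile–profile alignment with the same kernel along a
  UPGMA guide tree built from the pairwise dissimilarity matrix. This is a
  compact aligner in the Clustal tradition, not a Clustal Omega clone, so
  cluster-level structure — not column-level identity with published
  figures — is the reproduction target.
* ward.D2: implemented directly via the Lance–Williams update on squared
  dissimilarities, with merge heights reported unsquared and ties broken
  by the lexicographically smallest label pair. The test suite checks it
  against base R's `hclust(method = "ward.D2")` on hundreds of random
  matrices.

## Codon-level trees

Nucleotide alignments are obtained by back-threading each coding sequence
through the protein alignment (`codon_thread()`): one codon per residue
column, `---` per gap, trailing stop codons stripped. Distances use
pairwise deletion (columns with a gap or ambiguity in either row are
dropped for that pair) and either the p-distance or the Jukes–Cantor
transform $d = -\tfrac34 \ln(1 - \tfrac43 p)$. The Maximum Composite
Likelihood distance used in the original MEGA workflow is intentionally
not re-implemented: its full estimation machinery is out of proportion to
its role here, the published branch lengths are not reproducible without
the unpublished tool settings anyway, and topology-level behaviour is the
acceptance surface. JC69 is the default substitute.

Neighbor-Joining follows Saitou–Nei with deterministic label-order
tie-breaks; negative branch-length estimates are clamped to zero for
output with raw values kept in an attribute. Bootstrap resampling defaults
to codon units (the alignment is codon-threaded; single-column resampling
is available for comparison), requires an explicit seed, and reports for
each internal edge the percentage of replicates containing the same
bipartition.

## SASA and exposure classification

`shrake_rupley()` uses a deterministic golden-spiral lattice (default 960
points per atom, probe 1.4 Å, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 /
H 1.20 / P 1.80 Å; the originating analysis names neither algorithm nor
parameters, so these defaults are documented and swappable). Per-residue
SASA is the sum over the residue's atoms; whole-residue sums are the
default for domain statistics, with side-chain-only selectable.

Exposure classification compares each domain's combined cysteine SASA with
a buried-control baseline: the mean + 1 SD of the SASA of a conserved
buried cysteine (the analog of C83 in human γS) across the structure set,
strictly-greater threshold, multiplier configurable. Domain boundaries and
control residues are supplied per protein; residue numbering follows the
UniProt convention counting Met1 as residue 1. For multi-model NMR files
only model 1 is read.

## The synthetic-data generators

The generators emulate the statistical structure the analysis relies on,
not lens biology:

* `gen_family()` evolves an ancestral sequence of exact target Cys/Met
  composition down a random binary tree; substitutions draw replacements
  from the target composition distribution (a composition-preserving toy
  process, deliberately not a named evolutionary model), optional motifs
  are protected from substitution, and deletions occur only at 10-residue
  block boundaries, mimicking an interdomain linker. Defaults (length
  174 ± 6, Cys 5%, Met 5%, 20 sequences) mirror the four-domain
  γ-crystallin regime; the Met-rich γM regime is obtained with
  `met_fraction = 0.10` or higher.
* `gen_cds_for()` picks uniform synonymous codons, so translation
  round-trips exactly.
* `gen_additive_matrix()` returns a random tree (branch lengths uniform on
  [0.01, 1]) with its exact path-length matrix — the NJ recovery oracle.
* `gen_structure()` builds single atoms and sphere pairs (closed-form
  SASA), cysteines buried inside or placed outside a carbon shell
  (planted exposure labels), and ideal α-helix CA traces.

Because the sequence process is not a biological substitution model and
the toy structures are not folded proteins, passing tests demonstrate
algorithmic correctness (exact NJ recovery, clustering agreement, SASA
convergence, label recovery) — not that real crystallin data would yield
any particular biological conclusion.

## Numerical and design choices

* Rounding: percentages half-to-even at 1 decimal; ratios at 3 decimals.
* Greek-key domain completeness is operationalized as a length window
  (default 80–200 residues) plus name-pattern exclusions (e.g. "AIM"),
  since no domain-counting algorithm is published; the window is
  configurable and the 84-residue single-domain tunicate protein passes.
* The γS-like call requires ≥ 2 DC pairs within the first 90 residues
  (covering the NTD of ~174–183-residue crystallins); both threshold and
  window are configurable, and proteins too short to be two-domain
  (< 140 residues) are left unclassified rather than called γD-like.
* Degenerate inputs are defined, not crashed on: percent identity of an
  alignment with no mutually ungapped columns is 0 with a warning;
  structures without cysteines yield (0, 0) domain sums with a warning;
  JC69-saturated pairs (p ≥ 0.75) are flagged per pair.
* All stochastic stages (generators, bootstrap) require explicit seeds and
  restore the caller's RNG state.

Verification problem sizes are the package's own choice: NJ recovery on 50
random 4–12-leaf trees, ward.D2 agreement on 200 random matrices (n ≤ 6),
alignment-vs-enumeration on every ordered pair of length ≤ 3 over a
4-letter alphabet plus 300 seeded longer pairs, SASA against closed forms
and a 3000-point Monte-Carlo oracle on 50-atom clusters, and exposure
recovery on 10 shell structures. `scripts/acceptance.R` recomputes all of
these plus the survey-table and refractivity constants from scratch.

## Known limitations

* Progressive MSA quality is below dedicated aligners for distant
  sequences; guide trees can be supplied to mitigate order effects.
* The UniProt fetch is a convenience requiring explicit online opt-in; all
  shipped analyses run offline from packaged data and generators.
* mmCIF support covers the `_atom_site` loop (coordinates, elements,
  residues, occupancies, model selection), not the full CIF dictionary.
* Exposure classification is domain-level by design; it does not resolve
  individual cysteine environments.
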