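---
title: "Structural triage of missense variants: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural triage of missense variants: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StructTriage)
```

## The problem

Missense variants of uncertain significance (VUS) are abundant in clinical
sequencing, and sequence-based predictors (SIFT, PolyPhen2,
MutationAssessor, Condel) are sensitive but unspecific: they call a large
fraction of benign substitutions damaging. When an experimental structure
covers the variant position, the substitution can instead be judged by what
it does to the protein's three-dimensional environment. StructTriage
implements that judgement as a deterministic pipeline:

1. map the variant onto the best available experimental structure;
2. build a **mutant model** and a matched **repacked wild-type control**
   on the unchanged backbone;
3. evaluate eleven thresholded structural-damage rules on the pair;
4. call the variant structurally damaging if any rule fires;
5. aggregate a cohort into contingency tables and chi-square tests against
   the binarized predictor consensus.

## Model construction

The mutant model is built by removing the side chain of the query residue
and of every residue with at least one heavy atom within 5 Å of any atom of
the query (contacts with the query's backbone atoms count as well), then
rebuilding all removed side chains. Because rebuilding itself perturbs the
environment, the wild type is rebuilt through the identical procedure — the
comparison is always repacked-WT versus mutant, never crystal versus model,
so repacking bias cancels.

Side chains are rebuilt by a deterministic rotamer search on a fixed
backbone: residues are processed in descending side-chain size, each is
assigned the library rotamer minimizing its summed van der Waals overlap
with all currently fixed atoms (1-2/1-3/1-4 backbone interactions excluded;
cysteine Sγ–Sγ contacts excluded, since those may be covalent disulfides),
and one refinement sweep re-optimizes every rebuilt residue in the final
context. Ties resolve to the first rotamer in library order. There is no
randomness anywhere in model building; repeated builds are bit-identical,
and the backbone RMSD between input and both models is exactly zero by
construction. The shipped rotamer library (`inst/extdata/rotamers.tsv`)
enumerates staggered χ1/χ3/χ4 values with widened χ2 sets for planar groups
(aromatics near ±90°, carboxylates/amides near 0°); side-chain internal
coordinates (`sidechain_templates.tsv`) reproduce ideal amino-acid
stereochemistry. Full combinatorial packing and backbone relaxation are
deliberately out of scope — the downstream rules consume geometry, not
energies, and the greedy single-sweep search is exact enough for the
contact-level questions the rules ask.

## The eleven rules and their thresholds

All thresholds live in a single `ThresholdConfig` object and default to the
published values.

| rule | fires when | threshold |
|---|---|---|
| 1 accessibility switch | buried/exposed status changes | RSA < 9% = buried |
| 2 bridge breakage | a WT salt bridge or disulfide of the target no longer meets its distance criterion in the mutant | 5.0 Å (salt), 3.3 Å (Sγ–Sγ) |
| 3 disallowed torsion | backbone (φ,ψ) disallowed for the mutant class but not the WT class | reference grids |
| 4 buried charge change | buried residue gains/loses/flips charge (D,E,H,K,R) | RSA < 9% |
| 5 steric clash | mutant clash score high and strongly increased | score ≥ 30 and ≥ 70% increase |
| 6 buried hydrophobic→hydrophilic | V,I,L,M,F,W,C,A replaced by R,K,E,D,Q,N while buried | RSA < 9% |
| 7 proline in secondary structure | proline introduced in H/G/I/E | — |
| 8 buried glycine replaced | WT glycine, buried | RSA < 9% |
| 9 substitution to proline | any → proline | — |
| 10 glycine in sharp turn | WT glycine on a turn/bend code | codes {T, S} |
| 11 cavity change | total cavity volume shifts | ≥ 70 Å³ |

Notes on interpretation where the rule set left room:

* **Burial for rules 4/6/8** is read from the repacked wild-type model, the
  same control the comparison uses everywhere else.
* **Rule 3** works at fixed backbone torsions: the backbone never moves, so
  only the class map changes (glycine → general is the canonical positive).
  Residues preceding a proline use the pre-proline class.
* **Rules 7 and 9 overlap** on purpose (helix proline triggers both),
  mirroring their separate definitions.
* **"Sharp turn"** has no literal counterpart among the assignment codes;
  it is mapped to {T, S} and is configurable.
* **Rule 2** only considers bridges involving the target residue; serine,
  threonine, tyrosine, histidine-as-neutral and other borderline chemistry
  is deliberately not extended beyond the published atom sets.
* Amino acids outside both the hydrophobic and hydrophilic sets (S, T, Y,
  H, G, P) never trigger rule 6, as listed.
* A rule whose geometry cannot be resolved reports **not evaluable** and is
  excluded from the final disjunction rather than silently counted false;
  a variant with every rule unresolved gets an NA verdict.
* A wild-type clash score of zero with a mutant score above 30 counts as an
  unbounded increase (the limit of the ratio) and is damaging.
* The cavity comparison is two-sided (|Δ| ≥ 70 ų): cavity filling and
  cavity expansion both flag, with the signed value reported.

## Geometry engines

**Solvent accessibility.** Shrake–Rupley numerical integration over heavy
atoms with a 1.4 Å probe and a deterministic golden-angle sphere lattice of
960 points per atom (no RNG). Relative accessibility divides by the same
engine's value for the central residue of an extended (φ = ψ = 180°)
Gly–X–Gly tripeptide built in code — normalization is self-consistent by
construction, and the reference residue scores exactly 100%. Values above
100% can occur at termini and are legitimate. Against a 10,000-point
brute-force run the default lattice agrees within 2% per residue; areas
under ~0.5 Ų (a fraction of one lattice cell, two orders of magnitude
below anything the 9% threshold can see) are compared absolutely, since
relative error on a vanishing area is noise.

**Secondary structure.** A reimplementation of the Kabsch–Sander
hydrogen-bond pattern algorithm: amide hydrogens are reconstructed
anti-parallel to the preceding carbonyl, bonds use the electrostatic energy
model E = 0.084·(1/rON + 1/rCH − 1/rOH − 1/rCN)·332 kcal/mol with the
−0.5 kcal/mol cutoff, and n-turns, helices (H/G/I), bridges and ladders
(E/B), turns (T) and bends (S, κ > 70°) follow the published priorities.
Ladder bulges and sheet merging are not implemented; per-residue codes are
the product. On the helix and hairpin fixtures the assignment agrees
character-for-character with an independent port of the same algorithm
(frozen reference strings in the tests).

**Torsion classification.** Shipped 10°-bin grids per residue class
(general, glycine, proline, pre-proline) rasterized from analytic
polygon/ellipse approximations of the published favored/allowed contours.
The grids are data files with a documented format; a point on a bin edge
takes the more permissive neighbour. The approximation is coarse by design
— the triage rule only consumes the disallowed/not-disallowed boundary
between residue classes, which the region topology captures; tests compare
the grid against an independently coded polygon evaluator on a full lattice.

**Clash score.** Van der Waals overlap ≥ 0.4 Å between heavy-atom pairs
(C 1.70, N 1.55, O 1.52, S 1.80 Å) within 20 Å of the target Cα, excluding
pairs within three covalent bonds (bonding inferred from distances,
disulfides included), scored as overlapping pairs per 1000 atoms in the
sphere. Hydrogens are not used: most x-ray entries lack them, so the
heavy-atom convention keeps experimental and rebuilt atoms on equal
footing. The threshold stays at 0.4 Å. Boundary comparisons carry a 1e-9
epsilon so geometrically exact thresholds behave inclusively in floating
point.

**Cavities.** A dual-probe grid method (0.6 Å step, 1.4 Å inner and 4.0 Å
outer probe, the cited tool's defaults). Grid points host the small or
large probe where the distance to every atom exceeds its van der Waals
radius plus the probe radius; bulk solvent is the large-probe region
flood-filled from the box boundary; exposure then spreads from the bulk by
one outer-probe radius through atom-free space (a geodesic dilation —
exposure cannot tunnel through a sealed atomic wall). Sealed small-probe
centres define cavities, and each cavity's volume is the union of
small-probe balls around its centres clipped to the outside of the van der
Waals surface, so reported volumes are bounded by the molecular surface
rather than by probe-centre accessibility. On closed-shell fixtures with an
analytic void volume the default grid is within 15% and halving the step
converges to within a few percent.

**Superposition.** Closed-form Kabsch RMSD via singular value
decomposition with reflection correction; validated against a brute-force
rotation-grid oracle.

## Structure input, selection and quality

PDB and mmCIF parsing is delegated to bio3d. Waters are removed; common
modified residues (MSE and relatives) are normalized to their parents;
other non-polymer HETATM records are dropped; alternate locations resolve
to the highest occupancy with alphabetic tie-break. Residue numbering is
1-based author numbering with insertion codes; when a canonical sequence is
supplied, the observed chain sequence is globally aligned to a local region
of it and positions carried through the alignment. Mapped residues whose
type disagrees with the stated wild type are flagged and excluded
downstream.

Among candidate structures covering a position, those resolving fewer than
100 residues are discarded; x-ray beats NMR; higher resolution wins, with
resolutions within 0.05 Å falling back to the longest coverage, and any
remaining tie breaking on the identifier so selection is order-independent.
For multi-chain coverage the chain with most resolved residues is the
default, configurable per call. NMR ensembles use model 1.

The quality gate evaluates resolution < 2.0 Å, at most 5% of residues with
bond-length or bond-angle deviations beyond 4σ of standard stereochemical
targets, and at most 5% with a Cβ more than 0.25 Å from the position
implied by N, Cα and C. The MolProbity composite score is accepted as an
externally supplied number (its formula is not reimplemented); without one
that criterion reads "not evaluated" and the gate decides on the computable
criteria.

## Predictor consensus and cohort statistics

Raw categories binarize as published: PolyPhen2 probably/possibly
deleterious and MutationAssessor high/medium are damaging; PolyPhen2 benign
and MutationAssessor neutral/low are tolerated; SIFT and Condel are taken
at their native binary calls; empty or unrecognized values are unavailable.
The consensus is a majority vote: ties (including zero available verdicts)
are noninformative; *full* concordance is reserved for four available and
unanimous verdicts, any other majority is *partial* — a unanimous 3/3 is
still partial, because "by all predictors" reads as all four.

Cohort tables report counts with percentages recomputed from those counts,
rounded half-up to one decimal (`roundHalfUp`), and a Pearson chi-square
test (df = 1, no continuity correction by default; the Yates variant is one
argument away and every published significance bound holds under both).
One published percentage cell (40/410) is not reproducible by the same
rounding rule that produces its neighbours; the tests assert the half-up
value and its agreement with the printed figure to one decimal.

## The synthetic fixtures

`makeStructure()` builds ideal-geometry peptides and pseudo-structures:
α-helices (φ = −57°, ψ = −47°), β-hairpins (strands at (−120°, 135°) joined
by a tight turn), a seven-helix packed core whose spacing controls the
central residue's burial, cysteine and Lys/Asp pairs with bridging atoms at
an exact requested distance, closed atom shells enclosing an analytic void
(optionally pierced by a channel), and the extended reference tripeptide.
Bridge-pair side chains are built at the rotamer the packer itself selects
on that backbone, so the repacked wild-type control reproduces the bridge
exactly and rule 2 is exercised through the same code path as real data.
`makeCohort()` emits deterministic variant records whose predictor
patterns realize requested consensus strata and whose mapped/damaging
counts reproduce any consistent table of marginals.

What the fixtures do **not** emulate: real side-chain packing
heterogeneity, experimental noise and missing atoms, multi-domain
architecture, and crystallographic artifacts. Green fixture tests
demonstrate that every rule, threshold and report behaves exactly as
specified on controlled geometry; they do not measure classification
accuracy on real proteome-scale data, which depends on database snapshots
outside this package. Problem sizes in the test-suite were chosen at desk
scale (12–63 residue fixtures, 20-table round-trip samples, one
10,000-point SASA oracle run, one 0.3 Å cavity refinement).

## Case studies on real structures

The analyses behind the published case studies (TSHR 2XWT, APOE 2KC3, CASR
5FBK/5K5T, LDLR 3P5C/1N7D/1IJQ) require downloading those PDB entries; no
test depends on the network. With the files on disk the same calls apply,
e.g. Cys284→Ser on the LDLR complex:

```r
s <- readStructure("3p5c.pdb")
pair <- buildModelPair(s, chain = "A", resno = 284, mutantAa = "S")
structuralVerdict(evaluateVariant(pair))
# expected: damaging, triggered includes bridge_breakage (partner Cys302)
```

## Known limitations

* The repacker optimizes steric overlap only; it has no statistical rotamer
  priors or hydrogen-bond term, so rebuilt polar contacts are approximate.
* Torsion reference grids are analytic approximations at 10° resolution,
  not digitized experimental contours.
* Cavity volumes depend on the grid step and the geodesic exposure
  convention; absolute values are comparable within this package, not
  across tools.
* Protein–protein interfaces and homology models are out of scope, as is
  any re-implementation of the external predictors whose verdicts are
  inputs.
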