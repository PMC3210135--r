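---
title: "Detecting, solvating and classifying macromolecular interfaces"
author: "InterfaceRegions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, solvating and classifying macromolecular interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(InterfaceRegions)
```

## The problem

A protein family typically uses a small number of distinct surface patches
— *binding regions* — to recognize its partners: other proteins, peptides,
nucleic acids and carbohydrates. Given a collection of experimentally
determined complexes, one can recover these regions by (i) detecting every
atomic interface a family member makes, (ii) expressing each interface as a
set of columns on the family's structure-based multiple alignment, and
(iii) clustering interfaces whose interacting residues overlap.
`InterfaceRegions` implements this construction, including interfacial
water, and additionally transfers observed regions across structurally
similar families through non-sequential structural-alignment
correspondences, producing *predicted* binding regions for families that
may have no complex structures at all.

## Interaction model

All criteria are heavy-atom distance thresholds, applied symmetrically and
inclusively (`<=`):

| interaction    | condition                                   | cutoff |
|----------------|---------------------------------------------|--------|
| hydrogen bond  | donor atom vs acceptor atom                 | 3.6 Å  |
| salt bridge    | positively vs negatively charged atom       | 4.0 Å  |
| van der Waals  | any heavy-atom pair                         | 4.5 Å  |

A pair may carry several labels — a salt bridge at 3.2 Å is also a
hydrogen bond and a van der Waals contact; multi-labeling preserves
information and residue-level summaries can always report the strongest
label. No angular criterion is applied to hydrogen bonds: donor/acceptor
identity plus the distance threshold is the whole rule, which keeps the
model usable on structures without hydrogens (hydrogens, if present, are
dropped at parse time). Donor/acceptor/charge assignments live in an
editable chemistry dictionary (`defaultChemistry()`,
`writeChemistryDictionary()`); His ND1/NE2 are donor *and* acceptor and
His is uncharged by default, terminal OXT is an acceptor, and the
N-terminal nitrogen stays donor-only because protonation cannot be read
off coordinates.

A *water-mediated* interaction joins two residues on opposite sides of an
interface when each has a donor or acceptor atom within the hydrogen-bond
cutoff of the same water oxygen. Only single-water bridges are detected;
two-water chains are out of scope. Interface residues are then annotated
*dry* (direct contacts only), *wet* (water-mediated only) or *dual*
(both), and *hydrophobic* only when every contacting atom of the residue is
apolar — on mixed atoms "hydrophilic" wins, the conservative choice for
polarity-based analyses.

## Entity typing

A parsed structure (`parseStructure()`; fixed-column PDB, first model of
multi-model files, highest-occupancy alternate locations with ties broken
toward the lexicographically smallest identifier) is partitioned into typed
entities:

* **domains** — residue ranges from a SCOP-like domain-definition table;
* **peptides** — chains of ATOM-record standard amino acids, covered by no
  domain definition, with at most 89 observed residues (i.e. shorter than
  90). Longer undomained chains are reported as *unassigned-protein*, never
  silently dropped;
* **DNA/RNA units** — standard-nucleotide chains, merged transitively into
  one unit (a duplex) whenever at least one base-moiety atom pair between
  chains falls within the van der Waals cutoff. The merge criterion reads
  "inter-base atomic interaction" as base atoms only (no sugar, no
  phosphate), because base pairing is what defines a duplex. A merged unit
  is RNA if any member nucleotide carries an O2' atom — the presence rule
  is existential, so mixed content types as RNA;
* **oligosaccharides** — HETATM residues from a curated saccharide-code
  list, merged along covalent bonds (explicit CONECT records, or any
  inter-unit heavy-atom pair within 1.9 Å where connectivity is absent —
  wide enough for glycosidic C–O/C–N bonds at ~1.4–1.5 Å, narrow enough to
  exclude hydrogen bonds, which start near 2.4 Å heavy-atom). A unit bonded
  to a protein entity by the same criterion is flagged covalent
  (glycosylation); its interface is kept but marked and excluded by default
  search filters;
* **waters** — HOH/WAT/DOD residues, oxygen only.

Nucleic-acid typing runs before peptide typing, so a short nucleotide chain
can never satisfy the peptide rule. Peptide length counts observed ATOM
residues: working from coordinates alone, residues that were not modeled
cannot be counted, so the observed count is the only well-defined choice.

## Binding regions and the FA/BR/IF hierarchy

Each interface is mapped to 0-based alignment columns through its member's
residue-to-column map, derived by ungapped position counting against the
structure's ordered residues (columns are printed 1-based in every
report). Similarity between two interfaces is **overlap over the smaller
set**, `|A ∩ B| / min(|A|, |B|)` — chosen over Jaccard so that a small
interface fully contained in a larger region clusters with it. Interfaces
become nodes of a graph with edges where similarity is *strictly greater*
than the cutoff, and regions are the connected components (single
linkage). The strict inequality makes the default zero cutoff mean "any
shared column joins two interfaces". The shipped cutoff ladder is
{0, 0.2, 0.4, 0.6}, fully configurable; region counts are non-decreasing
along it, reaching all-singletons at cutoff 1.

The hierarchy has three levels: **FA** (family) lists binding regions;
**BR** (binding region) lists interface groups; **IF** groups interfaces
that bind the same partner family (protein ligands) or the same ligand
type (peptide/NA/saccharide ligands). Search filters reproduce the
navigation semantics: ligand-type selection is *conjunctive* (selecting
protein and DNA keeps only regions recognizing both through the same
region), homo/hetero filters on whether the partner domain belongs to the
same family, intra/inter on whether the partners share a chain.
Crystal-packing removal is a pluggable hook: an external classifier
returning a biological probability, filtered at 0.70; the built-in
alternative (`mode = "naive"`, dropping protein-protein interfaces with
fewer than five residues) is a crude size screen, clearly not an SVM, and
strictly opt-in.

## Cross-family inference

Given a residue correspondence between members of two families (from a
non-sequential structural alignment, supplied as input), an observed
region transfers to the target family when its interface residues are
sufficiently covered by the correspondence. *Conservation* is
operationalized as **coverage** — the mapped fraction of source interface
residues — against a named threshold, default 0.5: at least half of an
interface must have a structural counterpart before we hypothesize the
region transfers. This is a deliberate simplification of a full
statistical-significance treatment; the threshold is an explicit, documented
parameter rather than a hidden constant. Predicted regions carry ligand
identity and binding-mode provenance only — no coordinates are modeled.
Predictions on one family are deduplicated by the same overlap measure,
and a prediction overlapping an observed region is reported as
*corroborating* rather than emitted as a new region. Raising the threshold
can only remove predictions.

## The synthetic corpus: what it does and does not show

All tests run on generated fixtures (`makeAtomPair()`, `makeNaDuplex()`,
`makeProteinChain()`, `makeComplexCorpus()`). Geometry is schematic:
residues are placed so that exactly the intended atom pairs fall inside
the interaction envelopes, with coordinates written to 3 decimals and every
requested separation reproducible from the file to ±0.001 Å. The toy
corpus (three families; DNA, peptide, homodimer and saccharide ligands; a
bridging water; one glycosylation; one apo family reachable only through a
correspondence covering 3 of 5 interface residues) exercises every code
path end-to-end at desk scale — a few hundred atoms per structure, chosen
so the full suite and the acceptance script each finish in minutes.

Passing these tests shows that the distance criteria, typing rules,
clustering and transfer logic are implemented exactly as specified; it does
*not* show anything about stereochemical realism, about robustness to the
full heterogeneity of deposited PDB files (chain breaks, exotic chemistry,
symmetry copies), or about the biological precision of predictions on real
families. Whole-archive census numbers require the complete PDB plus a
domain classification release and are explicitly out of scope.

## Numerical and degenerate-input choices

* All three criteria are inclusive; fixtures at exactly 3.6/4.0/4.5 Å are
  classified positive, and the test suite pins these boundaries.
* Covalently bonded pairs (CONECT, or ≤ 1.9 Å) are excluded from
  non-covalent contact lists.
* Empty entities yield empty contact tables, not errors; an interface
  exists only when at least one direct or water-mediated contact does.
* Two empty column sets have similarity 0 by convention.
* Waters lacking an oxygen atom are skipped with a warning; malformed
  fixed-column lines fail with the line number; zero-atom files are an
  explicit empty-structure error.
* Region/interface identifiers are assigned in sorted deterministic order;
  rerunning any stage on the same inputs is byte-identical.

## Known limitations

mmCIF input, assembly/symmetry expansion and hydrogen placement are not
supported. Modified nucleotides are not recognized (standard nucleotides
only). The saccharide code list is a curated subset of PDB carbohydrate
chemistry, extensible through `readSaccharideCodes()`. The crystal-packing
hook's reference classifier is external by design. Structure-based family
alignments and cross-family correspondences are inputs, not computed here.
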