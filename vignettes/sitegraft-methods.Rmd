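---
title: "Mapping substrate-binding sites by structural homology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping substrate-binding sites by structural homology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sitegraft)
```

## The scientific setting

Human COQ2 is an integral-membrane prenyltransferase of the UbiA
family: it attaches the decaprenyl tail to the para-hydroxybenzoate
head in coenzyme-Q biosynthesis, and its missense variants cause
primary CoQ deficiency. No experimental structure of the human enzyme
exists. What does exist is (i) a high-confidence predicted model, and
(ii) several solved structures of family relatives crystallised with
bound ligands — prenyl-diphosphate analogs, Mg²⁺ ions, lipids. The
homology-transfer argument is that after superposing a ligand-bound
relative onto the predicted model, the model residues surrounding the
transplanted ligand are candidate substrate-binding residues, to be
read together with conserved motifs, membrane topology, and the
positions of disease variants.

sitegraft implements that argument as a pipeline of small, separately
testable operations. This vignette records the model behind each stage,
the tunable parameters and why their defaults are what they are, what
the synthetic fixtures do and do not establish, and the design
decisions that were genuinely open.

## Stage models and parameters

### Hit selection

Homologs come from a profile-HMM search report (HHR summary format).
Two rules decide which hits proceed:

* **probability > 50%** (strict inequality), the usual bar below which
  profile-profile matches stop being trustworthy;
* **at least one ligand bound to the hit's own chain.** "Bound to chain
  X" is operationalised as *any hetero heavy atom within 4.0 Å of any
  polymer heavy atom of chain X*. The original analysis curated this by
  eye; a distance rule makes it reproducible. 4.0 Å is a generous
  heavy-atom association distance — it asks "does this component sit on
  this chain", not "is this a specific interaction". Waters (`HOH`,
  `DOD`) are deny-listed; ions such as Mg²⁺ count as ligands, because
  in this family they are mechanistically central cofactors.

Repeated hits to one entry/chain (a homolog aligned over several
regions) collapse to the best probability. Substituting a ligand-bound
deposition for an apo top hit is supported only through an explicit
user-supplied alias map (`apply_hit_aliases()`): that substitution is a
scientific judgement, not something the code should guess.

### Substrate similarity

Each dictionary component is reduced to its public 166-key MACCS
structural-key fingerprint (computed from the component SMILES, via
Open Babel through ChemmineOB; hydrogens implicit), and compared with
the query substrate by the Tanimoto coefficient. The screening
threshold is 0.3 — the conventional "any meaningful similarity" bar
for MACCS/Tanimoto — and the comparison is strict (`> 0.3`) by default;
the boundary convention is configurable because descriptions of this
cutoff in the literature vary between "above" and "at least". On the
packaged dictionary both conventions select the same nine components,
so nothing here hinges on the boundary.

When a component lists several SMILES descriptors, one is chosen
deterministically: canonical SMILES before plain SMILES, descriptor
programs ordered OpenEye, then CACTVS, then anything else, first match
wins. Ranking ties are broken by component id. Both rules exist purely
so that two runs of the pipeline produce byte-identical tables.

### Confidence trimming

Predicted models store per-residue confidence (pLDDT, 0–100) in the
B-factor column; the per-residue value is read from the Cα atom. At the
default threshold of 90 ("very high" confidence), trimming removes the
maximal contiguous N- and C-terminal runs below threshold and keeps one
contiguous segment. Interior dips below threshold are *retained* and
logged: deleting them would fragment the chain, and the disorder that
trimming targets is terminal. The operation is idempotent and its
output is always a contiguous residue interval of its input — both are
property-tested on randomized confidence profiles.

### Superposition

Correspondence first, fit second.

* **Correspondence.** Cα residue pairs come from affine-gap pairwise
  alignment (BLOSUM62, gap open 11, extend 1 — the standard protein
  defaults; the choice is not critical at the identities involved).
  End gaps are free ("overlap" alignment): the query model is routinely
  a trimmed fragment, and a global alignment with penalised end gaps
  can buy a spurious terminal pair — one such stray pair costs more
  RMSD than any gap penalty saves. Sequence identity for gating,
  however, is measured on the *global* alignment, whose identity (over
  aligned columns) is insensitive to trimming but not inflated by
  clipping to the best-matching region.
* **Mode gate.** Above 30% identity a plain sequence alignment is
  reliable (`sequence_dependent`); at or below it, the alignment score
  is augmented with +2 per column whose residues share a three-state
  secondary-structure assignment, with relaxed gaps (open 5, extend
  0.5) — a lightweight structure-aware correspondence
  (`sequence_independent`). The SS assignment is geometric (i→i+3 Cα
  distance: ~5.1 Å helix, >9 Å strand), which is crude but sufficient
  to anchor an alignment within a fold family; full fragment-assembly
  alignment is deliberately out of scope. Note that identity estimated
  from an alignment is itself noisy: simulations that plant 25%
  identity occasionally measure just over 30%, so the gate should be
  read as a heuristic default, not a sharp classifier.
* **Fit.** The Kabsch closed-form solution (centroid subtraction,
  covariance SVD, determinant sign correction), iterated with outlier
  rejection: pairs with residual above 2.0 Å are dropped and the fit
  recomputed, for at most 5 cycles or until no pair drops — the default
  behaviour of the standard interactive superposition tools this
  mirrors. Rejection never reduces the pair set below 3 (the minimum
  fittable set): for a grossly divergent pair of structures the fit
  keeps its large RMSD rather than failing, which is more informative
  downstream.
* **Reported RMSD.** Two values: over retained pairs (the headline
  number) and over all aligned pairs under the final transform. The
  *exclusion* rule for divergent homologs (default 10 Å) tests the
  all-pair value, because outlier rejection can make the retained-pair
  RMSD of an unrelated fold look benign.

Degenerate inputs: fewer than 3 pairs, or (near-)collinear point sets
(second covariance singular value below 1e-8 of the first), are errors;
planar sets are fine. Orthonormality and det = +1 of every rotation are
asserted to 1e-8 in the tests.

### Site transfer and annotation

Transferred ligand atoms are the homolog's hetero heavy atoms mapped by
the fitted transform. Contacts use a 5.0 Å heavy-atom cutoff — the
standard residue-contact definition; the underlying study says only
"close to", so 5.0 Å is this package's choice, validated against the
planted-pocket fixtures rather than asserted as anyone else's value.
Clashes use 2.0 Å, safely below any van der Waals contact distance.
Both are configurable. Mg²⁺ ions are transferred regardless of the
similarity screen and reported as a separate cofactor category.

Annotations (membrane topology, motifs, variants, portal helices) are
joined by residue number; a contact outside every table is flagged
`unannotated`, never an error, because annotation tables are typically
incomplete.

### Variant comparison

Variant models are superposed with rejection *disabled*: a point mutant
aligns end to end, and rejection would silently remove exactly the
locally shifted residues whose deviation is the signal. The
rejection-on value is reported alongside for transparency, since the
convention behind published variant RMSDs is usually unstated. Local
alterations are flagged by a robust rule — maximal runs of ≥ 3 residues
with Cα deviation above median + 2·MAD of the profile — chosen because
the deviation profile of a point mutant is a heavy-tailed background
plus a localized excursion, and a mean/SD rule would let the excursion
inflate its own threshold. Both the multiplier and the run length are
exposed.

The published variant ranking ships as packaged data, and the
pathogenicity/RMSD association is tested by Spearman rank correlation
with a binary pathogenicity coding; with n = 12 the 5% two-sided
critical value is |ρ| = 0.587.

## What the synthetic fixtures emulate — and what they do not

The generators build ideal α-helical bundles (rise 1.5 Å, 100°/residue,
helical radius 2.3 Å, ~3.8 Å Cα spacing) on a ring enclosing a central
cavity — the channel-like architecture of the UbiA fold — with one
pseudo-side-chain centroid atom per residue at Cβ geometry. Homolog
derivation plants the full causal chain the pipeline must invert: a
known rigid motion, Gaussian coordinate noise, sequence mutated to a
target identity, a multi-atom ligand placed so that exactly the chosen
pocket residues lie within 3.5 Å and every other residue beyond 5.3 Å,
and optionally a component 1.2 Å from a cavity side chain (a planted
clash). Because the ligand is planted in the query frame, recovering
the pocket exactly at the 5 Å contact cutoff requires the recovered
transform to be accurate — the margins tolerate sub-0.3 Å transfer
error, which a correct fit achieves easily and a subtly wrong one does
not.

What passing these tests shows: the parsing, screening, trimming,
alignment, fitting, rejection, transfer, contact, clash, annotation and
ranking machinery is correct, deterministic under a seed, and
internally consistent end to end. What it does not show: performance on
real coordinates — real side chains are flexible rotamers, real
homologs diverge by loop remodelling rather than isotropic noise, real
pockets have no clean margin, and real alignment errors are structured.
The fixture margins were chosen to make the ground truth decidable, not
to mimic the difficulty of real data.

The packaged case-study inputs are reconstructions where the real files
could not be redistributed: component SMILES rewritten from the
published chemical identities (the digitonin and cardiolipin entries
are class-accurate approximations), a hit table whose entry ids and
>50% membership follow the published search summary but whose
probability values are invented, an approximate topology table
consistent with all published per-segment residue assignments, a
synthetic 371-residue scaffold sequence carrying every published pinned
residue at its position, and a confidence profile rebuilt from the
published per-region description. The last point matters for reading
the trim check: the profile's band boundaries are taken from the
published description, so trimming at 90 recovering residues 60–354
verifies the trimming rule against the published bands — it is not an
independent re-derivation from the real model, which would require the
deposited file.

## Problem sizes and determinism

The shipped analyses and tests run on 225-residue bundles (9 helices ×
25 residues), five homologs, three variant models, a 15-component
dictionary, and 20-seed property sweeps — sizes at which the full suite
finishes in well under a minute while still exercising multi-cycle
rejection, both alignment modes, and every filtering rule. All
generators draw from an isolated RNG stream (`seed` arguments; the
caller's RNG state is untouched), every pipeline run records its
configuration, input checksums and seed in a manifest, and re-running a
configuration reproduces the reports byte for byte.

## Known limitations

* The sequence-independent mode is alignment-based, not a true
  structural aligner; for folds related only at the architecture level
  it will produce a poor correspondence (and, by design, a large
  reported RMSD rather than a failure).
* MACCS/Tanimoto is a 2D similarity; it cannot see conformation,
  charge state or binding pose, which is precisely why screened ligands
  are only *candidates* for transfer.
* Contact and clash calls on predicted models inherit the model's local
  accuracy; a 5 Å contact on a region with pLDDT 70 is a weak
  statement, which is why trimming precedes transfer.
* Variant models compared here are consumed as files; regenerating them
  with a structure predictor is out of scope, so the variant stage
  validates the comparison machinery, not any particular predictor.
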