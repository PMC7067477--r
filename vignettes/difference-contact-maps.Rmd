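---
title: "Difference contact maps and differentially stabilizing residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference contact maps and differentially stabilizing residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffcontact)
```

## The problem

Many proteins are deposited in the PDB many times over, in different
functional states, crystal forms or complexes. Global measures such as
RMSD describe *how much* two such coordinate sets differ, but not
*which interactions* make each conformation what it is. `diffcontact`
answers the second question: given two structure models of (nearly) the
same protein, it identifies the residue–residue contacts present in
exactly one conformation, discards the ones attributable to small local
fluctuations, and reports the residues involved — *differentially
stabilizing residues* (DSRs) — as candidate modulators of the
conformational equilibrium (and therefore interesting sites for
mutagenesis or disease-variant interpretation).

## The method

For each model, only residues with an empty insertion code and a
non-hetero record type are used. The two chains are paired through
their SEQRES sequences: a global Needleman–Wunsch alignment is
computed, then columns are removed where either side is a gap or where
either side's SEQRES position has no observed coordinates. The result
is an order-preserving one-to-one residue map. If strictly more than 5%
of the paired residues differ in identity, the pair is declared
incompatible and no maps are computed — beyond that level of sequence
difference the two chains can no longer be treated as two conformations
of one protein.

Within each conformation, two mapped residues are **in contact** when
the minimum distance over all pairs of their side-chain heavy atoms is
strictly below 5 Å. Side chains are used rather than Cα/Cβ because they
carry the actual interactions; 5 Å is the upper end of the direct
(non-water-mediated) contact range. Glycine has no side chain and
contributes its Cα instead; a residue whose side-chain atoms are all
unresolved forms no contacts at all.

The **difference contact map** is the symmetric set difference of the
two contact sets, each entry labelled by the conformation it belongs
to. It is then **filtered**: an entry survives only when its
inter-residue distance (the same minimum side-chain metric) changes by
strictly more than 5 Å between the conformations. A change of at most
5 Å is treated as local rearrangement noise; a larger change marks a
contact made or broken by a genuine large-scale motion. Every residue
appearing in at least one surviving entry is a DSR.

Summary quantities: the Cα superposition RMSD over the mapped residues
(Kabsch least squares), the changed-contact fraction (filtered entries
over the union of the two contact sets), and, when domain annotations
are supplied, the count of filtered contacts per unordered domain pair.

## Parameters

| parameter            | default | unit      | meaning                                                |
|----------------------|---------|-----------|--------------------------------------------------------|
| `contact_threshold`  | 5.0     | Å         | contact iff min side-chain distance `<` this           |
| `delta_threshold`    | 5.0     | Å         | filtered entry iff distance change `>` this            |
| `mismatch_tolerance` | 0.05    | fraction  | incompatible iff mismatch fraction `>` this            |
| `min_seq_separation` | 1       | positions | minimum `j - i` for a contact pair (1 = no exclusion)  |

Boundary semantics are deliberately asymmetric and exact: the contact
rule is strict (`4.999` Å is a contact, `5.000` Å is not), the filter
removes changes *up to and including* the threshold (`5.000` Å removed,
`5.001` Å kept), and the compatibility rule passes exactly 5% and fails
anything above it. All distances are compared in double precision with
no rounding — PDB coordinates carry three decimals, and rounding inside
the method would create threshold artifacts.

`min_seq_separation` exists because contact-map methods differ on
whether sequence-adjacent pairs count as contacts; the default of 1
imposes no exclusion, the literal reading of the contact definition.
The changed-fraction denominator is likewise configurable
(`union`, the default, is symmetric and keeps the fraction in [0, 1];
`mean` and `min` are offered because "total number of contacts" admits
several readings).

## Design choices in the input path

* **Alternate locations.** For each atom the highest-occupancy
  conformer is kept, ties broken by altloc identifier (so `A` wins).
  This is the standard single-conformer convention and deterministic.
* **Hydrogens** (and deuteriums) are dropped at parse time: the contact
  definition involves heavy atoms only.
* **Multi-model files** read MODEL 1 unless another index is requested.
* **Missing SEQRES** records are tolerated with a warning; the sequence
  is then reconstructed from the observed residues. The pairing is
  SEQRES-based by design, so the warning matters for real depositions.
* **Nonstandard residues** with a regular ATOM record are kept; their
  one-letter code falls back to `X`, which the alignment treats as a
  (mis)matchable ordinary symbol. Two paired residues whose three-letter
  names differ count as one mismatch for the compatibility rule.
* The alignment uses BLOSUM62 with gap opening 10 and extension 0.5.
  The two chains come from the same protein (point variants at most),
  so the exact scoring scheme is immaterial to the matching; the
  parameters are recorded in the output metadata anyway.

## Entries the filter cannot evaluate

A contact can exist in one conformation while the partner residue's
side chain is unresolved in the other; the distance change is then
undefined. Such entries are never promoted to the filtered map — the
filter cannot be evaluated, and inventing a distance would fabricate
DSRs — and a warning reports how many were set aside. They remain
visible (unfiltered) in the difference table.

## The synthetic generator

`make_pair()` builds a two-conformation pair with known answers: a
jittered poly-alanine hairpin whose two arms pack their side chains
against each other, giving a band of cross-arm contacts; conformation B
applies a hinge rotation (or a shear translation, a whole-body rigid
motion, or nothing) to the arm past the hinge point, so cross-arm
contacts break with distance changes that grow with the distance from
the hinge. Glycines can be planted to exercise the Cα rule, and probe
contacts can be planted with exact distances in both conformations
(realized by intersecting the two distance spheres; geometrically
impossible requests fail with an error naming the pair). Coordinates
are emitted through the package's own PDB writer.

Two properties make the fixtures trustworthy rather than circular:
generation is deterministic given the seed (byte-identical files), and
the shipped ground truth is **re-measured from the emitted text** by an
independent brute-force pass (fixed-column line parsing and exhaustive
double loops, sharing no code with the package's parser or distance
engine). Tests then demand *exact* agreement between the pipeline and
that re-measurement, including plants right at the 5 Å boundaries,
where the emitted 3-decimal coordinates — not the requested values —
are the arbiter.

What the generator does **not** emulate: real backbone geometry
(the hairpin turn is not Ramachandran-valid), full side chains
(one pseudo-atom per probe), crystallographic noise, alternate
locations, or missing loops. Passing the fixture suite therefore shows
that the *rules* of the method are implemented exactly; it does not by
itself validate behaviour on pathological real depositions, which is
what the parser-level tests (altlocs, insertion codes, HETATM,
multi-model files) cover separately.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on generated
fixtures: chains of 15–30 residues for property checks (where the
brute-force oracles are exhaustive), 60 residues for the headline
pipeline run, 100 residues for the compatibility-boundary cases, and 20
seeded hinge/shear pairs for ground-truth recovery. These sizes keep
the exhaustive oracles honest and the whole suite fast; nothing in the
method is size-dependent, and real chains of several hundred residues
run in seconds (the distance engine aggregates one atom-level distance
matrix per conformation).

All randomness flows from explicit seeds; comparisons, CSV row order
and generated files are deterministic, so reruns are byte-identical.

## Known limitations

* Exact reproduction of published contact counts for real PDB pairs
  can hinge on conventions the method's description leaves open —
  end-gap handling in the alignment and whether sequence-adjacent
  contacts are excluded. `min_seq_separation` documents the second
  ambiguity; the first is fixed by the BLOSUM62/10/0.5 choice above.
* The RMSD here is a plain Cα Kabsch superposition over the mapped
  residues. Database-reported RMSDs for the same pair may differ
  slightly depending on their superposition protocol.
* One conformer per atom: occupancy-weighted multi-conformer geometry
  is out of scope, as are mmCIF input, assemblies and symmetry mates.
* The method detects contacts *made or broken by large motions*; a
  contact that merely changes character (e.g. a side chain rotamer
  flip within 5 Å) is invisible to it.
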