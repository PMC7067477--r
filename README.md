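# diffcontact

Difference contact maps and differentially stabilizing residues (DSRs)
for protein conformational pairs.

Structural biologists routinely have two (or many) coordinate sets of
the same protein — open and closed, active and inactive, apo and holo.
Global RMSD says how far apart the conformations are; it says nothing
about *which interactions hold each conformation together*.
`diffcontact` compares the two conformations through their
residue–residue contact maps and reports the contacts, and residues,
that distinguish them.

## Method

For two chains paired one-to-one through a SEQRES-based global
alignment (corrected so that every paired position has coordinates in
both models, and skipped entirely when > 5% of paired residues differ
in identity):

* residues *i*, *j* are **in contact** in one conformation when
  min over side-chain heavy atom pairs d(a_i, a_j) < 5 Å
  (glycine contributes Cα; residues with no resolved side chain form
  no contacts);
* the **difference contact map** is the symmetric difference of the
  two contact sets — contacts present in exactly one conformation;
* the map is **filtered**: an entry survives only if its inter-residue
  distance changes by strictly more than 5 Å between conformations
  (|d_A − d_B| > 5 Å), separating genuine large-scale motion from
  local fluctuation;
* every residue in a surviving contact is a **differentially
  stabilizing residue (DSR)** — a candidate modulator of the
  conformational equilibrium.

Summary metrics: Cα Kabsch superposition RMSD over the mapped
residues, the changed-contact fraction (filtered entries / union of
the two contact sets), and per-domain-pair counts of filtered contacts
when domain annotations are supplied.

## Worked example

The package ships a synthetic-pair generator with machine-checkable
ground truth, so the example is self-contained: a 60-residue hairpin
whose distal arm swings open by 60°, with one probe contact placed at
4.5 Å in the closed form and 16 Å in the open form.

```r
library(diffcontact)

fx <- make_pair(fixture_spec(
  60, motion = "hinge", hinge_position = 30, hinge_angle = 60,
  planted_contacts = data.frame(i = 25L, j = 35L, dist_a = 4.5, dist_b = 16),
  gly_positions = c(10L, 45L), seed = 1))

closed_model <- parse_structure(fx$pdb_a, "A", pdb_id = "CLOSED")
open_model   <- parse_structure(fx$pdb_b, "A", pdb_id = "OPEN")

cmp <- dcm_compare(closed_model, open_model)
cmp
#> Difference contact map: CLOSED:A vs OPEN:A
#>   60 residue pairs mapped, mismatch fraction 0.0000
#>   contacts: 117 (A) / 61 (B); exclusive: 58; filtered: 54 (54 A-only, 0 B-only)
#>   CA superposition RMSD: 28.59 A; changed-contact fraction (union): 0.4576
#>   DSRs: 54
```

Reading this: the closed form has 117 contacts, the open form 61;
58 contacts exist in exactly one conformation, of which 54 change
their inter-residue distance by more than 5 Å — all of them closed-form
contacts broken by the opening motion. 54 residues participate in
those contacts and are reported as DSRs:

```r
head(subset(as.data.frame(cmp), filtered), 3)
#>   i  j resno_a_i resname_a_i ... side   dist_a   dist_b    delta filtered
#> 1 1 59         1         ALA ... A_only 3.344405 106.8858 103.5414   TRUE
#> 2 1 60         1         ALA ... A_only 3.212339 108.9995 105.7872   TRUE
#> 3 2 58         2         ALA ... A_only 3.212591 103.2151 100.0026   TRUE

plot(cmp)   # two-colour difference map (A-only above, B-only below diagonal)
```

Every number above is checkable against the generator's ground truth,
which is re-measured from the emitted PDB text by an independent
brute-force pass: `fx$truth$expected_filtered` lists exactly the 54
filtered pairs.

For real structures, use `read_structure("file.pdb", "A")` (or
`fetch_pdb("4ake")` with network access) in place of the fixture
models, and `run_pipeline(run_config(...))` to get the contacts table,
per-pair metadata CSV, difference-map plot and log in one call. A thin
command-line wrapper with `compute`, `fixtures` and `summarize`
subcommands lives in `inst/cli/dcm.R`.

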