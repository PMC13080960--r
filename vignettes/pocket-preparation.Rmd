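---
title: "Pocket preparation for constrained conformer sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket preparation for constrained conformer sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crestpocket)
```

## The problem

Semiempirical conformer–rotamer ensemble sampling of a protein-bound ligand
(with CREST or a similar engine) cannot operate on a whole protein: the
practical system size is a few hundred atoms. The preparation problem is to
carve, around a posed ligand, a pocket that is (a) large enough to represent
the binding environment, (b) small enough to be tractable, and (c) chemically
closed — no dangling valences, no floating fragments, correct protonation and
total charge — and then to hold the protein scaffold fixed while the ligand
samples conformations. `crestpocket` implements that preparation plus the
inverse bookkeeping problem afterwards: CREST's xyz output has lost all
residue annotation, which must be restored positionally from the template.

## The procedure and its assumptions

The pocket is defined purely geometrically, by distance shells around the
ligand, then repaired chemically. The underlying assumptions are:

* the ligand pose is trusted — it arrives in MOL2 with 3D coordinates inside
  the pocket and with its own hydrogens and bond orders; it is never
  re-protonated;
* a distance criterion is an adequate pocket definition (no energetic or
  druggability scoring);
* residues are the right unit of chemical completeness: selections are
  completed to full residues (identity = chain, number, insertion code,
  name), and residues with no covalent link to any other residue are
  considered debris and removed;
* covalent structure can be recovered from geometry: two atoms are bonded
  when their distance does not exceed the sum of covalent radii plus
  0.45 Å, a standard heuristic; CONECT records, when present, are kept.

## Tunable parameters

All knobs live in `pipeline_config()`:

| parameter | default | unit | role |
|---|---|---|---|
| `max_ligand_atoms` | 120 | atoms | size gate; larger ligands push pockets past the ≈500-atom engine limit |
| `initial_radius` | 3.0 | Å | first selection shell around the ligand |
| `radius_step` | 0.5 | Å | shell growth per expansion |
| `min_pocket_atoms` | 70 | atoms | raw shell size that stops expansion |
| `max_expansion_attempts` | 50 | – | hard cap on expansions |
| `cap_extension_radius` | 2.6 | Å | pulls in cap-like neighbour atoms of cut residues |
| `isolation_cutoff` | 1.9 | Å | atoms with no neighbour within this distance are dropped |
| `keep_altloc` | "A" | – | alternate location retained besides blanks |
| `protonation_ph` | 7.4 | pH | handed to the protonation backend |
| `crest_temp` | "310" | K | CREST temperature argument |
| `crest_level` | "gfnff" | – | CREST level of theory flag |
| `crest_extra` | "-squick" | – | extra CREST arguments, whitespace-tokenized |

The defaults are the published behaviour of the method and are not tuned by
this package. Counts (70, 120) are raw atom counts including any hydrogens
present in the input; the 70-atom test applies to the shell *before* residue
completion.

## Numerical and contract choices

* **Boundary inclusivity.** "Within r" is implemented as `≤ r` everywhere
  (shell, caps, isolation). The choice is encoded in the brute-force oracle
  too, so tests pin it down; probes at 2.99/3.01 Å resolve it explicitly.
* **Expansion bookkeeping.** `iterations_used` counts expansions beyond the
  initial radius, so `final_radius = 3.0 + 0.5 × iterations_used`; a shell
  that is large enough immediately reports 0 iterations. A starved protein
  stops after exactly 50 expansions with a warning flag rather than an error.
* **Cap extension is atom-level.** Re-completing the 2.6 Å shell to full
  residues would re-inflate the pocket; the step exists to pick up terminal
  cap-like groups only.
* **Isolation removal is single-pass.** A pair of mutually-near stragglers
  survives it by design; the connectivity filter downstream removes any
  remaining fragment that is not covalently attached to another residue.
* **Waters** are excluded only where the procedure says so: at cap extension
  and (in practice) by the connectivity filter. They are not pre-stripped and
  may legitimately sit in the initial shell.
* **Order of operations is enforced**: dehydrogenate → perceive connectivity
  → drop unconnected residues → protonate. Hydrogens are added only after
  filtering so that their placement reflects the final heavy-atom
  environment; the pipeline writes the pre-protonation pocket
  (`pocket_connected.pdb`) so this is auditable.
* **Degenerate inputs.** An empty protein or a pocket that vanishes in the
  connectivity filter produces an empty structure with a loud warning at the
  operation level and a stage error at the pipeline level. A conformer count
  of zero at the write stage is an error, as is a frame whose element at any
  position disagrees with the template (a guard against silently reordered
  engine output).
* **Duplicate atom serials** are tolerated on read (kept, warned about);
  CONECT records resolve to the first occurrence. Serials above 99999 are
  renumbered on write with a warning.
* **PDB dialect**: strict fixed columns on write; tolerant on read with a
  whitespace fallback for drifting coordinate columns, because the altLoc
  logic is inherently column-17-based while real files drift elsewhere.

## Protonation backend

The published workflow delegates hydrogenation to Open Babel's pH model.
Re-implementing pKa prediction is out of scope, so protonation is a
pluggable backend behind `protonate(s, ph, backend)`. The default,
`protonation_backend_builtin()`, is a deterministic valence-based
protonator: after greedy bond-order assignment it fills each heavy atom's
standard valence with hydrogens, with two pH rules keyed to typical pKa
values — carboxylate oxygens stay bare above pH ≈ 4.8, primary sp3 amines
gain three hydrogens (+1) below pH ≈ 10.6. Hydrogen positions are placed
deterministically on a cone away from existing neighbours, so repeat runs
are byte-identical. `protonation_backend_obabel()` shells out to `obabel`
when available and errors actionably when not.

Bond-order promotion is deliberately restricted to bonds with exactly one
oxygen endpoint (C=O, S=O, P=O, N=O): from a distance-perceived single-bond
skeleton, a valence deficit on carbon is indistinguishable from missing
hydrogens, so promoting C=C or C=N would misassign chemistry far more often
than it would recover it. Consequences: isolated alkene/imine double bonds
are not perceived, histidine tautomers and guanidinium groups are not
treated specially, and metals receive charge 0 with a warning. These are
accepted limitations, not bugs; the formal-charge bookkeeping covers H, C,
N, O, S, P and halogens.

## The constraint file and command

Non-ligand atoms are identified by residue name in the merged structure
(pocket atoms first, ligand last, serials renumbered from 1 — the merged
file's atom order is the single source of truth for index meaning).
Indices are 1-based and compressed to maximal runs (`"1-6,8-10"`), with an
ASCII hyphen as separator. `constraints.inp` mirrors the layout of the
constraint generator's own sample output: a `$constrain` block with the atom
ranges, a force constant of 0.5 and the reference structure, and a
`$metadyn` block listing the free (ligand) atoms. The force constant is the
generator's conventional default; the source publication does not state one.
Extra CREST arguments are whitespace-tokenized and never shell-interpreted.

## What the synthetic generator emulates — and what it does not

`make_complex()` builds a ligand as a compact self-avoiding random walk and
lays protein atoms down as connected peptide-like chains (N/CA/C/O repeating,
1.45 Å steps) walking tangentially around the ligand. The key property is
*exactness*: each atom's minimum distance to the ligand atom set is solved
by 1-D root finding to its target value, so the configured cumulative shell
counts hold exactly — a 69-atom shell at 3 Å plus one atom at 3.1 Å is
constructible by construction, which is what makes the expansion-count and
boundary tests meaningful. Injected pathologies: altLoc A/B twins, missing
element columns, stray isolated atoms, floating residues, waters; all
pathology atoms are placed beyond the largest configured radius so the shell
counts stay exact.

What it does not emulate: real amino-acid side chains and their naming, real
backbone geometry (the chains are distance-plausible but not
Ramachandran-plausible), crystallographic noise, and force-field-quality
sterics (on crowded shells the generator relaxes its self-avoidance from
2.4 Å down to 1.0 Å before giving up, so an occasional extra contact bond can
appear). A green pocket-extraction test therefore establishes geometric
correctness of the selection algorithm against an independent brute-force
oracle — not that the chemistry of a real pocket would be prepared perfectly.
The oracle (`brute_force_pocket()`) shares no code with the implementation:
explicit nested loops over all atom pairs, compared for exact serial-set
equality across randomized fixtures.

## Known limitations

* No cavity detection: a bound ligand pose is required.
* pKa prediction, tautomers, His flips and ligand (re)protonation are out of
  scope by design; plug in an external backend where that matters.
* The connectivity filter can delete a pocket consisting of a single
  isolated residue entirely; this surfaces as a loud warning and a pipeline
  stage failure rather than a silent guess.
* CREST itself is treated as an external oracle: energies, ensemble weights
  and sampling quality are never parsed or asserted.
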