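# crestpocket

Preparing a protein–ligand binding pocket for semiempirical conformational
sampling with [CREST](https://crest-lab.github.io/) is a fiddly, error-prone
chore: the pocket has to be carved out of the full protein, truncated residues
must stay chemically sensible, hydrogens and charges must be assigned at a
physiological pH, the protein scaffold must be frozen with atom-index
constraints, and CREST's conformer output loses all residue annotation on the
way through xyz format. `crestpocket` automates the whole preparation and
post-processing round trip as an R package with a command-line entry point.

It is aimed at computational chemists and structural bioinformaticians who
have a protein structure (PDB) and a docked or crystallographic ligand pose
(TRIPOS MOL2) and want a reproducible, constrained conformer-rotamer ensemble
search of the bound ligand and its local environment.

## The algorithm

Starting from a protein `P` and a posed ligand `L` (all distances in Å):

1. **Size gate** — refuse ligands with more than 120 atoms (pockets around
   larger ligands typically exceed CREST's ≈500-atom practical limit).
2. **Shell selection** — select every protein atom within `r = 3.0` of any
   ligand atom: `S(r) = { a ∈ P : min_{b∈L} ‖a−b‖ ≤ r }`. While
   `|S(r)| < 70`, grow `r` by 0.5 (at most 50 expansions).
3. **Residue completion** — extend `S` to every atom of each touched residue.
4. **Cap extension** — add protein atoms within 2.6 of the preliminary
   pocket (excluding ligand and water), picking up the N-methyl/acetyl-like
   capping groups of cut residues; this added shell is *not* re-completed.
5. **Cleanup** — drop atoms with no neighbour within 1.9; strip hydrogens,
   perceive bonds from covalent radii (+0.45 tolerance, CONECT respected),
   and delete residues with no covalent link to another residue.
6. **Protonation & charge** — re-hydrogenate at pH 7.4 (pluggable backend),
   merge with the ligand, and compute the total formal charge by valence
   bookkeeping.
7. **CREST interface** — write `constraints.inp` holding every non-ligand
   atom fixed (compressed index ranges, e.g. `1,2,3,…,8,9,10 → "1-6,8-10"`),
   assemble and optionally run the CREST command (defaults `--gfnff`,
   `--temp 310`, `-squick`), then transfer the template's atom/residue
   metadata onto every conformer frame of the output ensemble.

All thresholds live in one `pipeline_config()` object.

## Worked example

The package ships a deterministic synthetic-complex generator, so the example
is fully self-contained:

```r
library(crestpocket)

fx <- make_complex(fixture_spec(seed = 42, shell_counts = c("3" = 72),
                                n_waters = 2))
writeLines(fx$protein_pdb, "protein.pdb")
writeLines(fx$ligand_mol2, "ligand.mol2")

prot <- filter_altloc(guess_elements(parse_pdb(fx$protein_pdb)))
lig  <- parse_mol2(fx$ligand_mol2)

ps <- extract_pocket(prot, lig)
ps
#> pocket_selection: 72 atoms in 20 residues (radius 3.0 A after 0 expansion(s))

s <- filter_connected_residues(perceive_bonds(strip_hydrogens(ps$structure)))
m <- merge_structures(protonate(s), lig)
m
#> structure3d: 178 atoms, 182 bonds (synthetic complex fixture)
compute_formal_charge(m)
#> charge_report: total formal charge +7 over 21 residue(s)
compress_ranges(constrained_atom_indices(m, "LIG"))
#> [1] "1-161"
```

72 pocket atoms were found already at the initial 3.0 Å shell (0 expansions);
after protonation the merged complex has 178 atoms, of which the first 161
(the pocket) are constrained and the last 17 (the ligand) stay free. The +7
formal charge comes from the protonated chain-terminal amines of the
synthetic pocket fragments.

The same run through the pipeline driver (here with a mock CREST runner):

```r
xyz <- make_mock_xyz(m, n_frames = 3)
run_pipeline("protein.pdb", "ligand.mol2", "run1",
             runner = crest_runner_mock(xyz))
list.files("run1")
#> [1] "constraints.inp"              "crest_conformers_updated.pdb"
#> [3] "crest_conformers.pdb"         "crest_conformers.xyz"
#> [5] "crest.out"                    "final_complex.pdb"
#> [7] "pocket_connected.pdb"         "run_manifest.json"
#> [9] "test_pocket_extended.pdb"
```

`constraints.inp` for this run:

```
$constrain
  atoms: 1-161
  force constant=0.5
  reference=final_complex.pdb
$metadyn
  atoms: 162-178
$end
```

`crest_conformers_updated.pdb` holds the conformers as MODEL/ENDMDL blocks
with the template's atom names, residue names and numbers restored;
`crest_conformers.pdb` is the un-annotated conversion; `crest.out` the
captured log.

From the command line:

```sh
Rscript inst/cli/crestpocket protein.pdb ligand.mol2 run1 \
    [--no-crest] [--temp 310] [--lvl-of-theory gfnff] \
    [--extra-crest-arguments "-squick"]
```

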