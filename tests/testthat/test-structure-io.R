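# PDB/MOL2 parsing, element guessing, altLoc filtering, round trips.

test_that("parse_pdb handles empty, single-atom and CONECT input", {
  expect_equal(n_atoms(parse_pdb("")), 0)
  expect_equal(nrow(parse_pdb("")$bonds), 0)

  s <- parse_pdb(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C")
  expect_equal(n_atoms(s), 1)
  expect_equal(unname(unlist(s$atoms[1, c("x", "y", "z")])), c(1, 2, 3))
  expect_equal(s$atoms$atom_name, "CA")
  expect_equal(s$atoms$element, "C")

  # 5 atoms, CONECT stated in both directions -> exactly one bond {1,2}
  fix <- c(
    sprintf("ATOM  %5d  C%d  GLY A   1       %.3f   0.000   0.000  1.00  0.00           C",
            1:5, 1:5, (1:5) * 1.5),
    "CONECT    1    2",
    "CONECT    2    1")
  s <- parse_pdb(fix)
  expect_equal(n_atoms(s), 5)
  expect_equal(nrow(s$bonds), 1)
  expect_equal(c(s$bonds$a, s$bonds$b), c(1L, 2L))
})

test_that("parse_pdb errors on malformed coordinates, warns on duplicate serials", {
  bad <- "ATOM      1  CA  ALA A   1       xx.000   2.000   3.000"
  expect_error(parse_pdb(bad), "line 1")

  dup <- c(
    "ATOM      7  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      7  CB  ALA A   1       2.000   2.000   3.000  1.00  0.00           C")
  expect_warning(s <- parse_pdb(dup), "duplicate")
  expect_equal(n_atoms(s), 2)
})

test_that("guess_elements infers from PDB naming conventions and is conservative", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 1HB  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "HETATM    3 CA    CA A   2       2.000   0.000   0.000  1.00  0.00",
    "HETATM    4 FE   HEM A   3       3.000   0.000   0.000  1.00  0.00",
    "ATOM      5  N   ALA A   1       4.000   0.000   0.000  1.00  0.00",
    "ATOM      6  OXT ALA A   1       5.000   0.000   0.000  1.00  0.00")
  s <- guess_elements(parse_pdb(lines))
  expect_equal(s$atoms$element, c("C", "H", "Ca", "Fe", "N", "O"))

  # pre-set elements are never touched, even when the name disagrees
  s2 <- parse_pdb(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           N")
  expect_equal(guess_elements(s2)$atoms$element, "N")
})

test_that("filter_altloc keeps blank + chosen, is idempotent, counts check out", {
  xyz <- matrix(seq_len(30), ncol = 3)
  s <- test_structure(xyz, alt_loc = c(" ", "A", "B", " ", "B", " ",
                                       "B", "A", " ", "B"))
  f1 <- suppressWarnings(filter_altloc(s))
  expect_equal(n_atoms(f1), 6)          # 10 atoms, 4 with altLoc B
  expect_true(all(f1$atoms$alt_loc %in% c(" ", "A")))
  f2 <- suppressWarnings(filter_altloc(f1))
  expect_identical(f1$atoms, f2$atoms)  # idempotent

  allblank <- test_structure(xyz)
  expect_identical(filter_altloc(allblank)$atoms, allblank$atoms)

  # atom present ONLY as altLoc B disappears, with a warning
  s3 <- test_structure(matrix(1:6, ncol = 3), alt_loc = c(" ", "B"),
                       atom_name = c("CA", "CG"))
  expect_warning(filter_altloc(s3), "only under a dropped altLoc")
})

test_that("extract_ligand_name follows the two documented fallbacks", {
  mol2 <- c("@<TRIPOS>MOLECULE", "m", " 1 0 1 0 0", "SMALL", "NO_CHARGES",
            "@<TRIPOS>ATOM",
            "      1 C1    0.0 0.0 0.0 C.3 1 MOL 0.0",
            "@<TRIPOS>SUBSTRUCTURE",
            "     1 LIG1      1 GROUP 0 **** 0 ROOT")
  expect_equal(extract_ligand_name(mol2), "LIG1")

  mol2_unnamed <- sub("1 LIG1", "1 UNNAMED", mol2)
  expect_equal(extract_ligand_name(mol2_unnamed), "MOL")

  mol2_bare <- c("@<TRIPOS>MOLECULE", "m", " 1 0 0 0 0", "SMALL",
                 "NO_CHARGES", "@<TRIPOS>ATOM",
                 "      1 C1    0.0 0.0 0.0 C.3 1 UNNAMED 0.0")
  expect_warning(nm <- extract_ligand_name(mol2_bare), "UNNAMED")
  expect_equal(nm, "UNNAMED")
  # total: any text yields a non-empty name
  expect_warning(nm2 <- extract_ligand_name("not a mol2 at all"))
  expect_equal(nm2, "UNNAMED")
})

test_that("parse_mol2 reads coordinates, charges column and ring bonds", {
  fx <- make_complex(fixture_spec(seed = 11, shell_counts = c("3" = 8),
                                  ligand_atom_count = 3))
  lig <- parse_mol2(fx$ligand_mol2)
  expect_equal(n_atoms(lig$structure), 3)
  expect_equal(coords(lig$structure), fx$truth$ligand_xyz,
               ignore_attr = TRUE, tolerance = 1e-4)

  benzene <- c(
    "@<TRIPOS>MOLECULE", "benzene", " 6 6 1 0 0", "SMALL", "USER_CHARGES",
    "@<TRIPOS>ATOM",
    sprintf("  %d C%d  %8.4f %8.4f  0.0000 C.ar 1 BNZ %7.4f",
            1:6, 1:6, 1.39 * cos((0:5) * pi / 3), 1.39 * sin((0:5) * pi / 3),
            rep(-0.06, 6)),
    "@<TRIPOS>BOND",
    sprintf(" %d %d %d ar", 1:6, 1:6, c(2:6, 1)),
    "@<TRIPOS>SUBSTRUCTURE", "  1 BNZ 1 GROUP 0 **** 0 ROOT")
  lig <- parse_mol2(benzene)
  expect_equal(n_atoms(lig$structure), 6)
  expect_equal(nrow(lig$structure$bonds), 6)
  expect_equal(lig$name, "BNZ")
  expect_true(all(lig$structure$bonds$order == 1.5))

  expect_error(parse_mol2("@<TRIPOS>MOLECULE\nm"), "ATOM")
})

test_that("write_pdb/parse_pdb round trip is identity on atoms", {
  fx <- make_complex(fixture_spec(seed = 5, shell_counts = c("3" = 40),
                                  n_waters = 1, n_isolated_atoms = 1))
  s <- suppressWarnings(guess_elements(parse_pdb(fx$protein_pdb)))
  rt <- parse_pdb(write_pdb(s))
  for (col in c("record", "serial", "atom_name", "alt_loc", "res_name",
                "chain_id", "res_seq", "i_code", "element")) {
    expect_identical(rt$atoms[[col]], s$atoms[[col]])
  }
  expect_equal(coords(rt), coords(s), tolerance = 5e-4)

  # empty structure -> header-only output, still parseable
  expect_equal(n_atoms(parse_pdb(write_pdb(structure3d()))), 0)

  # one-atom identity
  one <- test_structure(c(1.234, -5.678, 9.999), element = "N",
                        atom_name = "N")
  rt1 <- parse_pdb(write_pdb(one))
  expect_equal(coords(rt1), coords(one), tolerance = 5e-4)
  expect_identical(rt1$atoms$res_name, one$atoms$res_name)

  # serial overflow triggers renumbering with warning
  big <- one
  big$atoms$serial <- 123456L
  expect_warning(txt <- write_pdb(big), "renumbering")
  expect_equal(parse_pdb(txt)$atoms$serial, 1L)
})

test_that("200-atom pocket round trip preserves residue identity field by field", {
  fx <- make_complex(fixture_spec(seed = 9, shell_counts = c("4" = 60)))
  pre <- prepare_fixture(fx)
  rt <- parse_pdb(write_pdb(pre$protein))
  expect_identical(residue_ids(rt), residue_ids(pre$protein))
  expect_identical(rt$atoms$atom_name, pre$protein$atoms$atom_name)
})
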