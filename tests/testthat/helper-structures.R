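# Builders for small hand-made structures used across the unit tests.

# Compact structure3d constructor: xyz is an n x 3 matrix; the remaining
# vectors are recycled.
test_structure <- function(xyz, element = "C", res_seq = 1L,
                           res_name = "GLY", chain_id = "A",
                           atom_name = NULL, record = "ATOM",
                           alt_loc = " ", bonds = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  element <- rep_len(element, n)
  if (is.null(atom_name)) {
    atom_name <- paste0(element, seq_len(n))
  }
  atoms <- data.frame(
    record = rep_len(record, n), serial = seq_len(n),
    atom_name = rep_len(atom_name, n), name_raw = NA_character_,
    alt_loc = rep_len(alt_loc, n), res_name = rep_len(res_name, n),
    chain_id = rep_len(chain_id, n), res_seq = rep_len(as.integer(res_seq), n),
    i_code = " ", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, element = element,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, if (is.null(bonds)) empty_bonds_df() else bonds)
}

empty_bonds_df <- function() data.frame(a = integer(0), b = integer(0),
                                        order = numeric(0))

# single-atom ligand at the origin: the simplest distance reference
point_ligand <- function(name = "LIG") {
  ligand_spec(name, test_structure(c(0, 0, 0), element = "C",
                                   res_name = name, record = "HETATM"))
}

# parse + preprocess a generated complex, silencing expected warnings
prepare_fixture <- function(fx, keep_altloc = "A") {
  protein <- suppressWarnings(
    filter_altloc(guess_elements(parse_pdb(fx$protein_pdb)), keep_altloc))
  ligand <- parse_mol2(fx$ligand_mol2)
  list(protein = protein, ligand = ligand)
}

# a ready-to-use merged complex plus its canned CREST output
build_merged_complex <- function(seed = 3, shell = c("3" = 72),
                                 n_frames = 3L) {
  fx <- make_complex(fixture_spec(seed = seed, shell_counts = shell))
  pre <- prepare_fixture(fx)
  ps <- suppressWarnings(extract_pocket(pre$protein, pre$ligand))
  s <- filter_connected_residues(perceive_bonds(strip_hydrogens(ps$structure)))
  m <- merge_structures(suppressWarnings(protonate(s)), pre$ligand)
  list(fixture = fx, pre = pre, pocket = ps, merged = m,
       xyz = make_mock_xyz(m, n_frames = n_frames))
}
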