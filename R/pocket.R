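# Iterative distance-shell pocket extraction around a posed ligand:
# ligand-size gate, shell expansion, residue completion, cap extension
# and isolated-atom cleanup.

# Minimum Euclidean distance from each query point to a reference point
# set.  Vectorized; exact (no cutoff tricks) so it is bit-identical to a
# nested-loop scan.
min_dist_to_set <- function(query, ref) {
  if (nrow(query) == 0) return(numeric(0))
  if (nrow(ref) == 0) return(rep(Inf, nrow(query)))
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  cross <- query %*% t(ref)
  d2 <- outer(q2, r2, "+") - 2 * cross
  d2[d2 < 0] <- 0
  sqrt(apply(d2, 1, min))
}

# Row indices of protein atoms eligible for pocket selection: everything
# that is not the ligand itself (matched by residue name, in case the
# protein file carries a copy of the posed ligand as HETATM records).
protein_candidate_idx <- function(protein, ligand) {
  if (n_atoms(protein) == 0) return(integer(0))
  lig_res <- toupper(substr(ligand$name, 1, 4))
  which(toupper(protein$atoms$res_name) != lig_res)
}

#' Ligand-size gate
#'
#' The pipeline refuses ligands above `max_ligand_atoms` atoms (default
#' 120), since larger ligands tend to produce pockets beyond the roughly
#' 500-atom practical limit of CREST; a zero-atom ligand fails as "not
#' present".
#'
#' @param ligand [ligand_spec()]
#' @param cfg [pipeline_config()]
#' @return list with elements `pass` (logical) and `message`.
#' @export
check_ligand_size <- function(ligand, cfg = pipeline_config()) {
  n <- n_atoms(ligand$structure)
  if (n < 1) {
    return(list(pass = FALSE, message = "ligand not present (0 atoms)"))
  }
  if (n > cfg$max_ligand_atoms) {
    return(list(
      pass = FALSE,
      message = sprintf(
        paste0("ligand has %d atoms (> %d); pockets around ligands this ",
               "large typically exceed CREST's ~500-atom practical limit"),
        n, cfg$max_ligand_atoms)
    ))
  }
  list(pass = TRUE, message = sprintf("ligand size ok (%d atoms)", n))
}

#' Select the distance shell around the ligand
#'
#' Returns the row indices (into `protein$atoms`) of every protein atom
#' whose minimum distance to any ligand atom is less than or equal to
#' `radius` (inclusive boundary).  Atoms of a residue named like the
#' ligand are never included.
#'
#' @param protein structure3d
#' @param ligand [ligand_spec()]
#' @param radius shell radius in Angstrom.
#' @return integer atom row indices, increasing.
#' @export
select_shell <- function(protein, ligand, radius) {
  cand <- protein_candidate_idx(protein, ligand)
  if (length(cand) == 0 || n_atoms(ligand$structure) == 0) return(integer(0))
  d <- min_dist_to_set(coords(protein)[cand, , drop = FALSE],
                       coords(ligand$structure))
  cand[d <= radius]
}

#' Iteratively expand the selection shell
#'
#' Starts at `initial_radius` and grows by `radius_step` until the shell
#' holds at least `min_pocket_atoms` atoms or `max_expansion_attempts`
#' expansions have been made.  The iteration count is the number of
#' expansions beyond the initial radius (0 when the first shell is
#' already large enough).
#'
#' @inheritParams select_shell
#' @param cfg [pipeline_config()]
#' @return list: `idx` (atom row indices), `final_radius`,
#'   `iterations_used`, `starved` (TRUE when the atom target was never
#'   reached).
#' @export
iterative_expand <- function(protein, ligand, cfg = pipeline_config()) {
  if (n_atoms(protein) == 0) {
    warning("iterative_expand: empty protein; empty selection")
    return(list(idx = integer(0), final_radius = cfg$initial_radius,
                iterations_used = 0L, starved = TRUE))
  }
  for (it in 0:cfg$max_expansion_attempts) {
    radius <- cfg$initial_radius + cfg$radius_step * it
    idx <- select_shell(protein, ligand, radius)
    if (length(idx) >= cfg$min_pocket_atoms) {
      return(list(idx = idx, final_radius = radius,
                  iterations_used = as.integer(it), starved = FALSE))
    }
    if (it == cfg$max_expansion_attempts) {
      warning(sprintf(
        "iterative_expand: %d expansion attempts exhausted at %.1f A with %d atoms (< %d)",
        cfg$max_expansion_attempts, radius, length(idx),
        cfg$min_pocket_atoms))
      return(list(idx = idx, final_radius = radius,
                  iterations_used = as.integer(it), starved = TRUE))
    }
  }
}

#' Complete a selection to full residues
#'
#' Extends an atom selection to every atom of each touched residue
#' (residue identity: chain, number, insertion code and name).
#' Extensive and idempotent.
#'
#' @param protein structure3d
#' @param selected_idx integer atom row indices.
#' @return integer atom row indices (superset of the input), increasing.
#' @export
complete_residues <- function(protein, selected_idx) {
  if (length(selected_idx) == 0) return(integer(0))
  rid <- residue_ids(protein)
  which(rid %in% unique(rid[selected_idx]))
}

#' Cap extension around a preliminary pocket
#'
#' Adds every protein atom within `cap_extension_radius` (default 2.6 A)
#' of any preliminary-pocket atom, excluding ligand atoms and water
#' residues.  The added shell is atom-level: it is not completed to full
#' residues, because its purpose is to pick up cap-like terminal groups
#' (N-methyl/acetyl-like neighbours) of the cut residues.
#'
#' @param protein structure3d
#' @param pocket_idx residue-complete preliminary pocket (row indices).
#' @param ligand [ligand_spec()]
#' @param cfg [pipeline_config()]
#' @return integer atom row indices, increasing.
#' @export
extend_caps <- function(protein, pocket_idx, ligand, cfg = pipeline_config()) {
  if (length(pocket_idx) == 0) return(integer(0))
  cand <- setdiff(protein_candidate_idx(protein, ligand), pocket_idx)
  cand <- cand[!(toupper(protein$atoms$res_name[cand]) %in% cfg$water_res_names)]
  if (length(cand) == 0) return(sort(pocket_idx))
  d <- min_dist_to_set(coords(protein)[cand, , drop = FALSE],
                       coords(protein)[pocket_idx, , drop = FALSE])
  sort(c(pocket_idx, cand[d <= cfg$cap_extension_radius]))
}

#' Remove isolated atoms from a selection
#'
#' Drops every atom whose nearest neighbour within the selection is
#' farther than `isolation_cutoff` (default 1.9 A).  A single pass over
#' the input set: a pair of mutually-near stragglers survives here and is
#' left to the connectivity filter downstream.
#'
#' @param protein structure3d
#' @param idx integer atom row indices.
#' @param cfg [pipeline_config()]
#' @return integer atom row indices, increasing.
#' @export
remove_isolated_atoms <- function(protein, idx, cfg = pipeline_config()) {
  if (length(idx) <= 1) return(integer(0))
  xyz <- coords(protein)[idx, , drop = FALSE]
  d2 <- as.matrix(stats::dist(xyz))^2
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  sort(idx[nn <= cfg$isolation_cutoff])
}

#' Extract the binding pocket
#'
#' Full pocket-carving pass: ligand-size gate, iterative shell expansion,
#' residue completion, cap extension, isolated-atom cleanup.  When
#' `outdir` is given the pocket is written there as
#' `test_pocket_extended.pdb`.
#'
#' @param protein preprocessed structure3d (elements fixed, altLoc
#'   filtered).
#' @param ligand [ligand_spec()]
#' @param cfg [pipeline_config()]
#' @param outdir optional directory for `test_pocket_extended.pdb`.
#' @return object of class `pocket_selection`: `structure` (the pocket as
#'   structure3d), `idx` (row indices into the protein), `final_radius`,
#'   `iterations_used`, `starved`, `residues`.
#' @export
extract_pocket <- function(protein, ligand, cfg = pipeline_config(),
                           outdir = NULL) {
  gate <- check_ligand_size(ligand, cfg)
  if (!gate$pass) stop("extract_pocket: ", gate$message)
  shell <- iterative_expand(protein, ligand, cfg)
  idx <- complete_residues(protein, shell$idx)
  idx <- extend_caps(protein, idx, ligand, cfg)
  idx <- remove_isolated_atoms(protein, idx, cfg)
  pocket <- subset_structure(protein, idx)
  if (!is.null(outdir)) {
    write_pdb(pocket, file.path(outdir, "test_pocket_extended.pdb"))
  }
  structure(
    list(structure = pocket, idx = idx,
         final_radius = shell$final_radius,
         iterations_used = shell$iterations_used,
         starved = shell$starved,
         residues = unique(residue_ids(pocket))),
    class = "pocket_selection"
  )
}

#' @export
print.pocket_selection <- function(x, ...) {
  cat(sprintf(
    "pocket_selection: %d atoms in %d residues (radius %.1f A after %d expansion(s)%s)\n",
    n_atoms(x$structure), length(x$residues), x$final_radius,
    x$iterations_used, if (x$starved) ", starved" else ""))
  invisible(x)
}
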