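# Core containers: an ordered atom table plus an explicit bond list.
# Atoms are stored as a data.frame (one row per ATOM/HETATM record) and
# bonds as an unordered pair list over atom serial numbers.

ATOM_COLUMNS <- c(
  "record", "serial", "atom_name", "name_raw", "alt_loc", "res_name",
  "chain_id", "res_seq", "i_code", "x", "y", "z", "occupancy",
  "b_factor", "element"
)

#' Build an empty atom table
#' @keywords internal
empty_atoms <- function() {
  data.frame(
    record = character(0), serial = integer(0), atom_name = character(0),
    name_raw = character(0), alt_loc = character(0), res_name = character(0),
    chain_id = character(0), res_seq = integer(0), i_code = character(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    occupancy = numeric(0), b_factor = numeric(0), element = character(0),
    stringsAsFactors = FALSE
  )
}

empty_bonds <- function() {
  data.frame(a = integer(0), b = integer(0), order = numeric(0))
}

#' Construct a molecular structure
#'
#' @param atoms data.frame with the atom columns (see [empty_atoms()]);
#'   missing optional columns are filled with defaults.
#' @param bonds data.frame with integer columns `a`, `b` (atom serials)
#'   and optionally `order`; pairs are stored unordered with `a < b`.
#' @param title free-text title.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms = empty_atoms(), bonds = empty_bonds(),
                        title = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(
    record = "ATOM", alt_loc = " ", chain_id = "A", i_code = " ",
    occupancy = 1.00, b_factor = 0.00, element = "", name_raw = NA_character_
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]]) && nrow(atoms) > 0) atoms[[nm]] <- defaults[[nm]]
  }
  if (nrow(atoms) > 0) {
    atoms$serial <- as.integer(atoms$serial)
    atoms$res_seq <- as.integer(atoms$res_seq)
    if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
        any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
        any(!is.finite(atoms$z))) {
      stop("structure3d: non-finite coordinates")
    }
    if (any(is.na(atoms$name_raw))) {
      atoms$name_raw <- ifelse(is.na(atoms$name_raw),
                               pdb_justify_name(atoms$atom_name, atoms$element),
                               atoms$name_raw)
    }
    rownames(atoms) <- NULL
  }
  bonds <- normalize_bonds(bonds)
  if (nrow(bonds) > 0 && nrow(atoms) > 0) {
    known <- unique(atoms$serial)
    bad <- !(bonds$a %in% known) | !(bonds$b %in% known)
    if (any(bad)) stop("structure3d: bond endpoint names unknown atom serial")
  }
  structure(list(atoms = atoms, bonds = bonds, title = title),
            class = "structure3d")
}

# Deduplicate and orient bond pairs (a < b), drop self bonds.
normalize_bonds <- function(bonds) {
  if (is.null(bonds) || nrow(bonds) == 0) return(empty_bonds())
  bonds <- as.data.frame(bonds)
  if (is.null(bonds$order)) bonds$order <- 1
  a <- pmin(bonds$a, bonds$b)
  b <- pmax(bonds$a, bonds$b)
  keep <- a != b
  out <- data.frame(a = as.integer(a[keep]), b = as.integer(b[keep]),
                    order = as.numeric(bonds$order[keep]))
  out <- out[!duplicated(out[, c("a", "b")]), , drop = FALSE]
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d bonds%s\n",
              nrow(x$atoms), nrow(x$bonds),
              if (nzchar(x$title)) paste0(" (", x$title, ")") else ""))
  invisible(x)
}

#' Number of atoms in a structure
#' @param s structure3d
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Residue identity keys
#'
#' A residue is identified by chain, residue number, insertion code and
#' residue name together; insertion codes participate so that completion
#' to "full residues" is correct on structures that use them.
#'
#' @param atoms atom data.frame (or a structure3d).
#' @return character vector, one key per atom row.
#' @export
residue_ids <- function(atoms) {
  if (inherits(atoms, "structure3d")) atoms <- atoms$atoms
  if (nrow(atoms) == 0) return(character(0))
  paste(atoms$chain_id, atoms$res_seq, atoms$i_code, atoms$res_name,
        sep = "|")
}

#' Coordinates as an n x 3 matrix
#' @param s structure3d or atom data.frame
#' @export
coords <- function(s) {
  if (inherits(s, "structure3d")) s <- s$atoms
  cbind(x = s$x, y = s$y, z = s$z)
}

#' Subset a structure by atom row indices
#'
#' Keeps only bonds whose both endpoints survive.
#'
#' @param s structure3d
#' @param idx integer row indices into `s$atoms` (order-preserving
#'   subsets expected).
#' @export
subset_structure <- function(s, idx) {
  atoms <- s$atoms[idx, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- s$bonds
  if (nrow(bonds) > 0) {
    keep <- bonds$a %in% atoms$serial & bonds$b %in% atoms$serial
    bonds <- bonds[keep, , drop = FALSE]
  }
  structure3d(atoms, bonds, s$title)
}

#' Ligand specification
#'
#' Couples a ligand structure with the residue-name identifier used to
#' tag its atoms downstream.  An empty name falls back to "UNNAMED".
#'
#' @param name ligand residue identifier.
#' @param structure structure3d with the ligand atoms.
#' @export
ligand_spec <- function(name, structure) {
  if (is.null(name) || !nzchar(trimws(name))) name <- "UNNAMED"
  structure(list(name = name, structure = structure), class = "ligand_spec")
}

#' @export
print.ligand_spec <- function(x, ...) {
  cat(sprintf("ligand_spec '%s': %d atoms\n", x$name, n_atoms(x$structure)))
  invisible(x)
}
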