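# TRIPOS MOL2 parsing: MOLECULE, ATOM, BOND and SUBSTRUCTURE sections.

mol2_sections <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  hdr <- grep("^@<TRIPOS>", lines)
  sections <- list()
  if (length(hdr) == 0) return(sections)
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    name <- toupper(sub("^@<TRIPOS>", "", trimws(lines[hdr[k]])))
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[!grepl("^\\s*#", body)]
    body <- body[nzchar(trimws(body))]
    # a section can occur more than once; keep the first
    if (is.null(sections[[name]])) sections[[name]] <- body
  }
  sections
}

valid_subst_name <- function(x) {
  !is.null(x) && length(x) == 1 && nzchar(x) && toupper(x) != "UNNAMED"
}

#' Extract the ligand name from MOL2 text
#'
#' The name is taken from the line immediately following
#' `@<TRIPOS>SUBSTRUCTURE` (the substructure name field).  If that is
#' missing or "UNNAMED", the substructure name used in the ATOM section
#' is tried with the same validity check.  If neither yields a usable
#' name, "UNNAMED" is returned with a warning.  Always returns a
#' non-empty string.
#'
#' @param mol2_text MOL2 text (string or lines).
#' @return ligand name.
#' @export
extract_ligand_name <- function(mol2_text) {
  sec <- mol2_sections(mol2_text)
  # first fallback level: SUBSTRUCTURE record (subst_id subst_name ...)
  if (!is.null(sec$SUBSTRUCTURE) && length(sec$SUBSTRUCTURE) >= 1) {
    toks <- strsplit(trimws(sec$SUBSTRUCTURE[1]), "\\s+")[[1]]
    nm <- if (length(toks) >= 2 && grepl("^[0-9]+$", toks[1])) {
      toks[2]
    } else if (length(toks) >= 1) {
      toks[1]
    } else {
      ""
    }
    if (valid_subst_name(nm)) return(nm)
  }
  # second fallback level: substructure name column of the ATOM section
  if (!is.null(sec$ATOM) && length(sec$ATOM) >= 1) {
    toks <- strsplit(trimws(sec$ATOM[1]), "\\s+")[[1]]
    if (length(toks) >= 8 && valid_subst_name(toks[8])) return(toks[8])
  }
  warning("extract_ligand_name: no usable substructure name found; ",
          "using \"UNNAMED\"")
  "UNNAMED"
}

mol2_bond_order <- function(type) {
  vapply(tolower(type), function(t) {
    switch(t, "1" = 1, "2" = 2, "3" = 3, "am" = 1, "ar" = 1.5,
           "du" = 1, "un" = 1, "nc" = 0, 1)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Parse a TRIPOS MOL2 ligand
#'
#' Reads the ATOM section (coordinates, SYBYL atom types, substructure
#' membership) and the BOND section (with bond orders; aromatic bonds
#' count 1.5).  Partial charges, if present, are ignored for geometry.
#'
#' @param mol2_text MOL2 text (string or lines).
#' @return a [ligand_spec()].
#' @export
parse_mol2 <- function(mol2_text) {
  sec <- mol2_sections(mol2_text)
  if (is.null(sec$ATOM) || length(sec$ATOM) == 0) {
    stop("parse_mol2: missing @<TRIPOS>ATOM section")
  }
  name <- suppressWarnings(extract_ligand_name(mol2_text))
  n <- length(sec$ATOM)
  serial <- integer(n); anm <- character(n)
  xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
  elem <- character(n); resq <- integer(n)
  for (k in seq_len(n)) {
    toks <- strsplit(trimws(sec$ATOM[k]), "\\s+")[[1]]
    if (length(toks) < 6) {
      stop(sprintf("parse_mol2: malformed ATOM line %d", k))
    }
    serial[k] <- int_or_na(toks[1])
    anm[k] <- toks[2]
    xs[k] <- num_or_na(toks[3]); ys[k] <- num_or_na(toks[4])
    zs[k] <- num_or_na(toks[5])
    if (is.na(xs[k]) || is.na(ys[k]) || is.na(zs[k])) {
      stop(sprintf("parse_mol2: malformed coordinates on ATOM line %d", k))
    }
    # SYBYL type like "C.3", "O.co2", "N.ar" -> element before the dot
    elem[k] <- canonical_element(sub("\\..*$", "", toks[6]))
    resq[k] <- if (length(toks) >= 7) int_or_na(toks[7]) else 1L
    if (is.na(resq[k])) resq[k] <- 1L
  }
  bonds <- empty_bonds()
  if (!is.null(sec$BOND) && length(sec$BOND) > 0) {
    ba <- integer(0); bb <- integer(0); bo <- numeric(0)
    for (ln in sec$BOND) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(toks) >= 3) {
        ba <- c(ba, int_or_na(toks[2]))
        bb <- c(bb, int_or_na(toks[3]))
        bo <- c(bo, if (length(toks) >= 4) mol2_bond_order(toks[4]) else 1)
      }
    }
    bonds <- data.frame(a = ba, b = bb, order = bo)
  }
  res_name <- toupper(substr(name, 1, 4))
  atoms <- data.frame(
    record = "HETATM", serial = serial, atom_name = anm,
    name_raw = NA_character_, alt_loc = " ", res_name = res_name,
    chain_id = " ", res_seq = resq, i_code = " ",
    x = xs, y = ys, z = zs, occupancy = 1.00, b_factor = 0.00,
    element = elem, stringsAsFactors = FALSE
  )
  title <- if (!is.null(sec$MOLECULE) && length(sec$MOLECULE) >= 1) {
    trimws(sec$MOLECULE[1])
  } else {
    ""
  }
  ligand_spec(name, structure3d(atoms, bonds, title))
}
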