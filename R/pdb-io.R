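# Column-exact PDB reading and writing.
#
# Reading is tolerant: fixed columns are tried first, with a whitespace
# fallback for coordinate fields, because real-world PDB files drift.
# Writing is strict fixed-column, since downstream logic (altLoc in
# column 17, element in 77-78) is column based.

substr_or <- function(line, start, stop) {
  if (nchar(line) < start) return("")
  substr(line, start, min(stop, nchar(line)))
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))
int_or_na <- function(x) suppressWarnings(as.integer(x))

#' Parse PDB-format text
#'
#' Reads ATOM/HETATM records into an atom table and CONECT records into a
#' deduplicated unordered bond list.  Other record types are skipped.
#' Duplicate serial numbers are tolerated with a warning (both atoms are
#' kept; CONECT records resolve to the first atom carrying a serial).
#'
#' @param text a single string or a character vector of lines.
#' @return a [structure3d()].
#' @export
#' @examples
#' s <- parse_pdb(c(
#'   "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C"
#' ))
#' n_atoms(s)
parse_pdb <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  rec6 <- toupper(substr(lines, 1, 6))
  is_atom <- rec6 %in% c("ATOM  ", "HETATM") |
    toupper(substr(lines, 1, 5)) == "ATOM " |
    (nchar(lines) >= 4 & toupper(substr(lines, 1, 4)) == "ATOM" &
       nchar(lines) == 4)
  is_atom <- grepl("^(ATOM|HETATM)", lines, ignore.case = FALSE)
  atom_idx <- which(is_atom)
  conect_idx <- which(grepl("^CONECT", lines))

  if (length(atom_idx) == 0) {
    return(structure3d(title = pdb_title(lines)))
  }

  n <- length(atom_idx)
  rec <- character(n); serial <- integer(n); name_raw <- character(n)
  alt <- character(n); resn <- character(n); chain <- character(n)
  resq <- integer(n); icode <- character(n)
  xs <- numeric(n); ys <- numeric(n); zs <- numeric(n)
  occ <- numeric(n); bfac <- numeric(n); elem <- character(n)

  for (k in seq_len(n)) {
    i <- atom_idx[k]
    ln <- lines[i]
    rec[k] <- if (grepl("^HETATM", ln)) "HETATM" else "ATOM"
    serial[k] <- int_or_na(substr_or(ln, 7, 11))
    name_raw[k] <- formatC(substr_or(ln, 13, 16), width = 4, flag = "-")
    alt[k] <- substr_or(ln, 17, 17)
    if (!nzchar(alt[k])) alt[k] <- " "
    resn[k] <- trimws(substr_or(ln, 18, 21))
    chain[k] <- substr_or(ln, 22, 22)
    if (!nzchar(chain[k])) chain[k] <- " "
    resq[k] <- int_or_na(substr_or(ln, 23, 26))
    icode[k] <- substr_or(ln, 27, 27)
    if (!nzchar(icode[k])) icode[k] <- " "
    xs[k] <- num_or_na(substr_or(ln, 31, 38))
    ys[k] <- num_or_na(substr_or(ln, 39, 46))
    zs[k] <- num_or_na(substr_or(ln, 47, 54))
    if (is.na(xs[k]) || is.na(ys[k]) || is.na(zs[k])) {
      # whitespace fallback: records written without strict columns
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      numtok <- num_or_na(toks)
      cand <- which(!is.na(numtok))
      # take the first run of >=3 consecutive numeric tokens after token 2
      got <- FALSE
      for (j in cand) {
        if (j >= 3 && j + 2 <= length(toks) &&
            !is.na(numtok[j]) && !is.na(numtok[j + 1]) &&
            !is.na(numtok[j + 2]) &&
            grepl("\\.", toks[j])) {
          xs[k] <- numtok[j]; ys[k] <- numtok[j + 1]; zs[k] <- numtok[j + 2]
          got <- TRUE
          break
        }
      }
      if (!got) {
        stop(sprintf("parse_pdb: malformed coordinate fields at line %d: %s",
                     i, ln))
      }
    }
    occ[k] <- num_or_na(substr_or(ln, 55, 60))
    bfac[k] <- num_or_na(substr_or(ln, 61, 66))
    elem[k] <- canonical_element(substr_or(ln, 77, 78))
    if (is.na(serial[k])) serial[k] <- k
    if (is.na(resq[k])) resq[k] <- 0L
  }
  occ[is.na(occ)] <- 1.00
  bfac[is.na(bfac)] <- 0.00

  if (anyDuplicated(serial)) {
    warning("parse_pdb: duplicate atom serial numbers; keeping all atoms ",
            "(CONECT records resolve to the first occurrence)")
  }

  bonds <- empty_bonds()
  if (length(conect_idx) > 0) {
    pairs_a <- integer(0); pairs_b <- integer(0)
    for (i in conect_idx) {
      ln <- lines[i]
      # CONECT serials live in fixed 5-column fields; fall back to tokens
      toks <- int_or_na(strsplit(trimws(substr_or(ln, 7, 31)), "\\s+")[[1]])
      toks <- toks[!is.na(toks)]
      if (length(toks) >= 2) {
        pairs_a <- c(pairs_a, rep(toks[1], length(toks) - 1))
        pairs_b <- c(pairs_b, toks[-1])
      }
    }
    keep <- pairs_a %in% serial & pairs_b %in% serial
    bonds <- data.frame(a = pairs_a[keep], b = pairs_b[keep], order = 1)
  }

  atoms <- data.frame(
    record = rec, serial = serial, atom_name = trimws(name_raw),
    name_raw = name_raw, alt_loc = alt, res_name = resn, chain_id = chain,
    res_seq = resq, i_code = icode, x = xs, y = ys, z = zs,
    occupancy = occ, b_factor = bfac, element = elem,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, bonds, pdb_title(lines))
}

pdb_title <- function(lines) {
  ti <- grep("^TITLE", lines, value = TRUE)
  if (length(ti) == 0) return("")
  trimws(paste(trimws(substring(ti, 11)), collapse = " "))
}

#' PDB atom-name justification
#'
#' Produces the 4-character atom-name field.  One-letter elements start
#' in column 14 (i.e. a leading blank) unless the name is 4 characters
#' long; two-letter elements start in column 13.
#'
#' @param name trimmed atom name
#' @param element element symbol ("" allowed)
#' @keywords internal
pdb_justify_name <- function(name, element = "") {
  vapply(seq_along(name), function(i) {
    nm <- trimws(name[i])
    el <- if (length(element) >= i) element[i] else ""
    if (nchar(nm) >= 4) return(substr(nm, 1, 4))
    if (nchar(el) == 2 || grepl("^[0-9]", nm)) {
      formatC(nm, width = -4)
    } else {
      formatC(paste0(" ", nm), width = -4)
    }
  }, character(1))
}

#' Write a structure as PDB text
#'
#' Strict fixed-column output.  Serial numbers above 99999 trigger a
#' renumbering with a warning.  CONECT records are emitted for every
#' bond (both directions, as is conventional).
#'
#' @param s structure3d
#' @param path optional output file; when NULL only the text is returned.
#' @return the PDB text, invisibly when `path` is given.
#' @export
write_pdb <- function(s, path = NULL) {
  atoms <- s$atoms
  bonds <- s$bonds
  lines <- character(0)
  if (nzchar(s$title)) lines <- c(lines, sprintf("TITLE     %s", s$title))
  if (nrow(atoms) > 0) {
    if (any(atoms$serial > 99999L) || anyDuplicated(atoms$serial)) {
      if (any(atoms$serial > 99999L)) {
        warning("write_pdb: serial > 99999; renumbering atoms")
      }
      old <- atoms$serial
      atoms$serial <- seq_len(nrow(atoms))
      if (nrow(bonds) > 0) {
        map <- stats::setNames(atoms$serial, as.character(old))
        bonds$a <- as.integer(map[as.character(bonds$a)])
        bonds$b <- as.integer(map[as.character(bonds$b)])
        bonds <- bonds[!is.na(bonds$a) & !is.na(bonds$b), , drop = FALSE]
      }
    }
    raw <- ifelse(is.na(atoms$name_raw) | !nzchar(atoms$name_raw),
                  pdb_justify_name(atoms$atom_name, atoms$element),
                  atoms$name_raw)
    atom_lines <- sprintf(
      "%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      atoms$record, atoms$serial, raw, atoms$alt_loc,
      substr(paste0(atoms$res_name, "    "), 1, 4),
      atoms$chain_id, atoms$res_seq, atoms$i_code,
      atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
      toupper(atoms$element)
    )
    lines <- c(lines, atom_lines)
  }
  if (nrow(bonds) > 0) {
    cl <- c(sprintf("CONECT%5d%5d", bonds$a, bonds$b),
            sprintf("CONECT%5d%5d", bonds$b, bonds$a))
    lines <- c(lines, sort(cl))
  }
  lines <- c(lines, "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Guess missing element symbols from atom names
#'
#' Atoms whose element field is already populated are never modified.
#' For the rest, the element is inferred from the 4-character atom-name
#' field: digits and primes are stripped, then a greedy two-letter match
#' against the periodic table is attempted when the raw name starts in
#' column 13 (PDB two-letter justification); otherwise the one-letter
#' symbol is used.  Unresolvable names leave the element empty with a
#' warning.
#'
#' @param s structure3d
#' @return structure3d with elements filled in where possible.
#' @export
guess_elements <- function(s) {
  atoms <- s$atoms
  if (nrow(atoms) == 0) return(s)
  unresolved <- character(0)
  for (i in seq_len(nrow(atoms))) {
    if (nzchar(atoms$element[i])) next
    raw <- atoms$name_raw[i]
    if (is.na(raw) || !nzchar(trimws(raw))) raw <- atoms$atom_name[i]
    stripped <- gsub("[0-9' ]", "", raw)
    if (!nzchar(stripped)) {
      unresolved <- c(unresolved, atoms$atom_name[i])
      next
    }
    el <- ""
    two_letter_pos <- nzchar(trimws(substr(raw, 1, 1))) &&
      !grepl("^[0-9]", raw)
    if (two_letter_pos && nchar(stripped) >= 2) {
      cand <- canonical_element(substr(stripped, 1, 2))
      if (nzchar(cand)) el <- cand
    }
    if (!nzchar(el)) {
      cand <- canonical_element(substr(stripped, 1, 1))
      if (nzchar(cand)) el <- cand
    }
    if (!nzchar(el) && nchar(stripped) >= 2) {
      cand <- canonical_element(substr(stripped, 1, 2))
      if (nzchar(cand)) el <- cand
    }
    if (nzchar(el)) {
      atoms$element[i] <- el
    } else {
      unresolved <- c(unresolved, atoms$atom_name[i])
    }
  }
  if (length(unresolved) > 0) {
    warning("guess_elements: could not resolve element for atom name(s): ",
            paste(unique(unresolved), collapse = ", "))
  }
  s$atoms <- atoms
  s
}

#' Filter alternate locations
#'
#' Keeps exactly the atoms whose altLoc is blank or equals `keep_altloc`,
#' preserving order.  An atom position present only under a dropped
#' altLoc letter disappears entirely; this is flagged with a warning.
#'
#' @param s structure3d
#' @param keep_altloc single character (default "A").
#' @return filtered structure3d.
#' @export
filter_altloc <- function(s, keep_altloc = "A") {
  atoms <- s$atoms
  if (nrow(atoms) == 0) return(s)
  keep <- atoms$alt_loc %in% c(" ", "", keep_altloc)
  dropped <- atoms[!keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    kept_keys <- paste(residue_ids(atoms[keep, , drop = FALSE]),
                       atoms$atom_name[keep])
    lost <- !(paste(residue_ids(dropped), dropped$atom_name) %in% kept_keys)
    if (any(lost)) {
      warning("filter_altloc: atom(s) present only under a dropped altLoc ",
              "were removed: ",
              paste(unique(dropped$atom_name[lost]), collapse = ", "))
    }
  }
  subset_structure(s, which(keep))
}
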