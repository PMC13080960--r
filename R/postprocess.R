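# Conformer-ensemble postprocessing: MODEL splitting, template metadata
# transfer, XYZ-frame mapping and multi-model PDB output.

#' Split a multi-model PDB into conformer records
#'
#' Splits on MODEL/ENDMDL statements (the legacy spelling ENDMODEL is
#' accepted too) and returns the per-model line blocks in file order.
#' A file without MODEL records is treated as a single conformer.
#' Unbalanced MODEL/ENDMDL pairs raise an error naming the line.
#'
#' @param multi_pdb_text text (string or lines).
#' @return list of character vectors (lines inside each model).
#' @export
split_models <- function(multi_pdb_text) {
  lines <- if (length(multi_pdb_text) == 1 &&
               grepl("\n", multi_pdb_text, fixed = TRUE)) {
    strsplit(multi_pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(multi_pdb_text)
  }
  starts <- grep("^MODEL", lines)
  ends <- grep("^(ENDMDL|ENDMODEL)", lines)
  if (length(starts) == 0 && length(ends) == 0) {
    return(list(lines))
  }
  if (length(starts) != length(ends)) {
    bad <- if (length(starts) > length(ends)) {
      starts[length(ends) + 1L]
    } else {
      ends[length(starts) + 1L]
    }
    stop("split_models: unbalanced MODEL/ENDMDL at line ", bad)
  }
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    if (ends[k] <= starts[k]) {
      stop("split_models: ENDMDL before MODEL at line ", ends[k])
    }
    block <- lines[seq(starts[k] + 1L, ends[k] - 1L)]
    out[[k]] <- block
  }
  out
}

#' Extract atom metadata from a template PDB
#'
#' Returns, per atom and in file order, the fields later transcribed
#' onto each conformer: atom name, residue name, residue number, chain,
#' insertion code, element and record type.
#'
#' @param template template PDB text, path, or structure3d.
#' @return data.frame of metadata records.
#' @export
extract_template_metadata <- function(template) {
  s <- if (inherits(template, "structure3d")) {
    template
  } else if (length(template) == 1 && !grepl("\n", template) &&
             file.exists(template)) {
    parse_pdb(paste(readLines(template), collapse = "\n"))
  } else {
    parse_pdb(template)
  }
  a <- s$atoms
  data.frame(
    record = a$record, atom_name = a$atom_name, name_raw = a$name_raw,
    res_name = a$res_name, chain_id = a$chain_id, res_seq = a$res_seq,
    i_code = a$i_code, element = a$element, stringsAsFactors = FALSE
  )
}

#' Overwrite a conformer's metadata from the template
#'
#' Positionally replaces atom name, residue name, residue number (and
#' chain, needed for valid PDB output) while leaving every coordinate
#' untouched.  A length mismatch errors: atom-order corruption must not
#' be papered over.
#'
#' @param conformer structure3d.
#' @param metadata data.frame from [extract_template_metadata()].
#' @return annotated structure3d.
#' @export
apply_metadata <- function(conformer, metadata) {
  if (n_atoms(conformer) != nrow(metadata)) {
    stop(sprintf(
      "apply_metadata: conformer has %d atoms but template metadata has %d",
      n_atoms(conformer), nrow(metadata)))
  }
  a <- conformer$atoms
  a$record <- metadata$record
  a$atom_name <- metadata$atom_name
  a$name_raw <- metadata$name_raw
  a$res_name <- metadata$res_name
  a$chain_id <- metadata$chain_id
  a$res_seq <- metadata$res_seq
  a$i_code <- metadata$i_code
  a$element <- metadata$element
  conformer$atoms <- a
  conformer
}

#' Read a multi-frame XYZ into a conformer ensemble
#'
#' Maps each frame positionally onto the template metadata (this
#' replaces the usual external XYZ-to-PDB conversion step).  Per-frame
#' element symbols are cross-checked against the template: a mismatch at
#' any position errors, guarding against reordered output.  Comment
#' lines (CREST stores energies there) are preserved as frame titles.
#'
#' @param xyz_text multi-frame XYZ text (string or lines).
#' @param metadata data.frame from [extract_template_metadata()].
#' @return object of class `conformer_ensemble`: `frames` (list of n x 3
#'   matrices), `titles`, `template` (the metadata).
#' @export
xyz_to_conformers <- function(xyz_text, metadata) {
  lines <- if (length(xyz_text) == 1 && grepl("\n", xyz_text, fixed = TRUE)) {
    strsplit(xyz_text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(xyz_text)
  }
  n_tpl <- nrow(metadata)
  frames <- list(); titles <- character(0)
  i <- 1L; frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame_no <- frame_no + 1L
    nat <- int_or_na(trimws(lines[i]))
    if (is.na(nat)) {
      stop("xyz_to_conformers: malformed frame header at frame ", frame_no)
    }
    if (nat != n_tpl) {
      stop(sprintf(
        "xyz_to_conformers: frame %d has %d atoms but the template has %d",
        frame_no, nat, n_tpl))
    }
    if (i + 1L + nat > length(lines)) {
      stop("xyz_to_conformers: truncated frame ", frame_no)
    }
    title <- trimws(lines[i + 1L])
    xyz <- matrix(NA_real_, nrow = nat, ncol = 3)
    for (k in seq_len(nat)) {
      toks <- strsplit(trimws(lines[i + 1L + k]), "\\s+")[[1]]
      if (length(toks) < 4) {
        stop(sprintf("xyz_to_conformers: malformed atom line %d of frame %d",
                     k, frame_no))
      }
      el <- canonical_element(toks[1])
      tpl_el <- metadata$element[k]
      if (nzchar(tpl_el) && nzchar(el) && el != tpl_el) {
        stop(sprintf(
          "xyz_to_conformers: element mismatch at position %d of frame %d: '%s' vs template '%s'",
          k, frame_no, el, tpl_el))
      }
      xyz[k, ] <- num_or_na(toks[2:4])
      if (anyNA(xyz[k, ])) {
        stop(sprintf("xyz_to_conformers: bad coordinates at position %d of frame %d",
                     k, frame_no))
      }
    }
    frames[[frame_no]] <- xyz
    titles <- c(titles, title)
    i <- i + 2L + nat
  }
  structure(list(frames = frames, titles = titles, template = metadata),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer_ensemble: %d frame(s) of %d atoms\n",
              length(x$frames), nrow(x$template)))
  invisible(x)
}

ensemble_frame_structure <- function(ensemble, k) {
  m <- ensemble$template
  xyz <- ensemble$frames[[k]]
  atoms <- data.frame(
    record = m$record, serial = seq_len(nrow(m)), atom_name = m$atom_name,
    name_raw = m$name_raw, alt_loc = " ", res_name = m$res_name,
    chain_id = m$chain_id, res_seq = m$res_seq, i_code = m$i_code,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, element = m$element,
    stringsAsFactors = FALSE
  )
  structure3d(atoms, title = ensemble$titles[k])
}

#' Write an annotated conformer ensemble as multi-model PDB
#'
#' One MODEL/ENDMDL block per frame, in frame order; the frame title
#' (CREST's energy comment) is preserved as a REMARK inside each model.
#' An empty ensemble errors: no conformers is a pipeline failure.
#'
#' @param ensemble [xyz_to_conformers()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_updated_ensemble <- function(ensemble, path) {
  if (length(ensemble$frames) == 0) {
    stop("write_updated_ensemble: empty ensemble")
  }
  out <- character(0)
  for (k in seq_along(ensemble$frames)) {
    s <- ensemble_frame_structure(ensemble, k)
    body <- strsplit(write_pdb(s), "\n", fixed = TRUE)[[1]]
    body <- body[body != "END"]
    block <- c(sprintf("MODEL     %4d", k),
               if (nzchar(ensemble$titles[k]))
                 sprintf("REMARK   1 %s", ensemble$titles[k]),
               body,
               "ENDMDL")
    out <- c(out, block)
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Delete temporary files after a run
#'
#' Removes known intermediates from `outdir` unless listed in `keep`.
#' The principal outputs (crest_conformers_updated.pdb,
#' crest_conformers.pdb, crest_conformers.xyz, crest.out) and user
#' inputs are never touched.  Missing files are skipped silently.
#'
#' @param outdir directory to clean.
#' @param keep file names to preserve even if they are intermediates.
#' @return character vector of removed file names.
#' @export
cleanup_temp_files <- function(outdir, keep = character(0)) {
  protected <- c("crest_conformers_updated.pdb", "crest_conformers.pdb",
                 "crest_conformers.xyz", "crest.out", keep)
  intermediates <- c("pre_prepared.pdb", "prepared.pdb",
                     "pocket_dehydrogenated.pdb", "pocket_connected.pdb",
                     "pocket_protonated.pdb", ".xcontrol.sample",
                     "coord", "coord.ref", "wbo", "charges",
                     "cregen.out.tmp", "crest.energies", "crest_best.xyz",
                     "crest.restart", "cre_members", "struc.xyz",
                     "gfnff_topo", "gfnff_charges")
  removed <- character(0)
  for (f in setdiff(intermediates, protected)) {
    p <- file.path(outdir, f)
    if (file.exists(p)) {
      unlink(p)
      removed <- c(removed, f)
    }
  }
  removed
}
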