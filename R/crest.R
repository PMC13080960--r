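# CREST interface: constrained-atom index derivation, range compression,
# xcontrol constraint files, command assembly and (optionally mocked)
# execution.

#' Indices of constrained (non-ligand) atoms
#'
#' 1-based positions, in merged-structure atom order, of every atom whose
#' residue name differs from the ligand name.  The merged PDB's atom
#' order is the single source of truth for what an index means.
#'
#' @param merged merged structure3d (pocket first, ligand after).
#' @param ligand_name ligand residue name used at merge time.
#' @return sorted integer vector.
#' @export
constrained_atom_indices <- function(merged, ligand_name) {
  lig_res <- toupper(substr(ligand_name, 1, 4))
  is_lig <- toupper(merged$atoms$res_name) == lig_res
  if (!any(is_lig)) {
    stop("constrained_atom_indices: ligand residue '", lig_res,
         "' absent from the merged structure; constraining every atom ",
         "would freeze the ligand")
  }
  which(!is_lig)
}

#' Compress sorted indices to CREST range syntax
#'
#' Maximal runs of consecutive integers are rendered "a-b" (singletons as
#' "a") and comma-joined, e.g. `1,2,3,4,5,6,8,9,10` becomes
#' `"1-6,8-10"`.  Expanding the output recovers the input exactly.
#'
#' @param indices strictly increasing positive integers.
#' @return single string.
#' @export
#' @examples
#' compress_ranges(c(1:6, 8:10))
compress_ranges <- function(indices) {
  if (length(indices) == 0) return("")
  indices <- as.integer(indices)
  if (any(indices <= 0) || any(diff(indices) <= 0)) {
    stop("compress_ranges: indices must be strictly increasing positive ",
         "integers")
  }
  run_id <- cumsum(c(1L, diff(indices) != 1L))
  parts <- vapply(split(indices, run_id), function(r) {
    if (length(r) == 1) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, character(1))
  paste(parts, collapse = ",")
}

#' Expand CREST range syntax back to indices
#'
#' Inverse of [compress_ranges()].
#'
#' @param text range text like "1-6,8-10".
#' @return sorted integer vector.
#' @export
expand_ranges <- function(text) {
  if (!nzchar(trimws(text))) return(integer(0))
  parts <- strsplit(trimws(text), ",", fixed = TRUE)[[1]]
  out <- unlist(lapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq.int(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
  as.integer(out)
}

#' Constraint specification
#'
#' @param constrained_indices sorted 1-based indices of atoms to hold.
#' @param n_total total atom count of the merged structure (the
#'   complement is the metadynamics-active atom list).
#' @param reference_pdb reference structure path recorded in the file.
#' @param force_constant harmonic force constant as emitted by CREST's
#'   own `--constrain` sample file.
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(constrained_indices, n_total,
                            reference_pdb = "final_complex.pdb",
                            force_constant = 0.5) {
  constrained_indices <- as.integer(constrained_indices)
  n_total <- as.integer(n_total)
  stopifnot(n_total >= 1, all(constrained_indices >= 1),
            all(constrained_indices <= n_total))
  structure(
    list(constrained_indices = constrained_indices,
         range_text = compress_ranges(constrained_indices),
         free_indices = setdiff(seq_len(n_total), constrained_indices),
         n_total = n_total,
         reference_pdb = reference_pdb,
         force_constant = force_constant),
    class = "constraint_spec"
  )
}

#' Write a CREST constraint file
#'
#' Emits `constraints.inp` in xcontrol syntax, mirroring what CREST's
#' own `--constrain` run writes into `.xcontrol.sample` (an `$constrain`
#' block with the atom ranges, force constant and reference structure,
#' and a `$metadyn` block listing the free atoms).  An empty constrained
#' set is a misuse and errors.
#'
#' @param spec [constraint_spec()].
#' @param outdir output directory.
#' @return path to the written `constraints.inp`.
#' @export
write_constraints <- function(spec, outdir = ".") {
  if (length(spec$constrained_indices) == 0) {
    stop("write_constraints: empty constrained atom set")
  }
  lines <- c(
    "$constrain",
    sprintf("  atoms: %s", spec$range_text),
    sprintf("  force constant=%s", format(spec$force_constant)),
    sprintf("  reference=%s", spec$reference_pdb),
    "$metadyn",
    sprintf("  atoms: %s", compress_ranges(spec$free_indices)),
    "$end"
  )
  path <- file.path(outdir, "constraints.inp")
  writeLines(lines, path)
  path
}

#' Parse a constraint file back into atom indices
#'
#' Reads the `atoms:` line of the `$constrain` block; used for
#' round-trip validation.
#'
#' @param path path to a constraints file in xcontrol syntax.
#' @return sorted integer vector of constrained indices.
#' @export
parse_constraints <- function(path) {
  lines <- readLines(path)
  i0 <- grep("^\\$constrain", lines)
  if (length(i0) == 0) stop("parse_constraints: no $constrain block")
  atoms_line <- NULL
  for (i in seq(i0[1] + 1L, length(lines))) {
    if (grepl("^\\$", lines[i])) break
    if (grepl("^\\s*atoms:", lines[i])) {
      atoms_line <- sub("^\\s*atoms:\\s*", "", lines[i])
      break
    }
  }
  if (is.null(atoms_line)) stop("parse_constraints: no atoms: line")
  expand_ranges(atoms_line)
}

#' Assemble the CREST command line
#'
#' Pure function: input structure, constraint file, level of theory,
#' temperature and whitespace-tokenized extra arguments (never shell
#' interpreted).  User-supplied config values override the defaults
#' ("gfnff", "310", "-squick").
#'
#' @param final_pdb path to the merged input structure.
#' @param spec [constraint_spec()] (its file is assumed written as
#'   `constraints.inp`).
#' @param cfg [pipeline_config()].
#' @param constraints_path path of the constraint file.
#' @param charge optional total formal charge, passed as `--chrg`.
#' @return character vector of command tokens (element 1 = executable).
#' @export
build_crest_command <- function(final_pdb, spec, cfg = pipeline_config(),
                                constraints_path = "constraints.inp",
                                charge = NULL) {
  extra <- strsplit(trimws(cfg$crest_extra), "\\s+")[[1]]
  extra <- extra[nzchar(extra)]
  cmd <- c("crest", final_pdb,
           "--cinp", constraints_path,
           paste0("--", cfg$crest_level),
           "--temp", cfg$crest_temp)
  if (!is.null(charge)) cmd <- c(cmd, "--chrg", as.character(charge))
  c(cmd, extra)
}

#' Default subprocess runner for CREST
#'
#' Executes the command in `outdir`, capturing standard output.  Errors
#' actionably when the `crest` binary is missing.
#'
#' @param command character vector of tokens.
#' @param outdir working directory for the run.
#' @return list: `status` (exit code), `stdout` (character lines).
#' @export
crest_runner_system <- function(command, outdir) {
  exe <- Sys.which(command[1])
  if (!nzchar(exe)) {
    stop("CREST binary '", command[1], "' not found on PATH; install CREST ",
         "or rerun with --no-crest to stop after constraint generation")
  }
  old <- setwd(outdir)
  on.exit(setwd(old), add = TRUE)
  out <- suppressWarnings(system2(exe, command[-1], stdout = TRUE,
                                  stderr = TRUE))
  status <- attr(out, "status")
  if (is.null(status)) status <- 0L
  list(status = status, stdout = as.character(out))
}

#' Mock CREST runner for tests
#'
#' Returns a runner closure that writes the supplied multi-frame XYZ text
#' as `crest_conformers.xyz` and reports the given exit status with a
#' canned log.  Used so that the whole pipeline is exercisable with no
#' external binary.
#'
#' @param xyz_text multi-frame XYZ content the "run" should produce.
#' @param status exit status to report.
#' @param log log lines to emit as captured stdout.
#' @return function(command, outdir) suitable for [run_crest()].
#' @export
crest_runner_mock <- function(xyz_text, status = 0L,
                              log = c("mock CREST run",
                                      " CREST terminated normally.")) {
  force(xyz_text); force(status); force(log)
  function(command, outdir) {
    if (status == 0L) {
      writeLines(xyz_text, file.path(outdir, "crest_conformers.xyz"))
    }
    list(status = status, stdout = log)
  }
}

#' Run CREST
#'
#' Invokes the runner, captures its full standard output to `crest.out`,
#' and returns the conformer-file path.  A nonzero exit raises an error
#' carrying the tail of the log.
#'
#' @param command character vector from [build_crest_command()].
#' @param outdir working/output directory.
#' @param runner runner function (default: real subprocess).
#' @return list: `conformers` (path to crest_conformers.xyz), `log`
#'   (path to crest.out).
#' @export
run_crest <- function(command, outdir = ".",
                      runner = crest_runner_system) {
  res <- runner(command, outdir)
  log_path <- file.path(outdir, "crest.out")
  writeLines(res$stdout, log_path)
  if (res$status != 0) {
    tail_log <- paste(utils::tail(res$stdout, 10), collapse = "\n")
    stop("CREST exited with status ", res$status, "; log tail:\n", tail_log)
  }
  conf <- file.path(outdir, "crest_conformers.xyz")
  if (!file.exists(conf)) {
    stop("CREST finished but produced no crest_conformers.xyz in ", outdir)
  }
  list(conformers = conf, log = log_path)
}
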