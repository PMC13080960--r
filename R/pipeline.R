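# End-to-end orchestration: argument parsing, the seven pipeline stages,
# run manifest and exit codes.

PIPELINE_USAGE <- paste(
  "usage: crestpocket <protein_file.pdb> <ligand_file.mol2> <outdir>",
  "                   [--no-crest] [--temp T] [--lvl-of-theory L]",
  "                   [--extra-crest-arguments S] [--keep-altloc C] [-h]",
  "",
  "Prepares a constrained CREST conformer-search input from a protein",
  "PDB and a posed ligand MOL2, then re-annotates the CREST output.",
  "",
  "positional arguments:",
  "  protein_file.pdb          protein structure",
  "  ligand_file.mol2          ligand with 3D coordinates in the pocket",
  "  outdir                    name of the output subdirectory (created)",
  "",
  "options:",
  "  --no-crest                stop after writing constraints.inp",
  "  --temp T                  CREST temperature (default 310)",
  "  --lvl-of-theory L         CREST level of theory (default gfnff)",
  "  --extra-crest-arguments S extra CREST arguments (default -squick)",
  "  --keep-altloc C           altLoc letter to retain (default A)",
  "  -h, --help                show this help",
  sep = "\n")

#' Parse command-line arguments
#'
#' Three mandatory positional arguments (protein file, ligand file,
#' output directory) plus the optional CREST overrides.  Missing
#' mandatory arguments raise a usage error.
#'
#' @param argv character vector of arguments.
#' @return run-manifest skeleton: `protein_file`, `ligand_file`,
#'   `outdir`, `no_crest`, `config`, `help`.
#' @export
parse_run_args <- function(argv) {
  if (any(argv %in% c("-h", "--help"))) {
    return(list(help = TRUE, usage = PIPELINE_USAGE))
  }
  positional <- character(0)
  no_crest <- FALSE
  opts <- list(temp = NULL, lvl = NULL, extra = NULL, keep_altloc = NULL)
  i <- 1L
  take_value <- function(flag, i) {
    if (i + 1L > length(argv)) {
      stop("usage error: ", flag, " requires a value\n", PIPELINE_USAGE,
           call. = FALSE)
    }
    argv[i + 1L]
  }
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--no-crest") {
      no_crest <- TRUE
    } else if (a == "--temp") {
      opts$temp <- take_value(a, i); i <- i + 1L
    } else if (a == "--lvl-of-theory") {
      opts$lvl <- take_value(a, i); i <- i + 1L
    } else if (a == "--extra-crest-arguments") {
      opts$extra <- take_value(a, i); i <- i + 1L
    } else if (a == "--keep-altloc") {
      opts$keep_altloc <- take_value(a, i); i <- i + 1L
    } else if (grepl("^-", a)) {
      stop("usage error: unknown option ", a, "\n", PIPELINE_USAGE,
           call. = FALSE)
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1L
  }
  if (length(positional) != 3) {
    stop("usage error: expected 3 mandatory arguments ",
         "(protein_file, ligand_file, outdir), got ", length(positional),
         "\n", PIPELINE_USAGE, call. = FALSE)
  }
  cfg_args <- list()
  if (!is.null(opts$temp)) cfg_args$crest_temp <- opts$temp
  if (!is.null(opts$lvl)) cfg_args$crest_level <- opts$lvl
  if (!is.null(opts$extra)) cfg_args$crest_extra <- opts$extra
  if (!is.null(opts$keep_altloc)) cfg_args$keep_altloc <- opts$keep_altloc
  list(
    help = FALSE,
    protein_file = positional[1],
    ligand_file = positional[2],
    outdir = positional[3],
    no_crest = no_crest,
    config = do.call(pipeline_config, cfg_args)
  )
}

pipeline_stage_error <- function(stage_no, stage_name, message) {
  structure(
    class = c("pipeline_stage_error", "error", "condition"),
    list(message = sprintf("stage %d (%s): %s", stage_no, stage_name,
                           message),
         call = NULL, stage = stage_no, stage_name = stage_name)
  )
}

#' Run the full preparation pipeline
#'
#' Executes the seven stages: (1) setup/parsing, (2) preprocessing
#' (element fixing, altLoc filtering, ligand-name extraction),
#' (3) pocket extraction, (4) hydrogenation (dehydrogenate, perceive
#' connectivity, drop disconnected residues, protonate at pH 7.4),
#' (5) merging and formal-charge computation, (6) CREST constraint
#' generation and (optionally) the CREST run itself, (7) conformer
#' postprocessing and temp-file cleanup.  All work happens inside
#' `outdir`, created as a subdirectory of `base_dir`.
#'
#' @param protein_file path to the protein PDB.
#' @param ligand_file path to the ligand MOL2.
#' @param outdir output subdirectory name.
#' @param no_crest when TRUE, stop after writing constraints.inp.
#' @param config [pipeline_config()].
#' @param runner CREST runner (see [run_crest()]); defaults to the real
#'   subprocess runner, tests inject [crest_runner_mock()].
#' @param base_dir directory under which `outdir` is created.
#' @param protonation_backend backend for [protonate()].
#' @return completed run manifest (list), invisibly: produced files,
#'   warnings, pocket provenance, formal charge.
#' @export
run_pipeline <- function(protein_file, ligand_file, outdir,
                         no_crest = FALSE, config = pipeline_config(),
                         runner = crest_runner_system,
                         base_dir = getwd(),
                         protonation_backend = protonation_backend_builtin) {
  manifest <- list(
    protein_file = protein_file, ligand_file = ligand_file,
    outdir = outdir, no_crest = no_crest, config = unclass(config),
    produced_files = list(), warnings = character(0)
  )
  log_info <- function(fmt, ...) message(sprintf(paste0("[crestpocket] ", fmt), ...))
  note_warning <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  run_stage <- function(no, name, expr) {
    tryCatch(
      withCallingHandlers(expr, warning = note_warning),
      error = function(e) {
        if (inherits(e, "pipeline_stage_error")) stop(e)
        stop(pipeline_stage_error(no, name, conditionMessage(e)))
      }
    )
  }
  add_file <- function(key, path) {
    manifest$produced_files[[key]] <<- basename(path)
  }

  # stage 1: setup
  run_stage(1, "setup", {
    if (!file.exists(protein_file)) stop("protein file not readable: ",
                                         protein_file)
    if (!file.exists(ligand_file)) stop("ligand file not readable: ",
                                        ligand_file)
  })
  workdir <- file.path(base_dir, outdir)
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

  # stage 2: preprocessing
  pre <- run_stage(2, "preprocessing", {
    protein <- parse_pdb(paste(readLines(protein_file), collapse = "\n"))
    protein <- guess_elements(protein)
    write_pdb(protein, file.path(workdir, "pre_prepared.pdb"))
    add_file("pre_prepared", "pre_prepared.pdb")
    protein <- filter_altloc(protein, config$keep_altloc)
    write_pdb(protein, file.path(workdir, "prepared.pdb"))
    add_file("prepared", "prepared.pdb")
    ligand <- parse_mol2(paste(readLines(ligand_file), collapse = "\n"))
    log_info("ligand '%s' with %d atoms", ligand$name,
             n_atoms(ligand$structure))
    list(protein = protein, ligand = ligand)
  })

  # stage 3: pocket extraction
  pocket_sel <- run_stage(3, "pocket extraction", {
    ps <- extract_pocket(pre$protein, pre$ligand, config, outdir = workdir)
    add_file("pocket", "test_pocket_extended.pdb")
    log_info("pocket: %d atoms, radius %.1f A after %d expansion(s)",
             n_atoms(ps$structure), ps$final_radius, ps$iterations_used)
    ps
  })

  # stage 4: hydrogenation
  pocket <- run_stage(4, "hydrogenation", {
    s <- strip_hydrogens(pocket_sel$structure)
    s <- perceive_bonds(s)
    n_before <- n_atoms(s)
    s <- filter_connected_residues(s)
    log_info("connectivity filter: %d -> %d atoms", n_before, n_atoms(s))
    if (n_atoms(s) == 0) stop("pocket empty after connectivity filter")
    write_pdb(s, file.path(workdir, "pocket_connected.pdb"))
    protonate(s, config$protonation_ph, backend = protonation_backend)
  })

  # stage 5: merging and charge
  merged <- run_stage(5, "merging and charge", {
    m <- merge_structures(pocket, pre$ligand)
    write_pdb(m, file.path(workdir, "final_complex.pdb"))
    add_file("final", "final_complex.pdb")
    chg <- compute_formal_charge(m)
    log_info("total formal charge %+d", chg$total)
    manifest$formal_charge <- chg$total  # expr runs in this frame
    m
  })
  lig_res <- attr(merged, "ligand_res_name")

  # stage 6: CREST
  conf_xyz <- run_stage(6, "CREST", {
    idx <- constrained_atom_indices(merged, lig_res)
    spec <- constraint_spec(idx, n_atoms(merged),
                            reference_pdb = "final_complex.pdb")
    cpath <- write_constraints(spec, workdir)
    add_file("constraints", "constraints.inp")
    if (no_crest) {
      log_info("--no-crest: stopping after %s", basename(cpath))
      NULL
    } else {
      cmd <- build_crest_command("final_complex.pdb", spec, config,
                                 constraints_path = "constraints.inp",
                                 charge = manifest$formal_charge)
      res <- run_crest(cmd, workdir, runner = runner)
      add_file("crest_log", "crest.out")
      add_file("conformers_xyz", "crest_conformers.xyz")
      res$conformers
    }
  })

  # stage 7: postprocessing and cleanup
  run_stage(7, "postprocessing", {
    if (!is.null(conf_xyz)) {
      meta <- extract_template_metadata(merged)
      ens <- xyz_to_conformers(
        paste(readLines(conf_xyz), collapse = "\n"), meta)
      # un-annotated conversion: generic names, as a plain format dump
      generic <- meta
      generic$atom_name <- ifelse(nzchar(generic$element),
                                  generic$element, "X")
      generic$name_raw <- NA_character_
      generic$res_name <- "UNL"
      generic$res_seq <- 1L
      generic$chain_id <- " "
      generic$record <- "HETATM"
      ens_generic <- ens
      ens_generic$template <- generic
      write_updated_ensemble(ens_generic,
                             file.path(workdir, "crest_conformers.pdb"))
      add_file("conformers_pdb", "crest_conformers.pdb")
      write_updated_ensemble(ens,
                             file.path(workdir,
                                       "crest_conformers_updated.pdb"))
      add_file("conformers_updated", "crest_conformers_updated.pdb")
      log_info("wrote %d annotated conformer(s)", length(ens$frames))
    }
    removed <- cleanup_temp_files(workdir,
                                  keep = c("test_pocket_extended.pdb",
                                           "final_complex.pdb",
                                           "constraints.inp",
                                           "pocket_connected.pdb"))
    if (length(removed) > 0) {
      log_info("removed temp file(s): %s", paste(removed, collapse = ", "))
    }
  })

  manifest$pocket <- list(
    final_radius = pocket_sel$final_radius,
    iterations_used = pocket_sel$iterations_used,
    starved = pocket_sel$starved,
    n_atoms = n_atoms(pocket_sel$structure)
  )
  disk_manifest <- manifest[c("protein_file", "ligand_file", "outdir",
                              "no_crest", "produced_files", "warnings",
                              "pocket", "formal_charge")]
  # basenames on disk so repeat runs from different locations are
  # byte-identical
  disk_manifest$protein_file <- basename(disk_manifest$protein_file)
  disk_manifest$ligand_file <- basename(disk_manifest$ligand_file)
  jsonlite::write_json(
    disk_manifest,
    file.path(workdir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$produced_files[["manifest"]] <- "run_manifest.json"
  invisible(manifest)
}

#' Command-line entry point
#'
#' Parses `argv`, runs the pipeline, and returns a status code: 0 on
#' success, 64 on usage errors, and 10 + stage number when a stage
#' fails.  The launcher script in `inst/cli/` passes this to `quit()`.
#'
#' @param argv command-line arguments (default: the process arguments).
#' @param runner CREST runner override (tests).
#' @return integer exit status, invisibly.
#' @export
pipeline_main <- function(argv = commandArgs(trailingOnly = TRUE),
                          runner = crest_runner_system) {
  parsed <- tryCatch(parse_run_args(argv), error = function(e) e)
  if (inherits(parsed, "error")) {
    message(conditionMessage(parsed))
    return(invisible(64L))
  }
  if (isTRUE(parsed$help)) {
    cat(parsed$usage, "\n")
    return(invisible(0L))
  }
  res <- tryCatch(
    run_pipeline(parsed$protein_file, parsed$ligand_file, parsed$outdir,
                 no_crest = parsed$no_crest, config = parsed$config,
                 runner = runner),
    error = function(e) e
  )
  if (inherits(res, "pipeline_stage_error")) {
    message("crestpocket failed at ", res$message)
    return(invisible(10L + res$stage))
  }
  if (inherits(res, "error")) {
    message("crestpocket failed: ", conditionMessage(res))
    return(invisible(1L))
  }
  invisible(0L)
}
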