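#' Pipeline configuration
#'
#' Collects every numeric threshold and default of the pocket-preparation
#' workflow in one place.  The defaults encode the published behaviour of
#' the method: a ligand-size gate of 120 atoms, an initial 3.0 A selection
#' shell grown in 0.5 A steps until at least 70 atoms are found (at most
#' 50 expansion attempts), a 2.6 A cap extension, a 1.9 A isolated-atom
#' cutoff, altLoc "A" retention, protonation at pH 7.4, and CREST defaults
#' of temperature "310", level of theory "gfnff" and extra argument
#' "-squick".
#'
#' @param max_ligand_atoms maximum ligand atom count accepted by the
#'   size gate (larger ligands tend to produce pockets beyond the ~500
#'   atom practical limit of CREST).
#' @param initial_radius initial selection shell radius in Angstrom.
#' @param radius_step shell growth per expansion attempt, Angstrom.
#' @param min_pocket_atoms minimum raw shell size that stops expansion.
#' @param max_expansion_attempts maximum number of shell expansions.
#' @param cap_extension_radius radius (Angstrom) used to pull in cap-like
#'   atoms around the residue-completed pocket.
#' @param isolation_cutoff atoms with no other pocket atom within this
#'   distance (Angstrom) are discarded.
#' @param keep_altloc alternate-location indicator retained alongside
#'   blank ones.
#' @param protonation_ph pH handed to the protonation backend.
#' @param crest_temp CREST temperature argument (kept as text, as it is
#'   passed through to the command line).
#' @param crest_level CREST level of theory (e.g. "gfnff", "gfn2").
#' @param crest_extra extra CREST arguments, whitespace-tokenized.
#' @param water_res_names residue names treated as water.
#'
#' @return an object of class `pipeline_config` (a validated list).
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$min_pocket_atoms
pipeline_config <- function(max_ligand_atoms = 120L,
                            initial_radius = 3.0,
                            radius_step = 0.5,
                            min_pocket_atoms = 70L,
                            max_expansion_attempts = 50L,
                            cap_extension_radius = 2.6,
                            isolation_cutoff = 1.9,
                            keep_altloc = "A",
                            protonation_ph = 7.4,
                            crest_temp = "310",
                            crest_level = "gfnff",
                            crest_extra = "-squick",
                            water_res_names = c("HOH", "WAT", "TIP3", "SOL")) {
  stopifnot(
    is.numeric(initial_radius), initial_radius > 0,
    is.numeric(radius_step), radius_step > 0,
    is.numeric(cap_extension_radius), cap_extension_radius > 0,
    is.numeric(isolation_cutoff), isolation_cutoff > 0
  )
  max_ligand_atoms <- as.integer(max_ligand_atoms)
  min_pocket_atoms <- as.integer(min_pocket_atoms)
  max_expansion_attempts <- as.integer(max_expansion_attempts)
  stopifnot(
    max_ligand_atoms > 0L, min_pocket_atoms > 0L,
    max_expansion_attempts > 0L,
    is.character(keep_altloc), nchar(keep_altloc) == 1L
  )
  structure(
    list(
      max_ligand_atoms = max_ligand_atoms,
      initial_radius = initial_radius,
      radius_step = radius_step,
      min_pocket_atoms = min_pocket_atoms,
      max_expansion_attempts = max_expansion_attempts,
      cap_extension_radius = cap_extension_radius,
      isolation_cutoff = isolation_cutoff,
      keep_altloc = keep_altloc,
      protonation_ph = protonation_ph,
      crest_temp = as.character(crest_temp),
      crest_level = as.character(crest_level),
      crest_extra = as.character(crest_extra),
      water_res_names = toupper(water_res_names)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pocket preparation configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
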